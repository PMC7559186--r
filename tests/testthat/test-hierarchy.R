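test_that("judgment_matrix enforces squareness, positivity and reciprocity", {
  expect_error(judgment_matrix(matrix(1, 2, 3)), "square")
  expect_error(judgment_matrix(rbind(c(1, -2), c(-0.5, 1))), "positive")
  expect_error(judgment_matrix(rbind(c(1, 2), c(3, 1))), "reciprocal")
  expect_error(judgment_matrix(rbind(c(2, 2), c(0.5, 1))), "diagonal")
  expect_s3_class(judgment_matrix(rbind(c(1, 3), c(1 / 3, 1))), "judgment_matrix")
})

test_that("eigen_weights solves closed-form and identity cases", {
  w <- eigen_weights(rbind(c(1, 2), c(1 / 2, 1)))
  expect_equal(w$weights, c(2 / 3, 1 / 3), tolerance = 1e-9)
  expect_equal(w$lambda_max, 2, tolerance = 1e-8)
  expect_equal(w$CR, 0)

  for (n in c(3, 5, 7)) {
    u <- eigen_weights(matrix(1, n, n))
    expect_equal(u$weights, rep(1 / n, n), tolerance = 1e-9)
    expect_equal(u$CR, 0, tolerance = 1e-8)
  }
})

test_that("eigen_weights recovers the generator of a consistent matrix", {
  w <- c(0.6, 0.3, 0.1)
  ew <- eigen_weights(consistent_matrix(w))
  expect_equal(ew$weights, w, tolerance = 1e-9)
  expect_equal(ew$lambda_max, 3, tolerance = 1e-8)
  # scale invariance of the underlying value vector
  ew2 <- eigen_weights(consistent_matrix(w * 17))
  expect_equal(ew2$weights, ew$weights, tolerance = 1e-10)
})

test_that("eigen_weights matches the dense eigen oracle on random Saaty matrices", {
  set.seed(101)
  for (rep in 1:40) {
    n <- sample(3:5, 1)
    A <- random_saaty_matrix(n)
    got <- eigen_weights(A)
    want <- oracle_eigen_weights(A)
    expect_equal(got$weights, want$weights, tolerance = 1e-8)
    expect_equal(got$lambda_max, want$lambda_max, tolerance = 1e-8)
    expect_equal(sum(got$weights), 1, tolerance = 1e-9)
    # CR consistency with the oracle's lambda_max
    ri <- c(0, 0, 0.58, 0.90, 1.12)[n]
    expect_equal(got$CR, max((want$lambda_max - n) / ((n - 1) * ri), 0),
                 tolerance = 1e-7)
  }
})

test_that("consistency_ratio handles order-2 convention and table bounds", {
  expect_equal(consistency_ratio(2, 2), 0)
  expect_equal(consistency_ratio(3, 3), 0)
  expect_error(consistency_ratio(10.5, 10), "extend")
})

test_that("aggregate_experts: idempotence, passthrough and the hand-computed case", {
  v <- eigen_weights(consistent_matrix(c(0.5, 0.3, 0.2)))
  same <- aggregate_experts(list(v, v, v))
  expect_equal(same$weights, v$weights, tolerance = 1e-10)
  expect_equal(aggregate_experts(list(v))$weights, v$weights, tolerance = 1e-12)

  # two experts (0.5, 0.5) and (0.8, 0.2), lambda = 1/2 each:
  # unnormalized (sqrt(.4), sqrt(.1)) -> (2/3, 1/3)
  e1 <- eigen_weights(consistent_matrix(c(0.5, 0.5)))
  e2 <- eigen_weights(consistent_matrix(c(0.8, 0.2)))
  agg <- aggregate_experts(list(e1, e2))
  expect_equal(round(agg$weights, 4), c(0.6667, 0.3333))
  expect_equal(agg$weights, c(sqrt(0.4), sqrt(0.1)) / (sqrt(0.4) + sqrt(0.1)),
               tolerance = 1e-12)
})

test_that("excluded experts never change the aggregate", {
  set.seed(202)
  good <- lapply(1:4, function(i)
    eigen_weights(consistent_matrix(runif(4, 0.1, 1))))
  # manufacture an inconsistent expert (CR > 0.1)
  bad <- NULL
  repeat {
    cand <- eigen_weights(random_saaty_matrix(4))
    if (cand$CR > 0.1) { bad <- cand; break }
  }
  base <- aggregate_experts(good)
  with_bad <- aggregate_experts(c(good, list(bad)))
  expect_equal(with_bad$weights, base$weights, tolerance = 1e-12)
  expect_false(attr(with_bad, "included")[5])
  expect_error(aggregate_experts(list(bad)), "consistency")
})

test_that("compose_global_weights multiplies the layer chain", {
  h <- risk_hierarchy(data.frame(
    id = c("A", "P1", "P2", "c1", "c2", "c3", "c4"),
    parent = c(NA, "A", "A", "P1", "P1", "P2", "P2")))
  g <- compose_global_weights(h, list(A = c(0.7, 0.3),
                                      P1 = c(0.5, 0.5), P2 = c(0.5, 0.5)))
  expect_equal(g$weights, c(0.35, 0.35, 0.15, 0.15), tolerance = 1e-12)
  expect_equal(g$leaf_ids, c("c1", "c2", "c3", "c4"))
  expect_equal(sum(g$weights), 1, tolerance = 1e-9)

  # chain of single-child layers passes weight 1 through
  h1 <- risk_hierarchy(data.frame(id = c("A", "B", "C"),
                                  parent = c(NA, "A", "B")))
  g1 <- compose_global_weights(h1, list(A = 1, B = 1))
  expect_equal(g1$weights, 1)

  # dimension mismatch names the node
  expect_error(compose_global_weights(h, list(A = c(0.7, 0.3),
                                              P1 = c(1), P2 = c(0.5, 0.5))),
               "P1")
})

test_that("global weights sum to 1 for ragged trees with mid-depth leaves", {
  # u13 is a leaf directly under the root, beside two internal nodes
  h <- risk_hierarchy(data.frame(
    id = c("A", "B1", "B2", "u13", "x1", "x2", "x3"),
    parent = c(NA, "A", "A", "A", "B1", "B1", "B2")))
  g <- compose_global_weights(h, list(A = c(0.5, 0.3, 0.2),
                                      B1 = c(0.6, 0.4), B2 = 1))
  expect_equal(sum(g$weights), 1, tolerance = 1e-12)
  expect_equal(g$weights[g$leaf_ids == "u13"], 0.2, tolerance = 1e-12)
})

test_that("hierarchy validation rejects malformed trees", {
  expect_error(risk_hierarchy(data.frame(id = c("A", "B"),
                                         parent = c(NA, NA))), "exactly one root")
  expect_error(risk_hierarchy(data.frame(id = c("A", "A"),
                                         parent = c(NA, "A"))), "duplicate")
  expect_error(risk_hierarchy(data.frame(id = c("A", "B"),
                                         parent = c(NA, "Z"))), "unknown parent")
  h <- default_hierarchy()
  expect_equal(h$leaf_order, paste0("u", 1:12))
  expect_equal(h$root, "A")
})
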