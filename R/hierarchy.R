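#' Construct a risk-index hierarchy
#'
#' A rooted tree of named nodes: one target node, any number of intermediate
#' layers, and leaves that receive simulated risk inputs. Supplied as an edge
#' table `id -> parent` (root has `parent = NA`).
#'
#' @param edges data.frame with columns `id` and `parent` (character); exactly
#'   one row must have `parent = NA` (the root). Optional `label` column.
#' @return A `risk_hierarchy` object with components `edges`, `root`,
#'   `leaf_order` (leaves in the order given) and `children` (named list).
#' @examples
#' h <- default_hierarchy()
#' h$leaf_order
#' @export
risk_hierarchy <- function(edges) {
  stopifnot(is.data.frame(edges), all(c("id", "parent") %in% names(edges)))
  edges$id <- as.character(edges$id)
  edges$parent <- as.character(edges$parent)
  if (anyDuplicated(edges$id))
    stop("duplicate node ids: ", paste(edges$id[duplicated(edges$id)], collapse = ", "))
  root <- edges$id[is.na(edges$parent)]
  if (length(root) != 1L)
    stop("hierarchy must have exactly one root (parent = NA); found ", length(root))
  known <- edges$parent %in% edges$id | is.na(edges$parent)
  if (!all(known))
    stop("unknown parent id(s): ", paste(unique(edges$parent[!known]), collapse = ", "))
  children <- split(edges$id[!is.na(edges$parent)], edges$parent[!is.na(edges$parent)])
  # reachability from the root guarantees a single connected tree
  seen <- character(0); queue <- root
  while (length(queue)) {
    nd <- queue[1]; queue <- queue[-1]
    seen <- c(seen, nd)
    queue <- c(queue, children[[nd]])
  }
  if (length(seen) != nrow(edges))
    stop("nodes unreachable from root: ",
         paste(setdiff(edges$id, seen), collapse = ", "))
  leaves <- edges$id[!(edges$id %in% edges$parent)]
  structure(list(edges = edges, root = root, children = children,
                 leaf_order = leaves),
            class = "risk_hierarchy")
}

#' Default three-level risk-index hierarchy
#'
#' The shipped index system for a meat-processing enterprise: target layer A
#' (overall food quality safety risk); first-level indices B1 external
#' environmental risk, B2 internal environmental risk, B3 risk of consumer
#' concern; and twelve second-level leaf indicators u1..u12.
#'
#' @return A [risk_hierarchy()] with 16 nodes and 12 leaves.
#' @export
default_hierarchy <- function() {
  risk_hierarchy(data.frame(
    id = c("A", "B1", "B2", "B3", paste0("u", 1:12)),
    parent = c(NA, "A", "A", "A", rep("B1", 4), rep("B2", 4), rep("B3", 4)),
    label = c("Risk of food quality safety",
              "External environmental risk", "Internal environmental risk",
              "Risk of consumers concern",
              "Policy adjustment risk", "Economic environment risk",
              "Natural disasters and climate impacts",
              "Source hazards of raw materials",
              "Insufficiency of top management responsibility",
              "Personnel management risk", "Hazard control risk",
              "Product innovation risk",
              "Concerned about the harmful substances",
              "Concerned about counterfeiting",
              "Concerns about sensory quality",
              "Concerns about the environment"),
    stringsAsFactors = FALSE))
}

#' @export
print.risk_hierarchy <- function(x, ...) {
  cat("<risk_hierarchy>", nrow(x$edges), "nodes,", length(x$leaf_order),
      "leaves, root:", x$root, "\n")
  invisible(x)
}

saaty_values <- function() {
  c(1 / (9:2), 1, 2:9)
}

#' Expert pairwise-comparison (judgment) matrix
#'
#' Validates a square positive reciprocal matrix of Saaty-scale comparison
#' ratios for the children of one hierarchy node, as scored by one expert.
#'
#' @param m numeric matrix; must be square with unit diagonal and
#'   `m[j, i] == 1 / m[i, j]` within `tol`.
#' @param node,expert identifiers carried along for reporting.
#' @param tol reciprocity tolerance (default 1e-9).
#' @return A `judgment_matrix` object.
#' @export
judgment_matrix <- function(m, node = NA_character_, expert = NA_character_,
                            tol = 1e-9) {
  m <- as.matrix(m)
  if (!is.numeric(m) || nrow(m) != ncol(m))
    stop("judgment matrix must be a square numeric matrix")
  if (any(!is.finite(m)) || any(m <= 0))
    stop("judgment matrix entries must be positive and finite")
  if (any(abs(diag(m) - 1) > tol))
    stop("judgment matrix diagonal must be 1")
  if (any(abs(m * t(m) - 1) > tol))
    stop("judgment matrix must be reciprocal (a_ji = 1/a_ij) within ", tol)
  structure(list(m = m, node = node, expert = expert),
            class = "judgment_matrix")
}

#' Principal-eigenvector weights of a judgment matrix
#'
#' Computes the normalized principal right eigenvector by power iteration
#' (deterministic uniform start, tolerance 1e-10), the principal eigenvalue
#' lambda_max, and the consistency index/ratio.
#'
#' @param matrix a [judgment_matrix()] (or a plain matrix, validated first).
#' @param tol,max_iter power-iteration controls.
#' @return A `weight_vector`: list with `weights` (sum to 1), `lambda_max`,
#'   `CI`, `CR`, `n`, `node`, `expert`.
#' @examples
#' eigen_weights(judgment_matrix(rbind(c(1, 2), c(1/2, 1))))$weights
#' @export
eigen_weights <- function(matrix, tol = 1e-10, max_iter = 10000L) {
  if (!inherits(matrix, "judgment_matrix")) matrix <- judgment_matrix(matrix)
  A <- matrix$m
  n <- nrow(A)
  w <- rep(1 / n, n)
  lambda <- n
  for (it in seq_len(max_iter)) {
    v <- as.vector(A %*% w)
    lambda_new <- sum(v) / sum(w)
    v <- v / sum(v)
    if (max(abs(v - w)) < tol && abs(lambda_new - lambda) < tol) {
      w <- v; lambda <- lambda_new
      break
    }
    w <- v; lambda <- lambda_new
  }
  ci <- if (n <= 2) 0 else (lambda - n) / (n - 1)
  structure(list(weights = w, lambda_max = lambda, n = n,
                 CI = ci, CR = consistency_ratio(lambda, n),
                 node = matrix$node, expert = matrix$expert),
            class = "weight_vector")
}

# Saaty random-index table for matrix orders 1..9
saaty_ri_table <- c(0, 0, 0.58, 0.90, 1.12, 1.24, 1.32, 1.41, 1.45)

#' Consistency ratio of a judgment matrix
#'
#' CR = CI / RI with CI = (lambda_max - n)/(n - 1) and RI the Saaty
#' random-index table. Orders 1 and 2 are always perfectly consistent
#' (CR = 0 by convention).
#'
#' @param lambda_max principal eigenvalue (or a `weight_vector`, from which
#'   `lambda_max` and `n` are taken).
#' @param n matrix order.
#' @return CR (unitless, >= 0 up to numerical noise).
#' @export
consistency_ratio <- function(lambda_max, n) {
  if (inherits(lambda_max, "weight_vector")) {
    n <- lambda_max$n
    lambda_max <- lambda_max$lambda_max
  }
  if (n < 1) stop("matrix order must be >= 1")
  if (n <= 2) return(0)
  if (n > length(saaty_ri_table))
    stop("no random-index value for order ", n,
         "; extend saaty_ri_table to use larger matrices")
  ci <- (lambda_max - n) / (n - 1)
  max(ci / saaty_ri_table[n], 0)
}

#' Aggregate expert weight vectors by weighted geometric mean
#'
#' Experts whose judgment matrices fail the consistency screen
#' (CR > `cr_threshold`) are excluded; the remaining expert weights lambda are
#' renormalized (default: equal weights 1/m over included experts). Included
#' vectors are combined component-wise as `prod_j w_j^lambda_j` and
#' renormalized to sum 1.
#'
#' @param vectors list of `weight_vector`s for the same node, one per expert.
#' @param lambda optional per-expert weights (same length as `vectors`);
#'   default equal.
#' @param cr_threshold consistency cut-off; experts above it are dropped.
#' @return A `weight_vector` with an `included` attribute (logical per expert).
#' @export
aggregate_experts <- function(vectors, lambda = NULL, cr_threshold = 0.1) {
  stopifnot(length(vectors) >= 1)
  lens <- vapply(vectors, function(v) length(v$weights), integer(1))
  if (length(unique(lens)) != 1L)
    stop("expert weight vectors have differing lengths")
  crs <- vapply(vectors, function(v) v$CR, numeric(1))
  included <- crs <= cr_threshold
  if (!any(included))
    stop("no expert passes the consistency screen (all CR > ", cr_threshold, ")")
  if (is.null(lambda)) lambda <- rep(1, length(vectors))
  stopifnot(length(lambda) == length(vectors), all(lambda >= 0))
  lam <- lambda * included
  lam <- lam / sum(lam)
  W <- vapply(vectors, function(v) v$weights, numeric(lens[1]))
  if (any(W[, lam > 0] <= 0))
    stop("geometric aggregation undefined: zero weight component in an included expert")
  logw <- as.vector(log(W) %*% lam)
  w <- exp(logw - max(logw))
  w <- w / sum(w)
  out <- structure(list(weights = w, lambda_max = NA_real_,
                        n = lens[1], CI = NA_real_, CR = NA_real_,
                        node = vectors[[1]]$node, expert = "panel"),
                   class = "weight_vector")
  attr(out, "included") <- included
  out
}

#' Layer composition matrix
#'
#' The n_k x n_{k-1} matrix whose column j holds the local sorting weights of
#' the layer-k elements under parent j (zeros where an element is not
#' dominated by that parent). Every column must either sum to 1 or be all
#' zero.
#'
#' @param m numeric matrix of non-negative entries.
#' @param tol column-sum tolerance.
#' @return the validated matrix with class `composition_matrix`.
#' @export
composition_matrix <- function(m, tol = 1e-9) {
  m <- as.matrix(m)
  if (any(m < 0)) stop("composition matrix entries must be non-negative")
  cs <- colSums(m)
  bad <- abs(cs - 1) > tol & abs(cs) > tol
  if (any(bad))
    stop("composition matrix column(s) ", paste(which(bad), collapse = ", "),
         " neither sum to 1 nor are all-zero")
  structure(m, class = c("composition_matrix", "matrix"))
}

#' Compose global leaf weights from per-node local weights
#'
#' Multiplies the chain of layer composition matrices
#' `w(k) = U(k) U(k-1) ... U(3) w(2)` so that each leaf's global weight is the
#' product of the local weights along its root path. Local weights are given
#' per parent node and stitched into the layer matrices automatically.
#'
#' @param hierarchy a [risk_hierarchy()].
#' @param local_weights named list: for each internal node id, a numeric
#'   vector of local child weights in the order of `hierarchy$children[[id]]`
#'   (a `weight_vector` is also accepted).
#' @return A `weight_vector` over `hierarchy$leaf_order`, named, summing to 1.
#' @export
compose_global_weights <- function(hierarchy, local_weights) {
  stopifnot(inherits(hierarchy, "risk_hierarchy"))
  ch <- hierarchy$children
  for (nd in names(ch)) {
    lw <- local_weights[[nd]]
    if (is.null(lw))
      stop("missing local weights for internal node '", nd, "'")
    if (inherits(lw, "weight_vector")) lw <- lw$weights
    if (length(lw) != length(ch[[nd]]))
      stop("local weights for node '", nd, "' have length ", length(lw),
           " but it has ", length(ch[[nd]]), " children")
    local_weights[[nd]] <- lw / sum(lw)
  }
  w <- 1
  names(w) <- hierarchy$root
  prev <- hierarchy$root
  while (any(prev %in% names(ch))) {
    # leaves reached before the deepest layer are carried through unchanged
    carried <- setdiff(prev, names(ch))
    cur <- c(unlist(ch[intersect(prev, names(ch))], use.names = FALSE), carried)
    U <- matrix(0, length(cur), length(prev),
                dimnames = list(cur, prev))
    for (p in prev) {
      if (p %in% names(ch)) U[ch[[p]], p] <- local_weights[[p]]
      else U[p, p] <- 1
    }
    U <- composition_matrix(U)
    w <- as.vector(U %*% w[prev])
    names(w) <- cur
    prev <- cur
  }
  w <- w[hierarchy$leaf_order]
  structure(list(weights = unname(w), leaf_ids = names(w),
                 lambda_max = NA_real_, n = length(w),
                 CI = NA_real_, CR = NA_real_,
                 node = hierarchy$root, expert = "composed"),
            class = "weight_vector")
}

#' @export
print.weight_vector <- function(x, digits = 4, ...) {
  cat("<weight_vector>", if (!is.na(x$node)) paste0("node ", x$node), "\n")
  w <- round(x$weights, digits)
  if (!is.null(x$leaf_ids)) names(w) <- x$leaf_ids
  print(w)
  if (is.finite(x$lambda_max))
    cat("lambda_max =", format(x$lambda_max, digits = 6),
        " CR =", format(x$CR, digits = 4), "\n")
  invisible(x)
}
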