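# Shared fixtures built in code.

# A perfectly consistent judgment matrix a_ij = w_i / w_j.
consistent_matrix <- function(w) outer(w, w, "/")

# Random reciprocal matrix with Saaty-scale upper triangle.
random_saaty_matrix <- function(n) {
  vals <- c(1 / (9:2), 1, 2:9)
  A <- diag(1, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    A[i, j] <- sample(vals, 1)
    A[j, i] <- 1 / A[i, j]
  }
  A
}

# Independent AHP oracle: dense eigen decomposition (base::eigen), not the
# package's power iteration.
oracle_eigen_weights <- function(A) {
  e <- eigen(A)
  k <- which.max(Re(e$values))
  v <- Re(e$vectors[, k])
  v <- abs(v)
  list(weights = v / sum(v), lambda_max = Re(e$values[k]))
}

# Ladder used across fuzzy tests.
test_hazard <- function(cutoffs = c(1, 2, 3, 4, 5)) {
  hazard_definition("hz", cutoffs)
}
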