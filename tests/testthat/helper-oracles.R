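# Independent oracles used across test files.  Each one deliberately
# takes a different computational route than the implementation it
# checks.

# Textbook correspondence analysis: eigen-decomposition of the
# cross-product of the standardized residual matrix (not the SVD route
# the package uses), with row coordinates obtained by projecting row
# profiles onto the eigenvectors.
oracle_ca <- function(X) {
  X <- as.matrix(X)
  n <- sum(X)
  P <- X / n
  r <- rowSums(P)
  cm <- colSums(P)
  S <- (P - tcrossprod(r, cm)) / sqrt(tcrossprod(r, cm))
  ev <- eigen(crossprod(S), symmetric = TRUE)
  keep <- ev$values > max(ev$values) * 1e-10
  V <- ev$vectors[, keep, drop = FALSE]
  lambda <- ev$values[keep]
  # row profiles deviations projected on D_c^{-1/2} V give principal coords
  Rp <- sweep(P, 1, r, "/")
  Fc <- sweep(Rp, 2, cm, "-") %*% (V / sqrt(cm))
  d2 <- rowSums(Fc^2)
  list(eigenvalues = lambda,
       row_coords = Fc,
       sq_cos = Fc^2 / ifelse(d2 > 0, d2, 1))
}

# Naive exhaustive-split change-point search recomputing segment costs
# from scratch (no cumulative sums).
oracle_cpa <- function(x, cost_kind = "mean") {
  n <- length(x)
  pop_var <- function(v) mean((v - mean(v))^2)
  cost <- function(v) {
    if (cost_kind == "mean") sum((v - mean(v))^2)
    else length(v) * log(max(pop_var(v), 1e-12))
  }
  ks <- 3:(n - 1)
  splits <- vapply(ks, function(k)
    cost(x[1:(k - 1)]) + cost(x[k:n]), numeric(1))
  best <- which.min(splits)
  list(index = ks[best], cost_full = cost(x),
       cost_split = splits[best],
       improvement = cost(x) - splits[best])
}

# Two-block matrix with identical rows inside each block: exactly two
# distinct row profiles on disjoint column sets, so CA has a single
# nonzero axis that carries every row completely (cos2 = 1).
pure_block_matrix <- function() {
  m <- rbind(matrix(rep(c(1, 1, 1, 0, 0), 3), 3, byrow = TRUE),
             matrix(rep(c(0, 0, 0, 1, 1), 3), 3, byrow = TRUE))
  rownames(m) <- sprintf("doc_%04d", 1:6)
  colnames(m) <- letters[1:5]
  m
}

# Tiny deterministic two-block binary matrix: rows 1..3 use only the
# first column group, rows 4..6 only the second.
block_matrix <- function() {
  m <- rbind(
    c(1, 1, 0, 0, 0),
    c(1, 0, 1, 0, 0),
    c(0, 1, 1, 0, 0),
    c(0, 0, 0, 1, 1),
    c(0, 0, 0, 1, 0),
    c(0, 0, 0, 0, 1))
  rownames(m) <- sprintf("doc_%04d", 1:6)
  colnames(m) <- letters[1:5]
  m
}

# Random binary matrix with no all-zero row/column, rejection-sampled.
random_binary_matrix <- function(nr, nc) {
  repeat {
    m <- matrix(rbinom(nr * nc, 1, 0.45), nr, nc)
    if (all(rowSums(m) > 0) && all(colSums(m) > 0) &&
        qr(scale(m, scale = FALSE))$rank >= 2) return(m)
  }
}

# Small corpus shared by corpus-prep tests.
tiny_corpus <- function() {
  segment_corpus(c("A b, c.", "d e", "b c d", "c d e a b"))
}
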