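#' Correspondence analysis of the binary document-by-lemma matrix
#'
#' Simple CA of the indicator matrix: row and column masses are taken
#' from the grand total, the standardized-residual matrix
#' \eqn{S = D_r^{-1/2}(P - r c^T) D_c^{-1/2}} is decomposed by SVD,
#' eigenvalues are the squared singular values, and explained inertia is
#' the plain eigenvalue share (no Benzecri/Greenacre adjustment by
#' default).  Row principal coordinates and squared cosines (squared
#' coordinate over the row's squared chi-square distance to the
#' centroid) are returned for all axes; `K` marks the dimensionality
#' used downstream.
#'
#' Rows with an all-zero profile cannot be placed in the space; they are
#' excluded from the decomposition, given placeholder zero squared-cosine
#' vectors so the document series keeps its length, and reported in
#' `$excluded_rows`.
#'
#' @param mat Numeric matrix (typically a `lemma_matrix`), non-negative,
#'   at least 2 non-identical rows and 2 columns.
#' @param K Number of retained factors (default 10, clamped with a
#'   warning when fewer axes exist).
#' @param adjust_inertia If `TRUE`, also report Benzecri-adjusted
#'   explained percentages (informational only).
#' @return A `factor_space`: list with `row_coords` (N x R principal
#'   coordinates), `sq_cos` (N x R in \[0,1\]), `eigenvalues`,
#'   `explained_pct`, `K`, `row_ids`, `excluded_rows`.
#' @export
fit_correspondence <- function(mat, K = 10L, adjust_inertia = FALSE) {
  X <- unclass(as.matrix(mat))
  storage.mode(X) <- "double"
  stopifnot(nrow(X) >= 2L, ncol(X) >= 2L, all(X >= 0), all(is.finite(X)))
  ids <- rownames(X) %||% sprintf("doc_%04d", seq_len(nrow(X)))

  zero_row <- rowSums(X) == 0
  Xa <- X[!zero_row, , drop = FALSE]
  zero_col <- colSums(Xa) == 0
  Xa <- Xa[, !zero_col, drop = FALSE]
  if (nrow(Xa) < 2L || ncol(Xa) < 2L) stop("degenerate matrix")

  n <- sum(Xa)
  P <- Xa / n
  r <- rowSums(P)
  cm <- colSums(P)
  S <- (P - tcrossprod(r, cm)) / sqrt(tcrossprod(r, cm))
  dec <- svd(S)
  tol <- max(dim(S)) * .Machine$double.eps * dec$d[1]
  pos <- dec$d > max(tol, 0)
  if (!any(pos)) stop("degenerate matrix")
  d <- dec$d[pos]
  U <- dec$u[, pos, drop = FALSE]
  R <- length(d)

  eig <- d^2
  total_inertia <- sum(eig)
  explained_pct <- 100 * eig / total_inertia
  # row principal coordinates and squared chi-square distances to centroid
  Fc <- sweep(U, 1, sqrt(r), "/") %*% diag(d, R)
  d2 <- rowSums(Fc^2)
  sqcos <- Fc^2 / ifelse(d2 > 0, d2, 1)

  if (K > R) {
    warning("K = ", K, " exceeds available axes (", R, "); clamping")
    K <- R
  }
  row_coords <- matrix(0, nrow(X), R,
                       dimnames = list(ids, paste0("F", seq_len(R))))
  sq_cos <- row_coords
  row_coords[!zero_row, ] <- Fc
  sq_cos[!zero_row, ] <- sqcos

  structure(list(
    row_coords = row_coords,
    sq_cos = sq_cos,
    eigenvalues = eig,
    explained_pct = explained_pct,
    explained_pct_adjusted = if (adjust_inertia)
      benzecri_adjust(eig, ncol(Xa)) else NULL,
    K = as.integer(K),
    row_ids = ids,
    excluded_rows = ids[zero_row]
  ), class = "factor_space")
}

# Benzecri reweighting of eigenvalue shares for indicator-matrix CA;
# exposed as an option only, default off.
benzecri_adjust <- function(eig, Q) {
  thr <- 1 / Q
  adj <- ifelse(eig > thr, (Q / (Q - 1))^2 * (eig - thr)^2, 0)
  if (sum(adj) == 0) return(rep(0, length(eig)))
  100 * adj / sum(adj)
}

#' Extract per-document squared-cosine vectors over the retained factors
#'
#' The representation-quality vector of each document: its squared
#' cosines on the first `K` factor axes, in document order.  A high
#' squared cosine means the document is well represented by (polarized
#' onto) that factor.
#'
#' @param space A `factor_space` from [fit_correspondence()].
#' @param K Number of factors (defaults to the fitted `space$K`).
#' @return N x K numeric matrix of squared cosines.
#' @export
dream_vectors <- function(space, K = space$K) {
  stopifnot(inherits(space, "factor_space"), K >= 1L,
            K <= ncol(space$sq_cos))
  space$sq_cos[, seq_len(K), drop = FALSE]
}

#' Serialize a factor space
#'
#' Eigenvalues and explained percentages go to JSON, row coordinates and
#' squared cosines to TSV, next to each other under `prefix`.
#' @param space A `factor_space`.
#' @param prefix Path prefix (files `<prefix>_eigen.json`,
#'   `<prefix>_rows.tsv`).
#' @export
write_factor_space <- function(space, prefix) {
  jsonlite::write_json(
    list(eigenvalues = space$eigenvalues,
         explained_pct = space$explained_pct,
         K = space$K, excluded_rows = space$excluded_rows),
    paste0(prefix, "_eigen.json"), digits = NA, auto_unbox = TRUE)
  df <- data.frame(doc_id = space$row_ids,
                   space$row_coords,
                   stats::setNames(as.data.frame(space$sq_cos),
                                   paste0("cos2_", seq_len(ncol(space$sq_cos)))),
                   check.names = FALSE)
  utils::write.table(df, paste0(prefix, "_rows.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(prefix)
}
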