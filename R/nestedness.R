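#' NODF nestedness of a binary matrix
#'
#' Nestedness metric based on overlap and decreasing fill. For every
#' unordered pair of columns the paired score is 100 x (shared ones) /
#' (fill of the sparser column) when the two fills differ strictly, and 0
#' when the fills are tied or the sparser fill is zero; identically for row
#' pairs. The column, row and total components average these scores over
#' the respective pair counts, giving values in \[0, 100\] (100 = perfectly
#' nested, specialists interacting with strict subsets of generalists'
#' partners).
#'
#' @param mat binary matrix with at least 2 rows and 2 columns, no missing
#'   cells.
#' @return Object of class `nodf_result`: `nodf_total`, `nodf_rows`,
#'   `nodf_cols`, `n_row_pairs`, `n_col_pairs`.
#' @examples
#' nodf(rbind(c(1, 1), c(1, 0)))   # perfectly nested 2x2
#' @export
nodf <- function(mat) {
  mat <- .validate_pbim(mat)
  if (nrow(mat) < 2 || ncol(mat) < 2)
    stop("NODF undefined for a matrix with fewer than 2 rows or 2 columns")
  rows <- .nodf_pair_sum(mat)
  cols <- .nodf_pair_sum(t(mat))
  npr <- nrow(mat) * (nrow(mat) - 1) / 2
  npc <- ncol(mat) * (ncol(mat) - 1) / 2
  structure(list(nodf_total = (rows + cols) / (npr + npc),
                 nodf_rows = rows / npr,
                 nodf_cols = cols / npc,
                 n_row_pairs = npr, n_col_pairs = npc),
            class = "nodf_result")
}

# sum of paired overlap scores over all unordered row pairs of x
.nodf_pair_sum <- function(x) {
  f <- rowSums(x)
  ov <- tcrossprod(x)
  fmin <- outer(f, f, pmin)
  tied <- outer(f, f, "==")
  sc <- matrix(0, nrow(x), nrow(x))
  ok <- !tied & fmin > 0
  sc[ok] <- 100 * ov[ok] / fmin[ok]
  sum(sc[upper.tri(sc)])
}

#' @export
print.nodf_result <- function(x, ...) {
  cat(sprintf("NODF = %.2f (rows %.2f over %d pairs; columns %.2f over %d pairs)\n",
              x$nodf_total, x$nodf_rows, x$n_row_pairs, x$nodf_cols, x$n_col_pairs))
  invisible(x)
}
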