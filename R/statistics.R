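# Nonparametric comparison statistics, implemented from their standard
# definitions (base-R equivalents are used only as cross-checks in tests).

#' Friedman rank test for repeated measures
#'
#' Values are ranked within each block (mid-ranks for ties); the statistic
#' uses the standard tie-corrected chi-square approximation with k - 1
#' degrees of freedom. Under perfect concordance with no ties the statistic
#' equals n(k - 1).
#'
#' @param block_table numeric blocks x treatments matrix, no missing values.
#' @return Object of class `friedman_result`: `statistic`, `df`, `p_value`,
#'   `rank_sums` (per treatment; they always total n k (k + 1) / 2).
#' @export
friedman_test <- function(block_table) {
  y <- as.matrix(block_table)
  if (anyNA(y)) stop("missing values are not allowed (no imputation)")
  n <- nrow(y); k <- ncol(y)
  if (n < 2 || k < 2) stop("need at least 2 blocks and 2 treatments")
  r <- t(apply(y, 1, rank))
  rank_sums <- colSums(r)
  ties <- sum(apply(r, 1, function(u) { t <- table(u); sum(t^3 - t) }))
  denom <- n * k * (k + 1) - ties / (k - 1)
  stat <- if (denom <= 0) 0 else
    12 * sum((rank_sums - n * (k + 1) / 2)^2) / denom
  structure(list(statistic = stat, df = k - 1,
                 p_value = stats::pchisq(stat, k - 1, lower.tail = FALSE),
                 rank_sums = stats::setNames(rank_sums, colnames(y))),
            class = "friedman_result")
}

#' Dunn's post-hoc test on Friedman rank sums
#'
#' For every treatment pair, the rank-sum difference is standardized by
#' sqrt(n k (k + 1) / 6); two-sided normal p-values are Bonferroni-adjusted
#' over all k(k - 1)/2 comparisons (capped at 1).
#'
#' @param block_table numeric blocks x treatments matrix, no missing values.
#' @param alpha significance level used only to flag pairs.
#' @return data.frame of class `dunn_result`: one row per pair with
#'   `rank_sum_diff`, `z`, `p_raw`, `p_adjusted`, `significant`.
#' @export
dunn_posthoc <- function(block_table, alpha = 0.05) {
  fr <- friedman_test(block_table)
  y <- as.matrix(block_table)
  n <- nrow(y); k <- ncol(y)
  se <- sqrt(n * k * (k + 1) / 6)
  m <- k * (k - 1) / 2
  prs <- utils::combn(k, 2)
  trt <- names(fr$rank_sums) %||% as.character(seq_len(k))
  out <- data.frame(
    treatment_1 = trt[prs[1, ]], treatment_2 = trt[prs[2, ]],
    rank_sum_diff = fr$rank_sums[prs[1, ]] - fr$rank_sums[prs[2, ]])
  out$z <- out$rank_sum_diff / se
  out$p_raw <- 2 * stats::pnorm(-abs(out$z))
  out$p_adjusted <- pmin(1, out$p_raw * m)
  out$significant <- out$p_adjusted < alpha
  rownames(out) <- NULL
  class(out) <- c("dunn_result", "data.frame")
  out
}

#' Mantel test between two distance matrices
#'
#' r is the Pearson correlation over the strictly-lower-triangle entries;
#' significance is the one-tailed (greater) add-one permutation p-value
#' under simultaneous row/column permutation of the second matrix.
#'
#' @param d1,d2 symmetric zero-diagonal distance matrices with identical
#'   labels in identical order.
#' @param n_permutations number of label permutations (default 9999).
#' @param seed RNG seed for the permutation stream.
#' @return List of class `mantel_result`: `r`, `p_value`, `n_permutations`.
#' @export
mantel_test <- function(d1, d2, n_permutations = 9999, seed = 1) {
  d1 <- as.matrix(d1); d2 <- as.matrix(d2)
  if (!identical(dim(d1), dim(d2)) ||
      !identical(rownames(d1), rownames(d2)))
    stop("label mismatch between the two distance matrices")
  .check_distance(d1); .check_distance(d2)
  n <- nrow(d1)
  lt <- lower.tri(d1)
  v1 <- d1[lt]
  r_obs <- stats::cor(v1, d2[lt])
  set.seed(seed)
  r_perm <- vapply(seq_len(n_permutations), function(i) {
    p <- sample.int(n)
    stats::cor(v1, d2[p, p][lt])
  }, numeric(1))
  structure(list(r = r_obs,
                 p_value = (1 + sum(r_perm >= r_obs)) / (n_permutations + 1),
                 n_permutations = n_permutations),
            class = "mantel_result")
}

.check_distance <- function(d) {
  if (!isTRUE(all.equal(d, t(d), check.attributes = FALSE)))
    stop("distance matrix must be symmetric")
  if (any(abs(diag(d)) > 1e-12))
    stop("distance matrix must have a zero diagonal")
  invisible(TRUE)
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks. The p-value (two-sided) is exact by
#' full permutation enumeration for n <= 8 and uses the large-sample normal
#' approximation z = rho sqrt(n - 1) otherwise.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return List `rho`, `p_value`, `method`.
#' @export
spearman_test <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  n <- length(x)
  if (n < 3) stop("need at least 3 observations")
  if (length(unique(x)) < 2 || length(unique(y)) < 2)
    stop("rho undefined for constant input")
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= 8) {
    perms <- .permutations(n)
    rhos <- apply(perms, 1, function(p) stats::cor(rx, ry[p]))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
    method <- "exact permutation"
  } else {
    p <- 2 * stats::pnorm(-abs(rho) * sqrt(n - 1))
    method <- "normal approximation"
  }
  list(rho = rho, p_value = p, method = method)
}

# all permutations of 1..n as an n! x n matrix (n <= 8)
.permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

#' Flatten test results to a tidy table
#'
#' @param ... any mix of `friedman_result`, `dunn_result`, `mantel_result`
#'   and `spearman_test` outputs.
#' @param file optional CSV path.
#' @return data.frame with columns test, groups, statistic, df, p,
#'   adjusted_p.
#' @export
statistics_table <- function(..., file = NULL) {
  rows <- list()
  add <- function(test, groups, statistic, df = NA, p = NA, adjusted_p = NA)
    rows[[length(rows) + 1L]] <<- data.frame(test = test, groups = groups,
                                             statistic = statistic, df = df,
                                             p = p, adjusted_p = adjusted_p)
  for (obj in list(...)) {
    if (inherits(obj, "friedman_result"))
      add("friedman", "all", obj$statistic, obj$df, obj$p_value)
    else if (inherits(obj, "dunn_result"))
      for (i in seq_len(nrow(obj)))
        add("dunn", paste(obj$treatment_1[i], obj$treatment_2[i], sep = " vs "),
            obj$z[i], p = obj$p_raw[i], adjusted_p = obj$p_adjusted[i])
    else if (inherits(obj, "mantel_result"))
      add("mantel", "matrices", obj$r, p = obj$p_value)
    else if (!is.null(obj$rho))
      add("spearman", "vectors", obj$rho, p = obj$p_value)
    else stop("unrecognized result object")
  }
  df <- do.call(rbind, rows)
  if (!is.null(file)) utils::write.csv(df, file, row.names = FALSE)
  df
}
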