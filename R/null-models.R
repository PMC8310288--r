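#' Binary-matrix null models
#'
#' Three randomizations of a binary infection matrix, in increasing order of
#' stringency:
#' * `sim1`: keeps only the total number of interactions, placing them
#'   uniformly at random among all cells (no two in the same cell).
#' * `sim8`: keeps the total, placing interactions by sequential weighted
#'   sampling without replacement with cell weight proportional to
#'   row total x column total.
#' * `curveball`: preserves both margin vectors exactly by repeatedly
#'   trading the non-shared partners of two randomly chosen rows.
#'
#' All three preserve dimensions and dimnames. When `seed` is `NULL` the
#' current RNG stream is used (as [significance_test()] does internally).
#'
#' @param mat binary hosts x phages matrix.
#' @param seed optional integer seed.
#' @return A randomized binary matrix of the same dimensions.
#' @name null-models
NULL

#' @rdname null-models
#' @export
sim1 <- function(mat, seed = NULL) {
  mat <- .validate_pbim(mat)
  if (!is.null(seed)) set.seed(seed)
  out <- matrix(0L, nrow(mat), ncol(mat), dimnames = dimnames(mat))
  n1 <- sum(mat)
  if (n1 > 0) out[sample.int(length(out), n1)] <- 1L
  out
}

#' @rdname null-models
#' @export
sim8 <- function(mat, seed = NULL) {
  mat <- .validate_pbim(mat)
  if (!is.null(seed)) set.seed(seed)
  rs <- rowSums(mat); cs <- colSums(mat)
  if (any(rs == 0) || any(cs == 0))
    warning("zero-margin row(s)/column(s): those lines can never receive an interaction")
  w <- as.vector(outer(rs, cs))
  out <- matrix(0L, nrow(mat), ncol(mat), dimnames = dimnames(mat))
  n1 <- sum(mat)
  if (n1 > sum(w > 0))
    stop("not enough positive-weight cells to place all interactions")
  if (n1 > 0) out[sample.int(length(out), n1, prob = w)] <- 1L
  out
}

#' @rdname null-models
#' @param n_trades number of trade attempts; the default 5 x (rows +
#'   columns) comfortably mixes matrices of this scale and is configurable.
#' @export
curveball <- function(mat, n_trades = 5 * (nrow(mat) + ncol(mat)), seed = NULL) {
  mat <- .validate_pbim(mat)
  if (nrow(mat) < 2) stop("curveball needs at least 2 rows")
  if (n_trades < 1) stop("`n_trades` must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  for (t in seq_len(n_trades)) {
    ab <- sample.int(nrow(mat), 2)
    ra <- mat[ab[1], ]; rb <- mat[ab[2], ]
    ua <- which(ra == 1L & rb == 0L)            # partners of a only
    ub <- which(rb == 1L & ra == 0L)            # partners of b only
    if (length(ua) == 0 || length(ub) == 0) next
    pool <- c(ua, ub)
    new_a <- sample(pool, length(ua))
    mat[ab[1], pool] <- 0L; mat[ab[1], new_a] <- 1L
    mat[ab[2], pool] <- 0L; mat[ab[2], setdiff(pool, new_a)] <- 1L
  }
  mat
}

#' Permutation significance of nestedness or modularity
#'
#' Simulates `n_replicates` null matrices from the observed one, computes
#' the chosen statistic on each, and reports the one-tailed (greater)
#' add-one permutation p-value `p = (1 + #\{null >= observed\}) /
#' (n_replicates + 1)` together with the 95th percentile of the null
#' distribution (the significance threshold). For `statistic =
#' "modularity"` every null matrix is optimized with the same restart
#' budget as the observed matrix. Replicate `i` runs on its own RNG
#' sub-stream seeded by `seed + i`, so results are independent of
#' evaluation order and bit-for-bit reproducible.
#'
#' @param mat filtered binary hosts x phages matrix.
#' @param statistic `"nodf"` or `"modularity"`.
#' @param model `"sim1"`, `"sim8"` or `"curveball"`.
#' @param n_replicates number of simulated matrices (literature convention:
#'   1200).
#' @param seed master seed.
#' @param restarts optimizer restarts when `statistic = "modularity"`.
#' @param trade_multiplier curveball trades per replicate = multiplier x
#'   (rows + columns); each replicate re-randomizes the *observed* matrix.
#' @return Object of class `null_ensemble`: `model`, `statistic_name`,
#'   `n_replicates`, `null_scores`, `observed`, `p_value`, `threshold_95`,
#'   `seed`.
#' @export
significance_test <- function(mat, statistic = c("nodf", "modularity"),
                              model = c("sim1", "sim8", "curveball"),
                              n_replicates = 1200, seed = 1,
                              restarts = 20, trade_multiplier = 5) {
  statistic <- match.arg(statistic)
  model <- match.arg(model)
  mat <- .validate_pbim(mat)
  if (n_replicates < 1) stop("`n_replicates` must be >= 1")
  stat_fun <- switch(statistic,
    nodf = function(m, s) nodf(m)$nodf_total,
    modularity = function(m, s) optimize_modularity(m, restarts = restarts, seed = s)$q)
  gen <- switch(model,
    sim1 = function(m) sim1(m),
    sim8 = function(m) suppressWarnings(sim8(m)),
    curveball = function(m) curveball(m, n_trades = trade_multiplier * (nrow(m) + ncol(m))))
  observed <- stat_fun(mat, seed)
  null_scores <- vapply(seq_len(n_replicates), function(i) {
    set.seed(seed + i)
    stat_fun(gen(mat), seed + i)
  }, numeric(1))
  p <- (1 + sum(null_scores >= observed)) / (n_replicates + 1)
  structure(list(model = model, statistic_name = statistic,
                 n_replicates = n_replicates, null_scores = null_scores,
                 observed = observed, p_value = p,
                 threshold_95 = as.numeric(stats::quantile(null_scores, 0.95)),
                 seed = seed),
            class = "null_ensemble")
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat(sprintf("%s vs %s null (%d replicates): observed = %.4f, 95%% threshold = %.4f, p = %.4g%s\n",
              x$statistic_name, x$model, x$n_replicates, x$observed,
              x$threshold_95, x$p_value,
              if (x$p_value < 0.05) " *" else ""))
  invisible(x)
}

#' Serialize a null ensemble
#'
#' Writes the summary (model, seed, observed statistic, p-value,
#' percentiles) as JSON and, optionally, the raw null score vector as a
#' one-column CSV for external plotting.
#'
#' @param ensemble a [significance_test()] result.
#' @param json_file,scores_file output paths (`NULL` to skip either).
#' @return The summary list, invisibly.
#' @export
write_null_ensemble <- function(ensemble, json_file = NULL, scores_file = NULL) {
  stopifnot(inherits(ensemble, "null_ensemble"))
  pct <- stats::quantile(ensemble$null_scores, c(0.025, 0.25, 0.5, 0.75, 0.95, 0.975))
  summ <- list(model = ensemble$model, statistic = ensemble$statistic_name,
               n_replicates = ensemble$n_replicates, seed = ensemble$seed,
               observed = ensemble$observed, p_value = ensemble$p_value,
               threshold_95 = ensemble$threshold_95,
               null_percentiles = as.list(stats::setNames(as.numeric(pct), names(pct))))
  if (!is.null(json_file))
    jsonlite::write_json(summ, json_file, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(scores_file))
    utils::write.csv(data.frame(null_score = ensemble$null_scores),
                     scores_file, row.names = FALSE)
  invisible(summ)
}
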