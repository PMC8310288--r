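#' Lysis score categories
#'
#' Spot-test outcomes recorded in the double-layer agar assay. Confluent
#' (CL), semi-confluent (SCL) and opaque (OL) lysis as well as countable
#' plaques ("taches vierges", TV) all indicate a productive infection;
#' uninterrupted growth is scored resistant (R).
#'
#' @name lysis-scores
NULL

.lysis_positive <- c("CL", "SCL", "OL", "TV")
.lysis_levels <- c(.lysis_positive, "R")

#' Construct a raw lysis-score table
#'
#' Holds the categorical spot-test scores for every host strain x phage
#' clone combination, optionally replicated over several multiplicities of
#' infection (MOI). Missing cells (strain never tested against that phage at
#' that MOI) are `NA`.
#'
#' @param scores character matrix (hosts x phages, single MOI) or 3-d array
#'   (hosts x phages x MOI levels) with values in CL, SCL, OL, TV, R or `NA`.
#' @param host_ids,phage_ids label vectors; default taken from dimnames.
#' @param moi_levels labels of the third dimension, e.g. `c("1.0","0.1","0.01")`.
#' @return An object of class `lysis_table`.
#' @export
lysis_table <- function(scores, host_ids = NULL, phage_ids = NULL,
                        moi_levels = NULL) {
  if (is.matrix(scores)) {
    scores <- array(scores, dim = c(dim(scores), 1L),
                    dimnames = c(dimnames(scores), list(NULL)))
  }
  if (!is.array(scores) || length(dim(scores)) != 3L)
    stop("`scores` must be a hosts x phages matrix or 3-d array")
  storage.mode(scores) <- "character"
  if (is.null(host_ids)) host_ids <- dimnames(scores)[[1]]
  if (is.null(phage_ids)) phage_ids <- dimnames(scores)[[2]]
  if (is.null(host_ids)) host_ids <- sprintf("H%03d", seq_len(dim(scores)[1]))
  if (is.null(phage_ids)) phage_ids <- sprintf("P%02d", seq_len(dim(scores)[2]))
  if (is.null(moi_levels)) moi_levels <- dimnames(scores)[[3]]
  if (anyDuplicated(host_ids)) stop("host ids must be unique")
  if (anyDuplicated(phage_ids)) stop("phage ids must be unique")
  dimnames(scores) <- list(host_ids, phage_ids, moi_levels)
  .check_lysis_values(scores)
  structure(list(host_ids = host_ids, phage_ids = phage_ids,
                 moi_levels = moi_levels, scores = scores),
            class = "lysis_table")
}

.check_lysis_values <- function(scores) {
  bad <- which(!(scores %in% .lysis_levels) & !is.na(scores), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    i <- bad[1, ]
    stop(sprintf("unknown lysis score '%s' at host '%s', phage '%s'",
                 scores[bad[1, 1], bad[1, 2], bad[1, 3]],
                 dimnames(scores)[[1]][i[1]], dimnames(scores)[[2]][i[2]]))
  }
  invisible(TRUE)
}

#' Read a raw lysis-score CSV
#'
#' Expected layout: first column `host_id`; remaining headers either a bare
#' phage id (`GE_vB_B1`) or `phage@MOI` (`GE_vB_B1@0.1`); cells one of
#' CL/SCL/OL/TV/R or empty for missing.
#'
#' @param path CSV file path.
#' @return A [lysis_table()].
#' @export
read_lysis_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  if (names(df)[1] != "host_id")
    stop("first column of a lysis CSV must be 'host_id'")
  hosts <- df[[1]]
  cols <- names(df)[-1]
  parts <- strsplit(cols, "@", fixed = TRUE)
  phage_of <- vapply(parts, `[`, "", 1L)
  moi_of <- vapply(parts, function(p) if (length(p) > 1) p[2] else "", "")
  phages <- unique(phage_of)
  mois <- unique(moi_of)
  arr <- array(NA_character_, dim = c(length(hosts), length(phages), length(mois)),
               dimnames = list(hosts, phages, if (all(mois == "")) NULL else mois))
  for (j in seq_along(cols)) {
    v <- df[[j + 1L]]
    v[v == ""] <- NA_character_
    arr[, match(phage_of[j], phages), match(moi_of[j], mois)] <- v
  }
  lysis_table(arr, moi_levels = if (all(mois == "")) NULL else mois)
}

#' Binarize lysis scores into an infection matrix
#'
#' A host-phage pair scores 1 if *any* replicate at any MOI shows evidence of
#' lysis (CL, SCL, OL or TV), 0 if every non-missing replicate is resistant
#' (R), and `NA` if the pair was never tested. Missing cells are resolved
#' downstream by [filter_matrix()], never imputed.
#'
#' @param table a [lysis_table()].
#' @return Integer hosts x phages matrix in \{0, 1, `NA`\} with a
#'   `provenance` attribute describing the rule applied.
#' @export
binarize_lysis <- function(table) {
  stopifnot(inherits(table, "lysis_table"))
  if (length(table$host_ids) == 0 || length(table$phage_ids) == 0)
    stop("lysis table is empty")
  s <- table$scores
  pos <- apply(s %in% .lysis_positive & !is.na(s), c(1, 2), any)
  tested <- apply(!is.na(s), c(1, 2), any)
  out <- matrix(NA_integer_, nrow(pos), ncol(pos),
                dimnames = list(table$host_ids, table$phage_ids))
  out[tested] <- as.integer(pos[tested])
  attr(out, "provenance") <- "binarized: any lysis (CL/SCL/OL/TV) across MOI replicates = 1"
  out
}
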