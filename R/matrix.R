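# Infection matrices are plain integer matrices: rows = bacterial hosts,
# columns = phages, cells in {0,1} (NA allowed only pre-filtering).

.validate_pbim <- function(mat, allow_na = FALSE, arg = "matrix") {
  if (!is.matrix(mat)) stop(sprintf("`%s` must be a matrix", arg))
  if (is.null(rownames(mat)))
    rownames(mat) <- sprintf("H%03d", seq_len(nrow(mat)))
  if (is.null(colnames(mat)))
    colnames(mat) <- sprintf("P%02d", seq_len(ncol(mat)))
  if (anyDuplicated(rownames(mat))) stop("host (row) labels must be unique")
  if (anyDuplicated(colnames(mat))) stop("phage (column) labels must be unique")
  vals <- mat[!is.na(mat)]
  if (!all(vals %in% c(0L, 1L)))
    stop(sprintf("`%s` must be binary (0/1)", arg))
  if (!allow_na && anyNA(mat))
    stop(sprintf("`%s` contains missing cells; run filter_matrix() first", arg))
  storage.mode(mat) <- "integer"
  mat
}

#' Filter an infection matrix
#'
#' Applies the two row-removal rules used when assembling a phage-bacteria
#' infection matrix from incomplete screens: (i) hosts with at least one
#' untested (missing) cell are dropped first, then (ii) hosts showing no
#' lysis by any phage (all-zero rows). Columns are never removed; an
#' all-zero phage column only triggers a warning because zero-degree
#' entities break Jaccard profile similarity downstream.
#'
#' @param mat binary hosts x phages matrix, `NA` cells allowed.
#' @return A list with elements `matrix` (the filtered matrix, provenance
#'   attribute updated) and `report`, a `filter_report` listing
#'   `dropped_incomplete`, `dropped_zero` and `retained` (row count kept).
#' @examples
#' m <- rbind(h1 = c(1, 1), h2 = c(0, 0), h3 = c(1, NA))
#' colnames(m) <- c("p1", "p2")
#' filter_matrix(m)$report
#' @export
filter_matrix <- function(mat) {
  mat <- .validate_pbim(mat, allow_na = TRUE)
  incomplete <- rownames(mat)[apply(is.na(mat), 1, any)]
  kept <- mat[setdiff(rownames(mat), incomplete), , drop = FALSE]
  zero <- rownames(kept)[rowSums(kept) == 0]
  kept <- kept[setdiff(rownames(kept), zero), , drop = FALSE]
  if (nrow(kept) == 0) stop("empty matrix after filtering")
  if (any(colSums(kept) == 0))
    warning(sprintf("zero-degree phage column(s) retained: %s",
                    paste(colnames(kept)[colSums(kept) == 0], collapse = ", ")))
  attr(kept, "provenance") <- paste0(
    attr(mat, "provenance") %||% "",
    sprintf("; filtered: %d incomplete row(s), %d zero row(s) removed",
            length(incomplete), length(zero)))
  report <- structure(list(dropped_incomplete = incomplete,
                           dropped_zero = zero,
                           retained = nrow(kept)),
                      class = "filter_report")
  list(matrix = kept, report = report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("filter report: %d row(s) retained\n", x$retained))
  cat(sprintf("  dropped (incomplete): %s\n",
              if (length(x$dropped_incomplete)) paste(x$dropped_incomplete, collapse = ", ") else "none"))
  cat(sprintf("  dropped (no lysis):   %s\n",
              if (length(x$dropped_zero)) paste(x$dropped_zero, collapse = ", ") else "none"))
  invisible(x)
}

#' Summarize an infection matrix
#'
#' @param mat filtered binary hosts x phages matrix.
#' @return List with `n_hosts`, `n_phages`, `n_ones`, `fill` (fraction of
#'   1-cells), `row_degrees` (phages infecting each host) and `col_degrees`
#'   (hosts infected by each phage, the target range).
#' @export
matrix_summary <- function(mat) {
  mat <- .validate_pbim(mat)
  list(n_hosts = nrow(mat), n_phages = ncol(mat), n_ones = sum(mat),
       fill = sum(mat) / length(mat),
       row_degrees = rowSums(mat), col_degrees = colSums(mat))
}

#' Read / write a binary infection matrix CSV
#'
#' The CSV dialect has a header row of phage ids, host ids in the first
#' column, and strictly "0"/"1" cells.
#'
#' @param path CSV file path.
#' @return `read_infection_matrix`: an integer hosts x phages matrix.
#' @export
read_infection_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, row.names = 1)
  mat <- as.matrix(df)
  storage.mode(mat) <- "integer"
  .validate_pbim(mat)
}

#' @rdname read_infection_matrix
#' @param mat binary hosts x phages matrix.
#' @export
write_infection_matrix <- function(mat, path) {
  mat <- .validate_pbim(mat)
  utils::write.csv(as.data.frame(mat), path, row.names = TRUE)
  invisible(path)
}
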