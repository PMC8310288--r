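#' Barber bipartite modularity for a given partition
#'
#' Q = (1/m) * sum over host i, phage j of (A_ij - k_i d_j / m) *
#' delta(module(i), module(j)), with m the total number of interactions,
#' k_i the host degree and d_j the phage degree. Modules live in one shared
#' label space, so a module may contain hosts, phages or both; only
#' host-phage co-membership contributes. The single-module partition scores
#' exactly 0.
#'
#' @param mat filtered binary hosts x phages matrix with at least one 1.
#' @param partition list with named integer vectors `row_modules` (hosts)
#'   and `col_modules` (phages) covering every node.
#' @return Q, a number <= 1.
#' @export
barber_q <- function(mat, partition) {
  mat <- .validate_pbim(mat)
  mm <- sum(mat)
  if (mm < 1) stop("matrix has no interactions")
  g <- .module_vector(partition$row_modules, rownames(mat), "row")
  h <- .module_vector(partition$col_modules, colnames(mat), "column")
  k <- rowSums(mat); d <- colSums(mat)
  q <- 0
  for (c in intersect(unique(g), unique(h))) {
    rs <- g == c; cs <- h == c
    q <- q + sum(mat[rs, cs]) - sum(k[rs]) * sum(d[cs]) / mm
  }
  q / mm
}

.module_vector <- function(v, labels, what) {
  if (is.null(v)) stop(sprintf("partition is missing %s modules", what))
  v <- unlist(v)
  if (is.null(names(v)) && length(v) == length(labels)) names(v) <- labels
  miss <- setdiff(labels, names(v))
  if (length(miss))
    stop(sprintf("partition does not cover %s node(s): %s", what,
                 paste(miss, collapse = ", ")))
  as.integer(v[labels])
}

#' Maximize Barber modularity by weighted label propagation
#'
#' Searches for the partition maximizing [barber_q()]. Each restart starts
#' from singleton row modules (restart 1) or a random row grouping, then
#' alternates exact coordinate sweeps: with row labels fixed each phage's
#' optimal module is independent of the other phages (and vice versa), so a
#' full sweep is a strict coordinate ascent. When no single-node move
#' improves Q, an agglomerative stage repeatedly applies the single best
#' module-pair merge (steepest ascent) while Q improves. Moves that leave Q
#' unchanged are rejected, guaranteeing termination, and empty modules are
#' compacted so ids stay contiguous.
#'
#' @param mat filtered binary hosts x phages matrix.
#' @param restarts number of independent randomized initializations (>= 1).
#' @param seed master seed; restart r uses its own derived stream, so the
#'   first `r` restarts are identical whatever the total budget.
#' @param init_partition optional partition used as an extra starting point
#'   (refined by the same local search).
#' @return Object of class `modularity_result`: `q`, `partition`
#'   (`row_modules`, `col_modules`, `n_modules`), `restarts_used`,
#'   `per_restart_q`.
#' @export
optimize_modularity <- function(mat, restarts = 20, seed = 1,
                                init_partition = NULL) {
  mat <- .validate_pbim(mat)
  if (restarts < 1) stop("`restarts` must be >= 1")
  mm <- sum(mat)
  if (mm < 1) stop("matrix has no interactions")
  k <- rowSums(mat); d <- colSums(mat)
  R <- nrow(mat); C <- ncol(mat)

  starts <- vector("list", restarts)
  starts[[1]] <- seq_len(R)                       # singleton rows
  for (r in seq_len(restarts)[-1]) {
    set.seed(seed + 7919L * (r - 1L))
    nmod <- sample(seq_len(R), 1)
    starts[[r]] <- sample(seq_len(nmod), R, replace = TRUE)
  }
  if (!is.null(init_partition)) {
    starts[[length(starts) + 1L]] <- list(
      g = .module_vector(init_partition$row_modules, rownames(mat), "row"),
      h = .module_vector(init_partition$col_modules, colnames(mat), "column"))
  }

  best_q <- -Inf; best <- NULL
  per_restart <- numeric(length(starts))
  for (r in seq_along(starts)) {
    st <- starts[[r]]
    if (is.list(st)) {
      res <- .lpa_refine(mat, k, d, mm, st$g, st$h)
    } else {
      h0 <- .assign_side(t(mat), d, k, mm, st, max(st) + seq_len(C))
      res <- .lpa_refine(mat, k, d, mm, st, h0)
    }
    per_restart[r] <- res$q
    if (res$q > best_q + 1e-12) { best_q <- res$q; best <- res }
  }

  # compact ids to 1..n_modules, numbered by first appearance (rows then cols)
  ids <- unique(c(best$g, best$h))
  g <- match(best$g, ids); h <- match(best$h, ids)
  partition <- list(row_modules = stats::setNames(g, rownames(mat)),
                    col_modules = stats::setNames(h, colnames(mat)),
                    n_modules = length(ids))
  q_exact <- barber_q(mat, partition)
  structure(list(q = q_exact, partition = partition,
                 restarts_used = length(starts), per_restart_q = per_restart),
            class = "modularity_result")
}

# one local-search run: alternate exact sweeps, then steepest-ascent merges
.lpa_refine <- function(mat, k, d, mm, g, h, tol = 1e-12, max_iter = 200) {
  q <- .q_fast(mat, k, d, mm, g, h)
  for (it in seq_len(max_iter)) {
    h <- .assign_side(t(mat), d, k, mm, g, max(c(g, h)) + seq_along(h))
    g <- .assign_side(mat, k, d, mm, h, max(c(g, h)) + seq_along(g))
    q_new <- .q_fast(mat, k, d, mm, g, h)
    if (q_new <= q + tol) { q <- max(q, q_new); break }
    q <- q_new
  }
  # agglomerative stage
  repeat {
    ids <- unique(c(g, h))
    L <- length(ids)
    if (L < 2) break
    gi <- match(g, ids); hi <- match(h, ids)
    Ig <- matrix(0, length(gi), L); Ig[cbind(seq_along(gi), gi)] <- 1
    Ih <- matrix(0, length(hi), L); Ih[cbind(seq_along(hi), hi)] <- 1
    B <- t(Ig) %*% mat %*% Ih                     # ones between rows(a), cols(b)
    K <- as.vector(t(Ig) %*% k); D <- as.vector(t(Ih) %*% d)
    dq <- (B + t(B) - (outer(K, D) + outer(D, K)) / mm) / mm
    diag(dq) <- -Inf
    dq[lower.tri(dq)] <- -Inf
    mx <- max(dq)
    if (mx <= tol) break
    ab <- which(dq == mx, arr.ind = TRUE)[1, ]
    keep <- ids[ab[1]]; drop <- ids[ab[2]]
    g[g == drop] <- keep; h[h == drop] <- keep
    q <- q + mx
  }
  list(g = g, h = h, q = .q_fast(mat, k, d, mm, g, h))
}

# exact optimal assignment of one side's nodes given the other side's labels.
# x: nodes x items matrix (rows = nodes being assigned), deg: node degrees,
# odeg: item degrees, other: item labels, fresh: singleton labels per node.
.assign_side <- function(x, deg, odeg, mm, other, fresh) {
  labs <- sort(unique(other))
  ind <- matrix(0, length(other), length(labs))
  ind[cbind(seq_along(other), match(other, labs))] <- 1
  E <- x %*% ind                                  # nodes x modules ones
  Dc <- as.vector(crossprod(ind, odeg))
  S <- E - outer(deg, Dc) / mm                    # gain of joining each module
  best <- max.col(S, ties.method = "first")
  gain <- S[cbind(seq_len(nrow(S)), best)]
  out <- labs[best]
  out[gain <= 0] <- fresh[gain <= 0]              # better off alone
  as.integer(out)
}

.q_fast <- function(mat, k, d, mm, g, h) {
  q <- 0
  for (c in intersect(unique(g), unique(h))) {
    rs <- g == c; cs <- h == c
    q <- q + sum(mat[rs, cs]) - sum(k[rs]) * sum(d[cs]) / mm
  }
  q / mm
}

#' @export
print.modularity_result <- function(x, ...) {
  cat(sprintf("Barber Q = %.4f (%d modules, best of %d restart(s))\n",
              x$q, x$partition$n_modules, x$restarts_used))
  invisible(x)
}

#' Export a partition as a node/module table
#'
#' @param partition a partition as returned in a `modularity_result`.
#' @param file optional CSV path.
#' @return data.frame with `node_id`, `node_type` ("host"/"phage"),
#'   `module_id`.
#' @export
partition_table <- function(partition, file = NULL) {
  df <- rbind(
    data.frame(node_id = names(partition$row_modules), node_type = "host",
               module_id = unname(partition$row_modules)),
    data.frame(node_id = names(partition$col_modules), node_type = "phage",
               module_id = unname(partition$col_modules)))
  if (!is.null(file)) utils::write.csv(df, file, row.names = FALSE)
  df
}
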