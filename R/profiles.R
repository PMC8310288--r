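#' Jaccard similarity between two target sets
#'
#' @param a,b vectors interpreted as sets (e.g. the hosts two phages infect).
#' @return |a n b| / |a u b|, in \[0, 1\]. Undefined (error) when both sets
#'   are empty; zero-degree entities must be filtered upstream.
#' @export
jaccard_similarity <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (length(a) == 0 && length(b) == 0)
    stop("undefined Jaccard on two empty sets")
  length(intersect(a, b)) / length(union(a, b))
}

#' Pairwise Jaccard distances over an infection matrix
#'
#' Each phage is described by the set of hosts it infects (its infection
#' profile), each host by the set of phages infecting it; distance between
#' two entities is 1 - Jaccard similarity of their sets.
#'
#' @param mat filtered binary hosts x phages matrix.
#' @param axis `"phages"` (compare columns) or `"hosts"` (compare rows).
#' @return Symmetric distance matrix with zero diagonal and a `kind`
#'   attribute `"jaccard"`.
#' @export
pairwise_jaccard <- function(mat, axis = c("phages", "hosts")) {
  axis <- match.arg(axis)
  mat <- .validate_pbim(mat)
  x <- if (axis == "phages") t(mat) else mat   # entities in rows
  deg <- rowSums(x)
  if (any(deg == 0))
    stop(sprintf("zero-degree %s: %s", axis,
                 paste(rownames(x)[deg == 0], collapse = ", ")))
  inter <- tcrossprod(x)
  un <- outer(deg, deg, "+") - inter
  d <- 1 - inter / un
  diag(d) <- 0
  attr(d, "kind") <- "jaccard"
  d
}

#' Complete-linkage agglomerative clustering
#'
#' Agglomerates entities by the maximum inter-cluster distance rule. Among
#' pairs tied at the minimum distance, the pair whose (alphabetically
#' smallest) representative labels sort lexicographically first is merged,
#' making the tree fully deterministic. The tree is cut to exactly `k`
#' clusters; ids 1..k are numbered by first appearance in label order.
#'
#' @param d symmetric distance matrix with labelled rows/columns (e.g. from
#'   [pairwise_jaccard()]).
#' @param k number of clusters, `1 <= k <= n`.
#' @return Object of class `pbin_clust`: `labels`, `cluster` (named integer
#'   vector of ids 1..k), `k`, and the merge history `merge` / `height`
#'   (hclust convention: negative entries index leaves).
#' @export
hclust_complete <- function(d, k) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  labels <- rownames(d) %||% as.character(seq_len(nrow(d)))
  n <- length(labels)
  if (!is.numeric(k) || k <= 0) stop("`k` must be a positive integer")
  k <- as.integer(k)
  if (k > n) stop("`k` exceeds the number of labels")

  # active clusters: leaf index sets; representative = min label (sorted)
  members <- as.list(seq_len(n))
  node_id <- as.list(-seq_len(n))          # hclust merge coding
  reps <- labels
  D <- d
  diag(D) <- Inf
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  merge_state <- vector("list", n - 1)     # membership snapshot per step
  active <- seq_len(n)
  for (step in seq_len(n - 1)) {
    sub <- D[active, active, drop = FALSE]
    mn <- min(sub)
    idx <- which(sub == mn, arr.ind = TRUE)
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    # lexicographic tie-break on sorted representative label pairs
    keys <- apply(idx, 1, function(ij) {
      r <- sort(c(reps[active[ij[1]]], reps[active[ij[2]]]))
      paste(r, collapse = "\r")
    })
    pick <- idx[order(keys)[1], ]
    a <- active[pick[1]]; b <- active[pick[2]]
    merge[step, ] <- sort(c(node_id[[a]], node_id[[b]]))
    height[step] <- mn
    # complete linkage: distance to merged cluster = max of the two
    newd <- pmax(D[a, ], D[b, ])
    D[a, ] <- newd; D[, a] <- newd
    D[a, a] <- Inf
    members[[a]] <- c(members[[a]], members[[b]])
    reps[a] <- min(reps[a], reps[b])
    node_id[[a]] <- step
    active <- setdiff(active, b)
    merge_state[[step]] <- members[active]
  }
  # cut to k clusters = state after n-k merges
  state <- if (k == n) as.list(seq_len(n)) else merge_state[[n - k]]
  cl <- integer(n)
  for (i in seq_along(state)) cl[state[[i]]] <- i
  # renumber by first appearance in label order
  cl <- match(cl, unique(cl))
  names(cl) <- labels
  structure(list(labels = labels, cluster = cl, k = k,
                 merge = merge, height = height),
            class = "pbin_clust")
}

#' Export a linkage tree as a Newick string
#'
#' Branch lengths are differences in merge height (leaves at height 0), so
#' the dendrogram is ultrametric.
#'
#' @param clust a [hclust_complete()] result.
#' @param file optional path; when given the tree is written there.
#' @return Newick string, invisibly when `file` is given.
#' @export
linkage_newick <- function(clust, file = NULL) {
  stopifnot(inherits(clust, "pbin_clust"))
  h <- clust$height
  lab <- gsub("[,();: ]", "_", clust$labels)
  build <- function(node, parent_h) {
    if (node < 0)
      return(sprintf("%s:%g", lab[-node], parent_h))
    kids <- clust$merge[node, ]
    sprintf("(%s,%s):%g",
            build(kids[1], h[node]), build(kids[2], h[node]),
            parent_h - h[node])
  }
  top <- nrow(clust$merge)
  nwk <- if (top == 0) sprintf("(%s:0);", lab[1]) else {
    kids <- clust$merge[top, ]
    sprintf("(%s,%s);", build(kids[1], h[top]), build(kids[2], h[top]))
  }
  if (!is.null(file)) { writeLines(nwk, file); return(invisible(nwk)) }
  nwk
}

#' Principal coordinates (classical metric scaling) of a distance matrix
#'
#' Double-centers the squared distances and eigendecomposes the Gram matrix.
#' Negative eigenvalues (non-Euclidean distances such as Jaccard on some
#' configurations) are clamped to zero and excluded from the
#' variance-explained denominator.
#'
#' @param d symmetric distance matrix.
#' @param dims number of axes to return.
#' @return List `labels`, `coordinates` (n x dims, zero-padded past the last
#'   positive eigenvalue), `variance_explained` (fraction per axis, ordered
#'   decreasing).
#' @export
principal_coordinates <- function(d, dims = 2) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  n <- nrow(d)
  if (dims < 1) stop("`dims` must be >= 1")
  if (dims > n) stop("`dims` exceeds the number of labels")
  labels <- rownames(d) %||% as.character(seq_len(n))
  k <- min(dims, n - 1)
  fit <- suppressWarnings(stats::cmdscale(stats::as.dist(d), k = max(k, 1), eig = TRUE))
  eig <- pmax(fit$eig, 0)
  tot <- sum(eig)
  coords <- matrix(0, n, dims, dimnames = list(labels, paste0("Axis", seq_len(dims))))
  if (tot > 0 && !is.null(fit$points) && ncol(fit$points) > 0) {
    got <- min(ncol(fit$points), dims)
    coords[, seq_len(got)] <- fit$points[, seq_len(got)]
  }
  ve <- if (tot > 0) (eig / tot)[seq_len(dims)] else rep(0, dims)
  ve[is.na(ve)] <- 0
  list(labels = labels, coordinates = coords, variance_explained = ve)
}

.round_half_up <- function(x) floor(x + 0.5)

#' Group-level target-range summary
#'
#' Summarizes phage target ranges (column degrees, i.e. infected host
#' counts) per group: mean, min-max range, and the mean as a percent of the
#' total strains tested. Presentation values (`reported_mean`, `percent`)
#' round half-up to integers; raw means are retained. For the tiny group
#' sizes typical of phage panels the min-max range is reported instead of a
#' parametric confidence interval.
#'
#' @param degrees named vector of infected-host counts per phage, or a
#'   filtered infection matrix (column degrees are then used).
#' @param grouping named vector/list mapping every phage label to a group.
#' @param total_tested denominator for percent-of-total (strains screened).
#' @return data.frame, one row per group: `group`, `n_phages`, `members`,
#'   `mean_degree`, `min_degree`, `max_degree`, `reported_mean`, `percent`.
#' @export
group_target_summary <- function(degrees, grouping, total_tested) {
  if (is.matrix(degrees)) degrees <- colSums(.validate_pbim(degrees))
  grouping <- unlist(grouping)
  miss <- setdiff(names(degrees), names(grouping))
  if (length(miss)) stop(sprintf("unmapped phage label(s): %s", paste(miss, collapse = ", ")))
  g <- grouping[names(degrees)]
  out <- do.call(rbind, lapply(split(names(degrees), g), function(m) {
    v <- degrees[m]
    data.frame(group = unname(g[m[1]]), n_phages = length(v),
               members = paste(m, collapse = ";"),
               mean_degree = mean(v), min_degree = min(v), max_degree = max(v),
               reported_mean = .round_half_up(mean(v)),
               percent = .round_half_up(100 * mean(v) / total_tested))
  }))
  rownames(out) <- NULL
  out[order(out$group), , drop = FALSE]
}

#' Host coverage across phage-cluster combinations
#'
#' For every non-empty subset of phage clusters, counts the hosts infected
#' by at least one phage of *each* cluster in the subset. The row for the
#' full cluster set is the Venn-diagram core (hosts covered by every
#' cluster).
#'
#' @param mat filtered binary hosts x phages matrix.
#' @param phage_clusters named vector mapping every phage label to a cluster.
#' @return data.frame with `clusters` (ids joined by "+"), `n_clusters`,
#'   `hosts` (count).
#' @export
cluster_overlap_counts <- function(mat, phage_clusters) {
  mat <- .validate_pbim(mat)
  phage_clusters <- unlist(phage_clusters)
  miss <- setdiff(colnames(mat), names(phage_clusters))
  if (length(miss)) stop(sprintf("phage(s) not in any cluster: %s", paste(miss, collapse = ", ")))
  ids <- sort(unique(phage_clusters[colnames(mat)]))
  # hosts x clusters coverage indicator
  cov <- vapply(ids, function(cid) {
    rowSums(mat[, phage_clusters[colnames(mat)] == cid, drop = FALSE]) > 0
  }, logical(nrow(mat)))
  cov <- matrix(cov, nrow = nrow(mat))
  rows <- list()
  for (size in seq_along(ids)) {
    for (sub in as.data.frame(combn(seq_along(ids), size))) {
      rows[[length(rows) + 1L]] <- data.frame(
        clusters = paste(ids[sub], collapse = "+"),
        n_clusters = size,
        hosts = sum(rowSums(cov[, sub, drop = FALSE]) == size))
    }
  }
  do.call(rbind, rows)
}

#' Infected-host composition per phage cluster
#'
#' Cross-tabulates infected hosts by phage cluster and a host attribute
#' (e.g. serovar): `counts[g, c]` is the number of hosts in category `c`
#' infected by at least one phage of cluster `g`. `richness[g]` is the
#' number of categories with at least one infected host.
#'
#' @param mat filtered binary hosts x phages matrix.
#' @param host_attribute named vector mapping every host to a category.
#' @param phage_grouping named vector mapping every phage to a cluster.
#' @return List with `counts` (clusters x categories matrix) and `richness`.
#' @export
profile_composition <- function(mat, host_attribute, phage_grouping) {
  mat <- .validate_pbim(mat)
  host_attribute <- unlist(host_attribute)
  phage_grouping <- unlist(phage_grouping)
  if (length(setdiff(rownames(mat), names(host_attribute))))
    stop("every host needs an attribute")
  if (length(setdiff(colnames(mat), names(phage_grouping))))
    stop("every phage needs a group")
  gs <- sort(unique(phage_grouping[colnames(mat)]))
  cats <- sort(unique(host_attribute[rownames(mat)]))
  counts <- matrix(0L, length(gs), length(cats), dimnames = list(gs, cats))
  for (gi in seq_along(gs)) {
    hit <- rowSums(mat[, phage_grouping[colnames(mat)] == gs[gi], drop = FALSE]) > 0
    tb <- table(host_attribute[rownames(mat)][hit])
    counts[gi, names(tb)] <- as.integer(tb)
  }
  list(counts = counts, richness = rowSums(counts > 0))
}
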