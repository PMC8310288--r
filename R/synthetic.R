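# Synthetic phage-bacteria infection matrices reproducing the four
# canonical cross-infection structures (one-to-one, modular, nested,
# random) plus a Salmonella-scale emulator with exact literature column
# margins, so every pipeline stage is testable without external data.

.name_matrix <- function(mat, prefix_r = "H", prefix_c = "P") {
  dimnames(mat) <- list(sprintf("%s%03d", prefix_r, seq_len(nrow(mat))),
                        sprintf("%s%02d", prefix_c, seq_len(ncol(mat))))
  storage.mode(mat) <- "integer"
  mat
}

#' One-to-one (diagonal) infection matrix
#'
#' Every phage infects exactly one host and every host is infected by
#' exactly one phage: a random n x n permutation matrix, the signature of
#' extreme specialization.
#'
#' @param n matrix dimension (>= 1).
#' @param seed RNG seed.
#' @return Binary n x n matrix with unit margins.
#' @export
gen_one_to_one <- function(n, seed = 1) {
  if (n < 1) stop("`n` must be >= 1")
  set.seed(seed)
  mat <- matrix(0L, n, n)
  mat[cbind(seq_len(n), sample.int(n))] <- 1L
  .name_matrix(mat)
}

#' Nested infection matrix
#'
#' Draws per-host quotas (columns 1..q_i are infected before shuffling), so
#' at `noise = 0` the host one-sets form a containment chain — the nested
#' archetype. Quotas are spaced to make row fills distinct wherever
#' possible (tied fills annihilate NODF by the strict-decreasing-fill
#' convention) and scaled so total fill approximates the target. Each cell
#' is then flipped independently with probability `noise`; at `noise = 0.5`
#' all structure is gone.
#'
#' @param rows,cols dimensions.
#' @param fill target fill fraction in (0, 1).
#' @param noise per-cell flip probability in \[0, 0.5\].
#' @param seed RNG seed.
#' @return Binary matrix (rows and columns in randomized order).
#' @export
gen_nested <- function(rows, cols, fill, noise = 0, seed = 1) {
  if (fill <= 0 || fill >= 1) stop("`fill` must be in (0, 1)")
  set.seed(seed)
  q <- .nested_quotas(rows, cols, fill)
  mat <- outer(q, seq_len(cols), ">=") * 1L
  if (noise > 0) {
    flip <- matrix(runif(rows * cols) < noise, rows, cols)
    mat <- abs(mat - flip * 1L)
  }
  mat <- mat[sample.int(rows), sample.int(cols), drop = FALSE]
  .name_matrix(mat)
}

# distinct-where-possible integer quotas in [1, cols] summing ~ fill*rows*cols
.nested_quotas <- function(rows, cols, fill) {
  target <- round(fill * rows * cols)
  q <- round(seq(cols, 1, length.out = rows) * 2 * fill)
  q <- pmax(1L, pmin(cols, as.integer(q)))
  if (rows <= cols) {                     # enforce strictly decreasing
    for (i in seq_len(rows)[-1]) if (q[i] >= q[i - 1]) q[i] <- q[i - 1] - 1L
    if (q[rows] < 1) {                    # ran below 1: push back up
      q[rows] <- 1L
      for (i in rev(seq_len(rows - 1))) if (q[i] <= q[i + 1]) q[i] <- q[i + 1] + 1L
      q <- pmin(q, cols)
    }
  }
  # nudge toward the target total, preserving ordering/distinctness
  for (iter in seq_len(10 * rows)) {
    diff <- target - sum(q)
    if (diff == 0) break
    if (diff > 0) {
      up <- which(q < c(cols, q[-length(q)] - (rows <= cols)))
      if (!length(up)) break
      q[up[1]] <- q[up[1]] + 1L
    } else {
      dn <- which(q > c(q[-1] + (rows <= cols), 1))
      if (!length(dn)) break
      q[dn[length(dn)]] <- q[dn[length(dn)]] - 1L
    }
  }
  q
}

#' Modular (block) infection matrix
#'
#' Hosts and phages are partitioned near-evenly into `k_modules` blocks;
#' within-block cells are Bernoulli(`p_in`), between-block cells
#' Bernoulli(`p_out`). At `p_in = 1, p_out = 0` the matrix is a union of
#' complete bipartite blocks with planted-partition modularity (k-1)/k.
#'
#' @param rows,cols dimensions.
#' @param k_modules number of blocks (<= min(rows, cols)).
#' @param p_in,p_out within/between-block interaction probabilities
#'   (`p_in >= p_out`).
#' @param seed RNG seed.
#' @return List `matrix`, `row_modules`, `col_modules` (the planted
#'   partition, usable directly with [barber_q()]).
#' @export
gen_modular <- function(rows, cols, k_modules, p_in, p_out, seed = 1) {
  if (k_modules > min(rows, cols)) stop("`k_modules` exceeds min(rows, cols)")
  if (p_in < p_out) stop("`p_in` must be >= `p_out` for a modular structure")
  set.seed(seed)
  rm <- sort(rep_len(seq_len(k_modules), rows))
  cm <- sort(rep_len(seq_len(k_modules), cols))
  pr <- ifelse(outer(rm, cm, "=="), p_in, p_out)
  mat <- matrix(rbinom(rows * cols, 1L, as.vector(pr)), rows, cols)
  mat <- .name_matrix(mat)
  list(matrix = mat,
       row_modules = stats::setNames(rm, rownames(mat)),
       col_modules = stats::setNames(cm, colnames(mat)))
}

#' Random (unstructured) infection matrix
#'
#' i.i.d. Bernoulli(`fill`) cells; all-zero host rows are redrawn,
#' mirroring the removal of hosts showing no lysis, so the output is a
#' valid filtered matrix.
#'
#' @param rows,cols dimensions.
#' @param fill interaction probability in (0, 1\].
#' @param seed RNG seed.
#' @return Binary matrix with no all-zero rows.
#' @export
gen_random <- function(rows, cols, fill, seed = 1) {
  if (fill <= 0 || fill > 1) stop("`fill` must be in (0, 1]")
  set.seed(seed)
  mat <- matrix(rbinom(rows * cols, 1L, fill), rows, cols)
  for (i in which(rowSums(mat) == 0))
    while (sum(mat[i, ] <- rbinom(cols, 1L, fill)) == 0) NULL
  .name_matrix(mat)
}

#' Salmonella phage panel metadata
#'
#' The characteristics of the 13 phage clones of the study system this
#' package emulates: environmental source, taxonomy (family, genus-level
#' assignment, phylogenetic clade), infection-profile cluster, and target
#' range (number of infected host strains out of 141 screened).
#'
#' @return data.frame with columns `source`, `name`, `study_id`, `tax_id`,
#'   `family`, `genus`, `clade`, `cluster`, `infected_hosts`.
#' @export
salmonella_phage_metadata <- function() {
  data.frame(
    source = c(rep("Mtkari river water", 8), rep("Black sea water", 3),
               "Raw cow milk", "Tbilisi sewage water"),
    name = c("Salmonella phage GEC_vB_B1", "Salmonella phage GEC_vB_B3",
             "Salmonella phage GEC_vB_HIL", "Salmonella phage GEC_vB_7A",
             "Salmonella phage GEC_vB_TR", "Salmonella phage GEC_vB_N5",
             "Salmonella phage GEC_vB_N8", "Salmonella phage GEC_vB_N3",
             "Salmonella phage GEC_vB_BS", "Salmonella phage GEC_vB_M4",
             "Salmonella phage GEC_vB_M5", "Salmonella phage GEC_vB_NS7",
             "Salmonella phage GCE_vB_MG"),
    study_id = c("GE_vB_B1", "GE_vB_B3", "GE_vB_HIL", "GE_vB_7A", "GE_vB_TR",
                 "GE_vB_N5", "GE_vB_N8", "GEC_vB_N3", "GE_vB_BS", "GE_vB_M4",
                 "GE_vB_M5", "GE_vB_NS7", "GE_vB_MG"),
    tax_id = c(2108164L, 2108165L, 2108167L, 2108163L, 2108174L, 2108171L,
               2108172L, 2777377L, 2108166L, 2108168L, 2108169L, 2108173L,
               2108170L),
    family = c("Myoviridae", "Myoviridae", "Siphoviridae", "Myoviridae",
               "Podoviridae", "Demerecviridae", "Demerecviridae",
               "Demerecviridae", "Myoviridae", "Siphoviridae", "Siphoviridae",
               "Myoviridae", "Myoviridae"),
    genus = c("Unclassified Ounavirinae", "Unclassified Ounavirinae",
              "Unclassified Jerseyvirus", "Unclassified Felixounavirus",
              "Unclassified Lederbergvirus", "Unclassified Tequintavirus",
              "Unclassified Tequintavirus", "Unclassified Tequintavirus",
              "Unclassified Ounavirinae", "Unclassified Jerseyvirus",
              "Unclassified Jerseyvirus", "Unclassified Ounavirinae",
              "Unclassified Seunavirus"),
    clade = c(1L, 1L, 4L, 2L, 5L, 3L, 3L, 3L, 1L, 4L, 4L, 1L, 2L),
    cluster = c(1L, 1L, 1L, 2L, 2L, 3L, 3L, 3L, 1L, 4L, 4L, 1L, 2L),
    infected_hosts = c(111L, 106L, 82L, 52L, 57L, 76L, 76L, 96L, 107L, 33L,
                       52L, 97L, 56L))
}

#' Salmonella host-strain serovar frequencies
#'
#' Serovar composition of the 141 screened strains (19 named serovars plus
#' 9 of unknown serotype).
#'
#' @return Named integer vector of strain counts summing to 141.
#' @export
salmonella_serovar_counts <- function() {
  c(Typhimurium = 40L, Dublin = 22L, Enteritidis = 21L, Anatum = 10L,
    Infantis = 8L, Newport = 7L, Bredeney = 5L, Derbey = 4L, Braenderup = 2L,
    Germinara = 2L, Uganda = 2L, Senftenberg = 2L, Kentucky = 1L, Java = 1L,
    Branderburg = 1L, Bareilly = 1L, Virchow = 1L, Goldcost = 1L, Poona = 1L,
    unknown = 9L)
}

.salmonella_origin_counts <- function() {
  c(bovine = 36L, porcine = 34L, poultry = 17L, duck = 1L, human = 27L,
    food = 6L, terpene = 1L, unknown = 19L)
}

#' Salmonella-scale synthetic infection matrix
#'
#' Emulates the filtered 133-host x 13-phage study matrix: column sums
#' exactly equal the published target-range vector (111, 106, 82, 52, 57,
#' 76, 76, 96, 107, 33, 52, 97, 56; 1001 interactions in total), ones are
#' placed with a graded host-susceptibility weighting that induces the
#' nested tendency of real cross-infection panels, and any all-zero host
#' row is repaired by moving an interaction from a multi-infection host in
#' the same column (column margins stay exact). Host serovars and isolate
#' origins are drawn from the published frequency lists; row margins are
#' therefore distributional, not exact.
#'
#' @param seed RNG seed.
#' @param susceptibility_gradient log-range of the host susceptibility
#'   weights; 4 (about a 55-fold most/least susceptible ratio) gives
#'   realistically strong nesting.
#' @return List `matrix` (133 x 13), `phage_metadata`
#'   ([salmonella_phage_metadata()]), `host_metadata` (data.frame
#'   `host_id`, `serovar`, `origin`).
#' @export
gen_salmonella_like <- function(seed = 1, susceptibility_gradient = 4) {
  set.seed(seed)
  meta <- salmonella_phage_metadata()
  degrees <- meta$infected_hosts
  n_total <- 141L; n_keep <- 133L
  all_ids <- sprintf("T%03d", seq_len(n_total))
  keep <- sort(sample(all_ids, n_keep))
  w <- exp(susceptibility_gradient * seq(0, 1, length.out = n_keep))
  w <- sample(w)                                   # susceptibility not tied to id order
  mat <- matrix(0L, n_keep, length(degrees),
                dimnames = list(keep, meta$study_id))
  for (j in order(-degrees))
    mat[sample.int(n_keep, degrees[j], prob = w), j] <- 1L
  # repair all-zero hosts without touching column margins
  for (i in which(rowSums(mat) == 0)) {
    donors <- which(mat == 1L & rowSums(mat) >= 2, arr.ind = TRUE)
    pick <- donors[sample.int(nrow(donors), 1), ]
    mat[pick[1], pick[2]] <- 0L
    mat[i, pick[2]] <- 1L
  }
  serovars <- sample(rep(names(salmonella_serovar_counts()),
                         salmonella_serovar_counts()))
  origins <- sample(rep(names(.salmonella_origin_counts()),
                        .salmonella_origin_counts()))
  host_meta <- data.frame(host_id = keep,
                          serovar = serovars[match(keep, all_ids)],
                          origin = origins[match(keep, all_ids)])
  attr(mat, "provenance") <- "synthetic Salmonella-scale matrix (exact published column margins)"
  list(matrix = mat, phage_metadata = meta, host_metadata = host_meta)
}
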