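test_that("Jaccard similarity follows the set definition", {
  expect_equal(jaccard_similarity(c("h1", "h2", "h3"), c("h2", "h3", "h4")), 0.5)
  expect_equal(jaccard_similarity(letters[1:3], letters[1:3]), 1)
  expect_equal(jaccard_similarity(letters[1:2], letters[3:4]), 0)
  expect_error(jaccard_similarity(character(0), character(0)), "two empty sets")
})

test_that("pairwise Jaccard distances are a metric with zero diagonal", {
  m <- as_pbim(cbind(a = c(1L, 1L, 0L), b = c(1L, 1L, 0L), c = c(0L, 1L, 1L)))
  d <- pairwise_jaccard(m, "phages")
  expect_equal(d["a", "b"], 0)          # identical profiles
  expect_equal(diag(d), setNames(rep(0, 3), colnames(m)))
  expect_equal(d, t(d))

  disj <- as_pbim(diag(2))
  expect_equal(pairwise_jaccard(disj, "phages")[1, 2], 1)

  # triangle inequality on random matrices, both axes
  withr::with_seed(21, {
    for (rep in 1:20) {
      mm <- random_pbim(7, 5, 0.6)
      mm[rowSums(mm) == 0, 1] <- 1L; mm[1, colSums(mm) == 0] <- 1L
      for (axis in c("phages", "hosts")) {
        dd <- pairwise_jaccard(mm, axis)
        n <- nrow(dd)
        for (i in 1:n) for (j in 1:n) for (k in 1:n)
          expect_lte(dd[i, j], dd[i, k] + dd[k, j] + 1e-12)
      }
    }
  })
})

test_that("zero-degree entities are refused by name", {
  m <- as_pbim(cbind(a = c(1L, 1L), b = c(0L, 0L)))
  expect_error(pairwise_jaccard(m, "phages"), "zero-degree phages: b")
})

test_that("complete linkage merges by maximum distance with deterministic cuts", {
  d <- matrix(c(0, .1, .9, .1, 0, .8, .9, .8, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  cl <- hclust_complete(d, 2)
  expect_equal(cl$cluster[["A"]], cl$cluster[["B"]])
  expect_false(cl$cluster[["A"]] == cl$cluster[["C"]])

  expect_equal(unname(hclust_complete(d, 3)$cluster), 1:3)   # k = n
  expect_equal(unname(hclust_complete(d, 1)$cluster), rep(1L, 3))
  expect_error(hclust_complete(d, 0), "positive")
  expect_error(hclust_complete(d, 4), "exceeds")
})

test_that("successive cuts differ by exactly one merge", {
  withr::with_seed(31, {
    x <- matrix(rnorm(24), 8)
    d <- as.matrix(dist(x)); dimnames(d) <- list(letters[1:8], letters[1:8])
  })
  for (k in 2:7) {
    a <- hclust_complete(d, k)$cluster
    b <- hclust_complete(d, k + 1)$cluster
    # b refines a: every b-cluster sits inside one a-cluster, sizes differ by 1
    expect_equal(length(unique(paste(a, b))), k + 1)
  }
})

test_that("cluster memberships agree with stats::hclust on tie-free distances", {
  withr::with_seed(41, {
    for (rep in 1:10) {
      n <- sample(5:9, 1)
      d <- as.matrix(dist(matrix(rnorm(n * 3), n)))
      dimnames(d) <- list(letters[1:n], letters[1:n])
      k <- sample(2:(n - 1), 1)
      ours <- hclust_complete(d, k)$cluster
      ref <- stats::cutree(stats::hclust(stats::as.dist(d), "complete"), k)
      tab <- table(ours, ref[names(ours)])
      expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
    }
  })
})

test_that("linkage trees export as valid ultrametric Newick", {
  skip_if_not_installed("ape")
  withr::with_seed(13, m <- random_pbim(8, 5, 0.6))
  m[rowSums(m) == 0, 1] <- 1L; m[1, colSums(m) == 0] <- 1L
  cl <- hclust_complete(pairwise_jaccard(m, "hosts"), 3)
  tree <- ape::read.tree(text = linkage_newick(cl))
  expect_setequal(tree$tip.label, rownames(m))
})

test_that("principal coordinates recover simple geometries", {
  two <- matrix(c(0, 1, 1, 0), 2, dimnames = list(c("x", "y"), c("x", "y")))
  e <- principal_coordinates(two, 1)
  expect_equal(abs(diff(unname(e$coordinates[, 1]))), 1)
  expect_equal(e$variance_explained, 1)

  same <- matrix(0, 3, 3)
  expect_equal(max(abs(principal_coordinates(same, 2)$coordinates)), 0)

  simplex <- matrix(1, 4, 4) - diag(4)
  expect_equal(principal_coordinates(simplex, 3)$variance_explained,
               rep(1 / 3, 3))

  # Euclidean-embeddable distances are reproduced exactly
  withr::with_seed(17, x <- matrix(rnorm(15), 5))
  d <- as.matrix(dist(x))
  e2 <- principal_coordinates(d, 3)
  expect_equal(as.matrix(dist(e2$coordinates)), d, ignore_attr = TRUE)
  expect_true(all(diff(e2$variance_explained) <= 1e-12))

  expect_error(principal_coordinates(two, 3), "exceeds")
})

test_that("group target-range summaries reproduce the published panel values", {
  meta <- salmonella_phage_metadata()
  deg <- setNames(meta$infected_hosts, meta$study_id)

  by_cluster <- group_target_summary(deg, setNames(meta$cluster, meta$study_id), 141)
  expect_equal(by_cluster$mean_degree, c(100.6, 55, 82 + 2 / 3, 42.5))
  expect_equal(by_cluster$percent, c(71, 39, 59, 30))
  expect_true(all(by_cluster$mean_degree >= by_cluster$min_degree &
                  by_cluster$mean_degree <= by_cluster$max_degree))

  fam <- group_target_summary(deg, setNames(meta$family, meta$study_id), 141)
  expect_equal(fam$reported_mean[fam$group == "Myoviridae"], 88)

  single <- group_target_summary(deg["GE_vB_B1"], c(GE_vB_B1 = "solo"), 141)
  expect_equal(single$mean_degree, 111)
  expect_equal(single$min_degree, single$max_degree)
  expect_equal(single$percent, 79)

  expect_error(group_target_summary(deg, setNames(meta$cluster[-1], meta$study_id[-1]), 141),
               "unmapped")
})

test_that("summary means are invariant to host row order", {
  withr::with_seed(23, m <- random_pbim(12, 5, 0.5))
  m[rowSums(m) == 0, 1] <- 1L
  grp <- setNames(c(1, 1, 2, 2, 3), colnames(m))
  a <- group_target_summary(m, grp, 12)
  b <- group_target_summary(m[sample(nrow(m)), ], grp, 12)
  expect_equal(a, b)
})

test_that("cluster overlap counts the hosts covered by every cluster of a subset", {
  one <- as_pbim(rbind(c(1L, 0L), c(0L, 1L), c(1L, 1L)))
  all_one <- cluster_overlap_counts(one, setNames(c(1, 1), colnames(one)))
  expect_equal(all_one$hosts, nrow(one))      # single cluster: every filtered row

  ident <- as_pbim(diag(2))
  cc <- cluster_overlap_counts(ident, setNames(1:2, colnames(ident)))
  expect_equal(cc$hosts[cc$clusters == "1+2"], 0)
  expect_equal(cc$hosts[cc$clusters == "1"], 1)
})

test_that("profile composition cross-tabulates infected hosts and richness", {
  ident <- as_pbim(diag(2))
  comp <- profile_composition(ident,
                              setNames(c("X", "Y"), rownames(ident)),
                              setNames(1:2, colnames(ident)))
  expect_equal(unname(comp$counts), rbind(c(1L, 0L), c(0L, 1L)))
  expect_equal(unname(comp$richness), c(1, 1))

  m <- as_pbim(rbind(c(1L, 1L), c(1L, 0L), c(0L, 1L)))
  comp2 <- profile_composition(m, setNames(rep("only", 3), rownames(m)),
                               setNames(c(1, 2), colnames(m)))
  expect_true(all(comp2$richness == 1))
})
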