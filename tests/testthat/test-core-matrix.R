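test_that("binarization scores any lysis as infection, all-R as resistance", {
  arr <- array(NA_character_, c(3, 2, 3),
               dimnames = list(c("h1", "h2", "h3"), c("p1", "p2"),
                               c("1.0", "0.1", "0.01")))
  arr["h1", "p1", ] <- c("CL", "SCL", "R")   # lysis at two MOIs
  arr["h1", "p2", ] <- c("R", "R", "R")
  arr["h2", "p1", ] <- c("TV", NA, NA)
  arr["h2", "p2", ] <- c("OL", "R", "R")
  # h3 untested against p1; resistant to p2
  arr["h3", "p2", ] <- "R"
  m <- binarize_lysis(lysis_table(arr))
  expect_identical(m["h1", "p1"], 1L)
  expect_identical(m["h1", "p2"], 0L)
  expect_identical(m["h2", ], c(p1 = 1L, p2 = 1L))
  expect_true(is.na(m["h3", "p1"]))
  expect_identical(m["h3", "p2"], 0L)
})

test_that("unknown lysis categories are rejected with the offending cell named", {
  arr <- matrix(c("CL", "XX", "R", "R"), 2, 2,
                dimnames = list(c("h1", "h2"), c("p1", "p2")))
  expect_error(lysis_table(arr), "unknown lysis score 'XX'.*h2.*p1")
})

test_that("binarization is idempotent through the 1->CL / 0->R embedding", {
  withr::with_seed(11, m <- random_pbim(6, 4))
  arr <- ifelse(m == 1L, "CL", "R")
  expect_identical(bare(binarize_lysis(lysis_table(arr))), m)
})

test_that("filtering drops incomplete rows first, then zero rows, preserving cells", {
  m <- rbind(h1 = c(1L, 1L), h2 = c(0L, 0L), h3 = c(1L, NA))
  colnames(m) <- c("p1", "p2")
  res <- filter_matrix(m)
  expect_identical(rownames(res$matrix), "h1")
  expect_identical(res$report$dropped_incomplete, "h3")
  expect_identical(res$report$dropped_zero, "h2")
  expect_identical(res$report$retained, 1L)

  # surviving cells unchanged, column set unchanged
  withr::with_seed(3, big <- random_pbim(20, 5))
  big[2, 1] <- NA; big[7, ] <- 0L
  out <- filter_matrix(big)
  expect_identical(colnames(out$matrix), colnames(big))
  expect_identical(bare(out$matrix), big[rownames(out$matrix), ])
  expect_identical(out$report$retained,
                   nrow(big) - length(out$report$dropped_incomplete) -
                     length(out$report$dropped_zero))
})

test_that("a clean matrix passes through filtering untouched", {
  withr::with_seed(5, m <- random_pbim(8, 4))
  m[rowSums(m) == 0, 1] <- 1L
  out <- filter_matrix(m)
  expect_identical(bare(out$matrix), m)
  expect_length(out$report$dropped_incomplete, 0)
  expect_length(out$report$dropped_zero, 0)
})

test_that("the 148 -> 141 -> 133 filtering path reproduces the study arithmetic", {
  withr::with_seed(8, {
    m <- random_pbim(148, 13, fill = 0.4)
    m[rowSums(m) == 0, 1] <- 1L                       # ensure clean baseline
    incomplete <- sample(rownames(m), 7)
    m[incomplete, sample(13, 1)] <- NA
    zero <- sample(setdiff(rownames(m), incomplete), 8)
    m[zero, ] <- 0L
  })
  out <- filter_matrix(m)
  expect_identical(out$report$retained, 133L)
  expect_setequal(out$report$dropped_incomplete, incomplete)
  expect_setequal(out$report$dropped_zero, zero)
})

test_that("filtering an all-missing matrix errors rather than returning 0 rows", {
  m <- matrix(NA_integer_, 2, 2, dimnames = list(c("a", "b"), c("x", "y")))
  expect_error(filter_matrix(m), "empty matrix after filtering")
})

test_that("matrix summary reports degrees and fill consistently", {
  s <- matrix_summary(as_pbim(diag(2)))
  expect_equal(s$fill, 0.5)
  expect_equal(unname(s$row_degrees), c(1, 1))
  expect_equal(unname(s$col_degrees), c(1, 1))
  expect_equal(matrix_summary(as_pbim(matrix(1L, 3, 4)))$fill, 1)

  withr::with_seed(2, m <- random_pbim(9, 5))
  s <- matrix_summary(m)
  expect_equal(sum(s$row_degrees) / (s$n_hosts * s$n_phages), s$fill)
  expect_equal(sum(s$col_degrees) / (s$n_hosts * s$n_phages), s$fill)
})

test_that("infection-matrix CSV round-trips, lysis CSV parses phage@MOI headers", {
  withr::with_seed(4, m <- random_pbim(6, 3))
  f <- withr::local_tempfile(fileext = ".csv")
  write_infection_matrix(m, f)
  expect_identical(read_infection_matrix(f), m)

  lf <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("host_id,pA@1.0,pA@0.1,pB",
               "h1,CL,R,R",
               "h2,,,TV"), lf)
  tab <- read_lysis_table(lf)
  expect_identical(tab$phage_ids, c("pA", "pB"))
  b <- binarize_lysis(tab)
  expect_identical(b["h1", ], c(pA = 1L, pB = 0L))
  expect_true(is.na(b["h2", "pA"]))
  expect_identical(b["h2", "pB"], 1L)
})
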