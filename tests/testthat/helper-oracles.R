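# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (explicit loops, full enumeration) so they can vouch
# for the optimized implementations.

random_pbim <- function(rows, cols, fill = 0.5) {
  m <- matrix(rbinom(rows * cols, 1L, fill), rows, cols,
              dimnames = list(sprintf("h%02d", seq_len(rows)),
                              sprintf("p%02d", seq_len(cols))))
  storage.mode(m) <- "integer"
  m
}

# NODF by explicit double loop over all row and column pairs
nodf_brute <- function(m) {
  pair_sum <- function(x) {
    s <- 0
    for (i in seq_len(nrow(x) - 1)) for (j in (i + 1):nrow(x)) {
      fi <- sum(x[i, ]); fj <- sum(x[j, ])
      if (fi == fj || min(fi, fj) == 0) next
      sparse <- if (fi < fj) i else j
      other <- if (fi < fj) j else i
      s <- s + 100 * sum(x[sparse, ] == 1 & x[other, ] == 1) / sum(x[sparse, ])
    }
    s
  }
  npr <- choose(nrow(m), 2); npc <- choose(ncol(m), 2)
  (pair_sum(m) + pair_sum(t(m))) / (npr + npc)
}

# Barber Q by explicit cell loop
barber_q_brute <- function(m, g, h) {
  mm <- sum(m); k <- unname(rowSums(m)); d <- unname(colSums(m))
  q <- 0
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m)))
    if (g[i] == h[j]) q <- q + m[i, j] - k[i] * d[j] / mm
  q / mm
}

# all set partitions of n items as restricted growth strings
set_partitions <- function(n) {
  out <- list()
  recurse <- function(prefix, maxlab) {
    if (length(prefix) == n) { out[[length(out) + 1L]] <<- prefix; return() }
    for (lab in seq_len(maxlab + 1L))
      recurse(c(prefix, lab), max(maxlab, lab))
  }
  recurse(integer(0), 0L)
  out
}

# global maximum of Barber Q by exhaustive search over joint partitions
best_q_exhaustive <- function(m) {
  n <- nrow(m) + ncol(m)
  best <- -Inf
  for (p in set_partitions(n)) {
    q <- barber_q_brute(m, p[seq_len(nrow(m))], p[nrow(m) + seq_len(ncol(m))])
    if (q > best) best <- q
  }
  best
}

# staircase matrix: row r has ones in columns 1..r
staircase <- function(n) {
  m <- outer(seq_len(n), seq_len(n), ">=") * 1L
  dimnames(m) <- list(sprintf("h%02d", 1:n), sprintf("p%02d", 1:n))
  m
}

# drop the provenance note for value-only comparisons
bare <- function(m) { attr(m, "provenance") <- NULL; m }

as_pbim <- function(m) {
  if (is.null(rownames(m))) rownames(m) <- sprintf("h%02d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("p%02d", seq_len(ncol(m)))
  storage.mode(m) <- "integer"
  m
}

# exact placement probabilities of the sequential weighted draw used by
# sim8: probability that each cell remains empty when n1 of the cells are
# drawn without replacement with the given weights
empty_cell_probs <- function(w, n1) {
  stopifnot(n1 == length(w) - 1)   # enumeration for the one-empty-cell case
  cells <- seq_along(w)
  pr <- numeric(length(w))
  perms <- NULL
  recurse <- function(drawn, p) {
    if (length(drawn) == n1) {
      left <- setdiff(cells, drawn)
      pr[left] <<- pr[left] + p
      return()
    }
    left <- setdiff(cells, drawn)
    for (cell in left)
      recurse(c(drawn, cell), p * w[cell] / sum(w[left]))
  }
  recurse(integer(0), 1)
  pr
}
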