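# per-site calling rule and coverage eligibility

test_that("call_site applies the depth and agreement thresholds exactly", {
  expect_identical(call_site(c(9, 0, 0, 0)), "N")     # depth below 10
  expect_identical(call_site(c(10, 0, 0, 0)), "A")    # lower bound inclusive
  expect_identical(call_site(c(80, 20, 0, 0)), "A")   # 80% >= 70%
  expect_identical(call_site(c(70, 30, 0, 0)), "A")   # exact 70% passes
  expect_identical(call_site(c(65, 35, 0, 0)), "N")   # below 70%
  expect_identical(call_site(c(520, 0, 0, 0)), "N")   # depth >= 500
  expect_identical(call_site(c(499, 0, 0, 0)), "A")   # upper bound exclusive
  expect_identical(call_site(c(0, 0, 0, 0)), "N")     # no evidence
  expect_error(call_site(c(-1, 0, 0, 0)), "non-negative")
})

test_that("call_site is monotone in agreement at fixed depth", {
  for (d in c(10, 50, 200)) {
    prev_called <- FALSE
    for (maj in seq(ceiling(d / 2), d)) {
      call <- call_site(c(maj, d - maj, 0, 0))
      called <- call != "N"
      # once callable, increasing the majority count never flips back to N
      expect_false(prev_called && !called)
      prev_called <- called
    }
  }
})

test_that("call_matrix equals site-by-site rule application", {
  set.seed(14)
  strains <- sprintf("s%02d", 1:10)
  n_rows <- 700L
  tab <- data.frame(
    strain = sample(strains, n_rows, TRUE),
    pos0 = sample(0:99, n_rows, TRUE))
  tab <- tab[!duplicated(tab[, c("strain", "pos0")]), ]
  counts <- matrix(rpois(nrow(tab) * 4, 8) *
                     rbinom(nrow(tab) * 4, 1, 0.6), ncol = 4)
  # mix in some clearly callable rows
  hi <- sample(nrow(tab), nrow(tab) %/% 3)
  counts[hi, ] <- 0
  counts[cbind(hi, sample(1:4, length(hi), TRUE))] <-
    sample(10:499, length(hi), TRUE)
  tab[, c("nA", "nC", "nG", "nT")] <- counts
  m <- call_matrix(tab, strains, 100L)
  for (r in seq_len(nrow(tab))) {
    expect_identical(
      unname(m[match(tab$strain[r], strains), tab$pos0[r] + 1L]),
      call_site(as.numeric(tab[r, c("nA", "nC", "nG", "nT")])))
  }
  # absent positions are N
  seen <- matrix(FALSE, 10, 100)
  seen[cbind(match(tab$strain, strains), tab$pos0 + 1L)] <- TRUE
  expect_true(all(m[!seen] == "N"))
})

test_that("call_matrix rejects duplicates and out-of-range positions", {
  tab <- data.frame(strain = c("a", "a"), pos0 = c(3L, 3L),
                    nA = 20L, nC = 0L, nG = 0L, nT = 0L)
  expect_error(call_matrix(tab, c("a"), 10L), "duplicate")
  tab2 <- data.frame(strain = "a", pos0 = 10L, nA = 20L, nC = 0L,
                     nG = 0L, nT = 0L)
  expect_error(call_matrix(tab2, "a", 10L), "outside")
  empty <- tab2[0, ]
  m <- call_matrix(empty, c("a", "b"), 5L)
  expect_true(all(m == "N"))
})

test_that("re-calling a consensus-derived count table is idempotent", {
  set.seed(15)
  m <- rand_alignment(6, 200, miss = 0.1)
  tab <- consensus_to_counts(m)
  m2 <- call_matrix(tab, rownames(m), 200L, min_depth = 1,
                    max_depth = Inf, min_frac = 1)
  expect_identical(m2, m)
})

test_that("gene eligibility follows the strain- and site-fraction rule", {
  mk <- function(called_per_strain, L = 100L) {
    m <- matrix("N", length(called_per_strain), L)
    for (i in seq_along(called_per_strain))
      if (called_per_strain[i] > 0)
        m[i, seq_len(called_per_strain[i])] <- "A"
    rownames(m) <- sprintf("s%02d", seq_along(called_per_strain))
    m
  }
  gene <- list(start = 1L, end = 100L)
  # all strains fully called -> eligible
  expect_true(gene_eligibility(mk(rep(100L, 10)), gene)$eligible)
  # 7 strains with 95 called, 3 with 50: 7 < 0.8 * 10 -> ineligible
  expect_false(gene_eligibility(mk(c(rep(95L, 7), rep(50L, 3))),
                                gene)$eligible)
  # 8 strains with 91 called (0.91 > 0.9) -> eligible
  expect_true(gene_eligibility(mk(c(rep(91L, 8), rep(0L, 2))),
                               gene)$eligible)
  # 8 strains with exactly 90 called (0.90 not > 0.9) -> ineligible
  expect_false(gene_eligibility(mk(c(rep(90L, 8), rep(0L, 2))),
                                gene)$eligible)
  expect_error(gene_eligibility(mk(rep(100L, 4)),
                                list(start = 5L, end = 4L)), "invalid")
})

test_that("window eligibility uses strict bounds on sites and strains", {
  n <- 10L
  m <- matrix("A", n, 10000L)
  rownames(m) <- sprintf("s%02d", 1:n)
  expect_true(window_eligibility(m, 1L))
  # exactly 8,000 qualifying sites is not enough (strict >)
  m2 <- m
  m2[, 1:2000] <- "N"
  expect_false(window_eligibility(m2, 1L))
  m3 <- m
  m3[, 1:1999] <- "N"
  expect_true(window_eligibility(m3, 1L))
  # a site called in exactly 80% of strains does not qualify (strict >)
  m4 <- m
  m4[1:2, ] <- "N"
  expect_false(window_eligibility(m4, 1L))
  expect_error(window_eligibility(m, 2L), "grid")
})

test_that("window eligibility matches a brute-force recount", {
  set.seed(16)
  m <- rand_alignment(8, 10000, miss = 0.18)
  qualifying <- sum(colSums(m != "N") > 0.8 * 8)
  expect_identical(window_eligibility(m, 1L), qualifying > 8000)
})

test_that("consensus FASTA round-trips", {
  m <- rand_alignment(5, 120, miss = 0.05, seed = 21)
  f <- tempfile(fileext = ".fasta")
  write_consensus_fasta(m, f)
  expect_identical(read_consensus_fasta(f), m)
  unlink(f)
})
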