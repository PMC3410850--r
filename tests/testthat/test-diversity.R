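# diversity statistics: complete deletion, theta estimators, Tajima's D,
# frequency spectra, Fay & Wu's H, windowed scan

test_that("complete deletion drops exactly the columns containing N", {
  m <- matrix("A", 4, 10)
  expect_identical(complete_columns(m), 1:10)
  m[2, 4] <- "N"
  expect_identical(complete_columns(m), setdiff(1:10, 4L))
  set.seed(41)
  r <- rand_alignment(6, 200, miss = 0.1)
  oracle <- which(vapply(seq_len(200),
                         function(j) all(r[, j] != "N"), TRUE))
  expect_identical(complete_columns(r), oracle)
})

test_that("theta_pi matches hand-worked and brute-force values", {
  m <- matrix("G", 5, 50)
  expect_identical(theta_pi(m), 0)
  # two strains differing at 2 of 100 sites
  a <- matrix("A", 2, 100)
  a[2, c(10, 20)] <- "C"
  expect_equal(theta_pi(a), 0.02)
  # 4-strain toy with S_1 = 1, S_2 = 1: pi_total = (2*3 + 2*4) / 12 = 7/6
  toy <- matrix(c("A", "A", "A", "T",
                  "A", "A", "T", "T"), 4, 2)
  expect_equal(theta_pi(toy) * 2, 7 / 6, tolerance = 1e-12)
  expect_error(theta_pi(m[1, , drop = FALSE]), "n >= 2")
})

test_that("all-pairs brute force equals the SFS formula on random alignments", {
  set.seed(42)
  for (rep in 1:200) {
    n <- sample(3:8, 1)
    L <- sample(10:40, 1)
    aln <- rand_alignment(n, L, miss = if (rep %% 3 == 0) 0.08 else 0)
    if (!length(complete_columns(aln))) next
    expect_equal(theta_pi(aln), brute_theta_pi(aln), tolerance = 1e-12)
  }
})

test_that("Watterson's theta follows S / a_n / L", {
  expect_identical(watterson_theta(0, 10, 100), 0)
  expect_equal(watterson_theta(3, 4, 100), 3 / (1 + 1 / 2 + 1 / 3) / 100,
               tolerance = 1e-12)
  expect_equal(watterson_theta(3, 4, 100), 0.0163636, tolerance = 1e-5)
  expect_equal(watterson_theta(5, 2, 100), 0.05)  # a_1 = 1
  expect_error(watterson_theta(1, 1, 100), "n >= 2")
})

test_that("Tajima's D matches an independent constant evaluation", {
  # worked n = 4, S = 2, pi_total = 7/6 example, constants evaluated
  # independently here
  n <- 4; S <- 2; pi_total <- 7 / 6
  a1 <- sum(1 / 1:3); a2 <- sum(1 / (1:3)^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  oracle <- (pi_total - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
  expect_equal(tajima_d(S, n, pi_total), oracle, tolerance = 1e-12)
  expect_equal(tajima_d(S, n, pi_total), 0.592, tolerance = 1e-3)
  # numerator zero
  expect_equal(tajima_d(3, 6, 3 / sum(1 / 1:5)), 0)
  # fewer than two segregating sites: undefined
  expect_true(is.na(tajima_d(1, 10, 0.3)))
  expect_true(is.na(tajima_d(0, 10, 0)))
})

test_that("unfolded SFS polarizes against the outgroup and drops unpolarizable columns", {
  aln <- matrix(c("A", "A", "A", "T",
                  "A", "A", "T", "T"), 4, 2)
  u <- unfolded_sfs(aln, c("A", "A"))
  expect_identical(u$counts, c(1L, 1L, 0L))
  # outgroup base absent from the ingroup alleles -> excluded
  u2 <- unfolded_sfs(aln, c("C", "A"))
  expect_identical(u2$counts, c(0L, 1L, 0L))
  expect_identical(u2$n_unpolarizable, 1L)
  # outgroup N -> excluded
  u3 <- unfolded_sfs(aln, c("N", "A"))
  expect_identical(u3$counts, c(0L, 1L, 0L))
  mono <- matrix("G", 4, 5)
  expect_identical(sum(unfolded_sfs(mono, rep("G", 5))$counts), 0L)
  expect_error(unfolded_sfs(aln, "A"), "length")
})

test_that("Fay and Wu's H matches hand enumeration", {
  # n = 4, one derived singleton: pi = 0.5, theta_H = 2/12, H = +1/3
  aln <- matrix(c("A", "A", "A", "T"), 4, 1)
  fw <- fay_wu_h(unfolded_sfs(aln, "A"), 4, 1)
  expect_equal(fw$pi_total, 0.5)
  expect_equal(fw$theta_h, 1 / 6, tolerance = 1e-12)
  expect_equal(fw$h, 1 / 3, tolerance = 1e-12)
  # one derived triplet (i = 3): pi = 0.5, theta_H = 1.5, H = -1
  aln2 <- matrix(c("T", "T", "T", "A"), 4, 1)
  fw2 <- fay_wu_h(unfolded_sfs(aln2, "A"), 4, 1)
  expect_equal(fw2$theta_h, 1.5)
  expect_equal(fw2$h, -1)
  # no segregating sites: H = 0 through gene_stats
  gs <- gene_stats(matrix("C", 4, 8), outgroup = rep("C", 8))
  expect_identical(gs$fay_wu_h, 0)
})

test_that("folded SFS counts minor alleles and matches brute force", {
  n <- 32
  aln <- matrix("A", n, 3)
  aln[1, 1] <- "T"          # singleton -> class 1
  aln[1:16, 2] <- "G"       # fold midpoint -> class 16
  f <- folded_sfs(aln)
  expect_identical(f$counts[1], 1L)
  expect_identical(f$counts[16], 1L)
  set.seed(43)
  r <- rand_alignment(9, 120, miss = 0.05)
  f2 <- folded_sfs(r)
  cc <- complete_columns(r)
  oracle <- integer(4)
  for (j in cc) {
    tb <- table(r[, j])
    if (length(tb) == 2L) {
      m <- min(tb)
      oracle[m] <- oracle[m] + 1L
    }
  }
  expect_identical(f2$counts, oracle)
})

test_that("gene_stats agrees with the standalone estimators", {
  set.seed(44)
  aln <- rand_alignment(8, 150, miss = 0.04)
  gs <- gene_stats(aln)
  expect_equal(gs$theta_pi, theta_pi(aln), tolerance = 1e-12)
  cc <- complete_columns(aln)
  S <- sum(vapply(cc, function(j)
    length(unique(aln[, j])) >= 2L, TRUE))
  expect_identical(gs$S, as.integer(S))
  expect_equal(gs$theta_w, watterson_theta(S, 8, length(cc)),
               tolerance = 1e-12)
  expect_identical(gs$L_analyzed, length(cc))
})

test_that("window scan matches the per-gene path and honours eligibility", {
  set.seed(45)
  m <- rand_alignment(6, 20000)
  ws <- window_scan(m, replicon = "chr")
  expect_identical(nrow(ws), 2L)
  for (k in 1:2) {
    cols <- ((k - 1) * 10000 + 1):(k * 10000)
    gs <- gene_stats(m[, cols])
    expect_equal(ws$theta_pi[k], gs$theta_pi, tolerance = 1e-12)
    expect_equal(ws$tajima_d[k], gs$tajima_d, tolerance = 1e-12)
  }
  # monomorphic window -> zero diversity
  mono <- matrix("T", 6, 10000, dimnames = list(paste0("s", 1:6), NULL))
  wm <- window_scan(mono, replicon = "chr")
  expect_identical(wm$theta_pi, 0)
  expect_identical(wm$S, 0L)
  # an ineligible window is absent from the output
  m2 <- m
  m2[, 1:3000] <- "N"
  w2 <- window_scan(m2, replicon = "chr")
  expect_identical(w2$start, 10001L)
})
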