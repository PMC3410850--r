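# F84 distances, neighbor-joining, bootstrap, collapsing, consensus

test_that("identical sequences have zero distance; disjoint coverage errors", {
  s <- rep(c("A", "C", "G", "T"), 25)
  expect_identical(f84_distance(s, s), 0)
  s1 <- c("A", "N", "C"); s2 <- c("N", "A", "N")
  expect_error(f84_distance(s1, s2), "shared")
  expect_error(f84_distance(c("A", "C"), c("A")), "length")
})

test_that("F84 reduces to Jukes-Cantor at equal frequencies", {
  set.seed(71)
  bases <- c("A", "C", "G", "T")
  s1 <- rep(bases, 1000)  # exactly equal frequencies
  s2 <- s1
  flip <- sample(4000, 380)
  for (i in flip) s2[i] <- sample(setdiff(bases, s1[i]), 1)
  p <- mean(s1 != s2)
  jc <- -3 / 4 * log(1 - 4 * p / 3)
  # ts/tv = 0.5 makes every change equally likely, i.e. the JC model
  expect_equal(f84_distance(s1, s2, tstv = 0.5), jc, tolerance = 1e-4)
  # and ape agrees on the JC value
  x <- ape::as.DNAbin(matrix(c(tolower(s1), tolower(s2)), 2,
                             byrow = TRUE))
  expect_equal(as.numeric(ape::dist.dna(x, model = "JC69")), jc,
               tolerance = 1e-9)
})

test_that("the ML distance inverts exact expected counts under F84", {
  # independent oracle: rate-matrix exponential by eigendecomposition;
  # expected pattern counts at a known distance must be inverted exactly
  freqs <- c(0.31, 0.17, 0.28, 0.24)
  a <- 2; b <- 1
  tstv <- f84_implied_tstv(freqs, a, b)
  for (d_true in c(0.02, 0.10, 0.45)) {
    P <- f84_expm(d_true, freqs, a, b)
    counts <- diag(freqs) %*% P * 1e6
    d_hat <- rhizopopgen:::f84_from_counts(counts, tstv)
    expect_equal(d_hat, d_true, tolerance = 1e-6)
  }
})

test_that("F84 distance is at least the p-distance", {
  set.seed(72)
  for (rep in 1:10) {
    aln <- rand_alignment(2, 800)
    p <- mean(aln[1, ] != aln[2, ])
    if (p == 0) next
    expect_gte(f84_distance(aln[1, ], aln[2, ]), p - 1e-9)
  }
})

test_that("the pattern-compressed matrix path equals the per-pair path", {
  set.seed(73)
  aln <- rand_alignment(5, 400, miss = 0.05)
  D <- f84_dist_matrix(aln)
  for (i in 1:4) for (j in (i + 1):5)
    expect_equal(D[i, j], f84_distance(aln[i, ], aln[j, ]),
                 tolerance = 1e-9)
  expect_identical(D, t(D))
})

test_that("neighbor-joining recovers the worked additive 4-taxon case", {
  dm <- matrix(c(0, 3, 5, 6,
                 3, 0, 6, 7,
                 5, 6, 0, 7,
                 6, 7, 7, 0), 4, 4,
               dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tr <- nj_build(dm)
  # path lengths reproduce the input exactly
  expect_equal(ape::cophenetic.phylo(tr)[LETTERS[1:4], LETTERS[1:4]],
               dm, tolerance = 1e-12)
  # split AB|CD with internal branch 1 and leaf branches 1, 2, 3, 4
  expect_setequal(round(tr$edge.length, 9), c(1, 2, 3, 4, 1))
  internal <- tr$edge[, 2] > 4
  expect_equal(tr$edge.length[internal], 1)
  expect_error(nj_build(dm[1:2, 1:2]), "3 taxa")
})

test_that("NJ reproduces random additive matrices to 1e-9", {
  set.seed(74)
  for (rep in 1:5) {
    tr0 <- ape::rtree(8, br = function(n) runif(n, 0.1, 2))
    tr0 <- ape::unroot(tr0)
    dm <- ape::cophenetic.phylo(tr0)
    tr <- nj_build(dm)
    dm2 <- ape::cophenetic.phylo(tr)[rownames(dm), colnames(dm)]
    expect_lt(max(abs(dm2 - dm)), 1e-9)
  }
})

test_that("NJ recovers the topology of a clock tree with long edges", {
  set.seed(75)
  tr0 <- ape::rcoal(10)
  tr0$edge.length <- tr0$edge.length + 0.5  # long edges, easy topology
  dm <- ape::cophenetic.phylo(tr0)
  tr <- nj_build(dm)
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr0), tr)), 0)
})

# helper: support values keyed by the sorted tip set of each bipartition
support_by_clade <- function(tree) {
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  sup <- suppressWarnings(as.numeric(tree$node.label))
  out <- vapply(seq_along(pp), function(i)
    paste(sort(labs[pp[[i]]]), collapse = ","), character(1))
  stats::setNames(sup[seq_along(pp)], out)
}

test_that("bootstrap gives full support for deep clean splits and is seeded", {
  set.seed(76)
  # two 4-taxon clades separated by a long stem; within-clade structure is
  # star-like noise, so only the deep bipartition is asserted
  tr0 <- ape::read.tree(text =
    "((a:0.02,b:0.02,c:0.02,d:0.02):0.8,(e:0.02,f:0.02,g:0.02,h:0.02):0.8);")
  aln <- simulate_alignment_on_tree(tr0, L = 1500)
  bt <- bootstrap_support(aln, n_reps = 60, seed = 99)
  sbc <- support_by_clade(bt)
  deep <- sbc[names(sbc) %in% c("a,b,c,d", "e,f,g,h")]
  expect_true(length(deep) >= 1 && all(deep >= 95))
  bt2 <- bootstrap_support(aln, n_reps = 60, seed = 99)
  expect_identical(bt$node.label, bt2$node.label)
  expect_identical(ape::write.tree(bt), ape::write.tree(bt2))
  # star-like within-clade branches attract weak support
  shallow <- sbc[!names(sbc) %in% c("a,b,c,d", "e,f,g,h")]
  shallow <- shallow[!is.na(shallow)]
  expect_true(any(shallow < 80))
})

test_that("collapse contracts exactly the low-support edges", {
  tr <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1,(e:1,f:1):1);")
  tr$node.label <- c("", "100", "60", "85")
  col <- collapse_low_support(tr, cutoff = 80)
  expect_identical(ape::Nnode(col), 3L)
  # the a-b and e-f clades survive, c-d is dissolved into the root
  pp <- ape::prop.part(col)
  labs <- lapply(pp, function(x) sort(attr(pp, "labels")[x]))
  expect_true(list(c("a", "b")) %in% labs ||
                any(vapply(labs, identical, TRUE, y = c("a", "b"))))
  expect_false(any(vapply(labs, identical, TRUE, y = c("c", "d"))))
  # all supports high: unchanged
  tr2 <- tr; tr2$node.label <- c("", "100", "100", "100")
  expect_identical(ape::Nnode(collapse_low_support(tr2, 80)), 4L)
  # all supports low: star tree
  tr3 <- tr; tr3$node.label <- c("", "10", "20", "30")
  star <- collapse_low_support(tr3, 80)
  expect_identical(ape::Nnode(star), 1L)
  expect_error(collapse_low_support(ape::rtree(4)), "support")
})

test_that("majority-rule consensus keeps splits present in > half the trees", {
  t1 <- ape::read.tree(text = "((a,b),(c,d),e);")
  t2 <- ape::read.tree(text = "((a,b),(c,e),d);")
  t3 <- ape::read.tree(text = "((a,b),(d,e),c);")
  cons <- majority_rule_consensus(list(t1, t2, t3))
  pp <- ape::prop.part(cons)
  labs <- lapply(pp, function(x) sort(attr(pp, "labels")[x]))
  expect_true(any(vapply(labs, identical, TRUE, y = c("a", "b"))))
  expect_false(any(vapply(labs, identical, TRUE, y = c("c", "d"))))
  # identical inputs reproduce the topology
  cons2 <- majority_rule_consensus(list(t1, t1, t1))
  expect_equal(as.numeric(ape::dist.topo(cons2, t1)), 0)
  bad <- ape::read.tree(text = "((a,b),(c,z),e);")
  expect_error(majority_rule_consensus(list(t1, bad)), "differ")
})
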