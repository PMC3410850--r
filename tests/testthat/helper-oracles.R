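# fixtures and independent oracles used across the suite

`%||%` <- function(a, b) if (is.null(a)) b else a

# random haploid alignment; n_alleles = 2 keeps every polymorphic column
# biallelic, miss inserts N at random
rand_alignment <- function(n, L, n_alleles = 2, miss = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  bases <- c("A", "C", "G", "T")
  m <- matrix(NA_character_, n, L)
  for (j in seq_len(L)) {
    pool <- sample(bases, n_alleles)
    m[, j] <- sample(pool, n, replace = TRUE)
  }
  if (miss > 0) m[runif(n * L) < miss] <- "N"
  rownames(m) <- sprintf("s%02d", seq_len(n))
  m
}

# all-pairs brute-force per-site diversity, restricted (independently) to
# complete biallelic columns, divided by the number of complete columns
brute_theta_pi <- function(aln) {
  n <- nrow(aln)
  cc <- which(vapply(seq_len(ncol(aln)),
                     function(j) all(aln[, j] != "N"), TRUE))
  if (!length(cc)) return(NA_real_)
  bi <- cc[vapply(cc, function(j) length(unique(aln[, j])) == 2L, TRUE)]
  total <- 0
  np <- 0L
  for (i in seq_len(n - 1L)) for (k in (i + 1L):n) {
    if (length(bi))
      total <- total + sum(aln[i, bi] != aln[k, bi])
    np <- np + 1L
  }
  total / np / length(cc)
}

# independent F84 transition matrix via the rate matrix and eigendecomposition
f84_expm <- function(d, freqs, a, b) {
  grp <- list(c(1, 3), c(2, 4))  # purines, pyrimidines
  gfreq <- c(sum(freqs[grp[[1]]]), sum(freqs[grp[[2]]]))
  gi <- function(i) if (i %in% grp[[1]]) 1L else 2L
  Q <- matrix(0, 4, 4)
  for (i in 1:4) for (j in 1:4) {
    if (i == j) next
    Q[i, j] <- b * freqs[j] +
      (if (gi(i) == gi(j)) a * freqs[j] / gfreq[gi(j)] else 0)
  }
  diag(Q) <- -rowSums(Q)
  mu <- -sum(freqs * diag(Q))
  e <- eigen(Q * d / mu)
  Re(e$vectors %*% diag(exp(e$values)) %*% solve(e$vectors))
}

# implied instantaneous ts/tv flux ratio for the F84 (a, b) parametrisation
f84_implied_tstv <- function(freqs, a, b) {
  piR <- freqs[1] + freqs[3]; piY <- freqs[2] + freqs[4]
  ts <- 2 * freqs[1] * freqs[3] * (a / piR + b) +
    2 * freqs[2] * freqs[4] * (a / piY + b)
  tv <- 2 * piR * piY * b
  ts / tv
}

# evolve a gapless alignment down an ape tree under Jukes-Cantor
# (independent of the package's coalescent simulator)
simulate_alignment_on_tree <- function(tree, L = 1000) {
  bases <- c("A", "C", "G", "T")
  nt <- length(tree$tip.label)
  root <- nt + 1L
  seqs <- vector("list", nt + tree$Nnode)
  seqs[[root]] <- sample(bases, L, replace = TRUE)
  ord <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(nrow(ord$edge))) {
    par <- ord$edge[e, 1]; ch <- ord$edge[e, 2]
    bl <- ord$edge.length[e]
    p_change <- 3 / 4 * (1 - exp(-4 / 3 * bl))
    s <- seqs[[par]]
    hit <- runif(L) < p_change
    if (any(hit))
      s[hit] <- vapply(s[hit], function(x)
        sample(setdiff(bases, x), 1), character(1))
    seqs[[ch]] <- s
  }
  m <- do.call(rbind, seqs[seq_len(nt)])
  rownames(m) <- tree$tip.label
  m
}

# small neutral cohort wrapper used by several tests
small_cohort <- function(seed, n_genes = 40L, L = 1000L, theta = 0.005,
                         n_a = 12L, n_b = 8L, ...) {
  simulate_cohort(sim_config(
    n_a = n_a, n_b = n_b,
    replicons = data.frame(name = "chromosome", gene_count = n_genes,
                           gene_length = L, theta = theta),
    seed = seed, ...))
}
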