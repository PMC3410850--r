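# Two-species coalescent simulator: cohorts of haploid strains from a pair of
# diverged species, genes as independent non-recombining loci on named
# replicons, with optional HGT tracts (reduced interspecific divergence),
# sweep genes (truncated genealogies with escape), and read-count pileups.

#' Simulation configuration for a two-species cohort
#'
#' Defines the study conditions for [simulate_cohort()]: sample sizes of the
#' two species, the replicon layout (genes per replicon, gene length,
#' per-site theta), the interspecific divergence, and which genes carry a
#' recent interspecific transfer or a recent selective sweep.
#'
#' Time is measured in coalescent units (units of N_e generations for a
#' haploid population); the per-site mutation rate is `theta / 2`, so that a
#' neutral within-species sample has expected pairwise diversity `theta` per
#' site.  Genes are laid out left to right on each replicon, separated by
#' `spacer` bp of unaligned sequence.
#'
#' @param n_a,n_b number of haploid strains sampled from species A and B.
#' @param replicons data frame with columns `name`, `gene_count`,
#'   `gene_length` (bp) and `theta` (per-site, within-species).
#' @param t_split interspecific divergence in coalescent units.  The default
#'   is deep enough that fixed differences greatly exceed shared
#'   polymorphisms at neutral genes.
#' @param hgt_genes integer indices (into the cohort-wide gene table, see
#'   [simulate_cohort()]) of genes with a recent interspecific transfer.
#' @param t_hgt interspecific coalescent depth for transferred genes; must be
#'   smaller than `t_split`.
#' @param sweep_genes integer indices of genes affected by a recent sweep.
#' @param sweep_factor sweep strength `f` in (0, 1]: the sweep completed at
#'   time `f / 2` in the past, so smaller `f` means a more recent, more
#'   diversity-reducing sweep (at `f = 0.1` the median per-gene diversity of
#'   swept genes is roughly a fifth of the neutral median).  `f = 1`
#'   disables the sweep.
#' @param sweep_escape per-lineage probability of escaping the sweep
#'   (e.g. through recombination onto a non-swept background); escaped
#'   lineages retain ancestral variation and generate the high-frequency
#'   derived variants that drive Fay and Wu's H negative.
#' @param missing_ortholog_genes integer gene indices excluded from the
#'   ortholog map (emulating genes with no ortholog in the sister species).
#' @param spacer intergenic spacer length in bp.
#' @param seed integer seed; identical configurations and seeds give
#'   byte-identical cohorts.
#'
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_a = 24L, n_b = 12L,
                       replicons = data.frame(
                         name = c("chromosome", "pSymA", "pSymB"),
                         gene_count = c(120L, 60L, 60L),
                         gene_length = c(1000L, 1000L, 1000L),
                         theta = c(0.004, 0.012, 0.008),
                         stringsAsFactors = FALSE),
                       t_split = 10, hgt_genes = integer(), t_hgt = 0.2,
                       sweep_genes = integer(), sweep_factor = 1,
                       sweep_escape = 0.12,
                       missing_ortholog_genes = integer(),
                       spacer = 200L, seed = 1L) {
  stopifnot(is.data.frame(replicons),
            all(c("name", "gene_count", "gene_length", "theta") %in%
                  names(replicons)))
  if (n_a < 2L || n_b < 2L)
    stop("each species needs at least two sampled strains")
  if (any(replicons$gene_length <= 0L))
    stop("zero-length genes are not allowed")
  if (any(replicons$gene_count < 0L)) stop("negative gene counts")
  if (any(replicons$theta < 0)) stop("theta must be >= 0")
  if (t_split <= 0) stop("t_split must be positive")
  if (t_hgt < 0 || t_hgt >= t_split) stop("t_hgt must lie in [0, t_split)")
  if (sweep_factor <= 0 || sweep_factor > 1)
    stop("sweep_factor must be in (0, 1]")
  if (sweep_escape < 0 || sweep_escape > 1)
    stop("sweep_escape must be a probability")
  n_genes <- sum(replicons$gene_count)
  for (idx in list(hgt_genes, sweep_genes, missing_ortholog_genes))
    if (length(idx) && (any(idx < 1L) || any(idx > n_genes)))
      stop("gene indices out of range")
  cfg <- list(n_a = as.integer(n_a), n_b = as.integer(n_b),
              replicons = replicons, t_split = t_split,
              hgt_genes = as.integer(hgt_genes), t_hgt = t_hgt,
              sweep_genes = as.integer(sweep_genes),
              sweep_factor = sweep_factor, sweep_escape = sweep_escape,
              missing_ortholog_genes = as.integer(missing_ortholog_genes),
              spacer = as.integer(spacer), seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

# cohort-wide gene table: coordinates, tags, flags.  Gene indices are global
# across replicons in the order of `config$replicons`.
build_gene_table <- function(config) {
  reps <- config$replicons
  out <- vector("list", nrow(reps))
  idx0 <- 0L
  for (r in seq_len(nrow(reps))) {
    k <- reps$gene_count[r]
    if (k == 0L) next
    len <- reps$gene_length[r]
    sp <- config$spacer
    start <- sp + (seq_len(k) - 1L) * (len + sp) + 1L
    gi <- idx0 + seq_len(k)
    out[[r]] <- data.frame(
      index = gi,
      replicon = reps$name[r],
      start = start,
      end = start + len - 1L,
      strand = rep_len(c("+", "-"), k),
      length = len,
      theta = reps$theta[r],
      stringsAsFactors = FALSE)
    idx0 <- idx0 + k
  }
  g <- do.call(rbind, out)
  g$locus_tag_a <- sprintf("SA_%04d", g$index)
  g$locus_tag_b <- sprintf("SB_%04d", g$index)
  g$is_hgt <- g$index %in% config$hgt_genes
  g$is_sweep <- g$index %in% config$sweep_genes & config$sweep_factor < 1
  g$has_ortholog <- !(g$index %in% config$missing_ortholog_genes)
  rownames(g) <- NULL
  g
}

# Joint genealogy of n_a + n_b haploid lineages.  Species coalesce separately
# until t_join, then in a common ancestral population.  A sweep at sweep_time
# forces each surviving lineage to coalesce instantaneously with probability
# 1 - p_escape (multiple merger built from zero-length binary merges).
# Returns parent pointers and node times; tips are 1..(n_a+n_b), species A
# first.
sim_genealogy <- function(n_a, n_b, t_join, sweep_time = NULL,
                          p_escape = 0) {
  n <- n_a + n_b
  parent <- integer(2L * n - 1L)
  node_time <- numeric(2L * n - 1L)
  nxt <- n + 1L
  merge2 <- function(i, j, t) {
    id <- nxt
    parent[c(i, j)] <<- id
    node_time[id] <<- t
    nxt <<- nxt + 1L
    id
  }
  run_phase <- function(act, t0, t_end, sweep_t) {
    t <- t0
    repeat {
      k <- length(act)
      if (k <= 1L && is.null(sweep_t)) break
      w <- if (k > 1L) rexp(1L, k * (k - 1L) / 2) else Inf
      if (!is.null(sweep_t) && t + w >= sweep_t && sweep_t < t_end) {
        t <- sweep_t
        esc <- runif(k) < p_escape
        swept <- act[!esc]
        if (length(swept) >= 2L) {
          cur <- swept[1L]
          for (s in swept[-1L]) cur <- merge2(cur, s, t)
          act <- c(act[esc], cur)
        }
        sweep_t <- NULL
        next
      }
      if (t + w >= t_end) break
      t <- t + w
      pr <- sample(act, 2L)
      id <- merge2(pr[1L], pr[2L], t)
      act <- c(setdiff(act, pr), id)
    }
    act
  }
  a <- run_phase(seq_len(n_a), 0, t_join, sweep_time)
  b <- run_phase(n_a + seq_len(n_b), 0, t_join, sweep_time)
  root_set <- run_phase(c(a, b), t_join, Inf, NULL)
  list(parent = parent, node_time = node_time, n_tips = n,
       n_nodes = nxt - 1L, root = root_set[1L])
}

# total branch length of a genealogy, in coalescent units
tree_length <- function(gen) {
  non_root <- seq_len(gen$n_nodes)[gen$parent[seq_len(gen$n_nodes)] > 0L]
  sum(gen$node_time[gen$parent[non_root]] - gen$node_time[non_root])
}

# Drop finite-sites mutations on a genealogy (Poisson rate theta/2 per site
# per unit time; repeat hits allowed) and evolve sequences from a uniform
# random ancestral sequence.  Returns the tip alignment and the ancestral
# (root) sequence.
sim_alignment <- function(gen, theta, L) {
  kids <- vector("list", gen$n_nodes)
  for (i in seq_len(gen$n_nodes)) {
    p <- gen$parent[i]
    if (p > 0L) kids[[p]] <- c(kids[[p]], i)
  }
  anc <- sample(DNA_BASES, L, replace = TRUE)
  aln <- matrix(NA_character_, gen$n_tips, L)
  walk <- function(node, seqv) {
    for (ch in kids[[node]]) {
      bl <- gen$node_time[node] - gen$node_time[ch]
      nm <- if (bl > 0 && theta > 0) rpois(1L, theta / 2 * bl * L) else 0L
      s2 <- seqv
      if (nm > 0L) {
        sites <- sample.int(L, nm, replace = TRUE)
        for (s in sites)
          s2[s] <- sample(DNA_BASES[DNA_BASES != s2[s]], 1L)
      }
      if (ch <= gen$n_tips) aln[ch, ] <<- s2 else walk(ch, s2)
    }
  }
  walk(gen$root, anc)
  list(aln = aln, ancestral = anc)
}

#' Simulate a two-species cohort with known ground truth
#'
#' Each gene is an independent non-recombining locus.  Within-species
#' genealogies follow the standard neutral coalescent; the two species merge
#' into a common ancestral population at depth `t_split` (`t_hgt` for
#' transferred genes).  Sweep genes experience a hard sweep at time
#' `sweep_factor / 2`: lineages alive then coalesce instantaneously unless
#' they escape (probability `sweep_escape`).  Mutations fall on branches as a
#' Poisson process at rate `theta/2` per site (finite sites, repeat hits
#' allowed).
#'
#' @param config a [sim_config()] object.
#' @return an object of class `sim_cohort`: a list with elements
#'   `alignments` (per gene, a `(n_a+n_b) x L` character matrix over
#'   A/C/G/T with strain row names, species A first), `ancestral` (per gene,
#'   the root sequence, usable as a perfect outgroup), `genes_a`/`genes_b`
#'   (gene models per species; identical coordinates, species-specific
#'   locus tags), `orthologs` (data frame `locus_tag_a`, `locus_tag_b`),
#'   `truth` (one row per gene: replicon, index, true theta, `is_hgt`,
#'   `is_sweep`, joint depth `t_join`, realised total `tree_length`),
#'   `strains_a`, `strains_b`, and the `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  genes <- build_gene_table(config)
  strains <- c(sprintf("A%02d", seq_len(config$n_a)),
               sprintf("B%02d", seq_len(config$n_b)))
  ng <- nrow(genes)
  alignments <- vector("list", ng)
  ancestral <- vector("list", ng)
  tlen <- numeric(ng)
  tjoin <- numeric(ng)
  for (g in seq_len(ng)) {
    t_join <- if (genes$is_hgt[g]) config$t_hgt else config$t_split
    sweep_t <- if (genes$is_sweep[g]) config$sweep_factor / 2 else NULL
    gen <- sim_genealogy(config$n_a, config$n_b, t_join, sweep_t,
                         config$sweep_escape)
    sa <- sim_alignment(gen, genes$theta[g], genes$length[g])
    rownames(sa$aln) <- strains
    alignments[[g]] <- sa$aln
    ancestral[[g]] <- sa$ancestral
    tlen[g] <- tree_length(gen)
    tjoin[g] <- t_join
  }
  names(alignments) <- genes$locus_tag_a
  names(ancestral) <- genes$locus_tag_a
  truth <- data.frame(
    locus_tag_a = genes$locus_tag_a, locus_tag_b = genes$locus_tag_b,
    replicon = genes$replicon, index = genes$index, start = genes$start,
    end = genes$end, theta = genes$theta, is_hgt = genes$is_hgt,
    is_sweep = genes$is_sweep, has_ortholog = genes$has_ortholog,
    t_join = tjoin, tree_length = tlen, stringsAsFactors = FALSE)
  ga <- genes[, c("locus_tag_a", "replicon", "start", "end", "strand")]
  names(ga)[1L] <- "locus_tag"
  gb <- genes[, c("locus_tag_b", "replicon", "start", "end", "strand")]
  names(gb)[1L] <- "locus_tag"
  orth <- genes[genes$has_ortholog, c("locus_tag_a", "locus_tag_b")]
  rownames(orth) <- NULL
  structure(list(alignments = alignments, ancestral = ancestral,
                 genes_a = ga, genes_b = gb, orthologs = orth,
                 truth = truth,
                 strains_a = strains[seq_len(config$n_a)],
                 strains_b = strains[config$n_a + seq_len(config$n_b)],
                 config = config),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("sim_cohort:", length(x$alignments), "genes,",
      length(x$strains_a), "+", length(x$strains_b), "strains,",
      nrow(x$config$replicons), "replicons\n")
  cat("  HGT genes:", sum(x$truth$is_hgt),
      " sweep genes:", sum(x$truth$is_sweep), "\n")
  invisible(x)
}

#' Extract one species' rows from a cohort gene alignment
#'
#' @param cohort a `sim_cohort`.
#' @param gene gene index or locus tag (species A tag).
#' @param species `"A"`, `"B"` or `"both"`.
#' @return character alignment matrix.
#' @export
cohort_alignment <- function(cohort, gene, species = c("A", "B", "both")) {
  species <- match.arg(species)
  aln <- if (is.character(gene)) cohort$alignments[[gene]] else
    cohort$alignments[[gene]]
  if (is.null(aln)) stop("no such gene")
  switch(species,
         A = aln[cohort$strains_a, , drop = FALSE],
         B = aln[cohort$strains_b, , drop = FALSE],
         both = aln)
}

#' Assemble a replicon-wide consensus matrix from cohort truth
#'
#' Places the true gene alignments of one species at their genomic
#' coordinates; intergenic positions, which carry no aligned evidence, are
#' `N`.  This is the idealised (error-free, fully covered) input for the
#' downstream stages when the pileup stage is bypassed.
#'
#' @param cohort a `sim_cohort`.
#' @param species `"A"` or `"B"`.
#' @param replicon replicon name.
#' @return character matrix (strains x positions) over A/C/G/T/N.
#' @export
cohort_consensus_matrix <- function(cohort, species = c("A", "B"),
                                    replicon) {
  species <- match.arg(species)
  genes <- if (species == "A") cohort$genes_a else cohort$genes_b
  strains <- if (species == "A") cohort$strains_a else cohort$strains_b
  genes <- genes[genes$replicon == replicon, , drop = FALSE]
  if (!nrow(genes)) stop("no genes on replicon ", replicon)
  len <- max(genes$end) + cohort$config$spacer
  m <- matrix("N", length(strains), len, dimnames = list(strains, NULL))
  tags_a <- cohort$genes_a$locus_tag[cohort$genes_a$replicon == replicon]
  for (i in seq_len(nrow(genes))) {
    aln <- cohort$alignments[[tags_a[i]]][strains, , drop = FALSE]
    m[, genes$start[i]:genes$end[i]] <- aln
  }
  m
}

#' Simulate per-site read counts for an alignment
#'
#' Per strain-site read depth is Poisson(`mean_depth`); each read reports the
#' true base with probability `1 - error_rate` and otherwise a uniformly
#' drawn different base.  Positions where the truth is `N` draw all reads
#' uniformly from the four bases.
#'
#' @param alignment character matrix (strains x sites) over A/C/G/T/N.
#' @param mean_depth mean read depth per site (> 0).
#' @param error_rate per-base error probability in \[0, 0.25\].
#' @param seed optional integer seed.
#' @param replicon replicon name recorded in the table.
#' @param offset 0-based genomic position of the first alignment column.
#' @return data frame with columns `strain`, `replicon`, `pos0`, `nA`, `nC`,
#'   `nG`, `nT` (a read-count table).
#' @export
simulate_pileup <- function(alignment, mean_depth, error_rate = 0,
                            seed = NULL, replicon = "replicon",
                            offset = 0L) {
  if (error_rate < 0 || error_rate > 0.25)
    stop("error_rate must be in [0, 0.25]")
  if (mean_depth <= 0) stop("mean_depth must be positive")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(alignment); L <- ncol(alignment)
  nc <- n * L
  depth <- rpois(nc, mean_depth)
  truth <- match(as.vector(alignment), DNA_BASES)  # NA for N
  counts <- matrix(0L, nc, 4L)
  known <- !is.na(truth)
  corr <- integer(nc)
  corr[known] <- rbinom(sum(known), depth[known], 1 - error_rate)
  wrong <- integer(nc)
  wrong[known] <- depth[known] - corr[known]
  # split erroneous reads uniformly over the three non-true bases
  e1 <- rbinom(nc, wrong, 1 / 3)
  e2 <- rbinom(nc, wrong - e1, 1 / 2)
  e3 <- wrong - e1 - e2
  err <- cbind(e1, e2, e3)
  for (b in 1:4) {
    sel <- known & truth == b
    counts[sel, b] <- corr[sel]
    others <- setdiff(1:4, b)
    for (k in 1:3) counts[sel, others[k]] <- err[sel, k]
  }
  if (any(!known)) {
    # unknown truth: reads uniform over the four bases
    sel <- which(!known)
    c1 <- rbinom(length(sel), depth[sel], 1 / 4)
    c2 <- rbinom(length(sel), depth[sel] - c1, 1 / 3)
    c3 <- rbinom(length(sel), depth[sel] - c1 - c2, 1 / 2)
    counts[sel, ] <- cbind(c1, c2, c3, depth[sel] - c1 - c2 - c3)
  }
  data.frame(
    strain = rep(rownames(alignment) %||% sprintf("S%02d", seq_len(n)),
                 times = L),
    replicon = replicon,
    pos0 = rep(offset + seq_len(L) - 1L, each = n),
    nA = counts[, 1L], nC = counts[, 2L], nG = counts[, 3L],
    nT = counts[, 4L], stringsAsFactors = FALSE)
}

#' Construct a genome with a known GC-skew sign switch
#'
#' Builds a two-arm sequence whose first arm is G-biased and second arm is
#' C-biased on the forward strand, emulating the skew structure of a
#' bacterial chromosome replicated bidirectionally from an origin at
#' position 1; the skew changes sign at the arm boundary (the terminus).
#'
#' @param arm_length length of each arm in bp.
#' @param skew_strength excess probability mass on G (first arm) or C
#'   (second arm); 0 gives an unskewed sequence.
#' @param seed optional integer seed.
#' @return list with `sequence` (single string) and `terminus` (1-based
#'   boundary position).
#' @export
simulate_skewed_genome <- function(arm_length = 2e5, skew_strength = 0.06,
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p_plus <- c(0.25, 0.25 - skew_strength / 2, 0.25 + skew_strength / 2, 0.25)
  p_minus <- c(0.25, 0.25 + skew_strength / 2, 0.25 - skew_strength / 2, 0.25)
  arm1 <- sample(DNA_BASES, arm_length, replace = TRUE, prob = p_plus)
  arm2 <- sample(DNA_BASES, arm_length, replace = TRUE, prob = p_minus)
  list(sequence = paste0(paste(arm1, collapse = ""),
                         paste(arm2, collapse = "")),
       terminus = arm_length)
}
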