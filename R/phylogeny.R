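# Distance-based genealogies: maximum-likelihood pairwise distances under
# the F84 model with a fixed transition/transversion ratio, neighbor-joining
# via ape with negative branches clamped to zero, nonparametric bootstrap
# support, low-support collapsing, and majority-rule consensus.

# F84 rate parametrisation.  The model superimposes "general" events (rate
# b, target drawn from the base frequencies) and "within-group" events
# (rate a, target drawn from the purine or pyrimidine frequencies).  Given
# the expected transition:transversion ratio R, a is solved from the
# instantaneous fluxes (b is fixed at 1); mu is the total substitution rate
# used to express branch lengths in expected substitutions per site.
f84_rates <- function(freqs, tstv) {
  piA <- freqs[1L]; piC <- freqs[2L]; piG <- freqs[3L]; piT <- freqs[4L]
  piR <- piA + piG; piY <- piC + piT
  AG <- piA * piG; CT <- piC * piT
  b <- 1
  denom <- 0
  if (piR > 0) denom <- denom + AG / piR
  if (piY > 0) denom <- denom + CT / piY
  a <- 0
  if (denom > 0) {
    a <- b * (tstv * piR * piY - (AG + CT)) / denom
    if (a < 0) a <- 0  # requested ratio below the model's minimum
  }
  ts_flux <- 0
  if (piR > 0) ts_flux <- ts_flux + 2 * AG * (a / piR + b)
  if (piY > 0) ts_flux <- ts_flux + 2 * CT * (a / piY + b)
  mu <- 2 * piR * piY * b + ts_flux
  list(a = a, b = b, mu = mu, piR = piR, piY = piY)
}

# F84 transition probability matrix at distance d (expected substitutions
# per site), spectral form
f84_pmatrix <- function(d, freqs, rates) {
  t <- d / rates$mu
  ea <- exp(-(rates$a + rates$b) * t)
  eb <- exp(-rates$b * t)
  grp <- c(rates$piR, rates$piY, rates$piR, rates$piY)  # group freq per base
  same_group <- outer(c(1, 2, 1, 2), c(1, 2, 1, 2), "==")
  P <- matrix(0, 4L, 4L, dimnames = list(DNA_BASES, DNA_BASES))
  for (i in 1:4) for (j in 1:4) {
    P[i, j] <- (1 - eb) * freqs[j] +
      (if (same_group[i, j] && grp[j] > 0)
        eb * (1 - exp(-rates$a * t)) * freqs[j] / grp[j] else 0) +
      (if (i == j) ea else 0)
  }
  P
}

# ML F84 distance from a 4x4 substitution count matrix
f84_from_counts <- function(cmat, tstv = 2.0, tol = 1e-10) {
  total <- sum(cmat)
  if (total == 0) stop("no shared non-N columns between the sequences")
  if (sum(cmat) == sum(diag(cmat))) return(0)
  pooled <- rowSums(cmat) + colSums(cmat)
  freqs <- pooled / sum(pooled)
  rates <- f84_rates(freqs, tstv)
  nz <- which(cmat > 0)
  nij <- cmat[nz]
  nll <- function(d) {
    P <- f84_pmatrix(d, freqs, rates)
    M <- freqs * P  # pi_i * P_ij, row-scaled
    lv <- log(M[nz])
    if (any(!is.finite(lv))) return(1e12)
    -sum(nij * lv)
  }
  opt <- optimize(nll, c(1e-9, 12), tol = tol)
  if (opt$minimum > 11)
    stop("sequences appear saturated; F84 distance undefined")
  opt$minimum
}

#' Maximum-likelihood F84 distance between two sequences
#'
#' Columns with N in either sequence are dropped pairwise; base frequencies
#' are the empirical frequencies of the pooled pair; the
#' transition/transversion ratio is fixed (the classic dnadist default is
#' 2.0) and the distance, in expected substitutions per site, maximises the
#' F84 likelihood of the observed substitution counts.
#'
#' @param seq1,seq2 character vectors over A/C/G/T/N, equal length.
#' @param tstv fixed transition/transversion ratio.
#' @return the distance (>= the p-distance).  Errors when no shared non-N
#'   columns remain or when the sequences are saturated.
#' @export
f84_distance <- function(seq1, seq2, tstv = 2.0) {
  if (length(seq1) != length(seq2)) stop("sequences differ in length")
  keep <- seq1 != "N" & seq2 != "N"
  i <- match(seq1[keep], DNA_BASES)
  j <- match(seq2[keep], DNA_BASES)
  cmat <- matrix(0, 4L, 4L)
  tb <- table(factor(i, 1:4), factor(j, 1:4))
  cmat[] <- as.numeric(tb)
  f84_from_counts(cmat, tstv)
}

#' Pairwise F84 distance matrix for an alignment
#'
#' Site patterns are compressed before counting, so repeated columns cost
#' nothing; optional per-column weights support bootstrap resampling.
#'
#' @param aln alignment matrix (strains x columns) over A/C/G/T/N.
#' @param tstv fixed transition/transversion ratio.
#' @param weights optional non-negative column weights (default: 1 each).
#' @return symmetric distance matrix with taxa names.
#' @export
f84_dist_matrix <- function(aln, tstv = 2.0, weights = NULL) {
  pat <- compress_patterns(aln)
  w <- pat$weights
  if (!is.null(weights)) {
    if (length(weights) != ncol(aln)) stop("bad weights length")
    w <- numeric(length(pat$weights))
    agg <- rowsum(as.numeric(weights), pat$column_pattern)
    w[as.integer(rownames(agg))] <- agg[, 1L]
  }
  f84_dist_from_patterns(pat, w, tstv)
}

# compress alignment columns to unique site patterns.
# codes: 0 = N, 1..4 = A,C,G,T.  Returns the pattern matrix (taxa x P),
# per-pattern weights and the column -> pattern map.
compress_patterns <- function(aln) {
  code <- match(aln, DNA_BASES)
  code[is.na(code)] <- 0L
  dim(code) <- dim(aln)
  keys <- apply(code, 2L, paste, collapse = ".")
  uk <- unique(keys)
  map <- match(keys, uk)
  pat <- code[, match(uk, keys), drop = FALSE]
  list(patterns = pat, weights = as.numeric(tabulate(map, length(uk))),
       column_pattern = map, taxa = rownames(aln))
}

f84_dist_from_patterns <- function(pat, w, tstv) {
  n <- nrow(pat$patterns)
  if (n < 2L) stop("need at least two taxa")
  D <- matrix(0, n, n, dimnames = list(pat$taxa, pat$taxa))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ci <- pat$patterns[i, ]; cj <- pat$patterns[j, ]
    ok <- ci > 0L & cj > 0L
    if (!any(ok & w > 0)) stop("no shared non-N columns for a pair")
    cell <- (ci[ok] - 1L) * 4L + cj[ok]
    cw <- rowsum(w[ok], cell)
    cmat <- matrix(0, 4L, 4L)
    cmat[as.integer(rownames(cw))] <- cw
    # cell index was computed row-major (i-base major); transpose layout
    cmat <- t(matrix(cmat, 4L, 4L))
    D[i, j] <- D[j, i] <- f84_from_counts(cmat, tstv)
  }
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration (ape's implementation of the Studier-Keppler
#' criterion); negative branch lengths are clamped to zero.
#'
#' @param dm symmetric distance matrix (or `dist`) over >= 3 taxa.
#' @return an unrooted `phylo` tree.
#' @export
nj_build <- function(dm) {
  m <- as.matrix(dm)
  if (nrow(m) < 3L) stop("neighbor-joining needs at least 3 taxa")
  tr <- ape::nj(stats::as.dist(m))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Neighbor-joining tree with bootstrap support
#'
#' Columns are resampled with replacement `n_reps` times; the support of
#' each internal bipartition of the full-data tree is the percentage of
#' replicate trees containing it, stored in `node.label` (the root label is
#' empty).
#'
#' @param aln alignment matrix.
#' @param n_reps number of bootstrap replicates.
#' @param seed optional integer seed (supports are reproducible given the
#'   seed).
#' @param tstv transition/transversion ratio for [f84_dist_matrix()].
#' @return a `phylo` tree with integer percentage supports in `node.label`.
#' @export
bootstrap_support <- function(aln, n_reps = 200L, seed = NULL, tstv = 2.0) {
  if (ncol(aln) < 1L) stop("empty alignment")
  if (!is.null(seed)) set.seed(seed)
  pat <- compress_patterns(aln)
  full <- nj_build(f84_dist_from_patterns(pat, pat$weights, tstv))
  L <- ncol(aln)
  reps <- vector("list", n_reps)
  prob <- pat$weights / L
  for (r in seq_len(n_reps)) {
    w <- as.numeric(rmultinom(1L, L, prob))
    reps[[r]] <- nj_build(f84_dist_from_patterns(pat, w, tstv))
  }
  cnt <- ape::prop.clades(full, reps, rooted = FALSE)
  cnt[is.na(cnt)] <- 0L
  support <- round(100 * cnt / n_reps)
  lab <- as.character(support)
  lab[1L] <- ""  # root "bipartition" is trivial
  full$node.label <- lab
  full
}

#' Collapse poorly supported branches into polytomies
#'
#' Contracts every internal edge whose support (the child node's label) is
#' below `cutoff`; the lengths of contracted edges are discarded.
#'
#' @param tree a `phylo` with numeric supports in `node.label` (as from
#'   [bootstrap_support()]); unlabelled nodes (e.g. the root) are kept.
#' @param cutoff support threshold (percent); edges with support
#'   `< cutoff` are contracted.
#' @return the collapsed `phylo`.
#' @export
collapse_low_support <- function(tree, cutoff = 80) {
  if (is.null(tree$node.label)) stop("tree carries no support values")
  nt <- length(tree$tip.label)
  sup <- suppressWarnings(as.numeric(tree$node.label))
  edge <- tree$edge
  el <- tree$edge.length
  repeat {
    child <- edge[, 2L]
    s <- rep(NA_real_, length(child))
    s[child > nt] <- sup[child[child > nt] - nt]
    bad <- which(!is.na(s) & s < cutoff)
    if (!length(bad)) break
    e <- bad[1L]
    v <- edge[e, 2L]; p <- edge[e, 1L]
    edge[edge[, 1L] == v, 1L] <- p
    edge <- edge[-e, , drop = FALSE]
    el <- el[-e]
  }
  used_int <- sort(unique(edge[edge > nt]))
  remap <- integer(max(edge))
  remap[seq_len(nt)] <- seq_len(nt)
  remap[used_int] <- nt + seq_along(used_int)
  new_edge <- matrix(remap[edge], ncol = 2L)
  out <- list(edge = new_edge, edge.length = el,
              tip.label = tree$tip.label, Nnode = length(used_int),
              node.label = tree$node.label[used_int - nt])
  class(out) <- "phylo"
  attr(out, "order") <- NULL
  ape::reorder.phylo(out, "cladewise")
}

#' Majority-rule consensus of trees on identical leaf sets
#'
#' Retains the bipartitions present in more than half of the input trees.
#'
#' @param trees list of `phylo` trees with identical tip labels.
#' @return the consensus `phylo` (topology only).
#' @export
majority_rule_consensus <- function(trees) {
  if (length(trees) < 1L) stop("no trees")
  ref <- sort(trees[[1L]]$tip.label)
  for (tr in trees)
    if (!identical(sort(tr$tip.label), ref)) stop("leaf sets differ")
  ape::consensus(trees, p = 0.5)
}
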