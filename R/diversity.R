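# Per-gene and per-window nucleotide diversity statistics: segregating
# sites, theta-pi, Watterson's theta, Tajima's D, the unfolded SFS and Fay &
# Wu's H, folded (minor-allele) spectra, and a windowed scan.
#
# Missing-data policy (applied here, in one place): complete deletion --
# every statistic is computed on the columns with zero N across the analysed
# strains.  Columns with three or more alleles count toward S but are
# excluded from the SFS-based formulas (theta-pi, SFS, theta-H); they are
# rare under realistic theta and are reported as a per-gene diagnostic.

#' Columns with complete data
#'
#' @param aln alignment matrix over A/C/G/T/N.
#' @return integer vector of column indices with zero N.
#' @export
complete_columns <- function(aln) {
  which(colSums(aln == "N") == 0L)
}

# site summary used by all statistics: complete columns, allele counts,
# biallelic columns and their (alphabetically first) allele counts
site_summary <- function(aln) {
  cc <- complete_columns(aln)
  n <- nrow(aln)
  sub <- aln[, cc, drop = FALSE]
  cnt <- base_counts(sub)
  nal <- colSums(cnt > 0L)
  poly <- nal >= 2L
  bi <- nal == 2L
  a1 <- rep(NA_integer_, length(cc))
  c1 <- rep(NA_integer_, length(cc))
  if (any(bi)) {
    a1[bi] <- apply(cnt[, bi, drop = FALSE] > 0L, 2L,
                    function(z) which(z)[1L])
    c1[bi] <- cnt[, bi, drop = FALSE][cbind(a1[bi], seq_len(sum(bi)))]
  }
  list(cc = cc, L = length(cc), n = n, counts = cnt, n_alleles = nal,
       S = sum(poly), biallelic = bi, n_multi = sum(nal > 2L),
       allele1 = a1, count1 = c1)
}

#' Nucleotide diversity theta-pi (per site)
#'
#' Mean over all strain pairs of the per-site difference fraction on
#' complete biallelic columns; equivalent to the site-frequency-spectrum
#' form `sum_i 2 S_i i (n - i) / (n (n - 1)) / L`.
#'
#' @param aln alignment matrix; at least two rows.
#' @return per-site theta-pi over the analysed (complete) columns.
#' @export
theta_pi <- function(aln) {
  if (nrow(aln) < 2L) stop("theta_pi needs n >= 2")
  ss <- site_summary(aln)
  if (ss$L == 0L) return(NA_real_)
  pi_total_from_summary(ss) / ss$L
}

# total (per-gene) pairwise diversity from a site summary
pi_total_from_summary <- function(ss) {
  if (!any(ss$biallelic)) return(0)
  cts <- ss$count1[ss$biallelic]
  n <- ss$n
  sum(2 * cts * (n - cts)) / (n * (n - 1))
}

#' Watterson's theta (per site)
#'
#' `S / a_n / L` with `a_n = sum_{i=1}^{n-1} 1/i`.
#'
#' @param S number of segregating sites.
#' @param n sample size (>= 2).
#' @param L number of analysed sites (> 0).
#' @return per-site Watterson estimate.
#' @export
watterson_theta <- function(S, n, L) {
  if (n < 2L) stop("watterson_theta needs n >= 2")
  if (L <= 0) stop("L must be positive")
  S / harmonic_number(n - 1L) / L
}

harmonic_number <- function(k) sum(1 / seq_len(k))

#' Tajima's D
#'
#' Standardised difference between pairwise diversity and the
#' segregating-site estimate, using the Tajima (1989) constants.  Undefined
#' (returns `NA`) for `S < 2`; genes with fewer than two segregating sites
#' are excluded from D-based analyses.
#'
#' @param S number of segregating sites.
#' @param n sample size.
#' @param pi_total total (per-gene, not per-site) pairwise diversity.
#' @return Tajima's D, or `NA_real_` when `S < 2`.
#' @export
tajima_d <- function(S, n, pi_total) {
  if (S < 2L) return(NA_real_)
  a1 <- harmonic_number(n - 1L)
  a2 <- sum(1 / seq_len(n - 1L)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (pi_total - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

#' Folded (minor-allele) site frequency spectrum
#'
#' Counts `min(c, n - c)` per complete biallelic column.
#'
#' @param aln alignment matrix with `n >= 2` rows.
#' @return list of class `sfs`: `n`, `counts` (index i = number of sites at
#'   minor-allele count i, i in 1..floor(n/2)), `type = "folded"`.
#' @export
folded_sfs <- function(aln) {
  if (nrow(aln) < 2L) stop("folded_sfs needs n >= 2")
  ss <- site_summary(aln)
  n <- ss$n
  k <- floor(n / 2)
  counts <- integer(k)
  if (any(ss$biallelic)) {
    minor <- pmin(ss$count1[ss$biallelic], n - ss$count1[ss$biallelic])
    tb <- tabulate(minor, nbins = k)
    counts <- tb
  }
  structure(list(n = n, counts = counts, type = "folded"), class = "sfs")
}

#' Unfolded site frequency spectrum against an outgroup
#'
#' Per complete biallelic column whose outgroup base equals one of the two
#' alleles, the non-outgroup (derived) allele is counted.  Columns where the
#' outgroup base is `N` or absent from the ingroup alleles are unpolarizable
#' and excluded from the unfolded spectrum (they still count toward S and
#' the folded spectrum).
#'
#' @param aln ingroup alignment matrix.
#' @param outgroup character vector of outgroup bases, one per alignment
#'   column (length `ncol(aln)`).
#' @return list of class `sfs`: `n`, `counts` (derived counts 1..n-1),
#'   `type = "unfolded"`, plus `n_polarizable` and `n_unpolarizable`.
#' @export
unfolded_sfs <- function(aln, outgroup) {
  if (length(outgroup) != ncol(aln))
    stop("outgroup length must match the alignment")
  ss <- site_summary(aln)
  n <- ss$n
  counts <- integer(n - 1L)
  n_pol <- 0L; n_unpol <- 0L
  bi_idx <- which(ss$biallelic)
  for (j in bi_idx) {
    col <- ss$cc[j]
    og <- outgroup[col]
    al1 <- DNA_BASES[ss$allele1[j]]
    c1 <- ss$count1[j]
    alleles <- DNA_BASES[ss$counts[, j] > 0L]
    if (og == "N" || !(og %in% alleles)) {
      n_unpol <- n_unpol + 1L
      next
    }
    derived_count <- if (og == al1) n - c1 else c1
    counts[derived_count] <- counts[derived_count] + 1L
    n_pol <- n_pol + 1L
  }
  structure(list(n = n, counts = counts, type = "unfolded",
                 n_polarizable = n_pol, n_unpolarizable = n_unpol),
            class = "sfs")
}

#' Variance-normalised Fay and Wu's H
#'
#' The H statistic divided by the standard deviation of its neutral
#' sampling distribution given the segregating-site count (the form used by
#' joint D-H sweep tests).  Writing `theta_L = sum_i i S_i / (n - 1)`,
#' `H = 2 (pi - theta_L)` and the neutral variance of `pi - theta_L` is
#' `theta (n - 2) / (6 (n - 1)) +
#'  theta^2 (18 n^2 (3 n + 2) b_{n+1} - (88 n^3 + 9 n^2 - 13 n + 6)) /
#'  (9 n (n - 1)^2)`
#' with `b_{n+1} = sum_{i=1}^{n} 1/i^2`; `theta` and `theta^2` are
#' estimated from S as `S / a_1` and `S (S - 1) / (a_1^2 + a_2)`.  Unlike
#' the unnormalised H, whose neutral spread grows with diversity, the
#' normalised statistic puts genes of different theta on one scale, which
#' is what an empirical-tail scan across genes needs.
#'
#' @param sfs an unfolded `sfs` over the polarizable sites.
#' @param n sample size (defaults to `sfs$n`).
#' @return the normalised H (0 when no polarizable site segregates; `NA`
#'   when the variance is not positive).
#' @export
fay_wu_h_norm <- function(sfs, n = sfs$n) {
  stopifnot(inherits(sfs, "sfs"), identical(sfs$type, "unfolded"))
  i <- seq_len(n - 1L)
  Si <- sfs$counts
  S <- sum(Si)
  if (S == 0L) return(0)
  pi_total <- sum(2 * Si * i * (n - i)) / (n * (n - 1))
  theta_l <- sum(i * Si) / (n - 1)
  a1 <- harmonic_number(n - 1L)
  a2 <- sum(1 / seq_len(n - 1L)^2)
  bnp1 <- sum(1 / seq_len(n)^2)
  th <- S / a1
  th2 <- S * (S - 1) / (a1^2 + a2)
  v <- th * (n - 2) / (6 * (n - 1)) +
    th2 * (18 * n^2 * (3 * n + 2) * bnp1 -
             (88 * n^3 + 9 * n^2 - 13 * n + 6)) / (9 * n * (n - 1)^2)
  if (!is.finite(v) || v <= 0) return(NA_real_)
  (pi_total - theta_l) / sqrt(v)
}

#' Fay and Wu's H from an unfolded spectrum
#'
#' `theta_H_total = sum_i 2 S_i i^2 / (n (n - 1))`; H is the unnormalised
#' Fay & Wu (2000) statistic `pi - theta_H`, with pi computed over the same
#' polarizable columns, both returned per site (divided by `L`).
#'
#' @param sfs an unfolded `sfs` (see [unfolded_sfs()]).
#' @param n sample size (defaults to `sfs$n`).
#' @param L number of sites the statistic is scaled by (use 1 for per-gene
#'   totals).
#' @return list with `theta_h` (per site), `h` (per site), and the
#'   unscaled `theta_h_total`, `pi_total`, `h_total`.
#' @export
fay_wu_h <- function(sfs, n = sfs$n, L = 1) {
  stopifnot(inherits(sfs, "sfs"), identical(sfs$type, "unfolded"))
  i <- seq_len(n - 1L)
  Si <- sfs$counts
  th_total <- sum(2 * Si * i^2) / (n * (n - 1))
  pi_total <- sum(2 * Si * i * (n - i)) / (n * (n - 1))
  h_total <- pi_total - th_total
  list(theta_h = th_total / L, h = h_total / L,
       theta_h_total = th_total, pi_total = pi_total, h_total = h_total)
}

#' Per-gene diversity statistics
#'
#' Computes the full statistic set for one gene alignment: analysed length
#' (complete columns), S, per-site theta-pi and Watterson's theta, Tajima's
#' D (NA for S < 2), and -- when an outgroup is supplied -- theta-H and Fay
#' and Wu's H on the polarizable columns.  When `frame = TRUE` the
#' synonymous/nonsynonymous partition of [syn_partition()] is included.
#'
#' H conventions: with no segregating site H = 0; with segregating sites but
#' no polarizable column H is undefined (NA).
#'
#' @param aln gene alignment matrix (rows read in coding direction if a
#'   codon partition is requested).
#' @param outgroup optional outgroup base vector (length `ncol(aln)`), e.g.
#'   the sister-species ortholog consensus from [consensus_sequence()].
#' @param locus_tag optional gene id carried into the output.
#' @param frame if `TRUE`, compute the codon partition (reading frame
#'   starting at column 1).
#' @return one-row data frame (a GeneStats record).
#' @export
gene_stats <- function(aln, outgroup = NULL, locus_tag = NA_character_,
                       frame = FALSE) {
  ss <- site_summary(aln)
  n <- ss$n; L <- ss$L
  pi_total <- pi_total_from_summary(ss)
  out <- data.frame(
    locus_tag = locus_tag, n = n, L_analyzed = L, S = ss$S,
    n_multiallelic = ss$n_multi,
    theta_pi = if (L > 0L) pi_total / L else NA_real_,
    theta_w = if (L > 0L) watterson_theta(ss$S, n, L) else NA_real_,
    tajima_d = tajima_d(ss$S, n, pi_total),
    theta_h = NA_real_, fay_wu_h = NA_real_, fay_wu_h_norm = NA_real_,
    stringsAsFactors = FALSE)
  if (!is.null(outgroup)) {
    usfs <- unfolded_sfs(aln, outgroup)
    if (ss$S == 0L) {
      out$theta_h <- 0; out$fay_wu_h <- 0; out$fay_wu_h_norm <- 0
    } else if (usfs$n_polarizable > 0L) {
      fw <- fay_wu_h(usfs, n, L)
      out$theta_h <- fw$theta_h
      out$fay_wu_h <- fw$h
      out$fay_wu_h_norm <- fay_wu_h_norm(usfs, n)
    }
  }
  if (isTRUE(frame)) {
    sp <- syn_partition(aln)
    out$theta_pi_syn <- sp$theta_pi_syn
    out$theta_pi_nonsyn <- sp$theta_pi_nonsyn
    out$syn_sites <- sp$syn_sites
    out$nonsyn_sites <- sp$nonsyn_sites
    out$internal_stop <- sp$internal_stop
  }
  out
}

#' Majority-consensus sequence of an alignment
#'
#' Per column, the most frequent non-N base; ties and all-N columns give
#' `N`.  Used to build the outgroup sequence from the sister species'
#' ortholog alignment.
#'
#' @param aln alignment matrix.
#' @return character vector of length `ncol(aln)`.
#' @export
consensus_sequence <- function(aln) {
  cnt <- base_counts(aln)
  mx <- apply(cnt, 2L, max)
  top <- max.col(t(cnt), ties.method = "first")
  ties <- colSums(cnt == rep(mx, each = 4L) & cnt > 0L) > 1L
  out <- ifelse(mx == 0L | ties, "N", DNA_BASES[top])
  out
}

#' Windowed diversity scan over a consensus matrix
#'
#' Statistics are computed per non-overlapping grid window exactly as per
#' gene (no codon partition); only windows passing [window_eligibility()]
#' are reported.
#'
#' @param matrix consensus matrix.
#' @param window grid width in bp.
#' @param min_bp,strain_frac eligibility thresholds
#'   (see [window_eligibility()]).
#' @param outgroup optional outgroup base vector of length `ncol(matrix)`.
#' @param replicon replicon label carried into the output.
#' @return data frame of WindowStats (one row per eligible window; `start`
#'   is 1-based).
#' @export
window_scan <- function(matrix, window = 10000L, min_bp = 8000L,
                        strain_frac = 0.8, outgroup = NULL,
                        replicon = NA_character_) {
  starts <- seq(1L, ncol(matrix), by = window)
  rows <- list()
  for (st in starts) {
    if (!window_eligibility(matrix, st, window, min_bp, strain_frac)) next
    end <- min(st + window - 1L, ncol(matrix))
    aln <- matrix[, st:end, drop = FALSE]
    og <- if (!is.null(outgroup)) outgroup[st:end] else NULL
    gs <- gene_stats(aln, outgroup = og)
    gs$locus_tag <- NULL
    rows[[length(rows) + 1L]] <- cbind(
      data.frame(replicon = replicon, start = st, end = end,
                 stringsAsFactors = FALSE), gs)
  }
  if (!length(rows))
    return(data.frame(replicon = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
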