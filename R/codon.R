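# Nei-Gojobori-style partition of diversity into synonymous and
# nonsynonymous components, under the bacterial/plastid genetic code
# (translation table 11).  Site counts are fractional: each codon position
# contributes the fraction of its three possible changes that are silent.

# cached genetic code (table 11); stop codons translate to "*"
genetic_code_11 <- local({
  code <- NULL
  function() {
    if (is.null(code)) code <<- Biostrings::getGeneticCode("11")
    code
  }
})

translate_codon <- function(codon) {
  unname(genetic_code_11()[codon])
}

#' Synonymous / nonsynonymous partition of a gene alignment
#'
#' The reference codon of each codon column-set is the per-column majority
#' base ([consensus_sequence()]).  Per codon position, the synonymous site
#' fraction is the share of the three possible single-base changes that
#' leave the amino acid unchanged (changes to stop codons count as
#' nonsynonymous).  Each complete biallelic polymorphism is classified by
#' whether swapping the two alleles in the reference codon context changes
#' the amino acid, and per-site theta-pi is computed separately over the
#' synonymous and nonsynonymous site totals.
#'
#' Codons whose reference contains `N` are skipped.  An internal stop codon
#' in the reference frame flags the gene and the partition is skipped (all
#' components `NA`).  An incomplete terminal codon is trimmed; a terminal
#' stop codon is excluded from the site counts.
#'
#' @param aln gene alignment in coding orientation, frame starting at
#'   column 1.
#' @return list with `syn_sites`, `nonsyn_sites` (fractional site totals),
#'   `theta_pi_syn`, `theta_pi_nonsyn`, `n_syn_poly`, `n_nonsyn_poly`, and
#'   `internal_stop`.
#' @export
syn_partition <- function(aln) {
  n <- nrow(aln)
  L <- floor(ncol(aln) / 3) * 3L  # trim incomplete terminal codon
  empty <- list(syn_sites = NA_real_, nonsyn_sites = NA_real_,
                theta_pi_syn = NA_real_, theta_pi_nonsyn = NA_real_,
                n_syn_poly = NA_integer_, n_nonsyn_poly = NA_integer_,
                internal_stop = TRUE)
  if (L < 3L) {
    empty$internal_stop <- FALSE
    return(empty)
  }
  # reference base per column: majority call with deterministic
  # (alphabetical) tie-breaking, so a 50/50 column still yields a codon
  cnt <- base_counts(aln[, seq_len(L), drop = FALSE])
  top <- max.col(t(cnt), ties.method = "first")
  ref <- ifelse(colSums(cnt) == 0L, "N", DNA_BASES[top])
  ncod <- L / 3L
  codons <- vapply(seq_len(ncod), function(k)
    paste(ref[(3L * k - 2L):(3L * k)], collapse = ""), character(1L))
  usable <- !grepl("N", codons)
  aas <- rep(NA_character_, ncod)
  aas[usable] <- translate_codon(codons[usable])
  internal <- which(usable & aas == "*")
  internal <- internal[internal < ncod]  # a terminal stop is legitimate
  if (length(internal)) return(empty)
  count_cod <- usable & !(aas %in% "*")
  syn_sites <- 0; nonsyn_sites <- 0
  syn_frac <- matrix(NA_real_, ncod, 3L)
  for (k in which(count_cod)) {
    cod <- strsplit(codons[k], "")[[1L]]
    aa0 <- aas[k]
    for (p in 1:3) {
      alts <- DNA_BASES[DNA_BASES != cod[p]]
      nsyn <- 0L
      for (b in alts) {
        mut <- cod; mut[p] <- b
        if (identical(translate_codon(paste(mut, collapse = "")), aa0))
          nsyn <- nsyn + 1L
      }
      fr <- nsyn / 3
      syn_frac[k, p] <- fr
      syn_sites <- syn_sites + fr
      nonsyn_sites <- nonsyn_sites + (1 - fr)
    }
  }
  # classify complete biallelic polymorphisms within the counted codons
  ss <- site_summary(aln[, seq_len(L), drop = FALSE])
  pi_syn <- 0; pi_nonsyn <- 0
  n_syn <- 0L; n_nonsyn <- 0L
  bi_idx <- which(ss$biallelic)
  for (j in bi_idx) {
    col <- ss$cc[j]
    k <- (col - 1L) %/% 3L + 1L
    if (!count_cod[k]) next
    p <- (col - 1L) %% 3L + 1L
    alleles <- DNA_BASES[ss$counts[, j] > 0L]
    cod <- strsplit(codons[k], "")[[1L]]
    mk <- function(b) { m <- cod; m[p] <- b; paste(m, collapse = "") }
    aa1 <- translate_codon(mk(alleles[1L]))
    aa2 <- translate_codon(mk(alleles[2L]))
    silent <- identical(aa1, aa2)
    c1 <- ss$count1[j]
    contrib <- 2 * c1 * (n - c1) / (n * (n - 1))
    if (silent) {
      pi_syn <- pi_syn + contrib; n_syn <- n_syn + 1L
    } else {
      pi_nonsyn <- pi_nonsyn + contrib; n_nonsyn <- n_nonsyn + 1L
    }
  }
  list(syn_sites = syn_sites, nonsyn_sites = nonsyn_sites,
       theta_pi_syn = if (syn_sites > 0) pi_syn / syn_sites else NA_real_,
       theta_pi_nonsyn = if (nonsyn_sites > 0) pi_nonsyn / nonsyn_sites
                         else NA_real_,
       n_syn_poly = n_syn, n_nonsyn_poly = n_nonsyn,
       internal_stop = FALSE)
}
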