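# Interspecific HGT detection: shared polymorphisms vs fixed differences at
# ortholog pairs, classification at the ratio > 0.2 rule, and clustering of
# flagged genes into contiguous transferred regions.

#' Fixed differences and shared polymorphisms at an ortholog pair
#'
#' Over the complete biallelic columns of the joint two-species alignment:
#' a column is a fixed difference when each species is monomorphic but for
#' different bases, and a shared polymorphism when both species segregate
#' (necessarily for the same two alleles, given the biallelic restriction).
#'
#' @param aln_a,aln_b gene alignments of the two species (same gene,
#'   equal lengths; each with at least two strains).
#' @return list with `fixed`, `shared` and `detail` (the per-column
#'   biallelic table with a `class` column:
#'   fixed / shared / private_a / private_b).
#' @export
shared_fixed_counts <- function(aln_a, aln_b) {
  if (!ncol(aln_a) || !ncol(aln_b)) stop("empty alignment")
  if (nrow(aln_a) < 2L || nrow(aln_b) < 2L)
    stop("each species needs >= 2 strains")
  bs <- biallelic_sites(aln_a, aln_b)
  bs <- bs[bs$complete, , drop = FALSE]
  if (!nrow(bs)) {
    bs$class <- character(0)
    return(list(fixed = 0L, shared = 0L, detail = bs))
  }
  poly_a <- bs$n1_a > 0L & bs$n2_a > 0L
  poly_b <- bs$n1_b > 0L & bs$n2_b > 0L
  mono_a <- !poly_a
  mono_b <- !poly_b
  fixed <- mono_a & mono_b  # biallelic + both monomorphic => different bases
  shared <- poly_a & poly_b
  bs$class <- ifelse(fixed, "fixed",
                     ifelse(shared, "shared",
                            ifelse(poly_a, "private_a", "private_b")))
  list(fixed = sum(fixed), shared = sum(shared), detail = bs)
}

#' Classify an ortholog pair as putatively transferred
#'
#' Flags the gene when the ratio of shared polymorphisms to fixed
#' differences exceeds `threshold` (strictly).  With `fixed = 0` the ratio
#' is taken as `+Inf` when `shared > 0` (flagged) and is undefined for
#' `0/0` (not flagged), preserving monotonicity in both counts.
#'
#' @param fixed,shared non-negative counts.
#' @param threshold ratio threshold (default 0.2, strict).
#' @return list with `ratio` (may be `Inf` or `NA`) and `flag`.
#' @export
hgt_classify <- function(fixed, shared, threshold = 0.2) {
  if (fixed < 0 || shared < 0) stop("counts must be non-negative")
  if (fixed == 0 && shared == 0)
    return(list(ratio = NA_real_, flag = FALSE))
  ratio <- if (fixed == 0) Inf else shared / fixed
  list(ratio = ratio, flag = ratio > threshold)
}

#' Cluster flagged genes into contiguous transferred regions
#'
#' Two flagged genes belong to one region iff every gene between them either
#' lacks an ortholog in the other species (any number of such genes) or has
#' a shared:fixed ratio below `threshold`, with at most `max_low_ratio` such
#' low-ratio orthologous genes in any single gap between consecutive flagged
#' members.  Genes with an ortholog but no computable ratio (no biallelic
#' data) are treated as low-ratio.  Regions are maximal; the first and last
#' members are flagged genes.
#'
#' @param records data frame with one row per gene, ordered by `start`
#'   within each `replicon`: columns `locus_tag`, `replicon`, `start`,
#'   `end`, `has_ortholog`, `ratio` (NA allowed), `flagged`.
#' @param threshold low-ratio cutoff (same value as in [hgt_classify()]).
#' @param max_low_ratio maximum number of low-ratio orthologous genes
#'   tolerated in one gap.
#' @return data frame of regions: `replicon`, `span_start`, `span_end`,
#'   `n_flagged`, `n_genes` (all genes in the span), `n_no_ortholog`,
#'   `n_low_ratio`, `members` (comma-separated flagged locus tags).
#' @export
cluster_transfer_regions <- function(records, threshold = 0.2,
                                     max_low_ratio = 2L) {
  need <- c("locus_tag", "replicon", "start", "end", "has_ortholog",
            "ratio", "flagged")
  if (!all(need %in% names(records))) stop("records lack required columns")
  out <- list()
  for (rep_name in unique(records$replicon)) {
    rr <- records[records$replicon == rep_name, , drop = FALSE]
    if (is.unsorted(rr$start, strictly = FALSE))
      stop("records must be ordered by start within each replicon")
    fl <- which(rr$flagged)
    if (!length(fl)) next
    low_ok <- !rr$has_ortholog |
      (is.na(rr$ratio) | rr$ratio < threshold)
    counts_budget <- rr$has_ortholog & (is.na(rr$ratio) |
                                          rr$ratio < threshold)
    groups <- list(fl[1L])
    if (length(fl) > 1L) {
      for (k in 2L:length(fl)) {
        prev <- fl[k - 1L]; cur <- fl[k]
        between <- if (cur - prev > 1L) (prev + 1L):(cur - 1L) else integer()
        joinable <- all(low_ok[between]) &&
          sum(counts_budget[between]) <= max_low_ratio
        if (joinable) {
          groups[[length(groups)]] <- c(groups[[length(groups)]], cur)
        } else {
          groups[[length(groups) + 1L]] <- cur
        }
      }
    }
    for (g in groups) {
      lo <- min(g); hi <- max(g)
      inside <- lo:hi
      out[[length(out) + 1L]] <- data.frame(
        replicon = rep_name,
        span_start = rr$start[lo], span_end = rr$end[hi],
        n_flagged = length(g), n_genes = length(inside),
        n_no_ortholog = sum(!rr$has_ortholog[inside]),
        n_low_ratio = sum(counts_budget[inside] & !rr$flagged[inside]),
        members = paste(rr$locus_tag[g], collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(replicon = character(), span_start = integer(),
                      span_end = integer(), n_flagged = integer(),
                      n_genes = integer(), n_no_ortholog = integer(),
                      n_low_ratio = integer(), members = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}
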