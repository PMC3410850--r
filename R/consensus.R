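# Per-site consensus calling from read-count evidence, with gene- and
# window-level coverage eligibility.  A base is called only when read depth
# lies in [min_depth, max_depth) and the majority base is supported by at
# least min_frac of the reads; everything else is ambiguous (N).

#' Call a single site from per-base read counts
#'
#' Returns base `b` iff the total depth `d` satisfies
#' `min_depth <= d < max_depth` and `count(b) / d >= min_frac`; otherwise
#' `"N"`.  With the default `min_frac = 0.70` two bases can never qualify
#' simultaneously, so the call is unambiguous; exact 70% support passes
#' (the rule is `>=`).
#'
#' @param counts numeric vector of length 4 (reads supporting A, C, G, T).
#' @param min_depth inclusive lower depth bound.
#' @param max_depth exclusive upper depth bound (use `Inf` to disable).
#' @param min_frac minimum fraction of reads supporting the called base.
#' @return single character in `A`, `C`, `G`, `T`, `N`.
#' @export
call_site <- function(counts, min_depth = 10, max_depth = 500,
                      min_frac = 0.70) {
  if (length(counts) != 4L || any(counts < 0))
    stop("counts must be 4 non-negative numbers (A, C, G, T)")
  d <- sum(counts)
  if (d < min_depth || d >= max_depth || d == 0) return("N")
  i <- which.max(counts)
  if (counts[i] / d >= min_frac) DNA_BASES[i] else "N"
}

#' Call a consensus matrix from a read-count table
#'
#' Applies the [call_site()] rule at every strain-position of a read-count
#' table.  Positions absent from the table carry no aligned evidence and are
#' `N`.
#'
#' @param table data frame with columns `strain`, `pos0` (0-based position)
#'   and `nA`, `nC`, `nG`, `nT`; duplicate strain-position rows are an error.
#' @param strains character vector of strain ids (matrix rows, in order).
#' @param replicon_length number of positions (matrix columns).
#' @inheritParams call_site
#' @return character matrix (strains x positions) over A/C/G/T/N.
#' @export
call_matrix <- function(table, strains, replicon_length, min_depth = 10,
                        max_depth = 500, min_frac = 0.70) {
  need <- c("strain", "pos0", "nA", "nC", "nG", "nT")
  if (!all(need %in% names(table))) stop("table lacks required columns")
  if (any(table$pos0 < 0L) || any(table$pos0 >= replicon_length))
    stop("positions outside replicon")
  if (anyDuplicated(paste(table$strain, table$pos0)))
    stop("duplicate strain-position rows")
  if (!all(table$strain %in% strains)) stop("unknown strain in table")
  m <- matrix("N", length(strains), replicon_length,
              dimnames = list(strains, NULL))
  if (!nrow(table)) return(m)
  cm <- as.matrix(table[, c("nA", "nC", "nG", "nT")])
  if (any(cm < 0)) stop("negative read counts")
  d <- rowSums(cm)
  mx <- max.col(cm, ties.method = "first")
  mv <- cm[cbind(seq_len(nrow(cm)), mx)]
  ok <- d >= min_depth & d < max_depth & d > 0 & (mv / pmax(d, 1)) >= min_frac
  base <- ifelse(ok, DNA_BASES[mx], "N")
  m[cbind(match(table$strain, strains), table$pos0 + 1L)] <- base
  m
}

#' Turn a consensus matrix back into a read-count table
#'
#' Every called base becomes a single supporting read; `N` positions are
#' omitted.  Re-calling the result with thresholds `(1, Inf, 1)` reproduces
#' the matrix, which is the caller's idempotence property.
#'
#' @param matrix consensus matrix (strains x positions, A/C/G/T/N).
#' @param replicon replicon name recorded in the table.
#' @return read-count data frame as in [simulate_pileup()].
#' @export
consensus_to_counts <- function(matrix, replicon = "replicon") {
  idx <- which(matrix != "N", arr.ind = TRUE)
  b <- match(matrix[idx], DNA_BASES)
  counts <- base::matrix(0L, nrow(idx), 4L)
  counts[cbind(seq_len(nrow(idx)), b)] <- 1L
  data.frame(strain = rownames(matrix)[idx[, 1L]], replicon = replicon,
             pos0 = idx[, 2L] - 1L, nA = counts[, 1L], nC = counts[, 2L],
             nG = counts[, 3L], nT = counts[, 4L], stringsAsFactors = FALSE)
}

#' Gene-level coverage eligibility
#'
#' A gene is eligible when at least `strain_frac` of the strains have
#' unambiguous calls for more than `site_frac` of the gene length (the
#' "data for >90% of the gene length for >=80% of the strains" rule).
#'
#' @param matrix consensus matrix.
#' @param gene a list or one-row data frame with `start` and `end` (1-based,
#'   inclusive).
#' @param strain_frac minimum fraction of strains that must pass.
#' @param site_frac per-strain fraction of callable sites that must be
#'   exceeded (strict).
#' @return list with `eligible` (flag) and `mask` (per-strain data frame of
#'   callable fractions and pass flags).
#' @export
gene_eligibility <- function(matrix, gene, strain_frac = 0.8,
                             site_frac = 0.9) {
  start <- gene$start; end <- gene$end
  if (is.null(start) || is.null(end) || end < start)
    stop("invalid gene coordinates")
  if (end == start - 1L) stop("zero-length gene")
  if (start < 1L || end > ncol(matrix)) stop("gene outside replicon")
  sub <- matrix[, start:end, drop = FALSE]
  frac <- rowMeans(sub != "N")
  pass <- frac > site_frac
  eligible <- sum(pass) >= strain_frac * nrow(matrix)
  list(eligible = eligible,
       mask = data.frame(strain = rownames(matrix) %||%
                           seq_len(nrow(matrix)),
                         callable_frac = unname(frac), pass = unname(pass),
                         stringsAsFactors = FALSE))
}

#' Window-level coverage eligibility
#'
#' A 10-kb grid window is eligible when strictly more than `min_bp` of its
#' sites are called in strictly more than `strain_frac` of the strains
#' (">8,000 bp covered in >80% of strains").
#'
#' @param matrix consensus matrix.
#' @param start 1-based window start; must lie on the non-overlapping grid
#'   (`start - 1` a multiple of `window`).
#' @param window window width in bp.
#' @param min_bp number of qualifying sites that must be exceeded (strict).
#' @param strain_frac fraction of strains that must be exceeded per site
#'   (strict).
#' @return logical flag.
#' @export
window_eligibility <- function(matrix, start, window = 10000L,
                               min_bp = 8000L, strain_frac = 0.8) {
  if ((start - 1L) %% window != 0L)
    stop("window start not aligned to the grid")
  end <- min(start + window - 1L, ncol(matrix))
  sub <- matrix[, start:end, drop = FALSE]
  qualifying <- colSums(sub != "N") > strain_frac * nrow(matrix)
  sum(qualifying) > min_bp
}

#' Write / read a consensus matrix as multi-FASTA
#'
#' Strains are records; ambiguity is `N`.
#' @param matrix consensus matrix.
#' @param path file path.
#' @return `write_consensus_fasta` returns the path invisibly;
#'   `read_consensus_fasta` returns the matrix.
#' @export
write_consensus_fasta <- function(matrix, path) {
  seqs <- apply(matrix, 1L, paste, collapse = "")
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- rownames(matrix)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname write_consensus_fasta
#' @export
read_consensus_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  m <- do.call(rbind, strsplit(as.character(x), ""))
  rownames(m) <- names(x)
  m
}
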