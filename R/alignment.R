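# Alignment bookkeeping and standard-format I/O: gene extraction with strand
# handling, concatenation, biallelic-site enumeration, FASTA / GFF3 /
# ortholog-map readers and writers.  Internally alignments are character
# matrices (strains x columns) over A/C/G/T/N; genomic coordinates are
# 1-based inclusive at the interfaces (GFF3 convention).

# reverse complement of an alignment matrix; N maps to N
revcomp_alignment <- function(aln) {
  m <- chartr("ACGTN", "TGCAN", aln[, rev(seq_len(ncol(aln))), drop = FALSE])
  m
}

#' Extract a gene alignment from a consensus matrix
#'
#' Rows are the strain calls over `[start, end]`; minus-strand genes are
#' reverse-complemented so the rows read in the coding direction.
#'
#' @param matrix consensus matrix (strains x positions).
#' @param gene list or one-row data frame with `start`, `end` (1-based,
#'   inclusive), `strand` (`"+"`/`"-"`) and optionally `locus_tag`.
#' @return character alignment matrix with attributes `locus_tag` and
#'   `strand`.
#' @export
extract_gene_alignment <- function(matrix, gene) {
  if (gene$end < gene$start) stop("invalid gene coordinates")
  if (gene$start < 1L || gene$end > ncol(matrix))
    stop("gene outside replicon bounds")
  sub <- matrix[, gene$start:gene$end, drop = FALSE]
  strand <- gene$strand %||% "+"
  if (identical(strand, "-")) sub <- revcomp_alignment(sub)
  attr(sub, "locus_tag") <- gene$locus_tag %||% NA_character_
  attr(sub, "strand") <- strand
  sub
}

#' Concatenate gene alignments over a shared strain set
#'
#' Row-wise concatenation in the given order; all alignments must carry the
#' same strains (rows are matched by name to the first alignment's order).
#'
#' @param alignments list of alignment matrices with row names.
#' @return a single alignment matrix; total length is the sum of the parts.
#' @export
concatenate_alignments <- function(alignments) {
  if (!length(alignments)) stop("no alignments to concatenate")
  ref <- rownames(alignments[[1L]])
  if (is.null(ref)) stop("alignments must have strain row names")
  parts <- lapply(alignments, function(a) {
    if (is.null(rownames(a)) || !setequal(rownames(a), ref))
      stop("strain sets differ between alignments")
    a[ref, , drop = FALSE]
  })
  do.call(cbind, parts)
}

#' Enumerate biallelic sites of a paired two-species alignment
#'
#' Returns exactly the columns at which the union of both species' calls
#' shows two distinct non-N bases, together with per-species allele counts.
#' Columns containing N in some strains are still considered (counts are over
#' non-N calls); a completeness requirement, where needed, is applied by the
#' downstream statistic.
#'
#' @param aln_a,aln_b alignment matrices of the two species over the same
#'   gene; equal column counts required.
#' @return data frame with one row per biallelic column: `col`, `allele1`,
#'   `allele2` (alphabetical), counts `n1_a`, `n2_a`, `n1_b`, `n2_b`, and
#'   `complete` (no N anywhere in the column).
#' @export
biallelic_sites <- function(aln_a, aln_b) {
  if (ncol(aln_a) != ncol(aln_b)) stop("alignment length mismatch")
  joint <- rbind(aln_a, aln_b)
  cnt <- base_counts(joint)
  nal <- colSums(cnt > 0L)
  keep <- which(nal == 2L)
  if (!length(keep))
    return(data.frame(col = integer(), allele1 = character(),
                      allele2 = character(), n1_a = integer(),
                      n2_a = integer(), n1_b = integer(), n2_b = integer(),
                      complete = logical(), stringsAsFactors = FALSE))
  cnt_a <- base_counts(aln_a)[, keep, drop = FALSE]
  cnt_b <- base_counts(aln_b)[, keep, drop = FALSE]
  sub <- cnt[, keep, drop = FALSE]
  a1 <- apply(sub > 0L, 2L, function(z) which(z)[1L])
  a2 <- apply(sub > 0L, 2L, function(z) which(z)[2L])
  pick <- function(m, i) m[cbind(i, seq_along(i))]
  nn <- colSums(joint[, keep, drop = FALSE] == "N")
  data.frame(col = keep,
             allele1 = DNA_BASES[a1], allele2 = DNA_BASES[a2],
             n1_a = pick(cnt_a, a1), n2_a = pick(cnt_a, a2),
             n1_b = pick(cnt_b, a1), n2_b = pick(cnt_b, a2),
             complete = nn == 0L, stringsAsFactors = FALSE)
}

# 4 x L matrix of per-column base counts (N ignored)
base_counts <- function(aln) {
  out <- matrix(0L, 4L, ncol(aln), dimnames = list(DNA_BASES, NULL))
  for (b in seq_along(DNA_BASES))
    out[b, ] <- as.integer(colSums(aln == DNA_BASES[b]))
  out
}

#' FASTA alignment I/O
#'
#' Alignments travel as multi-FASTA with strains as records.
#' @param aln alignment matrix.
#' @param path file path.
#' @return `write_alignment_fasta` returns the path invisibly;
#'   `read_alignment_fasta` returns the alignment matrix.
#' @export
write_alignment_fasta <- function(aln, path) {
  write_consensus_fasta(aln, path)
}

#' @rdname write_alignment_fasta
#' @export
read_alignment_fasta <- function(path) {
  read_consensus_fasta(path)
}

#' Gene model I/O (GFF3)
#'
#' Gene models use 1-based inclusive coordinates with strand, carried in the
#' standard GFF3 format; `locus_tag` travels as the feature `ID`.
#'
#' @param genes data frame with `locus_tag`, `replicon`, `start`, `end`,
#'   `strand`.
#' @param path file path.
#' @return `write_gene_models` returns the path invisibly;
#'   `read_gene_models` returns the gene-model data frame.
#' @export
write_gene_models <- function(genes, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = genes$replicon,
    ranges = IRanges::IRanges(start = genes$start, end = genes$end),
    strand = genes$strand)
  S4Vectors::mcols(gr)$ID <- genes$locus_tag
  S4Vectors::mcols(gr)$type <- "gene"
  rtracklayer::export(gr, path, format = "GFF3")
  invisible(path)
}

#' @rdname write_gene_models
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "GFF3")
  data.frame(locus_tag = S4Vectors::mcols(gr)$ID,
             replicon = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}

#' Ortholog map I/O (TSV)
#'
#' One-to-one ortholog pairing between the two species, as a two-column TSV
#' (`locus_tag_a`, `locus_tag_b`).
#' @param map data frame with `locus_tag_a`, `locus_tag_b`.
#' @param path file path.
#' @return `write_ortholog_map` returns the path invisibly;
#'   `read_ortholog_map` returns the map.
#' @export
write_ortholog_map <- function(map, path) {
  if (anyDuplicated(map$locus_tag_a) || anyDuplicated(map$locus_tag_b))
    stop("ortholog map must be one-to-one")
  write.table(map[, c("locus_tag_a", "locus_tag_b")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ortholog_map
#' @export
read_ortholog_map <- function(path) {
  map <- read.delim(path, stringsAsFactors = FALSE)
  if (anyDuplicated(map$locus_tag_a) || anyDuplicated(map$locus_tag_b))
    stop("ortholog map must be one-to-one")
  map
}

#' Write a simulated cohort to standard formats
#'
#' Emits, under `dir`: per-gene per-species multi-FASTA alignments
#' (`genes/<tag>_<species>.fasta`), GFF3 gene models per species, the
#' ortholog map TSV, and the ground-truth TSV.
#'
#' @param cohort a `sim_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "genes"), recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(nrow(cohort$truth))) {
    tag_a <- cohort$truth$locus_tag_a[i]
    aln <- cohort$alignments[[tag_a]]
    write_alignment_fasta(aln[cohort$strains_a, , drop = FALSE],
                          file.path(dir, "genes", paste0(tag_a, "_A.fasta")))
    write_alignment_fasta(aln[cohort$strains_b, , drop = FALSE],
                          file.path(dir, "genes",
                                    paste0(cohort$truth$locus_tag_b[i],
                                           "_B.fasta")))
  }
  write_gene_models(cohort$genes_a, file.path(dir, "genes_a.gff3"))
  write_gene_models(cohort$genes_b, file.path(dir, "genes_b.gff3"))
  write_ortholog_map(cohort$orthologs, file.path(dir, "orthologs.tsv"))
  write.table(cohort$truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}
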