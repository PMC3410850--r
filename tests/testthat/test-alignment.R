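# gene extraction, strand handling, concatenation, biallelic enumeration,
# and the standard-format readers/writers

test_that("plus- and minus-strand extraction agree with a reverse-complement oracle", {
  m <- matrix(rep(c("A", "C", "G", "T", "N", "A"), 3), nrow = 3,
              byrow = TRUE)
  rownames(m) <- c("x", "y", "z")
  gplus <- list(start = 1L, end = 3L, strand = "+")
  expect_identical(unname(extract_gene_alignment(m, gplus)[1, ]),
                   c("A", "C", "G"))
  gminus <- list(start = 1L, end = 3L, strand = "-")
  got <- extract_gene_alignment(m, gminus)
  # independent oracle via Biostrings
  oracle <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString("ACG")))
  expect_identical(paste(got[1, ], collapse = ""), oracle)
  # N maps to N under reverse complement
  m2 <- matrix(c("N", "N", "A"), 1, 3)
  rownames(m2) <- "w"
  got2 <- extract_gene_alignment(m2, list(start = 1L, end = 3L,
                                          strand = "-"))
  expect_identical(unname(got2[1, ]), c("T", "N", "N"))
  expect_error(extract_gene_alignment(m, list(start = 2L, end = 9L,
                                              strand = "+")), "bounds")
})

test_that("random minus-strand extractions match Biostrings", {
  set.seed(31)
  m <- rand_alignment(4, 60, miss = 0.1)
  got <- extract_gene_alignment(m, list(start = 11L, end = 40L,
                                        strand = "-"))
  for (i in 1:4) {
    oracle <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(paste(m[i, 11:40], collapse = ""))))
    expect_identical(paste(got[i, ], collapse = ""), oracle)
  }
})

test_that("concatenation preserves order, length, and strain sets", {
  a <- matrix(c("A", "C", "G", "T", "A", "C"), 2, 3,
              dimnames = list(c("s1", "s2"), NULL))
  b <- matrix(c("T", "T", "G", "G", "C", "C"), 2, 3,
              dimnames = list(c("s2", "s1"), NULL))
  expect_identical(concatenate_alignments(list(a)), a)
  cc <- concatenate_alignments(list(a, b))
  expect_identical(ncol(cc), 6L)
  expect_identical(unname(cc["s1", 4:6]), unname(b["s1", ]))
  bad <- matrix("A", 2, 2, dimnames = list(c("s1", "s3"), NULL))
  expect_error(concatenate_alignments(list(a, bad)), "strain sets")
  # length additivity over a random batch
  set.seed(32)
  parts <- lapply(c(5, 9, 14), function(L) rand_alignment(3, L))
  expect_identical(ncol(concatenate_alignments(parts)), 28L)
})

test_that("extract then concatenate commutes with column subsetting", {
  set.seed(33)
  m <- rand_alignment(5, 90)
  g1 <- list(start = 1L, end = 30L, strand = "+")
  g2 <- list(start = 31L, end = 90L, strand = "+")
  whole <- concatenate_alignments(list(extract_gene_alignment(m, g1),
                                       extract_gene_alignment(m, g2)))
  expect_identical(unname(whole), unname(m))
})

test_that("biallelic site enumeration matches hand-worked cases", {
  # column 1 monomorphic, column 2 biallelic A/T with A:2,T:1 in species A
  # and T:2 in species B, column 3 tri-allelic
  A <- matrix(c("C", "A", "A",
                "C", "A", "C",
                "C", "T", "G"), 3, 3)
  B <- matrix(c("C", "T", "A",
                "C", "T", "A"), 2, 3, byrow = FALSE)
  A <- matrix(c("C", "C", "C",  # col1
                "A", "A", "T",  # col2
                "A", "C", "G"), # col3
              nrow = 3)
  rownames(A) <- paste0("a", 1:3)
  B <- matrix(c("C", "C",
                "T", "T",
                "A", "A"), nrow = 2)
  rownames(B) <- paste0("b", 1:2)
  bs <- biallelic_sites(A, B)
  expect_identical(bs$col, 2L)
  expect_identical(bs$allele1, "A")
  expect_identical(bs$allele2, "T")
  expect_identical(bs$n1_a, 2L); expect_identical(bs$n2_a, 1L)
  expect_identical(bs$n1_b, 0L); expect_identical(bs$n2_b, 2L)
  expect_error(biallelic_sites(A, B[, 1:2]), "length mismatch")
})

test_that("biallelic sites are invariant to strain order", {
  set.seed(34)
  A <- rand_alignment(6, 50, miss = 0.05)
  B <- rand_alignment(4, 50, miss = 0.05)
  b1 <- biallelic_sites(A, B)
  b2 <- biallelic_sites(A[sample(6), ], B[sample(4), ])
  expect_identical(b1, b2)
})

test_that("gene models survive a GFF3 round trip", {
  genes <- data.frame(locus_tag = c("g1", "g2"),
                      replicon = c("chr", "chr"),
                      start = c(10L, 200L), end = c(99L, 350L),
                      strand = c("+", "-"), stringsAsFactors = FALSE)
  f <- tempfile(fileext = ".gff3")
  write_gene_models(genes, f)
  back <- read_gene_models(f)
  expect_identical(back[, names(genes)], genes)
  unlink(f)
})

test_that("ortholog maps round-trip and must be one-to-one", {
  map <- data.frame(locus_tag_a = c("a1", "a2"),
                    locus_tag_b = c("b1", "b2"), stringsAsFactors = FALSE)
  f <- tempfile(fileext = ".tsv")
  write_ortholog_map(map, f)
  expect_identical(read_ortholog_map(f), map)
  bad <- data.frame(locus_tag_a = c("a1", "a1"),
                    locus_tag_b = c("b1", "b2"))
  expect_error(write_ortholog_map(bad, f), "one-to-one")
  unlink(f)
})

test_that("write_cohort emits the expected artifact set", {
  co <- small_cohort(35, n_genes = 3L, L = 60L)
  d <- tempfile()
  write_cohort(co, d)
  expect_true(file.exists(file.path(d, "orthologs.tsv")))
  expect_true(file.exists(file.path(d, "truth.tsv")))
  expect_true(file.exists(file.path(d, "genes_a.gff3")))
  fa <- list.files(file.path(d, "genes"), pattern = "fasta$")
  expect_identical(length(fa), 6L)  # 3 genes x 2 species
  # alignments round-trip
  back <- read_alignment_fasta(
    file.path(d, "genes", paste0(co$truth$locus_tag_a[1], "_A.fasta")))
  expect_identical(back,
                   co$alignments[[1]][co$strains_a, , drop = FALSE])
  unlink(d, recursive = TRUE)
})
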