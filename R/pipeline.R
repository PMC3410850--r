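# End-to-end orchestration: simulate (or load) a two-species cohort, call
# consensus, compute per-gene and windowed statistics, detect HGT, scan for
# selection, build genealogies, contrast chromosome halves, and render the
# aggregate report tables.

#' Pipeline configuration
#'
#' All thresholds default to the study values: calling depth \[10, 500) with
#' 70% agreement, gene eligibility >90% of sites in >=80% of strains,
#' window eligibility >8,000 bp in >80% of strains on a 10-kb grid, HGT
#' ratio > 0.2, 5% joint D-H tails, 200 bootstrap replicates with an 80%
#' collapse cutoff, and ts/tv 2.0.
#'
#' @param sim a [sim_config()] describing the synthetic cohort.
#' @param mode `"fasta"` (use the true alignments directly) or `"pileup"`
#'   (simulate read counts and run the consensus caller).
#' @param mean_depth,error_rate pileup parameters for `mode = "pileup"`.
#' @param min_depth,max_depth,min_frac consensus-calling thresholds.
#' @param gene_site_frac,gene_strain_frac gene eligibility thresholds.
#' @param window,window_min_bp,window_strain_frac window-scan settings.
#' @param hgt_threshold shared:fixed ratio cutoff (strict).
#' @param tail_q,tail_scale joint-scan tail settings (see [dth_scan()]).
#' @param bootstrap_reps,collapse_cutoff,tstv genealogy settings.
#' @param tree_genes optional cap on the number of genes concatenated per
#'   replicon for the genealogies (`NULL` = all eligible ortholog genes).
#' @param chromosome name of the replicon split into halves.
#' @param split split coordinate; `NULL` uses the chromosome midpoint.
#' @param codon_partition compute the synonymous/nonsynonymous partition
#'   per gene.
#' @param seed integer seed for the pileup and bootstrap stages.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(sim = sim_config(),
                            mode = c("fasta", "pileup"),
                            mean_depth = 100, error_rate = 0.005,
                            min_depth = 10, max_depth = 500,
                            min_frac = 0.70,
                            gene_site_frac = 0.9, gene_strain_frac = 0.8,
                            window = 10000L, window_min_bp = 8000L,
                            window_strain_frac = 0.8,
                            hgt_threshold = 0.2,
                            tail_q = 0.05,
                            tail_scale = c("eligible", "total"),
                            bootstrap_reps = 200L, collapse_cutoff = 80,
                            tstv = 2.0, tree_genes = NULL,
                            chromosome = "chromosome", split = NULL,
                            codon_partition = FALSE, seed = 1L) {
  cfg <- list(sim = sim, mode = match.arg(mode), mean_depth = mean_depth,
              error_rate = error_rate, min_depth = min_depth,
              max_depth = max_depth, min_frac = min_frac,
              gene_site_frac = gene_site_frac,
              gene_strain_frac = gene_strain_frac, window = window,
              window_min_bp = window_min_bp,
              window_strain_frac = window_strain_frac,
              hgt_threshold = hgt_threshold, tail_q = tail_q,
              tail_scale = match.arg(tail_scale),
              bootstrap_reps = as.integer(bootstrap_reps),
              collapse_cutoff = collapse_cutoff, tstv = tstv,
              tree_genes = tree_genes, chromosome = chromosome,
              split = split, codon_partition = codon_partition,
              seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

# stable fingerprint of a configuration, carried on every output table
config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(config, control = "all"), f)
  unname(tools::md5sum(f))
}

# consensus matrices for one species, either directly from truth or through
# the simulated-pileup -> caller path
stage_consensus <- function(cohort, config, species) {
  reps <- unique(cohort$truth$replicon)
  genes <- if (species == "A") cohort$genes_a else cohort$genes_b
  strains <- if (species == "A") cohort$strains_a else cohort$strains_b
  out <- list()
  for (rp in reps) {
    if (config$mode == "fasta") {
      out[[rp]] <- cohort_consensus_matrix(cohort, species, rp)
    } else {
      gsub_ <- genes[genes$replicon == rp, , drop = FALSE]
      tags_a <- cohort$genes_a$locus_tag[cohort$genes_a$replicon == rp]
      len <- max(gsub_$end) + cohort$config$spacer
      m <- matrix("N", length(strains), len,
                  dimnames = list(strains, NULL))
      for (i in seq_len(nrow(gsub_))) {
        truth_aln <- cohort$alignments[[tags_a[i]]][strains, ,
                                                    drop = FALSE]
        pl <- simulate_pileup(truth_aln, config$mean_depth,
                              config$error_rate, replicon = rp,
                              offset = gsub_$start[i] - 1L)
        called <- call_matrix(pl, strains, len, config$min_depth,
                              config$max_depth, config$min_frac)
        cols <- gsub_$start[i]:gsub_$end[i]
        m[, cols] <- called[, cols]
      }
      out[[rp]] <- m
    }
  }
  out
}

# per-gene alignments and coverage eligibility for one species
stage_extract <- function(cohort, config, matrices, species) {
  genes <- if (species == "A") cohort$genes_a else cohort$genes_b
  alns <- vector("list", nrow(genes))
  elig <- logical(nrow(genes))
  for (i in seq_len(nrow(genes))) {
    gene <- genes[i, ]
    m <- matrices[[gene$replicon]]
    elig[i] <- gene_eligibility(m, gene, config$gene_strain_frac,
                                config$gene_site_frac)$eligible
    alns[[i]] <- extract_gene_alignment(m, gene)
  }
  names(alns) <- genes$locus_tag
  list(alignments = alns, eligible = elig)
}

# per-gene statistics for one species, polarised against the sister
# species' ortholog consensus (built from the sister's called alignment)
stage_gene_stats <- function(cohort, config, species, own, sister) {
  genes <- if (species == "A") cohort$genes_a else cohort$genes_b
  tag_col <- if (species == "A") "locus_tag_a" else "locus_tag_b"
  sis_tags <- if (species == "A") cohort$truth$locus_tag_b else
    cohort$truth$locus_tag_a
  orth <- cohort$orthologs
  rows <- vector("list", nrow(genes))
  for (i in seq_len(nrow(genes))) {
    gene <- genes[i, ]
    has_orth <- gene$locus_tag %in% orth[[tag_col]]
    outg <- if (has_orth)
      consensus_sequence(sister$alignments[[sis_tags[i]]]) else NULL
    gs <- gene_stats(own$alignments[[i]], outgroup = outg,
                     locus_tag = gene$locus_tag,
                     frame = isTRUE(config$codon_partition))
    gs$replicon <- gene$replicon
    gs$start <- gene$start
    gs$end <- gene$end
    gs$eligible <- own$eligible[i]
    gs$has_ortholog <- has_orth
    rows[[i]] <- gs
  }
  list(stats = do.call(rbind, rows), alignments = own$alignments)
}

# shared/fixed counting and HGT classification over ortholog pairs that
# meet coverage in both species
stage_hgt <- function(cohort, config, stats_a, stats_b, alns_a, alns_b) {
  genes <- cohort$truth
  rows <- vector("list", nrow(genes))
  for (i in seq_len(nrow(genes))) {
    ta <- genes$locus_tag_a[i]; tb <- genes$locus_tag_b[i]
    has_orth <- genes$has_ortholog[i]
    fixed <- NA_integer_; shared <- NA_integer_
    ratio <- NA_real_; flag <- FALSE
    if (has_orth) {
      ok_a <- stats_a$eligible[stats_a$locus_tag == ta]
      ok_b <- stats_b$eligible[stats_b$locus_tag == tb]
      if (isTRUE(ok_a) && isTRUE(ok_b)) {
        sf <- shared_fixed_counts(alns_a[[ta]], alns_b[[tb]])
        cl <- hgt_classify(sf$fixed, sf$shared, config$hgt_threshold)
        fixed <- sf$fixed; shared <- sf$shared
        ratio <- cl$ratio; flag <- cl$flag
      }
    }
    rows[[i]] <- data.frame(
      locus_tag_a = ta, locus_tag_b = tb, replicon = genes$replicon[i],
      start = genes$start[i], end = genes$end[i],
      has_ortholog = has_orth, fixed = fixed, shared = shared,
      ratio = ratio, flagged = flag, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

# concatenated two-species alignment for one replicon's ortholog genes
stage_tree <- function(cohort, config, alns_a, alns_b, replicon,
                       stats_a, stats_b) {
  orth <- cohort$orthologs
  genes <- cohort$truth[cohort$truth$replicon == replicon &
                          cohort$truth$has_ortholog, , drop = FALSE]
  keep <- genes$locus_tag_a[
    genes$locus_tag_a %in% stats_a$locus_tag[stats_a$eligible] &
      genes$locus_tag_b %in% stats_b$locus_tag[stats_b$eligible]]
  if (!is.null(config$tree_genes))
    keep <- head(keep, config$tree_genes)
  if (length(keep) < 1L) return(NULL)
  joint <- lapply(keep, function(ta) {
    tb <- orth$locus_tag_b[orth$locus_tag_a == ta]
    rbind(alns_a[[ta]], alns_b[[tb]])
  })
  aln <- concatenate_alignments(joint)
  tr <- bootstrap_support(aln, config$bootstrap_reps, tstv = config$tstv)
  collapse_low_support(tr, config$collapse_cutoff)
}

#' Run the full pipeline on a synthetic cohort
#'
#' Executes call -> extract -> per-gene statistics -> shared/fixed + HGT ->
#' scan groups -> joint D-H scan -> genealogies -> chromosome-half
#' contrasts -> report tables.  Deterministic given the configuration (the
#' cohort seed drives the simulation; `config$seed` drives the pileup and
#' bootstrap stages).
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, all tables are written as
#'   TSV (with the config hash in a header comment) and trees as Newick.
#' @param trees build per-replicon genealogies (the slowest stage).
#' @return a report bundle (list) with elements `gene_stats_a`,
#'   `gene_stats_b`, `hgt_records`, `regions`, `candidates_a`,
#'   `candidates_b`, `window_stats_a`, `table1`, `table2_a`, `contrasts`,
#'   `trees`, `truth`, `config_hash`.
#' @export
run_pipeline <- function(config, out_dir = NULL, trees = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  cohort <- simulate_cohort(config$sim)
  set.seed(config$seed)
  mats_a <- stage_consensus(cohort, config, "A")
  mats_b <- stage_consensus(cohort, config, "B")
  ext_a <- stage_extract(cohort, config, mats_a, "A")
  ext_b <- stage_extract(cohort, config, mats_b, "B")
  sa <- stage_gene_stats(cohort, config, "A", ext_a, ext_b)
  sb <- stage_gene_stats(cohort, config, "B", ext_b, ext_a)
  hgt <- stage_hgt(cohort, config, sa$stats, sb$stats,
                   sa$alignments, sb$alignments)
  regions <- cluster_transfer_regions(
    data.frame(locus_tag = hgt$locus_tag_a, replicon = hgt$replicon,
               start = hgt$start, end = hgt$end,
               has_ortholog = hgt$has_ortholog, ratio = hgt$ratio,
               flagged = hgt$flagged, stringsAsFactors = FALSE),
    threshold = config$hgt_threshold)
  stats_a <- sa$stats
  stats_a$hgt <- hgt$flagged[match(stats_a$locus_tag, hgt$locus_tag_a)]
  stats_b <- sb$stats
  stats_b$hgt <- hgt$flagged[match(stats_b$locus_tag, hgt$locus_tag_b)]
  chr_genes <- stats_a[stats_a$replicon == config$chromosome, ,
                       drop = FALSE]
  split <- config$split %||%
    (if (nrow(chr_genes)) floor(max(chr_genes$end) / 2) else 1L)
  groups_a <- partition_groups(stats_a, config$chromosome, split)
  scan_one <- function(groups, n_total) {
    out <- lapply(groups, dth_scan, q = config$tail_q,
                  tail_scale = config$tail_scale, n_total = n_total)
    do.call(rbind, c(out, list(make.row.names = FALSE)))
  }
  candidates_a <- scan_one(groups_a, nrow(stats_a))
  groups_b <- lapply(split(stats_b, stats_b$replicon), function(df)
    make_scan_group(df, df$replicon[1L]))
  groups_b <- groups_b[vapply(groups_b, nrow, 1L) > 0L]
  candidates_b <- scan_one(groups_b, nrow(stats_b))
  win_a <- do.call(rbind, lapply(names(mats_a), function(rp)
    window_scan(mats_a[[rp]], config$window, config$window_min_bp,
                config$window_strain_frac, replicon = rp)))
  tree_list <- NULL
  if (isTRUE(trees)) {
    set.seed(config$seed + 1L)
    tree_list <- lapply(names(mats_a), function(rp)
      stage_tree(cohort, config, sa$alignments, sb$alignments, rp,
                 sa$stats, sb$stats))
    names(tree_list) <- names(mats_a)
    tree_list <- tree_list[!vapply(tree_list, is.null, TRUE)]
  }
  tab1_input <- hgt[hgt$has_ortholog & !is.na(hgt$fixed), , drop = FALSE]
  table1 <- table1_report(tab1_input)
  stats_a_half <- split_by_position(stats_a, split)
  stats_a_half$group <- ifelse(
    stats_a_half$replicon == config$chromosome,
    paste0(config$chromosome, "_", stats_a_half$half, "_half"),
    stats_a_half$replicon)
  table2 <- table2_report(stats_a_half)
  contrasts <- theta_contrast_table(
    data.frame(group = table2$group, value = table2$theta_pi_mean,
               stringsAsFactors = FALSE))
  bundle <- list(gene_stats_a = stats_a, gene_stats_b = stats_b,
                 hgt_records = hgt, regions = regions,
                 candidates_a = candidates_a, candidates_b = candidates_b,
                 window_stats_a = win_a, table1 = table1,
                 table2_a = table2, contrasts = contrasts,
                 trees = tree_list, truth = cohort$truth, split = split,
                 config_hash = config_hash(config))
  if (!is.null(out_dir)) write_report_bundle(bundle, out_dir)
  bundle
}

write_report_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hdr <- paste0("# config_hash: ", bundle$config_hash)
  wt <- function(df, name) {
    path <- file.path(out_dir, paste0(name, ".tsv"))
    con <- file(path, "w")
    writeLines(hdr, con)
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
  }
  for (nm in c("gene_stats_a", "gene_stats_b", "hgt_records", "regions",
               "candidates_a", "candidates_b", "window_stats_a",
               "table1", "table2_a", "contrasts", "truth"))
    if (!is.null(bundle[[nm]]) && nrow(bundle[[nm]]))
      wt(bundle[[nm]], nm)
  if (length(bundle$trees))
    for (rp in names(bundle$trees))
      ape::write.tree(bundle$trees[[rp]],
                      file.path(out_dir, paste0("tree_", rp, ".nwk")))
  invisible(out_dir)
}

#' Aggregate shared/fixed table by replicon and HGT class
#'
#' Per replicon and flag status: gene count, summed fixed differences,
#' summed shared polymorphisms, and the ratio of the sums (2 decimals;
#' `"-"` when undefined).
#'
#' @param records data frame with `replicon`, `flagged`, `fixed`, `shared`
#'   (one row per ortholog pair with computed counts).
#' @return aggregate data frame.
#' @export
table1_report <- function(records) {
  combos <- expand.grid(replicon = unique(records$replicon),
                        flagged = c(FALSE, TRUE),
                        stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(combos)), function(k) {
    sel <- records$replicon == combos$replicon[k] &
      records$flagged == combos$flagged[k]
    fx <- sum(records$fixed[sel]); sh <- sum(records$shared[sel])
    ratio <- if (fx > 0) sh / fx else if (sh > 0) Inf else NA_real_
    data.frame(replicon = combos$replicon[k],
               hgt = combos$flagged[k], genes = sum(sel),
               fixed = fx, shared = sh, ratio = ratio,
               ratio_label = if (is.na(ratio)) "-" else
                 if (is.infinite(ratio)) "Inf" else
                   sprintf("%.2f", ratio),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Diversity summary by group
#'
#' Per group: gene count, SNP total, mean per-gene theta-pi, pooled-site
#' theta-pi (total pairwise diversity over total analysed length), mean
#' synonymous theta-pi when available, and mean Tajima's D; only coverage-
#' eligible genes without evidence of transfer contribute.
#'
#' @param stats GeneStats data frame with a `group` column (plus `eligible`
#'   and `hgt` columns; missing columns admit every gene).
#' @return summary data frame, one row per group.
#' @export
table2_report <- function(stats) {
  eligible <- if ("eligible" %in% names(stats)) stats$eligible else TRUE
  hgt <- if ("hgt" %in% names(stats)) stats$hgt else FALSE
  use <- stats[eligible & !hgt, , drop = FALSE]
  rows <- lapply(split(use, use$group), function(df) {
    data.frame(
      group = df$group[1L], n_genes = nrow(df), snps = sum(df$S),
      theta_pi_mean = mean(df$theta_pi, na.rm = TRUE),
      theta_pi_pooled = sum(df$theta_pi * df$L_analyzed, na.rm = TRUE) /
        sum(df$L_analyzed[!is.na(df$theta_pi)]),
      theta_pi_syn_mean = if ("theta_pi_syn" %in% names(df))
        mean(df$theta_pi_syn, na.rm = TRUE) else NA_real_,
      tajima_d_mean = mean(df$tajima_d, na.rm = TRUE),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Diversity along a replicon
#'
#' Simple track plot of a per-gene or per-window statistic against start
#' coordinate.
#'
#' @param stats data frame with `start` and the chosen statistic.
#' @param stat column name to plot.
#' @param highlight optional logical vector marking points to emphasise.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, `NULL`.
#' @export
plot_diversity_track <- function(stats, stat = "tajima_d",
                                 highlight = NULL, ...) {
  graphics::plot(stats$start, stats[[stat]], pch = 20,
                 col = if (is.null(highlight)) "grey30" else
                   ifelse(highlight, "darkblue", "grey70"),
                 xlab = "position (bp)", ylab = stat, ...)
  invisible(NULL)
}

#' GC-skew profile plot
#'
#' @param profile data frame from [gc_skew_profile()].
#' @param terminus optional terminus coordinate drawn as a dashed line.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, `NULL`.
#' @export
plot_skew_profile <- function(profile, terminus = NULL, ...) {
  graphics::plot(profile$center, profile$skew, type = "l",
                 xlab = "position (bp)", ylab = "(G - C) / (G + C)", ...)
  graphics::abline(h = 0, col = "grey60")
  if (!is.null(terminus))
    graphics::abline(v = terminus, lty = 2, col = "firebrick")
  invisible(NULL)
}
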