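# Joint D_T-H empirical-tail scan for recent selective sweeps: genes in the
# lower q tail of both Tajima's D and Fay & Wu's H within an analysis group
# (a replicon, or a chromosome half) are candidate targets of selection.

#' Empirical lower-tail threshold
#'
#' The threshold is the value at rank `ceiling(q * m)` of the ascending sort
#' (`m` = group size); tail membership is `value <= threshold`, so ties at
#' the threshold are admitted.
#'
#' @param values numeric vector (no NA).
#' @param q tail fraction.
#' @return the threshold value.  Warns for groups smaller than 20 (a 5%
#'   tail is then poorly resolved) and when ties inflate the tail beyond
#'   `1.5 * ceiling(q * m)` members.
#' @export
lower_tail_threshold <- function(values, q = 0.05) {
  if (!length(values)) stop("empty group")
  if (anyNA(values)) stop("values must not contain NA")
  m <- length(values)
  if (m < 20L) warning("fewer than 20 values; the ", q,
                       " tail is poorly resolved")
  r <- ceiling(q * m)
  thr <- sort(values)[r]
  members <- sum(values <= thr)
  if (members > 1.5 * r)
    warning("ties inflate the lower tail to ", members,
            " members (nominal ", r, ")")
  thr
}

# column holding the H statistic used by the scan: the variance-normalised
# form when available (it puts genes of different theta on one scale),
# otherwise the plain per-site H
pick_h_col <- function(stats) {
  if ("fay_wu_h_norm" %in% names(stats)) "fay_wu_h_norm" else "fay_wu_h"
}

#' Build a scan group from gene statistics
#'
#' Restricts to the genes admissible for the selection scan: coverage
#' eligible, no evidence of interspecific transfer, at least two
#' segregating sites, and a defined H.
#'
#' @param stats GeneStats data frame with columns `locus_tag`, `S`,
#'   `tajima_d` and `fay_wu_h` (and, preferably, `fay_wu_h_norm`), plus
#'   logical `eligible` and `hgt` (missing columns are treated as
#'   all-eligible / no-HGT).
#' @param label group label.
#' @return the filtered data frame with a `group` column (class
#'   `scan_group`).
#' @export
make_scan_group <- function(stats, label = "group") {
  eligible <- if ("eligible" %in% names(stats)) stats$eligible else TRUE
  hgt <- if ("hgt" %in% names(stats)) stats$hgt else FALSE
  keep <- eligible & !hgt & stats$S >= 2L &
    !is.na(stats[[pick_h_col(stats)]]) & !is.na(stats$tajima_d)
  g <- stats[keep, , drop = FALSE]
  g$group <- rep_len(label, nrow(g))
  class(g) <- c("scan_group", class(g))
  g
}

#' Joint D-H lower-tail scan
#'
#' Candidates are the genes lying in the lower `q` tail of Tajima's D and of
#' H, both tails computed within the group.  With
#' `tail_scale = "total"` the tail fraction is rescaled by the ratio of
#' admissible to total genes (`q * m / n_total`), an alternative reading of
#' tail definition when many genes fail the coverage or HGT filters; the
#' default uses the plain empirical `q` quantile among admissible genes.
#'
#' @param group a data frame from [make_scan_group()] (columns `locus_tag`,
#'   `tajima_d`, `group`, and the H column).
#' @param q nominal tail fraction.
#' @param tail_scale `"eligible"` (default) or `"total"`.
#' @param n_total total gene count (required for `tail_scale = "total"`).
#' @param h_col name of the H column to rank on; defaults to the
#'   variance-normalised H when present.
#' @return data frame of candidates: `locus_tag`, `group`, `tajima_d`,
#'   `fay_wu_h` (the ranked H values), `d_rank`, `h_rank`.
#' @export
dth_scan <- function(group, q = 0.05,
                     tail_scale = c("eligible", "total"), n_total = NULL,
                     h_col = pick_h_col(group)) {
  tail_scale <- match.arg(tail_scale)
  m <- nrow(group)
  if (!m)
    return(data.frame(locus_tag = character(), group = character(),
                      tajima_d = numeric(), fay_wu_h = numeric(),
                      d_rank = integer(), h_rank = integer(),
                      stringsAsFactors = FALSE))
  h <- group[[h_col]]
  q_eff <- q
  if (tail_scale == "total") {
    if (is.null(n_total)) stop("n_total required for tail_scale = 'total'")
    q_eff <- q * m / n_total
  }
  if (length(unique(group$tajima_d)) == 1L || length(unique(h)) == 1L)
    warning("degenerate dispersion: a statistic is constant in this group")
  d_thr <- lower_tail_threshold(group$tajima_d, q_eff)
  h_thr <- lower_tail_threshold(h, q_eff)
  sel <- group$tajima_d <= d_thr & h <= h_thr
  out <- data.frame(locus_tag = group$locus_tag[sel],
                    group = group$group[sel],
                    tajima_d = group$tajima_d[sel],
                    fay_wu_h = h[sel],
                    d_rank = rank(group$tajima_d,
                                  ties.method = "min")[sel],
                    h_rank = rank(h, ties.method = "min")[sel],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Partition gene statistics into scan groups
#'
#' Each plasmid replicon forms one group; the designated chromosome is split
#' at `split` into `[1, split]` and `(split, end]` by gene start (a gene
#' starting exactly at the split belongs to the first half).  Empty groups
#' are omitted.
#'
#' @param stats GeneStats data frame with `replicon` and `start` columns.
#' @param chromosome name of the replicon to split.
#' @param split 1-based split position; must lie within the chromosome.
#' @return named list of [make_scan_group()] results.
#' @export
partition_groups <- function(stats, chromosome, split) {
  chr <- stats[stats$replicon == chromosome, , drop = FALSE]
  if (nrow(chr) && (split < 1L || split > max(chr$end %||% chr$start)))
    stop("split outside chromosome")
  groups <- list()
  if (nrow(chr)) {
    first <- chr[chr$start <= split, , drop = FALSE]
    second <- chr[chr$start > split, , drop = FALSE]
    if (nrow(first))
      groups[[paste0(chromosome, "_half1")]] <-
        make_scan_group(first, paste0(chromosome, "_half1"))
    if (nrow(second))
      groups[[paste0(chromosome, "_half2")]] <-
        make_scan_group(second, paste0(chromosome, "_half2"))
  }
  for (rep_name in setdiff(unique(stats$replicon), chromosome)) {
    sub <- stats[stats$replicon == rep_name, , drop = FALSE]
    if (nrow(sub))
      groups[[rep_name]] <- make_scan_group(sub, rep_name)
  }
  groups[vapply(groups, nrow, 1L) > 0L]
}
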