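# GC-skew profiling along a reference genome, terminus localisation from
# the most persistent skew sign change, and chromosome-half diversity
# contrasts.

#' GC skew profile in sliding windows
#'
#' Per window, skew = (#G - #C) / (#G + #C) over all nucleotide positions
#' (N excluded from the counts); windows with no G or C are omitted.
#'
#' @param sequence a single character string (or `DNAString`) over
#'   A/C/G/T/N.
#' @param window window width in bp.
#' @param step step between window starts in bp.
#' @return data frame with `start0` (0-based window start), `center`
#'   (midpoint coordinate), `g`, `c` counts and `skew`.
#' @export
gc_skew_profile <- function(sequence, window = 10000L, step = 5000L) {
  if (inherits(sequence, "DNAString") || inherits(sequence, "XString"))
    sequence <- as.character(sequence)
  if (!nchar(sequence)) stop("empty sequence")
  s <- strsplit(toupper(sequence), "")[[1L]]
  len <- length(s)
  if (len < window) stop("sequence shorter than one window")
  cg <- c(0L, cumsum(s == "G"))
  cc <- c(0L, cumsum(s == "C"))
  starts0 <- seq(0L, len - window, by = step)
  g <- cg[starts0 + window + 1L] - cg[starts0 + 1L]
  cvals <- cc[starts0 + window + 1L] - cc[starts0 + 1L]
  keep <- (g + cvals) > 0L
  data.frame(start0 = starts0[keep],
             center = starts0[keep] + window / 2,
             g = g[keep], c = cvals[keep],
             skew = (g[keep] - cvals[keep]) / (g[keep] + cvals[keep]))
}

#' Locate the replication terminus from a skew profile
#'
#' The skew is lightly smoothed with a centred running mean, the profile is
#' partitioned into runs of constant sign, and the terminus is placed at the
#' sign change with the greatest persistence (the summed |skew| of the two
#' flanking runs).  On a circular chromosome the skew changes sign at both
#' the origin and the terminus; when `origin` is given, the sign change
#' closest to it (circularly) is excluded.
#'
#' @param profile data frame from [gc_skew_profile()].
#' @param origin optional origin coordinate (bp).
#' @param genome_length genome length for circular distance to `origin`
#'   (defaults to the span covered by the profile).
#' @param k running-mean width in windows (odd).
#' @return terminus coordinate (bp; midpoint between the flanking window
#'   centres), with the persistence score as attribute `persistence`.
#' @export
find_terminus <- function(profile, origin = NULL, genome_length = NULL,
                          k = 3L) {
  if (nrow(profile) < 2L) stop("profile too short")
  sm <- as.numeric(stats::filter(profile$skew, rep(1 / k, k), sides = 2L))
  sm[is.na(sm)] <- profile$skew[is.na(sm)]
  sgn <- sign(sm)
  # zero-skew windows inherit the preceding sign
  for (i in seq_along(sgn))
    if (sgn[i] == 0) sgn[i] <- if (i > 1L) sgn[i - 1L] else 0
  nz <- sgn != 0
  if (!any(nz)) stop("no sign change in the skew profile")
  first_sign <- sgn[which(nz)[1L]]
  sgn[!nz & seq_along(sgn) < which(nz)[1L]] <- first_sign
  r <- rle(sgn)
  if (length(r$lengths) < 2L) stop("no sign change in the skew profile")
  ends <- cumsum(r$lengths)
  bnd_idx <- ends[-length(ends)]  # last window of each run but the final
  pos <- (profile$center[bnd_idx] + profile$center[bnd_idx + 1L]) / 2
  persistence <- vapply(seq_along(bnd_idx), function(b) {
    left <- (if (b == 1L) 1L else ends[b - 1L] + 1L):ends[b]
    right <- (ends[b] + 1L):ends[b + 1L]
    sum(abs(sm[left])) + sum(abs(sm[right]))
  }, numeric(1L))
  if (!is.null(origin)) {
    glen <- genome_length %||%
      (max(profile$start0) + 2 * (profile$center[1L] - profile$start0[1L]))
    dd <- abs(pos - origin)
    circ <- pmin(dd, glen - dd)
    if (length(pos) > 1L) {
      drop <- which.min(circ)
      pos <- pos[-drop]; persistence <- persistence[-drop]
    }
  }
  if (!length(pos)) stop("no sign change away from the origin")
  best <- which.max(persistence)
  structure(pos[best], persistence = persistence[best])
}

#' Split records at a chromosome position
#'
#' Partitions gene or window statistics into the first half `[1, split]`
#' and second half `(split, end]` by start coordinate (closed on the left:
#' a record starting exactly at `split` belongs to the first half).
#'
#' @param stats data frame with a `start` column.
#' @param split split coordinate (bp).
#' @return the input with an added `half` factor (`"first"`/`"second"`).
#' @export
split_by_position <- function(stats, split) {
  stats$half <- ifelse(stats$start <= split, "first", "second")
  stats
}

#' Diversity contrasts between genomic groups
#'
#' Given one summary statistic per group (e.g. mean theta-pi for each
#' chromosome half and plasmid), returns every ordered pair with the ratio
#' and the percentage (rounded to the nearest integer), the form in which
#' chromosome-half versus plasmid comparisons are usually quoted.
#'
#' @param groups data frame with columns `group` and `value`.
#' @return data frame with `numerator`, `denominator`, `ratio`, `percent`.
#' @export
theta_contrast_table <- function(groups) {
  stopifnot(all(c("group", "value") %in% names(groups)))
  n <- nrow(groups)
  idx <- expand.grid(i = seq_len(n), j = seq_len(n))
  idx <- idx[idx$i != idx$j, , drop = FALSE]
  ratio <- groups$value[idx$i] / groups$value[idx$j]
  data.frame(numerator = groups$group[idx$i],
             denominator = groups$group[idx$j],
             ratio = ratio,
             percent = round(100 * ratio),
             stringsAsFactors = FALSE)
}
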