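#' Run-level quality statistics
#'
#' Mapping composition of a sequencing run: fraction of reads assigned to
#' on-diagonal products, off-diagonal fraction among all reads and among
#' "unexpected" reads (everything that is not an on-diagonal product — the
#' off-diagonal share of unexpected reads is the assay's headline library
#' quality metric), unpaired fractions by category, and per-library read
#' shares.
#'
#' @param table a [tabulate_counts()] result with `total_reads > 0`.
#' @return object of class `run_qc`: list with `total_reads`,
#'   `mapped_product_fraction`, `off_diagonal_fraction_overall`,
#'   `off_diagonal_fraction_of_unexpected`, `unpaired_fractions`,
#'   `ambiguous_fraction`, `unmapped_fraction`, `library_shares`.
#' @export
run_qc <- function(table) {
  stopifnot(inherits(table, "count_table"), table$total_reads > 0)
  cats <- table$categories
  tot <- table$total_reads
  s <- function(col) sum(cats[[col]])
  product <- s("product")
  offd <- s("off_diagonal")
  unexpected <- tot - product
  lib <- cats[cats$library != "residue", , drop = FALSE]
  shares <- setNames(
    (lib$product + lib$off_diagonal + lib$barcode_forward) / tot,
    lib$library)
  structure(list(
    total_reads = tot,
    mapped_product_fraction = product / tot,
    off_diagonal_fraction_overall = offd / tot,
    off_diagonal_fraction_of_unexpected =
      if (unexpected > 0) offd / unexpected else 0,
    unpaired_fractions = c(barcode_forward = s("barcode_forward") / tot,
                           forward = s("forward") / tot,
                           reverse = s("reverse") / tot),
    ambiguous_fraction = s("ambiguous") / tot,
    unmapped_fraction = s("unmapped") / tot,
    library_shares = shares),
    class = "run_qc")
}

#' @export
print.run_qc <- function(x, ...) {
  cat("2C-ChIP run QC (", x$total_reads, " reads)\n",
      sprintf("  on-diagonal product fraction: %.4f\n",
              x$mapped_product_fraction),
      sprintf("  off-diagonal: %.4f of all reads, %.4f of unexpected reads\n",
              x$off_diagonal_fraction_overall,
              x$off_diagonal_fraction_of_unexpected),
      sep = "")
  invisible(x)
}

#' Average track value in a genomic window
#'
#' Unweighted mean of the probe values whose interval midpoint falls in
#' `[center - width/2, center + width/2)` (or, with
#' `rule = "overlap"`, whose interval overlaps the window). Used to compare
#' probe-level tracks with amplicon-level qPCR measurements.
#'
#' @param track a `normalized_track` (or any data.frame with `chrom`,
#'   `start`, `end`, `value`).
#' @param center window centre (bp).
#' @param width window width in bp (default 1000).
#' @param chrom optional chromosome filter.
#' @param rule probe-membership rule: `"midpoint"` (default) or `"overlap"`.
#' @return mean value, or `NA` when no probe falls in the window.
#' @export
window_average <- function(track, center, width = 1000, chrom = NULL,
                           rule = c("midpoint", "overlap")) {
  stopifnot(width > 0)
  rule <- match.arg(rule)
  df <- track
  if (!is.null(chrom)) df <- df[df$chrom == chrom, , drop = FALSE]
  lo <- center - width / 2
  hi <- center + width / 2
  inside <- if (rule == "midpoint") {
    mid <- (df$start + df$end) / 2
    mid >= lo & mid < hi
  } else {
    df$start < hi & df$end > lo
  }
  if (!any(inside)) return(NA_real_)
  mean(df$value[inside])
}

#' Spearman rank correlation with optional zero exclusion
#'
#' Rank correlation with average ranks for ties. With `drop_zeros = TRUE`,
#' pairs in which either value equals zero are removed before ranking (the
#' convention used when comparing against qPCR or ChIP-seq measurements,
#' where zeros denote absence of signal rather than a rankable quantity);
#' the number of dropped pairs is reported via a message.
#'
#' @param x,y numeric vectors of equal length.
#' @param drop_zeros drop pairs where either value is 0.
#' @return Spearman's rho.
#' @export
spearman_cor <- function(x, y, drop_zeros = FALSE) {
  stopifnot(length(x) == length(y))
  keep <- !is.na(x) & !is.na(y)
  if (drop_zeros) keep <- keep & x != 0 & y != 0
  dropped <- sum(!keep)
  if (dropped > 0L) message(dropped, " pair(s) dropped before correlation")
  if (sum(keep) < 3L) {
    stop("fewer than 3 retained pairs: correlation undefined", call. = FALSE)
  }
  cor(x[keep], y[keep], method = "spearman")
}

#' Sum sequencing reads over probed intervals
#'
#' Per probe, the number of reads (given as intervals on the same assembly
#' and 0-based half-open convention) overlapping the probed interval;
#' abutting intervals do not overlap. With `rule = "containment"` a read
#' must lie entirely within the probed interval. The resulting per-probe
#' sums are the quantity compared against probe-level signal with
#' [spearman_cor()] (`drop_zeros = TRUE`).
#'
#' @param probes data.frame with `probe_id`, `chrom`, `start`, `end`
#'   (e.g. [probe_intervals()] or a `normalized_track`).
#' @param reads data.frame with `chrom`, `start`, `end` read intervals.
#' @param rule `"overlap"` (default) or `"containment"`.
#' @return data.frame `probe_id`, `reads`.
#' @export
chipseq_overlap_score <- function(probes, reads,
                                  rule = c("overlap", "containment")) {
  rule <- match.arg(rule)
  pg <- GenomicRanges::GRanges(probes$chrom,
                               IRanges::IRanges(probes$start + 1L, probes$end))
  rg <- GenomicRanges::GRanges(reads$chrom,
                               IRanges::IRanges(reads$start + 1L, reads$end))
  if (rule == "overlap") {
    n <- GenomicRanges::countOverlaps(pg, rg)
  } else {
    hits <- GenomicRanges::findOverlaps(rg, pg, type = "within")
    n <- tabulate(S4Vectors::subjectHits(hits), nbins = length(pg))
  }
  data.frame(probe_id = probes$probe_id, reads = as.integer(n),
             stringsAsFactors = FALSE)
}

#' Assess the linear detection range of a titration series
#'
#' Over all contiguous sub-series of at least 3 points, fits
#' `log(yield) ~ log(amount)` by least squares and returns the widest
#' sub-series whose fit has `r^2 >= r2_threshold` and slope within
#' `slope_range` (a slope near 1 means yield proportional to template mass).
#' Ties on the number of points are broken towards the wider log-range, then
#' the leftmost window.
#'
#' @param series a `titration_series` or data.frame with `amount_ng` and
#'   `yield` (amounts strictly increasing, positive).
#' @param r2_threshold minimum r-squared of the log-log fit (default 0.98).
#' @param slope_range admissible slope interval (default `c(0.8, 1.2)`).
#' @return object of class `linearity_fit`: list with `qualified`, `lo`,
#'   `hi` (ng), `slope`, `r2`, `n_points`. When no sub-series qualifies,
#'   `qualified` is `FALSE` and the range is `NA` (no exception is thrown).
#' @export
assess_linearity <- function(series, r2_threshold = 0.98,
                             slope_range = c(0.8, 1.2)) {
  stopifnot(is.data.frame(series),
            all(c("amount_ng", "yield") %in% names(series)))
  a <- series$amount_ng
  y <- series$yield
  stopifnot(length(a) >= 3L, all(a > 0), all(y > 0),
            !is.unsorted(a, strictly = TRUE))
  n <- length(a)
  best <- NULL
  for (i in seq_len(n - 2L)) {
    for (j in (i + 2L):n) {
      la <- log(a[i:j]); ly <- log(y[i:j])
      if (stats::sd(ly) == 0) next
      fit <- lm(ly ~ la)
      sl <- unname(coef(fit)[2L])
      # r^2 computed directly (summary.lm warns on exact power-law input)
      r2 <- 1 - sum(fit$residuals^2) / sum((ly - mean(ly))^2)
      if (!is.finite(r2) || r2 < r2_threshold) next
      if (sl < slope_range[1L] || sl > slope_range[2L]) next
      cand <- list(qualified = TRUE, lo = a[i], hi = a[j], slope = sl,
                   r2 = r2, n_points = j - i + 1L, i = i)
      if (is.null(best) ||
          cand$n_points > best$n_points ||
          (cand$n_points == best$n_points &&
             log(cand$hi / cand$lo) > log(best$hi / best$lo)) ||
          (cand$n_points == best$n_points &&
             log(cand$hi / cand$lo) == log(best$hi / best$lo) &&
             cand$i < best$i)) {
        best <- cand
      }
    }
  }
  if (is.null(best)) {
    best <- list(qualified = FALSE, lo = NA_real_, hi = NA_real_,
                 slope = NA_real_, r2 = NA_real_, n_points = 0L)
  }
  best$i <- NULL
  structure(best, class = "linearity_fit")
}

#' @export
print.linearity_fit <- function(x, ...) {
  if (x$qualified) {
    cat(sprintf("linear detection range: %.3g-%.3g ng (slope %.3f, r2 %.4f, %d points)\n",
                x$lo, x$hi, x$slope, x$r2, x$n_points))
  } else {
    cat("no linear range found\n")
  }
  invisible(x)
}

#' Squared correlation between replicate tracks
#'
#' Squared Pearson correlation of the probe values shared by two tracks
#' (matched on `probe_id`).
#'
#' @param track_a,track_b `normalized_track` data.frames.
#' @return r-squared.
#' @export
replicate_correlation <- function(track_a, track_b) {
  shared <- intersect(track_a$probe_id, track_b$probe_id)
  if (length(shared) < 3L) {
    stop("fewer than 3 shared probes: correlation undefined", call. = FALSE)
  }
  va <- track_a$value[match(shared, track_a$probe_id)]
  vb <- track_b$value[match(shared, track_b$probe_id)]
  cor(va, vb)^2
}
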