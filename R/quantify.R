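#' Per-library normalization factors
#'
#' Multiplicative factors of the normalization chain: the dilution made for
#' sequencing (from TaqMan-style library quantitation), the dilution made to
#' keep the assay in its linear detection range, and — for ChIP libraries —
#' the adjustment for the fact that only a fraction of the input chromatin
#' (default 10%) is processed.
#'
#' @param library_label library this factor set belongs to.
#' @param seq_dilution sequencing-dilution factor (> 0).
#' @param linearity_dilution linear-range dilution factor (> 0).
#' @param is_input `TRUE` for the input (pre-immunoprecipitation) library.
#' @param input_fraction fraction of the input processed, in `(0, 1]`.
#' @return object of class `library_factors`.
#' @export
library_factors <- function(library_label, seq_dilution = 1,
                            linearity_dilution = 1, is_input = FALSE,
                            input_fraction = 0.10) {
  stopifnot(seq_dilution > 0, linearity_dilution > 0,
            input_fraction > 0, input_fraction <= 1)
  structure(list(library_label = library_label,
                 seq_dilution = seq_dilution,
                 linearity_dilution = linearity_dilution,
                 is_input = is_input,
                 input_fraction = input_fraction),
            class = "library_factors")
}

#' Normalize per-probe counts of one library
#'
#' Applies the factor chain: counts are first scaled per million over the
#' normalization base (`"product"`, the default: mapped on-diagonal product
#' reads of the library — off-diagonal and unpaired reads are artifacts;
#' `"total"`: all reads attributed to the library), then multiplied by the
#' sequencing and linearity dilution factors, and — for ChIP libraries — by
#' `input_fraction`. All steps are multiplicative, so their order is
#' immaterial.
#'
#' @param table a [tabulate_counts()] result.
#' @param factors a [library_factors()] object for one of the libraries in
#'   the table.
#' @param norm_base `"product"` (default) or `"total"`.
#' @return data.frame `probe_id`, `count`, `value`.
#' @export
normalize_counts <- function(table, factors, norm_base = c("product", "total")) {
  stopifnot(inherits(table, "count_table"),
            inherits(factors, "library_factors"))
  norm_base <- match.arg(norm_base)
  pc <- table$probe_counts[table$probe_counts$library ==
                             factors$library_label, , drop = FALSE]
  if (nrow(pc) == 0L) {
    stop("library '", factors$library_label, "' not found in count table",
         call. = FALSE)
  }
  cats <- table$categories[table$categories$library == factors$library_label, ]
  base <- if (norm_base == "product") {
    sum(pc$count)
  } else {
    sum(unlist(cats[, c("product", "off_diagonal", "barcode_forward",
                        "forward", "reverse", "ambiguous", "unmapped")]))
  }
  if (base <= 0L) {
    stop("zero mapped reads for library '", factors$library_label, "'",
         call. = FALSE)
  }
  scale <- 1e6 / base * factors$seq_dilution * factors$linearity_dilution
  if (!factors$is_input) scale <- scale * factors$input_fraction
  data.frame(probe_id = pc$probe_id, count = pc$count,
             value = pc$count * scale, stringsAsFactors = FALSE)
}

#' ChIP/input ratio track
#'
#' The final step of the normalization chain: the ratio of normalized ChIP to
#' normalized input signal, per probe, attached to the probed genomic
#' intervals. Probes with zero input signal yield no ratio: they are dropped
#' from the track (and listed in the `dropped_probes` attribute) rather than
#' pseudocounted, unless a positive `pseudocount` is supplied.
#'
#' @param chip,input data.frames from [normalize_counts()] over the same
#'   panel.
#' @param panel the `primer_panel` supplying probe intervals.
#' @param pseudocount optional value added to both normalized signals before
#'   the ratio (default 0: off).
#' @return data.frame of class `normalized_track`: `probe_id`, `chrom`,
#'   `start`, `end`, `value`, sorted by position, with attributes
#'   `dropped_probes` and `provenance`.
#' @export
chip_input_ratio <- function(chip, input, panel, pseudocount = 0) {
  stopifnot(inherits(panel, "primer_panel"))
  if (!setequal(chip$probe_id, input$probe_id) ||
      !setequal(chip$probe_id, panel$probe_id)) {
    stop("chip, input and panel must cover the same probes", call. = FALSE)
  }
  iv <- probe_intervals(panel)
  cv <- chip$value[match(iv$probe_id, chip$probe_id)] + pseudocount
  nv <- input$value[match(iv$probe_id, input$probe_id)] + pseudocount
  keep <- nv > 0
  track <- data.frame(probe_id = iv$probe_id[keep], chrom = iv$chrom[keep],
                      start = iv$start[keep], end = iv$end[keep],
                      value = cv[keep] / nv[keep], stringsAsFactors = FALSE)
  track <- track[order(track$chrom, track$start), , drop = FALSE]
  rownames(track) <- NULL
  structure(track,
            dropped_probes = iv$probe_id[!keep],
            provenance = list(pseudocount = pseudocount),
            class = c("normalized_track", "data.frame"))
}

#' Write a track as bedGraph
#'
#' Standard four-column bedGraph (`chrom start end value`, 0-based half-open
#' intervals) preceded by a single `track type=bedGraph` header line. Values
#' are written with 6 significant digits, the round-trip precision
#' guaranteed by [read_bedgraph()].
#'
#' @param track a data.frame with `chrom`, `start`, `end`, `value`.
#' @param path output path.
#' @param name track name for the header line.
#' @return invisibly, `path`.
#' @export
write_bedgraph <- function(track, path, name = "chip2c") {
  stopifnot(is.data.frame(track),
            all(c("chrom", "start", "end", "value") %in% names(track)))
  if (nrow(track) > 1L) {
    o <- order(track$chrom, track$start)
    if (!identical(o, seq_len(nrow(track)))) {
      stop("track intervals must be sorted by position", call. = FALSE)
    }
    same <- track$chrom[-nrow(track)] == track$chrom[-1L]
    if (any(same & track$end[-nrow(track)] > track$start[-1L])) {
      stop("track intervals must not overlap", call. = FALSE)
    }
  }
  lines <- sprintf('track type=bedGraph name="%s"', name)
  if (nrow(track)) {
    lines <- c(lines, paste(track$chrom, track$start, track$end,
                            sprintf("%.6g", track$value), sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a bedGraph file
#'
#' @param path bedGraph path; `track`, `browser` and `#` lines are skipped.
#' @return data.frame `chrom`, `start`, `end`, `value` (empty when the file
#'   holds only a header).
#' @export
read_bedgraph <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(track|browser|#)", lines) & nzchar(lines)]
  if (length(lines) == 0L) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), value = numeric(),
                      stringsAsFactors = FALSE))
  }
  df <- read.table(text = lines, sep = "\t",
                   col.names = c("chrom", "start", "end", "value"),
                   colClasses = c("character", "integer", "integer",
                                  "numeric"))
  df
}
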