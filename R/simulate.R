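#' Simulate a random genome sequence
#'
#' I.i.d. bases with the requested GC fraction (G and C equiprobable, A and T
#' equiprobable). Deterministic for a fixed seed.
#'
#' @param length sequence length in bp (> 0).
#' @param gc target GC fraction in `[0, 1]`.
#' @param seed optional RNG seed.
#' @return a single DNA string.
#' @export
simulate_genome <- function(length, gc = 0.5, seed = NULL) {
  stopifnot(length > 0)
  if (!is.numeric(gc) || gc < 0 || gc > 1) {
    stop("gc must be in [0, 1]", call. = FALSE)
  }
  with_seed_if(seed, {
    p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    paste(sample(names(p), length, replace = TRUE, prob = p), collapse = "")
  })
}

#' Simulate a per-probe enrichment profile
#'
#' Piecewise occupancy profile over the probes of a panel: `background`
#' everywhere, with `n_peaks` randomly placed contiguous runs of elevated
#' occupancy. With `peak_shape = "flat"` peak probes sit exactly at
#' `peak_height`; `"triangular"` peaks rise linearly from the background to
#' `peak_height` at the run centre and back, which emulates the graded peaks
#' and shoulders of real ChIP profiles. `probe_log_sd > 0` additionally
#' multiplies every probe by a lognormal factor (probe-efficiency /
#' accessibility heterogeneity), making the true occupancy continuous.
#'
#' Values are relative occupancies: unnormalized, consumed downstream as
#' multinomial weights. An input (pre-immunoprecipitation) library is the
#' `n_peaks = 0` case.
#'
#' @param panel a `primer_panel`.
#' @param n_peaks number of peak runs (0 for a flat input-like profile).
#' @param peak_height occupancy at the peak summit (same units as
#'   `background`).
#' @param background baseline occupancy (> 0).
#' @param mean_run_length mean number of probes per peak run.
#' @param peak_shape `"flat"` (default) or `"triangular"`.
#' @param probe_log_sd sd of the per-probe lognormal factor (default 0:
#'   none).
#' @param seed optional RNG seed.
#' @return data.frame `probe_id`, `occupancy`.
#' @export
simulate_profile <- function(panel, n_peaks = 0L, peak_height = 10,
                             background = 1, mean_run_length = 3,
                             peak_shape = c("flat", "triangular"),
                             probe_log_sd = 0, seed = NULL) {
  stopifnot(inherits(panel, "primer_panel"), background > 0)
  peak_shape <- match.arg(peak_shape)
  np <- nrow(panel)
  if (n_peaks > np) stop("n_peaks exceeds the number of probes", call. = FALSE)
  with_seed_if(seed, {
    occ <- rep(background, np)
    if (n_peaks > 0L) {
      starts <- sample.int(np, n_peaks)
      lens <- 1L + stats::rpois(n_peaks, max(mean_run_length - 1, 0))
      for (k in seq_len(n_peaks)) {
        idx <- starts[k]:min(np, starts[k] + lens[k] - 1L)
        if (peak_shape == "flat") {
          occ[idx] <- peak_height
        } else {
          m <- length(idx)
          centre <- (m + 1) / 2
          w <- 1 - abs(seq_len(m) - centre) / centre
          occ[idx] <- pmax(occ[idx], background + (peak_height - background) * w)
        }
      }
    }
    if (probe_log_sd > 0) {
      occ <- occ * stats::rlnorm(np, meanlog = 0, sdlog = probe_log_sd)
    }
    data.frame(probe_id = panel$probe_id, occupancy = occ,
               stringsAsFactors = FALSE)
  })
}

mutate_reads <- function(seqs, error_rate) {
  if (error_rate <= 0) return(seqs)
  lens <- nchar(seqs)
  n_err <- rbinom(length(seqs), lens, error_rate)
  idx <- which(n_err > 0L)
  for (i in idx) {
    ch <- strsplit(seqs[i], "")[[1L]]
    pos <- sample.int(lens[i], n_err[i])
    ch[pos] <- vapply(ch[pos], function(b) {
      sample(setdiff(DNA_ALPHABET, b), 1L)
    }, character(1L))
    seqs[i] <- paste(ch, collapse = "")
  }
  seqs
}

#' Simulate one barcoded 2C-ChIP sequencing library
#'
#' Draws `n_reads` single-end reads beginning at the barcode (the instrument
#' key is assumed stripped upstream). With probability
#' `1 - off_diagonal_rate - truncation_rate` a read is an on-diagonal product
#' of probe `i`, drawn proportionally to the enrichment profile; with
#' probability `off_diagonal_rate` it is a uniformly random off-diagonal
#' product (a primer-driven ligation artifact, hence independent of the
#' template profile); with probability `truncation_rate` it is an unpaired
#' barcode-forward fragment. Per-base substitutions are applied at
#' `error_rate`; qualities are a constant per-base string. Exact per-read
#' ground truth is recorded.
#'
#' The defaults emulate a library in the assay's optimal operating range;
#' PCR amplification is not modelled as a branching process (its effect is
#' absorbed into `n_reads`) and no indels are introduced.
#'
#' @param reference a [product_reference()].
#' @param profile data.frame from [simulate_profile()] covering every probe
#'   of the panel.
#' @param barcode_id which barcode/library to emit.
#' @param n_reads number of reads (> 0).
#' @param error_rate per-base substitution probability.
#' @param off_diagonal_rate fraction of off-diagonal artifact reads.
#' @param truncation_rate fraction of unpaired barcode-forward reads.
#' @param seed optional RNG seed.
#' @return list with `reads` (data.frame `read_id`, `sequence`, `quality`,
#'   `true_category`, `true_id`, `true_probe_id`) and `truth` (class
#'   `simulation_truth`: per-origin counts, the parameters, and the seed).
#' @export
simulate_library <- function(reference, profile, barcode_id, n_reads,
                             error_rate = 0.005, off_diagonal_rate = 0.05,
                             truncation_rate = 0.005, seed = NULL) {
  stopifnot(inherits(reference, "product_reference"))
  if (n_reads <= 0) stop("n_reads must be > 0", call. = FALSE)
  rates <- c(error_rate, off_diagonal_rate, truncation_rate)
  if (any(rates < 0) || any(rates > 1) ||
      off_diagonal_rate + truncation_rate > 1) {
    stop("rates must lie in [0, 1] with off_diagonal + truncation <= 1",
         call. = FALSE)
  }
  if (!barcode_id %in% reference$barcodes$barcode_id) {
    stop("unknown barcode_id: ", barcode_id, call. = FALSE)
  }
  panel <- reference$panel
  if (!all(panel$probe_id %in% profile$probe_id)) {
    stop("profile does not cover every probe of the panel", call. = FALSE)
  }
  occ <- profile$occupancy[match(panel$probe_id, profile$probe_id)]
  if (all(occ <= 0)) stop("profile has no positive occupancy", call. = FALSE)
  ond <- reference$full[reference$full$on_diagonal &
                          reference$full$barcode_id == barcode_id, ]
  ond <- ond[match(panel$probe_id, ond$forward_probe_id), ]
  offd <- reference$full[!reference$full$on_diagonal &
                           reference$full$barcode_id == barcode_id, ]
  stems <- reference$unpaired[reference$unpaired$category == "barcode-forward" &
                                reference$unpaired$barcode_id == barcode_id, ]
  stems <- stems[match(panel$probe_id, stems$probe_id), ]
  label <- reference$barcodes$library_label[
    match(barcode_id, reference$barcodes$barcode_id)]

  with_seed_if(seed, {
    cat_levels <- c("product", "off_diagonal", "barcode_forward")
    probs <- c(1 - off_diagonal_rate - truncation_rate,
               off_diagonal_rate, truncation_rate)
    category <- sample(cat_levels, n_reads, replace = TRUE, prob = probs)
    seqs <- character(n_reads)
    true_id <- character(n_reads)
    true_probe <- rep(NA_character_, n_reads)
    i_on <- which(category == "product")
    if (length(i_on)) {
      pk <- sample.int(nrow(panel), length(i_on), replace = TRUE, prob = occ)
      seqs[i_on] <- ond$sequence[pk]
      true_id[i_on] <- ond$product_id[pk]
      true_probe[i_on] <- panel$probe_id[pk]
    }
    i_off <- which(category == "off_diagonal")
    if (length(i_off)) {
      if (nrow(offd) == 0L) stop("panel has a single pair: no off-diagonal ",
                                 "products to draw from", call. = FALSE)
      ok <- sample.int(nrow(offd), length(i_off), replace = TRUE)
      seqs[i_off] <- offd$sequence[ok]
      true_id[i_off] <- offd$product_id[ok]
    }
    i_tr <- which(category == "barcode_forward")
    if (length(i_tr)) {
      tk <- sample.int(nrow(stems), length(i_tr), replace = TRUE)
      seqs[i_tr] <- stems$sequence[tk]
      true_id[i_tr] <- stems$id[tk]
    }
    seqs <- mutate_reads(seqs, error_rate)
    reads <- data.frame(
      read_id = sprintf("%s_read%07d", label, seq_len(n_reads)),
      sequence = seqs,
      quality = strrep("I", nchar(seqs)),
      true_category = category,
      true_id = true_id,
      true_probe_id = true_probe,
      stringsAsFactors = FALSE)
    counts <- stats::aggregate(list(n = seq_len(n_reads)),
                               by = list(category = category, id = true_id),
                               FUN = length)
    truth <- structure(list(counts = counts,
                            barcode_id = barcode_id,
                            library_label = label,
                            n_reads = n_reads,
                            error_rate = error_rate,
                            off_diagonal_rate = off_diagonal_rate,
                            truncation_rate = truncation_rate,
                            seed = seed),
                       class = "simulation_truth")
    list(reads = reads, truth = truth)
  })
}

#' Phenomenological titration series
#'
#' Convenience wrapper mapping template mass (ng) to library yield, read
#' count, and off-diagonal rate through a documented monotone function. The
#' functional form is a stated modelling assumption, not a chemistry model:
#' yield is proportional to the template amount clamped to
#' `[floor_break, sat_break]` (below the floor the ligation output is
#' dominated by a template-independent background; above the saturation
#' breakpoint primers become limiting), and the off-diagonal rate increases
#' as the template gets scarcer, as
#' `min(0.5, off_base * sqrt(sat_break / min(amount, sat_break)))`.
#'
#' @param amounts template amounts in ng, strictly increasing, > 0.
#' @param yield_per_ng arbitrary yield units per ng in the linear regime.
#' @param floor_break low breakpoint (ng) below which yield flattens.
#' @param sat_break saturation breakpoint (ng) above which yield flattens.
#' @param reads_at_sat read count assigned to a fully saturated library.
#' @param off_base off-diagonal rate in the saturated/optimal regime.
#' @param noise_sd sd of multiplicative lognormal yield noise (default 0).
#' @param seed optional RNG seed.
#' @return data.frame of class `titration_series`: `amount_ng`, `yield`,
#'   `n_reads`, `off_diagonal_rate`.
#' @export
simulate_titration <- function(amounts = c(0.016, 0.05, 0.16, 0.5, 1.6, 5, 16),
                               yield_per_ng = 1000, floor_break = 0.16,
                               sat_break = 1.6, reads_at_sat = 1e5,
                               off_base = 0.05, noise_sd = 0, seed = NULL) {
  stopifnot(all(amounts > 0), !is.unsorted(amounts, strictly = TRUE),
            floor_break < sat_break)
  with_seed_if(seed, {
    eff <- pmin(pmax(amounts, floor_break), sat_break)
    yield <- yield_per_ng * eff
    if (noise_sd > 0) {
      yield <- yield * stats::rlnorm(length(yield), 0, noise_sd)
    }
    structure(data.frame(
      amount_ng = amounts,
      yield = yield,
      n_reads = round(reads_at_sat * eff / sat_break),
      off_diagonal_rate = pmin(0.5, off_base * sqrt(sat_break / eff)),
      stringsAsFactors = FALSE),
      breakpoints = c(floor = floor_break, saturation = sat_break),
      class = c("titration_series", "data.frame"))
  })
}
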