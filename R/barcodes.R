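#' Barcode table
#'
#' Library-identifying sequences placed at the very start of every sequenced
#' read (the instrument key is consumed upstream, so barcodes are read
#' first). All barcodes in a run must have equal length and pairwise Hamming
#' distance >= `min_dist` so a single substitution cannot convert one into
#' another.
#'
#' @param sequence character vector of barcode sequences (A/C/G/T, equal
#'   length).
#' @param barcode_id ids; default `BC01`, `BC02`, ...
#' @param library_label per-barcode library label; defaults to the id.
#' @param min_dist minimum pairwise Hamming distance (default 2).
#' @return data.frame of class `barcode_table` with columns `barcode_id`,
#'   `sequence`, `library_label`.
#' @export
barcode_table <- function(sequence,
                          barcode_id = sprintf("BC%02d", seq_along(sequence)),
                          library_label = barcode_id, min_dist = 2L) {
  assert_dna(sequence, "barcode sequence")
  if (length(unique(nchar(sequence))) != 1L) {
    stop("all barcodes must have the same length", call. = FALSE)
  }
  if (anyDuplicated(barcode_id)) stop("barcode ids must be unique", call. = FALSE)
  n <- length(sequence)
  if (n > 1L) {
    m <- do.call(rbind, strsplit(sequence, ""))
    for (i in seq_len(n - 1L)) for (k in (i + 1L):n) {
      d <- sum(m[i, ] != m[k, ])
      if (d < min_dist) {
        stop("barcodes ", barcode_id[i], " and ", barcode_id[k],
             " are at Hamming distance ", d, " (< ", min_dist, ")",
             call. = FALSE)
      }
    }
  }
  structure(data.frame(barcode_id = barcode_id, sequence = sequence,
                       library_label = library_label,
                       stringsAsFactors = FALSE),
            class = c("barcode_table", "data.frame"))
}

#' Generate random barcodes satisfying the distance constraint
#'
#' Rejection sampling of random sequences of the given width until `n`
#' barcodes with pairwise Hamming distance >= `min_dist` are collected.
#'
#' @param n number of barcodes.
#' @param width barcode length in nt (default 8).
#' @param min_dist minimum pairwise Hamming distance.
#' @param library_label optional labels (length `n`).
#' @param seed optional RNG seed for reproducibility.
#' @return a [barcode_table()].
#' @export
random_barcodes <- function(n, width = 8L, min_dist = 2L,
                            library_label = NULL, seed = NULL) {
  stopifnot(n >= 1, width >= 2)
  with_seed_if(seed, {
    picked <- character()
    tries <- 0L
    while (length(picked) < n) {
      tries <- tries + 1L
      if (tries > 10000L) stop("could not find ", n, " barcodes", call. = FALSE)
      cand <- paste(sample(DNA_ALPHABET, width, replace = TRUE), collapse = "")
      ok <- TRUE
      for (p in picked) {
        d <- sum(strsplit(cand, "")[[1L]] != strsplit(p, "")[[1L]])
        if (d < min_dist) { ok <- FALSE; break }
      }
      if (ok) picked <- c(picked, cand)
    }
    if (is.null(library_label)) {
      barcode_table(picked, min_dist = min_dist)
    } else {
      barcode_table(picked, library_label = library_label, min_dist = min_dist)
    }
  })
}
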