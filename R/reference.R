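#' Enumerate all expected full ligation products
#'
#' Builds the first reference assembly: every barcode x forward x reverse
#' combination, `barcode + forward_tail + forward_homology +
#' reverse_homology` (optionally followed by the reverse tail). Products in
#' which the forward and reverse homologies come from the same probe pair are
#' the designed, on-diagonal products; all other combinations are
#' off-diagonal ligation artifacts, enumerated explicitly so they are
#' first-class countable categories.
#'
#' Rows are ordered barcode-major, then forward probe, then reverse probe;
#' downstream assignment relies on this ordering.
#'
#' @param panel a `primer_panel`.
#' @param barcodes a [barcode_table()].
#' @param include_reverse_tail append the reverse universal tail to each
#'   product (default `FALSE`: reads are sequenced from the barcode end and
#'   the constant tail adds no discriminative power).
#' @param enumerate `"full"` (default) enumerates every combination;
#'   `"sampled"` keeps all on-diagonal products plus at most
#'   `max_off_diagonal` off-diagonal ones per barcode (protection against
#'   pathologically large panels).
#' @param max_off_diagonal cap used when `enumerate = "sampled"`.
#' @param seed seed for the off-diagonal subsample.
#' @return data.frame with `product_id`, `barcode_id`, `forward_probe_id`,
#'   `reverse_probe_id`, `sequence`, `on_diagonal`, `length`,
#'   `sequence_unique`.
#' @export
build_full_reference <- function(panel, barcodes, include_reverse_tail = FALSE,
                                 enumerate = c("full", "sampled"),
                                 max_off_diagonal = 50000L, seed = NULL) {
  stopifnot(inherits(panel, "primer_panel"), nrow(panel) >= 1L,
            nrow(barcodes) >= 1L)
  enumerate <- match.arg(enumerate)
  ft <- attr(panel, "forward_tail")
  rt <- if (include_reverse_tail) attr(panel, "reverse_tail") else ""
  nb <- nrow(barcodes); np <- nrow(panel)
  bi <- rep(seq_len(nb), each = np * np)
  fi <- rep(rep(seq_len(np), each = np), times = nb)
  ri <- rep(seq_len(np), times = nb * np)
  df <- data.frame(
    barcode_id = barcodes$barcode_id[bi],
    forward_probe_id = panel$probe_id[fi],
    reverse_probe_id = panel$probe_id[ri],
    sequence = paste0(barcodes$sequence[bi], ft,
                      panel$forward_homology[fi],
                      panel$reverse_homology[ri], rt),
    on_diagonal = fi == ri,
    stringsAsFactors = FALSE)
  if (enumerate == "sampled") {
    off <- which(!df$on_diagonal)
    if (length(off) > max_off_diagonal * nb) {
      keep <- with_seed_if(seed,
        sort(sample(off, max_off_diagonal * nb)))
      df <- df[sort(c(which(df$on_diagonal), keep)), , drop = FALSE]
      rownames(df) <- NULL
    }
  }
  df$product_id <- paste(df$barcode_id, df$forward_probe_id,
                         df$reverse_probe_id, sep = "|")
  df$length <- nchar(df$sequence)
  dup <- duplicated(df$sequence) | duplicated(df$sequence, fromLast = TRUE)
  df$sequence_unique <- !dup
  if (any(dup)) {
    warning(sum(dup), " expected products share identical sequences ",
            "(identical homologies in the panel); all kept, flagged non-unique")
  }
  df[, c("product_id", "barcode_id", "forward_probe_id", "reverse_probe_id",
         "sequence", "on_diagonal", "length", "sequence_unique")]
}

#' Enumerate the unpaired primer reference
#'
#' The second assembly used for reads that do not map uniquely to a full
#' product: `barcode-forward` stems (barcode + forward tail + forward
#' homology), bare `forward` entries (forward tail + forward homology) and
#' `reverse` entries (reverse homology + reverse tail).
#'
#' @inheritParams build_full_reference
#' @return data.frame with `category`, `id`, `barcode_id`, `probe_id`,
#'   `sequence`, `length`.
#' @export
build_unpaired_reference <- function(panel, barcodes = NULL) {
  stopifnot(inherits(panel, "primer_panel"), nrow(panel) >= 1L)
  ft <- attr(panel, "forward_tail")
  rt <- attr(panel, "reverse_tail")
  out <- list()
  if (!is.null(barcodes) && nrow(barcodes) > 0L) {
    bi <- rep(seq_len(nrow(barcodes)), each = nrow(panel))
    fi <- rep(seq_len(nrow(panel)), times = nrow(barcodes))
    out$bf <- data.frame(
      category = "barcode-forward",
      id = paste(barcodes$barcode_id[bi], panel$probe_id[fi], "F", sep = "|"),
      barcode_id = barcodes$barcode_id[bi],
      probe_id = panel$probe_id[fi],
      sequence = paste0(barcodes$sequence[bi], ft, panel$forward_homology[fi]),
      stringsAsFactors = FALSE)
  }
  out$f <- data.frame(
    category = "forward", id = paste(panel$probe_id, "F", sep = "|"),
    barcode_id = NA_character_, probe_id = panel$probe_id,
    sequence = paste0(ft, panel$forward_homology), stringsAsFactors = FALSE)
  out$r <- data.frame(
    category = "reverse", id = paste(panel$probe_id, "R", sep = "|"),
    barcode_id = NA_character_, probe_id = panel$probe_id,
    sequence = paste0(panel$reverse_homology, rt), stringsAsFactors = FALSE)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res$length <- nchar(res$sequence)
  res
}

#' Expected-product reference for a 2C-ChIP run
#'
#' Couples the two reference assemblies ([build_full_reference()] and
#' [build_unpaired_reference()]) with the panel and barcode table that
#' produced them; this is the object [two_step_assign()] and
#' [simulate_library()] consume.
#'
#' @inheritParams build_full_reference
#' @return object of class `product_reference`: list with elements `full`,
#'   `unpaired`, `panel`, `barcodes`, `include_reverse_tail`,
#'   `min_full_product_len`, `min_unpaired_len`.
#' @export
product_reference <- function(panel, barcodes, include_reverse_tail = FALSE,
                              enumerate = "full", max_off_diagonal = 50000L,
                              seed = NULL) {
  full <- build_full_reference(panel, barcodes, include_reverse_tail,
                               enumerate, max_off_diagonal, seed)
  unpaired <- build_unpaired_reference(panel, barcodes)
  structure(list(full = full, unpaired = unpaired, panel = panel,
                 barcodes = barcodes,
                 include_reverse_tail = include_reverse_tail,
                 min_full_product_len = min(full$length),
                 min_unpaired_len = min(unpaired$length)),
            class = "product_reference")
}

#' @export
print.product_reference <- function(x, ...) {
  cat("2C-ChIP product reference\n",
      "  panel: ", nrow(x$panel), " probe pairs; barcodes: ",
      nrow(x$barcodes), "\n",
      "  full products: ", nrow(x$full), " (",
      sum(x$full$on_diagonal), " on-diagonal), min length ",
      x$min_full_product_len, " nt\n",
      "  unpaired entries: ", nrow(x$unpaired), ", min length ",
      x$min_unpaired_len, " nt\n", sep = "")
  invisible(x)
}

#' Write a product reference to FASTA + index files
#'
#' Serializes the two assemblies as FASTA (headers
#' `product|<barcode>|<F>|<R>|<diag>` and `unpaired|<category>|<id>`) plus a
#' TSV index with labels and lengths, so any external aligner could consume
#' them.
#'
#' @param reference a `product_reference`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_reference <- function(reference, dir) {
  stopifnot(inherits(reference, "product_reference"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  full <- reference$full
  fs <- Biostrings::DNAStringSet(full$sequence)
  names(fs) <- paste("product", full$barcode_id, full$forward_probe_id,
                     full$reverse_probe_id,
                     ifelse(full$on_diagonal, "on", "off"), sep = "|")
  up <- reference$unpaired
  us <- Biostrings::DNAStringSet(up$sequence)
  names(us) <- paste("unpaired", up$category, up$id, sep = "|")
  paths <- c(full_fasta = file.path(dir, "full_products.fa"),
             unpaired_fasta = file.path(dir, "unpaired.fa"),
             full_index = file.path(dir, "full_products.tsv"),
             unpaired_index = file.path(dir, "unpaired.tsv"))
  Biostrings::writeXStringSet(fs, paths[["full_fasta"]])
  Biostrings::writeXStringSet(us, paths[["unpaired_fasta"]])
  write.table(full, paths[["full_index"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(up, paths[["unpaired_index"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(paths)
}
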