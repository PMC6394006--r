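# file formats: FASTQ via Biostrings; primer/barcode tables and BED as TSV

#' Write reads as FASTQ
#'
#' @param reads data.frame with `read_id`, `sequence` and optionally
#'   `quality` (defaults to a constant per-base `"I"`).
#' @param path output path (`.gz` allowed).
#' @return invisibly, `path`.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("read_id", "sequence") %in% names(reads)))
  qual <- if ("quality" %in% names(reads)) reads$quality
          else strrep("I", nchar(reads$sequence))
  seqs <- Biostrings::DNAStringSet(reads$sequence)
  names(seqs) <- reads$read_id
  Biostrings::writeXStringSet(seqs, path, format = "fastq",
                              qualities = Biostrings::BStringSet(qual))
  invisible(path)
}

#' Read a FASTQ file
#'
#' @param path FASTQ path (`.gz` allowed).
#' @return data.frame `read_id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  # Biostrings warns about dropping its own internal metadata columns here
  x <- withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(path),
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  data.frame(read_id = names(x),
             sequence = as.character(x),
             quality = as.character(Biostrings::quality(x)),
             stringsAsFactors = FALSE)
}

#' Write a primer panel as a TSV oligo table
#'
#' One row per oligo (two per probe pair) with columns `probe_id`, `role`,
#' `chrom`, `start`, `end`, `strand`, `homology`, `full_oligo`, `phospho`.
#' Header comment lines record the universal tails and the strand
#' convention (homologies are stored in sequenced-product orientation; the
#' oligos anneal to the antisense strand).
#'
#' @param panel a `primer_panel`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_primer_table <- function(panel, path) {
  stopifnot(inherits(panel, "primer_panel"))
  tab <- assemble_full_primers(panel)
  header <- c(
    sprintf("# forward_tail=%s", attr(panel, "forward_tail")),
    sprintf("# reverse_tail=%s", attr(panel, "reverse_tail")),
    "# homologies in sequenced-product orientation; oligos anneal to the antisense strand",
    "# coordinates 0-based half-open")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a primer panel from a TSV oligo table
#'
#' Inverse of [write_primer_table()]: groups `F`/`R` rows by `probe_id`
#' and rebuilds the `primer_panel`, recovering the universal tails from the
#' header comments (or from the oligo/homology difference when absent).
#'
#' @param path TSV path.
#' @return a `primer_panel`.
#' @export
read_primer_table <- function(path) {
  lines <- readLines(path)
  hdr <- lines[grepl("^#", lines)]
  tab <- read.table(text = lines[!grepl("^#", lines)], sep = "\t",
                    header = TRUE, stringsAsFactors = FALSE,
                    colClasses = c(probe_id = "character"))
  need <- c("probe_id", "role", "chrom", "start", "end", "homology")
  if (!all(need %in% names(tab))) {
    stop("primer table lacks required columns: ",
         paste(setdiff(need, names(tab)), collapse = ", "), call. = FALSE)
  }
  grab_tail <- function(key, fallback) {
    m <- sub(paste0("^# ", key, "="), "", hdr[grepl(paste0("^# ", key, "="), hdr)])
    if (length(m) == 1L && nzchar(m)) m else fallback
  }
  fwd <- tab[tab$role == "F", , drop = FALSE]
  rev <- tab[tab$role == "R", , drop = FALSE]
  if (nrow(fwd) != nrow(rev) ||
      !setequal(fwd$probe_id, rev$probe_id)) {
    stop("primer table is not composed of complete F/R pairs", call. = FALSE)
  }
  rev <- rev[match(fwd$probe_id, rev$probe_id), , drop = FALSE]
  ft <- grab_tail("forward_tail",
                  if ("full_oligo" %in% names(fwd))
                    sub(paste0(fwd$homology[1L], "$"), "", fwd$full_oligo[1L])
                  else T3C_TAIL)
  rt <- grab_tail("reverse_tail",
                  if ("full_oligo" %in% names(rev))
                    sub(paste0("^", rev$homology[1L]), "", rev$full_oligo[1L])
                  else P1KEYC_TAIL)
  pairs <- data.frame(probe_id = fwd$probe_id, chrom = fwd$chrom,
                      junction = fwd$end,
                      f_start = fwd$start, f_end = fwd$end,
                      r_start = rev$start, r_end = rev$end,
                      strand = if ("strand" %in% names(fwd)) fwd$strand else "+",
                      forward_homology = fwd$homology,
                      reverse_homology = rev$homology,
                      stringsAsFactors = FALSE)
  pairs <- pairs[order(pairs$junction), , drop = FALSE]
  rownames(pairs) <- NULL
  new_primer_panel(pairs, pairs$chrom[1L], ft, rt)
}

#' Write probed intervals as BED
#'
#' @param panel a `primer_panel`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_panel_bed <- function(panel, path) {
  iv <- probe_intervals(panel)
  write.table(iv[, c("chrom", "start", "end", "probe_id")], path,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write the full oligos of a panel as FASTA
#'
#' @param panel a `primer_panel`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_oligo_fasta <- function(panel, path) {
  tab <- assemble_full_primers(panel)
  seqs <- Biostrings::DNAStringSet(tab$full_oligo)
  names(seqs) <- paste0(tab$probe_id, "_", tab$role,
                        ifelse(tab$phospho, "|5phos", ""))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Write / read a barcode table
#'
#' @param barcodes a [barcode_table()].
#' @param path TSV path.
#' @return invisibly `path` (write) or a `barcode_table` (read).
#' @export
write_barcode_table <- function(barcodes, path) {
  write.table(as.data.frame(barcodes), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_barcode_table
#' @export
read_barcode_table <- function(path) {
  tab <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  barcode_table(tab$sequence, barcode_id = tab$barcode_id,
                library_label = tab$library_label)
}
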