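#' Read-assignment gate parameters
#'
#' Minimum aligned-length and identity gates of the two mapping steps. The
#' defaults mirror the assay's word sizes: 50 nt for full products (the
#' smallest expected product) and 22 nt for unpaired primer sequences (the
#' length of one forward homology).
#'
#' @param min_match_full minimum aligned length against full products (nt).
#' @param min_match_unpaired minimum aligned length against unpaired entries.
#' @param min_identity minimum identity fraction over the aligned length.
#' @return object of class `match_params`.
#' @export
match_params <- function(min_match_full = 50L, min_match_unpaired = 22L,
                         min_identity = 0.95) {
  stopifnot(min_match_unpaired <= min_match_full,
            min_identity > 0, min_identity <= 1)
  structure(list(min_match_full = as.integer(min_match_full),
                 min_match_unpaired = as.integer(min_match_unpaired),
                 min_identity = min_identity),
            class = "match_params")
}

as_read_df <- function(reads) {
  if (is.data.frame(reads)) {
    stopifnot(all(c("read_id", "sequence") %in% names(reads)))
    return(reads[, c("read_id", "sequence")])
  }
  if (inherits(reads, "DNAStringSet")) {
    ids <- names(reads)
    if (is.null(ids)) ids <- sprintf("read%07d", seq_along(reads))
    return(data.frame(read_id = ids, sequence = as.character(reads),
                      stringsAsFactors = FALSE))
  }
  if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
    return(read_fastq(reads)[, c("read_id", "sequence")])
  }
  if (is.character(reads)) {
    ids <- names(reads)
    if (is.null(ids)) ids <- sprintf("read%07d", seq_along(reads))
    return(data.frame(read_id = ids, sequence = unname(reads),
                      stringsAsFactors = FALSE))
  }
  stop("unsupported reads input", call. = FALSE)
}

#' Match one or more reads against a reference sequence set
#'
#' Reads and references are compared by 5'-anchored ungapped overlap
#' alignment: both begin at the same structural position (the barcode for
#' reads and barcode-bearing references, the primer start otherwise), so
#' matches are counted from position 0 over `min(len(read), len(ref))`
#' positions. A reference is a hit when the aligned length is at least
#' `min_match` and the identity (matches / aligned length) at least
#' `min_identity`; the score is aligned length x identity.
#'
#' @param reads character vector of read sequences (named), a data.frame
#'   with `read_id`/`sequence`, or a `DNAStringSet`.
#' @param references named character vector of reference sequences.
#' @param min_match minimum aligned length (nt).
#' @param min_identity minimum identity fraction.
#' @return data.frame of hits: `read_id`, `ref_id`, `aligned_length`,
#'   `matches`, `identity`, `score`, sorted by read then descending score.
#' @export
match_read <- function(reads, references, min_match = 50L,
                       min_identity = 0.95) {
  rd <- as_read_df(reads)
  stopifnot(length(references) >= 1L)
  ref_ids <- names(references)
  if (is.null(ref_ids)) ref_ids <- sprintf("ref%05d", seq_along(references))
  m <- cpp_anchored_counts(rd$sequence, unname(references))
  rl <- nchar(rd$sequence)
  fl <- nchar(references)
  al <- outer(rl, fl, pmin)
  idy <- m / al
  hit <- al >= min_match & idy >= min_identity - 1e-12
  idx <- which(hit, arr.ind = TRUE)
  out <- data.frame(read_id = rd$read_id[idx[, 1L]],
                    ref_id = ref_ids[idx[, 2L]],
                    aligned_length = al[idx],
                    matches = m[idx],
                    identity = idy[idx],
                    score = al[idx] * idy[idx],
                    stringsAsFactors = FALSE)
  out[order(match(out$read_id, rd$read_id), -out$score), , drop = FALSE]
}

#' Two-step read assignment against the expected-product reference
#'
#' Step 1 matches every read against the full-product assembly with the
#' `min_match_full` gate; a read is assigned (`outcome = "product"`) iff
#' exactly one gated product attains the top score. Reads with tied top
#' scores or no gated hit are re-matched in step 2 against the unpaired
#' assembly with the `min_match_unpaired` gate, taking the category of the
#' unique best entry (`"barcode-forward"`, `"forward"` or `"reverse"`);
#' remaining ties are `"ambiguous"` and reads without any gated hit
#' `"unmapped"`. Score ties are never broken arbitrarily.
#'
#' The barcode of an assignment comes from the matched reference itself
#' (products and barcode-forward stems embed their barcode), so barcode
#' sequencing errors are tolerated up to the identity gate and demultiplexing
#' needs no separate pass.
#'
#' @param reads reads in any form accepted by [match_read()] (including a
#'   FASTQ path).
#' @param reference a [product_reference()].
#' @param params a [match_params()] object.
#' @return data.frame of class `read_assignment`: `read_id`, `outcome`,
#'   `product_id`, `barcode_id`, `probe_id`, `on_diagonal`, `score`.
#' @export
two_step_assign <- function(reads, reference, params = match_params()) {
  stopifnot(inherits(reference, "product_reference"),
            inherits(params, "match_params"))
  rd <- as_read_df(reads)
  n <- nrow(rd)
  panel <- reference$panel
  bcs <- reference$barcodes
  ft <- attr(panel, "forward_tail")
  np <- nrow(panel); nb <- nrow(bcs)

  out <- data.frame(read_id = rd$read_id,
                    outcome = rep("unmapped", n),
                    product_id = rep(NA_character_, n),
                    barcode_id = rep(NA_character_, n),
                    probe_id = rep(NA_character_, n),
                    on_diagonal = rep(NA, n),
                    score = rep(NA_real_, n),
                    stringsAsFactors = FALSE)
  if (n == 0L) return(structure(out, class = c("read_assignment", "data.frame")))

  if (identical(reference$full$product_id,
                paste(rep(bcs$barcode_id, each = np * np),
                      rep(rep(panel$probe_id, each = np), times = nb),
                      rep(panel$probe_id, times = nb * np), sep = "|"))) {
    # structured fast path: product(s, j) = stem_s || rev_j in reference order
    stems <- paste0(rep(bcs$sequence, each = np), ft,
                    rep(panel$forward_homology, times = nb))
    revs <- panel$reverse_homology
    if (reference$include_reverse_tail) {
      revs <- paste0(revs, attr(panel, "reverse_tail"))
    }
    a <- cpp_assign_full(rd$sequence, stems, revs,
                         params$min_match_full, params$min_identity)
    assigned <- a$best_idx > 0L & a$n_top == 1L
    pi <- a$best_idx[assigned]
    out$outcome[assigned] <- "product"
    out$product_id[assigned] <- reference$full$product_id[pi]
    out$barcode_id[assigned] <- reference$full$barcode_id[pi]
    out$on_diagonal[assigned] <- reference$full$on_diagonal[pi]
    out$probe_id[assigned] <- ifelse(reference$full$on_diagonal[pi],
                                     reference$full$forward_probe_id[pi],
                                     NA_character_)
    out$score[assigned] <- a$matches[assigned]
  } else {
    # generic path (e.g. sampled enumeration): dense anchored matching
    hits <- match_read(rd, setNames(reference$full$sequence,
                                    reference$full$product_id),
                       params$min_match_full, params$min_identity)
    assigned <- logical(n)
    if (nrow(hits)) {
      sp <- split(hits, hits$read_id)
      for (h in sp) {
        top <- h[h$score >= max(h$score) - 1e-9, , drop = FALSE]
        if (nrow(top) == 1L) {
          i <- match(top$read_id, rd$read_id)
          k <- match(top$ref_id, reference$full$product_id)
          assigned[i] <- TRUE
          out$outcome[i] <- "product"
          out$product_id[i] <- reference$full$product_id[k]
          out$barcode_id[i] <- reference$full$barcode_id[k]
          out$on_diagonal[i] <- reference$full$on_diagonal[k]
          out$probe_id[i] <- if (reference$full$on_diagonal[k])
            reference$full$forward_probe_id[k] else NA_character_
          out$score[i] <- top$score
        }
      }
    }
  }

  rest <- which(!out$outcome == "product")
  if (length(rest)) {
    up <- reference$unpaired
    m <- cpp_anchored_counts(rd$sequence[rest], up$sequence)
    rl <- nchar(rd$sequence[rest])
    al <- outer(rl, up$length, pmin)
    ok <- al >= params$min_match_unpaired &
      m / al >= params$min_identity - 1e-12
    sc <- ifelse(ok, m, -1L)
    best <- apply(sc, 1L, max)
    ntop <- rowSums(sc == best & best >= 0L)
    uniq <- best >= 0L & ntop == 1L
    if (any(uniq)) {
      k <- max.col(sc, ties.method = "first")[uniq]
      i <- rest[uniq]
      out$outcome[i] <- ifelse(up$category[k] == "barcode-forward",
                               "barcode-forward", up$category[k])
      out$product_id[i] <- up$id[k]
      out$barcode_id[i] <- up$barcode_id[k]
      out$probe_id[i] <- NA_character_
      out$score[i] <- best[uniq]
    }
    amb <- best >= 0L & ntop > 1L
    out$outcome[rest[amb]] <- "ambiguous"
  }
  structure(out, class = c("read_assignment", "data.frame"))
}

#' Split assignments by barcode/library
#'
#' Partitions a `read_assignment` table on `barcode_id`. Assignments without
#' a barcode (reverse-only, forward-only, ambiguous, unmapped) are pooled
#' into a run-level `residue` element.
#'
#' @param assignments output of [two_step_assign()].
#' @param barcodes optional [barcode_table()]; barcodes in the assignments
#'   but absent from the table are reported with a warning as unexpected.
#' @return named list of assignment data.frames (one per barcode, plus
#'   `residue`).
#' @export
split_by_barcode <- function(assignments, barcodes = NULL) {
  stopifnot(is.data.frame(assignments))
  has_bc <- !is.na(assignments$barcode_id)
  parts <- split(assignments[has_bc, , drop = FALSE],
                 assignments$barcode_id[has_bc])
  if (!is.null(barcodes)) {
    unexpected <- setdiff(names(parts), barcodes$barcode_id)
    if (length(unexpected)) {
      warning("assignments carry barcodes absent from the barcode table: ",
              paste(unexpected, collapse = ", "))
    }
  }
  parts$residue <- assignments[!has_bc, , drop = FALSE]
  parts
}

#' Tabulate per-library counts
#'
#' On-diagonal product counts per (library, probe) plus off-diagonal,
#' unpaired, ambiguous and unmapped tallies. Category sums are conserved:
#' they always add up to the total number of assigned reads.
#'
#' @param assignments a `read_assignment` data.frame, or the list returned by
#'   [split_by_barcode()].
#' @param reference the [product_reference()] the assignments were made
#'   against (supplies the probe and barcode universe so empty categories
#'   are zero-filled).
#' @return object of class `count_table`: list with `probe_counts`
#'   (data.frame `library`, `barcode_id`, `probe_id`, `count`), `categories`
#'   (per-library + residue tallies), and `total_reads`.
#' @export
tabulate_counts <- function(assignments, reference) {
  stopifnot(inherits(reference, "product_reference"))
  if (is.data.frame(assignments)) {
    assignments <- split_by_barcode(assignments, reference$barcodes)
  }
  panel <- reference$panel
  bcs <- reference$barcodes
  all_df <- do.call(rbind, c(assignments, list(make.row.names = FALSE)))
  total <- nrow(all_df)

  probe_counts <- expand.grid(probe_id = panel$probe_id,
                              barcode_id = bcs$barcode_id,
                              stringsAsFactors = FALSE)
  probe_counts$library <- bcs$library_label[
    match(probe_counts$barcode_id, bcs$barcode_id)]
  ond <- all_df[all_df$outcome == "product" & !is.na(all_df$on_diagonal) &
                  all_df$on_diagonal, , drop = FALSE]
  key <- paste(probe_counts$barcode_id, probe_counts$probe_id)
  tab <- table(paste(ond$barcode_id, ond$probe_id))
  probe_counts$count <- as.integer(tab[key])
  probe_counts$count[is.na(probe_counts$count)] <- 0L
  probe_counts <- probe_counts[, c("library", "barcode_id", "probe_id", "count")]

  tally_one <- function(df, label, bc) {
    data.frame(
      library = label, barcode_id = bc,
      product = sum(df$outcome == "product" & !is.na(df$on_diagonal) &
                      df$on_diagonal),
      off_diagonal = sum(df$outcome == "product" & !is.na(df$on_diagonal) &
                           !df$on_diagonal),
      barcode_forward = sum(df$outcome == "barcode-forward"),
      forward = sum(df$outcome == "forward"),
      reverse = sum(df$outcome == "reverse"),
      ambiguous = sum(df$outcome == "ambiguous"),
      unmapped = sum(df$outcome == "unmapped"),
      stringsAsFactors = FALSE)
  }
  cats <- list()
  for (b in bcs$barcode_id) {
    df <- assignments[[b]]
    if (is.null(df)) df <- all_df[0L, , drop = FALSE]
    cats[[b]] <- tally_one(df, bcs$library_label[match(b, bcs$barcode_id)], b)
  }
  cats$residue <- tally_one(assignments$residue, "residue", NA_character_)
  categories <- do.call(rbind, c(cats, list(make.row.names = FALSE)))
  structure(list(probe_counts = probe_counts, categories = categories,
                 total_reads = total),
            class = "count_table")
}

#' Write / read a count table as TSV files
#'
#' Serializes a [tabulate_counts()] result as two TSVs in a directory:
#' `probe_counts.tsv` (per library and probe) and `categories.tsv`
#' (per-library and residue tallies).
#'
#' @param table a `count_table`.
#' @param dir output directory (write) / directory holding the two TSVs
#'   (read).
#' @return invisibly the paths (write); a `count_table` (read).
#' @export
write_count_table <- function(table, dir) {
  stopifnot(inherits(table, "count_table"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(probe_counts = file.path(dir, "probe_counts.tsv"),
             categories = file.path(dir, "categories.tsv"))
  write.table(table$probe_counts, paths[["probe_counts"]], sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(table$categories, paths[["categories"]], sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' @rdname write_count_table
#' @export
read_count_table <- function(dir) {
  pc <- read.table(file.path(dir, "probe_counts.tsv"), sep = "\t",
                   header = TRUE, stringsAsFactors = FALSE,
                   colClasses = c(probe_id = "character"))
  cats <- read.table(file.path(dir, "categories.tsv"), sep = "\t",
                     header = TRUE, stringsAsFactors = FALSE)
  cat_cols <- c("product", "off_diagonal", "barcode_forward", "forward",
                "reverse", "ambiguous", "unmapped")
  structure(list(probe_counts = pc, categories = cats,
                 total_reads = sum(unlist(cats[, cat_cols]))),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat("2C-ChIP count table: ", x$total_reads, " reads, ",
      length(unique(x$probe_counts$probe_id)), " probes, ",
      length(setdiff(x$categories$library, "residue")), " libraries\n",
      sep = "")
  print(x$categories)
  invisible(x)
}
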