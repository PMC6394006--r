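# Two independent single-pass assignment oracles, both aligning every read
# against the union of the full-product and unpaired assemblies with the same
# gates and the same product-before-unpaired decision rule, but none of the
# two-step search-space shortcut (no leftover-only second pass, no structured
# stem/reverse decomposition, no compiled code).
#
# oracle_assign_anchored evaluates the package's documented alignment
# contract (5'-anchored ungapped overlap) in plain R.
# oracle_assign_dp scores by full dynamic-programming local alignment
# (Smith-Waterman, Biostrings::pairwiseAlignment, +1/-1, heavy gap
# penalties); on noiseless reads the two contracts coincide.

oracle_assign_anchored <- function(reads_df, reference,
                                   params = match_params()) {
  full <- reference$full
  up <- reference$unpaired
  n <- nrow(reads_df)
  rchars <- strsplit(reads_df$sequence, "", fixed = TRUE)
  fchars <- strsplit(full$sequence, "", fixed = TRUE)
  uchars <- strsplit(up$sequence, "", fixed = TRUE)
  score_pair <- function(a, b) {
    L <- min(length(a), length(b))
    c(m = sum(a[seq_len(L)] == b[seq_len(L)]), al = L)
  }
  out <- data.frame(read_id = reads_df$read_id,
                    outcome = rep("unmapped", n),
                    product_id = rep(NA_character_, n),
                    barcode_id = rep(NA_character_, n),
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    fs <- vapply(fchars, score_pair, c(m = 0, al = 0), a = rchars[[i]])
    ok <- fs["al", ] >= params$min_match_full &
      fs["m", ] / fs["al", ] >= params$min_identity - 1e-12
    if (any(ok)) {
      top <- max(fs["m", ok])
      hits <- which(ok & fs["m", ] == top)
      if (length(hits) == 1L) {
        out$outcome[i] <- "product"
        out$product_id[i] <- full$product_id[hits]
        out$barcode_id[i] <- full$barcode_id[hits]
        next
      }
    }
    us <- vapply(uchars, score_pair, c(m = 0, al = 0), a = rchars[[i]])
    ok2 <- us["al", ] >= params$min_match_unpaired &
      us["m", ] / us["al", ] >= params$min_identity - 1e-12
    if (!any(ok2)) next
    top <- max(us["m", ok2])
    hits <- which(ok2 & us["m", ] == top)
    if (length(hits) == 1L) {
      out$outcome[i] <- ifelse(up$category[hits] == "barcode-forward",
                               "barcode-forward", up$category[hits])
      out$product_id[i] <- up$id[hits]
      out$barcode_id[i] <- up$barcode_id[hits]
    } else {
      out$outcome[i] <- "ambiguous"
    }
  }
  out
}

oracle_assign_dp <- function(reads_df, reference, params = match_params()) {
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  score_against <- function(refseq) {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAStringSet(reads_df$sequence),
      Biostrings::DNAString(refseq), type = "local",
      substitutionMatrix = submat, gapOpening = 5, gapExtension = 2)
    list(m = Biostrings::nmatch(aln), al = Biostrings::nchar(aln))
  }
  full <- reference$full
  up <- reference$unpaired
  n <- nrow(reads_df)
  fm <- fal <- matrix(0L, n, nrow(full))
  for (k in seq_len(nrow(full))) {
    sc <- score_against(full$sequence[k])
    fm[, k] <- sc$m; fal[, k] <- sc$al
  }
  um <- ual <- matrix(0L, n, nrow(up))
  for (k in seq_len(nrow(up))) {
    sc <- score_against(up$sequence[k])
    um[, k] <- sc$m; ual[, k] <- sc$al
  }
  out <- data.frame(read_id = reads_df$read_id,
                    outcome = rep("unmapped", n),
                    product_id = rep(NA_character_, n),
                    barcode_id = rep(NA_character_, n),
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    ok <- fal[i, ] >= params$min_match_full &
      fm[i, ] / fal[i, ] >= params$min_identity - 1e-12
    if (any(ok)) {
      top <- max(fm[i, ok])
      hits <- which(ok & fm[i, ] == top)
      if (length(hits) == 1L) {
        out$outcome[i] <- "product"
        out$product_id[i] <- full$product_id[hits]
        out$barcode_id[i] <- full$barcode_id[hits]
        next
      }
    }
    ok2 <- ual[i, ] >= params$min_match_unpaired &
      um[i, ] / ual[i, ] >= params$min_identity - 1e-12
    if (!any(ok2)) next
    top <- max(um[i, ok2])
    hits <- which(ok2 & um[i, ] == top)
    if (length(hits) == 1L) {
      out$outcome[i] <- ifelse(up$category[hits] == "barcode-forward",
                               "barcode-forward", up$category[hits])
      out$product_id[i] <- up$id[hits]
      out$barcode_id[i] <- up$barcode_id[hits]
    } else {
      out$outcome[i] <- "ambiguous"
    }
  }
  out
}

# brute-force exhaustive substring occurrence count (both strands)
brute_occurrences <- function(pattern, genome) {
  L <- nchar(pattern)
  n <- nchar(genome)
  if (L > n) return(0L)
  subs <- substring(genome, seq_len(n - L + 1L), L:n)
  rc <- chartr("ACGT", "TGCA", pattern)
  rc <- paste(rev(strsplit(rc, "")[[1L]]), collapse = "")
  sum(subs == pattern) + sum(subs == rc)
}
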