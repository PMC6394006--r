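# internal helpers shared across modules

DNA_ALPHABET <- c("A", "C", "G", "T")

assert_dna <- function(seq, what = "sequence") {
  if (!is.character(seq) || length(seq) == 0 || anyNA(seq)) {
    stop(what, " must be a non-missing character vector", call. = FALSE)
  }
  bad <- !grepl("^[ACGT]+$", seq)
  if (any(bad)) {
    stop(what, " must be non-empty and contain only A/C/G/T (offending: ",
         paste(utils::head(seq[bad], 3), collapse = ", "), ")", call. = FALSE)
  }
  invisible(seq)
}

revcomp <- function(seq) {
  assert_dna(seq)
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}

# overlapping occurrence count of `pattern` in `subject`
# (subject may be a pre-built DNAString to avoid repeated conversion)
count_occurrences <- function(pattern, subject) {
  if (is.character(subject)) subject <- Biostrings::DNAString(subject)
  Biostrings::countPattern(pattern, subject)
}

# fast plain-string reverse complement for short k-mers (no Biostrings
# object overhead in the tiling inner loop)
revcomp_kmers <- function(kmers) {
  comp <- chartr("ACGT", "TGCA", kmers)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1L))
}

with_seed_if <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(seed, code)
}
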