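#' Default universal tails
#'
#' Constant tails appended to the target-homologous portions of the 2C-ChIP
#' primers: forwards carry a modified-T3 complement at their 5' end, reverses
#' a P1-key complement at their 3' end, so that every ligation product can be
#' amplified with a single primer pair and adapted to the sequencing platform.
#' @name tails
#' @keywords internal
NULL

T3C_TAIL <- "TAATTGGGAGTGATTTCCCT"
P1KEYC_TAIL <- "ATCACCGACTGCCCATAGAGAGG"

#' Primer design constraints
#'
#' Bundle of the rules a candidate primer homology must satisfy: homology
#' length between `min_homology_len` and `max_homology_len` nucleotides, GC
#' fraction within `[min_gc, max_gc]`, exact-occurrence uniqueness in the
#' target genome (both strands), and absence of self-complementary runs of
#' `max_selfcomp_run` or more nucleotides (a cheap proxy for self-annealing /
#' hairpin propensity).
#'
#' @param min_homology_len,max_homology_len homology length bounds in nt.
#' @param min_gc,max_gc GC-content bounds as fractions in `[0, 1]`.
#' @param uniqueness_required require the homology to occur exactly once in
#'   the supplied genome (counting both strands).
#' @param max_selfcomp_run a homology fails if it contains a subsequence of
#'   this length whose reverse complement also occurs within the homology.
#' @return an object of class `primer_constraints`.
#' @export
primer_constraints <- function(min_homology_len = 22L, max_homology_len = 34L,
                               min_gc = 0.40, max_gc = 0.60,
                               uniqueness_required = TRUE,
                               max_selfcomp_run = 6L) {
  stopifnot(min_homology_len >= 1, min_homology_len <= max_homology_len,
            min_gc >= 0, min_gc <= max_gc, max_gc <= 1,
            is.logical(uniqueness_required), max_selfcomp_run >= 2)
  structure(list(min_homology_len = as.integer(min_homology_len),
                 max_homology_len = as.integer(max_homology_len),
                 min_gc = min_gc, max_gc = max_gc,
                 uniqueness_required = uniqueness_required,
                 max_selfcomp_run = as.integer(max_selfcomp_run)),
            class = "primer_constraints")
}

#' GC content of DNA sequences
#'
#' @param seq character vector of A/C/G/T sequences.
#' @return numeric vector of GC fractions in `[0, 1]`.
#' @examples
#' gc_content("ATCACCGACTGCCCATAGAGAGG")  # 13/23
#' @export
gc_content <- function(seq) {
  assert_dna(seq, "seq")
  nchar(gsub("[AT]", "", seq)) / nchar(seq)
}

# self-complementarity: any k-mer of the homology whose reverse complement is
# also a k-mer of the homology (covers hairpin stems and homodimer seeds)
has_selfcomp_run <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(FALSE)
  kmers <- substring(seq, seq_len(n - k + 1L), k:n)
  any(revcomp_kmers(kmers) %in% kmers)
}

#' Check one primer homology against the design constraints
#'
#' @param homology candidate homology sequence (A/C/G/T).
#' @param constraints a [primer_constraints()] object.
#' @param genome genome sequence (plain string) used for the uniqueness check.
#' @param genome_rc optional pre-computed reverse complement of `genome`
#'   (plain string or `DNAString`); avoids recomputation in tiling loops.
#' @return list with `pass` (logical) and `violations` (character vector among
#'   `"length"`, `"gc"`, `"uniqueness"`, `"self_complementarity"`).
#' @export
check_primer <- function(homology, constraints = primer_constraints(),
                         genome = NULL, genome_rc = NULL) {
  assert_dna(homology, "homology")
  stopifnot(length(homology) == 1L)
  v <- character()
  n <- nchar(homology)
  if (n < constraints$min_homology_len || n > constraints$max_homology_len) {
    v <- c(v, "length")
  }
  gc <- gc_content(homology)
  if (gc < constraints$min_gc || gc > constraints$max_gc) v <- c(v, "gc")
  if (has_selfcomp_run(homology, constraints$max_selfcomp_run)) {
    v <- c(v, "self_complementarity")
  }
  if (constraints$uniqueness_required && !is.null(genome)) {
    if (is.null(genome_rc)) {
      genome_rc <- if (is.character(genome)) revcomp(genome)
                   else Biostrings::reverseComplement(genome)
    }
    hits <- count_occurrences(homology, genome) +
      count_occurrences(homology, genome_rc)
    if (hits != 1L) v <- c(v, "uniqueness")
  }
  list(pass = length(v) == 0L, violations = v)
}

new_primer_panel <- function(pairs, chrom, forward_tail, reverse_tail) {
  structure(pairs,
            chrom = chrom,
            forward_tail = forward_tail,
            reverse_tail = reverse_tail,
            reverse_phosphorylated = TRUE,
            class = c("primer_panel", "data.frame"))
}

#' Tile a genomic interval with adjacent forward/reverse primer pairs
#'
#' Greedy left-to-right scan: at each candidate junction the forward homology
#' is grown leftward and the reverse homology rightward from the minimum to
#' the maximum homology length; the first (shortest) combination in which
#' both homologies pass [check_primer()] is accepted and the scan advances.
#' Forward and reverse homologies of a pair abut at the junction with no gap
#' or overlap, as required by the nick-sealing ligase. The scan is a pure
#' function of its inputs (no randomness).
#'
#' Homologies are stored in the orientation of the sequenced product (the
#' supplied genome strand); the synthesized oligos anneal to the antisense
#' strand.
#'
#' @param genome genome sequence as a single string (or a length-1
#'   [Biostrings::DNAStringSet]).
#' @param interval list or data.frame row with `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param constraints a [primer_constraints()] object.
#' @param target_spacing minimum distance in bp between successive junctions,
#'   or `"max-density"` to pack pairs as tightly as the constraints allow.
#' @param forward_tail,reverse_tail universal tails attached when assembling
#'   full oligos.
#' @param id_prefix prefix for generated probe ids.
#' @return a `primer_panel`: data.frame with one row per probe pair
#'   (`probe_id`, `chrom`, `junction`, `f_start`, `f_end`, `r_start`,
#'   `r_end`, `strand`, `forward_homology`, `reverse_homology`) plus tail
#'   attributes. Empty (with a warning) when no valid pair fits.
#' @export
tile_region <- function(genome, interval, constraints = primer_constraints(),
                        target_spacing = "max-density",
                        forward_tail = T3C_TAIL, reverse_tail = P1KEYC_TAIL,
                        id_prefix = "probe") {
  if (inherits(genome, "DNAStringSet")) genome <- as.character(genome[[1L]])
  if (inherits(genome, "DNAString")) genome <- as.character(genome)
  assert_dna(genome, "genome")
  chrom <- as.character(interval$chrom)
  start <- as.integer(interval$start)
  end <- as.integer(interval$end)
  stopifnot(start >= 0, start < end, end <= nchar(genome))
  spacing <- if (identical(target_spacing, "max-density")) 0L
             else as.integer(target_spacing)
  cs <- constraints
  gdna <- Biostrings::DNAString(genome)
  gdna_rc <- Biostrings::reverseComplement(gdna)
  # cumulative GC lookup: gc of 0-based [s, s+L) = (gcp[s+L+1] - gcp[s+1]) / L
  gcp <- c(0L, cumsum(strsplit(genome, "", fixed = TRUE)[[1L]] %in% c("G", "C")))
  gc_of <- function(s, L) (gcp[s + L + 1L] - gcp[s + 1L]) / L
  # remaining constraints, cheapest first, short-circuited (GC prechecked)
  ok_rest <- function(seq) {
    !has_selfcomp_run(seq, cs$max_selfcomp_run) &&
      (!cs$uniqueness_required ||
         count_occurrences(seq, gdna) + count_occurrences(seq, gdna_rc) == 1L)
  }
  rows <- list()
  # junction j in 0-based genome coords: F covers [j - f_len, j), R [j, j + r_len)
  min_start <- start            # leftmost genome position usable by an F
  j <- start + cs$min_homology_len
  last_junction <- -Inf
  while (j + cs$min_homology_len <= end) {
    if (j - last_junction < spacing) {
      j <- as.integer(last_junction + spacing)
      next
    }
    found <- NULL
    for (f_len in cs$min_homology_len:cs$max_homology_len) {
      if (j - f_len < min_start) break
      gc <- gc_of(j - f_len, f_len)
      if (gc < cs$min_gc || gc > cs$max_gc) next
      f_seq <- substr(genome, j - f_len + 1L, j)
      if (!ok_rest(f_seq)) next
      for (r_len in cs$min_homology_len:cs$max_homology_len) {
        if (j + r_len > end) break
        gc <- gc_of(j, r_len)
        if (gc < cs$min_gc || gc > cs$max_gc) next
        r_seq <- substr(genome, j + 1L, j + r_len)
        if (!ok_rest(r_seq)) next
        found <- list(f_len = f_len, r_len = r_len,
                      f_seq = f_seq, r_seq = r_seq)
        break
      }
      if (!is.null(found)) break
    }
    if (is.null(found)) {
      j <- j + 1L
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      probe_id = NA_character_, chrom = chrom, junction = j,
      f_start = j - found$f_len, f_end = j,
      r_start = j, r_end = j + found$r_len,
      strand = "+",
      forward_homology = found$f_seq, reverse_homology = found$r_seq,
      stringsAsFactors = FALSE)
    last_junction <- j
    min_start <- j + found$r_len        # next pair must not overlap this one
    j <- max(j + spacing, min_start + cs$min_homology_len)
  }
  if (length(rows) == 0L) {
    warning("no valid primer pair found in ", chrom, ":", start, "-", end)
    pairs <- data.frame(probe_id = character(), chrom = character(),
                        junction = integer(), f_start = integer(),
                        f_end = integer(), r_start = integer(),
                        r_end = integer(), strand = character(),
                        forward_homology = character(),
                        reverse_homology = character(),
                        stringsAsFactors = FALSE)
  } else {
    pairs <- do.call(rbind, rows)
    pairs$probe_id <- sprintf("%s_%04d", id_prefix, seq_len(nrow(pairs)))
  }
  new_primer_panel(pairs, chrom, forward_tail, reverse_tail)
}

#' Full oligo sequences for a panel
#'
#' Forward oligo = forward tail + forward homology; reverse oligo = reverse
#' homology + reverse tail, flagged 5'-phosphorylated (required for the
#' ligation step).
#'
#' @param panel a `primer_panel`.
#' @return data.frame with one row per oligo: `probe_id`, `role` (`"F"` /
#'   `"R"`), `chrom`, `start`, `end`, `strand`, `homology`, `full_oligo`,
#'   `phospho`.
#' @export
assemble_full_primers <- function(panel) {
  stopifnot(inherits(panel, "primer_panel"))
  ft <- attr(panel, "forward_tail")
  rt <- attr(panel, "reverse_tail")
  if (nrow(panel) == 0L) {
    return(data.frame(probe_id = character(), role = character(),
                      chrom = character(), start = integer(), end = integer(),
                      strand = character(), homology = character(),
                      full_oligo = character(), phospho = logical(),
                      stringsAsFactors = FALSE))
  }
  fwd <- data.frame(probe_id = panel$probe_id, role = "F",
                    chrom = panel$chrom, start = panel$f_start,
                    end = panel$f_end, strand = panel$strand,
                    homology = panel$forward_homology,
                    full_oligo = paste0(ft, panel$forward_homology),
                    phospho = FALSE, stringsAsFactors = FALSE)
  rev <- data.frame(probe_id = panel$probe_id, role = "R",
                    chrom = panel$chrom, start = panel$r_start,
                    end = panel$r_end, strand = panel$strand,
                    homology = panel$reverse_homology,
                    full_oligo = paste0(panel$reverse_homology, rt),
                    phospho = TRUE, stringsAsFactors = FALSE)
  out <- rbind(fwd, rev)
  out[order(out$probe_id, out$role), , drop = FALSE]
}

#' Concentration of a reagent in a reaction
#'
#' Converts an amount in femtomoles and a reaction volume in microlitres to a
#' concentration in picomolar (1 fmol / 1 ul = 1000 pM).
#'
#' @param amount_fmol amount in fmol (>= 0).
#' @param volume_ul reaction volume in ul (> 0).
#' @return concentration in pM.
#' @examples
#' reaction_molarity(0.34, 10)  # 34 pM, the per-primer annealing concentration
#' @export
reaction_molarity <- function(amount_fmol, volume_ul) {
  if (!is.numeric(amount_fmol) || any(amount_fmol < 0)) {
    stop("amount_fmol must be >= 0", call. = FALSE)
  }
  if (!is.numeric(volume_ul) || any(volume_ul <= 0)) {
    stop("volume_ul must be > 0", call. = FALSE)
  }
  amount_fmol / volume_ul * 1000
}

#' Probed genomic intervals of a panel
#'
#' One interval per probe pair spanning the forward and reverse homologies
#' (`f_start` to `r_end`, 0-based half-open).
#'
#' @param panel a `primer_panel`.
#' @return data.frame `probe_id`, `chrom`, `start`, `end`.
#' @export
probe_intervals <- function(panel) {
  stopifnot(inherits(panel, "primer_panel"))
  data.frame(probe_id = panel$probe_id, chrom = panel$chrom,
             start = panel$f_start, end = panel$r_end,
             stringsAsFactors = FALSE)
}

#' @export
`[.primer_panel` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) {
    for (a in c("chrom", "forward_tail", "reverse_tail",
                "reverse_phosphorylated")) {
      attr(out, a) <- attr(x, a)
    }
    class(out) <- class(x)
  }
  out
}

#' @export
print.primer_panel <- function(x, ...) {
  cat("2C-ChIP primer panel: ", nrow(x), " probe pairs",
      if (nrow(x)) paste0(" on ", x$chrom[1L], ":", min(x$f_start), "-",
                          max(x$r_end)), "\n", sep = "")
  cat("  forward tail: ", attr(x, "forward_tail"),
      "   reverse tail: ", attr(x, "reverse_tail"),
      " (5'-phosphorylated reverses)\n", sep = "")
  if (nrow(x)) print(utils::head(as.data.frame(x), 5L))
  invisible(x)
}
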