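# shared fixtures: small panels, references and simulations built in code

fixture_panel <- function(n_pairs = NULL, genome_len = 4000, seed = 101,
                          spacing = "max-density") {
  g <- simulate_genome(genome_len, 0.5, seed = seed)
  panel <- tile_region(g, list(chrom = "chrT", start = 0, end = genome_len),
                       target_spacing = spacing)
  if (!is.null(n_pairs)) {
    stopifnot(nrow(panel) >= n_pairs)
    panel <- panel[seq_len(n_pairs), , drop = FALSE]
  }
  list(genome = g, panel = panel)
}

fixture_barcodes <- function(n = 2, seed = 77) {
  labels <- c("chip", "input", paste0("lib", seq_len(max(0, n - 2))))
  random_barcodes(n, seed = seed, library_label = labels[seq_len(n)])
}

# hand-built panel with full control over homologies (bypasses design checks)
manual_panel <- function(f_homs, r_homs, chrom = "chrM",
                         forward_tail = "TAATTGGGAGTGATTTCCCT",
                         reverse_tail = "ATCACCGACTGCCCATAGAGAGG") {
  n <- length(f_homs)
  f_len <- nchar(f_homs)
  r_len <- nchar(r_homs)
  junction <- cumsum(f_len + r_len) - r_len
  pairs <- data.frame(
    probe_id = sprintf("m_%03d", seq_len(n)), chrom = chrom,
    junction = junction,
    f_start = junction - f_len, f_end = junction,
    r_start = junction, r_end = junction + r_len,
    strand = "+", forward_homology = f_homs, reverse_homology = r_homs,
    stringsAsFactors = FALSE)
  structure(pairs, chrom = chrom, forward_tail = forward_tail,
            reverse_tail = reverse_tail, reverse_phosphorylated = TRUE,
            class = c("primer_panel", "data.frame"))
}

random_homology <- function(n, len = 22, seed = NULL) {
  draw <- function() {
    replicate(n, paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                       collapse = ""))
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}
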