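# chip2c

Computational toolkit for **carbon copy-ChIP (2C-ChIP)** — a
ligation-mediated-amplification (LMA) assay that quantifies chromatin
immunoprecipitation signal over predefined genomic regions by deep
sequencing. It is aimed at groups running targeted chromatin profiling
(histone marks, chromatin-bound proteins) across many conditions or time
points, where genome-wide ChIP-seq is unnecessarily expensive and
qPCR-based readouts do not scale.

## What the assay measures, and what the package does

In 2C-ChIP, adjacent forward/reverse primer pairs are annealed on the same
strand of immunoprecipitated DNA and joined by a nick-sealing ligase only
when they sit exactly side by side. Universal tails (T3-complement on
forwards; P1-key-complement on the 5'-phosphorylated reverses) let all
ligation products be amplified in one PCR that also adds a library barcode,
read first on the sequencer. Counting the sequenced products of the
*designed* ("on-diagonal") pairs gives a quantitative imprint of the ChIP
material at each probed position; products between non-adjacent primers
("off-diagonal") are artifacts tracked as a library quality metric.

The package covers the full computational arm:

* **design** — `tile_region()` tiles target intervals with probe pairs
  under homology-length (22–34 nt), GC (40–60 %), uniqueness and
  self-complementarity constraints; `assemble_full_primers()` emits the
  orderable oligos.
* **reference** — `product_reference()` enumerates every barcode × F × R
  product (on/off-diagonal) plus the unpaired barcode-forward / forward /
  reverse assemblies.
* **simulate** — `simulate_library()` generates barcoded reads with exact
  ground truth (multinomial probe abundances, off-diagonal and truncation
  artifacts, substitution errors).
* **mapcount** — `two_step_assign()` maps reads first against full
  products (aligned length ≥ 50), then remaps non-unique leftovers
  against unpaired sequences (≥ 22), demultiplexes by the barcode embedded
  in the matched reference, and `tabulate_counts()` builds per-library
  count tables.
* **quantify** — the normalization chain, per library with on-diagonal
  counts `c_i`:

  `v_i = c_i / Σ_j c_j × 10⁶ × d_seq × d_lin × f_input`  (the
  processed-input fraction `f_input`, default 0.10, applies to the ChIP
  side only), and the final per-probe track `v_chip / v_input`, written as
  bedGraph.
* **qc** — mapping composition and off-diagonal shares (`run_qc()`),
  1-kb window averaging against qPCR amplicons (`window_average()`),
  Spearman correlation with optional zero exclusion (`spearman_cor()`),
  ChIP-seq read summation over probed intervals
  (`chipseq_overlap_score()`), titration linearity (`assess_linearity()`),
  and replicate R² (`replicate_correlation()`).

See the methods vignette
(`vignettes/quantifying-targeted-chip.Rmd`) for the models, parameter
choices and known limitations.

## Worked example

Design a panel over a (here: simulated) 4-kb region, sequence two barcoded
libraries — a peaked ChIP and a flat input — through the simulator, and
recover the enrichment track:

```r
library(chip2c)

genome <- simulate_genome(4000, gc = 0.5, seed = 3)
panel  <- tile_region(genome, list(chrom = "chrDemo", start = 0, end = 4000))
panel
#> 2C-ChIP primer panel: 68 probe pairs on chrDemo:0-3990
#>   forward tail: TAATTGGGAGTGATTTCCCT   reverse tail: ATCACCGACTGCCCATAGAGAGG (5'-phosphorylated reverses)
#>     probe_id   chrom junction f_start f_end r_start r_end strand ...
#> 1 probe_0001 chrDemo       22       0    22      22    44      + ...

barcodes  <- random_barcodes(2, seed = 5, library_label = c("chip", "input"))
reference <- product_reference(panel, barcodes)
reference
#> 2C-ChIP product reference
#>   panel: 68 probe pairs; barcodes: 2
#>   full products: 9248 (136 on-diagonal), min length 72 nt
#>   unpaired entries: 272, min length 42 nt

profile   <- simulate_profile(panel, n_peaks = 4, peak_height = 10,
                              peak_shape = "triangular", probe_log_sd = 0.4,
                              seed = 8)
chip_sim  <- simulate_library(reference, profile, "BC01", 5e4, seed = 11)
input_sim <- simulate_library(reference, simulate_profile(panel), "BC02",
                              5e4, seed = 12)

assignments <- two_step_assign(rbind(chip_sim$reads, input_sim$reads),
                               reference)
counts <- tabulate_counts(assignments, reference)
counts
#> 2C-ChIP count table: 100000 reads, 68 probes, 2 libraries
#>   library barcode_id product off_diagonal barcode_forward forward reverse ambiguous unmapped
#> 1    chip       BC01   47193         2525             266       0       0         0        0
#> 2   input       BC02   47183         2547             257       0       0         0        0
#> 3 residue       <NA>       0            0               0       0       0         0       29

chip_vals  <- normalize_counts(counts, library_factors("chip"))
input_vals <- normalize_counts(counts, library_factors("input", is_input = TRUE))
track <- chip_input_ratio(chip_vals, input_vals, panel)
head(track, 3)
#>     probe_id   chrom start end      value
#> 1 probe_0001 chrDemo     0  44 0.04426648
#> 2 probe_0002 chrDemo    58 109 0.03412811
#> 3 probe_0003 chrDemo   109 153 0.01545915
write_bedgraph(track, "demo.bedGraph", name = "chip/input")

run_qc(counts)
#> 2C-ChIP run QC (100000 reads)
#>   on-diagonal product fraction: 0.9438
#>   off-diagonal: 0.0507 of all reads, 0.9018 of unexpected reads

spearman_cor(profile$occupancy[match(track$probe_id, profile$probe_id)],
             track$value)
#> [1] 0.9881666
```

Each simulated library used the default operating-range rates
(substitution error 0.005, off-diagonal 0.05, truncation 0.005), so ~94 %
of reads map to designed products and ~90 % of the unexpected remainder are
off-diagonal ligations. Background probes sit near
`input_fraction × relative occupancy ≈ 0.02–0.05`; peak probes rise
~10-fold above them, and the recovered track rank-correlates with the
simulated truth at ρ ≈ 0.99.

A thin command-line wrapper with `design`, `build-ref`, `simulate`, `map`,
`quantify` and `qc` subcommands is installed at
`system.file("scripts", "chip2c.R", package = "chip2c")`.

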