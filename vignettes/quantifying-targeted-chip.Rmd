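---
title: "Quantifying targeted ChIP signal from ligation products: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying targeted ChIP signal from ligation products}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chip2c)
```

## The assay and what the package computes

Carbon copy-ChIP (2C-ChIP) measures chromatin-immunoprecipitation signal
over predefined genomic regions. Pairs of oligonucleotides — a forward and a
reverse primer — are annealed side by side on the same strand of the
immunoprecipitated DNA. A nick-sealing DNA ligase joins a pair only when the
two homologies sit exactly next to each other, without gap or overlap, so
each ligation event is a molecular "carbon copy" of one probed position.
Universal tails on the primers (a modified-T3 complement on the 5' end of
forwards, a P1-key complement on the 3' end of reverses, which must be
5'-phosphorylated for ligation) let all products be amplified with a single
PCR in which the forward amplification primer introduces a library barcode.
Because the instrument key is consumed before the insert, the barcode is the
first thing sequenced in every read.

The read population therefore decomposes into:

* **on-diagonal products** — barcode + forward tail + forward homology +
  reverse homology of the *same* designed pair; their counts carry the
  signal;
* **off-diagonal products** — ligations between a forward and a
  *non-adjacent* reverse primer; artifacts whose share is a useful library
  quality metric;
* **unpaired fragments** — barcode-forward stems, bare forward or bare
  reverse primer sequences that never received a partner.

The package implements panel design, the two expected-product reference
assemblies, a ground-truth read simulator, two-step read assignment with
demultiplexing, the input-normalization chain, and the QC statistics used to
validate runs.

## Panel design

`tile_region()` scans the target interval left to right. At each candidate
junction the forward homology grows leftward and the reverse homology
rightward from the minimum homology length (22 nt) to the maximum (34 nt);
the first combination in which both homologies pass all constraints is
accepted, and the scan advances by `target_spacing` (or to the first
non-overlapping position under `"max-density"`). The procedure involves no
randomness: a panel is a pure function of genome, interval, constraints and
spacing.

The constraint set mirrors standard oligo-design practice for this assay
class:

| parameter | default | unit | why |
|---|---|---|---|
| `min_homology_len` / `max_homology_len` | 22 / 34 | nt | annealing specificity vs. synthesis cost; 22 nt is also the word size of the unpaired mapping step |
| `min_gc` / `max_gc` | 0.40 / 0.60 | fraction | keeps melting behaviour of all probes in one annealing regime |
| `uniqueness_required` | `TRUE` | — | the homology must occur exactly once in the supplied genome (both strands, exact matches) so a count maps to one locus |
| `max_selfcomp_run` | 6 | nt | a homology containing a ≥6-mer whose reverse complement also occurs in it is prone to hairpins/self-dimers |

Uniqueness is decided by exact occurrence counting in the supplied genome
sequence rather than by an external alignment service, which keeps design
self-contained and exactly testable; likewise the self-complementarity rule
is a deliberately simple, configurable proxy for thermodynamic folding
calculators. Melting-temperature modelling is out of scope.

Coordinates are 0-based half-open everywhere internally and in BED/bedGraph
output. Homologies are stored in the orientation of the sequenced product;
the synthesized oligos anneal to the antisense strand, and
`assemble_full_primers()` / `write_primer_table()` emit the orderable
sequences with the phosphorylation flag on every reverse.

`reaction_molarity()` is a small protocol helper: 0.34 fmol of each primer
in a 10 µl annealing reaction is a 34 pM final concentration per primer.

## Reference assemblies

`product_reference()` enumerates the first assembly — every barcode ×
forward × reverse combination, labelled on- or off-diagonal — and the second
assembly of unpaired sequences (barcode-forward stems, bare forwards,
reverses). Off-diagonal combinations are enumerated explicitly so they are
first-class countable categories rather than a post-hoc residue. For a
panel of $p$ pairs and $b$ barcodes the full assembly holds $b p^2$
sequences; a 160-pair panel with one barcode gives 25,600, which is entirely
tractable, but a cap with on-diagonal-plus-sampled-off-diagonal enumeration
is available for pathological panels.

The reverse universal tail is *excluded* from product sequences by default:
reads are sequenced from the barcode end, assignment is decided before the
constant tail adds any discriminative power, and reads that run into the
tail simply have trailing bases ignored. A flag includes it for long-read
setups. Default barcode length is 8 nt with pairwise Hamming distance ≥ 2;
8 + 20 (forward tail) + 22 (minimal forward homology) = 50 nt is exactly the
smallest expected product prefix, matching the full-product word size below.

## Read assignment

Assignment follows the assay's two-step strategy. Step 1 matches each read
against the full-product assembly with a minimum aligned length of 50 nt
(the smallest expected product); a read is assigned if and only if exactly
one top-scoring product passes the gates. Everything else — ties included —
is re-matched in step 2 against the unpaired assembly with a minimum
aligned length of 22 nt (one forward homology). Remaining ties are
`ambiguous`, reads without any gated hit `unmapped`. Score ties are never
broken arbitrarily; this is what makes "uniquely mapped" well defined.
The barcode of an assignment is taken from the matched reference itself
(products and stems embed their barcodes), so demultiplexing
(`split_by_barcode()`) happens after mapping and tolerates barcode
sequencing errors up to the identity gate.

**Alignment contract.** The library is strictly directional and the error
model substitution-only, and every reference category begins at the same
structural position as the reads (the barcode, or the primer start). The
package therefore scores a read against a reference by *5'-anchored
ungapped overlap alignment*: matches are counted from position 0 over
`min(len(read), len(ref))` positions, identity is matches/aligned-length,
and a hit requires aligned length ≥ the word-size gate and identity ≥
`min_identity` (default 0.95, exposed in `match_params()`; the original
word sizes are preserved as the length gates). This replaces a
general-purpose local aligner with a contract that is exact for the data
the assay produces, is fast enough to assign $10^5$ reads against thousands
of products in seconds, and keeps the uniqueness semantics sharp. The test
suite contains an independent single-pass brute force over the union of
both assemblies (pure R, no shortcut) that must agree with the two-step
engine on every read of 200 randomized instances, plus a gapped
Smith–Waterman cross-check on noiseless instances, where the two contracts
provably coincide.

*Known limitation*: on degenerate reads carrying several substitutions
inside one 50-nt window, a gapped local aligner can trim the errored
segment and rescue a partial hit (for instance an internal
reverse-homology match) where the anchored contract reports `unmapped`.
At the assay's operating error rates this concerns a fraction of order
$10^{-3}$ of reads and only moves them between artifact categories, not
into probe signal. Indels are not modelled; reads from platforms with
appreciable indel rates would need a different engine behind the same
gates.

## Simulator

The simulator exists so that every downstream stage can be tested against
exact ground truth at desk scale.

* `simulate_genome()` draws i.i.d. bases at a requested GC content.
* `simulate_profile()` lays a piecewise occupancy over the probes:
  `background` everywhere and `n_peaks` contiguous runs elevated to
  `peak_height` — rectangular by default, or `"triangular"` for graded
  summits. `probe_log_sd` multiplies each probe by a lognormal factor to
  emulate the continuous occupancy and probe-efficiency heterogeneity of
  real ChIP material. An input library is the flat `n_peaks = 0` case.
* `simulate_library()` draws each read as: on-diagonal product of probe $i$
  with probability $1 - r_\mathrm{off} - r_\mathrm{trunc}$, where $i$ is
  multinomial with weights proportional to the profile; a uniformly random
  off-diagonal product with probability $r_\mathrm{off}$ (ligation
  artifacts are primer-driven, hence independent of the template profile);
  an unpaired barcode-forward fragment with probability
  $r_\mathrm{trunc}$. Substitutions are applied per base at `error_rate`;
  qualities are a constant placeholder; reads start at the barcode and are
  full product length. Per-read ground truth is recorded and is exact by
  construction.

Default rates (`error_rate = 0.005`, `off_diagonal_rate = 0.05`,
`truncation_rate = 0.005`) describe a library in the assay's optimal
operating range: they reproduce the reported composition in which roughly
nine in ten unexpected reads are off-diagonal ligations. What the simulator
deliberately does **not** model: PCR jackpotting (amplification is absorbed
into `n_reads`, since the pipeline measures relative abundance), indels and
homopolymer errors, duplicate reads, and paired-end chemistry. Size
selection appears only as an optional length filter. Passing tests on
simulated data therefore demonstrate correctness of the computational
chain, not robustness to every wet-lab failure mode.

`simulate_titration()` is an explicitly phenomenological stand-in for the
template-mass titration: yield is proportional to the template amount
clamped to `[floor_break, sat_break]` (defaults 0.16 and 1.6 ng — below the
floor a template-independent background dominates, above saturation the
primers are limiting), and the off-diagonal rate rises as
$\min(0.5,\; r_0 \sqrt{\mathrm{sat}/\min(a, \mathrm{sat})})$ as template
gets scarce. No chemistry is claimed for these functional forms; they exist
so that `assess_linearity()` has a known breakpoint to recover.

## Normalization

For one library, with $c_i$ the on-diagonal count of probe $i$:

$$v_i \;=\; \frac{c_i}{\sum_j c_j} \times 10^6 \times d_\mathrm{seq}
  \times d_\mathrm{lin} \times \begin{cases} f_\mathrm{input} & \text{ChIP
  library} \\ 1 & \text{input library} \end{cases}$$

and the final track is $v^\mathrm{ChIP}_i / v^\mathrm{input}_i$ per probe.
All steps are multiplicative, so their order is immaterial. Choices made
where the procedure leaves room:

* **Per-million base.** Read-count normalization divides by mapped
  on-diagonal product reads, not total reads (`norm_base = "product"`,
  switchable to `"total"`): off-diagonal and unpaired reads are artifacts,
  and per-million over signal reads is what makes libraries of different
  quality comparable.
* **Direction of the 10 % adjustment.** Only a fraction (default 10 %) of
  the input chromatin is processed; the ChIP side is *multiplied* by
  `input_fraction`. Any global scale choice cancels when tracks are
  compared with each other; the factor and its side are explicit in
  `library_factors()` and recorded in the track provenance.
* **Zero-input probes.** A probe with zero input signal has no defined
  ratio: it is dropped from the track and listed in the `dropped_probes`
  attribute, mirroring the convention of excluding zeros from downstream
  correlations. An optional pseudocount exists but is off by default.
* **Serialization.** bedGraph values are written with 6 significant
  digits; the round-trip contract of `read_bedgraph()` is exact equality
  to that formatting (relative error ≤ 1e-5).

Two invariants pin the algebra down and are enforced per release: scaling
all raw counts of both libraries by any $c > 0$ leaves every ratio
unchanged to 1e-9, and ratios are linear in the ChIP sequencing dilution
and inverse in the input one.

## QC statistics

* `run_qc()` reports composition fractions; the off-diagonal share is given
  both over all reads and over "unexpected" reads (everything that is not
  an on-diagonal product), the latter being the headline artifact metric.
* `window_average()` compares probe tracks with amplicon measurements: the
  unweighted mean of probes whose interval *midpoint* falls in a 1-kb
  half-open window centred on the amplicon. Midpoint membership is the
  documented default because edge behaviour is otherwise ill-defined for
  probes straddling the window boundary; an any-overlap rule is available.
* `spearman_cor()` uses average ranks for ties; zero exclusion is opt-in
  (the convention when comparing against qPCR or sequencing coverage,
  where zero means "no signal", not a rank) and reports how many pairs it
  dropped.
* `chipseq_overlap_score()` counts reads overlapping each probed interval
  under half-open semantics (abutting intervals do not overlap), via
  `GenomicRanges`; a containment rule is available because "reads spanning
  the probed sequence" is ambiguous between the two readings.
* `assess_linearity()` fits $\log y \sim \log a$ on every contiguous
  sub-series of ≥ 3 titration points and returns the widest window with
  $r^2 \ge 0.98$ and slope in $[0.8, 1.2]$. The gates are package defaults
  — the assay's published linear range is stated without an explicit
  criterion — and are exposed as arguments. Ties on window width go to the
  wider log-range, then leftmost. Degenerate windows (constant yield) are
  skipped rather than fitted.
* `replicate_correlation()` is the squared Pearson correlation over shared
  probes.

## Problem sizes and determinism

The shipped tests run entirely on synthetic data: panels of 2–160 pairs
over genomes of 2.5–14 kb, libraries of 40 to $10^5$ reads, 200 randomized
small instances for the oracle-equivalence battery, and 1000 randomized
tables for the normalization invariants. These sizes give every binomial
tolerance in the suite a comfortable margin while keeping the whole run in
a few minutes. All stochastic steps take explicit seeds
(`withr::with_seed` underneath), so every simulated dataset in the tests
and the acceptance script is reproducible bit for bit; panel design is
deterministic without any seed.

The noisy-recovery check uses the triangular, lognormal-heterogeneous
profile rather than the rectangular default. That is deliberate: with a
two-level profile most probes are exactly tied in truth, and a rank
correlation against noisy recovered values is then bounded far below 1 for
purely combinatorial reasons; continuous occupancy is both the realistic
case and the one in which "rank agreement ≥ 0.99" is a meaningful
statement about recovery.

## Limitations

Beyond the simulator's stated scope: no SAM/BAM emission (the expected
product space is tiny and bespoke, so assignments are tabular), no
base-quality-aware alignment, no indel-tolerant barcode correction beyond
the identity gate, no peak calling, no spike-in or inter-antibody
calibration, and no attempt to regenerate the original published primer
panel primer-for-primer — the tiling rule is specified here, but the
published panel's exact junction placement was not.
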