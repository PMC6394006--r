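make_ref_small <- function(n_pairs = 5, n_bc = 2, seed = 351) {
  fx <- fixture_panel(n_pairs = n_pairs, seed = seed)
  bcs <- fixture_barcodes(n_bc)
  list(panel = fx$panel, bcs = bcs, ref = product_reference(fx$panel, bcs))
}

test_that("match_read gates on aligned length and identity", {
  s <- make_ref_small()
  refs <- setNames(s$ref$full$sequence, s$ref$full$product_id)
  r1 <- s$ref$full$sequence[1]
  hits <- match_read(c(read1 = r1), refs, min_match = 50)
  expect_identical(hits$ref_id[1], s$ref$full$product_id[1])
  expect_equal(hits$identity[1], 1)
  expect_equal(hits$score[1], nchar(r1))
  # a read shorter than min_match yields no hit
  expect_equal(nrow(match_read(c(r = substr(r1, 1, 40)), refs, min_match = 50)), 0)
  # equidistant read: one mismatch against each of two references
  a <- paste0(strrep("AC", 30), "TT")
  b <- paste0(strrep("AC", 30), "GG")
  q <- paste0(strrep("AC", 30), "TG")
  h <- match_read(c(q = q), c(A = a, B = b), min_match = 50, min_identity = 0.9)
  expect_setequal(h$ref_id, c("A", "B"))
  expect_equal(h$score[1], h$score[2])
})

test_that("noiseless simulated runs are assigned perfectly", {
  s <- make_ref_small()
  prof <- simulate_profile(s$panel, n_peaks = 1, peak_height = 5, seed = 1)
  sim <- simulate_library(s$ref, prof, "BC01", 400, error_rate = 0,
                          off_diagonal_rate = 0.1, truncation_rate = 0.05,
                          seed = 21)
  asg <- two_step_assign(sim$reads, s$ref)
  expect_identical(
    unname(c(product = "product", off_diagonal = "product",
             barcode_forward = "barcode-forward")[sim$reads$true_category]),
    asg$outcome)
  # product ids and barcodes recovered exactly
  isp <- asg$outcome == "product"
  expect_identical(asg$product_id[isp], sim$reads$true_id[isp])
  expect_true(all(asg$barcode_id == "BC01"))
})

test_that("structural read fragments land in the right unpaired category", {
  s <- make_ref_small()
  ft <- attr(s$panel, "forward_tail")
  stem <- paste0(s$bcs$sequence[1], ft, s$panel$forward_homology[1])
  asg <- two_step_assign(c(r1 = stem), s$ref)
  expect_identical(asg$outcome, "barcode-forward")
  expect_identical(asg$barcode_id, "BC01")
  # bare forward (no barcode) and bare reverse (+tail) fragments
  fwd <- paste0(ft, s$panel$forward_homology[2])
  rev <- paste0(s$panel$reverse_homology[3], attr(s$panel, "reverse_tail"))
  asg2 <- two_step_assign(c(f = fwd, r = rev), s$ref)
  expect_identical(asg2$outcome, c("forward", "reverse"))
  expect_true(all(is.na(asg2$barcode_id)))
  # junk read -> unmapped
  junk <- strrep("ACGGT", 12)
  expect_identical(two_step_assign(c(j = junk), s$ref)$outcome, "unmapped")
})

test_that("two probes sharing a forward homology make stem-only reads ambiguous", {
  h <- random_homology(1, len = 26, seed = 61)
  panel <- manual_panel(c(h, h), random_homology(2, len = 26, seed = 62))
  bcs <- fixture_barcodes(1)
  ref <- suppressWarnings(product_reference(panel, bcs))
  stem_read <- paste0(bcs$sequence[1], attr(panel, "forward_tail"), h)
  asg <- two_step_assign(c(r = stem_read), ref)
  expect_identical(asg$outcome, "ambiguous")
})

test_that("raising min_identity never increases product assignments", {
  s <- make_ref_small()
  prof <- simulate_profile(s$panel, n_peaks = 1, peak_height = 5, seed = 1)
  sim <- simulate_library(s$ref, prof, "BC02", 600, error_rate = 0.03,
                          off_diagonal_rate = 0.05, truncation_rate = 0.02,
                          seed = 31)
  n_assigned <- vapply(c(0.8, 0.9, 0.95, 0.99, 1), function(mi) {
    asg <- two_step_assign(sim$reads, s$ref, match_params(min_identity = mi))
    sum(asg$outcome == "product")
  }, numeric(1))
  expect_true(all(diff(n_assigned) <= 0))
})

test_that("split_by_barcode partitions assignments with a residue pool", {
  s <- make_ref_small(n_bc = 2)
  prof <- simulate_profile(s$panel)
  r1 <- simulate_library(s$ref, prof, "BC01", 150, error_rate = 0,
                         off_diagonal_rate = 0, truncation_rate = 0, seed = 41)
  r2 <- simulate_library(s$ref, prof, "BC02", 250, error_rate = 0,
                         off_diagonal_rate = 0, truncation_rate = 0, seed = 42)
  reads <- rbind(r1$reads, r2$reads)
  reads$read_id <- sprintf("r%04d", seq_len(nrow(reads)))
  rev_read <- paste0(s$panel$reverse_homology[1], attr(s$panel, "reverse_tail"))
  reads <- rbind(reads[, c("read_id", "sequence")],
                 data.frame(read_id = "rev1", sequence = rev_read))
  parts <- split_by_barcode(two_step_assign(reads, s$ref), s$bcs)
  expect_equal(nrow(parts$BC01), 150)
  expect_equal(nrow(parts$BC02), 250)
  expect_identical(parts$residue$outcome, "reverse")
  empty <- split_by_barcode(two_step_assign(character(0), s$ref), s$bcs)
  expect_equal(nrow(empty$residue), 0)
})

test_that("tabulate_counts conserves totals across categories", {
  s <- make_ref_small()
  prof <- simulate_profile(s$panel, n_peaks = 2, peak_height = 4, seed = 3)
  sim <- simulate_library(s$ref, prof, "BC01", 1200, error_rate = 0.02,
                          off_diagonal_rate = 0.08, truncation_rate = 0.04,
                          seed = 51)
  asg <- two_step_assign(sim$reads, s$ref)
  ct <- tabulate_counts(asg, s$ref)
  cat_cols <- c("product", "off_diagonal", "barcode_forward", "forward",
                "reverse", "ambiguous", "unmapped")
  expect_equal(sum(unlist(ct$categories[, cat_cols])), ct$total_reads)
  expect_equal(ct$total_reads, 1200)
  expect_equal(sum(ct$probe_counts$count), sum(ct$categories$product))
})

test_that("tabulate_counts reproduces hand-computed tallies", {
  s <- make_ref_small(n_pairs = 3, n_bc = 1)
  ond <- s$ref$full[s$ref$full$on_diagonal, ]
  offd <- s$ref$full[!s$ref$full$on_diagonal, ]
  asg <- structure(data.frame(
    read_id = sprintf("r%d", 1:4),
    outcome = c("product", "product", "product", "product"),
    product_id = c(rep(ond$product_id[1], 3), offd$product_id[1]),
    barcode_id = "BC01",
    probe_id = c(rep(ond$forward_probe_id[1], 3), NA),
    on_diagonal = c(TRUE, TRUE, TRUE, FALSE),
    score = 70, stringsAsFactors = FALSE),
    class = c("read_assignment", "data.frame"))
  ct <- tabulate_counts(asg, s$ref)
  expect_equal(ct$total_reads, 4)
  expect_equal(ct$probe_counts$count[ct$probe_counts$probe_id ==
                                       ond$forward_probe_id[1]], 3)
  expect_equal(sum(ct$categories$off_diagonal), 1)
  # noiseless simulation: count table equals simulation truth exactly
  prof <- simulate_profile(s$panel, n_peaks = 1, peak_height = 7, seed = 9)
  sim <- simulate_library(s$ref, prof, "BC01", 300, error_rate = 0,
                          off_diagonal_rate = 0, truncation_rate = 0, seed = 10)
  ct2 <- tabulate_counts(two_step_assign(sim$reads, s$ref), s$ref)
  truth_by_probe <- table(sim$reads$true_probe_id)
  got <- setNames(ct2$probe_counts$count, ct2$probe_counts$probe_id)
  expect_equal(got[names(truth_by_probe)],
               setNames(as.integer(truth_by_probe), names(truth_by_probe)))
  # empty input -> all-zero table
  ct0 <- tabulate_counts(two_step_assign(character(0), s$ref), s$ref)
  expect_equal(ct0$total_reads, 0)
  expect_true(all(ct0$probe_counts$count == 0))
})

test_that("two-step assignment equals single-pass union-reference oracles", {
  # a taste of the full oracle-equivalence battery (see acceptance tests):
  # the two-step shortcut must not change any outcome relative to a
  # single-pass brute force over the union of both assemblies
  set.seed(71)
  for (k in 1:5) {
    s <- make_ref_small(n_pairs = sample(2:4, 1), n_bc = sample(1:2, 1),
                        seed = 400 + k)
    prof <- simulate_profile(s$panel, n_peaks = 1,
                             peak_height = 5, seed = 500 + k)
    err <- sample(c(0, 0.005, 0.02), 1)
    sim <- simulate_library(s$ref, prof, s$bcs$barcode_id[1], 40,
                            error_rate = err,
                            off_diagonal_rate = 0.1, truncation_rate = 0.1,
                            seed = 600 + k)
    mine <- two_step_assign(sim$reads, s$ref)
    orac <- oracle_assign_anchored(sim$reads, s$ref)
    expect_identical(mine$outcome, orac$outcome)
    expect_identical(mine$product_id, orac$product_id)
    if (err == 0) {
      # on noiseless reads the gapped-DP contract coincides as well
      dp <- oracle_assign_dp(sim$reads, s$ref)
      expect_identical(mine$outcome, dp$outcome)
      expect_identical(mine$product_id, dp$product_id)
    }
  }
})
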