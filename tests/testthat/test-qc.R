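fab_table <- function(product = 0, off_diagonal = 0, barcode_forward = 0,
                      forward = 0, reverse = 0, ambiguous = 0, unmapped = 0) {
  cats <- data.frame(library = c("lib1", "residue"),
                     barcode_id = c("BC01", NA),
                     product = c(product, 0),
                     off_diagonal = c(off_diagonal, 0),
                     barcode_forward = c(barcode_forward, 0),
                     forward = c(0, forward), reverse = c(0, reverse),
                     ambiguous = c(0, ambiguous), unmapped = c(0, unmapped),
                     stringsAsFactors = FALSE)
  structure(list(
    probe_counts = data.frame(library = "lib1", barcode_id = "BC01",
                              probe_id = "p1", count = product,
                              stringsAsFactors = FALSE),
    categories = cats,
    total_reads = product + off_diagonal + barcode_forward + forward +
      reverse + ambiguous + unmapped),
    class = "count_table")
}

test_that("run_qc computes composition fractions", {
  all_prod <- run_qc(fab_table(product = 50))
  expect_equal(all_prod$mapped_product_fraction, 1)
  expect_equal(all_prod$off_diagonal_fraction_overall, 0)
  expect_equal(all_prod$off_diagonal_fraction_of_unexpected, 0)
  x <- run_qc(fab_table(product = 90, off_diagonal = 9, unmapped = 1))
  expect_equal(x$off_diagonal_fraction_of_unexpected, 0.9)
  expect_equal(x$off_diagonal_fraction_overall, 0.09)
  expect_equal(x$mapped_product_fraction, 0.9)
  expect_lte(sum(x$library_shares), 1)
})

test_that("run_qc recovers the simulated off-diagonal rate", {
  fx <- fixture_panel(n_pairs = 5, seed = 361)
  bcs <- fixture_barcodes(1)
  ref <- product_reference(fx$panel, bcs)
  n <- 10000; r <- 0.06
  sim <- simulate_library(ref, simulate_profile(fx$panel), "BC01", n,
                          error_rate = 0, off_diagonal_rate = r,
                          truncation_rate = 0, seed = 17)
  qc <- run_qc(tabulate_counts(two_step_assign(sim$reads, ref), ref))
  expect_lt(abs(qc$off_diagonal_fraction_overall - r),
            3 * sqrt(r * (1 - r) / n))
})

test_that("window_average uses midpoints in a half-open window", {
  tr <- data.frame(chrom = "c", start = c(0, 100, 200), end = c(60, 160, 260),
                   value = c(1, 3, 10))
  expect_equal(window_average(tr, center = 80, width = 120), 2)  # mids 30, 130
  expect_equal(window_average(tr, center = 30, width = 10), 1)
  expect_true(is.na(window_average(tr, center = 1000, width = 100)))
  # half-open right edge: midpoint 130 excluded when window is [30, 130)
  expect_equal(window_average(tr, center = 80, width = 100), 1)
  expect_equal(window_average(tr, center = 81, width = 102), 2)
  # any-overlap rule pulls in probes the midpoint rule excludes
  expect_equal(window_average(tr, center = 95, width = 20, rule = "overlap"), 3)
})

test_that("spearman_cor matches the rank formula and honours zero exclusion", {
  expect_equal(spearman_cor(1:10, (1:10)^3), 1)
  expect_equal(spearman_cor(1:10, -(1:10)), -1)
  # tie handling equals a hand-evaluated average-rank correlation
  x <- c(1, 2, 2, 3); y <- c(1, 2, 3, 4)
  avg_rank <- function(v) {
    vapply(v, function(vi) mean(which(sort(v) == vi)), numeric(1))
  }
  oracle <- stats::cor(avg_rank(x), avg_rank(y))
  expect_equal(spearman_cor(x, y), oracle)
  # invariance under strictly monotone transforms
  set.seed(101)
  a <- stats::runif(30); b <- stats::runif(30)
  expect_equal(spearman_cor(exp(a), log(b + 1)), spearman_cor(a, b))
  # zero exclusion
  x0 <- c(0, 5, 1, 2, 3); y0 <- c(9, 0, 1, 2, 3)
  expect_message(rho <- spearman_cor(x0, y0, drop_zeros = TRUE), "dropped")
  expect_equal(rho, 1)
  expect_error(suppressMessages(spearman_cor(c(0, 0, 1, 2), c(1, 2, 3, 4),
                                             drop_zeros = TRUE)), "fewer than 3")
})

test_that("chipseq_overlap_score counts half-open overlaps like the quadratic oracle", {
  probes <- data.frame(probe_id = c("p1", "p2"), chrom = "c",
                       start = c(100, 300), end = c(160, 360))
  reads <- data.frame(chrom = "c", start = c(100, 160, 90, 359), end = c(160, 220, 101, 420))
  sc <- chipseq_overlap_score(probes, reads)
  # read 2 abuts p1 end (half-open: no overlap); reads 1,3 overlap p1; read 4 overlaps p2
  expect_equal(sc$reads, c(2, 1))
  # random instance vs brute-force all-pairs count
  set.seed(111)
  pr <- data.frame(probe_id = sprintf("p%02d", 1:20), chrom = "c",
                   start = seq(0, by = 50, length.out = 20))
  pr$end <- pr$start + 40
  rd <- data.frame(chrom = "c", start = sample(0:1000, 100, replace = TRUE))
  rd$end <- rd$start + sample(10:80, 100, replace = TRUE)
  brute <- vapply(seq_len(nrow(pr)), function(i) {
    sum(rd$start < pr$end[i] & rd$end > pr$start[i])
  }, numeric(1))
  expect_equal(chipseq_overlap_score(pr, rd)$reads, as.integer(brute))
  # containment is stricter than overlap
  within <- chipseq_overlap_score(pr, rd, rule = "containment")$reads
  expect_true(all(within <= chipseq_overlap_score(pr, rd)$reads))
})

test_that("assess_linearity recovers exact power laws and saturation", {
  amounts <- c(0.05, 0.16, 0.5, 1.6, 5)
  exact <- data.frame(amount_ng = amounts, yield = 80 * amounts)
  fit <- assess_linearity(exact)
  expect_true(fit$qualified)
  expect_equal(c(fit$lo, fit$hi), c(0.05, 5))
  expect_equal(fit$slope, 1, tolerance = 1e-10)
  expect_equal(fit$r2, 1, tolerance = 1e-10)
  # saturation: constant yield above the breakpoint is excluded by the slope gate
  sat <- data.frame(amount_ng = amounts, yield = 80 * pmin(amounts, 1.6))
  fit2 <- assess_linearity(sat)
  expect_true(fit2$qualified)
  expect_equal(fit2$hi, 1.6)
  expect_equal(fit2$lo, 0.05)
  # nothing linear at all
  flat <- data.frame(amount_ng = amounts, yield = rep(7, 5))
  expect_false(assess_linearity(flat)$qualified)
})

test_that("replicate_correlation is scale-invariant and near zero under the null", {
  tr <- function(v) {
    data.frame(probe_id = sprintf("p%03d", seq_along(v)), chrom = "c",
               start = seq_along(v) * 100, end = seq_along(v) * 100 + 50,
               value = v)
  }
  set.seed(121)
  v <- stats::rlnorm(50)
  expect_equal(replicate_correlation(tr(v), tr(v)), 1)
  expect_equal(replicate_correlation(tr(v), tr(2 * v)), 1)
  a <- stats::rnorm(200); b <- stats::rnorm(200)
  expect_lt(replicate_correlation(tr(a), tr(b)), 0.05)
  expect_error(replicate_correlation(tr(v[1:2]), tr(v[1:2])), "fewer than 3")
})
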