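seg_fixture <- function(values) {
  # values: named list of sample -> per-segment vector
  n <- length(values[[1]])
  layout <- toy_layout(n_bins = 40 * n)
  out <- layout_segments(layout)[, c("segment", "chrom", "start", "end")]
  for (nm in names(values)) out[[nm]] <- values[[nm]]
  out
}

test_that("between-group distance and within-group null pool", {
  seg <- seg_fixture(list(a1 = c(0.5, 1), a2 = c(0.7, 1),
                          b1 = c(-0.2, 1), b2 = c(-0.4, 1)))
  raw <- segment_distances(seg, c("a1", "a2"), c("b1", "b2"), scale_null = FALSE)
  # |mean(A) - mean(B)| = |0.6 - (-0.3)|
  expect_equal(raw$stats$d[1], 0.9)
  expect_equal(raw$stats$delta[1], -0.9) # mutant minus control
  # identical groups give zero distance
  expect_equal(raw$stats$d[2], 0)
  # within pair (0.5, 0.7) contributes 0.2 to the raw pool
  expect_true(any(abs(raw$null_pool - 0.2) < 1e-12))
  expect_length(raw$null_pool, 4) # one pair per group per segment

  # calibrated pool: scaled by sqrt((1/2 + 1/2)/2) to variance-match the
  # between-group mean difference
  cal <- segment_distances(seg, c("a1", "a2"), c("b1", "b2"))
  expect_equal(sort(cal$null_pool), sort(raw$null_pool) * sqrt(0.5))

  # masked segments are excluded from stats and pool
  seg$a1[2] <- NA
  m <- segment_distances(seg, c("a1", "a2"), c("b1", "b2"))
  expect_true(is.na(m$stats$d[2]))
  expect_length(m$null_pool, 2)

  expect_error(segment_distances(seg, "a1", "b1"), "no within-group")
})

test_that("empirical p-values follow the add-one rule", {
  withr::with_seed(1, null <- stats::runif(999))
  expect_equal(empirical_pvalues(2, null), 1 / 1000)
  expect_equal(empirical_pvalues(0, null), 1)
  # matches a brute-force count on arbitrary data, including ties
  withr::with_seed(2, {
    d <- sample(c(stats::runif(50), null[1:10]))
    brute <- vapply(d, function(x) (1 + sum(null >= x)) / 1000, 0)
  })
  expect_equal(empirical_pvalues(d, null), brute)
  expect_true(is.na(empirical_pvalues(c(0.5, NA), null)[2]))
  expect_error(empirical_pvalues(1, numeric()), "empty")
})

test_that("q-values match the step-up oracle and stay ordered", {
  expect_equal(storey_qvalues(rep(1, 5)), rep(1, 5))
  # worked example with pi0 = 1: all q equal max step
  expect_equal(storey_qvalues(c(0.01, 0.02, 0.03, 0.04), pi0_method = "bh"),
               rep(0.04, 4))
  # independent Benjamini-Hochberg oracle on random p-values
  withr::with_seed(3, p <- stats::runif(500)^1.5)
  expect_equal(storey_qvalues(p, pi0_method = "bh"),
               stats::p.adjust(p, method = "BH"), tolerance = 1e-12)
  # invariant to input order
  o <- sample(length(p))
  expect_equal(storey_qvalues(p, pi0_method = "bh")[o],
               storey_qvalues(p[o], pi0_method = "bh"))
  # monotone in p
  q <- storey_qvalues(p)
  expect_true(all(diff(q[order(p)]) >= -1e-12))
  # fixed-lambda pi0 shrinks q when signal is present
  expect_true(all(storey_qvalues(p) <= stats::p.adjust(p, "BH") + 1e-12))
  expect_error(storey_qvalues(c(0.5, 0)), "must lie in")
  expect_error(storey_qvalues(1.2), "must lie in")
})

test_that("switch classification applies the sign and significance rules", {
  base <- tibble::tibble(ctrl_mean = 0.5, mut_mean = -0.4, delta = -0.9, q = 0.005)
  expect_equal(call_switches(base)$class, "EtoL")
  base$q <- 0.2
  expect_equal(call_switches(base)$class, "EtoE") # not significant
  ltoe <- tibble::tibble(ctrl_mean = -0.6, mut_mean = 0.3, delta = 0.9, q = 0.004)
  expect_equal(call_switches(ltoe)$class, "LtoE")
  # significant early-to-earlier keeps its endpoint class
  up <- tibble::tibble(ctrl_mean = 0.5, mut_mean = 1.5, delta = 1, q = 0.001)
  cc <- call_switches(up)
  expect_equal(cc$class, "EtoE")
  expect_true(cc$significant)
  masked <- tibble::tibble(ctrl_mean = NA, mut_mean = NA, delta = NA, q = NA)
  expect_equal(call_switches(masked)$class, "masked")
})

test_that("adjacent same-class segments merge into domains", {
  calls <- tibble::tibble(
    chrom = "chr1",
    start = seq(0, by = 2e5, length.out = 5),
    end = seq(2e5, by = 2e5, length.out = 5),
    class = c("EtoL", "EtoL", "EtoL", "EtoE", "EtoL"),
    significant = c(TRUE, TRUE, TRUE, FALSE, TRUE),
    q = c(0.004, 0.002, 0.009, 0.5, 0.01)
  )
  dom <- merge_to_domains(calls)
  expect_equal(nrow(dom), 3)
  expect_equal(dom$end[1] - dom$start[1], 6e5) # 3 x 200 kb merged
  expect_equal(dom$q[1], 0.002)
  expect_equal(dom$n_segments, c(3L, 1L, 1L))

  # a genomic gap splits a run
  gap <- calls[c(1, 3), ]
  expect_equal(nrow(merge_to_domains(gap)), 2)
  # empty input gives an empty table
  expect_equal(nrow(merge_to_domains(calls[0, ])), 0)
})

test_that("overlap test equals the exact hypergeometric tail", {
  res <- overlap_test(1:10, 6:15, universe_size = 100)
  expect_equal(res$overlap, 5)
  expect_equal(res$expected, 1)
  # enumeration oracle: P(X >= 5), X ~ Hypergeom(10 of 100, draw 10)
  k <- 5:10
  oracle <- sum(choose(10, k) * choose(90, 10 - k)) / choose(100, 10)
  expect_equal(res$p_value, oracle, tolerance = 1e-12)
  # A = universe: overlap is |B| with certainty
  all_a <- overlap_test(1:30, 3:7, universe_size = 30)
  expect_equal(all_a$overlap, 5)
  expect_equal(all_a$p_value, 1)
  # no overlap of small sets in a large universe is unremarkable
  expect_equal(overlap_test(1:3, 101:103, universe_size = 1e4)$p_value, 1,
               tolerance = 1e-6)
  expect_error(overlap_test(1:10, 1:2, universe_size = 5), "exceed")
})

test_that("rt_switch_test wires the stages together deterministically", {
  layout <- genome_layout(c(chr1 = 100e6))
  truth <- simulate_rt_landscape(layout, seed = 31)
  planted <- plant_switches(truth, n_switch = 25, seed = 32)
  counts <- dplyr::bind_rows(
    simulate_counts(truth, sample_prefix = "wt", seed = 33),
    simulate_counts(planted$truth, sample_prefix = "tko", seed = 34)
  )
  seg <- segment_rt(counts, layout)
  fit <- rt_switch_test(seg, c("wt_rep1", "wt_rep2"), c("tko_rep1", "tko_rep2"))
  calls <- tidy(fit)
  expect_s3_class(calls, "tbl_df")
  expect_true(all(c("d", "p", "q", "class", "significant") %in% names(calls)))
  # q-values do not depend on segment order
  o <- sample(nrow(seg))
  fit2 <- rt_switch_test(seg[o, ], c("wt_rep1", "wt_rep2"),
                         c("tko_rep1", "tko_rep2"))
  expect_equal(tidy(fit2)$q, calls$q[o])
  # class invariants from the sign rules
  expect_true(all(calls$delta[calls$class == "EtoL"] < 0))
  expect_true(all(calls$delta[calls$class == "LtoE"] > 0))
  g <- glance(fit)
  expect_equal(g$n_segments, nrow(seg))
  expect_equal(g$n_etol + g$n_ltoe + g$n_etoe + g$n_ltol + g$n_masked,
               g$n_segments)
})
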