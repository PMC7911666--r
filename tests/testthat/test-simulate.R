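test_that("generators are deterministic under a fixed seed", {
  layout <- genome_layout(c(chr1 = 10e6))
  t1 <- simulate_rt_landscape(layout, mean_domain_kb = 1000, seed = 7)
  t2 <- simulate_rt_landscape(layout, mean_domain_kb = 1000, seed = 7)
  expect_identical(t1$bins$rt, t2$bins$rt)
  c1 <- simulate_counts(t1, seed = 3)
  c2 <- simulate_counts(t1, seed = 3)
  expect_identical(c1$count, c2$count)
  expect_false(identical(simulate_counts(t1, seed = 4)$count, c1$count))
  f1 <- simulate_fibers(n_molecules = 5, seed = 9)
  f2 <- simulate_fibers(n_molecules = 5, seed = 9)
  expect_identical(f1$fibers, f2$fibers)
})

test_that("landscape levels and boundary process behave as specified", {
  layout <- genome_layout(c(chr1 = 10e6))
  # degenerate mixture: a single level with zero spread gives a flat landscape
  flat <- simulate_rt_landscape(layout, rt_levels = 2, rt_sd = 0, seed = 1)
  expect_true(all(flat$bins$rt == 2))
  expect_error(simulate_rt_landscape(layout, mean_domain_kb = 300),
               "too small")

  # Poisson boundary count: mean 1000 kb over 100 Mb gives 100 expected
  big <- genome_layout(c(chr1 = 100e6))
  n_bounds <- vapply(1:200, function(s) {
    nrow(simulate_rt_landscape(big, mean_domain_kb = 1000, seed = s)$domains) - 1
  }, 0)
  se <- sqrt(100 / 200) # var of a Poisson(100) mean over 200 draws
  expect_lt(abs(mean(n_bounds) - 100), 3 * se)
})

test_that("planted switches edit exactly the recorded segments", {
  layout <- genome_layout(c(chr1 = 100e6))
  truth <- simulate_rt_landscape(layout, seed = 11)
  planted <- plant_switches(truth, n_switch = 50, delta_magnitude = 1.5, seed = 12)
  expect_equal(nrow(planted$switches), 50)

  # the switch table is exactly recoverable by diffing the two truths
  diff <- planted$truth$bins$rt - truth$bins$rt
  bins <- add_segment_index(truth$bins, layout)
  touched <- sort(unique(bins$segment[abs(diff) > 1e-12]))
  expect_equal(touched, sort(planted$switches$segment))
  for (i in seq_len(nrow(planted$switches))) {
    inside <- bins$segment == planted$switches$segment[i]
    expect_true(all(abs(diff[inside] - planted$switches$delta[i]) < 1e-12))
  }
  expect_true(all(diff[!bins$segment %in% planted$switches$segment] == 0))
  # direction is consistent with the sign convention
  expect_true(all((planted$switches$direction == "EtoL") ==
                    (planted$switches$delta < 0)))

  # zero-magnitude edit is the identity
  null_edit <- plant_switches(truth, n_switch = 10, delta_magnitude = 0, seed = 1)
  expect_identical(null_edit$truth$bins$rt, truth$bins$rt)
  expect_error(plant_switches(truth, n_switch = 1e6), "exceeds eligible")
})

test_that("count model converges to the timing truth at high depth", {
  layout <- toy_layout(n_bins = 100)
  # symmetric rt so early and late totals balance exactly
  truth <- toy_truth(layout, rep(c(2, -2), each = 50))
  counts <- simulate_counts(truth, depth_per_fraction = 1e4,
                            replicate_noise_sd = 0, n_replicates = 1, seed = 5)
  early <- counts$count[counts$fraction == "early"]
  late <- counts$count[counts$fraction == "late"]
  est <- log2((early / sum(early)) / (late / sum(late)))
  expect_lt(max(abs(est - truth$bins$rt)), 0.1)

  # logit link closed form: rt = 2 gives p = 4/5, i.e. a 4:1 early:late rate
  # ratio once library sizes are equalized
  two_bin <- toy_truth(toy_layout(n_bins = 2), c(2, -2))
  cc <- simulate_counts(two_bin, depth_per_fraction = 5e5,
                        replicate_noise_sd = 0, n_replicates = 1, seed = 6)
  e <- cc$count[cc$fraction == "early"]
  l <- cc$count[cc$fraction == "late"]
  ratio <- (e[1] / sum(e)) / (l[1] / sum(l))
  expect_lt(abs(ratio - 4), 0.05)
})

test_that("omics generator couples deltas at the requested correlation", {
  layout <- genome_layout(c(chr1 = 100e6))
  segs <- layout_segments(layout)[, c("segment", "chrom", "start", "end")]
  withr::with_seed(21, segs$delta <- stats::rnorm(nrow(segs), 0, 0.4))

  # perfect coupling reproduces the standardized deltas exactly
  om1 <- simulate_omics(segs, layout, coupling_r = 1, n_genes = 100, seed = 1)
  expect_equal(stats::cor(om1$chip$chip_delta, segs$delta), 1)

  # zero coupling: |R| within sampling bounds
  big <- layout_segments(genome_layout(c(chr1 = 2000e6)))
  big <- big[, c("segment", "chrom", "start", "end")]
  withr::with_seed(22, big$delta <- stats::rnorm(nrow(big)))
  om0 <- simulate_omics(big, genome_layout(c(chr1 = 2000e6)), coupling_r = 0,
                        n_genes = 10, seed = 2)
  expect_lt(abs(stats::cor(om0$chip$chip_delta, big$delta)), 0.05)

  # gene placement respects the layout
  om <- simulate_omics(segs, layout, coupling_r = 0.5, n_genes = 500, seed = 3)
  expect_equal(nrow(om$genes), 500)
  expect_true(all(om$genes$tss >= 0 & om$genes$tss < 100e6))
  expect_error(simulate_omics(segs, layout, coupling_r = 1.5), "coupling_r")
})

test_that("fiber kinematics produce the two-pulse track geometry", {
  # sparse origins so signatures are isolated; no jitter; stretch 2 kb/um;
  # v = 1 kb/min, 20-min pulses: 40-kb central first-label track (20 um)
  # flanked by 20-kb (10 um) second-label tracks
  sim <- simulate_fibers(fork_speed_kb_min = 1, ori_spacing_kb = 5000,
                         spacing_shape = 10, label_minutes = c(20, 20),
                         stretch_kb_per_um = 2, n_molecules = 40,
                         molecule_kb = 1000, jitter_um_sd = 0, seed = 3)
  fb <- sim$fibers
  interior <- fb$start_um > 0.5 &
    fb$start_um + fb$length_um < fb$molecule_length_um - 0.5
  first <- fb[fb$label == "first" & interior, ]
  second <- fb[fb$label == "second" & interior, ]
  expect_true(nrow(first) > 5)
  expect_true(all(abs(first$length_um - 20) < 1e-6))
  expect_true(all(abs(second$length_um - 10) < 1e-6))

  # lambda molecules center on 48.5/stretch
  sim2 <- simulate_fibers(stretch_kb_per_um = 2.32, n_molecules = 2,
                          n_lambda = 2000, lambda_len_sd_um = 1, seed = 4)
  expect_lt(abs(mean(sim2$lambda$length_um) - 48.5 / 2.32), 3 * 1 / sqrt(2000))
  expect_error(simulate_fibers(fork_speed_kb_min = -1), "positive")
})
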