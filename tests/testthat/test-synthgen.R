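test_that("planted covariance has the stated block structure and is PSD", {
  part <- rep(1:2, each = 3)
  S <- planted_covariance(part, 0.5, 0.1)
  expect_true(all(diag(S) == 1))
  expect_equal(S[1, 2], 0.5)
  expect_equal(S[1, 4], 0.1)
  expect_equal(S, t(S))
  # eigen-decomposition oracle: 6 nodes, 2 modules of 3, rhos 0.5/0.1
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(min(ev), 0.5, tolerance = 1e-12)

  # all-distinct modules: compound symmetry at rho_between
  S2 <- planted_covariance(1:5, 0.9, 0.2)
  expect_true(all(S2[upper.tri(S2)] == 0.2))

  # equal rhos: partition-independent compound symmetry
  Sa <- planted_covariance(c(1, 1, 2, 2), 0.3, 0.3)
  Sb <- planted_covariance(c(1, 2, 1, 2), 0.3, 0.3)
  expect_equal(Sa, Sb)

  # PSD across admissible rho grid
  for (rw in c(0, 0.3, 0.6, 0.95)) {
    for (rb in c(0, rw / 2, rw)) {
      ev <- eigen(planted_covariance(rep(1:3, each = 4), rw, rb),
                  symmetric = TRUE, only.values = TRUE)$values
      expect_gte(min(ev), -1e-12)
    }
  }
})

test_that("inadmissible correlations are rejected", {
  expect_error(planted_covariance(1:4, 1, 0.5), "rho_within")
  expect_error(planted_covariance(1:4, 0.4, 0.5), "rho_between")
  expect_error(scenario_spec(8, atlas4(8), rho_within = 0.3,
                             rho_between = 0.5), "rho_between")
  expect_error(scenario_spec(8, atlas4(8),
                             condition_sequence = c("a", "b")),
               "condition_sequence")
})

test_that("panel generation is seed-reproducible and seed-sensitive", {
  spec <- scenario_spec(12, atlas4(12), n_blocks = 4,
                        samples_per_block = 5, seed = 42)
  p1 <- generate_panel(spec)
  p2 <- generate_panel(spec)
  expect_identical(p1$signal, p2$signal)
  spec2 <- scenario_spec(12, atlas4(12), n_blocks = 4,
                         samples_per_block = 5, seed = 43)
  expect_false(identical(p1$signal, generate_panel(spec2)$signal))
  expect_equal(ncol(p1$signal), 20)
  expect_equal(p1$annotations$block, rep(1:4, each = 5))
  expect_equal(unique(p1$annotations$condition), c("1-back", "2-back"))
})

test_that("empirical correlations match the generating covariance", {
  # law-of-large-numbers check at 500 samples per block
  spec <- scenario_spec(12, atlas4(12), n_blocks = 2,
                        samples_per_block = 500, rho_within = 0.6,
                        rho_between = 0.05, noise_sd = 0, seed = 7)
  p <- generate_panel(spec)
  sys <- atlas4(12)$system
  same <- outer(sys, sys, "==")
  for (b in 1:2) {
    R <- cor(t(p$signal[, p$annotations$block == b]))
    within <- mean(R[same & upper.tri(R)])
    expect_lt(abs(within - 0.6), 0.05)
  }
})

test_that("equal rhos plant no module contrast", {
  spec <- scenario_spec(12, atlas4(12), n_blocks = 1,
                        samples_per_block = 500, rho_within = 0.3,
                        rho_between = 0.3, noise_sd = 0, seed = 3)
  p <- generate_panel(spec)
  R <- cor(t(p$signal))
  sys <- atlas4(12)$system
  same <- outer(sys, sys, "==") & upper.tri(R)
  diff <- !outer(sys, sys, "==") & upper.tri(R)
  expect_lt(mean(R[same]) - mean(R[diff]), 0.05)
})

test_that("noise dilutes but does not restructure the planted pattern", {
  spec <- scenario_spec(12, atlas4(12), n_blocks = 1,
                        samples_per_block = 500, rho_within = 0.6,
                        rho_between = 0.05, noise_sd = 2, seed = 9)
  p <- generate_panel(spec)
  R <- cor(t(p$signal))
  sys <- atlas4(12)$system
  same <- outer(sys, sys, "==") & upper.tri(R)
  diff <- !outer(sys, sys, "==") & upper.tri(R)
  # contrast persists but attenuated below the noiseless 0.55
  expect_gt(mean(R[same]) - mean(R[diff]), 0.02)
  expect_lt(mean(R[same]) - mean(R[diff]), 0.4)
})

test_that("trial generation respects counts, probabilities and seeds", {
  ts <- trial_spec(10, 30, 1, 0, seed = 1)
  t1 <- generate_trials(ts)
  expect_equal(t1$hits, 10)
  expect_equal(t1$false_alarms, 0)

  # binomial sampling check at large n
  big <- generate_trials(trial_spec(10000, 100, 0.8, 0.1, seed = 2))
  expect_lt(abs(big$hits / 10000 - 0.8), 0.02)

  # conservation over random specs
  for (s in 1:10) {
    tt <- generate_trials(trial_spec(12, 36, runif(1), runif(1), seed = s))
    expect_equal(tt$hits + tt$misses, 12)
    expect_equal(tt$false_alarms + tt$correct_rejections, 36)
  }
  expect_identical(generate_trials(ts), generate_trials(ts))
})

test_that("simulated trial tables cover the full design grid", {
  tt <- simulate_trial_table(n_subjects = 3, seed = 5)
  expect_equal(nrow(tt), 3 * 4 * 2 * 2)
  expect_setequal(unique(tt$session), c("Naive", "Early", "Middle", "Late"))
  expect_true(all(tt$hits + tt$misses == 60))
  expect_identical(tt, simulate_trial_table(n_subjects = 3, seed = 5))
})

test_that("HRF smearing spreads signal across block boundaries", {
  make <- function(smear) {
    spec <- scenario_spec(8, atlas4(8), n_blocks = 4,
                          samples_per_block = 10, noise_sd = 0,
                          smear_hrf = smear, seed = 6)
    generate_panel(spec)
  }
  clean <- make(FALSE)
  smeared <- make(TRUE)
  expect_false(identical(clean$signal, smeared$signal))
  # smearing induces temporal autocorrelation absent in the clean panel
  ac <- function(panel) mean(apply(panel$signal, 1, function(x)
    cor(x[-1], x[-length(x)])))
  expect_gt(ac(smeared), ac(clean) + 0.2)
  # the smeared panel still supports block-wise connectivity
  st <- block_connectivity(smeared)
  expect_length(st$matrices, 4)
})

test_that("panels and ground truth round-trip through delimited text", {
  spec <- scenario_spec(8, atlas4(8), n_blocks = 2, samples_per_block = 4,
                        seed = 2)
  p <- generate_panel(spec)
  pre <- file.path(tempdir(), "panel_test")
  write_panel(p, pre)
  p2 <- read_panel(pre, tr_seconds = 2)
  expect_equal(p2$signal, p$signal, ignore_attr = TRUE, tolerance = 1e-8)
  expect_equal(p2$annotations$condition, p$annotations$condition)
  gt_path <- file.path(tempdir(), "gt.tsv")
  write_planted_partitions(spec, gt_path)
  gt <- read.table(gt_path, header = TRUE, sep = "\t")
  expect_equal(nrow(gt), 8)
  expect_equal(ncol(gt), 3)  # roi_id + 2 blocks
})
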