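test_that("canonical HRF peaks a few seconds in and has finite support", {
  h <- canonical_hrf(2)
  expect_equal(max(h$values), 1)
  peak_t <- h$times[which.max(h$values)]
  expect_gte(peak_t, 4)
  expect_lte(peak_t, 8)
  expect_lte(max(h$times), 32)
  # finer sampling moves samples, not the continuous-time peak
  h05 <- canonical_hrf(0.5)
  expect_lt(abs(h05$times[which.max(h05$values)] - peak_t), 2)
  expect_error(canonical_hrf(0), "positive")
})

test_that("HRF weights are the rectified boxcar convolution", {
  h <- canonical_hrf(2)
  expect_equal(hrf_weights(rep(0, 30), h), rep(0, 30))
  # unit impulse reproduces the rectified kernel
  imp <- c(1, rep(0, 29))
  w <- hrf_weights(imp, h)
  expect_equal(w, pmax(c(h$values, rep(0, 30 - length(h$values)))[1:30], 0),
               tolerance = 1e-10)
  # a long block rises to a plateau; rectification leaves no negatives
  blk <- c(rep(1, 40), rep(0, 30))
  wb <- hrf_weights(blk, h)
  expect_true(all(wb >= 0))
  expect_gt(wb[20], wb[2])
  plateau <- wb[25:35]
  expect_lt(diff(range(plateau)) / max(plateau), 0.05)
  expect_error(hrf_weights(numeric(0), h), "empty")
})

test_that("weighted Pearson matches its moment-formula oracle", {
  # independent high-precision evaluation of the weighted-moment formula
  x <- c(1, 2, 3); y <- c(1, 3, 2); w <- c(1, 1, 2)
  sw <- sum(w)
  mx <- sum(w * x) / sw; my <- sum(w * y) / sw
  oracle <- sum(w * (x - mx) * (y - my)) /
    sqrt(sum(w * (x - mx)^2) * sum(w * (y - my)^2))
  expect_equal(weighted_pearson(x, y, w), oracle, tolerance = 1e-14)

  set.seed(1)
  for (i in 1:5) {
    a <- rnorm(40); b <- rnorm(40); u <- runif(40)
    # uniform weights reduce to ordinary Pearson
    expect_equal(weighted_pearson(a, b, rep(2, 40)), cor(a, b),
                 tolerance = 1e-12)
    # affine relation gives exactly 1
    expect_equal(weighted_pearson(a, 2 * a + 1, u), 1, tolerance = 1e-10)
    # invariance to positive rescaling of weights
    expect_equal(weighted_pearson(a, b, u),
                 weighted_pearson(a, b, 7.3 * u), tolerance = 1e-12)
  }
  expect_error(weighted_pearson(1:3, 1:3, c(0, 0, 0)), "weight mass")
  expect_error(weighted_pearson(c(1, 1, 1), 1:3, c(1, 1, 1)), "variance")
})

test_that("condition connectivity exposes the planted module contrast", {
  atlas <- atlas4(16)
  spec <- scenario_spec(16, atlas, rho_within = 0.6, rho_between = 0.05,
                        seed = 21)
  p <- generate_panel(spec)
  for (cond in c("1-back", "2-back")) {
    A <- condition_connectivity(p, cond)
    expect_equal(unclass(A), t(unclass(A)), ignore_attr = TRUE)
    expect_true(all(diag(A) == 0))
    expect_true(all(A >= 0))
    same <- outer(atlas$system, atlas$system, "==") & upper.tri(A)
    diff <- !outer(atlas$system, atlas$system, "==") & upper.tri(A)
    expect_gt(mean(A[same]), mean(A[diff]))
  }
  expect_error(condition_connectivity(p, "3-back"), "not present")
})

test_that("independent noise produces a null-level edge distribution", {
  atlas <- atlas4(16)
  spec <- scenario_spec(16, atlas, rho_within = 0, rho_between = 0,
                        noise_sd = 1, seed = 8)  # 20 x 15 = 300 volumes
  p <- generate_panel(spec)
  A <- condition_connectivity(p, NULL)
  expect_gt(mean(A[upper.tri(A)] < atanh(0.3)), 0.95)
})

test_that("duplicated ROIs get the maximal finite weight", {
  atlas <- atlas4(8)
  spec <- scenario_spec(8, atlas, seed = 4)
  p <- generate_panel(spec)
  p$signal[2, ] <- p$signal[1, ]
  A <- condition_connectivity(p, "1-back")
  expect_true(is.finite(A[1, 2]))
  expect_equal(A[1, 2], max(A[1, ]))
})

test_that("Fisher transform preserves edge ranking", {
  atlas <- atlas4(12)
  p <- generate_panel(scenario_spec(12, atlas, seed = 31))
  Z <- condition_connectivity(p, "1-back", rectify = FALSE)
  R <- tanh(unclass(Z))  # invert the transform: the raw correlations
  iu <- upper.tri(R)
  expect_equal(order(R[iu]), order(unclass(Z)[iu]))
})

test_that("block connectivity yields one matrix per block", {
  atlas <- atlas4(12)
  p <- generate_panel(scenario_spec(12, atlas, seed = 13))
  st <- block_connectivity(p)
  expect_length(st$matrices, 20)
  expect_equal(st$conditions, rep(c("1-back", "2-back"), 10))
  for (m in st$matrices[1:3]) {
    expect_true(all(m >= 0))
    expect_true(all(diag(m) == 0))
  }
})

test_that("block matrices cluster by condition when structure alternates", {
  atlas <- atlas4(12)
  part1 <- rep(1:2, each = 6)       # condition A grouping
  part2 <- rep(1:2, times = 6)      # condition B grouping
  parts <- lapply(1:10, function(b) if (b %% 2 == 1) part1 else part2)
  spec <- scenario_spec(12, atlas, n_blocks = 10, samples_per_block = 40,
                        planted_partitions = parts, rho_within = 0.7,
                        rho_between = 0, noise_sd = 0.3, seed = 17)
  p <- generate_panel(spec)
  st <- block_connectivity(p)
  vecs <- vapply(st$matrices, function(m) m[upper.tri(m)],
                 numeric(12 * 11 / 2))
  D <- as.matrix(dist(t(vecs)))
  odd <- seq(1, 10, by = 2)
  within <- mean(D[odd, odd][upper.tri(D[odd, odd])])
  across <- mean(D[odd, -odd])
  expect_lt(within, across)
})

test_that("between-block variability shrinks with block length", {
  atlas <- atlas4(12)
  sd_for <- function(spb) {
    spec <- scenario_spec(12, atlas, n_blocks = 10,
                          samples_per_block = spb, seed = 23)
    st <- block_connectivity(generate_panel(spec))
    vecs <- vapply(st$matrices, function(m) m[upper.tri(m)],
                   numeric(12 * 11 / 2))
    mean(apply(vecs, 1, sd))
  }
  expect_lt(sd_for(120), sd_for(15))
})

test_that("connectivity matrices round-trip through delimited text", {
  atlas <- atlas4(8)
  p <- generate_panel(scenario_spec(8, atlas, seed = 3))
  A <- condition_connectivity(p, "2-back")
  path <- file.path(tempdir(), "conn.tsv")
  write_connectivity(A, path)
  A2 <- read_connectivity(path)
  expect_equal(unclass(A2), unclass(A), ignore_attr = TRUE,
               tolerance = 1e-8)
})
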