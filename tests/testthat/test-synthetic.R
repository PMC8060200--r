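test_that("profiles hit the target SD exactly and reproduce under a seed", {
  for (kind in c("uniform", "sparse_bursts", "dense_bursts", "slow_drift")) {
    p <- generate_profile(kind, T = 300, target_sd = 50, mean_rt = 1200,
                          seed = 10)
    expect_equal(sd(p$values), 50, tolerance = 1e-12)
    expect_equal(mean(p$values), 1200, tolerance = 1e-9)
    p2 <- generate_profile(kind, T = 300, target_sd = 50, mean_rt = 1200,
                           seed = 10)
    expect_identical(p$values, p2$values)
  }
  expect_error(generate_profile("uniform", target_sd = 0), "positive")
})

test_that("burst archetypes exceed the uniform archetype in windowed SD", {
  win_sd_max <- function(x, w = 20) {
    max(vapply(seq_len(length(x) - w + 1), function(i)
      sd(x[i:(i + w - 1)]), numeric(1)))
  }
  hits <- 0L
  n_seeds <- 40
  for (s in seq_len(n_seeds)) {
    u <- win_sd_max(generate_profile("uniform", seed = s)$values)
    sp <- win_sd_max(generate_profile("sparse_bursts", seed = s)$values)
    de <- win_sd_max(generate_profile("dense_bursts", seed = s)$values)
    if (sp > u && de > u) hits <- hits + 1L
  }
  expect_gte(hits, ceiling(0.95 * n_seeds))
})

test_that("sparse-burst power concentrates inside the burst epochs", {
  p <- generate_profile("sparse_bursts", seed = 5)
  epochs <- attr(p, "epochs")
  m <- decompose(p)
  marg <- trial_marginal_power(m)
  inside <- epoch_mask <- rep(FALSE, 300)
  for (k in seq_len(nrow(epochs))) inside[epochs[k, 1]:epochs[k, 2]] <- TRUE
  expect_gt(mean(marg[inside]), 3 * mean(marg[!inside]))

  # uniform jitter shows no such inside/outside contrast on the same epochs
  pu <- generate_profile("uniform", seed = 5)
  margu <- trial_marginal_power(decompose(pu))
  expect_lt(mean(margu[inside]) / mean(margu[!inside]), 2)
})

test_that("cohort simulation is seed-reproducible with the requested sizes", {
  spec <- cohort_spec(control_params(), add_params(), 4, 5)
  c1 <- simulate_cohort(spec, seed = 3)
  c2 <- simulate_cohort(spec, seed = 3)
  expect_identical(c1, c2)
  expect_equal(length(c1$a), 4)
  expect_equal(length(c1$b), 5)
  c3 <- simulate_cohort(spec, seed = 4)
  expect_false(identical(c1$a[[1]]$rt, c3$a[[1]]$rt))
})

test_that("patient cohorts show elevated RT_SD and burstier profiles than controls", {
  seeds <- tftperm:::derive_seeds(77, 40)
  sd_of <- function(params) vapply(seeds, function(s)
    summarize_session(simulate_session(params, seed = s))$sd_rt, numeric(1))
  ctrl <- sd_of(control_params())
  add <- sd_of(add_params())
  adhd <- sd_of(adhd_params())
  expect_lt(abs(mean(add) - 404) / 404, 0.10)
  expect_lt(abs(mean(adhd) - 382) / 382, 0.10)
  expect_gt(mean(add), mean(ctrl) * 1.3)

  # windowed-SD dispersion: patients fluctuate between quiet and burst
  win_sd_disp <- function(params, s) {
    x <- build_rt_series(simulate_session(params, seed = s))$values
    w <- vapply(seq(1, length(x) - 19, by = 10), function(i)
      sd(x[i:(i + 19)]), numeric(1))
    sd(w)
  }
  d_ctrl <- vapply(seeds[1:20], function(s) win_sd_disp(control_params(), s),
                   numeric(1))
  d_add <- vapply(seeds[1:20], function(s) win_sd_disp(add_params(), s),
                  numeric(1))
  expect_gt(mean(d_add), 2 * mean(d_ctrl))
})

test_that("tonic shifts translate RTs without touching spread or maps", {
  s <- simulate_session(control_params(miss_prob = 0.02), seed = 12)
  expect_identical(apply_tonic_shift(s, 0), s)
  sh <- apply_tonic_shift(s, -150)
  expect_equal(is.na(sh$rt), is.na(s$rt))
  expect_equal(sh$rt, s$rt - 150)
  b0 <- summarize_session(s); b1 <- summarize_session(sh)
  expect_equal(b1$sd_rt, b0$sd_rt, tolerance = 0.15)  # only misclassification at edges
  expect_error(apply_tonic_shift(s, -1e6), "negative")
})
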