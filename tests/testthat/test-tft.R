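test_that("frequency grid is discretized in 1/T steps up to Nyquist", {
  g <- frequency_grid(300)
  expect_equal(g$step, 1 / 300)
  expect_equal(length(g$frequencies), 150)
  expect_equal(g$frequencies[1], 1 / 300)
  expect_equal(g$frequencies, seq_along(g$frequencies) / 300)

  expect_equal(frequency_grid(100)$step, 0.01)
  expect_equal(length(frequency_grid(100, f_max = 0.2)$frequencies), 20)
  expect_error(frequency_grid(7), ">= 8")
  expect_error(frequency_grid(100, f_max = 0.7), "0.5")
})

test_that("kernels follow the Gabor parameterization", {
  k <- make_kernel(0.05)
  expect_equal(k$sigma_G, 10)        # 0.5 / f_G
  expect_equal(k$window, 40)         # 4 sigma_G (nominal)
  expect_equal(length(k$taps), 41)   # nearest odd >= nominal
  expect_equal(k$center_index, 20)

  k <- make_kernel(0.5)
  expect_equal(k$sigma_G, 1)
  expect_equal(length(k$taps), 5)

  # central tap modulus and full tap formula
  for (f in c(0.03, 0.1, 0.25)) {
    k <- make_kernel(f)
    expect_equal(Mod(k$taps[k$center_index + 1]),
                 1 / (sqrt(2 * pi) * k$sigma_G))
    dt <- seq_along(k$taps) - 1 - k$center_index
    expect_equal(k$taps,
                 (1 / (sqrt(2 * pi) * k$sigma_G)) *
                   exp(-dt^2 / (2 * k$sigma_G^2) + 1i * 2 * pi * f * dt))
  }
})

test_that("fast decomposition matches the direct inner-product oracle", {
  for (seed in 1:3) {
    set.seed(seed)
    T <- c(48, 57, 64)[seed]
    x <- rnorm(T, 1200, 250)
    grid <- frequency_grid(T)
    m <- decompose(x, grid)
    ref <- naive_decompose(x, grid)
    scale <- max(ref)
    expect_lt(max(abs(m$power - ref)) / scale, 1e-9)
  }
})

test_that("decomposition is mean-invariant, scale-quadratic and nonnegative", {
  set.seed(11)
  x <- rnorm(60, 1200, 200)
  g <- frequency_grid(60)
  m <- decompose(x, g)
  expect_true(all(m$power >= 0))

  # constant series: centering annihilates everything
  m0 <- decompose(rep(1200, 60), g)
  expect_lt(max(m0$power), 1e-18 * 1200^2)

  # adding an offset changes nothing
  m_off <- decompose(x + 500, g)
  expect_lt(max(abs(m$power - m_off$power)) / max(m$power), 1e-9)

  # scaling deviations by c multiplies power by c^2
  m_sc <- decompose(mean(x) + 3 * (x - mean(x)), g)
  expect_lt(max(abs(m_sc$power - 9 * m$power)) / max(m_sc$power), 1e-9)
})

test_that("a pure sinusoid localizes to the nearest grid frequency", {
  t <- 0:299
  m <- decompose(sin(2 * pi * 0.05 * t), frequency_grid(300))
  k_target <- which.min(abs(m$grid$frequencies - 0.05))
  interior <- !m$coi_mask[, k_target]
  expect_gt(sum(interior), 100)
  # argmax over frequencies at every interior trial
  argmax <- apply(m$power[interior, , drop = FALSE], 1, which.max)
  expect_true(all(argmax == k_target))
})

test_that("a variance burst produces its marginal-power peak near the burst", {
  set.seed(21)
  T <- 300
  x <- rnorm(T, 0, 1)
  a <- 120; b <- 160
  x[a:b] <- x[a:b] * 6
  m <- decompose(x, frequency_grid(300))
  # restrict to frequencies whose envelope is much shorter than the burst
  sel <- m$grid$frequencies >= 0.1
  marg <- rowMeans(m$power[, sel])
  peak <- which.max(marg)
  win <- max(4 * make_kernel(0.1)$sigma_G, 1)
  expect_gte(peak, a - win)
  expect_lte(peak, b + win)
})

test_that("group mean maps average element-wise and OR the edge masks", {
  maps <- iid_maps(4, 30, 10, seed = 3)
  maps[[1]]$coi_mask[1, 1] <- TRUE
  gm <- group_mean_map(maps)
  ref <- (maps[[1]]$power + maps[[2]]$power + maps[[3]]$power +
            maps[[4]]$power) / 4
  expect_equal(gm$power, ref)
  expect_true(gm$coi_mask[1, 1])
  expect_equal(group_mean_map(maps[1])$power, maps[[1]]$power)
  maps2 <- iid_maps(2, 20, 10, seed = 4)
  expect_error(group_mean_map(c(maps, maps2)), "heterogeneous")
})
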