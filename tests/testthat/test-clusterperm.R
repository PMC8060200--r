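test_that("permutation p-values agree with exhaustive enumeration on tiny designs", {
  # single-bin independent design {1,2,3} vs {4,5,6}: 20 relabelings
  a <- lapply(c(1, 2, 3), function(v) fake_map(matrix(v, 8, 1), f_max = 1 / 8))
  b <- lapply(c(4, 5, 6), function(v) fake_map(matrix(v, 8, 1), f_max = 1 / 8))
  bt <- binwise_permutation_test(a, b, n_shuffle = 5000, seed = 1)
  expect_true(bt$exhaustive)
  expect_equal(bt$p_map[1, 1], enum_p_independent(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(bt$p_map[1, 1], 2 / 20)

  # multi-bin random values, independent; map column c constant at va[c, i]
  set.seed(8)
  va <- matrix(rnorm(4 * 3), 4)  # 4 frequency bins x 3 subjects
  vb <- matrix(rnorm(4 * 4) + 1, 4)
  ma <- lapply(1:3, function(i) fake_map(matrix(rep(va[, i], each = 8), 8, 4), f_max = 4 / 8))
  mb <- lapply(1:4, function(i) fake_map(matrix(rep(vb[, i], each = 8), 8, 4), f_max = 4 / 8))
  bt <- binwise_permutation_test(ma, mb, n_shuffle = 10000, seed = 2)
  expect_true(bt$exhaustive)  # choose(7, 3) = 35 relabelings
  for (bin in 1:4)
    expect_equal(bt$p_map[1, bin], enum_p_independent(va[bin, ], vb[bin, ]))

  # paired sign-flip design, 2^6 = 64 relabelings
  set.seed(9)
  da <- matrix(rnorm(6 * 2), 2)
  a <- lapply(1:6, function(i) fake_map(matrix(rep(da[, i] + 1, each = 8), 8, 2), f_max = 2 / 8))
  b <- lapply(1:6, function(i) fake_map(matrix(0, 8, 2), f_max = 2 / 8))
  bt <- binwise_permutation_test(a, b, design = "paired", n_shuffle = 1000, seed = 3)
  expect_true(bt$exhaustive)
  for (bin in 1:2)
    expect_equal(bt$p_map[1, bin], enum_p_paired(da[bin, ] + 1))
})

test_that("identical groups yield zero t, no significant bins, no clusters", {
  maps <- iid_maps(5, 20, 8, seed = 5)
  bt <- binwise_permutation_test(maps, maps, n_shuffle = 200, seed = 1,
                                 alpha_bin = 0.05)
  expect_lt(max(abs(bt$t_map)), 1e-12)
  expect_false(any(bt$sig_mask))
  res <- cluster_permutation_test(maps, maps, n_shuffle = 200, seed = 1,
                                  alpha_bin = 0.05)
  expect_equal(length(res$clusters), 0)
  expect_equal(res$trials_covered_fraction, 0)
})

test_that("p-values are bounded, deterministic, label-symmetric and monotone in alpha", {
  set.seed(6)
  a <- iid_maps(6, 15, 6, seed = 61)
  b <- iid_maps(6, 15, 6, mean = 0.8, seed = 62)
  bt <- binwise_permutation_test(a, b, n_shuffle = 300, seed = 7, alpha_bin = 0.05)
  expect_true(all(bt$p_map >= 1 / 301 - 1e-12))
  expect_true(all(bt$p_map <= 1))

  # seed determinism, bit-identical
  r1 <- cluster_permutation_test(a, b, n_shuffle = 300, seed = 7, alpha_bin = 0.05)
  r2 <- cluster_permutation_test(a, b, n_shuffle = 300, seed = 7, alpha_bin = 0.05)
  expect_identical(r1, r2)

  # label symmetry (exact in exhaustive mode): 3 vs 3 -> 20 relabelings
  a3 <- a[1:3]; b3 <- b[1:3]
  bt_ab <- binwise_permutation_test(a3, b3, n_shuffle = 100, seed = 1, alpha_bin = 0.05)
  bt_ba <- binwise_permutation_test(b3, a3, n_shuffle = 100, seed = 1, alpha_bin = 0.05)
  expect_true(bt_ab$exhaustive)
  expect_equal(bt_ba$t_map, -bt_ab$t_map)
  expect_equal(bt_ba$p_map, bt_ab$p_map)
  expect_equal(bt_ba$sig_mask, bt_ab$sig_mask)

  # monotonicity: lowering alpha_bin never adds significant bins
  n_sig <- vapply(c(0.2, 0.1, 0.05, 0.01), function(al)
    sum(binwise_permutation_test(a, b, n_shuffle = 300, seed = 7,
                                 alpha_bin = al)$sig_mask),
    numeric(1))
  expect_true(all(diff(n_sig) <= 0))
})

test_that("bin p-values are calibrated under the null at a resolvable threshold", {
  # iid maps, same generative process both sides: P(p < 0.05) ~ 0.05
  frac <- vapply(1:3, function(rep) {
    a <- iid_maps(10, 25, 12, seed = 100 + rep)
    b <- iid_maps(10, 25, 12, seed = 200 + rep)
    bt <- binwise_permutation_test(a, b, n_shuffle = 500, seed = rep,
                                   alpha_bin = 0.05)
    mean(bt$p_map < 0.05)
  }, numeric(1))
  expect_gt(mean(frac), 0.025)
  expect_lt(mean(frac), 0.085)
})

test_that("clusters are sign-pure connected components with summed-t mass", {
  # hand-built t/p maps: two blocks split by a non-significant column
  T <- 12; Fq <- 6
  tmap <- matrix(0, T, Fq)
  pmap <- matrix(1, T, Fq)
  tmap[2:4, 2:3] <- 3; pmap[2:4, 2:3] <- 1e-4
  tmap[7:9, 2:3] <- 2.5; pmap[7:9, 2:3] <- 1e-4
  bt <- structure(list(t_map = tmap, p_map = pmap,
                       sig_mask = pmap < 0.001,
                       grid = frequency_grid(T, Fq / T)),
                  class = "tft_bintest")
  cl <- form_clusters(bt)
  expect_equal(length(cl), 2)
  expect_equal(sort(vapply(cl, `[[`, numeric(1), "mass")),
               c(2.5 * 6, 3 * 6))

  # L-shaped orthogonally connected region is one cluster under 4-connectivity
  tmap <- matrix(0, T, Fq); pmap <- matrix(1, T, Fq)
  tmap[2:6, 2] <- 1; pmap[2:6, 2] <- 1e-4
  tmap[6, 2:5] <- 1; pmap[6, 2:5] <- 1e-4
  bt$t_map <- tmap; bt$p_map <- pmap; bt$sig_mask <- pmap < 0.001
  cl <- form_clusters(bt, connectivity = 4)
  expect_equal(length(cl), 1)
  expect_equal(cl[[1]]$n_bins, 8)

  # opposite signs never merge, even when adjacent
  tmap <- matrix(0, T, Fq); pmap <- matrix(1, T, Fq)
  tmap[3:5, 3] <- 2; tmap[6:8, 3] <- -2
  pmap[3:8, 3] <- 1e-4
  bt$t_map <- tmap; bt$p_map <- pmap; bt$sig_mask <- pmap < 0.001
  cl <- form_clusters(bt)
  expect_equal(length(cl), 2)
  expect_setequal(vapply(cl, `[[`, integer(1), "sign"), c(1L, -1L))

  # diagonal touch: separate under 4-connectivity, merged under 8
  tmap <- matrix(0, T, Fq); pmap <- matrix(1, T, Fq)
  tmap[3, 3] <- 1; tmap[4, 4] <- 1
  pmap[3, 3] <- 1e-4; pmap[4, 4] <- 1e-4
  bt$t_map <- tmap; bt$p_map <- pmap; bt$sig_mask <- pmap < 0.001
  expect_equal(length(form_clusters(bt, 4)), 2)
  expect_equal(length(form_clusters(bt, 8)), 1)

  # empty mask
  bt$sig_mask <- matrix(FALSE, T, Fq)
  expect_equal(length(form_clusters(bt)), 0)
})

test_that("report tabulates counts, extents and coverage", {
  set.seed(31)
  base <- iid_maps(8, 100, 10, seed = 311)
  shifted <- iid_maps(8, 100, 10, seed = 312)
  # inject a strong group difference over trials 11-20, all frequencies
  shifted <- lapply(shifted, function(m) {
    m$power[11:20, ] <- m$power[11:20, ] + 10
    m
  })
  res <- cluster_permutation_test(base, shifted, n_shuffle = 300,
                                  alpha_bin = 0.01, seed = 4)
  df <- report(res)
  expect_s3_class(df, "data.frame")
  expect_equal(attr(df, "n_clusters"), length(res$clusters))
  expect_gte(res$n_significant, 1)
  sig <- df[df$significant, ]
  expect_true(any(sig$trial_start >= 9 & sig$trial_end <= 22))
  # coverage = distinct trials in significant clusters / T
  trials <- unique(unlist(lapply(res$clusters, function(cl)
    if (cl$significant) cl$bins[, "trial"])))
  expect_equal(res$trials_covered_fraction, length(trials) / 100)

  # empty result
  null_res <- cluster_permutation_test(base[1:4], base[5:8],
                                       n_shuffle = 200, alpha_bin = 0.01,
                                       seed = 5)
  df0 <- report(null_res)
  expect_equal(attr(df0, "n_significant"), 0)
})

test_that("degenerate bins get t = 0 and p = 1", {
  a <- lapply(1:3, function(i) fake_map(matrix(5, 8, 1), f_max = 1 / 8))
  b <- lapply(1:3, function(i) fake_map(matrix(5, 8, 1), f_max = 1 / 8))
  bt <- binwise_permutation_test(a, b, n_shuffle = 50, seed = 1)
  expect_true(all(bt$t_map == 0))
  expect_true(all(bt$p_map == 1))
})
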