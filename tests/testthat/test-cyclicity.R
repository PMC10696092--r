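test_that("lead matrix is skew-symmetric and vanishes for identical channels", {
  set.seed(21)
  p <- rsmooth_path(d = 4, n = 500)
  L <- lead_matrix(p)
  expect_equal(max(abs(unclass(L) + t(unclass(L)))), 0)
  expect_true(all(diag(L) == 0))

  same <- multichannel_path(cbind(sin(1:100 / 10), sin(1:100 / 10)))
  expect_equal(max(abs(lead_matrix(same))), 0)

  expect_error(lead_matrix(multichannel_path(matrix(1:5, 5, 1))), "channels")
})

test_that("lead matrix of lagged sines matches the analytic closed form", {
  ## two channels with offsets 0, pi/2 over one angular period 2*pi:
  ## |L_12| = (T/2) |sin(pi/2)| = pi
  p2 <- closed_sine_path(c(0, pi / 2), periods = 1, n_samples = 1e4)
  L2 <- lead_matrix(p2)
  expect_equal(abs(L2[1, 2]), pi, tolerance = 1e-5)
  expect_equal(L2[2, 1], -L2[1, 2])

  ## entrywise agreement with the closed form on 5 generic offsets
  al <- c(0.3, 1.1, 2.9, 4.0, 5.5)
  p <- closed_sine_path(al, periods = 2, n_samples = 8000)
  L <- lead_matrix(p)
  Lo <- analytic_sine_lead_matrix(al, 4 * pi)
  expect_equal(unclass(L), unclass(Lo), tolerance = 1e-5,
               ignore_attr = TRUE)

  ## the closed form itself: rank 2, skew, (T/2)(y x' - x y') structure
  expect_equal(Lo, 2 * pi * (outer(cos(al), sin(al)) - outer(sin(al), cos(al))))
  expect_lt(svd(Lo)$d[3], 1e-12 * svd(Lo)$d[1])
  expect_equal(analytic_sine_lead_matrix(rep(1.2, 4), 2 * pi),
               matrix(0, 4, 4))

  ## sign convention: channel with the smaller offset peaks first and leads
  expect_gt(L2[1, 2], 0)

  ## amplitude enters squared
  expect_equal(analytic_sine_lead_matrix(al, 2 * pi, amplitude = 3),
               9 * analytic_sine_lead_matrix(al, 2 * pi))
})

test_that("lead matrix spectrum is purely imaginary in conjugate pairs", {
  set.seed(22)
  for (d in c(3, 6, 11)) {
    L <- rskew(d)
    ev <- eigen(L, only.values = TRUE)$values
    expect_lt(max(abs(Re(ev))), 1e-10 * max(Mod(ev)))
    ## conjugate pairing: sorted moduli come in equal pairs
    mods <- sort(Mod(ev), decreasing = TRUE)
    expect_equal(mods[seq(1, 2 * (d %/% 2), by = 2)],
                 mods[seq(2, 2 * (d %/% 2), by = 2)], tolerance = 1e-10)
  }
})

test_that("cyclic order recovers balanced sine offsets exactly", {
  al <- balanced_alphas(5)
  p <- closed_sine_path(al, periods = 2, n_samples = 1e4)
  L <- lead_matrix(p)
  ## numerical rank 2
  sv <- svd(unclass(L))$d
  expect_lt(sv[3] / sv[1], 1e-8)
  res <- cyclic_order(L, n_pairs = 2)
  expect_equal(res$n_sets, 1L)
  al_rec <- res$pairs[[1]]$phases
  expect_lt(align_phases(al_rec, al)$error, 1e-6)
  ## ranking by phase gives the cyclic order in one of the two orientations
  ord <- res$pairs[[1]]$order
  expect_true(identical(ord, paste0("ch", 1:5)) ||
                identical(ord, paste0("ch", c(1, 5:2))))
})

test_that("cyclic order recovers the ordering of generic offsets", {
  ## unbalanced offsets: phases are approximate but the cyclic ORDER is kept
  al <- c(0.2, 1.0, 2.1, 3.9, 5.1)
  p <- closed_sine_path(al, periods = 2, n_samples = 8000)
  res <- cyclic_order(lead_matrix(p), n_pairs = 1)
  ord <- res$pairs[[1]]$order
  ## align orientation/rotation, then expect the circular sequence 1..5
  start <- which(ord == "ch1")
  fwd <- ord[((start - 1 + 0:4) %% 5) + 1]
  rev_ <- ord[((start - 1 - 0:4) %% 5) + 1]
  expect_true(identical(fwd, paste0("ch", 1:5)) ||
                identical(rev_, paste0("ch", 1:5)))
})

test_that("lead matrix is reparametrization invariant for warped sines", {
  al <- balanced_alphas(4)
  p <- closed_sine_path(al, periods = 2, n_samples = 4000)
  warped <- multichannel_path(p$values,
                              p$times[1] +
                                (p$times - p$times[1])^2 / diff(range(p$times)))
  expect_equal(unclass(lead_matrix(p)), unclass(lead_matrix(warped)))
})

test_that("two disjoint sine sets give two dominant pairs with block support", {
  c1 <- sine_system_config(balanced_alphas(4), frequency = 1, duration = 2,
                           sample_rate = 800)
  c2 <- sine_system_config(balanced_alphas(5) + 0.37, frequency = 2,
                           duration = 2, sample_rate = 800, amplitude = 0.6)
  p <- gen_multiset_sines(list(c1, c2))
  res <- cyclic_order(lead_matrix(p), n_pairs = 2)
  expect_equal(res$n_sets, 2L)
  ## each eigenvector's large components live on one block
  m1 <- res$pairs[[1]]$modulus
  m2 <- res$pairs[[2]]$modulus
  b1 <- grepl("^set1", names(m1))
  supp1 <- names(which(m1 > 0.5 * max(m1)))
  supp2 <- names(which(m2 > 0.5 * max(m2)))
  expect_true(all(grepl("^set1", supp1)) || all(grepl("^set2", supp1)))
  expect_true(all(grepl("^set1", supp2)) || all(grepl("^set2", supp2)))
  expect_false(identical(grepl("^set1", supp1)[1], grepl("^set1", supp2)[1]))
  ## per-block order recovery (blocks are balanced, so phases are exact)
  blk1 <- if (all(grepl("^set1", supp1))) res$pairs[[1]] else res$pairs[[2]]
  expect_lt(align_phases(blk1$phases[b1], balanced_alphas(4))$error, 1e-6)

  ## single set: one dominant pair
  res1 <- cyclic_order(lead_matrix(gen_lagged_sines(c1)), n_pairs = 1)
  expect_equal(res1$n_sets, 1L)

  ## overlapping duration mismatch is rejected
  c3 <- sine_system_config(1:3, frequency = 1, duration = 3, sample_rate = 800)
  expect_error(gen_multiset_sines(list(c1, c3)), "share")
})

test_that("zero lead matrix yields no cyclic structure", {
  res <- cyclic_order(matrix(0, 4, 4), n_pairs = 2)
  expect_equal(res$n_sets, 0L)
  expect_true(all(Mod(res$eigenvalues) == 0))
  expect_error(cyclic_order(matrix(0, 4, 4), n_pairs = 3), "n_pairs")
  expect_error(cyclic_order(diag(3), 1), "skew")
})

test_that("channel contribution counts mark top channels and conserve totals", {
  ## one trial, top_k = d: every channel counted once
  L <- rskew(4)
  r <- cyclic_order(L, 1)
  expect_true(all(channel_contribution_counts(list(r), top_k = 4) == 1L))

  ## trials with a dominant 3-channel sine block
  set.seed(23)
  results <- lapply(1:12, function(i) {
    cs <- sine_system_config(balanced_alphas(3), frequency = 1, duration = 2,
                             sample_rate = 400, noise_sd = 0.2, seed = i)
    vals <- gen_lagged_sines(cs)$values
    noise <- matrix(rnorm(nrow(vals) * 3, sd = 0.3), ncol = 3)
    p <- multichannel_path(cbind(vals, noise))
    cyclic_order(lead_matrix(p), 1)
  })
  counts <- channel_contribution_counts(results, top_k = 3)
  expect_equal(sum(counts), 12L * 3L)
  expect_true(all(counts[1:3] >= 10))
  expect_error(channel_contribution_counts(results, top_k = 7), "top_k")
})

test_that("eigenvalue spectrum summary averages and flags dominance", {
  al <- balanced_alphas(5)
  p <- closed_sine_path(al, periods = 2, n_samples = 3000)
  r <- cyclic_order(lead_matrix(p), 1)
  ## identical trials: mean equals each trial's spectrum
  s <- eigenvalue_spectrum_summary(list(r, r, r))
  expect_equal(s$mean_moduli, sort(Mod(r$eigenvalues), decreasing = TRUE))
  expect_gt(s$dominance_ratio, 1e6)  # rank-2: median is numerically zero

  ## pure white noise: no dominant pair
  set.seed(24)
  rn <- lapply(1:10, function(i) {
    cyclic_order(lead_matrix(multichannel_path(matrix(rnorm(200 * 8), 200, 8))), 1)
  })
  sn <- eigenvalue_spectrum_summary(rn)
  expect_lt(sn$dominance_ratio, 10)
  expect_error(eigenvalue_spectrum_summary(list()), "no results")
})
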