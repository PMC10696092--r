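test_that("segment signature matches the linear-path closed form", {
  ## d = 1, increment 2: levels are 2, 2, 4/3 (Delta^m / m!)
  s <- segment_signature(c(2), 3)
  expect_equal(s$tensors[[1]], 2)
  expect_equal(s$tensors[[2]], 2)
  expect_equal(s$tensors[[3]], 4 / 3)

  ## zero increment: all levels vanish
  z <- segment_signature(rep(0, 3), 3)
  expect_true(all(unlist(z$tensors) == 0))

  ## straight segment encloses no signed area
  s2 <- segment_signature(c(1, 1), 2)$tensors[[2]]
  expect_equal(s2[2], 0.5)  # S^{1,2}
  expect_equal(s2[3], 0.5)  # S^{2,1}
  expect_equal(0.5 * (s2[2] - s2[3]), 0)

  expect_error(segment_signature(c(1, 2), 0), "level")
  expect_error(segment_signature(c(1, NA), 2), "finite")
})

test_that("Chen's identity concatenates and inverts segments", {
  ## identity element
  s <- segment_signature(c(1, -2), 3)
  z <- truncated_signature(lapply(1:3, function(m) numeric(2^m)), 2, 3)
  expect_equal(chen_concat(s, z), s)
  expect_equal(chen_concat(z, s), s)

  ## retracing a segment cancels every level (tree-like equivalence)
  back <- chen_concat(s, segment_signature(c(-1, 2), 3))
  expect_lt(max(abs(unlist(back$tensors))), 1e-14)

  ## L-shaped path: right then up has S2^{1,2} = 1, S2^{2,1} = 0, area 1/2
  ls <- chen_concat(segment_signature(c(1, 0), 2), segment_signature(c(0, 1), 2))
  expect_equal(ls$tensors[[2]], c(0.5, 1, 0, 0.5))

  expect_error(chen_concat(s, segment_signature(c(1, 2, 3), 3)), "dim")
})

test_that("chen_concat is associative and splits reproduce full signatures", {
  set.seed(41)
  for (rep in 1:5) {
    p <- rsmooth_path(d = 3, n = 60)
    full <- signature(p, 3)
    for (cut in c(2, 17, 45)) {
      left <- multichannel_path(p$values[1:cut, ], p$times[1:cut])
      right <- multichannel_path(p$values[cut:60, ], p$times[cut:60])
      glued <- chen_concat(signature(left, 3), signature(right, 3))
      expect_lt(max(abs(unlist(glued$tensors) - unlist(full$tensors))), 1e-12)
    }
  }
})

test_that("signature is exact on 2-sample paths and level 1 is the displacement", {
  set.seed(11)
  for (d in c(1, 2, 5)) {
    v <- matrix(rnorm(2 * d), 2, d)
    p <- multichannel_path(v)
    s <- signature(p, 3)
    cf <- segment_signature(v[2, ] - v[1, ], 3)
    expect_equal(s$tensors, cf$tensors)
  }
  p <- rsmooth_path(d = 4, n = 300)
  s <- signature(p, 2)
  expect_equal(s$tensors[[1]],
               p$values[nrow(p$values), ] - p$values[1, ])
})

test_that("signature is translation invariant", {
  ## exact arithmetic case: integer lattice path + integer shift means the
  ## stored samples subtract back to bitwise-identical increments, so the
  ## signatures are bitwise identical
  set.seed(12)
  lattice <- matrix(sample(-50:50, 120, replace = TRUE), 40, 3)
  p_int <- multichannel_path(lattice)
  shifted_int <- multichannel_path(sweep(lattice, 2, c(-1000, 250, 7)))
  expect_identical(signature(p_int, 3)$tensors, signature(shifted_int, 3)$tensors)

  ## floating-point path: invariance up to the round-off of the shift itself
  p <- rsmooth_path(d = 3, n = 400)
  v <- c(10, -3, 0.5)
  shifted <- multichannel_path(sweep(p$values, 2, -v), p$times)
  s1 <- unlist(signature(p, 3)$tensors)
  s2 <- unlist(signature(shifted, 3)$tensors)
  expect_lt(max(abs(s1 - s2)) / max(abs(s1)), 1e-12)
})

test_that("signature is invariant to node-preserving monotone resampling", {
  set.seed(13)
  p <- rsmooth_path(d = 3, n = 50)
  ## refine with extra nodes placed by a nonlinear monotone map
  extra <- p$times[1] + (p$times[50] - p$times[1]) *
    sort(runif(200))^1.7
  q <- resample_path(p, c(p$times, extra))
  s1 <- unlist(signature(p, 3)$tensors)
  s2 <- unlist(signature(q, 3)$tensors)
  expect_lt(max(abs(s1 - s2)), 1e-10)

  ## warping the time stamps alone (same sample values) changes nothing
  warped <- multichannel_path(p$values, cumsum(runif(50, 0.1, 2)))
  expect_identical(signature(p, 3)$tensors, signature(warped, 3)$tensors)
})

test_that("closed circle has signed area pi at level 2", {
  p <- circle_path(10001)
  s2 <- signature(p, 2)$tensors[[2]]
  area <- 0.5 * (s2[2] - s2[3])
  expect_equal(area, pi, tolerance = 1e-6)
})

test_that("streaming updates reproduce the batch signature exactly", {
  set.seed(14)
  v <- matrix(rnorm(400), 100, 4)
  p <- multichannel_path(v)
  sig <- segment_signature(v[2, ] - v[1, ], 3)
  for (i in 3:100) sig <- signature_update(sig, v[i - 1, ], v[i, ])
  expect_equal(sig$tensors, signature(p, 3)$tensors)

  ## zero increment leaves the signature unchanged
  expect_equal(signature_update(sig, v[100, ], v[100, ])$tensors, sig$tensors)

  ## retracing the whole path back to the start cancels everything
  for (i in 99:1) sig <- signature_update(sig, v[i + 1, ], v[i, ])
  expect_lt(max(abs(unlist(sig$tensors))), 1e-10)

  expect_error(signature_update(sig, v[1, ], c(1, 2)), "length")
})

test_that("quadrature oracle agrees with the tensor-algebra route", {
  ## exact on a linear segment
  seg <- multichannel_path(rbind(c(0, 0), c(2, -1)), c(0, 1))
  q <- quadrature_oracle(seg, 3, steps = 2000)
  cf <- segment_signature(c(2, -1), 3)
  ## levels 1-2 are exact for a straight segment; level 3 is O(h^2)
  expect_equal(q$tensors[[1]], cf$tensors[[1]], tolerance = 1e-12)
  expect_equal(q$tensors[[2]], cf$tensors[[2]], tolerance = 1e-12)
  expect_equal(q$tensors[[3]], cf$tensors[[3]], tolerance = 1e-5)

  ## sine/cosine pair over one period: antisymmetric S2 part = circle area
  q2 <- quadrature_oracle(circle_path(2001), 2, steps = 2000)
  expect_equal(0.5 * (q2$tensors[[2]][2] - q2$tensors[[2]][3]), pi,
               tolerance = 1e-4)

  ## constant path
  cp <- multichannel_path(matrix(1, 5, 2), 0:4)
  expect_true(all(unlist(quadrature_oracle(cp, 2)$tensors) == 0))

  ## random smooth paths at levels <= 3: relative error < 1e-4
  set.seed(15)
  for (rep in 1:3) {
    p <- rsmooth_path(d = 3, n = 1200)
    ex <- signature(p, 3)
    q <- quadrature_oracle(p, 3, steps = 4000)
    for (m in 1:3) {
      expect_lt(max(abs(q$tensors[[m]] - ex$tensors[[m]])) /
                  max(abs(ex$tensors[[m]])), 1e-4)
    }
  }

  expect_error(quadrature_oracle(seg, 4), "level")
})

test_that("flatten orders levels lexicographically and round-trips", {
  set.seed(16)
  p <- rsmooth_path(d = 2, n = 30)
  s <- signature(p, 3)
  v <- flatten(s, 1:2)
  expect_length(v, 2 + 4)
  expect_identical(names(v), c("s1_1", "s1_2",
                               "s2_1_1", "s2_1_2", "s2_2_1", "s2_2_2"))
  expect_equal(unname(v), c(s$tensors[[1]], s$tensors[[2]]))
  ## 22-channel geometry at levels 1..2
  expect_length(signature_names(22, 1:2), 22 + 484)
  ## round trip
  back <- unflatten(flatten(s), 2, 1:3)
  expect_equal(back$tensors, s$tensors)
  expect_error(flatten(s, integer(0)), "non-empty")
  expect_error(flatten(s, 4), "levels")
})
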