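test_that("AIRM distance closed forms and axioms hold", {
  set.seed(51)
  A <- rspd(4)
  expect_equal(airm_distance(A, A), 0, tolerance = 1e-10)

  ## d(I, cI) = sqrt(d) |log c|
  for (d in c(2, 5)) {
    expect_equal(airm_distance(diag(d), diag(3.7, d)), sqrt(d) * log(3.7),
                 tolerance = 1e-10)
  }

  ## symmetry
  B <- rspd(4)
  expect_equal(airm_distance(A, B), airm_distance(B, A), tolerance = 1e-10)

  expect_error(airm_distance(matrix(1:4, 2), diag(2)), "positive definite")
})

test_that("AIRM congruence invariance and log/exp round-trips hold broadly", {
  set.seed(52)
  for (d in c(2, 8, 22)) {
    for (rep in 1:3) {
      A <- rspd(d)
      B <- rspd(d)
      G <- matrix(rnorm(d * d), d) + diag(d)
      expect_equal(airm_distance(G %*% A %*% t(G), G %*% B %*% t(G)),
                   airm_distance(A, B), tolerance = 1e-8)
      tv <- log_map(A, B)
      expect_equal(exp_map(A, tv), B, tolerance = 1e-8)
      expect_equal(sqrt(sum(tv^2)), airm_distance(A, B), tolerance = 1e-8)
      expect_length(tv, d * (d + 1) / 2)
    }
  }
  ## log at the reference itself is the zero vector
  A <- rspd(5)
  expect_lt(max(abs(log_map(A, A))), 1e-10)
})

test_that("Karcher mean matches closed forms and is congruence equivariant", {
  set.seed(53)
  A <- rspd(5)
  B <- rspd(5)
  ## singleton
  expect_equal(geometric_mean(list(A)), A, ignore_attr = TRUE)
  ## two-point mean is the geodesic midpoint
  gm <- geometric_mean(list(A, B))
  sa <- pathsig:::spd_sqrt(A)
  isa <- pathsig:::spd_invsqrt(A)
  mid <- sa %*% pathsig:::spd_fun(isa %*% B %*% isa, sqrt) %*% sa
  expect_equal(unclass(gm), mid, tolerance = 1e-8, ignore_attr = TRUE)
  expect_true(attr(gm, "karcher")$converged)

  ## commuting case: elementwise geometric mean of eigenvalues
  D1 <- diag(c(1, 4, 9))
  D2 <- diag(c(4, 1, 16))
  expect_equal(unclass(geometric_mean(list(D1, D2))), diag(c(2, 2, 12)),
               tolerance = 1e-8, ignore_attr = TRUE)

  ## congruence equivariance: mean({G Ai G'}) = G mean({Ai}) G'
  mats <- lapply(1:6, function(i) rspd(4))
  G <- matrix(rnorm(16), 4) + diag(4)
  m1 <- geometric_mean(lapply(mats, function(M) G %*% M %*% t(G)))
  m2 <- G %*% geometric_mean(mats) %*% t(G)
  expect_equal(unclass(m1), unclass(m2), tolerance = 1e-6, ignore_attr = TRUE)

  ## non-convergence is a warning, not an error
  expect_warning(geometric_mean(list(A, B), tol = 0, max_iter = 2L),
                 "converge")
})

test_that("MDM classifies tangent-noise SPD clusters and honors tie rules", {
  set.seed(54)
  cl <- spd_clusters(n_per = 25, d = 4, sigma = 0.08, sep = 1.2)
  tr <- c(1:18, 26:43)
  te <- setdiff(seq_along(cl$y), tr)
  fit <- mdm(cl$x[tr], cl$y[tr])
  expect_s3_class(fit, "mdm")
  acc <- mean(predict(fit, cl$x[te]) == cl$y[te])
  expect_gte(acc, 0.95)

  ## a sample equal to a class mean goes to that class
  expect_equal(as.character(predict(fit, list(fit$means[["a"]]))), "a")

  expect_error(mdm(cl$x[1:5], factor(rep("a", 5))), "2 classes")

  ## MDM invariant to a global congruence of all features
  G <- matrix(rnorm(16), 4) + diag(4)
  xg <- lapply(cl$x, function(M) G %*% M %*% t(G))
  fitg <- mdm(xg[tr], cl$y[tr])
  expect_equal(predict(fitg, xg[te]), predict(fit, cl$x[te]))
})

test_that("tangent classifier separates clusters and is chance on permuted labels", {
  set.seed(55)
  cl <- spd_clusters(n_per = 30, d = 4, sigma = 0.1, sep = 1.5)
  fit <- tangent_classifier(cl$x, cl$y, seed = 9L)
  expect_equal(mean(predict(fit, cl$x) == cl$y), 1)

  ## identity reference is legal and also separates
  fit_id <- tangent_classifier(cl$x, cl$y, reference = "identity", seed = 9L)
  expect_gte(mean(predict(fit_id, cl$x) == cl$y), 0.95)

  ## permuted labels: cross-validated accuracy inside the binomial band
  perm <- sample(cl$y)
  arr <- array(unlist(cl$x), c(4, 4, length(cl$x)))
  attr(arr, "labels") <- perm
  rep <- crossvalidate(arr, classifier = classifier_spec("tangent"),
                       k = 5L, seed = 3L)
  n <- length(perm)
  band <- 1.96 * sqrt(0.25 / n)
  expect_gte(rep$mean, 0.5 - band)
  expect_lte(rep$mean, 0.5 + band)
})
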