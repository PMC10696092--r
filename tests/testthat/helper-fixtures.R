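## Shared fixtures, all generated in code.

## random SPD matrix with moderate conditioning
rspd <- function(d, scale = 1) {
  M <- matrix(stats::rnorm(d * d), d)
  scale * (crossprod(M) / d + diag(d) * 0.5)
}

## random skew-symmetric matrix
rskew <- function(d) {
  M <- matrix(stats::rnorm(d * d), d)
  (M - t(M)) / 2
}

## random smooth multichannel path: sum of low-order polynomials and slow sines
rsmooth_path <- function(d = 3, n = 1200, t_max = 1) {
  t <- seq(0, t_max, length.out = n)
  vals <- sapply(seq_len(d), function(j) {
    a <- stats::rnorm(3)
    f <- stats::runif(1, 0.5, 2.5)
    a[1] * sin(2 * pi * f * t + a[2]) + a[3] * t^2 + stats::rnorm(1) * t
  })
  multichannel_path(vals, t)
}

## closed path on a circle (counterclockwise), encloses area pi * r^2
circle_path <- function(n = 10001, r = 1) {
  th <- seq(0, 2 * pi, length.out = n)
  multichannel_path(cbind(r * cos(th), r * sin(th)))
}

## balanced (uniformly spread) phase offsets: sum exp(2i*alpha) = 0, so
## eigenvector phases of the sine-system lead matrix are exact
balanced_alphas <- function(n) 2 * pi * (seq_len(n) - 1) / n

## closed sampled sine system with a given total sample count
closed_sine_path <- function(alphas, periods = 2, n_samples = 1e4) {
  dur <- periods * 2 * pi
  cfg <- sine_system_config(alphas, frequency = 1 / (2 * pi), duration = dur,
                            sample_rate = (n_samples - 1) / dur)
  gen_lagged_sines(cfg)
}

## small two-class SPD clusters around distinct centers via tangent noise
spd_clusters <- function(n_per = 20, d = 4, sigma = 0.1, sep = 1) {
  c1 <- diag(d)
  S <- matrix(0, d, d)
  S[1, 2] <- S[2, 1] <- sep / 2
  diag(S) <- sep * seq(-0.5, 0.5, length.out = d)
  c2 <- pathsig::exp_map(c1, vech_w(S))
  draw <- function(center, n) {
    lapply(seq_len(n), function(i) {
      E <- matrix(stats::rnorm(d * d, sd = sigma), d)
      E <- (E + t(E)) / 2
      pathsig::exp_map(center, vech_w(E))
    })
  }
  list(x = c(draw(c1, n_per), draw(c2, n_per)),
       y = factor(rep(c("a", "b"), each = n_per)))
}

## weighted half-vectorization matching the package's tangent convention
vech_w <- function(S) c(diag(S), sqrt(2) * S[upper.tri(S)])

## small, fast motor-imagery config for non-acceptance tests
small_mi <- function(preset, seed = 1L, n = 20L, d = 8L) {
  mi_preset(preset, n_trials_per_class = n, n_channels = d,
            sample_rate = 160, duration = 1.5, seed = seed)
}
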