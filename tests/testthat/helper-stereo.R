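# shared helpers for the suite

# linearised standard error of a ratio-of-sums estimator theta = sum(y)/sum(x)
ratio_se <- function(y, x) {
  th <- sum(y) / sum(x)
  n <- length(x)
  list(theta = th,
       se = sqrt(sum((y - th * x)^2) * n / (n - 1)) / sum(x))
}

# hand-built network from explicit segments (bypasses the generator)
manual_network <- function(region, p0, p1, radius) {
  to_m <- function(x) if (is.matrix(x)) x else matrix(x, ncol = 3, byrow = TRUE)
  structure(list(region = region,
                 p0 = to_m(p0),
                 p1 = to_m(p1),
                 radius = radius, seed = 0L, orientation = "isotropic"),
            class = "capillary_network")
}

# profile set from explicit ellipse parameters
manual_profiles <- function(cx, cy, b, a, phi) {
  n <- length(cx)
  structure(data.frame(
    profile_id = seq_len(n), cx_um = cx, cy_um = cy,
    semi_minor_um = b, semi_major_um = a, angle_rad = phi,
    cos_theta = b / a, segment_id = seq_len(n)
  ), class = c("profile_set", "data.frame"), n_parallel_skipped = 0L)
}

# random profile set inside [lo, hi]^2 with bounded axes
random_profiles <- function(n, lo = 0, hi = 100, rmax = 4) {
  b <- stats::runif(n, 0.5, rmax)
  manual_profiles(stats::runif(n, lo, hi), stats::runif(n, lo, hi),
                  b, b * stats::runif(n, 1, 2.5),
                  stats::runif(n, 0, pi))
}
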