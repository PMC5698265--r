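test_that("reference regions have exact closed-form volumes and convex membership", {
  box <- reference_region("box", c(500, 400, 300))
  ell <- reference_region("ellipsoid", c(300, 250, 200))
  sph <- reference_region("sphere", 300)
  expect_equal(region_volume(box), 500 * 400 * 300, tolerance = 1e-12)
  expect_equal(region_volume(ell), 4 / 3 * pi * 300 * 250 * 200,
               tolerance = 1e-12)
  expect_equal(region_volume(sph), 4 / 3 * pi * 300^3, tolerance = 1e-12)
  # boundary counts as inside; convexity: midpoints of inside points inside
  expect_true(region_contains(box, c(250, 200, 150)))
  expect_false(region_contains(box, c(250.001, 0, 0)))
  set.seed(1)
  pts <- cbind(runif(200, -300, 300), runif(200, -300, 300),
               runif(200, -300, 300))
  for (reg in list(box, ell, sph)) {
    inside <- pts[region_contains(reg, pts), , drop = FALSE]
    if (nrow(inside) >= 2) {
      mid <- (inside[-1, , drop = FALSE] +
                inside[-nrow(inside), , drop = FALSE]) / 2
      expect_true(all(region_contains(reg, mid)))
    }
  }
  expect_error(reference_region("box", c(1, 2)), "3 dimension")
  expect_error(reference_region("sphere", -1), "positive")
})

test_that("generate_network hits the target length, is deterministic, empty at zero density", {
  reg <- reference_region("box", c(500, 500, 500))
  net0 <- generate_network(reg, 0, seed = 1)
  expect_equal(nrow(net0$p0), 0)
  gt0 <- ground_truth(net0)
  expect_identical(c(gt0$total_length, gt0$total_volume, gt0$total_surface),
                   c(0, 0, 0))

  net <- generate_network(reg, 3e-4, seed = 7)
  gt <- ground_truth(net)
  target <- 3e-4 * region_volume(reg)   # 37,500 um
  expect_lt(abs(gt$total_length - target) / target, 0.01)
  # oracle: independent re-summation of emitted segments
  expect_equal(gt$total_length,
               sum(sqrt(rowSums((net$p1 - net$p0)^2))), tolerance = 1e-12)
  expect_identical(net, generate_network(reg, 3e-4, seed = 7))
  # all segments inside the region with the radius margin
  expect_true(all(region_contains(reg, net$p0, inset = net$radius[1] - 1e-9)))
  expect_true(all(region_contains(reg, net$p1, inset = net$radius[1] - 1e-9)))
})

test_that("ground truth matches cylinder closed forms and brute-force sums", {
  reg <- reference_region("box", c(500, 500, 500))
  one <- manual_network(reg, c(0, 0, -50), c(0, 0, 50), 2)
  gt <- ground_truth(one)
  expect_equal(gt$total_length, 100, tolerance = 1e-12)
  expect_equal(gt$total_volume, 400 * pi, tolerance = 1e-12)
  expect_equal(gt$total_surface, 400 * pi, tolerance = 1e-12)

  net <- generate_network(reg, 8e-4, seed = 3, length_range = c(20, 60))
  expect_gt(nrow(net$p0), 1000)
  gt <- ground_truth(net)
  l <- vol <- surf <- 0
  for (i in seq_len(nrow(net$p0))) {   # independent scalar re-summation
    li <- sqrt(sum((net$p1[i, ] - net$p0[i, ])^2))
    l <- l + li
    vol <- vol + pi * net$radius[i]^2 * li
    surf <- surf + 2 * pi * net$radius[i] * li
  }
  expect_equal(gt$total_length, l, tolerance = 1e-9)
  expect_equal(gt$total_volume, vol, tolerance = 1e-9)
  expect_equal(gt$total_surface, surf, tolerance = 1e-9)
  expect_equal(gt$length_density, l / region_volume(reg), tolerance = 1e-12)
})

test_that("ground truth is additive over disjoint networks and scale-equivariant", {
  reg <- reference_region("box", c(500, 500, 500))
  n1 <- generate_network(reg, 1e-4, seed = 5)
  n2 <- generate_network(reg, 2e-4, seed = 6)
  both <- manual_network(reg, rbind(n1$p0, n2$p0), rbind(n1$p1, n2$p1),
                         c(n1$radius, n2$radius))
  both$p0 <- rbind(n1$p0, n2$p0); both$p1 <- rbind(n1$p1, n2$p1)
  g1 <- ground_truth(n1); g2 <- ground_truth(n2); gb <- ground_truth(both)
  expect_equal(gb$total_length, g1$total_length + g2$total_length,
               tolerance = 1e-12)
  expect_equal(gb$total_volume, g1$total_volume + g2$total_volume,
               tolerance = 1e-12)
  expect_equal(gb$total_surface, g1$total_surface + g2$total_surface,
               tolerance = 1e-12)

  s <- 3.7
  sreg <- reference_region("box", c(500, 500, 500) * s)
  snet <- manual_network(sreg, n1$p0 * s, n1$p1 * s, n1$radius * s)
  gs <- ground_truth(snet)
  expect_equal(gs$total_length, g1$total_length * s, tolerance = 1e-9)
  expect_equal(gs$total_surface, g1$total_surface * s^2, tolerance = 1e-9)
  expect_equal(gs$total_volume, g1$total_volume * s^3, tolerance = 1e-9)
})

test_that("isotropic orientations are isotropic; axial mode is not", {
  reg <- reference_region("box", c(1000, 1000, 1000))
  net <- generate_network(reg, 9e-5, seed = 11, length_range = c(5, 10))
  u <- (net$p1 - net$p0)
  u <- u / sqrt(rowSums(u^2))
  n <- nrow(u)
  expect_gt(n, 1e4)
  # |cos| against any fixed axis has mean 1/2, sd 1/sqrt(12)
  for (ax in list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))) {
    m <- mean(abs(u %*% ax))
    expect_lt(abs(m - 0.5), 3 / sqrt(12 * n))
  }
  axial <- generate_network(reg, 1e-5, seed = 2, orientation = "axial")
  ua <- axial$p1 - axial$p0
  expect_true(all(abs(ua[, 1]) < 1e-12 & abs(ua[, 2]) < 1e-12))
})

test_that("no-overlap mode yields pairwise disjoint cylinders", {
  reg <- reference_region("box", c(400, 400, 400))
  net <- generate_network(reg, 2e-4, seed = 9, no_overlap = TRUE)
  n <- nrow(net$p0)
  expect_gt(n, 50)
  sdist <- stereovasc:::.seg_seg_dist
  ok <- TRUE
  for (i in seq_len(n - 1)) {
    d <- sdist(net$p0[i, ], net$p1[i, ],
               net$p0[(i + 1):n, , drop = FALSE],
               net$p1[(i + 1):n, , drop = FALSE])
    ok <- ok && all(d > net$radius[i] + net$radius[(i + 1):n])
  }
  expect_true(ok)
})

test_that("segment-segment distance agrees with dense enumeration", {
  sdist <- stereovasc:::.seg_seg_dist
  set.seed(42)
  worst <- 0
  for (k in 1:100) {
    a0 <- runif(3, -10, 10); a1 <- runif(3, -10, 10)
    B0 <- matrix(runif(9, -10, 10), 3, 3)
    B1 <- matrix(runif(9, -10, 10), 3, 3)
    d <- sdist(a0, a1, B0, B1)
    ts <- seq(0, 1, length.out = 120)
    for (i in 1:3) {
      Pa <- outer(ts, a1 - a0) + matrix(a0, 120, 3, byrow = TRUE)
      Pb <- outer(ts, B1[i, ] - B0[i, ]) + matrix(B0[i, ], 120, 3,
                                                  byrow = TRUE)
      dd <- min(sqrt(outer(rowSums(Pa^2), rowSums(Pb^2), "+") -
                       2 * Pa %*% t(Pb)))
      # enumeration overestimates the true minimum; bound the gap
      expect_gte(dd - d[i], -1e-8)
      worst <- max(worst, dd - d[i])
    }
  }
  expect_lt(worst, 0.05)  # enumeration granularity, not algorithm error
})

test_that("cohorts honour group distributions, degenerate SDs, and empty specs", {
  g0 <- cohort_spec(data.frame(label = character(0), n = integer(0),
                               lv_mean = numeric(0), lv_sd = numeric(0),
                               vol_mean = numeric(0), vol_sd = numeric(0)),
                    seed = 1)
  expect_length(generate_cohort(g0), 0)

  gd <- cohort_spec(data.frame(label = "g", n = 3, lv_mean = 2e-4,
                               lv_sd = 0, vol_mean = 1e8, vol_sd = 0),
                    seed = 2)
  coh <- generate_cohort(gd)
  expect_length(coh, 3)
  truths <- vapply(coh, function(a) c(a$truth$lv, a$truth$volume), numeric(2))
  expect_true(all(truths[1, ] == 2e-4) && all(truths[2, ] == 1e8))

  expect_error(cohort_spec(data.frame(label = "g", n = 1, lv_mean = 1,
                                      lv_sd = 0, vol_mean = 1, vol_sd = 0)),
               "n >= 2")
  expect_error(cohort_spec(data.frame(label = "g", n = 3, lv_mean = -1,
                                      lv_sd = 0, vol_mean = 1, vol_sd = 0)),
               "> 0")

  # calibrated three-group cohort: sample means of the truths within 3 SEM
  lv_means <- c(11.7e6 / 3.39e10, 9.67e6 / 2.92e10, 10.8e6 / 3.20e10)
  lv_sds <- lv_means * c(0.042, 0.055, 0.036)
  spec <- cohort_spec(data.frame(
    label = c("control", "standard", "running"), n = 10,
    lv_mean = lv_means, lv_sd = lv_sds,
    vol_mean = 1.25e8 * c(1, 0.86, 0.94), vol_sd = 1.1e7),
    seed = 33, length_range = c(50, 200))
  coh <- generate_cohort(spec)
  expect_length(coh, 30)
  for (g in 1:3) {
    lvs <- vapply(Filter(function(a) a$group == spec$groups$label[g], coh),
                  function(a) a$truth$lv, 1)
    expect_lt(abs(mean(lvs) - lv_means[g]), 3 * lv_sds[g] / sqrt(10))
    # the generated network realises the drawn truth
  }
  a1 <- coh[[1]]
  expect_equal(ground_truth(a1$network)$total_length,
               a1$truth$lv * a1$truth$volume,
               tolerance = 1e-6)
  expect_equal(region_volume(a1$network$region), a1$truth$volume,
               tolerance = 1e-9)
})

test_that("network JSON round-trips", {
  reg <- reference_region("ellipsoid", c(300, 250, 200))
  net <- generate_network(reg, 1e-4, seed = 13)
  path <- tempfile(fileext = ".json")
  write_network(net, path)
  back <- read_network(path)
  expect_equal(back$p0, net$p0, tolerance = 1e-12)
  expect_equal(back$p1, net$p1, tolerance = 1e-12)
  expect_equal(back$radius, net$radius, tolerance = 1e-12)
  expect_equal(back$region$dimensions, net$region$dimensions)
  expect_identical(back$seed, net$seed)
  unlink(path)
})

test_that("unreachable density fails loudly naming the achieved density", {
  reg <- reference_region("box", c(100, 100, 100))
  expect_error(
    generate_network(reg, 5e-2, seed = 1, no_overlap = TRUE,
                     max_tries = 200),
    "packing failure: achieved length density")
})
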