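test_that("cut_slabs partitions the extent with a uniform random phase", {
  reg <- reference_region("box", c(500, 500, 10000))  # extent 10 mm along z
  s0 <- cut_slabs(reg, 1000, offset = 0)
  expect_length(s0$faces, 10)
  s1 <- cut_slabs(reg, 1000, offset = 500)
  expect_length(s1$faces, 11)
  expect_equal(diff(s1$faces), rep(1000, 10), tolerance = 1e-12)
  expect_true(all(diff(s1$faces) > 0))
  s2 <- cut_slabs(reg, 1000, seed = 4)
  expect_identical(s2, cut_slabs(reg, 1000, seed = 4))
  expect_true(s2$offset >= 0 && s2$offset < 1000)
  expect_warning(cut_slabs(reference_region("sphere", 100), 300),
                 "single slab")
})

test_that("IUR planes are isotropic, uniform in position, deterministic", {
  reg <- reference_region("box", c(500, 400, 300))
  n <- 1e4
  set.seed(8)
  normals <- matrix(0, n, 3)
  pos_ok <- TRUE
  for (i in seq_len(n)) {
    pl <- iur_plane(reg)
    normals[i, ] <- pl$normal
    h <- region_support(reg, pl$normal)
    s <- sum(pl$normal * pl$point)
    pos_ok <- pos_ok && (abs(s) <= h)
  }
  expect_true(pos_ok)
  # CLT bound: |mean of n uniform-sphere vectors| ~ 1/sqrt(n)
  expect_lt(sqrt(sum(colMeans(normals)^2)), 3 / sqrt(n))
  # frame is orthonormal
  pl <- iur_plane(reg, seed = 5)
  expect_equal(sum(pl$normal^2), 1, tolerance = 1e-12)
  expect_equal(sum(pl$e1 * pl$e2), 0, tolerance = 1e-12)
  expect_equal(sum(pl$e1 * pl$normal), 0, tolerance = 1e-12)
  expect_equal(sum(pl$e1^2), 1, tolerance = 1e-12)
  expect_identical(pl, iur_plane(reg, seed = 5))
})

test_that("plane-cylinder profiles have the analytic ellipse axes", {
  reg <- reference_region("box", c(500, 500, 500))
  pl <- stereovasc:::.make_plane(c(0, 0, 1), c(0, 0, 0))
  # segment along the normal: circular profile
  net <- manual_network(reg, c(10, -20, -50), c(10, -20, 50), 2)
  pr <- section_network(net, pl)
  expect_equal(nrow(pr), 1)
  expect_equal(pr$semi_minor_um, 2, tolerance = 1e-12)
  expect_equal(pr$semi_major_um, 2, tolerance = 1e-12)
  centre3 <- pl$point + pr$cx_um * pl$e1 + pr$cy_um * pl$e2
  expect_equal(centre3, c(10, -20, 0), tolerance = 1e-9)

  # 60 degrees to the normal: semi-axes (2, 4)
  u <- c(sin(pi / 3), 0, cos(pi / 3))
  net <- manual_network(reg, -100 * u, 100 * u, 2)
  pr <- section_network(net, pl)
  expect_equal(pr$semi_minor_um, 2, tolerance = 1e-12)
  expect_equal(pr$semi_major_um, 4, tolerance = 1e-9)
  # numeric oracle: densely sample the cylinder surface, intersect with the
  # plane, and compare in-plane extents with the claimed ellipse
  th <- rep(seq(0, 2 * pi, length.out = 721)[-1], times = 801)
  zs <- rep(seq(-20, 20, length.out = 801), each = 720)
  e1 <- c(cos(pi / 3), 0, -sin(pi / 3))  # perp to u
  e2 <- c(0, 1, 0)
  surf <- outer(zs, u) + 2 * outer(cos(th), e1) + 2 * outer(sin(th), e2)
  surf <- surf[abs(surf[, 3]) < 0.05, 1:2, drop = FALSE]
  expect_gt(nrow(surf), 100)
  expect_lt(abs(max(surf[, 1]) - 4), 0.1)   # major axis along x
  expect_lt(abs(max(surf[, 2]) - 2), 0.1)   # minor axis along y

  # axis crossing outside the segment: no profile
  net <- manual_network(reg, c(0, 0, 10), c(0, 0, 50), 2)
  expect_equal(nrow(section_network(net, pl)), 0)
  # in-plane segment is skipped and logged
  net <- manual_network(reg, c(-50, 0, 0), c(50, 0, 0), 2)
  pr <- section_network(net, pl)
  expect_equal(nrow(pr), 0)
  expect_identical(attr(pr, "n_parallel_skipped"), 1L)
})

test_that("capillary filter is strict at the diameter threshold", {
  pr <- manual_profiles(c(0, 0, 0), c(0, 0, 0),
                        b = c(2, 6, 5), a = c(3, 7, 5), phi = 0)
  kept <- filter_capillary_profiles(pr, 10)
  expect_equal(kept$semi_minor_um, 2)      # 4 um kept, 12 um and exactly
  expect_equal(nrow(kept), 1)              # 10 um removed ("less than")
  pr2 <- manual_profiles(0, 0, 4.999, 5, 0)
  expect_equal(nrow(filter_capillary_profiles(pr2, 10)), 1)
})

test_that("section area, membership and chords agree with Monte-Carlo oracles", {
  set.seed(14)
  regions <- list(reference_region("box", c(500, 400, 300)),
                  reference_region("ellipsoid", c(300, 250, 200)),
                  reference_region("sphere", 250))
  for (reg in regions) {
    for (k in 1:3) {
      pl <- iur_plane(reg)
      bb <- section_bbox(reg, pl)
      area_bb <- diff(bb[1, ]) * diff(bb[2, ])
      pts <- cbind(runif(4e4, bb[1, 1], bb[1, 2]),
                   runif(4e4, bb[2, 1], bb[2, 2]))
      inside <- section_contains(reg, pl, pts)
      a_mc <- mean(inside) * area_bb
      a_an <- section_area(reg, pl)
      se <- sqrt(mean(inside) * (1 - mean(inside)) / 4e4) * area_bb
      expect_lt(abs(a_mc - a_an), 4 * se + 1e-9)
      # chord against membership along a random in-plane line
      phi <- runif(1, 0, pi)
      dvec <- c(cos(phi), sin(phi))
      u0 <- c(runif(1, bb[1, 1], bb[1, 2]), runif(1, bb[2, 1], bb[2, 2]))
      ch <- section_chord(reg, pl, u0, dvec)
      ts <- seq(-4 * max(abs(bb)), 4 * max(abs(bb)), length.out = 8000)
      on <- section_contains(reg, pl,
                             cbind(u0[1] + ts * dvec[1],
                                   u0[2] + ts * dvec[2]))
      if (is.null(ch)) {
        expect_lt(sum(on), 3)  # at most grazing
      } else {
        step <- diff(ts)[1]
        expect_lt(abs(sum(on) * step - diff(ch)), 3 * step)
      }
    }
  }
  # sphere closed form
  sph <- reference_region("sphere", 300)
  pl <- iur_plane(sph, seed = 2)
  d <- abs(sum(pl$normal * pl$point))
  expect_equal(section_area(sph, pl), pi * (300^2 - d^2), tolerance = 1e-9)
})

test_that("sectioning a rotated network with rotated planes is congruent", {
  reg <- reference_region("sphere", 300)
  net <- generate_network(reg, 2e-4, seed = 17)
  # rotation by 90 degrees about z: (x, y, z) -> (-y, x, z)
  rot <- function(m) cbind(-m[, 2], m[, 1], m[, 3])
  netr <- manual_network(reg, rot(net$p0), rot(net$p1), net$radius)
  pl <- iur_plane(reg, seed = 23)
  plr <- structure(list(normal = as.vector(rot(matrix(pl$normal, 1))),
                        point = as.vector(rot(matrix(pl$point, 1))),
                        e1 = as.vector(rot(matrix(pl$e1, 1))),
                        e2 = as.vector(rot(matrix(pl$e2, 1)))),
                   class = "section_plane")
  a <- section_network(net, pl)
  b <- section_network(netr, plr)
  expect_equal(nrow(a), nrow(b))
  expect_equal(a$cx_um, b$cx_um, tolerance = 1e-9)
  expect_equal(a$cy_um, b$cy_um, tolerance = 1e-9)
  expect_equal(a$semi_major_um, b$semi_major_um, tolerance = 1e-9)
})

test_that("transect rate on IUR planes matches L_V / 2 (the basis of the length formula)", {
  reg <- reference_region("sphere", 300)
  net <- generate_network(reg, 3e-4, seed = 19)
  gt <- ground_truth(net)
  set.seed(20)
  n <- 400
  Q <- A <- numeric(n)
  for (j in seq_len(n)) {
    pl <- iur_plane(reg)
    Q[j] <- nrow(section_network(net, pl))
    A[j] <- section_area(reg, pl)
  }
  r <- ratio_se(Q, A)
  expect_lt(abs(r$theta - gt$length_density / 2), 3 * r$se)
})

test_that("rasterize is geometrically faithful", {
  expect_true(all(rasterize(manual_profiles(numeric(0), numeric(0),
                                            numeric(0), numeric(0),
                                            numeric(0)),
                            50, 0.5) == 0L))
  pr <- manual_profiles(0, 0, 2, 2, 0)
  img <- rasterize(pr, 20, 0.1)
  expect_lt(abs(sum(img) - pi * 20^2) / (pi * 20^2), 0.02)
  expect_error(rasterize(pr, 0, 0.1), "positive")
  # raster and vector point counts agree at fine resolution
  set.seed(3)
  prs <- random_profiles(12, lo = -20, hi = 20, rmax = 3)
  img <- rasterize(prs, 60, 0.2)
  # offset 0.1 puts every test point exactly on a pixel centre, so raster
  # and vector membership must agree exactly
  grid <- point_grid(3, offset = c(0.1, 0.1))
  bbox <- rbind(c(-30, 30), c(-30, 30))
  expect_equal(count_point_hits(img, grid),
               count_point_hits(prs, grid, bbox))
})
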