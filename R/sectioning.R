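#' @title Virtual microtome
#' @description Cavalieri slab stacks, isotropic uniform random (IUR)
#'   section planes, plane-cylinder intersection profiles, and the in-plane
#'   geometry of the region cross-section (area, membership, line chords).
#' @name sectioning
NULL

# orthonormal in-plane basis perpendicular to a unit normal
.plane_basis <- function(normal) {
  a <- if (abs(normal[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- c(a[2] * normal[3] - a[3] * normal[2],
          a[3] * normal[1] - a[1] * normal[3],
          a[1] * normal[2] - a[2] * normal[1])
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(normal[2] * e1[3] - normal[3] * e1[2],
          normal[3] * e1[1] - normal[1] * e1[3],
          normal[1] * e1[2] - normal[2] * e1[1])
  list(e1 = e1, e2 = e2)
}

.make_plane <- function(normal, point, psi = 0) {
  b <- .plane_basis(normal)
  e1 <- cos(psi) * b$e1 + sin(psi) * b$e2
  e2 <- -sin(psi) * b$e1 + cos(psi) * b$e2
  structure(list(normal = normal, point = point, e1 = e1, e2 = e2),
            class = "section_plane")
}

#' Cavalieri slab stack
#'
#' Partitions the region's extent along `axis` into consecutive slabs of
#' thickness `t` with a uniform random phase in `[0, t)`, the randomization
#' required for an unbiased Cavalieri volume estimate. The returned `faces`
#' are the cut-plane positions (one per slab, at the upper face).
#'
#' @param region A [reference_region()].
#' @param t Slab thickness, um.
#' @param axis Cutting axis (3-vector, normalised internally).
#' @param offset Optional fixed phase in `[0, t)`; drawn uniformly if `NULL`.
#' @param seed Optional seed for the phase draw.
#' @return A `slab_stack`: list with `axis`, `t`, `offset`, `faces`,
#'   `lo`, `hi`.
#' @export
cut_slabs <- function(region, t, axis = c(0, 0, 1), offset = NULL,
                      seed = NULL) {
  stopifnot(t > 0)
  axis <- axis / sqrt(sum(axis^2))
  h <- region_support(region, axis)
  extent <- 2 * h
  if (t >= extent) warning("slab thickness >= region extent: single slab")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(offset)) offset <- stats::runif(1, 0, t)
  stopifnot(offset >= 0, offset < t)
  n <- ceiling((extent + offset) / t)
  faces <- -h - offset + t * seq_len(n)
  structure(list(axis = axis, t = t, offset = offset, faces = faces,
                 lo = -h, hi = h),
            class = "slab_stack")
}

#' Draw an isotropic uniform random section plane
#'
#' The plane normal is uniform on the unit sphere (area-uniform), the plane
#' position is uniform over the region's support interval along the normal,
#' and the in-plane frame carries an extra uniform rotation. This is the
#' mathematical target of physical IUR sectioning techniques (isector /
#' sector randomization).
#'
#' @param region A [reference_region()].
#' @param seed Optional integer seed; omit to consume the current RNG stream.
#' @return A `section_plane`: unit `normal`, `point` on the plane, and an
#'   orthonormal in-plane basis `e1`, `e2`.
#' @export
iur_plane <- function(region, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  normal <- as.vector(.runif_sphere(1))
  h <- region_support(region, normal)
  s <- stats::runif(1, -h, h)
  psi <- stats::runif(1, 0, 2 * pi)
  .make_plane(normal, s * normal, psi)
}

#' Cut a network with a section plane
#'
#' Emits one elliptical profile per segment whose axis crosses the plane
#' within the segment's length: semi-minor axis equal to the cylinder
#' radius, semi-major axis r / |cos theta| with theta the angle between the
#' segment axis and the plane normal (the exact plane-cylinder intersection
#' for a full transect). Segments lying in the plane (|cos theta| below
#' `parallel_eps`) are skipped; their count is recorded in the
#' `n_parallel_skipped` attribute.
#'
#' @param network A `capillary_network`.
#' @param plane A `section_plane`.
#' @param parallel_eps Tolerance on |cos theta| for "parallel to plane".
#' @return A data frame (class `profile_set`) with columns `profile_id`,
#'   `cx_um`, `cy_um` (in-plane coordinates, origin at `plane$point`),
#'   `semi_minor_um`, `semi_major_um`, `angle_rad` (major-axis direction),
#'   `cos_theta`, `segment_id`.
#' @export
section_network <- function(network, plane, parallel_eps = 1e-9) {
  stopifnot(inherits(network, "capillary_network"),
            inherits(plane, "section_plane"))
  empty <- data.frame(
    profile_id = integer(0), cx_um = numeric(0), cy_um = numeric(0),
    semi_minor_um = numeric(0), semi_major_um = numeric(0),
    angle_rad = numeric(0), cos_theta = numeric(0), segment_id = integer(0)
  )
  if (nrow(network$p0) == 0) {
    return(structure(empty, class = c("profile_set", "data.frame"),
                     n_parallel_skipped = 0L))
  }
  d <- network$p1 - network$p0
  len <- sqrt(rowSums(d^2))
  u <- d / len
  denom <- as.vector(d %*% plane$normal)
  cosab <- abs(as.vector(u %*% plane$normal))
  rel <- as.vector((matrix(plane$point, nrow(d), 3, byrow = TRUE) -
                      network$p0) %*% plane$normal)
  tpar <- ifelse(abs(denom) > 0, rel / denom, Inf)
  crossing <- cosab >= parallel_eps & tpar >= 0 & tpar <= 1
  n_par <- sum(cosab < parallel_eps & abs(rel) <= network$radius)  # in-plane
  idx <- which(crossing)
  if (length(idx) == 0) {
    return(structure(empty, class = c("profile_set", "data.frame"),
                     n_parallel_skipped = as.integer(n_par)))
  }
  centre3 <- network$p0[idx, , drop = FALSE] + d[idx, , drop = FALSE] * tpar[idx]
  relc <- centre3 - matrix(plane$point, length(idx), 3, byrow = TRUE)
  cx <- as.vector(relc %*% plane$e1)
  cy <- as.vector(relc %*% plane$e2)
  # major-axis direction: projection of the segment axis into the plane
  proj1 <- as.vector(u[idx, , drop = FALSE] %*% plane$e1)
  proj2 <- as.vector(u[idx, , drop = FALSE] %*% plane$e2)
  ang <- ifelse(proj1 == 0 & proj2 == 0, 0, atan2(proj2, proj1))
  out <- data.frame(
    profile_id = seq_along(idx),
    cx_um = cx, cy_um = cy,
    semi_minor_um = network$radius[idx],
    semi_major_um = network$radius[idx] / cosab[idx],
    angle_rad = ang,
    cos_theta = cosab[idx],
    segment_id = idx
  )
  structure(out, class = c("profile_set", "data.frame"),
            n_parallel_skipped = as.integer(n_par))
}

#' Keep only capillary-sized profiles
#'
#' Applies the capillary criterion: a vessel profile belongs to the
#' capillary network if its true diameter (twice the semi-minor axis, which
#' equals the cylinder diameter regardless of obliquity) is strictly less
#' than `max_diameter_um`. A profile of diameter exactly 10 um is excluded.
#'
#' @param profiles A `profile_set`.
#' @param max_diameter_um Threshold, um (default 10).
#' @return The filtered `profile_set`, order preserved.
#' @export
filter_capillary_profiles <- function(profiles, max_diameter_um = 10) {
  stopifnot(max_diameter_um > 0)
  keep <- 2 * profiles$semi_minor_um < max_diameter_um
  out <- profiles[keep, , drop = FALSE]
  structure(out, class = c("profile_set", "data.frame"),
            n_parallel_skipped = attr(profiles, "n_parallel_skipped"))
}

# ---- in-plane geometry of the region cross-section ----------------------

# quadratic form of an ellipsoid/sphere section: u' Q u + 2 b.u + c0 <= 0
.section_quadric <- function(region, plane) {
  semi <- .region_semi(region)
  Dm <- diag(1 / semi^2)
  E <- cbind(plane$e1, plane$e2)
  Q <- t(E) %*% Dm %*% E
  b <- as.vector(t(E) %*% Dm %*% plane$point)
  c0 <- sum(plane$point * (Dm %*% plane$point)) - 1
  list(Q = Q, b = b, c0 = c0)
}

# clip a convex polygon by half-plane a.u <= c (Sutherland-Hodgman step)
.clip_halfplane <- function(poly, a, cc) {
  if (nrow(poly) == 0) return(poly)
  v <- as.vector(poly %*% a) - cc
  n <- nrow(poly)
  out <- matrix(numeric(0), 0, 2)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    vi <- v[i]; vj <- v[j]
    if (vi <= 0) out <- rbind(out, poly[i, ])
    if ((vi < 0 && vj > 0) || (vi > 0 && vj < 0)) {
      t <- vi / (vi - vj)
      out <- rbind(out, poly[i, ] + t * (poly[j, ] - poly[i, ]))
    }
  }
  out
}

# box section as a convex polygon in plane coordinates (possibly empty)
.section_polygon <- function(region, plane) {
  semi <- region$dimensions / 2
  E <- cbind(plane$e1, plane$e2)
  R <- sqrt(sum(semi^2)) + sqrt(sum(plane$point^2)) + 1
  poly <- rbind(c(-R, -R), c(R, -R), c(R, R), c(-R, R))
  for (i in 1:3) {
    a <- E[i, ]
    poly <- .clip_halfplane(poly, a, semi[i] - plane$point[i])
    poly <- .clip_halfplane(poly, -a, semi[i] + plane$point[i])
    if (nrow(poly) == 0) break
  }
  poly
}

.polygon_area <- function(poly) {
  n <- nrow(poly)
  if (n < 3) return(0)
  j <- c(2:n, 1)
  abs(sum(poly[, 1] * poly[j, 2] - poly[j, 1] * poly[, 2])) / 2
}

#' Area of the region cross-section on a plane
#'
#' Closed form: polygon clipping for a box, conic algebra for sphere and
#' ellipsoid sections. This is the reference area `sum A` denominator that
#' an exhaustive tiling of counting frames over the section would sample.
#'
#' @param region A [reference_region()].
#' @param plane A `section_plane`.
#' @return Area in um^2 (0 if the plane misses the region).
#' @export
section_area <- function(region, plane) {
  if (region$shape == "box") {
    return(.polygon_area(.section_polygon(region, plane)))
  }
  q <- .section_quadric(region, plane)
  k <- sum(q$b * solve(q$Q, q$b)) - q$c0
  if (k <= 0) return(0)
  pi * k / sqrt(det(q$Q))
}

#' Membership of in-plane points in the region cross-section
#'
#' @param region A [reference_region()].
#' @param plane A `section_plane`.
#' @param U n x 2 matrix of in-plane coordinates (um).
#' @return Logical vector.
#' @export
section_contains <- function(region, plane, U) {
  if (is.null(dim(U))) U <- matrix(U, ncol = 2)
  X <- matrix(plane$point, nrow(U), 3, byrow = TRUE) +
    outer(U[, 1], plane$e1) + outer(U[, 2], plane$e2)
  region_contains(region, X)
}

#' In-plane bounding box of the region cross-section
#'
#' Exact support-function bounds of the section in plane coordinates.
#'
#' @param region A [reference_region()].
#' @param plane A `section_plane`.
#' @return 2 x 2 matrix, rows = in-plane axes, columns `min`, `max`.
#' @export
section_bbox <- function(region, plane) {
  h1 <- region_support(region, plane$e1)
  h2 <- region_support(region, plane$e2)
  p1 <- sum(plane$point * plane$e1)
  p2 <- sum(plane$point * plane$e2)
  rbind(c(-h1 - p1, h1 - p1), c(-h2 - p2, h2 - p2))
}

#' Chord of an in-plane line inside the region cross-section
#'
#' For the line `u0 + t * dvec` (in-plane coordinates, `dvec` unit), returns
#' the parameter interval `c(t_enter, t_exit)` lying inside the region, or
#' `NULL` if the line misses it. Used to measure test-line length within the
#' reference space.
#'
#' @param region A [reference_region()].
#' @param plane A `section_plane`.
#' @param u0 In-plane base point (2-vector, um).
#' @param dvec In-plane unit direction (2-vector).
#' @return Numeric length-2 vector or `NULL`.
#' @export
section_chord <- function(region, plane, u0, dvec) {
  P0 <- plane$point + u0[1] * plane$e1 + u0[2] * plane$e2
  D3 <- dvec[1] * plane$e1 + dvec[2] * plane$e2
  if (region$shape == "box") {
    semi <- region$dimensions / 2
    t0 <- -Inf; t1 <- Inf
    for (i in 1:3) {
      if (abs(D3[i]) < 1e-15) {
        if (abs(P0[i]) > semi[i]) return(NULL)
      } else {
        ta <- (-semi[i] - P0[i]) / D3[i]
        tb <- (semi[i] - P0[i]) / D3[i]
        t0 <- max(t0, min(ta, tb))
        t1 <- min(t1, max(ta, tb))
      }
    }
    if (t0 >= t1) return(NULL)
    return(c(t0, t1))
  }
  semi <- .region_semi(region)
  a <- sum((D3 / semi)^2)
  b <- 2 * sum(P0 * D3 / semi^2)
  cc <- sum((P0 / semi)^2) - 1
  disc <- b^2 - 4 * a * cc
  if (disc <= 0) return(NULL)
  s <- sqrt(disc)
  c((-b - s) / (2 * a), (-b + s) / (2 * a))
}

# ---- raster output -------------------------------------------------------

#' Rasterize profiles to a binary label image
#'
#' Pixel-centre sampling on a field centred at the in-plane origin; row
#' major, origin top-left (row 1 is the top of the field). Intended for
#' visual QC and raster-mode probe fixtures.
#'
#' @param profiles A `profile_set`.
#' @param field_um Field size: scalar (square) or `c(width, height)`, um.
#' @param resolution_um Pixel size, um/pixel.
#' @return Integer 0/1 matrix with attributes `resolution_um` and
#'   `origin_um` (in-plane coordinates of the top-left pixel corner).
#' @export
rasterize <- function(profiles, field_um, resolution_um) {
  stopifnot(resolution_um > 0)
  if (length(field_um) == 1) field_um <- c(field_um, field_um)
  if (any(field_um <= 0)) stop("field size must be positive")
  nx <- max(1L, as.integer(round(field_um[1] / resolution_um)))
  ny <- max(1L, as.integer(round(field_um[2] / resolution_um)))
  x0 <- -field_um[1] / 2
  y_top <- field_um[2] / 2
  xs <- x0 + (seq_len(nx) - 0.5) * resolution_um
  ys <- y_top - (seq_len(ny) - 0.5) * resolution_um
  img <- matrix(0L, nrow = ny, ncol = nx)
  if (nrow(profiles) > 0) {
    pts <- cbind(rep(xs, each = ny), rep(ys, times = nx))
    hit <- .points_in_profiles(profiles, pts)
    img[matrix(hit, nrow = ny)] <- 1L
  }
  attr(img, "resolution_um") <- resolution_um
  attr(img, "origin_um") <- c(x0, y_top)
  img
}

#' Write a profile table as CSV
#'
#' @param profiles A `profile_set` (or several rbind-ed ones).
#' @param path Output CSV path.
#' @param section_id Section identifier recycled across rows.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path, section_id = 1L) {
  df <- as.data.frame(profiles)
  df <- cbind(section_id = section_id, df)
  df$cos_theta <- NULL
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a binary label image as plain-text PGM (P2)
#'
#' A text-only raster format readable by standard image tools; the
#' um-per-pixel metadata travels in a JSON sidecar.
#'
#' @param img Matrix from [rasterize()].
#' @param path Output file (".pgm"); sidecar written to "<path>.json".
#' @return `path`, invisibly.
#' @export
write_raster_pgm <- function(img, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(img), nrow(img)), "1"), con)
  write(t(img), con, ncolumns = ncol(img))
  jsonlite::write_json(
    list(resolution_um = attr(img, "resolution_um"),
         origin_um = attr(img, "origin_um")),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
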