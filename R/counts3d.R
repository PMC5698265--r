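#' @title Exact section counting against the 3D phantom
#' @description The pipeline counts on virtual sections by testing probe
#'   points and lines against the 3D cylinders themselves rather than
#'   against idealized full profile ellipses. Near segment ends an oblique
#'   cut is a truncated ellipse; the full-ellipse idealization would
#'   overstate capillary area and boundary (severely so for near-parallel
#'   cuts), while the 3D tests reproduce exactly what a microscopist sees
#'   on the section. Transect counting (Q) is unaffected: a transect exists
#'   iff the axis crossing lies within the segment.
#' @name counts3d
NULL

# signed distance of each segment's closest axis point to the plane
.segment_plane_gap <- function(network, plane) {
  if (nrow(network$p0) == 0) return(numeric(0))
  d0 <- as.vector((network$p0 - matrix(plane$point, nrow(network$p0), 3,
                                       byrow = TRUE)) %*% plane$normal)
  d1 <- as.vector((network$p1 - matrix(plane$point, nrow(network$p1), 3,
                                       byrow = TRUE)) %*% plane$normal)
  ifelse(d0 * d1 <= 0, 0, pmin(abs(d0), abs(d1)))
}

# 2D point-to-segment distance, vectorised over points
.dist_pts_seg2 <- function(pts, a, b) {
  ab <- b - a
  den <- sum(ab^2)
  if (den < 1e-300) {
    return(sqrt((pts[, 1] - a[1])^2 + (pts[, 2] - a[2])^2))
  }
  t <- ((pts[, 1] - a[1]) * ab[1] + (pts[, 2] - a[2]) * ab[2]) / den
  t <- pmin(pmax(t, 0), 1)
  dx <- pts[, 1] - (a[1] + t * ab[1])
  dy <- pts[, 2] - (a[2] + t * ab[2])
  sqrt(dx^2 + dy^2)
}

#' Full counting summary of one IUR section
#'
#' Applies the whole probe battery to one section of a phantom: profile
#' transects (Q) against the reference section area (A), point-grid hits in
#' the capillary phase (P_cap) versus the reference phase (P_ref), and
#' test-line intersections with the capillary surface (I) along the
#' in-region test line length (L). Counting is exhaustive over the whole
#' cross-section, i.e. the limit of a complete unbiased-frame tiling, so A
#' is the analytic section area. Probe offsets and rotations are drawn from
#' the current RNG stream.
#'
#' @param network A `capillary_network`.
#' @param plane A `section_plane`.
#' @param point_spacing_um Point grid spacing, um.
#' @param line_spacing_um Test line spacing, um.
#' @param max_diameter_um Capillary criterion: only cylinders with diameter
#'   strictly below this threshold are counted as capillary phase.
#' @return List with `Q`, `A_um2`, `P_cap`, `P_ref`, `I`, `L_um`.
#' @export
section_counts <- function(network, plane, point_spacing_um,
                           line_spacing_um, max_diameter_um = 10) {
  region <- network$region
  A <- section_area(region, plane)
  bbox <- section_bbox(region, plane)
  cap <- 2 * network$radius < max_diameter_um

  profiles <- section_network(network, plane)
  profiles <- filter_capillary_profiles(profiles, max_diameter_um)
  Q <- nrow(profiles)

  # candidate capillary cylinders touching the plane
  gap <- .segment_plane_gap(network, plane)
  cand <- which(cap & gap <= network$radius + 1e-9)
  u3 <- network$p1 - network$p0
  seglen <- sqrt(rowSums(u3^2))
  u3 <- u3 / seglen
  P <- matrix(plane$point, 1, 3)
  a2 <- cbind(as.vector((network$p0 - P[rep(1, nrow(network$p0)), ]) %*%
                          plane$e1),
              as.vector((network$p0 - P[rep(1, nrow(network$p0)), ]) %*%
                          plane$e2))
  b2 <- cbind(as.vector((network$p1 - P[rep(1, nrow(network$p1)), ]) %*%
                          plane$e1),
              as.vector((network$p1 - P[rep(1, nrow(network$p1)), ]) %*%
                          plane$e2))

  # point grid
  pgrid <- point_grid(point_spacing_um)
  pts <- grid_points(pgrid, bbox)
  P_ref <- if (nrow(pts) > 0) sum(section_contains(region, plane, pts)) else 0L
  hit <- rep(FALSE, nrow(pts))
  if (nrow(pts) > 0 && length(cand) > 0) {
    X3 <- matrix(plane$point, nrow(pts), 3, byrow = TRUE) +
      outer(pts[, 1], plane$e1) + outer(pts[, 2], plane$e2)
    for (i in cand) {
      r <- network$radius[i]
      near <- which(!hit &
                      .dist_pts_seg2(pts, a2[i, ], b2[i, ]) <= r + 1e-9)
      if (length(near) == 0) next
      w <- X3[near, , drop = FALSE] -
        matrix(network$p0[i, ], length(near), 3, byrow = TRUE)
      ax <- as.vector(w %*% u3[i, ])
      rad2 <- rowSums(w^2) - ax^2
      hit[near] <- ax >= 0 & ax <= seglen[i] & rad2 <= r^2 + 1e-9
    }
  }
  P_cap <- sum(hit)

  # line grid: crossings with cylinder lateral surfaces in 3D
  lgrid <- line_grid(line_spacing_um, rotation_rad = stats::runif(1, 0, pi))
  gl <- grid_lines(lgrid, bbox)
  I <- 0L
  L <- 0
  for (ln in gl) {
    chord <- section_chord(region, plane, ln$base, ln$dvec)
    if (is.null(chord)) next
    L <- L + diff(chord)
    if (length(cand) == 0) next
    o3 <- plane$point + ln$base[1] * plane$e1 + ln$base[2] * plane$e2
    d3 <- ln$dvec[1] * plane$e1 + ln$dvec[2] * plane$e2
    w <- matrix(o3, length(cand), 3, byrow = TRUE) -
      network$p0[cand, , drop = FALSE]
    du <- as.vector(u3[cand, , drop = FALSE] %*% d3)
    wu <- rowSums(w * u3[cand, , drop = FALSE])
    aa <- 1 - du^2
    bb <- 2 * (as.vector(w %*% d3) - wu * du)
    cc <- rowSums(w^2) - wu^2 - network$radius[cand]^2
    disc <- bb^2 - 4 * aa * cc
    ok <- which(aa > 1e-12 & disc > 0)
    for (k in ok) {
      s <- sqrt(disc[k])
      for (t in c((-bb[k] - s) / (2 * aa[k]), (-bb[k] + s) / (2 * aa[k]))) {
        if (t >= chord[1] && t <= chord[2]) {
          axp <- wu[k] + t * du[k]
          if (axp >= 0 && axp <= seglen[cand[k]]) I <- I + 1L
        }
      }
    }
  }
  list(Q = as.integer(Q), A_um2 = A, P_cap = as.integer(P_cap),
       P_ref = as.integer(P_ref), I = as.integer(I), L_um = L)
}

#' Cavalieri point counts over a slab stack
#'
#' For each slab face, lays a fresh uniformly offset point grid over the
#' face and counts points hitting the region cross-section (boundary
#' contact counts). Offsets are drawn from the current RNG stream.
#'
#' @param region A [reference_region()].
#' @param slabs A `slab_stack` from [cut_slabs()].
#' @param spacing_um Point grid spacing, um.
#' @return Integer vector of per-slab counts.
#' @export
cavalieri_point_counts <- function(region, slabs, spacing_um) {
  counts <- integer(length(slabs$faces))
  for (k in seq_along(slabs$faces)) {
    plane <- .make_plane(slabs$axis, slabs$faces[k] * slabs$axis)
    bbox <- section_bbox(region, plane)
    if (any(!is.finite(bbox)) || bbox[1, 1] >= bbox[1, 2]) next
    grid <- point_grid(spacing_um)
    pts <- grid_points(grid, bbox)
    counts[k] <- if (nrow(pts) > 0) {
      sum(section_contains(region, plane, pts))
    } else 0L
  }
  counts
}
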