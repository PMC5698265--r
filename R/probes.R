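#' @title Geometric test systems
#' @description Point grids, unbiased counting frames and test line grids
#'   with the classical stereological counting rules, applied to vector
#'   profile sets or to binary label images. Boundary ties always count as
#'   hits; the unbiased-frame rule uses two inclusion edges (top, right) and
#'   two forbidden edges (left, bottom) with their infinite extensions.
#' @name probes
NULL

.rot2 <- function(phi) {
  matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2, 2)
}

# inverse shape matrix M of an ellipse: (p-c)' M (p-c) <= 1
.ellipse_M <- function(a, b, phi) {
  R <- .rot2(phi)
  R %*% diag(c(1 / a^2, 1 / b^2)) %*% t(R)
}

# membership of 2D points in the union of profile ellipses (boundary counts)
.points_in_profiles <- function(profiles, pts) {
  hit <- rep(FALSE, nrow(pts))
  tol <- 1e-12
  for (i in seq_len(nrow(profiles))) {
    a <- profiles$semi_major_um[i]
    b <- profiles$semi_minor_um[i]
    phi <- profiles$angle_rad[i]
    cx <- profiles$cx_um[i]; cy <- profiles$cy_um[i]
    ex <- sqrt((a * cos(phi))^2 + (b * sin(phi))^2)
    ey <- sqrt((a * sin(phi))^2 + (b * cos(phi))^2)
    cand <- which(!hit & abs(pts[, 1] - cx) <= ex + tol &
                    abs(pts[, 2] - cy) <= ey + tol)
    if (length(cand) == 0) next
    dx <- pts[cand, 1] - cx
    dy <- pts[cand, 2] - cy
    xp <- dx * cos(phi) + dy * sin(phi)
    yp <- -dx * sin(phi) + dy * cos(phi)
    hit[cand] <- (xp / a)^2 + (yp / b)^2 <= 1 + tol
  }
  hit
}

#' Point grid probe
#'
#' A square lattice of test points with spacing `u`; each point carries an
#' associated area a(p) = u^2. A uniform random offset within one unit cell
#' (and optionally a random rotation) makes point counting unbiased.
#'
#' @param spacing_um Lattice spacing u, um.
#' @param offset 2-vector in `[0, u)^2`, drawn uniformly if `NULL`.
#' @param rotation_rad Grid rotation.
#' @param seed Optional seed for the offset draw.
#' @return A `point_grid` list with `spacing_um`, `a_p_um2`, `offset`,
#'   `rotation_rad`.
#' @export
point_grid <- function(spacing_um, offset = NULL, rotation_rad = 0,
                       seed = NULL) {
  stopifnot(spacing_um > 0)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(offset)) offset <- stats::runif(2, 0, spacing_um)
  structure(list(spacing_um = spacing_um, a_p_um2 = spacing_um^2,
                 offset = offset, rotation_rad = rotation_rad),
            class = "point_grid")
}

#' Realise the test points of a grid over a bounding box
#'
#' @param grid A [point_grid()].
#' @param bbox 2 x 2 matrix (rows = axes, cols = min/max), um.
#' @return n x 2 matrix of point coordinates.
#' @export
grid_points <- function(grid, bbox) {
  u <- grid$spacing_um
  R <- .rot2(grid$rotation_rad)
  corners <- cbind(bbox[1, c(1, 2, 2, 1)], bbox[2, c(1, 1, 2, 2)])
  local <- corners %*% R  # rotate corners into grid frame (R^-1 = t(R))
  kx <- seq(floor((min(local[, 1]) - grid$offset[1]) / u) - 1,
            ceiling((max(local[, 1]) - grid$offset[1]) / u) + 1)
  ky <- seq(floor((min(local[, 2]) - grid$offset[2]) / u) - 1,
            ceiling((max(local[, 2]) - grid$offset[2]) / u) + 1)
  gx <- grid$offset[1] + u * kx
  gy <- grid$offset[2] + u * ky
  pts <- cbind(rep(gx, times = length(gy)), rep(gy, each = length(gx)))
  pts <- pts %*% t(R)
  keep <- pts[, 1] >= bbox[1, 1] & pts[, 1] <= bbox[1, 2] &
    pts[, 2] >= bbox[2, 1] & pts[, 2] <= bbox[2, 2]
  pts[keep, , drop = FALSE]
}

#' Count test-point hits
#'
#' A point hits the capillary phase iff it lies inside (or on the boundary
#' of) a profile ellipse. In raster mode `x` is a 0/1 label image from
#' [rasterize()] and a point hits iff its pixel is labelled.
#'
#' @param x A `profile_set` or a raster matrix from [rasterize()].
#' @param grid A [point_grid()].
#' @param bbox Field bounding box (2 x 2); for raster input defaults to the
#'   image extent.
#' @return Integer hit count.
#' @export
count_point_hits <- function(x, grid, bbox = NULL) {
  if (is.matrix(x) && !is.data.frame(x)) {
    res <- attr(x, "resolution_um")
    org <- attr(x, "origin_um")
    if (is.null(res) || is.null(org)) stop("raster lacks geometry attributes")
    if (is.null(bbox)) {
      bbox <- rbind(c(org[1], org[1] + ncol(x) * res),
                    c(org[2] - nrow(x) * res, org[2]))
    }
    pts <- grid_points(grid, bbox)
    col <- floor((pts[, 1] - org[1]) / res) + 1
    row <- floor((org[2] - pts[, 2]) / res) + 1
    ok <- col >= 1 & col <= ncol(x) & row >= 1 & row <= nrow(x)
    return(sum(x[cbind(row[ok], col[ok])] == 1L))
  }
  stopifnot(!is.null(bbox))
  pts <- grid_points(grid, bbox)
  if (nrow(pts) == 0 || nrow(x) == 0) return(0L)
  sum(.points_in_profiles(x, pts))
}

# ---- unbiased counting frame --------------------------------------------

#' Unbiased counting frame
#'
#' A rectangle with inclusion edges (top and right) and forbidden edges
#' (left and bottom) extended to infinity above the top-left corner and
#' below the bottom-right corner. With the Gundersen rule, tiling the plane
#' with such frames counts every bounded convex profile exactly once.
#'
#' @param width_um,height_um Frame dimensions, um.
#' @param origin Bottom-left corner `c(x0, y0)`, um.
#' @return A `counting_frame` list.
#' @export
counting_frame <- function(width_um, height_um, origin = c(0, 0)) {
  stopifnot(width_um > 0, height_um > 0)
  structure(list(x0 = origin[1], y0 = origin[2],
                 w = width_um, h = height_um,
                 area_um2 = width_um * height_um),
            class = "counting_frame")
}

# does ellipse i of `profiles` meet the closed vertical segment
# {x} x [ylo, yhi] (tangency counts)?
.ellipse_meets_vseg <- function(prof, x, ylo, yhi) {
  a <- prof$semi_major_um; b <- prof$semi_minor_um; phi <- prof$angle_rad
  M <- .ellipse_M(a, b, phi)
  dx <- x - prof$cx_um
  A <- M[2, 2]
  B <- 2 * M[1, 2] * dx
  C <- M[1, 1] * dx^2 - 1
  disc <- B^2 - 4 * A * C
  tol <- 1e-12 * max(1, B^2, abs(4 * A * C))
  if (disc < -tol) return(FALSE)
  disc <- max(disc, 0)
  r1 <- (-B - sqrt(disc)) / (2 * A) + prof$cy_um
  r2 <- (-B + sqrt(disc)) / (2 * A) + prof$cy_um
  r1 <= yhi & r2 >= ylo
}

.ellipse_meets_hseg <- function(prof, y, xlo, xhi) {
  a <- prof$semi_major_um; b <- prof$semi_minor_um; phi <- prof$angle_rad
  M <- .ellipse_M(a, b, phi)
  dy <- y - prof$cy_um
  A <- M[1, 1]
  B <- 2 * M[1, 2] * dy
  C <- M[2, 2] * dy^2 - 1
  disc <- B^2 - 4 * A * C
  tol <- 1e-12 * max(1, B^2, abs(4 * A * C))
  if (disc < -tol) return(FALSE)
  disc <- max(disc, 0)
  r1 <- (-B - sqrt(disc)) / (2 * A) + prof$cx_um
  r2 <- (-B + sqrt(disc)) / (2 * A) + prof$cx_um
  r1 <= xhi & r2 >= xlo
}

# ellipse vs closed rectangle overlap
.ellipse_meets_rect <- function(prof, x0, y0, x1, y1) {
  cx <- prof$cx_um; cy <- prof$cy_um
  if (cx >= x0 && cx <= x1 && cy >= y0 && cy <= y1) return(TRUE)
  if (.ellipse_meets_vseg(prof, x0, y0, y1)) return(TRUE)
  if (.ellipse_meets_vseg(prof, x1, y0, y1)) return(TRUE)
  if (.ellipse_meets_hseg(prof, y0, x0, x1)) return(TRUE)
  if (.ellipse_meets_hseg(prof, y1, x0, x1)) return(TRUE)
  # rectangle wholly inside the ellipse
  all(.points_in_profiles(prof, rbind(c(x0, y0))))
}

#' Count profiles with a counting frame
#'
#' Default `rule = "unbiased"` (Gundersen): a profile is counted iff it
#' meets the closed frame rectangle and does not touch the forbidden set
#' (left edge, bottom edge, the upward extension of the left edge above the
#' frame and the downward extension of the right edge below it).
#' `rule = "inclusive"` is the literal reading of the figure legend
#' ("completely inside or touching the solid top/right lines"); it is biased
#' and provided only for comparison.
#'
#' @param profiles A `profile_set`.
#' @param frame A [counting_frame()].
#' @param rule `"unbiased"` or `"inclusive"`.
#' @return Integer count Q.
#' @export
count_profiles_in_frame <- function(profiles, frame,
                                    rule = c("unbiased", "inclusive")) {
  rule <- match.arg(rule)
  if (nrow(profiles) == 0) return(0L)
  x0 <- frame$x0; y0 <- frame$y0
  x1 <- x0 + frame$w; y1 <- y0 + frame$h
  big <- 1e9 * max(1, frame$w, frame$h, abs(x0), abs(y0))
  q <- 0L
  for (i in seq_len(nrow(profiles))) {
    p <- profiles[i, ]
    meets <- .ellipse_meets_rect(p, x0, y0, x1, y1)
    if (!meets) next
    if (rule == "unbiased") {
      forb <- .ellipse_meets_vseg(p, x0, y0, big) ||      # left edge + up
        .ellipse_meets_hseg(p, y0, x0, x1) ||             # bottom edge
        .ellipse_meets_vseg(p, x1, -big, y0)              # right ext. down
      if (!forb) q <- q + 1L
    } else {
      inside <- !(.ellipse_meets_vseg(p, x0, y0, y1) ||
                    .ellipse_meets_vseg(p, x1, y0, y1) ||
                    .ellipse_meets_hseg(p, y0, x0, x1) ||
                    .ellipse_meets_hseg(p, y1, x0, x1)) &&
        p$cx_um >= x0 && p$cx_um <= x1 && p$cy_um >= y0 && p$cy_um <= y1
      solid <- .ellipse_meets_hseg(p, y1, x0, x1) ||
        .ellipse_meets_vseg(p, x1, y0, y1)
      if (inside || solid) q <- q + 1L
    }
  }
  q
}

#' Tile a bounding box with counting frames
#'
#' @param bbox 2 x 2 extent matrix, um.
#' @param width_um,height_um Frame dimensions, um.
#' @param offset Lattice phase `c(dx, dy)`; random in one cell if `NULL`.
#' @param seed Optional seed.
#' @return List of [counting_frame()] objects covering `bbox`.
#' @export
frame_tiles <- function(bbox, width_um, height_um, offset = NULL,
                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(offset)) {
    offset <- c(stats::runif(1, 0, width_um), stats::runif(1, 0, height_um))
  }
  kx <- seq(floor((bbox[1, 1] - offset[1]) / width_um) - 1,
            ceiling((bbox[1, 2] - offset[1]) / width_um))
  ky <- seq(floor((bbox[2, 1] - offset[2]) / height_um) - 1,
            ceiling((bbox[2, 2] - offset[2]) / height_um))
  frames <- list()
  for (j in ky) for (i in kx) {
    frames[[length(frames) + 1L]] <- counting_frame(
      width_um, height_um,
      origin = c(offset[1] + i * width_um, offset[2] + j * height_um))
  }
  frames
}

# ---- test line grid ------------------------------------------------------

#' Test line grid
#'
#' A family of parallel lines with spacing `d`, a uniform random offset in
#' `[0, d)` and a rotation. For full-field parallel lines the total test
#' line length per field is field_area / d.
#'
#' @param spacing_um Line spacing d, um.
#' @param offset Scalar phase in `[0, d)`, drawn uniformly if `NULL`.
#' @param rotation_rad Line direction angle.
#' @param seed Optional seed.
#' @return A `line_grid` list.
#' @export
line_grid <- function(spacing_um, offset = NULL, rotation_rad = 0,
                      seed = NULL) {
  stopifnot(spacing_um > 0)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(offset)) offset <- stats::runif(1, 0, spacing_um)
  structure(list(spacing_um = spacing_um, offset = offset,
                 rotation_rad = rotation_rad),
            class = "line_grid")
}

#' Realise the test lines of a grid over a bounding box
#'
#' @param lines A [line_grid()].
#' @param bbox 2 x 2 extent matrix, um.
#' @return List of lines, each with `base` (2-vector), unit `dvec` and the
#'   clipped parameter range `trange` within `bbox`.
#' @export
grid_lines <- function(lines, bbox) {
  dvec <- c(cos(lines$rotation_rad), sin(lines$rotation_rad))
  nvec <- c(-dvec[2], dvec[1])
  corners <- cbind(bbox[1, c(1, 2, 2, 1)], bbox[2, c(1, 1, 2, 2)])
  s <- corners %*% nvec
  ks <- seq(ceiling((min(s) - lines$offset) / lines$spacing_um),
            floor((max(s) - lines$offset) / lines$spacing_um))
  out <- list()
  for (k in ks) {
    base <- (lines$offset + k * lines$spacing_um) * nvec
    # clip to bbox (2D slab method)
    t0 <- -Inf; t1 <- Inf; ok <- TRUE
    for (ax in 1:2) {
      if (abs(dvec[ax]) < 1e-15) {
        if (base[ax] < bbox[ax, 1] || base[ax] > bbox[ax, 2]) {
          ok <- FALSE; break
        }
      } else {
        ta <- (bbox[ax, 1] - base[ax]) / dvec[ax]
        tb <- (bbox[ax, 2] - base[ax]) / dvec[ax]
        t0 <- max(t0, min(ta, tb))
        t1 <- min(t1, max(ta, tb))
      }
    }
    if (ok && t0 < t1) {
      out[[length(out) + 1L]] <- list(base = base, dvec = dvec,
                                      trange = c(t0, t1))
    }
  }
  out
}

# crossings of a parametric line with one ellipse boundary within [t0, t1];
# a tangency counts once
.line_ellipse_crossings <- function(prof, base, dvec, trange) {
  M <- .ellipse_M(prof$semi_major_um, prof$semi_minor_um, prof$angle_rad)
  w <- base - c(prof$cx_um, prof$cy_um)
  A <- as.numeric(t(dvec) %*% M %*% dvec)
  B <- as.numeric(2 * t(w) %*% M %*% dvec)
  C <- as.numeric(t(w) %*% M %*% w) - 1
  disc <- B^2 - 4 * A * C
  tol <- 1e-10 * max(B^2, abs(4 * A * C), A^2)
  if (disc < -tol) return(0L)
  if (abs(disc) <= tol) {
    t <- -B / (2 * A)
    return(as.integer(t >= trange[1] && t <= trange[2]))
  }
  s <- sqrt(disc)
  roots <- c((-B - s) / (2 * A), (-B + s) / (2 * A))
  sum(roots >= trange[1] & roots <= trange[2])
}

#' Count line-profile boundary intersections
#'
#' Lays the line grid over the field and counts crossing points between the
#' test lines and the profile ellipse boundaries; tangencies count once.
#'
#' @param profiles A `profile_set`.
#' @param lines A [line_grid()].
#' @param bbox Field bounding box (2 x 2), um.
#' @return List with `I` (intersection count) and `L_um` (total test line
#'   length laid over the field).
#' @export
count_line_intersections <- function(profiles, lines, bbox) {
  gl <- grid_lines(lines, bbox)
  I <- 0L
  L <- 0
  for (ln in gl) {
    L <- L + diff(ln$trange)
    for (i in seq_len(nrow(profiles))) {
      I <- I + .line_ellipse_crossings(profiles[i, ], ln$base, ln$dvec,
                                       ln$trange)
    }
  }
  list(I = as.integer(I), L_um = L)
}

#' Systematic uniform random field sampling
#'
#' Places `n_fields` field centres on a systematic lattice with a single
#' uniform random start, the standard design for choosing microscope fields
#' on a section.
#'
#' @param extent 2 x 2 bounding box of the section, um.
#' @param n_fields Number of fields (>= 1).
#' @param field_um Field size `c(w, h)` (or scalar), um.
#' @param seed Optional seed.
#' @param rotate If `TRUE` each field carries an independent uniform
#'   rotation in `[0, pi)` (returned as a column).
#' @return Data frame with `cx_um`, `cy_um` (+ `rotation_rad` if requested).
#' @export
sample_fields <- function(extent, n_fields, field_um, seed = NULL,
                          rotate = FALSE) {
  stopifnot(n_fields >= 1)
  if (length(field_um) == 1) field_um <- c(field_um, field_um)
  W <- diff(extent[1, ]); H <- diff(extent[2, ])
  if (field_um[1] > W || field_um[2] > H) {
    stop("fields exceed section extent")
  }
  if (!is.null(seed)) set.seed(seed)
  ncol_ <- max(1L, ceiling(sqrt(n_fields * W / H)))
  nrow_ <- ceiling(n_fields / ncol_)
  sx <- W / ncol_; sy <- H / nrow_
  start <- c(stats::runif(1, 0, sx), stats::runif(1, 0, sy))
  cx <- extent[1, 1] + start[1] + sx * (seq_len(ncol_) - 1)
  cy <- extent[2, 1] + start[2] + sy * (seq_len(nrow_) - 1)
  centres <- expand.grid(cx_um = cx, cy_um = cy)[seq_len(n_fields), ]
  rownames(centres) <- NULL
  if (rotate) centres$rotation_rad <- stats::runif(n_fields, 0, pi)
  centres
}
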