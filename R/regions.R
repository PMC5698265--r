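#' Convex reference region
#'
#' Constructs a convex 3D reference region centred at the origin, the
#' stand-in for an anatomical reference space (e.g. a hippocampal subfield)
#' whose volume is known in closed form. All lengths are in micrometres.
#'
#' @param shape One of `"box"`, `"ellipsoid"`, `"sphere"`.
#' @param dimensions For a box the three full edge lengths (um); for an
#'   ellipsoid the three semi-axes (um); for a sphere the radius (um).
#' @return An object of class `reference_region` with fields `shape`,
#'   `dimensions` and the analytic `volume` (um^3).
#' @examples
#' r <- reference_region("box", c(500, 500, 500))
#' region_volume(r)  # 1.25e8 um^3
#' @export
reference_region <- function(shape = c("box", "ellipsoid", "sphere"),
                             dimensions) {
  shape <- match.arg(shape)
  dimensions <- as.numeric(dimensions)
  n_expected <- if (shape == "sphere") 1L else 3L
  if (length(dimensions) != n_expected) {
    stop("shape '", shape, "' needs ", n_expected, " dimension(s)")
  }
  if (any(!is.finite(dimensions)) || any(dimensions <= 0)) {
    stop("dimensions must be positive and finite")
  }
  vol <- switch(shape,
    box       = prod(dimensions),
    ellipsoid = 4 / 3 * pi * prod(dimensions),
    sphere    = 4 / 3 * pi * dimensions^3
  )
  structure(
    list(shape = shape, dimensions = dimensions, volume = vol),
    class = "reference_region"
  )
}

#' @export
print.reference_region <- function(x, ...) {
  cat("reference_region:", x$shape,
      "[", paste(signif(x$dimensions, 6), collapse = " x "), "um ]",
      "volume", signif(x$volume, 6), "um^3\n")
  invisible(x)
}

#' Analytic region volume
#' @param region A [reference_region()].
#' @return Volume in um^3.
#' @export
region_volume <- function(region) region$volume

# semi-extents used for box/ellipsoid membership
.region_semi <- function(region) {
  switch(region$shape,
    box       = region$dimensions / 2,
    ellipsoid = region$dimensions,
    sphere    = rep(region$dimensions, 3)
  )
}

#' Point-in-region test
#'
#' Boundary points count as inside. `inset` shrinks the region by a margin
#' (exact for box and sphere, a conservative semi-axis shrink for
#' ellipsoids), used to keep whole cylinders of radius `inset` inside.
#'
#' @param region A [reference_region()].
#' @param pts Numeric matrix (n x 3) of points, um.
#' @param inset Nonnegative margin in um.
#' @return Logical vector of length n.
#' @export
region_contains <- function(region, pts, inset = 0) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 3)
  semi <- .region_semi(region) - inset
  if (any(semi <= 0)) return(rep(FALSE, nrow(pts)))
  if (region$shape == "box") {
    abs(pts[, 1]) <= semi[1] & abs(pts[, 2]) <= semi[2] & abs(pts[, 3]) <= semi[3]
  } else {
    (pts[, 1] / semi[1])^2 + (pts[, 2] / semi[2])^2 + (pts[, 3] / semi[3])^2 <= 1
  }
}

#' Support half-width of the region along a direction
#'
#' For a centred convex body K, returns h(u) = max_{x in K} u.x for a unit
#' vector u; the region's extent along u is `[-h, h]` (all shapes here are
#' centrally symmetric).
#'
#' @param region A [reference_region()].
#' @param direction Unit 3-vector.
#' @return Half-width in um.
#' @export
region_support <- function(region, direction) {
  u <- direction / sqrt(sum(direction^2))
  switch(region$shape,
    box       = sum(region$dimensions / 2 * abs(u)),
    ellipsoid = sqrt(sum((region$dimensions * u)^2)),
    sphere    = region$dimensions
  )
}

#' Axis-aligned bounding box of the region
#' @param region A [reference_region()].
#' @return 3 x 2 matrix, columns `min`, `max` (um).
#' @export
region_bbox <- function(region) {
  semi <- .region_semi(region)
  cbind(min = -semi, max = semi)
}
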