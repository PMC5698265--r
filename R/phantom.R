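#' @title Synthetic capillary phantoms
#' @description Generators for straight-cylinder capillary networks inside a
#'   convex reference region, with exact closed-form ground truth for total
#'   length, volume and lateral surface area. These phantoms stand in for
#'   tissue whose true microvascular quantities are unknowable, so that the
#'   section-based estimators can be validated against truth.
#' @name phantom
NULL

# uniform direction on the unit sphere (area-uniform)
.runif_sphere <- function(n = 1L) {
  z <- stats::runif(n, -1, 1)
  phi <- stats::runif(n, 0, 2 * pi)
  s <- sqrt(pmax(0, 1 - z^2))
  cbind(s * cos(phi), s * sin(phi), z)
}

#' Radius sampler specification
#'
#' @param type `"constant"` or `"normal"` (truncated at `min`).
#' @param value Radius in um for `"constant"`.
#' @param mean,sd Parameters in um for `"normal"`.
#' @param min Lower truncation bound (um) for `"normal"`.
#' @return A list usable as the `radius` argument of [generate_network()].
#' @export
radius_spec <- function(type = c("constant", "normal"), value = 2,
                        mean = 2, sd = 0.2, min = 0.5) {
  type <- match.arg(type)
  if (type == "constant" && value <= 0) stop("radius must be positive")
  if (type == "normal" && (mean <= 0 || sd < 0 || min <= 0)) {
    stop("invalid normal radius parameters")
  }
  list(type = type, value = value, mean = mean, sd = sd, min = min)
}

.draw_radius <- function(spec) {
  if (is.numeric(spec)) return(spec[1])
  if (spec$type == "constant") return(spec$value)
  repeat {
    r <- stats::rnorm(1, spec$mean, spec$sd)
    if (r >= spec$min) return(r)
  }
}

# Minimum distance between segment (a0,a1) and each row-segment of (B0,B1).
# Vectorised clamped closest-point algorithm; exactness is property-tested
# against dense parameter enumeration.
.seg_seg_dist <- function(a0, a1, B0, B1) {
  n <- nrow(B0)
  u <- a1 - a0
  v <- B1 - B0
  w <- matrix(a0, n, 3, byrow = TRUE) - B0
  a <- sum(u * u)
  b <- as.vector(v %*% u)
  cc <- rowSums(v * v)
  d <- as.vector(w %*% u)       # actually u.(a0-B0) per row
  e <- rowSums(v * w)
  D <- a * cc - b * b
  eps <- 1e-12 * max(a, 1)

  sN <- ifelse(D < eps, 0, b * e - cc * d)
  sD <- ifelse(D < eps, 1, D)
  tN <- ifelse(D < eps, e, a * e - b * d)
  tD <- ifelse(D < eps, cc, D)

  low <- sN < 0
  sN[low] <- 0
  tN[low] <- e[low]
  tD[low] <- cc[low]
  high <- sN > sD
  sN[high] <- sD[high]
  tN[high] <- (e + b)[high]
  tD[high] <- cc[high]

  tn0 <- tN < 0
  tN[tn0] <- 0
  sN[tn0] <- pmin(pmax(-d[tn0], 0), a) / max(a, eps) * sD[tn0]
  tn1 <- tN > tD
  tN[tn1] <- tD[tn1]
  sN[tn1] <- pmin(pmax((-d + b)[tn1], 0), a) / max(a, eps) * sD[tn1]

  s <- ifelse(abs(sN) < eps, 0, sN / sD)
  t <- ifelse(abs(tN) < eps, 0, tN / tD)
  dp <- w + outer(s, u) - v * t
  sqrt(rowSums(dp * dp))
}

#' Generate a synthetic capillary network
#'
#' Draws straight cylindrical segments inside `region` until the summed
#' centre-line length reaches `target_length_density * region_volume(region)`
#' (the last segment is truncated so the target is hit exactly). Isotropic
#' mode draws directions uniformly on the unit sphere, as required for an
#' IUR sectioning design; candidates whose cylinder would protrude through
#' the region boundary are rejected, so every cylinder lies wholly inside.
#'
#' @param region A [reference_region()].
#' @param target_length_density Target L_V in um^-2 (length per unit
#'   reference volume); e.g. 300 mm/mm^3 is `3e-4`.
#' @param radius A number (um) or a [radius_spec()]; drawn once per segment.
#' @param orientation `"isotropic"` or `"axial"` (all segments along z).
#' @param seed Integer seed; identical seeds give identical networks.
#' @param length_range Segment length range (um), drawn uniformly.
#' @param no_overlap If `TRUE`, candidates whose centre-line comes closer
#'   than the sum of radii to an accepted segment are rejected, so cylinders
#'   are pairwise disjoint (required for exact volume-fraction truth).
#' @param max_tries Consecutive rejections tolerated before failing.
#' @return A `capillary_network`: list with `region`, endpoint matrices
#'   `p0`, `p1` (n x 3, um), `radius` (um), `seed`, `orientation`.
#' @export
generate_network <- function(region, target_length_density,
                             radius = 2, orientation = c("isotropic", "axial"),
                             seed = 1L, length_range = c(50, 200),
                             no_overlap = FALSE, max_tries = 20000L) {
  orientation <- match.arg(orientation)
  stopifnot(inherits(region, "reference_region"),
            target_length_density >= 0, length_range[1] > 0,
            length_range[2] >= length_range[1])
  set.seed(seed)
  target <- target_length_density * region$volume
  bbox <- region_bbox(region)

  p0 <- p1 <- matrix(numeric(0), 0, 3)
  rad <- numeric(0)
  total <- 0
  fails <- 0L
  while (total < target - 1e-9 * max(target, 1)) {
    len <- stats::runif(1, length_range[1], length_range[2])
    len <- min(len, target - total)
    r <- .draw_radius(radius)
    dir <- if (orientation == "isotropic") .runif_sphere(1) else c(0, 0, 1)
    a0 <- c(stats::runif(1, bbox[1, 1], bbox[1, 2]),
            stats::runif(1, bbox[2, 1], bbox[2, 2]),
            stats::runif(1, bbox[3, 1], bbox[3, 2]))
    a1 <- a0 + as.vector(dir) * len
    ok <- region_contains(region, rbind(a0, a1), inset = r)
    ok <- all(ok)
    if (ok && no_overlap && nrow(p0) > 0) {
      dmin <- .seg_seg_dist(a0, a1, p0, p1)
      ok <- all(dmin > rad + r)
    }
    if (ok) {
      p0 <- rbind(p0, a0)
      p1 <- rbind(p1, a1)
      rad <- c(rad, r)
      total <- total + len
      fails <- 0L
    } else {
      fails <- fails + 1L
      if (fails >= max_tries) {
        stop(sprintf(
          "packing failure: achieved length density %.4g um^-2 of target %.4g um^-2",
          total / region$volume, target_length_density))
      }
    }
  }
  dimnames(p0) <- dimnames(p1) <- NULL
  structure(
    list(region = region, p0 = p0, p1 = p1, radius = rad,
         seed = as.integer(seed), orientation = orientation),
    class = "capillary_network"
  )
}

#' @export
print.capillary_network <- function(x, ...) {
  gt <- ground_truth(x)
  cat("capillary_network:", nrow(x$p0), "segments in a", x$region$shape,
      "region\n  total length", signif(gt$total_length, 5), "um, L_V",
      signif(gt$length_density, 5), "um^-2\n")
  invisible(x)
}

#' Exact ground truth of a phantom network
#'
#' Closed-form cylinder sums: total centre-line length, total volume
#' (sum pi r^2 l) and total lateral surface (sum 2 pi r l; no end caps),
#' plus the derived densities per unit reference volume. These are the true
#' values the section-based estimators are validated against.
#'
#' @param network A `capillary_network`.
#' @return A `ground_truth` list: `total_length` (um), `total_volume`
#'   (um^3), `total_surface` (um^2), `length_density` (um^-2),
#'   `volume_fraction`, `surface_density` (um^-1).
#' @export
ground_truth <- function(network) {
  stopifnot(inherits(network, "capillary_network"))
  v <- network$region$volume
  if (nrow(network$p0) == 0) {
    len <- vol <- surf <- 0
  } else {
    l <- sqrt(rowSums((network$p1 - network$p0)^2))
    len <- sum(l)
    vol <- sum(pi * network$radius^2 * l)
    surf <- sum(2 * pi * network$radius * l)
  }
  structure(list(
    total_length = len, total_volume = vol, total_surface = surf,
    length_density = len / v, volume_fraction = vol / v,
    surface_density = surf / v
  ), class = "ground_truth")
}

#' Cohort specification for a synthetic study arm
#'
#' Per-group distributions of the animal-level true parameters. Group means
#' and SDs describe normal distributions (negative draws are rejected and
#' redrawn) of true capillary length density and true reference-region
#' volume; radius parameters feed [radius_spec()].
#'
#' @param groups Data frame with columns `label`, `n`, `lv_mean`, `lv_sd`
#'   (um^-2), `vol_mean`, `vol_sd` (um^3), and optionally `r_mean`, `r_sd`
#'   (um; `r_sd = 0` gives a constant radius).
#' @param shape Region shape for every animal (volume is drawn per animal
#'   and the dimensions scaled isotropically).
#' @param seed Integer seed.
#' @param length_range,no_overlap Passed to [generate_network()].
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(groups, shape = "box", seed = 1L,
                        length_range = c(50, 200), no_overlap = FALSE) {
  stopifnot(is.data.frame(groups))
  need <- c("label", "n", "lv_mean", "lv_sd", "vol_mean", "vol_sd")
  if (!all(need %in% names(groups))) {
    stop("groups must have columns: ", paste(need, collapse = ", "))
  }
  if (nrow(groups) > 0) {
    if (any(groups$n < 2)) stop("each group needs n >= 2 animals")
    if (any(groups$lv_sd < 0) || any(groups$vol_sd < 0)) stop("SDs must be >= 0")
    if (any(groups$lv_mean <= 0) || any(groups$vol_mean <= 0)) {
      stop("means must be > 0")
    }
  }
  if (is.null(groups$r_mean)) groups$r_mean <- rep(2, nrow(groups))
  if (is.null(groups$r_sd)) groups$r_sd <- rep(0, nrow(groups))
  structure(list(groups = groups, shape = shape, seed = as.integer(seed),
                 length_range = length_range, no_overlap = no_overlap),
            class = "cohort_spec")
}

.rnorm_pos <- function(mean, sd) {
  if (sd == 0) return(mean)
  repeat {
    x <- stats::rnorm(1, mean, sd)
    if (x > 0) return(x)
  }
}

# region of given shape scaled to an exact target volume
.region_for_volume <- function(shape, volume) {
  base <- switch(shape,
    box       = reference_region("box", rep(1, 3)),
    ellipsoid = reference_region("ellipsoid", c(1, 0.85, 0.7)),
    sphere    = reference_region("sphere", 1)
  )
  s <- (volume / base$volume)^(1 / 3)
  reference_region(shape, base$dimensions * s)
}

#' Generate a synthetic cohort
#'
#' Draws per-animal true parameters from the group distributions and builds
#' one phantom network per animal. Mimics a multi-group animal study with
#' known per-animal truth.
#'
#' @param spec A [cohort_spec()].
#' @return List of animals; each has `id`, `group`, `network`, and `truth`
#'   (list with `lv`, `volume`, `radius` as drawn).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  animals <- list()
  k <- 0L
  for (g in seq_len(nrow(spec$groups))) {
    row <- spec$groups[g, ]
    for (i in seq_len(row$n)) {
      k <- k + 1L
      vol <- .rnorm_pos(row$vol_mean, row$vol_sd)
      lv <- .rnorm_pos(row$lv_mean, row$lv_sd)
      r <- if (row$r_sd == 0) row$r_mean else {
        repeat {
          x <- stats::rnorm(1, row$r_mean, row$r_sd)
          if (x > 0.2) break
        }
        x
      }
      net_seed <- sample.int(.Machine$integer.max - 1L, 1)
      region <- .region_for_volume(spec$shape, vol)
      net <- generate_network(region, lv, radius = r, seed = net_seed,
                              length_range = spec$length_range,
                              no_overlap = spec$no_overlap)
      animals[[k]] <- list(
        id = sprintf("%s_%02d", row$label, i), group = row$label,
        network = net, truth = list(lv = lv, volume = vol, radius = r)
      )
    }
  }
  animals
}

#' Write / read a network as versioned JSON
#'
#' @param network A `capillary_network`.
#' @param path File path.
#' @return `read_network` returns the `capillary_network`.
#' @export
write_network <- function(network, path) {
  stopifnot(inherits(network, "capillary_network"))
  segs <- lapply(seq_len(nrow(network$p0)), function(i) {
    list(p0 = network$p0[i, ], p1 = network$p1[i, ],
         radius_um = network$radius[i])
  })
  obj <- list(
    format = "stereovasc-network/1",
    region = list(shape = network$region$shape,
                  dimensions_um = network$region$dimensions),
    segments = segs,
    seed = network$seed,
    orientation = network$orientation
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$format) || obj$format != "stereovasc-network/1") {
    stop("not a stereovasc network file")
  }
  region <- reference_region(obj$region$shape, obj$region$dimensions_um)
  segs <- obj$segments
  if (NROW(segs) == 0) {
    p0 <- p1 <- matrix(numeric(0), 0, 3)
    rad <- numeric(0)
  } else {
    p0 <- do.call(rbind, segs$p0)
    p1 <- do.call(rbind, segs$p1)
    rad <- as.numeric(segs$radius_um)
  }
  structure(list(region = region, p0 = p0, p1 = p1, radius = rad,
                 seed = as.integer(obj$seed),
                 orientation = obj$orientation %||% "isotropic"),
            class = "capillary_network")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
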