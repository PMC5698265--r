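#' @title Stereological estimators
#' @description The four classical design-based formulas: Cavalieri region
#'   volume from slab point counts, capillary length density from transect
#'   counts on IUR sections, volume fraction from point ratios (Delesse),
#'   and surface density from line intersections, plus the scaling of the
#'   densities to per-animal totals in reporting units.
#' @name estimators
NULL

#' Cavalieri volume estimate
#'
#' V = t * a(p) * sum(P) * hemisphere_factor, where `t` is the slab
#' thickness, `a(p)` the area associated with each grid point, and `sum(P)`
#' the total number of points hitting the region across all slab faces. The
#' hemisphere factor doubles a one-hemisphere count to a whole-structure
#' volume; phantoms model a single region and use 1.
#'
#' @param point_counts_per_slab Integer vector of per-slab point counts.
#' @param t_um Slab thickness, um.
#' @param a_p_um2 Area per point, um^2.
#' @param hemisphere_factor 1 or 2.
#' @return Volume in um^3.
#' @export
cavalieri_volume <- function(point_counts_per_slab, t_um, a_p_um2,
                             hemisphere_factor = 1) {
  if (length(point_counts_per_slab) == 0) stop("empty point count list")
  stopifnot(t_um > 0, a_p_um2 > 0, hemisphere_factor %in% c(1, 2),
            all(point_counts_per_slab >= 0))
  t_um * a_p_um2 * sum(point_counts_per_slab) * hemisphere_factor
}

#' Length density from transect counts
#'
#' L_V = 2 * sum(Q) / sum(A): twice the number of capillary profiles per
#' unit reference area sampled, unbiased for IUR sections.
#'
#' @param Q Total transect (profile) count.
#' @param A_um2 Total reference area sampled, um^2.
#' @return L_V in um^-2.
#' @export
length_density <- function(Q, A_um2) {
  if (A_um2 <= 0) stop("total sampled area must be positive")
  stopifnot(Q >= 0)
  2 * Q / A_um2
}

#' Volume fraction from point counts (Delesse)
#'
#' V_V = sum(P_cap) / sum(P_ref) for a point grid applied to nested phases
#' (capillary points are a subset of reference points).
#'
#' @param P_cap Points hitting the capillary phase.
#' @param P_ref Points hitting the reference region.
#' @return Volume fraction in `[0, 1]`.
#' @export
volume_fraction <- function(P_cap, P_ref) {
  if (P_ref <= 0) stop("reference point count must be positive")
  if (P_cap > P_ref) stop("capillary phase not nested: P_cap > P_ref")
  stopifnot(P_cap >= 0)
  P_cap / P_ref
}

#' Surface density from line intersections
#'
#' S_V = 2 * sum(I) / sum(L): twice the number of intersections between the
#' capillary surface and the test lines per unit test line length, unbiased
#' for isotropic lines.
#'
#' @param I Intersection count.
#' @param L_um Total test line length within the reference space, um.
#' @return S_V in um^-1.
#' @export
surface_density <- function(I, L_um) {
  if (L_um <= 0) stop("total test line length must be positive")
  stopifnot(I >= 0)
  2 * I / L_um
}

#' Scale densities to totals
#'
#' Multiplies each density by the reference volume, giving per-animal
#' totals, and attaches the reporting-unit conversions (mm^3, m, cm^2).
#'
#' @param L_V Length density, um^-2.
#' @param V_V Volume fraction (dimensionless).
#' @param S_V Surface density, um^-1.
#' @param V_region_um3 Reference region volume, um^3.
#' @return A `stereo_estimates` list with totals in um units and a
#'   `report` data frame in reporting units.
#' @export
stereo_totals <- function(L_V, V_V, S_V, V_region_um3) {
  stopifnot(L_V >= 0, V_V >= 0, V_V <= 1, S_V >= 0, V_region_um3 >= 0)
  l_tot <- L_V * V_region_um3     # um
  v_tot <- V_V * V_region_um3     # um^3
  s_tot <- S_V * V_region_um3     # um^2
  structure(list(
    V_region_um3 = V_region_um3, L_V_um2 = L_V, V_V = V_V, S_V_um1 = S_V,
    L_total_um = l_tot, V_cap_total_um3 = v_tot, S_total_um2 = s_tot,
    report = data.frame(
      v_region_mm3 = V_region_um3 * 1e-9,
      l_total_m = l_tot * 1e-6,
      vcap_total_mm3 = v_tot * 1e-9,
      s_total_cm2 = s_tot * 1e-8
    )
  ), class = "stereo_estimates")
}

#' @export
print.stereo_estimates <- function(x, ...) {
  r <- x$report
  cat(sprintf(
    "stereo_estimates: V %s mm^3 | L %s m | Vcap %s mm^3 | S %s cm^2\n",
    signif(r$v_region_mm3, 3), signif(r$l_total_m, 3),
    signif(r$vcap_total_mm3, 3), signif(r$s_total_cm2, 3)))
  invisible(x)
}
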