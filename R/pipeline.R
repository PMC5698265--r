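#' @title End-to-end synthetic study pipeline
#' @description Orchestrates cohort phantoms -> Cavalieri slabs -> IUR
#'   sections -> probes -> estimators -> group statistics, and a
#'   reanalysis mode that replays the statistics from published summary
#'   tables alone.
#' @name pipeline
NULL

#' Published group summary table
#'
#' The per-group mean / SD / n values printed in the source study's
#' results (behaviour, region volumes, capillary length, volume and
#' surface for CA1 and DG), shipped as the package's only data fixture.
#'
#' @return Data frame with columns `metric`, `region`, `group`, `phase`,
#'   `n`, `mean`, `sd`, `unit`.
#' @export
published_group_summaries <- function() {
  path <- system.file("extdata", "published_group_summaries.csv",
                      package = "stereovasc")
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Study configuration
#'
#' @param cohorts Named list of [cohort_spec()] objects, one per reference
#'   region (e.g. `CA1`, `DG`).
#' @param slab_thickness_um Cavalieri slab thickness, um.
#' @param cavalieri_spacing_um Point spacing of the Cavalieri grid, um.
#' @param sections_per_animal IUR sections per animal.
#' @param point_spacing_um Point grid spacing on sections, um.
#' @param line_spacing_um Test line spacing on sections, um.
#' @param max_diameter_um Capillary diameter criterion, um.
#' @param alpha Significance level.
#' @param seed Integer master seed (no wall-clock defaults).
#' @return A `study_config` list.
#' @export
study_config <- function(cohorts, slab_thickness_um = 50,
                         cavalieri_spacing_um = 25,
                         sections_per_animal = 20,
                         point_spacing_um = 5, line_spacing_um = 20,
                         max_diameter_um = 10, alpha = 0.05, seed = 1L) {
  stopifnot(is.list(cohorts), length(cohorts) >= 1,
            !is.null(names(cohorts)),
            slab_thickness_um > 0, cavalieri_spacing_um > 0,
            sections_per_animal >= 1, point_spacing_um > 0,
            line_spacing_um > 0, max_diameter_um > 0,
            alpha > 0, alpha < 1)
  structure(list(
    cohorts = cohorts, slab_thickness_um = slab_thickness_um,
    cavalieri_spacing_um = cavalieri_spacing_um,
    sections_per_animal = as.integer(sections_per_animal),
    point_spacing_um = point_spacing_um,
    line_spacing_um = line_spacing_um,
    max_diameter_um = max_diameter_um, alpha = alpha,
    seed = as.integer(seed)
  ), class = "study_config")
}

#' Default scaled-down study calibrated to the published summaries
#'
#' Builds a three-group (control / CUS-standard / CUS-running) study whose
#' per-animal true parameters are drawn from distributions calibrated to
#' the published group tables: true length densities equal the published
#' total length / region volume ratios (density is scale-free), and region
#' volumes are the published volumes scaled down so the control CA1 region
#' is a (500 um)^3 box, which keeps a full 3 x 10 study tractable on one
#' CPU. The radius is a constant 2 um, consistent with the published
#' volume/length and surface/length ratios. The between-animal SD of the
#' length density is chosen so the induced total-length CV matches the
#' published one (with a 3% floor where volume variability alone already
#' exceeds it).
#'
#' @param seed Master seed.
#' @param regions Which regions to include.
#' @param n_per_group Animals per group.
#' @param ... Overrides passed on to [study_config()].
#' @return A `study_config`.
#' @export
default_study_config <- function(seed = 1L, regions = c("CA1", "DG"),
                                 n_per_group = 10, ...) {
  tab <- published_group_summaries()
  vscale <- 500^3 / (33.9 * 1e9)  # control CA1 -> (500 um)^3
  cohorts <- list()
  for (reg in regions) {
    vol <- tab[tab$metric == "region_volume" & tab$region == reg, ]
    len <- tab[tab$metric == "cap_length" & tab$region == reg, ]
    stopifnot(nrow(vol) == 3, nrow(len) == 3)
    len <- len[match(vol$group, len$group), ]
    lv_mean <- (len$mean * 1e6) / (vol$mean * 1e9)   # um^-2, scale-free
    cv_l <- len$sd / len$mean
    cv_v <- vol$sd / vol$mean
    cv_lv <- sqrt(pmax(cv_l^2 - cv_v^2, 0.03^2))
    cohorts[[reg]] <- cohort_spec(
      data.frame(label = vol$group, n = n_per_group,
                 lv_mean = lv_mean, lv_sd = lv_mean * cv_lv,
                 vol_mean = vol$mean * 1e9 * vscale,
                 vol_sd = vol$sd * 1e9 * vscale,
                 r_mean = 2, r_sd = 0),
      shape = "box", seed = seed + match(reg, regions)
    )
  }
  study_config(cohorts, seed = seed, ...)
}

# estimate one animal; consumes the current RNG stream
.estimate_animal <- function(network, cfg) {
  region <- network$region
  slabs <- cut_slabs(region, cfg$slab_thickness_um)
  counts <- cavalieri_point_counts(region, slabs, cfg$cavalieri_spacing_um)
  v_hat <- cavalieri_volume(counts, cfg$slab_thickness_um,
                            cfg$cavalieri_spacing_um^2,
                            hemisphere_factor = 1)
  Q <- P_cap <- P_ref <- I <- 0L
  A <- L <- 0
  for (j in seq_len(cfg$sections_per_animal)) {
    plane <- iur_plane(region)
    sc <- section_counts(network, plane, cfg$point_spacing_um,
                         cfg$line_spacing_um, cfg$max_diameter_um)
    Q <- Q + sc$Q; A <- A + sc$A_um2
    P_cap <- P_cap + sc$P_cap; P_ref <- P_ref + sc$P_ref
    I <- I + sc$I; L <- L + sc$L_um
  }
  est <- stereo_totals(length_density(Q, A),
                       volume_fraction(P_cap, P_ref),
                       surface_density(I, L), v_hat)
  list(est = est,
       counts = list(Q = Q, A_um2 = A, P_cap = P_cap, P_ref = P_ref,
                     I = I, L_um = L, sum_P_cavalieri = sum(counts)))
}

.study_metrics <- c("v_region_mm3", "l_total_m", "vcap_total_mm3",
                    "s_total_cm2")

#' Run a full synthetic study
#'
#' Generates the cohorts, pushes every animal through the virtual
#' microtome and probe battery, estimates the per-animal totals, and
#' replays the group comparison (one-way ANOVA plus pairwise pooled t
#' tests with the strict p < alpha criterion) for each of the metrics
#' (region volume, capillary total length, total volume, total surface)
#' in each region. Deterministic under a fixed config seed.
#'
#' @param config A [study_config()].
#' @param verbose Print one progress line per animal.
#' @return A `study_report`: `animals` (per-animal estimates and truths),
#'   `summaries`, `anova`, `pairwise` (with `significant` column),
#'   `config`.
#' @export
run_study <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "study_config"))
  animals_df <- NULL
  cohort_data <- list()
  for (reg in names(config$cohorts)) {
    cohort_data[[reg]] <- generate_cohort(config$cohorts[[reg]])
  }
  set.seed(config$seed)
  for (reg in names(cohort_data)) {
    for (an in cohort_data[[reg]]) {
      t0 <- proc.time()[["elapsed"]]
      res <- tryCatch(
        .estimate_animal(an$network, config),
        error = function(e) stop("stage estimate failed for animal ",
                                 an$id, " (", reg, "): ",
                                 conditionMessage(e))
      )
      r <- res$est$report
      animals_df <- rbind(animals_df, data.frame(
        region = reg, group = an$group, animal_id = an$id,
        v_region_mm3 = r$v_region_mm3, l_total_m = r$l_total_m,
        vcap_total_mm3 = r$vcap_total_mm3, s_total_cm2 = r$s_total_cm2,
        lv_um2 = res$est$L_V_um2, vv = res$est$V_V,
        sv_um1 = res$est$S_V_um1,
        true_v_region_mm3 = an$truth$volume * 1e-9,
        true_l_total_m = an$truth$lv * an$truth$volume * 1e-6,
        sum_Q = res$counts$Q, sum_A_um2 = res$counts$A_um2,
        sum_P_cap = res$counts$P_cap, sum_P_ref = res$counts$P_ref,
        sum_I = res$counts$I, sum_L_um = res$counts$L_um,
        sum_P_cavalieri = res$counts$sum_P_cavalieri
      ))
      if (verbose) {
        message(sprintf("estimated %s/%s in %.2fs", reg, an$id,
                        proc.time()[["elapsed"]] - t0))
      }
    }
  }
  summaries <- NULL
  anova_df <- NULL
  pairwise_df <- NULL
  for (reg in names(cohort_data)) {
    sub <- animals_df[animals_df$region == reg, ]
    for (metric in .study_metrics) {
      by_group <- split(sub[[metric]], sub$group)
      st <- data.frame(label = names(by_group),
                       n = vapply(by_group, length, 1L),
                       mean = vapply(by_group, mean, 1),
                       sd = vapply(by_group, stats::sd, 1))
      rownames(st) <- NULL
      summaries <- rbind(summaries, cbind(region = reg, metric = metric, st))
      av <- anova_oneway(st)
      anova_df <- rbind(anova_df, data.frame(
        region = reg, metric = metric, F = av$statistic,
        df1 = av$df[1], df2 = av$df[2], p = av$p_value))
      pw <- pairwise_tests(st)
      pairwise_df <- rbind(pairwise_df,
                           cbind(region = reg, metric = metric, pw))
    }
  }
  pairwise_df <- significance_pattern(pairwise_df, config$alpha)
  structure(list(animals = animals_df, summaries = summaries,
                 anova = anova_df, pairwise = pairwise_df,
                 config = config),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("study_report:", nrow(x$animals), "animals,",
      length(unique(x$animals$region)), "region(s)\n")
  sig <- x$pairwise[x$pairwise$significant, ]
  cat("significant comparisons (p <", x$config$alpha, "):\n")
  if (nrow(sig) == 0) cat("  none\n") else {
    for (i in seq_len(nrow(sig))) {
      cat(sprintf("  %s %s: %s vs %s (p = %.3g)\n", sig$region[i],
                  sig$metric[i], sig$group_a[i], sig$group_b[i], sig$p[i]))
    }
  }
  invisible(x)
}

#' Replay group statistics from a summary table
#'
#' Runs one-way ANOVA and pairwise t tests for every metric (x region x
#' phase) cell of a published summary table, without any phantom stages.
#'
#' @param x Data frame or CSV path with columns `metric`, `group`, `n`,
#'   `mean`, `sd` and optionally `region`, `phase`.
#' @param alpha Significance level.
#' @param method Pairwise method, see [pairwise_tests()].
#' @return List (class `study_stats`) with `anova` and `pairwise` data
#'   frames, the latter carrying the `significant` column.
#' @export
reanalyze_summaries <- function(x, alpha = 0.05,
                                method = c("pooled", "welch", "tukey")) {
  method <- match.arg(method)
  if (is.character(x)) {
    x <- utils::read.csv(x, comment.char = "#", stringsAsFactors = FALSE)
  }
  need <- c("metric", "group", "n", "mean", "sd")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) stop("summary table lacks columns: ",
                             paste(miss, collapse = ", "))
  bad <- which(!is.finite(x$n) | x$n < 2 | !is.finite(x$mean) |
                 !is.finite(x$sd) | x$sd < 0)
  if (length(bad) > 0) stop("invalid summary row ", bad[1],
                            " (need n >= 2, finite mean, sd >= 0)")
  if (is.null(x$region)) x$region <- ""
  if (is.null(x$phase)) x$phase <- ""
  x$region[is.na(x$region)] <- ""
  key <- interaction(x$metric, x$region, x$phase, drop = TRUE)
  anova_df <- NULL
  pairwise_df <- NULL
  for (cell in split(x, key)) {
    st <- data.frame(label = cell$group, n = cell$n, mean = cell$mean,
                     sd = cell$sd)
    id <- data.frame(metric = cell$metric[1], region = cell$region[1],
                     phase = cell$phase[1])
    if (nrow(st) >= 2) {
      av <- anova_oneway(st)
      anova_df <- rbind(anova_df, cbind(id, data.frame(
        F = av$statistic, df1 = av$df[1], df2 = av$df[2],
        p = av$p_value)))
      pairwise_df <- rbind(pairwise_df,
                           cbind(id[rep(1, nrow(st) * (nrow(st) - 1) / 2), ,
                                    drop = FALSE],
                                 pairwise_tests(st, method = method)))
    }
  }
  rownames(pairwise_df) <- rownames(anova_df) <- NULL
  structure(list(anova = anova_df,
                 pairwise = significance_pattern(pairwise_df, alpha),
                 alpha = alpha),
            class = "study_stats")
}

#' Write a study report to disk
#'
#' Writes `animals.csv`, `summaries.csv`, `anova.csv`, `pairwise.csv` and
#' a `manifest.json` recording the full configuration, its MD5 hash and
#' the master seed.
#'
#' @param report A `study_report` from [run_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_report <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$animals, file.path(dir, "animals.csv"),
                   row.names = FALSE)
  utils::write.csv(report$summaries, file.path(dir, "summaries.csv"),
                   row.names = FALSE)
  utils::write.csv(report$anova, file.path(dir, "anova.csv"),
                   row.names = FALSE)
  utils::write.csv(report$pairwise, file.path(dir, "pairwise.csv"),
                   row.names = FALSE)
  cfg <- report$config
  cfg_json <- jsonlite::toJSON(
    list(seed = cfg$seed, slab_thickness_um = cfg$slab_thickness_um,
         cavalieri_spacing_um = cfg$cavalieri_spacing_um,
         sections_per_animal = cfg$sections_per_animal,
         point_spacing_um = cfg$point_spacing_um,
         line_spacing_um = cfg$line_spacing_um,
         max_diameter_um = cfg$max_diameter_um, alpha = cfg$alpha,
         cohorts = lapply(cfg$cohorts, function(s) {
           list(shape = s$shape, seed = s$seed, groups = s$groups)
         })),
    auto_unbox = TRUE, digits = NA)
  tmp <- file.path(dir, "config.json")
  writeLines(cfg_json, tmp)
  manifest <- list(format = "stereovasc-report/1",
                   seed = cfg$seed,
                   config_md5 = unname(tools::md5sum(tmp)),
                   n_animals = nrow(report$animals))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}
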