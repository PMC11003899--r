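# Stereological morphometry: per-slide metrics, Weibel-Gomez volume,
# volumetric glomerular density, per-individual aggregation and cohort
# summary.
#
# Unit conventions: object areas in um2, cortex areas in mm2
# (conversion constant UM2_PER_MM2), glomerular volume in mm3,
# densities per mm2 (areal) and per mm3 (volumetric). Statistics that
# are undefined for zero glomeruli are NA, never 0, so they cannot
# silently corrupt cohort means.

# Weibel-Gomez constants: shape coefficient for spheres sectioned at
# random, and the size-distribution correction.
WG_SHAPE_COEF <- 1.382
WG_SIZE_CORR <- 1.01

#' Weibel-Gomez glomerular volume
#'
#' Mean glomerular volume from the mean cross-sectional profile area:
#' \deqn{GV = 1.382 \cdot \bar A^{3/2} / 1.01} with \eqn{\bar A} in
#' um2, converted to mm3 (1 mm3 = 1e9 um3).
#'
#' @param mean_area_um2 mean profile area of non-sclerotic glomeruli
#'   (um2); vectorized.
#' @return glomerular volume in mm3.
#' @export
weibel_gomez_volume <- function(mean_area_um2) {
  if (any(mean_area_um2 < 0, na.rm = TRUE)) stopf("mean area must be >= 0")
  WG_SHAPE_COEF * mean_area_um2^1.5 / WG_SIZE_CORR / 1e9
}

#' Volumetric glomerular density
#'
#' \deqn{VGD = \frac{1}{1.382}\sqrt{(N/A)^3 / (S/A)}} with N the
#' glomerulus count, A the cortex area (mm2) and S the total
#' glomerular profile area (mm2); result in glomeruli per mm3. The
#' quantity is invariant to scaling N, A and S together. The identity
#' \code{VGD * GV = (S/A) / 1.01} holds when GV uses mean area S/N.
#'
#' @param n_glomeruli count of kept glomeruli.
#' @param cortex_area_mm2 cortex area (mm2, > 0).
#' @param total_glom_area_mm2 summed glomerular profile area (mm2, > 0).
#' @return volumetric density, glomeruli per mm3.
#' @export
volumetric_density <- function(n_glomeruli, cortex_area_mm2, total_glom_area_mm2) {
  if (any(cortex_area_mm2 <= 0)) stopf("cortex area must be positive")
  if (any(total_glom_area_mm2 <= 0 & n_glomeruli > 0))
    stopf("total glomerular area must be positive when glomeruli are present")
  (1 / WG_SHAPE_COEF) *
    sqrt((n_glomeruli / cortex_area_mm2)^3 / (total_glom_area_mm2 / cortex_area_mm2))
}

#' Per-slide morphometry
#'
#' Computes count, glomerular density (GD, per mm2 of cortex), mean/SD
#' area, mean perimeter, total glomerular area, Weibel-Gomez volume and
#' volumetric density over the kept objects of one slide.
#'
#' @param kept \code{detected_objects} data.frame of kept objects.
#' @param cortex_area_mm2 measured cortex area (mm2, >= 0).
#' @param slide_id,kidney_side carried through to the output.
#' @return an object of class \code{slide_metrics} (named list). With
#'   zero objects GD is 0 and the size statistics are NA with
#'   \code{size_stats_defined = FALSE}.
#' @export
slide_metrics <- function(kept, cortex_area_mm2, slide_id = NA_character_,
                          kidney_side = NA_character_) {
  if (cortex_area_mm2 < 0) stopf("cortex area must be >= 0")
  n <- nrow(kept)
  if (cortex_area_mm2 == 0 && n > 0)
    stopf("glomeruli outside measurable cortex (cortex area is 0 but %d objects kept)", n)
  if (n > 0) {
    mean_area <- mean(kept$area_um2)
    sd_area <- stats::sd(kept$area_um2)
    mean_per <- mean(kept$perimeter_um)
    total_area_mm2 <- sum(kept$area_um2) / UM2_PER_MM2
    gd <- if (cortex_area_mm2 > 0) n / cortex_area_mm2 else NA_real_
    gv <- weibel_gomez_volume(mean_area)
    vgd <- volumetric_density(n, cortex_area_mm2, total_area_mm2)
  } else {
    mean_area <- sd_area <- mean_per <- gv <- vgd <- NA_real_
    total_area_mm2 <- 0
    gd <- 0
  }
  structure(list(
    slide_id = slide_id, kidney_side = kidney_side,
    n_glomeruli = n, cortex_area_mm2 = cortex_area_mm2,
    gd_per_mm2 = gd, mean_area_um2 = mean_area, sd_area_um2 = sd_area,
    mean_perimeter_um = mean_per, total_glom_area_mm2 = total_area_mm2,
    gv_mm3 = gv, vgd_per_mm3 = vgd,
    size_stats_defined = n > 0
  ), class = "slide_metrics")
}

#' Aggregate two kidneys into individual metrics
#'
#' Mean GD is the mean of the two per-kidney GDs; the total count is
#' the sum over sides and the mean count the total divided by two.
#' Size statistics are averaged over the sides on which they are
#' defined. With one side missing the "means" equal that side's values
#' and \code{single_side} is TRUE.
#'
#' @param left,right \code{slide_metrics} (either may be NULL).
#' @param id individual identifier.
#' @return an object of class \code{individual_metrics}.
#' @export
aggregate_individual <- function(left, right, id = NA_character_) {
  sides <- Filter(Negate(is.null), list(left = left, right = right))
  if (!length(sides)) stopf("at least one side must be present")
  pick <- function(field) vapply(sides, function(s) s[[field]], numeric(1))
  mean_def <- function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  total <- sum(pick("n_glomeruli"))
  structure(list(
    id = id,
    left = if (is.null(left)) NULL else left,
    right = if (is.null(right)) NULL else right,
    single_side = length(sides) == 1L,
    mean_gd = mean(pick("gd_per_mm2")),
    total_count = total,
    mean_count = total / length(sides),
    mean_area_um2 = mean_def(pick("mean_area_um2")),
    mean_perimeter_um = mean_def(pick("mean_perimeter_um")),
    mean_gv_mm3 = mean_def(pick("gv_mm3")),
    mean_vgd_per_mm3 = mean_def(pick("vgd_per_mm3"))
  ), class = "individual_metrics")
}

# 95% order-statistic (binomial) confidence interval for the median.
median_ci <- function(x, conf = 0.95) {
  x <- sort(x[is.finite(x)])
  n <- length(x)
  if (n < 2L) return(c(lower = NA_real_, upper = NA_real_))
  alpha <- (1 - conf) / 2
  lo <- stats::qbinom(alpha, n, 0.5)
  hi <- stats::qbinom(1 - alpha, n, 0.5) + 1L
  c(lower = x[max(1L, lo)], upper = x[min(n, hi)])
}

#' Cohort-level summary of glomerular counts and density
#'
#' @param individuals list of \code{individual_metrics}.
#' @return an object of class \code{cohort_summary}: total glomeruli,
#'   mean per individual, mean per kidney, per-kidney count range,
#'   mean/SD and median GD with a 95% order-statistic confidence
#'   interval.
#' @export
cohort_summary <- function(individuals) {
  if (!length(individuals)) stopf("empty cohort")
  totals <- vapply(individuals, `[[`, numeric(1), "total_count")
  gds <- vapply(individuals, `[[`, numeric(1), "mean_gd")
  side_counts <- unlist(lapply(individuals, function(ind) {
    vapply(Filter(Negate(is.null), list(ind$left, ind$right)),
           `[[`, numeric(1), "n_glomeruli")
  }))
  n <- length(individuals)
  ci <- median_ci(gds)
  structure(list(
    n_individuals = n,
    total_glomeruli = sum(totals),
    mean_per_individual = sum(totals) / n,
    sd_per_individual = stats::sd(totals),
    mean_per_kidney = sum(totals) / (2 * n),
    min_per_kidney = min(side_counts),
    max_per_kidney = max(side_counts),
    mean_gd = mean(gds), sd_gd = stats::sd(gds),
    median_gd = stats::median(gds),
    median_gd_ci_lower = ci[["lower"]], median_gd_ci_upper = ci[["upper"]]
  ), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf(paste0(
    "<cohort_summary> %d individuals\n",
    "  total glomeruli %d; mean %.1f per individual, %.1f per kidney (range %d-%d)\n",
    "  GD %.2f +/- %.2f per mm2; median %.2f (95%% CI %.2f-%.2f)\n"),
    x$n_individuals, x$total_glomeruli, x$mean_per_individual,
    x$mean_per_kidney, x$min_per_kidney, x$max_per_kidney,
    x$mean_gd, x$sd_gd, x$median_gd, x$median_gd_ci_lower, x$median_gd_ci_upper))
  invisible(x)
}

#' Flatten metrics to data.frames
#'
#' @param x a \code{slide_metrics} or \code{individual_metrics}, or a
#'   list of them.
#' @return one-row-per-object data.frame with the canonical column
#'   names (n_glomeruli, cortex_area_mm2, gd_per_mm2, mean_area_um2,
#'   mean_perimeter_um, gv_mm3, vgd_per_mm3, ...).
#' @export
metrics_to_df <- function(x) {
  if (inherits(x, "slide_metrics") || inherits(x, "individual_metrics")) x <- list(x)
  rows <- lapply(x, function(m) {
    if (inherits(m, "slide_metrics")) {
      data.frame(slide_id = m$slide_id, kidney_side = m$kidney_side,
                 n_glomeruli = m$n_glomeruli, cortex_area_mm2 = m$cortex_area_mm2,
                 gd_per_mm2 = m$gd_per_mm2, mean_area_um2 = m$mean_area_um2,
                 sd_area_um2 = m$sd_area_um2, mean_perimeter_um = m$mean_perimeter_um,
                 total_glom_area_mm2 = m$total_glom_area_mm2,
                 gv_mm3 = m$gv_mm3, vgd_per_mm3 = m$vgd_per_mm3)
    } else {
      data.frame(id = m$id, single_side = m$single_side, mean_gd = m$mean_gd,
                 total_count = m$total_count, mean_count = m$mean_count,
                 mean_area_um2 = m$mean_area_um2,
                 mean_perimeter_um = m$mean_perimeter_um,
                 gv_mm3 = m$mean_gv_mm3, vgd_per_mm3 = m$mean_vgd_per_mm3)
    }
  })
  do.call(rbind, rows)
}
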