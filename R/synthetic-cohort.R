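# Synthetic forensic cohort: subject covariates, slide specifications,
# and the eligibility filter that mirrors an autopsy inclusion flow.

# Per-sex covariate parameters (normal mean/SD plus truncation range).
# The kidney-weight dispersions are standard errors in the source
# cohort table; they are converted to SDs (SE * sqrt(n)) here — see the
# methods vignette.
#' Default covariate parameters of the synthetic cohort
#'
#' Returns the per-sex generator parameters: for each continuous
#' covariate a normal (mean, sd) with truncation bounds, plus
#' prevalences for the categorical flags and the glomerular parameters
#' (per-subject mean density 2.23 +/- 0.52 per mm2, mean tuft area
#' 24,337 +/- 5,775 um2, density-area correlation -0.59).
#'
#' @return nested list with elements \code{male}, \code{female},
#'   \code{glomerular}.
#' @export
default_covariate_params <- function() {
  list(
    male = list(
      n = 54L,
      age = c(mean = 40.2, sd = 15.2, min = 18, max = 76),
      height = c(mean = 178.4, sd = 7.1, min = 165, max = 196),
      weight = c(mean = 79.3, sd = 16.7, min = 47, max = 148),
      kidney_weight = c(mean = 161.1, sd = 5.5 * sqrt(54), min = 60, max = 320),
      kidney_length = c(mean = 11.98, sd = 1.0, min = 8, max = 16),
      p_smoker = 12 / 54, p_blood_alcohol = 17 / 54, p_chronic_alcohol = 7 / 54
    ),
    female = list(
      n = 32L,
      age = c(mean = 49.0, sd = 12.1, min = 20, max = 72),
      height = c(mean = 164.5, sd = 7.6, min = 150, max = 180),
      weight = c(mean = 65.0, sd = 14.5, min = 35, max = 100.5),
      kidney_weight = c(mean = 127.5, sd = 4.6 * sqrt(32), min = 50, max = 260),
      kidney_length = c(mean = 11.64, sd = 0.8, min = 8, max = 15),
      p_smoker = 7 / 32, p_blood_alcohol = 4 / 31, p_chronic_alcohol = 7 / 31
    ),
    glomerular = list(
      gd = c(mean = 2.23, sd = 0.52, min = 1.2, max = 3.6),
      area = c(mean = 24337, sd = 5775, min = 12000, max = 38000),
      gd_area_cor = -0.59,
      side_gd_sd = 0.15,     # left/right within-subject density jitter
      side_area_sd = 500     # left/right within-subject area jitter (um2)
    )
  )
}

#' Body surface area (Du Bois)
#'
#' \code{0.007184 * height^0.725 * weight^0.425} with height in cm and
#' weight in kg.
#'
#' @param height_cm,weight_kg vectors.
#' @return BSA in m2.
#' @export
bsa_du_bois <- function(height_cm, weight_kg) {
  0.007184 * height_cm^0.725 * weight_kg^0.425
}

EXCLUSION_FLAGS <- c("kidney_disease", "trauma", "putrefaction",
                     "drug_toxicity", "blood_depletion", "minor", "mutilated")

draw_covariate <- function(n, p) rnorm_trunc(n, p["mean"], p["sd"], p["min"], p["max"])

# analytic mean of a truncated normal (used by recovery tests as the
# reference the empirical mean must converge to)
truncnorm_mean <- function(mean, sd, min, max) {
  a <- (min - mean) / sd; b <- (max - mean) / sd
  z <- stats::pnorm(b) - stats::pnorm(a)
  mean + sd * (stats::dnorm(a) - stats::dnorm(b)) / z
}

#' Generate a synthetic cohort
#'
#' Draws \code{n_male + n_female} eligible subjects with covariates
#' from per-sex truncated normal distributions, flags from the stated
#' prevalences, BMI derived from height and weight, BSA by Du Bois.
#' Each subject receives a per-kidney glomerular parameter pair
#' (density, mean tuft area) with the configured negative
#' density-area correlation, and two slide specifications
#' (left/right).
#'
#' @param n_male,n_female subjects per sex (defaults 54 and 32).
#' @param covariate_params parameter list as returned by
#'   \code{\link{default_covariate_params}}.
#' @param seed integer seed.
#' @param slide_width_px,slide_height_px,slide_mpp geometry of the
#'   slides attached to each subject.
#' @return list with \code{subjects} (data.frame, one row per subject,
#'   exclusion flags all FALSE) and \code{slide_specs} (named list per
#'   subject of left/right \code{slide_spec}s).
#' @export
generate_cohort <- function(n_male = 54L, n_female = 32L,
                            covariate_params = default_covariate_params(),
                            seed = 1L,
                            slide_width_px = 1200L, slide_height_px = 900L,
                            slide_mpp = 2) {
  if (n_male < 0 || n_female < 0) stopf("subject counts must be >= 0")
  cp <- covariate_params
  with_seed(seed, {
    one_sex <- function(sex, n, p) {
      if (n == 0L) return(NULL)
      height <- draw_covariate(n, p$height)
      weight <- draw_covariate(n, p$weight)
      gp <- cp$glomerular
      area <- rnorm_trunc(n, gp$area["mean"], gp$area["sd"],
                          gp$area["min"], gp$area["max"])
      rho <- gp$gd_area_cor
      gd <- gp$gd["mean"] +
        rho * gp$gd["sd"] / gp$area["sd"] * (area - gp$area["mean"]) +
        sqrt(1 - rho^2) * gp$gd["sd"] * stats::rnorm(n)
      gd <- pmin(pmax(gd, gp$gd["min"]), gp$gd["max"])
      data.frame(
        sex = sex,
        age = draw_covariate(n, p$age),
        height = height, weight = weight,
        bmi = weight / (height / 100)^2,
        bsa = bsa_du_bois(height, weight),
        kidney_weight = draw_covariate(n, p$kidney_weight),
        kidney_length = draw_covariate(n, p$kidney_length),
        smoker = stats::runif(n) < p$p_smoker,
        chronic_alcohol = stats::runif(n) < p$p_chronic_alcohol,
        blood_alcohol = stats::runif(n) < p$p_blood_alcohol,
        mean_gd = gd, mean_area = area
      )
    }
    subjects <- rbind(one_sex("male", n_male, cp$male),
                      one_sex("female", n_female, cp$female))
    if (is.null(subjects) || nrow(subjects) == 0L) {
      subjects <- data.frame()
      return(list(subjects = subjects, slide_specs = list()))
    }
    subjects <- cbind(id = sprintf("S%03d", seq_len(nrow(subjects))), subjects)
    for (fl in EXCLUSION_FLAGS) subjects[[fl]] <- FALSE

    gp <- cp$glomerular
    specs <- lapply(seq_len(nrow(subjects)), function(i) {
      sides <- list()
      for (side in c("left", "right")) {
        gd_i <- max(0.3, subjects$mean_gd[i] + stats::rnorm(1, 0, gp$side_gd_sd))
        area_i <- max(11000, subjects$mean_area[i] + stats::rnorm(1, 0, gp$side_area_sd))
        sides[[side]] <- slide_spec(
          width_px = slide_width_px, height_px = slide_height_px, mpp = slide_mpp,
          target_gd = gd_i, area_mean = area_i, area_sd = 3000,
          seed = as.integer((as.numeric(seed) * 1000 + i * 2 +
                             (side == "right")) %% 2147483647)
        )
      }
      sides
    })
    names(specs) <- subjects$id
    list(subjects = subjects, slide_specs = specs)
  })
}

#' Simulate an autopsy intake with exclusions
#'
#' Produces an intake of \code{n_total} records of which exactly
#' \code{n_total - n_included} carry at least one exclusion flag, with
#' flags assigned from a fixed plausibility mix. Used to exercise the
#' eligibility filter at the scale of a multi-year autopsy series.
#'
#' @param n_total intake size (default 1165).
#' @param n_included records left untouched by any flag (default 86).
#' @param seed integer seed.
#' @return data.frame with id, age and the exclusion flag columns.
#' @export
synthetic_intake <- function(n_total = 1165L, n_included = 86L, seed = 1L) {
  if (n_included > n_total) stopf("n_included cannot exceed n_total")
  with_seed(seed, {
    n_excl <- n_total - n_included
    df <- data.frame(id = sprintf("A%04d", seq_len(n_total)),
                     age = round(rnorm_trunc(n_total, 44, 15, 19, 90)))
    for (fl in EXCLUSION_FLAGS) df[[fl]] <- FALSE
    if (n_excl > 0) {
      excl_rows <- sample(n_total, n_excl)
      # plausibility mix over first-listed reasons
      mix <- c(kidney_disease = 0.45, trauma = 0.15, putrefaction = 0.12,
               drug_toxicity = 0.12, blood_depletion = 0.08, minor = 0.04,
               mutilated = 0.04)
      reason <- sample(names(mix), n_excl, replace = TRUE, prob = mix)
      for (fl in EXCLUSION_FLAGS) df[[fl]][excl_rows[reason == fl]] <- TRUE
      # some records carry a second flag, as real files do
      second <- sample(excl_rows, round(0.2 * n_excl))
      extra <- sample(EXCLUSION_FLAGS, length(second), replace = TRUE)
      for (k in seq_along(second)) {
        fl <- extra[k]
        df[[fl]][second[k]] <- TRUE
      }
      df$age[df$minor] <- sample(14:17, sum(df$minor), replace = TRUE)
    }
    df
  })
}

#' Eligibility filter
#'
#' A record is included iff every exclusion flag is FALSE and age is at
#' least 18. Exclusions are attributed to the first triggered flag in
#' the fixed order kidney_disease, trauma, putrefaction, drug_toxicity,
#' blood_depletion, minor, mutilated; an under-age record without flags
#' is attributed to \code{minor}.
#'
#' @param records data.frame carrying \code{age} and the exclusion flag
#'   columns.
#' @return list with \code{included} (data.frame),
#'   \code{excluded_by_reason} (named integer vector over reasons, in
#'   filter order) and \code{excluded} (data.frame with a
#'   \code{exclusion_reason} column).
#' @export
eligibility_filter <- function(records) {
  if (nrow(records) == 0L) {
    return(list(included = records,
                excluded_by_reason = stats::setNames(integer(length(EXCLUSION_FLAGS)),
                                                     EXCLUSION_FLAGS),
                excluded = cbind(records, exclusion_reason = character(0))))
  }
  missing_cols <- setdiff(c("age", EXCLUSION_FLAGS), names(records))
  if (length(missing_cols))
    stopf("records lack required columns: %s", paste(missing_cols, collapse = ", "))
  flags <- as.matrix(records[, EXCLUSION_FLAGS])
  underage <- records$age < 18
  excluded <- rowSums(flags) > 0 | underage
  reason <- rep(NA_character_, nrow(records))
  for (fl in rev(EXCLUSION_FLAGS)) reason[flags[, fl]] <- fl
  reason[is.na(reason) & underage] <- "minor"
  by_reason <- stats::setNames(
    vapply(EXCLUSION_FLAGS, function(fl) sum(reason == fl, na.rm = TRUE), integer(1)),
    EXCLUSION_FLAGS)
  excl_df <- records[excluded, , drop = FALSE]
  excl_df$exclusion_reason <- reason[excluded]
  list(included = records[!excluded, , drop = FALSE],
       excluded_by_reason = by_reason,
       excluded = excl_df)
}
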