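# End-to-end orchestration: configuration, the synthetic / images
# pipelines, CSV schemas with round-trip guarantees, logging and a
# hashed output manifest.

OBJECT_CSV_COLS <- c("object_id", "slide_id", "kidney_side", "centroid_x_um",
                     "centroid_y_um", "area_um2", "perimeter_um", "excluded",
                     "exclusion_reason")

#' Pipeline configuration
#'
#' @param mode \code{"synthetic"} (generate a cohort with ground truth)
#'   or \code{"images"} (process image files listed in a metadata CSV).
#' @param out_dir output directory (created if absent).
#' @param seed integer seed recorded in every output header.
#' @param n_male,n_female synthetic cohort sizes.
#' @param slide_width_px,slide_height_px,slide_mpp synthetic slide
#'   geometry.
#' @param image_manifest for images mode: CSV with columns path,
#'   slide_id, kidney_side, individual_id, mpp.
#' @param target_mpp working resolution (um/px).
#' @param min_object_um2 detection-time minimum object size.
#' @param area_floor_um2 post-hoc cleaning threshold.
#' @param covariate_params synthetic-cohort parameters (default
#'   \code{\link{default_covariate_params}}).
#' @param run_stats whether to run the cohort statistics stage.
#' @return an object of class \code{run_config}.
#' @export
run_config <- function(mode = c("synthetic", "images"), out_dir, seed = 1L,
                       n_male = 4L, n_female = 4L,
                       slide_width_px = 1200L, slide_height_px = 900L,
                       slide_mpp = 2, image_manifest = NULL,
                       target_mpp = 2, min_object_um2 = 40,
                       area_floor_um2 = 10000,
                       covariate_params = default_covariate_params(),
                       run_stats = TRUE) {
  mode <- match.arg(mode)
  if (target_mpp <= 0 || min_object_um2 <= 0 || area_floor_um2 <= 0)
    stopf("thresholds must be positive")
  if (mode == "images" && is.null(image_manifest))
    stopf("images mode needs an image_manifest CSV")
  structure(list(mode = mode, out_dir = out_dir, seed = as.integer(seed),
                 n_male = n_male, n_female = n_female,
                 slide_width_px = slide_width_px,
                 slide_height_px = slide_height_px, slide_mpp = slide_mpp,
                 image_manifest = image_manifest, target_mpp = target_mpp,
                 min_object_um2 = min_object_um2,
                 area_floor_um2 = area_floor_um2,
                 covariate_params = covariate_params, run_stats = run_stats),
            class = "run_config")
}

log_line <- function(log, fmt, ...) {
  c(log, sprintf("%s %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                 sprintf(fmt, ...)))
}

# numeric columns written with full precision so read-back is exact
write_csv_exact <- function(df, path, header_comment = NULL) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_comment)) writeLines(paste0("# ", header_comment), con)
  utils::write.csv(out, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read the per-object CSV
#'
#' Canonical per-object export: columns object_id, slide_id,
#' kidney_side, centroid_x_um, centroid_y_um, area_um2, perimeter_um,
#' excluded, exclusion_reason. Numeric values round-trip exactly.
#'
#' @param objects \code{detected_objects} data.frame (slide_id /
#'   kidney_side columns added from arguments when absent).
#' @param path destination CSV.
#' @param slide_id,kidney_side identity stamped on rows lacking it.
#' @return \code{path} invisibly (write); the objects data.frame
#'   (read).
#' @export
write_object_csv <- function(objects, path, slide_id = NA_character_,
                             kidney_side = NA_character_) {
  df <- as.data.frame(objects)
  if (!"slide_id" %in% names(df)) df$slide_id <- slide_id
  if (!"kidney_side" %in% names(df)) df$kidney_side <- kidney_side
  if (!"excluded" %in% names(df)) df$excluded <- FALSE
  if (!"exclusion_reason" %in% names(df)) df$exclusion_reason <- "none"
  df$excluded <- as.integer(df$excluded)
  write_csv_exact(df[, OBJECT_CSV_COLS], path)
}

#' @rdname write_object_csv
#' @export
read_object_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  missing_cols <- setdiff(OBJECT_CSV_COLS, names(df))
  if (length(missing_cols))
    stopf("object CSV %s lacks columns: %s", path,
          paste(missing_cols, collapse = ", "))
  bad <- which(!is.finite(df$area_um2) | df$area_um2 < 0)
  if (length(bad))
    stopf("object CSV %s: malformed area_um2 at data line(s) %s", path,
          paste(bad, collapse = ", "))
  for (cl in c("centroid_x_um", "centroid_y_um", "area_um2", "perimeter_um"))
    df[[cl]] <- as.double(df[[cl]])
  df$excluded <- df$excluded != 0
  class(df) <- c("detected_objects", "data.frame")
  df
}

#' Read a cohort metadata CSV
#'
#' Requires id, sex and age columns; exclusion-flag and 0/1 boolean
#' columns are coerced to logical.
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  missing_cols <- setdiff(c("id", "sex", "age"), names(df))
  if (length(missing_cols))
    stopf("cohort CSV %s lacks columns: %s", path,
          paste(missing_cols, collapse = ", "))
  for (cl in intersect(c(EXCLUSION_FLAGS, "smoker", "chronic_alcohol",
                         "blood_alcohol"), names(df)))
    df[[cl]] <- df[[cl]] != 0
  df
}

process_one_slide <- function(image, config, truth = NULL) {
  seg <- segment_slide(image, target_mpp = config$target_mpp,
                       min_object_um2 = config$min_object_um2,
                       area_floor_um2 = config$area_floor_um2)
  sm <- slide_metrics(seg$kept, seg$regions$cortex_area_mm2,
                      slide_id = image$slide_id, kidney_side = image$kidney_side)
  match <- NULL
  if (!is.null(truth) && nrow(truth$glomeruli) > 0)
    match <- match_objects(seg$kept, truth$glomeruli)
  list(seg = seg, metrics = sm, match = match)
}

#' Run the full pipeline
#'
#' Synthetic mode generates a cohort (subjects plus two slides each),
#' runs segmentation, morphometry, validation against the planted
#' ground truth, and the cohort statistics; images mode does the same
#' on user images (without validation). All tables are written under
#' \code{config$out_dir} together with a plain-text log (one entry per
#' stage per slide with counts in/out) and an md5 manifest. Reruns
#' with the same config and seed reproduce the metrics CSVs
#' byte-identically.
#'
#' @param config a \code{run_config}.
#' @return invisibly, a list with subjects, slide metrics data.frame,
#'   individual metrics data.frame, validation report, cohort summary
#'   and (when run) the sex comparison table.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- character(0)
  log <- log_line(log, "run start: mode=%s seed=%d", config$mode, config$seed)

  slides <- list()   # each: list(image, truth or NULL, individual_id)
  subjects <- NULL
  if (config$mode == "synthetic") {
    cohort <- generate_cohort(config$n_male, config$n_female,
                              covariate_params = config$covariate_params,
                              seed = config$seed,
                              slide_width_px = config$slide_width_px,
                              slide_height_px = config$slide_height_px,
                              slide_mpp = config$slide_mpp)
    subjects <- cohort$subjects
    for (id in names(cohort$slide_specs)) {
      for (side in c("left", "right")) {
        sp <- cohort$slide_specs[[id]][[side]]
        sl <- generate_slide(sp, slide_id = paste(id, side, sep = "_"),
                             kidney_side = side)
        slides[[length(slides) + 1L]] <- list(image = sl$image, truth = sl$truth,
                                              individual_id = id)
        log <- log_line(log, "generate %s_%s: %d planted, cortex %.3f mm2",
                        id, side, nrow(sl$truth$glomeruli),
                        sl$truth$cortex_area_mm2)
      }
    }
  } else {
    man <- utils::read.csv(config$image_manifest, stringsAsFactors = FALSE)
    need <- c("path", "slide_id", "kidney_side", "individual_id", "mpp")
    missing_cols <- setdiff(need, names(man))
    if (length(missing_cols))
      stopf("image manifest lacks columns: %s", paste(missing_cols, collapse = ", "))
    if (any(!is.finite(man$mpp) | man$mpp <= 0))
      stopf("image manifest: every image needs a positive mpp")
    for (i in seq_len(nrow(man))) {
      img <- read_slide_image(man$path[i], mpp = man$mpp[i],
                              slide_id = man$slide_id[i],
                              kidney_side = man$kidney_side[i])
      slides[[length(slides) + 1L]] <- list(image = img, truth = NULL,
                                            individual_id = man$individual_id[i])
    }
  }

  slide_mets <- list(); matches <- list(); objects_df <- NULL
  failures <- character(0)
  for (s in slides) {
    res <- tryCatch(process_one_slide(s$image, config, s$truth),
                    error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, s$image$slide_id)
      log <- log_line(log, "FAIL %s: %s", s$image$slide_id, conditionMessage(res))
      next
    }
    log <- log_line(log,
      "segment %s: detected %d, kept %d (min_object %g um2, floor %g um2), cortex %.3f mm2",
      s$image$slide_id, nrow(res$seg$objects), nrow(res$seg$kept),
      config$min_object_um2, config$area_floor_um2,
      res$seg$regions$cortex_area_mm2)
    slide_mets[[s$image$slide_id]] <- c(res["metrics"],
                                        individual_id = s$individual_id)
    if (!is.null(res$match)) matches[[s$image$slide_id]] <- res$match
    obj <- res$seg$objects
    if (nrow(obj)) {
      obj$slide_id <- s$image$slide_id
      obj$kidney_side <- s$image$kidney_side
      objects_df <- rbind(objects_df, obj)
    }
  }

  # per-individual aggregation
  ind_ids <- unique(vapply(slide_mets, `[[`, character(1), "individual_id"))
  individuals <- lapply(ind_ids, function(id) {
    ms <- Filter(function(m) m$individual_id == id, slide_mets)
    side_of <- vapply(ms, function(m) m$metrics$kidney_side, character(1))
    aggregate_individual(
      left = if ("left" %in% side_of) ms[[which(side_of == "left")[1]]]$metrics else NULL,
      right = if ("right" %in% side_of) ms[[which(side_of == "right")[1]]]$metrics else NULL,
      id = id)
  })

  slide_df <- metrics_to_df(lapply(slide_mets, `[[`, "metrics"))
  ind_df <- if (length(individuals)) metrics_to_df(individuals) else NULL
  summ <- if (length(individuals)) cohort_summary(individuals) else NULL
  vrep <- if (length(matches)) validation_report(matches) else NULL

  # cohort statistics stage (synthetic mode with enough subjects)
  sex_tab <- NULL
  if (config$run_stats && !is.null(subjects) && !is.null(ind_df) &&
      all(c("male", "female") %in% subjects$sex)) {
    merged <- merge(subjects, ind_df, by = "id")
    m <- merged[merged$sex == "male", ]; f <- merged[merged$sex == "female", ]
    if (nrow(m) >= 3 && nrow(f) >= 3) {
      for (var in c("mean_gd", "mean_count", "mean_area_um2", "gv_mm3")) {
        cr <- compare_groups(m[[var]], f[[var]], labels = c("male", "female"),
                             variable = var)
        sex_tab <- rbind(sex_tab, data.frame(
          variable = var, mean_male = cr$mean[1], sd_male = cr$sd[1],
          mean_female = cr$mean[2], sd_female = cr$sd[2],
          test_used = cr$test_used, p_value = cr$p_value))
        log <- log_line(log, "stats %s: %s test, p=%.4g", var, cr$test_used,
                        cr$p_value)
      }
    }
  }

  hdr <- sprintf("seed=%d mode=%s", config$seed, config$mode)
  paths <- character(0)
  wr <- function(df, name) {
    if (is.null(df)) return(invisible(NULL))
    p <- file.path(config$out_dir, name)
    write_csv_exact(df, p, header_comment = hdr)
    paths <<- c(paths, p)
  }
  wr(slide_df, "slide_metrics.csv")
  wr(ind_df, "individual_metrics.csv")
  if (!is.null(subjects)) wr(subjects, "subjects.csv")
  if (!is.null(objects_df)) {
    p <- file.path(config$out_dir, "objects.csv")
    write_object_csv(objects_df, p)
    paths <- c(paths, p)
  }
  wr(vrep, "validation.csv")
  wr(sex_tab, "sex_comparison.csv")
  if (!is.null(summ)) {
    wr(data.frame(quantity = names(unclass(summ)),
                  value = unlist(unclass(summ))), "cohort_summary.csv")
  }
  cfg_path <- file.path(config$out_dir, "config.txt")
  cfg <- unclass(config)
  cfg$covariate_params <- NULL
  writeLines(sprintf("%s=%s", names(cfg),
                     vapply(cfg, function(v) paste(format(v), collapse = ","),
                            character(1))), cfg_path)
  manifest <- data.frame(file = basename(paths),
                         md5 = unname(tools::md5sum(paths)))
  utils::write.csv(manifest, file.path(config$out_dir, "manifest.csv"),
                   row.names = FALSE)
  log <- log_line(log, "run end: %d slides ok, %d failed", length(slide_mets),
                  length(failures))
  writeLines(log, file.path(config$out_dir, "run.log"))

  invisible(list(subjects = subjects, slide_metrics = slide_df,
                 individual_metrics = ind_df, validation = vrep,
                 summary = summ, sex_comparison = sex_tab,
                 failures = failures, out_dir = config$out_dir))
}
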