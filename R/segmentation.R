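# Deterministic three-stage segmentation: background/tissue,
# cortex/medulla, glomerulus detection, plus the two size filters.
#
# The detector is a fixed classical operator chain (stain-channel
# absorbance features -> smoothing -> thresholds -> 8-connected
# components) standing behind the same interface a learned model would
# use. Every decision is a pure function of the pixels: there is no
# randomness anywhere in this file.
#
# Feature list (documented contract of the region classifier):
#  * tissue vs background: chromatic saturation of the smoothed image —
#    stained tissue is pink/purple (saturation well above zero at every
#    staining level), background is neutral white;
#  * cortex vs medulla: local mean total absorbance (optical density
#    summed over channels, smoothed within tissue) — cortex stains
#    denser than the tubule-dominated medulla; Otsu's threshold on the
#    outlier-clipped field separates the two modes, with a guard that
#    declares a single region when the modes are not separated;
#  * glomerular tuft: ratio of red to green absorbance (stain-level
#    invariant) combined with relative absorbance depth against the
#    cortex median.

#' Resample a slide to a target resolution
#'
#' Downsamples so that the output is at \code{target_mpp} microns per
#' pixel. Integer factors use exact block averaging; fractional factors
#' use bilinear interpolation with antialiasing. Only downsampling is
#' supported.
#'
#' @param image a \code{slide_image}.
#' @param target_mpp target resolution, microns per pixel (default 2).
#' @return a \code{slide_image} at the target resolution; physical
#'   extent is preserved to within one pixel.
#' @export
standardize_resolution <- function(image, target_mpp = 2) {
  stopifnot(inherits(image, "slide_image"))
  if (image$mpp > target_mpp * 1.0001)
    stopf("resolution coarser than target (%.3g > %.3g um/px): upsampling not supported",
          image$mpp, target_mpp)
  if (abs(image$mpp - target_mpp) / target_mpp < 1e-3) return(image)
  d <- dim(image$pixels)
  f <- target_mpp / image$mpp
  if (abs(f - round(f)) < 1e-9) {
    f <- as.integer(round(f))
    H2 <- d[1] %/% f; W2 <- d[2] %/% f
    out <- array(0, c(H2, W2, 3))
    for (ch in 1:3) {
      m <- image$pixels[seq_len(H2 * f), seq_len(W2 * f), ch]
      # block mean: average f x f tiles
      m <- matrix(colMeans(matrix(m, nrow = f)), nrow = H2, byrow = FALSE)
      m <- t(matrix(colMeans(matrix(t(m), nrow = f)), nrow = W2))
      out[, , ch] <- m
    }
    new_mpp <- image$mpp * f
  } else {
    H2 <- as.integer(round(d[1] * image$mpp / target_mpp))
    W2 <- as.integer(round(d[2] * image$mpp / target_mpp))
    out <- array(0, c(H2, W2, 3))
    for (ch in 1:3) {
      sm <- EBImage::gblur(image$pixels[, , ch], sigma = 0.5 * f)
      out[, , ch] <- EBImage::resize(sm, w = H2, h = W2, filter = "bilinear")
    }
    new_mpp <- image$mpp * d[1] / H2
  }
  slide_image(out, mpp = new_mpp, slide_id = image$slide_id,
              kidney_side = image$kidney_side, stain_level = image$stain_level)
}

#' Classify tissue versus background
#'
#' Background pixels are neutral (near-zero chromatic saturation after
#' smoothing) while stained tissue is not, at any staining level.
#' Enclosed holes smaller than \code{fill_holes_um2} are filled.
#'
#' @param image a \code{slide_image}.
#' @param sat_floor absolute minimum smoothed saturation for tissue;
#'   the working threshold adapts to the slide (Otsu on the saturation
#'   map, guarded against unimodal slides) but never drops below this.
#' @param fill_holes_um2 holes below this area (um2) are filled.
#' @return logical H x W matrix, TRUE for tissue. If no tissue is
#'   found a warning is raised and an all-FALSE mask returned.
#' @export
classify_tissue <- function(image, sat_floor = 0.03,
                            fill_holes_um2 = 1000) {
  stopifnot(inherits(image, "slide_image"))
  sigma <- max(1, 10 / image$mpp)  # 10 um smoothing scale
  sm <- lapply(1:3, function(ch) EBImage::gblur(image$pixels[, , ch], sigma = sigma))
  hi <- pmax(sm[[1]], sm[[2]], sm[[3]])
  lo <- pmin(sm[[1]], sm[[2]], sm[[3]])
  sat <- (hi - lo) / pmax(hi, 0.05)
  t_otsu <- EBImage::otsu(matrix(sat, ncol = 1), range = range(sat) + c(-1e-9, 1e-9))
  upper_mean <- mean(sat[sat >= t_otsu])
  # on an all-tissue slide Otsu splits the tissue mode in half; cap the
  # threshold at half the upper-mode mean so such slides stay intact
  thr <- max(sat_floor, min(t_otsu, 0.5 * upper_mean))
  tissue <- sat >= thr
  if (!any(tissue)) {
    warning("no tissue found on slide: empty mask returned")
    return(tissue)
  }
  fill_small_holes(tissue, max_px = fill_holes_um2 / image$mpp^2)
}

#' Segment cortex and medulla
#'
#' Assigns every tissue pixel to cortex or medulla from the local mean
#' total absorbance (see the feature list in this file), then cleans
#' the medulla mask morphologically. If the absorbance field is
#' unimodal over the tissue (mode separation below
#' \code{min_separation}), the whole tissue is labeled with the denser
#' class, cortex.
#'
#' @param image a \code{slide_image}.
#' @param tissue logical tissue mask from \code{\link{classify_tissue}}.
#' @param smooth_um smoothing scale of the absorbance field (microns).
#' @param min_separation minimum relative contrast between the two
#'   Otsu classes for a medulla to be declared.
#' @return a \code{region_mask}; its \code{cortex_area_mm2} field is
#'   the reported cortical area.
#' @export
segment_cortex_medulla <- function(image, tissue, smooth_um = 30,
                                   min_separation = 0.12) {
  stopifnot(inherits(image, "slide_image"))
  H <- nrow(tissue); W <- ncol(tissue)
  if (!any(tissue)) return(region_mask(matrix(0L, H, W), mpp = image$mpp))

  od_total <- optical_density(image$pixels[, , 1]) +
    optical_density(image$pixels[, , 2]) +
    optical_density(image$pixels[, , 3])
  sm <- smooth_masked(od_total, tissue, sigma = smooth_um / image$mpp)
  v <- sm[tissue]
  clip <- 1.3 * stats::quantile(v, 0.75, names = FALSE)  # suppress tuft outliers
  vc <- pmin(v, clip)
  smc <- pmin(sm, clip)

  thr <- EBImage::otsu(matrix(vc, ncol = 1), range = range(vc) + c(-1e-9, 1e-9))
  lo_mean <- mean(vc[vc < thr])
  # judge mode separation on non-clipped pixels only, so that the
  # clipped glomerular-tuft spike cannot masquerade as a second region,
  # and require both modes to hold real mass: on a cortex-only slide the
  # "high" class is just the thin transition band around the tufts
  hi_sel <- vc >= thr & vc < clip - 1e-9
  hi_vals <- vc[hi_sel]
  hi_mean <- if (length(hi_vals)) mean(hi_vals) else clip
  frac_lo <- mean(vc < thr)
  frac_hi <- mean(hi_sel)
  labels <- matrix(0L, H, W)
  labels[tissue] <- 1L
  if (is.finite(lo_mean) && is.finite(hi_mean) &&
      min(frac_lo, frac_hi) >= 0.08 &&
      (hi_mean - lo_mean) / hi_mean >= min_separation) {
    med <- tissue & smc < thr
    r_px <- max(2L, as.integer(round(18 / image$mpp)))
    br <- disc_brush(r_px)
    med <- EBImage::closing(EBImage::opening(med, br), br) > 0
    med <- med & tissue
    med <- drop_small_components(med, min_px = 0.05 * UM2_PER_MM2 / image$mpp^2)
    labels[med] <- 2L
  }
  region_mask(labels, mpp = image$mpp)
}

#' Detect candidate glomeruli
#'
#' Finds hematoxylin-rich tuft blobs inside the tissue: pixels whose
#' red/green absorbance ratio and relative absorbance depth exceed
#' fixed, stain-level-invariant thresholds form candidates; holes are
#' filled and 8-connected components extracted. Components smaller
#' than \code{min_object_um2} are discarded at this stage; objects
#' whose centroid lies outside the cortex are returned flagged
#' \code{outside_cortex}. Area and Crofton perimeter are reported in
#' physical units.
#'
#' @param image a \code{slide_image} (already at the working
#'   resolution).
#' @param regions a \code{region_mask}.
#' @param min_object_um2 detection-time minimum object size (um2),
#'   default 40.
#' @param ratio_min red/green absorbance ratio threshold.
#' @param depth_min tuft absorbance relative to the cortex median.
#' @return a data.frame of class \code{detected_objects}: object_id,
#'   pixel_count, centroid_x_um, centroid_y_um, area_um2, perimeter_um,
#'   on_border, excluded, exclusion_reason.
#' @export
detect_glomeruli <- function(image, regions, min_object_um2 = 40,
                             ratio_min = 0.5, depth_min = 1.35) {
  stopifnot(inherits(image, "slide_image"), inherits(regions, "region_mask"))
  mpp <- image$mpp
  empty <- data.frame(object_id = integer(0), pixel_count = integer(0),
                      centroid_x_um = numeric(0), centroid_y_um = numeric(0),
                      area_um2 = numeric(0), perimeter_um = numeric(0),
                      on_border = logical(0), excluded = logical(0),
                      exclusion_reason = character(0))
  class(empty) <- c("detected_objects", "data.frame")
  cortex <- regions$labels == 1L
  if (!any(cortex)) return(empty)

  od_r <- optical_density(image$pixels[, , 1])
  od_g <- optical_density(image$pixels[, , 2])
  ratio <- od_r / pmax(od_g, 1e-6)
  depth_ref <- stats::median(od_g[cortex])
  tissue <- regions$labels != 0L
  cand <- tissue & ratio > ratio_min & od_g > depth_min * depth_ref
  cand <- fill_small_holes(cand, max_px = 2000 / mpp^2)

  lab <- label_components(cand, connectivity = 8)
  n <- max(lab)
  if (n == 0L) return(empty)

  idx <- which(lab > 0L)
  comp <- lab[idx]
  rows <- (idx - 1L) %% nrow(lab) + 1L
  cols <- (idx - 1L) %/% nrow(lab) + 1L
  npx <- tabulate(comp, n)
  keep <- which(npx * mpp^2 >= min_object_um2)
  if (!length(keep)) return(empty)

  cx <- (tapply(cols, comp, mean) - 1) * mpp
  cy <- (tapply(rows, comp, mean) - 1) * mpp
  rmin <- tapply(rows, comp, min); rmax <- tapply(rows, comp, max)
  cmin <- tapply(cols, comp, min); cmax <- tapply(cols, comp, max)

  out <- vector("list", length(keep))
  for (j in seq_along(keep)) {
    k <- keep[j]
    r0 <- rmin[[k]]; r1 <- rmax[[k]]; c0 <- cmin[[k]]; c1 <- cmax[[k]]
    sub <- lab[r0:r1, c0:c1, drop = FALSE] == k
    per <- crofton_perimeter(sub, spacing = mpp)
    cen_r <- as.integer(round(cy[[k]] / mpp)) + 1L
    cen_c <- as.integer(round(cx[[k]] / mpp)) + 1L
    cen_r <- min(max(cen_r, 1L), nrow(lab)); cen_c <- min(max(cen_c, 1L), ncol(lab))
    in_cortex <- cortex[cen_r, cen_c]
    out[[j]] <- data.frame(
      object_id = j, pixel_count = npx[k],
      centroid_x_um = cx[[k]], centroid_y_um = cy[[k]],
      area_um2 = npx[k] * mpp^2, perimeter_um = per,
      on_border = r0 == 1L || c0 == 1L || r1 == nrow(lab) || c1 == ncol(lab),
      excluded = !in_cortex,
      exclusion_reason = if (in_cortex) "none" else "outside_cortex"
    )
  }
  res <- do.call(rbind, out)
  res$object_id <- seq_len(nrow(res))
  class(res) <- c("detected_objects", "data.frame")
  res
}

#' Apply the post-hoc area cleaning filter
#'
#' Objects with area strictly below \code{area_floor_um2} are excluded
#' with reason \code{below_area_floor}; an object exactly at the floor
#' is kept. Already-excluded objects stay excluded with their original
#' reason. kept and excluded partition the input.
#'
#' @param objects a \code{detected_objects} data.frame.
#' @param area_floor_um2 cleaning threshold (um2), default 10,000.
#' @return list with elements \code{kept} and \code{excluded}.
#' @export
clean_objects <- function(objects, area_floor_um2 = 10000) {
  stopifnot(is.data.frame(objects), "area_um2" %in% names(objects))
  if (area_floor_um2 <= 0) stopf("area_floor_um2 must be positive")
  excl_prior <- if ("excluded" %in% names(objects)) objects$excluded else rep(FALSE, nrow(objects))
  below <- objects$area_um2 < area_floor_um2 & !excl_prior
  objects$excluded <- excl_prior | below
  if (!"exclusion_reason" %in% names(objects)) objects$exclusion_reason <- "none"
  objects$exclusion_reason[below] <- "below_area_floor"
  kept <- objects[!objects$excluded, , drop = FALSE]
  excluded <- objects[objects$excluded, , drop = FALSE]
  class(kept) <- class(excluded) <- c("detected_objects", "data.frame")
  list(kept = kept, excluded = excluded)
}

#' Run the full segmentation chain on one slide
#'
#' Convenience wrapper: resolution standardization, tissue
#' classification, cortex/medulla segmentation, glomerulus detection
#' and cleaning.
#'
#' @inheritParams standardize_resolution
#' @inheritParams detect_glomeruli
#' @inheritParams clean_objects
#' @return list with \code{image} (standardized), \code{tissue},
#'   \code{regions}, \code{objects} (all detections), \code{kept},
#'   \code{excluded}.
#' @export
segment_slide <- function(image, target_mpp = 2, min_object_um2 = 40,
                          area_floor_um2 = 10000) {
  image <- standardize_resolution(image, target_mpp)
  tissue <- classify_tissue(image)
  regions <- segment_cortex_medulla(image, tissue)
  objects <- detect_glomeruli(image, regions, min_object_um2 = min_object_um2)
  cleaned <- clean_objects(objects, area_floor_um2 = area_floor_um2)
  list(image = image, tissue = tissue, regions = regions, objects = objects,
       kept = cleaned$kept, excluded = cleaned$excluded)
}
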