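# Synthetic H&E kidney-section generator with known ground truth.
#
# A slide is sampled in two stages. `slide_geometry()` draws everything
# that defines the section in physical units (microns): an elliptical
# tissue profile, an inner medullary region bounded by a smooth
# harmonic boundary, and the planted glomeruli (elliptical tufts with a
# pale Bowman-space rim). `render_slide_geometry()` rasterizes that
# geometry at any resolution and staining level, so one geometry can be
# rendered at several scales or intensities for robustness checks.
# `generate_slide()` composes the two.
#
# Rendering works in optical-density (OD) space: each structure has an
# RGB absorbance triplet, textures modulate it multiplicatively, the
# staining level scales all absorbances globally, and the image is
# exp(-OD). Ratios of channel absorbances are therefore invariant to
# the staining level, which is the property the detector exploits.

STAIN_LEVELS <- c(very_low = 0.55, low = 0.80, high = 1.00, very_high = 1.35)

# absorbance palettes at staining level "high"
OD_PALETTE <- list(
  background = c(0.025, 0.030, 0.028),
  cortex     = c(0.095, 0.320, 0.220),
  medulla    = c(0.055, 0.175, 0.125),
  stripe     = c(0.030, 0.115, 0.080),   # added along medullary tubules
  bowman     = c(0.045, 0.130, 0.080),   # pale capsular space
  tuft       = c(0.600, 0.800, 0.360)    # hematoxylin-rich capillary tuft
)

#' Specify a synthetic slide
#'
#' Parameters of one synthetic kidney section. Defaults reproduce the
#' conditions the cohort analysis assumes: planted glomerular density
#' 2.23 per mm2 of cortex, mean tuft cross-section 24,337 um2 (SD
#' 5,775), 2 um/px resolution.
#'
#' @param width_px,height_px image size in pixels (>= 64).
#' @param mpp microns per pixel (> 0).
#' @param cortex_fraction fraction of the tissue profile that is cortex
#'   (0-1); the remainder is the inner medulla.
#' @param target_gd planted glomerular density, glomeruli per mm2 of
#'   cortex (>= 0).
#' @param area_mean,area_sd distribution of tuft cross-sectional area
#'   (um2); draws are truncated below at 10,500 um2 so every planted
#'   glomerulus survives the 10,000 um2 cleaning filter.
#' @param stain_level one of \code{"very_low"}, \code{"low"},
#'   \code{"high"}, \code{"very_high"}.
#' @param seed integer seed; the slide is a pure function of
#'   (spec, seed).
#' @return an object of class \code{slide_spec}.
#' @export
slide_spec <- function(width_px = 1200L, height_px = 900L, mpp = 2,
                       cortex_fraction = 0.55, target_gd = 2.23,
                       area_mean = 24337, area_sd = 5775,
                       stain_level = "high", seed = 1L) {
  if (width_px < 64 || height_px < 64) stopf("slide must be at least 64 x 64 px")
  if (mpp <= 0) stopf("mpp must be positive")
  if (cortex_fraction <= 0 || cortex_fraction > 1)
    stopf("cortex_fraction must be in (0, 1]")
  if (target_gd < 0) stopf("target_gd must be >= 0")
  if (target_gd > 0 && area_mean <= 10000)
    stopf("area_mean must exceed the 10,000 um2 cleaning floor")
  if (!stain_level %in% names(STAIN_LEVELS))
    stopf("stain_level must be one of %s", paste(names(STAIN_LEVELS), collapse = ", "))
  structure(list(width_px = as.integer(width_px), height_px = as.integer(height_px),
                 mpp = mpp, cortex_fraction = cortex_fraction,
                 target_gd = target_gd, area_mean = area_mean, area_sd = area_sd,
                 stain_level = stain_level, seed = as.integer(seed)),
            class = "slide_spec")
}

# Membership helpers for the analytic section geometry. Coordinates in
# microns; the tissue profile is the ellipse u <= 1 with
# u = ((x-cx)/rx)^2 + ((y-cy)/ry)^2, the medulla the region
# sqrt(u) <= s(theta) with s a low-order harmonic perturbation of
# sqrt(1 - cortex_fraction).
geom_u <- function(g, x, y) ((x - g$cx) / g$rx)^2 + ((y - g$cy) / g$ry)^2

geom_s <- function(g, theta) {
  s <- g$s0
  if (g$s0 > 0 && length(g$harm_a)) {
    for (k in seq_along(g$harm_a)) {
      s <- s + g$s0 * (g$harm_a[k] * cos((k + 1) * theta) +
                       g$harm_b[k] * sin((k + 1) * theta))
    }
  }
  pmin(pmax(s, 0), 0.95)
}

geom_region <- function(g, x, y) {
  # 0 background, 1 cortex, 2 medulla
  u <- geom_u(g, x, y)
  th <- atan2((y - g$cy) / g$ry, (x - g$cx) / g$rx)
  r <- sqrt(u)
  out <- integer(length(u))
  inside <- u <= 1
  med <- inside & r <= geom_s(g, th)
  out[inside] <- 1L
  out[med] <- 2L
  out
}

# Analytic cortex area in mm2 (tissue ellipse minus medulla, by
# quadrature over the harmonic boundary).
geom_cortex_area_mm2 <- function(g) {
  tissue <- pi * g$rx * g$ry
  th <- seq(0, 2 * pi, length.out = 4097L)[-1]
  med <- g$rx * g$ry * mean(geom_s(g, th)^2) * pi
  (tissue - med) / UM2_PER_MM2
}

ellipse_perimeter <- function(a, b) {
  h <- ((a - b) / (a + b))^2
  pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
}

#' Sample the physical geometry of a synthetic slide
#'
#' Draws the section outline, the cortex/medulla boundary and the
#' planted glomeruli in physical units. The result is independent of
#' resolution and staining level.
#'
#' @param spec a \code{slide_spec}.
#' @return an object of class \code{slide_geometry}: section ellipse,
#'   medullary boundary harmonics, per-glomerulus parameters (centre,
#'   semi-axes, orientation, true area and perimeter), analytic cortex
#'   area, and texture phases used by the renderer.
#' @export
slide_geometry <- function(spec) {
  stopifnot(inherits(spec, "slide_spec"))
  W_um <- spec$width_px * spec$mpp
  H_um <- spec$height_px * spec$mpp
  with_seed(spec$seed, {
    g <- list(
      cx = W_um / 2, cy = H_um / 2,
      rx = 0.46 * W_um, ry = 0.46 * H_um,
      s0 = sqrt(max(0, 1 - spec$cortex_fraction)),
      harm_a = stats::rnorm(4, 0, 0.05 / (1:4)),
      harm_b = stats::rnorm(4, 0, 0.05 / (1:4)),
      stripe_angle = stats::runif(1, 0, pi),
      stripe_lambda = 30,
      stripe_phase = stats::runif(1, 0, 2 * pi),
      tex_angles = stats::runif(4, 0, pi),
      tex_lambda = stats::runif(4, 25, 45),
      tex_phase = stats::runif(4, 0, 2 * pi),
      spec = spec
    )
    g$cortex_area_mm2 <- geom_cortex_area_mm2(g)
    n_glom <- round(spec$target_gd * g$cortex_area_mm2)

    glom <- NULL
    if (n_glom > 0) {
      area <- rnorm_trunc(n_glom, spec$area_mean, spec$area_sd,
                          lower = 10500, upper = spec$area_mean + 4 * spec$area_sd)
      q <- stats::runif(n_glom, 0.75, 1)
      a <- sqrt(area / (pi * q))
      b <- q * a
      phi <- stats::runif(n_glom, 0, pi)
      min_space <- 1.5 * 2 * sqrt(spec$area_mean / pi)
      cx <- cy <- numeric(n_glom)
      bt <- seq(0, 2 * pi, length.out = 33L)[-1]
      for (i in seq_len(n_glom)) {
        placed <- FALSE
        r_out <- 1.10 * a[i] + 4  # Bowman rim + safety margin, um
        for (try in seq_len(1000L)) {
          px <- stats::runif(1, g$cx - g$rx, g$cx + g$rx)
          py <- stats::runif(1, g$cy - g$ry, g$cy + g$ry)
          # the whole capsule outline must fall in cortex
          bx <- px + r_out * cos(bt); by <- py + r_out * sin(bt)
          if (any(geom_region(g, c(px, bx), c(py, by)) != 1L)) next
          if (i > 1 && any((cx[seq_len(i - 1)] - px)^2 +
                           (cy[seq_len(i - 1)] - py)^2 < min_space^2)) next
          cx[i] <- px; cy[i] <- py; placed <- TRUE; break
        }
        if (!placed) stopf("density infeasible for geometry: could not place glomerulus %d of %d",
                           i, n_glom)
      }
      glom <- data.frame(
        id = seq_len(n_glom), cx_um = cx, cy_um = cy,
        axis_a_um = a, axis_b_um = b, theta = phi,
        area_um2 = pi * a * b,
        perimeter_um = ellipse_perimeter(a, b)
      )
    } else {
      glom <- data.frame(id = integer(0), cx_um = numeric(0), cy_um = numeric(0),
                         axis_a_um = numeric(0), axis_b_um = numeric(0),
                         theta = numeric(0), area_um2 = numeric(0),
                         perimeter_um = numeric(0))
    }
    g$glomeruli <- glom
    class(g) <- "slide_geometry"
    g
  })
}

#' Render a slide geometry
#'
#' Rasterizes a sampled geometry at a given resolution and staining
#' level. The same geometry rendered twice with the same arguments is
#' bit-identical; rendering at a different \code{mpp} or
#' \code{stain_level} changes only the raster, never the ground truth.
#'
#' @param geom a \code{slide_geometry}.
#' @param mpp microns per pixel of the raster (default: the spec's).
#' @param stain_level staining level (default: the spec's).
#' @param noise_sd multiplicative absorbance noise (log-SD); 0 renders
#'   a clean slide.
#' @return a list with \code{image} (a \code{slide_image}) and
#'   \code{truth} (a \code{ground_truth}: region mask, glomerulus
#'   table, analytic cortex area).
#' @export
render_slide_geometry <- function(geom, mpp = NULL, stain_level = NULL,
                                  noise_sd = 0.04, slide_id = NA_character_,
                                  kidney_side = NA_character_) {
  stopifnot(inherits(geom, "slide_geometry"))
  spec <- geom$spec
  mpp <- mpp %||% spec$mpp
  stain_level <- stain_level %||% spec$stain_level
  k <- STAIN_LEVELS[[stain_level]]
  H <- as.integer(round(spec$height_px * spec$mpp / mpp))
  W <- as.integer(round(spec$width_px * spec$mpp / mpp))

  xs <- (seq_len(W) - 1) * mpp   # physical x of each column
  ys <- (seq_len(H) - 1) * mpp   # physical y of each row
  X <- matrix(xs, H, W, byrow = TRUE)
  Y <- matrix(ys, H, W)

  region <- matrix(geom_region(geom, as.vector(X), as.vector(Y)), H, W)
  cortex <- region == 1L
  medulla <- region == 2L

  od <- lapply(1:3, function(ch) matrix(OD_PALETTE$background[ch], H, W))

  # cortex: base palette with a smooth sinusoidal granularity field
  tex <- matrix(0, H, W)
  for (j in 1:4) {
    tex <- tex + sin(2 * pi * (X * cos(geom$tex_angles[j]) +
                               Y * sin(geom$tex_angles[j])) / geom$tex_lambda[j] +
                     geom$tex_phase[j])
  }
  tex <- 1 + 0.025 * tex
  for (ch in 1:3) od[[ch]][cortex] <- OD_PALETTE$cortex[ch] * tex[cortex]

  # medulla: paler base plus elongated tubule-like stripes
  stripe <- 0.5 * (1 + sin(2 * pi * (X * cos(geom$stripe_angle) +
                                     Y * sin(geom$stripe_angle)) /
                           geom$stripe_lambda + geom$stripe_phase))
  for (ch in 1:3) {
    od[[ch]][medulla] <- (OD_PALETTE$medulla[ch] +
                          OD_PALETTE$stripe[ch] * stripe[medulla]) * tex[medulla]
  }

  # glomeruli: pale Bowman rim around a dark mottled tuft
  gl <- geom$glomeruli
  for (i in seq_len(nrow(gl))) {
    a <- gl$axis_a_um[i]; b <- gl$axis_b_um[i]; phi <- gl$theta[i]
    r_out <- 1.10 * a
    c0 <- max(1L, floor((gl$cx_um[i] - r_out) / mpp)); c1 <- min(W, ceiling((gl$cx_um[i] + r_out) / mpp) + 1L)
    r0 <- max(1L, floor((gl$cy_um[i] - r_out) / mpp)); r1 <- min(H, ceiling((gl$cy_um[i] + r_out) / mpp) + 1L)
    xs_l <- xs[c0:c1] - gl$cx_um[i]; ys_l <- ys[r0:r1] - gl$cy_um[i]
    dX <- matrix(xs_l, length(ys_l), length(xs_l), byrow = TRUE)
    dY <- matrix(ys_l, length(ys_l), length(xs_l))
    xr <- (dX * cos(phi) + dY * sin(phi))
    yr <- (-dX * sin(phi) + dY * cos(phi))
    u_t <- (xr / a)^2 + (yr / b)^2
    u_o <- (xr / (1.10 * a))^2 + (yr / (1.10 * b))^2
    tuft <- u_t <= 1
    rim <- !tuft & u_o <= 1
    mott <- 1 + 0.12 * sin(2 * pi * xr / 40) * sin(2 * pi * yr / 40)
    for (ch in 1:3) {
      blk <- od[[ch]][r0:r1, c0:c1]
      blk[rim] <- OD_PALETTE$bowman[ch]
      blk[tuft] <- OD_PALETTE$tuft[ch] * mott[tuft]
      od[[ch]][r0:r1, c0:c1] <- blk
    }
  }

  if (noise_sd > 0) {
    noise_seed <- as.integer((as.numeric(spec$seed) + 77003) %% 2147483647)
    with_seed(noise_seed, {
      shared <- exp(stats::rnorm(H * W, 0, noise_sd))
      for (ch in 1:3) {
        od[[ch]] <- od[[ch]] * shared * exp(stats::rnorm(H * W, 0, noise_sd / 3))
      }
    })
  }

  px <- array(0, c(H, W, 3))
  for (ch in 1:3) px[, , ch] <- exp(-k * od[[ch]])
  px <- pmin(pmax(px, 0), 1)

  truth <- structure(list(
    region_mask = region_mask(region, mpp = mpp),
    glomeruli = gl[, c("id", "cx_um", "cy_um", "axis_a_um", "axis_b_um",
                       "area_um2", "perimeter_um")],
    cortex_area_mm2 = geom$cortex_area_mm2,
    geometry = geom
  ), class = "ground_truth")

  list(
    image = slide_image(px, mpp = mpp, slide_id = slide_id,
                        kidney_side = kidney_side, stain_level = stain_level),
    truth = truth
  )
}

#' Generate a synthetic slide with ground truth
#'
#' Samples a geometry from \code{spec} and renders it. Identical
#' (spec, seed) pairs yield bit-identical images and ground truth.
#'
#' @inheritParams slide_geometry
#' @inheritParams render_slide_geometry
#' @return list with \code{image} and \code{truth}; see
#'   \code{\link{render_slide_geometry}}.
#' @export
generate_slide <- function(spec, noise_sd = 0.04, slide_id = NA_character_,
                           kidney_side = NA_character_) {
  geom <- slide_geometry(spec)
  render_slide_geometry(geom, noise_sd = noise_sd, slide_id = slide_id,
                        kidney_side = kidney_side)
}

#' Write ground truth to plain-text files
#'
#' The region mask goes to an indexed PNG (0 background, 1 cortex,
#' 2 medulla), the glomerulus table to a CSV with columns id, cx_um,
#' cy_um, axis_a_um, axis_b_um, area_um2, perimeter_um.
#'
#' @param truth a \code{ground_truth}.
#' @param mask_path,csv_path destinations.
#' @return invisibly, the two paths.
#' @export
write_ground_truth <- function(truth, mask_path, csv_path) {
  write_region_mask(truth$region_mask, mask_path)
  utils::write.csv(truth$glomeruli, csv_path, row.names = FALSE)
  invisible(c(mask_path, csv_path))
}
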