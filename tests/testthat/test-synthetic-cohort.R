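# Slide generator and cohort generator: determinism, planted-count
# conservation, geometric invariants, covariate recovery, eligibility.

test_that("identical spec and seed reproduce a slide bit for bit", {
  spec <- tiny_spec(seed = 5L)
  a <- generate_slide(spec)
  b <- generate_slide(spec)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$truth$glomeruli, b$truth$glomeruli)
  expect_identical(a$truth$region_mask$labels, b$truth$region_mask$labels)
})

test_that("planted count conserves round(target_gd x cortex area) and areas match pi*a*b", {
  for (seed in 1:5) {
    spec <- tiny_spec(seed = seed, target_gd = runif(1, 1.3, 3.5))
    tr <- generate_slide(spec)$truth
    expect_identical(nrow(tr$glomeruli),
                     as.integer(round(spec$target_gd * tr$cortex_area_mm2)))
    if (nrow(tr$glomeruli)) {
      expect_true(all(abs(tr$glomeruli$area_um2 /
                          (pi * tr$glomeruli$axis_a_um * tr$glomeruli$axis_b_um) - 1)
                      < 1e-3))
      # every planted glomerulus survives the cleaning floor
      expect_true(all(tr$glomeruli$area_um2 > 10000))
    }
  }
})

test_that("no planted glomerulus extends into medulla or background", {
  sl <- generate_slide(tiny_spec(seed = 9L))
  g <- sl$truth$geometry
  th <- seq(0, 2 * pi, length.out = 73)[-1]
  for (i in seq_len(nrow(g$glomeruli))) {
    gl <- g$glomeruli[i, ]
    # outer capsule outline, densely sampled, must lie in cortex
    r_out <- 1.10 * gl$axis_a_um
    pts_x <- gl$cx_um + r_out * cos(th)
    pts_y <- gl$cy_um + r_out * sin(th)
    expect_true(all(glomorph:::geom_region(g, pts_x, pts_y) == 1L))
  }
  # and at pixel level: tuft-colored pixels only on cortex ground truth
  od_r <- -log(pmax(sl$image$pixels[, , 1], 0.02))
  od_g <- -log(pmax(sl$image$pixels[, , 2], 0.02))
  tuftish <- od_r / pmax(od_g, 1e-6) > 0.55 & od_g > 0.55
  expect_true(all(sl$truth$region_mask$labels[tuftish] == 1L))
})

test_that("degenerate densities behave: zero density and infeasible packing", {
  sl <- generate_slide(tiny_spec(seed = 2L, target_gd = 0))
  expect_identical(nrow(sl$truth$glomeruli), 0L)
  expect_identical(dim(sl$image$pixels)[1:2], c(600L, 800L))
  # far too many large glomeruli for a thin cortex band
  expect_error(
    generate_slide(slide_spec(width_px = 400L, height_px = 300L,
                              cortex_fraction = 0.3, target_gd = 30,
                              area_mean = 24000, area_sd = 1000, seed = 1L)),
    "density infeasible")
})

test_that("rendering the same geometry at another stain level or scale keeps ground truth", {
  geom <- slide_geometry(tiny_spec(seed = 3L))
  a <- render_slide_geometry(geom, stain_level = "very_low")
  b <- render_slide_geometry(geom, stain_level = "very_high")
  expect_identical(a$truth$glomeruli, b$truth$glomeruli)
  expect_false(identical(a$image$pixels, b$image$pixels))
  c1 <- render_slide_geometry(geom, mpp = 1)
  expect_identical(dim(c1$image$pixels)[1:2], 2L * dim(a$image$pixels)[1:2])
  expect_identical(c1$truth$glomeruli, a$truth$glomeruli)
})

test_that("cohort defaults are 54 men and 32 women with valid derived covariates", {
  co <- generate_cohort(seed = 7L)
  expect_identical(sum(co$subjects$sex == "male"), 54L)
  expect_identical(sum(co$subjects$sex == "female"), 32L)
  expect_true(all(abs(co$subjects$bmi -
                      co$subjects$weight / (co$subjects$height / 100)^2) < 1e-9))
  expect_true(all(co$subjects$age >= 18))
  expect_identical(length(co$slide_specs), 86L)
  expect_setequal(names(co$slide_specs[[1]]), c("left", "right"))
  # single-record edge case
  one <- generate_cohort(n_male = 0L, n_female = 1L, seed = 1L)
  expect_identical(nrow(one$subjects), 1L)
  expect_identical(one$subjects$sex, "female")
})

test_that("generated covariates recover their (truncated) distribution parameters", {
  cp <- default_covariate_params()
  co <- generate_cohort(n_male = 10000L, n_female = 0L, seed = 21L)$subjects
  for (var in c("height", "weight", "age", "kidney_weight")) {
    p <- cp$male[[var]]
    ref <- truncnorm_moments(p["mean"], p["sd"], p["min"], p["max"])
    se <- ref["sd"] / sqrt(10000)
    expect_lt(abs(mean(co[[var]]) - ref["mean"]), 3 * se)
    expect_lt(abs(sd(co[[var]]) / ref["sd"] - 1), 0.05)
  }
  # the worked height check: within 0.5 cm of the nominal 178.4
  expect_lt(abs(mean(co$height) - 178.4), 0.5)
  # planted density-area correlation is negative and near its parameter
  expect_lt(cor(co$mean_gd, co$mean_area), -0.45)
})

test_that("eligibility filter reproduces the intake flow and reason attribution", {
  intake <- synthetic_intake(n_total = 1165L, n_included = 86L, seed = 3L)
  res <- eligibility_filter(intake)
  expect_identical(nrow(res$included), 86L)
  expect_identical(sum(res$excluded_by_reason), 1079L)
  expect_identical(nrow(res$excluded), 1079L)

  # empty input
  empty <- eligibility_filter(intake[0, ])
  expect_identical(nrow(empty$included), 0L)
  expect_true(all(empty$excluded_by_reason == 0L))

  # single-flag record lands under that reason
  rec <- intake[1, ]; rec[glomorph:::EXCLUSION_FLAGS] <- FALSE
  rec$blood_depletion <- TRUE
  one <- eligibility_filter(rec)
  expect_identical(nrow(one$included), 0L)
  expect_identical(one$excluded$exclusion_reason, "blood_depletion")

  # first-triggered-flag order: kidney_disease outranks mutilated
  rec$kidney_disease <- TRUE; rec$mutilated <- TRUE
  expect_identical(eligibility_filter(rec)$excluded$exclusion_reason,
                   "kidney_disease")

  # under-age without flags is excluded as minor
  rec2 <- intake[2, ]; rec2[glomorph:::EXCLUSION_FLAGS] <- FALSE
  rec2$age <- 17
  expect_identical(eligibility_filter(rec2)$excluded$exclusion_reason, "minor")
})
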