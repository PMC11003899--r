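# Stereological quantities: direct quotients, Weibel-Gomez volume,
# volumetric density, aggregation, cohort summary; all against
# brute-force oracles or closed forms.

mk_objects <- function(areas, perims = NULL) {
  data.frame(object_id = seq_along(areas), area_um2 = areas,
             perimeter_um = if (is.null(perims)) sqrt(areas) * 3.8 else perims)
}

test_that("slide metrics equal a brute-force recomputation", {
  # the direct quotient: 682 glomeruli on 300 mm2 of cortex
  sm <- slide_metrics(mk_objects(rep(24000, 682)), 300)
  expect_equal(sm$gd_per_mm2, 682 / 300)
  expect_equal(sm$gd_per_mm2, 2.2733, tolerance = 1e-4)

  set.seed(31)
  for (trial in 1:5) {
    n <- sample(5:40, 1)
    areas <- runif(n, 10000, 35000)
    perims <- runif(n, 350, 700)
    A <- runif(1, 50, 400)
    sm <- slide_metrics(mk_objects(areas, perims), A)
    expect_equal(sm$n_glomeruli, n)
    expect_equal(sm$gd_per_mm2, n / A)
    expect_equal(sm$mean_area_um2, sum(areas) / n)
    expect_equal(sm$sd_area_um2, sd(areas))
    expect_equal(sm$mean_perimeter_um, sum(perims) / n)
    expect_equal(sm$total_glom_area_mm2, sum(areas) / 1e6)
    expect_equal(sm$gv_mm3, 1.382 * mean(areas)^1.5 / 1.01 / 1e9)
    expect_lte(sm$total_glom_area_mm2, sm$cortex_area_mm2)
  }
})

test_that("zero-object slides flag undefined size statistics instead of zeros", {
  sm <- slide_metrics(mk_objects(numeric(0)), 100)
  expect_identical(sm$gd_per_mm2, 0)
  expect_true(is.na(sm$mean_area_um2))
  expect_false(sm$size_stats_defined)
  expect_error(slide_metrics(mk_objects(c(20000)), 0), "outside measurable cortex")
})

test_that("Weibel-Gomez volume reproduces printed and exact values", {
  # the printed worked value: women's mean area 23,640.7 um2 -> 0.0050 mm3
  expect_equal(round(weibel_gomez_volume(23640.7), 4), 0.0050)
  # 10,000^1.5 = 1e6 exactly
  expect_equal(weibel_gomez_volume(10000), 1.382e6 / 1.01 / 1e9)
  expect_identical(weibel_gomez_volume(0), 0)
  expect_error(weibel_gomez_volume(-1), ">= 0")
  # monotone increasing
  v <- weibel_gomez_volume(seq(10000, 40000, by = 5000))
  expect_true(all(diff(v) > 0))
})

test_that("volumetric density evaluates its equation and is ratio-invariant", {
  # direct evaluation at cohort-scale numbers
  vgd <- volumetric_density(2.23 * 100, 100, 0.0536 * 100)
  expect_equal(vgd, (1 / 1.382) * sqrt(2.23^3 / 0.0536))
  expect_equal(vgd, 10.41, tolerance = 0.001)
  # doubling n, A and S together leaves it unchanged
  expect_equal(volumetric_density(400, 180, 9), volumetric_density(800, 360, 18))
  expect_error(volumetric_density(10, 100, 0), "positive")
})

test_that("VGD x GV equals areal fraction / 1.01 when GV uses the mean area", {
  set.seed(32)
  for (trial in 1:200) {
    n <- sample(10:2000, 1)
    A <- runif(1, 20, 500)              # mm2 cortex
    mean_area_um2 <- runif(1, 10000, 40000)
    S <- n * mean_area_um2 / 1e6        # mm2 of glomerular profile
    gv <- weibel_gomez_volume(mean_area_um2)
    vgd <- volumetric_density(n, A, S)
    expect_equal(vgd * gv, (S / A) / 1.01, tolerance = 1e-12)
  }
})

test_that("areal fraction stays in (0, 1) on generated slides", {
  sl <- generate_slide(tiny_spec(seed = 15L))
  seg <- segment_slide(sl$image)
  sm <- slide_metrics(seg$kept, seg$regions$cortex_area_mm2)
  frac <- sm$gd_per_mm2 * sm$mean_area_um2 / 1e6
  expect_gt(frac, 0); expect_lt(frac, 1)
  expect_equal(frac, sm$total_glom_area_mm2 / sm$cortex_area_mm2)
})

test_that("two-kidney aggregation matches the printed example and an oracle", {
  mk_sm <- function(n, A = 180) slide_metrics(mk_objects(runif(n, 15000, 30000)), A)
  set.seed(33)
  l <- mk_sm(404); r <- mk_sm(400)
  agg <- aggregate_individual(l, r, id = "X")
  expect_equal(agg$mean_count, 402)
  expect_equal(agg$total_count, 804)
  expect_equal(agg$mean_gd, (l$gd_per_mm2 + r$gd_per_mm2) / 2)

  # identical sides: means equal either side
  agg2 <- aggregate_individual(l, l)
  expect_equal(agg2$mean_gd, l$gd_per_mm2)
  expect_equal(agg2$mean_count, l$n_glomeruli)

  # random pairs against a brute-force recomputation
  for (trial in 1:5) {
    a <- mk_sm(sample(50:500, 1), runif(1, 80, 300))
    b <- mk_sm(sample(50:500, 1), runif(1, 80, 300))
    g <- aggregate_individual(a, b)
    expect_equal(g$total_count, a$n_glomeruli + b$n_glomeruli)
    expect_equal(g$mean_count, g$total_count / 2)
    expect_equal(g$mean_area_um2, mean(c(a$mean_area_um2, b$mean_area_um2)))
  }

  # single side: flagged, means equal that side
  g1 <- aggregate_individual(l, NULL, id = "Y")
  expect_true(g1$single_side)
  expect_equal(g1$mean_gd, l$gd_per_mm2)
  expect_equal(g1$mean_count, l$n_glomeruli)
})

test_that("cohort summary computes totals, per-kidney means and a median CI", {
  set.seed(34)
  mk_ind <- function(n_l, n_r) {
    aggregate_individual(
      slide_metrics(mk_objects(runif(n_l, 15000, 30000)), 170),
      slide_metrics(mk_objects(runif(n_r, 15000, 30000)), 190))
  }
  inds <- lapply(1:20, function(i) mk_ind(sample(100:600, 1), sample(100:600, 1)))
  s <- cohort_summary(inds)
  totals <- vapply(inds, `[[`, numeric(1), "total_count")
  expect_equal(s$total_glomeruli, sum(totals))
  expect_equal(s$mean_per_individual, mean(totals))
  expect_equal(s$mean_per_kidney, mean(totals) / 2)
  gds <- vapply(inds, `[[`, numeric(1), "mean_gd")
  expect_equal(s$median_gd, median(gds))
  expect_lte(s$median_gd_ci_lower, s$median_gd)
  expect_gte(s$median_gd_ci_upper, s$median_gd)

  one <- cohort_summary(list(mk_ind(60, 40)))
  expect_equal(one$mean_per_individual, one$total_glomeruli)
  expect_equal(one$mean_per_kidney, one$total_glomeruli / 2)
  expect_error(cohort_summary(list()), "empty")
})
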