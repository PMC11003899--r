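# Segmentation chain: resolution standardization, tissue and region
# classification, detection, size filters; determinism and robustness.

test_that("resolution standardization preserves physical extent and tissue area", {
  sl <- generate_slide(tiny_spec(seed = 4L, mpp = 1, width_px = 1600L,
                                 height_px = 1200L))
  out <- standardize_resolution(sl$image, 2)
  expect_equal(out$mpp, 2, tolerance = 1e-3)
  expect_identical(dim(out$pixels)[1:2], c(600L, 800L))
  # tissue area conserved across the resample within 1%
  a1 <- sum(classify_tissue(sl$image)) * sl$image$mpp^2
  a2 <- sum(classify_tissue(out)) * out$mpp^2
  expect_lt(abs(a2 / a1 - 1), 0.01)
  # identity when already at target
  expect_identical(standardize_resolution(out, 2), out)
  # upsampling refused
  expect_error(standardize_resolution(out, 1), "coarser than target")
})

test_that("tissue classification matches ground truth and handles blank slides", {
  geom <- slide_geometry(tiny_spec(seed = 6L))
  clean <- render_slide_geometry(geom, noise_sd = 0)
  tissue <- classify_tissue(clean$image)
  expect_gt(mean((clean$truth$region_mask$labels != 0) == tissue), 0.99)
  # determinism
  expect_identical(tissue, classify_tissue(clean$image))
  # uniform white image: warning, zero tissue
  white <- slide_image(array(0.97, c(100, 100, 3)), mpp = 2)
  expect_warning(wt <- classify_tissue(white), "no tissue")
  expect_identical(sum(wt), 0L)
})

test_that("cortex/medulla segmentation is accurate and area estimates track truth", {
  errs <- agree <- numeric(0)
  for (seed in 1:8) {
    sl <- generate_slide(tiny_spec(seed = seed))
    seg <- segment_slide(sl$image)
    truth <- sl$truth$region_mask$labels
    agree <- c(agree, mean((truth == 1) == (seg$regions$labels == 1)))
    errs <- c(errs, abs(seg$regions$cortex_area_mm2 / sl$truth$cortex_area_mm2 - 1))
  }
  expect_true(all(agree > 0.95))
  expect_true(all(errs < 0.05))
})

test_that("a slide without medulla yields zero medulla area", {
  sl <- generate_slide(tiny_spec(seed = 2L, cortex_fraction = 0.9999,
                                 target_gd = 1.5))
  seg <- segment_slide(sl$image)
  expect_lt(seg$regions$medulla_area_mm2, 0.01)
  expect_gt(seg$regions$cortex_area_mm2, 0.95 * sl$truth$cortex_area_mm2)
})

test_that("detection recovers planted glomeruli with matching counts and areas", {
  for (seed in c(11L, 12L, 13L)) {
    sl <- generate_slide(tiny_spec(seed = seed))
    seg <- segment_slide(sl$image)
    truth <- sl$truth$glomeruli
    expect_identical(nrow(seg$kept), nrow(truth))
    m <- match_objects(seg$kept, truth)
    expect_identical(m$n_false_positive, 0L)
    expect_identical(m$n_false_negative, 0L)
    # per-object area within 5% of the planted tuft area
    ord_d <- order(seg$kept$area_um2); ord_t <- order(truth$area_um2)
    expect_true(all(abs(seg$kept$area_um2[ord_d] / truth$area_um2[ord_t] - 1) < 0.05))
    # perimeters close to the true ellipse perimeters
    expect_true(all(abs(seg$kept$perimeter_um[ord_d] /
                        truth$perimeter_um[ord_t] - 1) < 0.05))
  }
})

test_that("detection is deterministic and respects the minimum object size", {
  sl <- generate_slide(tiny_spec(seed = 14L))
  seg1 <- segment_slide(sl$image)
  seg2 <- segment_slide(sl$image)
  expect_identical(seg1$objects, seg2$objects)

  # a sub-threshold tuft (area ~36 um2 < 40) is not returned
  im_small <- paint_tuft(flat_slide(), cx_um = 200, cy_um = 200,
                         a_um = 3.9, b_um = 2.9)
  det <- detect_glomeruli(im_small, all_cortex_mask(im_small))
  expect_identical(nrow(det), 0L)
  # the same shape above threshold is
  im_big <- paint_tuft(flat_slide(), cx_um = 200, cy_um = 200,
                       a_um = 60, b_um = 50)
  det2 <- detect_glomeruli(im_big, all_cortex_mask(im_big))
  expect_identical(nrow(det2), 1L)
  expect_equal(det2$area_um2, pi * 60 * 50, tolerance = 0.03)
})

test_that("medulla-only and empty-cortex inputs give empty detection lists", {
  im <- flat_slide(what = "medulla")
  med_mask <- region_mask(matrix(2L, 200, 200), mpp = 2)
  expect_identical(nrow(detect_glomeruli(im, med_mask)), 0L)
  bg_mask <- region_mask(matrix(0L, 200, 200), mpp = 2)
  expect_identical(nrow(detect_glomeruli(im, bg_mask)), 0L)
})

test_that("objects centred outside the cortex are flagged, not dropped", {
  # tuft painted on a slide whose left half is medulla
  im <- paint_tuft(flat_slide(), cx_um = 100, cy_um = 200, a_um = 60, b_um = 60)
  labels <- matrix(1L, 200, 200)
  labels[, 1:100] <- 2L   # left half (x < 200 um) is medulla
  det <- detect_glomeruli(im, region_mask(labels, mpp = 2))
  expect_identical(nrow(det), 1L)
  expect_true(det$excluded)
  expect_identical(det$exclusion_reason, "outside_cortex")
})

test_that("the cleaning filter applies a strict less-than floor and partitions input", {
  objs <- data.frame(object_id = 1:3, area_um2 = c(9999, 10000, 24750),
                     excluded = FALSE, exclusion_reason = "none")
  res <- clean_objects(objs)
  expect_identical(res$kept$area_um2, c(10000, 24750))
  expect_identical(res$excluded$area_um2, 9999)
  expect_identical(res$excluded$exclusion_reason, "below_area_floor")

  # empty input
  res0 <- clean_objects(objs[0, ])
  expect_identical(nrow(res0$kept), 0L)
  expect_identical(nrow(res0$excluded), 0L)

  # brute-force oracle on random areas; partition is exact
  set.seed(42)
  for (trial in 1:10) {
    areas <- runif(50, 0, 30000)
    o <- data.frame(object_id = 1:50, area_um2 = areas)
    r <- clean_objects(o)
    expect_identical(nrow(r$kept), sum(areas >= 10000))
    expect_identical(nrow(r$kept) + nrow(r$excluded), 50L)
    expect_setequal(c(r$kept$object_id, r$excluded$object_id), 1:50)
  }
})

test_that("density estimates are stable across the four staining levels", {
  geom <- slide_geometry(tiny_spec(seed = 8L))
  gd <- vapply(names(glomorph:::STAIN_LEVELS), function(lev) {
    seg <- segment_slide(render_slide_geometry(geom, stain_level = lev)$image)
    nrow(seg$kept) / seg$regions$cortex_area_mm2
  }, numeric(1))
  expect_lt(diff(range(gd)) / mean(gd), 0.05)
})

test_that("kept counts and areas agree between 1 and 2 um/px renders", {
  geom <- slide_geometry(tiny_spec(seed = 10L))
  seg_fine <- segment_slide(render_slide_geometry(geom, mpp = 1)$image, target_mpp = 2)
  seg_native <- segment_slide(render_slide_geometry(geom, mpp = 2)$image)
  expect_lte(abs(nrow(seg_fine$kept) - nrow(seg_native$kept)),
             ceiling(0.02 * nrow(seg_native$kept)))
  expect_lt(abs(mean(seg_fine$kept$area_um2) / mean(seg_native$kept$area_um2) - 1),
            0.03)
})
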