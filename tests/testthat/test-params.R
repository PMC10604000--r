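# The 13 parameter definitions on exact (unrasterized) landmark sets.

test_that("a fully neutral spine yields all-zero parameters", {
  spec <- spec_from_targets(list(ss = 0, pt = 0, ll = 0, tk = 0, c2s = 0,
                                 c27l = 0, c7_sva = 0, c2_7_sva = 0), seed = 1)
  lm <- landmarks_from_spec(spec)
  v <- signed_values(compute_all(lm))
  expect_true(all(abs(v) < 1e-9))
})

test_that("constructed pelvic geometry reproduces SS, PT and PI", {
  spec <- spec_from_targets(list(ss = 40, pt = 15), seed = 2)
  lm <- landmarks_from_spec(spec)
  expect_equal(sacral_slope(lm), 40, tolerance = 1e-9)
  expect_equal(pelvic_tilt(lm), 15, tolerance = 1e-9)
  expect_equal(pelvic_incidence(lm), 55, tolerance = 1e-9)
  # a horizontal sacral endplate has zero slope
  spec0 <- spec_from_targets(list(ss = 0, pt = 0), seed = 3)
  expect_equal(sacral_slope(landmarks_from_spec(spec0)), 0, tolerance = 1e-9)
  expect_equal(pelvic_tilt(landmarks_from_spec(spec0)), 0, tolerance = 1e-9)
})

test_that("slope and regional parameters match their constructed endplates", {
  spec <- spec_from_targets(list(c2s = 14, c27l = 16, t1s = -25, ss = 38, ll = 50),
                            seed = 4)
  lm <- landmarks_from_spec(spec)
  sl <- slope_parameters(lm)
  expect_equal(sl$c2s, 14, tolerance = 1e-9)
  expect_equal(sl$t1s, -25, tolerance = 1e-9)
  rg <- regional_angles(lm)
  expect_equal(rg$c27l, 16, tolerance = 1e-9)
  expect_equal(rg$ll, 50, tolerance = 1e-9)
  expect_equal(rg$tk, (38 - 50) - (-25), tolerance = 1e-9)  # tk = slope(L1s) - t1s
})

test_that("the additive incidence identities hold to numerical precision", {
  for (seed in 1:50) {
    spec <- spec_from_targets(seed = seed)
    v <- signed_values(compute_all(landmarks_from_spec(spec)))
    expect_lt(abs(v["pi"] - (v["pt"] + v["ss"])), 1e-9)
    expect_lt(abs(v["c2i"] - (v["pt"] + v["c2s"])), 1e-9)
    expect_lt(abs(v["t1i"] - (v["pt"] + v["t1s"])), 1e-9)
  }
})

test_that("the engine agrees with the independent trigonometric oracle", {
  for (seed in c(5, 17, 23)) {
    spec <- spec_from_targets(seed = seed)
    lm <- landmarks_from_spec(spec)
    v <- signed_values(compute_all(lm))
    o <- oracle_params(lm)
    expect_equal(v[names(o)], o, tolerance = 1e-9)
  }
})

test_that("SVA parameters scale with pixel spacing and follow the plumb-line sign", {
  spec <- spec_from_targets(list(c7_sva = 30, c2_7_sva = 18), seed = 6)
  lm <- landmarks_from_spec(spec)
  sva <- sagittal_vertical_axes(lm)
  expect_equal(sva$c7_sva, 30, tolerance = 1e-9)
  expect_equal(sva$c2_7_sva, 18, tolerance = 1e-9)
  sva2 <- sagittal_vertical_axes(lm, spacing = 2 * spec$spacing)
  expect_equal(sva2$c7_sva, 60, tolerance = 1e-9)
  lm$spacing <- NULL
  expect_error(sagittal_vertical_axes(lm), class = "spinalign_calibration_missing")
})

test_that("missing levels degrade to missing-landmarks statuses, not errors", {
  spec <- spec_from_targets(seed = 7)
  lm <- landmarks_from_spec(spec)
  lm$vertebrae$C7 <- NULL
  res <- compute_all(lm)
  st <- stats::setNames(res$status, res$parameter)
  expect_identical(unname(st[c("c27l", "c2_7_sva", "c7_sva")]),
                   rep("missing-landmarks", 3))
  expect_identical(unname(st[c("c2i", "c2s", "t1i", "t1s", "tk", "l1i", "ll",
                               "ss", "pt", "pi")]), rep("computed", 10))
})

test_that("normal-range flags use inclusive bounds on magnitudes", {
  spec <- spec_from_targets(list(ss = 40, pt = 15), seed = 8)
  lm <- landmarks_from_spec(spec)
  ranges <- data.frame(parameter = c("ss", "pt", "pi"),
                       lower = c(30, 0, 40), upper = c(40, 10, 65))
  res <- compute_all(lm, ranges = ranges)
  fl <- stats::setNames(res$range_flag, res$parameter)
  expect_identical(unname(fl["ss"]), "normal")      # 40 on the inclusive bound
  expect_identical(unname(fl["pt"]), "abnormal")    # 15 > 10
  expect_identical(unname(fl["pi"]), "normal")
  expect_identical(unname(fl["ll"]), "unevaluated") # no range supplied
})

test_that("all 13 signed parameters are invariant under translation and mirror+flip", {
  spec <- spec_from_targets(seed = 9)
  lm <- landmarks_from_spec(spec)
  v0 <- signed_values(compute_all(lm))
  lm_t <- transform_landmarks(lm, function(p) p + c(37.5, -12.25))
  expect_equal(signed_values(compute_all(lm_t)), v0, tolerance = 1e-9)
  W <- spec$frame[1]
  lm_m <- transform_landmarks(lm, function(p) c(W - p[1], p[2]), facing = "-x")
  expect_equal(signed_values(compute_all(lm_m)), v0, tolerance = 1e-9)
})

test_that("angles are scale-invariant while SVAs scale with the scene", {
  spec <- spec_from_targets(seed = 10)
  lm <- landmarks_from_spec(spec)
  v0 <- signed_values(compute_all(lm))
  lm_s <- transform_landmarks(lm, function(p) p * 0.5)
  v1 <- signed_values(compute_all(lm_s))
  ang <- setdiff(names(v0), c("c2_7_sva", "c7_sva"))
  expect_equal(v1[ang], v0[ang], tolerance = 1e-9)
  expect_equal(v1[c("c2_7_sva", "c7_sva")], 0.5 * v0[c("c2_7_sva", "c7_sva")],
               tolerance = 1e-9)
})

test_that("measure_case marks computed parameters failed-qc when the gate fails", {
  sc <- measured_scene(seed = 11)
  bad <- sc$masks
  bad[[15]] <- translate_mask(bad[[15]], dx = 40)
  mc <- measure_case(bad, spacing = sc$spec$spacing, reference_masks = sc$masks)
  expect_false(as.logical(mc$success))
  expect_true(all(mc$result$status %in% c("failed-qc", "missing-landmarks")))
})
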