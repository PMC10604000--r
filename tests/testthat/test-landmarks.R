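# Mask-to-landmark conversion: polygon approximation, corner extraction,
# femoral-head centers, scene labeling, IoU, and the success gate.

test_that("approximate_polygon reduces a filled rectangle raster to 4 corner vertices", {
  m <- matrix(0L, 120, 160)
  m[31:90, 41:140] <- 1L  # rectangle x in [40,140], y in [30,90]
  mask <- structure_mask("vertebra", raster = m, frame = c(160, 120))
  poly <- approximate_polygon(mask)
  expect_equal(nrow(poly), 4)
  truth <- rbind(c(40, 30), c(140, 30), c(140, 90), c(40, 90))
  for (i in 1:4) {
    d <- sqrt(rowSums(sweep(poly, 2, truth[i, ])^2))
    expect_lt(min(d), 1.0)
  }
})

test_that("approximate_polygon is idempotent on an already-simple quadrilateral", {
  quad <- rbind(c(0, 0), c(100, 5), c(98, 60), c(-2, 55))
  expect_equal(approximate_polygon(quad), quad)
})

test_that("approximate_polygon smooths sub-tolerance jitter back to 4 vertices", {
  set.seed(7)
  # 100-vertex noisy rectangle; jitter well below 2% of the perimeter
  corners <- rbind(c(0, 0), c(100, 0), c(100, 60), c(0, 60))
  ring <- do.call(rbind, lapply(1:4, function(i) {
    a <- corners[i, ]; b <- corners[(i %% 4) + 1, ]
    t <- seq(0, 1, length.out = 26)[-26]
    cbind(a[1] + t * (b[1] - a[1]), a[2] + t * (b[2] - a[2]))
  }))
  noisy <- ring + matrix(runif(nrow(ring) * 2, -1, 1), ncol = 2)
  poly <- approximate_polygon(noisy, tolerance_fraction = 0.02)
  expect_lte(nrow(poly), 6)
  expect_gte(nrow(poly), 4)
  # all surviving vertices are near the true corners
  for (j in seq_len(nrow(poly))) {
    d <- sqrt(rowSums(sweep(corners, 2, poly[j, ])^2))
    expect_lt(min(d), 3)
  }
  expect_error(approximate_polygon(noisy, tolerance_fraction = 0.5))
})

test_that("extract_corners assigns quadrant roles on an axis-aligned square", {
  sq <- rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10))
  v <- extract_corners(sq, facing = "+x")
  expect_equal(v$superior_anterior, c(10, 0))
  expect_equal(v$superior_posterior, c(0, 0))
  expect_equal(v$inferior_anterior, c(10, 10))
  expect_equal(v$inferior_posterior, c(0, 10))
  # with the opposite facing the anterior/posterior roles swap
  v2 <- extract_corners(sq, facing = "-x")
  expect_equal(v2$superior_anterior, c(0, 0))
  expect_equal(v2$inferior_anterior, c(0, 10))
})

test_that("rotation below 45 degrees cannot permute corner roles", {
  sq <- rbind(c(-5, -5), c(5, -5), c(5, 5), c(-5, 5))
  for (deg in c(-30, -10, 10, 30)) {
    th <- deg * pi / 180
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    rot <- sq %*% t(R)
    v <- extract_corners(rot, centroid = c(0, 0), facing = "+x")
    # oracle: rotate the known role corners and demand nearest-vertex equality
    truth <- list(superior_anterior = c(5, -5), superior_posterior = c(-5, -5),
                  inferior_anterior = c(5, 5), inferior_posterior = c(-5, 5))
    for (role in names(truth)) {
      expect_equal(v[[role]], as.numeric(R %*% truth[[role]]), tolerance = 1e-9)
    }
  }
})

test_that("degenerate polygons raise a corner-extraction failure", {
  expect_error(extract_corners(rbind(c(0, 0), c(10, 0), c(5, 9))),
               class = "spinalign_corner_failure")
  # 4 vertices but two of them nearly coincident
  expect_error(extract_corners(rbind(c(0, 0), c(10, 0), c(10.2, 0.2), c(5, 9))),
               class = "spinalign_corner_failure")
})

test_that("extracted corners are vertices of the input polygon", {
  set.seed(13)
  for (i in 1:20) {
    w <- runif(1, 40, 90); h <- runif(1, 30, 70); th <- runif(1, -30, 30) * pi / 180
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    quad <- sweep(rbind(c(-w/2, -h/2), c(w/2, -h/2), c(w/2, h/2), c(-w/2, h/2)) %*% t(R),
                  2, c(500, 500), `+`)
    v <- extract_corners(quad)
    for (role in CORNER_ROLES) {
      d <- sqrt(rowSums(sweep(quad, 2, v[[role]])^2))
      expect_lt(min(d), 1e-9)
    }
  }
})

test_that("femoral_head_center averages head centroids", {
  d1 <- structure_mask("femoral_head",
                       polygon = cbind(100 + 30 * cos(seq(0, 2 * pi, length.out = 61)[-61]),
                                       900 + 30 * sin(seq(0, 2 * pi, length.out = 61)[-61])))
  d2 <- structure_mask("femoral_head",
                       polygon = cbind(120 + 30 * cos(seq(0, 2 * pi, length.out = 61)[-61]),
                                       900 + 30 * sin(seq(0, 2 * pi, length.out = 61)[-61])))
  expect_equal(femoral_head_center(list(d1, d2)), c(110, 900), tolerance = 1e-6)
  expect_equal(femoral_head_center(list(d1)), c(100, 900), tolerance = 1e-6)
  expect_error(femoral_head_center(list()), class = "spinalign_missing_structure")
})

test_that("the centroid of a rasterized disk recovers the analytic center", {
  g <- expand.grid(x = 0:399 + 0.5, y = 700:1023 + 0.5)
  inside <- (g$x - 200)^2 + (g$y - 880)^2 <= 30^2
  m <- matrix(as.integer(inside), nrow = 324, ncol = 400, byrow = TRUE)
  mask <- structure_mask("femoral_head", raster = m, offset = c(0L, 700L),
                         frame = c(400, 1024))
  expect_lt(sqrt(sum((mask_centroid(mask) - c(200, 880))^2)), 0.5)
})

test_that("label_structures orders and labels a complete synthetic scene", {
  sc <- measured_scene(seed = 2)
  lm <- sc$landmarks
  expect_s3_class(lm, "spine_landmarks")
  expect_identical(names(lm$vertebrae), ALL_LEVELS)
  cy <- vapply(lm$vertebrae, function(v) v$centroid[2], numeric(1))
  expect_true(all(diff(cy) > 0))
  expect_gt(lm$sacral_endplate$midpoint[2], cy["L5"])
  expect_gt(lm$femoral_head_center[2], lm$sacral_endplate$midpoint[2])
})

test_that("labeling is invariant to the input order of the masks", {
  sc <- measured_scene(seed = 3)
  set.seed(99)
  shuffled <- sc$masks[sample(length(sc$masks))]
  lm2 <- label_structures(shuffled, facing = "+x", spacing = sc$spec$spacing)
  for (lvl in ALL_LEVELS) {
    for (role in CORNER_ROLES) {
      expect_equal(lm2$vertebrae[[lvl]][[role]], sc$landmarks$vertebrae[[lvl]][[role]])
    }
  }
  expect_equal(lm2$femoral_head_center, sc$landmarks$femoral_head_center)
})

test_that("strict mode rejects an incomplete vertebral count; partial labels from L5 up", {
  sc <- measured_scene(seed = 4)
  incomplete <- sc$masks[-(1:2)]  # drop C2 and C3
  expect_error(label_structures(incomplete, spacing = 0.25),
               class = "spinalign_level_ambiguity")
  lm <- label_structures(incomplete, spacing = 0.25, mode = "partial")
  expect_identical(names(lm$vertebrae), ALL_LEVELS[-(1:2)])
  expect_identical(names(lm$vertebrae)[1], "C4")
})

test_that("per-level category labels are honored when present", {
  spec <- spec_from_targets(list(ss = 38, pt = 12), seed = 5)
  masks <- rasterize_spec(spec, level_categories = TRUE)
  lm <- label_structures(masks, spacing = spec$spacing)
  expect_identical(names(lm$vertebrae), ALL_LEVELS)
})

test_that("mask_iou matches pixel counting and is symmetric", {
  r1 <- structure_mask("vertebra", polygon = rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10)),
                       frame = c(64, 64))
  r2 <- structure_mask("vertebra", polygon = rbind(c(5, 0), c(15, 0), c(15, 10), c(5, 10)),
                       frame = c(64, 64))
  r3 <- structure_mask("vertebra", polygon = rbind(c(30, 30), c(40, 30), c(40, 40), c(30, 40)),
                       frame = c(64, 64))
  expect_equal(mask_iou(r1, r1), 1.0)
  expect_equal(mask_iou(r1, r3), 0.0)
  expect_equal(mask_iou(r1, r2), 50 / 150, tolerance = 1e-9)
  expect_equal(mask_iou(r1, r2), mask_iou(r2, r1))
})

test_that("dropping masks below the detection-score threshold is applied before labeling", {
  sc <- measured_scene(seed = 6)
  masks <- sc$masks
  # a low-confidence spurious duplicate of one vertebra must be ignored
  dup <- masks[[10]]
  dup$score <- 0.2
  lm <- label_structures(c(masks, list(dup)), spacing = sc$spec$spacing,
                         score_threshold = 0.5)
  expect_identical(names(lm$vertebrae), ALL_LEVELS)
})

test_that("measurement_success gates on structure presence and reference IoU", {
  sc <- measured_scene(seed = 7)
  expect_true(measurement_success(sc$landmarks))
  # translated vertebra drives its IoU far below the 0.80 threshold
  bad <- sc$masks
  bad[[12]] <- translate_mask(bad[[12]], dx = 0.55 * 72)
  lm_bad <- try_label_structures(bad, facing = "+x", spacing = sc$spec$spacing)
  ok <- measurement_success(lm_bad, reference_masks = sc$masks, iou_threshold = 0.80)
  expect_false(as.logical(ok))
  expect_match(attr(ok, "reason"), "IoU")
  # the clean case passes against its own masks as reference
  expect_true(as.logical(measurement_success(sc$landmarks, reference_masks = sc$masks)))
  # a failure record is always unsuccessful
  fail <- try_label_structures(sc$masks[1:3], facing = "+x")
  expect_s3_class(fail, "spinalign_failure")
  expect_false(as.logical(measurement_success(fail)))
})
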