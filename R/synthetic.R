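# Parametric generator of sagittal spine scenes: a chain of convex
# quadrilateral vertebral bodies C2-L5, a sacral trapezoid whose superior
# endplate realizes the target sacral slope, and two femoral-head disks.
# Every one of the 13 parameters is analytically known from the construction,
# which makes the generator the ground-truth oracle for end-to-end tests of
# the mask -> corners -> parameters path.

.N_LEV <- 23L  # C2..C7 (6) + T1..T12 (12) + L1..L5 (5)

# default morphometry (pixels at 2048 x 2048, 0.25 mm/px); proportions are
# compact relative to adult anatomy so the full chain plus pelvis fits the
# frame; every value can be overridden
.default_morphometry <- function() {
  list(heights = c(rep(40, 6), rep(58, 12), rep(76, 5)),
       widths = c(rep(64, 6), rep(72, 12), rep(88, 5)),
       gaps = c(rep(12, 6), rep(13, 12), rep(15, 4), 15),  # gap below each body
       sacral_length = 150, sacral_depth = 130,
       head_radius = 48, head_separation = 36,
       pelvic_radius = 230,
       sacral_mid = c(1020, 1745),
       top_slope_jitter = 3, position_jitter = c(15, 10))
}

.ep_dir <- function(s_deg, fac) {   # anterior endplate direction, image coords
  s <- s_deg / .DEG
  c(fac * cos(s), -sin(s))
}
.ep_up <- function(s_deg, fac) {    # superior normal, image coords
  s <- s_deg / .DEG
  c(-fac * sin(s), -cos(s))
}

.draw <- function(targets, name, lo, hi) {
  if (!is.null(targets[[name]])) as.numeric(targets[[name]]) else stats::runif(1, lo, hi)
}

.stop_spec <- function(msg) {
  stop(errorCondition(msg, class = c("spinalign_infeasible_spec", "spinalign_error")))
}

#' Construct a synthetic spine specification from target parameters
#'
#' Builds the exact geometry of a sagittal spine scene whose analytic ground
#' truth matches every supplied target parameter; unspecified targets are
#' drawn reproducibly from the seed within plausible adult ranges. Regional
#' curvature is distributed across levels by linear interpolation of endplate
#' tilts between the constrained endplates, and the two SVA targets are
#' realized by horizontal placement of the cervical bodies (which leaves all
#' angular parameters untouched).
#'
#' Accepted targets (signed, package conventions): `ss`, `pt`, `ll`, `tk`,
#' `t1s`, `c2s`, `c27l` in degrees, `c7_sva`, `c2_7_sva` in millimetres.
#' `tk` and `t1s` are linked through `t1s = (ss - ll) - tk`; supplying both
#' with inconsistent values is an error, as are geometrically impossible
#' combinations.
#'
#' @param targets Named list of target parameter values (may be empty).
#' @param seed Integer seed for the unspecified draws.
#' @param frame Frame size `c(width, height)` px, default 2048 x 2048.
#' @param spacing Pixel spacing mm/px, default 0.25.
#' @param facing `"+x"` or `"-x"`.
#' @param morphometry Named list overriding entries of the default body
#'   dimensions (heights, widths, gaps, sacral_length, sacral_depth,
#'   head_radius, head_separation, pelvic_radius, sacral_mid).
#' @return An object of class `spine_spec`.
#' @export
spec_from_targets <- function(targets = list(), seed = 1L, frame = c(2048L, 2048L),
                              spacing = 0.25, facing = "+x", morphometry = list()) {
  mm <- utils::modifyList(.default_morphometry(), morphometry)
  fac <- .facing_sign(facing)
  unknown <- setdiff(names(targets),
                     c("ss", "pt", "ll", "tk", "t1s", "c2s", "c27l", "c7_sva", "c2_7_sva"))
  if (length(unknown)) .stop_spec(paste("unknown target(s):", paste(unknown, collapse = ", ")))

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(as.integer(seed))

  ss  <- .draw(targets, "ss", 32, 44)
  pt  <- .draw(targets, "pt", 8, 16)
  # lumbar lordosis tracks sacral slope in normal adults; drawing it relative
  # to SS keeps the implied L1 and T1 endplate tilts in a plausible band
  ll  <- if (!is.null(targets$ll)) as.numeric(targets$ll) else ss + stats::runif(1, 8, 18)
  c2s <- .draw(targets, "c2s", 8, 18)
  c27l <- .draw(targets, "c27l", 10, 22)
  s_l1 <- ss - ll                       # slope of the L1 superior endplate
  if (!is.null(targets$tk) && !is.null(targets$t1s)) {
    tk <- as.numeric(targets$tk); t1s <- as.numeric(targets$t1s)
    if (abs((s_l1 - t1s) - tk) > 1e-9) {
      .stop_spec("targets tk, t1s, ll, ss are mutually inconsistent (tk must equal (ss - ll) - t1s)")
    }
  } else if (!is.null(targets$t1s)) {
    t1s <- as.numeric(targets$t1s); tk <- s_l1 - t1s
  } else {
    tk <- .draw(targets, "tk", 10, 22); t1s <- s_l1 - tk
  }
  c7sva <- .draw(targets, "c7_sva", -5, 35)
  c27sva <- .draw(targets, "c2_7_sva", 8, 28)

  slopes_anchor <- c(c2s, c2s - c27l, t1s, s_l1, ss)
  if (abs(pt) >= 45 || any(abs(slopes_anchor) > 45)) {
    # beyond 45 degrees of endplate tilt the quadrant corner-role rule is
    # geometrically ambiguous, so such scenes are rejected as infeasible
    .stop_spec("target combination implies endplate or pelvic tilts beyond +/-45 degrees")
  }
  if (max(abs(c(c7sva, c27sva))) > 0.45 * frame[1] * spacing) {
    .stop_spec("SVA targets exceed the image frame")
  }

  # endplate slope profile: 46 endplates (sup/inf per body, top-down) plus the
  # sacral endplate as slot 47; linear interpolation between anchored slots
  anchor_idx <- c(1, 2, 12, 13, 37, 47)
  anchor_val <- c(c2s + stats::runif(1, -mm$top_slope_jitter, mm$top_slope_jitter),
                  c2s, c2s - c27l, t1s, s_l1, ss)
  ep_slopes <- stats::approx(anchor_idx, anchor_val, xout = 1:47)$y
  s_sup <- ep_slopes[2 * (1:.N_LEV) - 1]
  s_inf <- ep_slopes[2 * (1:.N_LEV)]

  jit <- mm$position_jitter
  M <- mm$sacral_mid + c(stats::runif(1, -jit[1], jit[1]), stats::runif(1, -jit[2], jit[2]))
  # pelvic line: PT positive when the sacral midpoint is anterior to the heads
  ptr <- pt / .DEG
  F <- M + mm$pelvic_radius * c(-fac * sin(ptr), cos(ptr))

  # chain of body centers, built upward from the sacral endplate
  h <- mm$heights; w <- mm$widths; g <- mm$gaps
  centers <- matrix(NA_real_, .N_LEV, 2)
  link <- (ss + s_inf[.N_LEV]) / 2
  centers[.N_LEV, ] <- M + .ep_up(link, fac) * (g[.N_LEV] + h[.N_LEV] / 2)
  for (i in .N_LEV:2) {
    link <- (s_sup[i] + s_inf[i - 1]) / 2
    centers[i - 1, ] <- centers[i, ] + .ep_up(link, fac) * (h[i] / 2 + g[i - 1] + h[i - 1] / 2)
  }

  # realize the SVA targets by horizontal placement of the cervical block:
  # C7 SVA via a rigid shift of C2..C7, C2-7 SVA via a tapered shift of C2..C6
  P_s <- M - (mm$sacral_length / 2) * .ep_dir(ss, fac)
  A_s <- M + (mm$sacral_length / 2) * .ep_dir(ss, fac)
  cur <- fac * (centers[6, 1] - P_s[1]) * spacing
  centers[1:6, 1] <- centers[1:6, 1] + fac * (c7sva - cur) / spacing
  c7_ps <- centers[6, ] + (h[6] / 2) * .ep_up((s_sup[6] + s_inf[6]) / 2, fac) -
    (w[6] / 2) * .ep_dir(s_sup[6], fac)
  cur2 <- fac * (centers[1, 1] - c7_ps[1]) * spacing
  shift2 <- fac * (c27sva - cur2) / spacing
  centers[1:5, 1] <- centers[1:5, 1] + shift2 * (6 - (1:5)) / 5

  levels <- data.frame(level = .LEVELS, cx = centers[, 1], cy = centers[, 2],
                       width = w, height = h, s_sup = s_sup, s_inf = s_inf,
                       stringsAsFactors = FALSE)

  spec <- structure(list(levels = levels,
                         sacrum = list(anterior = A_s, posterior = P_s, midpoint = M,
                                       slope = ss, length = mm$sacral_length,
                                       depth = mm$sacral_depth),
                         heads = list(center = F, radius = mm$head_radius,
                                      separation = mm$head_separation),
                         frame = as.integer(frame), spacing = spacing,
                         facing = facing, seed = as.integer(seed),
                         targets = list(ss = ss, pt = pt, ll = ll, tk = tk, t1s = t1s,
                                        c2s = c2s, c27l = c27l,
                                        c7_sva = c7sva, c2_7_sva = c27sva)),
                    class = "spine_spec")
  .check_in_frame(spec)
  spec
}

.body_corners <- function(spec, i) {
  fac <- .facing_sign(spec$facing)
  lv <- spec$levels[i, ]
  ctr <- c(lv$cx, lv$cy)
  mid <- (lv$s_sup + lv$s_inf) / 2
  sup_c <- ctr + (lv$height / 2) * .ep_up(mid, fac)
  inf_c <- ctr - (lv$height / 2) * .ep_up(mid, fac)
  list(superior_anterior  = sup_c + (lv$width / 2) * .ep_dir(lv$s_sup, fac),
       superior_posterior = sup_c - (lv$width / 2) * .ep_dir(lv$s_sup, fac),
       inferior_anterior  = inf_c + (lv$width / 2) * .ep_dir(lv$s_inf, fac),
       inferior_posterior = inf_c - (lv$width / 2) * .ep_dir(lv$s_inf, fac))
}

.sacrum_polygon <- function(spec) {
  fac <- .facing_sign(spec$facing)
  s <- spec$sacrum
  down <- -.ep_up(s$slope, fac)
  rbind(s$anterior,
        s$posterior,
        s$midpoint - (0.45 * s$length) * .ep_dir(s$slope, fac) + s$depth * down,
        s$midpoint + (0.30 * s$length) * .ep_dir(s$slope, fac) + s$depth * down)
}

.head_centers <- function(spec) {
  sep <- spec$heads$separation / 2
  rbind(spec$heads$center + c(-sep, 0), spec$heads$center + c(sep, 0))
}

.check_in_frame <- function(spec) {
  pts <- do.call(rbind, c(lapply(seq_len(.N_LEV), function(i) do.call(rbind, .body_corners(spec, i))),
                          list(.sacrum_polygon(spec)),
                          list(.head_centers(spec) + spec$heads$radius),
                          list(.head_centers(spec) - spec$heads$radius)))
  if (min(pts) < 0 || any(pts[, 1] > spec$frame[1]) || any(pts[, 2] > spec$frame[2])) {
    .stop_cls("synthetic geometry falls outside the image frame", "spinalign_frame_error")
  }
  invisible(spec)
}

#' @export
print.spine_spec <- function(x, ...) {
  t <- x$targets
  cat(sprintf("<spine_spec> seed %d, %dx%d px @ %.3g mm/px, facing %s\n",
              x$seed, x$frame[1], x$frame[2], x$spacing, x$facing))
  cat(sprintf("  SS %.1f  PT %.1f  PI %.1f  LL %.1f  TK %.1f  C7 SVA %.1f mm\n",
              t$ss, t$pt, t$ss + t$pt, t$ll, t$tk, t$c7_sva))
  invisible(x)
}

#' Exact landmark set of a synthetic spine
#'
#' The analytically exact (unrasterized) landmark coordinates of a spec, in
#' the same structure the mask-measurement path produces.
#'
#' @param spec A `spine_spec`.
#' @return A `spine_landmarks` object.
#' @export
landmarks_from_spec <- function(spec) {
  vertebrae <- stats::setNames(vector("list", .N_LEV), spec$levels$level)
  for (i in seq_len(.N_LEV)) {
    cs <- .body_corners(spec, i)
    cs$centroid <- (cs$superior_anterior + cs$superior_posterior +
                      cs$inferior_anterior + cs$inferior_posterior) / 4
    vertebrae[[i]] <- structure(cs, class = "vertebra_landmarks")
  }
  structure(list(vertebrae = vertebrae,
                 sacral_endplate = list(anterior = spec$sacrum$anterior,
                                        posterior = spec$sacrum$posterior,
                                        midpoint = spec$sacrum$midpoint),
                 femoral_head_center = spec$heads$center,
                 spacing = spec$spacing, facing = spec$facing),
            class = "spine_landmarks")
}

#' Analytic ground truth of a synthetic spine
#'
#' The 13 parameters computed directly from the construction algebra of the
#' spec (slopes, pelvic geometry, and plumb-line positions), independent of
#' the geometric measurement engine. The additive identities hold to machine
#' precision by construction.
#'
#' @param spec A `spine_spec`.
#' @return Named numeric vector of the 13 signed parameters (degrees / mm).
#' @export
ground_truth <- function(spec) {
  fac <- .facing_sign(spec$facing)
  lv <- spec$levels
  ss <- spec$sacrum$slope
  u <- spec$sacrum$midpoint - spec$heads$center
  pt <- atan2(fac * u[1], -u[2]) * .DEG
  s_c2i <- lv$s_inf[lv$level == "C2"]
  s_c7i <- lv$s_inf[lv$level == "C7"]
  s_t1s <- lv$s_sup[lv$level == "T1"]
  s_l1s <- lv$s_sup[lv$level == "L1"]
  c7_ps <- .body_corners(spec, 6)$superior_posterior
  c2_ctr <- c(lv$cx[1], lv$cy[1])
  c7_ctr <- c(lv$cx[6], lv$cy[6])
  c(c2i = pt + s_c2i, c2s = s_c2i, c27l = s_c2i - s_c7i,
    t1i = pt + s_t1s, t1s = s_t1s, tk = s_l1s - s_t1s,
    l1i = pt + s_l1s, ll = ss - s_l1s, ss = ss, pt = pt, pi = pt + ss,
    c2_7_sva = fac * (c2_ctr[1] - c7_ps[1]) * spec$spacing,
    c7_sva = fac * (c7_ctr[1] - spec$sacrum$posterior[1]) * spec$spacing)
}

#' Rasterize a synthetic spine into structure masks
#'
#' Fills each structure polygon into a binary raster crop (pixel centers
#' inside the polygon) and returns the mask list together with COCO-style
#' polygon annotations. Deterministic for a given spec.
#'
#' @param spec A `spine_spec`.
#' @param circle_vertices Number of vertices of the femoral-head polygon
#'   annotation, default 60.
#' @param level_categories Use per-level category names (`"C2"`..`"L5"`)
#'   instead of the generic `"vertebra"`. Default `FALSE`.
#' @return List of 26 `structure_mask` objects (23 bodies, sacrum, 2 heads),
#'   each with polygon, raster crop, and frame.
#' @export
rasterize_spec <- function(spec, circle_vertices = 60L, level_categories = FALSE) {
  frame <- spec$frame
  masks <- vector("list", .N_LEV + 3L)
  for (i in seq_len(.N_LEV)) {
    cs <- .body_corners(spec, i)
    poly <- rbind(cs$superior_anterior, cs$superior_posterior,
                  cs$inferior_posterior, cs$inferior_anterior)
    sp <- .fill_polygon(poly, frame)
    masks[[i]] <- structure_mask(if (level_categories) spec$levels$level[i] else "vertebra",
                                 polygon = poly, raster = sp$m, offset = sp$offset,
                                 frame = frame)
  }
  spoly <- .sacrum_polygon(spec)
  sp <- .fill_polygon(spoly, frame)
  masks[[.N_LEV + 1L]] <- structure_mask("sacrum", polygon = spoly, raster = sp$m,
                                         offset = sp$offset, frame = frame)
  hc <- .head_centers(spec)
  th <- seq(0, 2 * base::pi, length.out = circle_vertices + 1L)[-(circle_vertices + 1L)]
  for (k in 1:2) {
    poly <- cbind(hc[k, 1] + spec$heads$radius * cos(th),
                  hc[k, 2] + spec$heads$radius * sin(th))
    sp <- .fill_disk(hc[k, ], spec$heads$radius, frame)
    masks[[.N_LEV + 1L + k]] <- structure_mask("femoral_head", polygon = poly,
                                               raster = sp$m, offset = sp$offset,
                                               frame = frame)
  }
  masks
}

# disk raster: pixel centers within radius of the center
.fill_disk <- function(center, radius, frame) {
  x0 <- max(0L, floor(center[1] - radius) - 1L)
  y0 <- max(0L, floor(center[2] - radius) - 1L)
  x1 <- min(frame[1], ceiling(center[1] + radius) + 1L)
  y1 <- min(frame[2], ceiling(center[2] + radius) + 1L)
  xs <- seq(x0, x1 - 1L) + 0.5
  ys <- seq(y0, y1 - 1L) + 0.5
  dx2 <- outer(rep(1, length(ys)), (xs - center[1])^2)
  dy2 <- outer((ys - center[2])^2, rep(1, length(xs)))
  list(offset = c(x0, y0), m = (dx2 + dy2 <= radius^2) * 1L)
}

#' Jitter mask boundaries to emulate segmentation noise
#'
#' Adds independent uniform noise in \[-magnitude, magnitude\] px to every
#' polygon vertex of every mask (rasters are refilled from the jittered
#' polygons). Magnitude 0 returns the masks unchanged; the same seed gives
#' identical output.
#'
#' @param masks List of `structure_mask` objects with polygons.
#' @param magnitude Maximum per-coordinate displacement in pixels (>= 0).
#' @param seed Integer seed.
#' @return List of perturbed `structure_mask` objects.
#' @export
perturb <- function(masks, magnitude, seed = 1L) {
  stopifnot(magnitude >= 0)
  if (magnitude == 0) return(masks)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  lapply(masks, function(m) {
    if (is.null(m$polygon)) stop("perturb() needs polygon geometry")
    poly <- m$polygon + matrix(stats::runif(2 * nrow(m$polygon), -magnitude, magnitude),
                               ncol = 2)
    sp <- if (!is.null(m$raster)) .fill_polygon(poly, m$frame) else NULL
    structure_mask(m$label, polygon = poly,
                   raster = if (is.null(sp)) NULL else sp$m,
                   offset = if (is.null(sp)) c(0L, 0L) else sp$offset,
                   frame = m$frame, score = m$score)
  })
}

# deterministic translation of one mask (used to construct IoU-gate failures
# of known size: IoU after a shift is controlled by the shift fraction)
#' Translate a structure mask
#'
#' Rigidly shifts a mask's polygon (and refills its raster). Useful for
#' constructing controlled segmentation errors of known overlap.
#'
#' @param mask A `structure_mask` with polygon geometry.
#' @param dx,dy Shift in pixels.
#' @return The translated `structure_mask`.
#' @export
translate_mask <- function(mask, dx, dy = 0) {
  poly <- mask$polygon
  poly[, 1] <- poly[, 1] + dx
  poly[, 2] <- poly[, 2] + dy
  sp <- if (!is.null(mask$raster)) .fill_polygon(poly, mask$frame) else NULL
  structure_mask(mask$label, polygon = poly,
                 raster = if (is.null(sp)) NULL else sp$m,
                 offset = if (is.null(sp)) c(0L, 0L) else sp$offset,
                 frame = mask$frame, score = mask$score)
}
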