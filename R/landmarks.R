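# Landmark extraction: polygon approximation, endplate corner extraction,
# femoral-head center, anatomical level labeling, and the IoU quality gate.

# ---- Douglas-Peucker simplification -----------------------------------------

# Perpendicular distances of points to the infinite line through a and b.
.pdist <- function(pts, a, b) {
  d <- b - a
  n2 <- sum(d^2)
  if (n2 < 1e-12) return(sqrt((pts[, 1] - a[1])^2 + (pts[, 2] - a[2])^2))
  abs(d[1] * (a[2] - pts[, 2]) - d[2] * (a[1] - pts[, 1])) / sqrt(n2)
}

# Douglas-Peucker on an open chain (keeps first and last points). Iterative.
.dp_chain <- function(pts, eps) {
  n <- nrow(pts)
  keep <- logical(n)
  keep[c(1, n)] <- TRUE
  stack <- list(c(1, n))
  while (length(stack)) {
    seg <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- seg[1]; j <- seg[2]
    if (j - i < 2) next
    mid <- (i + 1):(j - 1)
    d <- .pdist(pts[mid, , drop = FALSE], pts[i, ], pts[j, ])
    k <- which.max(d)
    if (d[k] > eps) {
      m <- mid[k]
      keep[m] <- TRUE
      stack <- c(stack, list(c(i, m), c(m, j)))
    }
  }
  which(keep)
}

#' Approximate the shape of a mask by a simplified polygon
#'
#' Reduces a mask outline (the traced raster contour, or a supplied polygon)
#' to a simplified polygon by Douglas-Peucker, with the distance tolerance
#' expressed as a fraction of the contour perimeter. On a rasterized convex
#' quadrilateral this recovers the four corner region vertices; vertex jitter
#' smaller than the tolerance is smoothed away.
#'
#' @param mask A `structure_mask`, or a bare n x 2 polygon matrix.
#' @param tolerance_fraction Simplification tolerance as a fraction of the
#'   contour perimeter, in (0, 0.1). Default 0.02.
#' @return Simplified polygon as an m x 2 matrix (m <= n).
#' @export
approximate_polygon <- function(mask, tolerance_fraction = 0.02) {
  if (!is.numeric(tolerance_fraction) || tolerance_fraction <= 0 || tolerance_fraction >= 0.1) {
    stop("tolerance_fraction must lie in (0, 0.1)")
  }
  ring <- if (inherits(mask, "structure_mask")) {
    if (!is.null(mask$polygon)) mask$polygon else .trace_contour(.mask_raster(mask))
  } else {
    as.matrix(mask)
  }
  n <- nrow(ring)
  if (n <= 4) return(ring)
  per <- sum(sqrt(rowSums((ring - ring[c(2:n, 1), , drop = FALSE])^2)))
  eps <- tolerance_fraction * per
  # split the closed ring at two mutually far points, simplify both chains
  cen <- colMeans(ring)
  i1 <- which.max((ring[, 1] - cen[1])^2 + (ring[, 2] - cen[2])^2)
  ring <- ring[c(i1:n, seq_len(i1 - 1)), , drop = FALSE]  # rotate so i1 first
  d1 <- (ring[, 1] - ring[1, 1])^2 + (ring[, 2] - ring[1, 2])^2
  i2 <- which.max(d1)
  k1 <- .dp_chain(ring[1:i2, , drop = FALSE], eps)
  k2 <- .dp_chain(ring[i2:n, , drop = FALSE], eps)
  idx <- unique(c(k1, i2 + k2 - 1))
  idx <- idx[idx != n + 1 & idx != 1 | c(TRUE, rep(FALSE, length(idx) - 1))]
  out <- ring[sort(unique(pmin(idx, n))), , drop = FALSE]
  # drop a duplicated closing vertex if present
  if (nrow(out) > 1 && sqrt(sum((out[1, ] - out[nrow(out), ])^2)) < 1e-9) {
    out <- out[-nrow(out), , drop = FALSE]
  }
  # the chain split points are always kept by the open-chain pass even when
  # they are collinear leftovers; prune them with a cyclic deviation test
  repeat {
    m <- nrow(out)
    if (m <= 3) break
    dev <- vapply(seq_len(m), function(j) {
      .pdist(out[j, , drop = FALSE], out[if (j == 1) m else j - 1, ],
             out[if (j == m) 1 else j + 1, ])
    }, numeric(1))
    jmin <- which.min(dev)
    if (dev[jmin] > eps) break
    out <- out[-jmin, , drop = FALSE]
  }
  out
}

# ---- corner extraction ------------------------------------------------------

.quadrant_dirs <- function(fac) {
  s <- 1 / sqrt(2)
  list(superior_anterior  = c( fac, -1) * s,
       superior_posterior = c(-fac, -1) * s,
       inferior_anterior  = c( fac,  1) * s,
       inferior_posterior = c(-fac,  1) * s)
}

# argmax of projections with ties broken by distance from centroid, then by
# vertex order.
.pick_corner <- function(rel, dir) {
  proj <- rel %*% dir
  d2 <- rowSums(rel^2)
  ord <- order(-proj, -d2, seq_len(nrow(rel)))
  ord[1]
}

# Total-least-squares line fit: list(point, direction) or NULL.
.tls_line <- function(pts) {
  if (nrow(pts) < 2) return(NULL)
  ctr <- colMeans(pts)
  cc <- crossprod(sweep(pts, 2, ctr))
  ev <- eigen(cc, symmetric = TRUE)
  list(point = ctr, direction = ev$vectors[, 1])
}

.line_intersect <- function(l1, l2) {
  d1 <- l1$direction; d2 <- l2$direction
  cr <- d1[1] * d2[2] - d1[2] * d2[1]
  if (abs(cr) < 1e-6) return(NULL)
  dp <- l2$point - l1$point
  t <- (dp[1] * d2[2] - dp[2] * d2[1]) / cr
  l1$point + t * d1
}

# Subpixel refinement of the four corner positions: fit each of the four edges
# of the contour ring between consecutive corners by total least squares
# (excluding points near the corners) and intersect adjacent edge lines.
# Because a pixel is foreground iff its center lies inside the polygon, the
# traced boundary centers sit on average half a pixel inside the true edge;
# each fitted line is therefore shifted half a pixel along its outward normal
# before intersecting, which removes the systematic inward bias.
.refine_corners <- function(corners, contour, exclude_px = 3) {
  m <- nrow(contour)
  body_center <- colMeans(corners)
  ci <- vapply(seq_len(nrow(corners)), function(i) {
    which.min((contour[, 1] - corners[i, 1])^2 + (contour[, 2] - corners[i, 2])^2)
  }, integer(1))
  ord <- order(ci)
  ci <- ci[ord]
  lines <- vector("list", 4)
  for (e in 1:4) {
    i <- ci[e]; j <- if (e < 4) ci[e + 1] else ci[1] + m
    seg <- ((i:j - 1) %% m) + 1
    # drop points close (arc-wise) to either corner
    drop <- min(exclude_px, max(0, (length(seg) - 4) %/% 2))
    if (length(seg) > 2 * drop + 3) seg <- seg[(drop + 1):(length(seg) - drop)]
    l <- .tls_line(contour[seg, , drop = FALSE])
    if (!is.null(l)) {
      nrm <- c(l$direction[2], -l$direction[1])
      if (sum((l$point - body_center) * nrm) < 0) nrm <- -nrm  # outward
      l$point <- l$point + 0.5 * nrm
    }
    lines[[e]] <- l
  }
  refined <- corners
  for (e in 1:4) {
    prev <- if (e == 1) 4 else e - 1
    if (is.null(lines[[prev]]) || is.null(lines[[e]])) next
    p <- .line_intersect(lines[[prev]], lines[[e]])
    k <- ord[e]
    if (!is.null(p) && sqrt(sum((p - corners[k, ])^2)) < 3) refined[k, ] <- p
  }
  refined
}

#' Extract the four endplate corner points of a vertebral body
#'
#' Assigns polygon vertices to the four anatomical corner roles
#' (superior/inferior x anterior/posterior) by maximizing the projection onto
#' the four diagonal directions from the centroid, the rule being stable for
#' near-quadrilateral bodies rotated by less than 45 degrees. When the full
#' traced raster contour is supplied, corner positions are refined to subpixel
#' accuracy by intersecting total-least-squares fits of the adjacent edges.
#'
#' @param polygon Simplified polygon (n x 2 matrix), typically from
#'   [approximate_polygon()].
#' @param centroid Centroid point; computed from the polygon when omitted.
#' @param facing `"+x"` or `"-x"`.
#' @param contour Optional full contour ring for subpixel refinement.
#' @return An object of class `vertebra_landmarks`: points
#'   `superior_anterior`, `superior_posterior`, `inferior_anterior`,
#'   `inferior_posterior`, and `centroid` (mean of the four corners).
#' @export
extract_corners <- function(polygon, centroid = NULL, facing = "+x", contour = NULL) {
  polygon <- as.matrix(polygon)
  if (nrow(polygon) < 4) {
    .stop_cls(sprintf("corner extraction needs >= 4 polygon vertices, got %d", nrow(polygon)),
              "spinalign_corner_failure")
  }
  fac <- .facing_sign(facing)
  if (is.null(centroid)) centroid <- .polygon_centroid(polygon)
  rel <- sweep(polygon, 2, centroid)
  dirs <- .quadrant_dirs(fac)
  idx <- vapply(dirs, function(d) .pick_corner(rel, d), integer(1))
  if (length(unique(idx)) < 4) {
    .stop_cls("fewer than 4 well-separated corner candidates", "spinalign_corner_failure")
  }
  pts <- polygon[idx, , drop = FALSE]
  if (min(dist(pts)) < 1) {
    .stop_cls("corner candidates are not well separated", "spinalign_corner_failure")
  }
  if (!is.null(contour)) {
    pts <- .refine_corners(pts, contour)
    # re-assign roles on the refined positions (refinement is < 3 px, so the
    # quadrant assignment cannot flip for admissible bodies)
    rel2 <- sweep(pts, 2, colMeans(pts))
    ridx <- vapply(dirs, function(d) .pick_corner(rel2, d), integer(1))
    if (length(unique(ridx)) == 4) pts <- pts[ridx, , drop = FALSE]
  }
  out <- list(superior_anterior  = pts[1, ],
              superior_posterior = pts[2, ],
              inferior_anterior  = pts[3, ],
              inferior_posterior = pts[4, ],
              centroid           = colMeans(pts))
  if (out$superior_anterior[2] >= out$inferior_anterior[2] ||
      out$superior_posterior[2] >= out$inferior_posterior[2]) {
    .stop_cls("corner role assignment violates the superior/inferior ordering",
              "spinalign_corner_failure")
  }
  structure(out, class = "vertebra_landmarks")
}

#' Center of the femoral heads
#'
#' With two femoral-head masks, the midpoint of the two per-mask centroids;
#' with one mask, that mask's centroid (single-head fallback when the heads
#' project onto each other).
#'
#' @param masks List of `structure_mask` objects labeled as femoral heads.
#' @return Point `c(x, y)`.
#' @export
femoral_head_center <- function(masks) {
  if (inherits(masks, "structure_mask")) masks <- list(masks)
  if (length(masks) == 0) {
    .stop_cls("no femoral-head mask present", "spinalign_missing_structure")
  }
  if (length(masks) > 2) {
    .stop_cls(sprintf("expected 1 or 2 femoral-head masks, got %d", length(masks)),
              "spinalign_missing_structure")
  }
  ctrs <- vapply(masks, mask_centroid, numeric(2))
  rowMeans(ctrs)
}

# ---- whole-scene labeling ---------------------------------------------------

# polygon (+ contour when rastered) + centroid for a mask
.mask_geometry <- function(mask, tolerance) {
  if (!is.null(mask$raster)) {
    ring <- .trace_contour(.mask_raster(mask))
    list(poly = approximate_polygon(ring, tolerance), contour = ring,
         centroid = .polygon_centroid(ring))
  } else {
    list(poly = approximate_polygon(mask$polygon, tolerance), contour = NULL,
         centroid = .polygon_centroid(mask$polygon))
  }
}

.sacral_endplate <- function(mask, facing, tolerance) {
  g <- .mask_geometry(mask, tolerance)
  fac <- .facing_sign(facing)
  rel <- sweep(g$poly, 2, g$centroid)
  dirs <- .quadrant_dirs(fac)
  ia <- .pick_corner(rel, dirs$superior_anterior)
  ip <- .pick_corner(rel, dirs$superior_posterior)
  if (ia == ip) .stop_cls("cannot identify the sacral superior endplate corners",
                          "spinalign_corner_failure")
  ant <- g$poly[ia, ]; post <- g$poly[ip, ]
  if (!is.null(g$contour)) {
    # refine via the full quadrilateral when possible
    ref <- tryCatch(extract_corners(g$poly, g$centroid, facing, g$contour),
                    error = function(e) NULL)
    if (!is.null(ref)) {
      ant <- ref$superior_anterior
      post <- ref$superior_posterior
    }
  }
  list(anterior = ant, posterior = post, midpoint = (ant + post) / 2)
}

#' Label structure masks into an anatomical landmark set
#'
#' Converts the list of instance masks for one radiograph into anatomically
#' labeled landmarks: vertebral bodies are reduced to four endplate corners
#' and sorted by centroid height, levels are assigned top-down C2..L5 (or
#' taken from per-level category labels when all masks carry them), the sacral
#' superior endplate is the pair of most-superior sacrum corners, and the
#' femoral-head center is attached.
#'
#' @param masks List of `structure_mask` objects (any order).
#' @param facing `"+x"` or `"-x"`.
#' @param spacing Optional pixel spacing in mm/px (kept with the landmark set
#'   for distance parameters).
#' @param mode `"strict"` requires all 23 vertebral bodies C2-L5;
#'   `"partial"` labels upward from L5 (adjacent to the sacrum) when cranial
#'   levels are missing.
#' @param score_threshold Masks with a detection score below this are dropped
#'   before labeling. Default 0.5.
#' @param tolerance_fraction Polygon simplification tolerance, see
#'   [approximate_polygon()].
#' @return An object of class `spine_landmarks`: `vertebrae` (named list of
#'   `vertebra_landmarks` in top-down order), `sacral_endplate` (anterior,
#'   posterior, midpoint), `femoral_head_center`, `spacing`, `facing`. The
#'   input masks are kept in `attr(, "source_masks")` for the QC gate.
#' @export
label_structures <- function(masks, facing = "+x", spacing = NULL,
                             mode = c("strict", "partial"),
                             score_threshold = 0.5, tolerance_fraction = 0.02) {
  mode <- match.arg(mode)
  if (inherits(masks, "structure_mask")) masks <- list(masks)
  keep <- vapply(masks, function(m) is.null(m$score) || m$score >= score_threshold,
                 logical(1))
  masks <- masks[keep]
  cls <- vapply(masks, function(m) .label_class(m$label), character(1))
  sac <- masks[cls == "sacrum"]
  heads <- masks[cls == "femoral_head"]
  verts <- masks[cls == "vertebra"]
  if (length(sac) != 1) {
    .stop_cls(sprintf("expected exactly 1 sacrum mask, got %d", length(sac)),
              "spinalign_missing_structure")
  }
  if (length(heads) < 1) {
    .stop_cls("no femoral-head mask present", "spinalign_missing_structure")
  }
  if (length(verts) < 1) {
    .stop_cls("no vertebral-body masks present", "spinalign_missing_structure")
  }

  geoms <- lapply(verts, .mask_geometry, tolerance = tolerance_fraction)
  cy <- vapply(geoms, function(g) g$centroid[2], numeric(1))
  ord <- order(cy)
  verts <- verts[ord]; geoms <- geoms[ord]; cy <- cy[ord]
  if (any(diff(cy) <= 0)) {
    .stop_cls("vertebral centroid heights are not strictly ordered", "spinalign_level_ambiguity")
  }

  given <- vapply(verts, function(m) .norm_label(m$label), character(1))
  if (all(given %in% .LEVELS) && !anyDuplicated(given)) {
    levels <- given
    if (!identical(order(match(levels, .LEVELS)), seq_along(levels))) {
      .stop_cls("per-level category labels contradict the vertical ordering",
                "spinalign_level_ambiguity")
    }
  } else if (mode == "strict") {
    if (length(verts) != length(.LEVELS)) {
      .stop_cls(sprintf("expected %d vertebral bodies (C2-L5), got %d; use mode='partial' for incomplete scenes",
                        length(.LEVELS), length(verts)),
                "spinalign_level_ambiguity")
    }
    levels <- .LEVELS
  } else {
    if (length(verts) > length(.LEVELS)) {
      .stop_cls("more vertebral bodies than known levels", "spinalign_level_ambiguity")
    }
    levels <- utils::tail(.LEVELS, length(verts))  # label upward from L5
  }

  vertebrae <- stats::setNames(vector("list", length(verts)), levels)
  for (i in seq_along(verts)) {
    vertebrae[[i]] <- extract_corners(geoms[[i]]$poly, geoms[[i]]$centroid,
                                      facing, geoms[[i]]$contour)
  }

  endplate <- .sacral_endplate(sac[[1]], facing, tolerance_fraction)
  fh <- femoral_head_center(heads)

  if (endplate$midpoint[2] <= cy[length(cy)]) {
    .stop_cls("sacral endplate is not below the lowest vertebral body",
              "spinalign_level_ambiguity")
  }
  if (fh[2] <= endplate$midpoint[2]) {
    .stop_cls("femoral-head center is not below the sacral endplate midpoint",
              "spinalign_level_ambiguity")
  }

  out <- structure(list(vertebrae = vertebrae,
                        sacral_endplate = endplate,
                        femoral_head_center = fh,
                        spacing = spacing,
                        facing = facing),
                   class = "spine_landmarks")
  attr(out, "source_masks") <- masks
  out
}

#' @export
print.spine_landmarks <- function(x, ...) {
  lv <- names(x$vertebrae)
  cat(sprintf("<spine_landmarks> %d vertebrae (%s..%s), sacral endplate, femoral-head center (%.1f, %.1f)\n",
              length(lv), lv[1], lv[length(lv)],
              x$femoral_head_center[1], x$femoral_head_center[2]))
  cat(sprintf("  facing %s, spacing %s mm/px\n", x$facing,
              if (is.null(x$spacing)) "<none>" else format(x$spacing)))
  invisible(x)
}

# ---- QC gate ----------------------------------------------------------------

#' Attempt to label a case, capturing failure as a record
#'
#' Wraps [label_structures()] so that extraction failures become a returned
#' failure record rather than an error, matching how unmeasurable cases are
#' accounted for in success-rate summaries.
#'
#' @inheritParams label_structures
#' @return A `spine_landmarks` object, or a `spinalign_failure` record with
#'   the failure message.
#' @export
try_label_structures <- function(masks, ...) {
  tryCatch(label_structures(masks, ...),
           spinalign_error = function(e) {
             structure(list(message = conditionMessage(e), masks = masks),
                       class = "spinalign_failure")
           })
}

#' Measurement success gate
#'
#' A case counts as successfully measured when all required structures were
#' found, corner extraction succeeded, and (when reference masks are
#' available) every structure's IoU against its reference reaches the
#' threshold. Failure is a return state, not an error.
#'
#' @param case A `spine_landmarks` object or a failure record from
#'   [try_label_structures()].
#' @param reference_masks Optional list of reference `structure_mask` objects
#'   for the same scene (matched by structure class and vertical order).
#' @param iou_threshold Minimum acceptable IoU, default 0.80 (strict: a value
#'   just below fails).
#' @return `TRUE`/`FALSE`, with attribute `"reason"` on failure.
#' @export
measurement_success <- function(case, reference_masks = NULL, iou_threshold = 0.80) {
  if (inherits(case, "spinalign_failure")) {
    return(structure(FALSE, reason = case$message))
  }
  if (!inherits(case, "spine_landmarks")) {
    stop("case must be a spine_landmarks object or a failure record")
  }
  if (is.null(reference_masks)) return(TRUE)
  masks <- attr(case, "source_masks")
  if (is.null(masks)) stop("case carries no source masks to compare against references")
  pair_key <- function(ms) {
    cl <- vapply(ms, function(m) .label_class(m$label), character(1))
    cy <- vapply(ms, function(m) mask_centroid(m)[2], numeric(1))
    cx <- vapply(ms, function(m) mask_centroid(m)[1], numeric(1))
    ms[order(cl, round(cy, 3), cx)]
  }
  a <- pair_key(masks); b <- pair_key(reference_masks)
  if (length(a) != length(b)) {
    return(structure(FALSE, reason = "structure count differs from reference"))
  }
  for (i in seq_along(a)) {
    if (.label_class(a[[i]]$label) != .label_class(b[[i]]$label)) {
      return(structure(FALSE, reason = "structure classes do not match reference"))
    }
    iou <- mask_iou(a[[i]], b[[i]])
    if (iou < iou_threshold) {
      return(structure(FALSE,
                       reason = sprintf("%s IoU %.3f below threshold %.2f",
                                        a[[i]]$label, iou, iou_threshold)))
    }
  }
  TRUE
}
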