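# The 13 sagittal alignment and spinopelvic parameters, computed from an
# anatomically labeled landmark set.
#
# Signed conventions (magnitudes are reported alongside; clinical tables
# conventionally print magnitudes):
#   * endplate slopes: positive when the anterior corner is superior,
#   * PT: positive when the sacral endplate midpoint lies anterior to the
#     femoral-head center,
#   * lordosis positive for C27L and LL, kyphosis positive for TK,
#   * SVA: positive when the plumb line falls anterior to its reference
#     landmark.
# These choices make the additive identities exact on ideal landmarks:
#   PI = PT + SS, C2I = PT + C2S, T1I = PT + T1S, L1I = PT + slope(L1 sup).

.PARAMS <- data.frame(
  name = c("c2i", "c2s", "c27l", "t1i", "t1s", "tk", "l1i", "ll",
           "ss", "pt", "pi", "c2_7_sva", "c7_sva"),
  label = c("C2I", "C2S", "C27L", "T1I", "T1S", "TK", "L1I", "LL",
            "SS", "PT", "PI", "C2-7 SVA", "C7 SVA"),
  unit = c(rep("deg", 11), "mm", "mm"),
  stringsAsFactors = FALSE
)

.has_level <- function(lm, level) level %in% names(lm$vertebrae)

# endplate corner pair (anterior, posterior) of a body
.endplate <- function(lm, level, which = c("superior", "inferior")) {
  which <- match.arg(which)
  v <- lm$vertebrae[[level]]
  if (which == "superior") list(anterior = v$superior_anterior, posterior = v$superior_posterior)
  else list(anterior = v$inferior_anterior, posterior = v$inferior_posterior)
}

.endplate_slope_of <- function(lm, level, which) {
  e <- .endplate(lm, level, which)
  endplate_slope(e$anterior, e$posterior, lm$facing)
}

# anatomical-frame down-pointing pelvic ray (sacral midpoint -> femoral heads)
.pelvic_down_ray <- function(lm) {
  d <- lm$femoral_head_center - lm$sacral_endplate$midpoint
  if (sqrt(sum(d^2)) < 1e-9) {
    .stop_geom("femoral-head center coincides with the sacral endplate midpoint")
  }
  .anat(d, .facing_sign(lm$facing))
}

# anatomical-frame downward normal of an endplate with slope s (degrees):
# the down-vertical rotated anteriorly by s
.down_normal <- function(slope_deg) {
  s <- slope_deg / .DEG
  c(sin(s), -cos(s))
}

# signed angle (deg) from vector a to vector b, counterclockwise in the
# anatomical frame (from anterior toward superior)
.anat_angle <- function(a, b) {
  .wrap180(atan2(a[1] * b[2] - a[2] * b[1], sum(a * b)) * .DEG)
}

#' Sacral slope
#'
#' Angle between the sacral superior endplate and the horizontal, positive
#' when the anterior corner is superior.
#'
#' @param landmarks A `spine_landmarks` object.
#' @return Signed angle in degrees (`NA` when the sacrum is missing).
#' @export
sacral_slope <- function(landmarks) {
  ep <- landmarks$sacral_endplate
  if (is.null(ep)) return(NA_real_)
  endplate_slope(ep$anterior, ep$posterior, landmarks$facing)
}

#' Pelvic tilt
#'
#' Angle between the line connecting the femoral-head center to the sacral
#' endplate midpoint and the vertical, positive when the sacral midpoint lies
#' anterior to the femoral heads (so that PI = PT + SS holds exactly).
#'
#' @param landmarks A `spine_landmarks` object.
#' @return Signed angle in degrees.
#' @export
pelvic_tilt <- function(landmarks) {
  if (is.null(landmarks$sacral_endplate) || is.null(landmarks$femoral_head_center)) {
    return(NA_real_)
  }
  d <- .pelvic_down_ray(landmarks)
  .anat_angle(d, c(0, -1))
}

#' Pelvic incidence
#'
#' Angle between the pelvic line (femoral-head center to sacral endplate
#' midpoint) and the perpendicular to the sacral superior endplate, the
#' position-independent pelvic morphology parameter.
#'
#' @param landmarks A `spine_landmarks` object.
#' @return Signed angle in degrees.
#' @export
pelvic_incidence <- function(landmarks) {
  ss <- sacral_slope(landmarks)
  if (is.na(ss)) return(NA_real_)
  d <- .pelvic_down_ray(landmarks)
  .anat_angle(d, .down_normal(ss))
}

#' Slope parameters C2S and T1S
#'
#' C2S: angle between the horizontal and the C2 inferior endplate. T1S: angle
#' between the horizontal and the T1 superior endplate.
#'
#' @param landmarks A `spine_landmarks` object.
#' @return Named list `list(c2s=, t1s=)` in degrees (`NA` for absent levels).
#' @export
slope_parameters <- function(landmarks) {
  list(c2s = if (.has_level(landmarks, "C2")) .endplate_slope_of(landmarks, "C2", "inferior") else NA_real_,
       t1s = if (.has_level(landmarks, "T1")) .endplate_slope_of(landmarks, "T1", "superior") else NA_real_)
}

#' Regional curvature angles C27L, TK, LL
#'
#' Signed angles between bounding endplate lines: cervical lordosis C27L
#' (C2 inferior vs C7 inferior), thoracic kyphosis TK (T1 superior vs L1
#' superior), lumbar lordosis LL (L1 superior vs S1 superior); lordosis is
#' positive for C27L and LL, kyphosis positive for TK.
#'
#' @param landmarks A `spine_landmarks` object.
#' @return Named list `list(c27l=, tk=, ll=)` in degrees.
#' @export
regional_angles <- function(landmarks) {
  s_c2i <- if (.has_level(landmarks, "C2")) .endplate_slope_of(landmarks, "C2", "inferior") else NA_real_
  s_c7i <- if (.has_level(landmarks, "C7")) .endplate_slope_of(landmarks, "C7", "inferior") else NA_real_
  s_t1s <- if (.has_level(landmarks, "T1")) .endplate_slope_of(landmarks, "T1", "superior") else NA_real_
  s_l1s <- if (.has_level(landmarks, "L1")) .endplate_slope_of(landmarks, "L1", "superior") else NA_real_
  ss <- sacral_slope(landmarks)
  list(c27l = .wrap180(s_c2i - s_c7i),
       tk   = .wrap180(s_l1s - s_t1s),
       ll   = .wrap180(ss - s_l1s))
}

#' Incidence parameters C2I, T1I, L1I
#'
#' Signed angle between the pelvic line (femoral-head center to sacral
#' endplate midpoint) and the perpendicular to the named endplate (C2
#' inferior, T1 superior, L1 superior); the two lines are compared by
#' direction. Satisfies C2I = PT + C2S (and analogues) exactly on ideal
#' landmarks.
#'
#' @param landmarks A `spine_landmarks` object.
#' @return Named list `list(c2i=, t1i=, l1i=)` in degrees.
#' @export
incidence_parameters <- function(landmarks) {
  if (is.null(landmarks$sacral_endplate) || is.null(landmarks$femoral_head_center)) {
    return(list(c2i = NA_real_, t1i = NA_real_, l1i = NA_real_))
  }
  d <- .pelvic_down_ray(landmarks)
  one <- function(level, which) {
    if (!.has_level(landmarks, level)) return(NA_real_)
    .anat_angle(d, .down_normal(.endplate_slope_of(landmarks, level, which)))
  }
  list(c2i = one("C2", "inferior"),
       t1i = one("T1", "superior"),
       l1i = one("L1", "superior"))
}

#' Sagittal vertical axes C2-7 SVA and C7 SVA
#'
#' C2-7 SVA: horizontal distance between the plumb line dropped from the C2
#' body center and the posterosuperior corner of C7. C7 SVA: horizontal
#' distance between the plumb line dropped from the C7 body center and the
#' posterosuperior corner of S1. Body centers are the mean of the four
#' extracted corners; values are in millimetres, positive when the plumb line
#' falls anterior to the reference corner.
#'
#' @param landmarks A `spine_landmarks` object.
#' @param spacing Pixel spacing in mm/px; defaults to the spacing stored in
#'   the landmark set.
#' @return Named list `list(c2_7_sva=, c7_sva=)` in millimetres.
#' @export
sagittal_vertical_axes <- function(landmarks, spacing = NULL) {
  sp <- if (is.null(spacing)) landmarks$spacing else spacing
  if (is.null(sp)) {
    stop(errorCondition("pixel spacing is required to report SVA in millimetres",
                        class = c("spinalign_calibration_missing", "spinalign_error")))
  }
  fac <- landmarks$facing
  c27 <- if (.has_level(landmarks, "C2") && .has_level(landmarks, "C7")) {
    plumbline_horizontal_offset(landmarks$vertebrae$C2$centroid,
                                landmarks$vertebrae$C7$superior_posterior, sp, fac)
  } else NA_real_
  c7 <- if (.has_level(landmarks, "C7") && !is.null(landmarks$sacral_endplate)) {
    plumbline_horizontal_offset(landmarks$vertebrae$C7$centroid,
                                landmarks$sacral_endplate$posterior, sp, fac)
  } else NA_real_
  list(c2_7_sva = c27, c7_sva = c7)
}

#' Read a normal-range table
#'
#' A CSV with columns `parameter` (the lower-case parameter names, e.g. `pi`,
#' `c2_7_sva`), `lower`, `upper`, in the parameter's units, applied to the
#' magnitude values. No ranges ship with the package (population standards
#' differ); until a table is supplied all range flags are `unevaluated`.
#'
#' @param path CSV path.
#' @return A data frame usable as the `ranges` argument of [compute_all()].
#' @export
read_normal_ranges <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("parameter", "lower", "upper")
  if (!all(need %in% names(tab))) {
    stop("normal-range table needs columns: parameter, lower, upper")
  }
  bad <- !is.na(tab$lower) & !is.na(tab$upper) & tab$lower >= tab$upper
  if (any(bad)) stop("normal-range table has lower >= upper")
  tab
}

#' Compute all 13 spinopelvic parameters
#'
#' Attempts every parameter; those whose landmarks (or pixel spacing, for the
#' SVAs) are unavailable are reported with status `missing-landmarks` instead
#' of aborting the case. When a normal-range table is supplied, each computed
#' magnitude is flagged `normal`/`abnormal` by an inclusive bounds test,
#' otherwise `unevaluated`.
#'
#' @param landmarks A `spine_landmarks` object.
#' @param spacing Pixel spacing mm/px (defaults to the landmark set's).
#' @param ranges Optional normal-range data frame, see [read_normal_ranges()].
#' @param case_id Optional case identifier carried into the result.
#' @return A `spinopelvic_result`: data frame with columns `parameter`,
#'   `label`, `value` (signed), `magnitude`, `unit`, `status`, `range_flag`.
#' @export
compute_all <- function(landmarks, spacing = NULL, ranges = NULL, case_id = "case") {
  stopifnot(inherits(landmarks, "spine_landmarks"))
  sl <- slope_parameters(landmarks)
  rg <- regional_angles(landmarks)
  inc <- incidence_parameters(landmarks)
  sva <- tryCatch(sagittal_vertical_axes(landmarks, spacing),
                  spinalign_calibration_missing = function(e) {
                    list(c2_7_sva = NA_real_, c7_sva = NA_real_)
                  })
  vals <- c(c2i = inc$c2i, c2s = sl$c2s, c27l = rg$c27l, t1i = inc$t1i,
            t1s = sl$t1s, tk = rg$tk, l1i = inc$l1i, ll = rg$ll,
            ss = sacral_slope(landmarks), pt = pelvic_tilt(landmarks),
            pi = pelvic_incidence(landmarks),
            c2_7_sva = sva$c2_7_sva, c7_sva = sva$c7_sva)
  vals <- vals[.PARAMS$name]
  out <- .PARAMS
  out$value <- as.numeric(vals)
  out$magnitude <- abs(out$value)
  out$status <- ifelse(is.na(out$value), "missing-landmarks", "computed")
  out$range_flag <- "unevaluated"
  if (!is.null(ranges) && nrow(ranges)) {
    m <- match(out$name, ranges$parameter)
    lo <- ranges$lower[m]; hi <- ranges$upper[m]
    ok <- !is.na(m) & !is.na(lo) & !is.na(hi) & !is.na(out$magnitude)
    out$range_flag[ok] <- ifelse(out$magnitude[ok] >= lo[ok] & out$magnitude[ok] <= hi[ok],
                                 "normal", "abnormal")
  }
  names(out)[names(out) == "name"] <- "parameter"
  attr(out, "case_id") <- case_id
  attr(out, "facing") <- landmarks$facing
  attr(out, "spacing") <- if (is.null(spacing)) landmarks$spacing else spacing
  class(out) <- c("spinopelvic_result", "data.frame")
  out
}

#' @export
print.spinopelvic_result <- function(x, digits = 2, ...) {
  cat(sprintf("Spinopelvic parameters for '%s':\n", attr(x, "case_id")))
  df <- data.frame(parameter = x$label,
                   value = round(x$value, digits),
                   magnitude = round(x$magnitude, digits),
                   unit = x$unit, status = x$status, flag = x$range_flag)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

#' Measure one case end to end
#'
#' Convenience wrapper: label the masks, compute all parameters, evaluate the
#' QC gate. Labeling failures are captured rather than raised.
#'
#' @inheritParams label_structures
#' @param ranges Optional normal-range table.
#' @param reference_masks Optional reference masks for the IoU gate.
#' @param iou_threshold IoU threshold, default 0.80.
#' @param case_id Case identifier.
#' @return List with elements `landmarks` (or failure record), `result`
#'   (`spinopelvic_result` or `NULL`), `success` (logical with failure
#'   reason attribute).
#' @export
measure_case <- function(masks, facing = "+x", spacing = NULL, mode = "strict",
                         ranges = NULL, reference_masks = NULL,
                         iou_threshold = 0.80, score_threshold = 0.5,
                         tolerance_fraction = 0.02, case_id = "case") {
  lm <- try_label_structures(masks, facing = facing, spacing = spacing, mode = mode,
                             score_threshold = score_threshold,
                             tolerance_fraction = tolerance_fraction)
  success <- measurement_success(lm, reference_masks, iou_threshold)
  result <- if (inherits(lm, "spine_landmarks")) {
    res <- compute_all(lm, ranges = ranges, case_id = case_id)
    if (!isTRUE(as.logical(success))) {
      res$status[res$status == "computed"] <- "failed-qc"
    }
    res
  } else NULL
  list(landmarks = lm, result = result, success = success)
}
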