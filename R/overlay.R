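# Deterministic overlay rendering: mask outlines, landmark corners,
# construction lines, and color-coded parameter labels painted into a raw
# RGB array and written as PNG. Text uses a built-in 5x7 bitmap font so the
# output is byte-identical across systems (no font rasterizer involved).

.FONT5x7 <- list(
  "0" = c("01110","10001","10011","10101","11001","10001","01110"),
  "1" = c("00100","01100","00100","00100","00100","00100","01110"),
  "2" = c("01110","10001","00001","00110","01000","10000","11111"),
  "3" = c("11110","00001","00001","01110","00001","00001","11110"),
  "4" = c("00010","00110","01010","10010","11111","00010","00010"),
  "5" = c("11111","10000","11110","00001","00001","10001","01110"),
  "6" = c("01110","10000","10000","11110","10001","10001","01110"),
  "7" = c("11111","00001","00010","00100","01000","01000","01000"),
  "8" = c("01110","10001","10001","01110","10001","10001","01110"),
  "9" = c("01110","10001","10001","01111","00001","00001","01110"),
  "A" = c("01110","10001","10001","11111","10001","10001","10001"),
  "C" = c("01110","10001","10000","10000","10000","10001","01110"),
  "D" = c("11110","10001","10001","10001","10001","10001","11110"),
  "E" = c("11111","10000","10000","11110","10000","10000","11111"),
  "F" = c("11111","10000","10000","11110","10000","10000","10000"),
  "G" = c("01110","10001","10000","10111","10001","10001","01111"),
  "I" = c("01110","00100","00100","00100","00100","00100","01110"),
  "K" = c("10001","10010","10100","11000","10100","10010","10001"),
  "L" = c("10000","10000","10000","10000","10000","10000","11111"),
  "M" = c("10001","11011","10101","10101","10001","10001","10001"),
  "N" = c("10001","11001","10101","10011","10001","10001","10001"),
  "O" = c("01110","10001","10001","10001","10001","10001","01110"),
  "P" = c("11110","10001","10001","11110","10000","10000","10000"),
  "Q" = c("01110","10001","10001","10001","10101","10010","01101"),
  "R" = c("11110","10001","10001","11110","10100","10010","10001"),
  "S" = c("01111","10000","10000","01110","00001","00001","11110"),
  "T" = c("11111","00100","00100","00100","00100","00100","00100"),
  "U" = c("10001","10001","10001","10001","10001","10001","01110"),
  "V" = c("10001","10001","10001","10001","10001","01010","00100"),
  "X" = c("10001","01010","00100","00100","00100","01010","10001"),
  "-" = c("00000","00000","00000","11111","00000","00000","00000"),
  "." = c("00000","00000","00000","00000","00000","00110","00110"),
  ":" = c("00000","00110","00110","00000","00110","00110","00000"),
  " " = c("00000","00000","00000","00000","00000","00000","00000")
)

# pixel coordinates (x, y) covered by `text` drawn with its top-left at
# (x0, y0), integer scale
.text_pixels <- function(text, x0, y0, scale = 2) {
  chars <- strsplit(toupper(text), "")[[1]]
  out <- matrix(numeric(0), 0, 2)
  cx <- x0
  for (ch in chars) {
    g <- .FONT5x7[[ch]]
    if (!is.null(g)) {
      bits <- do.call(rbind, lapply(g, function(r) as.integer(strsplit(r, "")[[1]])))
      idx <- which(bits == 1, arr.ind = TRUE)
      if (nrow(idx)) {
        for (sy in 0:(scale - 1)) for (sx in 0:(scale - 1)) {
          out <- rbind(out, cbind(cx + (idx[, 2] - 1) * scale + sx,
                                  y0 + (idx[, 1] - 1) * scale + sy))
        }
      }
    }
    cx <- cx + 6 * scale
  }
  out
}

# pixels along a segment, sampled at half-pixel steps
.segment_pixels <- function(p1, p2, width = 1) {
  len <- sqrt(sum((p2 - p1)^2))
  n <- max(2L, ceiling(len * 2))
  t <- seq(0, 1, length.out = n)
  pts <- cbind(round(p1[1] + t * (p2[1] - p1[1])), round(p1[2] + t * (p2[2] - p1[2])))
  if (width > 1) {
    off <- expand.grid(dx = -(width %/% 2):(width %/% 2), dy = -(width %/% 2):(width %/% 2))
    pts <- do.call(rbind, lapply(seq_len(nrow(off)), function(i) {
      cbind(pts[, 1] + off$dx[i], pts[, 2] + off$dy[i])
    }))
  }
  unique(pts)
}

.marker_pixels <- function(p, half = 2) {
  g <- expand.grid(dx = -half:half, dy = -half:half)
  cbind(round(p[1]) + g$dx, round(p[2]) + g$dy)
}

# paint a pixel list (x, y) into img [y, x, channel] with an RGB color
.paint <- function(img, pix, col) {
  if (nrow(pix) == 0) return(img)
  w <- dim(img)[2]; h <- dim(img)[1]
  keep <- pix[, 1] >= 1 & pix[, 1] <= w & pix[, 2] >= 1 & pix[, 2] <= h
  pix <- pix[keep, , drop = FALSE]
  for (ch in 1:3) img[cbind(pix[, 2], pix[, 1], ch)] <- col[ch]
  img
}

.OVERLAY_COLS <- list(normal = c(0.25, 0.5, 1), abnormal = c(1, 0.25, 0.25),
                      unevaluated = c(0.75, 0.75, 0.75),
                      outline = c(0.55, 0.55, 0.55), corner = c(1, 1, 1),
                      endplate = c(0.3, 0.9, 0.3), pelvic = c(1, 0.85, 0.2),
                      plumb = c(0.35, 0.65, 1))

#' Render a measurement overlay image
#'
#' Paints the mask outlines, the extracted corner landmarks, the pelvic and
#' plumb construction lines, and a parameter legend whose entries are colored
#' blue when inside the supplied normal range, red when outside, and gray
#' when unevaluated. Rendering is fully deterministic: identical inputs give
#' byte-identical PNGs.
#'
#' @param masks List of `structure_mask` objects (or a `case_record`).
#' @param landmarks Optional `spine_landmarks` to draw corners and
#'   construction lines.
#' @param result Optional `spinopelvic_result` for the legend.
#' @param path Output PNG path.
#' @param frame Frame `c(width, height)`; inferred when omitted.
#' @return The path, invisibly.
#' @export
render_overlay <- function(masks, landmarks = NULL, result = NULL, path,
                           frame = NULL) {
  if (inherits(masks, "case_record")) {
    if (is.null(frame)) frame <- masks$frame
    masks <- masks$masks
  }
  if (is.null(frame)) {
    frame <- Filter(Negate(is.null), lapply(masks, `[[`, "frame"))[[1]]
  }
  img <- array(0.08, dim = c(frame[2], frame[1], 3))
  cols <- .OVERLAY_COLS
  for (m in masks) {
    poly <- if (!is.null(m$polygon)) m$polygon else approximate_polygon(m)
    n <- nrow(poly)
    for (i in seq_len(n)) {
      img <- .paint(img, .segment_pixels(poly[i, ], poly[(i %% n) + 1, ]), cols$outline)
    }
  }
  if (!is.null(landmarks)) {
    ep <- landmarks$sacral_endplate
    img <- .paint(img, .segment_pixels(ep$anterior, ep$posterior, width = 3), cols$endplate)
    img <- .paint(img, .segment_pixels(ep$midpoint, landmarks$femoral_head_center,
                                       width = 3), cols$pelvic)
    for (lvl in c("C2", "C7")) {
      v <- landmarks$vertebrae[[lvl]]
      if (!is.null(v)) {
        img <- .paint(img, .segment_pixels(v$centroid, c(v$centroid[1], frame[2])), cols$plumb)
      }
    }
    for (v in landmarks$vertebrae) {
      for (role in c("superior_anterior", "superior_posterior",
                     "inferior_anterior", "inferior_posterior")) {
        img <- .paint(img, .marker_pixels(v[[role]]), cols$corner)
      }
    }
  }
  if (!is.null(result)) {
    scale <- 2
    for (i in seq_len(nrow(result))) {
      colr <- cols[[result$range_flag[i]]] %||% cols$unevaluated
      txt <- if (result$status[i] == "computed") {
        sprintf("%s: %.1f %s", result$label[i], result$magnitude[i],
                ifelse(result$unit[i] == "deg", "DEG", "MM"))
      } else {
        sprintf("%s: %s", result$label[i], toupper(result$status[i]))
      }
      img <- .paint(img, .text_pixels(txt, 12, 12 + (i - 1) * 9 * scale, scale), colr)
    }
  }
  png::writePNG(img, path)
  invisible(path)
}
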