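# Structure masks: one labeled instance (polygon and/or binary raster) for a
# vertebral body, the sacrum, or a femoral head, plus raster helpers.

.LEVELS <- c(paste0("C", 2:7), paste0("T", 1:12), paste0("L", 1:5))

.stop_cls <- function(msg, cls) {
  stop(errorCondition(msg, class = c(cls, "spinalign_error")))
}

#' Create a structure mask
#'
#' One labeled instance for a single radiograph: a vertebral body, the sacrum,
#' or a femoral head. The geometry can be a closed polygon (ordered vertex
#' list in continuous image coordinates, not repeating the first vertex) or a
#' binary raster crop with a pixel offset, or both.
#'
#' @param label Structure category. Recognized labels: `"sacrum"`,
#'   `"femoral_head"` (also `"femur"`), a vertebral level (`"C2"`..`"L5"`), or
#'   generic `"vertebra"`.
#' @param polygon Optional n x 2 numeric matrix of polygon vertices (x, y).
#' @param raster Optional binary matrix (rows = y, cols = x) cropped to the
#'   structure, values 0/1.
#' @param offset 0-based pixel offset `c(x0, y0)` of the raster crop within
#'   the image frame.
#' @param frame Image frame size `c(width, height)` in pixels.
#' @param score Optional detection confidence in \[0, 1\].
#' @return An object of class `structure_mask`.
#' @export
structure_mask <- function(label, polygon = NULL, raster = NULL,
                           offset = c(0L, 0L), frame = NULL, score = NULL) {
  if (is.null(polygon) && is.null(raster)) {
    .stop_cls("a structure_mask needs a polygon or a raster", "spinalign_empty_mask")
  }
  if (!is.null(polygon)) {
    polygon <- as.matrix(polygon)
    if (ncol(polygon) != 2 || nrow(polygon) < 3 || !all(is.finite(polygon))) {
      .stop_cls("polygon must be a finite n x 2 matrix with n >= 3", "spinalign_empty_mask")
    }
    dimnames(polygon) <- NULL
  }
  if (!is.null(raster)) {
    raster <- (as.matrix(raster) > 0) * 1L
    if (sum(raster) < 1) .stop_cls("raster mask has no foreground pixel", "spinalign_empty_mask")
  }
  structure(list(label = as.character(label), polygon = polygon, raster = raster,
                 offset = as.integer(round(offset)), frame = frame,
                 score = if (is.null(score)) NULL else as.numeric(score)),
            class = "structure_mask")
}

#' @export
print.structure_mask <- function(x, ...) {
  geom <- c(if (!is.null(x$polygon)) sprintf("polygon[%d]", nrow(x$polygon)),
            if (!is.null(x$raster)) sprintf("raster %dx%d@(%d,%d)",
                                            ncol(x$raster), nrow(x$raster),
                                            x$offset[1], x$offset[2]))
  cat(sprintf("<structure_mask> %s (%s)%s\n", x$label, paste(geom, collapse = ", "),
              if (is.null(x$score)) "" else sprintf(" score=%.2f", x$score)))
  invisible(x)
}

# Normalize a free-form category label to one of: the level tags, "vertebra",
# "sacrum", "femoral_head".
.norm_label <- function(label) {
  l <- gsub("[ .-]", "_", tolower(trimws(label)))
  if (l %in% c("sacrum", "s1")) return("sacrum")
  if (l %in% c("femoral_head", "femur", "femoral_heads", "hip")) return("femoral_head")
  up <- toupper(l)
  if (up %in% .LEVELS) return(up)
  if (grepl("vertebra", l)) return("vertebra")
  "vertebra"
}

.label_class <- function(label) {
  n <- .norm_label(label)
  if (n %in% c("sacrum", "femoral_head")) n else "vertebra"
}

# Rasterize a polygon: pixels whose centers fall inside. Returns a sparse
# raster: list(offset = c(x0, y0) 0-based, m = binary matrix rows=y, cols=x).
.fill_polygon <- function(poly, frame) {
  x0 <- max(0L, floor(min(poly[, 1])) - 1L)
  y0 <- max(0L, floor(min(poly[, 2])) - 1L)
  x1 <- ceiling(max(poly[, 1])) + 1L
  y1 <- ceiling(max(poly[, 2])) + 1L
  if (!is.null(frame)) {
    x1 <- min(x1, frame[1])
    y1 <- min(y1, frame[2])
  }
  if (x1 <= x0 || y1 <= y0) .stop_cls("polygon outside the image frame", "spinalign_frame_error")
  xs <- seq(x0, x1 - 1L) + 0.5
  ys <- seq(y0, y1 - 1L) + 0.5
  g <- expand.grid(x = xs, y = ys)
  inside <- pracma::inpolygon(g$x, g$y, poly[, 1], poly[, 2], boundary = TRUE)
  m <- matrix(as.integer(inside), nrow = length(ys), ncol = length(xs), byrow = TRUE)
  list(offset = c(x0, y0), m = m)
}

# Sparse raster of a structure_mask (rasterizes the polygon if needed).
.mask_raster <- function(mask, frame = NULL) {
  if (!is.null(mask$raster)) {
    return(list(offset = mask$offset, m = mask$raster))
  }
  .fill_polygon(mask$polygon, if (is.null(frame)) mask$frame else frame)
}

# Ordered boundary ring of a sparse raster, as continuous pixel-center
# coordinates in the image frame. Uses EBImage's contour follower on the
# (padded) crop.
.trace_contour <- function(sp) {
  if (sum(sp$m) < 1) .stop_cls("raster mask has no foreground pixel", "spinalign_empty_mask")
  pad <- 1L
  m <- sp$m
  mp <- matrix(0L, nrow(m) + 2 * pad, ncol(m) + 2 * pad)
  mp[(pad + 1):(pad + nrow(m)), (pad + 1):(pad + ncol(m))] <- m
  oc <- EBImage::ocontour(EBImage::Image(t(mp)))
  if (length(oc) == 0) .stop_cls("contour tracing failed on raster mask", "spinalign_empty_mask")
  # largest contour by vertex count if the mask has several components
  ring <- oc[[which.max(vapply(oc, nrow, integer(1)))]]
  # ocontour coordinates are 0-based (x, y) pixel indices of the padded crop
  cbind(ring[, 1] - pad + sp$offset[1] + 0.5,
        ring[, 2] - pad + sp$offset[2] + 0.5)
}

#' Shoelace area of a polygon
#' @param poly n x 2 matrix of vertices.
#' @return Unsigned polygon area in square pixels.
#' @export
polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

# Area-weighted (shoelace) centroid; falls back to the vertex mean when the
# polygon is (near) degenerate.
.polygon_centroid <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-9) return(c(mean(x), mean(y)))
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

#' Centroid of a structure mask
#'
#' Raster masks use the mean of foreground pixel centers; polygon masks use
#' the area-weighted (shoelace) centroid. For a rasterized disk this equals
#' the disk center up to quantization.
#'
#' @param mask A `structure_mask`.
#' @return Point `c(x, y)`.
#' @export
mask_centroid <- function(mask) {
  if (!is.null(mask$raster)) {
    idx <- which(mask$raster > 0, arr.ind = TRUE)
    return(c(mean(idx[, 2]) - 0.5 + mask$offset[1],
             mean(idx[, 1]) - 0.5 + mask$offset[2]))
  }
  .polygon_centroid(mask$polygon)
}

#' Intersection-over-union of two structure masks
#'
#' Pixel-wise IoU of the rasterized masks: 1 for identical masks, 0 for
#' disjoint ones. Both masks must live in the same raster frame.
#'
#' @param a,b `structure_mask` objects.
#' @param frame Image frame `c(width, height)`; taken from the masks when
#'   omitted.
#' @return IoU ratio in \[0, 1\].
#' @export
mask_iou <- function(a, b, frame = NULL) {
  fa <- if (is.null(frame)) a$frame else frame
  fb <- if (is.null(frame)) b$frame else frame
  if (!is.null(fa) && !is.null(fb) && !identical(as.integer(fa), as.integer(fb))) {
    .stop_cls("masks live in different raster frames", "spinalign_frame_error")
  }
  ra <- .mask_raster(a, fa)
  rb <- .mask_raster(b, fb)
  na <- sum(ra$m); nb <- sum(rb$m)
  if (na == 0 && nb == 0) .stop_cls("IoU undefined for two empty masks", "spinalign_undefined_iou")
  # common bounding box of the two crops
  x0 <- max(ra$offset[1], rb$offset[1]); y0 <- max(ra$offset[2], rb$offset[2])
  x1 <- min(ra$offset[1] + ncol(ra$m), rb$offset[1] + ncol(rb$m))
  y1 <- min(ra$offset[2] + nrow(ra$m), rb$offset[2] + nrow(rb$m))
  inter <- 0
  if (x1 > x0 && y1 > y0) {
    sa <- ra$m[(y0 - ra$offset[2] + 1):(y1 - ra$offset[2]),
               (x0 - ra$offset[1] + 1):(x1 - ra$offset[1]), drop = FALSE]
    sb <- rb$m[(y0 - rb$offset[2] + 1):(y1 - rb$offset[2]),
               (x0 - rb$offset[1] + 1):(x1 - rb$offset[1]), drop = FALSE]
    inter <- sum(sa * sb)
  }
  inter / (na + nb - inter)
}
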