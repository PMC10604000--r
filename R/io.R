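# Readers and writers: COCO-style annotation JSON, per-structure PNG label
# masks, and result serialization (JSON with signed values and statuses, CSV
# with one row per case).

#' Create a case record
#'
#' One radiograph's worth of input: the structure masks plus frame and
#' optional calibration metadata.
#'
#' @param case_id Case identifier.
#' @param masks List of `structure_mask` objects.
#' @param frame Frame size `c(width, height)` px.
#' @param spacing Optional pixel spacing mm/px.
#' @param facing Optional facing flag (`"+x"`/`"-x"`).
#' @return An object of class `case_record`.
#' @export
case_record <- function(case_id, masks, frame, spacing = NULL, facing = NULL) {
  if (!is.null(spacing) && (!is.numeric(spacing) || spacing <= 0)) {
    stop("spacing must be positive (mm/px)")
  }
  structure(list(case_id = as.character(case_id), masks = masks,
                 frame = as.integer(frame), spacing = spacing, facing = facing),
            class = "case_record")
}

#' Write masks as a COCO-style annotation file
#'
#' Serializes polygon masks in the de-facto COCO instance-annotation dialect:
#' `images`, `annotations` (polygon `segmentation` as one flat interleaved
#' x,y list, `bbox`, `area`, `category_id`), and `categories` keyed by the
#' structure labels. Pixel spacing and facing, when known, are stored on the
#' image entry so a round-trip preserves them.
#'
#' @param masks List of `structure_mask` objects with polygons, or a
#'   `case_record`.
#' @param path Output JSON path.
#' @param case_id Image identifier (ignored when a `case_record` is given).
#' @param frame Frame `c(width, height)`; taken from masks/record if omitted.
#' @param spacing,facing Optional metadata.
#' @return The path, invisibly.
#' @export
write_coco <- function(masks, path, case_id = "case_001", frame = NULL,
                       spacing = NULL, facing = NULL) {
  if (inherits(masks, "case_record")) {
    rec <- masks
    masks <- rec$masks
    case_id <- rec$case_id
    if (is.null(frame)) frame <- rec$frame
    if (is.null(spacing)) spacing <- rec$spacing
    if (is.null(facing)) facing <- rec$facing
  }
  if (is.null(frame)) {
    frame <- Filter(Negate(is.null), lapply(masks, `[[`, "frame"))[[1]]
  }
  labs <- vapply(masks, `[[`, character(1), "label")
  cats <- unique(labs)
  img <- list(id = 1L, width = as.integer(frame[1]), height = as.integer(frame[2]),
              file_name = paste0(case_id, ".png"))
  if (!is.null(spacing)) img$pixel_spacing <- spacing
  if (!is.null(facing)) img$facing <- facing
  anns <- lapply(seq_along(masks), function(i) {
    m <- masks[[i]]
    if (is.null(m$polygon)) stop("write_coco() needs polygon geometry on every mask")
    p <- m$polygon
    a <- list(id = i, image_id = 1L, category_id = match(m$label, cats),
              segmentation = list(as.numeric(t(p))),
              bbox = c(min(p[, 1]), min(p[, 2]),
                       max(p[, 1]) - min(p[, 1]), max(p[, 2]) - min(p[, 2])),
              area = polygon_area(p), iscrowd = 0L)
    if (!is.null(m$score)) a$score <- m$score
    a
  })
  obj <- list(images = list(img),
              annotations = anns,
              categories = lapply(seq_along(cats), function(i) list(id = i, name = cats[i])))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = FALSE)
  invisible(path)
}

#' Read COCO-style instance annotations
#'
#' Accepts the polygon dialect written by [write_coco()] and by common
#' annotation tools: per-image entries, polygon `segmentation` lists
#' (interleaved 0-based x,y pixel coordinates, implicitly closed), and
#' category names mapped to structure labels (vertebral level names are
#' honored when present, otherwise a generic vertebra label is used).
#' Run-length-encoded segmentations are not supported.
#'
#' @param path Path to the annotation JSON.
#' @return List of `case_record` objects, one per image.
#' @export
read_coco_annotations <- function(path) {
  obj <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) {
                    stop(sprintf("failed to parse COCO JSON '%s': %s", path, conditionMessage(e)))
                  })
  if (is.null(obj$images) || is.null(obj$annotations) || is.null(obj$categories)) {
    stop(sprintf("'%s' is not COCO-style JSON (needs images/annotations/categories)", path))
  }
  cat_names <- stats::setNames(
    vapply(obj$categories, function(c) as.character(c$name), character(1)),
    vapply(obj$categories, function(c) as.character(c$id), character(1)))
  lapply(obj$images, function(img) {
    frame <- c(img$width, img$height)
    anns <- Filter(function(a) identical(as.integer(a$image_id), as.integer(img$id)),
                   obj$annotations)
    masks <- lapply(anns, function(a) {
      seg <- a$segmentation
      if (is.null(seg) || !is.null(names(seg)) && "counts" %in% names(seg)) {
        .stop_cls("RLE-encoded segmentations are not supported (polygon dialect only)",
                  "spinalign_unsupported_dialect")
      }
      xy <- unlist(seg[[1]])
      poly <- matrix(as.numeric(xy), ncol = 2, byrow = TRUE)
      structure_mask(cat_names[[as.character(a$category_id)]], polygon = poly,
                     frame = frame, score = a$score)
    })
    case_record(sub("\\.[a-zA-Z]+$", "", img$file_name %||% paste0("image_", img$id)),
                masks, frame, spacing = img$pixel_spacing, facing = img$facing)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read structure masks from PNG label images
#'
#' Two layouts are supported: one binary PNG per structure (supply one label
#' per file), or a single labeled PNG where each distinct non-zero gray level
#' is one structure (supply a named `label_map` from gray level, on the 0-255
#' scale, to label). All PNGs must share the same dimensions.
#'
#' @param paths Character vector of PNG paths.
#' @param labels Labels, one per file (first layout).
#' @param label_map Named character vector mapping gray level to label
#'   (second layout, single path).
#' @param case_id Case identifier.
#' @return A `case_record`. A PNG with no foreground produces no mask and a
#'   warning.
#' @export
read_label_masks <- function(paths, labels = NULL, label_map = NULL, case_id = "case") {
  imgs <- lapply(paths, function(p) {
    a <- png::readPNG(p)
    if (length(dim(a)) == 3) a <- a[, , 1]
    a
  })
  dims <- vapply(imgs, dim, integer(2))
  if (ncol(dims) > 1 && any(dims != dims[, 1])) {
    .stop_cls("label-mask PNGs have mismatched dimensions", "spinalign_frame_error")
  }
  frame <- c(dims[2, 1], dims[1, 1])  # width, height
  crop <- function(bin, label) {
    idx <- which(bin, arr.ind = TRUE)
    if (nrow(idx) == 0) return(NULL)
    y0 <- min(idx[, 1]); y1 <- max(idx[, 1]); x0 <- min(idx[, 2]); x1 <- max(idx[, 2])
    structure_mask(label, raster = bin[y0:y1, x0:x1, drop = FALSE] * 1L,
                   offset = c(x0 - 1L, y0 - 1L), frame = frame)
  }
  masks <- list()
  if (!is.null(label_map)) {
    if (length(paths) != 1) stop("label_map mode expects a single labeled PNG")
    lev <- round(imgs[[1]] * 255)
    for (g in names(label_map)) {
      m <- crop(lev == as.numeric(g), label_map[[g]])
      if (is.null(m)) warning(sprintf("gray level %s has no pixels", g)) else masks <- c(masks, list(m))
    }
  } else {
    if (is.null(labels) || length(labels) != length(paths)) {
      stop("supply one label per PNG path")
    }
    for (i in seq_along(paths)) {
      m <- crop(imgs[[i]] > 0, labels[i])
      if (is.null(m)) warning(sprintf("'%s' has no foreground pixels", paths[i])) else masks <- c(masks, list(m))
    }
  }
  case_record(case_id, masks, frame)
}

#' Write per-structure mask PNGs
#'
#' One binary PNG per mask, named `<case_id>_<index>_<label>.png`.
#'
#' @param masks List of `structure_mask` objects.
#' @param dir Output directory.
#' @param case_id Case identifier used in file names.
#' @return Written paths, invisibly.
#' @export
write_mask_pngs <- function(masks, dir, case_id = "case") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(length(masks))
  for (i in seq_along(masks)) {
    m <- masks[[i]]
    sp <- .mask_raster(m)
    frame <- m$frame %||% c(sp$offset[1] + ncol(sp$m), sp$offset[2] + nrow(sp$m))
    full <- matrix(0, frame[2], frame[1])
    full[(sp$offset[2] + 1):(sp$offset[2] + nrow(sp$m)),
         (sp$offset[1] + 1):(sp$offset[1] + ncol(sp$m))] <- sp$m
    paths[i] <- file.path(dir, sprintf("%s_%02d_%s.png", case_id, i,
                                       gsub("[^A-Za-z0-9]", "_", m$label)))
    png::writePNG(full, paths[i])
  }
  invisible(paths)
}

#' Write measurement results
#'
#' JSON carries the full per-parameter records (signed value, magnitude,
#' unit, status, range flag); CSV has one row per case with the 13 magnitude
#' columns in fixed order plus a status summary, missing parameters left
#' empty.
#'
#' @param results A `spinopelvic_result` or list of them.
#' @param path_prefix Output path without extension; `<prefix>.json` and/or
#'   `<prefix>.csv` are written.
#' @param formats Subset of `c("json", "csv")`.
#' @return Written paths, invisibly.
#' @export
write_results <- function(results, path_prefix, formats = c("json", "csv")) {
  formats <- match.arg(formats, several.ok = TRUE)
  if (inherits(results, "spinopelvic_result")) results <- list(results)
  written <- character(0)
  if ("json" %in% formats) {
    obj <- lapply(results, function(r) {
      list(case_id = attr(r, "case_id"), facing = attr(r, "facing"),
           spacing = attr(r, "spacing"),
           parameters = lapply(seq_len(nrow(r)), function(i) {
             list(parameter = r$parameter[i], label = r$label[i],
                  value = if (is.na(r$value[i])) NULL else r$value[i],
                  magnitude = if (is.na(r$magnitude[i])) NULL else r$magnitude[i],
                  unit = r$unit[i], status = r$status[i], range_flag = r$range_flag[i])
           }))
    })
    p <- paste0(path_prefix, ".json")
    jsonlite::write_json(obj, p, auto_unbox = TRUE, digits = NA, null = "null")
    written <- c(written, p)
  }
  if ("csv" %in% formats) {
    rows <- lapply(results, function(r) {
      v <- stats::setNames(as.list(r$magnitude), r$parameter)
      c(list(case_id = attr(r, "case_id")), v,
        list(n_computed = sum(r$status == "computed"),
             status_summary = paste(unique(r$status), collapse = ";")))
    })
    df <- do.call(rbind, lapply(rows, function(x) as.data.frame(x, stringsAsFactors = FALSE)))
    p <- paste0(path_prefix, ".csv")
    utils::write.csv(df, p, row.names = FALSE, na = "")
    written <- c(written, p)
  }
  invisible(written)
}

#' Read back results written by [write_results()]
#'
#' @param path JSON results path.
#' @return List of `spinopelvic_result` objects.
#' @export
read_results <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(obj, function(case) {
    df <- .PARAMS
    get1 <- function(p, field) {
      hit <- Filter(function(e) identical(e$parameter, p), case$parameters)
      if (!length(hit) || is.null(hit[[1]][[field]])) NA else hit[[1]][[field]]
    }
    df$value <- vapply(df$name, function(p) as.numeric(get1(p, "value") %||% NA), numeric(1))
    df$magnitude <- abs(df$value)
    df$status <- vapply(df$name, function(p) as.character(get1(p, "status")), character(1))
    df$range_flag <- vapply(df$name, function(p) as.character(get1(p, "range_flag")), character(1))
    names(df)[names(df) == "name"] <- "parameter"
    attr(df, "case_id") <- case$case_id
    attr(df, "facing") <- case$facing
    attr(df, "spacing") <- case$spacing
    class(df) <- c("spinopelvic_result", "data.frame")
    df
  })
}
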