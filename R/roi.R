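#' Axis-aligned bounding box (0-based, half-open)
#'
#' The package-wide box convention is 0-based, half-open, row-major:
#' a box covers rows `row_start .. row_end - 1` and columns
#' `col_start .. col_end - 1` of the image, counting from 0. PASCAL VOC
#' XML (1-based inclusive `xmin/ymin/xmax/ymax`) is converted at the I/O
#' boundary only ([read_annotation()] / [write_annotation()]).
#'
#' @param row_start,row_end,col_start,col_end integer pixel indices with
#'   `row_start < row_end` and `col_start < col_end`.
#' @return An object of class `bounding_box`.
#' @export
bounding_box <- function(row_start, row_end, col_start, col_end) {
  vals <- c(row_start, row_end, col_start, col_end)
  if (any(!is.finite(vals)) || any(vals != round(vals))) {
    stop("box coordinates must be finite integers", call. = FALSE)
  }
  if (row_start < 0 || col_start < 0) {
    stop("box coordinates are 0-based and must be non-negative", call. = FALSE)
  }
  if (row_start >= row_end) {
    stop(sprintf("invalid box rows: row_start (%d) must be < row_end (%d)",
                 row_start, row_end), call. = FALSE)
  }
  if (col_start >= col_end) {
    stop(sprintf("invalid box cols: col_start (%d) must be < col_end (%d)",
                 col_start, col_end), call. = FALSE)
  }
  structure(list(row_start = as.integer(row_start),
                 row_end = as.integer(row_end),
                 col_start = as.integer(col_start),
                 col_end = as.integer(col_end)),
            class = "bounding_box")
}

#' @export
print.bounding_box <- function(x, ...) {
  cat(sprintf("Bounding box rows [%d, %d) x cols [%d, %d)\n",
              x$row_start, x$row_end, x$col_start, x$col_end))
  invisible(x)
}

validate_box_in_frame <- function(box, height, width) {
  if (!inherits(box, "bounding_box")) {
    stop("expected a bounding_box", call. = FALSE)
  }
  if (box$row_end > height || box$col_end > width) {
    stop(sprintf("box [%d,%d)x[%d,%d) exceeds the %dx%d frame",
                 box$row_start, box$row_end, box$col_start, box$col_end,
                 height, width), call. = FALSE)
  }
  invisible(box)
}

#' Intersection-over-union of two bounding boxes
#'
#' @param a,b [bounding_box()] objects.
#' @return IoU in `[0, 1]`.
#' @export
box_iou <- function(a, b) {
  ir <- max(0, min(a$row_end, b$row_end) - max(a$row_start, b$row_start))
  ic <- max(0, min(a$col_end, b$col_end) - max(a$col_start, b$col_start))
  inter <- ir * ic
  area <- function(x) (x$row_end - x$row_start) * (x$col_end - x$col_start)
  inter / (area(a) + area(b) - inter)
}

#' Detect the sponge region in an image
#'
#' A deterministic colour-distance detector standing in for a learned object
#' detector: pixels whose Euclidean RGB distance to the background colour
#' exceeds `threshold` are foreground; connected components smaller than
#' `min_area_frac` of the frame are discarded as specks; the tightest box
#' around the surviving foreground is returned. Any detector honouring the
#' same contract (one in-frame box per image) can be substituted upstream of
#' the predictors.
#'
#' @param image H x W x 3 array, either 8-bit (0--255) or unit scale.
#' @param background_color RGB triple in `[0, 1]`; default matches
#'   [scene_params()].
#' @param threshold foreground colour-distance threshold on the `[0, 1]`
#'   scale (default 30/255).
#' @param min_area_frac minimum connected-component area as a fraction of the
#'   frame (default 0.001).
#' @return A [bounding_box()] (0-based, half-open).
#' @export
detect_sponge_region <- function(image,
                                 background_color = scene_params()$background_color,
                                 threshold = 30 / 255,
                                 min_area_frac = 0.001) {
  img <- as_unit_pixels(image)
  H <- dim(img)[1]; W <- dim(img)[2]
  d2 <- (img[, , 1] - background_color[1])^2 +
    (img[, , 2] - background_color[2])^2 +
    (img[, , 3] - background_color[3])^2
  fg <- d2 > threshold^2
  if (!any(fg)) {
    stop("no sponge found: no pixel differs from the background colour by ",
         "more than the threshold", call. = FALSE)
  }
  labels <- EBImage::bwlabel(fg)
  sizes <- tabulate(labels[labels > 0])
  keep <- which(sizes >= min_area_frac * H * W)
  if (length(keep) == 0L) {
    stop("no sponge found: all foreground components are below the minimum ",
         "area", call. = FALSE)
  }
  sel <- labels %in% keep
  dim(sel) <- dim(fg)
  rows <- which(rowSums(sel) > 0)
  cols <- which(colSums(sel) > 0)
  bounding_box(min(rows) - 1L, max(rows), min(cols) - 1L, max(cols))
}

#' Crop an image to a bounding box
#'
#' @param image H x W x 3 array.
#' @param box a [bounding_box()] lying inside the frame.
#' @return The half-open sub-array, shape
#'   `(row_end - row_start, col_end - col_start, 3)`.
#' @export
crop <- function(image, box) {
  if (!is.array(image) || length(dim(image)) != 3L) {
    stop("`image` must be an H x W x 3 array", call. = FALSE)
  }
  validate_box_in_frame(box, dim(image)[1], dim(image)[2])
  image[(box$row_start + 1L):box$row_end,
        (box$col_start + 1L):box$col_end, , drop = FALSE]
}

#' Image annotation: labelled bounding boxes
#'
#' @param image_filename name of the annotated image file.
#' @param boxes list of `list(label = <string>, box = <bounding_box>)`.
#' @param width,height image size in pixels (recorded in VOC XML).
#' @return An object of class `annotation`.
#' @export
annotation <- function(image_filename, boxes, width = NA_integer_,
                       height = NA_integer_) {
  if (!is.character(image_filename) || length(image_filename) != 1L) {
    stop("`image_filename` must be a single string", call. = FALSE)
  }
  for (b in boxes) {
    if (!is.character(b$label) || nchar(b$label) == 0L) {
      stop("every box needs a non-empty string label", call. = FALSE)
    }
    if (!inherits(b$box, "bounding_box")) {
      stop("every entry needs a bounding_box in `box`", call. = FALSE)
    }
  }
  structure(list(image_filename = image_filename, boxes = boxes,
                 width = as.integer(width), height = as.integer(height)),
            class = "annotation")
}

#' Read / write PASCAL-VOC-style XML annotations
#'
#' The XML dialect is the one produced by common box-annotation tools:
#' `object/bndbox` entries with 1-based inclusive `xmin, ymin, xmax, ymax`.
#' Reading converts to the package's 0-based half-open convention
#' (`row_start = ymin - 1`, `row_end = ymax`, `col_start = xmin - 1`,
#' `col_end = xmax`); writing inverts the conversion exactly, so a
#' write-read round trip is bit-exact on coordinates.
#'
#' @param xml_path path to the XML file.
#' @return [read_annotation()] returns an [annotation()];
#'   [write_annotation()] returns `xml_path` invisibly.
#' @export
read_annotation <- function(xml_path) {
  doc <- xml2::read_xml(xml_path)
  fname <- xml2::xml_text(xml2::xml_find_first(doc, "./filename"))
  size <- xml2::xml_find_first(doc, "./size")
  w <- h <- NA_integer_
  if (!inherits(size, "xml_missing")) {
    w <- as.integer(xml2::xml_text(xml2::xml_find_first(size, "./width")))
    h <- as.integer(xml2::xml_text(xml2::xml_find_first(size, "./height")))
  }
  objs <- xml2::xml_find_all(doc, "./object")
  boxes <- lapply(objs, function(obj) {
    label <- xml2::xml_text(xml2::xml_find_first(obj, "./name"))
    bb <- xml2::xml_find_first(obj, "./bndbox")
    get_coord <- function(field) {
      node <- xml2::xml_find_first(bb, paste0("./", field))
      if (inherits(node, "xml_missing")) {
        stop(sprintf("malformed annotation: bndbox is missing <%s>", field),
             call. = FALSE)
      }
      v <- suppressWarnings(as.numeric(xml2::xml_text(node)))
      if (!is.finite(v)) {
        stop(sprintf("malformed annotation: <%s> is not numeric", field),
             call. = FALSE)
      }
      v
    }
    xmin <- get_coord("xmin"); ymin <- get_coord("ymin")
    xmax <- get_coord("xmax"); ymax <- get_coord("ymax")
    if (xmax < xmin) {
      stop(sprintf("malformed annotation: xmax (%g) < xmin (%g)", xmax, xmin),
           call. = FALSE)
    }
    if (ymax < ymin) {
      stop(sprintf("malformed annotation: ymax (%g) < ymin (%g)", ymax, ymin),
           call. = FALSE)
    }
    list(label = label,
         box = bounding_box(ymin - 1, ymax, xmin - 1, xmax))
  })
  annotation(fname, boxes, width = w, height = h)
}

#' @rdname read_annotation
#' @param ann an [annotation()] to serialise.
#' @export
write_annotation <- function(ann, xml_path) {
  if (!inherits(ann, "annotation")) {
    stop("`ann` must be an annotation", call. = FALSE)
  }
  doc <- xml2::xml_new_root("annotation")
  xml2::xml_add_child(doc, "folder", dirname(ann$image_filename))
  xml2::xml_add_child(doc, "filename", basename(ann$image_filename))
  size <- xml2::xml_add_child(doc, "size")
  xml2::xml_add_child(size, "width", as.character(ann$width))
  xml2::xml_add_child(size, "height", as.character(ann$height))
  xml2::xml_add_child(size, "depth", "3")
  for (b in ann$boxes) {
    obj <- xml2::xml_add_child(doc, "object")
    xml2::xml_add_child(obj, "name", b$label)
    bb <- xml2::xml_add_child(obj, "bndbox")
    xml2::xml_add_child(bb, "xmin", as.character(b$box$col_start + 1L))
    xml2::xml_add_child(bb, "ymin", as.character(b$box$row_start + 1L))
    xml2::xml_add_child(bb, "xmax", as.character(b$box$col_end))
    xml2::xml_add_child(bb, "ymax", as.character(b$box$row_end))
  }
  xml2::write_xml(doc, xml_path)
  invisible(xml_path)
}
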