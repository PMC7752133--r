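# Region-of-interest geometry. The user restricts detection to the nucleus;
# here an ROI is an ellipse or a polygon in 0-based pixel coordinates
# (x = column, y = row).

#' Elliptical region of interest
#'
#' @param cx,cy Center, 0-based pixel coordinates (x = column, y = row).
#' @param rx,ry Semi-axes in pixels.
#' @return An object of class `roi` (subtype ellipse).
#' @export
roi_ellipse <- function(cx, cy, rx, ry) {
  stopifnot(rx > 0, ry > 0)
  structure(list(type = "ellipse", cx = cx, cy = cy, rx = rx, ry = ry),
            class = "roi")
}

#' Polygonal region of interest
#'
#' @param x,y Vertex coordinates (0-based pixels), in order; the polygon is
#'   closed implicitly.
#' @return An object of class `roi` (subtype polygon).
#' @export
roi_polygon <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  structure(list(type = "polygon", x = as.numeric(x), y = as.numeric(y)),
            class = "roi")
}

#' Test points for ROI membership
#'
#' @param roi An [roi_ellipse()] or [roi_polygon()].
#' @param x,y Point coordinates (0-based pixels).
#' @return Logical vector.
#' @export
in_roi <- function(roi, x, y) {
  stopifnot(inherits(roi, "roi"), length(x) == length(y))
  if (length(x) == 0) return(logical(0))
  if (roi$type == "ellipse") {
    ((x - roi$cx) / roi$rx)^2 + ((y - roi$cy) / roi$ry)^2 <= 1
  } else {
    bnd <- cbind(c(roi$x, roi$x[1]), c(roi$y, roi$y[1]))
    mgcv::in.out(bnd, cbind(as.numeric(x), as.numeric(y)))
  }
}

# Logical mask of an ROI over an image of the given dim (rows, cols).
roi_mask <- function(roi, dim) {
  xs <- rep(seq_len(dim[2]) - 1, each = dim[1])
  ys <- rep(seq_len(dim[1]) - 1, times = dim[2])
  matrix(in_roi(roi, xs, ys), nrow = dim[1], ncol = dim[2])
}

# Default nuclear ROI: inscribed ellipse with a fixed pixel margin.
default_nuclear_roi <- function(image_shape_px, margin_px = 8) {
  h <- image_shape_px[1]; w <- image_shape_px[2]
  roi_ellipse(cx = (w - 1) / 2, cy = (h - 1) / 2,
              rx = (w - 1) / 2 - margin_px, ry = (h - 1) / 2 - margin_px)
}
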