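#' Gradient mask pairs
#'
#' Returns the classical horizontal/vertical derivative mask pair. `mx`
#' responds to horizontal intensity changes (vertical edges), `my` to
#' vertical changes. Coefficients are the textbook ones:
#'
#' * Sobel: `mx = [[-1,0,1],[-2,0,2],[-1,0,1]]`,
#'   `my = [[1,2,1],[0,0,0],[-1,-2,-1]]`
#' * Prewitt: `mx = [[-1,0,1],[-1,0,1],[-1,0,1]]`,
#'   `my = [[1,1,1],[0,0,0],[-1,-1,-1]]`
#' * Roberts: `mx = [[-1,0],[0,1]]`, `my = [[0,-1],[1,0]]`
#'
#' Each mask's coefficients sum to zero, so constant images have exactly
#' zero gradient.
#'
#' @param name `"sobel"`, `"prewitt"` or `"roberts"`.
#' @return a list of class `mask_pair` with elements `name`, `mx`, `my`.
#' @export
mask_pair <- function(name = c("sobel", "prewitt", "roberts")) {
  name <- match.arg(name)
  masks <- switch(name,
    sobel = list(
      mx = matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE),
      my = matrix(c(1, 2, 1, 0, 0, 0, -1, -2, -1), 3, 3, byrow = TRUE)),
    prewitt = list(
      mx = matrix(c(-1, 0, 1, -1, 0, 1, -1, 0, 1), 3, 3, byrow = TRUE),
      my = matrix(c(1, 1, 1, 0, 0, 0, -1, -1, -1), 3, 3, byrow = TRUE)),
    roberts = list(
      mx = matrix(c(-1, 0, 0, 1), 2, 2, byrow = TRUE),
      my = matrix(c(0, -1, 1, 0), 2, 2, byrow = TRUE)))
  structure(c(list(name = name), masks), class = "mask_pair")
}

# Interior pixels (those whose mask window fits under the active anchoring
# convention) as row/column index ranges. 3x3 masks are centered, so the
# window of pixel (i, j) spans i-1..i+1; the four image borders get zero
# gradient. 2x2 Roberts masks are anchored at the top-left of the window,
# so only the last row/column are zeroed.
mask_interior <- function(mask, h, w) {
  k <- nrow(mask)
  if (k == 3L) list(rows = 2:(h - 1L), cols = 2:(w - 1L), off = -1L)
  else list(rows = 1:(h - 1L), cols = 1:(w - 1L), off = 0L)
}

#' Directional gradients by mask correlation
#'
#' Slides each mask over the image without flipping (correlation) and
#' accumulates coefficient-weighted pixel values in mask row-major order.
#' Pixels whose window does not fit inside the image get gradient 0 (the
#' image borders for 3x3 masks; the last row/column for Roberts).
#'
#' @param image a [gray_image()] or plain numeric matrix.
#' @param masks a [mask_pair()] or a mask name.
#' @return list with matrices `gx` and `gy`, the same size as the image.
#' @export
directional_gradients <- function(image, masks = mask_pair("sobel")) {
  if (is.character(masks)) masks <- mask_pair(masks)
  m <- unclass(image); attributes(m) <- list(dim = dim(m))
  h <- nrow(m); w <- ncol(m)
  if (h < nrow(masks$mx) || w < ncol(masks$mx))
    stop("image (", h, "x", w, ") is smaller than the ",
         nrow(masks$mx), "x", ncol(masks$mx), " mask window", call. = FALSE)
  list(gx = correlate_interior(m, masks$mx),
       gy = correlate_interior(m, masks$my))
}

# correlation restricted to interior pixels, zero elsewhere; term order is
# mask row-major, matching the canonical production-expression term order of
# the membrane-system compiler so both pipelines round identically
correlate_interior <- function(m, mask) {
  h <- nrow(m); w <- ncol(m)
  int <- mask_interior(mask, h, w)
  out <- matrix(0, h, w)
  acc <- matrix(0, length(int$rows), length(int$cols))
  for (a in seq_len(nrow(mask))) {
    for (b in seq_len(ncol(mask))) {
      cf <- mask[a, b]
      if (cf == 0) next
      block <- m[int$rows + int$off + (a - 1L),
                 int$cols + int$off + (b - 1L), drop = FALSE]
      acc <- if (cf == 1) acc + block
             else if (cf == -1) acc - block
             else acc + cf * block
    }
  }
  out[int$rows, int$cols] <- acc
  out
}

#' Gradient magnitude
#'
#' Elementwise `sqrt(gx^2 + gy^2)`.
#'
#' @param gx,gy equally sized numeric matrices of directional gradients.
#' @return matrix of non-negative gradient magnitudes.
#' @export
gradient_magnitude <- function(gx, gy) {
  if (!identical(dim(gx), dim(gy)))
    stop("gx and gy must have identical dimensions", call. = FALSE)
  sqrt(gx^2 + gy^2)
}

#' Threshold a gradient-magnitude grid into a binary edge map
#'
#' A pixel is an edge iff `g - theta >= 0`; the boundary case `g == theta`
#' (difference exactly zero) is classified as an edge.
#'
#' @param g matrix of gradient magnitudes.
#' @param theta non-negative scalar threshold, on the same intensity scale
#'   as the image the magnitudes came from.
#' @return an `edge_map`: integer 0/1 matrix of the same size.
#' @export
threshold_edges <- function(g, theta) {
  if (theta < 0) stop("theta must be non-negative", call. = FALSE)
  edge_map(matrix(as.integer(g - theta >= 0), nrow(g), ncol(g)))
}

edge_map <- function(m) {
  structure(m, class = c("edge_map", "matrix", "array"))
}

#' @export
print.edge_map <- function(x, ...) {
  cat(sprintf("<edge_map> %d x %d, %d edge pixel(s)\n",
              nrow(x), ncol(x), sum(unclass(x))))
  invisible(x)
}

#' Serial gradient-based edge detection
#'
#' The reference pipeline: directional gradients by mask correlation,
#' elementwise magnitude, and thresholding. This is the serial ground truth
#' the membrane-computing engine ([edenp_detect()]) is verified against.
#'
#' @param image a [gray_image()] or numeric matrix. When `normalize` is
#'   `TRUE` (default) a raw 8-bit image is first rescaled to \[0, 1\], the
#'   scale on which the default threshold 0.2 is meaningful.
#' @param mask mask name or [mask_pair()].
#' @param theta edge threshold (on the active intensity scale).
#' @param normalize rescale raw 8-bit input to the unit scale first.
#' @return a list of class `gbed_result`: `edges` (an `edge_map`), `gx`,
#'   `gy`, `g`, `d` (gradient and difference grids), `theta`, `mask`.
#' @examples
#' img <- synth_image("vstep", 8, seed = 1)
#' res <- gbed(img, "sobel", theta = 0.2)
#' res$edges
#' @export
gbed <- function(image, mask = "sobel", theta = 0.2, normalize = TRUE) {
  if (is.character(mask)) mask <- mask_pair(mask)
  if (inherits(image, "gray_image") && normalize)
    image <- normalize_gray(image, "unit")
  gr <- directional_gradients(image, mask)
  g <- gradient_magnitude(gr$gx, gr$gy)
  edges <- threshold_edges(g, theta)
  structure(list(edges = edges, gx = gr$gx, gy = gr$gy, g = g,
                 d = g - theta, theta = theta, mask = mask$name),
            class = "gbed_result")
}

#' @export
print.gbed_result <- function(x, ...) {
  cat(sprintf("<gbed_result> %s mask, theta = %g: %d / %d edge pixels\n",
              x$mask, x$theta, sum(unclass(x$edges)),
              length(x$edges)))
  invisible(x)
}
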