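#' Seeded synthetic test images with known edge structure
#'
#' Generates grayscale images whose true discontinuity locus is known by
#' construction, so every stage of the pipeline can be tested without
#' external data. Kinds:
#'
#' * `constant` — uniform background; no edges at any positive threshold.
#' * `vstep` — left half background, right half foreground; the
#'   discontinuity sits between columns `floor(cols/2)` and
#'   `floor(cols/2) + 1`.
#' * `hstep` — top/bottom halves, analogous rows.
#' * `square` — centred foreground square (side about half the image).
#' * `disk` — centred foreground disk (radius about a quarter of the size).
#' * `ramp` — linear left-to-right gradient from background to foreground.
#' * `checker` — checkerboard with blocks of a quarter of the image side.
#' * `noise` — i.i.d. uniform intensities over the full raw range.
#'
#' Additive Gaussian noise (`noise_sd`, raw intensity units) and
#' salt-and-pepper corruption (`salt_pepper`, fraction of pixels forced to
#' 0 or 255) can be applied to any kind; the result is clipped to the valid
#' range and rounded back to 8-bit integers. Identical spec and seed give
#' bit-identical images.
#'
#' For the noiseless geometric kinds the returned image carries a
#' `"discontinuity"` attribute: a logical matrix marking the pixels whose
#' 3x3 neighbourhood contains both intensities (the analytic edge band).
#'
#' @param kind pattern name (see above).
#' @param rows,cols image dimensions; `cols` defaults to `rows`.
#' @param fg,bg foreground/background intensities on the raw 8-bit scale.
#' @param noise_sd standard deviation of additive Gaussian noise (raw
#'   units), default 0.
#' @param salt_pepper fraction of pixels replaced by 0 or 255, default 0.
#' @param seed integer seed; when given, the generator is deterministic and
#'   does not disturb the caller's random-number state.
#' @return a [gray_image()] on the raw 8-bit scale.
#' @examples
#' img <- synth_image("square", 16, seed = 7, noise_sd = 10)
#' @export
synth_image <- function(kind = c("constant", "vstep", "hstep", "square",
                                 "disk", "ramp", "checker", "noise"),
                        rows, cols = rows, fg = 255, bg = 0,
                        noise_sd = 0, salt_pepper = 0, seed = NULL) {
  kind <- match.arg(kind)
  rows <- as.integer(rows); cols <- as.integer(cols)
  if (is.na(rows) || is.na(cols) || rows < 1L || cols < 1L)
    stop("image dimensions must be positive", call. = FALSE)
  if (noise_sd < 0 || salt_pepper < 0 || salt_pepper > 1)
    stop("noise parameters must be non-negative (salt_pepper in [0, 1])",
         call. = FALSE)
  if (any(c(fg, bg) < 0 | c(fg, bg) > 255))
    stop("fg/bg intensities must lie in [0, 255]", call. = FALSE)

  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    }, add = TRUE)
    set.seed(as.integer(seed))
  }

  m <- matrix(bg, rows, cols)
  switch(kind,
    constant = {},
    vstep = {
      c0 <- max(1L, cols %/% 2L)
      if (c0 < cols) m[, (c0 + 1L):cols] <- fg
    },
    hstep = {
      r0 <- max(1L, rows %/% 2L)
      if (r0 < rows) m[(r0 + 1L):rows, ] <- fg
    },
    square = {
      s <- max(1L, min(rows, cols) %/% 4L)
      ri <- max(1L, rows %/% 2L - s + 1L):min(rows, rows %/% 2L + s)
      ci <- max(1L, cols %/% 2L - s + 1L):min(cols, cols %/% 2L + s)
      m[ri, ci] <- fg
    },
    disk = {
      r <- min(rows, cols) / 4
      ci <- (row(m) - (rows + 1) / 2)^2 + (col(m) - (cols + 1) / 2)^2 <= r^2
      m[ci] <- fg
    },
    ramp = {
      grad <- if (cols == 1L) bg else
        bg + (fg - bg) * (col(m) - 1) / (cols - 1)
      m <- matrix(grad, rows, cols)
    },
    checker = {
      blk <- max(1L, min(rows, cols) %/% 4L)
      pat <- ((row(m) - 1L) %/% blk + (col(m) - 1L) %/% blk) %% 2L == 1L
      m[pat] <- fg
    },
    noise = {
      m <- matrix(sample.int(256L, rows * cols, replace = TRUE) - 1L,
                  rows, cols)
    })
  m <- round(m)

  clean <- m  # pre-noise pattern, for the discontinuity annotation
  if (noise_sd > 0)
    m <- m + stats::rnorm(length(m), sd = noise_sd)
  if (salt_pepper > 0) {
    k <- round(salt_pepper * length(m))
    if (k > 0) {
      at <- sample.int(length(m), k)
      m[at] <- sample(c(0, 255), k, replace = TRUE)
    }
  }
  m <- round(pmin(pmax(m, 0), 255))

  img <- gray_image(m, "raw")
  if (noise_sd == 0 && salt_pepper == 0 &&
      kind %in% c("vstep", "hstep", "square", "disk", "checker"))
    attr(img, "discontinuity") <- discontinuity_band(clean)
  img
}

# pixels whose 3x3 neighbourhood (clipped at the image edge) is not
# constant: the analytic locus of non-zero 3x3 mask response for two-level
# patterns
discontinuity_band <- function(m) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(FALSE, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    ri <- max(1L, i - 1L):min(h, i + 1L)
    ci <- max(1L, j - 1L):min(w, j + 1L)
    v <- m[ri, ci]
    out[i, j] <- max(v) != min(v)
  }
  out
}
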