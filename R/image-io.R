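#' Grayscale image container
#'
#' A numeric matrix with a `scale` attribute: `"raw"` means 8-bit
#' integer intensities in \[0, 255\]; `"unit"` means real intensities in
#' \[0, 1\]. Rows are image rows, top-left origin; user-facing pixel
#' coordinates are 1-based `(i = row, j = column)`.
#'
#' @param pixels numeric matrix of intensities.
#' @param scale `"raw"` or `"unit"`.
#' @return an object of class `gray_image` (a matrix).
#' @export
gray_image <- function(pixels, scale = c("raw", "unit")) {
  scale <- match.arg(scale)
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("pixels must be a numeric matrix", call. = FALSE)
  if (anyNA(pixels)) stop("pixels contain missing values", call. = FALSE)
  if (scale == "raw") {
    if (any(pixels < 0 | pixels > 255))
      stop("raw-scale intensities must lie in [0, 255]", call. = FALSE)
    if (any(pixels != round(pixels)))
      stop("raw-scale intensities must be integral", call. = FALSE)
  } else if (any(pixels < 0 | pixels > 1)) {
    stop("unit-scale intensities must lie in [0, 1]", call. = FALSE)
  }
  structure(pixels, scale = scale, class = c("gray_image", "matrix", "array"))
}

img_scale <- function(image) attr(image, "scale") %||% "raw"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Rescale a grayscale image between the 8-bit and unit intensity scales
#'
#' `raw -> unit` divides by 255; `unit -> raw` multiplies by 255 and rounds
#' half-up. Idempotent when the image is already on the target scale.
#'
#' @param image a [gray_image()].
#' @param scale target scale, `"unit"` or `"raw"`.
#' @return a [gray_image()] on the target scale.
#' @export
normalize_gray <- function(image, scale = c("unit", "raw")) {
  scale <- match.arg(scale)
  from <- img_scale(image)
  m <- unclass(image); attr(m, "scale") <- NULL
  if (from == scale) return(gray_image(m, scale))
  if (scale == "unit") gray_image(m / 255, "unit")
  else gray_image(floor(m * 255 + 0.5), "raw")
}

#' Read a grayscale image
#'
#' Supports PGM in both the ASCII (`P2`) and binary (`P5`) dialects, and
#' delimited text grids (comma or whitespace separated). PGM files with a
#' maxval other than 255 are rescaled to the canonical 8-bit range on read.
#'
#' @param path path to the image file.
#' @param format `"pgm"`, `"csv"`, or `"auto"` (default: decide from the file
#'   extension, falling back to sniffing the magic number).
#' @return a [gray_image()] on the raw 8-bit scale.
#' @export
read_gray <- function(path, format = c("auto", "pgm", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("pgm", "pnm")) "pgm"
    else if (ext %in% c("csv", "txt", "tsv", "dat")) "csv"
    else {
      magic <- readBin(path, "raw", n = 2L)
      if (length(magic) == 2L && rawToChar(magic[1L]) == "P") "pgm" else "csv"
    }
  }
  if (format == "pgm") read_pgm(path) else read_gray_text(path)
}

read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  tokens <- character(0)
  # header: magic, width, height, maxval; '#' starts a comment to end-of-line
  read_token <- function() {
    tok <- ""
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (length(ch) == 0L || !nzchar(ch))
        stop("malformed PGM header: unexpected end of file in ", path,
             call. = FALSE)
      if (ch == "#") {
        repeat {
          ch <- readChar(con, 1L, useBytes = TRUE)
          if (!length(ch) || ch == "\n") break
        }
        next
      }
      if (grepl("[ \t\r\n]", ch)) {
        if (nzchar(tok)) return(tok)
      } else tok <- paste0(tok, ch)
    }
  }
  magic <- read_token()
  if (!magic %in% c("P2", "P5"))
    stop("unsupported PGM magic number '", magic, "' in ", path,
         call. = FALSE)
  width <- suppressWarnings(as.integer(read_token()))
  height <- suppressWarnings(as.integer(read_token()))
  maxval <- suppressWarnings(as.integer(read_token()))
  if (anyNA(c(width, height, maxval)) || width < 1L || height < 1L ||
      maxval < 1L)
    stop("malformed PGM header in ", path, call. = FALSE)
  n <- width * height
  if (magic == "P2") {
    rest <- readChar(con, file.size(path), useBytes = TRUE)
    vals <- suppressWarnings(as.numeric(strsplit(trimws(rest),
                                                 "[ \t\r\n]+")[[1L]]))
    if (anyNA(vals)) stop("non-numeric pixel in PGM file ", path,
                          call. = FALSE)
  } else {
    if (maxval > 255L) {
      raw2 <- readBin(con, "integer", n = n, size = 2L, signed = FALSE,
                      endian = "big")
      vals <- as.numeric(raw2)
    } else {
      vals <- as.numeric(readBin(con, "integer", n = n, size = 1L,
                                 signed = FALSE))
    }
  }
  if (length(vals) != n)
    stop("PGM file ", path, " has ", length(vals), " pixels, expected ", n,
         call. = FALSE)
  if (any(vals < 0 | vals > maxval))
    stop("pixel value out of range [0, maxval] in ", path, call. = FALSE)
  if (maxval != 255L) vals <- floor(vals * 255 / maxval + 0.5)
  gray_image(matrix(vals, nrow = height, ncol = width, byrow = TRUE), "raw")
}

read_gray_text <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty image file: ", path, call. = FALSE)
  sep <- if (any(grepl(",", lines))) "," else "[ \t]+"
  rows <- lapply(lines, function(l)
    suppressWarnings(as.numeric(strsplit(trimws(l), sep)[[1L]])))
  if (any(vapply(rows, anyNA, logical(1))))
    stop("non-numeric cell in ", path, call. = FALSE)
  w <- unique(lengths(rows))
  if (length(w) != 1L)
    stop("ragged rows in ", path, " (widths: ",
         paste(sort(w), collapse = ", "), ")", call. = FALSE)
  m <- do.call(rbind, rows)
  scale <- if (all(m >= 0 & m <= 1)) "unit" else "raw"
  gray_image(m, scale)
}

#' Write a grayscale image
#'
#' PGM output always uses maxval 255 (the unit scale is converted to raw
#' first); `P2` is ASCII, `P5` binary. Text output writes the grid as-is on
#' its current scale, one row per line. Round trip with [read_gray()] is
#' lossless at the 8-bit scale.
#'
#' @param image a [gray_image()].
#' @param path output file path.
#' @param format `"pgm"` (default) or `"csv"`.
#' @param pgm_type `"P2"` or `"P5"`.
#' @return `path`, invisibly.
#' @export
write_gray <- function(image, path, format = c("pgm", "csv"),
                       pgm_type = c("P2", "P5")) {
  format <- match.arg(format)
  pgm_type <- match.arg(pgm_type)
  stopifnot(inherits(image, "gray_image"))
  if (format == "csv") {
    m <- unclass(image)
    utils::write.table(m, path, sep = ",", row.names = FALSE,
                       col.names = FALSE)
    return(invisible(path))
  }
  raw <- normalize_gray(image, "raw")
  m <- unclass(raw)
  h <- nrow(m); w <- ncol(m)
  vals <- as.integer(t(m))  # row-major
  if (pgm_type == "P2") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("P2", paste(w, h), "255"), con)
    writeLines(paste(vals, collapse = " "), con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeChar(sprintf("P5\n%d %d\n255\n", w, h), con, eos = NULL)
    writeBin(as.raw(vals), con)
  }
  invisible(path)
}

#' Write a binary edge map
#'
#' Edge maps are 0/1 integer matrices (see [edenp_detect()]). PGM output
#' maps 1 to 255 and 0 to 0; text output keeps 0/1.
#'
#' @param map an `edge_map` or any 0/1 matrix.
#' @param path output file path.
#' @param format `"pgm"` (default) or `"csv"`.
#' @param pgm_type `"P2"` or `"P5"`.
#' @return `path`, invisibly.
#' @export
write_edges <- function(map, path, format = c("pgm", "csv"),
                        pgm_type = c("P2", "P5")) {
  format <- match.arg(format)
  pgm_type <- match.arg(pgm_type)
  m <- unclass(map)
  attributes(m) <- list(dim = dim(m))
  if (!all(m %in% c(0, 1)))
    stop("edge map must be binary (0/1)", call. = FALSE)
  if (format == "csv") {
    utils::write.table(m, path, sep = ",", row.names = FALSE,
                       col.names = FALSE)
    return(invisible(path))
  }
  write_gray(gray_image(m * 255, "raw"), path, "pgm", pgm_type)
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image> %d x %d, scale: %s\n", nrow(x), ncol(x),
              img_scale(x)))
  invisible(x)
}

#' Display a grayscale image or an edge map
#'
#' @param x a `gray_image` or `edge_map`.
#' @param y ignored.
#' @param ... passed to [graphics::image()].
#' @export
plot.gray_image <- function(x, y, ...) {
  m <- unclass(x)
  # flip so row 1 is at the top, like an image viewer
  graphics::image(t(m)[, nrow(m):1, drop = FALSE],
                  col = grDevices::gray.colors(256, 0, 1), axes = FALSE,
                  asp = nrow(m) / ncol(m), ...)
  invisible(x)
}

#' @rdname plot.gray_image
#' @export
plot.edge_map <- function(x, y, ...) {
  m <- unclass(x)
  graphics::image(t(m)[, nrow(m):1, drop = FALSE],
                  col = c("black", "white"), axes = FALSE,
                  asp = nrow(m) / ncol(m), ...)
  invisible(x)
}
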