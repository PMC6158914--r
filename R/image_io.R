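# Image containers and raster input/output.
#
# Coordinate convention used throughout the package: matrices are indexed
# (row, col), row 1 at the top of the image.  Intensities are carried as
# real numbers in [0, 255] after reading so the PDE stages do not quantize;
# quantization to 8 bits happens only on write.

GRAY_STAGES <- c("green", "enhanced", "median", "difference", "inpainted")
MASK_ROLES  <- c("vessel", "inpaint_region", "inpaint_band", "cup", "disc")

#' Construct a fundus image
#'
#' A fundus image is an H x W x 3 numeric array with channels ordered red,
#' green, blue and values in \[0, 255\].
#'
#' @param pixels numeric H x W x 3 array.
#' @return An object of class `fundus_image`.
#' @export
fundus_image <- function(pixels) {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("`pixels` must be an H x W x 3 array")
  if (!all(is.finite(pixels)))
    stop("fundus image contains non-finite values")
  if (min(pixels) < 0 || max(pixels) > 255)
    stop("fundus image values must lie in [0, 255]")
  structure(list(pixels = pixels), class = "fundus_image")
}

#' Construct a single-channel image
#'
#' @param pixels numeric H x W matrix, finite everywhere.
#' @param stage one of `"green"`, `"enhanced"`, `"median"`, `"difference"`,
#'   `"inpainted"`, recording the pipeline stage the image belongs to.
#' @return An object of class `gray_image`.
#' @export
gray_image <- function(pixels, stage) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix")
  if (!all(is.finite(pixels)))
    stop("gray image contains non-finite values")
  stage <- match.arg(stage, GRAY_STAGES)
  structure(list(pixels = pixels, stage = stage), class = "gray_image")
}

#' Construct a binary mask
#'
#' @param pixels logical H x W matrix.
#' @param role one of `"vessel"`, `"inpaint_region"`, `"inpaint_band"`,
#'   `"cup"`, `"disc"`.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(pixels, role) {
  if (!is.matrix(pixels) || !is.logical(pixels))
    stop("`pixels` must be a logical matrix")
  role <- match.arg(role, MASK_ROLES)
  structure(list(pixels = pixels, role = role), class = "binary_mask")
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image %dx%d stage=%s range=[%.2f, %.2f]>\n",
              nrow(x$pixels), ncol(x$pixels), x$stage,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask %dx%d role=%s foreground=%d px>\n",
              nrow(x$pixels), ncol(x$pixels), x$role, sum(x$pixels)))
  invisible(x)
}

#' @export
print.fundus_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<fundus_image %dx%d rgb>\n", d[1], d[2]))
  invisible(x)
}

#' @export
as.matrix.gray_image <- function(x, ...) x$pixels

#' @export
as.matrix.binary_mask <- function(x, ...) x$pixels

# Accept a gray_image or a bare matrix.
as_gray_matrix <- function(x) {
  if (inherits(x, "gray_image")) x$pixels
  else if (is.matrix(x) && is.numeric(x)) x
  else stop("expected a gray_image or a numeric matrix")
}

as_mask_matrix <- function(x) {
  if (inherits(x, "binary_mask")) x$pixels
  else if (is.matrix(x) && is.logical(x)) x
  else stop("expected a binary_mask or a logical matrix")
}

# EBImage stores rasters as (x = width, y = height[, channel]); transpose to
# the (row, col) convention and rescale to [0, 255].  16-bit rasters arrive
# from the reader already scaled to [0, 1], so the same factor applies.
read_raster <- function(path) {
  if (!file.exists(path))
    stop("cannot read image file (does not exist): ", path)
  img <- tryCatch(EBImage::readImage(path),
                  error = function(e)
                    stop("cannot read image file: ", path, " (",
                         conditionMessage(e), ")", call. = FALSE))
  arr <- as.array(img)
  if (length(dim(arr)) == 2L) t(arr) * 255
  else aperm(arr, c(2L, 1L, 3L)) * 255
}

#' Read a fundus photograph
#'
#' Reads a PNG, TIFF or JPEG raster as an RGB fundus image.  A fourth
#' (alpha) channel is discarded; single-channel rasters are rejected because
#' the method's first step is an explicit color-channel choice.  16-bit
#' rasters are rescaled linearly to \[0, 255\].
#'
#' @param path path to a decodable 3- or 4-channel raster.
#' @return A [fundus_image()].
#' @export
read_fundus <- function(path) {
  arr <- read_raster(path)
  if (length(dim(arr)) != 3L)
    stop("fundus image must have 3 channels, got a single-channel raster: ",
         path)
  nc <- dim(arr)[3]
  if (nc == 4L) arr <- arr[, , 1:3, drop = FALSE]
  else if (nc != 3L)
    stop("fundus image must have 3 channels, got ", nc, ": ", path)
  fundus_image(arr)
}

#' Extract the green channel
#'
#' The green channel offers the best cup/background contrast of the three
#' color components and is the only channel the method consumes.
#'
#' @param img a [fundus_image()].
#' @return A [gray_image()] with stage `"green"`.
#' @export
extract_green <- function(img) {
  if (!inherits(img, "fundus_image")) stop("`img` must be a fundus_image")
  gray_image(img$pixels[, , 2], "green")
}

#' Read a binary mask
#'
#' Reads a raster, takes its first channel, and thresholds at the intensity
#' midpoint (nonzero above 127.5 becomes foreground).
#'
#' @param path path to the mask raster (PNG recommended; 0 = background,
#'   255 = foreground).
#' @param shape integer `c(H, W)` the mask must match.
#' @param role mask role tag, see [binary_mask()].
#' @return A [binary_mask()].
#' @export
read_mask <- function(path, shape, role = "cup") {
  arr <- read_raster(path)
  if (length(dim(arr)) == 3L) arr <- arr[, , 1]
  if (!identical(dim(arr), as.integer(shape)))
    stop(sprintf("mask shape %dx%d does not match expected %dx%d",
                 nrow(arr), ncol(arr), shape[1], shape[2]))
  binary_mask(arr > 127.5, role)
}

#' Write a binary mask as PNG
#'
#' @param mask a [binary_mask()].
#' @param path output path (PNG; foreground written as 255).
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  m <- as_mask_matrix(mask)
  EBImage::writeImage(t(m * 1), path)
  invisible(path)
}

#' Write a gray image as PNG
#'
#' Values are clipped to \[0, 255\] and quantized to 8 bits on write.
#'
#' @param img a [gray_image()] or numeric matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gray <- function(img, path) {
  m <- as_gray_matrix(img)
  EBImage::writeImage(t(pmin(pmax(m, 0), 255)) / 255, path)
  invisible(path)
}
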