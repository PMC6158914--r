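# Contrast enhancement of the green channel by top-hat and bottom-hat
# morphological transforms with a flat square structuring element.

#' Enhancement parameters
#'
#' @param se_size side length in pixels of the flat square structuring
#'   element; odd and >= 3.  5 gives the best cup boundary contrast and is
#'   the default.  Even sizes are admitted only by the parameter-sweep
#'   harness (`.allow_even`), where the element is anchored at its top-left
#'   pixel.
#' @param clamp clip the enhanced image to \[0, 255\]; the enhancement sum
#'   can otherwise overshoot the nominal range.
#' @param .allow_even internal: permit even `se_size` (sweep harness only).
#' @return An object of class `enhance_params`.
#' @export
enhance_params <- function(se_size = 5L, clamp = TRUE, .allow_even = FALSE) {
  se_size <- as.integer(se_size)
  if (se_size < 2L || (!.allow_even && (se_size %% 2L == 0L || se_size < 3L)))
    stop("`se_size` must be an odd integer >= 3")
  structure(list(se_size = se_size, clamp = isTRUE(clamp)),
            class = "enhance_params")
}

# SE footprint offsets relative to the anchor pixel: symmetric for odd
# sizes, extending down-right for even sizes (top-left anchored).
se_offsets <- function(se_size) {
  o0 <- -((se_size - 1L) %/% 2L)
  c(o0, se_size - 1L + o0)
}

morpho_open <- function(m, se_size) {
  o <- se_offsets(se_size)
  cpp_dilate(cpp_erode(m, o[1], o[2]), o[1], o[2])
}

morpho_close <- function(m, se_size) {
  o <- se_offsets(se_size)
  cpp_erode(cpp_dilate(m, o[1], o[2]), o[1], o[2])
}

#' Top-hat transform
#'
#' Image minus its morphological opening; nonnegative everywhere, large on
#' bright structures smaller than the structuring element.
#'
#' @param img a [gray_image()] or numeric matrix.
#' @param p an [enhance_params()].
#' @return A [gray_image()] at the stage of the input.
#' @export
top_hat <- function(img, p = enhance_params()) {
  m <- as_gray_matrix(img)
  stage <- if (inherits(img, "gray_image")) img$stage else "green"
  gray_image(m - morpho_open(m, p$se_size), stage)
}

#' Bottom-hat transform
#'
#' Morphological closing minus the image; nonnegative everywhere, large on
#' dark structures (vessels) smaller than the structuring element.
#'
#' @inheritParams top_hat
#' @return A [gray_image()] at the stage of the input.
#' @export
bottom_hat <- function(img, p = enhance_params()) {
  m <- as_gray_matrix(img)
  stage <- if (inherits(img, "gray_image")) img$stage else "green"
  gray_image(morpho_close(m, p$se_size) - m, stage)
}

#' Morphological contrast enhancement
#'
#' Adds the top-hat and subtracts the bottom-hat transform:
#' `U = (U_G + tophat(U_G)) - bottomhat(U_G)`.  Bright structure is boosted
#' and dark structure (vessels) darkened, sharpening the cup rim.
#'
#' @inheritParams top_hat
#' @return A [gray_image()] with stage `"enhanced"`.
#' @export
enhance <- function(img, p = enhance_params()) {
  m <- as_gray_matrix(img)
  out <- m + (m - morpho_open(m, p$se_size)) - (morpho_close(m, p$se_size) - m)
  if (p$clamp) out <- pmin(pmax(out, 0), 255)
  gray_image(out, "enhanced")
}
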