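# Blood-vessel extraction by median-filter differencing, mask cleanup, and
# the dilated band that the inpainting stage diffuses over.

#' Vessel-extraction parameters
#'
#' @param median_size odd side length in pixels of the median window
#'   (default 9, the size at which vessel suppression is most accurate).
#' @param tau threshold on the difference image; the extraction rule is
#'   strictly `U_med - U > tau`.  The default 0 is the literal rule, which
#'   is exact on noise-free imagery but fires on about half of all pixels
#'   under any additive continuous noise.  `"auto"` thresholds at twice the
#'   robust noise scale of the difference image
#'   (`2 * 1.4826 * MAD(U_sub)`), which reduces to the literal rule when
#'   the image is noise-free (the MAD is then 0).
#' @param min_component smallest 8-connected component (pixels) kept by
#'   [clean_vessel_mask()]; 0 keeps the raw thresholded mask.
#' @param band_radius radius in pixels of the Euclidean disc used to dilate
#'   the vessel mask into the diffusion band.
#' @return An object of class `vessel_params`.
#' @export
vessel_params <- function(median_size = 9L, tau = 0, min_component = 10L,
                          band_radius = 2L) {
  median_size <- as.integer(median_size)
  if (median_size < 3L || median_size %% 2L == 0L)
    stop("`median_size` must be an odd integer >= 3")
  if (identical(tau, "auto")) {
    # resolved against the difference image in binarize_vessels()
  } else if (!is.numeric(tau) || length(tau) != 1L || tau < 0) {
    stop("`tau` must be a nonnegative number or \"auto\"")
  }
  if (min_component < 0L) stop("`min_component` must be >= 0")
  if (band_radius < 0L) stop("`band_radius` must be >= 0")
  structure(list(median_size = median_size, tau = tau,
                 min_component = as.integer(min_component),
                 band_radius = as.integer(band_radius)),
            class = "vessel_params")
}

#' Median-filtered image
#'
#' Per-pixel median over a `median_size` square window, with border
#' reflection.  Dark, thin vessels brighten toward the local background
#' level, which the difference image then picks up.
#'
#' @param img a [gray_image()] or numeric matrix.
#' @param p a [vessel_params()].
#' @return A [gray_image()] with stage `"median"`.
#' @export
median_image <- function(img, p = vessel_params()) {
  m <- as_gray_matrix(img)
  gray_image(cpp_median_filter(m, p$median_size), "median")
}

#' Difference image
#'
#' Element-wise `med - img`; positive where the image is darker than its
#' local median (vessel candidates), possibly negative elsewhere.
#'
#' @param img enhanced image (a [gray_image()] or matrix).
#' @param med its median-filtered version.
#' @return A [gray_image()] with stage `"difference"`.
#' @export
difference_image <- function(img, med) {
  a <- as_gray_matrix(img)
  b <- as_gray_matrix(med)
  if (!identical(dim(a), dim(b)))
    stop("image and median image have different shapes")
  gray_image(b - a, "difference")
}

#' Threshold the difference image into a vessel mask
#'
#' Pixels with difference strictly greater than `tau` (default 0) are marked
#' as vessel.  With `tau = "auto"` the threshold is twice the robust noise
#' scale of the difference image (vessels occupy a small fraction of the
#' frame, so the MAD measures the noise, not the signal).
#'
#' @param diff a difference-stage [gray_image()].
#' @param p a [vessel_params()].
#' @return A [binary_mask()] with role `"vessel"`.
#' @export
binarize_vessels <- function(diff, p = vessel_params()) {
  if (inherits(diff, "gray_image") && diff$stage != "difference")
    stop("`diff` must be a difference-stage image, got stage ", diff$stage)
  d <- as_gray_matrix(diff)
  tau <- if (identical(p$tau, "auto")) 2 * stats::mad(d) else p$tau
  binary_mask(d > tau, "vessel")
}

#' Remove small components from a vessel mask
#'
#' Drops 8-connected components smaller than `min_component` pixels; the
#' strict positive threshold of the extraction rule fires on isolated noise
#' pixels, which this removes.
#'
#' @param mask a vessel [binary_mask()].
#' @param p a [vessel_params()].
#' @return A [binary_mask()], subset of the input, same role.
#' @export
clean_vessel_mask <- function(mask, p = vessel_params()) {
  m <- as_mask_matrix(mask)
  role <- if (inherits(mask, "binary_mask")) mask$role else "vessel"
  if (p$min_component <= 1L || !any(m)) return(binary_mask(m, role))
  lab <- cpp_label8(m)
  sizes <- tabulate(lab)
  keep <- which(sizes >= p$min_component)
  binary_mask(matrix(lab %in% keep, nrow(m), ncol(m)), role)
}

#' Dilate a mask into the inpainting band
#'
#' Binary dilation by a Euclidean disc of radius `band_radius` (a pixel
#' belongs to the disc iff its center distance is at most the radius, so
#' radius 1 is the 4-neighborhood cross).  The result is a superset of the
#' input and is the region the diffusion half of the inpainting scheme acts
#' on.
#'
#' @param mask a vessel or inpaint-region [binary_mask()].
#' @param p a [vessel_params()].
#' @return A [binary_mask()] with role `"inpaint_band"`.
#' @export
inpaint_band <- function(mask, p = vessel_params()) {
  m <- as_mask_matrix(mask)
  out <- if (p$band_radius == 0L) m else cpp_dilate_disc(m, p$band_radius)
  binary_mask(out, "inpaint_band")
}

#' Extract the blood-vessel mask from an enhanced image
#'
#' Convenience composition: median filter, difference, threshold, small
#' component cleanup.
#'
#' @param img enhanced [gray_image()].
#' @param p a [vessel_params()].
#' @return A [binary_mask()] with role `"vessel"`.
#' @export
extract_vessels <- function(img, p = vessel_params()) {
  med <- median_image(img, p)
  clean_vessel_mask(binarize_vessels(difference_image(img, med), p), p)
}
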