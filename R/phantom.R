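# Deterministic synthetic fundus phantom: a bright elliptical disc on a
# darker background, a brighter elliptical cup inside it with a smooth rim
# ramp, dark quadratic-Bezier vessels crossing the cup boundary, and
# additive Gaussian noise.  Ground-truth cup/disc/vessel masks and the true
# vertical CDR come with every phantom.

#' Phantom specification
#'
#' Ellipse membership uses a half-pixel-shifted center so that an integer
#' vertical semi-axis `a` covers exactly `2a` pixel rows; the true vertical
#' CDR of a centered phantom is then exactly the ratio of the vertical
#' semi-axes.
#'
#' @param height,width image size in pixels.
#' @param disc_center (row, col) of the disc center.
#' @param disc_axes (vertical, horizontal) semi-axes of the disc, px.
#' @param cup_axes (vertical, horizontal) semi-axes of the cup, strictly
#'   smaller than `disc_axes`.
#' @param bg_level,disc_level,cup_level intensities, `bg < disc < cup`.
#' @param rim_softness width (px) of the smooth intensity ramp at the cup
#'   edge; the ramp is centered on the true cup boundary.
#' @param n_vessels number of vessels drawn across the cup boundary.
#' @param vessel_width vessel strip width, px.
#' @param vessel_depth intensity drop inside a vessel.
#' @param noise_sigma standard deviation of the additive Gaussian noise.
#' @param seed integer RNG seed; identical spec + seed gives bit-identical
#'   phantoms.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(height = 480L, width = 480L,
                         disc_center = c(height / 2, width / 2),
                         disc_axes = c(120, 132), cup_axes = c(60, 66),
                         bg_level = 60, disc_level = 140, cup_level = 210,
                         rim_softness = 6, n_vessels = 5L, vessel_width = 3,
                         vessel_depth = 70, noise_sigma = 4, seed = 1L) {
  if (any(cup_axes >= disc_axes))
    stop("the cup ellipse must lie strictly inside the disc ellipse")
  if (!(bg_level < disc_level && disc_level < cup_level))
    stop("levels must be ordered bg < disc < cup")
  if (rim_softness <= 0) stop("`rim_softness` must be positive")
  if (noise_sigma < 0) stop("`noise_sigma` must be >= 0")
  structure(list(height = as.integer(height), width = as.integer(width),
                 disc_center = as.numeric(disc_center),
                 disc_axes = as.numeric(disc_axes),
                 cup_axes = as.numeric(cup_axes),
                 bg_level = bg_level, disc_level = disc_level,
                 cup_level = cup_level, rim_softness = rim_softness,
                 n_vessels = as.integer(n_vessels),
                 vessel_width = vessel_width, vessel_depth = vessel_depth,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "phantom_spec")
}

# Normalized elliptical radius on the pixel grid (1 on the ellipse).
elliptic_radius <- function(H, W, center, axes) {
  r <- matrix(seq_len(H), H, W)
  c <- matrix(seq_len(W), H, W, byrow = TRUE)
  sqrt(((r - center[1] + 0.5) / axes[1])^2 +
       ((c - center[2] + 0.5) / axes[2])^2)
}

smoothstep <- function(t) {
  t <- pmin(pmax(t, 0), 1)
  t * t * (3 - 2 * t)
}

# Mark pixels within `width/2` of a densely sampled quadratic Bezier.
stamp_bezier <- function(mask, p0, p1, p2, width) {
  H <- nrow(mask); W <- ncol(mask)
  tt <- seq(0, 1, length.out = 400)
  pr <- (1 - tt)^2 * p0[1] + 2 * (1 - tt) * tt * p1[1] + tt^2 * p2[1]
  pc <- (1 - tt)^2 * p0[2] + 2 * (1 - tt) * tt * p1[2] + tt^2 * p2[2]
  rad <- width / 2
  ir <- floor(rad)
  off <- expand.grid(di = -ir:ir, dj = -ir:ir)
  off <- off[off$di^2 + off$dj^2 <= rad^2, , drop = FALSE]
  for (k in seq_len(nrow(off))) {
    rr <- round(pr) + off$di[k]
    cc <- round(pc) + off$dj[k]
    ok <- rr >= 1 & rr <= H & cc >= 1 & cc <= W
    mask[cbind(rr[ok], cc[ok])] <- TRUE
  }
  mask
}

#' Generate a synthetic fundus phantom
#'
#' Renders the phantom described by `spec` and returns the image together
#' with its ground truth.  The green channel carries the full signal; the
#' red and blue channels are fixed fractions (0.8 and 0.4) of it.  Channels
#' are clipped to \[0, 255\] and quantized to whole intensities, emulating
#' 24-bit capture.
#'
#' @param spec a [phantom_spec()].
#' @return A list with elements `image` ([fundus_image()]) and `truth`
#'   (list: `cup_mask`, `disc_mask`, `vessel_mask`, `true_cdr`).
#' @export
make_phantom <- function(spec = phantom_spec()) {
  H <- spec$height; W <- spec$width
  r_disc <- elliptic_radius(H, W, spec$disc_center, spec$disc_axes)
  r_cup <- elliptic_radius(H, W, spec$disc_center, spec$cup_axes)
  disc_mask <- r_disc <= 1
  cup_mask <- r_cup <= 1

  # smooth ramps centered on the ellipse boundaries, widths in approximate
  # pixel units via the shorter semi-axis
  disc_edge <- 2
  s_disc <- smoothstep(0.5 + (1 - r_disc) * min(spec$disc_axes) / disc_edge)
  s_cup <- smoothstep(0.5 + (1 - r_cup) * min(spec$cup_axes) /
                        spec$rim_softness)
  g <- spec$bg_level + (spec$disc_level - spec$bg_level) * s_disc +
    (spec$cup_level - spec$disc_level) * s_cup

  vessel_mask <- matrix(FALSE, H, W)
  if (spec$n_vessels > 0) {
    with_seed(spec$seed * 2L + 1L, {
      for (k in seq_len(spec$n_vessels)) {
        th <- 2 * pi * (k - 1) / spec$n_vessels + runif(1, -0.25, 0.25)
        u <- c(sin(th), cos(th))
        p0 <- spec$disc_center + u * spec$disc_axes * 1.45
        p2 <- spec$disc_center + u * spec$cup_axes * runif(1, 0.15, 0.35)
        mid <- (p0 + p2) / 2
        perp <- c(-u[2], u[1]) * runif(1, -0.25, 0.25) *
          sqrt(sum((p0 - p2)^2))
        vessel_mask <- stamp_bezier(vessel_mask, p0, mid + perp, p2,
                                    spec$vessel_width)
      }
    })
    g[vessel_mask] <- g[vessel_mask] - spec$vessel_depth
  }
  if (spec$noise_sigma > 0)
    g <- g + with_seed(spec$seed,
                       matrix(rnorm(H * W, 0, spec$noise_sigma), H, W))
  clip8 <- function(x) round(pmin(pmax(x, 0), 255))
  img <- fundus_image(array(c(clip8(0.8 * g), clip8(g), clip8(0.4 * g)),
                            dim = c(H, W, 3)))
  truth <- list(cup_mask = binary_mask(cup_mask, "cup"),
                disc_mask = binary_mask(disc_mask, "disc"),
                vessel_mask = binary_mask(vessel_mask, "vessel"),
                true_cdr = vertical_cdr(cup_mask, disc_mask))
  list(image = img, truth = truth, spec = spec)
}

#' Generate a phantom suite with jittered geometry
#'
#' `n` phantoms whose disc geometry is jittered (axes within +/-10%, center
#' within +/-10 px) and whose cup size sweeps the clinically relevant CDR
#' range: the target vertical CDR of phantom `i` moves linearly across
#' [0.32, 0.78].  Phantom `i` uses the derived seed
#' `(seed mod 5e5) * 1000 + i` (so every internally derived seed stays within the 32-bit RNG seed range), so
#' the suite is reproducible from `(base, seed)` alone.
#'
#' @param n number of phantoms, >= 1.
#' @param base a [phantom_spec()] supplying everything the jitter does not
#'   touch.
#' @param seed integer master seed.
#' @return A list of `n` phantom objects as returned by [make_phantom()].
#' @export
make_suite <- function(n = 20L, base = phantom_spec(), seed = 1L) {
  if (n < 1L) stop("`n` must be >= 1")
  target_cdr <- if (n == 1L) 0.55 else seq(0.32, 0.78, length.out = n)
  lapply(seq_len(n), function(i) {
    di <- (seed %% 500000L) * 1000L + i
    jit <- with_seed(di + 7L, list(
      axes = runif(2, 0.9, 1.1), center = runif(2, -10, 10),
      shape = runif(1, 0.95, 1.05)))
    disc_axes <- base$disc_axes * jit$axes
    cup_axes <- c(target_cdr[i] * disc_axes[1],
                  target_cdr[i] * disc_axes[2] * jit$shape)
    spec <- phantom_spec(height = base$height, width = base$width,
                         disc_center = base$disc_center + jit$center,
                         disc_axes = disc_axes, cup_axes = cup_axes,
                         bg_level = base$bg_level,
                         disc_level = base$disc_level,
                         cup_level = base$cup_level,
                         rim_softness = base$rim_softness,
                         n_vessels = base$n_vessels,
                         vessel_width = base$vessel_width,
                         vessel_depth = base$vessel_depth,
                         noise_sigma = base$noise_sigma, seed = di)
    make_phantom(spec)
  })
}
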