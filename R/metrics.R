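# Evaluation criteria: pixel-wise precision/recall/F-score, radial boundary
# distance between closed contours, and the vertical cup-to-disc ratio.

#' Pixel-wise confusion counts
#'
#' @param pred predicted [binary_mask()] (or logical matrix).
#' @param truth ground-truth mask of the same shape.
#' @return A list with integer fields `tp`, `fp`, `fn`.
#' @export
confusion <- function(pred, truth) {
  a <- as_mask_matrix(pred)
  b <- as_mask_matrix(truth)
  if (!identical(dim(a), dim(b)))
    stop("prediction and truth masks have different shapes")
  list(tp = sum(a & b), fp = sum(a & !b), fn = sum(!a & b))
}

#' Precision, recall and F-score
#'
#' `F = 2 * precision * recall / (precision + recall)`, the harmonic mean.
#' With no true positives the score is 0 (unless every count is 0, which is
#' an error).
#'
#' @param c confusion counts from [confusion()].
#' @return For `f_score`, the scalar score in \[0, 1\].
#' @export
f_score <- function(c) {
  if (c$tp + c$fp + c$fn == 0)
    stop("F-score undefined: prediction and truth are both empty")
  if (c$tp == 0) return(0)
  pr <- c$tp / (c$tp + c$fp)
  rc <- c$tp / (c$tp + c$fn)
  2 * pr * rc / (pr + rc)
}

#' @rdname f_score
#' @export
precision_score <- function(c) {
  if (c$tp + c$fp == 0) return(0)
  c$tp / (c$tp + c$fp)
}

#' @rdname f_score
#' @export
recall_score <- function(c) {
  if (c$tp + c$fn == 0) return(0)
  c$tp / (c$tp + c$fn)
}

#' Construct a closed contour
#'
#' @param vertices n x 2 numeric matrix of (row, col) points, ordered along
#'   the curve; the last vertex connects implicitly back to the first.
#' @param centroid optional (row, col) centroid; defaults to the area
#'   centroid of the polygon.
#' @return An object of class `cup_contour`.
#' @export
cup_contour <- function(vertices, centroid = NULL) {
  vertices <- as.matrix(vertices)
  if (nrow(vertices) < 3L || ncol(vertices) != 2L)
    stop("a contour needs >= 3 (row, col) vertices")
  if (is.null(centroid)) {
    # area centroid by the shoelace formula
    r <- vertices[, 1]; c <- vertices[, 2]
    r2 <- c(r[-1], r[1]); c2 <- c(c[-1], c[1])
    cr <- r * c2 - r2 * c
    A <- sum(cr) / 2
    centroid <- if (abs(A) < 1e-12) c(mean(r), mean(c))
                else c(sum((r + r2) * cr) / (6 * A),
                       sum((c + c2) * cr) / (6 * A))
  }
  structure(list(vertices = vertices,
                 centroid = c(row = centroid[[1]], col = centroid[[2]])),
            class = "cup_contour")
}

#' @export
print.cup_contour <- function(x, ...) {
  cat(sprintf("<cup_contour: %d vertices, centroid (%.1f, %.1f)>\n",
              nrow(x$vertices), x$centroid[1], x$centroid[2]))
  invisible(x)
}

#' Trace the boundary of a single-component mask
#'
#' Traces the 0.5 iso-level of the mask (marching squares on the zero-padded
#' indicator), orients the vertices counter-clockwise in (row, col)
#' coordinates, and stores the foreground pixel centroid.  A single pixel
#' yields the 4-vertex diamond through its edge midpoints.
#'
#' @param mask a [binary_mask()] (or logical matrix) with exactly one
#'   8-connected foreground component.
#' @return A [cup_contour()].
#' @export
mask_to_contour <- function(mask) {
  m <- as_mask_matrix(mask)
  if (!any(m)) stop("cannot trace the contour of an empty mask")
  ncomp <- max(cpp_label8(m))
  if (ncomp != 1L)
    stop("mask has ", ncomp, " components; contour tracing needs exactly 1")
  H <- nrow(m); W <- ncol(m)
  z <- matrix(0, H + 2, W + 2)
  z[2:(H + 1), 2:(W + 1)] <- m * 1
  cl <- contourLines(x = 0:(H + 1), y = 0:(W + 1), z = z, levels = 0.5)
  # outer boundary = contour enclosing the largest |area|
  areas <- vapply(cl, function(s) {
    r <- s$x; c <- s$y
    abs(sum(r * c(c[-1], c[1]) - c(r[-1], r[1]) * c)) / 2
  }, numeric(1))
  s <- cl[[which.max(areas)]]
  v <- cbind(s$x, s$y)
  if (nrow(v) > 1 && all(v[1, ] == v[nrow(v), ])) v <- v[-nrow(v), , drop = FALSE]
  # orient counter-clockwise in a right-handed frame (x = col, y = -row)
  r <- v[, 1]; c <- v[, 2]
  signed <- sum(c * c(-r[-1], -r[1]) - c(c[-1], c[1]) * (-r)) / 2
  if (signed < 0) v <- v[rev(seq_len(nrow(v))), , drop = FALSE]
  idx <- which(m, arr.ind = TRUE)
  cup_contour(v, centroid = c(mean(idx[, 1]), mean(idx[, 2])))
}

# Farthest intersection distance of the ray origin + t*dir (t > 0) with a
# closed polygon; NA when the ray misses.
ray_polygon_distance <- function(origin, dir, vertices) {
  a <- vertices
  b <- vertices[c(2:nrow(vertices), 1), , drop = FALSE]
  e1 <- b[, 1] - a[, 1]; e2 <- b[, 2] - a[, 2]
  w1 <- a[, 1] - origin[1]; w2 <- a[, 2] - origin[2]
  den <- dir[1] * e2 - dir[2] * e1
  ok <- abs(den) > 1e-12
  t <- (w1 * e2 - w2 * e1) / den
  s <- (w1 * dir[2] - w2 * dir[1]) / den
  hit <- ok & t >= 0 & s >= -1e-9 & s <= 1 + 1e-9
  if (!any(hit)) return(NA_real_)
  max(t[hit])
}

#' Mean radial boundary distance between two contours
#'
#' Casts `n_angles` rays from the centroid of the reference contour `c_e`
#' at equally spaced angles; along each ray the distance to the farthest
#' intersection with each contour is measured and the mean absolute
#' difference of the two radii is returned (pixels).
#'
#' @param c_e reference contour (the expert curve); rays originate at its
#'   centroid.
#' @param c_m contour under evaluation.
#' @param n_angles number of rays (default 360, i.e. 1 degree sampling).
#' @return Mean absolute radial difference in pixels.
#' @export
boundary_distance <- function(c_e, c_m, n_angles = 360L) {
  if (!inherits(c_e, "cup_contour") || !inherits(c_m, "cup_contour"))
    stop("both arguments must be cup_contour objects")
  if (n_angles < 1L) stop("`n_angles` must be >= 1")
  o <- c_e$centroid
  th <- 2 * pi * (seq_len(n_angles) - 1L) / n_angles
  d <- vapply(seq_len(n_angles), function(k) {
    dir <- c(sin(th[k]), cos(th[k]))   # (row, col) direction
    de <- ray_polygon_distance(o, dir, c_e$vertices)
    dm <- ray_polygon_distance(o, dir, c_m$vertices)
    if (is.na(de) || is.na(dm))
      stop(sprintf("ray at angle %.1f deg misses a contour",
                   th[k] * 180 / pi))
    abs(de - dm)
  }, numeric(1))
  mean(d)
}

#' Vertical cup-to-disc ratio
#'
#' Ratio of the vertical pixel extents (inclusive row span,
#' `max row - min row + 1`) of the cup and disc masks; the masks are
#' measured independently, containment is not required.
#'
#' @param cup cup [binary_mask()] (or logical matrix), nonempty.
#' @param disc disc mask, nonempty.
#' @return The scalar ratio.
#' @export
vertical_cdr <- function(cup, disc) {
  a <- as_mask_matrix(cup)
  b <- as_mask_matrix(disc)
  if (!any(a) || !any(b)) stop("cup and disc masks must be nonempty")
  ra <- range(which(rowSums(a) > 0))
  rb <- range(which(rowSums(b) > 0))
  (ra[2] - ra[1] + 1) / (rb[2] - rb[1] + 1)
}

#' Full evaluation report for a predicted cup mask
#'
#' @param pred predicted cup mask.
#' @param truth ground-truth cup mask.
#' @param disc optional disc mask; when given, the vertical CDR of the
#'   prediction against the disc is reported.
#' @param n_angles rays for the boundary distance.
#' @return An object of class `metrics_report` with fields `precision`,
#'   `recall`, `f_score`, `distance_px` (`NA` when a radial comparison is
#'   geometrically impossible, e.g. the prediction does not surround the
#'   reference centroid), `cdr` (or `NA`), `n_angles`.
#' @export
evaluate_masks <- function(pred, truth, disc = NULL, n_angles = 360L) {
  cc <- confusion(pred, truth)
  d <- tryCatch(
    boundary_distance(mask_to_contour(truth), mask_to_contour(pred),
                      n_angles),
    error = function(e) NA_real_)
  cdr <- if (is.null(disc)) NA_real_ else vertical_cdr(pred, disc)
  structure(list(precision = precision_score(cc), recall = recall_score(cc),
                 f_score = f_score(cc), distance_px = d, cdr = cdr,
                 n_angles = as.integer(n_angles)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "<metrics_report: P=%.4f R=%.4f F=%.4f D=%.2f px CDR=%s>\n",
    x$precision, x$recall, x$f_score, x$distance_px,
    ifelse(is.na(x$cdr), "-", sprintf("%.4f", x$cdr))))
  invisible(x)
}
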