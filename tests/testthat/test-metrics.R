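circle_contour <- function(center, radius, n = 720) {
  th <- 2 * pi * (0:(n - 1)) / n
  cup_contour(cbind(center[1] + radius * sin(th),
                    center[2] + radius * cos(th)))
}

test_that("confusion counts are exact set arithmetic", {
  a <- matrix(FALSE, 10, 10); a[2:5, 2:11 - 1] <- TRUE   # 40 px
  expect_equal(confusion(a, a), list(tp = 40L, fp = 0L, fn = 0L))
  b <- matrix(FALSE, 10, 10); b[8:9, 1:10] <- TRUE       # 20 px disjoint
  d <- matrix(FALSE, 10, 10); d[2:3, 2:6] <- TRUE        # 10 px disjoint
  expect_equal(confusion(d, b), list(tp = 0L, fp = 10L, fn = 20L))
  sup <- a; sup[6, 2:6] <- TRUE                          # truth + 5 px
  expect_equal(confusion(sup, a), list(tp = 40L, fp = 5L, fn = 0L))
  expect_error(confusion(a, matrix(FALSE, 9, 10)), "shapes")
})

test_that("F-score is the harmonic mean with the stated edge rules", {
  expect_equal(f_score(list(tp = 40, fp = 0, fn = 0)), 1.0)
  expect_equal(f_score(list(tp = 0, fp = 7, fn = 3)), 0.0)
  expect_equal(f_score(list(tp = 2, fp = 1, fn = 1)), 2 / 3)
  expect_error(f_score(list(tp = 0, fp = 0, fn = 0)), "empty")
  # symmetry under swapping prediction and truth (fp <-> fn)
  set.seed(2)
  for (rep in 1:20) {
    cc <- list(tp = sample(0:50, 1), fp = sample(0:50, 1),
               fn = sample(0:50, 1))
    if (cc$tp + cc$fp + cc$fn == 0) next
    expect_equal(f_score(cc), f_score(list(tp = cc$tp, fp = cc$fn,
                                           fn = cc$fp)))
  }
  # F(A, A) = 1 for any nonempty mask
  m <- matrix(runif(64) < 0.3, 8, 8); m[1, 1] <- TRUE
  expect_equal(f_score(confusion(m, m)), 1.0)
})

test_that("a single pixel traces to the 0.5-level diamond", {
  m <- matrix(FALSE, 7, 7); m[4, 3] <- TRUE
  ct <- mask_to_contour(m)
  v <- ct$vertices
  expect_equal(nrow(v), 4L)
  expect_setequal(apply(v, 1, paste, collapse = ","),
                  c("3.5,3", "4,2.5", "4.5,3", "4,3.5"))
  expect_equal(unname(ct$centroid), c(4, 3))
})

test_that("rectangles and discs trace to enclosing contours", {
  m <- matrix(FALSE, 20, 30); m[5:12, 7:19] <- TRUE
  ct <- mask_to_contour(m)
  v <- ct$vertices
  expect_equal(range(v[, 1]), c(4.5, 12.5))
  expect_equal(range(v[, 2]), c(6.5, 19.5))
  expect_equal(unname(ct$centroid), c(8.5, 13))
  # counter-clockwise in (x = col, y = -row): positive signed area
  x <- v[, 2]; y <- -v[, 1]
  area <- sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y) / 2
  expect_gt(area, 0)
  # centered disc: centroid within 0.5 px of the center
  r <- matrix(1:41, 41, 41); cc <- t(r)
  dm <- sqrt((r - 21)^2 + (cc - 21)^2) <= 12
  expect_equal(unname(mask_to_contour(dm)$centroid), c(21, 21),
               tolerance = 0.5)
  expect_error(mask_to_contour(matrix(FALSE, 4, 4)), "empty")
  two <- matrix(FALSE, 9, 9); two[2, 2] <- TRUE; two[8, 8] <- TRUE
  expect_error(mask_to_contour(two), "2 components")
})

test_that("boundary distance reproduces analytic radial differences", {
  c10 <- circle_contour(c(50, 50), 10)
  c12 <- circle_contour(c(50, 50), 12)
  expect_equal(boundary_distance(c10, c10, 360), 0)
  expect_equal(boundary_distance(c10, c12, 360), 2.0, tolerance = 0.1)
  # identity on polygon-identical inputs is exactly zero
  expect_identical(boundary_distance(c12, c12, 97), 0)
  # morphing c_m toward c_e along rays decreases the distance weakly
  d <- vapply(c(0, 0.5, 1), function(t)
    boundary_distance(c12, circle_contour(c(50, 50), 10 + 2 * t), 180),
    numeric(1))
  expect_true(all(diff(d) <= 1e-9))
  # a ray that misses reports the angle
  off <- circle_contour(c(200, 200), 2)
  expect_error(boundary_distance(c10, off, 8), "angle")
})

test_that("vertical CDR uses inclusive row extents", {
  cup <- matrix(FALSE, 120, 50); cup[30:69, 10:30] <- TRUE
  disc <- matrix(FALSE, 120, 50); disc[10:109, 5:45] <- TRUE
  expect_equal(vertical_cdr(cup, disc), 0.4)
  expect_equal(vertical_cdr(disc, disc), 1.0)
  # horizontal translation changes nothing
  cup2 <- matrix(FALSE, 120, 50); cup2[30:69, 25:45] <- TRUE
  expect_equal(vertical_cdr(cup2, disc), 0.4)
  # doubling both heights leaves the ratio unchanged
  cup3 <- matrix(FALSE, 240, 50); cup3[30:109, 10:30] <- TRUE
  disc3 <- matrix(FALSE, 240, 50); disc3[10:209, 5:45] <- TRUE
  expect_equal(vertical_cdr(cup3, disc3), 80 / 200)
  expect_error(vertical_cdr(matrix(FALSE, 5, 5), disc), "nonempty")
})

test_that("evaluate_masks assembles a coherent report", {
  r <- matrix(1:41, 41, 41); cc <- t(r)
  truth <- sqrt((r - 21)^2 + (cc - 21)^2) <= 12
  pred <- sqrt((r - 21)^2 + (cc - 21)^2) <= 10
  disc <- sqrt((r - 21)^2 + (cc - 21)^2) <= 18
  rep <- evaluate_masks(pred, truth, disc = disc)
  expect_s3_class(rep, "metrics_report")
  expect_equal(rep$precision, 1.0)
  expect_lt(rep$recall, 1.0)
  expect_equal(rep$f_score,
               2 * rep$precision * rep$recall / (rep$precision + rep$recall))
  expect_equal(rep$distance_px, 2.0, tolerance = 0.25)
  expect_equal(rep$cdr, vertical_cdr(pred, disc))
  expect_true(is.na(evaluate_masks(pred, truth)$cdr))
})
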