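two_phase <- function(H = 96, r0 = 20, lev = c(50, 200), center = c(48, 48)) {
  r <- matrix(seq_len(H), H, H)
  cc <- matrix(seq_len(H), H, H, byrow = TRUE)
  disc <- sqrt((r - center[1])^2 + (cc - center[2])^2) <= r0
  I <- matrix(lev[1], H, H)
  I[disc] <- lev[2]
  list(I = I, disc = disc)
}

test_that("seed selection finds the bright region centroid", {
  I <- matrix(10, 100, 100)
  I[46:55, 46:55] <- 200
  s <- select_seed(I)
  expect_equal(unname(s), c(50.5, 50.5), tolerance = 0.5)
  # two blobs: the larger one wins
  I2 <- matrix(10, 100, 100)
  I2[20:29, 20:29] <- 200          # 100 px
  I2[60:79, 60:79] <- 200          # 400 px
  s2 <- select_seed(I2)
  expect_true(s2[1] > 55 && s2[2] > 55)
  expect_error(select_seed(matrix(5, 10, 10)), "constant")
  # phantom: seed within 5 px of the cup center
  ph <- make_phantom(small_spec(seed = 1))
  s3 <- select_seed(extract_green(ph$image)$pixels)
  expect_lt(sqrt(sum((s3 - c(96, 96))^2)), 5)
})

test_that("the initial field is a signed distance to the seed circle", {
  phi <- init_phi(c(20, 30), 10, c(50, 60))
  expect_equal(phi[20, 30], 10)
  expect_equal(phi[20, 40], 0, tolerance = 1e-12)  # on the circle
  expect_lt(phi[45, 55], 0)
  expect_error(init_phi(c(60, 30), 10, c(50, 60)), "outside")
  expect_error(init_phi(c(20, 30), -1, c(50, 60)), "positive")
})

test_that("the energy matches a direct per-pixel summation oracle", {
  set.seed(31)
  for (rep in 1:4) {
    I <- matrix(runif(144, 0, 255), 12, 12)
    phi <- matrix(runif(144, -8, 8), 12, 12)
    p <- lcv_params(alpha = 0.1, mu = 0.1 * 255^2, local_window = 5)
    expect_equal(lcv_energy(I, phi, p),
                 o_lcv_energy(I, phi, 0.1, 0.1 * 255^2, 5),
                 tolerance = 1e-9)
  }
  # perfect two-level partition: zero energy when alpha = mu = 0
  tp <- two_phase(24, 6, center = c(12, 12))
  phi <- init_phi(c(12, 12), 6, c(24, 24))
  phi_exact <- ifelse(tp$disc, 1e12, -1e12)  # effectively sharp partition
  expect_equal(lcv_energy(tp$I, phi_exact, lcv_params(alpha = 0, mu = 0)),
               0, tolerance = 1e-4)
  # with mu > 0 only the length term survives on that partition
  e <- lcv_energy(tp$I, phi_exact, lcv_params(alpha = 0))
  expect_gt(e, 0)
})

test_that("evolution recovers a clean two-phase disc", {
  tp <- two_phase()
  phi <- init_phi(c(48, 48), 14, c(96, 96))
  seg <- evolve(tp$I, phi, lcv_params(iters = 300))
  expect_gte(jaccard(seg$cup_mask$pixels, tp$disc), 0.95)
  expect_identical(seg$cup_mask$role, "cup")
  # single filled component containing the seed
  expect_equal(max(cupseg:::cpp_label8(seg$cup_mask$pixels)), 1L)
  expect_true(seg$cup_mask$pixels[48, 48])
  # contour encloses the seed: some vertices on every side
  v <- seg$contour$vertices
  expect_true(min(v[, 1]) < 48 && max(v[, 1]) > 48)
  expect_true(min(v[, 2]) < 48 && max(v[, 2]) > 48)
})

test_that("energy is non-increasing within reinitialization blocks", {
  tp <- two_phase()
  phi <- init_phi(c(48, 48), 14, c(96, 96))
  p <- lcv_params(iters = 300, reinit_every = 50)
  seg <- evolve(tp$I, phi, p)
  e <- seg$energy_trace
  tol <- 1e-6 * e[1]
  for (b in split(seq_along(e), (seq_along(e) - 1) %/% p$reinit_every))
    expect_true(all(diff(e[b]) <= tol))
})

test_that("with alpha 0 the local window has no effect (global CV)", {
  tp <- two_phase()
  phi <- init_phi(c(48, 48), 14, c(96, 96))
  s1 <- evolve(tp$I, phi, lcv_params(alpha = 0, local_window = 9,
                                     iters = 300))
  s2 <- evolve(tp$I, phi, lcv_params(alpha = 0, local_window = 21,
                                     iters = 300))
  expect_gte(jaccard(s1$cup_mask$pixels, s2$cup_mask$pixels), 0.99)
})

test_that("the contour-length weight shrinks perimeters monotonically", {
  tp <- two_phase()
  phi <- init_phi(c(48, 48), 14, c(96, 96))
  for (sd_i in 1:3) {
    set.seed(sd_i)
    In <- tp$I + matrix(rnorm(96 * 96, 0, 10), 96, 96)
    per <- vapply(c(0.01, 0.1, 1) * 255^2, function(mu) {
      contour_perimeter(evolve(In, phi, lcv_params(mu = mu,
                                                   iters = 400))$contour)
    }, numeric(1))
    expect_true(all(diff(per) <= 1e-9))
  }
})

test_that("reinitialization restores a unit-gradient field near the front", {
  tp <- two_phase()
  phi0 <- init_phi(c(48, 48), 14, c(96, 96))
  seg <- evolve(tp$I, phi0, lcv_params(iters = 100))
  phi <- cupseg:::redistance(seg$cup_mask$pixels)
  nr <- nrow(phi)
  rp <- c(2:nr, nr); rm <- c(1, 1:(nr - 1))
  gmag <- sqrt((0.5 * (phi[, rp] - phi[, rm]))^2 +
               (0.5 * (phi[rp, ] - phi[rm, ]))^2)
  near <- abs(phi) <= 5 & abs(phi) >= 1
  expect_gt(mean(abs(gmag[near] - 1) <= 0.2), 0.9)
})

test_that("collapse to an empty region raises a helpful error", {
  I <- matrix(200, 60, 60)
  I[30, 30] <- 201  # barely non-constant
  phi <- init_phi(c(10, 10), 3, c(60, 60))
  expect_error(evolve(I, phi, lcv_params(iters = 200)), "seed radius")
})

test_that("the disc domain restricts statistics and the mask", {
  tp <- two_phase(lev = c(140, 210))
  # surround the working area by dark background that would otherwise
  # shift the outside mean
  I <- matrix(60, 96, 96)
  dom <- sqrt(outer(1:96, rep(1, 96), function(a, b) (a - 48)^2) +
              t(outer(1:96, rep(1, 96), function(a, b) (a - 48)^2))) <= 40
  I[dom] <- tp$I[dom]
  phi <- init_phi(c(48, 48), 14, c(96, 96))
  seg <- evolve(I, phi, lcv_params(iters = 400), domain = dom)
  expect_gte(jaccard(seg$cup_mask$pixels, tp$disc & dom), 0.95)
  expect_true(all(!seg$cup_mask$pixels[!dom]))
})
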