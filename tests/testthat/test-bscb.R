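mask_of <- function(m, role = "vessel") binary_mask(m, role)

test_that("state initialization builds a normalized band smoothing", {
  u <- matrix(100, 40, 40)
  om <- matrix(FALSE, 40, 40); om[18:22, 18:22] <- TRUE
  bd <- matrix(FALSE, 40, 40); bd[12:28, 12:28] <- TRUE
  st <- init_state(u, mask_of(om), mask_of(bd, "inpaint_band"))
  expect_equal(st$g[20, 20], 1, tolerance = 1e-6)   # deep inside the band
  expect_true(all(st$g[!bd] == 0))                  # exactly 0 outside
  expect_true(all(st$g >= 0 & st$g <= 1))
  expect_identical(st$u, u)
  expect_equal(st$n, 0L)
  expect_error(init_state(u, mask_of(bd), mask_of(om, "inpaint_band")),
               "subset")
})

test_that("propagation information matches the hand oracle", {
  # constant -> zero
  st <- list(u = matrix(5, 8, 8))
  expect_true(all(cupseg:::cpp_propagation_info(st$u, TRUE, FALSE) == 0))
  # u = i^2 varies along rows only: sum mode gives 2 in the interior
  u <- outer((1:9)^2, rep(1, 9))
  L <- cupseg:::cpp_propagation_info(u, TRUE, FALSE)
  expect_true(all(abs(L[3:7, 3:7] - 2) < 1e-12))
  Lp <- cupseg:::cpp_propagation_info(u, TRUE, TRUE)
  expect_true(all(abs(Lp[3:7, 3:7]) < 1e-12))  # product with u_xx = 0
  # random grid vs exhaustive oracle, both modes, both propagation variants
  set.seed(21)
  v <- matrix(runif(49, 0, 255), 7, 7)
  for (nb in c(TRUE, FALSE)) for (pr in c(TRUE, FALSE))
    expect_equal(cupseg:::cpp_propagation_info(v, nb, pr),
                 o_propagation(v, nb, pr), tolerance = 1e-12)
})

test_that("isophote direction is unit, perpendicular to the gradient", {
  om <- matrix(FALSE, 10, 10)
  bd <- om
  ramp_r <- outer(1:10, rep(1, 10)) * 3        # varies with row only
  st <- init_state(ramp_r, mask_of(om), mask_of(bd, "inpaint_band"))
  Tf <- isophote_direction(st)
  expect_true(all(abs(Tf[2:9, 2:9, 1]) < 1e-12))       # row component 0
  expect_true(all(abs(abs(Tf[2:9, 2:9, 2]) - 1) < 1e-12))
  # constant -> zero vectors
  stc <- init_state(matrix(7, 6, 6), mask_of(matrix(FALSE, 6, 6)),
                    mask_of(matrix(FALSE, 6, 6), "inpaint_band"))
  expect_true(all(isophote_direction(stc) == 0))
  # u = c(i + j): unit vectors along +/- (1, -1)/sqrt(2)
  uij <- outer(1:10, 1:10, `+`) * 2
  std <- init_state(uij, mask_of(om), mask_of(bd, "inpaint_band"))
  Td <- isophote_direction(std)
  expect_true(all(abs(abs(Td[3:8, 3:8, 1]) - 1 / sqrt(2)) < 1e-12))
  expect_true(all(abs(Td[3:8, 3:8, 1] + Td[3:8, 3:8, 2]) < 1e-12))
})

test_that("single transport and diffusion steps match per-pixel oracles", {
  set.seed(5)
  u <- matrix(runif(100, 0, 255), 10, 10)
  om <- matrix(FALSE, 10, 10); om[cbind(c(4, 6, 7), c(5, 3, 8))] <- TRUE
  bd <- cupseg:::cpp_dilate_disc(om, 1)
  p <- bscb_params()
  st <- init_state(u, mask_of(om), mask_of(bd, "inpaint_band"), p)
  st1 <- inpaint_step(st, p)
  L <- o_propagation(u, TRUE, FALSE)
  for (k in which(om)) {
    i <- (k - 1) %% 10 + 1; j <- (k - 1) %/% 10 + 1
    expect_equal(st1$u[i, j], u[i, j] + o_transport_update(u, L, i, j, p$dt),
                 tolerance = 1e-12)
  }
  expect_identical(st1$u[!om], u[!om])     # untouched outside omega
  expect_equal(st1$n, 1L)
  std <- diffuse_step(st, p)
  for (k in which(bd)) {
    i <- (k - 1) %% 10 + 1; j <- (k - 1) %/% 10 + 1
    expect_equal(std$u[i, j],
                 u[i, j] + o_diffuse_update(u, st$g, i, j, p$dt),
                 tolerance = 1e-10)
  }
  expect_identical(std$u[!bd], u[!bd])
})

test_that("steps leave constants and straight ramps fixed", {
  om <- matrix(FALSE, 12, 12); om[5:7, 5:7] <- TRUE
  bd <- cupseg:::cpp_dilate_disc(om, 2)
  p <- bscb_params()
  # constant: both updates vanish
  stc <- init_state(matrix(50, 12, 12), mask_of(om),
                    mask_of(bd, "inpaint_band"), p)
  expect_identical(inpaint_step(stc, p)$u, stc$u)
  expect_identical(diffuse_step(stc, p)$u, stc$u)
  # empty omega: transport is the identity
  ste <- init_state(matrix(runif(144), 12, 12),
                    mask_of(matrix(FALSE, 12, 12)),
                    mask_of(matrix(FALSE, 12, 12), "inpaint_band"), p)
  expect_identical(inpaint_step(ste, p)$u, ste$u)
  # linear ramp: straight isophotes, curvature 0, diffusion ~ 0
  ramp <- outer(1:12, rep(1, 12)) * 7
  str <- init_state(ramp, mask_of(om), mask_of(bd, "inpaint_band"), p)
  expect_equal(diffuse_step(str, p)$u, ramp, tolerance = 1e-9)
})

test_that("inpainting is local, preserves constants, and fills holes", {
  # empty omega identity (bit-exact)
  set.seed(13)
  u <- matrix(runif(400, 0, 255), 20, 20)
  none <- matrix(FALSE, 20, 20)
  out <- inpaint(u, mask_of(none), mask_of(none, "inpaint_band"))
  expect_identical(out$pixels, u)
  # constant fixed point
  k <- matrix(42, 20, 20)
  om <- none; om[9:11, 9:11] <- TRUE
  bd <- cupseg:::cpp_dilate_disc(om, 2)
  expect_identical(inpaint(k, mask_of(om), mask_of(bd, "inpaint_band"))$pixels,
                   k)
  # locality: output equals input outside the band, bit-exact
  filled <- inpaint(u, mask_of(om), mask_of(bd, "inpaint_band"),
                    bscb_params(total_iters = 200))
  expect_identical(filled$pixels[!bd], u[!bd])
  # hole in a constant recovers the constant within 1 intensity unit
  h <- matrix(100, 32, 32); h[15:17, 15:17] <- 0
  omh <- matrix(FALSE, 32, 32); omh[15:17, 15:17] <- TRUE
  bdh <- cupseg:::cpp_dilate_disc(omh, 2)
  rec <- inpaint(h, mask_of(omh), mask_of(bdh, "inpaint_band"),
                 bscb_params(total_iters = 100000))
  expect_true(attr(rec, "converged"))
  expect_true(max(abs(rec$pixels[omh] - 100)) < 1.0)
  expect_identical(rec$stage, "inpainted")
})

test_that("a ramp hole is restored close to the harmonic fill", {
  H <- 32
  ramp <- outer(seq(0, 124, 4), rep(1, H))
  u <- ramp; u[16, 16] <- 0
  om <- matrix(FALSE, H, H); om[16, 16] <- TRUE
  bd <- cupseg:::cpp_dilate_disc(om, 2)
  rec <- inpaint(u, mask_of(om), mask_of(bd, "inpaint_band"),
                 bscb_params(total_iters = 30000))
  lap <- o_laplace_fill(u, om)
  expect_lt(abs(rec$pixels[16, 16] - lap[16, 16]), 2.0)
})

test_that("phantom inpainting stays bounded and honors the residual rule", {
  ph <- make_phantom(small_spec(seed = 2))
  g <- extract_green(ph$image)
  enh <- enhance(g)
  vp <- vessel_params(tau = "auto")
  vm <- clean_vessel_mask(binarize_vessels(
    difference_image(enh, median_image(enh, vp)), vp), vp)
  bd <- inpaint_band(vm, vp)
  p <- bscb_params(total_iters = 600)
  out <- inpaint(enh, vm, bd, p)
  expect_true(max(out$pixels) <= max(enh$pixels) + 5)
  expect_true(min(out$pixels) >= min(enh$pixels) - 5)
  if (isTRUE(attr(out, "converged")))
    expect_lt(attr(out, "residual"), p$stop_tol)
})

test_that("numerical blow-up raises an informative error", {
  set.seed(10)
  u <- matrix(runif(225, 0, 255), 15, 15)
  om <- matrix(TRUE, 15, 15)
  expect_error(
    inpaint(u, mask_of(om), mask_of(om, "inpaint_band"),
            bscb_params(dt = 2e4, total_iters = 400)),
    "dt")
})
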