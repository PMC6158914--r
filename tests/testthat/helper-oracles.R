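# Brute-force oracles, written independently of the package's C++ paths:
# plain R loops over pixels, no shared helpers.

# symmetric border reflection (edge pixel duplicated), as documented
o_refl <- function(i, n) {
  while (i < 1 || i > n) {
    if (i < 1) i <- 1 - i else i <- 2 * n + 1 - i
  }
  i
}

# grayscale erosion/dilation with a flat square SE given by offsets o0:o1
# (erosion: min over p + o; dilation: max over p - o), window clipped at the
# frame
o_erode <- function(x, o0, o1) {
  H <- nrow(x); W <- ncol(x)
  out <- x
  for (i in 1:H) for (j in 1:W) {
    ii <- pmax(1, pmin(H, i + (o0:o1)))
    jj <- pmax(1, pmin(W, j + (o0:o1)))
    out[i, j] <- min(x[unique(ii), unique(jj)])
  }
  out
}

o_dilate <- function(x, o0, o1) {
  H <- nrow(x); W <- ncol(x)
  out <- x
  for (i in 1:H) for (j in 1:W) {
    ii <- pmax(1, pmin(H, i - (o0:o1)))
    jj <- pmax(1, pmin(W, j - (o0:o1)))
    out[i, j] <- max(x[unique(ii), unique(jj)])
  }
  out
}

o_offsets <- function(k) {
  o0 <- -((k - 1) %/% 2)
  c(o0, k - 1 + o0)
}

o_top_hat <- function(x, k) {
  o <- o_offsets(k)
  x - o_dilate(o_erode(x, o[1], o[2]), o[1], o[2])
}

o_bottom_hat <- function(x, k) {
  o <- o_offsets(k)
  o_erode(o_dilate(x, o[1], o[2]), o[1], o[2]) - x
}

# windowed median by explicit sort-and-pick, reflected borders
o_median <- function(x, k) {
  H <- nrow(x); W <- ncol(x); r <- (k - 1) / 2
  out <- x
  for (i in 1:H) for (j in 1:W) {
    v <- numeric(0)
    for (di in -r:r) for (dj in -r:r)
      v <- c(v, x[o_refl(i + di, H), o_refl(j + dj, W)])
    out[i, j] <- sort(v)[(k * k + 1) / 2]
  }
  out
}

# propagation information: per-pixel second differences, 3x3 means, sum or
# product
o_propagation <- function(u, nbhd_mean = TRUE, product = FALSE) {
  H <- nrow(u); W <- ncol(u)
  uxx <- u; uyy <- u
  for (i in 1:H) for (j in 1:W) {
    uxx[i, j] <- u[i, o_refl(j - 1, W)] - 2 * u[i, j] + u[i, o_refl(j + 1, W)]
    uyy[i, j] <- u[o_refl(i - 1, H), j] - 2 * u[i, j] + u[o_refl(i + 1, H), j]
  }
  if (nbhd_mean) {
    mxx <- uxx; myy <- uyy
    for (i in 1:H) for (j in 1:W) {
      sxx <- 0; syy <- 0
      for (di in -1:1) for (dj in -1:1) {
        sxx <- sxx + uxx[o_refl(i + di, H), o_refl(j + dj, W)]
        syy <- syy + uyy[o_refl(i + di, H), o_refl(j + dj, W)]
      }
      mxx[i, j] <- sxx / 9; myy[i, j] <- syy / 9
    }
    uxx <- mxx; uyy <- myy
  }
  if (product) uxx * uyy else uxx + uyy
}

# transport update at one pixel: beta = grad(L).T with unit T, times the
# slope-limited upwind gradient norm, times dt/255
o_transport_update <- function(u, L, i, j, dt) {
  H <- nrow(u); W <- ncol(u)
  Lx <- 0.5 * (L[i, o_refl(j + 1, W)] - L[i, o_refl(j - 1, W)])
  Ly <- 0.5 * (L[o_refl(i + 1, H), j] - L[o_refl(i - 1, H), j])
  ux <- 0.5 * (u[i, o_refl(j + 1, W)] - u[i, o_refl(j - 1, W)])
  uy <- 0.5 * (u[o_refl(i + 1, H), j] - u[o_refl(i - 1, H), j])
  m <- sqrt(ux^2 + uy^2)
  if (m < 1e-8) return(0)
  beta <- Lx * (-uy / m) + Ly * (ux / m)
  uxb <- u[i, j] - u[i, o_refl(j - 1, W)]
  uxf <- u[i, o_refl(j + 1, W)] - u[i, j]
  uyb <- u[i, j] - u[o_refl(i - 1, H), j]
  uyf <- u[o_refl(i + 1, H), j] - u[i, j]
  sl <- if (beta > 0)
    sqrt(min(uxb, 0)^2 + max(uxf, 0)^2 + min(uyb, 0)^2 + max(uyf, 0)^2)
  else
    sqrt(max(uxb, 0)^2 + min(uxf, 0)^2 + max(uyb, 0)^2 + min(uyf, 0)^2)
  (dt / 255) * beta * sl
}

# curvature-diffusion update at one pixel
o_diffuse_update <- function(u, g, i, j, dt) {
  H <- nrow(u); W <- ncol(u)
  nfield <- function(a, b) {
    ux <- 0.5 * (u[a, o_refl(b + 1, W)] - u[a, o_refl(b - 1, W)])
    uy <- 0.5 * (u[o_refl(a + 1, H), b] - u[o_refl(a - 1, H), b])
    m <- sqrt(ux^2 + uy^2)
    c(ux / (m + 1e-8), uy / (m + 1e-8), m)
  }
  kappa <- 0.5 * (nfield(i, o_refl(j + 1, W))[1] -
                  nfield(i, o_refl(j - 1, W))[1]) +
           0.5 * (nfield(o_refl(i + 1, H), j)[2] -
                  nfield(o_refl(i - 1, H), j)[2])
  dt * g[i, j] * kappa * nfield(i, j)[3]
}

# LCV energy by direct per-pixel summation
o_lcv_energy <- function(I, phi, alpha, mu, win) {
  H <- nrow(I); W <- ncol(I); eps <- 1.5
  r <- (win - 1) / 2
  Id <- I
  for (i in 1:H) for (j in 1:W) {
    s <- 0
    for (di in -r:r) for (dj in -r:r)
      s <- s + I[o_refl(i + di, H), o_refl(j + dj, W)]
    Id[i, j] <- s / win^2 - I[i, j]
  }
  Hv <- 0.5 * (1 + (2 / pi) * atan(phi / eps))
  c1 <- sum(I * Hv) / sum(Hv)
  c2 <- sum(I * (1 - Hv)) / sum(1 - Hv)
  d1 <- sum(Id * Hv) / sum(Hv)
  d2 <- sum(Id * (1 - Hv)) / sum(1 - Hv)
  en <- 0
  for (i in 1:H) for (j in 1:W) {
    px <- 0.5 * (phi[i, o_refl(j + 1, W)] - phi[i, o_refl(j - 1, W)])
    py <- 0.5 * (phi[o_refl(i + 1, H), j] - phi[o_refl(i - 1, H), j])
    dl <- (1 / pi) * eps / (eps^2 + phi[i, j]^2)
    en <- en + mu * dl * sqrt(px^2 + py^2) +
      Hv[i, j] * (I[i, j] - c1)^2 + (1 - Hv[i, j]) * (I[i, j] - c2)^2 +
      alpha * (Hv[i, j] * (Id[i, j] - d1)^2 +
               (1 - Hv[i, j]) * (Id[i, j] - d2)^2)
  }
  en
}

# Dirichlet solve of Laplace's equation on the hole pixels (Gauss-Seidel)
o_laplace_fill <- function(u, hole, iters = 5000) {
  H <- nrow(u); W <- ncol(u)
  idx <- which(hole, arr.ind = TRUE)
  for (it in 1:iters) {
    delta <- 0
    for (k in seq_len(nrow(idx))) {
      i <- idx[k, 1]; j <- idx[k, 2]
      v <- mean(c(u[o_refl(i - 1, H), j], u[o_refl(i + 1, H), j],
                  u[i, o_refl(j - 1, W)], u[i, o_refl(j + 1, W)]))
      delta <- max(delta, abs(v - u[i, j]))
      u[i, j] <- v
    }
    if (delta < 1e-10) break
  }
  u
}

jaccard <- function(a, b) {
  a <- if (inherits(a, "binary_mask")) a$pixels else a
  b <- if (inherits(b, "binary_mask")) b$pixels else b
  sum(a & b) / sum(a | b)
}

contour_perimeter <- function(ct) {
  v <- ct$vertices
  sum(sqrt(rowSums((v - v[c(2:nrow(v), 1), , drop = FALSE])^2)))
}

# small, quick phantom for module-level tests
small_spec <- function(...) {
  args <- list(height = 192L, width = 192L, disc_center = c(96, 96),
               disc_axes = c(52, 56), cup_axes = c(26, 28),
               rim_softness = 4, n_vessels = 3L)
  user <- list(...)
  args[names(user)] <- user
  do.call(phantom_spec, args)
}
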