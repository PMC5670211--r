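test_that("binary initialization places -rho inside, 0 on the rim, +rho outside", {
  inside <- matrix(FALSE, 12, 12)
  inside[4:8, 5:9] <- TRUE
  fld <- init_binary(inside)
  phi <- fld$phi
  expect_identical(fld$iteration, 0L)
  expect_true(all(phi[!inside] == 1))
  # rim = inside pixels 4-adjacent to outside
  expect_true(all(phi[4, 5:9] == 0))
  expect_true(all(phi[8, 5:9] == 0))
  expect_true(all(phi[4:8, 5] == 0))
  expect_true(all(phi[4:8, 9] == 0))
  expect_true(all(phi[5:7, 6:8] == -1))
  expect_equal(sort(unique(as.vector(phi))), c(-1, 0, 1))
})

test_that("binary initialization scales with rho and handles thin regions", {
  inside <- matrix(FALSE, 9, 9)
  inside[5, 5] <- TRUE
  phi <- init_binary(inside, rho = 2.5)$phi
  # a single pixel is all rim: no strictly interior value
  expect_identical(sort(unique(as.vector(phi))), c(0, 2.5))
  expect_error(init_binary(matrix(FALSE, 5, 5)), "empty")
  expect_error(init_binary(matrix(TRUE, 5, 5)), "full|frame")
  expect_error(init_binary(inside, rho = 0), "positive")
})

test_that("regularized heaviside hits its exact anchor values", {
  expect_equal(heaviside_eps(0), 0.5)
  expect_equal(heaviside_eps(1, 1), 0.75)
  expect_equal(heaviside_eps(-1, 1), 0.25)
  expect_equal(heaviside_eps(3, 3), 0.75)   # scales with epsilon
  expect_equal(heaviside_eps(1e12), 1, tolerance = 1e-9)
  expect_equal(heaviside_eps(-1e12), 0, tolerance = 1e-9)
})

test_that("heaviside is monotone with algebraic (non-Gaussian) tails", {
  x <- seq(-50, 50, by = 0.25)
  h <- heaviside_eps(x)
  expect_true(all(diff(h) > 0))
  # heavy tails: still measurably above 0 far from the interface
  expect_gt(heaviside_eps(-50), 1e-3)
})

test_that("dirac is the derivative of the heaviside and integrates to one", {
  x <- seq(-7, 7, by = 0.37)
  h <- 1e-6
  fd <- (heaviside_eps(x + h) - heaviside_eps(x - h)) / (2 * h)
  expect_equal(fd, dirac_eps(x), tolerance = 1e-7)
  expect_equal(dirac_eps(0, 2), 1 / (2 * pi))
  # trapezoid quadrature of the full integral
  y <- seq(-2000, 2000, by = 0.05)
  d <- dirac_eps(y)
  expect_equal(sum((d[-1] + d[-length(y)]) / 2) * 0.05, 1, tolerance = 1e-3)
  expect_equal(dirac_eps(y), dirac_eps(-y))   # even symmetry
})

test_that("curvature of a planar field vanishes including at the border", {
  rr <- matrix(seq_len(20), 20, 20)
  plane <- 0.7 * rr - 1.3 * t(rr) + 4
  expect_lt(max(abs(curvature(plane))), 1e-8)
})

test_that("curvature of a circle SDF approximates one over the radius", {
  phi <- circle_sdf(101, c(51, 51), 20)
  k <- curvature(phi)
  band <- abs(phi) < 0.5
  expect_gt(sum(band), 50)
  expect_lt(max(abs(k[band] - 1 / 20)), 0.05 / 20)
  # concentric level circles: curvature 1/(20 + c) on the band phi ~ c
  # (looser tolerance: discretization error grows as the radius shrinks)
  for (c0 in c(-5, 5)) {
    ring <- abs(phi - c0) < 0.5
    expect_lt(max(abs(k[ring] - 1 / (20 + c0))), 0.1 / (20 + c0))
  }
})

test_that("distance regularization vanishes on planes of any slope", {
  rr <- matrix(seq_len(24), 24, 24)
  for (s in c(1, 2, 0.5)) {
    plane <- s * (rr - 12.5)
    expect_lt(max(abs(dist_reg(plane))), 1e-8)
  }
  tilted <- 0.6 * rr + 0.8 * t(rr)   # unit-gradient diagonal plane
  expect_lt(max(abs(dist_reg(tilted))), 1e-8)
})

test_that("distance regularization acts only near the binary interface", {
  inside <- matrix(FALSE, 30, 30)
  inside[10:20, 10:20] <- TRUE
  phi <- init_binary(inside)$phi
  r <- dist_reg(phi)
  far <- matrix(TRUE, 30, 30)
  far[8:22, 8:22] <- FALSE   # 2 px margin around the seed
  expect_equal(max(abs(r[far])), 0)
  expect_gt(max(abs(r[!far])), 0.1)
})

test_that("a planar SDF is a fixed point of the pure regularization flow", {
  rr <- matrix(seq_len(16), 16, 16)
  fld <- dogcontour:::.new_field(rr - 8.5)
  p <- evolution_params(nu = 0, mu = 0, alpha = 1)
  zero_edge <- matrix(0, 16, 16)
  out <- evolve_step(fld, zero_edge, p)
  expect_equal(out$phi, fld$phi, tolerance = 1e-12)
  expect_identical(out$iteration, 1L)
})

test_that("one evolution step matches the per-pixel scalar oracle", {
  phi0 <- random_smooth_field(16, seed = 21)
  img <- withr::with_seed(22, matrix(stats::runif(256, 0, 255), 16, 16))
  G <- dog_indicator(img, 1, 2)
  p <- evolution_params()
  out <- evolve_step(dogcontour:::.new_field(phi0), G, p)
  ref <- oracle_evolve_pixel(phi0, unclass(G), p$mu, p$nu, p$alpha,
                             p$epsilon, p$tau)
  expect_equal(out$phi, ref, tolerance = 1e-10)
})

test_that("the update is proportional to the time step", {
  phi0 <- random_smooth_field(12, seed = 31)
  G <- matrix(withr::with_seed(32, stats::rnorm(144)), 12, 12)
  fld <- dogcontour:::.new_field(phi0)
  d1 <- evolve_step(fld, G, evolution_params(tau = 0.05))$phi - phi0
  d2 <- evolve_step(fld, G, evolution_params(tau = 0.1))$phi - phi0
  expect_equal(d2, 2 * d1, tolerance = 1e-12)
})

test_that("evolution is equivariant under image translation", {
  img <- matrix(50, 64, 64)
  img[20:36, 24:40] <- 200
  shift <- function(m, dr, dc) {
    out <- matrix(m[1, 1], nrow(m), ncol(m))
    out[(1 + dr):nrow(m), (1 + dc):ncol(m)] <-
      m[1:(nrow(m) - dr), 1:(ncol(m) - dc)]
    out
  }
  p <- evolution_params(max_iters = 40L, stop_tol = 0)
  r1 <- segment(img, region_rect(22, 26, 34, 38), p)
  r2 <- segment(shift(img, 3, 5), region_rect(25, 31, 37, 43), p)
  # the recovered region (the zero level set) translates exactly; the field
  # itself only approximately, since the frame boundary does not translate
  m1 <- shift(r1$mask, 3, 5)
  inner <- 8:60
  expect_identical(m1[inner, inner], r2$mask[inner, inner])
  deep <- 20:48   # away from the frame, where boundary effects cannot reach
  expect_lt(max(abs(shift(r1$final_phi$phi, 3, 5)[deep, deep] -
                    r2$final_phi$phi[deep, deep])), 0.1)
})

test_that("five hundred steps on an 8-bit phantom stay finite and bounded", {
  ph <- make_object_phantom("disk", size = c(64, 64),
                            shape_args = list(radius = 18))
  res <- segment(ph$image, region_rect(20, 20, 44, 44),
                 evolution_params(max_iters = 500L, stop_tol = 0))
  expect_true(all(is.finite(res$final_phi$phi)))
  expect_lt(max(abs(res$final_phi$phi)), 1e4)
})

test_that("a blow-up is reported with the stability relation named", {
  phi0 <- 100 * random_smooth_field(16, seed = 41)
  G <- matrix(0, 16, 16)
  p <- suppressWarnings(evolution_params(tau = 2, alpha = 10, nu = 0, mu = 0,
                                         allow_unstable = TRUE))
  fld <- dogcontour:::.new_field(phi0)
  expect_error(
    for (i in 1:200) fld <- evolve_step(fld, G, p),
    "tau \\* alpha"
  )
})

test_that("stability guideline violations warn at construction", {
  expect_warning(evolution_params(tau = 0.3, alpha = 1), "0.2")
  expect_silent(evolution_params(tau = 0.3, alpha = 1, allow_unstable = TRUE))
  expect_silent(evolution_params())
})

test_that("the noisy preset swaps scales and regularization but yields to explicit arguments", {
  p <- evolution_params(preset = "noisy")
  expect_equal(c(p$sigma1, p$sigma2, p$mu), c(2, 10, 0.01 * 255^2))
  expect_equal(c(p$nu, p$alpha, p$epsilon, p$tau), c(-40, 1, 1, 0.1))
  q <- evolution_params(sigma2 = 6, preset = "noisy")
  expect_equal(c(q$sigma1, q$sigma2, q$mu), c(2, 6, 0.01 * 255^2))
})

test_that("parameter validation rejects out-of-domain values", {
  expect_error(evolution_params(mu = -1), "mu")
  expect_error(evolution_params(tau = 0), "tau")
  expect_error(evolution_params(epsilon = -2), "epsilon")
  expect_error(evolution_params(sigma1 = 3, sigma2 = 2), "strictly smaller")
  expect_error(evolution_params(rho = -1), "rho")
  expect_error(evolution_params(stop_window = 0), "stop_window")
})

test_that("sdf deviation is zero for an SDF, one for a doubled SDF", {
  rr <- matrix(seq_len(30), 30, 30)
  plane <- rr - 15.5
  expect_equal(sdf_deviation(plane), 0, tolerance = 1e-12)
  expect_equal(sdf_deviation(2 * plane, band = 4), 1, tolerance = 1e-12)
  expect_error(sdf_deviation(plane + 100), "band")
  expect_error(sdf_deviation(plane, band = -1), "positive")
})
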