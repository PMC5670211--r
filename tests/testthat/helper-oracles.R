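# Independent brute-force oracles used to pin down expected values.
# These deliberately share no code with the package internals: padding is
# materialized explicitly, convolution is summed per pixel, differential
# operators are evaluated with scalar arithmetic.

# truncated, mass-normalized 1D Gaussian taps at offsets -r..r
oracle_kernel <- function(sigma) {
  r <- ceiling(4 * sigma)
  w <- exp(-(-r:r)^2 / (2 * sigma^2))
  w / sum(w)
}

# pad a matrix by r on every side with linear extrapolation from the edges
oracle_pad_extrap <- function(img, r) {
  n <- nrow(img); m <- ncol(img)
  out <- matrix(NA_real_, n + 2 * r, m + 2 * r)
  out[r + (1:n), r + (1:m)] <- img
  for (d in 1:r) {
    out[r + 1 - d, r + (1:m)] <- (1 + d) * img[1, ] - d * img[2, ]
    out[r + n + d, r + (1:m)] <- (1 + d) * img[n, ] - d * img[n - 1, ]
  }
  for (d in 1:r) {
    out[, r + 1 - d] <- (1 + d) * out[, r + 1] - d * out[, r + 2]
    out[, r + m + d] <- (1 + d) * out[, r + m] - d * out[, r + m - 1]
  }
  out
}

# dense 2D convolution with the separable truncated kernel, summed per pixel
oracle_conv_dense <- function(img, sigma) {
  k <- oracle_kernel(sigma)
  r <- (length(k) - 1) / 2
  k2 <- outer(k, k)
  pad <- oracle_pad_extrap(img, r)
  out <- matrix(0, nrow(img), ncol(img))
  for (i in seq_len(nrow(img))) {
    for (j in seq_len(ncol(img))) {
      out[i, j] <- sum(k2 * pad[i:(i + 2 * r), j:(j + 2 * r)])
    }
  }
  out
}

# circular (periodic-boundary) convolution, for the zero-sum identity
oracle_conv_circular <- function(img, sigma) {
  k <- oracle_kernel(sigma)
  r <- (length(k) - 1) / 2
  n <- nrow(img); m <- ncol(img)
  out <- matrix(0, n, m)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      acc <- 0
      for (a in -r:r) {
        for (b in -r:r) {
          acc <- acc + k[a + r + 1] * k[b + r + 1] *
            img[(i - 1 + a) %% n + 1, (j - 1 + b) %% m + 1]
        }
      }
      out[i, j] <- acc
    }
  }
  out
}

# scalar per-pixel evaluation of one explicit step of the gradient flow:
# phi <- phi + tau*[(nu*G + mu*kappa)*delta_eps(phi) + alpha*(lap - kappa)]
# with central differences and linear-extrapolation ghosts, written with
# an explicit value lookup instead of vectorized shifts
oracle_evolve_pixel <- function(phi, G, mu, nu, alpha, epsilon, tau,
                                eta = 1e-10) {
  n <- nrow(phi); m <- ncol(phi)
  at <- function(M, i, j) {
    if (i < 1) return(2 * at(M, 1, j) - at(M, 2, j))
    if (i > n) return(2 * at(M, n, j) - at(M, n - 1, j))
    if (j < 1) return(2 * at(M, i, 1) - at(M, i, 2))
    if (j > m) return(2 * at(M, i, m) - at(M, i, m - 1))
    M[i, j]
  }
  nx <- matrix(0, n, m); ny <- matrix(0, n, m)
  for (i in 1:n) {
    for (j in 1:m) {
      gx <- (at(phi, i + 1, j) - at(phi, i - 1, j)) / 2
      gy <- (at(phi, i, j + 1) - at(phi, i, j - 1)) / 2
      mag <- sqrt(gx^2 + gy^2 + eta)
      nx[i, j] <- gx / mag
      ny[i, j] <- gy / mag
    }
  }
  out <- matrix(0, n, m)
  for (i in 1:n) {
    for (j in 1:m) {
      kappa <- (at(nx, i + 1, j) - at(nx, i - 1, j)) / 2 +
        (at(ny, i, j + 1) - at(ny, i, j - 1)) / 2
      lap <- at(phi, i + 1, j) + at(phi, i - 1, j) +
        at(phi, i, j + 1) + at(phi, i, j - 1) - 4 * phi[i, j]
      delta <- epsilon / (pi * (phi[i, j]^2 + epsilon^2))
      out[i, j] <- phi[i, j] + tau *
        ((nu * G[i, j] + mu * kappa) * delta + alpha * (lap - kappa))
    }
  }
  out
}

# O(n^2) double-loop Hausdorff distance between two (row, col) point sets
oracle_hausdorff <- function(A, B) {
  directed <- function(P, Q) {
    worst <- 0
    for (i in seq_len(nrow(P))) {
      best <- Inf
      for (j in seq_len(nrow(Q))) {
        d <- sqrt((P[i, 1] - Q[j, 1])^2 + (P[i, 2] - Q[j, 2])^2)
        if (d < best) best <- d
      }
      if (best > worst) worst <- best
    }
    worst
  }
  max(directed(A, B), directed(B, A))
}

# signed distance to a circle, pixel centers at integer coordinates
circle_sdf <- function(n, center, radius) {
  rr <- matrix(seq_len(n), n, n)
  cc <- t(rr)
  sqrt((rr - center[1])^2 + (cc - center[2])^2) - radius
}

# smooth random field for operator tests (sum of a few sinusoids)
random_smooth_field <- function(n, seed) {
  withr::with_seed(seed, {
    a <- stats::runif(3, -2, 2)
    f <- stats::runif(3, 0.05, 0.3)
    p <- stats::runif(3, 0, 2 * pi)
    rr <- matrix(seq_len(n), n, n)
    cc <- t(rr)
    a[1] * sin(f[1] * rr + p[1]) + a[2] * cos(f[2] * cc + p[2]) +
      a[3] * sin(f[3] * (rr + cc) + p[3])
  })
}

random_mask <- function(n, seed, p = 0.3) {
  withr::with_seed(seed, matrix(stats::runif(n * n) < p, n, n))
}
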