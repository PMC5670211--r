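# Numerical core of the level-set evolution.
#
# All spatial derivatives of the level-set field use central differences
# (spatial step h = 1 pixel) with linear-extrapolation ghost cells at the
# frame border, i.e. one-sided differences on the boundary rows/columns.
# This choice makes planar fields exact fixed points of the
# distance-regularization operator everywhere, including the border, which
# replicate padding does not achieve (it bends level lines at the frame).

# Neighbor shifts with linear-extrapolation ghosts: ghost = 2*edge - next.
.sh_up <- function(m) {
  r <- nrow(m)
  out <- m[c(2:r, r), , drop = FALSE]
  out[r, ] <- 2 * m[r, ] - m[r - 1L, ]
  out
}
.sh_down <- function(m) {
  out <- m[c(1L, 1:(nrow(m) - 1L)), , drop = FALSE]
  out[1L, ] <- 2 * m[1L, ] - m[2L, ]
  out
}
.sh_left <- function(m) {
  k <- ncol(m)
  out <- m[, c(2:k, k), drop = FALSE]
  out[, k] <- 2 * m[, k] - m[, k - 1L]
  out
}
.sh_right <- function(m) {
  out <- m[, c(1L, 1:(ncol(m) - 1L)), drop = FALSE]
  out[, 1L] <- 2 * m[, 1L] - m[, 2L]
  out
}

# central-difference gradient, d/d(row) and d/d(col)
.grad <- function(m) {
  list(
    x = (.sh_up(m) - .sh_down(m)) / 2,
    y = (.sh_left(m) - .sh_right(m)) / 2
  )
}
.div <- function(fx, fy) {
  (.sh_up(fx) - .sh_down(fx)) / 2 + (.sh_left(fy) - .sh_right(fy)) / 2
}
.lap <- function(m) {
  .sh_up(m) + .sh_down(m) + .sh_left(m) + .sh_right(m) - 4 * m
}

# stabilizer inside sqrt for |grad phi|: the binary initialization has flat
# plateaus where the gradient is exactly zero and Eq. of motion divides by it
.GRAD_EPS <- 1e-10

#' Evolution parameters
#'
#' Bundles and validates every tunable of the curve evolution. The defaults
#' are the parameter set used for clean images: `mu = 0.001 * 255^2`
#' (length/regularization weight), `nu = -40` (balloon weight; negative pulls
#' the interior onto positive DoG response, i.e. bright structures),
#' `alpha = 1` (distance-regularization weight), `epsilon = 1`
#' (Heaviside/Dirac width), `tau = 0.1` (time step), `sigma1 = 1`,
#' `sigma2 = 2` (DoG scales, pixels) and `rho = 1` (binary initialization
#' magnitude). The `"noisy"` preset switches to the wide-kernel,
#' strongly-regularized variant intended for noisy input:
#' `sigma1 = 2`, `sigma2 = 10`, `mu = 0.01 * 255^2`.
#'
#' The explicit scheme is only stable when the time step and the
#' distance-regularization weight satisfy `tau * alpha <= 0.2`; violating the
#' relation raises a warning (an error can be avoided with
#' `allow_unstable = TRUE` since the bound is a guideline, not a law).
#'
#' @param mu Non-negative length-regularization weight.
#' @param nu Balloon weight (any sign; negative targets bright interiors).
#' @param alpha Non-negative distance-regularization weight.
#' @param epsilon Positive width of the regularized Heaviside/Dirac pair.
#' @param tau Positive time step of the explicit Euler update.
#' @param sigma1,sigma2 Positive DoG standard deviations, `sigma1 < sigma2`.
#' @param rho Positive magnitude of the binary initialization.
#' @param max_iters Positive iteration budget.
#' @param stop_tol Non-negative convergence tolerance: largest allowed
#'   fraction of pixels changing phase per iteration.
#' @param stop_window Number of consecutive iterations that must satisfy
#'   `stop_tol` before the run is declared converged.
#' @param preset `"default"` or `"noisy"`. Explicitly supplied arguments
#'   always win over the preset.
#' @param allow_unstable Set `TRUE` to downgrade the `tau * alpha > 0.2`
#'   check from warning to silence.
#' @return An object of class `evolution_params`.
#' @examples
#' evolution_params()                 # clean-image defaults
#' evolution_params(preset = "noisy") # wide-kernel noisy preset
#' @export
evolution_params <- function(mu = 0.001 * 255^2, nu = -40, alpha = 1,
                             epsilon = 1, tau = 0.1,
                             sigma1 = 1, sigma2 = 2, rho = 1,
                             max_iters = 500L, stop_tol = 1e-4,
                             stop_window = 10L,
                             preset = c("default", "noisy"),
                             allow_unstable = FALSE) {
  preset <- match.arg(preset)
  if (preset == "noisy") {
    if (missing(sigma1)) sigma1 <- 2
    if (missing(sigma2)) sigma2 <- 10
    if (missing(mu)) mu <- 0.01 * 255^2
  }
  num1 <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
      stop(sprintf("`%s` must be a single finite number", nm), call. = FALSE)
    }
    as.numeric(x)
  }
  mu <- num1(mu, "mu"); nu <- num1(nu, "nu"); alpha <- num1(alpha, "alpha")
  epsilon <- num1(epsilon, "epsilon"); tau <- num1(tau, "tau")
  sigma1 <- num1(sigma1, "sigma1"); sigma2 <- num1(sigma2, "sigma2")
  rho <- num1(rho, "rho"); stop_tol <- num1(stop_tol, "stop_tol")
  if (mu < 0) stop("`mu` must be >= 0", call. = FALSE)
  if (alpha < 0) stop("`alpha` must be >= 0", call. = FALSE)
  if (epsilon <= 0) stop("`epsilon` must be > 0", call. = FALSE)
  if (tau <= 0) stop("`tau` must be > 0", call. = FALSE)
  if (sigma1 <= 0 || sigma2 <= 0) stop("`sigma1` and `sigma2` must be > 0", call. = FALSE)
  if (sigma1 >= sigma2) stop("`sigma1` must be strictly smaller than `sigma2`", call. = FALSE)
  if (rho <= 0) stop("`rho` must be > 0", call. = FALSE)
  if (stop_tol < 0) stop("`stop_tol` must be >= 0", call. = FALSE)
  max_iters <- as.integer(max_iters)
  stop_window <- as.integer(stop_window)
  if (is.na(max_iters) || max_iters < 0L) stop("`max_iters` must be a non-negative integer", call. = FALSE)
  if (is.na(stop_window) || stop_window < 1L) stop("`stop_window` must be a positive integer", call. = FALSE)
  if (tau * alpha > 0.2 && !isTRUE(allow_unstable)) {
    warning(sprintf(
      "tau * alpha = %.3g exceeds the stability guideline tau * alpha <= 0.2; the explicit scheme may blow up",
      tau * alpha
    ), call. = FALSE)
  }
  structure(
    list(
      mu = mu, nu = nu, alpha = alpha, epsilon = epsilon, tau = tau,
      sigma1 = sigma1, sigma2 = sigma2, rho = rho,
      max_iters = max_iters, stop_tol = stop_tol, stop_window = stop_window,
      preset = preset
    ),
    class = "evolution_params"
  )
}

#' @export
print.evolution_params <- function(x, ...) {
  cat("<evolution_params>\n")
  cat(sprintf("  mu = %g, nu = %g, alpha = %g, epsilon = %g, tau = %g\n",
              x$mu, x$nu, x$alpha, x$epsilon, x$tau))
  cat(sprintf("  sigma1 = %g, sigma2 = %g, rho = %g\n", x$sigma1, x$sigma2, x$rho))
  cat(sprintf("  max_iters = %d, stop_tol = %g, stop_window = %d (preset: %s)\n",
              x$max_iters, x$stop_tol, x$stop_window, x$preset))
  invisible(x)
}

.new_field <- function(phi, iteration = 0L) {
  structure(list(phi = phi, iteration = as.integer(iteration)),
            class = "levelset_field")
}

.as_phi <- function(x) {
  if (inherits(x, "levelset_field")) x$phi else x
}

#' @export
print.levelset_field <- function(x, ...) {
  cat(sprintf(
    "<levelset_field> %d x %d, iteration %d, interior (phi < 0): %d px\n",
    nrow(x$phi), ncol(x$phi), x$iteration, sum(x$phi < 0)
  ))
  invisible(x)
}

#' Binary level-set initialization
#'
#' Initializes the level-set field as a three-valued step: `-rho` strictly
#' inside the seed region, `+rho` outside it, and `0` on the region boundary
#' (an inside pixel 4-adjacent to an outside pixel). No signed-distance
#' computation is involved: the distance-regularization term of the
#' evolution reshapes the field on the fly, so the field never needs to be
#' (re-)initialized as a signed distance function.
#'
#' @param inside Logical matrix marking the seed region (`TRUE` = inside).
#'   Must be neither empty nor the full frame.
#' @param rho Positive step magnitude (default 1).
#' @return A `levelset_field` with `phi` taking values in `{-rho, 0, rho}`
#'   and iteration counter 0. The sign convention is `phi < 0` inside.
#' @examples
#' inside <- matrix(FALSE, 10, 10); inside[4:7, 4:7] <- TRUE
#' fld <- init_binary(inside)
#' table(fld$phi)
#' @export
init_binary <- function(inside, rho = 1) {
  if (!is.matrix(inside) || !is.logical(inside)) {
    stop("`inside` must be a logical matrix", call. = FALSE)
  }
  if (any(is.na(inside))) stop("`inside` contains NA", call. = FALSE)
  if (!any(inside)) stop("seed region is empty: nothing to evolve", call. = FALSE)
  if (all(inside)) stop("seed region fills the frame: no interface to evolve", call. = FALSE)
  if (!is.numeric(rho) || length(rho) != 1L || !is.finite(rho) || rho <= 0) {
    stop("`rho` must be a single positive number", call. = FALSE)
  }
  # 4-neighbors clamped at the frame so frame-edge pixels look at themselves
  r <- nrow(inside); k <- ncol(inside)
  nb <- inside[c(2:r, r), ] & inside[c(1, 1:(r - 1)), ] &
    inside[, c(2:k, k)] & inside[, c(1, 1:(k - 1))]
  boundary <- inside & !nb
  phi <- matrix(rho, r, k)
  phi[inside] <- -rho
  phi[boundary] <- 0
  .new_field(phi)
}

#' Regularized Heaviside function
#'
#' The smooth step \eqn{H_\varepsilon(\phi) = 1/2 + \arctan(\phi/\varepsilon)/\pi},
#' mapping any real input into (0, 1). As `epsilon` shrinks it approaches
#' the ideal unit step. Its heavy (algebraic) tails are what make the
#' balloon force act over the whole frame rather than only in a narrow band
#' around the current contour — the property behind the method's
#' insensitivity to contour initialization.
#'
#' @param phi Numeric array of level-set values.
#' @param epsilon Positive width parameter.
#' @return Array of the same shape with values in (0, 1).
#' @seealso [dirac_eps()], its elementwise derivative.
#' @export
heaviside_eps <- function(phi, epsilon = 1) {
  if (!is.numeric(epsilon) || length(epsilon) != 1L || !is.finite(epsilon) || epsilon <= 0) {
    stop("`epsilon` must be a single positive number", call. = FALSE)
  }
  0.5 + atan(phi / epsilon) / pi
}

#' Regularized Dirac function
#'
#' The smooth impulse
#' \eqn{\delta_\varepsilon(\phi) = \varepsilon / (\pi (\phi^2 + \varepsilon^2))},
#' the exact derivative of [heaviside_eps()]. It peaks at `1/(pi*epsilon)` on
#' the zero level set and decays like \eqn{1/\phi^2}, so it never vanishes:
#' every pixel keeps feeling the edge and curvature terms, with a weight that
#' fades as the field moves away from zero.
#'
#' @inheritParams heaviside_eps
#' @return Non-negative array of the same shape; integrates to 1 over the
#'   real line.
#' @export
dirac_eps <- function(phi, epsilon = 1) {
  if (!is.numeric(epsilon) || length(epsilon) != 1L || !is.finite(epsilon) || epsilon <= 0) {
    stop("`epsilon` must be a single positive number", call. = FALSE)
  }
  epsilon / (pi * (phi^2 + epsilon^2))
}

#' Mean curvature of the level-set field
#'
#' Computes \eqn{\mathrm{div}(\nabla\phi / |\nabla\phi|)} with central
#' differences; the gradient magnitude is stabilized as
#' \eqn{\sqrt{|\nabla\phi|^2 + 10^{-10}}} because the binary initialization
#' has plateaus with exactly zero gradient. On a signed distance function of
#' a circle of radius r, the result approximates 1/r on the zero level set.
#'
#' @param phi A `levelset_field` or numeric matrix.
#' @return Numeric matrix of curvature values.
#' @export
curvature <- function(phi) {
  p <- .as_phi(phi)
  .check_image(p, "phi")
  g <- .grad(p)
  mag <- sqrt(g$x^2 + g$y^2 + .GRAD_EPS)
  .div(g$x / mag, g$y / mag)
}

#' Distance-regularization operator
#'
#' The term \eqn{\Delta\phi - \mathrm{div}(\nabla\phi/|\nabla\phi|)}, the
#' descent direction of the penalty \eqn{\frac12\int(|\nabla\phi|-1)^2}. It
#' vanishes on any plane (in particular on exact signed distance functions)
#' and elsewhere drives the field toward unit gradient magnitude, which is
#' what removes the need for periodic re-initialization. The Laplacian uses
#' the standard 5-point stencil, matching the central-difference order of
#' the rest of the scheme.
#'
#' @inheritParams curvature
#' @return Numeric matrix.
#' @export
dist_reg <- function(phi) {
  p <- .as_phi(phi)
  .check_image(p, "phi")
  .lap(p) - curvature(p)
}

#' One explicit evolution step
#'
#' Advances the level-set field by one explicit Euler step of the gradient
#' flow
#' \deqn{\phi \leftarrow \phi + \tau\,[(\nu\Gamma + \mu\,\kappa)\,
#'   \delta_\varepsilon(\phi) + \alpha\,(\Delta\phi - \kappa)],}
#' where \eqn{\Gamma} is the DoG edge response, \eqn{\kappa} the mean
#' curvature and \eqn{\delta_\varepsilon} the regularized Dirac. Note that
#' the Dirac factor applies only to the edge and curvature terms; the
#' distance regularization acts unweighted on the whole field. The input
#' field is not modified.
#'
#' @param field A `levelset_field`.
#' @param edge An `edge_map` (or numeric matrix) of the same shape.
#' @param params An [evolution_params()] object.
#' @return A new `levelset_field` with the iteration counter incremented.
#' @export
evolve_step <- function(field, edge, params = evolution_params()) {
  stopifnot(inherits(field, "levelset_field"), inherits(params, "evolution_params"))
  phi <- field$phi
  G <- .as_phi(edge)
  attributes(G) <- list(dim = dim(G))   # drop edge_map class and scale attrs
  if (!identical(dim(phi), dim(G))) {
    stop("`field` and `edge` must have the same dimensions", call. = FALSE)
  }
  g <- .grad(phi)
  mag <- sqrt(g$x^2 + g$y^2 + .GRAD_EPS)
  curv <- .div(g$x / mag, g$y / mag)
  delta <- dirac_eps(phi, params$epsilon)
  phi_new <- phi + params$tau * (
    (params$nu * G + params$mu * curv) * delta +
      params$alpha * (.lap(phi) - curv)
  )
  if (!all(is.finite(phi_new))) {
    stop(sprintf(
      paste0(
        "level-set evolution blew up at iteration %d (non-finite values); ",
        "check the stability relation tau * alpha <= 0.2 ",
        "(currently tau * alpha = %.3g)"
      ),
      field$iteration + 1L, params$tau * params$alpha
    ), call. = FALSE)
  }
  .new_field(phi_new, field$iteration + 1L)
}

#' Deviation of the field from a signed distance function
#'
#' Diagnostic for the distance-regularization term: the mean of
#' \eqn{||\nabla\phi| - 1|} over the band of pixels with \eqn{|\phi| <}
#' `band`. Zero for an exact signed distance function; 1 for a doubled one.
#'
#' @inheritParams curvature
#' @param band Positive half-width of the band around the zero level set.
#' @return A single non-negative number.
#' @export
sdf_deviation <- function(phi, band = 2) {
  p <- .as_phi(phi)
  .check_image(p, "phi")
  if (!is.numeric(band) || length(band) != 1L || !is.finite(band) || band <= 0) {
    stop("`band` must be a single positive number", call. = FALSE)
  }
  sel <- abs(p) < band
  if (!any(sel)) stop("no pixels with |phi| < band", call. = FALSE)
  g <- .grad(p)
  mag <- sqrt(g$x^2 + g$y^2)
  mean(abs(mag[sel] - 1))
}
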