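# Orchestration of a full segmentation run.
#
# The DoG response depends only on the image, so it is computed once before
# the loop; the per-iteration work is just the explicit update plus a cheap
# convergence record.

#' Initial-region specifications
#'
#' Helpers describing the seed region for [segment()]. Coordinates are
#' (row, col), 1-based, pixel centers at integer positions. An arbitrary
#' logical matrix can be passed to `segment()` directly instead.
#'
#' @param r0,c0,r1,c1 Inclusive corner coordinates of the rectangle.
#' @param row,col Center of the circle.
#' @param radius Circle radius in pixels.
#' @return A region-spec object understood by [segment()].
#' @examples
#' region_rect(30, 30, 60, 60)
#' region_circle(125, 125, 20)
#' @export
region_rect <- function(r0, c0, r1, c1) {
  structure(list(r0 = r0, c0 = c0, r1 = r1, c1 = c1), class = "region_rect")
}

#' @rdname region_rect
#' @export
region_circle <- function(row, col, radius) {
  structure(list(row = row, col = col, radius = radius), class = "region_circle")
}

.resolve_init <- function(init, dims) {
  if (is.matrix(init) && is.logical(init)) {
    if (!identical(dim(init), dims)) {
      stop("initial mask dimensions do not match the image", call. = FALSE)
    }
    return(init)
  }
  rr <- matrix(seq_len(dims[1]), dims[1], dims[2])
  cc <- matrix(seq_len(dims[2]), dims[1], dims[2], byrow = TRUE)
  if (inherits(init, "region_rect")) {
    with(init, rr >= r0 & rr <= r1 & cc >= c0 & cc <= c1)
  } else if (inherits(init, "region_circle")) {
    with(init, (rr - row)^2 + (cc - col)^2 <= radius^2)
  } else {
    stop("`init` must be a logical matrix, region_rect() or region_circle()",
         call. = FALSE)
  }
}

#' Segment an image by DoG-driven level-set evolution
#'
#' Runs the full pipeline: compute the DoG edge response once, initialize
#' the level-set field as a binary step over the seed region, iterate the
#' explicit evolution, and extract the interior mask (`phi < 0`). The run
#' stops early once the fraction of pixels changing phase per iteration has
#' stayed below `params$stop_tol` for `params$stop_window` consecutive
#' iterations; because the balloon force acts globally, the final mask is
#' largely independent of where the seed region is placed.
#'
#' @param img Numeric matrix on the 0-255 intensity scale.
#' @param init Seed region: logical matrix, [region_rect()] or
#'   [region_circle()]. Must be non-empty and not the full frame.
#' @param params An [evolution_params()] object.
#' @return An object of class `segmentation_result` with elements
#'   `final_phi` (`levelset_field`), `mask` (logical, `TRUE` = interior),
#'   `edge` (the `edge_map` used), `iterations_run`, `converged`,
#'   `empty_mask` flag, and `trace` — a data frame with one row per
#'   iteration: `iteration`, `interior_px` (current interior size),
#'   `changed_frac` (fraction of pixels that changed phase) and
#'   `sdf_dev` ([sdf_deviation()] in a band of 2, `NA` if the band is
#'   empty).
#' @examples
#' ph <- make_object_phantom("disk", size = c(64, 64),
#'                           shape_args = list(radius = 15))
#' res <- segment(ph$image, region_rect(5, 5, 15, 15),
#'                evolution_params(max_iters = 300L))
#' res$converged
#' @export
segment <- function(img, init, params = evolution_params()) {
  .check_image(img)
  stopifnot(inherits(params, "evolution_params"))
  inside <- .resolve_init(init, dim(img))
  if (!any(inside)) stop("initial region is empty", call. = FALSE)
  if (all(inside)) stop("initial region covers the full frame", call. = FALSE)

  edge <- dog_indicator(img, params$sigma1, params$sigma2)
  field <- init_binary(inside, params$rho)

  n_px <- length(img)
  iters <- params$max_iters
  tr_interior <- integer(iters)
  tr_changed <- numeric(iters)
  tr_sdf <- numeric(iters)
  mask_old <- field$phi < 0
  run <- 0L      # consecutive iterations satisfying the stability rule
  converged <- FALSE
  it <- 0L
  while (it < iters) {
    field <- evolve_step(field, edge, params)
    it <- it + 1L
    mask <- field$phi < 0
    changed <- sum(mask != mask_old) / n_px
    tr_interior[it] <- sum(mask)
    tr_changed[it] <- changed
    tr_sdf[it] <- if (any(abs(field$phi) < 2)) sdf_deviation(field, 2) else NA_real_
    mask_old <- mask
    run <- if (changed < params$stop_tol) run + 1L else 0L
    if (run >= params$stop_window) {
      converged <- TRUE
      break
    }
  }
  mask <- field$phi < 0
  trace <- data.frame(
    iteration = seq_len(it),
    interior_px = tr_interior[seq_len(it)],
    changed_frac = tr_changed[seq_len(it)],
    sdf_dev = tr_sdf[seq_len(it)]
  )
  structure(
    list(
      final_phi = field, mask = mask, edge = edge,
      iterations_run = it, converged = converged,
      empty_mask = !any(mask), trace = trace, params = params
    ),
    class = "segmentation_result"
  )
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf(
    "<segmentation_result> %d x %d, %d iterations (%s), interior %d px%s\n",
    nrow(x$mask), ncol(x$mask), x$iterations_run,
    if (x$converged) "converged" else "budget exhausted",
    sum(x$mask), if (x$empty_mask) " [EMPTY MASK]" else ""
  ))
  invisible(x)
}

#' Extract the zero level-set contour
#'
#' Traces the sub-pixel zero crossings of the level-set field with marching
#' squares (via [grDevices::contourLines()]). Coordinates are (row, col)
#' with pixel centers at integers.
#'
#' @param phi A `levelset_field`, `segmentation_result` or numeric matrix.
#' @return A list of data frames, one per contour, with columns `row` and
#'   `col`; an empty list if the field does not change sign.
#' @export
extract_contour <- function(phi) {
  if (inherits(phi, "segmentation_result")) phi <- phi$final_phi
  p <- .as_phi(phi)
  .check_image(p, "phi")
  if (all(p > 0) || all(p < 0)) return(list())
  cl <- grDevices::contourLines(
    x = seq_len(nrow(p)), y = seq_len(ncol(p)), z = p, levels = 0
  )
  lapply(cl, function(seg) data.frame(row = seg$x, col = seg$y))
}

#' Two-phase split of a segmentation within a region of interest
#'
#' Partitions the pixels of `roi` into the two phases of the level-set
#' field: `phase1` where `phi < 0` (interior) and `phase2` where
#' `phi >= 0`. Used e.g. to separate white matter from gray matter inside a
#' manually extracted brain mask; the ROI is an input, never computed here.
#'
#' @param result A `segmentation_result` (or `levelset_field`).
#' @param roi Logical matrix, same shape as the field, non-empty.
#' @return A list of two disjoint logical masks, `phase1` and `phase2`,
#'   whose union equals `roi` exactly.
#' @export
two_phase_split <- function(result, roi) {
  phi <- if (inherits(result, "segmentation_result")) {
    result$final_phi$phi
  } else {
    .as_phi(result)
  }
  if (!is.matrix(roi) || !is.logical(roi)) {
    stop("`roi` must be a logical matrix", call. = FALSE)
  }
  if (!identical(dim(roi), dim(phi))) {
    stop("`roi` dimensions do not match the field", call. = FALSE)
  }
  if (!any(roi)) stop("`roi` is empty", call. = FALSE)
  list(phase1 = (phi < 0) & roi, phase2 = (phi >= 0) & roi)
}
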