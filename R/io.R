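# Raster I/O and run configuration.
#
# Conventions used throughout: matrices indexed (row, col), 1-based, pixel
# centers at integer coordinates; intensities on the 0-255 scale; output
# masks encoded as 8-bit PNG with 255 = interior (phi < 0) and 0 = exterior.

.read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  tokens <- character(0)
  magic <- readChar(con, 2L, useBytes = TRUE)
  if (!magic %in% c("P2", "P5")) stop("not a PGM file: ", path, call. = FALSE)
  # header tokens (width, height, maxval), skipping comments
  while (length(tokens) < 3L) {
    ch <- readChar(con, 1L, useBytes = TRUE)
    if (length(ch) == 0L || ch == "") stop("truncated PGM header: ", path, call. = FALSE)
    if (ch == "#") {
      repeat {
        ch <- readChar(con, 1L, useBytes = TRUE)
        if (length(ch) == 0L || ch == "\n") break
      }
    } else if (grepl("[0-9]", ch)) {
      tok <- ch
      repeat {
        ch <- readChar(con, 1L, useBytes = TRUE)
        if (length(ch) == 0L || !grepl("[0-9]", ch)) break
        tok <- paste0(tok, ch)
      }
      tokens <- c(tokens, tok)
    }
  }
  dims <- as.integer(tokens[1:2])   # width, height
  maxval <- as.integer(tokens[3])
  npx <- dims[1] * dims[2]
  vals <- if (magic == "P5") {
    if (maxval < 256L) {
      as.integer(readBin(con, "raw", npx))
    } else {
      readBin(con, "integer", npx, size = 2L, signed = FALSE, endian = "big")
    }
  } else {
    scan(con, integer(), n = npx, quiet = TRUE)
  }
  if (length(vals) < npx) stop("truncated PGM data: ", path, call. = FALSE)
  # PGM stores row-major (top row first)
  img <- matrix(vals, nrow = dims[2], ncol = dims[1], byrow = TRUE)
  img * (255 / maxval)
}

#' Load a grayscale image
#'
#' Reads PNG, TIFF or PGM rasters into a numeric matrix on the 0-255
#' scale. Color input is converted to luminance with the Rec. 601 weights
#' `0.299 R + 0.587 G + 0.114 B`; an alpha channel is discarded; 16-bit
#' samples are rescaled to 0-255. Images smaller than 3 x 3 are rejected
#' (too small for the finite-difference stencils).
#'
#' @param path Path to a `.png`, `.tif(f)` or `.pgm` file.
#' @return Numeric matrix (rows = image rows), values in \[0, 255\].
#' @export
load_image <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path) * 255,
    tif = ,
    tiff = tiff::readTIFF(path) * 255,
    pgm = .read_pgm(path),
    stop("unsupported image format '.", ext, "' (use PNG, TIFF or PGM)",
         call. = FALSE)
  )
  img <- if (length(dim(arr)) == 3L) {
    if (dim(arr)[3] >= 3L) {
      0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3]
    } else {
      arr[, , 1]   # gray + alpha
    }
  } else {
    arr
  }
  if (nrow(img) < 3L || ncol(img) < 3L) {
    stop("image must be at least 3 x 3 pixels", call. = FALSE)
  }
  img
}

#' Save a grayscale image or a binary mask as 8-bit PNG
#'
#' `save_image()` writes intensities clipped to \[0, 255\]; `save_mask()`
#' encodes `TRUE` (interior) as 255 and `FALSE` as 0; `load_mask()` reads
#' such a file back, thresholding at 127.
#'
#' @param img Numeric matrix on the 0-255 scale.
#' @param mask Logical matrix.
#' @param path Output/input PNG path.
#' @return `path` invisibly (`load_mask()` returns the logical matrix).
#' @export
save_image <- function(img, path) {
  .check_image(img)
  png::writePNG(pmin(pmax(img, 0), 255) / 255, path)
  invisible(path)
}

#' @rdname save_image
#' @export
save_mask <- function(mask, path) {
  if (!is.matrix(mask) || !is.logical(mask)) {
    stop("`mask` must be a logical matrix", call. = FALSE)
  }
  png::writePNG(mask * 1, path)
  invisible(path)
}

#' @rdname save_image
#' @export
load_mask <- function(path) {
  load_image(path) > 127
}

.parse_init_spec <- function(spec) {
  if (is.null(spec)) return(NULL)
  if (inherits(spec, c("region_rect", "region_circle")) ||
      (is.matrix(spec) && is.logical(spec))) {
    return(spec)
  }
  if (!is.character(spec) || length(spec) != 1L) {
    stop("`init` must be a region spec, logical mask, or string like 'rect:r0,c0,r1,c1'",
         call. = FALSE)
  }
  parts <- strsplit(spec, ":", fixed = TRUE)[[1]]
  numbers <- function() {
    suppressWarnings(as.numeric(strsplit(parts[2] %||% "", ",")[[1]]))
  }
  switch(parts[1],
    rect = {
      nums <- numbers()
      if (length(nums) != 4L || any(is.na(nums))) {
        stop("rect init needs 4 numbers: rect:r0,c0,r1,c1", call. = FALSE)
      }
      region_rect(nums[1], nums[2], nums[3], nums[4])
    },
    circle = {
      nums <- numbers()
      if (length(nums) != 3L || any(is.na(nums))) {
        stop("circle init needs 3 numbers: circle:row,col,radius", call. = FALSE)
      }
      region_circle(nums[1], nums[2], nums[3])
    },
    mask = load_mask(parts[2]),
    stop("unknown init spec '", parts[1], "'", call. = FALSE)
  )
}

#' Assemble a run configuration
#'
#' Merges evolution parameters from three layers with increasing
#' precedence: package defaults (or the named `preset`), a YAML config
#' file, and explicit overrides (e.g. command-line flags). Recognized keys
#' are the [evolution_params()] arguments plus `preset`, `input`, `init`,
#' `out_mask`, `trace` and `contour`. Validation (including the
#' `sigma1 < sigma2` and `tau * alpha <= 0.2` checks) happens before any
#' computation.
#'
#' @param path Optional YAML file.
#' @param overrides Named list of highest-precedence values.
#' @param preset Optional preset name forwarded to [evolution_params()]
#'   (a `preset` key in the file or overrides wins over this argument).
#' @return A list with `params` (an `evolution_params`), `init` (parsed
#'   region spec or `NULL`) and any I/O paths (`input`, `out_mask`,
#'   `trace`, `contour`).
#' @export
load_config <- function(path = NULL, overrides = list(), preset = NULL) {
  file_cfg <- if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    yaml::read_yaml(path)
  } else {
    list()
  }
  stopifnot(is.list(file_cfg), is.list(overrides))
  cfg <- utils::modifyList(file_cfg, overrides[!vapply(overrides, is.null, TRUE)])
  if (!is.null(preset) && is.null(cfg$preset)) cfg$preset <- preset

  par_names <- setdiff(names(formals(evolution_params)), "preset")
  par_args <- cfg[intersect(names(cfg), par_names)]
  if (!is.null(cfg$preset)) par_args$preset <- cfg$preset
  params <- do.call(evolution_params, par_args)

  io_keys <- c("input", "out_mask", "trace", "contour")
  c(list(params = params, init = .parse_init_spec(cfg$init)),
    cfg[intersect(names(cfg), io_keys)])
}

#' Write a per-iteration trace as CSV
#'
#' @param result A `segmentation_result`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
save_trace <- function(result, path) {
  stopifnot(inherits(result, "segmentation_result"))
  utils::write.csv(result$trace, path, row.names = FALSE)
  invisible(path)
}
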