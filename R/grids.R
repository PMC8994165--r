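# Test-location grids: standard registry, custom generation, eye mirroring.
#
# All grids are stored in right-eye (OD) format: positive x is temporal,
# positive y is superior, coordinates in degrees of visual angle. Left-eye
# data are mirrored into this frame at import so a single normative model
# serves both eyes.

#' Construct a grid of visual-field test locations
#'
#' A grid is a named, ordered set of test locations in degrees of visual
#' angle, right-eye format. The location order is stable and defines the
#' column order of the field CSV schema (see [read_vf_csv()]).
#'
#' @param name grid identifier.
#' @param x,y numeric vectors of coordinates in degrees (|x|, |y| <= 90).
#' @param is_blind_spot logical vector flagging locations inside the
#'   physiological blind spot; these are skipped during testing and excluded
#'   from all statistics.
#' @param wave optional positive-integer growth-wave index per location.
#' @return an object of class `vf_grid`: a list with `name` and `locations`
#'   (a data frame with columns `x`, `y`, `is_blind_spot`, `wave`).
#' @examples
#' g <- vf_grid("tiny", x = c(-3, 3), y = c(3, 3))
#' nrow(g$locations)
#' @export
vf_grid <- function(name, x, y, is_blind_spot = FALSE, wave = NA_integer_) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop_perisim("x and y must have equal length")
  if (length(x) < 1L) stop_perisim("a grid needs at least one location", class = "grid_spec_error")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop_perisim("grid coordinates must be finite")
  if (any(abs(x) > 90) || any(abs(y) > 90))
    stop_perisim("grid coordinates must lie within +/-90 degrees")
  if (anyDuplicated(paste(x, y)))
    stop_perisim("duplicate grid coordinates", class = "grid_spec_error")
  loc <- data.frame(x = x, y = y,
                    is_blind_spot = rep_len(as.logical(is_blind_spot), length(x)),
                    wave = rep_len(as.integer(wave), length(x)))
  structure(list(name = as.character(name), locations = loc), class = "vf_grid")
}

#' @export
print.vf_grid <- function(x, ...) {
  nbs <- sum(x$locations$is_blind_spot)
  cat(sprintf("Visual field grid '%s': %d locations (%d blind-spot)\n",
              x$name, nrow(x$locations), nbs))
  cat(sprintf("  x range [%g, %g], y range [%g, %g] degrees (right-eye format)\n",
              min(x$locations$x), max(x$locations$x),
              min(x$locations$y), max(x$locations$y)))
  invisible(x)
}

# 24-2: rows at y = +/-3 carry nine points (nasal extension to -27 degrees);
# rows at y = +/-9, +/-15, +/-21 carry 8, 6 and 4 points. 54 in total, with
# the two temporal blind-spot locations at (15, +/-3).
grid_24_2 <- function() {
  rows <- list(
    `21`  = seq(-9, 9, by = 6),
    `15`  = seq(-15, 15, by = 6),
    `9`   = seq(-21, 21, by = 6),
    `3`   = seq(-27, 21, by = 6)
  )
  x <- c(); y <- c()
  for (ay in c(21, 15, 9, 3, -3, -9, -15, -21)) {
    xs <- rows[[as.character(abs(ay))]]
    x <- c(x, xs); y <- c(y, rep(ay, length(xs)))
  }
  bs <- x == 15 & abs(y) == 3
  vf_grid("24-2", x, y, is_blind_spot = bs)
}

grid_registry_env <- new.env(parent = emptyenv())

#' Registered standard grids
#'
#' @return character vector of registered grid names.
#' @export
registered_grids <- function() {
  c("24-2", ls(grid_registry_env))
}

#' Register a custom grid for CSV input/output
#'
#' Field CSV files name their grid; reading requires the grid to be
#' registered so that the sensitivity column count can be validated.
#'
#' @param grid a `vf_grid`.
#' @return the grid, invisibly.
#' @export
register_grid <- function(grid) {
  stopifnot(inherits(grid, "vf_grid"))
  assign(grid$name, grid, envir = grid_registry_env)
  invisible(grid)
}

#' Build a standard test-location grid
#'
#' The conventional 24-2 pattern (54 locations, 6-degree spacing, right-eye
#' format) is built in; its two blind-spot locations at (15, +/-3) are
#' flagged, leaving the 52 locations used for statistical analysis.
#'
#' @param name grid identifier; `"24-2"` is always available, plus any grid
#'   added with [register_grid()].
#' @return a `vf_grid`.
#' @examples
#' g <- build_standard_grid("24-2")
#' sum(!g$locations$is_blind_spot)  # 52 analyzed locations
#' @export
build_standard_grid <- function(name) {
  if (identical(name, "24-2")) return(grid_24_2())
  if (exists(name, envir = grid_registry_env, inherits = FALSE))
    return(get(name, envir = grid_registry_env, inherits = FALSE))
  stop_perisim("unknown grid '", name, "'; registered grids: ",
               paste(registered_grids(), collapse = ", "),
               class = "grid_registry_error")
}

#' Generate a custom grid from a specification
#'
#' Supports three modes. `cartesian`: a lattice from coordinate ranges and a
#' spacing. `polar`: all combinations of eccentricity rings and meridians.
#' `explicit`: a verbatim list of locations. Duplicate coordinates are
#' rejected in every mode.
#'
#' @param spec a list, e.g. `list(mode = "cartesian", x_range = c(-27, 27),
#'   y_range = c(-21, 21), spacing = 6)`, `list(mode = "polar",
#'   rings = c(10, 20), meridians = c(0, 90, 180, 270))`, or
#'   `list(mode = "explicit", points = list(c(x1, y1), ...))`. A `name`
#'   entry overrides the default `"custom"`.
#' @return a `vf_grid`.
#' @examples
#' generate_custom_grid(list(mode = "polar", rings = 10,
#'                           meridians = c(45, 135, 225, 315)))
#' @export
generate_custom_grid <- function(spec) {
  mode <- spec$mode %||% stop_perisim("grid spec needs a 'mode'", class = "grid_spec_error")
  name <- spec$name %||% "custom"
  if (mode == "cartesian") {
    sx <- spec$spacing_x %||% spec$spacing
    sy <- spec$spacing_y %||% spec$spacing
    if (is.null(sx) || is.null(sy)) stop_perisim("cartesian mode needs 'spacing'", class = "grid_spec_error")
    xs <- seq(spec$x_range[1], spec$x_range[2], by = sx)
    ys <- seq(spec$y_range[1], spec$y_range[2], by = sy)
    pts <- expand.grid(x = xs, y = ys)
  } else if (mode == "polar") {
    rings <- spec$rings; mer <- spec$meridians
    if (length(rings) < 1 || length(mer) < 1)
      stop_perisim("polar mode needs rings and meridians", class = "grid_spec_error")
    pg <- expand.grid(r = rings, theta = mer * pi / 180)
    pts <- data.frame(x = round(pg$r * cos(pg$theta), 10),
                      y = round(pg$r * sin(pg$theta), 10))
  } else if (mode == "explicit") {
    if (length(spec$points) < 1) stop_perisim("explicit mode needs points", class = "grid_spec_error")
    m <- do.call(rbind, lapply(spec$points, function(p) as.numeric(p[1:2])))
    pts <- data.frame(x = m[, 1], y = m[, 2])
  } else {
    stop_perisim("unknown grid mode '", mode, "'", class = "grid_spec_error")
  }
  if (nrow(pts) < 1) stop_perisim("grid spec yields no locations", class = "grid_spec_error")
  if (anyDuplicated(paste(pts$x, pts$y)))
    stop_perisim("grid spec yields duplicate coordinates", class = "grid_spec_error")
  bs <- spec$blind_spot %||% FALSE
  vf_grid(name, pts$x, pts$y, is_blind_spot = bs)
}

#' Mirror a grid or field table into right-eye format
#'
#' All analysis runs in right-eye (OD) coordinates. For OD input this is the
#' identity; for OS input every location's x coordinate is negated (for field
#' tables the sensitivity columns are re-matched to the mirrored location
#' order, so column `l1` still refers to the grid's first OD-format
#' location). Applying the OS mirror twice returns the input.
#'
#' @param obj a `vf_grid` or a `vf` field table (see [vf_table()]).
#' @param eye `"OD"` or `"OS"`.
#' @param grid for `vf` input, the grid the table's columns refer to.
#' @return an object of the same kind.
#' @export
mirror_to_right_eye <- function(obj, eye, grid = NULL) {
  eye <- match.arg(eye, c("OD", "OS"))
  if (eye == "OD") return(obj)
  if (inherits(obj, "vf_grid")) {
    out <- obj
    out$locations$x <- -out$locations$x
    return(out)
  }
  if (inherits(obj, "vf")) {
    if (is.null(grid)) stop_perisim("mirroring a field table requires its grid")
    # mirrored location i sits where location j had x = -x_i, y = y_i
    loc <- grid$locations
    key <- paste(loc$x, loc$y)
    mirrored_key <- paste(-loc$x, loc$y)
    idx <- match(mirrored_key, key)
    if (anyNA(idx))
      stop_perisim("grid is not mirror-symmetric; cannot re-match OS sensitivities")
    sens <- vf_sens_matrix(obj)
    sens <- sens[, idx, drop = FALSE]
    obj[, vf_sens_cols(obj)] <- sens
    return(obj)
  }
  stop_perisim("cannot mirror object of class ", paste(class(obj), collapse = "/"))
}
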