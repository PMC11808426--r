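#' Structured-grid two-phase flow snapshot
#'
#' Container for a cell-centered snapshot of a two-phase (volume of
#' fluid) flow on a uniform structured grid: velocity components,
#' liquid volume fraction and, optionally, the turbulence fields of an
#' eddy-viscosity model (turbulent kinetic energy `k` and specific
#' dissipation rate `omega`).
#'
#' @param x,y,z Cell-center coordinate vectors (m), uniformly spaced,
#'   strictly increasing.
#' @param u,v,w Velocity component arrays (m/s) with dim
#'   `c(length(x), length(y), length(z))`.
#' @param alpha Liquid volume fraction array in \[0, 1\] (1 = liquid).
#' @param k Optional turbulent kinetic energy array (m^2/s^2).
#' @param omega Optional specific dissipation rate array (1/s).
#' @param wall_radius Optional cylindrical wall radius (m) around
#'   `axis_center`, needed for contact-line extraction.
#' @param axis_center Optional x/y coordinates of the cylinder axis
#'   (m); defaults to the grid mid-point when `wall_radius` is given.
#' @return An object of class `field_grid`; cell spacings `dx`, `dy`,
#'   `dz` and the cell volume are precomputed.
#' @export
field_grid <- function(x, y, z, u, v, w, alpha, k = NULL, omega = NULL,
                       wall_radius = NULL, axis_center = NULL) {
  dims <- c(length(x), length(y), length(z))
  if (any(dims < 2L)) stop("each axis needs at least 2 cells", call. = FALSE)
  spacing <- function(coord, name) {
    d <- diff(coord)
    if (any(d <= 0)) stop("'", name, "' must be strictly increasing",
                          call. = FALSE)
    if (max(d) - min(d) > 1e-9 * max(d)) {
      stop("'", name, "' spacing is not uniform", call. = FALSE)
    }
    mean(d)
  }
  dx <- spacing(x, "x"); dy <- spacing(y, "y"); dz <- spacing(z, "z")
  for (nm in c("u", "v", "w", "alpha")) {
    arr <- get(nm)
    if (!is.array(arr) || !identical(dim(arr), as.integer(dims))) {
      stop("'", nm, "' must be an array of dim (nx, ny, nz) = (",
           paste(dims, collapse = ", "), ")", call. = FALSE)
    }
  }
  if (any(alpha < -1e-6) || any(alpha > 1 + 1e-6)) {
    stop("volume fraction 'alpha' outside [0, 1] beyond tolerance 1e-6",
         call. = FALSE)
  }
  alpha <- pmin(pmax(alpha, 0), 1)
  for (nm in c("k", "omega")) {
    arr <- get(nm)
    if (!is.null(arr) && !identical(dim(arr), as.integer(dims))) {
      stop("'", nm, "' must match the grid dimensions", call. = FALSE)
    }
  }
  if (!is.null(wall_radius)) {
    .check_positive(wall_radius, "wall_radius")
    if (is.null(axis_center)) axis_center <- c(mean(range(x)), mean(range(y)))
  }
  structure(list(x = x, y = y, z = z, u = u, v = v, w = w, alpha = alpha,
                 k = k, omega = omega,
                 dx = dx, dy = dy, dz = dz,
                 cell_volume = dx * dy * dz,
                 wall_radius = wall_radius, axis_center = axis_center),
            class = "field_grid")
}

#' @export
print.field_grid <- function(x, ...) {
  cat(sprintf("field_grid: %d x %d x %d cells, spacing (%.3g, %.3g, %.3g) m\n",
              length(x$x), length(x$y), length(x$z), x$dx, x$dy, x$dz))
  cat(sprintf("  liquid volume: %.4g mL; turbulence fields: %s\n",
              liquid_volume(x) * 1e6,
              if (is.null(x$k)) "absent" else "present"))
  if (!is.null(x$wall_radius)) {
    cat(sprintf("  cylindrical wall: R = %.4g m about (%.4g, %.4g)\n",
                x$wall_radius, x$axis_center[1], x$axis_center[2]))
  }
  invisible(x)
}

#' Liquid volume of a snapshot
#'
#' Alpha-weighted cell-volume sum \eqn{\sum_i \alpha_i V_{cell}}.
#'
#' @param grid A [field_grid()].
#' @return Liquid volume in m^3.
#' @export
liquid_volume <- function(grid) {
  stopifnot(inherits(grid, "field_grid"))
  sum(grid$alpha) * grid$cell_volume
}

# Partial derivative of a cell array along one axis: second-order
# central differences in the interior, first-order one-sided at the
# two boundary layers.
.axis_gradient <- function(f, h, axis) {
  n <- dim(f)[axis]
  if (n < 3L) stop("need at least 3 cells along each axis for gradients",
                   call. = FALSE)
  # build f[, i, ] style slab indexing programmatically
  idx <- function(i) {
    do.call(`[`, c(list(f),
                   lapply(seq_along(dim(f)), function(a) {
                     if (a == axis) i else seq_len(dim(f)[a])
                   }),
                   list(drop = FALSE)))
  }
  out <- array(0, dim = dim(f))
  assign_slab <- function(i, value) {
    ind <- lapply(seq_along(dim(f)), function(a) {
      if (a == axis) i else seq_len(dim(f)[a])
    })
    out <- do.call(`[<-`, c(list(out), ind, list(value)))
    out
  }
  out <- assign_slab(2:(n - 1), (idx(3:n) - idx(1:(n - 2))) / (2 * h))
  out <- assign_slab(1L, (idx(2L) - idx(1L)) / h)
  out <- assign_slab(n, (idx(n) - idx(n - 1L)) / h)
  out
}
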