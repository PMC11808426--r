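#' Synthetic two-phase flow snapshots with closed-form references
#'
#' Generates [field_grid()] snapshots whose post-processing results are
#' known in closed form, so every snapshot operator can be validated
#' without a flow solver.  Five kinds are available:
#'
#' * `couette` — planar shear `u = gamma0 * z` in a fully liquid box;
#'   reference `S_norm = gamma0`, `lambda1 = gamma0/2` everywhere.
#' * `rigid_rotation` — solid-body rotation at rate `Omega` about the
#'   vertical axis; carries no strain (`S_norm = lambda1 = 0`).
#' * `slab_interface` — liquid below a horizontal diffuse interface at
#'   height `h0` with prescribed thickness; reference interfacial area
#'   equals the box cross-section.
#' * `droplet` — diffuse spherical droplet of radius `r`; reference
#'   area `4*pi*r^2`.
#' * `annulus` — a rotating liquid ring against a cylindrical wall
#'   with a thinner trailing wall film above it and a rigid-rotation
#'   velocity field, emulating the liquid distribution in an orbitally
#'   shaken flask; closed-form contact-line heights per offset.
#'
#' Diffuse interfaces use a clipped linear ramp of the prescribed
#' thickness: the integral of `|grad alpha|` across such a ramp
#' telescopes to the geometric area regardless of the profile.
#'
#' @param kind Snapshot kind, see above.
#' @param resolution Cells per axis (scalar or length 3), >= 16
#'   recommended for convergence studies.
#' @param box Box edge lengths (m, length 3) for box kinds; cylinder
#'   kinds derive the box from `R` and `H`.
#' @param gamma0 Couette shear rate (1/s).
#' @param Omega Rotation rate (rad/s) for `rigid_rotation` and
#'   `annulus`.
#' @param h0 Liquid (bulk) surface height (m) for `slab_interface` and
#'   `annulus`.
#' @param r Droplet radius (m).
#' @param interface_thickness Diffuse interface thickness (m); must
#'   cover at least 4 cell spacings; defaults to 4.5 spacings.
#' @param R Cylinder (wall) radius (m) for `annulus`.
#' @param H Domain height (m) for `annulus`.
#' @param film_thickness Wall-film radial thickness (m).
#' @param film_height Wall-film top height (m), >= `h0`.
#' @param liquid_volume Optional requested liquid volume (m^3) for
#'   `annulus`; the ring's inner radius is solved to honor it.
#' @param tilt Tilt angle (deg) of the bulk liquid surface about the
#'   axis (`annulus` only); the surface plane passes through the axis
#'   at height `h0`.
#' @param jitter Amplitude (m/s) of seeded uniform velocity noise
#'   added to the field (default 0, exact closed forms).
#' @param seed Integer seed for the jitter; same seed, same snapshot.
#' @return A list with `grid` (a [field_grid()]) and `reference`, a
#'   list of the closed-form values applicable to the kind (`S_norm`,
#'   `lambda1`, `area_total`, `liquid_volume`, `contact_height`
#'   function, ...).
#' @examples
#' syn <- synthetic_field("couette", gamma0 = 10, resolution = 16)
#' syn$reference$S_norm
#' @export
synthetic_field <- function(kind = c("couette", "rigid_rotation", "annulus",
                                     "droplet", "slab_interface"),
                            resolution = 32,
                            box = c(0.1, 0.1, 0.1),
                            gamma0 = 10,
                            Omega = 10,
                            h0 = NULL,
                            r = NULL,
                            interface_thickness = NULL,
                            R = 0.04065,
                            H = 0.06,
                            film_thickness = 0.001,
                            film_height = NULL,
                            liquid_volume = NULL,
                            tilt = 0,
                            jitter = 0,
                            seed = 1L) {
  kind <- match.arg(kind)
  res <- rep_len(as.integer(resolution), 3L)
  if (any(res < 4L)) stop("resolution must be at least 4 per axis",
                          call. = FALSE)
  if (kind == "annulus") box <- c(2.05 * R, 2.05 * R, H)
  dx <- box / res
  x <- (seq_len(res[1]) - 0.5) * dx[1]
  y <- (seq_len(res[2]) - 0.5) * dx[2]
  z <- (seq_len(res[3]) - 0.5) * dx[3]
  thick <- if (is.null(interface_thickness)) 4.5 * max(dx) else
    interface_thickness
  if (thick < 4 * max(dx)) {
    stop(sprintf(paste0("interface thickness %.3g m spans fewer than 4 ",
                        "cells (spacing %.3g m); refine the grid or ",
                        "thicken the interface"), thick, max(dx)),
         call. = FALSE)
  }
  ramp <- function(signed_dist) pmin(pmax(signed_dist / thick + 0.5, 0), 1)
  zero <- array(0, dim = res)
  X <- array(rep(x, times = res[2] * res[3]), dim = res)
  Y <- array(rep(rep(y, each = res[1]), times = res[3]), dim = res)
  Z <- array(rep(z, each = res[1] * res[2]), dim = res)

  u <- zero; v <- zero; w <- zero
  wall_radius <- NULL; axis_center <- NULL
  reference <- list(kind = kind)

  if (kind == "couette") {
    u <- gamma0 * Z
    alpha <- array(1, dim = res)
    reference$S_norm <- gamma0
    reference$lambda1 <- gamma0 / 2
    reference$area_total <- 0
  } else if (kind == "rigid_rotation") {
    xc <- box[1] / 2; yc <- box[2] / 2
    u <- -Omega * (Y - yc)
    v <- Omega * (X - xc)
    alpha <- array(1, dim = res)
    reference$S_norm <- 0
    reference$lambda1 <- 0
    reference$area_total <- 0
  } else if (kind == "slab_interface") {
    if (is.null(h0)) h0 <- box[3] / 2
    alpha <- ramp(h0 - Z)
    reference$area_total <- box[1] * box[2]
    reference$liquid_volume <- box[1] * box[2] * h0
    reference$S_norm <- 0
    reference$lambda1 <- 0
  } else if (kind == "droplet") {
    if (is.null(r)) r <- 0.2 * min(box)
    if (r < 10 * max(dx)) {
      warning("droplet radius below 10 cell spacings; area recovery ",
              "degrades on coarse grids", call. = FALSE)
    }
    cx <- box / 2
    dist <- sqrt((X - cx[1])^2 + (Y - cx[2])^2 + (Z - cx[3])^2)
    alpha <- ramp(r - dist)
    reference$area_total <- 4 * pi * r^2
    reference$liquid_volume <- 4 / 3 * pi * r^3
  } else { # annulus
    if (is.null(h0)) h0 <- 0.4 * H
    if (is.null(film_height)) film_height <- max(0.45 * H, h0 + 0.05 * H)
    xc <- box[1] / 2; yc <- box[2] / 2
    rad <- sqrt((X - xc)^2 + (Y - yc)^2)
    film_inner <- R - film_thickness
    Ri <- 0.6 * R
    tilt_rad <- tilt * pi / 180
    in_bulk <- rad >= Ri & rad < film_inner
    in_film <- rad >= film_inner & rad <= R
    cellV <- prod(dx)
    build_alpha <- function(h) {
      surf <- h + tan(tilt_rad) * (X - xc)
      pmax(ramp(surf - Z) * in_bulk, ramp(film_height - Z) * in_film)
    }
    if (!is.null(liquid_volume)) {
      # the ramped surface makes discrete volume continuous and
      # monotone in the bulk height: bisect h0 to honor the request
      vol_at <- function(h) sum(build_alpha(h)) * cellV
      lo <- -thick; hi <- film_height
      if (liquid_volume < vol_at(lo) || liquid_volume > vol_at(hi)) {
        stop("requested liquid volume outside the attainable range ",
             sprintf("[%.3g, %.3g] mL of this annulus geometry",
                     vol_at(lo) * 1e6, vol_at(hi) * 1e6), call. = FALSE)
      }
      for (i in 1:60) {
        mid <- (lo + hi) / 2
        if (vol_at(mid) < liquid_volume) lo <- mid else hi <- mid
      }
      h0 <- (lo + hi) / 2
    }
    alpha <- build_alpha(h0)
    u <- -Omega * (Y - yc)
    v <- Omega * (X - xc)
    wall_radius <- R
    axis_center <- c(xc, yc)
    reference$S_norm <- 0
    reference$lambda1 <- 0
    reference$liquid_volume <- sum(alpha) * cellV
    reference$inner_radius <- Ri
    reference$h0 <- h0
    reference$film_height <- film_height
    # closed-form contact height at wall-normal offset delta and
    # azimuth theta (deg): film rim inside the film ring, tilted bulk
    # surface inside the bulk ring, absent inside the dry core
    reference$contact_height <- function(delta, theta_deg) {
      rs <- R - delta
      if (rs >= film_inner) return(rep(film_height, length(theta_deg)))
      if (rs < Ri) return(rep(NA_real_, length(theta_deg)))
      h0 + tan(tilt_rad) * rs * cos(theta_deg * pi / 180)
    }
  }

  if (jitter > 0) {
    set.seed(as.integer(seed))
    u <- u + array(stats::runif(prod(res), -jitter, jitter), dim = res)
    v <- v + array(stats::runif(prod(res), -jitter, jitter), dim = res)
    w <- w + array(stats::runif(prod(res), -jitter, jitter), dim = res)
  }

  grid <- field_grid(x, y, z, u, v, w, alpha,
                     wall_radius = wall_radius, axis_center = axis_center)
  list(grid = grid, reference = reference)
}
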