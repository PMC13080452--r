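.upper_mask <- function(domain) {
  # cells strictly above the membrane layer (all cells in 2D mode)
  m <- array(TRUE, dim = c(domain$nx, domain$ny, domain$nz))
  if (domain$mode == "3d" && domain$k_mem > 0)
    m[, , seq_len(domain$k_mem)] <- FALSE
  m
}

#' Mean fluid speed in the X1 / Y1 edge band
#'
#' Averages the cell-centered speed over the upper-chamber cells lying within
#' `band_fraction` of the chamber diameter from the X1 (far +x) or Y1
#' (far +y) reference point, i.e. between the wall and a vertical plane 10%
#' of the diameter inboard of it.
#'
#' @param field a `flow_field` from [solve_steady_flow()].
#' @param which `"X1"` or `"Y1"`.
#' @param band_fraction band width as a fraction of the chamber diameter,
#'   in (0, 0.5).
#' @return Mean speed (m/s).
#' @export
edge_region_speed <- function(field, which = c("X1", "Y1"),
                              band_fraction = 0.10) {
  stopifnot(inherits(field, "flow_field"))
  which <- match.arg(which)
  if (band_fraction <= 0 || band_fraction >= 0.5)
    stop("band_fraction must lie in (0, 0.5)", call. = FALSE)
  d <- field$domain
  cc <- cell_velocities(field)
  sel <- .upper_mask(d)
  if (which == "X1") {
    xc <- (seq_len(d$nx) - 0.5) * d$dx
    sel <- sel & outer(xc > d$Lx - band_fraction * d$D,
                       array(TRUE, c(d$ny, d$nz)))
    dim(sel) <- c(d$nx, d$ny, d$nz)
  } else {
    yc <- (seq_len(d$ny) - 0.5) * d$dy
    band <- yc > d$Ly - band_fraction * d$D
    keep <- array(rep(rep(band, each = d$nx), d$nz), c(d$nx, d$ny, d$nz))
    sel <- sel & keep
  }
  if (!any(sel))
    stop(sprintf("edge band is empty at this resolution; need at least %d cells per axis",
                 ceiling(1 / band_fraction)), call. = FALSE)
  mean(cc$speed[sel])
}

#' Mirror-asymmetry index of a flow field
#'
#' `||u - M(u)|| / (||u|| + ||M(u)||)` where `M` reflects the field about the
#' x-z midplane (y -> -y with the y-velocity negated). The index is 0 for an
#' exactly mirror-symmetric field and approaches 1 for a purely antisymmetric
#' one; Coriolis deflection raises it with rotation speed.
#'
#' @param field a `flow_field` solved on a mirror-symmetric domain.
#' @return Scalar in \[0, 1\].
#' @export
asymmetry_index <- function(field) {
  stopifnot(inherits(field, "flow_field"))
  d <- field$domain
  if (!all(d$bct_xmin == d$bct_xmin[d$ny:1, , drop = FALSE]) ||
      !all(d$bct_xmax == d$bct_xmax[d$ny:1, , drop = FALSE]))
    stop("domain is not mirror-symmetric about the x-z plane", call. = FALSE)
  cc <- cell_velocities(field)
  ucm <- cc$uc[, d$ny:1, , drop = FALSE]
  vcm <- -cc$vc[, d$ny:1, , drop = FALSE]
  wcm <- cc$wc[, d$ny:1, , drop = FALSE]
  num <- sqrt(sum((cc$uc - ucm)^2 + (cc$vc - vcm)^2 + (cc$wc - wcm)^2))
  den <- sqrt(sum(cc$uc^2 + cc$vc^2 + cc$wc^2)) +
    sqrt(sum(ucm^2 + vcm^2 + wcm^2))
  if (den == 0) return(0)
  min(num / den, 1)
}

.face_box <- function(domain, face) {
  # (y_lo, y_hi, z_lo, z_hi) extents of a boundary window
  y <- range((face$j - 1) * domain$dy, face$j * domain$dy)
  z <- range((face$k - 1) * domain$dz, face$k * domain$dz)
  c(y[1], y[2], z[1], z[2])
}

#' Inlet-to-outlet bypass fraction by tracer advection
#'
#' Seeds massless tracers across the inlet window, advects them through the
#' steady velocity field with fixed-arclength midpoint steps, and reports the
#' fraction that reaches the outlet without ever entering the far half of the
#' chamber (x beyond the chamber center). High bypass means the flow
#' short-circuits from inlet to outlet and leaves the chamber unswept.
#'
#' @param field a converged `flow_field`.
#' @param n_tracers number of tracers (stratified-jittered over the inlet).
#' @param seed RNG seed for the jitter.
#' @param max_steps integration step cap per tracer; tracers that exceed it
#'   (or stall in a dead zone) count as retained, with a warning.
#' @return Fraction in \[0, 1\].
#' @export
bypass_fraction <- function(field, n_tracers = 200, seed = 1L,
                            max_steps = 1e5) {
  stopifnot(inherits(field, "flow_field"))
  d <- field$domain
  inl <- d$inlet; out <- d$outlet
  if (inl$wall != "xmin")
    stop("bypass_fraction expects the inlet on the x-min wall", call. = FALSE)
  ibox <- .face_box(d, inl)
  obox <- .face_box(d, out)
  seeds <- local({
    if (exists(".Random.seed", envir = globalenv()))
      old <- get(".Random.seed", envir = globalenv()) else old <- NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
    ny_s <- max(1L, round(sqrt(n_tracers * (ibox[2] - ibox[1]) /
                                 max(ibox[4] - ibox[3], 1e-12))))
    if (d$nz == 1L) ny_s <- n_tracers
    nz_s <- max(1L, ceiling(n_tracers / ny_s))
    g <- expand.grid(a = seq_len(ny_s), b = seq_len(nz_s))[seq_len(min(n_tracers, ny_s * nz_s)), ]
    # stratified quasi-uniform seeding: stratum centers with a small seeded
    # jitter (5% of the stratum), keeping the estimate stable across seeds
    jit <- function(n) 0.05 * (runif(n) - 0.5)
    y <- ibox[1] + (g$a - 0.5 + jit(nrow(g))) / ny_s * (ibox[2] - ibox[1])
    z <- if (d$nz == 1L) rep(d$dz / 2, nrow(g))
         else ibox[3] + (g$b - 0.5 + jit(nrow(g))) / nz_s * (ibox[4] - ibox[3])
    cbind(rep(0.25 * d$dx, nrow(g)), y, z)
  })
  cc <- cell_velocities(field)
  vmax <- max(cc$speed)
  if (vmax == 0) return(0)
  res <- .advect_tracers(as.numeric(field$u), as.numeric(field$v),
                         as.numeric(field$w),
                         d$nx, d$ny, d$nz, d$dx, d$dy, d$dz,
                         seeds, d$Lx / 2, obox, ibox,
                         out$wall == "xmax",
                         0.25 * min(d$dx, d$dy, if (d$nz > 1) d$dz else Inf),
                         as.integer(max_steps), 1e-6 * vmax)
  n_cap <- sum(res$status == 0L)
  if (n_cap > 0)
    warning(sprintf("%d of %d tracers stalled or hit the step cap; counted as retained",
                    n_cap, nrow(seeds)))
  mean(res$status == 1L & !res$far)
}

#' Fraction of inlet flux passing down through the membrane
#'
#' Gross downward volumetric flux across the top of the membrane layer,
#' relative to the inlet flux, clamped to \[0, 1\]. In the default geometry
#' (outlet draining the sub-membrane cavity) essentially all through-flow
#' crosses the membrane; in the `outlet_level = "upper"` variant (closed
#' cavity) the fraction measures how much of the through-flow dips into the
#' protected compartment below the membrane, and it vanishes in the
#' impermeable limit.
#'
#' @param field a `flow_field` on a 3D domain with a membrane.
#' @return Fraction in \[0, 1\].
#' @export
membrane_flux_fraction <- function(field) {
  stopifnot(inherits(field, "flow_field"))
  d <- field$domain
  if (d$mode != "3d" || is.null(d$membrane))
    stop("membrane_flux_fraction requires a 3D domain with a membrane",
         call. = FALSE)
  wtop <- field$w[, , d$k_mem + 1L]
  flux_down <- sum(pmax(-wtop, 0)) * d$dx * d$dy
  if (field$flux_in <= 0) return(0)
  min(max(flux_down / field$flux_in, 0), 1)
}

#' Net downward flux through the membrane layer
#'
#' @param field a `flow_field` on a 3D membrane domain.
#' @return Net downward volumetric flux (m^3/s); positive means into the
#'   cavity.
#' @export
membrane_net_flux <- function(field) {
  stopifnot(inherits(field, "flow_field"))
  d <- field$domain
  if (d$mode != "3d" || is.null(d$membrane))
    stop("membrane_net_flux requires a 3D domain with a membrane", call. = FALSE)
  -sum(field$w[, , d$k_mem + 1L]) * d$dx * d$dy
}

#' Summary diagnostics of a solved flow field
#'
#' Bundles the edge-region speeds, mirror-asymmetry index, tracer bypass
#' fraction and (where defined) membrane flux fraction into one row, keyed by
#' rotation speed and membrane resistance for sweep tabulation.
#'
#' @inheritParams bypass_fraction
#' @param band_fraction edge band width (fraction of chamber diameter).
#' @return An object of class `flow_diagnostics` (also a one-row data.frame).
#' @export
flow_diagnostics <- function(field, n_tracers = 200, seed = 1L,
                             band_fraction = 0.10) {
  stopifnot(inherits(field, "flow_field"))
  d <- field$domain
  rh <- if (is.null(d$membrane)) 0
        else membrane_hydraulics(d$membrane, field$fluid)$R_h
  sym_dom <- all(d$bct_xmin == d$bct_xmin[d$ny:1, , drop = FALSE]) &&
    all(d$bct_xmax == d$bct_xmax[d$ny:1, , drop = FALSE])
  out <- data.frame(
    rpm = field$frame$rpm,
    R_h = rh,
    Q = field$Q,
    speed_X1 = edge_region_speed(field, "X1", band_fraction),
    speed_Y1 = edge_region_speed(field, "Y1", band_fraction),
    asymmetry = if (sym_dom) asymmetry_index(field) else NA_real_,
    bypass = bypass_fraction(field, n_tracers = n_tracers, seed = seed),
    membrane_fraction = if (d$mode == "3d" && !is.null(d$membrane))
      membrane_flux_fraction(field) else NA_real_,
    mass_imbalance = abs(field$flux_in - field$flux_out) /
      max(abs(field$flux_in), 1e-300))
  class(out) <- c("flow_diagnostics", class(out))
  out
}
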