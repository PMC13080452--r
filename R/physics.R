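#' @useDynLib discassay, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats median sd quantile rnorm rlnorm runif setNames
#' @importFrom utils read.csv write.csv
"_PACKAGE"

.check_num <- function(x, name, positive = FALSE, nonneg = FALSE, len = NULL) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x)))
    stop(sprintf("'%s' must be finite numeric", name), call. = FALSE)
  if (!is.null(len) && length(x) != len)
    stop(sprintf("'%s' must have length %d", name, len), call. = FALSE)
  if (positive && any(x <= 0))
    stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  if (nonneg && any(x < 0))
    stop(sprintf("'%s' must be >= 0", name), call. = FALSE)
  invisible(x)
}

#' Convert rotational speed between rpm and rad/s
#'
#' @param rpm revolutions per minute.
#' @param omega angular speed in rad/s.
#' @return The converted angular speed (`rpm_to_omega`: rad/s;
#'   `omega_to_rpm`: rpm). The conversion `omega = 2*pi*rpm/60` is exact and
#'   round-trips.
#' @export
rpm_to_omega <- function(rpm) {
  .check_num(rpm, "rpm", nonneg = TRUE)
  2 * pi * rpm / 60
}

#' @rdname rpm_to_omega
#' @export
omega_to_rpm <- function(omega) {
  .check_num(omega, "omega", nonneg = TRUE)
  60 * omega / (2 * pi)
}

#' Rotating reference frame of the disc
#'
#' The disc spins at constant angular speed about the z-axis through the disc
#' center. The rotation sense is stated as seen from +z looking down on the
#' disc; a clockwise sense corresponds to an angular-velocity vector
#' `Omega = -omega * z_hat`.
#'
#' @param rpm rotational speed in revolutions per minute (exclusive with
#'   `omega`).
#' @param omega angular speed in rad/s (exclusive with `rpm`).
#' @param sense rotation sense viewed from +z: `"clockwise"` (the device
#'   default) or `"counterclockwise"`.
#' @return An object of class `rotating_frame` with fields `omega` (rad/s),
#'   `rpm`, `sense`, and `omega_z` (signed z-component of the angular-velocity
#'   vector).
#' @export
rotating_frame <- function(rpm = NULL, omega = NULL,
                           sense = c("clockwise", "counterclockwise")) {
  sense <- match.arg(sense)
  if (is.null(omega) == is.null(rpm))
    stop("give exactly one of 'rpm' or 'omega'", call. = FALSE)
  if (is.null(omega)) omega <- rpm_to_omega(rpm)
  .check_num(omega, "omega", nonneg = TRUE, len = 1)
  structure(list(omega = omega,
                 rpm = omega_to_rpm(omega),
                 sense = sense,
                 omega_z = if (sense == "clockwise") -omega else omega),
            class = "rotating_frame")
}

#' @export
print.rotating_frame <- function(x, ...) {
  cat(sprintf("Rotating frame: %.6g rpm (%.6g rad/s), %s viewed from +z\n",
              x$rpm, x$omega, x$sense))
  invisible(x)
}

#' Newtonian working fluid
#'
#' @param density mass density rho in kg/m^3 (default: water at 20 C).
#' @param viscosity dynamic viscosity mu in Pa s.
#' @return Object of class `fluid` with fields `density`, `viscosity` and the
#'   derived kinematic viscosity `nu = mu/rho` (m^2/s).
#' @export
fluid <- function(density = 998, viscosity = 1.002e-3) {
  .check_num(density, "density", positive = TRUE, len = 1)
  .check_num(viscosity, "viscosity", positive = TRUE, len = 1)
  structure(list(density = density, viscosity = viscosity,
                 nu = viscosity / density), class = "fluid")
}

#' @export
print.fluid <- function(x, ...) {
  cat(sprintf("Fluid: rho = %g kg/m^3, mu = %g Pa s (nu = %g m^2/s)\n",
              x$density, x$viscosity, x$nu))
  invisible(x)
}

#' Spherical capture-bead specification
#'
#' @param diameter bead diameter in m (default: 5-um polystyrene assay bead).
#' @param density bead material density in kg/m^3 (default: polystyrene).
#' @return Object of class `bead_spec`.
#' @export
bead_spec <- function(diameter = 5e-6, density = 1050) {
  .check_num(diameter, "diameter", positive = TRUE, len = 1)
  .check_num(density, "density", positive = TRUE, len = 1)
  structure(list(diameter = diameter, density = density), class = "bead_spec")
}

#' Radial microchannel specification
#'
#' Describes a straight channel on the disc through which rotation drives
#' flow: cross-section area `A`, hydraulic diameter `d_H`, length `L`, the
#' mean radial position `r_mean` of the fluid column and its radial extent
#' `dr` (the centrifugal pressure head is `rho * omega^2 * r_mean * dr`).
#'
#' @param area cross-sectional area A (m^2).
#' @param hydraulic_diameter hydraulic diameter d_H (m); must satisfy
#'   `d_H^2 <= 4*A/pi` (the circular cross-section bound).
#' @param length channel length L (m).
#' @param r_mean mean distance of the fluid column from the rotation center (m).
#' @param dr radial extent of the fluid column (m).
#' @return Object of class `channel_spec`.
#' @export
channel_spec <- function(area, hydraulic_diameter, length, r_mean, dr) {
  .check_num(area, "area", positive = TRUE, len = 1)
  .check_num(hydraulic_diameter, "hydraulic_diameter", positive = TRUE, len = 1)
  .check_num(length, "length", positive = TRUE, len = 1)
  .check_num(r_mean, "r_mean", positive = TRUE, len = 1)
  .check_num(dr, "dr", positive = TRUE, len = 1)
  if (hydraulic_diameter^2 > 4 * area / pi * (1 + 1e-12))
    stop("hydraulic_diameter^2 exceeds 4*area/pi: inconsistent cross-section",
         call. = FALSE)
  structure(list(area = area, hydraulic_diameter = hydraulic_diameter,
                 length = length, r_mean = r_mean, dr = dr),
            class = "channel_spec")
}

#' Porous membrane filter specification
#'
#' A track-etched membrane idealised as parallel cylindrical pores. Exactly
#' one of `porosity` (open-area fraction) or `pore_density` (pores per m^2)
#' must be given; the other is derived from the pore cross-section.
#'
#' @param pore_diameter pore diameter (m), e.g. `200e-9` for the 200-nm
#'   track-etched polycarbonate filter.
#' @param porosity open-area fraction in (0, 1).
#' @param pore_density areal pore density (pores/m^2).
#' @param thickness membrane thickness (m).
#' @param area membrane face area (m^2); default is a 13-mm diameter disc.
#' @return Object of class `membrane` with derived fields `porosity`,
#'   `pore_density`, `permeability` (kappa, m^2).
#' @seealso [membrane_hydraulics()] for the permeability and hydraulic
#'   resistance of the membrane in a given fluid.
#' @export
membrane <- function(pore_diameter, porosity = NULL, pore_density = NULL,
                     thickness = 10e-6, area = pi * (13e-3 / 2)^2) {
  .check_num(pore_diameter, "pore_diameter", positive = TRUE, len = 1)
  .check_num(thickness, "thickness", positive = TRUE, len = 1)
  .check_num(area, "area", positive = TRUE, len = 1)
  if (is.null(porosity) == is.null(pore_density))
    stop("give exactly one of 'porosity' or 'pore_density'", call. = FALSE)
  pore_area <- pi * pore_diameter^2 / 4
  if (is.null(porosity)) {
    .check_num(pore_density, "pore_density", positive = TRUE, len = 1)
    porosity <- pore_density * pore_area
  } else {
    .check_num(porosity, "porosity", len = 1)
    pore_density <- porosity / pore_area
  }
  if (porosity <= 0 || porosity >= 1)
    stop("porosity must lie strictly in (0, 1)", call. = FALSE)
  structure(list(pore_diameter = pore_diameter, porosity = porosity,
                 pore_density = pore_density, thickness = thickness,
                 area = area,
                 permeability = porosity * pore_diameter^2 / 32),
            class = "membrane")
}

#' @export
print.membrane <- function(x, ...) {
  cat(sprintf(paste0("Membrane: %g-nm pores, porosity %.3g, thickness %g um,",
                     " kappa = %.3g m^2\n"),
              x$pore_diameter * 1e9, x$porosity, x$thickness * 1e6,
              x$permeability))
  invisible(x)
}

#' Rotating-frame body-force densities
#'
#' Evaluates the three apparent body forces acting on fluid in the co-rotating
#' disc frame at a point: gravity `(0, 0, -rho*g)`, the centrifugal force
#' `rho*omega^2*(x, y, 0)` pointing radially outward from the rotation axis,
#' and the Coriolis force `-2*rho*(Omega x u)` perpendicular to both the
#' velocity and the rotation axis. The Euler force is zero at constant spin
#' and is not modelled.
#'
#' @param u fluid velocity vector (m/s), length 3, in the rotating frame.
#' @param position Cartesian position (m), length 3, origin at the disc
#'   center with z along the rotation axis.
#' @param frame a [rotating_frame()].
#' @param fluid a [fluid()].
#' @param include_gravity include the gravitational term (default TRUE; it is
#'   much smaller than the rotational terms at assay speeds).
#' @param g gravitational acceleration (m/s^2).
#' @return A list with components `gravity`, `centrifugal`, `coriolis` (each a
#'   length-3 force density in N/m^3) and their sum `total`.
#' @examples
#' fr <- rotating_frame(rpm = 1800)
#' body_force_density(c(0.1, 0, 0), c(0.04, 0, 0), fr, fluid(1000, 1e-3))
#' @export
body_force_density <- function(u, position, frame, fluid,
                               include_gravity = TRUE, g = 9.80665) {
  .check_num(u, "u", len = 3)
  .check_num(position, "position", len = 3)
  stopifnot(inherits(frame, "rotating_frame"), inherits(fluid, "fluid"))
  rho <- fluid$density
  f_g <- if (include_gravity) c(0, 0, -rho * g) else c(0, 0, 0)
  f_cen <- rho * frame$omega^2 * c(position[1], position[2], 0)
  oz <- frame$omega_z
  # -2 rho (Omega x u) with Omega = (0, 0, oz)
  f_cor <- -2 * rho * c(-oz * u[2], oz * u[1], 0)
  list(gravity = f_g, centrifugal = f_cen, coriolis = f_cor,
       total = f_g + f_cen + f_cor)
}

#' Hagen-Poiseuille resistance of a channel
#'
#' `R = 32 * mu * L / (d_H^2 * A)`, the laminar fully developed flow
#' resistance of a duct expressed through its hydraulic diameter.
#'
#' @inheritParams centrifugal_flow_rate
#' @return Hydraulic resistance (Pa s/m^3).
#' @export
channel_resistance <- function(channel, fluid) {
  stopifnot(inherits(channel, "channel_spec"), inherits(fluid, "fluid"))
  32 * fluid$viscosity * channel$length /
    (channel$hydraulic_diameter^2 * channel$area)
}

#' Centrifugally driven channel flow rate
#'
#' Volumetric flow rate through a radial channel on the spinning disc,
#' from the Hagen-Poiseuille law driven by the centrifugally induced pressure
#' `dP = rho * omega^2 * r_mean * dr`:
#' `Q = d_H^2 * A * rho * omega^2 * r_mean * dr / (32 * mu * L)`.
#'
#' @param channel a [channel_spec()].
#' @param fluid a [fluid()].
#' @param frame a [rotating_frame()].
#' @return Volumetric flow rate Q (m^3/s). Scales as omega^2 and 1/mu.
#' @export
centrifugal_flow_rate <- function(channel, fluid, frame) {
  stopifnot(inherits(channel, "channel_spec"), inherits(fluid, "fluid"),
            inherits(frame, "rotating_frame"))
  dP <- fluid$density * frame$omega^2 * channel$r_mean * channel$dr
  dP / channel_resistance(channel, fluid)
}

#' Ekman number
#'
#' `E_k = nu / (omega * H^2)`: the ratio of viscous to Coriolis effects over a
#' characteristic fluid height H. Constant E_k (e.g. scaling viscosity and
#' rotation rate together) preserves the rotating-flow pattern. At omega = 0
#' the Coriolis effect vanishes and `Inf` is returned.
#'
#' @param fluid a [fluid()].
#' @param frame a [rotating_frame()].
#' @param height characteristic fluid height H (m), typically the chamber
#'   fluid depth above the membrane.
#' @return Dimensionless Ekman number (Inf when omega = 0).
#' @export
ekman_number <- function(fluid, frame, height) {
  stopifnot(inherits(fluid, "fluid"), inherits(frame, "rotating_frame"))
  .check_num(height, "height", positive = TRUE, len = 1)
  if (frame$omega == 0) return(Inf)
  fluid$nu / (frame$omega * height^2)
}

#' Stokes number of a suspended bead
#'
#' `Stk = tau_p * omega` with the particle relaxation time
#' `tau_p = rho_p * d_p^2 / (18 * mu)` and the rotation rate as the
#' characteristic inverse flow time. Stk << 1 means beads are overdamped and
#' faithfully follow the fluid.
#'
#' @param bead a [bead_spec()].
#' @param fluid a [fluid()].
#' @param frame a [rotating_frame()].
#' @return Dimensionless Stokes number (0 when omega = 0).
#' @export
stokes_number <- function(bead, fluid, frame) {
  stopifnot(inherits(bead, "bead_spec"), inherits(fluid, "fluid"),
            inherits(frame, "rotating_frame"))
  tau_p <- bead$density * bead$diameter^2 / (18 * fluid$viscosity)
  tau_p * frame$omega
}

#' Membrane permeability and hydraulic resistance
#'
#' Cylindrical-pore model of a track-etched membrane:
#' permeability `kappa = phi * d_pore^2 / 32` and hydraulic resistance
#' `R_h = mu * thickness / (kappa * area)`. R_h decreases with pore diameter
#' (quadratically) and porosity, and increases with thickness.
#'
#' @param membrane a [membrane()].
#' @param fluid a [fluid()].
#' @return A list with `kappa` (m^2) and `R_h` (Pa s/m^3).
#' @export
membrane_hydraulics <- function(membrane, fluid) {
  stopifnot(inherits(membrane, "membrane"), inherits(fluid, "fluid"))
  kappa <- membrane$permeability
  list(kappa = kappa,
       R_h = fluid$viscosity * membrane$thickness / (kappa * membrane$area))
}

#' Channel Reynolds number
#'
#' `Re = rho * U * d_H / mu` with U the mean speed `Q/A` of the centrifugally
#' driven flow; used only to confirm the laminar-flow assumption.
#'
#' @inheritParams centrifugal_flow_rate
#' @return Dimensionless Reynolds number.
#' @export
channel_reynolds <- function(channel, fluid, frame) {
  Q <- centrifugal_flow_rate(channel, fluid, frame)
  U <- Q / channel$area
  fluid$density * U * channel$hydraulic_diameter / fluid$viscosity
}
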