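#' Wash-cycle configuration
#'
#' Parameters of the two-compartment washing model: a swept compartment (the
#' chamber volume reached by the wash flow) and a dead compartment (the
#' sub-membrane cavity, which the sweeping flow does not displace directly
#' and which only exchanges with the swept volume between cycles).
#'
#' @param V_wash wash volume delivered per cycle (m^3); default 120 uL.
#' @param n_cycles number of wash cycles.
#' @param V_chamber swept chamber fluid volume (m^3).
#' @param V_sub sub-membrane cavity volume (m^3), `membrane area * h`.
#' @param eta sweep efficiency in \[0, 1\] (from [sweep_efficiency()] or set
#'   directly).
#' @param exchange between-cycle dead/swept re-equilibration fraction in
#'   \[0, 1\].
#' @return Object of class `wash_config`.
#' @export
wash_config <- function(V_wash = 120e-9, n_cycles = 1L,
                        V_chamber = 1.3e-7, V_sub = 6.6e-8,
                        eta = 1, exchange = 0.5) {
  .check_num(V_wash, "V_wash", nonneg = TRUE, len = 1)
  .check_num(V_chamber, "V_chamber", positive = TRUE, len = 1)
  .check_num(V_sub, "V_sub", nonneg = TRUE, len = 1)
  .check_num(eta, "eta", len = 1)
  .check_num(exchange, "exchange", len = 1)
  if (eta < 0 || eta > 1) stop("eta must lie in [0, 1]", call. = FALSE)
  if (exchange < 0 || exchange > 1)
    stop("exchange must lie in [0, 1]", call. = FALSE)
  if (n_cycles < 1) stop("n_cycles must be >= 1", call. = FALSE)
  structure(list(V_wash = V_wash, n_cycles = as.integer(n_cycles),
                 V_chamber = V_chamber, V_sub = V_sub, eta = eta,
                 exchange = exchange), class = "wash_config")
}

#' Sweep efficiency from flow diagnostics
#'
#' Maps the tracer bypass fraction of a solved flow field to a wash sweep
#' efficiency: `eta = 1 - bypass`. Flow that short-circuits from inlet to
#' outlet does not sweep contaminant out of the chamber.
#'
#' @param diag a `flow_diagnostics` row (or anything with a `bypass` field).
#' @return eta in \[0, 1\].
#' @export
sweep_efficiency <- function(diag) {
  b <- if (is.list(diag) || is.data.frame(diag)) diag$bypass else diag
  .check_num(b, "bypass", len = 1)
  min(max(1 - b, 0), 1)
}

#' Residual contaminant fraction after washing
#'
#' Two-compartment dilution model. Within each cycle the swept compartment is
#' diluted exponentially, `r_swept <- r_swept * exp(-eta * V_wash /
#' V_chamber)` (well-mixed displacement by the effective wash volume), while
#' the dead compartment is untouched. Between cycles the two compartments
#' partially re-equilibrate: both relax toward the volume-weighted mixture
#' concentration by the `exchange` fraction (mass-conserving). The returned
#' residual is the volume-weighted mean concentration after `n_cycles`,
#' relative to the initial uniform concentration.
#'
#' @param cfg a [wash_config()].
#' @return Residual fraction in \[0, 1\]; strictly decreasing in `eta`,
#'   `V_wash` and `n_cycles`, strictly increasing in `V_sub` (hence in the
#'   sub-membrane cavity height).
#' @export
residual_after_wash <- function(cfg) {
  stopifnot(inherits(cfg, "wash_config"))
  r_s <- 1; r_d <- 1
  f_dead <- cfg$V_sub / (cfg$V_sub + cfg$V_chamber)
  for (cyc in seq_len(cfg$n_cycles)) {
    r_s <- r_s * exp(-cfg$eta * cfg$V_wash / cfg$V_chamber)
    if (cyc < cfg$n_cycles && cfg$V_sub > 0) {
      mix <- f_dead * r_d + (1 - f_dead) * r_s
      r_d <- (1 - cfg$exchange) * r_d + cfg$exchange * mix
      r_s <- (1 - cfg$exchange) * r_s + cfg$exchange * mix
    }
  }
  f_dead * r_d + (1 - f_dead) * r_s
}

#' Fluid retention above the membrane during spinning
#'
#' Quasi-static level balance: the centrifugal pressure of the retained fluid
#' drives drainage through the membrane at rate
#' `Q_mem(level) = rho * omega^2 * r_a * level / R_h`, which balances the
#' wash inflow `Q_in`. The equilibrium level relative to the full chamber
#' height gives the retention fraction (clamped to \[0, 1\]). Low-resistance
#' filters fail to retain fluid; high-resistance filters stay filled.
#'
#' @param membrane a [membrane()].
#' @param frame a [rotating_frame()] with omega > 0.
#' @param fluid a [fluid()].
#' @param H_full full chamber fluid height (m).
#' @param r_a chamber radial position (m).
#' @param Q_in wash inflow rate (m^3/s).
#' @return Retention fraction in \[0, 1\]; increasing in R_h and Q_in,
#'   decreasing in omega^2. An `R_h = 0` (free-draining) configuration
#'   returns 0.
#' @export
volume_retention <- function(membrane, frame, fluid, H_full = 1e-3,
                             r_a = 0.04, Q_in = 1e-8) {
  stopifnot(inherits(frame, "rotating_frame"), inherits(fluid, "fluid"))
  .check_num(H_full, "H_full", positive = TRUE, len = 1)
  .check_num(Q_in, "Q_in", nonneg = TRUE, len = 1)
  if (frame$omega <= 0) stop("volume_retention requires omega > 0", call. = FALSE)
  R_h <- if (is.null(membrane)) 0 else membrane_hydraulics(membrane, fluid)$R_h
  if (R_h == 0) return(0)
  level <- Q_in * R_h / (fluid$density * frame$omega^2 * r_a)
  min(max(level / H_full, 0), 1)
}

#' Washing-performance sweep
#'
#' Runs the full solve -> diagnostics -> wash chain over a grid of rotation
#' speeds and membranes and tabulates residual fraction and sweep efficiency.
#'
#' @param rpms vector of rotation speeds (rpm).
#' @param membranes list of [membrane()] objects (or `NULL` entries for the
#'   no-filter control).
#' @param fluid a [fluid()].
#' @param domain_args named list of extra arguments for [chamber_domain()].
#' @param wash a [wash_config()] whose `eta` is replaced by the computed
#'   sweep efficiency of each run.
#' @param settings a [solver_settings()].
#' @param n_tracers,seed tracer settings for [bypass_fraction()].
#' @return A data.frame, one row per (rpm, membrane) combination.
#' @export
wash_sweep <- function(rpms, membranes, fluid = discassay::fluid(),
                       domain_args = list(), wash = wash_config(),
                       settings = solver_settings(),
                       n_tracers = 200, seed = 1L) {
  rows <- list()
  for (m in seq_along(membranes)) {
    dom <- do.call(chamber_domain, c(list(membrane = membranes[[m]]), domain_args))
    for (r in rpms) {
      fld <- solve_steady_flow(dom, rotating_frame(rpm = r), fluid, settings)
      dg <- flow_diagnostics(fld, n_tracers = n_tracers, seed = seed)
      w <- wash
      w$eta <- sweep_efficiency(dg)
      rows[[length(rows) + 1L]] <- cbind(dg,
        data.frame(eta = w$eta, residual = residual_after_wash(w)))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
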