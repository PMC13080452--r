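# shared fixtures: reference water-like fluid and small, fast solver domains

water <- function() fluid(density = 1000, viscosity = 1e-3)

frame1800 <- function(sense = "clockwise") rotating_frame(rpm = 1800, sense = sense)

# small 3D chamber used across solver tests (coarse but resolves all layers)
small_chamber <- function(membrane = discassay::membrane(200e-9, porosity = 0.05),
                          ...) {
  chamber_domain(membrane = membrane, nx = 18, ny = 18, nz = 8, ...)
}

fast_settings <- function(...) solver_settings(max_iter = 40000, ...)

# memoized solves so expensive fields are shared between expectations
.solve_cache <- new.env(parent = emptyenv())
cached_solve <- function(key, domain, frame, fl = water(),
                         settings = fast_settings(), Q = NULL) {
  if (!exists(key, envir = .solve_cache))
    assign(key, solve_steady_flow(domain, frame, fl, settings, Q = Q),
           envir = .solve_cache)
  get(key, envir = .solve_cache)
}

# hand-built uniform plug-flow field on a 2D far-outlet strip, for tracer and
# diagnostics unit tests
plug_flow_field <- function(speed = 1e-3, nx = 16, ny = 8) {
  dom <- chamber_domain(D = 8e-3, Ly = 4e-3, H = 0.3e-3, h = 1e-4,
                        membrane = NULL, mode = "2d", outlet_side = "far",
                        nx = nx, ny = ny, inlet_width = 4e-3,
                        outlet_width = 4e-3)
  u <- array(speed, dim = c(nx + 1, ny, 1))
  v <- array(0, dim = c(nx, ny + 1, 1))
  w <- array(0, dim = c(nx, ny, 2))
  structure(list(u = u, v = v, w = w, p = array(0, c(nx, ny, 1)),
                 domain = dom, frame = rotating_frame(rpm = 0),
                 fluid = water(), Q = speed * dom$Ly * dom$H, dt = 1,
                 iterations = 0L, final_residual = 0, max_divergence = 0,
                 residuals = numeric(0),
                 flux_in = speed * dom$Ly * dom$H,
                 flux_out = speed * dom$Ly * dom$H, converged = TRUE),
            class = "flow_field")
}
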