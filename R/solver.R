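#' Settings for the steady-flow projection solver
#'
#' The solver marches the incompressible rotating-frame momentum equations in
#' pseudo-time with a pressure-projection (Chorin) scheme on a staggered grid
#' until the velocity field stops changing. Porous (membrane) cells carry an
#' implicit Darcy drag; the projection uses drag-consistent face
#' transmissibilities so every iterate is discretely divergence-free.
#'
#' @param dt pseudo-time step (s); `NULL` picks a stable step from the
#'   viscous, Coriolis and advective rates times `cfl`.
#' @param tol convergence tolerance on the relative maximum velocity change
#'   per step.
#' @param max_iter maximum pseudo-time iterations.
#' @param min_iter iterations to run before testing convergence.
#' @param div_tol acceptable maximum discrete divergence at convergence (1/s).
#' @param advection `"upwind"` (first order, default) or `"central"`.
#' @param include_gravity add the gravitational body force (off by default;
#'   it is negligible next to the rotational forces at assay speeds).
#' @param cfl safety factor for the automatic time step.
#' @param u_scale characteristic speed (m/s) used for the advective stability
#'   estimate and blow-up detection; `NULL` derives it from the boundary flow.
#' @param p_in,p_out pressures (Pa) held at open x-min / x-max faces. In the
#'   default `"potential"` centrifugal treatment these are reduced pressures
#'   (the centrifugal potential is absorbed into the pressure field).
#' @param centrifugal `"potential"` (default) absorbs the conservative
#'   centrifugal body force `rho*omega^2*(x, y, 0) = grad(rho*omega^2*r^2/2)`
#'   into a reduced pressure, so open boundaries are referenced to the local
#'   centrifugal head (as a feed channel is); `"explicit"` keeps the raw
#'   force in the momentum equation.
#' @param record_every store the residual every this many iterations.
#' @param verbose print progress.
#' @return An object of class `solver_settings`.
#' @export
solver_settings <- function(dt = NULL, tol = 1e-6, max_iter = 20000L,
                            min_iter = 50L, div_tol = 1e-8,
                            advection = c("upwind", "central"),
                            include_gravity = FALSE, cfl = 0.4,
                            u_scale = NULL, p_in = 0, p_out = 0,
                            centrifugal = c("potential", "explicit"),
                            record_every = 25L, verbose = FALSE) {
  advection <- match.arg(advection)
  centrifugal <- match.arg(centrifugal)
  stopifnot(tol > 0, div_tol > 0, max_iter >= 1, cfl > 0)
  structure(list(dt = dt, tol = tol, max_iter = as.integer(max_iter),
                 min_iter = as.integer(min_iter), div_tol = div_tol,
                 advection = advection, include_gravity = include_gravity,
                 cfl = cfl, u_scale = u_scale, p_in = p_in, p_out = p_out,
                 centrifugal = centrifugal,
                 record_every = as.integer(record_every),
                 verbose = isTRUE(verbose)),
            class = "solver_settings")
}

.cell_drag <- function(domain, fluid) {
  # per-cell drag coefficient c (1/s) entering u/(1 + dt*c)
  cdrag <- array(0, dim = c(domain$nx, domain$ny, domain$nz))
  if (!is.null(domain$membrane))
    cdrag[domain$cell_type == 2L] <- fluid$nu / domain$kappa_eff
  if (domain$mode == "2d" && domain$hele_shaw)
    cdrag <- cdrag + 12 * fluid$nu / domain$H^2
  cdrag
}

.assemble_poisson <- function(domain, cdrag, dt) {
  nx <- domain$nx; ny <- domain$ny; nz <- domain$nz
  N <- nx * ny * nz
  cd <- as.vector(cdrag)
  ii <- integer(0); jj <- integer(0); vv <- numeric(0)
  add_faces <- function(c1, c2, inv_d2) {
    Tf <- 1 / (1 + dt * 0.5 * (cd[c1] + cd[c2]))
    coef <- Tf * inv_d2
    ii <<- c(ii, c1, c2, c1, c2)
    jj <<- c(jj, c1, c2, c2, c1)
    vv <<- c(vv, coef, coef, -coef, -coef)
  }
  idx <- function(i, j, k) i + nx * (j - 1L) + nx * ny * (k - 1L)
  g <- expand.grid(i = seq_len(nx - 1L), j = seq_len(ny), k = seq_len(nz))
  add_faces(idx(g$i, g$j, g$k), idx(g$i + 1L, g$j, g$k), 1 / domain$dx^2)
  g <- expand.grid(i = seq_len(nx), j = seq_len(ny - 1L), k = seq_len(nz))
  add_faces(idx(g$i, g$j, g$k), idx(g$i, g$j + 1L, g$k), 1 / domain$dy^2)
  if (nz > 1) {
    g <- expand.grid(i = seq_len(nx), j = seq_len(ny), k = seq_len(nz - 1L))
    add_faces(idx(g$i, g$j, g$k), idx(g$i, g$j, g$k + 1L), 1 / domain$dz^2)
  }
  # open (fixed-pressure) boundary faces on the x walls: half-cell Dirichlet
  # with the drag-consistent transmissibility of the adjacent cell
  open_min <- which(domain$bct_xmin == 1L, arr.ind = TRUE)
  if (nrow(open_min)) {
    c0 <- idx(1L, open_min[, 1], open_min[, 2])
    ii <- c(ii, c0); jj <- c(jj, c0)
    vv <- c(vv, 2 / (1 + dt * cd[c0]) / domain$dx^2)
  }
  open_max <- which(domain$bct_xmax == 1L, arr.ind = TRUE)
  if (nrow(open_max)) {
    c0 <- idx(nx, open_max[, 1], open_max[, 2])
    ii <- c(ii, c0); jj <- c(jj, c0)
    vv <- c(vv, 2 / (1 + dt * cd[c0]) / domain$dx^2)
  }
  if (!nrow(open_min) && !nrow(open_max))
    stop("domain has no open boundary face: pressure level undetermined",
         call. = FALSE)
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = vv, dims = c(N, N))
  list(A = A, open_min = open_min, open_max = open_max, idx = idx)
}

#' Solve the steady rotating-frame flow in a chamber domain
#'
#' Marches the incompressible Navier-Stokes equations in the co-rotating
#' frame (centrifugal + Coriolis body forces, optional gravity) to steady
#' state. Membrane cells add Darcy drag `-(mu/kappa) u`. Under the default
#' boundary orientation the rotation-driven volumetric flow rate from
#' [centrifugal_flow_rate()] is prescribed at the outlet while the inlet is
#' an open boundary at fixed pressure; `bc_orientation = "inlet_flow"` in the
#' domain swaps the roles.
#'
#' @param domain a [chamber_domain()].
#' @param frame a [rotating_frame()].
#' @param fluid a [fluid()].
#' @param settings a [solver_settings()].
#' @param Q boundary volumetric flow rate (m^3/s); default derives it from
#'   the domain's inlet channel via [centrifugal_flow_rate()].
#' @return An object of class `flow_field`: staggered velocity arrays `u`
#'   (nx+1 x ny x nz), `v`, `w`, cell pressures `p`, convergence metadata and
#'   boundary-flux summary.
#' @export
solve_steady_flow <- function(domain, frame, fluid,
                              settings = solver_settings(), Q = NULL) {
  stopifnot(inherits(domain, "chamber_domain"),
            inherits(frame, "rotating_frame"), inherits(fluid, "fluid"),
            inherits(settings, "solver_settings"))
  nx <- domain$nx; ny <- domain$ny; nz <- domain$nz
  dx <- domain$dx; dy <- domain$dy; dz <- domain$dz
  two_d <- domain$mode == "2d"

  if (is.null(Q)) Q <- centrifugal_flow_rate(domain$inlet_channel, fluid, frame)
  .check_num(Q, "Q", nonneg = TRUE, len = 1)

  # boundary value tables (normal velocity for prescribed faces, phi for open)
  bcu_xmin <- matrix(0, ny, nz); bcu_xmax <- matrix(0, ny, nz)
  inl <- domain$inlet; out <- domain$outlet
  if (domain$bc_orientation == "outlet_flow") {
    if (out$wall == "xmin") bcu_xmin[out$j, out$k] <- -Q / out$area
    else bcu_xmax[out$j, out$k] <- Q / out$area
  } else {
    if (inl$wall == "xmin") bcu_xmin[inl$j, inl$k] <- Q / inl$area
    else bcu_xmax[inl$j, inl$k] <- -Q / inl$area
  }

  u_scale <- settings$u_scale
  if (is.null(u_scale)) {
    u_scale <- max(Q / inl$area, Q / out$area, 1e-12)
    dp <- abs(settings$p_in - settings$p_out)
    if (dp > 0)
      u_scale <- max(u_scale, dp * min(domain$Ly, domain$Lz)^2 /
                       (8 * fluid$viscosity * domain$Lx))
  }
  rate <- 2 * fluid$nu * (1 / dx^2 + 1 / dy^2 + if (nz > 1) 1 / dz^2 else 0) +
    3 * u_scale / min(dx, dy, if (nz > 1) dz else Inf)
  dt <- if (is.null(settings$dt)) settings$cfl / rate else settings$dt

  cdrag <- .cell_drag(domain, fluid)
  gz <- if (settings$include_gravity && !two_d) -9.80665 else 0
  Xu <- domain$r_a - domain$D / 2 + (0:nx) * dx
  Yv <- (0:ny) * dy - domain$Ly / 2

  for (attempt in 1:4) {
    pois <- .assemble_poisson(domain, cdrag, dt)
    ch <- Matrix::Cholesky(methods::as(pois$A, "symmetricMatrix"), LDL = FALSE)
    b0 <- numeric(nx * ny * nz)
    phi_in <- settings$p_in * dt / fluid$density
    phi_out <- settings$p_out * dt / fluid$density
    bcp_xmin <- matrix(phi_in, ny, nz); bcp_xmax <- matrix(phi_out, ny, nz)
    cdv <- as.vector(cdrag)
    if (nrow(pois$open_min) && phi_in != 0) {
      c0 <- pois$idx(1L, pois$open_min[, 1], pois$open_min[, 2])
      b0[c0] <- 2 * phi_in / (1 + dt * cdv[c0]) / dx^2
    }
    if (nrow(pois$open_max) && phi_out != 0) {
      c0 <- pois$idx(nx, pois$open_max[, 1], pois$open_max[, 2])
      b0[c0] <- b0[c0] + 2 * phi_out / (1 + dt * cdv[c0]) / dx^2
    }

    u <- numeric((nx + 1) * ny * nz)
    v <- numeric(nx * (ny + 1) * nz)
    w <- numeric(nx * ny * (nz + 1))
    phi <- numeric(nx * ny * nz)
    residuals <- numeric(0)
    converged <- FALSE
    blowup <- FALSE
    it <- 0L
    stats <- c(NA_real_, NA_real_, NA_real_)

    while (it < settings$max_iter) {
      it <- it + 1L
      st <- .mac_momentum_rhs(u, v, w, nx, ny, nz, dx, dy, dz, dt,
                              fluid$nu, cdrag, Xu, Yv,
                              if (settings$centrifugal == "explicit")
                                frame$omega^2 else 0,
                              2 * frame$omega_z * dt, gz,
                              settings$advection == "upwind", two_d,
                              domain$bct_xmin, bcu_xmin,
                              domain$bct_xmax, bcu_xmax)
      phi <- as.numeric(Matrix::solve(ch, b0 - st$div))
      stats <- .mac_project(st$us, st$vs, st$ws, u, v, w, phi,
                            nx, ny, nz, dx, dy, dz, dt, cdrag,
                            domain$bct_xmin, bcp_xmin,
                            domain$bct_xmax, bcp_xmax)
      u <- st$us; v <- st$vs; w <- st$ws
      if (!all(is.finite(stats)) || stats[2] > 100 * max(u_scale, 1e-12)) {
        blowup <- TRUE
        break
      }
      rel <- stats[1] / max(stats[2], 1e-300)
      if (it %% settings$record_every == 0L || it == 1L) {
        residuals <- c(residuals, rel)
        if (settings$verbose)
          message(sprintf("iter %d: rel change %.3e, max|u| %.3e", it, rel, stats[2]))
      }
      if (it >= settings$min_iter && rel < settings$tol) {
        converged <- TRUE
        break
      }
    }
    if (!blowup) break
    dt <- dt / 2
    if (attempt == 4)
      stop("flow solve diverged even after reducing the time step", call. = FALSE)
  }
  if (!converged) {
    cond <- structure(class = c("discassay_no_convergence", "error", "condition"),
                      list(message = sprintf(
                        "flow solve did not converge in %d iterations (last rel change %.3e)",
                        settings$max_iter, stats[1] / max(stats[2], 1e-300)),
                        call = sys.call(), residuals = residuals))
    stop(cond)
  }

  dim(u) <- c(nx + 1, ny, nz); dim(v) <- c(nx, ny + 1, nz)
  dim(w) <- c(nx, ny, nz + 1); dim(phi) <- c(nx, ny, nz)

  # boundary flux bookkeeping (positive = into the domain at x-min)
  flux_in <- if (inl$wall == "xmin") sum(u[1, inl$j, inl$k]) * dy * dz
             else -sum(u[nx + 1, inl$j, inl$k]) * dy * dz
  flux_out <- if (out$wall == "xmin") -sum(u[1, out$j, out$k]) * dy * dz
              else sum(u[nx + 1, out$j, out$k]) * dy * dz

  structure(list(u = u, v = v, w = w, p = phi * fluid$density / dt,
                 domain = domain, frame = frame, fluid = fluid,
                 Q = Q, dt = dt, iterations = it,
                 final_residual = stats[1] / max(stats[2], 1e-300),
                 max_divergence = stats[3], residuals = residuals,
                 flux_in = flux_in, flux_out = flux_out,
                 converged = converged),
            class = "flow_field")
}

#' @rdname solve_steady_flow
#' @details `solve_depth_averaged()` is the 2D entry point; it requires a
#'   domain built with `mode = "2d"`.
#' @export
solve_depth_averaged <- function(domain, frame, fluid,
                                 settings = solver_settings(), Q = NULL) {
  if (domain$mode != "2d")
    stop("solve_depth_averaged() needs a domain built with mode = '2d'",
         call. = FALSE)
  solve_steady_flow(domain, frame, fluid, settings, Q)
}

#' @export
print.flow_field <- function(x, ...) {
  cat(sprintf("Flow field (%s, %dx%dx%d): %d iterations, rel change %.2e\n",
              x$domain$mode, x$domain$nx, x$domain$ny, x$domain$nz,
              x$iterations, x$final_residual))
  cat(sprintf("  max |div u| = %.2e 1/s; influx %.3e, outflux %.3e m^3/s\n",
              x$max_divergence, x$flux_in, x$flux_out))
  invisible(x)
}

#' Cell-centered velocity components and speed
#'
#' Averages the staggered face velocities to cell centers.
#'
#' @param field a `flow_field`.
#' @return A list with arrays `uc`, `vc`, `wc` and `speed` (all nx x ny x nz).
#' @export
cell_velocities <- function(field) {
  stopifnot(inherits(field, "flow_field"))
  nx <- field$domain$nx; ny <- field$domain$ny; nz <- field$domain$nz
  uc <- 0.5 * (field$u[1:nx, , , drop = FALSE] + field$u[2:(nx + 1), , , drop = FALSE])
  vc <- 0.5 * (field$v[, 1:ny, , drop = FALSE] + field$v[, 2:(ny + 1), , drop = FALSE])
  wc <- 0.5 * (field$w[, , 1:nz, drop = FALSE] + field$w[, , 2:(nz + 1), drop = FALSE])
  dim(uc) <- dim(vc) <- dim(wc) <- c(nx, ny, nz)
  list(uc = uc, vc = vc, wc = wc, speed = sqrt(uc^2 + vc^2 + wc^2))
}

#' Mirror a flow field about the x-z plane
#'
#' Reflects the field about the chamber midline y = 0: positions are mirrored
#' and the y-velocity component is negated. Reversing the rotation sense of a
#' solve yields exactly the mirror image of the original field.
#'
#' @param field a `flow_field`.
#' @return The mirrored `flow_field`.
#' @export
mirror_field <- function(field) {
  stopifnot(inherits(field, "flow_field"))
  ny <- field$domain$ny
  out <- field
  out$u <- field$u[, ny:1, , drop = FALSE]
  out$v <- -field$v[, (ny + 1):1, , drop = FALSE]
  out$w <- field$w[, ny:1, , drop = FALSE]
  out$p <- field$p[, ny:1, , drop = FALSE]
  out
}
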