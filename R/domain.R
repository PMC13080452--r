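#' Discretized assay-chamber domain
#'
#' Builds a voxelized model of the bead-assay chamber: a square-footprint
#' chamber of side `D` centered at disc radius `r_a`, with (in 3D mode) an
#' upper fluid layer of height `H`, a horizontal porous-membrane layer
#' spanning the chamber, and a sub-membrane cavity of height `h`. The inlet
#' channel enters the upper layer on the rotation-center side of the chamber;
#' the outlet channel leaves the sub-membrane cavity on the same side (the X0
#' reference point), so that fluid must cross the membrane (or, in the
#' no-filter control, fall freely) to exit. Reference points X1 and Y1 are the
#' far ends of the chamber along +x and +y.
#'
#' In 2D depth-averaged mode (`mode = "2d"`) a single layer of height `H` is
#' used with out-of-plane viscous resistance modelled as Hele-Shaw drag
#' `12*mu*u/H^2`; a membrane adds Brinkman drag over its footprint. Three 2D
#' outlet placements are supported: `"far"` (prescribed outflow at the x-max
#' wall, mirror-symmetric configurations) and `"open"` (both end walls held at
#' fixed pressures, for pressure-driven benchmarks).
#'
#' @param D chamber side length (m); defaults to the 13-mm membrane diameter.
#' @param Ly 2D mode only: transverse width of the domain (m); default `D`.
#'   Allows rectangular strips for channel benchmarks.
#' @param H fluid height above the membrane (m).
#' @param h sub-membrane cavity height (m).
#' @param membrane a [membrane()], or `NULL` for the no-filter control.
#' @param r_a radial offset of the chamber center from the disc center (m).
#' @param nx,ny,nz grid resolution per axis (`nz` ignored in 2D mode).
#' @param mode `"3d"` (default) or `"2d"` depth-averaged.
#' @param inlet_width,outlet_width widths of the inlet/outlet windows (m),
#'   centered on the chamber midline (y = 0).
#' @param outlet_side 2D only: `"far"` or `"open"` (see Details).
#' @param outlet_level 3D only: `"cavity"` (default; the outlet drains the
#'   sub-membrane cavity at X0, so all through-flow crosses the membrane) or
#'   `"upper"` (inlet and outlet both in the upper layer, offset to either
#'   side of the midline, with a closed cavity below the membrane; used to
#'   quantify how much of the through-flow dips into the protected
#'   sub-membrane compartment).
#' @param inlet_channel a [channel_spec()] describing the feed channel; used
#'   to compute the rotation-driven boundary flow rate. A device-plausible
#'   default is supplied.
#' @param bc_orientation `"outlet_flow"` (volumetric flow prescribed at the
#'   outlet, open inlet held at fixed pressure) or the conventional
#'   `"inlet_flow"` scheme.
#' @param hele_shaw logical; include the Hele-Shaw depth drag in 2D mode.
#' @return An object of class `chamber_domain`.
#' @export
chamber_domain <- function(D = 13e-3, Ly = NULL, H = 0.3e-3, h = 0.5e-3,
                           membrane = discassay::membrane(200e-9, porosity = 0.05),
                           r_a = 0.04,
                           nx = 26, ny = 26, nz = 12,
                           mode = c("3d", "2d"),
                           inlet_width = 2e-3, outlet_width = 2e-3,
                           outlet_side = c("near", "far", "open"),
                           outlet_level = c("cavity", "upper"),
                           inlet_channel = NULL,
                           bc_orientation = c("outlet_flow", "inlet_flow"),
                           hele_shaw = TRUE) {
  mode <- match.arg(mode)
  outlet_side <- match.arg(outlet_side)
  outlet_level <- match.arg(outlet_level)
  bc_orientation <- match.arg(bc_orientation)
  .check_num(D, "D", positive = TRUE, len = 1)
  .check_num(H, "H", positive = TRUE, len = 1)
  .check_num(h, "h", positive = TRUE, len = 1)
  .check_num(r_a, "r_a", positive = TRUE, len = 1)
  if (!is.null(membrane) && !inherits(membrane, "membrane"))
    stop("'membrane' must be a membrane() or NULL", call. = FALSE)
  if (nx < 4 || ny < 4) stop("nx, ny must be >= 4", call. = FALSE)
  if (inlet_width > D || outlet_width > D)
    stop("inlet/outlet window extends outside the chamber wall", call. = FALSE)
  if (r_a <= D / 2)
    stop("chamber (r_a - D/2) overlaps the rotation center: disconnected/overlapping geometry",
         call. = FALSE)
  if (is.null(inlet_channel))
    inlet_channel <- channel_spec(area = 4e-8, hydraulic_diameter = 2e-4,
                                  length = 0.02, r_mean = max(r_a - D / 2 - 0.01, 0.01),
                                  dr = 5e-3)

  if (!is.null(Ly) && mode != "2d")
    stop("'Ly' is only supported in 2D mode", call. = FALSE)
  Lx <- D
  Ly <- Ly %||% D
  .check_num(Ly, "Ly", positive = TRUE, len = 1)
  if (inlet_width > Ly || outlet_width > Ly)
    stop("inlet/outlet window extends outside the chamber wall", call. = FALSE)
  dx <- Lx / nx
  dy <- Ly / ny

  if (mode == "3d") {
    if (nz < 5) stop("3D mode needs nz >= 5", call. = FALSE)
    dz <- (H + h) / (nz - 1)          # membrane occupies one grid layer
    k_mem <- min(max(round(h / dz) + 1L, 2L), nz - 1L)
    Lz <- nz * dz
    h_eff <- (k_mem - 1L) * dz
    H_eff <- (nz - k_mem) * dz
  } else {
    nz <- 1L
    dz <- H
    Lz <- H
    k_mem <- 0L
    h_eff <- h
    H_eff <- H
  }

  cell_type <- array(1L, dim = c(nx, ny, nz))
  kappa_eff <- NA_real_
  if (!is.null(membrane)) {
    if (mode == "3d") {
      cell_type[, , k_mem] <- 2L
      # one grid layer stands in for the thin physical membrane; scale the
      # permeability so the layer's total hydraulic resistance is preserved
      kappa_eff <- membrane$permeability * dz / membrane$thickness
    } else {
      cell_type[] <- 2L
      kappa_eff <- membrane$permeability * H / membrane$thickness
    }
  }

  yc <- (seq_len(ny) - 0.5) * dy - Ly / 2
  y_in_c <- if (mode == "3d" && outlet_level == "upper") D / 4 else 0
  y_out_c <- if (mode == "3d" && outlet_level == "upper") -D / 4 else 0
  j_in <- which(abs(yc - y_in_c) <= inlet_width / 2 + 1e-12)
  j_out <- which(abs(yc - y_out_c) <= outlet_width / 2 + 1e-12)
  if (!length(j_in) || !length(j_out))
    stop("grid too coarse to resolve the inlet/outlet window", call. = FALSE)

  bct_xmin <- matrix(0L, ny, nz)
  bct_xmax <- matrix(0L, ny, nz)
  if (mode == "3d") {
    k_up <- (k_mem + 1L):nz
    k_lo <- if (outlet_level == "cavity") 1L:(k_mem - 1L) else k_up
    inlet <- list(wall = "xmin", j = j_in, k = k_up,
                  area = length(j_in) * length(k_up) * dy * dz)
    outlet <- list(wall = "xmin", j = j_out, k = k_lo,
                   area = length(j_out) * length(k_lo) * dy * dz)
    if (outlet_level == "upper" && length(intersect(j_in, j_out)))
      stop("inlet and outlet windows overlap: widen the chamber or narrow the windows",
           call. = FALSE)
    if (bc_orientation == "outlet_flow") {
      bct_xmin[inlet$j, inlet$k] <- 1L    # open, fixed pressure
      bct_xmin[outlet$j, outlet$k] <- 2L  # prescribed flow
    } else {
      bct_xmin[inlet$j, inlet$k] <- 2L
      bct_xmin[outlet$j, outlet$k] <- 1L
    }
  } else if (outlet_side == "far") {
    inlet <- list(wall = "xmin", j = j_in, k = 1L, area = length(j_in) * dy * dz)
    outlet <- list(wall = "xmax", j = j_out, k = 1L, area = length(j_out) * dy * dz)
    if (bc_orientation == "outlet_flow") {
      bct_xmin[inlet$j, 1] <- 1L
      bct_xmax[outlet$j, 1] <- 2L
    } else {
      bct_xmin[inlet$j, 1] <- 2L
      bct_xmax[outlet$j, 1] <- 1L
    }
  } else if (outlet_side == "open") {
    inlet <- list(wall = "xmin", j = seq_len(ny), k = 1L, area = ny * dy * dz)
    outlet <- list(wall = "xmax", j = seq_len(ny), k = 1L, area = ny * dy * dz)
    bct_xmin[, 1] <- 1L
    bct_xmax[, 1] <- 1L
  } else {
    stop("2D mode supports outlet_side 'far' or 'open'", call. = FALSE)
  }

  structure(list(mode = mode, nx = as.integer(nx), ny = as.integer(ny),
                 nz = as.integer(nz),
                 dx = dx, dy = dy, dz = dz, Lx = Lx, Ly = Ly, Lz = Lz,
                 D = D, H = H_eff, h = h_eff, r_a = r_a,
                 membrane = membrane, kappa_eff = kappa_eff, k_mem = k_mem,
                 cell_type = cell_type,
                 bct_xmin = bct_xmin, bct_xmax = bct_xmax,
                 inlet = inlet, outlet = outlet,
                 inlet_channel = inlet_channel,
                 bc_orientation = bc_orientation,
                 outlet_level = if (mode == "3d") outlet_level else NA_character_,
                 hele_shaw = isTRUE(hele_shaw),
                 label_counts = c(fluid = sum(cell_type == 1L),
                                  membrane = sum(cell_type == 2L),
                                  inlet_face = length(inlet$j) * length(inlet$k),
                                  outlet_face = length(outlet$j) * length(outlet$k))),
            class = "chamber_domain")
}

#' @rdname chamber_domain
#' @param config a named list of arguments for [chamber_domain()].
#' @export
build_domain <- function(config = list()) {
  stopifnot(is.list(config))
  known <- names(formals(chamber_domain))
  bad <- setdiff(names(config), known)
  if (length(bad))
    stop("unknown domain config field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  do.call(chamber_domain, config)
}

#' @export
print.chamber_domain <- function(x, ...) {
  cat(sprintf("Chamber domain (%s): %d x %d x %d cells, D = %g mm, r_a = %g mm\n",
              x$mode, x$nx, x$ny, x$nz, x$D * 1e3, x$r_a * 1e3))
  if (!is.null(x$membrane))
    cat(sprintf("  membrane layer %d (%g-nm pores), H = %.3g mm above, h = %.3g mm below\n",
                x$k_mem, x$membrane$pore_diameter * 1e9, x$H * 1e3, x$h * 1e3))
  else cat("  no filter (control)\n")
  cat("  cells:", paste(names(x$label_counts), x$label_counts,
                        sep = "=", collapse = ", "), "\n")
  invisible(x)
}
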