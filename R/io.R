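#' Read a flow-cytometry event export CSV
#'
#' Reads a FlowJo-style per-event CSV export (header row, one column per
#' channel) into a [bead_event_table()]. The intensity channel is taken from
#' `column` if given, else from a column named `intensity` (case
#' insensitive), else from the first numeric column.
#'
#' @param path CSV file path.
#' @param column intensity column name (optional).
#' @param sample_id,marker labels; default to the file name and column name.
#' @return A [bead_event_table()].
#' @export
read_event_csv <- function(path, column = NULL, sample_id = NULL,
                           marker = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  if (!length(first) || !nzchar(first))
    stop("no header: file '", path, "' is empty", call. = FALSE)
  df <- tryCatch(read.csv(path, check.names = FALSE),
                 error = function(e) stop("malformed CSV '", path, "': ",
                                          conditionMessage(e), call. = FALSE))
  if (!nrow(df)) stop("no events in '", path, "'", call. = FALSE)
  if (is.null(column)) {
    hit <- which(tolower(names(df)) == "intensity")
    if (!length(hit)) hit <- which(vapply(df, is.numeric, TRUE))[1]
    if (is.na(hit) || !length(hit))
      stop("no numeric intensity column in '", path, "'", call. = FALSE)
    column <- names(df)[hit[1]]
  } else if (!column %in% names(df)) {
    stop("missing required column '", column, "' in '", path, "'",
         call. = FALSE)
  }
  x <- df[[column]]
  if (!is.numeric(x)) {
    bad <- which(is.na(suppressWarnings(as.numeric(as.character(x)))))[1]
    stop(sprintf("non-numeric intensity in '%s', column '%s', row %d",
                 path, column, bad), call. = FALSE)
  }
  bead_event_table(x, sample_id = sample_id %||% basename(path),
                   marker = marker %||% column)
}

#' @rdname read_event_csv
#' @param events a [bead_event_table()].
#' @export
write_event_csv <- function(events, path) {
  stopifnot(inherits(events, "bead_event_table"))
  # 17 significant digits so doubles round-trip exactly
  writeLines(c("intensity", sprintf("%.17g", events$intensity)), path)
  invisible(path)
}

#' Read / write a cohort marker-profile CSV
#'
#' The schema matches [generate_cohort()] output: `sample_id`, `group`, raw
#' channels `I_<marker>`, `I_CD63`, `I_IgG` (and optionally derived
#' `xi_<marker>` columns, which are recomputed on read).
#'
#' @param path CSV file path.
#' @return A `cohort_profile` data.frame.
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- read.csv(path, check.names = FALSE)
  need <- c("sample_id", "group", "I_CD63", "I_IgG")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("cohort CSV missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  df$group <- factor(df$group, levels = intersect(c("HD", "ES", "PS", "PR"),
                                                  unique(df$group)))
  xi <- xi_matrix(df)
  for (m in colnames(xi)) df[[paste0("xi_", m)]] <- xi[, m]
  class(df) <- c("cohort_profile", "data.frame")
  df
}

#' @rdname read_cohort_csv
#' @param cohort a `cohort_profile`.
#' @export
write_cohort_csv <- function(cohort, path) {
  write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}

#' Write a flow field as a legacy-ASCII VTK structured-points file
#'
#' Emits cell-centered velocity vectors and pressure on a
#' `STRUCTURED_POINTS` dataset readable by standard VTK viewers.
#'
#' @param field a `flow_field`.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_field_vtk <- function(field, path) {
  stopifnot(inherits(field, "flow_field"))
  d <- field$domain
  cc <- cell_velocities(field)
  n <- d$nx * d$ny * d$nz
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "discassay steady rotating-frame flow field",
               "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", d$nx, d$ny, d$nz),
               sprintf("ORIGIN %.9g %.9g %.9g",
                       d$r_a - d$D / 2 + d$dx / 2, -d$Ly / 2 + d$dy / 2,
                       d$dz / 2),
               sprintf("SPACING %.9g %.9g %.9g", d$dx, d$dy, d$dz),
               sprintf("POINT_DATA %d", n),
               "VECTORS velocity double"), con)
  vel <- cbind(as.numeric(cc$uc), as.numeric(cc$vc), as.numeric(cc$wc))
  writeLines(sprintf("%.9e %.9e %.9e", vel[, 1], vel[, 2], vel[, 3]), con)
  writeLines(c("SCALARS pressure double 1", "LOOKUP_TABLE default"), con)
  writeLines(sprintf("%.9e", as.numeric(field$p)), con)
  invisible(path)
}

#' Read back a legacy-ASCII VTK structured-points field file
#'
#' Minimal reader for files produced by [write_field_vtk()]; used for
#' round-trip validation.
#'
#' @param path VTK file path.
#' @return A list with `dims`, `origin`, `spacing`, `velocity` (n x 3) and
#'   `pressure`.
#' @export
read_field_vtk <- function(path) {
  ln <- readLines(path)
  if (length(ln) < 10 || !startsWith(ln[1], "# vtk DataFile"))
    stop("not a legacy VTK file: ", path, call. = FALSE)
  if (ln[3] != "ASCII" || ln[4] != "DATASET STRUCTURED_POINTS")
    stop("unsupported VTK layout in ", path, call. = FALSE)
  dims <- as.integer(strsplit(ln[5], " ")[[1]][-1])
  origin <- as.numeric(strsplit(ln[6], " ")[[1]][-1])
  spacing <- as.numeric(strsplit(ln[7], " ")[[1]][-1])
  n <- as.integer(strsplit(ln[8], " ")[[1]][2])
  if (n != prod(dims)) stop("POINT_DATA count mismatch in ", path, call. = FALSE)
  vel <- do.call(rbind, lapply(ln[10:(9 + n)],
                               function(s) as.numeric(strsplit(s, " ")[[1]])))
  stopifnot(ln[10 + n] == "SCALARS pressure double 1")
  pres <- as.numeric(ln[(12 + n):(11 + 2 * n)])
  list(dims = dims, origin = origin, spacing = spacing,
       velocity = vel, pressure = pres)
}

.validate_config <- function(config, schema, path = "config") {
  if (!is.list(config))
    stop(path, " must be a list", call. = FALSE)
  bad <- setdiff(names(config), names(schema))
  if (length(bad))
    stop("unknown config field(s): ",
         paste(paste0(path, "$", bad), collapse = ", "), call. = FALSE)
  for (nm in names(schema)) {
    if (is.list(schema[[nm]]) && nm %in% names(config))
      .validate_config(config[[nm]], schema[[nm]], paste0(path, "$", nm))
  }
  invisible(TRUE)
}

.flow_schema <- function() {
  list(rpm = NA, sense = NA, density = NA, viscosity = NA,
       domain = as.list(setNames(rep(NA, length(formals(chamber_domain))),
                                 names(formals(chamber_domain)))),
       settings = as.list(setNames(rep(NA, length(formals(solver_settings))),
                                   names(formals(solver_settings)))),
       Q = NA, n_tracers = NA, seed = NA)
}

#' Run a configured flow simulation
#'
#' Validates the configuration (unknown keys are rejected with their field
#' path), builds the domain, solves the steady flow, and reduces it to a
#' diagnostics row. Optionally writes the field as legacy-ASCII VTK and
#' appends the diagnostics row to a CSV file. Deterministic: identical
#' configuration and seed give identical outputs.
#'
#' @param config nested list: `rpm`, optional `sense`, `density`,
#'   `viscosity`, `Q`, `n_tracers`, `seed`, plus `domain` and `settings`
#'   blocks of arguments for [chamber_domain()] and [solver_settings()].
#' @param out_vtk optional VTK output path.
#' @param out_csv optional diagnostics CSV path (row appended; header written
#'   when the file does not exist).
#' @return The `flow_diagnostics` row, with the `flow_field` attached as
#'   attribute `"field"`.
#' @export
run_flow_simulation <- function(config, out_vtk = NULL, out_csv = NULL) {
  .validate_config(config, .flow_schema())
  if (is.null(config$rpm)) stop("config$rpm is required", call. = FALSE)
  fl <- fluid(density = config$density %||% 998,
              viscosity = config$viscosity %||% 1.002e-3)
  fr <- rotating_frame(rpm = config$rpm, sense = config$sense %||% "clockwise")
  dom <- build_domain(config$domain %||% list())
  st <- do.call(solver_settings, config$settings %||% list())
  fld <- solve_steady_flow(dom, fr, fl, st, Q = config$Q)
  dg <- flow_diagnostics(fld, n_tracers = config$n_tracers %||% 200,
                         seed = config$seed %||% 1L)
  if (!is.null(out_vtk)) write_field_vtk(fld, out_vtk)
  if (!is.null(out_csv)) {
    df <- as.data.frame(dg)
    suppressWarnings(write.table(df, out_csv, sep = ",", row.names = FALSE,
                                 col.names = !file.exists(out_csv),
                                 append = file.exists(out_csv)))
  }
  attr(dg, "field") <- fld
  dg
}

.assay_schema <- list(seed = NA,
                      contrast_pairs = NA,
                      events = list(path = NA, column = NA, n = NA,
                                    location = NA, dispersion = NA),
                      titration = list(path = NA, recipe = NA),
                      cohort = list(path = NA, recipe = NA,
                                    risk_groups = NA, n_boot = NA))

#' Run a configured assay-analytics pipeline
#'
#' Runs the measurement/inference chain as configured: bead-event
#' summarization, target-to-background contrasts on supplied intensity
#' pairs, titration detection limit, and cohort classification (risk-score
#' ROC on the configured two groups, four-group LDA, LOOCV, optional
#' bootstrap SE). All stochastic steps are seeded from the configuration.
#'
#' @param config nested list; see the schema in the function definition.
#'   `events`, `titration` and `cohort` blocks each accept either a `path`
#'   to a CSV or generator parameters.
#' @param out_dir optional directory for report files (`metrics.json`,
#'   `confusion.csv`).
#' @return A list of metric values (invisibly also written to `out_dir`).
#' @export
run_assay <- function(config, out_dir = NULL) {
  .validate_config(config, .assay_schema)
  seed <- config$seed %||% 1L
  metrics <- list()
  if (!is.null(config$contrast_pairs)) {
    for (nm in names(config$contrast_pairs)) {
      pr <- config$contrast_pairs[[nm]]
      metrics[[paste0("target_to_background_", nm)]] <-
        target_to_background(pr[1], pr[2])
    }
  }
  if (!is.null(config$events)) {
    ev <- if (!is.null(config$events$path))
      read_event_csv(config$events$path, column = config$events$column)
    else generate_bead_events(n = config$events$n %||% 5000,
                              location = config$events$location %||% 3195,
                              dispersion = config$events$dispersion %||% 0.4,
                              seed = seed)
    metrics$median_intensity <- summarize_events(ev)
    metrics$n_events <- ev$n_events
  }
  if (!is.null(config$titration)) {
    ti <- if (!is.null(config$titration$path)) {
      df <- read.csv(config$titration$path)
      titration_series(unique(df$concentration),
                       t(sapply(split(df$intensity[!df$blank],
                                      df$concentration[!df$blank]), identity)),
                       df$intensity[df$blank])
    } else {
      rc <- do.call(titration_recipe,
                    c(config$titration$recipe %||% list(), list(seed = seed)))
      generate_titration(rc)
    }
    ld <- estimate_lod(ti)
    metrics$lod_evs_per_ml <- ld$lod
    metrics$lod_status <- ld$status
    metrics$lod_molar <- if (is.na(ld$lod)) NA_real_
                         else ev_concentration_to_molar(ld$lod)
  }
  confusion <- NULL
  if (!is.null(config$cohort)) {
    co <- if (!is.null(config$cohort$path)) read_cohort_csv(config$cohort$path)
    else generate_cohort(do.call(cohort_recipe,
                                 c(config$cohort$recipe %||% list(),
                                   list(seed = seed))))
    X <- cohort_features(co)
    z <- zscore_standardize(X)
    rg <- config$cohort$risk_groups %||% c("HD", "ES")
    sel <- co$group %in% rg
    rs <- fit_risk_score(z$X[sel, , drop = FALSE],
                         factor(co$group[sel], levels = rg))
    metrics$risk_auc <- rs$auc
    lda <- fit_lda(z$X, co$group)
    metrics$lda_accuracy <- lda$accuracy
    cv <- loocv(z$X, co$group)
    metrics$loocv_accuracy <- cv$accuracy
    metrics$loocv_weighted_f1 <- cv$weighted_f1
    metrics$loocv_weighted_recall <- cv$weighted_recall
    confusion <- lda$confusion
    nb <- config$cohort$n_boot %||% 0L
    if (nb > 0) {
      bs <- bootstrap_se(function(Xb, yb) fit_lda(Xb, yb)$accuracy,
                         z$X, co$group, n_boot = nb, seed = seed)
      metrics$accuracy_bootstrap_se <- bs$se
    }
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
    if (!is.null(confusion))
      write.csv(as.data.frame.matrix(confusion),
                file.path(out_dir, "confusion.csv"))
  }
  invisible(metrics)
}
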