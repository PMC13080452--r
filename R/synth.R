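.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Synthetic bead-event table
#'
#' Draws per-event fluorescence intensities from a log-normal distribution
#' (fluorescence noise is multiplicative) with a planted median. Bit
#' reproducible under a fixed seed.
#'
#' @param n number of events (default 5000, the per-sample acquisition
#'   count).
#' @param location planted median intensity (> 0).
#' @param dispersion log-scale standard deviation (> 0).
#' @param seed RNG seed.
#' @param sample_id,marker labels for the table.
#' @return A [bead_event_table()].
#' @export
generate_bead_events <- function(n = 5000, location = 3195, dispersion = 0.4,
                                 seed = 1L, sample_id = "synthetic",
                                 marker = "CD63") {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  .check_num(location, "location", positive = TRUE, len = 1)
  .check_num(dispersion, "dispersion", positive = TRUE, len = 1)
  x <- .with_seed(seed, rlnorm(n, meanlog = log(location), sdlog = dispersion))
  bead_event_table(x, sample_id = sample_id, marker = marker)
}

#' Titration recipe
#'
#' Parameters of the synthetic titration generator. The mean response is the
#' blank baseline below a planted onset concentration and rises log-linearly
#' above it; the onset is placed so that the mean response crosses the
#' `baseline_mean + 3 * baseline_sd` detection threshold exactly at
#' `planted_lod`.
#'
#' @param concentrations log-spaced grid (EVs/mL), ascending.
#' @param baseline_mean,baseline_sd blank intensity mean and SD.
#' @param slope response rise per decade of concentration.
#' @param planted_lod planted threshold-crossing concentration (EVs/mL).
#' @param n_replicates replicates per concentration.
#' @param n_blanks blank replicates.
#' @param cv multiplicative noise coefficient of variation on replicate
#'   intensities.
#' @param seed RNG seed.
#' @return Object of class `titration_recipe`.
#' @export
titration_recipe <- function(concentrations = 10^seq(4, 9, by = 0.25),
                             baseline_mean = 100, baseline_sd = 25,
                             slope = 300, planted_lod = 4.6e5,
                             n_replicates = 3, n_blanks = 12,
                             cv = 0.06, seed = 1L) {
  .check_num(concentrations, "concentrations", positive = TRUE)
  if (is.unsorted(concentrations, strictly = TRUE))
    stop("concentration grid must be ascending", call. = FALSE)
  .check_num(cv, "cv", nonneg = TRUE, len = 1)
  if (n_replicates < 2) stop("need >= 2 replicates", call. = FALSE)
  .check_num(planted_lod, "planted_lod", positive = TRUE, len = 1)
  .check_num(slope, "slope", positive = TRUE, len = 1)
  onset <- planted_lod / 10^(3 * baseline_sd / slope)
  if (onset < min(concentrations) || planted_lod > max(concentrations))
    stop("planted onset/crossing lies outside the concentration grid",
         call. = FALSE)
  structure(list(concentrations = concentrations,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 slope = slope, planted_lod = planted_lod, onset = onset,
                 n_replicates = as.integer(n_replicates),
                 n_blanks = as.integer(n_blanks), cv = cv,
                 seed = as.integer(seed)),
            class = "titration_recipe")
}

#' Generate a synthetic titration series
#'
#' @param recipe a [titration_recipe()].
#' @return A [titration_series()] carrying the planted crossing concentration
#'   in `$planted_lod`.
#' @export
generate_titration <- function(recipe = titration_recipe()) {
  stopifnot(inherits(recipe, "titration_recipe"))
  m <- recipe$baseline_mean + recipe$slope *
    pmax(0, log10(recipe$concentrations) - log10(recipe$onset))
  .with_seed(recipe$seed, {
    reps <- matrix(rnorm(length(m) * recipe$n_replicates,
                         mean = rep(m, recipe$n_replicates),
                         sd = rep(recipe$cv * m, recipe$n_replicates)),
                   nrow = length(m))
    # blank panel drawn with exact sample statistics, so the blank + 3 sigma
    # threshold equals its planted value and the planted crossing is the
    # ground truth of the series (replicate noise still enters through cv)
    z <- rnorm(recipe$n_blanks)
    z <- (z - mean(z)) / sd(z)
    blanks <- recipe$baseline_mean + recipe$baseline_sd * z
    titration_series(recipe$concentrations, reps, blanks,
                     planted_lod = recipe$planted_lod)
  })
}

.default_markers <- c("EpCAM", "CLDN4", "CLDN3", "IL6R", "STn", "CD44",
                      "FOLR1", "CD24", "CA125")

.default_pattern <- function(markers = .default_markers) {
  P <- matrix(0, 4, length(markers),
              dimnames = list(c("HD", "ES", "PS", "PR"), markers))
  P["ES", c("CLDN3", "CLDN4", "EpCAM")] <- 1
  P["PS", c("CLDN3", "CLDN4", "EpCAM")] <- 1.2
  P["PS", c("CA125", "STn")] <- 1.5
  P["PR", c("CLDN3", "CLDN4", "EpCAM")] <- 1.2
  P["PR", c("CA125", "STn")] <- 1.5
  P["PR", "IL6R"] <- 2
  P["PR", "CD44"] <- 0.5
  P
}

#' Cohort recipe
#'
#' Ground-truth structure for the synthetic 82-sample marker-profile cohort:
#' healthy donors (HD, n = 28), early-stage ovarian cancer (ES, n = 16), and
#' late-stage platinum-sensitive (PS, n = 19) / platinum-resistant (PR,
#' n = 19) patients, profiled for nine cancer-associated markers plus the
#' CD63 EV-abundance reference and an isotype-IgG background channel. The
#' default effect pattern elevates CLDN3/CLDN4/EpCAM in all cancer groups
#' (the diagnostic panel), adds CA125/STn in late-stage disease, and shifts
#' IL6R between PS and PR (the resistance signal).
#'
#' @param group_sizes named sizes for HD/ES/PS/PR.
#' @param markers marker names (9 by default).
#' @param pattern groups x markers matrix of planted mean shifts in units of
#'   the within-group SD; scaled by `effect_size`.
#' @param effect_size overall planted separation in within-group SD units
#'   (0 = null cohort).
#' @param sdlog within-group SD of log-xi.
#' @param xi_base baseline xi level of every marker in healthy donors.
#' @param cd63_meanlog,cd63_sdlog log-normal parameters of the
#'   background-corrected CD63 intensity (EV abundance per sample).
#' @param igg_meanlog,igg_sdlog log-normal parameters of the isotype
#'   background intensity.
#' @param gain arbitrary detector gain applied to all raw channels (xi is
#'   invariant to it).
#' @param seed RNG seed.
#' @return Object of class `cohort_recipe`.
#' @export
cohort_recipe <- function(group_sizes = c(HD = 28, ES = 16, PS = 19, PR = 19),
                          markers = .default_markers,
                          pattern = .default_pattern(markers),
                          effect_size = 2, sdlog = 0.5, xi_base = 0.15,
                          cd63_meanlog = log(2417), cd63_sdlog = 0.3,
                          igg_meanlog = log(778), igg_sdlog = 0.2,
                          gain = 1, seed = 1L) {
  stopifnot(length(group_sizes) == 4, all(group_sizes >= 2),
            all(c("HD", "ES", "PS", "PR") %in% names(group_sizes)))
  pattern <- as.matrix(pattern)
  if (!all(dim(pattern) == c(4, length(markers))))
    stop("pattern must be 4 groups x ", length(markers), " markers",
         call. = FALSE)
  .check_num(sdlog, "sdlog", positive = TRUE, len = 1)
  .check_num(effect_size, "effect_size", nonneg = TRUE, len = 1)
  .check_num(gain, "gain", positive = TRUE, len = 1)
  structure(list(group_sizes = group_sizes[c("HD", "ES", "PS", "PR")],
                 markers = markers, pattern = pattern,
                 effect_size = effect_size, sdlog = sdlog, xi_base = xi_base,
                 cd63_meanlog = cd63_meanlog, cd63_sdlog = cd63_sdlog,
                 igg_meanlog = igg_meanlog, igg_sdlog = igg_sdlog,
                 gain = gain, seed = as.integer(seed)),
            class = "cohort_recipe")
}

#' Generate a synthetic marker-profile cohort
#'
#' Draws per-sample raw intensity channels (nine markers, CD63 and IgG) such
#' that the derived `xi = (I_M - I_IgG) / (I_CD63 - I_IgG)` values follow the
#' planted per-group log-normal structure of the recipe. Ground-truth labels
#' are included.
#'
#' @param recipe a [cohort_recipe()].
#' @return A data.frame of class `cohort_profile` with columns `sample_id`,
#'   `group`, raw channels `I_<marker>`, `I_CD63`, `I_IgG`, and derived
#'   `xi_<marker>` columns.
#' @export
generate_cohort <- function(recipe = cohort_recipe()) {
  stopifnot(inherits(recipe, "cohort_recipe"))
  sizes <- recipe$group_sizes
  n <- sum(sizes)
  groups <- factor(rep(names(sizes), sizes), levels = names(sizes))
  nm <- length(recipe$markers)
  .with_seed(recipe$seed, {
    dI_cd63 <- rlnorm(n, recipe$cd63_meanlog, recipe$cd63_sdlog)
    I_igg <- rlnorm(n, recipe$igg_meanlog, recipe$igg_sdlog)
    shift <- recipe$effect_size * recipe$pattern[as.integer(groups), , drop = FALSE]
    logxi <- matrix(log(recipe$xi_base), n, nm) + recipe$sdlog * shift +
      matrix(rnorm(n * nm, sd = recipe$sdlog), n, nm)
    xi <- exp(logxi)
    dI <- xi * dI_cd63
    I_M <- recipe$gain * (dI + I_igg)
    I_cd63_raw <- recipe$gain * (dI_cd63 + I_igg)
    I_igg_raw <- recipe$gain * I_igg
    out <- data.frame(sample_id = sprintf("S%03d", seq_len(n)), group = groups)
    colnames(I_M) <- paste0("I_", recipe$markers)
    out <- cbind(out, I_M)
    out$I_CD63 <- I_cd63_raw
    out$I_IgG <- I_igg_raw
    xi_chk <- (I_M - I_igg_raw) / (I_cd63_raw - I_igg_raw)
    colnames(xi_chk) <- paste0("xi_", recipe$markers)
    out <- cbind(out, xi_chk)
    attr(out, "recipe") <- recipe
    class(out) <- c("cohort_profile", class(out))
    out
  })
}

#' Feature matrix for cohort classification
#'
#' Returns the marker matrix used by the classification workflow:
#' log-transformed xi values (the within-group structure of fluorescence
#' ratios is multiplicative, so the log is variance-stabilizing) when all xi
#' are positive, otherwise the raw xi values. Standardize with
#' [zscore_standardize()] before fitting.
#'
#' @param cohort a `cohort_profile`.
#' @param log_transform apply the log (default); ignored (with a warning)
#'   when non-positive xi values are present.
#' @return Numeric matrix, samples x markers.
#' @export
cohort_features <- function(cohort, log_transform = TRUE) {
  X <- xi_matrix(cohort)
  if (log_transform) {
    if (all(X > 0, na.rm = TRUE)) return(log(X))
    warning("non-positive xi values: returning untransformed features")
  }
  X
}

#' Extract the xi marker matrix from a cohort profile
#'
#' Recomputes `xi_M = (I_M - I_IgG) / (I_CD63 - I_IgG)` from the raw
#' channels; samples with non-positive CD63 contrast get `NA` rows.
#'
#' @param cohort a `cohort_profile` (or data.frame with the raw channels).
#' @return Numeric matrix, samples x markers, with marker column names.
#' @export
xi_matrix <- function(cohort) {
  raw_cols <- grep("^I_", colnames(cohort), value = TRUE)
  markers <- setdiff(sub("^I_", "", raw_cols), c("CD63", "IgG"))
  d_cd63 <- cohort$I_CD63 - cohort$I_IgG
  X <- sapply(markers, function(m)
    ifelse(d_cd63 > 0, (cohort[[paste0("I_", m)]] - cohort$I_IgG) / d_cd63,
           NA_real_))
  rownames(X) <- cohort$sample_id
  X
}
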