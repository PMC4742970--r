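TRAJECTORY_SCHEMA_VERSION <- "1.0"

.trajectory_cols <- c("molecule_id", "dna_axis_id", "frame", "time_s",
                      "x_px", "y_px", "position_um", "position_bp",
                      "sigma_px", "amplitude", "background", "detected",
                      "nucleotide", "nacl_mM")
.trajectory_mandatory <- c("molecule_id", "frame", "time_s", "position_um",
                           "detected")

#' Read an uncompressed grayscale TIFF stack
#'
#' Movies are saved as uncompressed 16-bit grayscale TIFF, one page per
#' frame. Multichannel (RGB) pages and pages of unequal shape are rejected as
#' an unsupported dialect; corrupt files report the failing page.
#'
#' @param path TIFF file path.
#' @return A list: `frames` (ny x nx x n_frames integer array), `n_frames`,
#'   `ny`, `nx`.
#' @export
read_tiff_stack <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                    error = function(e)
                      stop(sprintf("corrupt or unreadable TIFF '%s': %s",
                                   path, conditionMessage(e))))
  if (!is.list(pages)) pages <- list(pages)
  for (i in seq_along(pages)) {
    p <- pages[[i]]
    if (length(dim(p)) == 3)
      stop(sprintf("unsupported TIFF dialect: page %d is multichannel (RGB); expected grayscale", i))
    if (!identical(dim(p), dim(pages[[1]])))
      stop(sprintf("corrupt TIFF: page %d has a different shape than page 1", i))
  }
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  frames <- array(0L, dim = c(ny, nx, length(pages)))
  for (i in seq_along(pages)) frames[, , i] <- pages[[i]]
  list(frames = frames, n_frames = length(pages), ny = ny, nx = nx)
}

#' Write and read trajectory tables
#'
#' Trajectories are stored as CSV with a schema-version comment line. The
#' table holds one row per (molecule, frame) with the fit columns empty on
#' undetected (dark) rows. Readers reject files with a newer major schema
#' version and report missing mandatory columns by name.
#'
#' @param tracks A trajectory data frame or a list of them (rows are
#'   concatenated).
#' @param path Output CSV path.
#' @return `write_trajectories` returns `path` invisibly; `read_trajectories`
#'   returns the validated data frame.
#' @export
write_trajectories <- function(tracks, path) {
  if (is.data.frame(tracks)) tracks <- list(tracks)
  df <- do.call(rbind, lapply(tracks, function(tr) {
    for (col in .trajectory_cols)
      if (!col %in% names(tr)) tr[[col]] <- rep(NA, nrow(tr))
    tr[, .trajectory_cols]
  }))
  .validate_trajectories(df)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# curtainr trajectory table v%s", TRAJECTORY_SCHEMA_VERSION), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectories
#' @export
read_trajectories <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  first <- readLines(path, n = 1)
  ver <- sub("^# curtainr trajectory table v", "", first)
  if (ver != first) {  # version line present
    major <- as.integer(strsplit(ver, ".", fixed = TRUE)[[1]][1])
    here <- as.integer(strsplit(TRAJECTORY_SCHEMA_VERSION, ".", fixed = TRUE)[[1]][1])
    if (is.finite(major) && major > here)
      stop(sprintf("trajectory table schema v%s is newer than supported v%s",
                   ver, TRAJECTORY_SCHEMA_VERSION))
  }
  df <- utils::read.csv(path, comment.char = "#")
  missing_cols <- setdiff(.trajectory_mandatory, names(df))
  if (length(missing_cols))
    stop(sprintf("trajectory table is missing mandatory column(s): %s",
                 paste(missing_cols, collapse = ", ")))
  .validate_trajectories(df)
  df
}

.validate_trajectories <- function(df) {
  key <- paste(df$molecule_id, df$frame)
  if (anyDuplicated(key))
    stop("invalid trajectory table: duplicated (molecule_id, frame) pairs")
  invisible(df)
}

#' Read roadblock/lesion annotations from a BED-like TSV
#'
#' Tab-separated columns: axis id, start bp, end bp, kind (no header). The
#' roadblock position is the interval midpoint and the zone halfwidth is half
#' the interval width.
#'
#' @param path Annotation file path.
#' @return A list of [roadblock()] objects.
#' @export
read_roadblocks <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("axis", "start_bp", "end_bp", "kind"),
                          stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i) {
    roadblock(id = sprintf("rb%d", i),
              position_bp = (df$start_bp[i] + df$end_bp[i]) / 2,
              kind = if (df$kind[i] %in% c("nucleosome", "restriction-enzyme",
                                           "protein")) df$kind[i] else "other",
              zone_halfwidth_bp = max((df$end_bp[i] - df$start_bp[i]) / 2, 1),
              axis_id = df$axis[i])
  })
}

# Polynomial rolling hash of the canonicalized config, for provenance stamps.
.config_hash <- function(config) {
  txt <- paste(utils::capture.output(utils::str(config)), collapse = "\n")
  h <- 0
  for (b in utf8ToInt(txt)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Load a pipeline run configuration
#'
#' The declarative run config is a single YAML file with nested sections
#' `geometry`, `optics`, `simulation`, `analysis`, `buffer`, plus top-level
#' `seed` and `output_dir`. Missing sections fall back to package defaults.
#' The full config (with its hash) is echoed into every output for
#' provenance.
#'
#' @param path YAML file path, or a named list already in config shape.
#' @return A list of class `run_config`.
#' @export
load_run_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  defaults <- list(geometry = list(), optics = list(), simulation = list(),
                   analysis = list(min_frames = 50L, n_lags = 10L,
                                   end_zone_bp = 1000),
                   buffer = list(), seed = 1L, output_dir = ".")
  for (nm in names(defaults)) {
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
    else if (is.list(defaults[[nm]]))
      for (k in names(defaults[[nm]]))
        if (is.null(cfg[[nm]][[k]])) cfg[[nm]][[k]] <- defaults[[nm]][[k]]
  }
  structure(cfg, class = "run_config")
}

#' Run the analysis pipeline on synthetic data
#'
#' Chains the stages of the synthetic study: `simulate` (population of
#' ground-truth trajectories rendered to measured trajectory tables),
#' `msd`/`dfit` (per-molecule diffusion coefficients and the population
#' summary), `ionic` (buffer ionic strength), `dwell` (dwell extraction and
#' survival fit), and `report` (JSON aggregation stamped with the seed and
#' config hash). Stages depend on their upstream outputs; requesting a stage
#' without its inputs is an error. Outputs are deterministic given the seed.
#'
#' @param config A `run_config` (see [load_run_config()]), or a path to one.
#' @param stages Character vector of stages to run, in pipeline order.
#' @return The report as a named list (also written to
#'   `<output_dir>/report.json` when `report` is among the stages).
#' @export
run_pipeline <- function(config,
                         stages = c("simulate", "msd", "dfit", "ionic",
                                    "dwell", "report")) {
  cfg <- if (inherits(config, "run_config")) config else load_run_config(config)
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  geom <- do.call(dna_geometry, cfg$geometry)
  report <- list(schema_version = "1.0", seed = cfg$seed,
                 config_hash = .config_hash(unclass(cfg)))
  tracks <- NULL
  estimates <- NULL

  if ("simulate" %in% stages) {
    sim_args <- cfg$simulation
    n_mol <- sim_args$n_molecules %||% 20L
    sim_args$n_molecules <- NULL
    sim_args$seed <- cfg$seed
    sc <- do.call(sim_config, sim_args)
    pop <- simulate_population(sc, n_mol, geom)
    tracks <- lapply(seq_along(pop), function(k)
      measure_trajectory(pop[[k]], molecule_id = k,
                         seed = (cfg$seed * 69621 + k) %% 2147483647))
    write_trajectories(tracks, file.path(cfg$output_dir, "trajectories.csv"))
    report$simulate <- list(n_molecules = n_mol,
                            n_frames = sc$n_frames,
                            frame_interval_s = sc$frame_interval_s)
  }

  if (any(c("msd", "dfit") %in% stages)) {
    if (is.null(tracks)) {
      tpath <- file.path(cfg$output_dir, "trajectories.csv")
      if (!file.exists(tpath))
        stop("msd/dfit require trajectories: run the simulate stage or provide trajectories.csv")
      df <- read_trajectories(tpath)
      tracks <- split(df, df$molecule_id)
    }
    kept <- filter_trajectories(tracks, cfg$analysis$min_frames)
    estimates <- lapply(kept, function(tr)
      fit_diffusion(compute_msd(tr, n_max = cfg$analysis$n_lags),
                    molecule_id = tr$molecule_id[1]))
    est_df <- do.call(rbind, lapply(estimates, function(e)
      data.frame(molecule_id = e$molecule_id, D_um2_s = e$D_um2_s,
                 intercept_um2 = e$intercept_um2, rmse_um2 = e$rmse_um2,
                 n_lags = e$n_lags)))
    utils::write.csv(est_df, file.path(cfg$output_dir, "diffusion_estimates.csv"),
                     row.names = FALSE)
    if ("dfit" %in% stages && length(estimates)) {
      summ <- summarize_population(estimates, label = "synthetic")
      utils::write.csv(summ, file.path(cfg$output_dir, "population_summary.csv"),
                       row.names = FALSE)
      report$diffusion <- list(mean_D_um2_s = summ$mean_D, sd_D_um2_s = summ$sd_D,
                               n = summ$n,
                               n_filtered_out = attr(kept, "n_removed"))
    }
  }

  if ("ionic" %in% stages) {
    buf_args <- cfg$buffer
    mode <- buf_args$mode %||% "consistent"
    buf_args$mode <- NULL
    buf <- do.call(buffer_composition, buf_args)
    isr <- total_ionic_strength(buf, mode = mode)
    report$ionic <- list(total_mM = isr$total_mM, mode = isr$mode,
                         contributions_mM = as.list(isr$contributions_mM))
  }

  if ("dwell" %in% stages) {
    t_half <- cfg$simulation$t_half_s %||% NA
    n_dwell <- cfg$analysis$n_dwells %||% 50L
    if (!is.finite(t_half))
      stop("dwell stage requires simulation$t_half_s in the config")
    dw <- simulate_dwell_times(t_half, n_dwell,
                               censor_at_s = cfg$analysis$censor_at_s %||% Inf,
                               seed = cfg$seed + 1L)
    fit <- fit_survival(dw)
    report$dwell <- list(half_life_s = fit$half_life_s, se_s = fit$se_s,
                         n = fit$n, n_events = fit$n_events, method = fit$method)
  }

  if ("report" %in% stages) {
    jsonlite::write_json(report, file.path(cfg$output_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
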