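#' Experiment configuration
#'
#' Collects everything one end-to-end run needs: the motor preset, the
#' number of binding events, acquisition overrides, analysis settings and a
#' mandatory seed. Settings precedence is argument > config file > preset
#' default.
#'
#' @param preset Preset name (see [curtain_presets()]).
#' @param n_events Number of binding events to simulate.
#' @param seed Integer seed (mandatory for simulation runs).
#' @param out_dir Output directory (`NULL` = do not write files).
#' @param acquisition Named list of [acquisition_params()] overrides.
#' @param mode Magenta-channel rendering mode; default inferred from the
#'   preset (`rpa` for `"rpa"`, `dmc1` for `"dmc1"`, otherwise `rad51`).
#' @param n_clusters RPA clusters per molecule.
#' @param bin_width Velocity histogram bin width (nt/s).
#' @param threshold_sd Spot-detection threshold.
#' @param max_jump_px,max_gap_frames,min_frames Linking settings.
#' @param min_run_nt Translocation classification threshold (nt).
#' @param coloc_threshold_nt Colocalization threshold (nt).
#' @param n_boot Bootstrap replicates for confidence intervals.
#' @param save_kymographs Write rendered kymographs as TIFF files.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(preset, n_events, seed,
                              out_dir = NULL,
                              acquisition = list(),
                              mode = NULL,
                              n_clusters = 9,
                              bin_width = 10,
                              threshold_sd = 5,
                              max_jump_px = 3,
                              max_gap_frames = 1,
                              min_frames = 3,
                              min_run_nt = NULL,
                              coloc_threshold_nt = 1000,
                              n_boot = 1000,
                              save_kymographs = TRUE) {
  if (missing(seed) || is.null(seed)) abort("`seed` is mandatory.")
  known <- curtain_presets()$name
  if (!preset %in% known) {
    abort(sprintf("unknown preset '%s'; available presets: %s",
                  preset, paste(known, collapse = ", ")))
  }
  acq <- do.call(acquisition_params, acquisition)
  structure(list(
    preset = preset, n_events = as.integer(n_events),
    seed = as.integer(seed), out_dir = out_dir, acq = acq,
    mode = mode %||% switch(preset, rpa = "rpa", dmc1 = "dmc1", "rad51"),
    n_clusters = n_clusters, bin_width = bin_width,
    threshold_sd = threshold_sd, max_jump_px = max_jump_px,
    max_gap_frames = max_gap_frames, min_frames = min_frames,
    min_run_nt = min_run_nt %||% (2 * acq$pixel_size_nt),
    coloc_threshold_nt = coloc_threshold_nt, n_boot = n_boot,
    save_kymographs = save_kymographs
  ), class = "experiment_config")
}

#' Read an experiment configuration from a YAML file
#'
#' The file may contain any [experiment_config()] argument; `acquisition`
#' is a nested mapping of [acquisition_params()] overrides.
#'
#' @param path YAML file path.
#' @param ... Overrides taking precedence over the file.
#' @return An `experiment_config`.
#' @examples
#' cfg <- read_experiment_config(
#'   system.file("extdata", "example-config.yaml", package = "curtainr"),
#'   n_events = 10)
#' @export
read_experiment_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  vals <- utils::modifyList(vals, list(...))
  do.call(experiment_config, vals)
}

#' Simulate, render and track one experiment
#'
#' Simulates `n_events` binding events (one molecule per event, each with
#' its own cluster landscape), renders a noisy two-colour kymograph per
#' molecule, detects and links spots in the green channel, and measures the
#' resulting trajectories. Returns everything downstream quantification
#' needs, plus the ground truth for validation.
#'
#' @param config An [experiment_config()].
#' @return A list: `ground_truth`, `trajectories` (measured, with
#'   `molecule_id`), `events`, `clusters`, `kymographs` (list, only when
#'   `config$save_kymographs`), `config`.
#' @export
simulate_and_track <- function(config) {
  acq <- config$acq
  preset <- motor_preset(config$preset)
  mol_len <- (acq$n_pixels - 1) * acq$pixel_size_nt
  recording_s <- (acq$n_frames - 1) * acq$frame_interval_s
  with_seed_if(config$seed, {
    out <- purrr::map(seq_len(config$n_events), function(m) {
      cl <- place_clusters(mol_len, config$n_clusters, molecule_id = m)
      gt <- simulate_trajectories(preset, 1L, clusters = cl,
                                  molecule_length_nt = mol_len,
                                  recording_s = recording_s,
                                  molecule_id = m)
      ky <- render_kymograph(gt, acq, clusters = cl, mode = config$mode,
                             direction = preset$direction)
      spots <- detect_spots(ky, "green", threshold_sd = config$threshold_sd)
      linked <- link_spots(spots, max_jump_px = config$max_jump_px,
                           max_gap_frames = config$max_gap_frames,
                           min_frames = config$min_frames)
      meas <- measure_trajectories(linked, acq, min_frames = config$min_frames,
                                   min_run_nt = config$min_run_nt)
      if (nrow(meas) > 0) meas$molecule_id <- m
      ev <- classify_events(meas, cl,
                            coloc_threshold_nt = config$coloc_threshold_nt,
                            molecule_id = m)
      list(gt = gt, cl = cl, meas = meas, ev = ev,
           ky = if (isTRUE(config$save_kymographs)) ky else NULL)
    })
    list(
      ground_truth = dplyr::bind_rows(purrr::map(out, "gt")),
      trajectories = dplyr::bind_rows(purrr::map(out, "meas")),
      events = dplyr::bind_rows(purrr::map(out, "ev")),
      clusters = dplyr::bind_rows(purrr::map(out, "cl")),
      kymographs = purrr::compact(purrr::map(out, "ky")),
      config = config
    )
  })
}

#' Quantify measured trajectories and events
#'
#' Runs the full statistics layer on a table of measured trajectories:
#' Gaussian velocity fit on translocating trajectories (detection floor 5
#' nt/s, the simulator's velocity floor), survival half-life on the
#' detection-floor-corrected excess run lengths of all trajectories,
#' colocalization fraction, and events per molecule. Fits that cannot be
#' computed (too few observations, no translocation) are reported as `NULL`
#' with an explanatory flag.
#'
#' @param trajectories Measured trajectory tibble ([measure_trajectories()]).
#' @param events Optional binding-event tibble ([classify_events()]).
#' @param config An [experiment_config()] (for bin width, bootstrap reps,
#'   seed).
#' @return A list: `velocity_fit`, `survival_fit`, `coloc`, `events_summary`,
#'   `flags` (character vector of conditions such as
#'   `"no translocation events"`).
#' @export
quantify_experiment <- function(trajectories, events = NULL, config) {
  flags <- character()
  # velocity sample: every tracked trajectory moving at or above the
  # detection floor; static binders fall below it and drop out naturally
  vel <- trajectories$velocity_nt_s[trajectories$velocity_nt_s >= 5]
  if (sum(trajectories$translocating) == 0) vel <- numeric()
  velocity_fit <- NULL
  if (length(vel) >= 10) {
    velocity_fit <- tryCatch(
      fit_velocity_gaussian(vel, bin_width = config$bin_width,
                            detection_floor = 5),
      error = function(e) {
        # degenerate histogram: fall back to descriptive raw moments
        flags <<- c(flags, conditionMessage(e))
        structure(list(
          mean_nt_s = mean(vel), sd_nt_s = sd(vel), amplitude = NA_real_,
          bin_width_nt_s = config$bin_width, detection_floor = 5,
          n = length(vel), histogram = NULL, method = "moments",
          converged = FALSE), class = "gaussian_fit")
      })
  } else if (length(vel) == 0) {
    flags <- c(flags, "no translocation events")
  } else {
    flags <- c(flags, sprintf("only %d translocating trajectories; no velocity fit",
                              length(vel)))
  }
  survival_fit <- NULL
  runs <- trajectories$excess_run_nt[trajectories$translocating |
                                       trajectories$run_length_nt > 0]
  runs <- runs[runs > 0]
  if (length(vel) > 0 && length(runs) >= 10) {
    survival_fit <- tryCatch(
      fit_survival_halflife(runs, n_boot = config$n_boot,
                            seed = config$seed + 1L),
      error = function(e) { flags <<- c(flags, conditionMessage(e)); NULL })
  }
  # Detection-selection correction for the velocity mean: an event is only
  # tracked if its run lasts min_frames sampled frames, which for a uniform
  # binding phase means a duration threshold of (min_frames - 0.5) frame
  # intervals on average, i.e. observation probability exp(-lambda * v) with
  # lambda = (min_frames - 0.5) * dt * ln2 / half-life. Tilting a Gaussian
  # by exp(-lambda * v) shifts its mean by -lambda * sigma^2 and leaves
  # sigma unchanged, so the fitted mean is debiased by adding
  # lambda * sigma_hat^2.
  if (!is.null(velocity_fit) && identical(velocity_fit$method, "histogram") &&
      !is.null(survival_fit)) {
    lambda <- (config$min_frames - 0.5) * config$acq$frame_interval_s *
      log(2) / (survival_fit$halflife_knt * 1000)
    velocity_fit$mean_raw_nt_s <- velocity_fit$mean_nt_s
    velocity_fit$selection_shift_nt_s <- lambda * velocity_fit$sd_nt_s^2
    velocity_fit$mean_nt_s <- velocity_fit$mean_nt_s +
      velocity_fit$selection_shift_nt_s
  }
  coloc <- NULL
  if (!is.null(events) && nrow(events) > 0) {
    coloc <- coloc_fraction(events, n_boot = config$n_boot,
                            seed = config$seed + 2L)
  }
  events_summary <- NULL
  if (!is.null(events) && nrow(events) > 0) {
    events_summary <- events_per_molecule(events, config$n_events)
  }
  list(velocity_fit = velocity_fit, survival_fit = survival_fit,
       coloc = coloc, events_summary = events_summary, flags = flags)
}

#' Run the full pipeline from a configuration
#'
#' simulate -> render -> track -> quantify -> report. When `out_dir` is set,
#' writes a deterministic bundle: `ground_truth.csv`, `trajectories.csv`,
#' `events.csv`, `kymographs/*.tif` (+ JSON sidecars), `report.json` and
#' `log.txt`. `report.json` contains every estimate with its confidence
#' interval, the sample sizes, the settings, and the configuration echoed
#' verbatim; it contains no timestamps, so identical configurations produce
#' byte-identical reports.
#'
#' @param config An [experiment_config()] or the path to a YAML file for
#'   [read_experiment_config()].
#' @return The report, invisibly as a list, with the tracked tables attached
#'   in `$tables`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_experiment_config(config)
  run <- simulate_and_track(config)
  q <- quantify_experiment(run$trajectories, run$events, config)
  report <- build_report(q, run, config)
  if (!is.null(config$out_dir)) {
    write_bundle(run, report, config)
  }
  report$tables <- list(ground_truth = run$ground_truth,
                        trajectories = run$trajectories,
                        events = run$events)
  invisible(report)
}

#' Re-analyse previously tracked data
#'
#' Skips simulation and tracking: reads a measured-trajectory table (and
#' optionally an event table) from a prior run or an external source and
#' runs the quantification layer, producing the same report structure as
#' [run_pipeline()]. An empty trajectory table yields a report with `n = 0`
#' and no fits, with a warning rather than an error.
#'
#' @param config An [experiment_config()].
#' @param trajectories Path to a `trajectories.csv` or a tibble.
#' @param events Optional path to an `events.csv` or a tibble.
#' @return The report list, invisibly.
#' @export
run_analysis_only <- function(config, trajectories, events = NULL) {
  if (is.character(trajectories)) {
    trajectories <- read_curtain_table(
      trajectories,
      required = c("run_length_nt", "excess_run_nt", "velocity_nt_s",
                   "duration_s", "translocating"))
  }
  if (is.character(events)) {
    events <- read_curtain_table(events,
                                 required = c("position_nt", "colocalized"))
  }
  if (nrow(trajectories) == 0) {
    warn("empty trajectory table; report contains no fits.")
    q <- list(velocity_fit = NULL, survival_fit = NULL, coloc = NULL,
              events_summary = NULL, flags = "empty trajectory table")
  } else {
    q <- quantify_experiment(trajectories, events, config)
  }
  run <- list(ground_truth = tibble::tibble(), trajectories = trajectories,
              events = events %||% tibble::tibble(), clusters = tibble::tibble(),
              kymographs = list(), config = config)
  report <- build_report(q, run, config)
  if (!is.null(config$out_dir)) write_bundle(run, report, config, tables_only = TRUE)
  invisible(report)
}

build_report <- function(q, run, config) {
  cfg_echo <- unclass(config)
  cfg_echo$acq <- unclass(cfg_echo$acq)
  cfg_echo$out_dir <- NULL
  transl <- run$trajectories$translocating %||% logical()
  list(
    preset = config$preset,
    n_events_simulated = config$n_events,
    n_trajectories = nrow(run$trajectories),
    n_translocating = sum(as.logical(transl)),
    velocity = if (!is.null(q$velocity_fit)) glance(q$velocity_fit),
    processivity = if (!is.null(q$survival_fit)) glance(q$survival_fit),
    colocalization = if (!is.null(q$coloc)) glance(q$coloc),
    events_per_molecule = q$events_summary,
    flags = q$flags,
    config = cfg_echo
  )
}

write_bundle <- function(run, report, config, tables_only = FALSE) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(config$out_dir, ...)
  write_curtain_table(run$trajectories, p("trajectories.csv"))
  write_curtain_table(run$events, p("events.csv"))
  if (!tables_only) {
    write_curtain_table(run$ground_truth, p("ground_truth.csv"))
    if (length(run$kymographs) > 0) {
      dir.create(p("kymographs"), showWarnings = FALSE)
      for (ky in run$kymographs) {
        for (ch in names(ky$channels)) {
          st <- structure(list(ky$channels[[ch]]), class = "curtain_stack",
                          frame_interval_s = ky$acq$frame_interval_s,
                          pixel_size_nt = ky$acq$pixel_size_nt)
          write_stack(st, p("kymographs",
                            sprintf("mol%04d_%s.tif", ky$molecule_id, ch)))
        }
      }
    }
  }
  rep_out <- report
  rep_out$tables <- NULL
  jsonlite::write_json(rep_out, p("report.json"), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  log_lines <- c(
    sprintf("preset=%s n_events=%d seed=%d", config$preset, config$n_events,
            config$seed),
    sprintf("trajectories=%d translocating=%d events=%d",
            nrow(run$trajectories),
            sum(as.logical(run$trajectories$translocating %||% logical())),
            nrow(run$events)),
    if (length(report$flags) > 0) paste("flag:", report$flags)
  )
  writeLines(log_lines, p("log.txt"))
  invisible(config$out_dir)
}
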