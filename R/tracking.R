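#' Detect fluorescent spots in a kymograph channel
#'
#' Per frame, finds local intensity maxima exceeding the background mean plus
#' `threshold_sd` background standard deviations, then refines each position
#' to sub-pixel precision by an intensity-weighted centroid over a +/- 2 px
#' window (background-subtracted, negative weights clipped). Background
#' statistics are estimated robustly from the whole channel (median and MAD),
#' which is safe because spots occupy a small fraction of the pixels.
#' Detection is deterministic for a fixed input.
#'
#' @param kymograph A [new_kymograph()] object.
#' @param channel Channel name to search.
#' @param threshold_sd Detection threshold in background standard deviations.
#' @return A tibble of spots: `frame` (0-based), `position_px` (sub-pixel),
#'   `position_nt`, `intensity` (background-subtracted window sum),
#'   `channel`. Empty result allowed.
#' @examples
#' acq <- acquisition_params(n_frames = 3, n_pixels = 40,
#'   background_photons = 0, read_noise_sd = 0)
#' tr <- tibble::tibble(id = 1L, molecule_id = 1L, x0_nt = 10300, t0_s = 0,
#'   v_nt_s = 0, run_nt = 0, t_end_s = 30, channel = 0L, coloc = FALSE)
#' ky <- render_kymograph(tr, acq, mode = "dmc1", noise = FALSE)
#' detect_spots(ky, "green")
#' @export
detect_spots <- function(kymograph, channel = "green", threshold_sd = 5) {
  m <- kymograph$channels[[channel]]
  if (is.null(m)) abort(sprintf("channel '%s' not present.", channel))
  bg_mean <- median(m)
  bg_sd <- max(mad(m), 1e-9)
  thr <- bg_mean + threshold_sd * bg_sd
  nf <- nrow(m); np <- ncol(m)
  # local maxima: strictly above left neighbour, at least right neighbour
  left <- cbind(-Inf, m[, -np, drop = FALSE])
  right <- cbind(m[, -1, drop = FALSE], -Inf)
  is_peak <- (m > thr) & (m > left) & (m >= right)
  idx <- which(is_peak, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    return(tibble::tibble(frame = integer(), position_px = double(),
                          position_nt = double(), intensity = double(),
                          channel = character()))
  }
  # vectorised centroid over a +/-2 px window
  offs <- -2:2
  win <- vapply(offs, function(o) {
    j <- pmin(pmax(idx[, 2] + o, 1L), np)
    m[cbind(idx[, 1], j)]
  }, numeric(nrow(idx)))
  win <- pmax(win - bg_mean, 0)
  jc <- vapply(offs, function(o) pmin(pmax(idx[, 2] + o, 1L), np),
               numeric(nrow(idx)))
  if (nrow(idx) == 1) { win <- matrix(win, 1); jc <- matrix(jc, 1) }
  tot <- rowSums(win)
  pos_px <- rowSums(win * (jc - 1)) / tot # pixel j at coordinate j (0-based)
  out <- tibble::tibble(
    frame = as.integer(idx[, 1] - 1L),
    position_px = pos_px,
    position_nt = pos_px * kymograph$acq$pixel_size_nt,
    intensity = tot,
    channel = channel
  )
  dplyr::arrange(out, .data$frame, .data$position_px)
}

#' Link detected spots into trajectories
#'
#' Greedy nearest-neighbour frame-to-frame linking: spots in each frame are
#' matched to the closest open trajectory end within `max_jump_px`;
#' trajectories missing a spot for up to `max_gap_frames` frames stay open
#' (gaps are bridged); unmatched spots open new trajectories. Each spot
#' belongs to at most one trajectory. Trajectories with fewer than
#' `min_frames` spots are discarded. Greedy assignment is deterministic but
#' order-dependent where tracks cross; crossing tracks are outside the
#' sparse-binding regime this is designed for.
#'
#' @param spots Tibble from [detect_spots()], sorted by frame.
#' @param max_jump_px Maximum frame-to-frame displacement, pixels.
#' @param max_gap_frames Maximum bridged gap, frames.
#' @param min_frames Minimum spots per kept trajectory.
#' @return The input spots with a `traj_id` column, restricted to spots that
#'   belong to a kept trajectory.
#' @export
link_spots <- function(spots, max_jump_px = 3, max_gap_frames = 1,
                       min_frames = 3) {
  if (nrow(spots) == 0) {
    return(dplyr::mutate(spots, traj_id = integer()))
  }
  spots <- dplyr::arrange(spots, .data$frame, .data$position_px)
  n <- nrow(spots)
  traj_of <- integer(n)
  # open trajectory ends
  end_frame <- integer(0); end_pos <- double(0); end_traj <- integer(0)
  next_id <- 1L
  for (f in sort(unique(spots$frame))) {
    rows <- which(spots$frame == f)
    open <- which(f - end_frame >= 1 & f - end_frame <= max_gap_frames + 1)
    pos <- spots$position_px[rows]
    taken_spot <- rep(FALSE, length(rows))
    taken_open <- rep(FALSE, length(open))
    if (length(open) > 0) {
      d <- abs(outer(pos, end_pos[open], "-"))
      repeat {
        k <- which(d == min(d), arr.ind = TRUE)[1, , drop = TRUE]
        if (!is.finite(d[k[1], k[2]]) || d[k[1], k[2]] > max_jump_px) break
        i <- rows[k[1]]; o <- open[k[2]]
        traj_of[i] <- end_traj[o]
        end_frame[o] <- f; end_pos[o] <- spots$position_px[i]
        taken_spot[k[1]] <- TRUE; taken_open[k[2]] <- TRUE
        d[k[1], ] <- Inf; d[, k[2]] <- Inf
        if (all(taken_spot) || all(taken_open)) break
      }
    }
    for (k in which(!taken_spot)) {
      i <- rows[k]
      traj_of[i] <- next_id
      end_frame <- c(end_frame, f); end_pos <- c(end_pos, spots$position_px[i])
      end_traj <- c(end_traj, next_id)
      next_id <- next_id + 1L
    }
  }
  spots$traj_id <- traj_of
  keep <- names(which(table(traj_of) >= min_frames))
  dplyr::filter(spots, .data$traj_id %in% as.integer(keep))
}

#' Measure trajectories: run length, duration, velocity, direction
#'
#' Summarises linked spots per trajectory. Velocity is the end-to-end
#' displacement over the elapsed time (matching distance-versus-time
#' measurement on a kymograph), not a regression slope; see
#' [measure_trajectories_slope()] for the regression alternative. The run
#' length is the absolute displacement converted to nucleotides; `censored`
#' flags trajectories still present in the final frame or reaching the
#' tether, whose runs are lower bounds. `excess_run_nt` is the run length in
#' excess of the trajectory's detection floor
#' (`(min_frames - 1) * frame_interval_s * velocity`): a trajectory must last
#' `min_frames` frames to be detected at all, and for exponentially
#' distributed run lengths the excess over that floor follows the same
#' exponential law (memorylessness), so survival analysis of the excess is
#' free of detection-floor bias.
#'
#' @param linked Spots with `traj_id`, from [link_spots()].
#' @param acq An [acquisition_params()] object.
#' @param min_frames The linking threshold used (for the detection floor).
#' @param min_run_nt Minimum run length to classify a trajectory as
#'   translocating (default two pixels).
#' @return One row per trajectory: `traj_id`, `channel`, `n_spots`,
#'   `t_start_s`, `t_end_s`, `duration_s`, `x_start_nt`, `x_end_nt`,
#'   `run_length_nt`, `excess_run_nt`, `velocity_nt_s`, `direction_sign`,
#'   `translocating`, `censored`.
#' @export
measure_trajectories <- function(linked, acq, min_frames = 3,
                                 min_run_nt = 2 * acq$pixel_size_nt) {
  if (nrow(linked) == 0) {
    return(tibble::tibble(
      traj_id = integer(), channel = character(), n_spots = integer(),
      t_start_s = double(), t_end_s = double(), duration_s = double(),
      x_start_nt = double(), x_end_nt = double(), run_length_nt = double(),
      excess_run_nt = double(), velocity_nt_s = double(),
      direction_sign = double(), translocating = logical(),
      censored = logical()))
  }
  px <- acq$pixel_size_nt; dt <- acq$frame_interval_s
  out <- linked |>
    dplyr::group_by(.data$traj_id) |>
    dplyr::arrange(.data$frame, .by_group = TRUE) |>
    dplyr::summarise(
      channel = dplyr::first(.data$channel),
      n_spots = dplyr::n(),
      frame_first = dplyr::first(.data$frame),
      frame_last = dplyr::last(.data$frame),
      x_start_nt = dplyr::first(.data$position_px) * px,
      x_end_nt = dplyr::last(.data$position_px) * px,
      .groups = "drop"
    ) |>
    dplyr::filter(.data$frame_last > .data$frame_first) |>
    dplyr::mutate(
      t_start_s = .data$frame_first * dt,
      t_end_s = .data$frame_last * dt,
      duration_s = (.data$frame_last - .data$frame_first) * dt,
      run_length_nt = abs(.data$x_end_nt - .data$x_start_nt),
      velocity_nt_s = .data$run_length_nt / .data$duration_s,
      direction_sign = sign(.data$x_end_nt - .data$x_start_nt),
      excess_run_nt = pmax(
        .data$run_length_nt - (min_frames - 1) * dt * .data$velocity_nt_s, 0),
      translocating = .data$run_length_nt >= min_run_nt,
      censored = .data$frame_last >= acq$n_frames - 1L |
        pmin(.data$x_end_nt, .data$x_start_nt) <= px
    ) |>
    dplyr::select(-"frame_first", -"frame_last")
  dplyr::relocate(out, "traj_id", "channel", "n_spots", "t_start_s",
                  "t_end_s", "duration_s", "x_start_nt", "x_end_nt",
                  "run_length_nt", "excess_run_nt", "velocity_nt_s",
                  "direction_sign", "translocating", "censored")
}

#' Regression-slope velocity estimator
#'
#' Alternative velocity estimate: the absolute slope of an ordinary
#' least-squares fit of position against time over all spots of a
#' trajectory. On constant-velocity tracks it agrees with the end-to-end
#' estimator to within a few percent.
#'
#' @inheritParams measure_trajectories
#' @return A tibble `traj_id`, `velocity_slope_nt_s`.
#' @export
measure_trajectories_slope <- function(linked, acq) {
  linked |>
    dplyr::group_by(.data$traj_id) |>
    dplyr::summarise(
      velocity_slope_nt_s = abs(
        coef(lm(position_nt ~ I(frame * acq$frame_interval_s),
                data = dplyr::pick(dplyr::everything())))[2]),
      .groups = "drop")
}

#' Classify binding events and their cluster colocalization
#'
#' Each green-channel trajectory defines one binding event at its starting
#' position. The event is `colocalized` when the distance to the nearest
#' cluster centre is at most `coloc_threshold_nt` (default one pixel, the
#' optical resolution), and `translocating` when its run length reaches
#' `min_run_nt`. An empty cluster set yields all events non-colocalized.
#'
#' @param trajectories Measured trajectories ([measure_trajectories()]), or
#'   any tibble with `x_start_nt`, `t_start_s` and optionally
#'   `translocating`.
#' @param clusters Cluster tibble ([place_clusters()]) from the magenta
#'   channel (detected or ground truth); may be empty.
#' @param coloc_threshold_nt Colocalization distance threshold.
#' @param molecule_id Identifier copied into the output.
#' @return A tibble of binding events: `molecule_id`, `position_nt`,
#'   `t_start_s`, `colocalized`, `translocating`.
#' @export
classify_events <- function(trajectories, clusters,
                            coloc_threshold_nt = 1000,
                            molecule_id = 1L) {
  if (nrow(trajectories) == 0) {
    return(tibble::tibble(molecule_id = integer(), position_nt = double(),
                          t_start_s = double(), colocalized = logical(),
                          translocating = logical()))
  }
  pos <- trajectories$x_start_nt
  if (is.null(clusters) || nrow(clusters) == 0) {
    colo <- rep(FALSE, length(pos))
  } else {
    dmin <- vapply(pos, function(p) min(abs(clusters$position_nt - p)),
                   numeric(1))
    colo <- dmin <= coloc_threshold_nt
  }
  tibble::tibble(
    molecule_id = trajectories$molecule_id %||% molecule_id,
    position_nt = pos,
    t_start_s = trajectories$t_start_s,
    colocalized = colo,
    translocating = trajectories$translocating %||% rep(NA, length(pos))
  )
}
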