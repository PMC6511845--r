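#' Place RPA clusters along an ssDNA molecule
#'
#' Draws cluster centres uniformly along the molecule, emulating the random
#' placement of RPA patches embedded between adjacent recombinase filaments.
#'
#' @param molecule_length_nt Length of the ssDNA molecule in nucleotides.
#' @param n_clusters Number of clusters to place (may be 0).
#' @param seed Optional integer seed; fixed seeds give identical placements.
#' @param molecule_id Identifier copied into the output.
#' @param width_nt Apparent cluster width (sd of its fluorescent footprint).
#' @param intensity Relative cluster brightness (1 = one spot equivalent).
#'
#' @return A tibble with columns `molecule_id`, `cluster_id`, `position_nt`,
#'   `width_nt`, `intensity`, sorted by position.
#' @examples
#' place_clusters(50000, 5, seed = 1)
#' @export
place_clusters <- function(molecule_length_nt, n_clusters, seed = NULL,
                           molecule_id = 1L, width_nt = 300, intensity = 1) {
  stopifnot_scalar_number(molecule_length_nt, "molecule_length_nt", min = 0,
                          strict = TRUE)
  stopifnot_scalar_number(n_clusters, "n_clusters", min = 0)
  n_clusters <- as.integer(n_clusters)
  pos <- with_seed_if(seed, runif(n_clusters, 0, molecule_length_nt))
  tibble::tibble(
    molecule_id = molecule_id,
    cluster_id = seq_len(n_clusters),
    position_nt = sort(pos),
    width_nt = width_nt,
    intensity = intensity
  )
}

#' Simulate ground-truth binding and translocation events
#'
#' Generates one row per binding event. With probability `p_coloc` the event
#' initiates at a cluster centre (uniformly chosen among clusters), otherwise
#' uniformly along the molecule. Per-event velocities are drawn from a
#' Gaussian truncated below at the preset's detection floor `v_min_nt_s`, and
#' run lengths from an exponential distribution with half-life
#' `halflife_knt * 1000` nucleotides (decay rate `log(2) / (halflife_knt *
#' 1000)`). Binding times are uniform over the first half of the recording so
#' that most runs complete within the observation window. Runs are clipped at
#' the molecule boundary. Translocation-incompetent presets yield static
#' events (`v_nt_s = 0`, `run_nt = 0`) that persist to the end of the
#' recording.
#'
#' @param preset A [motor_preset()].
#' @param n_events Number of binding events to generate.
#' @param clusters Cluster tibble from [place_clusters()], or `NULL`.
#' @param molecule_length_nt Molecule length in nucleotides.
#' @param recording_s Recording duration in seconds.
#' @param seed Optional integer seed.
#' @param molecule_id Identifier copied into the output.
#'
#' @return A tibble with one row per event: `id`, `molecule_id`, `x0_nt`,
#'   `t0_s`, `v_nt_s`, `run_nt`, `t_end_s`, `channel` (0 = green), `coloc`.
#' @examples
#' tr <- simulate_trajectories(motor_preset("rad51"), 10, seed = 1)
#' @export
simulate_trajectories <- function(preset, n_events,
                                  clusters = NULL,
                                  molecule_length_nt = 150000,
                                  recording_s = 1500,
                                  seed = NULL,
                                  molecule_id = 1L) {
  validate_motor_preset(preset)
  stopifnot_scalar_number(n_events, "n_events", min = 0)
  n_events <- as.integer(n_events)
  if (n_events == 0L) {
    return(tibble::tibble(
      id = integer(), molecule_id = integer(), x0_nt = double(),
      t0_s = double(), v_nt_s = double(), run_nt = double(),
      t_end_s = double(), channel = integer(), coloc = logical()))
  }
  p_coloc <- preset$p_coloc
  have_clusters <- !is.null(clusters) && nrow(clusters) > 0
  if (p_coloc > 0 && !have_clusters) {
    warn("`p_coloc` > 0 but no clusters supplied; binding positions fall back to uniform.")
    p_coloc <- 0
  }
  with_seed_if(seed, {
    coloc <- runif(n_events) < p_coloc
    x0 <- runif(n_events, 0, molecule_length_nt)
    if (any(coloc)) {
      x0[coloc] <- sample(clusters$position_nt, sum(coloc), replace = TRUE)
    }
    t0 <- runif(n_events, 0, recording_s / 2)
    if (preset$translocation_competent) {
      v <- rtrunc_norm(n_events, preset$v_mean_nt_s, preset$v_sd_nt_s,
                       preset$v_min_nt_s)
      run <- rexp(n_events, rate = log(2) / (preset$halflife_knt * 1000))
      # clip at the molecule boundary in the direction of travel
      room <- if (preset$direction < 0) x0 else molecule_length_nt - x0
      run <- pmin(run, room)
      t_end <- pmin(t0 + run / v, recording_s)
      run <- pmin(run, v * (recording_s - t0))
    } else {
      v <- rep(0, n_events)
      run <- rep(0, n_events)
      t_end <- rep(recording_s, n_events)
    }
    tibble::tibble(
      id = seq_len(n_events), molecule_id = molecule_id,
      x0_nt = x0, t0_s = t0, v_nt_s = v, run_nt = run, t_end_s = t_end,
      channel = 0L, coloc = coloc)
  })
}

# Gaussian truncated below at `lo`, by rejection (exact).
rtrunc_norm <- function(n, mean, sd, lo) {
  if (sd == 0) return(rep(max(mean, lo), n))
  v <- rnorm(n, mean, sd)
  while (any(bad <- v < lo)) v[bad] <- rnorm(sum(bad), mean, sd)
  v
}

#' Simulate a curtain of molecules
#'
#' Draws a Poisson number of binding events (mean `preset$binding_rate`) for
#' each of `n_molecules` molecules, places a cluster landscape per molecule,
#' and simulates ground-truth trajectories for each. Molecules with zero
#' events are retained (they matter for events-per-molecule statistics).
#'
#' @inheritParams simulate_trajectories
#' @param n_molecules Number of ssDNA molecules observed.
#' @param n_clusters Clusters per molecule.
#' @param seed Optional integer seed.
#'
#' @return A list with `trajectories` (tibble over all molecules),
#'   `clusters` (tibble over all molecules) and `n_molecules`.
#' @examples
#' cur <- simulate_curtain(motor_preset("rad51"), n_molecules = 5, seed = 1)
#' @export
simulate_curtain <- function(preset, n_molecules,
                             molecule_length_nt = 150000,
                             recording_s = 1500,
                             n_clusters = 9,
                             seed = NULL) {
  validate_motor_preset(preset)
  with_seed_if(seed, {
    counts <- rpois(n_molecules, preset$binding_rate)
    out <- purrr::map(seq_len(n_molecules), function(m) {
      cl <- place_clusters(molecule_length_nt, n_clusters, molecule_id = m)
      tr <- simulate_trajectories(preset, counts[m], clusters = cl,
                                  molecule_length_nt = molecule_length_nt,
                                  recording_s = recording_s, molecule_id = m)
      list(clusters = cl, trajectories = tr)
    })
    list(
      trajectories = dplyr::bind_rows(purrr::map(out, "trajectories")),
      clusters = dplyr::bind_rows(purrr::map(out, "clusters")),
      n_molecules = n_molecules
    )
  })
}

#' Simulate an ATP-hydrolysis time course
#'
#' Models the hydrolysed ATP fraction as a linear early regime saturating at
#' 1: `frac(t) = min(1, kcat_s * enzyme_conc * t / atp_conc)`, plus optional
#' Gaussian noise, clipped to `[0, 1]`.
#'
#' @param kcat_s Catalytic turnover number, ATP per enzyme per second.
#' @param enzyme_conc Enzyme concentration (molar).
#' @param atp_conc ATP concentration (molar). Must be positive.
#' @param times_s Sampling times in seconds (strictly increasing, >= 0).
#' @param noise_sd Gaussian noise sd on each fraction (0 = noise-free).
#' @param seed Optional integer seed.
#'
#' @return A tibble with columns `time_s`, `frac_hydrolyzed`, and attributes
#'   `enzyme_conc`, `atp_conc`.
#' @examples
#' simulate_atpase(256, 1e-9, 2e-3, times_s = seq(0, 500, by = 100))
#' @export
simulate_atpase <- function(kcat_s, enzyme_conc, atp_conc, times_s,
                            noise_sd = 0, seed = NULL) {
  stopifnot_scalar_number(kcat_s, "kcat_s", min = 0)
  stopifnot_scalar_number(enzyme_conc, "enzyme_conc", min = 0)
  stopifnot_scalar_number(atp_conc, "atp_conc", min = 0, strict = TRUE)
  if (any(diff(times_s) <= 0) || any(times_s < 0)) {
    abort("`times_s` must be nonnegative and strictly increasing.")
  }
  frac <- pmin(1, kcat_s * enzyme_conc * times_s / atp_conc)
  if (noise_sd > 0) {
    frac <- with_seed_if(seed, pmin(1, pmax(0, frac + rnorm(length(frac), 0, noise_sd))))
  }
  out <- tibble::tibble(time_s = times_s, frac_hydrolyzed = frac)
  attr(out, "enzyme_conc") <- enzyme_conc
  attr(out, "atp_conc") <- atp_conc
  out
}
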