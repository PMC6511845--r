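#' Acquisition parameters for a curtain recording
#'
#' Bundles the imaging geometry and camera model shared by the simulator and
#' the analysis chain. Defaults describe shuttered two-colour TIRF imaging of
#' tethered ssDNA at 1 frame per 10 s with 200 ms integration and a spatial
#' conversion of 1000 nucleotides per pixel. The inter-channel shutter offset
#' (100 ms) is carried as metadata only: at a 10 s cadence the two channels
#' are treated as synchronous.
#'
#' @param frame_interval_s Seconds between consecutive frames.
#' @param integration_s Camera exposure per frame, seconds. Must be smaller
#'   than `frame_interval_s`.
#' @param shutter_offset_s Timing offset between the two colour channels,
#'   seconds (metadata only).
#' @param pixel_size_nt Nucleotides of ssDNA imaged per camera pixel.
#' @param psf_sigma_px Standard deviation of the Gaussian point-spread
#'   function, in pixels.
#' @param photons_per_spot Mean photons collected from one fluorescent spot
#'   per frame.
#' @param background_photons Mean background photons per pixel per frame.
#' @param read_noise_sd Standard deviation of additive Gaussian camera read
#'   noise, in photon-equivalent counts.
#' @param n_frames Frames per recording.
#' @param n_pixels Pixels along the molecule's long axis.
#'
#' @return An object of class `acq_params` (a named list).
#' @examples
#' acq <- acquisition_params()
#' acq$n_frames * acq$frame_interval_s # recording length in seconds
#' @export
acquisition_params <- function(frame_interval_s = 10,
                               integration_s = 0.2,
                               shutter_offset_s = 0.1,
                               pixel_size_nt = 1000,
                               psf_sigma_px = 1.0,
                               photons_per_spot = 200,
                               background_photons = 5,
                               read_noise_sd = 2,
                               n_frames = 150,
                               n_pixels = 150) {
  acq <- list(
    frame_interval_s = frame_interval_s,
    integration_s = integration_s,
    shutter_offset_s = shutter_offset_s,
    pixel_size_nt = pixel_size_nt,
    psf_sigma_px = psf_sigma_px,
    photons_per_spot = photons_per_spot,
    background_photons = background_photons,
    read_noise_sd = read_noise_sd,
    n_frames = as.integer(n_frames),
    n_pixels = as.integer(n_pixels)
  )
  for (f in c("frame_interval_s", "integration_s", "pixel_size_nt",
              "psf_sigma_px", "n_frames", "n_pixels")) {
    stopifnot_scalar_number(acq[[f]], f, min = 0, strict = TRUE)
  }
  for (f in c("shutter_offset_s", "photons_per_spot", "background_photons",
              "read_noise_sd")) {
    stopifnot_scalar_number(acq[[f]], f, min = 0)
  }
  if (acq$frame_interval_s <= acq$integration_s) {
    abort("`frame_interval_s` must be larger than `integration_s`.")
  }
  structure(acq, class = "acq_params")
}

#' @export
print.acq_params <- function(x, ...) {
  cat("<acq_params>", sprintf(
    "%d frames x %d px | %g s/frame (%g s integration) | %g nt/px | PSF sd %g px",
    x$n_frames, x$n_pixels, x$frame_interval_s, x$integration_s,
    x$pixel_size_nt, x$psf_sigma_px), "\n")
  invisible(x)
}

# Built-in experimental conditions. Velocities (mean +/- sd, nt/s) and
# run-length half-lives (knt) are the values measured for GFP-Sgs1 on each
# ssDNA substrate; the str condition carries a 3-fold velocity reduction
# relative to the rad51 condition and a provisional half-life, and the dmc1
# condition is binding-attenuated (12-fold) and translocation-incompetent.
motor_preset_table <- function() {
  tibble::tribble(
    ~name,    ~v_mean_nt_s, ~v_sd_nt_s, ~halflife_knt, ~binding_rate, ~p_coloc, ~translocation_competent,
    "rpa",    47,           37,         5.2,           3,             0,        TRUE,
    "rad51",  29,           29,         4.1,           3,             0.79,     TRUE,
    "i345t",  23,           18,         3.9,           3,             0.79,     TRUE,
    "k191r",  34,           16,         4.2,           3,             0.79,     TRUE,
    "str",    29 / 3,       29 / 3,     2.9,           3,             0.79,     TRUE,
    "dmc1",   0,            0,          4.1,           3 / 12,        0,        FALSE
  )
}

#' Motor presets: named parameter sets for experimental conditions
#'
#' A `motor_preset` collects the translocation statistics and binding
#' behaviour of one experimental condition: the Gaussian velocity
#' distribution (truncated below at the practical detection floor), the
#' exponential run-length half-life, the expected number of binding events
#' per molecule per recording, the probability that binding initiates at an
#' RPA cluster, and the direction of travel (-1 = toward the tether at
#' position 0).
#'
#' Built-in presets: `"rpa"` (motor on RPA-coated ssDNA, 47 +/- 37 nt/s,
#' 5.2 knt), `"rad51"` (on Rad51 filaments, 29 +/- 29 nt/s, 4.1 knt),
#' `"i345t"` (Rad51 I345T, 23 +/- 18 nt/s, 3.9 knt), `"k191r"` (Rad51 K191R,
#' 34 +/- 16 nt/s, 4.2 knt), `"str"` (with Top3-Rmi1: 3-fold slower than
#' `"rad51"`; half-life 2.9 knt, a provisional value), and `"dmc1"`
#' (Dmc1 filaments: binding reduced 12-fold, no translocation).
#'
#' @param name One of the built-in preset names, or any string when all
#'   numeric fields are supplied explicitly.
#' @param ... Named overrides for any preset field (`v_mean_nt_s`,
#'   `v_sd_nt_s`, `v_min_nt_s`, `halflife_knt`, `binding_rate`, `p_coloc`,
#'   `translocation_competent`, `direction`).
#'
#' @return An object of class `motor_preset`.
#' @examples
#' motor_preset("rad51")
#' motor_preset("rad51", binding_rate = 5)
#' @export
motor_preset <- function(name, ...) {
  tab <- motor_preset_table()
  dots <- list(...)
  if (name %in% tab$name) {
    row <- as.list(tab[tab$name == name, ])
  } else {
    required <- c("v_mean_nt_s", "v_sd_nt_s", "halflife_knt", "binding_rate",
                  "p_coloc")
    if (!all(required %in% names(dots))) {
      abort(sprintf(
        "Unknown preset '%s'. Available presets: %s (or supply all fields).",
        name, paste(tab$name, collapse = ", ")))
    }
    row <- list(name = name, translocation_competent = TRUE)
  }
  defaults <- list(v_min_nt_s = 5, direction = -1)
  preset <- utils::modifyList(c(row, defaults[setdiff(names(defaults), names(row))]), dots)
  preset$name <- name
  validate_motor_preset(structure(preset, class = "motor_preset"))
}

validate_motor_preset <- function(p) {
  stopifnot_scalar_number(p$v_mean_nt_s, "v_mean_nt_s", min = 0)
  stopifnot_scalar_number(p$v_sd_nt_s, "v_sd_nt_s", min = 0)
  stopifnot_scalar_number(p$halflife_knt, "halflife_knt", min = 0, strict = TRUE)
  stopifnot_scalar_number(p$binding_rate, "binding_rate", min = 0)
  stopifnot_scalar_number(p$p_coloc, "p_coloc", min = 0)
  if (p$p_coloc > 1) abort("`p_coloc` must lie in [0, 1].")
  if (abs(p$direction) != 1) abort("`direction` must be -1 or +1.")
  if (!is.logical(p$translocation_competent)) {
    abort("`translocation_competent` must be TRUE or FALSE.")
  }
  p
}

#' @export
print.motor_preset <- function(x, ...) {
  cat(sprintf(
    "<motor_preset '%s'> v = %g +/- %g nt/s (floor %g) | half-life %g knt | %g events/molecule | p_coloc %g | %s\n",
    x$name, x$v_mean_nt_s, x$v_sd_nt_s, x$v_min_nt_s, x$halflife_knt,
    x$binding_rate, x$p_coloc,
    if (x$translocation_competent) sprintf("direction %+d", x$direction)
    else "translocation-incompetent"))
  invisible(x)
}

#' List the built-in motor presets
#'
#' @return A tibble with one row per built-in preset and the fields used by
#'   [simulate_trajectories()].
#' @examples
#' curtain_presets()
#' @export
curtain_presets <- function() {
  dplyr::mutate(motor_preset_table(), v_min_nt_s = 5, direction = -1)
}
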