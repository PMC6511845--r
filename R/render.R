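#' Kymograph container
#'
#' A kymograph holds one intensity matrix per colour channel (rows = frames,
#' columns = pixels along the molecule; pixel 0 at the tether), together with
#' the acquisition parameters.
#'
#' @param channels Named list of numeric matrices (`n_frames` x `n_pixels`),
#'   conventionally `green` and `magenta`.
#' @param acq An [acquisition_params()] object.
#' @param molecule_id Identifier.
#' @return An object of class `kymograph`.
#' @export
new_kymograph <- function(channels, acq, molecule_id = 1L) {
  stopifnot(is.list(channels), length(channels) >= 1)
  for (nm in names(channels)) {
    m <- channels[[nm]]
    if (!is.matrix(m) || nrow(m) != acq$n_frames || ncol(m) != acq$n_pixels) {
      abort(sprintf("channel '%s' must be a %d x %d matrix.",
                    nm, acq$n_frames, acq$n_pixels))
    }
    if (any(m < 0)) abort(sprintf("channel '%s' has negative intensities.", nm))
  }
  structure(list(channels = channels, acq = acq, molecule_id = molecule_id),
            class = "kymograph")
}

#' @export
print.kymograph <- function(x, ...) {
  cat(sprintf("<kymograph molecule %s> channels: %s | %d frames x %d px\n",
              x$molecule_id, paste(names(x$channels), collapse = ", "),
              x$acq$n_frames, x$acq$n_pixels))
  invisible(x)
}

#' @describeIn new_kymograph Long-format view: one row per
#'   channel/frame/pixel with time and position in physical units.
#' @param x A `kymograph`.
#' @param ... Unused.
#' @exportS3Method tibble::as_tibble
as_tibble.kymograph <- function(x, ...) {
  purrr::imap_dfr(x$channels, function(m, nm) {
    tibble::tibble(
      channel = nm,
      frame = rep(seq_len(nrow(m)) - 1L, times = ncol(m)),
      pixel = rep(seq_len(ncol(m)) - 1L, each = nrow(m)),
      time_s = (rep(seq_len(nrow(m)) - 1L, times = ncol(m))) * x$acq$frame_interval_s,
      position_nt = rep(seq_len(ncol(m)) - 1L, each = nrow(m)) * x$acq$pixel_size_nt,
      intensity = as.vector(m)
    )
  })
}

# Expected photons per pixel for one Gaussian spot centred at `position_px`
# (pixel j sits at coordinate j). Mass is normalised on an unbounded pixel
# grid, so spots clipped at the field edge lose photons, as on a camera.
spot_expected <- function(position_px, photons, sigma_px, n_pixels) {
  j <- seq_len(n_pixels) - 1
  norm <- sum(dnorm(seq(-ceiling(8 * sigma_px), ceiling(8 * sigma_px)),
                    sd = sigma_px))
  dnorm(j, mean = position_px, sd = sigma_px) / norm * photons
}

#' Render a two-colour kymograph from ground-truth trajectories
#'
#' The green channel receives one Gaussian spot (sd `psf_sigma_px`) per
#' active trajectory at its current position in every frame. The magenta
#' channel depends on `mode`:
#' \describe{
#'   \item{`"rpa"`}{a uniform fluorescent coat (`coat_photons` per pixel)
#'     plus cluster spots, the appearance of RPA-coated ssDNA;}
#'   \item{`"rad51"`}{cluster spots plus a uniform tract extending over the
#'     interval each green trajectory has already traversed (fluorescent RPA
#'     rebinding in the motor's wake as the filament is stripped);}
#'   \item{`"dmc1"`}{cluster spots only.}
#' }
#' Photon counts are Poisson-distributed around their expectation, background
#' photons are added everywhere, Gaussian read noise is added, and
#' intensities are clipped at zero. Trajectories extending beyond the field
#' of view are clipped, not an error.
#'
#' @param trajectories Tibble from [simulate_trajectories()].
#' @param acq An [acquisition_params()] object.
#' @param clusters Optional cluster tibble from [place_clusters()].
#' @param mode One of `"rpa"`, `"rad51"`, `"dmc1"`.
#' @param direction Travel direction of the motors (-1 = toward the tether).
#' @param coat_photons Per-pixel photons of the uniform coat (`"rpa"` mode).
#' @param tract_photons Per-pixel photons of the cleared-wake tract
#'   (`"rad51"` mode).
#' @param noise If `FALSE`, render noise-free expected intensities (no
#'   Poisson sampling, background still added as its expectation, no read
#'   noise).
#' @param seed Optional integer seed.
#'
#' @return A [new_kymograph()] object with channels `green` and `magenta`.
#' @examples
#' acq <- acquisition_params(n_frames = 20, n_pixels = 30)
#' tr <- simulate_trajectories(motor_preset("rpa"), 2,
#'   molecule_length_nt = 30000, recording_s = 200, seed = 1)
#' ky <- render_kymograph(tr, acq, mode = "rpa", seed = 1)
#' @export
render_kymograph <- function(trajectories, acq,
                             clusters = NULL,
                             mode = c("rpa", "rad51", "dmc1"),
                             direction = -1,
                             coat_photons = acq$background_photons * 4,
                             tract_photons = acq$photons_per_spot / 5,
                             noise = TRUE,
                             seed = NULL) {
  mode <- match.arg(mode)
  nf <- acq$n_frames; np <- acq$n_pixels
  px <- acq$pixel_size_nt; sig <- acq$psf_sigma_px
  times <- (seq_len(nf) - 1L) * acq$frame_interval_s

  green <- matrix(0, nf, np)
  magenta <- matrix(0, nf, np)
  if (mode == "rpa") magenta <- magenta + coat_photons

  if (!is.null(clusters) && nrow(clusters) > 0 && mode != "rpa") {
    for (k in seq_len(nrow(clusters))) {
      prof <- spot_expected(clusters$position_nt[k] / px,
                            acq$photons_per_spot * clusters$intensity[k],
                            max(sig, clusters$width_nt[k] / px), np)
      magenta <- magenta + matrix(prof, nf, np, byrow = TRUE)
    }
  }

  if (nrow(trajectories) > 0) {
    for (i in seq_len(nrow(trajectories))) {
      tr <- trajectories[i, ]
      active <- which(times >= tr$t0_s & times <= tr$t_end_s)
      if (length(active) == 0) next
      pos_nt <- tr$x0_nt + direction * tr$v_nt_s * (times[active] - tr$t0_s)
      pos_nt <- pmin(pmax(pos_nt, 0), (np - 1) * px) # clip to field
      for (a in seq_along(active)) {
        green[active[a], ] <- green[active[a], ] +
          spot_expected(pos_nt[a] / px, acq$photons_per_spot, sig, np)
      }
      if (mode == "rad51" && tr$v_nt_s > 0) {
        # uniform magenta tract over the traversed interval (wake rebinding)
        for (a in seq_along(active)) {
          lo <- min(tr$x0_nt, pos_nt[a]); hi <- max(tr$x0_nt, pos_nt[a])
          jlo <- max(0, floor(lo / px)); jhi <- min(np - 1, ceiling(hi / px))
          if (hi > lo) {
            idx <- (jlo:jhi) + 1L
            magenta[active[a], idx] <- magenta[active[a], idx] + tract_photons
          }
        }
        # tract persists after the motor stops
        after <- which(times > tr$t_end_s)
        if (length(after) > 0) {
          end_nt <- pos_nt[length(pos_nt)]
          lo <- min(tr$x0_nt, end_nt); hi <- max(tr$x0_nt, end_nt)
          jlo <- max(0, floor(lo / px)); jhi <- min(np - 1, ceiling(hi / px))
          if (hi > lo) magenta[after, (jlo:jhi) + 1L] <-
              magenta[after, (jlo:jhi) + 1L] + tract_photons
        }
      }
    }
  }

  mol_id <- if (nrow(trajectories) > 0) trajectories$molecule_id[1] else 1L
  with_seed_if(seed, {
    finish <- function(expected) {
      lambda <- expected + acq$background_photons
      if (!noise) return(lambda)
      counts <- matrix(rpois(length(lambda), lambda), nrow(lambda), ncol(lambda))
      if (acq$read_noise_sd > 0) {
        counts <- counts + matrix(rnorm(length(counts), 0, acq$read_noise_sd),
                                  nrow(counts), ncol(counts))
      }
      pmax(counts, 0)
    }
    new_kymograph(list(green = finish(green), magenta = finish(magenta)),
                  acq, molecule_id = mol_id)
  })
}

#' Render an image stack from a kymograph channel
#'
#' Produces one 2-D image per frame in which the molecule occupies row
#' `molecule_row` (1-based) and the kymograph intensities are spread across
#' neighbouring rows with a Gaussian transverse profile normalised to total
#' mass 1, so total intensity per frame is conserved. The inverse operation
#' is [extract_kymograph()]; dividing the extracted line by the profile's
#' centre weight (`attr(stack, "transverse_peak")`) recovers the source
#' kymograph exactly when noise is off.
#'
#' @param kymograph A [new_kymograph()] object.
#' @param channel Channel name to render.
#' @param molecule_row Image row carrying the molecule (1-based).
#' @param image_height_px Image height in pixels.
#' @param transverse_sigma_px Transverse PSF sd in pixels.
#'
#' @return A `curtain_stack`: list of frame matrices
#'   (`image_height_px` x `n_pixels`) with metadata attributes
#'   (`frame_interval_s`, `pixel_size_nt`, `molecule_row`,
#'   `transverse_peak`).
#' @examples
#' acq <- acquisition_params(n_frames = 5, n_pixels = 20)
#' ky <- new_kymograph(list(green = matrix(1, 5, 20)), acq)
#' st <- render_stack(ky, "green", molecule_row = 4, image_height_px = 9)
#' @export
render_stack <- function(kymograph, channel = "green", molecule_row = 5,
                         image_height_px = 11, transverse_sigma_px = 1) {
  if (!channel %in% names(kymograph$channels)) {
    abort(sprintf("channel '%s' not present in kymograph.", channel))
  }
  if (molecule_row < 1 || molecule_row > image_height_px) {
    abort("`molecule_row` must lie within the image height.")
  }
  m <- kymograph$channels[[channel]]
  rows <- seq_len(image_height_px)
  w <- dnorm(rows, mean = molecule_row, sd = transverse_sigma_px)
  w <- w / sum(w) # discrete profile sums to exactly 1 -> flux conserved
  frames <- purrr::map(seq_len(nrow(m)), function(f) outer(w, m[f, ]))
  structure(frames,
            class = "curtain_stack",
            frame_interval_s = kymograph$acq$frame_interval_s,
            pixel_size_nt = kymograph$acq$pixel_size_nt,
            molecule_row = molecule_row,
            transverse_peak = w[molecule_row])
}

#' @export
print.curtain_stack <- function(x, ...) {
  cat(sprintf("<curtain_stack> %d frames of %d x %d px\n",
              length(x), nrow(x[[1]]), ncol(x[[1]])))
  invisible(x)
}
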