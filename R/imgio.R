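#' Write an image stack as multi-page TIFF with a JSON sidecar
#'
#' Frames are written one per TIFF page. TIFF sample values live in
#' `[0, 1]`, so intensities are stored divided by a scale factor recorded in
#' the sidecar (`<path>.json`), which is the authoritative carrier of
#' metadata (frame interval, pixel size, scale, bit depth). Integer data are
#' written at 16 bits with scale 65535 and round-trip exactly; other data are
#' written as 32-bit floats scaled by their maximum.
#'
#' @param stack A `curtain_stack` or plain list of equally sized matrices.
#' @param path Output TIFF path; the sidecar is written to `<path>.json`.
#' @param frame_interval_s,pixel_size_nt Metadata; taken from the stack's
#'   attributes when present.
#' @return `path`, invisibly.
#' @seealso [read_stack()]
#' @export
write_stack <- function(stack, path,
                        frame_interval_s = attr(stack, "frame_interval_s"),
                        pixel_size_nt = attr(stack, "pixel_size_nt")) {
  frames <- lapply(unclass(stack), identity) # plain list of matrices
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    abort("all frames must have identical dimensions.")
  }
  vals <- unlist(frames)
  if (any(vals < 0)) abort("stack intensities must be nonnegative.")
  integerish <- all(abs(vals - round(vals)) < 1e-9) && max(vals) <= 65535
  if (integerish) {
    scale <- 65535
    bits <- 16L
  } else {
    scale <- max(vals, 1e-12)
    bits <- 32L
  }
  tiff::writeTIFF(purrr::map(frames, ~ .x / scale), path,
                  bits.per.sample = bits)
  meta <- list(
    n_frames = length(frames),
    height = unname(dims[1, 1]), width = unname(dims[2, 1]),
    scale = scale, bits = bits,
    frame_interval_s = frame_interval_s,
    pixel_size_nt = pixel_size_nt,
    molecule_row = attr(stack, "molecule_row"),
    transverse_peak = attr(stack, "transverse_peak")
  )
  jsonlite::write_json(meta[!vapply(meta, is.null, logical(1))],
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an image stack written by [write_stack()]
#'
#' @param path TIFF path. A sidecar `<path>.json` is used when present;
#'   without it, intensities are returned on the TIFF's native `[0, 1]`
#'   scale and no physical metadata is attached.
#' @return A `curtain_stack` (list of frame matrices with metadata
#'   attributes).
#' @export
read_stack <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: '%s'", path))
  pages <- tiff::readTIFF(path, all = TRUE, info = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  dims <- purrr::map(pages, dim)
  ref <- dims[[1]]
  for (i in seq_along(dims)) {
    if (!identical(dims[[i]], ref)) {
      abort(sprintf("inconsistent frame shapes: page %d is %s, expected %s.",
                    i, paste(dims[[i]], collapse = "x"),
                    paste(ref, collapse = "x")))
    }
  }
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar) else list()
  scale <- meta$scale %||% 1
  frames <- purrr::map(pages, function(p) {
    m <- p * scale
    if (identical(meta$bits, 16L) || identical(meta$bits, 16)) m <- round(m)
    m
  })
  structure(frames, class = "curtain_stack",
            frame_interval_s = meta$frame_interval_s,
            pixel_size_nt = meta$pixel_size_nt,
            molecule_row = meta$molecule_row,
            transverse_peak = meta$transverse_peak)
}

#' Extract a kymograph from an image stack along a 1-pixel-wide ROI line
#'
#' Reproduces the standard kymograph construction: a 1-pixel-wide region of
#' interest is drawn along the molecule's long axis and its intensity
#' profile is collected frame by frame. For an axis-aligned line (a single
#' image row) pixels are copied without interpolation.
#'
#' @param stack A `curtain_stack` (see [read_stack()], [render_stack()]).
#' @param roi_row Image row of the ROI line (1-based). Defaults to the
#'   stack's recorded `molecule_row`.
#' @param acq Optional [acquisition_params()]; defaults to one rebuilt from
#'   the stack metadata and dimensions.
#' @param channel Channel name for the output kymograph.
#' @return A [new_kymograph()] with the single requested channel.
#' @export
extract_kymograph <- function(stack, roi_row = attr(stack, "molecule_row"),
                              acq = NULL, channel = "green") {
  if (is.null(roi_row)) abort("`roi_row` must be supplied (no molecule_row metadata).")
  h <- nrow(stack[[1]])
  if (roi_row < 1 || roi_row > h) {
    abort(sprintf("`roi_row` %d lies outside the image (height %d).", roi_row, h))
  }
  m <- do.call(rbind, purrr::map(stack, ~ .x[roi_row, ]))
  if (is.null(acq)) {
    acq <- acquisition_params(
      frame_interval_s = attr(stack, "frame_interval_s") %||% 10,
      pixel_size_nt = attr(stack, "pixel_size_nt") %||% 1000,
      n_frames = length(stack), n_pixels = ncol(stack[[1]]))
  }
  new_kymograph(setNames(list(m), channel), acq)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- tables ----------------------------------------------------------------

trajectory_columns <- c("id", "molecule_id", "x0_nt", "t0_s", "v_nt_s",
                        "run_nt", "channel", "coloc")

#' Read and write trajectory, event and summary tables
#'
#' Plain CSV with a header row. Columns carry physical units in their names
#' (`*_nt` nucleotides, `*_s` seconds, `*_nt_s` nt/s). `read_curtain_table()`
#' rejects files missing any required column, naming the first missing one.
#' An empty table with a valid header is returned as an empty tibble, not an
#' error.
#'
#' @param x A data frame.
#' @param path CSV path.
#' @param required Character vector of required column names.
#' @return `read_curtain_table()` returns a tibble; `write_curtain_table()`
#'   returns `path` invisibly.
#' @examples
#' p <- tempfile(fileext = ".csv")
#' write_curtain_table(simulate_trajectories(motor_preset("rpa"), 3, seed = 1), p)
#' read_curtain_table(p, required = c("x0_nt", "v_nt_s"))
#' @export
write_curtain_table <- function(x, path) {
  readr::write_csv(x, path)
  invisible(path)
}

#' @rdname write_curtain_table
#' @export
read_curtain_table <- function(path, required = character()) {
  if (!file.exists(path)) abort(sprintf("no such file: '%s'", path))
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(required, names(x))
  if (length(missing) > 0) {
    abort(sprintf("missing column %s", missing[1]))
  }
  x
}

#' @rdname write_curtain_table
#' @export
read_trajectory_table <- function(path) {
  read_curtain_table(path, required = trajectory_columns)
}
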