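#' Convert an RGB frame to luminance
#'
#' Per-pixel unweighted mean of the three colour channels, on the same
#' \[0, 255\] scale (real-valued).
#'
#' @param frame A `height x width x 3` intensity array with values in
#'   \[0, 255\].
#' @return A `height x width` numeric matrix.
#' @export
to_luminance <- function(frame) {
  d <- dim(frame)
  if (length(d) != 3L || d[3] != 3L)
    stop("frame must be a height x width x 3 array", call. = FALSE)
  if (any(!is.finite(frame)) || min(frame) < 0 || max(frame) > 255)
    stop("frame values must be finite and in [0, 255]", call. = FALSE)
  (frame[, , 1] + frame[, , 2] + frame[, , 3]) / 3
}

#' Row-averaged horizontal power spectrum of one luminance image
#'
#' Each pixel row is Fourier transformed along the horizontal axis; the
#' power of bin k is `|F_k|^2 / width`, and the returned spectrum is the
#' mean over all rows, for bins 0..floor(width/2) in cycles per image
#' width. With this normalization the sum of power over the full (two-sided)
#' spectrum of a row equals the sum of its squared luminances (Parseval).
#'
#' @param lum A numeric luminance matrix (width >= 4).
#' @param rows Optional integer vector of row indices to analyse (default:
#'   all rows; a single row reproduces a one-line analysis).
#' @return Named numeric vector of mean power per bin; names are the
#'   frequencies in cycles per image width.
#' @export
frame_power_spectrum <- function(lum, rows = NULL) {
  if (!is.matrix(lum)) stop("lum must be a matrix", call. = FALSE)
  if (any(!is.finite(lum))) stop("non-finite luminance values", call. = FALSE)
  w <- ncol(lum)
  if (w < 4L) stop("image width must be >= 4", call. = FALSE)
  if (!is.null(rows)) lum <- lum[rows, , drop = FALSE]
  ft <- stats::mvfft(t(lum))                # one column per image row
  pow <- Mod(ft)^2 / w
  half <- floor(w / 2)
  out <- rowMeans(pow)[seq_len(half + 1L)]  # bins 0..floor(w/2)
  names(out) <- 0:half
  out
}

#' Average power spectrum of a movie
#'
#' Converts every frame to luminance, computes its row-averaged horizontal
#' power spectrum, and summarizes across frames: mean and s.e.m. per
#' frequency bin, plus the non-DC peak of the mean spectrum.
#'
#' @param frames A `frame_sequence`.
#' @param rows Optional row subset passed to [frame_power_spectrum()].
#' @return A `spectrum_summary` with fields `frequencies` (cycles per image
#'   width), `mean_power`, `sem_power`, `n_frames`, `peak_power`,
#'   `peak_frequency`.
#' @export
movie_spectrum <- function(frames, rows = NULL) {
  stopifnot(inherits(frames, "frame_sequence"))
  if (length(frames$frames) < 1L) stop("empty frame sequence", call. = FALSE)
  specs <- vapply(frames$frames,
                  function(fr) frame_power_spectrum(to_luminance(fr), rows),
                  numeric(floor(ncol(frames$frames[[1]]) / 2) + 1L))
  specs <- matrix(specs, ncol = length(frames$frames))
  n <- ncol(specs)
  mean_power <- rowMeans(specs)
  sem_power <- if (n > 1) apply(specs, 1, stats::sd) / sqrt(n) else
    rep(0, nrow(specs))
  freqs <- 0:(nrow(specs) - 1L)
  pk <- which.max(mean_power[-1L])          # DC excluded
  structure(
    list(frequencies = freqs, mean_power = mean_power, sem_power = sem_power,
         n_frames = n, peak_power = mean_power[pk + 1L],
         peak_frequency = freqs[pk + 1L]),
    class = "spectrum_summary"
  )
}

#' @export
print.spectrum_summary <- function(x, ...) {
  cat(sprintf(
    "<spectrum_summary> %d frame(s), %d bins; peak power %.4g at %d cycles/image-width\n",
    x$n_frames, length(x$frequencies), x$peak_power, x$peak_frequency))
  invisible(x)
}

#' Peak of the mean power spectrum, DC excluded
#'
#' The maximum of the frame-averaged power over bins >= 1 and its bin. The
#' DC bin is excluded so that mean luminance cannot masquerade as image
#' structure: this peak is the movie's image-regularity score.
#'
#' @param summary A `spectrum_summary` from [movie_spectrum()].
#' @return A list with elements `power` and `frequency`.
#' @export
peak_power <- function(summary) {
  stopifnot(inherits(summary, "spectrum_summary"))
  if (length(summary$mean_power) < 2L)
    stop("spectrum has no non-DC bins", call. = FALSE)
  k <- which.max(summary$mean_power[-1L])
  list(power = summary$mean_power[k + 1L], frequency = summary$frequencies[k + 1L])
}

#' Convert spectrum frequencies to cycles per degree
#'
#' Frequencies are reported in cycles per image width by default; this
#' helper converts them using the screen geometry.
#'
#' @param summary A `spectrum_summary`.
#' @param geometry A [screen_geometry()].
#' @return The summary with an added `frequencies_cpd` field.
#' @export
spectrum_frequencies_cpd <- function(summary, geometry) {
  stopifnot(inherits(summary, "spectrum_summary"),
            inherits(geometry, "screen_geometry"))
  width_deg <- geometry$width_px / geometry$pixels_per_degree
  summary$frequencies_cpd <- summary$frequencies / width_deg
  summary
}
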