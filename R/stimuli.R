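#' Screen geometry for stimulus rendering
#'
#' All stimulus specifications are expressed in visual degrees; the screen
#' geometry is the single point of conversion between degrees and pixels,
#' and between seconds and frames.
#'
#' @param width_px,height_px Screen size in pixels (positive integers).
#' @param pixels_per_degree Pixels per visual degree (> 0).
#' @param frame_rate_hz Frame rate in Hz (> 0).
#'
#' @return A `screen_geometry` object.
#' @examples
#' geom <- screen_geometry()          # 640 x 480, 2 px/deg, 60 fps
#' geom$width_px / geom$pixels_per_degree  # screen width in degrees
#' @export
screen_geometry <- function(width_px = 640L, height_px = 480L,
                            pixels_per_degree = 2, frame_rate_hz = 60) {
  width_px <- as.integer(width_px)
  height_px <- as.integer(height_px)
  if (is.na(width_px) || width_px <= 0L || is.na(height_px) || height_px <= 0L)
    stop("width_px and height_px must be positive integers", call. = FALSE)
  if (!is.finite(pixels_per_degree) || pixels_per_degree <= 0)
    stop("pixels_per_degree must be > 0", call. = FALSE)
  if (!is.finite(frame_rate_hz) || frame_rate_hz <= 0)
    stop("frame_rate_hz must be > 0", call. = FALSE)
  structure(
    list(width_px = width_px, height_px = height_px,
         pixels_per_degree = as.numeric(pixels_per_degree),
         frame_rate_hz = as.numeric(frame_rate_hz)),
    class = "screen_geometry"
  )
}

.check_rgb <- function(x, what) {
  x <- as.numeric(x)
  if (length(x) != 3L || any(!is.finite(x)) || any(x < 0) || any(x > 255))
    stop(what, " must be an RGB triple with values in [0, 255]", call. = FALSE)
  x
}

#' Square-wave grating specification
#'
#' A drifting two-colour (foreground/background) square-wave grating with
#' bars perpendicular to the horizontal motion axis. The sign of
#' `velocity_dps` sets the motion direction (positive = rightward).
#'
#' @param spatial_frequency_cpd Spatial frequency in cycles per visual
#'   degree (>= 0; 0 gives a uniform field).
#' @param velocity_dps Drift velocity in degrees per second (signed).
#' @param fg_color,bg_color Bar colours as RGB triples in \[0, 255\].
#' @param phase0 Initial phase in cycles, in \[0, 1).
#'
#' @return A `grating_spec` object.
#' @export
grating_spec <- function(spatial_frequency_cpd = 0.016, velocity_dps = 130,
                         fg_color = c(0, 255, 0), bg_color = c(0, 0, 0),
                         phase0 = 0) {
  if (!is.finite(spatial_frequency_cpd) || spatial_frequency_cpd < 0)
    stop("spatial_frequency_cpd must be >= 0", call. = FALSE)
  if (!is.finite(velocity_dps))
    stop("velocity_dps must be finite", call. = FALSE)
  if (!is.finite(phase0) || phase0 < 0 || phase0 >= 1)
    stop("phase0 must lie in [0, 1)", call. = FALSE)
  structure(
    list(spatial_frequency_cpd = spatial_frequency_cpd,
         velocity_dps = velocity_dps,
         fg_color = .check_rgb(fg_color, "fg_color"),
         bg_color = .check_rgb(bg_color, "bg_color"),
         phase0 = phase0),
    class = "grating_spec"
  )
}

#' Random-dot kinematogram specification
#'
#' A field of `n_dots` dots on a uniform background. A fraction `coherence`
#' of them (the signal dots) translate along `direction_deg`; each remaining
#' noise dot moves at the same speed along its own uniform-random direction,
#' redrawn when the dot is respawned. Dots age, die at `lifespan_s`, and are
#' respawned at uniform-random positions; positions wrap toroidally.
#'
#' @param n_dots Number of dots (integer >= 0).
#' @param coherence Fraction of signal dots, in \[0, 1\].
#' @param direction_deg Signal direction in degrees; 0 = rightward,
#'   counterclockwise positive.
#' @param speed_dps Dot speed in degrees per second (>= 0).
#' @param dot_diameter_deg Dot diameter in visual degrees (> 0).
#' @param lifespan_s Dot lifespan in seconds (> 0).
#' @param dot_color,bg_color RGB triples in \[0, 255\].
#' @param shape `"circle"` or `"square"`. Squares are rasterized to exactly
#'   the same pixel count as the circle of the same nominal diameter.
#'
#' @return An `rdk_spec` object.
#' @export
rdk_spec <- function(n_dots = 1500L, coherence = 1, direction_deg = 0,
                     speed_dps = 130, dot_diameter_deg = 13.8,
                     lifespan_s = 10, dot_color = c(0, 255, 0),
                     bg_color = c(0, 0, 0), shape = c("circle", "square")) {
  shape <- match.arg(shape)
  n_dots <- as.integer(n_dots)
  if (is.na(n_dots) || n_dots < 0L)
    stop("n_dots must be a non-negative integer", call. = FALSE)
  if (!is.finite(coherence) || coherence < 0 || coherence > 1)
    stop("coherence must lie in [0, 1]", call. = FALSE)
  if (!is.finite(speed_dps) || speed_dps < 0)
    stop("speed_dps must be >= 0", call. = FALSE)
  if (!is.finite(dot_diameter_deg) || dot_diameter_deg <= 0)
    stop("dot_diameter_deg must be > 0", call. = FALSE)
  if (!is.finite(lifespan_s) || lifespan_s <= 0)
    stop("lifespan_s must be > 0", call. = FALSE)
  structure(
    list(n_dots = n_dots, coherence = coherence,
         direction_deg = as.numeric(direction_deg), speed_dps = speed_dps,
         dot_diameter_deg = dot_diameter_deg, lifespan_s = lifespan_s,
         dot_color = .check_rgb(dot_color, "dot_color"),
         bg_color = .check_rgb(bg_color, "bg_color"),
         shape = shape),
    class = "rdk_spec"
  )
}

#' Combined grating-plus-dots competition stimulus
#'
#' Coherent dots layered opaquely onto a drifting grating, with the dot
#' motion direction expressed relative to the grating motion direction.
#' Only the eight multiples of 45 degrees are admissible.
#'
#' @param grating A [grating_spec()].
#' @param rdk An [rdk_spec()]; its `direction_deg` is ignored and replaced by
#'   the grating direction rotated by `relative_direction_deg`.
#' @param relative_direction_deg Dot direction minus grating direction, one
#'   of 0, 45, ..., 315 degrees.
#'
#' @return A `combined_spec` object.
#' @export
combined_spec <- function(grating, rdk, relative_direction_deg = 0) {
  stopifnot(inherits(grating, "grating_spec"), inherits(rdk, "rdk_spec"))
  if (!relative_direction_deg %in% seq(0, 315, by = 45))
    stop("relative_direction_deg must be a multiple of 45 in [0, 315]",
         call. = FALSE)
  structure(
    list(grating = grating, rdk = rdk,
         relative_direction_deg = as.numeric(relative_direction_deg)),
    class = "combined_spec"
  )
}

.frame_sequence <- function(frames, geometry, seed = NULL) {
  structure(list(frames = frames, geometry = geometry, seed = seed),
            class = "frame_sequence")
}

#' @export
print.frame_sequence <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<frame_sequence> %d frame(s), %d x %d px, %g fps%s\n",
              length(x$frames), d[2], d[1], x$geometry$frame_rate_hz,
              if (is.null(x$seed)) "" else sprintf(", seed %d", x$seed)))
  invisible(x)
}

#' @export
length.frame_sequence <- function(x) length(x$frames)

#' Temporal frequency implied by spatial frequency and velocity
#'
#' For a drifting periodic pattern the temporal frequency is the product of
#' spatial frequency and drift speed, `tf = sf * |v|`. The engine always
#' derives temporal frequency from these two primaries rather than taking it
#' as an independent parameter.
#'
#' @param sf Spatial frequency in cycles/degree (>= 0).
#' @param v Velocity in degrees/second (signed).
#' @return Temporal frequency in Hz.
#' @examples
#' derive_temporal_frequency(0.016, 130)  # 2.08 Hz
#' @export
derive_temporal_frequency <- function(sf, v) {
  if (!is.finite(sf) || sf < 0) stop("sf must be >= 0", call. = FALSE)
  if (!is.finite(v)) stop("v must be finite", call. = FALSE)
  sf * abs(v)
}

#' Michelson contrast
#'
#' `(l_max - l_min) / (l_max + l_min)`, with the convention that a pair of
#' zero luminances has contrast 0.
#'
#' @param l_max,l_min Maximum and minimum intensity, `l_max >= l_min >= 0`.
#' @return Contrast in \[0, 1\].
#' @examples
#' michelson_contrast(255, 0)   # 1
#' michelson_contrast(192, 64)  # 0.5
#' @export
michelson_contrast <- function(l_max, l_min) {
  if (!is.finite(l_max) || !is.finite(l_min) || l_min < 0)
    stop("intensities must be finite and non-negative", call. = FALSE)
  if (l_min > l_max) stop("l_min must not exceed l_max", call. = FALSE)
  if (l_max == 0) return(0)
  (l_max - l_min) / (l_max + l_min)
}

# one grating frame as a h x w x 3 array; pattern computed per column
.grating_frame <- function(spec, geometry, phase) {
  w <- geometry$width_px; h <- geometry$height_px
  x_deg <- (seq_len(w) - 1L) / geometry$pixels_per_degree
  is_fg <- ((x_deg * spec$spatial_frequency_cpd + phase) %% 1) < 0.5
  fr <- array(0, dim = c(h, w, 3L))
  for (ch in 1:3) {
    row <- ifelse(is_fg, spec$fg_color[ch], spec$bg_color[ch])
    fr[, , ch] <- matrix(row, nrow = h, ncol = w, byrow = TRUE)
  }
  storage.mode(fr) <- "integer"
  fr
}

#' Render a drifting square-wave grating
#'
#' Bars are vertical (perpendicular to the horizontal motion axis) and every
#' pixel is exactly `fg_color` or `bg_color`. The phase advances by
#' `velocity_dps * spatial_frequency_cpd / frame_rate_hz` cycles per frame.
#' Rendering is fully deterministic.
#'
#' @param spec A [grating_spec()].
#' @param geometry A [screen_geometry()].
#' @param n_frames Number of frames (>= 1).
#' @return A `frame_sequence`.
#' @export
render_grating <- function(spec, geometry = screen_geometry(), n_frames = 1L) {
  stopifnot(inherits(spec, "grating_spec"), inherits(geometry, "screen_geometry"))
  n_frames <- as.integer(n_frames)
  if (is.na(n_frames) || n_frames < 1L)
    stop("n_frames must be >= 1", call. = FALSE)
  if (spec$spatial_frequency_cpd > 0) {
    period_px <- geometry$pixels_per_degree / spec$spatial_frequency_cpd
    if (period_px < 2)
      stop(sprintf(
        "grating period is %.3f px (< 2 px): unrepresentable at this geometry",
        period_px), call. = FALSE)
  }
  dphase <- spec$velocity_dps * spec$spatial_frequency_cpd /
    geometry$frame_rate_hz
  frames <- lapply(seq_len(n_frames) - 1L, function(t)
    .grating_frame(spec, geometry, spec$phase0 + t * dphase))
  .frame_sequence(frames, geometry)
}

# Pixel-offset mask for one dot. Circles keep pixel centres within the
# radius; squares use the smallest square covering the circle's pixel count,
# trimmed corner-first to exactly the same count (equal-area constraint).
.dot_offsets <- function(dot_diameter_deg, pixels_per_degree, shape) {
  if (dot_diameter_deg * pixels_per_degree < 1)
    stop("dot_diameter_deg rasterizes to 0 pixels at this geometry",
         call. = FALSE)
  rad <- dot_diameter_deg * pixels_per_degree / 2
  R <- ceiling(rad)
  g <- expand.grid(dx = -R:R, dy = -R:R)
  circ <- g[g$dx^2 + g$dy^2 <= rad^2, , drop = FALSE]
  n_c <- nrow(circ)
  if (n_c == 0L)
    stop("dot_diameter_deg rasterizes to 0 pixels at this geometry",
         call. = FALSE)
  if (shape == "circle") return(circ)
  side <- ceiling(sqrt(n_c))
  half <- (side - 1) / 2
  lo <- -floor(half); hi <- ceiling(half)
  sq <- expand.grid(dx = lo:hi, dy = lo:hi)
  drop_n <- nrow(sq) - n_c
  if (drop_n > 0L) {
    ord <- order(-(sq$dx^2 + sq$dy^2), sq$dx, sq$dy)
    sq <- sq[-ord[seq_len(drop_n)], , drop = FALSE]
  }
  sq
}

# Simulate dot centre trajectories (degrees). Returns a list with one
# matrix [x, y] per frame, all n_dots rows. Signal dots are the first
# round(coherence * n) dots; noise dots redraw a direction at each respawn.
.rdk_trajectories <- function(spec, geometry, n_frames, seed,
                              direction_deg = NULL) {
  n <- spec$n_dots
  w_deg <- geometry$width_px / geometry$pixels_per_degree
  h_deg <- geometry$height_px / geometry$pixels_per_degree
  dt <- 1 / geometry$frame_rate_hz
  dir0 <- if (is.null(direction_deg)) spec$direction_deg else direction_deg
  withr::with_seed(seed, {
    n_sig <- round(spec$coherence * n)
    is_signal <- seq_len(n) <= n_sig
    x <- stats::runif(n, 0, w_deg)
    y <- stats::runif(n, 0, h_deg)
    dir <- ifelse(is_signal, dir0, stats::runif(n, 0, 360))
    age <- stats::runif(n, 0, spec$lifespan_s)
    out <- vector("list", n_frames)
    for (t in seq_len(n_frames)) {
      out[[t]] <- cbind(x = x, y = y)
      # screen y grows downward; positive direction_deg is counterclockwise
      x <- (x + spec$speed_dps * cospi(dir / 180) * dt) %% w_deg
      y <- (y - spec$speed_dps * sinpi(dir / 180) * dt) %% h_deg
      age <- age + dt
      dead <- age > spec$lifespan_s
      if (any(dead)) {
        nd <- sum(dead)
        x[dead] <- stats::runif(nd, 0, w_deg)
        y[dead] <- stats::runif(nd, 0, h_deg)
        dir[dead] <- ifelse(is_signal[dead], dir0, stats::runif(nd, 0, 360))
        age[dead] <- 0
      }
    }
    out
  })
}

# Paint dots onto a frame (modified in place and returned). Toroidal wrap.
.draw_dots <- function(fr, centers_deg, offsets, color, geometry) {
  if (nrow(centers_deg) == 0L) return(fr)
  w <- geometry$width_px; h <- geometry$height_px
  cx <- floor(centers_deg[, 1] * geometry$pixels_per_degree)
  cy <- floor(centers_deg[, 2] * geometry$pixels_per_degree)
  px <- outer(cx, offsets$dx, `+`) %% w   # 0-based columns
  py <- outer(cy, offsets$dy, `+`) %% h   # 0-based rows
  idx <- as.vector(py + 1L + px * h)      # linear index into h x w matrix
  plane <- h * w
  for (ch in 1:3) fr[idx + (ch - 1L) * plane] <- as.integer(color[ch])
  fr
}

#' Render a random-dot kinematogram
#'
#' Signal dots drift coherently along `direction_deg`; noise dots each move
#' at the same speed along an independent uniform-random direction. Dot ages
#' are initialized uniformly over the lifespan so respawning is desynchronized,
#' and expired dots reappear at uniform-random positions with age 0.
#' Identical inputs (including `seed`) give identical frames.
#'
#' @param spec An [rdk_spec()].
#' @param geometry A [screen_geometry()].
#' @param n_frames Number of frames (>= 1).
#' @param seed Integer seed (required: the reproducibility contract).
#' @return A `frame_sequence`.
#' @export
render_rdk <- function(spec, geometry = screen_geometry(), n_frames = 1L,
                       seed) {
  stopifnot(inherits(spec, "rdk_spec"), inherits(geometry, "screen_geometry"))
  n_frames <- as.integer(n_frames)
  if (is.na(n_frames) || n_frames < 1L)
    stop("n_frames must be >= 1", call. = FALSE)
  if (missing(seed)) stop("seed is required for RDK rendering", call. = FALSE)
  offsets <- .dot_offsets(spec$dot_diameter_deg, geometry$pixels_per_degree,
                          spec$shape)
  traj <- .rdk_trajectories(spec, geometry, n_frames, seed)
  bg <- .uniform_frame(spec$bg_color, geometry)
  frames <- lapply(traj, function(cen)
    .draw_dots(bg, cen, offsets, spec$dot_color, geometry))
  .frame_sequence(frames, geometry, seed = as.integer(seed))
}

.uniform_frame <- function(color, geometry) {
  fr <- array(rep(as.integer(color),
                  each = geometry$height_px * geometry$width_px),
              dim = c(geometry$height_px, geometry$width_px, 3L))
  storage.mode(fr) <- "integer"
  fr
}

#' Render a combined grating-plus-dots competition movie
#'
#' The grating is rendered first and the dots are drawn opaquely on top.
#' The dot motion direction is the grating motion direction (0 degrees for
#' positive grating velocity, 180 for negative) rotated counterclockwise by
#' `relative_direction_deg`.
#'
#' @param spec A [combined_spec()].
#' @param geometry A [screen_geometry()].
#' @param n_frames Number of frames (>= 1).
#' @param seed Integer seed for the dot field.
#' @return A `frame_sequence`.
#' @export
render_combined <- function(spec, geometry = screen_geometry(), n_frames = 1L,
                            seed) {
  stopifnot(inherits(spec, "combined_spec"))
  if (missing(seed)) stop("seed is required", call. = FALSE)
  base <- render_grating(spec$grating, geometry, n_frames)
  grating_dir <- if (spec$grating$velocity_dps >= 0) 0 else 180
  dot_dir <- (grating_dir + spec$relative_direction_deg) %% 360
  offsets <- .dot_offsets(spec$rdk$dot_diameter_deg,
                          geometry$pixels_per_degree, spec$rdk$shape)
  traj <- .rdk_trajectories(spec$rdk, geometry, n_frames, seed,
                            direction_deg = dot_dir)
  frames <- mapply(function(fr, cen)
    .draw_dots(fr, cen, offsets, spec$rdk$dot_color, geometry),
    base$frames, traj, SIMPLIFY = FALSE)
  .frame_sequence(frames, geometry, seed = as.integer(seed))
}

#' Synthetic translating texture with a power-law spectrum
#'
#' Generates a grayscale noise texture whose expected horizontal power
#' spectrum falls as `frequency^-spectral_exponent` (flat white noise at
#' exponent 0), rescales it to \[0, 255\], and translates it rigidly at
#' `velocity_dps` with toroidal wrap. The spectral shaping is applied to
#' horizontal frequencies, matching the row-wise spectral analysis used to
#' quantify image regularity. Deterministic per seed.
#'
#' @param geometry A [screen_geometry()].
#' @param spectral_exponent Log-log spectral slope magnitude (>= 0).
#' @param velocity_dps Translation speed in degrees/second (signed).
#' @param n_frames Number of frames (>= 1).
#' @param seed Integer seed.
#' @return A `frame_sequence`.
#' @export
synth_texture <- function(geometry = screen_geometry(), spectral_exponent = 2,
                          velocity_dps = 130, n_frames = 1L, seed) {
  stopifnot(inherits(geometry, "screen_geometry"))
  if (!is.finite(spectral_exponent) || spectral_exponent < 0)
    stop("spectral_exponent must be >= 0", call. = FALSE)
  if (missing(seed)) stop("seed is required", call. = FALSE)
  n_frames <- as.integer(n_frames)
  if (is.na(n_frames) || n_frames < 1L)
    stop("n_frames must be >= 1", call. = FALSE)
  w <- geometry$width_px; h <- geometry$height_px
  img <- withr::with_seed(seed, {
    z <- matrix(stats::rnorm(h * w), nrow = h, ncol = w)
    k <- 0:(w - 1)
    freq <- pmin(k, w - k)                  # cycles per image width
    amp <- ifelse(freq == 0, 0, freq^(-spectral_exponent / 2))
    zf <- t(stats::mvfft(t(z)))             # row-wise DFT
    zf <- sweep(zf, 2, amp, `*`)
    Re(t(stats::mvfft(t(zf), inverse = TRUE))) / w
  })
  rng <- range(img)
  if (rng[2] > rng[1]) {
    img <- (img - rng[1]) / (rng[2] - rng[1]) * 255
  } else {
    img <- img * 0 + 127.5
  }
  img <- round(img)
  px_per_frame <- velocity_dps * geometry$pixels_per_degree /
    geometry$frame_rate_hz
  frames <- lapply(seq_len(n_frames) - 1L, function(t) {
    shift <- round(t * px_per_frame) %% w
    shifted <- if (shift == 0) img else
      img[, c((w - shift + 1):w, seq_len(w - shift)), drop = FALSE]
    fr <- array(rep(shifted, 3L), dim = c(h, w, 3L))
    storage.mode(fr) <- "integer"
    fr
  })
  .frame_sequence(frames, geometry, seed = as.integer(seed))
}
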