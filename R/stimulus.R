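## Stimulus generation and the linear-nonlinear-Poisson input stage.
##
## A stimulus movie is a square luminance grid in visual degrees sampled at a
## fixed frame interval.  Surrogate retinal waves are traveling elongated
## activity fronts (Gaussian cross-section, random origin and direction,
## constant speed); white noise is i.i.d. Gaussian pixels smoothed with a
## 2-degree Gaussian.  Synaptic receptive fields are two-lobe Gabors (or
## single-sign On/Off Gaussians); the LN cascade turns filter responses into
## inhomogeneous Poisson trains of 50-ms events.

.movie_grid <- function(extent, pixel_scale) {
  half <- extent / 2
  ax <- seq(-half, half, by = pixel_scale)
  list(ax = ax, n = length(ax))
}

.new_movie <- function(frames, grid, pixel_scale, frame_interval, extent,
                       kind, pars = list()) {
  structure(list(frames = frames, n = grid$n, ax = grid$ax,
                 pixel_scale = pixel_scale, frame_interval = frame_interval,
                 extent = extent, kind = kind, pars = pars),
            class = "stimulus_movie")
}

#' @export
print.stimulus_movie <- function(x, ...) {
  cat(sprintf("<stimulus_movie> %s, %dx%d px (%g deg/px), %d frames @ %g ms\n",
              x$kind, x$n, x$n, x$pixel_scale, ncol(x$frames),
              x$frame_interval))
  invisible(x)
}

## wave bookkeeping.  Two front geometries:
##   "plane": an infinite straight ridge with random direction entering from
##            outside the domain and sweeping across it;
##   "ring":  a front expanding at constant speed from a random origin point
##            (the wave is an annulus whose local orientation is everywhere
##            tangential), resembling the growing domains of real retinal
##            waves.
.sample_waves <- function(duration_ms, rate_per_min, extent, speed_deg_s,
                          width_fwhm, kind = "ring") {
  n <- rpois(1, rate_per_min * duration_ms / 60000)
  R <- extent / sqrt(2) + 2 * width_fwhm       # covers the full square
  if (n == 0)
    return(data.frame(t0 = numeric(0), dir = numeric(0), ox = numeric(0),
                      oy = numeric(0), start = numeric(0), stop = numeric(0),
                      kind = character(0)))
  data.frame(t0 = sort(runif(n, 0, duration_ms)),
             dir = runif(n, 0, 360),
             ox = runif(n, -extent / 2, extent / 2),
             oy = runif(n, -extent / 2, extent / 2),
             start = -R, stop = R,
             kind = kind)
}

.render_waves <- function(waves, frame_times_ms, grid, speed_deg_s,
                          width_fwhm) {
  sig <- width_fwhm / (2 * sqrt(2 * log(2)))
  n <- grid$n
  X <- matrix(grid$ax, n, n)
  Y <- matrix(grid$ax, n, n, byrow = TRUE)
  frames <- matrix(0, n * n, length(frame_times_ms))
  if (!nrow(waves)) return(frames)
  half <- max(abs(grid$ax))
  for (w in seq_len(nrow(waves))) {
    if (identical(waves$kind[w], "ring")) {
      r <- as.vector(sqrt((X - waves$ox[w])^2 + (Y - waves$oy[w])^2))
      rmax <- sqrt(2) * (2 * half) + 2 * width_fwhm
      tend <- waves$t0[w] + rmax / speed_deg_s * 1000
      idx <- which(frame_times_ms >= waves$t0[w] & frame_times_ms <= tend)
      for (fi in idx) {
        p <- speed_deg_s * (frame_times_ms[fi] - waves$t0[w]) / 1000
        frames[, fi] <- pmax(frames[, fi], exp(-(r - p)^2 / (2 * sig^2)))
      }
    } else {
      th <- waves$dir[w] * pi / 180
      proj <- as.vector(X * cos(th) + Y * sin(th))
      span <- waves$stop[w] - waves$start[w]
      tend <- waves$t0[w] + span / speed_deg_s * 1000
      idx <- which(frame_times_ms >= waves$t0[w] & frame_times_ms <= tend)
      for (fi in idx) {
        p <- waves$start[w] +
          speed_deg_s * (frame_times_ms[fi] - waves$t0[w]) / 1000
        frames[, fi] <- pmax(frames[, fi], exp(-(proj - p)^2 / (2 * sig^2)))
      }
    }
  }
  frames
}

#' Surrogate retinal-wave movie
#'
#' Traveling elongated activity fronts: each wave has a uniform random
#' direction, a Gaussian cross-section of full width at half maximum
#' `wave_width`, and sweeps the domain at `wave_speed`.  This surrogate
#' reproduces the property the plasticity model consumes — coactivation of
#' receptive fields that share orientation and location — without simulating
#' retinal circuitry.
#'
#' @param extent side of the square field of view (deg, >= 100 recommended so
#'   receptive fields truncated at 50 deg stay inside).
#' @param duration movie duration (ms).
#' @param wave_speed front speed (deg/s).
#' @param wave_rate waves per minute.
#' @param wave_width front full width at half maximum (deg), along the
#'   direction of travel.
#' @param wave_kind `"ring"` (front expanding from a random origin point,
#'   locally oriented tangentially — resembling the growing domains of real
#'   retinal waves) or `"plane"` (infinite straight ridge with random
#'   direction).
#' @param pixel_scale deg per pixel.
#' @param frame_interval ms per frame.
#' @param seed integer seed.
#' @return A `stimulus_movie` (pixels in \[0, 1\]).
#' @export
generate_wave_movie <- function(extent = 120, duration = 10000,
                                wave_speed = 100, wave_rate = 6,
                                wave_width = 10,
                                wave_kind = c("ring", "plane"),
                                pixel_scale = 1,
                                frame_interval = 50, seed = 1) {
  wave_kind <- match.arg(wave_kind)
  if (duration <= 0 || extent <= 0) stop("duration and extent must be positive")
  set.seed(seed)
  grid <- .movie_grid(extent, pixel_scale)
  times <- seq(0, duration - frame_interval / 2, by = frame_interval)
  waves <- .sample_waves(duration, wave_rate, extent, wave_speed, wave_width,
                         wave_kind)
  frames <- .render_waves(waves, times, grid, wave_speed, wave_width)
  .new_movie(frames, grid, pixel_scale, frame_interval, extent, "waves",
             list(wave_speed = wave_speed, wave_rate = wave_rate,
                  wave_width = wave_width, wave_kind = wave_kind,
                  seed = seed, waves = waves))
}

#' Spatially smoothed white-noise movie
#'
#' Independent standard-normal pixels per frame, smoothed with a spatial
#' Gaussian of 2-degree standard deviation; frames are temporally
#' independent.  The smoothed field is normalized to unit pixel variance and
#' scaled by `amplitude`; the default amplitude is calibrated so that the
#' LN cascade at its nominal gain produces the same ~15 events per minute as
#' the wave stimulus (the control is rate-matched, so any difference in the
#' emerging organization reflects spatiotemporal structure, not drive).
#'
#' @inheritParams generate_wave_movie
#' @param smooth_sigma spatial smoothing standard deviation (deg).
#' @param amplitude luminance scale of the normalized field.
#' @export
generate_white_noise_movie <- function(extent = 120, duration = 10000,
                                       pixel_scale = 1, frame_interval = 50,
                                       smooth_sigma = 2, amplitude = 0.09,
                                       seed = 1) {
  if (duration <= 0 || extent <= 0) stop("duration and extent must be positive")
  set.seed(seed)
  grid <- .movie_grid(extent, pixel_scale)
  times <- seq(0, duration - frame_interval / 2, by = frame_interval)
  n <- grid$n
  ## separable Gaussian smoothing by row/column convolution
  ks <- smooth_sigma / pixel_scale
  half <- max(1L, ceiling(3 * ks))
  kern <- exp(-(-half:half)^2 / (2 * ks^2)); kern <- kern / sum(kern)
  smooth1 <- function(M) {
    pad <- matrix(0, half, ncol(M))
    M2 <- rbind(pad, M, pad)
    out <- matrix(0, n, ncol(M))
    for (k in seq_along(kern)) out <- out + kern[k] * M2[(k - 1) + 1:n, , drop = FALSE]
    out
  }
  frames <- matrix(rnorm(n * n * length(times)), n * n, length(times))
  for (fi in seq_along(times)) {
    M <- matrix(frames[, fi], n, n)
    M <- smooth1(M)            # rows
    M <- t(smooth1(t(M)))      # columns
    frames[, fi] <- as.vector(M)
  }
  frames <- frames / stats::sd(frames[, 1]) * amplitude
  .new_movie(frames, grid, pixel_scale, frame_interval, extent, "white_noise",
             list(smooth_sigma = smooth_sigma, seed = seed))
}

#' Sample synaptic receptive fields
#'
#' Centers are drawn from a symmetric 2-D Gaussian with standard deviation
#' `sigma_p` and rejected/resampled until inside the 50-degree circle;
#' orientations are uniform on \[0, 360).
#'
#' @param n number of receptive fields.
#' @param sigma_p center spread (deg).
#' @param diameter Gabor diameter (deg).
#' @param kind `"gabor"` (two-lobe), `"on"` or `"off"` (single Gaussian).
#' @param seed integer seed (NULL: use the current RNG state).
#' @param max_radius truncation radius (deg).
#' @return Data frame with columns x, y, theta, diameter, kind.
#' @export
sample_receptive_fields <- function(n, sigma_p = 5.3, diameter = 13.4,
                                    kind = c("gabor", "on", "off"),
                                    seed = NULL, max_radius = 50) {
  kind <- match.arg(kind)
  if (n <= 0 || sigma_p <= 0 || diameter <= 0) stop("n, sigma_p, diameter must be positive")
  if (!is.null(seed)) set.seed(seed)
  x <- rnorm(n, 0, sigma_p); y <- rnorm(n, 0, sigma_p)
  while (any(bad <- x^2 + y^2 > max_radius^2)) {
    x[bad] <- rnorm(sum(bad), 0, sigma_p)
    y[bad] <- rnorm(sum(bad), 0, sigma_p)
  }
  data.frame(x = x, y = y, theta = runif(n, 0, 360),
             diameter = diameter, kind = kind)
}

## lobe geometry shared by the rasterizer: displacement of the two lobes is
## diameter/2 along the theta axis; each lobe is an anisotropic Gaussian with
## sigma diameter/4 along the ridge (perpendicular to theta) and diameter/8
## along theta, so the composite footprint is ~diameter in every direction.
.rasterize_rf_values <- function(rf, ax) {
  n <- length(ax)
  X <- matrix(ax, n, n)
  Y <- matrix(ax, n, n, byrow = TRUE)
  th <- rf$theta * pi / 180
  e1 <- c(cos(th), sin(th))                 # displacement axis
  dx <- X - rf$x; dy <- Y - rf$y
  a <- dx * e1[1] + dy * e1[2]              # along theta
  b <- -dx * e1[2] + dy * e1[1]             # along the ridge
  if (rf$kind == "gabor") {
    s_long <- rf$diameter / 4; s_short <- rf$diameter / 8
    sep <- rf$diameter / 4                  # lobe center offset from middle
    lobe <- function(center) exp(-((a - center)^2 / (2 * s_short^2) +
                                     b^2 / (2 * s_long^2)))
    pos <- lobe(sep); neg <- lobe(-sep)
    pos <- pos / sum(pos); neg <- neg / sum(neg)   # unit absolute integral
    img <- pos - neg
  } else {
    s <- rf$diameter / 4
    img <- exp(-(dx^2 + dy^2) / (2 * s^2))
    img <- img / sum(img)
    if (rf$kind == "off") img <- -img
  }
  img
}

#' Rasterize a receptive-field filter
#'
#' Two opposite-sign Gaussian lobes of identical shape displaced
#' symmetrically about the center along the orientation axis, each
#' normalized to unit absolute integral before differencing (so the
#' pixel sum of a two-lobe filter is 0 and the exponential-nonlinearity gain
#' `b` has a consistent meaning across diameters).  On/Off kinds give a
#' single +/- Gaussian.
#'
#' @param rf one receptive field (single-row data frame or list with x, y,
#'   theta, diameter, kind).
#' @param pixel_scale deg per pixel.
#' @param extent field-of-view side (deg); the filter must fit inside.
#' @return Square matrix (`n x n` image over the same grid a movie of the
#'   same geometry uses).
#' @export
rasterize_filter <- function(rf, pixel_scale = 1, extent = 120) {
  rf <- as.list(rf)
  if (sqrt(rf$x^2 + rf$y^2) + rf$diameter / 2 > extent / 2 + 1e-9)
    stop("filter support exceeds the movie extent")
  ax <- .movie_grid(extent, pixel_scale)$ax
  .rasterize_rf_values(rf, ax)
}

#' Add structured noise to a rasterized receptive field
#'
#' Standard-normal pixel noise filtered by a Gabor kernel with random
#' orientation, wavelength of 2 pixels per cycle and axis ratio 1/2, scaled
#' to the standard deviation of the clean filter times a factor drawn
#' uniformly from `scale_range`, then added to the image.
#'
#' @param rf_image rasterized filter (matrix).
#' @param seed integer seed (NULL: current RNG state).
#' @param scale_range range of the uniform scale factor.
#' @return Noised filter image.
#' @export
add_rf_noise <- function(rf_image, seed = NULL, scale_range = c(0.5, 2)) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(rf_image)
  noise <- matrix(rnorm(n * n), n, n)
  th <- runif(1, 0, pi)
  ## small Gabor kernel: carrier wavelength 2 px, envelope sigma 2 px x 1 px
  half <- 4L
  gx <- matrix(-half:half, 2 * half + 1, 2 * half + 1)
  gy <- t(gx)
  a <- gx * cos(th) + gy * sin(th)
  b <- -gx * sin(th) + gy * cos(th)
  kern <- cos(2 * pi * a / 2) * exp(-(a^2 / (2 * 1^2) + b^2 / (2 * 2^2)))
  ## direct 2-D convolution (kernel is tiny)
  pad <- matrix(0, n + 2 * half, n + 2 * half)
  pad[half + 1:n, half + 1:n] <- noise
  filt <- matrix(0, n, n)
  for (i in seq_len(2 * half + 1)) for (j in seq_len(2 * half + 1)) {
    filt <- filt + kern[i, j] * pad[(i - 1) + 1:n, (j - 1) + 1:n]
  }
  filt <- filt - mean(filt)
  filt <- filt / stats::sd(filt)
  fac <- runif(1, scale_range[1], scale_range[2])
  rf_image + fac * stats::sd(rf_image) * filt
}

## ---- event trains -------------------------------------------------------

.new_event_train <- function(onsets, x_dur, duration_ms) {
  structure(list(onsets = onsets, x_dur = x_dur, duration_ms = duration_ms,
                 n = length(onsets)),
            class = "event_train_set")
}

#' @export
print.event_train_set <- function(x, ...) {
  r <- mean(vapply(x$onsets, length, 1L)) / (x$duration_ms / 60000)
  cat(sprintf("<event_train_set> %d trains, %.0f ms, mean rate %.2f /min\n",
              x$n, x$duration_ms, r))
  invisible(x)
}

#' Binary indicator matrix of an event train set
#'
#' Expands each onset into a boxcar of `x_dur` (overlaps merge; runs truncate
#' only at the end of the record).
#'
#' @param trains an `event_train_set`.
#' @param dt sampling step (ms).
#' @return 0/1 matrix, steps x trains.
#' @export
event_indicator <- function(trains, dt = 5) {
  ns <- ceiling(trains$duration_ms / dt)
  out <- matrix(0L, ns, trains$n)
  ddur <- max(1L, round(trains$x_dur / dt))
  for (k in seq_len(trains$n)) {
    on <- floor(trains$onsets[[k]] / dt) + 1
    for (o in on) out[o:min(ns, o + ddur - 1), k] <- 1L
    }
  out
}

#' Mean event rate per train (events per minute)
#' @param trains an `event_train_set`.
#' @export
event_rate <- function(trains) {
  vapply(trains$onsets, length, 1L) / (trains$duration_ms / 60000)
}

#' Linear-nonlinear-Poisson encoding
#'
#' For each receptive field the movie is passed through the rasterized linear
#' filter and the exponential nonlinearity `a * exp(b * response)`; events
#' are drawn as an inhomogeneous Poisson process (one Bernoulli onset per
#' frame at probability `1 - exp(-rate * frame_interval)`) and extended to
#' `x_dur`.  With `off_double_baseline = TRUE`, Off-kind fields use baseline
#' `2a`.
#'
#' @param movie a `stimulus_movie`.
#' @param rfs receptive fields ([sample_receptive_fields()]).
#' @param a baseline rate (Hz).
#' @param b nonlinearity gain (unitless).
#' @param x_dur event duration (ms).
#' @param seed integer seed (NULL: current RNG state).
#' @param off_double_baseline double the baseline of Off-kind fields.
#' @return An `event_train_set`; filter responses are attached as the
#'   `"responses"` attribute (rfs x frames).
#' @export
ln_encode <- function(movie, rfs, a = 0.2, b = 9.4, x_dur = 50, seed = NULL,
                      off_double_baseline = FALSE) {
  if (a <= 0) stop("a must be positive")
  if (!inherits(movie, "stimulus_movie")) stop("movie must be a stimulus_movie")
  if (!is.null(seed)) set.seed(seed)
  resp <- .rf_responses(movie, rfs)
  a_vec <- rep_len(a, nrow(rfs))
  if (off_double_baseline) a_vec[rfs$kind == "off"] <- 2 * a
  rate <- a_vec / 1000 * exp(b * resp)       # per ms, rfs x frames
  p_on <- 1 - exp(-rate * movie$frame_interval)
  nt <- ncol(resp)
  ft <- (seq_len(nt) - 1) * movie$frame_interval
  onsets <- lapply(seq_len(nrow(rfs)), function(k)
    ft[runif(nt) < p_on[k, ]])
  tr <- .new_event_train(onsets, x_dur, nt * movie$frame_interval)
  attr(tr, "responses") <- resp
  tr
}

## sparse filter bank x movie frames -> responses (rfs x frames).
## filters are rasterized on the movie grid and kept as sparse columns.
.rf_filter_matrix <- function(movie, rfs) {
  n <- movie$n
  ii <- vector("list", nrow(rfs)); xx <- vector("list", nrow(rfs))
  for (k in seq_len(nrow(rfs))) {
    img <- as.vector(.rasterize_rf_values(as.list(rfs[k, ]), movie$ax))
    nz <- which(abs(img) >= max(abs(img)) * 1e-4)
    ii[[k]] <- nz
    xx[[k]] <- img[nz]
  }
  Matrix::sparseMatrix(
    i = unlist(ii),
    j = rep(seq_len(nrow(rfs)), vapply(ii, length, 1L)),
    x = unlist(xx), dims = c(n * n, nrow(rfs)))
}

.rf_responses <- function(movie, rfs) {
  Fs <- .rf_filter_matrix(movie, rfs)
  as.matrix(Matrix::t(Fs) %*% movie$frames)
}

#' Correlated Poisson event trains (multiple-interaction process)
#'
#' A mother Poisson train of rate `rate/c` is thinned independently per
#' child with copy probability `c`, so each child has expected rate `rate`
#' and every pair has expected event-count correlation `c`.  `c = 0` gives
#' independent trains.
#'
#' @param n number of trains.
#' @param rate target rate (events per minute).
#' @param c copy probability / pairwise correlation in \[0, 1\].
#' @param duration record duration (ms).
#' @param x_dur event duration (ms).
#' @param seed integer seed (NULL: current RNG state).
#' @return An `event_train_set`.
#' @export
correlated_poisson <- function(n, rate = 15, c = 0, duration = 720000,
                               x_dur = 50, seed = NULL) {
  if (c < 0 || c > 1) stop("c must lie in [0, 1]")
  if (rate <= 0 || n < 1) stop("rate and n must be positive")
  if (!is.null(seed)) set.seed(seed)
  if (c == 0) {
    onsets <- lapply(seq_len(n), function(k) {
      m <- rpois(1, rate * duration / 60000)
      sort(runif(m, 0, duration))
    })
  } else {
    m <- rpois(1, rate / c * duration / 60000)
    mother <- sort(runif(m, 0, duration))
    onsets <- lapply(seq_len(n), function(k) mother[runif(m) < c])
  }
  .new_event_train(onsets, x_dur, duration)
}

#' Export an event train set as CSV
#'
#' Two columns: synapse_id, event_onset_ms.
#'
#' @param trains an `event_train_set`.
#' @param path output file.
#' @export
write_event_trains <- function(trains, path) {
  df <- data.frame(
    synapse_id = rep(seq_len(trains$n), vapply(trains$onsets, length, 1L)),
    event_onset_ms = unlist(trains$onsets))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read an event train CSV written by [write_event_trains()]
#' @param path CSV path.
#' @param n number of trains (defaults to the largest id present).
#' @param x_dur event duration (ms).
#' @param duration_ms record duration (defaults to the last onset + x_dur).
#' @export
read_event_trains <- function(path, n = NULL, x_dur = 50, duration_ms = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = ",")
  if (nrow(df) == 0 && is.null(n))
    stop("empty train file: pass n explicitly")
  if (is.null(n)) n <- max(df$synapse_id)
  if (is.null(duration_ms))
    duration_ms <- if (nrow(df)) max(df$event_onset_ms) + x_dur else x_dur
  onsets <- split(df$event_onset_ms, factor(df$synapse_id, levels = seq_len(n)))
  onsets <- lapply(onsets, function(v) sort(as.numeric(v)))
  .new_event_train(onsets, x_dur, duration_ms)
}
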