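## Organization statistics: filtered correlations, coactivity, orientation
## differences, circular dispersion, receptive-field offset/overlap, cluster
## size, survival/turnover summaries, coaxial/orthogonal partition.

#' Boxcar-filtered pairwise correlations
#'
#' Applies a moving-average (boxcar) filter of `window` ms to each binary
#' event train (mimicking slow calcium-indicator dynamics) and returns the
#' Pearson correlation matrix.  Pairs involving a constant filtered train are
#' NA.
#'
#' @param trains an `event_train_set` (>= 2 trains).
#' @param window boxcar length (ms).
#' @param bin sampling resolution of the filtered signal (ms).
#' @export
boxcar_correlation <- function(trains, window = 3000, bin = 50) {
  if (trains$n < 2) stop("need at least 2 trains")
  X <- event_indicator(trains, dt = bin)
  k <- max(1L, round(window / bin))
  if (nrow(X) <= k) stop("record too short for the boxcar window")
  ## moving average via cumulative sums: sm[i] = mean(X[i:(i+k-1)])
  cs <- apply(X, 2, cumsum)
  n <- nrow(cs)
  sm <- (cs[k:n, , drop = FALSE] -
           rbind(0, cs[seq_len(n - k), , drop = FALSE])) / k
  sds <- apply(sm, 2, stats::sd)
  C <- suppressWarnings(stats::cor(sm))
  C[sds == 0, ] <- NA
  C[, sds == 0] <- NA
  diag(C) <- 1
  C
}

#' Coactivity of one synapse with a neighbor set
#'
#' Fraction of the reference synapse's events whose ON interval overlaps at
#' least one event of any synapse in `neighbors`.  NA when the reference has
#' no events.
#'
#' @param trains an `event_train_set`.
#' @param reference index of the reference synapse.
#' @param neighbors indices of the neighbor set.
#' @export
coactivity <- function(trains, reference, neighbors) {
  on_ref <- trains$onsets[[reference]]
  if (!length(on_ref)) return(NA_real_)
  d <- trains$x_dur
  nb <- sort(unlist(trains$onsets[neighbors]))
  if (!length(nb)) return(0)
  hit <- vapply(on_ref, function(t) {
    i <- findInterval(t + d, nb)     # last neighbor onset before ref offset
    i >= 1 && nb[i] > t - d          # overlap: |t - t_nb| < d
  }, logical(1))
  mean(hit)
}

#' Orientation difference (mod 180)
#'
#' `min(|a' - b'|, 180 - |a' - b'|)` with angles reduced mod 180; the result
#' lies in \[0, 90\] degrees.
#'
#' @param theta_i,theta_j orientations in degrees (vectorized).
#' @export
orientation_difference <- function(theta_i, theta_j) {
  a <- theta_i %% 180; b <- theta_j %% 180
  d <- abs(a - b)
  pmin(d, 180 - d)
}

#' Somatic orientation preference (circular average)
#'
#' `arg(mean(exp(i*theta)))` over all synaptic preferences, in degrees on
#' \[0, 360).  A vanishing resultant (perfectly balanced angles) is
#' degenerate and raises an error.  Orientation is a 180-degree-periodic
#' quantity, so the plain circular mean degenerates as soon as both
#' polarities of one orientation are present; `axial = TRUE` doubles the
#' angles before averaging (the standard axial-data convention) and returns
#' the preference on \[0, 180).
#'
#' @param theta orientations in degrees.
#' @param axial use the angle-doubling axial mean.
#' @export
somatic_preference <- function(theta, axial = FALSE) {
  if (!length(theta)) stop("need at least one synapse")
  if (axial) {
    z <- mean(exp(2i * theta * pi / 180))
    if (Mod(z) < 1e-12) stop("degenerate input: zero resultant vector")
    r <- (Arg(z) * 90 / pi) %% 180
    if (r > 180 - 1e-9) r <- 0      # snap the wrap-around rounding artifact
    return(r)
  }
  z <- mean(exp(1i * theta * pi / 180))
  if (Mod(z) < 1e-12) stop("degenerate input: zero resultant vector")
  (Arg(z) * 180 / pi) %% 360
}

#' Circular dispersion of synaptic preferences around the soma
#'
#' Orientation difference (mod 180) between each synapse and the somatic
#' preference.
#'
#' @param theta synaptic orientations (deg).
#' @param theta_soma somatic preference (deg), default the circular average
#'   of `theta`.
#' @export
circular_dispersion <- function(theta, theta_soma = somatic_preference(theta)) {
  orientation_difference(theta, theta_soma)
}

#' Receptive-field offset
#'
#' Euclidean distance (deg) between each synaptic receptive-field center and
#' the somatic center (the mean of all centers by default).
#'
#' @param centers two-column matrix or data frame of (x, y) centers.
#' @param reference somatic center; defaults to the column means.
#' @export
rf_offset <- function(centers, reference = colMeans(as.matrix(centers))) {
  m <- as.matrix(centers)
  sqrt((m[, 1] - reference[1])^2 + (m[, 2] - reference[2])^2)
}

#' Receptive-field overlap (pixelwise correlation)
#'
#' Pearson correlation between two rasterized filters over pixels; NA for a
#' zero-variance filter.
#'
#' @param filter_i,filter_j filter images on the same grid.
#' @export
rf_overlap <- function(filter_i, filter_j) {
  a <- as.vector(filter_i); b <- as.vector(filter_j)
  if (length(a) != length(b)) stop("filters must share the raster geometry")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  stats::cor(a, b)
}

#' Cluster size from the correlation-distance profile
#'
#' Bins pairwise correlations by distance (2-um bins), subtracts the mean
#' correlation of pairs more than `baseline_beyond` um apart, and fits
#' `A0 * exp(-d^2/(2*lambda^2))` by nonlinear least squares.  The fitted
#' `lambda` is the cluster size.
#'
#' @param pair_table data frame with columns `distance` (um) and
#'   `correlation`.
#' @param bin_width distance bin width (um).
#' @param baseline_beyond baseline distance cutoff (um).
#' @return List with `lambda`, `A0` and the binned `profile`.
#' @export
cluster_size_fit <- function(pair_table, bin_width = 2, baseline_beyond = 50) {
  pt <- pair_table[stats::complete.cases(pair_table[, c("distance",
                                                        "correlation")]), ]
  far <- pt$correlation[pt$distance > baseline_beyond]
  if (!length(far) || !any(pt$distance <= baseline_beyond))
    stop("need pairs both below and above the baseline distance")
  base <- mean(far)
  near <- pt[pt$distance <= baseline_beyond, ]
  bins <- floor(near$distance / bin_width)
  prof <- data.frame(
    distance = (unique(sort(bins)) + 0.5) * bin_width,
    correlation = tapply(near$correlation, bins, mean)[as.character(unique(sort(bins)))] - base)
  fit <- try(minpack.lm::nlsLM(
    correlation ~ A0 * exp(-distance^2 / (2 * lambda^2)),
    data = prof, start = list(A0 = max(prof$correlation), lambda = 5),
    lower = c(-Inf, 0.1), control = minpack.lm::nls.lm.control(maxiter = 200)),
    silent = TRUE)
  if (inherits(fit, "try-error")) stop("fit-failure: Gaussian fit did not converge")
  co <- stats::coef(fit)
  if (co[["A0"]] < 2 * stats::sd(prof$correlation) / sqrt(nrow(prof)) ||
      co[["lambda"]] > baseline_beyond)
    stop("fit-failure: no distance-dependent structure (A0 ~ 0)")
  list(lambda = unname(co[["lambda"]]), A0 = unname(co[["A0"]]),
       profile = prof)
}

#' Survival and stability statistics from a turnover log
#'
#' `survival(t)`: fraction of the initial synapses never replaced up to t.
#' `stable(t)`: fraction of the synapse slots whose final occupant was
#' already in place at t.  Also returns turnover counts per simulated day.
#'
#' @param log turnover log (columns time_ms, old_id).
#' @param n_synapses total number of synapse slots.
#' @param t_grid_ms evaluation times (ms).
#' @param end_ms end of the simulation (defaults to max(t_grid_ms)).
#' @export
survival_stats <- function(log, n_synapses, t_grid_ms, end_ms = max(t_grid_ms)) {
  first_rep <- if (nrow(log)) tapply(log$time_ms, log$old_id, min) else numeric(0)
  last_rep <- if (nrow(log)) tapply(log$time_ms, log$old_id, max) else numeric(0)
  surv <- vapply(t_grid_ms, function(t) 1 - sum(first_rep <= t) / n_synapses, 1)
  stable <- vapply(t_grid_ms, function(t) {
    ## final occupant present at t <=> last replacement of the slot was <= t
    (n_synapses - sum(last_rep > t)) / n_synapses
  }, 1)
  day <- if (nrow(log)) floor(log$time_ms / 86400000) else integer(0)
  data.frame(t_ms = t_grid_ms, survival = surv, stable = stable) ->
    curves
  list(curves = curves,
       turnovers_per_day = if (length(day)) table(day) else table(integer(0)),
       survival_final = 1 - length(first_rep) / n_synapses)
}

#' Coaxial / orthogonal partition of visual space
#'
#' Labels each synapse "coaxial" when the angle between the line from the
#' somatic receptive-field center to the synaptic center and the somatic
#' orientation axis (mod 180) is at most 45 degrees, "orthogonal" otherwise.
#' Centers coinciding with the somatic center are labelled coaxial and
#' flagged.
#'
#' @param centers (x, y) synaptic centers (deg).
#' @param theta_soma somatic orientation preference (deg).
#' @param soma_center somatic center; defaults to the mean center.
#' @return Data frame with `label` and `ambiguous` columns.
#' @export
coaxial_orthogonal_partition <- function(centers, theta_soma,
                                         soma_center = colMeans(as.matrix(centers))) {
  m <- as.matrix(centers)
  dx <- m[, 1] - soma_center[1]; dy <- m[, 2] - soma_center[2]
  r <- sqrt(dx^2 + dy^2)
  ang <- (atan2(dy, dx) * 180 / pi) %% 180
  d <- orientation_difference(ang, theta_soma)
  lab <- ifelse(d <= 45, "coaxial", "orthogonal")
  amb <- r < 1e-9
  lab[amb] <- "coaxial"
  data.frame(label = lab, ambiguous = amb)
}
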