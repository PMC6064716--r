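#' GCaMP indicator response kernel
#'
#' Difference-of-exponentials model of the single-event fluorescence
#' transient, \eqn{k(t) = A (e^{-t/\tau_d} - e^{-t/\tau_r})} rescaled so the
#' peak equals `unit_amplitude`. Defaults (rise 0.2 s, decay 1.5 s) give a
#' slow GCaMP6s-like transient that spans several frames at 7.8 Hz.
#'
#' @param rise_tau_s rise time constant in seconds (> 0).
#' @param decay_tau_s decay time constant in seconds (> rise_tau_s).
#' @param unit_amplitude peak \eqn{\Delta F/F} of a unit event.
#' @return object of class `gcamp_kernel`.
#' @export
gcamp_kernel <- function(rise_tau_s = 0.2, decay_tau_s = 1.5,
                         unit_amplitude = 1) {
  .assert_scalar_num(rise_tau_s, "rise_tau_s", min = 1e-9)
  .assert_scalar_num(decay_tau_s, "decay_tau_s", min = 1e-9)
  .assert_scalar_num(unit_amplitude, "unit_amplitude", min = 1e-12)
  if (decay_tau_s <= rise_tau_s)
    stop("decay_tau_s must exceed rise_tau_s", call. = FALSE)
  structure(list(rise_tau_s = rise_tau_s, decay_tau_s = decay_tau_s,
                 unit_amplitude = unit_amplitude),
            class = "gcamp_kernel")
}

#' Sample a kernel at the acquisition frame rate
#'
#' @param kernel a [gcamp_kernel()].
#' @param frame_rate_hz frames per second.
#' @param rel_tol kernel is truncated once the decay envelope falls below
#'   `rel_tol` of the peak.
#' @return numeric vector of kernel values starting at the event frame
#'   (lag 0), peak equal to `unit_amplitude`, all values non-negative.
#' @export
sample_kernel <- function(kernel, frame_rate_hz, rel_tol = 1e-4) {
  stopifnot(inherits(kernel, "gcamp_kernel"))
  .assert_scalar_num(frame_rate_hz, "frame_rate_hz", min = 1e-12)
  t_max <- kernel$decay_tau_s * log(1 / rel_tol)
  t <- seq(0, t_max, by = 1 / frame_rate_hz)
  k <- exp(-t / kernel$decay_tau_s) - exp(-t / kernel$rise_tau_s)
  # normalize on the sampled grid so an event's drawn amplitude is exactly
  # the peak of its sampled transient
  pmax(k, 0) * (kernel$unit_amplitude / max(k))
}

#' Simulation regime configuration
#'
#' Parameterizes one spontaneous-activity regime: population-wide "network"
#' events occur as a Poisson process and each neuron joins each event
#' independently with `participation_prob`; on top of that each neuron fires
#' independent events as its own Poisson process. High participation with
#' infrequent network events reproduces the immature synchronous regime;
#' mostly independent events reproduce the mature desynchronized regime.
#'
#' Defaults follow the acquisition settings the pipeline targets:
#' 60-s recordings at 7.8 Hz. Amplitude and noise defaults put single-event
#' peaks around Z = 10 relative to quiet-period noise, so activity epochs at
#' threshold 3 are unambiguous.
#'
#' @param n_neurons number of ROIs.
#' @param duration_s recording length in seconds.
#' @param frame_rate_hz acquisition rate in Hz.
#' @param network_event_rate_hz rate of population-wide events (Hz).
#' @param participation_prob probability a neuron joins a network event.
#' @param indep_event_rate_hz per-neuron independent event rate (Hz).
#' @param amplitude_mean,amplitude_sd event peak amplitude distribution
#'   (\eqn{\Delta F/F}; Normal truncated at 0).
#' @param noise_sd additive Gaussian noise SD (\eqn{\Delta F/F}).
#' @param seed integer RNG seed; every generator operation is deterministic
#'   given the seed.
#' @return object of class `regime_config`.
#' @export
regime_config <- function(n_neurons = 30, duration_s = 60,
                          frame_rate_hz = 7.8,
                          network_event_rate_hz = 0.05,
                          participation_prob = 0.85,
                          indep_event_rate_hz = 0.02,
                          amplitude_mean = 1.0, amplitude_sd = 0.25,
                          noise_sd = 0.1, seed = 1L) {
  .assert_scalar_num(n_neurons, "n_neurons", min = 1)
  .assert_scalar_num(duration_s, "duration_s", min = 1e-9)
  .assert_scalar_num(frame_rate_hz, "frame_rate_hz", min = 1e-9)
  .assert_scalar_num(network_event_rate_hz, "network_event_rate_hz", min = 0)
  .assert_scalar_num(participation_prob, "participation_prob", min = 0, max = 1)
  .assert_scalar_num(indep_event_rate_hz, "indep_event_rate_hz", min = 0)
  .assert_scalar_num(amplitude_mean, "amplitude_mean", min = 0)
  .assert_scalar_num(amplitude_sd, "amplitude_sd", min = 0)
  .assert_scalar_num(noise_sd, "noise_sd", min = 0)
  .assert_scalar_num(seed, "seed")
  structure(list(n_neurons = as.integer(n_neurons), duration_s = duration_s,
                 frame_rate_hz = frame_rate_hz,
                 network_event_rate_hz = network_event_rate_hz,
                 participation_prob = participation_prob,
                 indep_event_rate_hz = indep_event_rate_hz,
                 amplitude_mean = amplitude_mean, amplitude_sd = amplitude_sd,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "regime_config")
}

.n_frames_of <- function(config) {
  max(2L, as.integer(round(config$duration_s * config$frame_rate_hz)))
}

#' Draw ground-truth spike trains for one spontaneous session
#'
#' Network events are a Poisson process at `network_event_rate_hz`; each
#' neuron joins each event independently with `participation_prob`.
#' Independent per-neuron events are Poisson at `indep_event_rate_hz`.
#' Event times are uniform over the recording and stored as 0-based frames.
#'
#' @param config a [regime_config()].
#' @return object of class `ground_truth`: a list with `event_frames`
#'   (per-neuron sorted integer vectors of 0-based event frames),
#'   `network_event_frames`, `n_frames`, `responsive_set` (empty here),
#'   and the generating `config`.
#' @export
generate_spikes <- function(config) {
  stopifnot(inherits(config, "regime_config"))
  set.seed(config$seed)
  n_frames <- .n_frames_of(config)
  n_net <- stats::rpois(1, config$network_event_rate_hz * config$duration_s)
  net_frames <- sort(.uniform_frames(n_net, n_frames))
  event_frames <- vector("list", config$n_neurons)
  for (i in seq_len(config$n_neurons)) {
    joins <- if (n_net > 0)
      net_frames[stats::runif(n_net) < config$participation_prob]
    else integer(0)
    n_ind <- stats::rpois(1, config$indep_event_rate_hz * config$duration_s)
    own <- .uniform_frames(n_ind, n_frames)
    event_frames[[i]] <- sort(c(joins, own))
  }
  names(event_frames) <- paste0("roi_", seq_len(config$n_neurons))
  structure(list(event_frames = event_frames,
                 network_event_frames = net_frames,
                 n_frames = n_frames,
                 responsive_set = character(0),
                 response_prob = NA_real_,
                 config = config),
            class = "ground_truth")
}

.uniform_frames <- function(n, n_frames) {
  if (n == 0) return(integer(0))
  as.integer(floor(stats::runif(n, 0, n_frames)))
}

# amplitude ~ Normal(mean, sd) truncated at 0, by rejection
.draw_amplitudes <- function(n, mean, sd) {
  if (n == 0) return(numeric(0))
  if (sd == 0) return(rep(max(mean, 0), n))
  a <- stats::rnorm(n, mean, sd)
  while (any(bad <- a < 0)) a[bad] <- stats::rnorm(sum(bad), mean, sd)
  a
}

#' Forward model: spike trains to \eqn{\Delta F/F} traces
#'
#' Each event contributes one kernel transient scaled by a per-event
#' amplitude drawn from Normal(`amplitude_mean`, `amplitude_sd`) truncated
#' at zero; transients superpose linearly and i.i.d. Gaussian noise with SD
#' `noise_sd` is added.
#'
#' @param events a `ground_truth` from [generate_spikes()] /
#'   [generate_evoked_session()], or a plain list of per-neuron 0-based
#'   event-frame vectors.
#' @param kernel a [gcamp_kernel()].
#' @param config the [regime_config()] supplying frame rate, duration,
#'   amplitude and noise parameters.
#' @param seed RNG seed for amplitudes and noise; defaults to
#'   `split_seed(config$seed, 1)`.
#' @return a [trace_matrix()] on the `"dff"` scale.
#' @export
spikes_to_traces <- function(events, kernel = gcamp_kernel(), config,
                             seed = split_seed(config$seed, 1)) {
  stopifnot(inherits(config, "regime_config"))
  ev <- if (inherits(events, "ground_truth")) events$event_frames else events
  n_frames <- .n_frames_of(config)
  bad <- vapply(ev, function(f) length(f) > 0 && (min(f) < 0 || max(f) >= n_frames),
                logical(1))
  if (any(bad))
    stop("event frames out of range [0, n_frames) for: ",
         paste(names(ev)[bad], collapse = ", "), call. = FALSE)
  set.seed(seed)
  k <- sample_kernel(kernel, config$frame_rate_hz)
  m <- length(k)
  x <- matrix(0, nrow = length(ev), ncol = n_frames)
  for (i in seq_along(ev)) {
    frames <- ev[[i]]
    amps <- .draw_amplitudes(length(frames), config$amplitude_mean,
                             config$amplitude_sd)
    for (j in seq_along(frames)) {
      i0 <- frames[j] + 1L
      i1 <- min(n_frames, i0 + m - 1L)
      x[i, i0:i1] <- x[i, i0:i1] + amps[j] * k[seq_len(i1 - i0 + 1L)]
    }
  }
  if (config$noise_sd > 0)
    x <- x + matrix(stats::rnorm(length(x), 0, config$noise_sd), nrow(x))
  rn <- names(ev) %||% paste0("roi_", seq_along(ev))
  rownames(x) <- rn
  trace_matrix(x, frame_rate_hz = config$frame_rate_hz, scale = "dff")
}

#' Whisker stimulation protocol
#'
#' Describes a train of stimulation epochs: by default 10 stimuli of 1 s
#' duration (10 Hz deflections within each epoch, kept as metadata) with a
#' 10-s interstimulus interval, i.e. an 11-s cycle.
#'
#' @param onsets_s explicit stimulus onset times in seconds (sorted,
#'   non-overlapping); if `NULL`, built from the other arguments.
#' @param n_stimuli number of stimulation epochs.
#' @param epoch_duration_s duration of each stimulation epoch (s).
#' @param isi_s interstimulus interval, offset to next onset after an epoch
#'   ends (s).
#' @param first_onset_s time of the first onset (s).
#' @param within_freq_hz deflection frequency within an epoch (metadata).
#' @return object of class `stimulus_protocol`.
#' @export
stimulus_protocol <- function(onsets_s = NULL, n_stimuli = 10,
                              epoch_duration_s = 1, isi_s = 10,
                              first_onset_s = 10, within_freq_hz = 10) {
  .assert_scalar_num(epoch_duration_s, "epoch_duration_s", min = 1e-9)
  if (is.null(onsets_s)) {
    .assert_scalar_num(n_stimuli, "n_stimuli", min = 1)
    .assert_scalar_num(isi_s, "isi_s", min = 0)
    .assert_scalar_num(first_onset_s, "first_onset_s", min = 0)
    onsets_s <- first_onset_s +
      (seq_len(n_stimuli) - 1) * (epoch_duration_s + isi_s)
  }
  onsets_s <- as.numeric(onsets_s)
  if (is.unsorted(onsets_s, strictly = TRUE))
    stop("onsets must be strictly increasing", call. = FALSE)
  if (length(onsets_s) > 1 && any(diff(onsets_s) < epoch_duration_s))
    stop("stimulation epochs overlap", call. = FALSE)
  structure(list(onsets_s = onsets_s, n_stimuli = length(onsets_s),
                 epoch_duration_s = epoch_duration_s,
                 isi_s = if (length(onsets_s) > 1)
                   onsets_s[2] - onsets_s[1] - epoch_duration_s else isi_s,
                 within_freq_hz = within_freq_hz),
            class = "stimulus_protocol")
}

#' @export
print.stimulus_protocol <- function(x, ...) {
  cat(sprintf("<stimulus_protocol> %d stimuli, %.3g s epochs, %.3g s i.s.i., first onset %.3g s\n",
              x$n_stimuli, x$epoch_duration_s, x$isi_s, x$onsets_s[1]))
  invisible(x)
}

protocol_end_s <- function(protocol) {
  max(protocol$onsets_s) + protocol$epoch_duration_s
}

#' Simulate a whisker-evoked session
#'
#' Neurons in `responsive_set` emit, for each stimulus independently with
#' probability `response_prob`, one evoked event at a latency drawn
#' uniformly within the stimulation epoch; all neurons additionally follow
#' the spontaneous regime described by `config`.
#'
#' @inheritParams spikes_to_traces
#' @param protocol a [stimulus_protocol()]; must fit inside
#'   `config$duration_s`.
#' @param responsive_set ROI ids (e.g. `"roi_3"`) or integer indices of the
#'   designed responders.
#' @param response_prob per-stimulus response probability.
#' @return list of class `evoked_session` with `traces` (a `trace_matrix`,
#'   dff scale), `ground_truth` (with `responsive_set` and per-neuron event
#'   frames including evoked ones) and `protocol`.
#' @export
generate_evoked_session <- function(config, protocol = stimulus_protocol(),
                                    responsive_set = integer(0),
                                    response_prob = 0.8,
                                    kernel = gcamp_kernel(),
                                    seed = config$seed) {
  stopifnot(inherits(config, "regime_config"),
            inherits(protocol, "stimulus_protocol"))
  .assert_scalar_num(response_prob, "response_prob", min = 0, max = 1)
  if (protocol_end_s(protocol) > config$duration_s)
    stop("stimulation protocol extends beyond the recording", call. = FALSE)
  ids <- paste0("roi_", seq_len(config$n_neurons))
  if (is.numeric(responsive_set)) responsive_set <- ids[responsive_set]
  if (!all(responsive_set %in% ids))
    stop("responsive_set contains unknown ROI ids", call. = FALSE)

  spont_cfg <- config
  spont_cfg$seed <- split_seed(seed, 2)
  gt <- generate_spikes(spont_cfg)
  n_frames <- gt$n_frames

  set.seed(split_seed(seed, 3))
  for (id in responsive_set) {
    hit <- stats::runif(protocol$n_stimuli) < response_prob
    lat <- stats::runif(protocol$n_stimuli, 0, protocol$epoch_duration_s)
    t_ev <- (protocol$onsets_s + lat)[hit]
    f_ev <- pmin(as.integer(floor(t_ev * config$frame_rate_hz)), n_frames - 1L)
    gt$event_frames[[id]] <- sort(c(gt$event_frames[[id]], f_ev))
  }
  gt$responsive_set <- as.character(responsive_set)
  gt$response_prob <- response_prob
  traces <- spikes_to_traces(gt, kernel, config, seed = split_seed(seed, 4))
  structure(list(traces = traces, ground_truth = gt, protocol = protocol),
            class = "evoked_session")
}

#' Render traces into a synthetic movie
#'
#' Somata are drawn as 2-D Gaussian disks on a dark background, brightness
#' scaling with \eqn{1 + \Delta F/F}; an optional per-frame integer rigid
#' shift and Gaussian pixel noise are applied. The returned label mask gives
#' ground-truth ROI pixels in the unshifted coordinate frame.
#'
#' @param traces a `trace_matrix` (dff scale).
#' @param canvas `c(ny, nx)` image size in pixels; default 128 x 256.
#' @param roi_geometry data frame with columns `x`, `y` (0-based pixel
#'   centers) and `radius`; `NULL` lays ROIs out on a grid.
#' @param shifts integer matrix `n_frames x 2` of per-frame `(dx, dy)`
#'   drift, or `NULL` for none.
#' @param image_noise_sd SD of additive Gaussian pixel noise (counts).
#' @param baseline_brightness background level in counts.
#' @param roi_gain brightness of a resting soma above background (counts).
#' @param min_separation_px minimum allowed distance between ROI centers;
#'   closer centers are a configuration error.
#' @return list of class `synthetic_movie`: `movie` (array
#'   `frame x ny x nx`), `label_mask` (integer `ny x nx`), `shifts`,
#'   `roi_geometry`, `frame_rate_hz`.
#' @export
render_movie <- function(traces, canvas = c(128, 256), roi_geometry = NULL,
                         shifts = NULL, image_noise_sd = 0,
                         baseline_brightness = 100, roi_gain = 100,
                         min_separation_px = 8) {
  stopifnot(inherits(traces, "trace_matrix"))
  n_roi <- nrow(traces); nt <- ncol(traces)
  ny <- canvas[1]; nx <- canvas[2]
  if (is.null(roi_geometry)) roi_geometry <- .grid_layout(n_roi, ny, nx)
  stopifnot(nrow(roi_geometry) == n_roi,
            all(c("x", "y", "radius") %in% names(roi_geometry)))
  if (any(roi_geometry$x < 0 | roi_geometry$x >= nx |
          roi_geometry$y < 0 | roi_geometry$y >= ny))
    stop("ROI centers must lie inside the canvas", call. = FALSE)
  d <- as.matrix(stats::dist(roi_geometry[, c("x", "y")]))
  diag(d) <- Inf
  if (any(d < min_separation_px))
    stop("ROI centers closer than min_separation_px", call. = FALSE)
  if (is.null(shifts)) shifts <- matrix(0L, nt, 2)
  shifts <- matrix(as.integer(shifts), ncol = 2)
  stopifnot(nrow(shifts) == nt)

  px <- matrix(rep(seq_len(nx) - 1, each = ny), ny)   # x coordinate per pixel
  py <- matrix(rep(seq_len(ny) - 1, nx), ny)          # y coordinate per pixel
  profiles <- vector("list", n_roi)
  label_mask <- matrix(0L, ny, nx)
  for (i in seq_len(n_roi)) {
    r <- roi_geometry$radius[i]
    g <- exp(-((px - roi_geometry$x[i])^2 + (py - roi_geometry$y[i])^2) /
               (2 * (r / 2)^2))
    g[g < 1e-4] <- 0
    profiles[[i]] <- g
    inside <- (px - roi_geometry$x[i])^2 + (py - roi_geometry$y[i])^2 <= r^2
    label_mask[inside] <- i
  }
  movie <- array(0, dim = c(nt, ny, nx))
  for (t in seq_len(nt)) {
    img <- matrix(baseline_brightness, ny, nx)
    for (i in seq_len(n_roi))
      img <- img + roi_gain * profiles[[i]] * (1 + traces[i, t])
    img <- .shift_image(img, shifts[t, 1], shifts[t, 2],
                        fill = baseline_brightness)
    movie[t, , ] <- img
  }
  if (image_noise_sd > 0)
    movie <- movie + array(stats::rnorm(length(movie), 0, image_noise_sd),
                           dim = dim(movie))
  structure(list(movie = movie, label_mask = label_mask, shifts = shifts,
                 roi_geometry = roi_geometry,
                 frame_rate_hz = frame_rate(traces)),
            class = "synthetic_movie")
}

.grid_layout <- function(n_roi, ny, nx, radius = 3) {
  ncol_g <- ceiling(sqrt(n_roi * nx / ny))
  nrow_g <- ceiling(n_roi / ncol_g)
  # keep a margin so drift up to ~5 px never pushes a soma off-canvas
  xs <- seq(12, nx - 13, length.out = ncol_g)
  ys <- seq(12, ny - 13, length.out = max(nrow_g, 1))
  g <- expand.grid(x = xs, y = ys)[seq_len(n_roi), ]
  data.frame(x = round(g$x), y = round(g$y), radius = radius)
}

# translate image content by (dx, dy); vacated pixels get `fill`
.shift_image <- function(img, dx, dy, fill) {
  ny <- nrow(img); nx <- ncol(img)
  out <- matrix(fill, ny, nx)
  xs <- seq_len(nx); ys <- seq_len(ny)
  x_dst <- xs + dx; y_dst <- ys + dy
  okx <- x_dst >= 1 & x_dst <= nx
  oky <- y_dst >= 1 & y_dst <= ny
  out[y_dst[oky], x_dst[okx]] <- img[ys[oky], xs[okx]]
  out
}

#' Developmental stage presets
#'
#' Regime parameters for the three imaged ages. P11 is the immature regime:
#' infrequent population-wide events joined by most neurons. By P15 activity
#' is mostly independent sparse firing, and more so at P30, so the designed
#' population synchrony decreases strictly with age. Evoked-session presets
#' give the fraction of designed whisker-responders and their per-stimulus
#' response probability (low and unreliable at P11, peaking at P15).
#'
#' @return named list of per-stage parameter lists.
#' @export
stage_presets <- function() {
  list(
    P11 = list(network_event_rate_hz = 0.10, participation_prob = 0.75,
               indep_event_rate_hz = 0.02,
               responsive_frac = 0.2, response_prob = 0.5),
    P15 = list(network_event_rate_hz = 0.08, participation_prob = 0.40,
               indep_event_rate_hz = 0.06,
               responsive_frac = 0.6, response_prob = 0.85),
    P30 = list(network_event_rate_hz = 0.03, participation_prob = 0.20,
               indep_event_rate_hz = 0.07,
               responsive_frac = 0.4, response_prob = 0.85)
  )
}

#' Generate a full longitudinal synthetic dataset
#'
#' One spontaneous (60 s) and one whisker-evoked (120 s, 10 stimuli at 10-s
#' i.s.i.) session per developmental stage, sharing a single ROI identity
#' space, with per-session RNG substreams derived from the master seed via
#' [split_seed()]. Designed synchrony decreases strictly P11 > P15 > P30.
#'
#' @param seed master seed.
#' @param n_neurons shared number of ROIs.
#' @param presets stage preset list as from [stage_presets()].
#' @param kernel indicator kernel.
#' @param spont_duration_s,evoked_duration_s session lengths in seconds.
#' @param frame_rate_hz acquisition rate.
#' @return object of class `session_set`: list with `stages` (per stage:
#'   `spontaneous` trace matrix, `evoked` trace matrix, `protocol`,
#'   `ground_truth_spont`, `ground_truth_evoked`, `config`), `roi_ids`,
#'   `master_seed`.
#' @export
generate_developmental_dataset <- function(seed = 1, n_neurons = 30,
                                           presets = stage_presets(),
                                           kernel = gcamp_kernel(),
                                           spont_duration_s = 60,
                                           evoked_duration_s = 120,
                                           frame_rate_hz = 7.8) {
  ids <- paste0("roi_", seq_len(n_neurons))
  stages <- vector("list", length(presets))
  names(stages) <- names(presets)
  for (s in seq_along(presets)) {
    p <- presets[[s]]
    cfg_sp <- regime_config(
      n_neurons = n_neurons, duration_s = spont_duration_s,
      frame_rate_hz = frame_rate_hz,
      network_event_rate_hz = p$network_event_rate_hz,
      participation_prob = p$participation_prob,
      indep_event_rate_hz = p$indep_event_rate_hz,
      seed = split_seed(seed, 100 + s))
    gt_sp <- generate_spikes(cfg_sp)
    tr_sp <- spikes_to_traces(gt_sp, kernel, cfg_sp)
    cfg_ev <- cfg_sp
    cfg_ev$duration_s <- evoked_duration_s
    cfg_ev$seed <- split_seed(seed, 200 + s)
    n_resp <- round(p$responsive_frac * n_neurons)
    responsive <- ids[seq_len(n_resp)]
    ev <- generate_evoked_session(cfg_ev, stimulus_protocol(),
                                  responsive_set = responsive,
                                  response_prob = p$response_prob,
                                  kernel = kernel, seed = cfg_ev$seed)
    stages[[s]] <- list(spontaneous = tr_sp, evoked = ev$traces,
                        protocol = ev$protocol,
                        ground_truth_spont = gt_sp,
                        ground_truth_evoked = ev$ground_truth,
                        config = cfg_sp)
  }
  structure(list(stages = stages, roi_ids = ids,
                 master_seed = as.integer(seed)),
            class = "session_set")
}

#' @export
print.session_set <- function(x, ...) {
  cat(sprintf("<session_set> %d stages (%s), %d shared ROIs, master seed %d\n",
              length(x$stages), paste(names(x$stages), collapse = ", "),
              length(x$roi_ids), x$master_seed))
  invisible(x)
}
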