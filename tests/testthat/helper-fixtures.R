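# Shared fixture builders. Everything is generated in code; no files.

# quiet-background config: responders driven almost only by the stimulus
quiet_cfg <- function(seed, n_neurons = 1, duration_s = 120,
                      indep_rate = 0.02) {
  regime_config(n_neurons = n_neurons, duration_s = duration_s,
                network_event_rate_hz = 0, participation_prob = 0,
                indep_event_rate_hz = indep_rate, seed = seed)
}

# mature desynchronized background (P15-like spontaneous regime)
mature_cfg <- function(seed, n_neurons = 1, duration_s = 120) {
  regime_config(n_neurons = n_neurons, duration_s = duration_s,
                network_event_rate_hz = 0.08, participation_prob = 0.4,
                indep_event_rate_hz = 0.06, seed = seed)
}

# single synthetic z-scored spontaneous trace (numeric vector)
spont_z_trace <- function(seed, duration_s = 120, cfg_fn = mature_cfg) {
  cfg <- cfg_fn(seed, n_neurons = 1, duration_s = duration_s)
  tm <- spikes_to_traces(generate_spikes(cfg), gcamp_kernel(), cfg)
  as.numeric(modified_zscore(tm)[1, ])
}

# independent brute-force oracle: exhaustive quietest-window scan
oracle_quietest <- function(x, w) {
  best_sd <- Inf; best_s <- NA
  for (s in seq_len(length(x) - w + 1)) {
    v <- stats::sd(x[s:(s + w - 1)])
    if (v < best_sd) { best_sd <- v; best_s <- s }
  }
  list(start0 = best_s - 1L, sd = best_sd)
}

# independent brute-force oracle: scan runs of z >= thr frame by frame
oracle_epochs <- function(z, thr) {
  out <- NULL
  in_run <- FALSE; s <- NA
  for (t in seq_along(z)) {
    if (z[t] >= thr && !in_run) { in_run <- TRUE; s <- t }
    if ((z[t] < thr || t == length(z)) && in_run) {
      e <- if (z[t] < thr) t - 1L else t
      out <- rbind(out, c(s - 1L, e))  # 0-based half-open
      in_run <- FALSE
    }
  }
  out
}
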