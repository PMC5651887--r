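# Shared fixtures and independent oracles, built in code at test time.

# Reduced-axis configuration covering the 815-1065 cm-1 fitting region and
# three toluene calibration bands; used where many replicate cohorts are
# simulated.
quick_config <- function(seed = 1, effect_size = 2, noise_sd = 0.01,
                         spike_rate = 0.5, ...) {
  sim_config(
    axis_range = c(700, 1100), n_points = 401,
    band_library = data.frame(center = c(855, 900, 940, 1003),
                              sigma = c(12, 8, 9, 6),
                              amplitude = c(0.30, 0.35, 0.40, 1.00)),
    toluene_shifts = c(785.8, 1003.6, 1030.6),
    noise_sd = noise_sd, spike_rate = spike_rate,
    effect_size = effect_size, seed = seed, ...
  )
}

# A clean deterministic spectrum: bands only, no baseline/water/noise/spikes.
clean_band_spectrum <- function(center, sigma, amplitude,
                                axis = seq(600, 1800, by = 1),
                                sample_id = "clean") {
  raman_spectrum(axis, gaussian_mix(axis, center, sigma, amplitude),
                 sample_id)
}

# Exact two-sided Mann-Whitney p-value by complete enumeration of the
# C(n1+n2, n1) equally likely rank assignments (no ties assumed).
enum_mw_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  all_u <- apply(utils::combn(n1 + n2, n1), 2, function(ix)
    sum(ix) - n1 * (n1 + 1) / 2)
  min(1, 2 * min(mean(all_u <= u_obs), mean(all_u >= u_obs)))
}

# Rank-based concordance AUC (probability a pregnant score exceeds a
# nonpregnant one, ties counted half), independent of roc_analysis.
rank_auc <- function(scores, labels) {
  pos <- labels == "pregnant"
  r <- rank(scores)
  (sum(r[pos]) - sum(pos) * (sum(pos) + 1) / 2) / (sum(pos) * sum(!pos))
}
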