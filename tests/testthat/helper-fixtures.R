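# Fixtures and independent oracles shared across the suite. Everything is
# generated in code at test time; nothing is read from disk.

# A session with flat (frequency-independent) latent spectra, built directly
# from the path-additivity rule: channel (0,i) = limb + finger_i,
# channel (i,j) = finger_i + finger_j. Used for arithmetic-identity tests.
flat_session <- function(limb = 100, fingers = c(50, 60, 70, 80),
                         nfreq = 25, grid = frequency_grid()) {
  keys <- c("0-1", "0-2", "0-3", "0-4",
            "1-2", "1-3", "1-4", "2-3", "2-4", "3-4")
  channels <- matrix(NA_real_, length(keys), nfreq,
                     dimnames = list(keys, NULL))
  for (i in 1:4) channels[paste0("0-", i), ] <- limb + fingers[i]
  for (i in 1:3) for (j in (i + 1):4) {
    channels[paste(i, j, sep = "-"), ] <- fingers[i] + fingers[j]
  }
  structure(list(subject_id = "S01", day_index = 1L, repeat_index = 1L,
                 hand_temp_c = 33, placement_label = "P2",
                 channels = channels, grid = grid),
            class = "bis_session")
}

# Noise-free generator configuration (optionally drift-free too).
quiet_config <- function(drift = TRUE, ...) {
  if (drift) {
    study_config(noise_rel = 0, ...)
  } else {
    study_config(noise_rel = 0, sigma_day_limb = 0, sigma_day_finger = 0,
                 sigma_day_finger_idio = 0, ...)
  }
}

# --- open-set oracles -------------------------------------------------------

# AUC by direct Mann-Whitney pair counting: P(genuine > impostor) plus half
# the ties. Exactly the area under the threshold-swept ROC.
auc_pair_counting <- function(genuine, impostor) {
  wins <- 0
  for (g in genuine) {
    for (i in impostor) {
      wins <- wins + (g > i) + 0.5 * (g == i)
    }
  }
  wins / (length(genuine) * length(impostor))
}

# FAR/FRR at every candidate threshold by explicit counting.
far_frr_enumeration <- function(genuine, impostor) {
  thr <- sort(unique(c(genuine, impostor)))
  thr <- c(thr[1] - 1, thr, thr[length(thr)] + 1)
  far <- numeric(length(thr))
  frr <- numeric(length(thr))
  for (k in seq_along(thr)) {
    far[k] <- sum(impostor >= thr[k]) / length(impostor)
    frr[k] <- sum(genuine < thr[k]) / length(genuine)
  }
  data.frame(threshold = thr, far = far, frr = frr)
}

# Bracket for the EER from the enumeration: the crossing of the FAR and FRR
# step curves must lie between the adjacent enumerated operating points.
eer_bracket <- function(genuine, impostor) {
  e <- far_frr_enumeration(genuine, impostor)
  d <- e$far - e$frr
  k <- which(d <= 0)[1]
  vals <- c(e$far[k - 1], e$frr[k - 1], e$far[k], e$frr[k])
  c(lo = min(vals), hi = max(vals))
}

# --- shared heavy fixture ---------------------------------------------------
# RF ablation and day-accumulation accuracies under strong finger drift and
# placement jitter (15 subjects x 4 days x 8 repeats, 5 paired seeds),
# computed once and reused by several tests.

.ablation_cache <- new.env(parent = emptyenv())

ablation_results <- function() {
  if (!is.null(.ablation_cache$res)) {
    return(.ablation_cache$res)
  }
  cfg <- study_config(sigma_day_finger = 0.10, sigma_day_finger_idio = 0.04,
                      placement_jitter = c(0.90, 1.12))
  res <- lapply(101:105, function(sd) {
    st <- simulate_study(15, 4, 8, config = cfg, seed = sd)
    spec <- classifier_spec("rf", seed = sd)
    list(
      finger = cross_validated_accuracy(st, "finger", spec),
      limb = cross_validated_accuracy(st, "limb", spec),
      ratio_limb = cross_validated_accuracy(st, c("ratio", "limb"), spec),
      ratio_by_days = vapply(2:4, function(d)
        cross_validated_accuracy(accumulate_days(st, d), "ratio", spec),
        numeric(1)))
  })
  .ablation_cache$res <- res
  res
}
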