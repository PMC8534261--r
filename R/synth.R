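#' Synthetic study generator configuration
#'
#' Bundles the population ranges for the latent Cole spectra and the
#' condition model (day-to-day drift, hand temperature, finger placement,
#' device noise). All parameters of the data-generating process live here so
#' a study is reproducible from `config + seed` alone.
#'
#' Day-to-day physiological drift is lognormal and much stronger in the
#' fingers than in the limb. The finger drift has a component shared by all
#' four fingers (`sigma_day_finger`, the dominant, hydration/vasomotion-like
#' part, cancelled by ratiometric features) and a smaller per-finger
#' idiosyncratic component (`sigma_day_finger_idio`). Finger impedance rises
#' linearly as the hand cools below `t_ref` with slope `kappa` per degree
#' Celsius; the limb is temperature- and placement-invariant.
#'
#' @param grid measurement frequency grid (Hz), see [frequency_grid()].
#' @param limb_r0,finger_r0 uniform population ranges (ohm) for the
#'   low-frequency resistance of the limb and of each finger.
#' @param r_inf_frac uniform range for `r_inf` as a fraction of `r0`.
#' @param fc_range uniform range (Hz) for the characteristic frequency.
#' @param alpha_range uniform range for the Cole broadening exponent.
#' @param sigma_day_limb,sigma_day_finger,sigma_day_finger_idio lognormal
#'   sigmas of the per-subject-day drift factors (limb; shared across
#'   fingers; per-finger idiosyncratic).
#' @param kappa finger temperature coefficient (1/degC), impedance factor
#'   `1 + kappa * (t_ref - hand_temp_c)`.
#' @param t_ref reference hand temperature (degC) at which the factor is 1.
#' @param hand_temp nominal hand temperature (degC) outside sweeps.
#' @param temp_range temperature-sweep range (degC), swept high to low.
#' @param placement_levels named multiplicative placement factors for the
#'   three contact positions P1-P3 (P2 is the nominal position).
#' @param placement_jitter range of a per-session, per-finger uniform
#'   multiplicative placement factor; `c(1, 1)` disables jitter.
#' @param noise_rel relative device noise (sd of the multiplicative
#'   Gaussian perturbation per reading).
#' @return a list of class `study_config`.
#' @export
study_config <- function(grid = frequency_grid(),
                         limb_r0 = c(120, 260),
                         finger_r0 = c(300, 900),
                         r_inf_frac = c(0.4, 0.7),
                         fc_range = c(30e3, 200e3),
                         alpha_range = c(0.6, 0.9),
                         sigma_day_limb = 0.005,
                         sigma_day_finger = 0.05,
                         sigma_day_finger_idio = 0.02,
                         kappa = 0.01,
                         t_ref = 33,
                         hand_temp = 33,
                         temp_range = c(18, 32),
                         placement_levels = c(P1 = 0.90, P2 = 1.00, P3 = 1.12),
                         placement_jitter = c(1, 1),
                         noise_rel = 2e-5) {
  stopifnot(noise_rel >= 0, sigma_day_limb >= 0, sigma_day_finger >= 0,
            sigma_day_finger_idio >= 0, kappa >= 0,
            length(placement_jitter) == 2, all(placement_jitter > 0))
  structure(
    list(grid = grid, limb_r0 = limb_r0, finger_r0 = finger_r0,
         r_inf_frac = r_inf_frac, fc_range = fc_range,
         alpha_range = alpha_range,
         sigma_day_limb = sigma_day_limb,
         sigma_day_finger = sigma_day_finger,
         sigma_day_finger_idio = sigma_day_finger_idio,
         kappa = kappa, t_ref = t_ref, hand_temp = hand_temp,
         temp_range = temp_range, placement_levels = placement_levels,
         placement_jitter = placement_jitter, noise_rel = noise_rel),
    class = "study_config")
}

#' Draw one subject's latent ground truth
#'
#' Samples a limb Cole parameter set and four finger Cole parameter sets
#' from the population ranges of a [study_config()]. Uses the current RNG
#' stream (callers seed it).
#'
#' @param config a [study_config()].
#' @param subject_id subject label.
#' @return list of class `subject_truth` with elements `subject_id`, `limb`,
#'   `fingers` (list of 4), and the precomputed base spectra `limb_base`,
#'   `finger_base` (4 x n_freq matrix).
#' @export
draw_subject_truth <- function(config, subject_id) {
  draw_one <- function(r0_range) {
    r0 <- runif(1, r0_range[1], r0_range[2])
    r_inf <- runif(1, config$r_inf_frac[1], config$r_inf_frac[2]) * r0
    fc <- runif(1, config$fc_range[1], config$fc_range[2])
    alpha <- runif(1, config$alpha_range[1], config$alpha_range[2])
    cole_params(r_inf, r0, fc, alpha)
  }
  limb <- draw_one(config$limb_r0)
  fingers <- lapply(1:4, function(i) draw_one(config$finger_r0))
  finger_base <- t(vapply(fingers, cole_magnitude, numeric(length(config$grid)),
                          grid = config$grid))
  structure(
    list(subject_id = subject_id, limb = limb, fingers = fingers,
         limb_base = cole_magnitude(limb, config$grid),
         finger_base = finger_base),
    class = "subject_truth")
}

#' Apply measurement-day conditions to a latent spectrum
#'
#' Multiplies a base spectrum by (i) its subject-day drift factor, and, for
#' fingers only, (ii) the linear temperature factor
#' `1 + kappa * (t_ref - hand_temp_c)` and (iii) the placement factor.
#' Limb spectra are unaffected by temperature and placement by construction.
#'
#' @param base positive spectrum (ohm per frequency).
#' @param role `"limb"` or `"finger"`.
#' @param cond condition list with `hand_temp_c` and, for fingers,
#'   `placement` (scalar multiplicative factor).
#' @param day_factor the subject-day drift factor for this spectrum.
#' @param kappa,t_ref temperature model parameters (see [study_config()]).
#' @return the conditioned spectrum (ohm per frequency).
#' @export
apply_condition <- function(base, role = c("limb", "finger"), cond,
                            day_factor = 1, kappa = 0.01, t_ref = 33) {
  role <- match.arg(role)
  assert_positive_spectrum(base, "base spectrum")
  factor <- day_factor
  if (role == "finger") {
    temp <- cond$hand_temp_c %||% t_ref
    factor <- factor * (1 + kappa * (t_ref - temp)) * (cond$placement %||% 1)
  }
  out <- base * factor
  assert_positive_spectrum(out, "conditioned spectrum")
  out
}

#' Simulate one device placement (session)
#'
#' Composes the 10 channel spectra of one measurement from the conditioned
#' limb and finger spectra: channel (0, i) = limb + finger i; channel
#' (i, j) = finger i + finger j. Each channel is then perturbed by
#' multiplicative Gaussian device noise of relative sd `noise_rel`. Uses the
#' current RNG stream.
#'
#' @param truth a [draw_subject_truth()] result.
#' @param cond condition list: `day_index`, `repeat_index`, `hand_temp_c`,
#'   `placement_offsets` (length-4, per finger), `day_factors` (named:
#'   `limb`, `f1`..`f4`), optional `placement_label`.
#' @param config a [study_config()].
#' @return list of class `bis_session`: metadata plus `channels`, a
#'   10 x n_freq matrix with rownames `"0-1"`, ..., `"3-4"`.
#' @export
simulate_session <- function(truth, cond, config) {
  df <- cond$day_factors %||% c(limb = 1, f1 = 1, f2 = 1, f3 = 1, f4 = 1)
  offsets <- cond$placement_offsets %||% rep(1, 4)
  limb <- apply_condition(truth$limb_base, "limb", cond, df[["limb"]],
                          config$kappa, config$t_ref)
  fingers <- lapply(1:4, function(i) {
    ci <- cond
    ci$placement <- offsets[i]
    apply_condition(truth$finger_base[i, ], "finger", ci,
                    df[[paste0("f", i)]], config$kappa, config$t_ref)
  })
  pairs <- all_pairs()
  nfreq <- length(config$grid)
  channels <- matrix(NA_real_, nrow = length(pairs), ncol = nfreq,
                     dimnames = list(vapply(pairs, function(p)
                       pair_key(p[1], p[2]), character(1)), NULL))
  for (p in pairs) {
    spec <- if (p[1] == 0) limb + fingers[[p[2]]] else
      fingers[[p[1]]] + fingers[[p[2]]]
    if (config$noise_rel > 0) {
      spec <- spec * rnorm(nfreq, mean = 1, sd = config$noise_rel)
    }
    channels[pair_key(p[1], p[2]), ] <- spec
  }
  structure(
    list(subject_id = truth$subject_id,
         day_index = cond$day_index %||% 1L,
         repeat_index = cond$repeat_index %||% 1L,
         hand_temp_c = cond$hand_temp_c %||% config$hand_temp,
         placement_label = cond$placement_label %||% "P2",
         placement_offsets = offsets,
         day_factors = df,
         channels = channels, grid = config$grid),
    class = "bis_session")
}

#' Simulate a complete measurement study
#'
#' Generates a seeded, fully reproducible dataset of sessions for
#' `n_subjects` subjects over `n_days` measurement days with
#' `repeats_per_day` repeated placements per day. Three scenarios are
#' supported:
#'
#' * `"nominal"` — constant nominal hand temperature, nominal placement
#'   (plus optional placement jitter if enabled in the config);
#' * `"temperature_sweep"` — hand temperature swept from the warm to the
#'   cold end of `config$temp_range` across the repeats of each day,
#'   emulating a cooling-room experiment;
#' * `"placement_sweep"` — the three placement levels P1-P3 cycled across
#'   repeats on one designated finger.
#'
#' @param n_subjects,n_days,repeats_per_day study dimensions (all >= 1).
#' @param scenario one of `"nominal"`, `"temperature_sweep"`,
#'   `"placement_sweep"`.
#' @param config a [study_config()].
#' @param seed integer seed; identical `(config, seed)` give bit-identical
#'   studies.
#' @param placement_finger finger index (1-4) receiving the placement sweep.
#' @return list of class `bis_study`: `sessions` (list of `bis_session`),
#'   `truths` (list of `subject_truth`), `grid`, `config`, `scenario`,
#'   `seed` and the study dimensions.
#' @export
#' @examples
#' st <- simulate_study(3, 2, 2, seed = 1)
#' length(st$sessions) # 12
simulate_study <- function(n_subjects, n_days, repeats_per_day,
                           scenario = c("nominal", "temperature_sweep",
                                        "placement_sweep"),
                           config = study_config(), seed,
                           placement_finger = 1) {
  scenario <- match.arg(scenario)
  stopifnot(n_subjects >= 1, n_days >= 1, repeats_per_day >= 1)
  if (missing(seed)) stop("seed is required")
  with_seed(seed, {
    truths <- lapply(seq_len(n_subjects), function(s)
      draw_subject_truth(config, sprintf("S%02d", s)))
    sessions <- list()
    lev <- config$placement_levels
    for (s in seq_len(n_subjects)) {
      for (d in seq_len(n_days)) {
        day_factors <- c(
          limb = rlnorm(1, 0, config$sigma_day_limb),
          setNames(rlnorm(1, 0, config$sigma_day_finger) *
                     rlnorm(4, 0, config$sigma_day_finger_idio),
                   paste0("f", 1:4)))
        for (r in seq_len(repeats_per_day)) {
          temp <- config$hand_temp
          offsets <- rep(1, 4)
          label <- "P2"
          if (scenario == "temperature_sweep") {
            temp <- if (repeats_per_day == 1) mean(config$temp_range) else
              seq(max(config$temp_range), min(config$temp_range),
                  length.out = repeats_per_day)[r]
          } else if (scenario == "placement_sweep") {
            k <- (r - 1L) %% length(lev) + 1L
            offsets[placement_finger] <- lev[[k]]
            label <- names(lev)[k]
          }
          if (!identical(config$placement_jitter, c(1, 1))) {
            offsets <- offsets * runif(4, config$placement_jitter[1],
                                       config$placement_jitter[2])
          }
          cond <- list(day_index = d, repeat_index = r, hand_temp_c = temp,
                       placement_offsets = offsets, day_factors = day_factors,
                       placement_label = label)
          sessions[[length(sessions) + 1L]] <-
            simulate_session(truths[[s]], cond, config)
        }
      }
    }
    structure(
      list(sessions = sessions, truths = truths, grid = config$grid,
           config = config, scenario = scenario, seed = seed,
           n_subjects = n_subjects, n_days = n_days,
           repeats_per_day = repeats_per_day),
      class = "bis_study")
  })
}

#' @export
print.bis_study <- function(x, ...) {
  cat(sprintf(
    "<bis_study> %d sessions: %d subjects x %d days x %d repeats (%s)\n",
    length(x$sessions), x$n_subjects, x$n_days, x$repeats_per_day,
    x$scenario))
  cat(sprintf("  grid: %d frequencies, %.0f-%.0f kHz\n", length(x$grid),
              min(x$grid) / 1e3, max(x$grid) / 1e3))
  invisible(x)
}

# Session metadata as a data.frame (one row per session).
session_meta <- function(study) {
  data.frame(
    subject_id = vapply(study$sessions, `[[`, character(1), "subject_id"),
    day_index = vapply(study$sessions, `[[`, integer(1), "day_index"),
    repeat_index = vapply(study$sessions, `[[`, integer(1), "repeat_index"),
    hand_temp_c = vapply(study$sessions, `[[`, numeric(1), "hand_temp_c"),
    placement_label = vapply(study$sessions, `[[`, character(1),
                             "placement_label"),
    stringsAsFactors = FALSE)
}
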