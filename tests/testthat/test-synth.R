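test_that("condition model: limb is temperature/placement invariant, fingers scale", {
  base <- rep(200, 25)
  cold <- list(hand_temp_c = 23, placement = 0.9)

  # limb unchanged apart from its day factor
  expect_equal(apply_condition(base, "limb", cold, day_factor = 1), base)
  expect_equal(apply_condition(base, "limb", cold, day_factor = 1.02),
               base * 1.02)

  # neutral finger condition is the identity
  neutral <- list(hand_temp_c = 33, placement = 1)
  expect_equal(apply_condition(base, "finger", neutral, 1,
                               kappa = 0.01, t_ref = 33), base)

  # kappa = 0.01/degC, t_ref = 33, hand at 23 -> x1.10
  warm10 <- list(hand_temp_c = 23, placement = 1)
  expect_equal(apply_condition(base, "finger", warm10, 1,
                               kappa = 0.01, t_ref = 33), base * 1.10)

  # impedance must stay positive
  expect_error(apply_condition(base, "finger",
                               list(hand_temp_c = 200, placement = 1), 1),
               "positive")
})

test_that("session channels compose additively from limb and finger paths", {
  s <- flat_session(limb = 100, fingers = c(50, 60, 70, 80))
  expect_equal(unname(channel(s, 0, 1)), rep(150, 25))
  expect_equal(unname(channel(s, 0, 2)), rep(160, 25))
  expect_equal(unname(channel(s, 1, 2)), rep(110, 25))

  # simulated noiseless session obeys the same rule against ground truth
  cfg <- quiet_config(drift = FALSE)
  truth <- local({
    set.seed(5)
    draw_subject_truth(cfg, "S01")
  })
  cond <- list(day_index = 1L, repeat_index = 1L, hand_temp_c = 33,
               placement_offsets = rep(1, 4),
               day_factors = c(limb = 1, f1 = 1, f2 = 1, f3 = 1, f4 = 1))
  sess <- simulate_session(truth, cond, cfg)
  for (i in 1:4) {
    expect_equal(unname(channel(sess, 0, i)),
                 truth$limb_base + truth$finger_base[i, ])
  }
  expect_equal(unname(channel(sess, 2, 4)),
               truth$finger_base[2, ] + truth$finger_base[4, ])
})

test_that("path additivity recovers twice the limb for every finger pair", {
  cfg <- quiet_config()
  st <- simulate_study(3, 2, 2, config = cfg, seed = 11)
  for (sess in st$sessions) {
    two_limb <- lapply(limb_triples(), function(p)
      channel(sess, 0, p[1]) + channel(sess, 0, p[2]) -
        channel(sess, p[1], p[2]))
    for (k in 2:6) expect_equal(two_limb[[k]], two_limb[[1]])
  }
})

test_that("device noise stays within the Gaussian tail bound", {
  cfg0 <- quiet_config(drift = FALSE)
  cfgn <- study_config(noise_rel = 0.001, sigma_day_limb = 0,
                       sigma_day_finger = 0, sigma_day_finger_idio = 0)
  set.seed(3)
  truth <- draw_subject_truth(cfg0, "S01")
  cond <- list(day_index = 1L, repeat_index = 1L,
               day_factors = c(limb = 1, f1 = 1, f2 = 1, f3 = 1, f4 = 1),
               placement_offsets = rep(1, 4), hand_temp_c = 33)
  clean <- simulate_session(truth, cond, cfg0)$channels
  set.seed(99)
  rel <- replicate(100, {
    noisy <- simulate_session(truth, cond, cfgn)$channels
    abs(noisy / clean - 1)
  })
  # P(|N(0, 0.001)| > 0.005) ~ 5.7e-7; 25000 draws should essentially all pass
  expect_gte(mean(rel <= 0.005), 0.999)
})

test_that("studies are seed-deterministic with the right dimensions", {
  a <- simulate_study(4, 3, 5, seed = 21)
  b <- simulate_study(4, 3, 5, seed = 21)
  c <- simulate_study(4, 3, 5, seed = 22)
  expect_identical(a$sessions, b$sessions)
  expect_identical(a$truths, b$truths)
  expect_false(identical(a$sessions, c$sessions))
  expect_length(a$sessions, 60)
  expect_true(all(vapply(a$sessions, function(s)
    nrow(s$channels) == 10 && ncol(s$channels) == 25, logical(1))))
  expect_error(simulate_study(2, 2, 2, scenario = "banana", seed = 1))
})

test_that("subject limb spectra from continuous draws are almost surely distinct", {
  cfg <- study_config()
  set.seed(77)
  truths <- lapply(1:1000, function(i) draw_subject_truth(cfg, i))
  for (i in seq_len(999)) {
    expect_true(all(truths[[i]]$limb_base != truths[[i + 1]]$limb_base))
  }
})

test_that("temperature sweep: finger channels rise monotonically as hand cools, limb constant", {
  cfg <- quiet_config(drift = FALSE)
  st <- simulate_study(2, 1, 8, scenario = "temperature_sweep",
                       config = cfg, seed = 13)
  meta <- data.frame(
    subject = vapply(st$sessions, `[[`, character(1), "subject_id"),
    temp = vapply(st$sessions, `[[`, numeric(1), "hand_temp_c"))
  for (subj in unique(meta$subject)) {
    idx <- which(meta$subject == subj)
    ord <- idx[order(meta$temp[idx], decreasing = TRUE)]  # warm -> cold
    finger_band <- vapply(st$sessions[ord], function(s)
      band_average(channel(s, 1, 2)), numeric(1))
    limb_band <- vapply(st$sessions[ord], function(s)
      band_average(upper_limb_impedance(s, 1, 2)), numeric(1))
    expect_true(all(diff(finger_band) > 0))
    expect_equal(limb_band, rep(limb_band[1], length(limb_band)))
  }
})

test_that("placement sweep applies the configured P1-P3 factors to one finger", {
  cfg <- quiet_config(drift = FALSE)
  st <- simulate_study(1, 1, 3, scenario = "placement_sweep",
                       config = cfg, seed = 4, placement_finger = 2)
  labels <- vapply(st$sessions, `[[`, character(1), "placement_label")
  expect_identical(labels, c("P1", "P2", "P3"))
  f2 <- st$truths[[1]]$finger_base[2, ]
  f3 <- st$truths[[1]]$finger_base[3, ]
  for (k in 1:3) {
    fac <- cfg$placement_levels[[k]]
    expect_equal(unname(channel(st$sessions[[k]], 2, 3)), fac * f2 + f3)
  }
})
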