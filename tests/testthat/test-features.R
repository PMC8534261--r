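test_that("channel lookup is unordered and validates its pair", {
  s <- flat_session()
  expect_identical(channel(s, 1, 0), channel(s, 0, 1))
  expect_error(channel(s, 2, 2), "distinct")
  truncated <- s
  truncated$channels <- s$channels[rownames(s$channels) != "1-2", ,
                                   drop = FALSE]
  expect_error(channel(truncated, 1, 2), "missing")
})

test_that("upper-limb extraction is exact arithmetic on flat spectra", {
  s <- flat_session(limb = 100, fingers = c(50, 60, 70, 80))
  # (150 + 160 - 110) / 2 = 100 at every frequency
  expect_equal(unname(upper_limb_impedance(s, 1, 2)), rep(100, 25))
  for (p in limb_triples()) {
    expect_equal(unname(upper_limb_impedance(s, p[1], p[2])), rep(100, 25))
  }
})

test_that("all six limb triples recover the generator's conditioned limb exactly", {
  cfg <- quiet_config()
  st <- simulate_study(4, 3, 2, config = cfg, seed = 31)
  truth_of <- setNames(st$truths,
                       vapply(st$truths, `[[`, character(1), "subject_id"))
  for (sess in st$sessions) {
    # the ground-truth oracle: the conditioned limb this session was built on
    expected <- truth_of[[sess$subject_id]]$limb_base *
      sess$day_factors[["limb"]]
    for (p in limb_triples()) {
      got <- upper_limb_impedance(sess, p[1], p[2])
      expect_lt(max(abs(got / expected - 1)), 1e-12)
    }
  }
})

test_that("single-finger perturbations cancel out of every limb triple", {
  s <- flat_session(limb = 100, fingers = c(50, 60, 70, 80))
  for (c_fac in c(0.9, 1.12, 3)) {
    pert <- s
    # multiply finger 1's latent impedance by c: affects (0,1), (1,j)
    pert$channels["0-1", ] <- 100 + c_fac * 50
    for (j in 2:4) {
      pert$channels[paste0("1-", j), ] <-
        c_fac * 50 + c(50, 60, 70, 80)[j]
    }
    for (p in limb_triples()) {
      expect_equal(upper_limb_impedance(pert, p[1], p[2]),
                   upper_limb_impedance(s, p[1], p[2]))
    }
  }
})

test_that("ratiometric features: direct division, identity and scale invariance", {
  s <- flat_session(limb = 100, fingers = c(50, 60, 70, 80))
  r <- ratiometric_features(s)
  # channel(1,2) = 110, channel(3,4) = 150
  expect_equal(unname(r["ratio_e1e2_over_e3e4", ]), rep(110 / 150, 25))
  expect_equal(unname(r["ratio_e1e3_over_e1e2", ]), rep(120 / 110, 25))

  # identical finger-pair channels -> all ratios 1
  same <- flat_session(limb = 100, fingers = c(60, 60, 60, 60))
  expect_true(all(unclass(ratiometric_features(same)) == 1))

  # common multiplicative drift leaves ratios unchanged; raw shifts
  drift <- s
  for (i in 1:3) for (j in (i + 1):4) {
    k <- paste(i, j, sep = "-")
    drift$channels[k, ] <- 1.37 * s$channels[k, ]
  }
  expect_equal(ratiometric_features(drift), ratiometric_features(s),
               tolerance = 1e-14)
  expect_equal(unclass(raw_finger_features(drift)),
               1.37 * unclass(raw_finger_features(s)))

  # zero denominator is a hard error
  zs <- s
  zs$channels["3-4", 5] <- 0
  expect_error(ratiometric_features(zs), "denominator")
})

test_that("raw finger features follow the canonical pair order regardless of storage order", {
  s <- flat_session(limb = 100, fingers = c(50, 60, 70, 80))
  r <- raw_finger_features(s)
  expect_identical(rownames(r),
                   c("finger_e1e2", "finger_e1e3", "finger_e1e4",
                     "finger_e2e3", "finger_e2e4", "finger_e3e4"))
  expect_equal(unname(r["finger_e1e2", ]), rep(110, 25))
  expect_equal(unname(r["finger_e3e4", ]), rep(150, 25))
  shuffled <- s
  shuffled$channels <- s$channels[rev(rownames(s$channels)), ]
  expect_equal(raw_finger_features(shuffled), r)
})

test_that("feature vectors conserve length and layout across families", {
  s <- flat_session()
  limb <- limb_features(s)
  ratio <- ratiometric_features(s)
  expect_length(build_vector(limb, "flat"), 150)
  expect_length(build_vector(list(ratio, limb), "flat"), 300)
  ch <- build_vector(list(ratio, limb), "channels")
  expect_equal(dim(ch), c(25, 12))
  # flat layout concatenates combos in canonical order
  flat <- build_vector(limb, "flat")
  expect_equal(unname(flat[1:25]), unname(limb[1, ]))
  expect_equal(unname(flat[26:50]), unname(limb[2, ]))
  expect_error(build_vector(list(), "flat"), "at least one")
  short <- flat_session(nfreq = 10, grid = frequency_grid(20e3, 200e3, 20e3))
  expect_error(build_vector(list(limb, limb_features(short))), "grid")
})

test_that("study feature matrices have one row per session and family-scaled width", {
  st <- simulate_study(3, 2, 2, seed = 41)
  for (spec in list(list(f = "finger", p = 150), list(f = "limb", p = 150),
                    list(f = c("ratio", "limb"), p = 300))) {
    fm <- feature_matrix(st, spec$f)
    expect_equal(dim(fm$x), c(12, spec$p))
    expect_equal(fm$n_channels * 25, spec$p)
  }
  expect_error(feature_matrix(st, "iris"), "unknown feature family")
})
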