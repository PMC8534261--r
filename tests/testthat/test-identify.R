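test_that("fold plans are day-determined and leak-free", {
  st <- simulate_study(3, 5, 2, seed = 71)
  plan <- make_fold_plan(st)
  expect_equal(plan$n_folds, 5)
  day <- vapply(st$sessions, `[[`, integer(1), "day_index")
  for (f in seq_len(plan$n_folds)) {
    expect_length(unique(day[plan$fold == f]), 1)
    expect_length(intersect(day[plan$fold == f], day[plan$fold != f]), 0)
  }
  # shuffled session order yields the same plan
  shuffled <- with_seed(1, sample(day))
  expect_equal(make_fold_plan(shuffled)$fold, match(shuffled, sort(unique(day))))
  expect_error(make_fold_plan(rep(1L, 10)), ">= 2 distinct days")
})

test_that("day accumulation retains exactly the first d day labels", {
  st <- simulate_study(3, 5, 2, seed = 72)
  full <- accumulate_days(st, 5)
  expect_length(full$sessions, length(st$sessions))
  sub2 <- accumulate_days(st, 2)
  expect_true(all(vapply(sub2$sessions, `[[`, integer(1),
                         "day_index") %in% 1:2))
  counts <- vapply(2:5, function(d)
    length(accumulate_days(st, d)$sessions), integer(1))
  expect_equal(diff(counts), rep(6L, 3))  # 3 subjects x 2 repeats per day
  expect_error(accumulate_days(st, 1), "must lie in")
  expect_error(accumulate_days(st, 6), "must lie in")
})

test_that("pooled CV accuracy: perfect on separated features, chance on permuted labels", {
  st <- simulate_study(5, 3, 4, config = quiet_config(), seed = 73)
  expect_equal(cross_validated_accuracy(st, "limb", classifier_spec("knn")),
               100)

  # permutation null: destroy the label-feature link, keep the fold plan
  fm <- feature_matrix(st, "limb")
  perm <- with_seed(74, sample(fm$subject))
  plan <- make_fold_plan(fm$day)
  hits <- 0
  for (f in seq_len(plan$n_folds)) {
    te <- plan$fold == f
    ss <- train_and_score(classifier_spec("knn"), fm$x[!te, ], perm[!te],
                          fm$x[te, ])
    hits <- hits + sum(as.character(ss$predicted) ==
                         as.character(perm[te]))
  }
  acc <- 100 * hits / length(perm)
  expect_lt(acc, 45)  # chance is 20% for 5 subjects
})

test_that("confusion matrices are consistent with pooled accuracy", {
  st <- simulate_study(4, 3, 3, seed = 75)
  cv <- cross_validated_scores(st, "limb", classifier_spec("rf"))
  cm <- confusion(cv)
  expect_equal(100 * sum(diag(cm)) / sum(cm),
               100 * mean(cv$predicted == cv$true))
  expect_equal(unname(rowSums(cm)),
               unname(as.vector(table(cv$true))))
  expect_equal(unname(colSums(cm)),
               unname(as.vector(table(cv$predicted))))
  # all-correct scores give a diagonal matrix
  cm2 <- confusion(factor(c("a", "b", "b")), factor(c("a", "b", "b"),
                                                    levels = c("a", "b")))
  expect_equal(sum(cm2) - sum(diag(cm2)), 0)
})

test_that("open-set ROC: closed forms on separable and exchangeable scores", {
  # perfect separation
  r <- roc_open_set(list(genuine = rep(0.9, 5), impostor = rep(0.1, 7)))
  expect_equal(r$eer, 0)
  expect_equal(r$auc, 1)

  # same distribution -> EER 50%, AUC 0.5 at large n
  set.seed(76)
  u <- runif(4000)
  r2 <- roc_open_set(list(genuine = u[1:2000], impostor = u[2001:4000]))
  expect_equal(r2$eer, 50, tolerance = 0.05)
  expect_equal(r2$auc, 0.5, tolerance = 0.05)

  # hand-worked four-score case
  r3 <- roc_open_set(list(genuine = c(0.8, 0.6), impostor = c(0.7, 0.2)))
  expect_equal(r3$eer, 50)
  expect_equal(r3$auc, 0.75)  # 3 of 4 genuine/impostor pairs ordered

  expect_error(roc_open_set(list(genuine = numeric(0), impostor = 1)),
               "required")
})

test_that("EER and AUC agree with exhaustive enumeration on small score sets", {
  set.seed(77)
  score_grid <- seq(0.05, 0.95, by = 0.1)
  for (trial in 1:200) {
    ng <- sample(1:5, 1)
    ni <- sample(1:5, 1)
    g <- sample(score_grid, ng, replace = TRUE)
    i <- sample(score_grid, ni, replace = TRUE)
    r <- roc_open_set(list(genuine = g, impostor = i))
    expect_equal(r$auc, auc_pair_counting(g, i), tolerance = 1e-12)
    br <- eer_bracket(g, i)
    expect_gte(r$eer / 100, br[["lo"]] - 1e-12)
    expect_lte(r$eer / 100, br[["hi"]] + 1e-12)
  }
})

test_that("evaluate_study produces a coherent closed- and open-set report", {
  st <- simulate_study(5, 3, 3, seed = 78)
  rep1 <- evaluate_study(st, "ratio+limb", classifier_spec("rf"))
  expect_s3_class(rep1, "eval_report")
  expect_equal(rep1$accuracy,
               100 * sum(diag(rep1$confusion)) / sum(rep1$confusion))
  expect_true(rep1$auc >= 0 && rep1$auc <= 1)
  expect_equal(rep1$families, "ratiometric+upper_limb")
  expect_equal(rep1$n_sessions, 45)
  rep2 <- evaluate_study(st, "limb", classifier_spec("rf"), days = 2)
  expect_equal(rep2$days, 2)
  expect_equal(rep2$n_sessions, 30)
})

test_that("asymptote fitter recovers exact decay parameters", {
  n <- c(5, 10, 15, 20, 25, 30)
  truth <- c(a_inf = 95.2, b = 18, c = 1.3)
  acc <- truth["a_inf"] + truth["b"] * exp(-truth["c"] * log(n))
  fit <- fit_accuracy_asymptote(n, acc)
  expect_equal(unname(fit["a_inf"]), 95.2, tolerance = 1e-6)
  expect_equal(unname(fit["b"]), 18, tolerance = 1e-5)
  expect_equal(unname(fit["c"]), 1.3, tolerance = 1e-5)
})

test_that("scalability: full-cohort draws are deterministic, subsets honour counts", {
  st <- simulate_study(6, 3, 3, seed = 79)
  sc <- scalability_curve(st, subject_counts = c(3, 6), n_repeats = 3,
                          spec = classifier_spec("rf"), families = "limb",
                          seed = 80)
  expect_equal(sc$curve$n_subjects, c(3, 6))
  # count = full cohort: every draw is the same subject set -> sd 0
  expect_equal(sc$curve$sd_accuracy[2], 0)
  expect_error(scalability_curve(st, subject_counts = 7), "exceeds")
})
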