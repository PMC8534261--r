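# Closed-set and open-set identification under date-stratified
# cross-validation, plus cohort-scalability analysis.

#' Date-stratified fold plan
#'
#' One fold per distinct measurement day: a session's fold is determined
#' solely by its day label, so train and test folds never share a day and
#' same-day physiological state cannot leak across the split.
#'
#' @param day integer vector of per-session day labels (or a `bis_study`).
#' @return list of class `fold_plan`: `days` (sorted distinct labels),
#'   `n_folds`, and `fold` (per-session fold id).
#' @export
make_fold_plan <- function(day) {
  if (inherits(day, "bis_study")) day <- session_meta(day)$day_index
  days <- sort(unique(day))
  if (length(days) < 2) stop("date-stratified CV needs >= 2 distinct days")
  structure(list(days = days, n_folds = length(days),
                 fold = match(day, days)),
            class = "fold_plan")
}

#' Restrict a study to the first d measurement days
#'
#' Keeps sessions whose day label is among the `d` earliest distinct
#' labels, emulating accumulating enrolment days.
#'
#' @param study a `bis_study`.
#' @param d number of days to retain, `2 <= d <=` number of distinct days.
#' @return a `bis_study` with the retained sessions.
#' @export
accumulate_days <- function(study, d) {
  days <- sort(unique(session_meta(study)$day_index))
  if (d < 2 || d > length(days)) {
    stop(sprintf("d must lie in [2, %d]", length(days)))
  }
  keep <- session_meta(study)$day_index %in% days[seq_len(d)]
  out <- study
  out$sessions <- study$sessions[keep]
  out$n_days <- d
  out
}

# Restrict a study to a subset of subjects.
subset_subjects <- function(study, subjects) {
  keep <- session_meta(study)$subject_id %in% subjects
  out <- study
  out$sessions <- study$sessions[keep]
  out$n_subjects <- length(unique(subjects))
  out
}

#' Cross-validated identification scores
#'
#' Runs day-fold cross-validation of one classifier on one feature-family
#' selection and pools the per-sample scores over all folds. Every fold is
#' checked for day leakage (empty train/test day intersection) before
#' fitting.
#'
#' @param study a `bis_study`.
#' @param families feature families (see [feature_matrix()]).
#' @param spec a [classifier_spec()].
#' @return list of class `cv_scores`: `true` (factor), `predicted`
#'   (factor), `scores` (n x n_classes posterior matrix), `fold`
#'   (per-sample test fold), `classes`.
#' @export
cross_validated_scores <- function(study, families = "limb",
                                   spec = classifier_spec("rf")) {
  fm <- feature_matrix(study, families)
  plan <- make_fold_plan(fm$day)
  classes <- levels(fm$subject)
  n <- nrow(fm$x)
  scores <- matrix(NA_real_, n, length(classes),
                   dimnames = list(NULL, classes))
  predicted <- factor(rep(NA, n), levels = classes)
  for (f in seq_len(plan$n_folds)) {
    test <- plan$fold == f
    stopifnot(length(intersect(fm$day[!test], fm$day[test])) == 0)
    fold_spec <- spec
    fold_spec$seed <- derive_seed(spec$seed, f)
    ss <- train_and_score(fold_spec, fm$x[!test, , drop = FALSE],
                          fm$subject[!test], fm$x[test, , drop = FALSE],
                          n_channels = fm$n_channels)
    scores[test, ss$classes] <- ss$scores
    predicted[test] <- factor(as.character(ss$predicted), levels = classes)
  }
  scores[is.na(scores)] <- 0  # classes absent from a fold's training days
  structure(list(true = fm$subject, predicted = predicted, scores = scores,
                 fold = plan$fold, classes = classes),
            class = "cv_scores")
}

#' Pooled cross-validated accuracy
#'
#' Correct predictions divided by total test predictions, pooled over all
#' day folds, as a percentage.
#'
#' @inheritParams cross_validated_scores
#' @return accuracy in percent.
#' @export
cross_validated_accuracy <- function(study, families = "limb",
                                     spec = classifier_spec("rf")) {
  cv <- cross_validated_scores(study, families, spec)
  100 * mean(cv$predicted == cv$true)
}

#' Confusion matrix of a score set
#'
#' @param scores a `cv_scores` or `score_set` with `predicted`, or a factor
#'   of true labels with `predicted` given separately.
#' @param predicted predicted labels (when `scores` is a factor).
#' @return class x class contingency table, rows = true, columns =
#'   predicted; `sum(diag(.)) / sum(.)` equals the pooled accuracy.
#' @export
confusion <- function(scores, predicted = NULL) {
  if (is.list(scores)) {
    true <- scores$true
    predicted <- scores$predicted
  } else {
    true <- scores
  }
  table(true = true, predicted = predicted)
}

# Genuine and impostor posterior populations of a cv_scores object.
genuine_impostor <- function(cv) {
  ti <- match(as.character(cv$true), colnames(cv$scores))
  idx <- cbind(seq_len(nrow(cv$scores)), ti)
  list(genuine = cv$scores[idx], impostor = cv$scores[-(
    (ti - 1) * nrow(cv$scores) + seq_len(nrow(cv$scores)))])
}

#' Open-set ROC, equal error rate and AUC
#'
#' Sweeps an acceptance threshold over pooled genuine (true-class
#' posterior) and impostor (other-class posterior) score populations. At
#' threshold t, FAR is the fraction of impostor scores >= t and FRR the
#' fraction of genuine scores < t. The EER is found by linear interpolation
#' where FAR crosses FRR; the AUC is the trapezoidal area under the
#' (FAR, 1 - FRR) curve.
#'
#' @param scores a `cv_scores` object, or a list with numeric elements
#'   `genuine` and `impostor`.
#' @return list of class `roc_report`: `roc` (data.frame `threshold`,
#'   `far`, `frr`), `eer` (percent), `auc` (in `[0, 1]`).
#' @export
#' @examples
#' roc_open_set(list(genuine = c(0.9, 0.8), impostor = c(0.1, 0.2)))$eer # 0
roc_open_set <- function(scores) {
  if (inherits(scores, "cv_scores")) scores <- genuine_impostor(scores)
  g <- scores$genuine
  i <- scores$impostor
  if (length(g) == 0 || length(i) == 0) {
    stop("both genuine and impostor scores are required")
  }
  thr <- sort(unique(c(g, i)))
  thr <- c(thr[1] - 1, thr, thr[length(thr)] + 1)
  far <- vapply(thr, function(t) mean(i >= t), numeric(1))
  frr <- vapply(thr, function(t) mean(g < t), numeric(1))
  # EER: FAR is non-increasing and FRR non-decreasing in t; interpolate
  # the sign change of (FAR - FRR).
  d <- far - frr
  k <- which(d <= 0)[1]
  eer <- if (k == 1) {
    (far[1] + frr[1]) / 2
  } else if (d[k] == d[k - 1]) {
    (far[k] + frr[k]) / 2
  } else {
    w <- d[k - 1] / (d[k - 1] - d[k])
    fa <- far[k - 1] + w * (far[k] - far[k - 1])
    fr <- frr[k - 1] + w * (frr[k] - frr[k - 1])
    (fa + fr) / 2
  }
  ord <- order(far, 1 - frr)
  auc <- sum(diff(far[ord]) * (head(1 - frr[ord], -1) +
                                 diff(1 - frr[ord]) / 2))
  structure(list(roc = data.frame(threshold = thr, far = far, frr = frr),
                 eer = 100 * eer, auc = auc),
            class = "roc_report")
}

#' Full evaluation of one configuration
#'
#' Convenience wrapper producing the complete closed- and open-set report
#' for one feature selection, classifier and (optionally) accumulated day
#' count.
#'
#' @inheritParams cross_validated_scores
#' @param days optional number of accumulated days to retain first.
#' @return list of class `eval_report`: `accuracy` (percent), `eer`
#'   (percent), `auc`, `confusion`, `roc` (data.frame), `n_sessions`,
#'   `families`, `classifier`, `days`.
#' @export
evaluate_study <- function(study, families = "limb",
                           spec = classifier_spec("rf"), days = NULL) {
  if (!is.null(days)) study <- accumulate_days(study, days)
  cv <- cross_validated_scores(study, families, spec)
  roc <- roc_open_set(cv)
  structure(list(accuracy = 100 * mean(cv$predicted == cv$true),
                 eer = roc$eer, auc = roc$auc,
                 confusion = confusion(cv), roc = roc$roc,
                 n_sessions = length(cv$true),
                 families = paste(normalise_families(families),
                                  collapse = "+"),
                 classifier = spec$kind,
                 days = length(unique(session_meta(study)$day_index))),
            class = "eval_report")
}

#' Accuracy versus cohort size, with asymptote fit
#'
#' Draws random subject subsets of increasing size, computes the
#' day-fold cross-validated accuracy for each draw, and fits the decay
#' model `a(n) = a_inf + b * exp(-c * log(n))` (a log-scale exponential,
#' equivalently `a_inf + b * n^-c`) to the mean accuracies.
#'
#' @param study a `bis_study`.
#' @param subject_counts increasing cohort sizes to test (each <= number of
#'   subjects in the study).
#' @param n_repeats random subset draws per count (sd is 0 when the count
#'   equals the full cohort).
#' @param spec classifier (default RF).
#' @param families feature families.
#' @param seed seed for the subset draws.
#' @return list of class `scalability_report`: `curve` (data.frame
#'   `n_subjects`, `mean_accuracy`, `sd_accuracy`), `a_inf` (fitted
#'   asymptote, percent), `fit` coefficients.
#' @export
scalability_curve <- function(study, subject_counts, n_repeats = 10,
                              spec = classifier_spec("rf"),
                              families = "limb", seed = 1) {
  all_subj <- unique(session_meta(study)$subject_id)
  if (max(subject_counts) > length(all_subj)) {
    stop("subject count exceeds cohort size")
  }
  rows <- list()
  for (ci in seq_along(subject_counts)) {
    cnt <- subject_counts[ci]
    acc <- vapply(seq_len(n_repeats), function(r) {
      pick <- with_seed(derive_seed(seed, ci * 1000 + r),
                        sample(all_subj, cnt))
      cross_validated_accuracy(subset_subjects(study, pick),
                               families, spec)
    }, numeric(1))
    rows[[ci]] <- data.frame(n_subjects = cnt, mean_accuracy = mean(acc),
                             sd_accuracy = sd(acc))
  }
  curve <- do.call(rbind, rows)
  fit <- if (nrow(curve) >= 3) {
    fit_accuracy_asymptote(curve$n_subjects, curve$mean_accuracy)
  } else {
    c(a_inf = NA_real_, b = NA_real_, c = NA_real_)  # underdetermined
  }
  structure(list(curve = curve, a_inf = fit[["a_inf"]], fit = fit),
            class = "scalability_report")
}

#' Fit the accuracy-decay asymptote
#'
#' Least-squares fit of `a(n) = a_inf + b * exp(-c * log(n))` to accuracy
#' versus cohort size, returning the converged asymptote `a_inf`.
#'
#' @param n cohort sizes.
#' @param accuracy accuracies (percent).
#' @return named vector `a_inf`, `b`, `c`.
#' @export
fit_accuracy_asymptote <- function(n, accuracy) {
  stopifnot(length(n) >= 3, length(n) == length(accuracy))
  # the model is linear in (a_inf, b) for fixed c: profile the decay rate,
  # then polish with Levenberg-Marquardt. The profiling step keeps the fit
  # well-behaved on flat (saturated) accuracy curves where b ~ 0.
  profile_fit <- function(c_val) {
    lm(accuracy ~ I(exp(-c_val * log(n))))
  }
  rss <- function(c_val) sum(residuals(profile_fit(c_val))^2)
  c_hat <- optimize(rss, c(1e-3, 10), tol = 1e-10)$minimum
  co <- coef(profile_fit(c_hat))
  # accuracy is a percentage, so the asymptote is constrained to [0, 100]
  # and the decay amplitude/rate to be non-negative
  lower <- c(a_inf = 0, b = 0, c = 1e-3)
  upper <- c(a_inf = 100, b = 500, c = 10)
  start <- pmin(pmax(c(a_inf = co[[1]], b = co[[2]], c = c_hat), lower),
                upper)
  fit <- tryCatch(
    coef(minpack.lm::nlsLM(
      accuracy ~ a_inf + b * exp(-c * log(n)),
      data = data.frame(n = n, accuracy = accuracy),
      start = as.list(start), lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = 500))),
    error = function(e) start)
  setNames(as.numeric(fit), c("a_inf", "b", "c"))
}
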