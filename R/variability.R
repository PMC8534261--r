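# Reproducibility analyses: coefficient of variation across days,
# band-averaged temperature response, PCA cluster views.

#' Coefficient of variation
#'
#' Sample standard deviation (n - 1 denominator) divided by the mean; the
#' scale-free dispersion measure used for day-to-day repeatability.
#'
#' @param values numeric vector, length >= 2, nonzero mean.
#' @return dimensionless CV.
#' @export
#' @examples
#' coefficient_of_variation(c(8, 10, 12)) # 0.2
coefficient_of_variation <- function(values) {
  if (length(values) < 2) stop("CV requires at least 2 values")
  m <- mean(values)
  if (m == 0) stop("CV undefined for zero mean")
  sd(values) / m
}

#' Band-averaged impedance
#'
#' Arithmetic mean of a spectrum over the full measurement band.
#'
#' @param spectrum numeric vector, one value per grid frequency.
#' @param grid the frequency grid the spectrum must cover (default: the
#'   standard 25-point grid).
#' @return scalar mean (ohm, or dimensionless for ratio spectra).
#' @export
band_average <- function(spectrum, grid = frequency_grid()) {
  if (length(spectrum) != length(grid)) {
    stop("spectrum does not cover the full frequency grid")
  }
  mean(spectrum)
}

#' Day-to-day coefficient-of-variation profile
#'
#' For each subject, combo and frequency: average the repeated measurements
#' within each day, then compute the CV across the daily means. Per-combo
#' CVs are averaged into a family-level CV per subject and frequency, and
#' the profile reports the mean and standard deviation across subjects.
#'
#' @param study a `bis_study`.
#' @param family feature family (`"finger"`, `"ratio"` or `"limb"`, see
#'   [feature_matrix()]).
#' @return data.frame with columns `family`, `frequency`, `cv_mean`,
#'   `cv_sd`, one row per grid frequency. Subjects with fewer than two
#'   distinct days are excluded with a warning.
#' @export
daily_cv_profile <- function(study, family = "limb") {
  fam <- normalise_families(family)
  stopifnot(length(fam) == 1)
  meta <- session_meta(study)
  nfreq <- length(study$grid)
  vals <- lapply(study$sessions, feature_set, family = fam)
  subjects <- unique(meta$subject_id)
  per_subject <- list()
  for (s in subjects) {
    idx <- which(meta$subject_id == s)
    days <- unique(meta$day_index[idx])
    if (length(days) < 2) {
      warning(sprintf("subject %s has a single day; excluded from CV", s))
      next
    }
    # daily means: day x combo x freq
    daily <- vapply(days, function(d) {
      di <- idx[meta$day_index[idx] == d]
      Reduce(`+`, lapply(vals[di], unclass)) / length(di)
    }, matrix(0, 6, nfreq))
    # CV across days, per combo and frequency, then average over combos
    cv <- apply(daily, c(1, 2), coefficient_of_variation)
    per_subject[[s]] <- colMeans(cv)
  }
  if (length(per_subject) == 0) stop("no subject has two or more days")
  m <- do.call(rbind, per_subject)
  data.frame(family = fam, frequency = study$grid,
             cv_mean = colMeans(m),
             cv_sd = apply(m, 2, sd),
             row.names = NULL)
}

#' Band-averaged impedance response to hand temperature
#'
#' For each subject and feature family, regresses the session band-averaged
#' family value (mean over the six combos) on hand temperature: the
#' ordinary-least-squares slope and the Pearson correlation. In the
#' generator's noiseless linear temperature model, finger-derived families
#' have negative slope and correlation -1 while the limb slope is zero.
#'
#' @param study a `bis_study`, typically from the `"temperature_sweep"`
#'   scenario, covering >= 3 distinct temperatures.
#' @param families families to analyse (default all three).
#' @return data.frame with columns `family`, `subject_id`, `slope`
#'   (ohm/degC), `correlation`.
#' @export
temperature_response <- function(study,
                                 families = c("finger", "ratio", "limb")) {
  meta <- session_meta(study)
  if (length(unique(meta$hand_temp_c)) < 3) {
    stop("temperature response needs >= 3 distinct temperatures")
  }
  out <- list()
  for (family in families) {
    fam <- normalise_families(family)
    value <- vapply(study$sessions, function(s)
      mean(rowMeans(feature_set(s, fam))), numeric(1))
    for (s in unique(meta$subject_id)) {
      idx <- meta$subject_id == s
      tt <- meta$hand_temp_c[idx]
      vv <- value[idx]
      if (var(tt) == 0) stop("constant temperature for subject ", s)
      slope <- coef(lm(vv ~ tt))[["tt"]]
      r <- if (var(vv) == 0) 0 else cor(tt, vv)
      out[[length(out) + 1]] <- data.frame(
        family = fam, subject_id = s, slope = slope, correlation = r)
    }
  }
  do.call(rbind, out)
}

#' Principal-component embedding of a feature matrix
#'
#' Column-centred (not variance-scaled) PCA via singular value
#' decomposition. The sign of each component is fixed by making its
#' largest-magnitude loading positive, so embeddings are deterministic.
#'
#' @param x numeric matrix, samples in rows.
#' @param k number of components (default 3).
#' @return list of class `pca_embedding`: `scores` (n x k),
#'   `explained_variance` (length k, non-increasing), `loadings` (p x k).
#' @export
pca_embedding <- function(x, k = 3) {
  x <- as.matrix(x)
  if (nrow(x) < k) stop("need at least k samples")
  p <- prcomp(x, center = TRUE, scale. = FALSE)
  k <- min(k, ncol(p$rotation))
  rot <- p$rotation[, seq_len(k), drop = FALSE]
  sc <- p$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) {
      rot[, j] <- -rot[, j]
      sc[, j] <- -sc[, j]
    }
  }
  structure(list(scores = sc, explained_variance = p$sdev[seq_len(k)]^2,
                 loadings = rot),
            class = "pca_embedding")
}
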