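# Long-format CSV interchange (no standard container exists for
# multi-channel bioimpedance spectra), JSON/CSV evaluation reports, and
# run configuration files.

#' Write a study as long-format CSV
#'
#' One row per (session, electrode pair, frequency) with columns
#' `subject_id, day_index, repeat_index, electrode_a, electrode_b,
#' frequency_hz, impedance_ohm, hand_temp_c, placement_label`. Impedance is
#' written with enough decimal digits for a lossless round trip at 9
#' significant figures.
#'
#' @param study a `bis_study`.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_study_csv <- function(study, path) {
  pairs <- all_pairs()
  nfreq <- length(study$grid)
  npair <- length(pairs)
  rows <- lapply(study$sessions, function(s) {
    data.frame(
      subject_id = s$subject_id,
      day_index = s$day_index,
      repeat_index = s$repeat_index,
      electrode_a = rep(vapply(pairs, `[`, numeric(1), 1), each = nfreq),
      electrode_b = rep(vapply(pairs, `[`, numeric(1), 2), each = nfreq),
      frequency_hz = rep(study$grid, npair),
      impedance_ohm = sprintf("%.12g", as.numeric(t(s$channels))),
      hand_temp_c = s$hand_temp_c,
      placement_label = s$placement_label,
      stringsAsFactors = FALSE)
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a long-format study CSV
#'
#' Validates the schema, the completeness of every session (all 10
#' electrode pairs, every grid frequency, positive impedance) and
#' reassembles `bis_session` objects.
#'
#' @param path CSV path as written by [write_study_csv()] (or produced by a
#'   real device in the same schema).
#' @return a `bis_study` (without latent ground truths).
#' @export
read_study_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop("empty dataset: no measurement rows in ", path)
  required <- c("subject_id", "day_index", "repeat_index", "electrode_a",
                "electrode_b", "frequency_hz", "impedance_ohm")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("missing required columns: ", paste(missing, collapse = ", "))
  }
  if (any(df$impedance_ohm <= 0)) stop("non-positive impedance values")
  grid <- sort(unique(df$frequency_hz))
  expected_keys <- vapply(all_pairs(), function(p) pair_key(p[1], p[2]),
                          character(1))
  key <- paste(df$subject_id, df$day_index, df$repeat_index, sep = "|")
  sessions <- lapply(split(seq_len(nrow(df)), key), function(idx) {
    sub <- df[idx, ]
    pk <- vapply(seq_len(nrow(sub)), function(i)
      pair_key(sub$electrode_a[i], sub$electrode_b[i]), character(1))
    absent <- setdiff(expected_keys, unique(pk))
    if (length(absent) > 0) {
      stop(sprintf("incomplete session %s/%s/%s: missing pair(s) %s",
                   sub$subject_id[1], sub$day_index[1], sub$repeat_index[1],
                   paste(absent, collapse = ", ")))
    }
    channels <- matrix(NA_real_, length(expected_keys), length(grid),
                       dimnames = list(expected_keys, NULL))
    for (k in expected_keys) {
      ss <- sub[pk == k, ]
      if (!identical(sort(ss$frequency_hz), grid)) {
        stop(sprintf("session %s/%s/%s pair %s does not cover the grid",
                     sub$subject_id[1], sub$day_index[1],
                     sub$repeat_index[1], k))
      }
      channels[k, ] <- ss$impedance_ohm[order(ss$frequency_hz)]
    }
    structure(
      list(subject_id = as.character(sub$subject_id[1]),
           day_index = as.integer(sub$day_index[1]),
           repeat_index = as.integer(sub$repeat_index[1]),
           hand_temp_c = as.numeric(sub$hand_temp_c[1] %||% NA),
           placement_label = as.character(sub$placement_label[1] %||% "P2"),
           channels = channels, grid = grid),
      class = "bis_session")
  })
  names(sessions) <- NULL
  meta_order <- order(vapply(sessions, `[[`, character(1), "subject_id"),
                      vapply(sessions, `[[`, integer(1), "day_index"),
                      vapply(sessions, `[[`, integer(1), "repeat_index"))
  sessions <- sessions[meta_order]
  message(sprintf("read %d rows, %d sessions from %s", nrow(df),
                  length(sessions), path))
  structure(
    list(sessions = sessions, truths = NULL, grid = grid,
         config = study_config(grid = grid), scenario = "file",
         seed = NA_integer_,
         n_subjects = length(unique(df$subject_id)),
         n_days = length(unique(df$day_index)),
         repeats_per_day = max(df$repeat_index)),
    class = "bis_study")
}

#' Write an evaluation report to disk
#'
#' Emits `report.json` (schema-versioned summary with accuracy, EER and
#' AUC; AUC also formatted with 4 decimals and EER with 2), `roc.csv` (the
#' threshold sweep) and `confusion.csv` (true x predicted counts, labelled
#' by subject id) under `dir`.
#'
#' @param report an [evaluate_study()] result.
#' @param dir output directory (created if absent).
#' @return invisible character vector of the files written.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "eval_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  json_path <- file.path(dir, "report.json")
  jsonlite::write_json(
    list(schema_version = "1.0",
         classifier = report$classifier,
         families = report$families,
         days = report$days,
         n_sessions = report$n_sessions,
         accuracy_pct = report$accuracy,
         eer_pct = report$eer,
         auc = report$auc,
         eer_printed = sprintf("%.2f", report$eer),
         auc_printed = sprintf("%.4f", report$auc)),
    json_path, auto_unbox = TRUE, digits = NA)
  roc_path <- file.path(dir, "roc.csv")
  write.csv(report$roc, roc_path, row.names = FALSE)
  conf_path <- file.path(dir, "confusion.csv")
  cm <- as.data.frame.matrix(report$confusion)
  write.csv(cbind(subject_id = rownames(cm), cm), conf_path,
            row.names = FALSE)
  invisible(c(json_path, roc_path, conf_path))
}

#' Read a run configuration file
#'
#' YAML key-value configuration describing a reproducible run. `seed` is
#' required; recognised optional keys are `n_subjects`, `n_days`,
#' `repeats_per_day`, `scenario`, `families`, `classifier`, `days`, and a
#' `generator` block of [study_config()] overrides.
#'
#' @param path YAML file path.
#' @return a validated named list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$seed)) stop("run configuration must set a seed")
  defaults <- list(n_subjects = 10, n_days = 3, repeats_per_day = 10,
                   scenario = "nominal", families = "limb",
                   classifier = "rf", days = NULL, generator = list())
  defaults[names(cfg)] <- cfg
  structure(defaults, class = "run_config")
}

#' Run simulate -> extract -> evaluate from a configuration
#'
#' The end-to-end pipeline: simulate the configured study, extract the
#' configured feature families, evaluate the configured classifier under
#' day-fold cross-validation. Deterministic given the configuration.
#'
#' @param config a [read_run_config()] result (or equivalent list).
#' @param out_dir optional directory; when given, [write_report()] is
#'   called on the result.
#' @return an [evaluate_study()] report.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  gen <- do.call(study_config, config$generator %||% list())
  study <- simulate_study(config$n_subjects, config$n_days,
                          config$repeats_per_day,
                          scenario = config$scenario %||% "nominal",
                          config = gen, seed = config$seed)
  spec <- classifier_spec(config$classifier %||% "rf",
                          seed = config$seed)
  report <- evaluate_study(study, config$families %||% "limb", spec,
                           days = config$days)
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}
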