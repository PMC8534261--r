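# Feature families: raw finger-pair, ratiometric, and pure upper-limb
# spectra, in the canonical orderings used throughout the package.

# Canonical finger-pair order.
finger_pairs <- function() {
  list(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
}

#' The six upper-limb extraction triples
#'
#' Each triple pairs the wrist electrode e0 with an ordered finger pair
#' (i, j); exactly six exist.
#'
#' @return list of integer pairs `(i, j)`, `1 <= i < j <= 4`, in canonical
#'   order (1,2), (1,3), (1,4), (2,3), (2,4), (3,4).
#' @export
limb_triples <- function() finger_pairs()

#' The six canonical ratiometric combinations
#'
#' Each of the six finger pairs appears exactly once as a numerator and
#' once as a denominator across the set.
#'
#' @return list of lists with elements `num` and `den` (finger pairs).
#' @export
ratio_combos <- function() {
  list(list(num = c(1, 2), den = c(3, 4)),
       list(num = c(1, 3), den = c(1, 2)),
       list(num = c(1, 4), den = c(1, 3)),
       list(num = c(2, 3), den = c(1, 4)),
       list(num = c(2, 4), den = c(2, 3)),
       list(num = c(3, 4), den = c(2, 4)))
}

#' Channel spectrum of one electrode pair
#'
#' @param session a `bis_session`.
#' @param a,b distinct electrode ids in 0..4 (order irrelevant).
#' @return impedance magnitudes (ohm) over the session grid.
#' @export
channel <- function(session, a, b) {
  if (a == b) stop("electrodes of a pair must be distinct")
  key <- pair_key(a, b)
  if (!key %in% rownames(session$channels)) {
    stop(sprintf("channel (%s) missing from session", key))
  }
  session$channels[key, ]
}

#' Pure upper-limb impedance from one extraction triple
#'
#' Recovers the limb spectrum by path decomposition: the two wrist-finger
#' channels each read limb + one finger, the finger-finger channel reads the
#' two fingers, so
#' `limb = (channel(0, i) + channel(0, j) - channel(i, j)) / 2`.
#' Any single finger's impedance (and any artifact multiplying it) enters
#' the sum and the subtraction equally and cancels exactly.
#'
#' @param session a `bis_session`.
#' @param i,j finger indices, `1 <= i < j <= 4`.
#' @return limb impedance spectrum (ohm). Warns (does not fail) if noise
#'   drives any value non-positive.
#' @export
upper_limb_impedance <- function(session, i, j) {
  stopifnot(i >= 1, j <= 4, i < j)
  out <- (channel(session, 0, i) + channel(session, 0, j) -
            channel(session, i, j)) / 2
  if (any(out <= 0)) {
    warning("non-positive extracted limb impedance (heavy noise?)")
  }
  out
}

#' Extract one feature family from a session
#'
#' @param session a `bis_session`.
#' @param family `"raw_finger"` (six finger-pair channel spectra, ohm),
#'   `"ratiometric"` (six same-frequency finger-pair ratios,
#'   dimensionless), or `"upper_limb"` (six limb extractions, ohm).
#' @return object of class `feature_set`: a 6 x n_freq numeric matrix with
#'   combo labels as rownames and attributes `family` and `grid`.
#' @export
#' @examples
#' st <- simulate_study(1, 1, 1, seed = 1)
#' dim(feature_set(st$sessions[[1]], "upper_limb")) # 6 x 25
feature_set <- function(session,
                        family = c("raw_finger", "ratiometric",
                                   "upper_limb")) {
  family <- match.arg(family)
  nfreq <- length(session$grid)
  values <- switch(
    family,
    raw_finger = {
      m <- t(vapply(finger_pairs(), function(p)
        channel(session, p[1], p[2]), numeric(nfreq)))
      rownames(m) <- vapply(finger_pairs(), function(p)
        sprintf("finger_e%de%d", p[1], p[2]), character(1))
      m
    },
    upper_limb = {
      m <- t(vapply(limb_triples(), function(p)
        upper_limb_impedance(session, p[1], p[2]), numeric(nfreq)))
      rownames(m) <- vapply(limb_triples(), function(p)
        sprintf("limb_e0e%de%d", p[1], p[2]), character(1))
      m
    },
    ratiometric = {
      m <- t(vapply(ratio_combos(), function(cb) {
        den <- channel(session, cb$den[1], cb$den[2])
        if (any(den == 0)) stop("zero denominator channel in ratio feature")
        channel(session, cb$num[1], cb$num[2]) / den
      }, numeric(nfreq)))
      rownames(m) <- vapply(ratio_combos(), function(cb)
        sprintf("ratio_e%de%d_over_e%de%d", cb$num[1], cb$num[2],
                cb$den[1], cb$den[2]), character(1))
      m
    })
  structure(values, family = family, grid = session$grid,
            class = c("feature_set", "matrix", "array"))
}

#' Raw finger-pair features (convenience wrapper)
#' @inheritParams feature_set
#' @return a `feature_set` of family `"raw_finger"`.
#' @export
raw_finger_features <- function(session) feature_set(session, "raw_finger")

#' Ratiometric features (convenience wrapper)
#' @inheritParams feature_set
#' @return a `feature_set` of family `"ratiometric"`.
#' @export
ratiometric_features <- function(session) feature_set(session, "ratiometric")

#' Upper-limb features (convenience wrapper)
#' @inheritParams feature_set
#' @return a `feature_set` of family `"upper_limb"`.
#' @export
limb_features <- function(session) feature_set(session, "upper_limb")

#' Fuse feature sets into a classifier-ready vector
#'
#' @param sets a single `feature_set` or list of them (all on one grid).
#' @param layout `"flat"` concatenates combos in (family, combo, frequency)
#'   order into one vector (length 25 x n_combos on the default grid);
#'   `"channels"` stacks the same combos as an n_freq x n_combos matrix
#'   (one column per input channel of the 1D CNN).
#' @return numeric vector (`flat`) or matrix (`channels`).
#' @export
build_vector <- function(sets, layout = c("flat", "channels")) {
  layout <- match.arg(layout)
  if (inherits(sets, "feature_set")) sets <- list(sets)
  if (length(sets) == 0) stop("at least one feature set is required")
  grids <- lapply(sets, attr, "grid")
  if (!all(vapply(grids, identical, logical(1), grids[[1]]))) {
    stop("feature sets must share the frequency grid")
  }
  stacked <- do.call(rbind, lapply(sets, unclass))
  if (layout == "flat") {
    setNames(as.numeric(t(stacked)),
             as.vector(t(outer(rownames(stacked),
                               seq_len(ncol(stacked)), paste, sep = "_f"))))
  } else {
    t(stacked)
  }
}

# Families argument parser: "finger", "ratio", "limb" or combinations
# c("ratio", "limb"); also accepts "ratio+limb".
normalise_families <- function(families) {
  families <- unlist(strsplit(families, "+", fixed = TRUE))
  map <- c(finger = "raw_finger", raw_finger = "raw_finger",
           ratio = "ratiometric", ratiometric = "ratiometric",
           limb = "upper_limb", upper_limb = "upper_limb")
  if (!all(families %in% names(map))) {
    stop("unknown feature family: ",
         paste(setdiff(families, names(map)), collapse = ", "))
  }
  unname(map[families])
}

#' Study-level feature matrix
#'
#' Extracts and fuses the requested feature families for every session of a
#' study, in flat layout.
#'
#' @param study a `bis_study` (or any list of `bis_session`s under
#'   `$sessions`).
#' @param families character vector of families: `"finger"`, `"ratio"`,
#'   `"limb"` (or full names); `"ratio+limb"` is accepted as shorthand.
#' @return list with `x` (n_sessions x n_features matrix), `subject`
#'   (factor), `day` (integer vector), `families` (normalised names) and
#'   `n_channels` (combos per session, for the CNN layout).
#' @export
feature_matrix <- function(study, families = "limb") {
  fams <- normalise_families(families)
  rows <- lapply(study$sessions, function(s)
    build_vector(lapply(fams, function(f) feature_set(s, f)), "flat"))
  x <- do.call(rbind, rows)
  meta <- session_meta(study)
  list(x = x, subject = factor(meta$subject_id), day = meta$day_index,
       families = fams, n_channels = 6L * length(fams),
       grid = study$grid)
}

#' Write a study feature table as wide CSV
#'
#' One row per session; feature columns named `family_combo_f<index>`,
#' preceded by `subject_id` and `day_index` labels.
#'
#' @param study a `bis_study`.
#' @param families feature families (see [feature_matrix()]).
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_feature_csv <- function(study, families, path) {
  fm <- feature_matrix(study, families)
  df <- data.frame(subject_id = as.character(fm$subject),
                   day_index = fm$day, fm$x, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
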