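# Feature and NASA-TLX table I/O, z-score standardization, score unification.

#' Feature column names
#'
#' The eleven fused features, in their canonical order: three flight-stability
#' features (per-phase standard deviations of pitch angle in degrees, heading
#' in degrees, airspeed in knots) followed by eight physiological features
#' (heart rate in beats/min, heart-rate variability in s, respiratory rate in
#' breaths/min, respiratory depth in mm, pupil diameter in mm, and gaze,
#' glance and blink time proportions in percent).
#'
#' @return Character vector `c("x1", ..., "x11")`.
#' @export
feature_cols <- function() paste0("x", 1:11)

#' @rdname feature_cols
#' @export
tlx_cols <- function() c("MD", "PD", "TD", "OP", "EF", "FR")

#' @rdname feature_cols
#' @export
phase_levels <- function() c("taxiing", "normal_climbing", "fault", "flaring_out")

#' @rdname feature_cols
#' @export
difficulty_levels <- function() c("LL", "ML", "HL")

# Features positively / negatively related to workload.  Flight dispersions
# x1..x3 are treated as positively related by the synthetic generator but are
# not part of the documented sign contract.
positive_features <- function() c("x4", "x5", "x6", "x8", "x9")
negative_features <- function() c("x7", "x10", "x11")

feature_header <- function() c("run_id", "subject_id", "difficulty", "phase", feature_cols())
tlx_header <- function() c("run_id", tlx_cols())

stop_row <- function(row, fmt, ...) {
  stop(sprintf("row %d: %s", row, sprintf(fmt, ...)), call. = FALSE)
}

validate_feature_row <- function(df, i) {
  v <- as.numeric(df[i, feature_cols()])
  names(v) <- feature_cols()
  if (anyNA(v)) stop_row(i, "non-numeric or missing feature value")
  if (any(v[c("x1", "x2", "x3")] < 0))
    stop_row(i, "flight dispersion features x1..x3 must be >= 0")
  if (any(v[c("x4", "x5", "x6", "x7", "x8")] <= 0))
    stop_row(i, "physiological features x4..x8 must be > 0")
  props <- v[c("x9", "x10", "x11")]
  if (any(props < 0) || any(props > 100))
    stop_row(i, "time proportions x9..x11 must lie in [0, 100]")
  if (sum(props) > 100 + 1e-9)
    stop_row(i, "time proportions x9 + x10 + x11 must not exceed 100 (got %.4f)", sum(props))
  if (!df$difficulty[i] %in% difficulty_levels())
    stop_row(i, "unknown difficulty '%s'", df$difficulty[i])
  if (!df$phase[i] %in% phase_levels())
    stop_row(i, "unknown phase '%s'", df$phase[i])
  invisible(TRUE)
}

#' Read a per-run, per-phase feature table
#'
#' Reads a CSV with header `run_id,subject_id,difficulty,phase,x1,...,x11`
#' (see [feature_cols()] for the feature meanings) and validates every row:
#' dispersions nonnegative, physiological magnitudes positive, eye-time
#' proportions in `[0, 100]` summing to at most 100, difficulty in
#' `LL/ML/HL`, phase one of [phase_levels()].
#'
#' @param path Path to a CSV file.
#' @return A `data.frame` with typed columns; `difficulty` and `phase` are
#'   factors with the canonical level order.
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(feature_header(), names(df))
  if (length(missing))
    stop("missing column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  df <- df[feature_header()]
  for (cl in feature_cols()) df[[cl]] <- as.numeric(df[[cl]])
  for (i in seq_len(nrow(df))) validate_feature_row(df, i)
  df$difficulty <- factor(df$difficulty, levels = difficulty_levels())
  df$phase <- factor(df$phase, levels = phase_levels())
  df
}

#' Read a NASA-TLX score table
#'
#' Reads a CSV with header `run_id,MD,PD,TD,OP,EF,FR`. Each dimension must be
#' in `[0, 100]` and a multiple of 5 (the instrument's minimum division).
#'
#' @param path Path to a CSV file.
#' @return A `data.frame` of run ids and the six dimension scores.
#' @export
read_tlx_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(tlx_header(), names(df))
  if (length(missing))
    stop("missing column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  df <- df[tlx_header()]
  for (cl in tlx_cols()) {
    v <- as.numeric(df[[cl]])
    bad <- which(is.na(v) | v < 0 | v > 100 | (v %% 5) != 0)
    if (length(bad))
      stop_row(bad[1], "%s must be a multiple of 5 in [0, 100]", cl)
    df[[cl]] <- v
  }
  df
}

#' @rdname read_feature_table
#' @param df Table as returned by [read_feature_table()] / [read_tlx_table()].
#' @export
write_feature_table <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_feature_table
#' @export
write_tlx_table <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Extract the numeric feature matrix from a feature table
#'
#' @param df Feature table (see [read_feature_table()]).
#' @return Numeric matrix with columns `x1..x11`.
#' @export
feature_matrix <- function(df) {
  as.matrix(df[, feature_cols(), drop = FALSE])
}

#' Fit z-score standardization
#'
#' Centers and scales each column to zero mean and unit standard deviation,
#' y = (x - mean) / s, with s the sample standard deviation (denominator
#' n - 1). Standardization puts features with incommensurable units (degrees,
#' beats/min, mm, percent) on a common unitless scale before PCA.
#'
#' @param x Numeric matrix, observations in rows (at least 2), features in
#'   columns. Every column must have nonzero standard deviation.
#' @return An object of class `wl_standardizer`: list with `values` (the
#'   standardized matrix), `center`, `scale`, and `columns`.
#' @export
zscore_standardize <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("need at least 2 rows to standardize", call. = FALSE)
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  zero <- which(scl == 0 | !is.finite(scl))
  if (length(zero)) {
    nm <- colnames(x)[zero]
    if (is.null(nm)) nm <- as.character(zero)
    stop("zero-variance column(s): ", paste(nm, collapse = ", "), call. = FALSE)
  }
  values <- sweep(sweep(x, 2, ctr, "-"), 2, scl, "/")
  structure(
    list(values = values, center = ctr, scale = scl,
         columns = colnames(x)),
    class = "wl_standardizer"
  )
}

#' Apply a fitted standardization to new data
#'
#' Uses the training-set means and standard deviations, so new observations
#' land on the scale the model was fitted on.
#'
#' @param x Numeric matrix with the same number of columns as the training
#'   matrix.
#' @param standardizer A `wl_standardizer` from [zscore_standardize()].
#' @return Standardized numeric matrix.
#' @export
apply_standardization <- function(x, standardizer) {
  x <- as.matrix(x)
  if (ncol(x) != length(standardizer$center))
    stop("column count mismatch: got ", ncol(x), ", standardizer has ",
         length(standardizer$center), call. = FALSE)
  sweep(sweep(x, 2, standardizer$center, "-"), 2, standardizer$scale, "/")
}

#' Aggregate a NASA-TLX record to a single workload score
#'
#' Unweighted arithmetic mean of the six dimensions (MD, PD, TD, OP, EF, FR),
#' treating every dimension as equally important for the task.
#'
#' @param tlx A TLX table row / data.frame (uses columns MD..FR), or a
#'   numeric vector of the six scores.
#' @return Numeric vector of mean scores, one per row.
#' @export
aggregate_tlx <- function(tlx) {
  if (is.data.frame(tlx)) m <- as.matrix(tlx[, tlx_cols(), drop = FALSE])
  else m <- matrix(as.numeric(tlx), ncol = 6)
  rowMeans(m)
}

#' Snap a raw fused score to the NASA-TLX grid
#'
#' Rounds to the nearest multiple of `step` (default 5, the scale's minimum
#' division). Exact halfway values round away from zero; the sign is
#' preserved, so out-of-range raw scores such as 102.26 or -3.13 map to 100
#' and -5 rather than being clipped.
#'
#' @param raw Numeric vector of raw fused scores.
#' @param step Grid spacing, default 5.
#' @return Numeric vector of multiples of `step`.
#' @export
unify_to_scale <- function(raw, step = 5) {
  stopifnot(is.numeric(raw), all(is.finite(raw)), step > 0)
  sign(raw) * floor(abs(raw) / step + 0.5) * step
}
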