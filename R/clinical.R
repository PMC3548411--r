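# The 0-5 amplitude-anchored clinical tremor scale.

#' Construct a clinical amplitude scale
#'
#' Six-level ordinal scale anchored to visible hand-tremor excursion:
#' 0 = no visible tremor, then five bins of (by default) 1.5 cm each with
#' score 5 open-ended above the last boundary. Bins are half-open
#' `(lower, upper]`, so "up to 1.5 cm" includes 1.5 cm exactly.
#'
#' @param boundaries Strictly increasing upper bin edges in cm
#'   (default `c(1.5, 3, 4.5, 6)`).
#' @return Object of class `clinical_scale`.
#' @export
clinical_scale <- function(boundaries = c(1.5, 3, 4.5, 6)) {
  if (any(diff(boundaries) <= 0) || any(boundaries <= 0))
    stop("boundaries must be positive and strictly increasing")
  structure(list(boundaries = boundaries,
                 max_score = length(boundaries) + 1L),
            class = "clinical_scale")
}

#' Map a visible tremor excursion to a clinical score
#'
#' @param excursion_cm Visible peak-to-peak tremor excursion in cm (>= 0);
#'   vectorized.
#' @param scale A [clinical_scale()].
#' @return Integer score(s) 0-5: 0 for exactly zero excursion, otherwise the
#'   smallest score whose bin contains the excursion.
#' @export
score_from_amplitude <- function(excursion_cm, scale = clinical_scale()) {
  if (any(excursion_cm < 0)) stop("excursion must be >= 0")
  vapply(excursion_cm, function(e) {
    if (e == 0) return(0L)
    s <- which(e <= scale$boundaries)
    if (length(s)) s[1L] else scale$max_score
  }, 0L)
}

#' Convert displacement RMS to a visible excursion
#'
#' A rater judges the peak-to-peak excursion of the oscillation, while the
#' device computes RMS displacement. Under a sinusoidal tremor the
#' peak-to-peak excursion is `2*sqrt(2)` times the RMS; this parameter-free
#' bridge converts the recorded RMS (mm) to the excursion a rater would see
#' (cm).
#'
#' @param rms_mm Displacement RMS in mm (vectorized, >= 0).
#' @return Excursion in cm.
#' @export
rms_to_excursion <- function(rms_mm) {
  if (any(rms_mm < 0)) stop("rms must be >= 0")
  2 * sqrt(2) * rms_mm / 10
}

#' Retained amplitude across axes
#'
#' For multi-axis recordings the per-axis RMS amplitudes are computed and
#' the highest value is retained as the trial's amplitude.
#'
#' @param metrics A `tremor_metrics` data frame (one row per axis) or a
#'   numeric vector of per-axis RMS values.
#' @return Maximum RMS in the metrics' amplitude unit (mm on the
#'   displacement pathway).
#' @export
retained_amplitude <- function(metrics) {
  v <- if (is.data.frame(metrics)) metrics$rms else as.numeric(metrics)
  if (length(v) < 1L) stop("no axes supplied")
  max(v)
}

#' Kinetic-task tremor severity marker
#'
#' During a kinetic task the voluntary movement (below 3 Hz) dominates the
#' RMS amplitude, so amplitude itself no longer tracks tremor severity. The
#' proportion of spectral power inside the 3-7 Hz tremor band
#' (`pow_dist`) is used instead: it rises with tremor power while ignoring
#' the slow voluntary component.
#'
#' @param metrics A single-row `tremor_metrics` data frame (or any object
#'   with a `pow_dist` element).
#' @return The 3-7 Hz power percentage.
#' @export
kinetic_marker <- function(metrics) {
  v <- metrics$pow_dist
  if (is.null(v)) stop("metrics must carry pow_dist")
  v
}

#' Per-task correlation of clinical score with the recorded marker
#'
#' For each task, Pearson-correlates the clinical score with the
#' task-appropriate severity marker: retained RMS amplitude for the static
#' tasks (rest, postural, intention) and the 3-7 Hz power fraction for the
#' kinetic task.
#'
#' @param trials Data frame of scored trials with columns `trial_id`,
#'   `task`, `clinical_score`, `retained_amplitude` (mm) and `pow_dist`.
#' @return Data frame with one row per task: `task`, `marker`, `n`, `r`,
#'   `p`. Tasks with fewer than 3 trials are skipped with a warning.
#' @export
clinical_correlation <- function(trials) {
  stopifnot(all(c("task", "clinical_score", "retained_amplitude",
                  "pow_dist") %in% names(trials)))
  rows <- list()
  for (tk in sort(unique(trials$task))) {
    sub <- trials[trials$task == tk, ]
    if (nrow(sub) < 3L) {
      warning("task ", tk, " has fewer than 3 trials; skipped")
      next
    }
    marker_name <- if (tk == "kinetic") "pow_dist" else "retained_amplitude"
    marker <- sub[[marker_name]]
    pr <- pearson(sub$clinical_score, marker)
    rows[[length(rows) + 1L]] <- data.frame(
      task = tk, marker = marker_name, n = nrow(sub), r = pr$r, p = pr$p,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Read a scored-trial CSV
#'
#' Columns: `trial_id`, `task`, `clinical_score` (integer 0-5), per-axis
#' RMS columns (`rms_x`, `rms_y`, `rms_z`, any subset), and optionally
#' precomputed `retained_amplitude` and `pow_dist`. `retained_amplitude` is
#' filled in as the row-wise max of the per-axis columns when absent.
#'
#' @param path CSV path.
#' @return Data frame of scored trials.
#' @export
read_scored_trials <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("trial_id", "task", "clinical_score") %in% names(df)))
  if (!all(df$clinical_score %in% 0:5))
    stop("clinical_score outside 0..5 at row ",
         which(!df$clinical_score %in% 0:5)[1L])
  if (!"retained_amplitude" %in% names(df)) {
    axis_cols <- intersect(c("rms_x", "rms_y", "rms_z"), names(df))
    if (length(axis_cols) == 0L)
      stop("need retained_amplitude or per-axis rms_{x,y,z} columns")
    df$retained_amplitude <- do.call(pmax, df[axis_cols])
  }
  df
}
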