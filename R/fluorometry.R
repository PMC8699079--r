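#' Fluorometry trace
#'
#' One kinetic fluorometer run: time, a fluorescence signal (arbitrary units,
#' or an excitation ratio for TMRM), and titration event markers.
#'
#' @param time_s Time in seconds, strictly increasing.
#' @param signal Fluorescence signal or ratio, finite, same length.
#' @param events Data frame with columns `label`, `time_s` (may be empty).
#' @return An object of class `fluor_trace`.
#' @export
fluor_trace <- function(time_s, signal, events = NULL) {
  time_s <- as.numeric(time_s); signal <- as.numeric(signal)
  if (length(time_s) != length(signal))
    stop("time_s and signal must have the same length", call. = FALSE)
  if (anyNA(time_s) || is.unsorted(time_s, strictly = TRUE))
    stop("time_s must be strictly increasing", call. = FALSE)
  if (any(!is.finite(signal)))
    stop("signal must be finite", call. = FALSE)
  if (is.null(events))
    events <- data.frame(label = character(), time_s = numeric())
  events <- as.data.frame(events)[, c("label", "time_s")]
  structure(list(time_s = time_s, signal = signal, events = events),
            class = "fluor_trace")
}

#' Read a fluorometry trace from delimited text
#'
#' Trace columns: `time_s`, `signal`; optional event file columns: `label`,
#' `time_s`.
#'
#' @param trace_file Path to the trace CSV.
#' @param events_file Optional path to the events CSV.
#' @return A [fluor_trace()].
#' @export
read_fluor_trace <- function(trace_file, events_file = NULL) {
  tr <- utils::read.csv(trace_file)
  ev <- if (!is.null(events_file)) utils::read.csv(events_file) else NULL
  fluor_trace(tr$time_s, tr$signal, events = ev)
}

#' Percent reduction of the NAD(P)H/NAD(P)+ couple
#'
#' Normalises a fluorescence level between the no-substrate baseline (0%
#' reduced) and the cyanide plateau (100% reduced):
#' `100 * (x - x0) / (x100 - x0)`.
#'
#' @param x Signal at the state of interest (a.u.).
#' @param x0 Baseline anchor (0% reduction).
#' @param x100 Cyanide anchor (100% reduction).
#' @param clamp Clamp results into \[0, 100\] with a warning when the signal
#'   falls outside the anchors (default `TRUE`).
#' @return Percent reduction.
#' @export
percent_reduction <- function(x, x0, x100, clamp = TRUE) {
  if (!all(is.finite(c(x0, x100))) || x100 == x0)
    stop("degenerate anchors: x100 must differ from x0", call. = FALSE)
  pct <- 100 * (x - x0) / (x100 - x0)
  if (clamp && any(pct < 0 | pct > 100, na.rm = TRUE)) {
    warning("signal outside [x0, x100] anchors; clamping to [0, 100]",
            call. = FALSE)
    pct <- pmin(pmax(pct, 0), 100)
  }
  pct
}

#' Fit a linear standard curve
#'
#' Least-squares line `signal = slope * quantity + intercept` over known
#' addition points, used to convert fluorescence (rates) into quantities:
#' H2O2 standard additions for the Amplex-red assay, NAD(P)H additions for
#' dehydrogenase assays, KCl/valinomycin steps (as mV) for TMRM.
#'
#' @param quantity Known quantities (>= 2 distinct values).
#' @param signal Measured signals.
#' @param r2_warn Warn when the fit r2 falls below this threshold.
#' @return An object of class `standard_curve` with `slope`, `intercept`,
#'   `r2`, `n` and the points.
#' @export
fit_standard_curve <- function(quantity, signal, r2_warn = 0.95) {
  quantity <- as.numeric(quantity); signal <- as.numeric(signal)
  if (length(quantity) != length(signal) || length(quantity) < 2)
    stop("need >= 2 (quantity, signal) pairs", call. = FALSE)
  if (max(quantity) - min(quantity) < .Machine$double.eps * 10)
    stop("singular design: quantities must be distinct", call. = FALSE)
  fit <- stats::lm.fit(cbind(1, quantity), signal)
  b <- unname(fit$coefficients)
  sst <- sum((signal - mean(signal))^2)
  r2 <- if (sst < .Machine$double.eps * length(signal)) 1
        else 1 - sum(fit$residuals^2) / sst
  if (r2 < r2_warn)
    warning(sprintf("standard curve r2 = %.3f below %.2f", r2, r2_warn),
            call. = FALSE)
  structure(list(slope = b[2], intercept = b[1], r2 = r2,
                 n = length(signal), quantity = quantity, signal = signal),
            class = "standard_curve")
}

#' Invert a standard curve
#'
#' Maps a measured signal (or signal rate) back to the known-quantity scale:
#' `(signal - intercept) / slope`. Round-trips exactly on the fitted line.
#' For rate conversion the intercept cancels, so pass `rate = TRUE` to apply
#' only the gain.
#'
#' @param signal Signal value(s) or signal rate(s).
#' @param curve A [fit_standard_curve()] object.
#' @param rate If `TRUE`, convert a signal *rate* (divide by the slope only).
#' @return Quantity (or quantity rate) on the curve's unit scale.
#' @export
apply_standard_curve <- function(signal, curve, rate = FALSE) {
  stopifnot(inherits(curve, "standard_curve"))
  if (abs(curve$slope) < .Machine$double.eps)
    stop("standard curve has zero slope", call. = FALSE)
  if (rate) signal / curve$slope
  else (signal - curve$intercept) / curve$slope
}

#' Read a two-column standard-curve file
#'
#' Columns: `known_quantity`, `signal`.
#'
#' @param file Path to the CSV.
#' @inheritParams fit_standard_curve
#' @return A [fit_standard_curve()] object.
#' @export
read_standard_curve <- function(file, r2_warn = 0.95) {
  d <- utils::read.csv(file)
  fit_standard_curve(d$known_quantity, d$signal, r2_warn = r2_warn)
}

#' Convert TMRM fluorescence ratios to membrane potential
#'
#' Inverts a KCl/valinomycin calibration line fitted over (mV, ratio) pairs.
#' The calibration must be strictly monotone; ratios outside the calibrated
#' range are extrapolated with a warning.
#'
#' @param ratio TMRM excitation-ratio values.
#' @param calibration A [fit_standard_curve()] fitted with quantity = mV and
#'   signal = ratio.
#' @return A data frame with columns `tmrm_ratio` and `delta_psi_mV`.
#' @export
tmrm_to_mv <- function(ratio, calibration) {
  stopifnot(inherits(calibration, "standard_curve"))
  if (abs(calibration$slope) < .Machine$double.eps)
    stop("non-monotone (flat) TMRM calibration", call. = FALSE)
  rng <- range(calibration$signal)
  if (any(ratio < rng[1] | ratio > rng[2]))
    warning("TMRM ratio outside calibration range; extrapolating",
            call. = FALSE)
  mv <- apply_standard_curve(ratio, calibration)
  data.frame(tmrm_ratio = as.numeric(ratio), delta_psi_mV = as.numeric(mv))
}

#' Mean steady-state signal in a window
#'
#' @param trace A [fluor_trace()].
#' @param window Numeric `c(start, end)` in seconds.
#' @return Mean signal over the window (>= 3 samples required).
#' @export
window_signal <- function(trace, window) {
  stopifnot(inherits(trace, "fluor_trace"))
  idx <- trace$time_s >= window[1] & trace$time_s <= window[2]
  if (sum(idx) < 3) stop("window must contain at least 3 samples", call. = FALSE)
  mean(trace$signal[idx])
}

#' Signal slope in a window
#'
#' OLS slope of the fluorescence signal over a time window (a.u. per
#' second), with the window r2.
#'
#' @inheritParams window_signal
#' @return A list with `slope_per_s`, `r2`, `n`.
#' @export
window_slope <- function(trace, window) {
  stopifnot(inherits(trace, "fluor_trace"))
  idx <- trace$time_s >= window[1] & trace$time_s <= window[2]
  if (sum(idx) < 5) stop("window must contain at least 5 samples", call. = FALSE)
  tt <- trace$time_s[idx]; ss <- trace$signal[idx]
  fit <- stats::lm.fit(cbind(1, tt), ss)
  sst <- sum((ss - mean(ss))^2)
  r2 <- if (sst < .Machine$double.eps * length(ss)) 1
        else 1 - sum(fit$residuals^2) / sst
  list(slope_per_s = unname(fit$coefficients[2]), r2 = r2, n = sum(idx))
}

#' Redox (percent-reduction) series from an NAD(P)H autofluorescence trace
#'
#' Extracts the steady-state signal of each demand segment and expresses it
#' between the no-substrate baseline segment (0% reduction) and the cyanide
#' plateau (100% reduction). Segment boundaries come from the trace events;
#' the baseline is the segment labelled `baseline_label` and the cyanide
#' plateau the one labelled `cyanide_label`.
#'
#' @param trace A [fluor_trace()] with events delimiting segments.
#' @param demand_labels Labels of the demand segments, in titration order.
#' @param baseline_label,cyanide_label Anchor segment labels.
#' @param settle_s Settling time discarded after each addition (s).
#' @return A data frame with columns `label`, `signal`, `pct_reduction`,
#'   plus attributes `x0` and `x100`.
#' @export
redox_series <- function(trace, demand_labels,
                         baseline_label = "baseline",
                         cyanide_label = "KCN", settle_s = 30) {
  stopifnot(inherits(trace, "fluor_trace"))
  seg <- .fluor_segments(trace, settle_s)
  need <- c(baseline_label, cyanide_label, demand_labels)
  miss <- setdiff(need, seg$label)
  if (length(miss))
    stop("missing trace segments: ", paste(miss, collapse = ", "), call. = FALSE)
  sig <- function(lb) {
    i <- which(seg$label == lb)[1]
    window_signal(trace, c(seg$start_s[i], seg$end_s[i]))
  }
  x0 <- sig(baseline_label); x100 <- sig(cyanide_label)
  s <- vapply(demand_labels, sig, 0)
  out <- data.frame(label = demand_labels, signal = unname(s),
                    pct_reduction = percent_reduction(unname(s), x0, x100))
  attr(out, "x0") <- x0; attr(out, "x100") <- x100
  out
}

# segment table from fluor trace events; the pre-event segment is the
# no-substrate baseline
.fluor_segments <- function(trace, settle_s) {
  t0 <- trace$time_s[1]; t1 <- trace$time_s[length(trace$time_s)]
  ev_t <- c(t0, trace$events$time_s)
  ev_l <- c("baseline", as.character(trace$events$label))
  ord <- order(ev_t)
  ev_t <- ev_t[ord]; ev_l <- ev_l[ord]
  # stop a hair before the next addition so the sample taken at the event
  # time (already at the new level) stays out of the window
  data.frame(label = ev_l, start_s = ev_t + settle_s,
             end_s = c(ev_t[-1] - 1e-6, t1), stringsAsFactors = FALSE)
}

#' Membrane-potential series from a TMRM trace
#'
#' Extracts the steady-state excitation ratio of each demand segment and
#' converts it to millivolts through the KCl/valinomycin calibration.
#'
#' @param trace A [fluor_trace()] of TMRM ratios with segment events.
#' @param calibration A [fit_standard_curve()] over (mV, ratio) pairs.
#' @param demand_labels Labels of the demand segments, in titration order.
#' @param settle_s Settling time discarded after each addition (s).
#' @return A data frame with columns `label`, `tmrm_ratio`, `delta_psi_mV`.
#' @export
tmrm_series <- function(trace, calibration, demand_labels, settle_s = 30) {
  stopifnot(inherits(trace, "fluor_trace"))
  seg <- .fluor_segments(trace, settle_s)
  miss <- setdiff(demand_labels, seg$label)
  if (length(miss))
    stop("missing trace segments: ", paste(miss, collapse = ", "), call. = FALSE)
  ratios <- vapply(demand_labels, function(lb) {
    i <- which(seg$label == lb)[1]
    window_signal(trace, c(seg$start_s[i], seg$end_s[i]))
  }, 0)
  mv <- tmrm_to_mv(unname(ratios), calibration)
  data.frame(label = demand_labels, tmrm_ratio = mv$tmrm_ratio,
             delta_psi_mV = mv$delta_psi_mV)
}

#' H2O2 production series from an Amplex-red trace
#'
#' Runs [h2o2_rate()] on each demand segment of the trace.
#'
#' @param trace A [fluor_trace()] with segment events.
#' @param curve The H2O2 [fit_standard_curve()].
#' @param protein_ug Protein in the cuvette (ug).
#' @param demand_labels Labels of the demand segments, in titration order.
#' @param settle_s Settling time discarded after each addition (s).
#' @return A data frame with columns `label`, `jh2o2` (pmol min^-1 mg^-1).
#' @export
h2o2_series <- function(trace, curve, protein_ug, demand_labels,
                        settle_s = 30) {
  stopifnot(inherits(trace, "fluor_trace"))
  seg <- .fluor_segments(trace, settle_s)
  miss <- setdiff(demand_labels, seg$label)
  if (length(miss))
    stop("missing trace segments: ", paste(miss, collapse = ", "), call. = FALSE)
  jh <- vapply(demand_labels, function(lb) {
    i <- which(seg$label == lb)[1]
    h2o2_rate(trace, c(seg$start_s[i], seg$end_s[i]), curve, protein_ug)
  }, 0)
  data.frame(label = demand_labels, jh2o2 = unname(jh))
}

#' H2O2 production rate from an Amplex-red trace
#'
#' Resorufin accumulation slope within a window, converted to pmol/min via
#' the H2O2 standard curve gain and normalised per mg mitochondrial protein.
#'
#' @param trace A [fluor_trace()].
#' @param window Numeric `c(start, end)` seconds.
#' @param curve H2O2 [fit_standard_curve()] (signal a.u. per pmol H2O2).
#' @param protein_ug Protein in the cuvette (ug).
#' @return JH2O2 in pmol H2O2 min^-1 mg^-1.
#' @export
h2o2_rate <- function(trace, window, curve, protein_ug) {
  if (protein_ug <= 0) stop("protein_ug must be positive", call. = FALSE)
  sl <- window_slope(trace, window)
  au_per_min <- sl$slope_per_s * 60
  pmol_per_min <- apply_standard_curve(au_per_min, curve, rate = TRUE)
  pmol_per_min / (protein_ug / 1000)
}

#' Electron leak
#'
#' JH2O2 expressed as a percentage of JO2 measured under identical
#' conditions. JO2 is per second; JH2O2 defaults to the assay convention of
#' per minute and is converted to per second internally, so both rates share
#' a time base before the ratio is taken. No electron-stoichiometry
#' correction is applied.
#'
#' @param jh2o2 H2O2 production rate (pmol mg^-1, per `h2o2_time_base`).
#' @param jo2 Oxygen consumption rate (pmol O2 s^-1 mg^-1, > 0).
#' @param h2o2_time_base `"per_min"` (default) or `"per_s"`.
#' @return Electron leak in percent.
#' @export
electron_leak <- function(jh2o2, jo2, h2o2_time_base = c("per_min", "per_s")) {
  h2o2_time_base <- match.arg(h2o2_time_base)
  if (any(!is.finite(jo2)) || any(jo2 <= 0))
    stop("jo2 must be positive", call. = FALSE)
  if (h2o2_time_base == "per_min") jh2o2 <- jh2o2 / 60
  100 * jh2o2 / jo2
}
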