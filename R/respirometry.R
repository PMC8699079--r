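#' Oxygen-electrode (oxygraph) trace
#'
#' Container for one high-resolution respirometry run: a strictly increasing
#' time base, the chamber O2 concentration, titration event markers, and the
#' chamber/protein quantities needed to normalise rates.
#'
#' @param time_s Time in seconds, strictly increasing.
#' @param o2_uM O2 concentration (umol/L), same length as `time_s`.
#' @param events Data frame with columns `label`, `time_s` marking titration
#'   additions; times must lie within the trace span. May have zero rows.
#' @param chamber_mL Chamber volume (mL).
#' @param protein_ug Mitochondrial protein loaded (ug).
#'
#' @return An object of class `resp_trace`.
#' @export
resp_trace <- function(time_s, o2_uM, events = NULL,
                       chamber_mL = 2, protein_ug = 20) {
  time_s <- as.numeric(time_s); o2_uM <- as.numeric(o2_uM)
  if (length(time_s) != length(o2_uM))
    stop("time_s and o2_uM must have the same length", call. = FALSE)
  if (anyNA(time_s) || is.unsorted(time_s, strictly = TRUE))
    stop("time_s must be strictly increasing", call. = FALSE)
  if (chamber_mL <= 0 || protein_ug <= 0)
    stop("chamber_mL and protein_ug must be positive", call. = FALSE)
  if (is.null(events))
    events <- data.frame(label = character(), time_s = numeric())
  events <- as.data.frame(events)[, c("label", "time_s")]
  if (nrow(events) &&
      (min(events$time_s) < time_s[1] || max(events$time_s) > time_s[length(time_s)]))
    stop("event times must lie within the trace span", call. = FALSE)
  structure(list(time_s = time_s, o2_uM = o2_uM, events = events,
                 chamber_mL = chamber_mL, protein_ug = protein_ug),
            class = "resp_trace")
}

#' Read a respirometry trace from delimited text
#'
#' The trace file must have columns `time_s` and `o2_uM`; the optional
#' companion event file has columns `label` and `time_s`.
#'
#' @param trace_file Path to the trace CSV.
#' @param events_file Optional path to the events CSV.
#' @inheritParams resp_trace
#' @return A [resp_trace()].
#' @export
read_resp_trace <- function(trace_file, events_file = NULL,
                            chamber_mL = 2, protein_ug = 20) {
  tr <- utils::read.csv(trace_file)
  ev <- if (!is.null(events_file)) utils::read.csv(events_file) else NULL
  resp_trace(tr$time_s, tr$o2_uM, events = ev,
             chamber_mL = chamber_mL, protein_ug = protein_ug)
}

# pmol O2 / s / mg protein from a uM/s O2 decline
.jo2_from_slope <- function(slope_uM_s, chamber_mL, protein_ug) {
  # uM/s * (chamber L) = umol/s; * 1e6 = pmol/s; / (protein mg)
  -slope_uM_s * (chamber_mL / 1000) * 1e6 / (protein_ug / 1000)
}

#' Extract a steady-state oxygen consumption rate
#'
#' Fits an ordinary least-squares line to the O2 concentration within a time
#' window and converts the (negative) slope to JO2 in
#' pmol O2 s^-1 mg protein^-1.
#'
#' @param trace A [resp_trace()].
#' @param window Numeric length-2 vector `c(start, end)` in seconds.
#' @param noise_tol_uM_s Positive O2 slopes larger than this tolerance are
#'   flagged with a warning (rates are still returned, as negative numbers).
#'
#' @return A list of class `steady_state_rate` with `jo2`, `window`,
#'   `fit_r2`, `slope_uM_s` and `n`.
#' @export
extract_jo2 <- function(trace, window, noise_tol_uM_s = 1e-3) {
  stopifnot(inherits(trace, "resp_trace"))
  if (length(window) != 2 || window[2] <= window[1])
    stop("window must be c(start, end) with end > start", call. = FALSE)
  idx <- trace$time_s >= window[1] & trace$time_s <= window[2]
  if (sum(idx) < 5)
    stop("window must contain at least 5 samples", call. = FALSE)
  tt <- trace$time_s[idx]; oo <- trace$o2_uM[idx]
  fit <- stats::lm.fit(cbind(1, tt), oo)
  slope <- unname(fit$coefficients[2])
  sst <- sum((oo - mean(oo))^2)
  r2 <- if (sst < .Machine$double.eps * length(oo)) 1
        else 1 - sum(fit$residuals^2) / sst
  if (slope > noise_tol_uM_s)
    warning("O2 rising in window: negative respiration rate", call. = FALSE)
  structure(list(jo2 = .jo2_from_slope(slope, trace$chamber_mL, trace$protein_ug),
                 window = as.numeric(window), fit_r2 = unname(r2),
                 slope_uM_s = unname(slope), n = sum(idx)),
            class = "steady_state_rate")
}

#' Steady-state windows implied by titration events
#'
#' Each demand segment is taken as `[event + settle_s, next event]` (the last
#' segment runs to the end of the trace). The segment before the first event
#' starts at the trace start.
#'
#' @param trace A [resp_trace()].
#' @param settle_s Settling time discarded after each addition (s).
#' @return A data frame with columns `label`, `start_s`, `end_s`.
#' @export
steady_windows <- function(trace, settle_s = 60) {
  stopifnot(inherits(trace, "resp_trace"))
  t0 <- trace$time_s[1]; t1 <- trace$time_s[length(trace$time_s)]
  ev_t <- c(t0, trace$events$time_s)
  ev_l <- c("start", as.character(trace$events$label))
  ord <- order(ev_t)
  ev_t <- ev_t[ord]; ev_l <- ev_l[ord]
  ends <- c(ev_t[-1], t1)
  data.frame(label = ev_l, start_s = ev_t + settle_s, end_s = ends,
             stringsAsFactors = FALSE)
}

#' JO2 at every demand step of a titration trace
#'
#' Convenience wrapper: computes [steady_windows()] and runs [extract_jo2()]
#' on each. Windows whose label is in `skip_labels` (non-respiring or
#' calibration segments) are dropped.
#'
#' @inheritParams steady_windows
#' @param skip_labels Labels of segments to skip.
#' @return A data frame with one row per retained segment: `label`,
#'   `start_s`, `end_s`, `jo2`, `fit_r2`.
#' @export
trace_jo2_series <- function(trace, settle_s = 60, skip_labels = character()) {
  win <- steady_windows(trace, settle_s)
  win <- win[!(win$label %in% skip_labels), , drop = FALSE]
  rates <- lapply(seq_len(nrow(win)), function(i)
    extract_jo2(trace, c(win$start_s[i], win$end_s[i])))
  win$jo2 <- vapply(rates, `[[`, 0, "jo2")
  win$fit_r2 <- vapply(rates, `[[`, 0, "fit_r2")
  rownames(win) <- NULL
  win
}

#' Cytochrome-c outer-membrane integrity test
#'
#' A JO2 increase after exogenous cytochrome c indicates outer-membrane
#' damage. Samples responding by strictly more than `threshold_pct` percent
#' are excluded.
#'
#' @param jo2_before JO2 before the cytochrome-c bolus (must be > 0).
#' @param jo2_after_cytc JO2 after the bolus.
#' @param threshold_pct Exclusion threshold (percent, strict inequality).
#' @return A list with `response_pct` and logical `exclude`.
#' @export
cytc_exclusion <- function(jo2_before, jo2_after_cytc, threshold_pct = 15) {
  if (!is.finite(jo2_before) || jo2_before <= 0)
    stop("jo2_before must be positive", call. = FALSE)
  response <- 100 * (jo2_after_cytc - jo2_before) / jo2_before
  list(response_pct = response, exclude = response > threshold_pct)
}

#' Fit the force-flow line (OXPHOS conductance)
#'
#' Ordinary least squares of JO2 against Delta-G_ATP across the demand
#' series. JO2 rises as Delta-G_ATP becomes less negative, so the raw OLS
#' slope is positive along the demand axis; the conductance is reported as
#' the magnitude of d(JO2)/d(Delta-G_ATP) so that a steeper response means a
#' higher conductance.
#'
#' @param dg_atp_kcal Delta-G_ATP values (kcal/mol), length >= 3, distinct.
#' @param jo2 Matching JO2 values (pmol O2 s^-1 mg^-1).
#' @return An object of class `forceflow_fit` with `slope` (conductance
#'   magnitude), `raw_slope`, `intercept`, `r2`, `n_points`.
#' @export
fit_conductance <- function(dg_atp_kcal, jo2) {
  dg_atp_kcal <- as.numeric(dg_atp_kcal); jo2 <- as.numeric(jo2)
  if (length(dg_atp_kcal) != length(jo2))
    stop("dg_atp_kcal and jo2 must have the same length", call. = FALSE)
  if (length(dg_atp_kcal) < 3)
    stop("at least 3 demand states are required", call. = FALSE)
  if (max(dg_atp_kcal) - min(dg_atp_kcal) < .Machine$double.eps * 10)
    stop("demand states must be distinct (singular design)", call. = FALSE)
  fit <- stats::lm.fit(cbind(1, dg_atp_kcal), jo2)
  b <- unname(fit$coefficients)
  sst <- sum((jo2 - mean(jo2))^2)
  r2 <- if (sst < .Machine$double.eps * length(jo2)) 1
        else 1 - sum(fit$residuals^2) / sst
  structure(list(slope = abs(b[2]), raw_slope = b[2], intercept = b[1],
                 r2 = r2, n_points = length(jo2)),
            class = "forceflow_fit")
}

#' @export
print.forceflow_fit <- function(x, ...) {
  cat("OXPHOS conductance (force-flow) fit\n")
  cat(sprintf("  conductance: %.2f pmol O2/s/mg per kcal/mol  (r2 = %.4f, n = %d)\n",
              x$slope, x$r2, x$n_points))
  invisible(x)
}

#' Group difference in OXPHOS conductance
#'
#' Percent change in mean conductance between a control and a treated group
#' (positive = reduction in the treated group), with an unpaired two-tailed
#' equal-variance t-test.
#'
#' @param control,treated Numeric vectors of per-sample conductances, or
#'   lists of [fit_conductance()] objects; each of length >= 2.
#' @return A list with `percent_change`, `mean_control`, `mean_treated`,
#'   `t`, `p`, `df` and `degenerate`.
#' @export
group_conductance_change <- function(control, treated) {
  pull <- function(g) {
    if (is.list(g) && all(vapply(g, inherits, TRUE, "forceflow_fit")))
      vapply(g, `[[`, 0, "slope")
    else as.numeric(g)
  }
  x <- pull(control); y <- pull(treated)
  if (length(x) < 2 || length(y) < 2)
    stop("each group needs at least 2 fits", call. = FALSE)
  tt <- ttest_equal_var(x, y)
  list(percent_change = 100 * (mean(x) - mean(y)) / mean(x),
       mean_control = mean(x), mean_treated = mean(y),
       t = tt$t, p = tt$p, df = tt$df, degenerate = tt$degenerate)
}
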