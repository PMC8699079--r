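#' Kinetic enzyme-assay trace
#'
#' One well of a kinetic plate-reader (or cuvette) run following NAD(P)H
#' autofluorescence or an absorbance signal. `direction` states whether the
#' assay produces signal (dehydrogenases generating NAD(P)H) or consumes it
#' (HADHA, ATP synthase coupled assays).
#'
#' @param time_s Time (s), strictly increasing.
#' @param signal Fluorescence or absorbance, same length.
#' @param direction `"production"` or `"consumption"`.
#' @param protein_ug Protein per well (ug).
#' @param enzyme Enzyme label (e.g. "PDH", "AKGDH", "HADHA", "CV", "CIV").
#' @return An object of class `kinetic_trace`.
#' @export
kinetic_trace <- function(time_s, signal,
                          direction = c("production", "consumption"),
                          protein_ug = 5, enzyme = NA_character_) {
  direction <- match.arg(direction)
  time_s <- as.numeric(time_s); signal <- as.numeric(signal)
  if (length(time_s) != length(signal))
    stop("time_s and signal must have the same length", call. = FALSE)
  if (anyNA(time_s) || is.unsorted(time_s, strictly = TRUE))
    stop("time_s must be strictly increasing", call. = FALSE)
  if (protein_ug <= 0) stop("protein_ug must be positive", call. = FALSE)
  structure(list(time_s = time_s, signal = signal, direction = direction,
                 protein_ug = protein_ug, enzyme = enzyme),
            class = "kinetic_trace")
}

# all sliding windows of length w (step 1): slopes and r2 via lm.fit
.sliding_slopes <- function(time_s, signal, w) {
  n <- length(time_s)
  starts <- seq_len(n - w + 1)
  slope <- numeric(length(starts)); r2 <- numeric(length(starts))
  for (k in seq_along(starts)) {
    i <- starts[k]:(starts[k] + w - 1)
    tt <- time_s[i]; ss <- signal[i]
    fit <- stats::lm.fit(cbind(1, tt), ss)
    slope[k] <- fit$coefficients[2]
    sst <- sum((ss - mean(ss))^2)
    r2[k] <- if (sst < .Machine$double.eps * w) 1
             else 1 - sum(fit$residuals^2) / sst
  }
  data.frame(start = starts, slope = slope, r2 = r2)
}

#' Maximal linear-phase rate of an enzyme trace
#'
#' Finds the linear portion of the kinetic curve as the sliding window (of
#' width `window_frac` of the trace, at least 10 samples) with the largest
#' slope magnitude among windows whose internal r2 meets `r2_min`, then
#' converts the a.u./s slope to a quantity rate per minute via the standard
#' curve gain and normalises per mg protein. Consumption-direction assays
#' negate the slope so reported activities are non-negative.
#'
#' @param trace A [kinetic_trace()] with >= 10 samples.
#' @param curve A [fit_standard_curve()] mapping quantity (pmol) to signal
#'   (a.u.); `NULL` leaves the rate in a.u./min/mg.
#' @param window_frac Sliding-window width as a fraction of the trace.
#' @param r2_min Minimum within-window r2 for a window to count as linear.
#' @return An object of class `activity_result` with `enzyme`, `rate`
#'   (pmol min^-1 mg^-1, or a.u. if no curve), `window` (start/end s),
#'   `r2`, `slope_au_s`.
#' @export
linear_rate <- function(trace, curve = NULL, window_frac = 0.2,
                        r2_min = 0.98) {
  stopifnot(inherits(trace, "kinetic_trace"))
  n <- length(trace$time_s)
  if (n < 10) stop("need at least 10 samples", call. = FALSE)
  w <- max(10, ceiling(window_frac * n))
  sl <- .sliding_slopes(trace$time_s, trace$signal, w)
  ok <- sl$r2 >= r2_min
  if (!any(ok))
    stop("no linear phase: no window meets the r2 threshold", call. = FALSE)
  best <- sl[ok, ][which.max(abs(sl$slope[ok])), ]
  slope <- best$slope
  if (trace$direction == "consumption") slope <- -slope
  rate_au_min <- slope * 60
  rate <- if (is.null(curve)) rate_au_min
          else apply_standard_curve(rate_au_min, curve, rate = TRUE)
  rate <- rate / (trace$protein_ug / 1000)
  i0 <- best$start; i1 <- best$start + w - 1
  structure(list(enzyme = trace$enzyme, rate = unname(rate),
                 window = c(trace$time_s[i0], trace$time_s[i1]),
                 r2 = best$r2, slope_au_s = unname(best$slope)),
            class = "activity_result")
}

#' @export
print.activity_result <- function(x, ...) {
  cat(sprintf("%s activity: %.4g pmol/min/mg (window %.0f-%.0f s, r2 = %.4f)\n",
              ifelse(is.na(x$enzyme), "enzyme", x$enzyme),
              x$rate, x$window[1], x$window[2], x$r2))
  invisible(x)
}

#' ATP synthase (complex V) activity
#'
#' In the lysed-mitochondria coupled assay, ATP hydrolysis by the ATP
#' synthase consumes NADH with 1:1 stoichiometry, so the NADH consumption
#' rate *is* the reported ATP hydrolysis rate. Requires a
#' consumption-direction trace; otherwise identical to [linear_rate()].
#'
#' @inheritParams linear_rate
#' @return An `activity_result` with enzyme label "CV".
#' @export
atp_synthase_rate <- function(trace, curve = NULL, window_frac = 0.2,
                              r2_min = 0.98) {
  stopifnot(inherits(trace, "kinetic_trace"))
  if (trace$direction != "consumption")
    stop("ATP synthase assay must be a consumption-direction trace",
         call. = FALSE)
  res <- linear_rate(trace, curve, window_frac, r2_min)
  if (is.na(res$enzyme)) res$enzyme <- "CV"
  res
}

#' Group comparison of enzyme activities
#'
#' Percent change in mean activity (positive = reduction in the treated
#' group) with an unpaired two-tailed equal-variance t-test. Same contract
#' as [group_conductance_change()].
#'
#' @param control,treated Numeric activity vectors or lists of
#'   `activity_result` objects, each length >= 2.
#' @return A list with `percent_change`, group means, `t`, `p`, `df`.
#' @export
activity_group_compare <- function(control, treated) {
  pull <- function(g) {
    if (is.list(g) && all(vapply(g, inherits, TRUE, "activity_result")))
      vapply(g, `[[`, 0, "rate")
    else as.numeric(g)
  }
  x <- pull(control); y <- pull(treated)
  if (length(x) < 2 || length(y) < 2)
    stop("each group needs at least 2 activities", call. = FALSE)
  tt <- ttest_equal_var(x, y)
  list(percent_change = 100 * (mean(x) - mean(y)) / mean(x),
       mean_control = mean(x), mean_treated = mean(y),
       t = tt$t, p = tt$p, df = tt$df, degenerate = tt$degenerate)
}

#' Read a long-format plate export with plate map
#'
#' The plate file has columns `well`, `time_s`, `signal`; the map file has
#' columns `well`, `enzyme`, `sample`, `group`, `direction`, `protein_ug`.
#'
#' @param plate_file Path to the kinetic export CSV.
#' @param map_file Path to the plate-map CSV.
#' @return A named list of [kinetic_trace()] objects (one per well), each
#'   carrying `sample` and `group` attributes.
#' @export
read_plate_traces <- function(plate_file, map_file) {
  plate <- utils::read.csv(plate_file)
  map <- utils::read.csv(map_file)
  out <- lapply(seq_len(nrow(map)), function(i) {
    d <- plate[plate$well == map$well[i], ]
    d <- d[order(d$time_s), ]
    tr <- kinetic_trace(d$time_s, d$signal,
                        direction = map$direction[i],
                        protein_ug = map$protein_ug[i],
                        enzyme = map$enzyme[i])
    attr(tr, "sample") <- map$sample[i]
    attr(tr, "group") <- map$group[i]
    tr
  })
  names(out) <- map$well
  out
}
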