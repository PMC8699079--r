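#' Two-tailed unpaired equal-variance t-test
#'
#' Pooled-variance Student's t with df = n1 + n2 - 2, the test used for all
#' pairwise group comparisons in this package. A zero pooled variance is
#' handled as a degenerate case: p = 1 when the group means are equal
#' (t = 0), p = 0 otherwise, with `degenerate = TRUE`.
#'
#' @param x,y Numeric vectors, each of length >= 2.
#' @param shapiro_gate If `TRUE`, also run [shapiro_wilk_gate()] on each
#'   group (only when 3 <= n <= 50) and report advisory normality flags.
#' @return A list of class `group_comparison`: `mean_x`, `mean_y`, `sd_x`,
#'   `sd_y`, `n_x`, `n_y`, `t`, `df`, `p`, `degenerate`, and (optionally)
#'   `normal_x`, `normal_y`.
#' @export
ttest_equal_var <- function(x, y, shapiro_gate = FALSE) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 2 || length(y) < 2)
    stop("each group needs n >= 2", call. = FALSE)
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / (n1 + n2 - 2)
  out <- list(mean_x = mean(x), mean_y = mean(y),
              sd_x = stats::sd(x), sd_y = stats::sd(y),
              n_x = n1, n_y = n2, df = n1 + n2 - 2)
  if (sp2 < .Machine$double.eps) {
    eq <- isTRUE(all.equal(mean(x), mean(y)))
    out$t <- if (eq) 0 else sign(mean(x) - mean(y)) * Inf
    out$p <- if (eq) 1 else 0
    out$degenerate <- TRUE
  } else {
    tt <- stats::t.test(x, y, var.equal = TRUE)
    out$t <- unname(tt$statistic)
    out$p <- tt$p.value
    out$degenerate <- FALSE
  }
  if (shapiro_gate) {
    gate <- function(v) {
      if (length(v) >= 3 && length(v) <= 50 && stats::sd(v) > 0)
        shapiro_wilk_gate(v)$normal
      else NA
    }
    out$normal_x <- gate(x); out$normal_y <- gate(y)
  }
  class(out) <- "group_comparison"
  out
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("two-tailed equal-variance t-test: t = %.4g, df = %d, p = %.4g\n",
              x$t, x$df, x$p))
  cat(sprintf("  group means %.4g +/- %.3g (n=%d) vs %.4g +/- %.3g (n=%d)\n",
              x$mean_x, x$sd_x, x$n_x, x$mean_y, x$sd_y, x$n_y))
  invisible(x)
}

#' Shapiro-Wilk normality gate
#'
#' Advisory normality screen applied before group comparisons. Uses the
#' standard Royston approximation of the Shapiro-Wilk W statistic; the flag
#' is `TRUE` (treat as normal) when p >= alpha.
#'
#' @param x Numeric vector with 3 <= n <= 50.
#' @param alpha Gate level (default 0.05).
#' @return A list with `W`, `p` and logical `normal`.
#' @export
shapiro_wilk_gate <- function(x, alpha = 0.05) {
  x <- as.numeric(x)
  if (length(x) < 3 || length(x) > 50)
    stop("shapiro_wilk_gate supports 3 <= n <= 50", call. = FALSE)
  if (stats::sd(x) == 0)
    stop("constant vector: normality test degenerate", call. = FALSE)
  sw <- stats::shapiro.test(x)
  list(W = unname(sw$statistic), p = sw$p.value, normal = sw$p.value >= alpha)
}
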