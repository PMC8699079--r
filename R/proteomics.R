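#' TMT reporter-intensity matrix
#'
#' Wraps a proteins x channels matrix of raw reporter intensities together
#' with its sample sheet (channel, group, tissue).
#'
#' @param intensities Numeric matrix, rows = proteins (rownames = protein
#'   ids), columns = channels (colnames = channel ids); non-negative.
#' @param groups Character/factor vector of group labels per channel (e.g.
#'   "control"/"CKD"); each group needs >= 2 channels.
#' @param tissue Optional tissue label for the whole plex.
#' @return An object of class `reporter_matrix`.
#' @export
reporter_matrix <- function(intensities, groups, tissue = NA_character_) {
  intensities <- as.matrix(intensities)
  if (is.null(rownames(intensities)))
    rownames(intensities) <- paste0("P", seq_len(nrow(intensities)))
  if (is.null(colnames(intensities)))
    colnames(intensities) <- paste0("ch", seq_len(ncol(intensities)))
  if (any(intensities < 0, na.rm = TRUE))
    stop("reporter intensities must be non-negative", call. = FALSE)
  groups <- as.character(groups)
  if (length(groups) != ncol(intensities))
    stop("one group label per channel required", call. = FALSE)
  if (any(table(groups) < 2))
    stop("each group needs at least 2 channels", call. = FALSE)
  structure(list(intensities = intensities, groups = groups, tissue = tissue),
            class = "reporter_matrix")
}

#' Channel loading normalization
#'
#' Each channel's intensity sum is divided by the mean of all channels' sums
#' to give a channel-specific loading factor; every intensity is then
#' divided by its channel's factor. Post-normalization channel sums are
#' equal, and the operation is idempotent.
#'
#' @param x A [reporter_matrix()] or a non-negative numeric matrix.
#' @return A list of class `normalized_matrix` with `intensities`
#'   (loading-normalized, linear scale), `loading_factors` (mean 1), and the
#'   input `groups`/`tissue` when available.
#' @export
loading_normalize <- function(x) {
  m <- if (inherits(x, "reporter_matrix")) x$intensities else as.matrix(x)
  sums <- colSums(m)
  if (any(sums <= 0))
    stop("zero channel sum: cannot compute loading factors", call. = FALSE)
  factors <- sums / mean(sums)
  out <- sweep(m, 2, factors, "/")
  structure(list(intensities = out, loading_factors = factors,
                 groups = if (inherits(x, "reporter_matrix")) x$groups else NULL,
                 tissue = if (inherits(x, "reporter_matrix")) x$tissue else NA),
            class = "normalized_matrix")
}

#' Log2 transform and per-protein mean centering
#'
#' Converts loading-normalized intensities to log2 space and subtracts, per
#' protein, the mean over all samples, so every row of the result has mean
#' zero. Non-positive intensities are an error (an upstream completeness
#' filter should have removed them).
#'
#' @param x A `normalized_matrix` from [loading_normalize()] or a positive
#'   numeric matrix.
#' @return The input object with `intensities` replaced by the log2
#'   mean-centered values and `log2_centered = TRUE`.
#' @export
log2_center <- function(x) {
  m <- if (inherits(x, "normalized_matrix")) x$intensities else as.matrix(x)
  if (any(m <= 0))
    stop("non-positive intensity: filter or impute before log2", call. = FALSE)
  lm2 <- log2(m)
  cen <- lm2 - rowMeans(lm2)
  if (inherits(x, "normalized_matrix")) {
    x$intensities <- cen
    x$log2_centered <- TRUE
    x
  } else {
    structure(list(intensities = cen, loading_factors = NULL, groups = NULL,
                   tissue = NA, log2_centered = TRUE),
              class = "normalized_matrix")
  }
}

# vectorized per-row pooled-variance two-sample t-test
.row_ttest <- function(m, i1, i2) {
  n1 <- length(i1); n2 <- length(i2)
  m1 <- rowMeans(m[, i1, drop = FALSE]); m2 <- rowMeans(m[, i2, drop = FALSE])
  v1 <- apply(m[, i1, drop = FALSE], 1, stats::var)
  v2 <- apply(m[, i2, drop = FALSE], 1, stats::var)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t <- (m2 - m1) / se
  df <- n1 + n2 - 2
  p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  degen <- sp2 < .Machine$double.eps
  t[degen] <- 0; p[degen] <- 1
  list(mean1 = m1, mean2 = m2, sd1 = sqrt(v1), sd2 = sqrt(v2),
       t = t, p = p, df = df, degenerate = degen)
}

#' Differential protein abundance
#'
#' Per-protein group means, standard deviations, log2 fold change
#' (treated - control), a two-tailed equal-variance Student's t-test, and
#' Benjamini-Hochberg adjusted p-values computed over all proteins of the
#' plex (one tissue = one adjustment family). Proteins with zero pooled
#' variance get p = 1 and a degeneracy flag.
#'
#' @param x A log2-centered `normalized_matrix` (see [log2_center()]) or a
#'   numeric matrix of log2 abundances.
#' @param groups Group label per column; required when `x` is a bare matrix.
#' @param control Label of the reference group (default `"control"`).
#' @return A data frame of class `da_result`: `protein`, `mean_control`,
#'   `mean_treated`, `sd_control`, `sd_treated`, `log2fc`, `t`, `p`,
#'   `p_adj`, `degenerate`.
#' @export
differential_abundance <- function(x, groups = NULL, control = "control") {
  m <- if (inherits(x, "normalized_matrix")) x$intensities else as.matrix(x)
  if (is.null(groups)) groups <- x$groups
  if (is.null(groups)) stop("group labels required", call. = FALSE)
  lv <- unique(groups)
  if (length(lv) != 2 || !(control %in% lv))
    stop("exactly two groups required, one named '", control, "'",
         call. = FALSE)
  treated <- setdiff(lv, control)
  i1 <- which(groups == control); i2 <- which(groups == treated)
  if (length(i1) < 2 || length(i2) < 2)
    stop("each group needs >= 2 samples", call. = FALSE)
  tt <- .row_ttest(m, i1, i2)
  out <- data.frame(protein = rownames(m),
                    mean_control = tt$mean1, mean_treated = tt$mean2,
                    sd_control = tt$sd1, sd_treated = tt$sd2,
                    log2fc = tt$mean2 - tt$mean1,
                    t = tt$t, p = tt$p,
                    p_adj = stats::p.adjust(tt$p, method = "BH"),
                    degenerate = tt$degenerate,
                    row.names = NULL)
  class(out) <- c("da_result", "data.frame")
  out
}

#' Count significant proteins
#'
#' Totals and up/down splits (by sign of the log2 fold change) at a
#' significance threshold, on raw or BH-adjusted p-values.
#'
#' @param results A `da_result` data frame.
#' @param alpha Significance threshold.
#' @param adjusted Use `p_adj` (default) rather than raw `p`.
#' @return A list with `total`, `up`, `down` and the significant `proteins`.
#' @export
count_significant <- function(results, alpha = 0.05, adjusted = TRUE) {
  if (!nrow(results)) stop("empty results", call. = FALSE)
  p <- if (adjusted) results$p_adj else results$p
  sig <- p < alpha
  list(total = sum(sig),
       up = sum(sig & results$log2fc > 0),
       down = sum(sig & results$log2fc < 0),
       proteins = results$protein[sig])
}

#' Intersection cardinalities of per-tissue significant sets
#'
#' Computes all pairwise and (for three sets) the three-way intersection
#' counts, as displayed in a Venn diagram.
#'
#' @param sets Named list of character vectors of protein ids.
#' @return A list with `sizes`, `pairwise` (named counts), and `threeway`
#'   (when three sets are supplied), plus `common` (ids in every set).
#' @export
overlap_sets <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 2)
  if (is.null(names(sets))) names(sets) <- paste0("set", seq_along(sets))
  sets <- lapply(sets, unique)
  nm <- names(sets)
  pairs <- utils::combn(nm, 2, simplify = FALSE)
  pw <- vapply(pairs, function(p)
    length(intersect(sets[[p[1]]], sets[[p[2]]])), 0L)
  names(pw) <- vapply(pairs, paste, "", collapse = ":")
  out <- list(sizes = vapply(sets, length, 0L), pairwise = pw,
              common = Reduce(intersect, sets))
  if (length(sets) == 3) out$threeway <- length(out$common)
  out
}

#' Correlate protein abundance with OXPHOS conductance
#'
#' Per-protein Pearson correlation between log2-centered abundance and a
#' per-sample conductance value (samples pooled across groups within a
#' tissue), with a two-tailed p-value from the t transform on n - 2 degrees
#' of freedom. Proteins with zero abundance variance are flagged and get
#' `r = NA`.
#'
#' @param x A log2-centered `normalized_matrix` or numeric matrix (rows =
#'   proteins, columns = samples).
#' @param conductance Numeric vector, one value per sample; >= 4 samples.
#' @return A data frame of class `correlation_result`: `protein`, `r`, `t`,
#'   `p`, `sign`, `degenerate`.
#' @export
correlate_conductance <- function(x, conductance) {
  m <- if (inherits(x, "normalized_matrix")) x$intensities else as.matrix(x)
  conductance <- as.numeric(conductance)
  n <- length(conductance)
  if (n != ncol(m)) stop("one conductance per sample required", call. = FALSE)
  if (n < 4) stop("need >= 4 paired samples", call. = FALSE)
  if (stats::sd(conductance) == 0)
    stop("conductance vector has zero variance", call. = FALSE)
  rsd <- apply(m, 1, stats::sd)
  degen <- rsd < .Machine$double.eps
  r <- rep(NA_real_, nrow(m))
  r[!degen] <- as.numeric(stats::cor(t(m[!degen, , drop = FALSE]), conductance))
  t <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(t), n - 2, lower.tail = FALSE)
  out <- data.frame(protein = rownames(m), r = r, t = t, p = p,
                    sign = sign(r), degenerate = degen, row.names = NULL)
  class(out) <- c("correlation_result", "data.frame")
  out
}

#' Read a reporter-intensity matrix with its sample sheet
#'
#' The matrix file has one `protein` column followed by one column per
#' channel; the sample sheet has columns `channel`, `tissue`, `group`.
#'
#' @param matrix_file Path to the intensity CSV.
#' @param samples_file Path to the sample-sheet CSV.
#' @return A [reporter_matrix()].
#' @export
read_reporter_matrix <- function(matrix_file, samples_file) {
  d <- utils::read.csv(matrix_file, check.names = FALSE)
  ss <- utils::read.csv(samples_file)
  m <- as.matrix(d[, setdiff(names(d), "protein"), drop = FALSE])
  rownames(m) <- d$protein
  ss <- ss[match(colnames(m), ss$channel), ]
  reporter_matrix(m, groups = ss$group, tissue = ss$tissue[1])
}
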