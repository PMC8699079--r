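#' Configuration for the synthetic-data generators
#'
#' Returns the default truth parameters driving every generator. The tissue
#' profile encodes the published control hierarchy (kidney conductance ~82%
#' below cardiac and ~72% below skeletal muscle) and the CKD multipliers the
#' reported ~20% (skeletal), ~30% (cardiac) and ~75% (renal) conductance
#' reductions. Phenotype means and SDs are the published group summaries
#' (BUN 24.14 +/- 7.70 vs 105.3 +/- 18.35 mg/dL, etc.). Proteome structure
#' follows the published design: n = 3/group, differential sets of 0
#' (skeletal), 115 (cardiac) and 164 (renal) proteins, ~75% upregulated.
#' Quantities the source experiments do not print (instrument noise,
#' animal-to-animal spread, fluorescence gains) are fixed here at
#' field-typical values; see the methods vignette for the rationale.
#'
#' @param ... Named overrides of top-level config entries.
#' @return A nested list of class `synth_config`.
#' @export
synth_config <- function(...) {
  cfg <- list(
    pcr_titration_mM = c(1, 6, 15, 30),
    medium = ck_medium(),
    constants = thermo_constants(),
    tissues = list(
      skeletal = list(control_slope = 225, ckd_multiplier = 0.80, basal_jo2 = 60),
      cardiac  = list(control_slope = 350, ckd_multiplier = 0.70, basal_jo2 = 90),
      renal    = list(control_slope = 63,  ckd_multiplier = 0.25, basal_jo2 = 30)
    ),
    animal_sdlog = 0.06,
    resp = list(o2_start_uM = 220, noise_uM = 0.02, segment_s = 300,
                dt_s = 1, settle_s = 60, chamber_mL = 2, protein_ug = 20),
    cytc = list(damage_rate = 0.07, intact_range = c(0, 12),
                damaged_range = c(18, 40), threshold_pct = 15),
    redox = list(
      x0 = 200, x100 = 1000, noise_au = 2, settle_s = 30,
      pct = list(  # percent reduction at PCr 1, 6, 15, 30 mM
        skeletal = list(control = c(40, 50, 55, 60), CKD = c(25, 35, 40, 45)),
        cardiac  = list(control = c(30, 40, 45, 50), CKD = c(25, 32, 36, 40)),
        renal    = list(control = c(55, 65, 72, 78), CKD = c(60, 74, 82, 88))
      )
    ),
    tmrm = list(
      cal_intercept = 2.0, cal_slope = -0.005, noise_ratio = 0.002,
      k_in_mM = 120, k_out_mM = c(0.1, 0.25, 0.5, 1, 2.5, 5),
      nernst_mV_per_decade = 61.5, settle_s = 30,
      mv = list(  # Delta-psi (mV) at PCr 1, 6, 15, 30 mM
        skeletal = list(control = c(162, 169, 174, 178), CKD = c(158, 165, 170, 174)),
        cardiac  = list(control = c(165, 172, 177, 181), CKD = c(160, 167, 172, 176)),
        renal    = list(control = c(155, 162, 167, 171), CKD = c(140, 145, 148, 150))
      )
    ),
    h2o2 = list(
      gain_au_per_pmol = 2, noise_au = 1, protein_ug = 75, settle_s = 30,
      segment_s = 240, dt_s = 1,
      curve_pmol = c(0, 100, 200, 400, 800), curve_noise_au = 2,
      jh2o2 = list(  # pmol/min/mg at PCr 1, 6, 15, 30 mM
        skeletal = list(control = c(20, 26, 32, 38), CKD = c(20, 26, 32, 38)),
        cardiac  = list(control = c(18, 24, 30, 36), CKD = c(26, 34, 44, 54)),
        renal    = list(control = c(60, 75, 90, 105), CKD = c(25, 32, 38, 45))
      )
    ),
    enzymes = list(
      protein_ug = 5, gain_au_per_pmol = 1, noise_au = 0.15,
      lag_s = 40, linear_s = 180, total_s = 300, dt_s = 2,
      animal_cv = 0.10,
      curve_pmol = c(0, 500, 1000, 2000, 4000),
      consumption = c("HADHA", "CV"),
      control_rates = c(PDH = 3000, AKGDH = 2500, ME = 1500, GDH = 2000,
                        BCKDH = 800, ICDH = 2200, MDH = 8000, HADHA = 3500,
                        CI = 5000, CII = 2500, CIII = 4000, CIV = 6000,
                        CV = 9000),
      ckd_multipliers = list(
        skeletal = c(PDH = 0.85, AKGDH = 0.75, ME = 0.85, ICDH = 0.85,
                     CI = 0.66, CIII = 0.80, CIV = 0.62),
        cardiac  = c(AKGDH = 0.75, CIV = 0.64, CV = 1.10),
        renal    = c(BCKDH = 1.20, CII = 0.76, CIII = 0.70, CIV = 0.57)
      )
    ),
    proteome = list(
      n_proteins = 800, n_per_group = 3,
      da_n = c(skeletal = 0, cardiac = 115, renal = 164),
      up_frac = 0.75, lfc_range = c(0.7, 2), log2_sd = 0.25,
      base_log2_mean = 20, base_log2_sd = 2, loading_range = c(0.8, 1.2)
    ),
    phenotypes = list(
      n_per_group = 7,
      bun_mg_dl = list(control = c(mean = 24.14, sd = 7.70),
                       CKD = c(mean = 105.3, sd = 18.35)),
      body_g = list(control = c(mean = 32.9, sd = 1.2),
                    CKD = c(mean = 23.6, sd = 1.3)),
      kidney_mg = list(control = c(mean = 178.8, sd = 27.7),
                       CKD = c(mean = 137.7, sd = 24.4))
    )
  )
  dots <- list(...)
  for (nm in names(dots)) cfg[[nm]] <- dots[[nm]]
  class(cfg) <- "synth_config"
  cfg
}

# run expr under a fixed seed without disturbing the caller's RNG
.with_seed <- function(seed, expr) {
  if (is.null(seed)) eval.parent(substitute(expr))
  else withr::with_seed(seed, eval.parent(substitute(expr)))
}

# demand axis shared by all generators
.synth_demands <- function(config) {
  demand_series(config$medium, config$pcr_titration_mM, config$constants)
}

#' Generate one synthetic respirometry trace
#'
#' Builds a piecewise-steady-state O2 decline whose per-segment true rate
#' follows the linear force-flow law
#' `jo2 = basal + slope * (dG - min(dG))` over the four-step PCr demand
#' series, with Gaussian instrument noise on the O2 signal and a lognormal
#' animal-to-animal factor on the slope. A membrane-damage draw provides the
#' cytochrome-c response used by the integrity exclusion rule.
#'
#' @param config A [synth_config()].
#' @param tissue `"skeletal"`, `"cardiac"` or `"renal"`.
#' @param group `"control"` or `"CKD"`.
#' @param seed Integer seed for this animal (NULL = use current RNG state).
#' @return A list with `trace` ([resp_trace()]), and `truth` (list:
#'   `slope_true`, `basal`, `dg_atp_kcal`, `jo2_true`, `cytc_response_pct`,
#'   `damaged`, `tissue`, `group`).
#' @export
gen_resp_trace <- function(config, tissue, group, seed = NULL) {
  stopifnot(inherits(config, "synth_config"))
  tis <- config$tissues[[tissue]]
  if (is.null(tis)) stop("unknown tissue: ", tissue, call. = FALSE)
  dem <- .synth_demands(config)
  rp <- config$resp
  .with_seed(seed, {
    mult <- if (group == "CKD") tis$ckd_multiplier else 1
    animal <- if (config$animal_sdlog > 0)
      stats::rlnorm(1, meanlog = -config$animal_sdlog^2 / 2,
                    sdlog = config$animal_sdlog) else 1
    slope <- tis$control_slope * mult * animal
    basal <- tis$basal_jo2 * mult * animal
    jo2_true <- basal + slope * (dem$dg_atp_kcal - min(dem$dg_atp_kcal))
    nseg <- nrow(dem)
    tmax <- nseg * rp$segment_s
    t <- seq(0, tmax, by = rp$dt_s)
    seg <- pmin(floor(t / rp$segment_s) + 1, nseg)
    # uM/s decline implied by each segment's JO2
    rate_uM <- jo2_true * (rp$protein_ug / 1000) / (rp$chamber_mL / 1000) / 1e6
    dt <- diff(t)
    o2 <- rp$o2_start_uM - cumsum(c(0, rate_uM[seg[-length(seg)]] * dt))
    if (rp$noise_uM > 0) o2 <- o2 + stats::rnorm(length(o2), 0, rp$noise_uM)
    ev_t <- rp$segment_s * seq_len(nseg - 1)
    events <- data.frame(label = paste0("PCr", dem$pcr_mM[-1]), time_s = ev_t)
    damaged <- stats::runif(1) < config$cytc$damage_rate
    resp_pct <- if (damaged)
      stats::runif(1, config$cytc$damaged_range[1], config$cytc$damaged_range[2])
    else
      stats::runif(1, config$cytc$intact_range[1], config$cytc$intact_range[2])
    list(trace = resp_trace(t, o2, events = events,
                            chamber_mL = rp$chamber_mL,
                            protein_ug = rp$protein_ug),
         truth = list(slope_true = slope, basal = basal,
                      dg_atp_kcal = dem$dg_atp_kcal, jo2_true = jo2_true,
                      cytc_response_pct = resp_pct, damaged = damaged,
                      tissue = tissue, group = group))
  })
}

#' Analyse one synthetic respirometry trace
#'
#' Runs the standard extraction on a generated trace: steady-state JO2 per
#' demand segment and the force-flow conductance fit against the demand
#' series of the same configuration.
#'
#' @param config The [synth_config()] used to generate the trace.
#' @param trace A [resp_trace()].
#' @return A list with `jo2` (per demand), `dg_atp_kcal` and `fit`
#'   ([fit_conductance()] result).
#' @export
analyze_resp_trace <- function(config, trace) {
  dem <- .synth_demands(config)
  ser <- trace_jo2_series(trace, settle_s = config$resp$settle_s)
  if (nrow(ser) != nrow(dem))
    stop("trace segments do not match the demand series", call. = FALSE)
  list(jo2 = ser$jo2, dg_atp_kcal = dem$dg_atp_kcal,
       fit = fit_conductance(dem$dg_atp_kcal, ser$jo2))
}

#' Generate a cohort of respirometry traces
#'
#' @inheritParams gen_resp_trace
#' @param n Number of animals.
#' @param seed Base seed; animal i uses `seed + i`.
#' @return A list of [gen_resp_trace()] results.
#' @export
gen_resp_cohort <- function(config, tissue, group, n = 6, seed = NULL) {
  lapply(seq_len(n), function(i)
    gen_resp_trace(config, tissue, group,
                   seed = if (is.null(seed)) NULL else seed + i))
}

# steady percent/level per demand segment -> stepped fluorescence trace
.segment_signal <- function(levels, seg_s, dt_s, noise, seed_offset = 0) {
  t <- seq(0, length(levels) * seg_s, by = dt_s)
  seg <- pmin(floor(t / seg_s) + 1, length(levels))
  s <- levels[seg]
  if (noise > 0) s <- s + stats::rnorm(length(s), 0, noise)
  list(t = t, s = s, seg = seg)
}

#' Generate a synthetic NAD(P)H redox trace
#'
#' Segments: no-substrate baseline (0% anchor), substrate (state 2), ATP
#' (PCr 1 mM demand), PCr 6/15/30 titrations, and a cyanide plateau (100%
#' anchor). Steady segment levels are placed between the anchors at the
#' configured true percent reduction, with Gaussian noise.
#'
#' @inheritParams gen_resp_trace
#' @return A list with `trace` ([fluor_trace()]) and `truth` (list:
#'   `pct_true` per demand, `x0`, `x100`, `demand_labels`).
#' @export
gen_redox_trace <- function(config, tissue, group, seed = NULL) {
  stopifnot(inherits(config, "synth_config"))
  rx <- config$redox
  pct <- rx$pct[[tissue]][[group]]
  if (is.null(pct)) stop("no redox profile for ", tissue, "/", group, call. = FALSE)
  .with_seed(seed, {
    sub_pct <- min(95, max(pct) + 10)
    levels_pct <- c(0, sub_pct, pct, 100)
    labels <- c("baseline", "substrate", "ATP",
                paste0("PCr", config$pcr_titration_mM[-1]), "KCN")
    lv <- rx$x0 + levels_pct / 100 * (rx$x100 - rx$x0)
    seg_s <- 120
    zz <- .segment_signal(lv, seg_s, 1, rx$noise_au)
    events <- data.frame(label = labels[-1],
                         time_s = seg_s * seq_len(length(lv) - 1))
    list(trace = fluor_trace(zz$t, zz$s, events = events),
         truth = list(pct_true = pct, x0 = rx$x0, x100 = rx$x100,
                      demand_labels = labels[3:(2 + length(pct))],
                      tissue = tissue, group = group))
  })
}

#' Generate a synthetic TMRM trace with its KCl/valinomycin calibration
#'
#' True membrane potentials per demand step are mapped to excitation ratios
#' through a fixed linear ratio-vs-mV law; the emitted calibration series
#' places KCl steps on the same line, with the step potentials given by the
#' Nernst relation (61.5 mV per decade of \[K+\]out at 37 degrees C).
#'
#' @inheritParams gen_resp_trace
#' @return A list with `trace` ([fluor_trace()]), `calibration` (data frame
#'   `mv`, `ratio`) and `truth` (list: `mv_true` per demand,
#'   `demand_labels`).
#' @export
gen_tmrm_trace <- function(config, tissue, group, seed = NULL) {
  stopifnot(inherits(config, "synth_config"))
  tm <- config$tmrm
  mv <- tm$mv[[tissue]][[group]]
  if (is.null(mv)) stop("no TMRM profile for ", tissue, "/", group, call. = FALSE)
  .with_seed(seed, {
    ratio_of_mv <- function(v) tm$cal_intercept + tm$cal_slope * v
    # baseline/substrate segments carry arbitrary levels outside the demand set
    lv <- ratio_of_mv(c(mv[1] - 25, mv[1] - 8, mv))
    labels <- c("baseline", "substrate", "ATP",
                paste0("PCr", config$pcr_titration_mM[-1]))
    seg_s <- 120
    zz <- .segment_signal(lv, seg_s, 1, tm$noise_ratio)
    events <- data.frame(label = labels[-1],
                         time_s = seg_s * seq_len(length(lv) - 1))
    cal_mv <- tm$nernst_mV_per_decade * log10(tm$k_in_mM / tm$k_out_mM)
    cal <- data.frame(mv = cal_mv,
                      ratio = ratio_of_mv(cal_mv) +
                        stats::rnorm(length(cal_mv), 0, tm$noise_ratio))
    list(trace = fluor_trace(zz$t, zz$s, events = events),
         calibration = cal,
         truth = list(mv_true = mv,
                      demand_labels = labels[3:(2 + length(mv))],
                      tissue = tissue, group = group))
  })
}

#' Generate a synthetic Amplex-red H2O2 trace and standard curve
#'
#' Resorufin fluorescence accumulates linearly within each demand segment at
#' a slope set by the configured true JH2O2, the cuvette protein and the
#' standard-curve gain. The addition series for the standard curve is
#' emitted alongside.
#'
#' @inheritParams gen_resp_trace
#' @return A list with `trace` ([fluor_trace()]), `curve_points` (data frame
#'   `known_quantity` pmol, `signal` a.u.) and `truth` (list: `jh2o2_true`
#'   pmol/min/mg per demand, `gain`, `demand_labels`).
#' @export
gen_h2o2_trace <- function(config, tissue, group, seed = NULL) {
  stopifnot(inherits(config, "synth_config"))
  hz <- config$h2o2
  j <- hz$jh2o2[[tissue]][[group]]
  if (is.null(j)) stop("no H2O2 profile for ", tissue, "/", group, call. = FALSE)
  .with_seed(seed, {
    # a.u./s slope per segment; 60 s background segment before the first
    # demand addition
    base_s <- 60
    slope <- c(0, j * (hz$protein_ug / 1000) * hz$gain_au_per_pmol / 60)
    nseg <- length(j)
    t <- seq(0, base_s + nseg * hz$segment_s, by = hz$dt_s)
    seg <- pmin(floor(pmax(t - base_s, 0) / hz$segment_s) + 2, nseg + 1)
    seg[t < base_s] <- 1
    dt <- diff(t)
    s <- 10 + cumsum(c(0, slope[seg[-length(seg)]] * dt))
    if (hz$noise_au > 0) s <- s + stats::rnorm(length(s), 0, hz$noise_au)
    labels <- c("ATP", paste0("PCr", config$pcr_titration_mM[-1]))
    events <- data.frame(label = labels,
                         time_s = base_s + hz$segment_s * (seq_len(nseg) - 1))
    cp <- data.frame(known_quantity = hz$curve_pmol,
                     signal = 5 + hz$gain_au_per_pmol * hz$curve_pmol +
                       stats::rnorm(length(hz$curve_pmol), 0, hz$curve_noise_au))
    list(trace = fluor_trace(t, s, events = events),
         curve_points = cp,
         truth = list(jh2o2_true = j, gain = hz$gain_au_per_pmol,
                      demand_labels = labels, tissue = tissue, group = group))
  })
}

#' Generate a synthetic enzyme kinetic trace with its standard curve
#'
#' Lag phase, linear phase at the true rate, then plateau; consumption-
#' direction enzymes (HADHA, ATP synthase) run downward from a loaded NADH
#' pool. A lognormal animal factor perturbs the configured tissue/group rate
#' unless `rate_true` is supplied.
#'
#' @inheritParams gen_resp_trace
#' @param enzyme Enzyme label present in `config$enzymes$control_rates`.
#' @param rate_true Optional exact true rate (pmol/min/mg), bypassing the
#'   tissue/group lookup and animal variation.
#' @return A list with `trace` ([kinetic_trace()]), `curve_points` and
#'   `truth` (`rate_true`, `gain`, `direction`).
#' @export
gen_enzyme_trace <- function(config, enzyme, tissue = "skeletal",
                             group = "control", rate_true = NULL,
                             seed = NULL) {
  stopifnot(inherits(config, "synth_config"))
  en <- config$enzymes
  if (!enzyme %in% names(en$control_rates))
    stop("unknown enzyme: ", enzyme, call. = FALSE)
  .with_seed(seed, {
    if (is.null(rate_true)) {
      mult <- 1
      if (group == "CKD") {
        mm <- en$ckd_multipliers[[tissue]]
        if (!is.null(mm) && enzyme %in% names(mm)) mult <- mm[[enzyme]]
      }
      animal <- if (en$animal_cv > 0)
        stats::rlnorm(1, meanlog = -log(1 + en$animal_cv^2) / 2,
                      sdlog = sqrt(log(1 + en$animal_cv^2))) else 1
      rate_true <- en$control_rates[[enzyme]] * mult * animal
    }
    direction <- if (enzyme %in% en$consumption) "consumption" else "production"
    slope_au <- rate_true * (en$protein_ug / 1000) * en$gain_au_per_pmol / 60
    t <- seq(0, en$total_s, by = en$dt_s)
    lin_end <- en$lag_s + en$linear_s
    ramp <- pmin(pmax(t - en$lag_s, 0), en$linear_s)
    s0 <- if (direction == "consumption") 20 + slope_au * en$linear_s + 5 else 20
    s <- if (direction == "consumption") s0 - slope_au * ramp
         else s0 + slope_au * ramp
    if (en$noise_au > 0) s <- s + stats::rnorm(length(s), 0, en$noise_au)
    cp <- data.frame(known_quantity = en$curve_pmol,
                     signal = 2 + en$gain_au_per_pmol * en$curve_pmol +
                       stats::rnorm(length(en$curve_pmol), 0, en$noise_au))
    list(trace = kinetic_trace(t, s, direction = direction,
                               protein_ug = en$protein_ug, enzyme = enzyme),
         curve_points = cp,
         truth = list(rate_true = rate_true, gain = en$gain_au_per_pmol,
                      direction = direction, tissue = tissue, group = group))
  })
}

#' Generate a synthetic TMT reporter matrix
#'
#' Log-normal base intensities per protein; a configured differential subset
#' is shifted by sampled log2 fold changes in the CKD channels; channel
#' loading biases multiply each channel. The truth record lists the
#' differential protein ids, their fold changes and the loading factors.
#'
#' @inheritParams gen_resp_trace
#' @return A list with `matrix` ([reporter_matrix()]) and `truth` (list:
#'   `da` data frame of `protein`, `lfc`; `loading_factors` raw and
#'   normalized to mean 1).
#' @export
gen_reporter_matrix <- function(config, tissue, seed = NULL) {
  stopifnot(inherits(config, "synth_config"))
  pr <- config$proteome
  nda <- pr$da_n[[tissue]]
  if (is.null(nda)) stop("unknown tissue: ", tissue, call. = FALSE)
  .with_seed(seed, {
    np <- pr$n_proteins; ng <- pr$n_per_group
    prot <- sprintf("PROT%04d", seq_len(np))
    base <- stats::rnorm(np, pr$base_log2_mean, pr$base_log2_sd)
    lfc <- numeric(np)
    da_idx <- integer(0)
    if (nda > 0) {
      da_idx <- sample.int(np, nda)
      up <- stats::runif(nda) < pr$up_frac
      mag <- stats::runif(nda, pr$lfc_range[1], pr$lfc_range[2])
      lfc[da_idx] <- ifelse(up, mag, -mag)
    }
    groups <- rep(c("control", "CKD"), each = ng)
    eff <- outer(lfc, as.numeric(groups == "CKD"))
    log2x <- base + eff +
      matrix(stats::rnorm(np * 2 * ng, 0, pr$log2_sd), np, 2 * ng)
    fac <- stats::runif(2 * ng, pr$loading_range[1], pr$loading_range[2])
    m <- sweep(2^log2x, 2, fac, "*")
    colnames(m) <- paste0(groups, "_", rep(seq_len(ng), 2))
    rownames(m) <- prot
    list(matrix = reporter_matrix(m, groups = groups, tissue = tissue),
         truth = list(da = data.frame(protein = prot[da_idx],
                                      lfc = lfc[da_idx]),
                      loading_factors = fac,
                      loading_factors_norm = fac / mean(fac)))
  })
}

#' Generate synthetic animal phenotypes
#'
#' Normal draws per group at the configured n for body weight, kidney weight
#' and blood urea nitrogen (BUN), matching the published group means and
#' standard deviations.
#'
#' @inheritParams gen_resp_trace
#' @return A data frame with columns `animal`, `group`, `body_g`,
#'   `kidney_mg`, `bun_mg_dl`.
#' @export
gen_phenotypes <- function(config, seed = NULL) {
  stopifnot(inherits(config, "synth_config"))
  ph <- config$phenotypes
  .with_seed(seed, {
    n <- ph$n_per_group
    draw <- function(spec, grp) stats::rnorm(n, spec[[grp]]["mean"],
                                             spec[[grp]]["sd"])
    grp <- rep(c("control", "CKD"), each = n)
    data.frame(animal = paste0(grp, "_", rep(seq_len(n), 2)),
               group = grp,
               body_g = c(draw(ph$body_g, "control"), draw(ph$body_g, "CKD")),
               kidney_mg = c(draw(ph$kidney_mg, "control"),
                             draw(ph$kidney_mg, "CKD")),
               bun_mg_dl = c(draw(ph$bun_mg_dl, "control"),
                             draw(ph$bun_mg_dl, "CKD")))
  })
}
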