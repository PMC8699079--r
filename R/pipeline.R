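#' Parse a key-value configuration file
#'
#' Minimal INI-style parser: `[section]` headers followed by `key = value`
#' lines; values are numeric when they parse as numbers. Used for the
#' `[thermo]` section overriding the calibrated clamp constants.
#'
#' @param file Path to the config file.
#' @return A named list of sections, each a named list of values.
#' @export
read_config_file <- function(file) {
  lines <- trimws(readLines(file))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list(); sect <- "default"
  for (ln in lines) {
    if (grepl("^\\[.+\\]$", ln)) {
      sect <- gsub("^\\[|\\]$", "", ln)
    } else if (grepl("=", ln, fixed = TRUE)) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      key <- trimws(kv[1]); val <- trimws(paste(kv[-1], collapse = "="))
      num <- suppressWarnings(as.numeric(val))
      out[[sect]][[key]] <- if (!is.na(num)) num else val
    }
  }
  out
}

#' Thermo constants and medium from a config file
#'
#' Reads the `[thermo]` section (keys `k_ck_apparent`, `dg0_atp_kcal`,
#' `temp_K`, `pi_mM`; all optional) and merges it with the calibrated
#' defaults.
#'
#' @param file Path to a config file (see [read_config_file()]).
#' @return A list with `constants` ([thermo_constants()]) and `medium`
#'   ([ck_medium()]).
#' @export
thermo_from_config <- function(file) {
  cfg <- read_config_file(file)$thermo
  cons <- thermo_constants(
    k_ck_apparent = cfg$k_ck_apparent %||% 347.6,
    dg0_atp_kcal = cfg$dg0_atp_kcal %||% -7.60)
  med <- ck_medium(pi_mM = cfg$pi_mM %||% 10, temp_K = cfg$temp_K %||% 310.15)
  list(constants = cons, medium = med)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# short stable hash of an R object (for the run manifest)
.config_hash <- function(x) {
  raw <- serialize(x, NULL, version = 2)
  sprintf("%08x", sum(as.double(raw) * seq_along(raw)) %% 2^31)
}

#' Run the full synthetic phenotyping pipeline
#'
#' Generates a complete synthetic study at the configured truth (or
#' validates and loads an input directory), then runs every analysis stage:
#' the CK-clamp demand series, per-sample JO2 extraction and force-flow
#' conductance fits with the cytochrome-c exclusion rule, group conductance
#' comparisons, redox / membrane-potential / H2O2 / electron-leak series,
#' enzyme activities with group comparisons, TMT differential abundance with
#' BH adjustment, up/down counts and cross-tissue overlap sets,
#' protein-conductance correlations, and simulated phenotypes. Re-running
#' with the same config and seed is byte-identical.
#'
#' @param config A [synth_config()].
#' @param seed Integer seed driving every generator.
#' @param out_dir Optional directory; when given, all result tables are
#'   written as CSV plus a JSON run manifest.
#' @param n_resp Respirometry animals per tissue/group.
#' @param n_fluor Fluorometry animals per tissue/group.
#' @param n_enzyme Enzyme-assay animals per tissue/group.
#' @param input_dir Reserved for instrument-data runs: a directory that must
#'   contain trace files; an empty or missing directory is a validation
#'   error.
#' @return A list of class `mitophen_report`: `demand`, `conductance`
#'   (per-sample table), `conductance_groups`, `exclusions`, `redox`,
#'   `membrane_potential`, `h2o2`, `leak`, `enzymes`, `da` (per-tissue
#'   list), `da_counts`, `overlap`, `correlations`, `phenotypes`,
#'   `phenotype_tests`, `manifest`.
#' @export
run_full_pipeline <- function(config = synth_config(), seed = 1,
                              out_dir = NULL, n_resp = 6, n_fluor = 3,
                              n_enzyme = 6, input_dir = NULL) {
  stopifnot(inherits(config, "synth_config"))
  if (!is.null(input_dir)) {
    files <- if (dir.exists(input_dir))
      list.files(input_dir, pattern = "\\.(csv|tsv)$") else character()
    if (!length(files))
      stop("input validation failed: no trace/matrix files in '",
           input_dir, "'", call. = FALSE)
    stop("instrument-data input is read per assay via the read_* functions; ",
         "run_full_pipeline orchestrates the synthetic study", call. = FALSE)
  }
  tissues <- names(config$tissues)
  dem <- .synth_demands(config)
  demand_tbl <- data.frame(pcr_mM = dem$pcr_mM,
                           atp_adp_ratio = dem$atp_adp_ratio,
                           dg_atp_kcal = dem$dg_atp_kcal)

  cond_rows <- list(); excl_rows <- list(); grp_rows <- list()
  jo2_group_mean <- list()
  sample_cond <- list()
  off <- 0L
  for (ti in tissues) {
    for (gr in c("control", "CKD")) {
      cohort <- gen_resp_cohort(config, ti, gr, n = n_resp,
                                seed = seed + 1000L * off)
      off <- off + 1L
      res <- lapply(cohort, function(a) analyze_resp_trace(config, a$trace))
      slopes <- vapply(res, function(r) r$fit$slope, 0)
      cyt <- vapply(cohort, function(a) a$truth$cytc_response_pct, 0)
      dec <- lapply(cyt, function(r) cytc_exclusion(100, 100 + r,
        threshold_pct = config$cytc$threshold_pct))
      keep <- !vapply(dec, `[[`, TRUE, "exclude")
      cond_rows[[paste(ti, gr)]] <- data.frame(
        tissue = ti, group = gr, animal = seq_len(n_resp),
        conductance = slopes, cytc_response_pct = cyt, included = keep)
      nex <- sum(!keep)
      excl_rows[[paste(ti, gr)]] <- data.frame(
        tissue = rep(ti, nex), group = rep(gr, nex), animal = which(!keep),
        cytc_response_pct = cyt[!keep],
        reason = rep("cytochrome-c response > threshold", nex))
      jo2m <- colMeans(do.call(rbind, lapply(res[keep], `[[`, "jo2")))
      jo2_group_mean[[paste(ti, gr)]] <- jo2m
      sample_cond[[paste(ti, gr)]] <- slopes[keep]
    }
    gc <- group_conductance_change(sample_cond[[paste(ti, "control")]],
                                   sample_cond[[paste(ti, "CKD")]])
    grp_rows[[ti]] <- data.frame(tissue = ti,
                                 percent_change = gc$percent_change,
                                 mean_control = gc$mean_control,
                                 mean_ckd = gc$mean_treated,
                                 t = gc$t, p = gc$p)
  }
  conductance <- do.call(rbind, c(cond_rows, list(make.row.names = FALSE)))
  exclusions <- do.call(rbind, c(excl_rows, list(make.row.names = FALSE)))
  conductance_groups <- do.call(rbind, c(grp_rows, list(make.row.names = FALSE)))

  redox_rows <- list(); mv_rows <- list(); h2o2_rows <- list(); leak_rows <- list()
  for (ti in tissues) for (gr in c("control", "CKD")) {
    for (i in seq_len(n_fluor)) {
      s_base <- seed + 20000L + 100L * match(ti, tissues) + 10L * (gr == "CKD") + i
      rx <- gen_redox_trace(config, ti, gr, seed = s_base)
      rs <- redox_series(rx$trace, rx$truth$demand_labels,
                         settle_s = config$redox$settle_s)
      redox_rows[[length(redox_rows) + 1L]] <- data.frame(
        tissue = ti, group = gr, animal = i, pcr_mM = dem$pcr_mM,
        dg_atp_kcal = dem$dg_atp_kcal, pct_reduction = rs$pct_reduction)
      tm <- gen_tmrm_trace(config, ti, gr, seed = s_base + 1L)
      cal <- fit_standard_curve(tm$calibration$mv, tm$calibration$ratio)
      mv <- tmrm_series(tm$trace, cal, tm$truth$demand_labels,
                        settle_s = config$tmrm$settle_s)
      mv_rows[[length(mv_rows) + 1L]] <- data.frame(
        tissue = ti, group = gr, animal = i, pcr_mM = dem$pcr_mM,
        dg_atp_kcal = dem$dg_atp_kcal, delta_psi_mV = mv$delta_psi_mV)
      hz <- gen_h2o2_trace(config, ti, gr, seed = s_base + 2L)
      cur <- fit_standard_curve(hz$curve_points$known_quantity,
                                hz$curve_points$signal)
      jh <- h2o2_series(hz$trace, cur, config$h2o2$protein_ug,
                        hz$truth$demand_labels,
                        settle_s = config$h2o2$settle_s)$jh2o2
      h2o2_rows[[length(h2o2_rows) + 1L]] <- data.frame(
        tissue = ti, group = gr, animal = i, pcr_mM = dem$pcr_mM,
        dg_atp_kcal = dem$dg_atp_kcal, jh2o2 = jh)
      leak_rows[[length(leak_rows) + 1L]] <- data.frame(
        tissue = ti, group = gr, animal = i, pcr_mM = dem$pcr_mM,
        dg_atp_kcal = dem$dg_atp_kcal,
        leak_pct = electron_leak(jh, jo2_group_mean[[paste(ti, gr)]]))
    }
  }

  enz_rows <- list()
  for (ti in tissues) {
    for (ez in names(config$enzymes$control_rates)) {
      acts <- list()
      for (gr in c("control", "CKD")) {
        rr <- vapply(seq_len(n_enzyme), function(i) {
          g <- gen_enzyme_trace(config, ez, ti, gr,
            seed = seed + 40000L + 1000L * match(ti, tissues) +
              37L * match(ez, names(config$enzymes$control_rates)) +
              10L * (gr == "CKD") + i)
          cur <- fit_standard_curve(g$curve_points$known_quantity,
                                    g$curve_points$signal)
          linear_rate(g$trace, cur)$rate
        }, 0)
        acts[[gr]] <- rr
      }
      cmp <- activity_group_compare(acts$control, acts$CKD)
      enz_rows[[paste(ti, ez)]] <- data.frame(
        tissue = ti, enzyme = ez,
        mean_control = cmp$mean_control, mean_ckd = cmp$mean_treated,
        percent_change = cmp$percent_change, t = cmp$t, p = cmp$p)
    }
  }
  enzymes <- do.call(rbind, c(enz_rows, list(make.row.names = FALSE)))

  da_list <- list(); da_count_rows <- list(); cor_list <- list()
  sig_sets <- list()
  for (ti in tissues) {
    gm <- gen_reporter_matrix(config, ti,
                              seed = seed + 60000L + match(ti, tissues))
    cen <- log2_center(loading_normalize(gm$matrix))
    da <- differential_abundance(cen)
    da_list[[ti]] <- da
    cs_adj <- count_significant(da, adjusted = TRUE)
    cs_raw <- count_significant(da, adjusted = FALSE)
    da_count_rows[[ti]] <- data.frame(
      tissue = ti, total_adj = cs_adj$total, up_adj = cs_adj$up,
      down_adj = cs_adj$down, total_raw = cs_raw$total, up_raw = cs_raw$up,
      down_raw = cs_raw$down)
    sig_sets[[ti]] <- cs_adj$proteins
    ng <- config$proteome$n_per_group
    cond_ctl <- sample_cond[[paste(ti, "control")]]
    cond_ckd <- sample_cond[[paste(ti, "CKD")]]
    cond6 <- c(cond_ctl[seq_len(min(ng, length(cond_ctl)))],
               cond_ckd[seq_len(min(ng, length(cond_ckd)))])
    if (length(cond6) == ncol(cen$intensities))
      cor_list[[ti]] <- correlate_conductance(cen, cond6)
  }
  da_counts <- do.call(rbind, c(da_count_rows, list(make.row.names = FALSE)))
  overlap <- overlap_sets(sig_sets)

  phen <- gen_phenotypes(config, seed = seed + 70000L)
  pt <- lapply(c("body_g", "kidney_mg", "bun_mg_dl"), function(v) {
    tt <- ttest_equal_var(phen[[v]][phen$group == "control"],
                          phen[[v]][phen$group == "CKD"])
    data.frame(variable = v, mean_control = tt$mean_x, mean_ckd = tt$mean_y,
               t = tt$t, p = tt$p)
  })
  phenotype_tests <- do.call(rbind, pt)

  manifest <- list(seed = seed, config_hash = .config_hash(config),
                   package_version = as.character(utils::packageVersion("mitophen")),
                   n_resp = n_resp, n_fluor = n_fluor, n_enzyme = n_enzyme,
                   n_traces = nrow(conductance),
                   n_included = sum(conductance$included),
                   n_excluded = sum(!conductance$included),
                   exclusions = exclusions)

  report <- list(demand = demand_tbl, conductance = conductance,
                 conductance_groups = conductance_groups,
                 exclusions = exclusions,
                 redox = do.call(rbind, redox_rows),
                 membrane_potential = do.call(rbind, mv_rows),
                 h2o2 = do.call(rbind, h2o2_rows),
                 leak = do.call(rbind, leak_rows),
                 enzymes = enzymes, da = da_list, da_counts = da_counts,
                 overlap = overlap, correlations = cor_list,
                 phenotypes = phen, phenotype_tests = phenotype_tests,
                 manifest = manifest)
  class(report) <- "mitophen_report"
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Write a pipeline report bundle to disk
#'
#' One CSV per result table (per-tissue DA and correlation tables as
#' `da_<tissue>.csv` / `correlations_<tissue>.csv`) plus `manifest.json`.
#'
#' @param report A `mitophen_report` from [run_full_pipeline()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_report <- function(report, out_dir) {
  stopifnot(inherits(report, "mitophen_report"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  wr <- function(d, name) {
    f <- file.path(out_dir, paste0(name, ".csv"))
    utils::write.csv(d, f, row.names = FALSE)
    files <<- c(files, f)
  }
  for (nm in c("demand", "conductance", "conductance_groups", "exclusions",
               "redox", "membrane_potential", "h2o2", "leak", "enzymes",
               "da_counts", "phenotypes", "phenotype_tests"))
    wr(report[[nm]], nm)
  for (ti in names(report$da)) wr(report$da[[ti]], paste0("da_", ti))
  for (ti in names(report$correlations))
    wr(report$correlations[[ti]], paste0("correlations_", ti))
  mf <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(report$manifest, mf, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(c(files, mf))
}

#' @export
print.mitophen_report <- function(x, ...) {
  cat("mitophen synthetic phenotyping report\n")
  cat(sprintf("  traces: %d (%d included, %d excluded by cytochrome-c rule)\n",
              x$manifest$n_traces, x$manifest$n_included,
              x$manifest$n_excluded))
  cat("  conductance group changes:\n")
  print(x$conductance_groups, row.names = FALSE)
  invisible(x)
}
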