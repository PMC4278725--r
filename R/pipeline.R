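#' Read a time-series CSV
#'
#' The pipeline's on-disk curve format: two comma-separated columns with
#' header exactly `time_s,value`, decimal point, one sample per row.
#'
#' @param path file path.
#' @param units unit tag to attach ([time_series()] units).
#' @return A [time_series()].
#' @export
read_timeseries <- function(path, units = "a.u.") {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- utils::read.csv(path, nrows = 1, header = FALSE,
                            colClasses = "character")
  if (ncol(header) != 2L || header[[1]] != "time_s" || header[[2]] != "value")
    stop("malformed header in ", path, ": expected 'time_s,value'")
  df <- utils::read.csv(path, header = TRUE, colClasses = "numeric")
  bad <- which(!stats::complete.cases(df) | !is.finite(df$time_s) |
                 !is.finite(df$value))
  if (length(bad) > 0L)
    stop("malformed row(s) in ", path, " at line(s) ",
         paste(bad + 1L, collapse = ", "))
  if (any(diff(df$time_s) <= 0))
    stop("non-monotone time column in ", path)
  time_series(df$time_s, df$value, units)
}

#' Write a time-series CSV
#'
#' Inverse of [read_timeseries()]; writing then reading reproduces the
#' series.
#'
#' @param series a [time_series()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(series, path) {
  stopifnot(is_dce_ts(series))
  # 17 significant digits so every double survives the text round trip
  writeLines(c("time_s,value",
               sprintf("%.17g,%.17g", series$t, series$y)), path)
  invisible(path)
}

#' Assemble and validate a pipeline configuration
#'
#' A single nested list drives the whole study. Unknown keys at any
#' validated level are rejected so that typos fail loudly. Either a
#' `simulate` block (synthetic cohort) or an `inputs` list (per-subject
#' file paths and scalars) must be present.
#'
#' @param config a nested list, e.g. from [read_pipeline_config()].
#' @return The validated config with defaults filled in.
#' @export
pipeline_config <- function(config = list()) {
  known_top <- c("simulate", "inputs", "protocol", "relaxation", "metrics",
                 "fit", "stats", "seed", "out_dir", "log_level")
  unknown <- setdiff(names(config), known_top)
  if (length(unknown) > 0L)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  defaults <- list(
    simulate = NULL,
    inputs = NULL,
    protocol = list(pre_volume = 1.3, pre_rate = 4.1,
                    main_dose_per_kg = 0.05, weight = 70,
                    agent_molarity = 0.5, main_rate = 5),
    relaxation = list(T10_blood = 1.2, T10_liver = 0.586, r1 = 6.3),
    metrics = list(n_baseline_pre = 25, n_baseline_main = 3, k_sd = 3),
    fit = list(delay_step = 0.5, delay_max_a = 10, delay_max_p = 15),
    stats = list(ba_mode = "percent"),
    seed = 1L,
    out_dir = "results",
    log_level = "info")
  merge_block <- function(name) {
    block <- defaults[[name]]
    user <- config[[name]]
    if (is.null(user)) return(block)
    unknown <- setdiff(names(user), names(block))
    if (length(unknown) > 0L)
      stop("unknown key(s) in config block '", name, "': ",
           paste(unknown, collapse = ", "))
    utils::modifyList(block, user)
  }
  out <- defaults
  for (nm in c("protocol", "relaxation", "metrics", "fit", "stats"))
    out[[nm]] <- merge_block(nm)
  for (nm in c("simulate", "inputs", "seed", "out_dir", "log_level"))
    if (!is.null(config[[nm]])) out[[nm]] <- config[[nm]]
  if (!is.null(out$simulate)) {
    known_sim <- c("n_subjects", "master_seed", "retest", "noise_sd",
                   "inflow_amplitude")
    unknown <- setdiff(names(out$simulate), known_sim)
    if (length(unknown) > 0L)
      stop("unknown key(s) in config block 'simulate': ",
           paste(unknown, collapse = ", "))
  }
  if (is.null(out$simulate) && is.null(out$inputs))
    stop("config needs either a 'simulate' block or an 'inputs' list")
  out
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path path to a `.yaml`/`.yml` or `.json` config file.
#' @return A validated config (see [pipeline_config()]).
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  pipeline_config(cfg)
}

fit_options_from_config <- function(fit_cfg) {
  fit_options(delay_grid_a = seq(0, fit_cfg$delay_max_a,
                                 by = fit_cfg$delay_step),
              delay_grid_p = seq(0, fit_cfg$delay_max_p,
                                 by = fit_cfg$delay_step))
}

#' Process one subject through the full quantification chain
#'
#' Signal to concentration for all four series, plasma correction of the
#' vascular curves, AIF reconstruction from the pre-bolus response, shape
#' parameters of both AIFs, and the dual-input model fit with each AIF.
#' Both fits use the liver samples inside the window covered by the
#' pre-bolus AIF (60 s) so the two routes see identical data.
#'
#' @param prebolus_si,aorta_si,portal_si,liver_si the four signal-intensity
#'   [time_series()] (pre-bolus aorta; main-bolus aorta, portal vein,
#'   liver).
#' @param hematocrit subject hematocrit.
#' @param protocol an [injection_protocol()].
#' @param config a [pipeline_config()] (relaxation/metrics/fit blocks used).
#' @param T10_liver per-subject liver T1; defaults to the config value.
#' @param fit run the kinetic fits (disable to compute only conversions,
#'   AIFs and shape parameters, e.g. for shape-only comparisons).
#' @return List with the concentration curves, both AIFs, both
#'   [shape_parameters()] results, and both [fit_dual_input()] results
#'   (`NULL` when `fit = FALSE`).
#' @export
process_subject <- function(prebolus_si, aorta_si, portal_si, liver_si,
                            hematocrit, protocol, config = pipeline_config(
                              list(simulate = list(n_subjects = 0))),
                            T10_liver = config$relaxation$T10_liver,
                            fit = TRUE) {
  acq <- acquisition_defaults()
  relax_blood <- relaxation_params(T10 = config$relaxation$T10_blood,
                                   r1 = config$relaxation$r1)
  relax_liver <- relaxation_params(T10 = T10_liver, r1 = config$relaxation$r1)
  nb_pre <- config$metrics$n_baseline_pre
  nb_main <- config$metrics$n_baseline_main

  conv_pre <- signal_to_concentration(prebolus_si, nb_pre, acq$pre,
                                      relax_blood)
  conv_aorta <- signal_to_concentration(aorta_si, nb_main, acq$main,
                                        relax_blood)
  conv_portal <- signal_to_concentration(portal_si, nb_main, acq$main,
                                         relax_blood)
  conv_liver <- signal_to_concentration(liver_si, nb_main, acq$main,
                                        relax_liver)

  pre_plasma <- blood_to_plasma(conv_pre$series, hematocrit)
  aorta_plasma <- blood_to_plasma(conv_aorta$series, hematocrit)
  portal_plasma <- blood_to_plasma(conv_portal$series, hematocrit)
  liver_conc <- conv_liver$series   # tissue concentration: no hct correction

  prebolus_aif <- reconstruct_aif(pre_plasma, protocol)
  mainbolus_aif <- aorta_plasma

  k_sd <- config$metrics$k_sd
  shape_pre <- shape_parameters(prebolus_aif,
                                detect_trise(prebolus_aif, nb_pre, k_sd))
  shape_main <- shape_parameters(mainbolus_aif,
                                 detect_trise(mainbolus_aif, nb_main, k_sd))

  # fit on the liver samples covered by the pre-bolus AIF so both routes
  # compare like with like
  fit_pre <- fit_main <- NULL
  if (fit) {
    t_fit_end <- max(prebolus_aif$t)
    keep <- liver_conc$t <= t_fit_end
    liver_fit <- time_series(liver_conc$t[keep], liver_conc$y[keep],
                             "mmol/L")
    opts <- fit_options_from_config(config$fit)
    fit_pre <- fit_dual_input(prebolus_aif, portal_plasma, liver_fit, opts)
    fit_main <- fit_dual_input(mainbolus_aif, portal_plasma, liver_fit, opts)
  }

  list(prebolus_conc = pre_plasma, prebolus_aif = prebolus_aif,
       mainbolus_aif = mainbolus_aif, portal_plasma = portal_plasma,
       liver_conc = liver_conc,
       shape_pre = shape_pre, shape_main = shape_main,
       fit_pre = fit_pre, fit_main = fit_main,
       n_saturated = conv_aorta$n_saturated)
}

process_synthetic_subject <- function(subj, config, fit = TRUE) {
  process_subject(subj$prebolus_si, subj$mainbolus_aorta_si, subj$portal_si,
                  subj$liver_si, hematocrit = subj$truth$hematocrit,
                  protocol = subj$protocol, config = config,
                  T10_liver = subj$truth$T10_liver, fit = fit)
}

shape_df <- function(id, kind, sp) {
  data.frame(subject_id = id, curve_kind = kind, Cpeak = sp$cpeak,
             TTP = sp$ttp, upslope = sp$upslope, AUC60 = sp$auc60,
             FWHM = sp$fwhm, stringsAsFactors = FALSE)
}

perfusion_df <- function(id, source, fit) {
  p <- fit$perfusion
  data.frame(subject_id = id, aif_source = source, Fa = p$Fa, Fp = p$Fp,
             Ft = p$Ft, ART = p$ART, PV = p$PV, DV = p$DV, MTT = p$MTT,
             sse = fit$sse, converged = fit$converged,
             stringsAsFactors = FALSE)
}

agreement_table <- function(wide_pre, wide_main, params, ba_mode) {
  rows <- lapply(params, function(p) {
    pm <- paired_measurements(wide_pre$subject_id, wide_pre[[p]],
                              wide_main[[p]], label = p)
    rep_ <- bland_altman(pm, mode = ba_mode)
    wt <- tryCatch(
      stats::wilcox.test(wide_pre[[p]], wide_main[[p]], paired = TRUE,
                         exact = FALSE)$p.value,
      error = function(e) NA_real_)
    data.frame(parameter = p,
               mean_prebolus = mean(wide_pre[[p]]),
               sd_prebolus = stats::sd(wide_pre[[p]]),
               mean_mainbolus = mean(wide_main[[p]]),
               sd_mainbolus = stats::sd(wide_main[[p]]),
               mean_cv_pct = rep_$mean_cv_pct,
               bias_pct = rep_$bias_pct,
               loa_low_pct = rep_$loa_low_pct,
               loa_high_pct = rep_$loa_high_pct,
               wilcoxon_p = wt,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Run the end-to-end comparison study
#'
#' Simulates (or ingests) the cohort, processes every subject through
#' [process_subject()], and writes: per-subject concentration curves and
#' AIFs, the cohort shape-parameter and perfusion CSVs, the pre-bolus vs
#' main-bolus agreement tables, and — when retest replicates exist — the
#' test-retest CV tables. Per-subject failures are quarantined with their
#' error message; the run fails only if every subject fails. Deterministic
#' given the config.
#'
#' @param config a [pipeline_config()] (or raw list; validated here).
#' @param out_dir output directory; overrides `config$out_dir`.
#' @param quiet suppress progress messages.
#' @return Invisibly, a list with `shape`, `perfusion`, `agreement_shape`,
#'   `agreement_perfusion`, `retest_shape`, `retest_perfusion` (data
#'   frames or NULL) and `quarantine`.
#' @export
run_pipeline <- function(config, out_dir = NULL, quiet = FALSE) {
  config <- pipeline_config(config)
  if (is.null(out_dir)) out_dir <- config$out_dir
  dir.create(file.path(out_dir, "subjects"), recursive = TRUE,
             showWarnings = FALSE)
  say <- function(...) if (!quiet) message(...)

  proto <- do.call(injection_protocol, config$protocol)

  # assemble per-subject work units
  units <- list()
  if (!is.null(config$simulate)) {
    sim <- config$simulate
    td <- subject_truth()
    if (!is.null(sim$noise_sd) || !is.null(sim$inflow_amplitude)) {
      td <- subject_truth(
        noise_sd = if (is.null(sim$noise_sd)) td$noise_sd else sim$noise_sd,
        inflow_amplitude = if (is.null(sim$inflow_amplitude))
          td$inflow$amplitude else sim$inflow_amplitude)
    }
    say("simulating ", sim$n_subjects, " subject(s), master seed ", sim$master_seed)
    cohort <- generate_cohort(sim$n_subjects, sim$master_seed,
                              retest = isTRUE(sim$retest),
                              protocol = proto, truth_defaults = td)
    for (subj in cohort) {
      units[[length(units) + 1L]] <- list(
        id = subj$subject_id, visit = 1L, data = subj)
      if (!is.null(subj$retest))
        units[[length(units) + 1L]] <- list(
          id = subj$subject_id, visit = 2L, data = subj$retest)
    }
  } else {
    for (inp in config$inputs) {
      units[[length(units) + 1L]] <- list(
        id = inp$subject_id, visit = if (is.null(inp$visit)) 1L else inp$visit,
        paths = inp)
    }
  }

  shape_rows <- list(); perf_rows <- list(); quarantine <- list()
  for (u in units) {
    res <- tryCatch({
      if (!is.null(u$data)) {
        process_synthetic_subject(u$data, config)
      } else {
        p <- u$paths
        for (f in c("prebolus", "aorta", "portal", "liver"))
          if (!file.exists(p[[f]]))
            stop("missing input file for ", u$id, ": ", p[[f]])
        process_subject(
          read_timeseries(p$prebolus), read_timeseries(p$aorta),
          read_timeseries(p$portal), read_timeseries(p$liver),
          hematocrit = p$hematocrit, protocol = proto, config = config,
          T10_liver = if (is.null(p$T10_liver))
            config$relaxation$T10_liver else p$T10_liver)
      }
    }, error = function(e) e)
    if (inherits(res, "error")) {
      say("  quarantined ", u$id, " visit ", u$visit, ": ",
          conditionMessage(res))
      quarantine[[length(quarantine) + 1L]] <- data.frame(
        subject_id = u$id, visit = u$visit,
        reason = conditionMessage(res), stringsAsFactors = FALSE)
      next
    }
    say("  processed ", u$id, " visit ", u$visit)
    sdir <- file.path(out_dir, "subjects",
                      sprintf("%s_v%d", u$id, u$visit))
    dir.create(sdir, showWarnings = FALSE)
    write_timeseries(res$prebolus_aif, file.path(sdir, "prebolus_aif.csv"))
    write_timeseries(res$mainbolus_aif, file.path(sdir, "mainbolus_aif.csv"))
    write_timeseries(res$portal_plasma, file.path(sdir, "portal_conc.csv"))
    write_timeseries(res$liver_conc, file.path(sdir, "liver_conc.csv"))
    shape_rows[[length(shape_rows) + 1L]] <- cbind(
      rbind(shape_df(u$id, "prebolus_aif", res$shape_pre),
            shape_df(u$id, "mainbolus_aif", res$shape_main)),
      visit = u$visit)
    perf_rows[[length(perf_rows) + 1L]] <- cbind(
      rbind(perfusion_df(u$id, "prebolus", res$fit_pre),
            perfusion_df(u$id, "mainbolus", res$fit_main)),
      visit = u$visit)
  }

  if (length(shape_rows) == 0L)
    stop("all subjects failed; see quarantine")
  shape <- do.call(rbind, shape_rows)
  perf <- do.call(rbind, perf_rows)
  utils::write.csv(shape, file.path(out_dir, "shape_parameters.csv"),
                   row.names = FALSE)
  utils::write.csv(perf, file.path(out_dir, "perfusion_parameters.csv"),
                   row.names = FALSE)

  ba_mode <- config$stats$ba_mode
  v1 <- shape$visit == 1L
  shape_params <- c("Cpeak", "TTP", "upslope", "AUC60", "FWHM")
  perf_params <- c("Fa", "Fp", "Ft", "ART", "PV", "DV", "MTT")
  agr_shape <- agr_perf <- NULL
  if (sum(v1 & shape$curve_kind == "prebolus_aif") >= 2L) {
    agr_shape <- agreement_table(
      shape[v1 & shape$curve_kind == "prebolus_aif", ],
      shape[v1 & shape$curve_kind == "mainbolus_aif", ],
      shape_params, ba_mode)
    pv1 <- perf$visit == 1L
    agr_perf <- agreement_table(
      perf[pv1 & perf$aif_source == "prebolus", ],
      perf[pv1 & perf$aif_source == "mainbolus", ],
      perf_params, ba_mode)
    utils::write.csv(agr_shape, file.path(out_dir, "agreement_shape.csv"),
                     row.names = FALSE)
    utils::write.csv(agr_perf, file.path(out_dir, "agreement_perfusion.csv"),
                     row.names = FALSE)
  }

  retest_shape <- retest_perf <- NULL
  if (any(shape$visit == 2L)) {
    rt <- function(df, kindcol, kind, params) {
      a <- df[df$visit == 1L & df[[kindcol]] == kind,
              c("subject_id", params)]
      b <- df[df$visit == 2L & df[[kindcol]] == kind,
              c("subject_id", params)]
      a <- a[a$subject_id %in% b$subject_id, ]
      test_retest_cv(a, b)
    }
    retest_shape <- rbind(
      cbind(rt(shape, "curve_kind", "prebolus_aif", shape_params),
            aif_source = "prebolus"),
      cbind(rt(shape, "curve_kind", "mainbolus_aif", shape_params),
            aif_source = "mainbolus"))
    retest_perf <- rbind(
      cbind(rt(perf, "aif_source", "prebolus", perf_params),
            aif_source = "prebolus"),
      cbind(rt(perf, "aif_source", "mainbolus", perf_params),
            aif_source = "mainbolus"))
    utils::write.csv(retest_shape, file.path(out_dir, "retest_shape.csv"),
                     row.names = FALSE)
    utils::write.csv(retest_perf, file.path(out_dir, "retest_perfusion.csv"),
                     row.names = FALSE)
  }

  quarantine <- if (length(quarantine) > 0L) do.call(rbind, quarantine)
  if (!is.null(quarantine))
    utils::write.csv(quarantine, file.path(out_dir, "quarantine.csv"),
                     row.names = FALSE)

  invisible(list(shape = shape, perfusion = perf,
                 agreement_shape = agr_shape,
                 agreement_perfusion = agr_perf,
                 retest_shape = retest_shape,
                 retest_perfusion = retest_perf,
                 quarantine = quarantine))
}
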