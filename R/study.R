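#' Study configuration
#'
#' A simulated study: named groups, each with a dose, a dosing regimen and a
#' number of animals, plus shared simulator parameters, PK, analysis
#' thresholds and a base seed. Per-animal seeds are derived as
#' `seed_base + hash(group label, animal index)` with a stable string hash,
#' so adding a group never perturbs the data of existing animals.
#'
#' @param groups list of group specs, each a list with fields `label`,
#'   `dose`, `n` and optionally `regimen` (a [dose_regimen()]; defaults to
#'   the canonical 10\% bolus + 60-minute infusion of `dose`) and
#'   `sim_params` (a group-specific [flow_sim_params()] override, used e.g.
#'   for aged-thrombus presets)
#' @param sim_params shared [flow_sim_params()]
#' @param pk a [pk_params()]
#' @param analysis list of analysis thresholds: `monitor_min`, `frac`,
#'   `sustain_min`, `reocclusion_frac`, `reocclusion_sustain_min`, and
#'   aggregometry readouts `readout_s` (see [agg_readout_defaults()])
#' @param seed_base integer base seed
#' @return an object of class `study_config`
#' @export
study_config <- function(groups, sim_params = flow_sim_params(),
                         pk = pk_params(half_life_min = 4.1),
                         analysis = list(), seed_base = 1L) {
  labels <- vapply(groups, function(g) g$label, character(1))
  if (anyDuplicated(labels))
    stop_with("thrombolyzer_invalid_input", "group labels must be unique")
  for (g in groups) {
    if (is.null(g$dose) || is.null(g$n) || g$n < 1)
      stop_with("thrombolyzer_invalid_input",
                "each group needs `label`, `dose` and `n` >= 1")
  }
  defaults <- list(monitor_min = 120, frac = 0.5, sustain_min = 30,
                   reocclusion_frac = 0.10, reocclusion_sustain_min = 2,
                   readout_s = as.list(agg_readout_defaults()))
  analysis <- utils::modifyList(defaults, analysis)
  structure(list(groups = groups, sim_params = sim_params, pk = pk,
                 analysis = analysis, seed_base = as.integer(seed_base)),
            class = "study_config")
}

#' Per-animal simulation seed
#'
#' @param config a [study_config()] (or anything with `seed_base`)
#' @param label group label
#' @param index animal index within the group
#' @return integer seed below 2^31
#' @export
animal_seed <- function(config, label, index) {
  (config$seed_base + stable_hash(paste(label, index))) %% 2147483647
}

#' Seven-group dose-response design
#'
#' Saline control plus 1, 1.75, 2.5, 3.75, 5 and 10 mg/kg, each given as a
#' 10\% bolus with the remainder infused over 60 minutes, n animals per
#' group.
#'
#' @param n_per_group animals per group
#' @param seed_base base seed
#' @param sim_params,pk shared simulator and PK parameters
#' @return a [study_config()]
#' @export
dose_response_design <- function(n_per_group = 5, seed_base = 1L,
                                 sim_params = flow_sim_params(),
                                 pk = pk_params(half_life_min = 4.1)) {
  doses <- c(0, 1, 1.75, 2.5, 3.75, 5, 10)
  labels <- c("saline", paste0(doses[-1], " mg/kg"))
  groups <- Map(function(l, d) list(label = l, dose = d, n = n_per_group),
                labels, doses)
  study_config(unname(groups), sim_params = sim_params, pk = pk,
               seed_base = seed_base)
}

#' Four-regimen administration design
#'
#' The administration-method comparison at a fixed total dose: total-dose
#' bolus, double bolus (half at 0 and 60 minutes), half bolus + 60-minute
#' infusion, and 10\% bolus + 60-minute infusion.
#'
#' @param total_dose total dose, mg/kg
#' @param n_per_group animals per group
#' @param seed_base base seed
#' @param sim_params,pk shared simulator and PK parameters
#' @return a [study_config()]
#' @export
regimen_design <- function(total_dose = 5, n_per_group = 5, seed_base = 1L,
                           sim_params = flow_sim_params(),
                           pk = pk_params(half_life_min = 4.1)) {
  groups <- list(
    list(label = "total bolus", dose = total_dose,
         regimen = regimen_total_bolus(total_dose), n = n_per_group),
    list(label = "double bolus", dose = total_dose,
         regimen = regimen_double_bolus(total_dose), n = n_per_group),
    list(label = "half bolus + infusion", dose = total_dose,
         regimen = regimen_half_bolus_infusion(total_dose), n = n_per_group),
    list(label = "10% bolus + infusion", dose = total_dose,
         regimen = regimen_fractional_bolus_infusion(total_dose),
         n = n_per_group))
  study_config(groups, sim_params = sim_params, pk = pk,
               seed_base = seed_base)
}

#' Aged-thrombus design
#'
#' Thrombus age presets: lysis resistance grows with thrombus age, modeled
#' as a decaying multiplier on `k_lysis` (no new analysis code). All groups
#' receive the canonical 10\% bolus + infusion regimen of `total_dose`.
#'
#' @param total_dose total dose, mg/kg
#' @param ages_h thrombus ages in hours (0 = fresh)
#' @param n_per_group animals per group
#' @param age_scale_h e-folding age of lysis susceptibility, hours
#' @param seed_base base seed
#' @return a [study_config()]
#' @export
aged_thrombus_design <- function(total_dose = 5,
                                 ages_h = c(0, 1, 3, 6, 12, 24),
                                 n_per_group = 5, age_scale_h = 3,
                                 seed_base = 1L) {
  base <- flow_sim_params()
  groups <- lapply(ages_h, function(a) {
    p <- base
    p$k_lysis <- base$k_lysis * exp(-a / age_scale_h)
    list(label = sprintf("%g h", a), dose = total_dose, n = n_per_group,
         sim_params = p)
  })
  study_config(groups, sim_params = base, seed_base = seed_base)
}

# deterministic 31-bit hash of a config (stable JSON serialization)
config_hash <- function(config) {
  plain <- rapply(unclass(config), function(x)
    if (is.numeric(x)) signif(x, 12) else x, how = "replace")
  stable_hash(jsonlite::toJSON(plain, auto_unbox = TRUE, digits = NA,
                               force = TRUE))
}

#' Run a simulated study end to end
#'
#' Simulates every animal, analyzes each trace, summarizes groups and
#' compares them (ANOVA + Tukey vs the first group). Deterministic given
#' `seed_base`. With `out_dir` set, writes per-animal trace CSVs + marker
#' JSONs, per-animal report JSONs, a group summary TSV, a comparison/report
#' JSON and a manifest carrying the config hash and per-animal seeds.
#'
#' @param config a [study_config()]
#' @param out_dir output directory, or `NULL` for no files
#' @return an object of class `study_report`
#' @export
run_study <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "study_config"))
  an <- config$analysis
  reports <- list(); doses <- numeric(); glabels <- character()
  if (!is.null(out_dir)) {
    dir.create(file.path(out_dir, "traces"), recursive = TRUE,
               showWarnings = FALSE)
    dir.create(file.path(out_dir, "reports"), showWarnings = FALSE)
  }
  for (g in config$groups) {
    regimen <- g$regimen %||% dose_regimen(g$dose)
    params <- g$sim_params %||% config$sim_params
    for (j in seq_len(g$n)) {
      id <- sprintf("%s_%02d", gsub("[^A-Za-z0-9]+", "-", g$label), j)
      seed <- animal_seed(config, g$label, j)
      res <- tryCatch({
        tr <- simulate_flow_trace(g$dose, regimen = regimen, params = params,
                                  pk = config$pk, seed = seed,
                                  animal_id = id)
        rep <- analyze_flow_trace(
          tr, monitor_min = an$monitor_min, frac = an$frac,
          sustain_min = an$sustain_min,
          reocclusion_frac = an$reocclusion_frac,
          reocclusion_sustain_min = an$reocclusion_sustain_min)
        if (!is.null(out_dir)) {
          write_flow_trace(tr, file.path(out_dir, "traces",
                                         paste0(id, ".csv")))
          jsonlite::write_json(
            report_to_list(rep),
            file.path(out_dir, "reports", paste0(id, ".json")),
            auto_unbox = TRUE, digits = NA)
        }
        rep
      }, error = function(e) {
        stop_with("thrombolyzer_study_error",
                  sprintf("group '%s', animal %d: %s", g$label, j,
                          conditionMessage(e)))
      })
      reports[[id]] <- res
      doses <- c(doses, g$dose)
      glabels <- c(glabels, g$label)
    }
  }
  summaries <- summarize_doses(reports, doses, glabels)
  scores <- vapply(reports, function(r) r$score_pct, numeric(1))
  comparison <- if (length(unique(glabels)) >= 2 &&
                    all(table(glabels) >= 2))
    compare_groups(scores, glabels, control = config$groups[[1]]$label)
  else NULL
  report <- structure(
    list(reports = reports, group = glabels, dose = doses,
         summaries = summaries, comparison = comparison,
         provenance = list(config_hash = config_hash(config),
                           seed_base = config$seed_base,
                           seeds = vapply(names(reports), function(id)
                             NA_real_, numeric(1)),
                           package_version =
                             as.character(utils::packageVersion("thrombolyzer")),
                           timestamp = format(Sys.time(), tz = "UTC"))),
    class = "study_report")
  # record per-animal seeds keyed by id
  seeds <- numeric(0)
  for (g in config$groups)
    for (j in seq_len(g$n))
      seeds[sprintf("%s_%02d", gsub("[^A-Za-z0-9]+", "-", g$label), j)] <-
    animal_seed(config, g$label, j)
  report$provenance$seeds <- seeds

  if (!is.null(out_dir)) {
    utils::write.table(
      cbind(summaries[, setdiff(names(summaries),
                                "times_to_recanalization_min")],
            times_to_recanalization_min =
              vapply(summaries$times_to_recanalization_min,
                     function(v) paste(round(v, 3), collapse = ";"),
                     character(1))),
      file.path(out_dir, "group_summary.tsv"),
      sep = "\t", row.names = FALSE, quote = FALSE)
    jsonlite::write_json(study_report_to_list(report),
                         file.path(out_dir, "study_report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  report
}

report_to_list <- function(r) {
  list(animal_id = r$animal_id, baseline_flow = r$baseline_flow,
       min_flow = r$min_flow, score_pct = r$score_pct,
       complete_occlusion_time_s = r$complete_occlusion_time_s,
       effective_recanalization_time_min = r$effective_recanalization_time_min,
       reocclusion_times_min = as.numeric(r$reocclusion_times_min),
       minute_means = r$minute_means, params = r$params)
}

study_report_to_list <- function(report) {
  list(provenance = report$provenance,
       summaries = cbind(
         report$summaries[, setdiff(names(report$summaries),
                                    "times_to_recanalization_min")],
         times_to_recanalization_min = I(unname(
           report$summaries$times_to_recanalization_min))),
       comparison = if (!is.null(report$comparison))
         unclass(report$comparison) else NULL,
       animals = lapply(report$reports, report_to_list))
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> %d animals in %d groups (config %d)\n",
              length(x$reports), length(unique(x$group)),
              x$provenance$config_hash))
  s <- x$summaries
  for (k in seq_len(nrow(s)))
    cat(sprintf("  %-24s n=%d  score %6.2f%s%%  recanalized %d/%d\n",
                s$group[k], s$n[k], s$mean_score_pct[k],
                if (is.na(s$sd_score_pct[k])) "" else
                  sprintf(" +/- %.2f", s$sd_score_pct[k]),
                s$n_effective_recanalization[k], s$n[k]))
  if (!is.null(x$comparison))
    cat(sprintf("  %s p = %.4g\n", x$comparison$method, x$comparison$p_value))
  invisible(x)
}

#' Materialize a synthetic study to disk
#'
#' Writes a full synthetic study (by default the seven-dose design with
#' five animals per group) as trace CSVs with marker sidecars plus a
#' `manifest.json` recording the seed, per-animal seeds, regimens and
#' parameters, so the fixture set is exactly reproducible.
#'
#' @param dir output directory
#' @param design a [study_config()]
#' @param seed_base base seed override, or `NULL` to keep the design's
#' @return `dir`, invisibly
#' @export
write_study_fixtures <- function(dir, design = dose_response_design(),
                                 seed_base = NULL) {
  if (!is.null(seed_base)) design$seed_base <- as.integer(seed_base)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed_base = design$seed_base,
                   config_hash = config_hash(design),
                   sim_params = unclass(design$sim_params),
                   pk = unclass(design$pk), animals = list())
  for (g in design$groups) {
    regimen <- g$regimen %||% dose_regimen(g$dose)
    params <- g$sim_params %||% design$sim_params
    for (j in seq_len(g$n)) {
      id <- sprintf("%s_%02d", gsub("[^A-Za-z0-9]+", "-", g$label), j)
      seed <- animal_seed(design, g$label, j)
      tr <- simulate_flow_trace(g$dose, regimen = regimen, params = params,
                                pk = design$pk, seed = seed, animal_id = id)
      write_flow_trace(tr, file.path(dir, paste0(id, ".csv")))
      manifest$animals[[id]] <- list(group = g$label, dose = g$dose,
                                     seed = seed,
                                     regimen = unclass(regimen))
    }
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
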