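# --- metric catalogue ------------------------------------------------------

density_metric_name <- function(phenotype, compartment) {
  paste("density", phenotype, compartment, sep = "_")
}

pct_metric_name <- function(phenotype, parent, compartment) {
  paste("pct", phenotype, "of",
        if (identical(parent, "any_immune")) "any" else parent,
        compartment, sep = "_")
}

spatial_metric_name <- function(metric, reference, target, radius_um = NULL) {
  if (metric == "nn_mean_distance") {
    paste("nn", reference, target, sep = "_")
  } else {
    paste0("fwr", radius_um, "_", reference, "_", target)
  }
}

#' Default analysis metric catalogue
#'
#' The full set of per-patient metrics of the standard immune-contexture
#' analysis: densities and panel percentages of every immune phenotype
#' per compartment (tumor, stroma, total), activated-CTL percentages
#' (CD8+GrzB+ among CD8+), Treg percentages, CD8/CD4 and Treg/CTL
#' ratios, the intra-tumoral/peri-tumoral (I/P) ratio of the
#' activated-CTL percentage, nearest-neighbor distances from tumor cells
#' to T cells, and fraction-within-radius metrics at the 20/25/30 um
#' contact radii.
#'
#' @return List with elements `densities`, `percentages`, `ratios`,
#'   `spatial`, each a tibble of metric definitions.
#' @export
default_metric_spec <- function() {
  phenos <- list(
    panel1 = c("CD3", "CD20", "CD68", "CD56", "NE"),
    panel2 = c("CD4", "CD8", "CD8_GrzB", "CD4_GrzB", "Treg", "CD163")
  )
  densities <- tidyr::expand_grid(
    phenotype = unlist(phenos, use.names = FALSE),
    compartment = c("tumor", "stroma", "total")
  )
  percentages <- bind_rows(
    tidyr::expand_grid(
      phenotype = unlist(phenos, use.names = FALSE),
      parent = "any_immune",
      compartment = c("tumor", "stroma")
    ),
    tidyr::expand_grid(phenotype = "CD8_GrzB", parent = "CD8",
                       compartment = c("tumor", "stroma", "total")),
    tidyr::expand_grid(phenotype = "Treg", parent = "CD4",
                       compartment = c("tumor", "stroma", "total"))
  )
  ratios <- tibble::tribble(
    ~name, ~numerator, ~denominator,
    "cd8_cd4_ratio_tumor", "density_CD8_tumor", "density_CD4_tumor",
    "cd8_cd4_ratio_stroma", "density_CD8_stroma", "density_CD4_stroma",
    "ip_ratio_pct_CD8_GrzB", "pct_CD8_GrzB_of_CD8_tumor",
    "pct_CD8_GrzB_of_CD8_stroma",
    "treg_ctl_ratio_tumor", "density_Treg_tumor", "density_CD8_GrzB_tumor",
    "treg_ctl_ratio_total", "density_Treg_total", "density_CD8_GrzB_total",
    "treg_cd8_ratio_stroma", "density_Treg_stroma", "density_CD8_stroma"
  )
  spatial <- tibble::tribble(
    ~metric, ~reference, ~target, ~radius_um,
    "nn_mean_distance", "tumor", "CD3", NA_real_,
    "nn_mean_distance", "tumor", "CD8", NA_real_,
    "fraction_within", "tumor", "CD8", 25,
    "fraction_within", "tumor", "CD8", 20,
    "fraction_within", "tumor", "CD163", 20,
    "fraction_within", "CD8", "CD163", 20,
    "fraction_within", "tumor", "CD8_GrzB", 30
  )
  list(densities = densities, percentages = percentages,
       ratios = ratios, spatial = spatial)
}

# --- analysis configuration ------------------------------------------------

#' Build an analysis configuration
#'
#' A validated configuration for [run_pipeline()]: where the cohort
#' comes from (simulated with known ground truth, or ingested from cell
#' tables + clinical records), which metrics to compute, which groupings
#' to compare, and which metrics to take into survival analysis via
#' median dichotomization.
#'
#' @param mode `"simulate"` or `"ingest"`.
#' @param simulation A [sim_config()] (simulate mode).
#' @param patient_profiles Optional profile tibble (simulate mode); see
#'   [simulate_cohort()].
#' @param input List for ingest mode: `cell_tables` (character vector of
#'   paths readable by [read_cell_table()] with embedded metadata) and
#'   `clinical` (path for [read_clinical_table()]).
#' @param metrics Metric catalogue as in [default_metric_spec()].
#' @param groupings Clinical grouping columns for two-group comparisons
#'   (default `dcr_group`, `metastasis_site`, `treatment_class`,
#'   `status`).
#' @param correlations Tibble with columns `x`, `y` of metric names to
#'   correlate (Spearman).
#' @param survival_metrics Metric names analyzed by cohort-median split
#'   (Kaplan-Meier + log-rank + Cox HR for the high group).
#' @param immunoscore Compute the CD3/CD8 Immunoscore (logical).
#' @param concordance Named list `cd3`, `cd68` of the intra-tumoral
#'   density metrics combined into concordance groups, or `NULL`.
#' @param seed Integer seed for the run.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(mode = c("simulate", "ingest"),
                            simulation = sim_config(),
                            patient_profiles = NULL,
                            input = NULL,
                            metrics = default_metric_spec(),
                            groupings = c("dcr_group", "metastasis_site",
                                          "treatment_class", "status"),
                            correlations = tibble::tribble(
                              ~x, ~y,
                              "density_CD4_tumor", "density_Treg_tumor",
                              "density_CD3_tumor", "density_CD68_tumor"
                            ),
                            survival_metrics = c(
                              "pct_CD8_GrzB_of_CD8_total",
                              "pct_CD8_GrzB_of_CD8_tumor",
                              "density_CD8_tumor",
                              "treg_cd8_ratio_stroma",
                              "pct_Treg_of_CD4_stroma"
                            ),
                            immunoscore = TRUE,
                            concordance = list(
                              cd3 = "density_CD3_tumor",
                              cd68 = "density_CD68_tumor"
                            ),
                            seed = 1L) {
  mode <- arg_match(mode)
  cfg <- structure(
    list(mode = mode, simulation = simulation,
         patient_profiles = patient_profiles, input = input,
         metrics = metrics, groupings = groupings,
         correlations = as_tibble(correlations),
         survival_metrics = survival_metrics,
         immunoscore = isTRUE(immunoscore), concordance = concordance,
         seed = as.integer(seed)),
    class = "analysis_config"
  )
  validate_analysis_config(cfg)
  cfg
}

#' Validate an analysis configuration
#'
#' Checks that every metric referenced by a ratio, correlation,
#' concordance definition or survival analysis is defined by the metric
#' catalogue, and that phenotype names exist in the default panels;
#' errors list the offending names. Runs before any computation.
#'
#' @param config An `analysis_config`.
#' @return `config`, invisibly.
#' @export
validate_analysis_config <- function(config) {
  m <- config$metrics
  known_phenos <- unique(unlist(lapply(default_panels(),
                                       function(p) p$phenotype_names)))
  bad_ph <- setdiff(
    unique(c(m$densities$phenotype, m$percentages$phenotype,
             setdiff(m$percentages$parent, "any_immune"),
             m$spatial$reference, m$spatial$target)),
    known_phenos
  )
  if (length(bad_ph)) {
    ctx_abort(paste0("undefined phenotype(s) in metric catalogue: ",
                     paste(bad_ph, collapse = ", ")),
              class = "contexture_config_error")
  }
  defined <- c(
    density_metric_name(m$densities$phenotype, m$densities$compartment),
    pct_metric_name(m$percentages$phenotype, m$percentages$parent,
                    m$percentages$compartment),
    mapply(spatial_metric_name, m$spatial$metric, m$spatial$reference,
           m$spatial$target, m$spatial$radius_um),
    m$ratios$name
  )
  refs <- c(m$ratios$numerator, m$ratios$denominator,
            config$correlations$x, config$correlations$y,
            config$survival_metrics,
            unlist(config$concordance, use.names = FALSE))
  bad <- setdiff(refs, defined)
  if (length(bad)) {
    ctx_abort(paste0("config references undefined metric(s): ",
                     paste(bad, collapse = ", ")),
              class = "contexture_config_error")
  }
  if (config$mode == "ingest" &&
      (is.null(config$input) || is.null(config$input$cell_tables) ||
       is.null(config$input$clinical))) {
    ctx_abort("ingest mode requires input$cell_tables and input$clinical.",
              class = "contexture_config_error")
  }
  invisible(config)
}

#' Read an analysis configuration from YAML
#'
#' Supported keys mirror the arguments of [analysis_config()] and
#' [sim_config()]; `preset: um_default` loads the
#' [preset_um_cohort()] cohort design. Metric tables (`metrics`,
#' `correlations`) are lists of records.
#'
#' @param path YAML file.
#' @return An `analysis_config`.
#' @export
read_analysis_config <- function(path) {
  if (!file.exists(path)) ctx_abort(sprintf("config file not found: %s", path))
  y <- yaml::read_yaml(path)
  seed <- y$seed %||% 1L
  if (identical(y$preset, "um_default")) {
    preset <- preset_um_cohort(seed = seed)
    simulation <- preset$config
    profiles <- preset$patient_profiles
  } else {
    sim_args <- y$simulation %||% list()
    if (!is.null(sim_args$intensities)) {
      sim_args$intensities <- bind_rows(lapply(sim_args$intensities, as_tibble))
    }
    if (!is.null(sim_args$proximity)) {
      sim_args$proximity <- bind_rows(lapply(sim_args$proximity, as_tibble))
    }
    sim_args$seed <- sim_args$seed %||% seed
    simulation <- do.call(sim_config, sim_args)
    profiles <- if (!is.null(y$patient_profiles)) {
      bind_rows(lapply(y$patient_profiles, as_tibble))
    } else NULL
  }
  args <- list(
    mode = y$mode %||% "simulate",
    simulation = simulation,
    patient_profiles = profiles,
    seed = seed
  )
  if (!is.null(y$input)) args$input <- y$input
  if (!is.null(y$groupings)) args$groupings <- unlist(y$groupings)
  if (!is.null(y$survival_metrics)) {
    args$survival_metrics <- unlist(y$survival_metrics)
  }
  if (!is.null(y$correlations)) {
    args$correlations <- bind_rows(lapply(y$correlations, as_tibble))
  }
  if (!is.null(y$immunoscore)) args$immunoscore <- y$immunoscore
  do.call(analysis_config, args)
}

# --- per-patient metric computation ----------------------------------------

compute_sample_metrics <- function(sample, metrics) {
  rows <- list()
  d <- metrics$densities
  for (i in seq_len(nrow(d))) {
    r <- compartment_density(sample, d$phenotype[i], d$compartment[i])
    r$metric <- density_metric_name(d$phenotype[i], d$compartment[i])
    rows[[length(rows) + 1L]] <- r
  }
  p <- metrics$percentages
  for (i in seq_len(nrow(p))) {
    r <- phenotype_percentage(sample, p$phenotype[i], p$parent[i],
                              p$compartment[i])
    r$metric <- pct_metric_name(p$phenotype[i], p$parent[i], p$compartment[i])
    rows[[length(rows) + 1L]] <- r
  }
  s <- metrics$spatial
  for (i in seq_len(nrow(s))) {
    r <- aggregate_spatial_metric(
      sample, s$metric[i], s$reference[i], s$target[i],
      radius_um = if (is.na(s$radius_um[i])) NULL else s$radius_um[i]
    )
    rows[[length(rows) + 1L]] <- tibble(
      patient_id = r$patient_id,
      metric = spatial_metric_name(s$metric[i], s$reference[i],
                                   s$target[i], s$radius_um[i]),
      value = r$value,
      n_fields_used = r$n_fields_used,
      n_fields_excluded = r$n_fields_excluded
    )
  }
  long <- bind_rows(lapply(rows, function(r) {
    tibble(patient_id = r$patient_id, metric = r$metric, value = r$value,
           n_fields_used = r$n_fields_used,
           n_fields_excluded = r$n_fields_excluded)
  }))
  rt <- metrics$ratios
  if (!is.null(rt) && nrow(rt) > 0) {
    lookup <- setNames(long$value, long$metric)
    for (i in seq_len(nrow(rt))) {
      num <- lookup[[rt$numerator[i]]] %||% NA_real_
      den <- lookup[[rt$denominator[i]]] %||% NA_real_
      val <- if (is.na(num) || is.na(den)) NA_real_ else
        suppressWarnings(ratio_metric(num, den))
      long <- bind_rows(long, tibble(
        patient_id = sample$patient_id, metric = rt$name[i], value = val,
        n_fields_used = NA_integer_, n_fields_excluded = NA_integer_
      ))
    }
  }
  long
}

clinical_from_samples <- function(samples, survival = NULL) {
  cl <- bind_rows(lapply(samples, function(s) {
    c0 <- s$clinical
    tibble(
      patient_id = s$patient_id,
      recist = c0$recist %||% NA_character_,
      metastasis_site = s$metastasis_site %||% NA_character_,
      treatment_class = c0$treatment_class %||% NA_character_,
      tls_present = c0$tls_present %||% NA,
      os_months = c0$os_months %||% NA_real_,
      event = c0$event %||% NA_integer_
    )
  }))
  if (!is.null(survival)) {
    cl$os_months <- survival$time[match(cl$patient_id, survival$patient_id)]
    cl$event <- survival$event[match(cl$patient_id, survival$patient_id)]
  }
  if (!all(is.na(cl$recist))) {
    cl$dcr_group <- classify_response(cl$recist)$dcr_group
  } else {
    cl$dcr_group <- NA_character_
  }
  cl$status <- ifelse(is.na(cl$event), NA_character_,
                      ifelse(cl$event == 1, "dead", "alive"))
  cl
}

# --- pipeline --------------------------------------------------------------

#' Run the full immune-contexture analysis
#'
#' Orchestrates the end-to-end analysis from a single configuration:
#' obtain the cohort (simulate with known ground truth, or ingest cell
#' tables + clinical records), compute every configured per-patient
#' metric, run all two-group Mann-Whitney comparisons and Spearman
#' correlations, dichotomize the configured metrics by cohort median and
#' run Kaplan-Meier / log-rank / Cox survival analyses, compute the
#' Immunoscore and CD3/CD68 concordance groups. A failure in one metric
#' or analysis never aborts the others; failures are collected in the
#' bundle's error ledger. Deterministic for a fixed seed in simulate
#' mode.
#'
#' @param config An [analysis_config()] (or path handled by
#'   [read_analysis_config()]).
#' @return A `ctx_report` list: `metrics` (long per-patient table),
#'   `clinical`, `comparisons`, `correlations`, `survival`,
#'   `immunoscore`, `concordance`, `errors`, `manifest`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_analysis_config(config)
  validate_analysis_config(config)
  errors <- list()
  note_error <- function(stage, e) {
    errors[[length(errors) + 1L]] <<- tibble(
      stage = stage, message = conditionMessage(e)
    )
  }

  if (config$mode == "simulate") {
    cohort <- simulate_cohort(config$simulation, config$patient_profiles)
    samples <- cohort$samples
    survival_tbl <- cohort$survival
  } else {
    fields <- lapply(config$input$cell_tables, read_cell_table)
    panels <- default_panels()
    fields <- lapply(fields, function(f) {
      assign_phenotypes(f, panels[[field_panel(f)]])
    })
    by_sample <- split(fields, vapply(fields, function(f)
      as.character(attr(f, "sample_id")), character(1)))
    clin <- read_clinical_table(config$input$clinical)
    samples <- lapply(names(by_sample), function(sid) {
      row <- clin[clin$patient_id == sid, , drop = FALSE]
      assemble_sample(by_sample[[sid]],
                      clinical = if (nrow(row)) row else list())
    })
    names(samples) <- names(by_sample)
    survival_tbl <- if (all(c("os_months", "event") %in% names(clin))) {
      tibble(patient_id = clin$patient_id, time = clin$os_months,
             event = clin$event)
    } else NULL
    cohort <- NULL
  }
  if (length(samples) == 0L) ctx_abort("empty cohort: nothing to analyze.")

  metrics <- bind_rows(lapply(samples, function(s) {
    tryCatch(compute_sample_metrics(s, config$metrics),
             error = function(e) {
               note_error(paste0("metrics:", s$patient_id), e)
               tibble()
             })
  }))
  clinical <- clinical_from_samples(samples, survival_tbl)

  wide <- tidyr::pivot_wider(metrics[, c("patient_id", "metric", "value")],
                             names_from = "metric", values_from = "value")

  comparisons <- list()
  for (g in config$groupings) {
    if (!g %in% names(clinical)) next
    lev <- unique(stats::na.omit(clinical[[g]]))
    if (length(lev) != 2L) next
    for (m in setdiff(names(wide), "patient_id")) {
      v <- wide[[m]]
      grp <- clinical[[g]][match(wide$patient_id, clinical$patient_id)]
      x <- v[grp == lev[1] & !is.na(grp)]
      y <- v[grp == lev[2] & !is.na(grp)]
      res <- tryCatch(mann_whitney_test(x, y), error = function(e) {
        note_error(paste0("comparison:", g, ":", m), e)
        NULL
      })
      if (!is.null(res)) {
        comparisons[[length(comparisons) + 1L]] <- tibble(
          grouping = g, group1 = lev[1], group2 = lev[2], metric = m,
          statistic = res$statistic, p_value = res$p_value,
          n1 = res$n1, n2 = res$n2, method = res$method
        )
      }
    }
  }
  comparisons <- bind_rows(comparisons)

  correlations <- bind_rows(lapply(seq_len(nrow(config$correlations)),
                                   function(i) {
    cx <- config$correlations$x[i]
    cy <- config$correlations$y[i]
    res <- tryCatch(
      suppressWarnings(spearman_correlation(wide[[cx]], wide[[cy]])),
      error = function(e) {
        note_error(paste0("correlation:", cx, "~", cy), e)
        NULL
      }
    )
    if (is.null(res)) return(tibble())
    tibble(x = cx, y = cy, r = res$r, ci_low = res$ci_low,
           ci_high = res$ci_high, n = res$n)
  }))

  surv_ok <- !is.null(survival_tbl) && !all(is.na(clinical$os_months))
  surv_records <- if (surv_ok) {
    tibble(patient_id = clinical$patient_id, time = clinical$os_months,
           event = clinical$event)
  } else NULL

  med_get <- function(med, k) if (k %in% names(med)) med[[k]] else NA_real_
  survival_rows <- list()
  if (surv_ok) {
    for (m in config$survival_metrics) {
      res <- tryCatch({
        di <- suppressWarnings(dichotomize_by_median(
          setNames(wide[[m]], wide$patient_id)))
        rec <- surv_records
        rec$label <- di$labels[match(rec$patient_id, names(di$labels))]
        rec <- rec[!is.na(rec$label), ]
        km <- kaplan_meier(rec, group = "label")
        lr <- suppressWarnings(logrank_test(rec, "label"))
        cox <- suppressWarnings(cox_hazard_ratio(rec, "label", level = "high"))
        med <- setNames(km$medians$median, km$medians$group)
        tibble(
          metric = m, split = "median", cutoff = di$rule$median,
          n_low = sum(rec$label == "low"), n_high = sum(rec$label == "high"),
          median_os_low = med_get(med, "low"),
          median_os_high = med_get(med, "high"),
          logrank_chisq = lr$chisq, logrank_p = lr$p_value,
          hr_high = cox$hr, hr_ci_low = cox$ci_low,
          hr_ci_high = cox$ci_high, hr_p = cox$p_value
        )
      }, error = function(e) {
        note_error(paste0("survival:", m), e)
        NULL
      })
      if (!is.null(res)) survival_rows[[length(survival_rows) + 1L]] <- res
    }
  }

  immunoscore <- NULL
  if (config$immunoscore) {
    immunoscore <- tryCatch({
      dens <- tibble(
        patient_id = wide$patient_id,
        cd3_tumor = wide[["density_CD3_tumor"]],
        cd3_stroma = wide[["density_CD3_stroma"]],
        cd8_tumor = wide[["density_CD8_tumor"]],
        cd8_stroma = wide[["density_CD8_stroma"]]
      )
      compute_immunoscore(dens)
    }, error = function(e) {
      note_error("immunoscore", e)
      NULL
    })
    if (!is.null(immunoscore) && surv_ok) {
      for (cls in c("I0", "I4")) {
        res <- tryCatch({
          rec <- surv_records
          rec$class <- immunoscore$class[match(rec$patient_id,
                                               immunoscore$patient_id)]
          rec <- rec[!is.na(rec$class) & rec$class %in% c(cls, "IntI"), ]
          lr <- suppressWarnings(logrank_test(rec, "class"))
          cox <- suppressWarnings(cox_hazard_ratio(rec, "class",
                                                   level = "IntI"))
          km <- kaplan_meier(rec, group = "class")
          med <- setNames(km$medians$median, km$medians$group)
          tibble(
            metric = paste0("immunoscore_IntI_vs_", cls), split = "class",
            cutoff = NA_real_,
            n_low = sum(rec$class == cls), n_high = sum(rec$class == "IntI"),
            median_os_low = med_get(med, cls),
            median_os_high = med_get(med, "IntI"),
            logrank_chisq = lr$chisq, logrank_p = lr$p_value,
            hr_high = cox$hr, hr_ci_low = cox$ci_low,
            hr_ci_high = cox$ci_high, hr_p = cox$p_value
          )
        }, error = function(e) {
          note_error(paste0("survival:immunoscore:", cls), e)
          NULL
        })
        if (!is.null(res)) survival_rows[[length(survival_rows) + 1L]] <- res
      }
    }
  }

  concordance <- NULL
  if (!is.null(config$concordance)) {
    concordance <- tryCatch({
      l3 <- suppressWarnings(dichotomize_by_median(
        setNames(wide[[config$concordance$cd3]], wide$patient_id)))$labels
      l68 <- suppressWarnings(dichotomize_by_median(
        setNames(wide[[config$concordance$cd68]], wide$patient_id)))$labels
      tibble(
        patient_id = wide$patient_id,
        cd3_label = unname(l3), cd68_label = unname(l68),
        group = concordance_group(l3, l68)
      )
    }, error = function(e) {
      note_error("concordance", e)
      NULL
    })
    if (!is.null(concordance) && surv_ok) {
      res <- tryCatch({
        rec <- surv_records
        rec$group <- concordance$group[match(rec$patient_id,
                                             concordance$patient_id)]
        rec <- rec[!is.na(rec$group), ]
        lr <- suppressWarnings(logrank_test(rec, "group"))
        cox <- suppressWarnings(cox_hazard_ratio(rec, "group",
                                                 level = "concordant"))
        km <- kaplan_meier(rec, group = "group")
        med <- setNames(km$medians$median, km$medians$group)
        tibble(
          metric = "cd3_cd68_concordance", split = "class",
          cutoff = NA_real_,
          n_low = sum(rec$group == "discordant"),
          n_high = sum(rec$group == "concordant"),
          median_os_low = med_get(med, "discordant"),
          median_os_high = med_get(med, "concordant"),
          logrank_chisq = lr$chisq, logrank_p = lr$p_value,
          hr_high = cox$hr, hr_ci_low = cox$ci_low,
          hr_ci_high = cox$ci_high, hr_p = cox$p_value
        )
      }, error = function(e) {
        note_error("survival:concordance", e)
        NULL
      })
      if (!is.null(res)) survival_rows[[length(survival_rows) + 1L]] <- res
    }
  }

  structure(
    list(
      metrics = metrics,
      clinical = clinical,
      comparisons = comparisons,
      correlations = correlations,
      survival = bind_rows(survival_rows),
      immunoscore = immunoscore,
      concordance = concordance,
      errors = bind_rows(errors),
      manifest = tibble(
        package_version = as.character(utils::packageVersion("contexture")),
        seed = config$seed,
        mode = config$mode,
        n_patients = length(samples),
        config_hash = rlang::hash(config),
        timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
      ),
      truth = if (config$mode == "simulate") cohort$truth else NULL
    ),
    class = "ctx_report"
  )
}

#' @export
print.ctx_report <- function(x, ...) {
  cat(sprintf(
    "<ctx_report> %d patients, %d metric values, %d comparisons, %d survival analyses, %d errors\n",
    x$manifest$n_patients, nrow(x$metrics), nrow(x$comparisons),
    nrow(x$survival), nrow(x$errors)
  ))
  invisible(x)
}

#' Write a report bundle to disk
#'
#' Writes every table of a [run_pipeline()] bundle as tab-separated
#' text (`metrics.tsv`, `clinical.tsv`, `comparisons.tsv`,
#' `correlations.tsv`, `survival.tsv`, `immunoscore.tsv`,
#' `concordance.tsv`, `errors.tsv`, `manifest.tsv`) plus a
#' human-readable `summary.txt`.
#'
#' @param bundle A `ctx_report`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
generate_report <- function(bundle, dir) {
  stopifnot(inherits(bundle, "ctx_report"))
  if (is.null(bundle$metrics) || nrow(bundle$metrics) == 0L) {
    ctx_abort("empty bundle: nothing to report.")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) ctx_abort(sprintf("cannot create '%s'.", dir))
  tabs <- list(
    metrics = bundle$metrics, clinical = bundle$clinical,
    comparisons = bundle$comparisons, correlations = bundle$correlations,
    survival = bundle$survival, immunoscore = bundle$immunoscore,
    concordance = bundle$concordance, errors = bundle$errors,
    manifest = bundle$manifest
  )
  for (nm in names(tabs)) {
    if (!is.null(tabs[[nm]])) {
      readr::write_tsv(tabs[[nm]], file.path(dir, paste0(nm, ".tsv")))
    }
  }
  n_pat <- length(unique(bundle$metrics$patient_id))
  lines <- c(
    "contexture analysis summary",
    sprintf("patients: %d", n_pat),
    sprintf("metric values: %d", nrow(bundle$metrics)),
    sprintf("group comparisons: %d (significant at p <= 0.05: %d)",
            nrow(bundle$comparisons),
            sum(bundle$comparisons$p_value <= 0.05, na.rm = TRUE)),
    sprintf("survival analyses: %d", nrow(bundle$survival)),
    sprintf("errors: %d", nrow(bundle$errors))
  )
  if (!is.null(bundle$immunoscore)) {
    tb <- table(bundle$immunoscore$class)
    lines <- c(lines, paste0(
      "immunoscore classes: ",
      paste(sprintf("%s=%d", names(tb), as.integer(tb)), collapse = ", ")
    ))
  }
  writeLines(lines, file.path(dir, "summary.txt"))
  invisible(dir)
}
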