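# --- tissue geometry -------------------------------------------------------

make_nests <- function(config) {
  n <- config$tumor_nest_count
  tibble(
    x = runif(n, 0, config$field_width_um),
    y = runif(n, 0, config$field_height_um),
    r = rep(config$tumor_nest_radius_um, n)
  )
}

in_tumor_region <- function(x, y, nests) {
  inside <- rep(FALSE, length(x))
  for (i in seq_len(nrow(nests))) {
    inside <- inside |
      ((x - nests$x[i])^2 + (y - nests$y[i])^2 <= nests$r[i]^2)
  }
  inside
}

# Tumor area in mm^2: analytic (sum of disc areas) when the discs are
# pairwise disjoint and fully inside the field, else a ~1 um pixel raster
# of the disc union (clipped at the field border).
tumor_area_mm2 <- function(nests, width, height) {
  n <- nrow(nests)
  if (n == 0L) return(0)
  fully_inside <- all(
    nests$x - nests$r >= 0, nests$x + nests$r <= width,
    nests$y - nests$r >= 0, nests$y + nests$r <= height
  )
  disjoint <- TRUE
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        d2 <- (nests$x[i] - nests$x[j])^2 + (nests$y[i] - nests$y[j])^2
        if (d2 < (nests$r[i] + nests$r[j])^2) disjoint <- FALSE
      }
    }
  }
  if (fully_inside && disjoint) {
    return(sum(pi * nests$r^2) / 1e6)
  }
  nx <- max(1L, round(width))
  ny <- max(1L, round(height))
  px <- width / nx
  py <- height / ny
  gx <- (seq_len(nx) - 0.5) * px
  gy <- (seq_len(ny) - 0.5) * py
  xs <- rep(gx, times = ny)
  ys <- rep(gy, each = nx)
  sum(in_tumor_region(xs, ys, nests)) * px * py / 1e6
}

# Uniform points in one compartment by rejection from the field rectangle.
sample_in_compartment <- function(n, compartment, nests, width, height,
                                  frac) {
  if (n == 0L) {
    return(tibble(x_um = numeric(0), y_um = numeric(0)))
  }
  xs <- numeric(0)
  ys <- numeric(0)
  want_tumor <- compartment == "tumor"
  iter <- 0L
  while (length(xs) < n) {
    iter <- iter + 1L
    if (iter > 1000L) {
      ctx_abort("rejection sampling failed: compartment area is (near) zero.")
    }
    m <- max(200L, ceiling(1.5 * (n - length(xs)) / max(frac, 1e-3)))
    cx <- runif(m, 0, width)
    cy <- runif(m, 0, height)
    keep <- in_tumor_region(cx, cy, nests) == want_tumor
    xs <- c(xs, cx[keep])
    ys <- c(ys, cy[keep])
  }
  tibble(x_um = xs[seq_len(n)], y_um = ys[seq_len(n)])
}

# Re-place a subset of target cells uniformly within `radius` of randomly
# chosen anchor cells (rejected until inside the field).
attract_cells <- function(cells, target, anchor, fraction, radius,
                          width, height) {
  tgt <- which(cells$true_phenotype == target)
  anc <- which(cells$true_phenotype == anchor)
  if (length(tgt) == 0L || length(anc) == 0L || fraction == 0) return(cells)
  move <- tgt[runif(length(tgt)) < fraction]
  for (i in move) {
    a <- if (length(anc) == 1L) anc else sample(anc, 1L)
    repeat {
      rr <- radius * sqrt(runif(1))
      th <- runif(1, 0, 2 * pi)
      nx <- cells$x_um[a] + rr * cos(th)
      ny <- cells$y_um[a] + rr * sin(th)
      if (nx >= 0 && nx <= width && ny >= 0 && ny <= height) break
    }
    cells$x_um[i] <- nx
    cells$y_um[i] <- ny
  }
  cells
}

# --- field simulation ------------------------------------------------------

#' Simulate one mIHC tissue field
#'
#' Places cells by independent homogeneous Poisson processes per
#' (phenotype, compartment) over a tumor-nest/stroma geometry: disc
#' nests with uniformly random centers define the tumor compartment
#' (overlapping nests are unioned, discs clipped at the field border,
#' areas accounted exactly); each phenotype's expected count is
#' `intensity x compartment area`. Optional proximity structure then
#' re-places a fraction of target cells near anchor cells (see
#' [sim_config()]). Marker positivity columns are generated directly
#' from the phenotype identity (noise-free unless
#' `misclassification_rate > 0`), a cell's compartment label is
#' re-derived from its final position, and phenotype labels are assigned
#' with the default panel definitions. Fully reproducible for a fixed
#' seed.
#'
#' @param config A [sim_config()].
#' @param panel_id `"panel1"` or `"panel2"`.
#' @param patient_profile Optional one-row data frame or named list with
#'   `mult_<phenotype>` intensity multipliers (and arbitrary other
#'   entries, ignored here).
#' @param field_id,sample_id Identifiers stored on the field.
#' @param seed Integer seed for this field (`NULL`: use the current RNG
#'   stream).
#' @return A phenotyped [field_tbl()] with a `true_phenotype` column
#'   carrying the simulated ground-truth label of every cell.
#' @export
simulate_field <- function(config, panel_id = "panel2",
                           patient_profile = NULL,
                           field_id = "F01", sample_id = "S01",
                           seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  with_local_seed(seed, {
    width <- config$field_width_um
    height <- config$field_height_um
    nests <- make_nests(config)
    area_t <- tumor_area_mm2(nests, width, height)
    area_s <- width * height / 1e6 - area_t
    if (area_t + area_s <= 0) {
      ctx_abort("zero total compartment area.")
    }
    intens <- config$intensities[config$intensities$panel == panel_id, ]
    if (nrow(intens) == 0L) {
      ctx_abort(sprintf("no intensities defined for panel '%s'.", panel_id))
    }
    if (!is.null(config$proximity)) {
      missing <- setdiff(
        unique(c(config$proximity$target, config$proximity$anchor)),
        intens$phenotype
      )
      if (length(missing)) {
        ctx_abort(paste0(
          "proximity phenotype(s) absent from the intensity map: ",
          paste(missing, collapse = ", ")
        ))
      }
    }
    mult <- rep(1, nrow(intens))
    if (!is.null(patient_profile)) {
      pp <- as.list(patient_profile)
      for (k in seq_len(nrow(intens))) {
        key <- paste0("mult_", intens$phenotype[k])
        if (!is.null(pp[[key]]) && !is.na(pp[[key]])) {
          mult[k] <- as.numeric(pp[[key]])
        }
      }
    }
    frac_t <- area_t / (area_t + area_s)
    cells_list <- list()
    for (k in seq_len(nrow(intens))) {
      for (comp in c("tumor", "stroma")) {
        lam <- intens[[comp]][k] * mult[k]
        area <- if (comp == "tumor") area_t else area_s
        if (lam > 0 && area <= 0) {
          ctx_abort(sprintf(
            "phenotype '%s' has positive %s intensity but the %s area is zero.",
            intens$phenotype[k], comp, comp
          ))
        }
        n_cells <- rpois(1L, lam * area)
        if (n_cells > 0L) {
          pos <- sample_in_compartment(
            n_cells, comp, nests, width, height,
            if (comp == "tumor") frac_t else 1 - frac_t
          )
          pos$true_phenotype <- intens$phenotype[k]
          cells_list[[length(cells_list) + 1L]] <- pos
        }
      }
    }
    cells <- if (length(cells_list)) bind_rows(cells_list) else
      tibble(x_um = numeric(0), y_um = numeric(0),
             true_phenotype = character(0))
    if (!is.null(config$proximity)) {
      for (k in seq_len(nrow(config$proximity))) {
        pr <- config$proximity[k, ]
        cells <- attract_cells(cells, pr$target, pr$anchor,
                               pr$attracted_fraction,
                               pr$placement_radius_um, width, height)
      }
    }
    n <- nrow(cells)
    if (n > 0L && config$misclassification_rate > 0) {
      phenos <- unique(intens$phenotype)
      flip <- which(runif(n) < config$misclassification_rate)
      for (i in flip) {
        others <- setdiff(phenos, cells$true_phenotype[i])
        if (length(others)) {
          cells$true_phenotype[i] <-
            if (length(others) == 1L) others else sample(others, 1L)
        }
      }
    }
    mk_map <- simulated_marker_map(panel_id)
    markers <- unique(unlist(mk_map))
    for (m in markers) cells[[m]] <- FALSE
    if (n > 0L) {
      for (ph in names(mk_map)) {
        rows <- cells$true_phenotype == ph
        for (m in mk_map[[ph]]) cells[[m]][rows] <- TRUE
      }
      cells$compartment <- ifelse(
        in_tumor_region(cells$x_um, cells$y_um, nests), "tumor", "stroma"
      )
      cells$cell_id <- seq_len(n)
    } else {
      cells$compartment <- character(0)
      cells$cell_id <- integer(0)
    }
    cells <- cells[, c("cell_id", "x_um", "y_um", "compartment",
                       markers, "true_phenotype")]
    fld <- field_tbl(cells, field_id = field_id, sample_id = sample_id,
                     panel_id = panel_id,
                     areas = c(tumor = area_t, stroma = area_s),
                     markers = markers)
    assign_phenotypes(fld, default_panels()[[panel_id]])
  })
}

# --- survival layer --------------------------------------------------------

#' Simulate survival outcomes under a proportional-hazards model
#'
#' Event times are exponential with per-patient hazard
#' `baseline_hazard * exp(sum(log_hr * feature))`, features taken from
#' the columns of `features` named in `log_hr`. Censoring is independent
#' uniform over `[0, followup_months]` applied to a Bernoulli-thinned
#' subset of patients (probability `censoring_rate`), plus
#' administrative censoring at the follow-up horizon for everyone.
#'
#' @param features Data frame with `patient_id` and one numeric column
#'   per named coefficient.
#' @param baseline_hazard Baseline hazard per month (> 0).
#' @param log_hr Named numeric vector of log hazard ratios (may be
#'   empty).
#' @param censoring_rate In `[0, 1)`.
#' @param followup_months Horizon (> 0).
#' @param seed Integer seed (`NULL`: current RNG stream).
#' @return Tibble: `patient_id`, `time` (months), `event` (1 death /
#'   0 censored), plus all `features` columns.
#' @export
simulate_survival <- function(features, baseline_hazard, log_hr = c(),
                              censoring_rate = 0, followup_months = 120,
                              seed = NULL) {
  check_number(baseline_hazard, "baseline_hazard", min = 0, allow_min = FALSE)
  check_number(censoring_rate, "censoring_rate", min = 0, max = 1,
               allow_max = FALSE)
  check_number(followup_months, "followup_months", min = 0, allow_min = FALSE)
  features <- as_tibble(features)
  missing <- setdiff(names(log_hr), names(features))
  if (length(missing)) {
    ctx_abort(paste0("log_hr names absent from `features`: ",
                     paste(missing, collapse = ", ")))
  }
  with_local_seed(seed, {
    n <- nrow(features)
    lp <- rep(0, n)
    for (nm in names(log_hr)) {
      lp <- lp + log_hr[[nm]] * as.numeric(features[[nm]])
    }
    hazard <- baseline_hazard * exp(lp)
    t_event <- rexp(n, rate = hazard)
    censored_candidate <- runif(n) < censoring_rate
    c_time <- ifelse(censored_candidate, runif(n, 0, followup_months),
                     Inf)
    c_time <- pmin(c_time, followup_months)
    time <- pmin(t_event, c_time)
    event <- as.integer(t_event <= c_time)
    # guard against zero observed time (KM requires time > 0)
    time <- pmax(time, 1e-9)
    dplyr::bind_cols(
      tibble(patient_id = features$patient_id, time = time, event = event),
      features[, setdiff(names(features), "patient_id"), drop = FALSE]
    )
  })
}

# --- cohort simulation -----------------------------------------------------

#' Simulate a full synthetic mIHC cohort
#'
#' Generates, for every patient, `n_fields_per_patient` fields per panel
#' (both default panels) plus a survival record tied to the patient's
#' features by a proportional-hazards model, and returns the
#' ground-truth quantities used to generate them. All randomness derives
#' deterministically from `config$seed`: per-field seeds are a fixed
#' function of seed, patient index, panel and field index, so any field
#' can be regenerated independently and the whole cohort is
#' byte-identical across runs.
#'
#' @param config A [sim_config()].
#' @param patient_profiles Optional tibble with `patient_id` and
#'   per-patient columns: `mult_<phenotype>` intensity multipliers,
#'   covariates named in `config$log_hr`, and clinical columns (e.g.
#'   `recist`, `metastasis_site`, `treatment_class`). Defaults to
#'   `n_patients` identical patients.
#' @param panels Panel ids to image (default both).
#' @return List of class `sim_cohort`: `samples` (named list of
#'   `sample_set`), `survival` (tibble from [simulate_survival()]),
#'   `truth` (list: `intensities`, `proximity`, `log_hr`,
#'   `patient_profiles`).
#' @export
simulate_cohort <- function(config, patient_profiles = NULL,
                            panels = c("panel1", "panel2")) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_patients < 2L) ctx_abort("n_patients must be >= 2.")
  if (is.null(patient_profiles)) {
    patient_profiles <- tibble(
      patient_id = sprintf("P%02d", seq_len(config$n_patients))
    )
  }
  patient_profiles <- as_tibble(patient_profiles)
  if (nrow(patient_profiles) != config$n_patients) {
    ctx_abort("patient_profiles must have one row per patient.")
  }
  samples <- vector("list", nrow(patient_profiles))
  names(samples) <- patient_profiles$patient_id
  for (i in seq_len(nrow(patient_profiles))) {
    prof <- patient_profiles[i, ]
    pid <- prof$patient_id
    fields <- list()
    for (pnl_i in seq_along(panels)) {
      for (f in seq_len(config$n_fields_per_patient)) {
        fseed <- (config$seed + 524287L * i + 8191L * pnl_i + f) %% 2147483647L
        fields[[length(fields) + 1L]] <- simulate_field(
          config, panel_id = panels[pnl_i], patient_profile = prof,
          field_id = sprintf("%s_%s_F%02d", pid, panels[pnl_i], f),
          sample_id = pid, seed = fseed
        )
      }
    }
    samples[[i]] <- assemble_sample(fields, clinical = as.list(prof))
  }
  survival <- simulate_survival(
    patient_profiles, config$baseline_hazard, config$log_hr,
    config$censoring_rate, config$followup_months,
    seed = (config$seed + 1000003L) %% 2147483647L
  )
  structure(
    list(
      samples = samples,
      survival = survival,
      truth = list(
        intensities = config$intensities,
        proximity = config$proximity,
        log_hr = config$log_hr,
        patient_profiles = patient_profiles
      )
    ),
    class = "sim_cohort"
  )
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("<sim_cohort> %d patients, %d fields total, %d events\n",
              length(x$samples),
              sum(vapply(x$samples, function(s) length(s$fields), numeric(1))),
              sum(x$survival$event)))
  invisible(x)
}
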