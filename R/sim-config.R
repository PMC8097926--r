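# Run code under a temporary RNG state seeded with `seed`; the caller's
# global RNG stream is restored afterwards. `seed = NULL` runs as-is.
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Default per-phenotype placement intensities
#'
#' Baseline Poisson intensities (cells/mm^2) per phenotype and
#' compartment for the two default panels, chosen to resemble a
#' T-cell-infiltrated melanoma metastasis: tumor cells dominate the
#' tumor nests, T cells and macrophages are abundant, NK cells and
#' neutrophils negligible.
#'
#' @return Tibble with columns `panel`, `phenotype`, `tumor`, `stroma`
#'   (intensities in cells/mm^2).
#' @export
default_intensities <- function() {
  tibble::tribble(
    ~panel,   ~phenotype, ~tumor, ~stroma,
    "panel1", "tumor",      2000,      50,
    "panel1", "CD3",         150,     300,
    "panel1", "CD20",         20,      60,
    "panel1", "CD68",        250,     150,
    "panel1", "CD56",          5,      10,
    "panel1", "NE",            5,      15,
    "panel2", "tumor",      2000,      50,
    "panel2", "CD4",           80,     200,
    "panel2", "CD8",          120,     250,
    "panel2", "CD8_GrzB",      30,      40,
    "panel2", "CD4_GrzB",       5,      10,
    "panel2", "Treg",          20,      60,
    "panel2", "CD163",        180,     120
  )
}

#' Simulation configuration for a synthetic mIHC cohort
#'
#' Defines the tissue geometry, per-phenotype placement intensities,
#' optional proximity structure and the survival model of a synthetic
#' cohort. Defaults emulate the design of a metastatic uveal-melanoma
#' mIHC study: 21 patients, at least 20 fields per slide at 20X
#' (669 x 500 um fields), tumor nests inside stroma, two staining
#' panels.
#'
#' @param field_width_um,field_height_um Field dimensions in um (> 0).
#' @param n_fields_per_patient Fields acquired per patient and panel
#'   (>= 1; default 20).
#' @param tumor_nest_count Number of disc-shaped tumor nests per field
#'   (centers uniform in the field; overlapping nests are unioned,
#'   discs clipped at the field border with exact area accounting).
#' @param tumor_nest_radius_um Nest radius in um.
#' @param intensities Tibble `panel`, `phenotype`, `tumor`, `stroma`
#'   with Poisson intensities in cells/mm^2 (all >= 0);
#'   default [default_intensities()].
#' @param proximity Optional tibble `target`, `anchor`,
#'   `attracted_fraction` (in `[0, 1]`), `placement_radius_um` (> 0):
#'   after Poisson placement, each target-phenotype cell is independently
#'   re-placed, with the given probability, uniformly within the
#'   placement radius of a randomly chosen anchor-phenotype cell.
#' @param misclassification_rate Probability a simulated cell's phenotype
#'   is swapped for another panel phenotype before marker generation
#'   (staining/phenotyping noise; default 0 = noise-free markers).
#' @param baseline_hazard Baseline death hazard per month (> 0).
#' @param log_hr Named numeric vector of log hazard ratios; names refer
#'   to numeric columns of the patient-profile table.
#' @param censoring_rate Probability a patient receives a uniform
#'   censoring time over `[0, followup_months]` (in `[0, 1)`).
#' @param followup_months Administrative follow-up horizon in months.
#' @param n_patients Number of patients (>= 2).
#' @param seed Integer seed; per-field seeds are derived
#'   deterministically from it so every field is independently
#'   reproducible.
#' @return A `sim_config` list.
#' @export
sim_config <- function(field_width_um = 669,
                       field_height_um = 500,
                       n_fields_per_patient = 20,
                       tumor_nest_count = 3,
                       tumor_nest_radius_um = 100,
                       intensities = default_intensities(),
                       proximity = NULL,
                       misclassification_rate = 0,
                       baseline_hazard = 0.02,
                       log_hr = c(),
                       censoring_rate = 0.2,
                       followup_months = 120,
                       n_patients = 21,
                       seed = 1L) {
  check_number(field_width_um, "field_width_um", min = 0, allow_min = FALSE)
  check_number(field_height_um, "field_height_um", min = 0, allow_min = FALSE)
  check_number(n_fields_per_patient, "n_fields_per_patient", min = 1)
  check_number(tumor_nest_count, "tumor_nest_count", min = 0)
  check_number(tumor_nest_radius_um, "tumor_nest_radius_um", min = 0,
               allow_min = FALSE)
  check_number(misclassification_rate, "misclassification_rate",
               min = 0, max = 1)
  check_number(baseline_hazard, "baseline_hazard", min = 0, allow_min = FALSE)
  check_number(censoring_rate, "censoring_rate", min = 0, max = 1,
               allow_max = FALSE)
  check_number(followup_months, "followup_months", min = 0, allow_min = FALSE)
  check_number(n_patients, "n_patients", min = 2)
  check_number(seed, "seed")
  intensities <- as_tibble(intensities)
  req <- c("panel", "phenotype", "tumor", "stroma")
  if (!all(req %in% names(intensities))) {
    ctx_abort("`intensities` needs columns panel, phenotype, tumor, stroma.")
  }
  if (any(intensities$tumor < 0) || any(intensities$stroma < 0)) {
    ctx_abort("placement intensities must be >= 0.")
  }
  if (!is.null(proximity)) {
    proximity <- as_tibble(proximity)
    reqp <- c("target", "anchor", "attracted_fraction", "placement_radius_um")
    if (!all(reqp %in% names(proximity))) {
      ctx_abort("`proximity` needs columns target, anchor, attracted_fraction, placement_radius_um.")
    }
    if (any(proximity$attracted_fraction < 0 | proximity$attracted_fraction > 1)) {
      ctx_abort("attracted_fraction must be in [0, 1].")
    }
    if (any(proximity$placement_radius_um <= 0)) {
      ctx_abort("placement_radius_um must be > 0.")
    }
  }
  structure(
    list(
      field_width_um = field_width_um,
      field_height_um = field_height_um,
      n_fields_per_patient = as.integer(n_fields_per_patient),
      tumor_nest_count = as.integer(tumor_nest_count),
      tumor_nest_radius_um = tumor_nest_radius_um,
      intensities = intensities,
      proximity = proximity,
      misclassification_rate = misclassification_rate,
      baseline_hazard = baseline_hazard,
      log_hr = log_hr,
      censoring_rate = censoring_rate,
      followup_months = followup_months,
      n_patients = as.integer(n_patients),
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> %d patients x %d fields (%g x %g um), %d nests r = %g um, h0 = %g/month, seed %d\n",
    x$n_patients, x$n_fields_per_patient, x$field_width_um,
    x$field_height_um, x$tumor_nest_count, x$tumor_nest_radius_um,
    x$baseline_hazard, x$seed
  ))
  invisible(x)
}

#' Default metastatic-melanoma study preset
#'
#' Configuration plus patient profiles emulating the structure of a
#' 21-patient metastatic uveal-melanoma cohort: 14 controlled-disease
#' (CD: 7 SD, 6 PR, 1 CR) vs 7 progressive-disease (PD) patients, 17
#' liver / 4 extra-hepatic metastases, 13 immunotherapy-treated, and
#' group-wise intensity multipliers giving CD patients more (activated)
#' CTL and fewer Treg/M2 macrophages. Disease control halves the death
#' hazard (`log_hr = log(0.5)` on the CD indicator).
#'
#' @param seed Integer seed.
#' @return List with `config` ([sim_config()]) and `patient_profiles`
#'   (tibble: `patient_id`, `recist`, `dcr_group`, `cd`,
#'   `metastasis_site`, `treatment_class`, `tls_present`, and
#'   `mult_<phenotype>` intensity multipliers).
#' @export
preset_um_cohort <- function(seed = 1L) {
  recist <- c(rep("PD", 7), rep("SD", 7), rep("PR", 6), "CR")
  cd <- as.integer(recist != "PD")
  n <- length(recist)
  profiles <- tibble(
    patient_id = sprintf("P%02d", seq_len(n)),
    recist = recist,
    dcr_group = ifelse(cd == 1, "CD", "PD"),
    cd = cd,
    metastasis_site = c(rep("liver", 3), "extra_hepatic", rep("liver", 9),
                        rep("extra_hepatic", 2), rep("liver", 5),
                        "extra_hepatic")[seq_len(n)],
    treatment_class = c(rep("immunotherapy", 4), rep("other", 3),
                        rep("immunotherapy", 9), rep("other", 5))[seq_len(n)],
    tls_present = rep(c(FALSE, TRUE, FALSE), length.out = n),
    mult_CD8 = ifelse(cd == 1, 1.6, 1),
    mult_CD8_GrzB = ifelse(cd == 1, 2.2, 1),
    mult_Treg = ifelse(cd == 1, 0.5, 1.2),
    mult_CD163 = ifelse(cd == 1, 0.7, 1.3),
    mult_CD3 = ifelse(cd == 1, 1.4, 1)
  )
  list(
    config = sim_config(log_hr = c(cd = log(0.5)), seed = seed),
    patient_profiles = profiles
  )
}
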