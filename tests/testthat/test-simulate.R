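test_that("config invariants are enforced", {
  expect_error(sim_config(censoring_rate = 1), "censoring_rate")
  expect_silent(sim_config(censoring_rate = 0.999))
  expect_error(sim_config(baseline_hazard = 0), "baseline_hazard")
  expect_error(sim_config(n_patients = 1), "n_patients")
  expect_error(sim_config(field_width_um = 0), "field_width_um")
  expect_error(
    sim_config(intensities = tibble::tibble(
      panel = "panel2", phenotype = "CD8", tumor = -1, stroma = 0
    )),
    ">= 0"
  )
  expect_error(
    sim_config(proximity = tibble::tibble(
      target = "CD4", anchor = "CD8", attracted_fraction = 1.2,
      placement_radius_um = 20
    )),
    "attracted_fraction"
  )
})

test_that("zero intensity in a compartment places zero cells there", {
  cfg <- sim_config(
    tumor_nest_count = 1,
    intensities = one_pheno_intensities("CD8", tumor = 0, stroma = 300)
  )
  f <- simulate_field(cfg, "panel2", seed = 2)
  expect_equal(sum(f$compartment == "tumor"), 0)
  expect_gt(nrow(f), 0)
})

test_that("realized counts are Poisson around intensity times exact area", {
  # no nests: the stroma is the whole 1000 x 1000 um field, exactly 1 mm^2
  cfg <- sim_config(
    field_width_um = 1000, field_height_um = 1000, tumor_nest_count = 0,
    intensities = one_pheno_intensities("CD8", tumor = 0, stroma = 100)
  )
  counts <- vapply(0:199, function(s) {
    nrow(simulate_field(cfg, "panel2", seed = s))
  }, numeric(1))
  se <- sqrt(100) / sqrt(200)
  expect_lt(abs(mean(counts) - 100), 3 * se)
  # areas recorded exactly from the geometry
  f <- simulate_field(cfg, "panel2", seed = 0)
  expect_equal(field_areas(f), c(tumor = 0, stroma = 1))
})

test_that("clipped or overlapping nests keep density estimation unbiased", {
  cfg <- sim_config(
    tumor_nest_count = 4, tumor_nest_radius_um = 150,
    intensities = one_pheno_intensities("CD8", tumor = 120, stroma = 40)
  )
  dens <- vapply(1:80, function(s) {
    f <- simulate_field(cfg, "panel2", seed = 3000 + s)
    sum(f$compartment == "tumor" & has_phenotype(f, "CD8")) /
      field_areas(f)[["tumor"]]
  }, numeric(1))
  se <- sd(dens) / sqrt(length(dens))
  expect_lt(abs(mean(dens) - 120), 3 * se)
})

test_that("full attraction places every target within the radius of an anchor", {
  cfg <- sim_config(
    tumor_nest_count = 0,
    intensities = one_pheno_intensities(
      c("CD4", "CD8"), tumor = c(0, 0), stroma = c(100, 50)
    ),
    proximity = tibble::tibble(
      target = "CD4", anchor = "CD8", attracted_fraction = 1,
      placement_radius_um = 20
    )
  )
  f <- simulate_field(cfg, "panel2", seed = 6)
  expect_equal(fraction_within_radius(f, "CD4", "CD8", 20), 100)
})

test_that("proximity spec naming an unknown phenotype errors", {
  cfg <- sim_config(
    intensities = one_pheno_intensities("CD8", stroma = 100),
    proximity = tibble::tibble(
      target = "CD4", anchor = "CD8", attracted_fraction = 0.5,
      placement_radius_um = 20
    )
  )
  expect_error(simulate_field(cfg, "panel2", seed = 1),
               "absent from the intensity map")
})

test_that("positive intensity with a zero-area compartment errors", {
  cfg <- sim_config(
    tumor_nest_count = 0, # no tumor compartment at all
    intensities = one_pheno_intensities("CD8", tumor = 50, stroma = 10)
  )
  expect_error(simulate_field(cfg, "panel2", seed = 1), "area is zero")
})

test_that("cohorts are byte-identical for a fixed seed", {
  cfg <- sim_config(n_fields_per_patient = 2, n_patients = 3,
                    tumor_nest_count = 1, seed = 42,
                    log_hr = c(cd = log(0.5)))
  profiles <- tibble::tibble(patient_id = c("P1", "P2", "P3"),
                             cd = c(1, 0, 1))
  c1 <- simulate_cohort(cfg, profiles)
  c2 <- simulate_cohort(cfg, profiles)
  expect_identical(c1$survival, c2$survival)
  for (p in names(c1$samples)) {
    f1 <- c1$samples[[p]]$fields
    f2 <- c2$samples[[p]]$fields
    expect_identical(lapply(f1, as.data.frame), lapply(f2, as.data.frame))
  }
  # ground truth echoes the generating configuration
  expect_identical(c1$truth$log_hr, cfg$log_hr)
  expect_identical(c1$truth$patient_profiles$patient_id, profiles$patient_id)
  # fields are independently reproducible from their derived seeds
  expect_equal(length(c1$samples$P1$fields), 4) # 2 fields x 2 panels
})

test_that("a fixed-seed field regenerates identically in isolation", {
  cfg <- sim_config(tumor_nest_count = 2, seed = 10)
  f1 <- simulate_field(cfg, "panel1", seed = 77)
  f2 <- simulate_field(cfg, "panel1", seed = 77)
  expect_identical(as.data.frame(f1), as.data.frame(f2))
})

test_that("with no covariate effects event times are exponential", {
  features <- tibble::tibble(patient_id = sprintf("P%03d", 1:500))
  h0 <- 0.05
  # three independent n = 500 cohorts: averaging the KM medians keeps the
  # closed-form 10 % check well inside the estimator's sampling noise
  medians <- vapply(101:103, function(s) {
    sv <- simulate_survival(features, baseline_hazard = h0,
                            censoring_rate = 0, followup_months = 1e4,
                            seed = s)
    stopifnot(all(sv$event == 1))
    kaplan_meier(sv)$medians$median
  }, numeric(1))
  expect_lt(abs(mean(medians) - log(2) / h0) / (log(2) / h0), 0.1)
})

test_that("survival generator respects covariates and censoring bounds", {
  features <- tibble::tibble(patient_id = c("a", "b"), x = c(0, 1))
  expect_error(simulate_survival(features, baseline_hazard = -1), "baseline")
  expect_error(simulate_survival(features, 0.1, censoring_rate = 1),
               "censoring_rate")
  expect_error(simulate_survival(features, 0.1, log_hr = c(z = 1)), "z")
  sv <- simulate_survival(features, 0.1, log_hr = c(x = log(0.5)),
                          censoring_rate = 0.3, seed = 1)
  expect_true(all(sv$time > 0 & sv$time <= 120))
})

test_that("the default study preset encodes the cohort structure", {
  pre <- preset_um_cohort(seed = 3)
  pp <- pre$patient_profiles
  expect_equal(nrow(pp), 21)
  expect_equal(sum(pp$dcr_group == "CD"), 14)
  expect_equal(sum(pp$dcr_group == "PD"), 7)
  expect_equal(unname(table(pp$recist)[c("PD", "SD", "PR", "CR")]),
               c(7L, 7L, 6L, 1L), ignore_attr = TRUE)
  expect_equal(sum(pp$metastasis_site == "liver"), 17)
  expect_equal(sum(pp$treatment_class == "immunotherapy"), 13)
  expect_equal(pre$config$n_fields_per_patient, 20)
})
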