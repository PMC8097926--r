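#' Aggregate per-field values to a patient value
#'
#' Patient-level metrics are the unweighted arithmetic mean of the
#' per-field values of the same tissue slide; fields excluded for a
#' metric (encoded as `NA`) are tallied, never silently zeroed.
#'
#' @param values Numeric vector of per-field values; `NA` marks an
#'   excluded field.
#' @return List with `mean` (`NA` when no field is usable), `n_used`,
#'   `n_excluded`.
#' @export
#' @examples
#' patient_aggregate(c(10, NA, 30)) # mean 20, 2 used, 1 excluded
patient_aggregate <- function(values) {
  usable <- values[!is.na(values)]
  list(
    mean = if (length(usable)) mean(usable) else NA_real_,
    n_used = length(usable),
    n_excluded = sum(is.na(values))
  )
}

count_in_compartment <- function(field, phenotype, compartment) {
  sel <- phenotype_selector(field, phenotype)
  if (compartment == "total") sum(sel) else sum(sel & field$compartment == compartment)
}

field_density <- function(field, phenotype, compartment) {
  a <- field_areas(field)
  area <- if (compartment == "total") sum(a) else a[[compartment]]
  if (!is.finite(area) || area <= 0) return(NA_real_)
  count_in_compartment(field, phenotype, compartment) / area
}

fields_defining <- function(sample, phenotype) {
  keep <- vapply(sample$fields, function(f) {
    identical(phenotype, "any_immune") ||
      phenotype %in% field_phenotype_names(f)
  }, logical(1))
  sample$fields[keep]
}

density_record <- function(sample, phenotype, compartment, metric, values,
                           parent = NA_character_) {
  agg <- patient_aggregate(values)
  tibble(
    patient_id = sample$patient_id,
    phenotype = phenotype,
    parent = parent,
    compartment = compartment,
    metric = metric,
    value = agg$mean,
    n_fields_used = agg$n_used,
    n_fields_excluded = agg$n_excluded
  )
}

#' Compartment-specific phenotype density
#'
#' Per-field density is the phenotype's cell count divided by the
#' compartment area (cells/mm^2); the patient value is the unweighted
#' mean over fields. Fields with zero area for the requested compartment
#' are excluded and tallied. `compartment = "total"` uses
#' (tumor + stroma counts) / (tumor + stroma areas) per field — not the
#' mean of the two compartment densities.
#'
#' @param sample A `sample_set` of phenotyped fields.
#' @param phenotype Phenotype label (only fields whose panel defines the
#'   label contribute).
#' @param compartment `"tumor"`, `"stroma"` or `"total"`.
#' @return One-row tibble: `patient_id`, `phenotype`, `compartment`,
#'   `metric = "density"`, `value` (cells/mm^2; `NA` if every field was
#'   excluded), `n_fields_used`, `n_fields_excluded`.
#' @export
compartment_density <- function(sample, phenotype,
                                compartment = c("tumor", "stroma", "total")) {
  compartment <- arg_match(compartment)
  fields <- fields_defining(sample, phenotype)
  vals <- vapply(fields, field_density, numeric(1),
                 phenotype = phenotype, compartment = compartment)
  density_record(sample, phenotype, compartment, "density", vals)
}

field_percentage <- function(field, phenotype, parent, compartment) {
  sel_child <- phenotype_selector(field, phenotype)
  sel_parent <- phenotype_selector(field, parent)
  if (compartment != "total") {
    in_comp <- field$compartment == compartment
    sel_child <- sel_child & in_comp
    sel_parent <- sel_parent & in_comp
  }
  n_parent <- sum(sel_parent)
  if (n_parent == 0L) return(NA_real_)
  100 * sum(sel_child & sel_parent) / n_parent
}

#' Percentage of a phenotype within a parent population
#'
#' Per-field percentage is `100 * count(phenotype & parent) /
#' count(parent)` in the compartment; fields with zero parent cells are
#' excluded; the patient value is the mean over included fields. The
#' parent defaults to `"any_immune"`, i.e. all phenotyped non-tumor cells
#' of the panel in the compartment.
#'
#' @inheritParams compartment_density
#' @param parent Parent phenotype label, or `"any_immune"`.
#' @return One-row tibble as in [compartment_density()] with
#'   `metric = "percentage"` and `value` in percent.
#' @export
phenotype_percentage <- function(sample, phenotype, parent = "any_immune",
                                 compartment = c("tumor", "stroma", "total")) {
  compartment <- arg_match(compartment)
  fields <- fields_defining(sample, phenotype)
  vals <- vapply(fields, field_percentage, numeric(1),
                 phenotype = phenotype, parent = parent,
                 compartment = compartment)
  density_record(sample, phenotype, compartment, "percentage", vals,
                 parent = parent)
}
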