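# Pairwise Euclidean distances between two point sets (matrix n_ref x n_tgt).
# Entries where reference and target are the same cell are set to Inf
# (a cell is never its own neighbor).
ref_target_distances <- function(field, ref_idx, tgt_idx) {
  dx <- outer(field$x_um[ref_idx], field$x_um[tgt_idx], "-")
  dy <- outer(field$y_um[ref_idx], field$y_um[tgt_idx], "-")
  d <- sqrt(dx * dx + dy * dy)
  same <- outer(ref_idx, tgt_idx, "==")
  d[same] <- Inf
  d
}

#' Mean nearest-neighbor distance between two phenotypes
#'
#' For every reference-phenotype cell of a field, the Euclidean
#' (center-to-center, 2-D) distance to the nearest target-phenotype cell
#' in the same field; returns the mean over reference cells, in
#' micrometres. When reference and target phenotypes overlap a cell is
#' never its own neighbor. Fields without reference cells, or without any
#' target cell after self-exclusion, are excluded for this metric
#' (returned as `NA`), not an error: exclusion is resolved per field at
#' patient aggregation. No edge-effect correction is applied.
#'
#' @param field A phenotyped [field_tbl()].
#' @param reference,target Phenotype labels.
#' @return Mean distance in micrometres, or `NA` if the field is excluded.
#' @export
nearest_neighbor_mean_distance <- function(field, reference, target) {
  ref_idx <- which(phenotype_selector(field, reference))
  tgt_idx <- which(phenotype_selector(field, target))
  if (length(ref_idx) == 0L || length(tgt_idx) == 0L) return(NA_real_)
  d <- ref_target_distances(field, ref_idx, tgt_idx)
  nearest <- apply(d, 1L, min)
  nearest <- nearest[is.finite(nearest)] # refs whose only target was themselves
  if (length(nearest) == 0L) return(NA_real_)
  mean(nearest)
}

#' Fraction of reference cells within a radius of a target phenotype
#'
#' Percentage of reference-phenotype cells having at least one
#' target-phenotype cell at center-to-center distance less than or equal
#' to `radius_um` (the boundary counts as within), among all reference
#' cells of the field. Absence of target cells is a valid 0%, not an
#' exclusion; only fields without reference cells are excluded (`NA`).
#'
#' @inheritParams nearest_neighbor_mean_distance
#' @param radius_um Radius in micrometres (> 0); study presets use
#'   20, 25 and 30 um, the range indicative of direct cell-to-cell
#'   contact.
#' @return Percentage in `[0, 100]`, or `NA` if the field is excluded.
#' @export
fraction_within_radius <- function(field, reference, target, radius_um) {
  check_number(radius_um, "radius_um", min = 0, allow_min = FALSE)
  ref_idx <- which(phenotype_selector(field, reference))
  if (length(ref_idx) == 0L) return(NA_real_)
  tgt_idx <- which(phenotype_selector(field, target))
  if (length(tgt_idx) == 0L) return(0)
  d <- ref_target_distances(field, ref_idx, tgt_idx)
  within <- apply(d <= radius_um, 1L, any)
  100 * sum(within) / length(ref_idx)
}

#' Aggregate a spatial metric over a patient's fields
#'
#' Computes a proximity statistic per field and averages it (unweighted)
#' over the fields whose panel defines both phenotypes; per-field
#' exclusions are tallied.
#'
#' @param sample A `sample_set` of phenotyped fields.
#' @param metric `"nn_mean_distance"` or `"fraction_within"`.
#' @param reference,target Phenotype labels.
#' @param radius_um Radius in micrometres (required for
#'   `"fraction_within"`).
#' @return One-row tibble: `patient_id`, `metric`, `reference`, `target`,
#'   `radius_um`, `value` (`NA` with all fields excluded),
#'   `n_reference_cells`, `n_fields_used`, `n_fields_excluded`, and a
#'   `per_field_values` list-column.
#' @export
aggregate_spatial_metric <- function(sample,
                                     metric = c("nn_mean_distance",
                                                "fraction_within"),
                                     reference, target, radius_um = NULL) {
  metric <- arg_match(metric)
  fields <- Filter(function(f) {
    defs <- field_phenotype_names(f)
    all(vapply(c(reference, target), function(p) {
      identical(p, "any_immune") || p %in% defs
    }, logical(1)))
  }, sample$fields)
  vals <- vapply(fields, function(f) {
    if (metric == "nn_mean_distance") {
      nearest_neighbor_mean_distance(f, reference, target)
    } else {
      fraction_within_radius(f, reference, target, radius_um)
    }
  }, numeric(1))
  n_ref <- sum(vapply(fields, function(f) sum(phenotype_selector(f, reference)),
                      numeric(1)))
  agg <- patient_aggregate(vals)
  tibble(
    patient_id = sample$patient_id,
    metric = metric,
    reference = reference,
    target = target,
    radius_um = radius_um %||% NA_real_,
    value = agg$mean,
    n_reference_cells = n_ref,
    n_fields_used = agg$n_used,
    n_fields_excluded = agg$n_excluded,
    per_field_values = list(vals)
  )
}
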