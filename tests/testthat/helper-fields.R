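# Build a minimal phenotyped field directly (no simulator, no markers):
# cells at given coordinates with explicit phenotype label sets.
toy_field <- function(x, y, labels, compartment = "stroma",
                      areas = c(tumor = 0.5, stroma = 0.5),
                      phenotype_names = c("A", "B", "C", "tumor"),
                      field_id = "F1", sample_id = "S1",
                      panel_id = "panel2") {
  stopifnot(length(x) == length(y), length(labels) == length(x))
  cells <- tibble::tibble(
    cell_id = seq_along(x), x_um = x, y_um = y,
    compartment = rep_len(compartment, length(x))
  )
  f <- contexture::field_tbl(cells, field_id, sample_id, panel_id,
                             areas, markers = character(0))
  f$phenotypes <- labels
  attr(f, "phenotype_names") <- phenotype_names
  f
}

toy_sample <- function(fields, patient_id = "P1") {
  contexture::assemble_sample(fields, clinical = list(patient_id = patient_id))
}

# Random field for property tests: n cells uniform in a 600 x 500 um
# field, labels drawn from {A, B, tumor} with occasional multi-label
# cells (exercises self-exclusion when reference and target overlap).
random_field <- function(n, seed) {
  set.seed(seed)
  labels <- lapply(seq_len(n), function(i) {
    r <- runif(1)
    if (r < 0.35) "A"
    else if (r < 0.65) "B"
    else if (r < 0.8) c("A", "B")
    else "tumor"
  })
  toy_field(runif(n, 0, 600), runif(n, 0, 500), labels)
}

# --- independent brute-force oracles (per-cell loops) ----------------------

oracle_labels_have <- function(field, i, what) what %in% field$phenotypes[[i]]

oracle_nn <- function(field, reference, target) {
  n <- nrow(field)
  refs <- which(vapply(seq_len(n), oracle_labels_have, logical(1),
                       field = field, what = reference))
  tgts <- which(vapply(seq_len(n), oracle_labels_have, logical(1),
                       field = field, what = target))
  if (length(refs) == 0L || length(tgts) == 0L) return(NA_real_)
  mins <- numeric(0)
  for (i in refs) {
    best <- Inf
    for (j in tgts) {
      if (i == j) next
      d <- sqrt((field$x_um[i] - field$x_um[j])^2 +
                  (field$y_um[i] - field$y_um[j])^2)
      if (d < best) best <- d
    }
    if (is.finite(best)) mins <- c(mins, best)
  }
  if (length(mins) == 0L) NA_real_ else mean(mins)
}

oracle_fwr <- function(field, reference, target, radius) {
  n <- nrow(field)
  refs <- which(vapply(seq_len(n), oracle_labels_have, logical(1),
                       field = field, what = reference))
  if (length(refs) == 0L) return(NA_real_)
  tgts <- which(vapply(seq_len(n), oracle_labels_have, logical(1),
                       field = field, what = target))
  hit <- 0L
  for (i in refs) {
    found <- FALSE
    for (j in tgts) {
      if (i == j) next
      d <- sqrt((field$x_um[i] - field$x_um[j])^2 +
                  (field$y_um[i] - field$y_um[j])^2)
      if (d <= radius) {
        found <- TRUE
        break
      }
    }
    if (found) hit <- hit + 1L
  }
  100 * hit / length(refs)
}

# Single-phenotype intensity table for simulator tests.
one_pheno_intensities <- function(phenotype = "CD8", tumor = 0, stroma = 0,
                                  panel = "panel2", extra = NULL) {
  tb <- tibble::tibble(panel = panel, phenotype = phenotype,
                       tumor = tumor, stroma = stroma)
  if (!is.null(extra)) tb <- dplyr::bind_rows(tb, extra)
  tb
}
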