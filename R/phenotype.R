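#' Assign phenotype labels from marker combinations
#'
#' Applies a panel's [phenotype_rule()]s to every cell of a field and
#' stores the matching labels in a `phenotypes` list-column. Phenotyping
#' is multi-label: a cell carries every rule it satisfies (a CD8+
#' Granzyme B+ cell is both `"CD8"` and `"CD8_GrzB"`). Cells positive for
#' the panel's tumor pseudo-marker (the anti-melanoma cocktail) are
#' labelled `"tumor"` only and never receive immune labels, treating
#' double-positives as tumor cells.
#'
#' @param field A [field_tbl()] whose `panel_id` matches `panel`.
#' @param panel A [panel_definition()].
#' @return The field with a `phenotypes` list-column and a
#'   `phenotype_names` attribute listing the labels the panel can assign.
#' @export
assign_phenotypes <- function(field, panel) {
  stopifnot(inherits(field, "field_tbl"), inherits(panel, "panel_definition"))
  fp <- field_panel(field)
  if (!is.na(fp) && fp != panel$panel_id) {
    ctx_abort(sprintf("field is %s but panel definition is %s.",
                      fp, panel$panel_id))
  }
  needed <- unique(c(panel$tumor_marker,
                     unlist(lapply(panel$rules, function(r) c(r$positive, r$negative)))))
  missing <- setdiff(needed, names(field))
  if (length(missing)) {
    ctx_abort(paste0("panel rules reference marker(s) absent from the field: ",
                     paste(missing, collapse = ", ")))
  }
  n <- nrow(field)
  labels <- vector("list", n)
  if (n > 0) {
    is_tumor <- as.logical(field[[panel$tumor_marker]])
    hit <- matrix(FALSE, nrow = n, ncol = length(panel$rules))
    for (j in seq_along(panel$rules)) {
      r <- panel$rules[[j]]
      ok <- rep(TRUE, n)
      for (m in r$positive) ok <- ok & as.logical(field[[m]])
      for (m in r$negative) ok <- ok & !as.logical(field[[m]])
      hit[, j] <- ok & !is_tumor
    }
    rule_names <- vapply(panel$rules, `[[`, character(1), "name")
    for (i in seq_len(n)) {
      labels[[i]] <- if (is_tumor[i]) "tumor" else rule_names[hit[i, ]]
    }
  }
  out <- field
  out$phenotypes <- labels
  attr(out, "phenotype_names") <- panel$phenotype_names
  out
}

#' Which cells carry a phenotype label?
#'
#' @param field A phenotyped [field_tbl()].
#' @param phenotype Label to look up.
#' @return Logical vector over cells.
#' @export
has_phenotype <- function(field, phenotype) {
  if (is.null(field$phenotypes)) {
    ctx_abort("field has no phenotype labels; run assign_phenotypes() first.")
  }
  if (nrow(field) == 0L) return(logical(0))
  vapply(field$phenotypes, function(p) phenotype %in% p, logical(1))
}

# Labels a field's panel can assign (set by assign_phenotypes).
field_phenotype_names <- function(field) {
  attr(field, "phenotype_names") %||% character()
}

# Logical selector for a phenotype spec: a label, or "any_immune" for all
# phenotyped non-tumor cells of the panel.
phenotype_selector <- function(field, phenotype) {
  if (identical(phenotype, "any_immune")) {
    if (nrow(field) == 0L) return(logical(0))
    vapply(field$phenotypes,
           function(p) length(setdiff(p, "tumor")) > 0, logical(1))
  } else {
    has_phenotype(field, phenotype)
  }
}
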