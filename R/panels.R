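#' Define a marker-combination phenotype rule
#'
#' A phenotype is defined by the set of markers a cell must stain positive
#' for and, optionally, markers it must be negative for. A cell may satisfy
#' several rules and then carries every matching label (multi-label
#' phenotyping), e.g. a CD8+ Granzyme B+ cell is both `"CD8"` and
#' `"CD8_GrzB"`.
#'
#' @param name Phenotype label, e.g. `"Treg"`.
#' @param positive Character vector of markers that must be positive
#'   (non-empty).
#' @param negative Character vector of markers that must be negative
#'   (default none). Must be disjoint from `positive`.
#' @return A `phenotype_rule` list.
#' @export
#' @examples
#' phenotype_rule("Treg", c("CD4", "FoxP3"))
phenotype_rule <- function(name, positive, negative = character()) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    ctx_abort("`name` must be a non-empty string.")
  }
  if (!is.character(positive) || length(positive) < 1L) {
    ctx_abort("`positive` must name at least one marker.")
  }
  if (length(intersect(positive, negative)) > 0L) {
    ctx_abort("`positive` and `negative` marker sets must be disjoint.")
  }
  structure(
    list(name = name, positive = positive, negative = negative),
    class = "phenotype_rule"
  )
}

#' @export
print.phenotype_rule <- function(x, ...) {
  neg <- if (length(x$negative)) {
    paste0(" ", paste0(x$negative, "-", collapse = " "))
  } else ""
  cat(sprintf("<phenotype_rule> %s: %s%s\n",
              x$name, paste0(x$positive, "+", collapse = " "), neg))
  invisible(x)
}

#' Define a staining panel
#'
#' Bundles the marker list of one mIHC panel with its ordered phenotype
#' rules and the name of the tumor pseudo-marker (the anti-melanoma
#' antibody cocktail, recorded per cell like any other marker). Cells
#' positive for the tumor marker are labelled `"tumor"` and receive no
#' immune phenotype labels.
#'
#' @param panel_id Panel identifier, e.g. `"panel1"`.
#' @param markers Character vector of all marker names scored on the panel
#'   (including the tumor pseudo-marker).
#' @param rules List of [phenotype_rule()] objects; every rule's markers
#'   must be a subset of `markers`.
#' @param tumor_marker Name of the tumor pseudo-marker column
#'   (default `"melanoma"`).
#' @return A `panel_definition` list.
#' @export
panel_definition <- function(panel_id, markers, rules,
                             tumor_marker = "melanoma") {
  if (!tumor_marker %in% markers) {
    ctx_abort(sprintf("tumor marker '%s' is not in `markers`.", tumor_marker))
  }
  for (r in rules) {
    if (!inherits(r, "phenotype_rule")) {
      ctx_abort("`rules` must be a list of phenotype_rule objects.")
    }
    missing <- setdiff(c(r$positive, r$negative), markers)
    if (length(missing)) {
      ctx_abort(sprintf(
        "rule '%s' references markers absent from the panel: %s",
        r$name, paste(missing, collapse = ", ")
      ))
    }
  }
  structure(
    list(
      panel_id = panel_id,
      markers = markers,
      rules = rules,
      tumor_marker = tumor_marker,
      phenotype_names = c(vapply(rules, `[[`, character(1), "name"), "tumor")
    ),
    class = "panel_definition"
  )
}

#' @export
print.panel_definition <- function(x, ...) {
  cat(sprintf("<panel_definition> %s\n  markers: %s\n  phenotypes: %s\n",
              x$panel_id, paste(x$markers, collapse = ", "),
              paste(x$phenotype_names, collapse = ", ")))
  invisible(x)
}

#' Default mIHC panel definitions
#'
#' Two panels mirroring a standard immune-contexture study design for
#' melanoma metastases. Panel 1 captures the main immune lineages
#' (CD20 B cells, CD3 T cells, CD68 macrophages, CD56 NK cells, NE
#' neutrophils); panel 2 captures T-cell functional state (CD4 helpers,
#' CD8 cytotoxic T lymphocytes, Granzyme B activation, FoxP3 regulatory
#' T cells, CD163 M2-polarized macrophages). Both carry the anti-melanoma
#' cocktail as the `melanoma` pseudo-marker that outlines tumor cells.
#'
#' Composite phenotypes on panel 2: `Treg` = CD4+FoxP3+, `CD8_GrzB` =
#' CD8+GranzymeB+ (activated CTL), `CD4_GrzB` = CD4+GranzymeB+.
#'
#' @return Named list of two [panel_definition()] objects
#'   (`panel1`, `panel2`).
#' @export
default_panels <- function() {
  p1 <- panel_definition(
    "panel1",
    markers = c("melanoma", "CD20", "CD3", "CD68", "CD56", "NE"),
    rules = list(
      phenotype_rule("CD20", "CD20"),
      phenotype_rule("CD3", "CD3"),
      phenotype_rule("CD68", "CD68"),
      phenotype_rule("CD56", "CD56"),
      phenotype_rule("NE", "NE")
    )
  )
  p2 <- panel_definition(
    "panel2",
    markers = c("melanoma", "CD4", "CD8", "GranzymeB", "FoxP3", "CD163"),
    rules = list(
      phenotype_rule("CD4", "CD4"),
      phenotype_rule("CD8", "CD8"),
      phenotype_rule("Treg", c("CD4", "FoxP3")),
      phenotype_rule("CD4_GrzB", c("CD4", "GranzymeB")),
      phenotype_rule("CD8_GrzB", c("CD8", "GranzymeB")),
      phenotype_rule("CD163", "CD163")
    )
  )
  list(panel1 = p1, panel2 = p2)
}

# Marker combinations realized by each simulated phenotype, per panel.
# Used by the simulator to emit marker-positivity columns.
simulated_marker_map <- function(panel_id) {
  switch(panel_id,
    panel1 = list(
      tumor = "melanoma", CD20 = "CD20", CD3 = "CD3",
      CD68 = "CD68", CD56 = "CD56", NE = "NE"
    ),
    panel2 = list(
      tumor = "melanoma", CD4 = "CD4", CD8 = "CD8",
      Treg = c("CD4", "FoxP3"),
      CD4_GrzB = c("CD4", "GranzymeB"),
      CD8_GrzB = c("CD8", "GranzymeB"),
      CD163 = "CD163"
    ),
    ctx_abort(sprintf("unknown panel_id '%s'", panel_id))
  )
}
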