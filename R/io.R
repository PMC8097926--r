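#' Construct a per-field cell table
#'
#' A `field_tbl` is a tibble with one row per segmented cell plus field
#' metadata stored in attributes. Columns: `cell_id`, `x_um`, `y_um`
#' (positions in micrometres from the field's top-left corner, y
#' increasing downward), `compartment` (`"tumor"` or `"stroma"`), one
#' logical column per marker, and after [assign_phenotypes()] a
#' `phenotypes` list-column of character labels.
#'
#' @param cells Tibble/data frame of cells (may have zero rows).
#' @param field_id,sample_id Identifiers.
#' @param panel_id `"panel1"` or `"panel2"`.
#' @param areas Named numeric `c(tumor = , stroma = )`, compartment areas
#'   in mm^2; both must be >= 0 and at least one > 0.
#' @param markers Character vector naming the logical marker columns.
#' @return A `field_tbl`.
#' @export
field_tbl <- function(cells, field_id, sample_id, panel_id, areas, markers) {
  cells <- as_tibble(cells)
  if (!all(c("tumor", "stroma") %in% names(areas))) {
    ctx_abort("`areas` must be named with 'tumor' and 'stroma'.")
  }
  areas <- c(tumor = unname(areas[["tumor"]]), stroma = unname(areas[["stroma"]]))
  if (any(!is.finite(areas)) || any(areas < 0)) {
    ctx_abort("compartment areas must be finite and >= 0.")
  }
  if (sum(areas) <= 0) {
    ctx_abort("at least one compartment area must be > 0.")
  }
  if (nrow(cells) > 0) {
    req <- c("cell_id", "x_um", "y_um", "compartment")
    missing <- setdiff(req, names(cells))
    if (length(missing)) {
      ctx_abort(paste0("cell table lacks required column(s): ",
                       paste(missing, collapse = ", ")))
    }
    if (anyDuplicated(cells$cell_id)) {
      ctx_abort("duplicate cell_id within one field.",
                class = "contexture_schema_error")
    }
    if (any(!is.finite(cells$x_um)) || any(!is.finite(cells$y_um)) ||
        any(cells$x_um < 0) || any(cells$y_um < 0)) {
      ctx_abort("cell coordinates must be finite and >= 0.")
    }
    bad <- !cells$compartment %in% c("tumor", "stroma")
    if (any(bad)) {
      ctx_abort(sprintf(
        "unknown tissue category '%s'; allowed values: tumor, stroma.",
        cells$compartment[which(bad)[1]]
      ))
    }
    if (any(areas[unique(cells$compartment)] <= 0)) {
      ctx_abort("cells present in a compartment with zero recorded area.")
    }
    missing_mk <- setdiff(markers, names(cells))
    if (length(missing_mk)) {
      ctx_abort(paste0("cell table lacks marker column(s): ",
                       paste(missing_mk, collapse = ", ")))
    }
  }
  structure(
    cells,
    field_id = field_id,
    sample_id = sample_id,
    panel_id = panel_id,
    areas = areas,
    markers = markers,
    class = c("field_tbl", class(cells))
  )
}

#' Field metadata accessors
#' @param field A [field_tbl()].
#' @return `field_areas()`: named numeric (mm^2); the others: scalars.
#' @export
field_areas <- function(field) attr(field, "areas")

#' @rdname field_areas
#' @export
field_panel <- function(field) attr(field, "panel_id")

#' @rdname field_areas
#' @export
field_markers <- function(field) attr(field, "markers")

#' @export
print.field_tbl <- function(x, ...) {
  a <- field_areas(x)
  cat(sprintf(
    "<field_tbl> field '%s' (sample '%s', %s): %d cells; areas tumor %.4f / stroma %.4f mm^2\n",
    attr(x, "field_id"), attr(x, "sample_id"), attr(x, "panel_id"),
    nrow(x), a[["tumor"]], a[["stroma"]]
  ))
  NextMethod()
}

#' Describe the columns of an external cell-segmentation export
#'
#' Maps the logical columns the pipeline needs onto the header strings of
#' a source file (e.g. an inForm-style cell-seg export) and states the
#' unit of the coordinate columns.
#'
#' @param cell_id,x,y,tissue Source header names for the cell identifier,
#'   x/y position and tissue-category columns.
#' @param markers Named character vector mapping marker name -> source
#'   header, e.g. `c(CD8 = "Phenotype CD8")`. Must be non-empty.
#' @param unit `"um"` or `"pixel"`; pixel coordinates are converted with
#'   the `scale` argument of [read_cell_table()].
#' @return A `column_mapping` list.
#' @export
#' @examples
#' column_mapping(
#'   cell_id = "Cell ID", x = "Cell X Position", y = "Cell Y Position",
#'   tissue = "Tissue Category", markers = c(CD8 = "CD8", CD4 = "CD4")
#' )
column_mapping <- function(cell_id = "cell_id", x = "x_um", y = "y_um",
                           tissue = "tissue_category", markers,
                           unit = c("um", "pixel")) {
  unit <- arg_match(unit)
  if (missing(markers) || length(markers) == 0L) {
    ctx_abort("`markers` must map at least one marker column.")
  }
  if (is.null(names(markers)) || any(!nzchar(names(markers)))) {
    ctx_abort("`markers` must be a named character vector (name -> source header).")
  }
  structure(
    list(cell_id = cell_id, x = x, y = y, tissue = tissue,
         markers = markers, unit = unit),
    class = "column_mapping"
  )
}

parse_marker_values <- function(x, column) {
  v <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(v))
  out[v %in% c("true", "t", "1", "pos", "positive", "+", "yes")] <- TRUE
  out[v %in% c("false", "f", "0", "neg", "negative", "-", "no", "")] <- FALSE
  if (anyNA(out)) {
    ctx_abort(sprintf(
      "column '%s': cannot parse value '%s' as marker positivity.",
      column, x[which(is.na(out))[1]]
    ), class = "contexture_parse_error")
  }
  as.logical(out)
}

parse_coord <- function(x, column) {
  out <- suppressWarnings(readr::parse_double(as.character(x)))
  bad <- which(is.na(out) & !is.na(x))
  if (length(bad)) {
    ctx_abort(sprintf(
      "column '%s', row %d: cannot parse coordinate '%s' (decimal point required).",
      column, bad[1], as.character(x)[bad[1]]
    ), class = "contexture_parse_error")
  }
  out
}

read_header_meta <- function(path) {
  meta <- list()
  con <- file(path, "r")
  on.exit(close(con))
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L || !startsWith(line, "#")) break
    m <- regmatches(line, regexec("^#\\s*([A-Za-z0-9_]+)\\s*:\\s*(.*)\\s*$", line))[[1]]
    if (length(m) == 3L) meta[[m[2]]] <- m[3]
  }
  meta
}

#' Read a per-cell segmentation table
#'
#' Reads a CSV (or TSV) table with one row per cell into a [field_tbl()].
#' Files written by [write_cell_table()] carry field metadata (ids, panel,
#' compartment areas) in leading `#` comment lines and need no further
#' arguments; external exports supply a [column_mapping()] plus the
#' compartment areas (the upstream tissue segmentation is the source of
#' truth for areas). The reader is locale-independent: decimal points
#' only, comma-decimal numbers are rejected rather than misparsed.
#'
#' @param path File path.
#' @param mapping A [column_mapping()]; `NULL` (default) uses the native
#'   dialect written by [write_cell_table()], discovering marker columns
#'   from the header.
#' @param scale Micrometres per pixel, used only when the mapping declares
#'   pixel coordinates.
#' @param areas Named numeric `c(tumor = , stroma = )` in mm^2; required
#'   unless present in the file's comment header.
#' @param field_id,sample_id,panel_id Metadata overrides; required for
#'   external files lacking a comment header.
#' @param delim Field delimiter, `","` (default) or `"\t"`.
#' @return A [field_tbl()].
#' @export
read_cell_table <- function(path, mapping = NULL, scale = 1, areas = NULL,
                            field_id = NULL, sample_id = NULL,
                            panel_id = NULL, delim = ",") {
  if (!file.exists(path)) {
    ctx_abort(sprintf("file not found: %s", path))
  }
  meta <- read_header_meta(path)
  raw <- readr::read_delim(
    path, delim = delim, comment = "#",
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE,
    locale = readr::locale(decimal_mark = ".")
  )
  if (is.null(mapping)) {
    known <- c("cell_id", "x_um", "y_um", "tissue_category")
    mk <- setdiff(names(raw), known)
    mapping <- structure(
      list(cell_id = "cell_id", x = "x_um", y = "y_um",
           tissue = "tissue_category", markers = setNames(mk, mk),
           unit = "um"),
      class = "column_mapping"
    )
  }
  src_cols <- c(mapping$cell_id, mapping$x, mapping$y, mapping$tissue,
                unname(mapping$markers))
  missing <- setdiff(src_cols, names(raw))
  if (length(missing)) {
    ctx_abort(paste0("input lacks mapped column(s): ",
                     paste(missing, collapse = ", ")),
              class = "contexture_schema_error")
  }
  x <- parse_coord(raw[[mapping$x]], mapping$x)
  y <- parse_coord(raw[[mapping$y]], mapping$y)
  if (mapping$unit == "pixel") {
    check_number(scale, "scale", min = 0, allow_min = FALSE)
    x <- x * scale
    y <- y * scale
  }
  comp <- tolower(trimws(raw[[mapping$tissue]]))
  bad <- setdiff(unique(comp), c("tumor", "stroma"))
  if (length(bad)) {
    ctx_abort(sprintf(
      "unknown tissue category '%s'; allowed values: tumor, stroma.", bad[1]
    ), class = "contexture_schema_error")
  }
  cells <- tibble(
    cell_id = raw[[mapping$cell_id]],
    x_um = x, y_um = y, compartment = comp
  )
  for (mk in names(mapping$markers)) {
    cells[[mk]] <- parse_marker_values(raw[[mapping$markers[[mk]]]],
                                       mapping$markers[[mk]])
  }
  if (is.null(areas)) {
    if (!is.null(meta$tumor_mm2) && !is.null(meta$stroma_mm2)) {
      areas <- c(tumor = as.numeric(meta$tumor_mm2),
                 stroma = as.numeric(meta$stroma_mm2))
    } else {
      ctx_abort("compartment `areas` must be supplied (no area metadata in file).")
    }
  }
  field_tbl(
    cells,
    field_id = field_id %||% meta$field_id %||% basename(path),
    sample_id = sample_id %||% meta$sample_id %||% NA_character_,
    panel_id = panel_id %||% meta$panel_id %||% NA_character_,
    areas = areas,
    markers = names(mapping$markers)
  )
}

#' Write a per-cell table to CSV
#'
#' Writes the cells of a [field_tbl()] as UTF-8 comma-separated text with
#' field metadata (ids, panel, compartment areas at full precision) in
#' leading `#` comment lines. Coordinates are written with 6 decimals;
#' [read_cell_table()] round-trips all cells and areas. Derived
#' `phenotypes` labels are not serialized (re-derive with
#' [assign_phenotypes()]).
#'
#' @param field A [field_tbl()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(field, path) {
  stopifnot(inherits(field, "field_tbl"))
  a <- field_areas(field)
  header <- c(
    "# contexture cell table v1",
    sprintf("# field_id: %s", attr(field, "field_id")),
    sprintf("# sample_id: %s", attr(field, "sample_id")),
    sprintf("# panel_id: %s", attr(field, "panel_id")),
    sprintf("# tumor_mm2: %s", format(a[["tumor"]], digits = 17)),
    sprintf("# stroma_mm2: %s", format(a[["stroma"]], digits = 17))
  )
  mk <- field_markers(field)
  cols <- c("cell_id", "x_um", "y_um", "tissue_category", mk)
  if (nrow(field) > 0) {
    body <- tibble(
      cell_id = as.character(field$cell_id),
      x_um = sprintf("%.6f", field$x_um),
      y_um = sprintf("%.6f", field$y_um),
      tissue_category = field$compartment
    )
    for (m in mk) body[[m]] <- as.character(field[[m]])
    lines <- c(paste(cols, collapse = ","),
               do.call(paste, c(as.list(body), sep = ",")))
  } else {
    lines <- paste(cols, collapse = ",")
  }
  tryCatch(
    writeLines(c(header, lines), path, useBytes = TRUE),
    error = function(e) ctx_abort(sprintf("cannot write '%s': %s",
                                          path, conditionMessage(e)))
  )
  invisible(path)
}

#' Assemble the fields of one patient sample
#'
#' Collects all imaged fields of one tissue sample (possibly spanning both
#' staining panels; panels come from consecutive sections and are never
#' merged cell-wise) together with the patient's clinical record.
#'
#' @param fields List of [field_tbl()]; all must share one `sample_id`.
#' @param clinical Named list or one-row data frame of patient metadata;
#'   recognized entries include `patient_id`, `metastasis_site`
#'   (`"liver"` or `"extra_hepatic"`), `recist`, `os_months`, `event`,
#'   `treatment_class`, `tls_present`.
#' @return A `sample_set`.
#' @export
assemble_sample <- function(fields, clinical = list()) {
  if (length(fields) == 0L) {
    ctx_abort("a sample needs at least one field.")
  }
  sids <- unique(vapply(fields, function(f) as.character(attr(f, "sample_id")),
                        character(1)))
  if (length(sids) != 1L) {
    ctx_abort(sprintf("fields mix sample_ids: %s", paste(sids, collapse = ", ")))
  }
  if (is.data.frame(clinical)) clinical <- as.list(clinical[1, , drop = FALSE])
  site <- clinical$metastasis_site
  if (!is.null(site) && !site %in% c("liver", "extra_hepatic")) {
    ctx_abort("metastasis_site must be 'liver' or 'extra_hepatic'.")
  }
  structure(
    list(
      sample_id = sids,
      patient_id = clinical$patient_id %||% sids,
      metastasis_site = site,
      clinical = clinical,
      fields = fields
    ),
    class = "sample_set"
  )
}

#' @export
print.sample_set <- function(x, ...) {
  panels <- table(vapply(x$fields, field_panel, character(1)))
  cat(sprintf(
    "<sample_set> sample '%s' (patient '%s'%s): %d fields [%s]\n",
    x$sample_id, x$patient_id,
    if (!is.null(x$metastasis_site)) paste0(", ", x$metastasis_site) else "",
    length(x$fields),
    paste(sprintf("%s: %d", names(panels), as.integer(panels)), collapse = ", ")
  ))
  invisible(x)
}

#' Read a per-field compartment-area sidecar table
#'
#' @param path CSV/TSV with columns `field_id`, `tumor_mm2`, `stroma_mm2`.
#' @param delim Delimiter (default comma).
#' @return Tibble.
#' @export
read_area_table <- function(path, delim = ",") {
  tb <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE)
  missing <- setdiff(c("field_id", "tumor_mm2", "stroma_mm2"), names(tb))
  if (length(missing)) {
    ctx_abort(paste0("area table lacks column(s): ",
                     paste(missing, collapse = ", ")),
              class = "contexture_schema_error")
  }
  tb
}

#' Read a clinical/outcome table
#'
#' @param path CSV/TSV with at least `patient_id`; typical columns:
#'   `metastasis_site`, `recist`, `os_months`, `event`, `treatment_class`,
#'   `tls_present`.
#' @param delim Delimiter (default comma).
#' @return Tibble.
#' @export
read_clinical_table <- function(path, delim = ",") {
  tb <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE)
  if (!"patient_id" %in% names(tb)) {
    ctx_abort("clinical table lacks column 'patient_id'.",
              class = "contexture_schema_error")
  }
  tb
}
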