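#' Marker-name alias map
#'
#' Segmentation exports spell marker names inconsistently (Greek letters,
#' capitalisation). Readers map any alias on the left to the canonical name
#' on the right before validation, so that "CD3ε" and "CD3e" refer to
#' the same channel. Marker names are otherwise case-sensitive exact strings.
#'
#' @param extra named character vector of additional aliases
#'   (`c(alias = canonical)`), merged over the defaults.
#' @return named character vector mapping alias to canonical marker name.
#' @export
marker_aliases <- function(extra = NULL) {
  al <- c(
    "CD3ε" = "CD3e", "CD3E" = "CD3e",
    "CD8α" = "CD8a", "CD8A" = "CD8a",
    "FOXP3" = "FoxP3", "FoxP3+" = "FoxP3",
    "PANCK" = "PanCK", "panCK" = "PanCK"
  )
  if (!is.null(extra)) al[names(extra)] <- extra
  al
}

canonical_marker <- function(x, aliases = marker_aliases()) {
  hit <- match(x, names(aliases))
  ifelse(is.na(hit), x, unname(aliases[hit]))
}

# Column names the qupath-like dialect uses for the id/coordinate fields.
.qupath_cols <- c(
  cell_id = "Object ID",
  section_id = "Image",
  x_um = "Centroid X µm",
  y_um = "Centroid Y µm"
)

.sniff_sep <- function(path) {
  l1 <- readLines(path, n = 1L, warn = FALSE)
  if (length(l1) && !grepl(",", l1, fixed = TRUE) && grepl("\t", l1, fixed = TRUE)) "\t" else ","
}

#' Read a per-cell feature table
#'
#' One row per segmented cell: an opaque cell id, the section it came from,
#' centroid coordinates in microns (continuous, arbitrary origin) and the
#' mean fluorescence intensity per marker channel (arbitrary units, >= 0).
#'
#' Two header dialects are supported. `"generic"` expects columns
#' `cell_id, section_id, x_um, y_um` followed by one column per marker.
#' `"qupath"` accepts `Object ID` / `Image` / `Centroid X µm` /
#' `Centroid Y µm` headers and strips `": Cell: Mean"` / `": Mean"`
#' suffixes from channel columns before applying the alias map.
#'
#' Rows with a missing intensity are rejected (never imputed) and reported
#' by row number; a negative intensity is an error.
#'
#' @param path file path; delimited text with a header row (comma default,
#'   tab accepted).
#' @param dialect `"generic"` or `"qupath"`.
#' @param aliases marker alias map, see [marker_aliases()].
#' @return tibble with columns `cell_id`, `section_id`, `x_um`, `y_um`
#'   and one numeric column per marker.
#' @export
read_cell_table <- function(path, dialect = c("generic", "qupath"),
                            aliases = marker_aliases()) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("cell table not found: ", path)
  df <- read.csv(path, sep = .sniff_sep(path), check.names = FALSE,
                 stringsAsFactors = FALSE)
  if (dialect == "qupath") {
    for (std in names(.qupath_cols)) {
      qp <- .qupath_cols[[std]]
      if (!qp %in% names(df)) stop("missing required column '", qp, "' in ", path)
      names(df)[names(df) == qp] <- std
    }
    names(df) <- sub(":\\s*(Cell:\\s*)?Mean$", "", names(df))
  }
  req <- c("cell_id", "section_id", "x_um", "y_um")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("missing required column '", miss[1], "' in ", path)
  marker_cols <- setdiff(names(df), req)
  names(df)[match(marker_cols, names(df))] <- canonical_marker(marker_cols, aliases)
  marker_cols <- setdiff(names(df), req)
  df$cell_id <- as.character(df$cell_id)
  df$section_id <- as.character(df$section_id)
  cells <- tibble::as_tibble(df[c(req, marker_cols)])
  if (nrow(cells) == 0) return(cells)
  for (m in marker_cols) cells[[m]] <- as.numeric(cells[[m]])
  im <- as.matrix(cells[marker_cols])
  bad <- which(rowSums(is.na(im)) > 0)
  if (length(bad)) {
    warning("rejected ", length(bad), " row(s) with missing intensity in ",
            basename(path), " (rows ",
            paste(head(bad, 10), collapse = ", "),
            if (length(bad) > 10) ", ..." else "", ")")
    cells <- cells[-bad, , drop = FALSE]
    im <- im[-bad, , drop = FALSE]
  }
  if (any(im < 0)) {
    stop("negative intensity in ", basename(path), " (first at row ",
         which(rowSums(im < 0) > 0)[1], ")")
  }
  cells
}

#' Write a per-cell feature table
#'
#' Inverse of [read_cell_table()]: `read_cell_table(write_cell_table(x))`
#' reproduces `x` up to floating-point text precision.
#'
#' @param cells tibble as returned by [read_cell_table()].
#' @param path output path.
#' @param markers optional marker ordering; defaults to column order.
#' @param dialect output header dialect, `"generic"` or `"qupath"`.
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(cells, path, markers = NULL,
                             dialect = c("generic", "qupath")) {
  dialect <- match.arg(dialect)
  req <- c("cell_id", "section_id", "x_um", "y_um")
  markers <- markers %||% setdiff(names(cells), c(req, "true_class"))
  miss <- setdiff(c(req, markers), names(cells))
  if (length(miss)) stop("cells table lacks column(s): ", paste(miss, collapse = ", "))
  if (nrow(cells) && any(is.na(as.matrix(cells[markers]))))
    stop("inconsistent marker sets: missing intensities in table")
  out <- as.data.frame(cells[c(req, markers)])
  if (dialect == "qupath") {
    names(out)[1:4] <- unname(.qupath_cols[names(out)[1:4]])
    names(out)[-(1:4)] <- paste0(names(out)[-(1:4)], ": Cell: Mean")
  }
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Section metadata constructor
#'
#' @param section_id unique section identifier.
#' @param specimen specimen / tumor-model label (e.g. `"CT26"`).
#' @param serial_index position of the section in the serial-section series
#'   (1-based, unique within a specimen).
#' @param run_id staining run (batch) identifier.
#' @param replicate_index replicate number within the run (>= 1).
#' @param assay `"multiplex"` or `"singleplex:<marker>"`.
#' @return one-row tibble.
#' @export
section_meta <- function(section_id, specimen, serial_index, run_id,
                         replicate_index = 1L, assay = "multiplex") {
  stopifnot(serial_index >= 1, replicate_index >= 1)
  if (!(assay == "multiplex" || grepl("^singleplex:", assay)))
    stop("assay must be 'multiplex' or 'singleplex:<marker>', got: ", assay)
  tibble::tibble(
    section_id = as.character(section_id), specimen = as.character(specimen),
    serial_index = as.integer(serial_index), run_id = as.character(run_id),
    replicate_index = as.integer(replicate_index), assay = assay
  )
}

#' The marker a singleplex section was labeled for, or NA for multiplex
#' @param assay assay string(s) from section metadata.
#' @return character vector of marker names (NA for multiplex sections).
#' @export
singleplex_marker <- function(assay) {
  ifelse(grepl("^singleplex:", assay), sub("^singleplex:", "", assay), NA_character_)
}

validate_sections <- function(sections, markers) {
  stopifnot(is.data.frame(sections))
  if (anyDuplicated(sections$section_id))
    stop("duplicate section_id in manifest: ",
         sections$section_id[duplicated(sections$section_id)][1])
  dup <- sections |>
    dplyr::count(.data$specimen, .data$serial_index) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup))
    stop("serial_index not unique within specimen '", dup$specimen[1], "'")
  sm <- singleplex_marker(sections$assay)
  unknown <- setdiff(stats::na.omit(sm), markers)
  if (length(unknown))
    stop("singleplex assay references unknown marker: ", unknown[1])
  invisible(sections)
}

#' Assemble a study object
#'
#' A study bundles the manifest (section metadata, marker panel, phenotype
#' definitions) with all per-cell tables. Cells of every section must carry
#' exactly the manifest's marker set; in strict mode (default) an extra
#' marker column is an error — a silent channel mismatch is the most
#' dangerous QC failure — otherwise it is dropped with a warning.
#'
#' @param sections tibble of section metadata rows ([section_meta()]).
#' @param markers ordered character vector of marker names.
#' @param cells combined per-cell tibble (must reference only manifest
#'   sections).
#' @param phenotypes list of [phenotype_def()]s, priority-ordered.
#' @param strict error (TRUE) or drop-with-warning (FALSE) on marker
#'   columns not present in `markers`.
#' @return an object of class `mif_study`.
#' @export
new_study <- function(sections, markers, cells, phenotypes = default_phenotypes(),
                      strict = TRUE) {
  validate_sections(sections, markers)
  extra_cols <- setdiff(names(cells),
                        c("cell_id", "section_id", "x_um", "y_um", "true_class", markers))
  if (length(extra_cols)) {
    msg <- paste0("cell table has marker(s) not in manifest: ",
                  paste(extra_cols, collapse = ", "))
    if (strict) stop(msg) else {
      warning(msg, " (dropped)")
      cells <- cells[setdiff(names(cells), extra_cols)]
    }
  }
  miss_m <- setdiff(markers, names(cells))
  if (length(miss_m)) stop("cell table lacks manifest marker(s): ",
                           paste(miss_m, collapse = ", "))
  dangling <- setdiff(unique(cells$section_id), sections$section_id)
  if (length(dangling)) stop("cells reference section(s) not in manifest: ",
                             paste(dangling, collapse = ", "))
  if (nrow(cells) && any(as.matrix(cells[markers]) < 0, na.rm = TRUE))
    stop("negative intensity in cell table")
  structure(list(sections = tibble::as_tibble(sections), markers = markers,
                 phenotypes = phenotypes, cells = tibble::as_tibble(cells)),
            class = "mif_study")
}

#' @export
print.mif_study <- function(x, ...) {
  cat("<mif_study> ", nrow(x$sections), " sections, ",
      nrow(x$cells), " cells, markers: ",
      paste(x$markers, collapse = ", "), "\n", sep = "")
  cat("  specimens: ", paste(unique(x$sections$specimen), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Write a study to a directory
#'
#' Emits `manifest.json`, one `<section_id>.csv` cell table per section and,
#' when the cells carry a simulated `true_class` column, a
#' `ground_truth.csv` with the per-cell ground-truth phenotype.
#'
#' @param study a `mif_study`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    markers = study$markers,
    phenotypes = lapply(study$phenotypes, function(p)
      list(name = p$name, require_pos = p$require_pos, require_neg = p$require_neg)),
    sections = study$sections
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (sid in study$sections$section_id) {
    sc <- study$cells[study$cells$section_id == sid, , drop = FALSE]
    write_cell_table(sc, file.path(dir, paste0(sid, ".csv")), markers = study$markers)
  }
  if ("true_class" %in% names(study$cells)) {
    write.csv(study$cells[c("cell_id", "section_id", "true_class")],
              file.path(dir, "ground_truth.csv"), row.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}

#' Load a study from a manifest and a directory of cell tables
#'
#' @param manifest_path path to `manifest.json`.
#' @param table_dir directory holding `<section_id>.csv` tables (defaults to
#'   the manifest's directory).
#' @param dialect cell-table dialect, see [read_cell_table()].
#' @param strict see [new_study()].
#' @return a `mif_study`.
#' @export
load_study <- function(manifest_path, table_dir = dirname(manifest_path),
                       dialect = "generic", strict = TRUE) {
  man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  sections <- tibble::as_tibble(man$sections)
  sections$serial_index <- as.integer(sections$serial_index)
  sections$replicate_index <- as.integer(sections$replicate_index)
  phen <- list()
  if (!is.null(man$phenotypes) && length(man$phenotypes)) {
    pl <- man$phenotypes
    if (is.data.frame(pl)) pl <- split(pl, seq_len(nrow(pl)))
    phen <- lapply(pl, function(p)
      phenotype_def(p$name, unlist(p$require_pos), unlist(p$require_neg)))
    names(phen) <- vapply(phen, `[[`, "", "name")
  }
  paths <- file.path(table_dir, paste0(sections$section_id, ".csv"))
  missing <- sections$section_id[!file.exists(paths)]
  if (length(missing))
    stop("manifest section(s) missing a cell table: ",
         paste(missing, collapse = ", "))
  tabs <- lapply(paths, read_cell_table, dialect = dialect)
  cells <- dplyr::bind_rows(tabs)
  gt_path <- file.path(table_dir, "ground_truth.csv")
  if (file.exists(gt_path)) {
    gt <- read.csv(gt_path, stringsAsFactors = FALSE)
    gt$cell_id <- as.character(gt$cell_id); gt$section_id <- as.character(gt$section_id)
    cells <- dplyr::left_join(cells, tibble::as_tibble(gt),
                              by = c("cell_id", "section_id"))
  }
  new_study(sections, man$markers, cells, phenotypes = phen, strict = strict)
}

#' Split a study's cells by section
#' @param study a `mif_study`.
#' @return named list of per-section cell tibbles, in manifest order.
#' @export
section_cells <- function(study) {
  sp <- split(study$cells, study$cells$section_id)
  sp[intersect(study$sections$section_id, names(sp))]
}
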