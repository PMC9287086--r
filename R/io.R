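# Skyline-compatible exports and foreign-table ingestion.

#' Write a Skyline-importable small-molecule transition list
#'
#' One precursor row per compound plus one row per template fragment.
#' Columns: Molecule List Name, Precursor Name, Molecular Formula, Precursor
#' Adduct (`[M-H]`, `[M+H]`, `[M-CO2-H]`), Precursor Charge, Explicit
#' Retention Time, Product m/z, Product Charge, Note. Mass-only entries
#' (no public formula) are emitted with their m/z in lieu of a formula and
#' flagged in the Note column.
#'
#' @param registry a `compound_registry`.
#' @param path output CSV path.
#' @param list_name Molecule List Name value.
#' @return `path`, invisibly.
#' @export
write_transition_list <- function(registry, path, list_name = "PFAS") {
  stopifnot(inherits(registry, "compound_registry"))
  adduct_of <- function(species) switch(species, "[M-H]-" = "[M-H]",
                                        "[M+H]+" = "[M+H]",
                                        "[M-CO2-H]-" = "[M-CO2-H]")
  charge_of <- function(species) if (species == "[M+H]+") 1L else -1L
  masses <- registry_masses(registry)
  rows <- list()
  for (i in seq_len(nrow(registry))) {
    if (registry$role[i] == "interference") next
    id <- registry$id[i]
    has_formula <- !is.null(registry$parsed_formula[[i]])
    base <- data.frame(
      `Molecule List Name` = list_name,
      `Precursor Name` = registry$name[i],
      `Molecular Formula` = if (has_formula)
        format_formula(registry$parsed_formula[[i]]) else "",
      `Precursor Adduct` = adduct_of(registry$species[i]),
      `Precursor Charge` = charge_of(registry$species[i]),
      `Explicit Retention Time` = registry$rt_min[i],
      `Product m/z` = NA_real_,
      `Product Charge` = NA_integer_,
      Note = if (has_formula) "" else
        sprintf("mass-only entry, m/z %.4f", masses$mz[match(id, masses$id)]),
      check.names = FALSE, stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- base
    frag <- parse_frag_template(registry$frag_template[i])
    for (k in seq_len(nrow(frag))) {
      r <- base
      r$`Product m/z` <- frag$mz[k]
      r$`Product Charge` <- charge_of(registry$species[i])
      rows[[length(rows) + 1L]] <- r
    }
  }
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

AREA_TABLE_COLUMNS <- c("replicate_id", "level_ngL", "compound",
                        "is_internal_standard", "area")

#' Read a peak-area table
#'
#' Reads a CSV in the standard area-table schema (`replicate_id`,
#' `level_ngL`, `compound`, `is_internal_standard`, `area`), or a foreign
#' export (e.g. from Skyline) via `column_map`, a named character vector
#' mapping standard names to the file's headers. Rows whose area or level
#' fails numeric coercion are dropped and counted in
#' `attr(, "rejected_rows")`.
#'
#' @param path CSV path.
#' @param column_map optional named character vector, e.g.
#'   `c(compound = "Molecule Name", area = "Total Area")`.
#' @return a data.frame in the standard schema.
#' @export
read_area_table <- function(path, column_map = NULL) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(column_map)) {
    missing_src <- setdiff(unname(column_map), names(df))
    if (length(missing_src))
      stop("mapped column(s) not in file: ", paste(missing_src, collapse = ", "),
           call. = FALSE)
    for (std in names(column_map)) names(df)[names(df) == column_map[[std]]] <- std
  }
  missing_cols <- setdiff(AREA_TABLE_COLUMNS, names(df))
  if (length(missing_cols))
    stop("area table missing column(s): ",
         paste(missing_cols, collapse = ", "),
         "; expected schema: ", paste(AREA_TABLE_COLUMNS, collapse = ", "),
         call. = FALSE)
  df <- df[AREA_TABLE_COLUMNS]
  area <- suppressWarnings(as.numeric(df$area))
  lev <- suppressWarnings(as.numeric(df$level_ngL))
  bad <- is.na(area) | is.na(lev)
  if (any(bad))
    warning(sum(bad), " row(s) with non-numeric area/level rejected")
  df$area <- area; df$level_ngL <- lev
  df$is_internal_standard <- as.logical(df$is_internal_standard)
  out <- df[!bad, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejected_rows") <- sum(bad)
  out
}

#' Write an area table CSV
#'
#' @param areas a data.frame in the standard area-table schema.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_area_table <- function(areas, path) {
  stopifnot(all(AREA_TABLE_COLUMNS %in% names(areas)))
  utils::write.csv(areas[AREA_TABLE_COLUMNS], path, row.names = FALSE)
  invisible(path)
}
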