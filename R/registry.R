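# Compound registry: the panel definition driving every other module.

REGISTRY_COLUMNS <- c("id", "name", "class", "formula", "mz", "species",
                      "polarity", "rt_min", "role", "n13C", "n2H",
                      "surrogate_is", "frag_template", "early_eluter")

REGISTRY_ROLES <- c("analyte", "internal_standard", "interference")

REGISTRY_CLASSES <- c("sulfonate", "carboxylate", "fluorotelomer_sulfonate",
                      "sulfonamide", "sulfonamidoacetic_acid", "ether_acid",
                      "zwitterion", "other")

#' Read and validate a compound registry
#'
#' Reads a comma- or tab-separated registry of analytes, internal standards
#' and known interferences. Each row carries a compound id, display name,
#' chemical class, molecular formula (or an explicit `mz` for mass-only
#' entries such as Hydro-EVE, for which no public formula exists), ion
#' species, polarity, expected retention time, role, stable-isotope label
#' counts (`n13C`, `n2H`), the assigned surrogate internal standard for
#' analytes, a packed MS2 fragment template (`"mz:rel;mz:rel"`), and an
#' early-eluter flag (drives the bimodal "breakthrough" peak shape in the
#' simulator).
#'
#' All structural violations are collected and reported together: duplicate
#' ids, unknown roles/classes/species, analytes whose assigned surrogate is
#' missing or not an internal standard, zwitterions not in positive mode,
#' label counts exceeding the formula, and rows with neither formula nor mz.
#'
#' @param path path to a registry CSV/TSV (separator sniffed from the header).
#' @return a `compound_registry`: a data.frame with one row per compound and
#'   an attached list column `parsed_formula` of [element_counts()] (NULL for
#'   mass-only rows).
#' @seealso [pfas_registry()] for the packaged default panel.
#' @export
read_registry <- function(path) {
  if (!file.exists(path)) stop("registry file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = '"',
                          stringsAsFactors = FALSE, na.strings = c("NA", ""),
                          comment.char = "")
  missing_cols <- setdiff(REGISTRY_COLUMNS, names(df))
  if (length(missing_cols))
    stop("registry is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  df <- df[REGISTRY_COLUMNS]
  df$n13C[is.na(df$n13C)] <- 0L
  df$n2H[is.na(df$n2H)] <- 0L
  df$early_eluter[is.na(df$early_eluter)] <- FALSE
  df$early_eluter <- as.logical(df$early_eluter)
  as_compound_registry(df)
}

#' Construct / validate a compound registry from a data.frame
#'
#' @param df a data.frame with the columns documented in [read_registry()].
#' @return a validated `compound_registry`.
#' @export
as_compound_registry <- function(df) {
  problems <- character(0)
  note <- function(...) problems <<- c(problems, sprintf(...))

  dup <- unique(df$id[duplicated(df$id)])
  if (length(dup)) note("duplicate compound id(s): %s", paste(dup, collapse = ", "))

  bad_role <- setdiff(unique(df$role), REGISTRY_ROLES)
  if (length(bad_role)) note("unknown role(s): %s", paste(bad_role, collapse = ", "))
  bad_class <- setdiff(unique(df$class), REGISTRY_CLASSES)
  if (length(bad_class)) note("unknown class(es): %s", paste(bad_class, collapse = ", "))
  bad_sp <- setdiff(unique(df$species), ION_SPECIES)
  if (length(bad_sp)) note("unknown ion species: %s", paste(bad_sp, collapse = ", "))

  parsed <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    has_formula <- !is.na(df$formula[i]) && nzchar(df$formula[i])
    if (has_formula) {
      parsed[[i]] <- tryCatch(
        element_counts(parse_formula(df$formula[i])$counts,
                       n13C = df$n13C[i], n2H = df$n2H[i]),
        error = function(e) {
          note("row %s: %s", df$id[i], conditionMessage(e))
          NULL
        })
    } else if (is.na(df$mz[i])) {
      note("row %s: neither formula nor mz given", df$id[i])
    }
    if (df$species[i] %in% ION_SPECIES &&
        !is.na(df$polarity[i]) &&
        df$polarity[i] != ion_polarity(df$species[i]))
      note("row %s: polarity '%s' inconsistent with species %s",
           df$id[i], df$polarity[i], df$species[i])
    if (identical(df$class[i], "zwitterion") && !identical(df$polarity[i], "positive"))
      note("row %s: zwitterion must be positive polarity", df$id[i])
  }

  is_is <- df$role == "internal_standard"
  for (i in which(df$role == "analyte")) {
    s <- df$surrogate_is[i]
    if (is.na(s) || !nzchar(s)) {
      note("analyte %s has no assigned internal standard", df$id[i])
    } else if (!(s %in% df$id)) {
      note("analyte %s references missing internal standard '%s'", df$id[i], s)
    } else if (!is_is[match(s, df$id)]) {
      note("analyte %s surrogate '%s' is not an internal standard", df$id[i], s)
    }
  }

  if (length(problems))
    stop("invalid compound registry:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  df$parsed_formula <- parsed
  class(df) <- c("compound_registry", "data.frame")
  df
}

#' Write a registry back to CSV
#'
#' Round-trips bit-identically through [read_registry()] for its own dialect.
#'
#' @param registry a `compound_registry`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_registry <- function(registry, path) {
  stopifnot(inherits(registry, "compound_registry"))
  out <- as.data.frame(registry)[REGISTRY_COLUMNS]
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' The packaged default PFAS panel
#'
#' Loads the registry shipped with the package: 45 analytes across eight
#' chemical classes, 23 stable-isotope-labeled internal standards, and one
#' mass-only interference entry (Hydro-EVE, deprotonated m/z 426.9657, the
#' near-isobar of 6:2 FTS). Molecular formulas were compiled from the
#' compound names; retention times and fragment templates are synthetic
#' defaults for simulation, not measured values.
#'
#' @return a `compound_registry`.
#' @examples
#' reg <- pfas_registry()
#' table(reg$role)
#' @export
pfas_registry <- function() {
  read_registry(system.file("extdata", "pfas_registry.csv", package = "pfasq",
                            mustWork = TRUE))
}

#' @export
print.compound_registry <- function(x, ...) {
  cat(sprintf("<compound_registry> %d analytes, %d internal standards, %d interference(s)\n",
              sum(x$role == "analyte"), sum(x$role == "internal_standard"),
              sum(x$role == "interference")))
  cat("classes:", paste(sort(unique(x$class)), collapse = ", "), "\n")
  invisible(x)
}

# internal: single registry row by id
registry_row <- function(registry, id) {
  i <- match(id, registry$id)
  if (is.na(i)) stop("unknown compound id: ", id, call. = FALSE)
  registry[i, , drop = FALSE]
}

#' Theoretical m/z for every registry entry
#'
#' Computes each compound's ion m/z from its formula (including isotope
#' labels) under its registered ion species; mass-only rows pass their
#' registered m/z through.
#'
#' @param registry a `compound_registry`.
#' @param electron_correction passed to [ion_mz()].
#' @return a data.frame: id, name, role, species, polarity, mz.
#' @export
registry_masses <- function(registry, electron_correction = FALSE) {
  stopifnot(inherits(registry, "compound_registry"))
  mz <- vapply(seq_len(nrow(registry)), function(i) {
    f <- registry$parsed_formula[[i]]
    if (is.null(f)) registry$mz[i]
    else ion_mz(f, registry$species[i], electron_correction = electron_correction)
  }, numeric(1))
  data.frame(id = registry$id, name = registry$name, role = registry$role,
             species = registry$species, polarity = registry$polarity,
             mz = mz, stringsAsFactors = FALSE)
}

# internal: parse "mz:rel;mz:rel" packed fragment template
parse_frag_template <- function(text) {
  if (is.na(text) || !nzchar(text))
    return(data.frame(mz = numeric(0), abundance = numeric(0)))
  parts <- strsplit(strsplit(text, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
  data.frame(mz = vapply(parts, function(p) as.numeric(p[1]), numeric(1)),
             abundance = vapply(parts, function(p) as.numeric(p[2]), numeric(1)))
}
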