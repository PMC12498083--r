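#' @keywords internal
"_PACKAGE"

# Closed vocabularies -------------------------------------------------------

#' Controlled vocabularies for lake community tables
#'
#' The four peri-Alpine catchments, the occurrence origin classes and the
#' species endemism classes form closed sets; all readers and validators
#' reject tokens outside them.
#'
#' @name vocabularies
#' @keywords internal
NULL

CATCHMENTS <- c("Rhine", "Rhone", "Po", "Danube")
ORIGINS <- c("native", "translocated", "introduced")
ENDEMISM_CLASSES <- c("none", "single_lake", "sister_lake")
POOL_ORIGINS <- c("in_basin", "out_of_basin")
SCENARIOS <- c("OC", "OC_plus_Int", "OC_minus_Ext", "CC")

# "Rhône" and lower/upper case variants are normalised to the canonical token.
normalise_catchment <- function(x) {
  x <- as.character(x)
  x[x %in% c("Rhône", "rhone", "RHONE", "Rhône ")] <- "Rhone"
  x <- ifelse(tolower(x) %in% tolower(CATCHMENTS),
    CATCHMENTS[match(tolower(x), tolower(CATCHMENTS))], x)
  x
}

as_flag <- function(x, what) {
  if (is.logical(x)) return(x)
  tok <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(tok))
  out[tok %in% c("true", "t", "1", "yes")] <- TRUE
  out[tok %in% c("false", "f", "0", "no", "")] <- FALSE
  if (anyNA(out)) {
    stop(sprintf("column '%s': unrecognised boolean token(s): %s",
      what, paste(unique(tok[is.na(out)]), collapse = ", ")), call. = FALSE)
  }
  out
}

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(sprintf("%s: missing required column(s): %s",
      what, paste(missing, collapse = ", ")), call. = FALSE)
  }
}

# Validators ----------------------------------------------------------------

#' Validate a lake table
#'
#' Checks the invariants of the lake table: unique `lake_id`, strictly
#' positive `area_km2`, catchments drawn from the closed set
#' (Rhine, Rhone, Po, Danube). Extra numeric feature columns (e.g.
#' `max_depth_m`, `elevation_m`) are carried through untouched.
#'
#' @param lakes data frame with at least `lake_id`, `catchment`, `area_km2`.
#' @return the validated data frame (catchment normalised), invisibly the
#'   same rows in the same order.
#' @export
validate_lakes <- function(lakes) {
  require_columns(lakes, c("lake_id", "catchment", "area_km2"), "lake table")
  lakes$lake_id <- as.character(lakes$lake_id)
  lakes$catchment <- normalise_catchment(lakes$catchment)
  lakes$area_km2 <- as.numeric(lakes$area_km2)

  bad <- which(!lakes$catchment %in% CATCHMENTS)
  if (length(bad)) {
    stop(sprintf(
      "lake table row %d (lake '%s'): unknown catchment '%s' (allowed: %s)",
      bad[1], lakes$lake_id[bad[1]], lakes$catchment[bad[1]],
      paste(CATCHMENTS, collapse = ", ")), call. = FALSE)
  }
  bad <- which(!is.finite(lakes$area_km2) | lakes$area_km2 <= 0)
  if (length(bad)) {
    stop(sprintf("lake table row %d (lake '%s'): area must be > 0 km^2, got %s",
      bad[1], lakes$lake_id[bad[1]], lakes$area_km2[bad[1]]), call. = FALSE)
  }
  dup <- lakes$lake_id[duplicated(lakes$lake_id)]
  if (length(dup)) {
    stop(sprintf("lake table: duplicate lake_id '%s'", dup[1]), call. = FALSE)
  }
  rownames(lakes) <- NULL
  lakes
}

#' Validate a species table
#'
#' @param species data frame with `species_id`, `family`, `endemism_class`
#'   (none / single_lake / sister_lake) and optional `pool_origin`
#'   (in_basin / out_of_basin, defaulting to in_basin).
#' @return validated data frame.
#' @export
validate_species <- function(species) {
  require_columns(species, c("species_id", "family", "endemism_class"),
    "species table")
  species$species_id <- as.character(species$species_id)
  species$family <- as.character(species$family)
  species$endemism_class <- as.character(species$endemism_class)
  if (is.null(species$pool_origin)) species$pool_origin <- "in_basin"
  species$pool_origin <- as.character(species$pool_origin)

  dup <- species$species_id[duplicated(species$species_id)]
  if (length(dup)) {
    stop(sprintf("species table: duplicate species_id '%s'", dup[1]),
      call. = FALSE)
  }
  bad <- which(!species$endemism_class %in% ENDEMISM_CLASSES)
  if (length(bad)) {
    stop(sprintf(
      "species table row %d ('%s'): unknown endemism_class '%s' (allowed: %s)",
      bad[1], species$species_id[bad[1]], species$endemism_class[bad[1]],
      paste(ENDEMISM_CLASSES, collapse = ", ")), call. = FALSE)
  }
  bad <- which(!species$pool_origin %in% POOL_ORIGINS)
  if (length(bad)) {
    stop(sprintf(
      "species table row %d ('%s'): unknown pool_origin '%s' (allowed: %s)",
      bad[1], species$species_id[bad[1]], species$pool_origin[bad[1]],
      paste(POOL_ORIGINS, collapse = ", ")), call. = FALSE)
  }
  rownames(species) <- NULL
  species
}

#' Validate an occurrence table
#'
#' Each row is one (lake, species) record with an `origin` class
#' (native / translocated / introduced) and an `extirpated` flag marking
#' anthropogenic loss of that population. `(lake_id, species_id)` pairs must
#' be unique and every id must resolve in the companion tables when given.
#'
#' @param occ data frame with `lake_id`, `species_id`, `origin`, `extirpated`.
#' @param species optional validated species table for id resolution.
#' @param lakes optional validated lake table for id resolution.
#' @return validated data frame with logical `extirpated`.
#' @export
validate_occurrences <- function(occ, species = NULL, lakes = NULL) {
  require_columns(occ, c("lake_id", "species_id", "origin", "extirpated"),
    "occurrence table")
  occ$lake_id <- as.character(occ$lake_id)
  occ$species_id <- as.character(occ$species_id)
  occ$origin <- as.character(occ$origin)
  occ$extirpated <- as_flag(occ$extirpated, "extirpated")

  bad <- which(!occ$origin %in% ORIGINS)
  if (length(bad)) {
    stop(sprintf(
      "occurrence table row %d ('%s' in '%s'): unknown origin '%s' (allowed: %s)",
      bad[1], occ$species_id[bad[1]], occ$lake_id[bad[1]], occ$origin[bad[1]],
      paste(ORIGINS, collapse = ", ")), call. = FALSE)
  }
  key <- paste(occ$lake_id, occ$species_id, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup)) {
    stop(sprintf("occurrence table: duplicate record for species '%s' in lake '%s'",
      occ$species_id[dup[1]], occ$lake_id[dup[1]]), call. = FALSE)
  }
  if (!is.null(species)) {
    unresolved <- setdiff(occ$species_id, species$species_id)
    if (length(unresolved)) {
      stop(sprintf("occurrence table: species_id '%s' not in species table",
        unresolved[1]), call. = FALSE)
    }
  }
  if (!is.null(lakes)) {
    unresolved <- setdiff(occ$lake_id, lakes$lake_id)
    if (length(unresolved)) {
      stop(sprintf("occurrence table: lake_id '%s' not in lake table",
        unresolved[1]), call. = FALSE)
    }
  }
  rownames(occ) <- NULL
  occ
}

# Readers -------------------------------------------------------------------

#' Read and validate the lake table
#'
#' Expects a comma-separated UTF-8 file with a header row and at least the
#' columns `lake_id`, `catchment` and `area_km2`; any further columns
#' (e.g. `max_depth_m`) are kept as numeric features where possible.
#'
#' @param path path to `lakes.csv`.
#' @return validated lake data frame, row order preserved.
#' @export
read_lakes <- function(path) {
  validate_lakes(utils::read.csv(path, stringsAsFactors = FALSE,
    fileEncoding = "UTF-8"))
}

#' Read and validate the species table
#' @param path path to `species.csv`.
#' @return validated species data frame.
#' @export
read_species <- function(path) {
  validate_species(utils::read.csv(path, stringsAsFactors = FALSE,
    fileEncoding = "UTF-8"))
}

#' Read and validate the occurrence table
#' @param path path to `occurrences.csv`.
#' @param species optional species table used to resolve ids.
#' @param lakes optional lake table used to resolve ids.
#' @return validated occurrence data frame.
#' @export
read_occurrences <- function(path, species = NULL, lakes = NULL) {
  validate_occurrences(utils::read.csv(path, stringsAsFactors = FALSE,
    fileEncoding = "UTF-8"), species = species, lakes = lakes)
}

#' Write a lake/species/occurrence dataset as CSV files
#'
#' @param dataset list with elements `lakes`, `species`, `occurrences`.
#' @param dir output directory, created if needed.
#' @return invisibly, the three file paths.
#' @export
write_dataset_csv <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("lakes.csv", "species.csv", "occurrences.csv"))
  utils::write.csv(dataset$lakes, paths[1], row.names = FALSE)
  utils::write.csv(dataset$species, paths[2], row.names = FALSE)
  occ <- dataset$occurrences
  occ$extirpated <- tolower(as.character(occ$extirpated))
  utils::write.csv(occ, paths[3], row.names = FALSE)
  invisible(paths)
}

# Scenario membership -------------------------------------------------------

#' Row membership of an occurrence table under a community scenario
#'
#' Scenarios partition the records into the pre-1900 baseline and
#' human-modified communities:
#' * `OC` - original community: native records, including extirpated natives;
#' * `OC_plus_Int` - OC plus all introduced and translocated records;
#' * `OC_minus_Ext` - OC minus extirpated records;
#' * `CC` - current community: `(OC` \eqn{\cup} `Int) \ Ext`, i.e. everything
#'   not extirpated.
#'
#' @param occ validated occurrence table.
#' @param scenario one of `"OC"`, `"OC_plus_Int"`, `"OC_minus_Ext"`, `"CC"`.
#' @return logical vector over the rows of `occ`.
#' @export
scenario_members <- function(occ, scenario) {
  scenario <- match.arg(scenario, SCENARIOS)
  native <- occ$origin == "native"
  switch(scenario,
    OC = native,
    OC_plus_Int = rep(TRUE, nrow(occ)),
    OC_minus_Ext = native & !occ$extirpated,
    CC = !occ$extirpated)
}

#' Per-lake richness under a community scenario
#'
#' @inheritParams scenario_members
#' @param lakes validated lake table; every lake gets a row, lakes without
#'   qualifying records get richness 0.
#' @return data frame `lake_id`, `richness` in the lake-table row order.
#' @export
scenario_richness <- function(occ, lakes, scenario) {
  members <- occ[scenario_members(occ, scenario), , drop = FALSE]
  counts <- table(factor(members$lake_id, levels = lakes$lake_id))
  data.frame(lake_id = lakes$lake_id, richness = as.integer(counts),
    stringsAsFactors = FALSE)
}

# Community metrics ---------------------------------------------------------

#' Per-lake community richness metrics
#'
#' Computes, for every lake, the metrics used throughout the analysis:
#' total native species richness `tnsr` (natives including extirpated ones),
#' endemic count `n_endemic` and proportion `pens` (= n_endemic / tnsr, 0
#' when tnsr is 0), native salmonid richness `nssr`, the non-native record
#' count `n_nonnative` (introduced + translocated), the extirpated native
#' count `n_extirpated` (plus `n_extirpated_nonnative` for completeness),
#' and `richness` under the requested scenario.
#'
#' Endemics are native species whose `endemism_class` is not `"none"`
#' (single-lake and sister-lake endemics pooled); salmonids are native
#' records whose family is Salmonidae.
#'
#' @param occ validated occurrence table.
#' @param species validated species table.
#' @param lakes validated lake table.
#' @param scenario community scenario for the `richness` column (default OC).
#' @return data frame with one row per lake, in lake-table order.
#' @export
community_metrics <- function(occ, species, lakes, scenario = "OC") {
  scenario <- match.arg(scenario, SCENARIOS)
  occ <- validate_occurrences(occ, species = species, lakes = lakes)

  sp_idx <- match(occ$species_id, species$species_id)
  is_endemic <- species$endemism_class[sp_idx] != "none"
  is_salmonid <- species$family[sp_idx] == "Salmonidae"
  native <- occ$origin == "native"

  lake_f <- function(keep) {
    as.integer(table(factor(occ$lake_id[keep], levels = lakes$lake_id)))
  }

  tnsr <- lake_f(native)
  n_endemic <- lake_f(native & is_endemic)
  nssr <- lake_f(native & is_salmonid)
  n_nonnative <- lake_f(!native)
  n_extirpated <- lake_f(native & occ$extirpated)
  n_ext_nonnat <- lake_f(!native & occ$extirpated)
  richness <- lake_f(scenario_members(occ, scenario))

  data.frame(
    lake_id = lakes$lake_id,
    scenario = scenario,
    richness = richness,
    tnsr = tnsr,
    n_endemic = n_endemic,
    pens = ifelse(tnsr > 0, n_endemic / tnsr, 0),
    nssr = nssr,
    n_nonnative = n_nonnative,
    n_extirpated = n_extirpated,
    n_extirpated_nonnative = n_ext_nonnat,
    stringsAsFactors = FALSE)
}

# Supplementary-sheet converter ---------------------------------------------

#' Convert supplementary-style sheets to the package's CSV layout
#'
#' Accepts CSV exports of a lake-features sheet and a long-format occurrence
#' sheet (one row per lake x species record) whose column names may differ
#' from the package's canonical ones, remaps them, validates, and writes
#' `lakes.csv`, `species.csv`, `occurrences.csv`.
#'
#' Column matching is case-insensitive on the supplied `map`, e.g.
#' `map = list(lake_id = "Lake", area_km2 = "Surface area", ...)`. The
#' species table is derived from the occurrence sheet's `family` and
#' `endemism_class` columns (one value per species).
#'
#' @param lake_sheet path to the lake-features CSV export.
#' @param occ_sheet path to the long occurrence CSV export.
#' @param out_dir output directory for the three canonical CSVs.
#' @param map named list mapping canonical column names to sheet column
#'   names; canonical names already present are used as-is.
#' @return invisibly, the validated dataset list.
#' @export
convert_supplementary <- function(lake_sheet, occ_sheet, out_dir,
                                  map = list()) {
  pick <- function(df, canonical) {
    for (nm in canonical) {
      src <- if (!is.null(map[[nm]])) map[[nm]] else nm
      hit <- which(tolower(names(df)) == tolower(src))
      if (!length(hit) && nm %in% names(map)) {
        stop(sprintf("column '%s' (for '%s') not found", src, nm),
          call. = FALSE)
      }
      if (length(hit)) names(df)[hit[1]] <- nm
    }
    df
  }
  lk <- pick(utils::read.csv(lake_sheet, stringsAsFactors = FALSE),
    c("lake_id", "catchment", "area_km2", "max_depth_m"))
  oc <- pick(utils::read.csv(occ_sheet, stringsAsFactors = FALSE),
    c("lake_id", "species_id", "origin", "extirpated", "family",
      "endemism_class"))
  if (is.null(oc$extirpated)) oc$extirpated <- FALSE
  if (is.null(oc$family)) oc$family <- "unknown"
  if (is.null(oc$endemism_class)) oc$endemism_class <- "none"

  sp <- unique(oc[, c("species_id", "family", "endemism_class")])
  sp$pool_origin <- ifelse(
    sp$species_id %in% oc$species_id[oc$origin == "introduced"] &
      !sp$species_id %in% oc$species_id[oc$origin != "introduced"],
    "out_of_basin", "in_basin")

  dataset <- list(
    lakes = validate_lakes(lk),
    species = validate_species(sp),
    occurrences = validate_occurrences(
      oc[, c("lake_id", "species_id", "origin", "extirpated")]))
  dataset$occurrences <- validate_occurrences(dataset$occurrences,
    species = dataset$species, lakes = dataset$lakes)
  write_dataset_csv(dataset, out_dir)
  invisible(dataset)
}
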