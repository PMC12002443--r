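# Chemical data model: a wide table with one row per chemical, species-
# specific in vitro columns suffixed ".Human"/".Rat" etc., uncertainty
# tuples stored as their raw strings, and per-field provenance in "ref.*"
# columns.  Substitution rules (e.g. the 0.5% fraction-unbound default) are
# applied at parameterization time, never in the library itself, so the raw
# data stay intact.

.species_fields <- c("Clint", "fup", "Rblood2plasma")
.numeric_fields <- c("MW", "logP", "logHenry", "caco2_papp", "Fabs_measured")
.string_fields <- c("dtxsid", "casrn", "name", "pKa_donor", "pKa_accept",
                    "chem_class")

.canonical_columns <- function(species = c("Human", "Rat")) {
  c(.string_fields[1:3], .numeric_fields[1:2], "pKa_donor", "pKa_accept",
    "logHenry", "caco2_papp", "Fabs_measured", "chem_class",
    as.vector(outer(.species_fields, species, paste, sep = ".")))
}

#' Construct a chemical library
#'
#' @param records A data.frame with at least `dtxsid` and `MW` columns in the
#'   canonical wide layout (species-specific columns suffixed, e.g.
#'   `Clint.Human`; tuple-encoded strings for `Clint`/`fup`; `;`-separated
#'   pKa lists and chemical-class tags).
#' @param sources Character vector naming the data source(s).
#' @return An object of class `chem_library` with a creation timestamp.
#' @export
chem_library <- function(records, sources = "user") {
  stopifnot(is.data.frame(records))
  if (!"dtxsid" %in% names(records))
    abort("missing mandatory column 'dtxsid'", class = "pbtksim_schema_error")
  if (!"MW" %in% names(records))
    abort("missing mandatory column 'MW'", class = "pbtksim_schema_error")
  records$dtxsid <- as.character(records$dtxsid)
  if (anyDuplicated(records$dtxsid))
    abort("duplicate chemical identifiers (dtxsid) in library",
          class = "pbtksim_validation_error")
  mw <- suppressWarnings(as.numeric(records$MW))
  bad <- which(!is.na(records$MW) & (is.na(mw) | mw <= 0))
  if (length(bad))
    abort(sprintf("non-numeric or non-positive MW in row %s",
                  paste(bad, collapse = ", ")),
          class = "pbtksim_validation_error")
  records$MW <- mw
  for (col in intersect(c("logP", "logHenry", "caco2_papp", "Fabs_measured",
                          grep("^Rblood2plasma\\.", names(records), value = TRUE)),
                        names(records))) {
    v <- suppressWarnings(as.numeric(records[[col]]))
    badv <- which(!is.na(records[[col]]) & nzchar(trimws(as.character(records[[col]]))) & is.na(v))
    if (length(badv))
      abort(sprintf("non-numeric value in column '%s', row %s", col,
                    paste(badv, collapse = ", ")),
            class = "pbtksim_validation_error")
    records[[col]] <- v
  }
  # validate tuple encodings eagerly so malformed rows fail at load time
  for (col in grep("^(Clint|fup)\\.", names(records), value = TRUE)) {
    kind <- if (startsWith(col, "Clint")) "clint" else "fup"
    for (i in seq_len(nrow(records))) {
      v <- records[[col]][i]
      if (!is.na(v) && nzchar(trimws(as.character(v))))
        tryCatch(parse_uncertainty_tuple(v, kind), error = function(e)
          abort(sprintf("row %d, column '%s': %s", i, col, conditionMessage(e)),
                class = "pbtksim_validation_error"))
    }
  }
  rownames(records) <- NULL
  structure(list(records = records,
                 metadata = list(created = Sys.time(), sources = sources)),
            class = "chem_library")
}

#' @export
print.chem_library <- function(x, ...) {
  cat(sprintf("<chem_library> %d chemicals, %d fields (created %s; sources: %s)\n",
              nrow(x$records), ncol(x$records),
              format(x$metadata$created, "%Y-%m-%d"),
              paste(x$metadata$sources, collapse = ", ")))
  invisible(x)
}

#' @export
length.chem_library <- function(x) nrow(x$records)

#' Load a chemical library from CSV
#'
#' @param path Path to an RFC-4180 CSV, UTF-8, one row per chemical.
#' @param dialect Optional column mapping: a named character vector (or a
#'   YAML file path of `canonical: actual` pairs) translating the file's
#'   headers to the canonical layout.
#' @param sources Source label recorded in the metadata.
#' @return A [chem_library()].
#' @export
load_chem_library <- function(path, dialect = NULL, sources = basename(path)) {
  if (!file.exists(path))
    abort(sprintf("file not found: %s", path), class = "pbtksim_io_error")
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  if (is.character(dialect) && length(dialect) == 1L && file.exists(dialect))
    dialect <- unlist(yaml::read_yaml(dialect))
  if (!is.null(dialect)) {
    for (canon in names(dialect)) {
      actual <- dialect[[canon]]
      if (!actual %in% names(raw))
        abort(sprintf("dialect maps '%s' to missing column '%s'", canon, actual),
              class = "pbtksim_schema_error")
      names(raw)[names(raw) == actual] <- canon
    }
  }
  for (col in names(raw)) raw[[col]][!nzchar(trimws(raw[[col]]))] <- NA
  chem_library(raw, sources = sources)
}

#' Write a chemical library to the canonical CSV dialect
#'
#' Numeric fields are serialized with 17 significant digits so that a
#' load/write round trip preserves every value bit-for-bit.
#'
#' @param lib A [chem_library()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_chem_library <- function(lib, path) {
  stopifnot(inherits(lib, "chem_library"))
  out <- lib$records
  for (col in names(out)) {
    if (is.numeric(out[[col]])) {
      v <- out[[col]]
      out[[col]] <- ifelse(is.na(v), "", sprintf("%.17g", v))
    } else {
      out[[col]] <- ifelse(is.na(out[[col]]), "", as.character(out[[col]]))
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' Resolve a chemical identifier to a library row
#'
#' Looks up `dtxsid` first, then `casrn`, then `name`.
#'
#' @param lib A [chem_library()].
#' @param id Identifier string.
#' @return List with `row` (index), `dtxsid`, `casrn`, `name`.
#' @export
get_chem_id <- function(lib, id) {
  stopifnot(inherits(lib, "chem_library"))
  rec <- lib$records
  row <- match(id, rec$dtxsid)
  if (is.na(row) && "casrn" %in% names(rec)) row <- match(id, rec$casrn)
  if (is.na(row) && "name" %in% names(rec)) row <- match(id, rec$name)
  if (is.na(row))
    abort(sprintf("chemical '%s' not found in library", id),
          class = "pbtksim_missing_data_error")
  list(row = row, dtxsid = rec$dtxsid[row],
       casrn = if ("casrn" %in% names(rec)) rec$casrn[row] else NA_character_,
       name = if ("name" %in% names(rec)) rec$name[row] else NA_character_)
}

#' Extract one chemical as a plain record list
#'
#' Returns the library row as a list with parsed pKa lists and chemical
#' class tags; species-specific fields keep their raw (tuple-string)
#' encodings.  This is the form the parameterizers and samplers accept
#' directly.
#'
#' @param lib A [chem_library()].
#' @param id Chemical identifier (dtxsid, casrn, or name).
#' @return A named list.
#' @export
chem_record <- function(lib, id) {
  row <- get_chem_id(lib, id)$row
  rec <- as.list(lib$records[row, , drop = FALSE])
  rec <- lapply(rec, function(v) v[[1]])
  rec$pKa_donor <- parse_num_list(rec$pKa_donor)
  rec$pKa_accept <- parse_num_list(rec$pKa_accept)
  cc <- rec$chem_class
  rec$chem_class <- if (is.null(cc) || is.na(cc)) character(0)
                    else trimws(strsplit(cc, ";")[[1]])
  rec
}

#' Merge a new chemical table into a library
#'
#' Field-level merge keyed on `dtxsid`: fields present only in `new` fill
#' gaps; fields present in both are resolved per `precedence`.  Per-field
#' provenance (`ref.*` columns) is updated for every field taken from `new`.
#'
#' @param lib Existing [chem_library()].
#' @param new Incoming [chem_library()] (or data.frame).
#' @param precedence `"overwrite"` (new wins on conflict) or
#'   `"keep_existing"`.
#' @param source Provenance label for fields taken from `new`.
#' @return The merged [chem_library()].
#' @export
add_chemtable <- function(lib, new, precedence = c("overwrite", "keep_existing"),
                          source = "added") {
  precedence <- match.arg(precedence)
  if (is.data.frame(new)) new <- chem_library(new, sources = source)
  stopifnot(inherits(lib, "chem_library"), inherits(new, "chem_library"))
  old <- lib$records; add <- new$records
  all_cols <- union(names(old), names(add))
  pad <- function(df) {
    for (col in setdiff(all_cols, names(df))) {
      df[[col]] <- if (col %in% c("MW", "logP", "logHenry", "caco2_papp",
                                  "Fabs_measured") ||
                       grepl("^Rblood2plasma\\.", col)) NA_real_ else NA_character_
    }
    df[all_cols]
  }
  old <- pad(old); add <- pad(add)
  data_cols <- setdiff(all_cols, c("dtxsid", grep("^ref\\.", all_cols, value = TRUE)))
  for (i in seq_len(nrow(add))) {
    id <- add$dtxsid[i]
    j <- match(id, old$dtxsid)
    if (is.na(j)) {
      j <- nrow(old) + 1L
      old[j, ] <- NA
      for (col in names(add)) old[[col]][j] <- add[[col]][i]
      for (col in data_cols)
        if (!is.na(add[[col]][i])) old <- .set_ref(old, j, col, source)
      next
    }
    for (col in data_cols) {
      nv <- add[[col]][i]
      if (is.na(nv)) next
      ov <- old[[col]][j]
      if (is.na(ov)) {
        old[[col]][j] <- nv
        old <- .set_ref(old, j, col, source)
      } else if (!identical(ov, nv)) {
        if (precedence == "overwrite") {
          old[[col]][j] <- nv
          old <- .set_ref(old, j, col, sprintf("%s (replaced previous value)", source))
        } else {
          warning(sprintf(
            "conflicting value for %s/%s kept from existing library (precedence = keep_existing)",
            id, col))
        }
      }
    }
  }
  out <- chem_library(old, sources = unique(c(lib$metadata$sources,
                                              new$metadata$sources, source)))
  out
}

.set_ref <- function(df, row, col, source) {
  refcol <- paste0("ref.", col)
  if (!refcol %in% names(df)) df[[refcol]] <- NA_character_
  df[[refcol]][row] <- source
  df
}

# Does chemical `row` of `rec` have a usable value for `field` at `species`
# (with optional human fallback)?  Returns the column used or NA.
.species_column <- function(rec, row, field, species, default_to_human) {
  if (field %in% .species_fields) {
    col <- paste(field, species, sep = ".")
    if (col %in% names(rec) && !is.na(rec[[col]][row])) return(col)
    hcol <- paste(field, "Human", sep = ".")
    if (default_to_human && hcol %in% names(rec) && !is.na(rec[[hcol]][row]))
      return(hcol)
    return(NA_character_)
  }
  if (field %in% names(rec) && !is.na(rec[[field]][row])) return(field)
  NA_character_
}

#' Retrieve a chemical parameter with provenance
#'
#' Species-specific fields (`Clint`, `fup`, `Rblood2plasma`) return the
#' species value when measured, otherwise the human value when
#' `default_to_human` is `TRUE`.  Tuple-encoded fields are parsed to
#' [uncertain_value()] objects.
#'
#' @param lib A [chem_library()].
#' @param id Chemical identifier.
#' @param field Field name (e.g. `"Clint"`, `"fup"`, `"logP"`).
#' @param species Species name matching a column suffix (default `"Human"`).
#' @param default_to_human Fall back to the human value when the species
#'   value is absent.
#' @return List with `value` and `provenance` (`"measured"`,
#'   `"human-default"`, or the column used).
#' @export
get_param <- function(lib, id, field, species = "Human",
                      default_to_human = TRUE) {
  row <- get_chem_id(lib, id)$row
  rec <- lib$records
  col <- .species_column(rec, row, field, species, default_to_human)
  if (is.na(col))
    abort(sprintf("no value for field '%s' (species %s%s) for chemical '%s'",
                  field, species,
                  if (default_to_human) ", incl. human fallback" else "", id),
          class = "pbtksim_missing_data_error")
  value <- rec[[col]][row]
  if (field %in% c("Clint", "fup"))
    value <- parse_uncertainty_tuple(value,
                                     if (field == "Clint") "clint" else "fup")
  prov <- if (!field %in% .species_fields) "measured"
          else if (endsWith(col, paste0(".", species))) species
          else "human-default"
  list(value = value, provenance = prov)
}

#' List chemicals with sufficient data for a model
#'
#' Applies the registered model's data requirements: every required field
#' must be resolvable (after the human fallback), chemicals whose fraction
#' unbound was recorded as exactly 0 are dropped when `exclude_fup_zero`,
#' chemicals more volatile than the model's Henry's-law threshold are
#' dropped, and chemicals carrying an excluded class tag (e.g. `"PFAS"`)
#' are dropped.
#'
#' @param lib A [chem_library()].
#' @param model Registered model name (default `"3compartmentss"`).
#' @param species Species for species-specific fields.
#' @param default_to_human Fall back to human in vitro values.
#' @param info Character vector of fields to return (default the identifier).
#' @param exclude_fup_zero Override of the model's own setting; when `FALSE`
#'   a recorded-zero fup is retained and flagged (`fup_defaulted` column)
#'   for default substitution downstream.
#' @return A data.frame of the requested `info` fields for eligible
#'   chemicals, plus a logical `fup_defaulted` column when fup is required.
#' @export
get_cheminfo <- function(lib, model = "3compartmentss", species = "Human",
                         default_to_human = TRUE, info = "dtxsid",
                         exclude_fup_zero = NULL) {
  stopifnot(inherits(lib, "chem_library"))
  minfo <- get_model_info(model)
  req <- minfo$data_requirements
  exclude_fup_zero <- exclude_fup_zero %||% req$exclude_fup_zero %||% FALSE
  rec <- lib$records
  valid_info <- unique(c(.string_fields, .numeric_fields, .species_fields,
                         names(rec)))
  bad <- setdiff(info, valid_info)
  if (length(bad))
    abort(sprintf("unknown info field(s): %s", paste(bad, collapse = ", ")),
          class = "pbtksim_validation_error")
  keep <- rep(TRUE, nrow(rec))
  fup_defaulted <- rep(FALSE, nrow(rec))
  for (i in seq_len(nrow(rec))) {
    for (field in req$required_params) {
      col <- .species_column(rec, i, field, species, default_to_human)
      if (is.na(col)) { keep[i] <- FALSE; break }
      if (field == "fup") {
        uv <- parse_uncertainty_tuple(rec[[col]][i], "fup")
        if (uv$point == 0) {
          if (exclude_fup_zero) keep[i] <- FALSE else fup_defaulted[i] <- TRUE
        }
      }
    }
    if (!keep[i]) next
    if (!is.null(req$log_henry_threshold) && "logHenry" %in% names(rec)) {
      lh <- rec$logHenry[i]
      if (!is.na(lh) && lh > req$log_henry_threshold) keep[i] <- FALSE
    }
    if (!keep[i]) next
    if (length(req$chem_class_filter)) {
      cc <- rec$chem_class[i]
      tags <- if (is.null(cc) || is.na(cc)) character(0)
              else trimws(strsplit(cc, ";")[[1]])
      if (length(intersect(tags, req$chem_class_filter))) keep[i] <- FALSE
    }
  }
  out <- rec[keep, intersect(info, names(rec)), drop = FALSE]
  for (f in setdiff(info, names(rec))) out[[f]] <- NA
  if ("fup" %in% req$required_params) out$fup_defaulted <- fup_defaulted[keep]
  rownames(out) <- NULL
  out
}
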