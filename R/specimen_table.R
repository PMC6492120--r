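#' Column-name schema for specimen tables
#'
#' Maps the column names of a museum-style export onto the fields a
#' [specimen_table] expects. Any metadata entry may be set to `NULL` if
#' the corresponding column does not exist in the file; `measurements`
#' left `NULL` means "every column not claimed by the metadata".
#'
#' @param specimen_id,species,sex,age_class,provenance,latitude,longitude
#'   column names in the file, or `NULL` when absent (species is
#'   mandatory and cannot be `NULL`).
#' @param measurements character vector of measurement column names, or
#'   `NULL` to take all remaining columns.
#' @return a named list of class `specimen_schema`.
#' @export
specimen_schema <- function(specimen_id = "specimen_id",
                            species = "species",
                            sex = "sex",
                            age_class = "age_class",
                            provenance = "provenance",
                            latitude = "latitude",
                            longitude = "longitude",
                            measurements = NULL) {
  if (is.null(species)) stop("a species column is required")
  structure(list(specimen_id = specimen_id, species = species, sex = sex,
                 age_class = age_class, provenance = provenance,
                 latitude = latitude, longitude = longitude,
                 measurements = measurements),
            class = "specimen_schema")
}

#' Specimen-level measurement table
#'
#' Bundles per-specimen metadata (species, sex, age class, provenance,
#' locality coordinates) with a numeric matrix of linear measurements in
#' millimetres. Measurements must be strictly positive where observed;
#' missing cells are `NA`.
#'
#' @param meta data frame with columns `specimen_id`, `species`, `sex`,
#'   `age_class`, `provenance`, `latitude`, `longitude` (the last five
#'   may contain `NA`).
#' @param measurements numeric matrix, one row per specimen, columns
#'   named by measurement variable.
#' @param check_positive enforce strict positivity of observed
#'   measurements (the invariant for raw millimetre data). Synthetic
#'   analysis-scale tables set this to `FALSE`.
#' @return an object of class `specimen_table`.
#' @export
specimen_table <- function(meta, measurements, check_positive = TRUE) {
  measurements <- as_numeric_matrix(measurements, "measurements")
  if (nrow(meta) != nrow(measurements)) {
    stop("meta and measurements must have the same number of rows")
  }
  need <- c("specimen_id", "species", "sex", "age_class", "provenance",
            "latitude", "longitude")
  for (col in setdiff(need, names(meta))) meta[[col]] <- NA
  meta <- meta[need]
  meta$specimen_id <- as.character(meta$specimen_id)
  if (anyNA(meta$specimen_id) || any(meta$specimen_id == "")) {
    meta$specimen_id <- ifelse(is.na(meta$specimen_id) | meta$specimen_id == "",
                               sprintf("spec%04d", seq_len(nrow(meta))),
                               meta$specimen_id)
  }
  meta$species <- as.character(meta$species)
  x <- structure(list(meta = meta, measurements = measurements),
                 class = "specimen_table")
  validate_specimen_table(x, check_positive = check_positive)
  x
}

validate_specimen_table <- function(x, check_positive = TRUE) {
  meta <- x$meta
  m <- x$measurements
  if (is.null(colnames(m)) || anyDuplicated(colnames(m))) {
    stop("measurement variable names must be present and unique")
  }
  if (anyNA(meta$species) || any(meta$species == "")) {
    stop("every specimen row must carry a species label")
  }
  check_tokens <- function(col, allowed) {
    v <- meta[[col]]
    bad <- !is.na(v) & !(tolower(as.character(v)) %in% allowed)
    if (any(bad)) {
      stop(sprintf("unknown %s token(s): %s (rows %s)", col,
                   paste(unique(v[bad]), collapse = ", "),
                   paste(which(bad), collapse = ", ")))
    }
  }
  check_tokens("sex", c("female", "male"))
  check_tokens("age_class", c("adult", "subadult"))
  check_tokens("provenance", c("wild", "captive", "unknown"))
  nonpos <- if (check_positive) which(!is.na(m) & m <= 0, arr.ind = TRUE)
            else matrix(integer(0), 0, 2)
  if (nrow(nonpos) > 0) {
    stop(sprintf("nonpositive measurement %s = %g in row '%s'",
                 colnames(m)[nonpos[1, 2]], m[nonpos[1, , drop = FALSE]],
                 meta$specimen_id[nonpos[1, 1]]))
  }
  lat <- meta$latitude; lon <- meta$longitude
  if (any(xor(is.na(lat), is.na(lon)))) {
    stop("latitude and longitude must be present together or absent together")
  }
  ok <- !is.na(lat)
  if (any(ok & (abs(lat) > 90))) stop("latitude outside [-90, 90]")
  if (any(ok & (abs(lon) > 180))) stop("longitude outside [-180, 180]")
  invisible(x)
}

#' Read a specimen table from CSV or TSV
#'
#' The delimiter is sniffed from the header line (tab wins over comma
#' when both occur). Empty cells and the token `NA` are treated as
#' missing measurements.
#'
#' @param path file path.
#' @param schema a [specimen_schema()] mapping file columns to fields.
#' @return a [specimen_table].
#' @export
read_specimen_table <- function(path, schema = specimen_schema()) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (lengths(regmatches(header, gregexpr("\t", header))) >=
             lengths(regmatches(header, gregexpr(",", header)))) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("", "NA"), quote = "\"",
                          comment.char = "")
  specimen_table_from_df(df, schema)
}

#' Build a specimen table from an in-memory data frame
#'
#' @param df data frame as read from a trait export.
#' @param schema a [specimen_schema()].
#' @return a [specimen_table].
#' @export
specimen_table_from_df <- function(df, schema = specimen_schema()) {
  stopifnot(inherits(schema, "specimen_schema"))
  pick <- function(field) {
    col <- schema[[field]]
    if (is.null(col)) return(rep(NA, nrow(df)))
    if (!col %in% names(df)) {
      if (field == "species") stop("missing required column: ", col)
      return(rep(NA, nrow(df)))
    }
    df[[col]]
  }
  meta <- data.frame(specimen_id = as.character(pick("specimen_id")),
                     species = as.character(pick("species")),
                     sex = pick("sex"), age_class = pick("age_class"),
                     provenance = pick("provenance"),
                     latitude = suppressWarnings(as.numeric(pick("latitude"))),
                     longitude = suppressWarnings(as.numeric(pick("longitude"))),
                     stringsAsFactors = FALSE)
  meas_cols <- schema$measurements %||%
    setdiff(names(df), unlist(schema[c("specimen_id", "species", "sex",
                                       "age_class", "provenance",
                                       "latitude", "longitude")]))
  missing_cols <- setdiff(meas_cols, names(df))
  if (length(missing_cols) > 0) {
    stop("missing measurement column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (length(meas_cols) == 0) stop("no measurement columns found")
  m <- as.matrix(df[meas_cols])
  if (!is.numeric(m)) {
    bad <- meas_cols[!vapply(df[meas_cols], is.numeric, logical(1))]
    stop("non-numeric measurement column(s): ", paste(bad, collapse = ", "))
  }
  specimen_table(meta, m)
}

#' Write a specimen table to CSV
#'
#' Missing measurements are written as empty cells; the output round-trips
#' through [read_specimen_table()].
#'
#' @param x a [specimen_table].
#' @param path output file path.
#' @export
write_specimen_table <- function(x, path) {
  stopifnot(inherits(x, "specimen_table"))
  utils::write.csv(cbind(x$meta, as.data.frame(x$measurements)),
                   path, row.names = FALSE, na = "")
  invisible(path)
}

#' @export
print.specimen_table <- function(x, ...) {
  m <- x$measurements
  cat(sprintf("specimen_table: %d specimens, %d species, %d measurements (%d missing cells)\n",
              nrow(m), length(unique(x$meta$species)), ncol(m), sum(is.na(m))))
  invisible(x)
}

#' @export
dim.specimen_table <- function(x) dim(x$measurements)
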