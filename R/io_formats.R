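# internal key helper: county-year composite key
.cy_key <- function(fips, year) paste(fips, year, sep = "|")

#' Default column-name dialect for drug-report tables
#'
#' Logical column names used by [read_drug_reports()] mapped to the
#' physical header names of NFLIS-style extracts. Any entry can be
#' overridden through the `dialect` argument.
#'
#' @return Named character vector mapping logical names (`year`, `state`,
#'   `county`, `fips`, `substance`, `dr`, `tdrc`, `tdrs`) to header names.
#' @export
default_dialect <- function() {
  c(year = "YYYY", state = "State", county = "COUNTY",
    fips = "FIPS_Combined", substance = "SubstanceName",
    dr = "DrugReports", tdrc = "TotalDrugReportsCounty",
    tdrs = "TotalDrugReportsState")
}

#' Construct and validate a drug-report panel
#'
#' A panel holds long-format county x year x substance identification
#' counts together with per-county-year and per-state-year totals. The
#' totals are carried separately because opioid substances are only a
#' subset of all drugs reported: for every county-year, the per-substance
#' counts must not exceed the county total.
#'
#' @param records data.frame with columns `fips`, `state`, `county`,
#'   `year`, `substance`, `dr` (non-negative integer counts).
#' @param tdrc data.frame with columns `fips`, `year`, `tdrc` (total
#'   county drug reports).
#' @param tdrs data.frame with columns `state`, `year`, `tdrs` (total
#'   state drug reports).
#' @return An object of class `drug_panel`.
#' @export
drug_panel <- function(records, tdrc, tdrs) {
  records$fips <- pad_fips(records$fips)
  tdrc$fips <- pad_fips(tdrc$fips)
  records$year <- as.integer(records$year)
  tdrc$year <- as.integer(tdrc$year)
  tdrs$year <- as.integer(tdrs$year)
  panel <- structure(list(records = records, tdrc = tdrc, tdrs = tdrs),
                     class = "drug_panel")
  validate_drug_panel(panel)
  panel
}

#' Zero-pad county FIPS codes to five characters
#'
#' FIPS identifiers are stored as character strings so that leading zeros
#' (e.g. Virginia's "51041") survive numeric round-trips.
#'
#' @param x vector of FIPS codes (numeric or character).
#' @return Character vector, numeric-looking values padded to width 5.
#' @export
pad_fips <- function(x) {
  x <- as.character(x)
  num <- grepl("^[0-9]+$", x)
  x[num] <- gsub(" ", "0", formatC(x[num], width = 5))
  x
}

#' Validate drug-panel invariants
#'
#' Checks that counts are non-negative, that no (fips, year, substance)
#' key is duplicated, that substance counts never exceed the county total,
#' and that the years form a contiguous range.
#'
#' @param panel a `drug_panel`.
#' @return The panel, invisibly; stops with a descriptive error otherwise.
#' @export
validate_drug_panel <- function(panel) {
  rec <- panel$records
  need <- c("fips", "state", "county", "year", "substance", "dr")
  miss <- setdiff(need, names(rec))
  if (length(miss) > 0)
    stop("drug panel records missing column(s): ", paste(miss, collapse = ", "))
  bad <- which(!is.finite(rec$dr) | rec$dr < 0)
  if (length(bad) > 0)
    stop("negative or non-finite drug-report count at record row ", bad[1])
  if (any(!is.finite(panel$tdrc$tdrc) | panel$tdrc$tdrc < 0))
    stop("negative or non-finite total county drug reports")
  key <- paste(rec$fips, rec$year, rec$substance, sep = "|")
  if (anyDuplicated(key))
    stop("duplicated (fips, year, substance) key: ", key[which(duplicated(key))[1]])
  yrs <- sort(unique(c(rec$year, panel$tdrc$year)))
  if (length(yrs) > 1 && !identical(yrs, seq(min(yrs), max(yrs))))
    stop("years do not form a contiguous range: ", paste(yrs, collapse = ", "))
  # per county-year, sum over substances must not exceed the county total
  sums <- tapply(rec$dr, .cy_key(rec$fips, rec$year), sum)
  tot <- stats::setNames(panel$tdrc$tdrc, .cy_key(panel$tdrc$fips, panel$tdrc$year))
  common <- intersect(names(sums), names(tot))
  over <- common[sums[common] > tot[common] + 1e-9]
  if (length(over) > 0)
    stop("substance counts exceed total county drug reports for county-year ",
         over[1])
  invisible(panel)
}

#' Read a drug-report table
#'
#' Parses a delimited NFLIS-style text file into a validated
#' [drug_panel()]. Physical column names are remappable via `dialect`;
#' rows with zero drug reports are retained.
#'
#' @param path path to a delimited text file with a header row.
#' @param dialect named character vector overriding entries of
#'   [default_dialect()].
#' @param sep field separator, default comma.
#' @return A `drug_panel`.
#' @export
read_drug_reports <- function(path, dialect = default_dialect(), sep = ",") {
  d <- default_dialect()
  d[names(dialect)] <- dialect
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE)
  miss <- d[!(d %in% names(raw))]
  if (length(miss) > 0)
    stop("input file is missing required column(s): ",
         paste(miss, collapse = ", "))
  records <- data.frame(
    fips = pad_fips(raw[[d["fips"]]]),
    state = raw[[d["state"]]],
    county = raw[[d["county"]]],
    year = as.integer(raw[[d["year"]]]),
    substance = raw[[d["substance"]]],
    dr = as.numeric(raw[[d["dr"]]]),
    stringsAsFactors = FALSE)
  tdrc <- unique(data.frame(
    fips = records$fips, year = records$year,
    tdrc = as.numeric(raw[[d["tdrc"]]]), stringsAsFactors = FALSE))
  if (anyDuplicated(.cy_key(tdrc$fips, tdrc$year)))
    stop("inconsistent total county drug reports within a county-year")
  tdrs <- unique(data.frame(
    state = records$state, year = records$year,
    tdrs = as.numeric(raw[[d["tdrs"]]]), stringsAsFactors = FALSE))
  if (anyDuplicated(paste(tdrs$state, tdrs$year)))
    stop("inconsistent total state drug reports within a state-year")
  drug_panel(records, tdrc, tdrs)
}

#' Read a county-coordinate table
#'
#' @param path delimited text with header columns `fips`, `lat`, `lon`
#'   (degrees).
#' @return data.frame of class `county_geo` with one row per county.
#' @export
read_geo <- function(path) {
  g <- utils::read.csv(path, colClasses = c(fips = "character"))
  county_geo(g$fips, g$lat, g$lon)
}

#' Construct a county-coordinate table
#'
#' @param fips county identifiers.
#' @param lat,lon centroid coordinates in degrees.
#' @return data.frame of class `county_geo`.
#' @export
county_geo <- function(fips, lat, lon) {
  fips <- pad_fips(fips)
  if (anyDuplicated(fips)) stop("duplicated county in coordinate table")
  if (any(lat < -90 | lat > 90)) stop("latitude outside [-90, 90]")
  if (any(lon < -180 | lon > 180)) stop("longitude outside [-180, 180]")
  structure(data.frame(fips = fips, lat = lat, lon = lon,
                       stringsAsFactors = FALSE),
            class = c("county_geo", "data.frame"))
}

#' Construct a census table of percent-valued demographic variables
#'
#' @param values numeric matrix, counties (rows, rownames = FIPS) x
#'   variable codes (columns). `NA` cells are treated as missing.
#' @return An object of class `census_table` (list with `values` matrix
#'   and `missing` logical matrix).
#' @export
census_table <- function(values) {
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("census table needs FIPS rownames and variable-code colnames")
  if (anyDuplicated(colnames(values))) stop("duplicated census variable code")
  rownames(values) <- pad_fips(rownames(values))
  out <- any(values < 0 | values > 100, na.rm = TRUE)
  if (out) warning("census values outside [0, 100] retained")
  structure(list(values = values, missing = is.na(values)),
            class = "census_table")
}

#' Read a census demographic table
#'
#' One row per county; the first column holds the county FIPS and the
#' remaining columns hold percent values under ACS-style variable codes.
#' Unparseable cells are flagged missing; values outside \[0, 100\] raise
#' a warning but are retained.
#'
#' @param path delimited text file with header.
#' @return A `census_table`.
#' @export
read_census <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  if (anyDuplicated(names(raw))) stop("duplicated census variable code")
  fips <- pad_fips(raw[[1]])
  vals <- as.matrix(raw[, -1, drop = FALSE])
  m <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals),
                               dimnames = list(fips, colnames(vals))))
  census_table(m)
}

#' Impute missing census cells with column means
#'
#' Each missing cell is replaced by the arithmetic mean of the non-missing
#' values in its column (imputation is per variable, across counties).
#' The operation is idempotent and leaves each column mean unchanged.
#'
#' @param table a `census_table`.
#' @return A `census_table` with no missing cells.
#' @export
impute_missing <- function(table) {
  stopifnot(inherits(table, "census_table"))
  v <- table$values
  for (j in seq_len(ncol(v))) {
    isna <- is.na(v[, j])
    if (all(isna))
      stop("census column '", colnames(v)[j], "' has no observed values")
    if (any(isna)) v[isna, j] <- mean(v[!isna, j])
  }
  census_table(v)
}

#' Write a pipeline output table to delimited text
#'
#' Writes any of the pipeline's tabular outputs (indicator tables,
#' evaluation results, forecasts, scenario trajectories) as CSV with a
#' stable column order. Numeric fields round-trip through [read_results()]
#' to better than 1e-10.
#'
#' @param result a data.frame-like pipeline output.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_results <- function(result, path) {
  df <- as.data.frame(result)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read back a table written by [write_results()]
#'
#' @param path file path.
#' @return data.frame; a `fips` column, if present, is restored as a
#'   zero-padded string.
#' @export
read_results <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE,
                        stringsAsFactors = FALSE)
  if ("fips" %in% names(df)) df$fips <- pad_fips(df$fips)
  df
}

# opioid substance totals per county-year, as a data.frame(fips, year, opioid)
.opioid_by_county_year <- function(panel, opioid_set) {
  rec <- panel$records
  op <- rec[rec$substance %in% opioid_set, , drop = FALSE]
  key <- .cy_key(panel$tdrc$fips, panel$tdrc$year)
  tot <- stats::setNames(rep(0, length(key)), key)
  if (nrow(op) > 0) {
    s <- tapply(op$dr, .cy_key(op$fips, op$year), sum)
    tot[names(s)] <- s
  }
  data.frame(fips = panel$tdrc$fips, year = panel$tdrc$year,
             opioid = as.numeric(tot), stringsAsFactors = FALSE)
}
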