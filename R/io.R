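#' Column-mapping dialect for localization tables
#'
#' Describes how coordinate (and optional extra) columns of a CSV/TSV
#' localization table map onto nanometer coordinates.  Two presets cover
#' the dominant community formats: `"default"` (columns `x`, `y`, optional
#' `z`, already in nm, comma-separated) and `"thunderstorm"` (ThunderSTORM
#' export headers `"x [nm]"`, `"y [nm]"`, `"z [nm]"`).
#'
#' @param preset `"default"` or `"thunderstorm"`, used as a starting point.
#' @param x,y,z Column names holding the coordinates; `z = NA` for 2D data.
#' @param unit `"nm"` or `"um"` -- micrometer input is converted to nm.
#' @param sep Field separator.
#' @param extras Character vector of additional columns to carry along.
#' @return A named list with class `"locDialect"`.
#' @export
#' @examples
#' locDialect()
#' locDialect("thunderstorm")
#' locDialect(x = "X_nm", y = "Y_nm", z = NA, unit = "um")
locDialect <- function(preset = c("default", "thunderstorm"), x = NULL,
                       y = NULL, z = NULL, unit = NULL, sep = NULL,
                       extras = NULL) {
  preset <- match.arg(preset)
  d <- switch(preset,
    default = list(x = "x", y = "y", z = "z", unit = "nm", sep = ",",
                   extras = character()),
    thunderstorm = list(x = "x [nm]", y = "y [nm]", z = "z [nm]", unit = "nm",
                        sep = ",", extras = character()))
  if (!is.null(x)) d$x <- x
  if (!is.null(y)) d$y <- y
  if (!missing(z)) d$z <- z
  if (!is.null(unit)) d$unit <- match.arg(unit, c("nm", "um"))
  if (!is.null(sep)) d$sep <- sep
  if (!is.null(extras)) d$extras <- extras
  structure(d, class = "locDialect")
}

#' Read a localization table
#'
#' Reads a CSV/TSV table with one row per localization, maps the coordinate
#' columns named by the dialect, converts micrometers to nanometers when
#' required, and returns a [LocalizationSet-class] with the tight bounding
#' box of the data (unless `bounds` overrides it).  Row order is preserved
#' and exact duplicate positions are retained; the tessellation stage
#' decides their handling.
#'
#' @param path Path to an existing file.
#' @param dialect A [locDialect()].
#' @param bounds Optional explicit bounding box (must contain the data).
#' @return A [LocalizationSet-class].
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write.csv(data.frame(x = 1:3, y = 4:6, z = 7:9), f, row.names = FALSE)
#' readLocalizations(f)
readLocalizations <- function(path, dialect = locDialect(), bounds = NULL) {
  vcAssert(file.exists(path), sprintf("file not found: %s", path), "io")
  tab <- tryCatch(
    read.csv(path, sep = dialect$sep, check.names = FALSE,
             stringsAsFactors = FALSE),
    error = function(e) vcStop(sprintf("cannot parse %s: %s", path,
                                       conditionMessage(e)), "format"))
  vcAssert(nrow(tab) >= 1L, sprintf("no localizations in %s", path),
           "empty_input")
  wanted <- c(dialect$x, dialect$y)
  if (!is.null(dialect$z) && !is.na(dialect$z) && dialect$z %in% names(tab))
    wanted <- c(wanted, dialect$z)
  missing_cols <- setdiff(c(dialect$x, dialect$y), names(tab))
  if (length(missing_cols))
    vcStop(sprintf("missing coordinate column(s): %s",
                   paste(missing_cols, collapse = ", ")), "format")
  co <- as.matrix(tab[, wanted, drop = FALSE])
  suppressWarnings(storage.mode(co) <- "double")
  if (anyNA(co)) {
    bad <- which(rowSums(is.na(co)) > 0L)[1L]
    vcStop(sprintf("non-numeric coordinate at row %d of %s", bad, path),
           "parse")
  }
  vcAssert(all(is.finite(co)), "non-finite coordinate value", "parse")
  if (dialect$unit == "um") co <- co * 1000
  ex <- intersect(dialect$extras, names(tab))
  extras <- if (length(ex)) tab[, ex, drop = FALSE] else NULL
  LocalizationSet(co, bounds = bounds, extras = extras)
}

#' Write a localization table
#'
#' Writes the coordinates (columns `x`, `y`, optionally `z`, in nm) followed
#' by any extras columns in their declared order, as a comma-separated file
#' with header and full double precision, so that a write/read round trip
#' reproduces the coordinates bit for bit.
#'
#' @param locs A [LocalizationSet-class].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeLocalizations <- function(locs, path) {
  stopifnot(is(locs, "LocalizationSet"))
  df <- as.data.frame(locCoords(locs))
  if (ncol(locExtras(locs)) > 0L) df <- cbind(df, locExtras(locs))
  ok <- tryCatch(suppressWarnings({
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste(colnames(df), collapse = ","), con)
    cols <- lapply(df, function(col) {
      if (is.double(col)) sprintf("%.17g", col) else as.character(col)
    })
    writeLines(do.call(paste, c(cols, sep = ",")), con)
    TRUE
  }), error = function(e) FALSE)
  if (!ok) vcStop(sprintf("cannot write %s", path), "io")
  invisible(path)
}
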