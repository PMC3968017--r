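# Plate time-series container and reader-export parsing.
#
# Two plain-text dialects are supported (comma or tab, autodetected):
#   wide: first column = time in minutes, remaining columns = well addresses
#   long: columns well, time_min, od411
# Both describe the same rectangular grid: one OD reading per (well, time).

WELL_RE <- "^[A-H](1[0-2]|[1-9])$"

normalize_well <- function(x) {
  x <- toupper(trimws(as.character(x)))
  bad <- x[!grepl(WELL_RE, x)]
  if (length(bad) > 0) {
    stop_parse(sprintf("invalid well address '%s' (expected A1..H12)", bad[[1]]))
  }
  x
}

# canonical plate order: row letter, then column number
order_wells <- function(wells) {
  wells[order(substr(wells, 1, 1), as.integer(substring(wells, 2)))]
}

#' Construct a plate time series
#'
#' A rectangular grid of 411 nm absorbance readings: every well has one
#' reading at every time point. Negative OD values are permitted (blanked
#' exports) but counted and reported.
#'
#' @param absorbance Numeric matrix, rows = wells (rownames are well
#'   addresses, e.g. "A1"), columns = time points.
#' @param times Numeric vector of minutes from start, strictly increasing,
#'   non-negative; length must equal `ncol(absorbance)`.
#' @param plate_id Text label for the plate.
#' @param pathlength_corrected Logical; `TRUE` if absorbance is already
#'   standardised to a 1 cm optical path.
#' @return An object of class `plate_ts`.
#' @seealso [read_plate_timeseries()], [apply_pathlength_correction()]
#' @export
plate_timeseries <- function(absorbance, times, plate_id = "plate",
                             pathlength_corrected = FALSE) {
  if (!is.matrix(absorbance) || !is.numeric(absorbance)) {
    stop_parse("absorbance must be a numeric matrix (wells x times)")
  }
  if (is.null(rownames(absorbance))) {
    stop_parse("absorbance matrix needs well addresses as rownames")
  }
  times <- as.numeric(times)
  if (length(times) != ncol(absorbance)) {
    stop_parse("length(times) must equal ncol(absorbance)")
  }
  if (any(!is.finite(times)) || any(times < 0)) {
    stop_parse("times must be finite and non-negative")
  }
  if (is.unsorted(times, strictly = TRUE)) {
    stop_parse("times must be strictly increasing")
  }
  wells <- normalize_well(rownames(absorbance))
  if (anyDuplicated(wells)) {
    stop_parse(sprintf("duplicate well '%s'", wells[duplicated(wells)][[1]]))
  }
  rownames(absorbance) <- wells
  if (any(!is.finite(absorbance))) {
    bad <- which(!is.finite(absorbance), arr.ind = TRUE)[1, ]
    stop_parse(sprintf("non-finite absorbance at well %s, time %g",
                       wells[bad[["row"]]], times[bad[["col"]]]))
  }
  ord <- order_wells(wells)
  absorbance <- absorbance[ord, , drop = FALSE]
  structure(
    list(plate_id = as.character(plate_id),
         times = times,
         wells = rownames(absorbance),
         absorbance = absorbance,
         pathlength_corrected = isTRUE(pathlength_corrected),
         n_negative = sum(absorbance < 0)),
    class = "plate_ts"
  )
}

#' @export
print.plate_ts <- function(x, ...) {
  cat(sprintf("<plate_ts> %s: %d wells x %d reads, t = %g..%g min\n",
              x$plate_id, length(x$wells), length(x$times),
              min(x$times), max(x$times)))
  cat(sprintf("  OD range [%.4g, %.4g]; path-length corrected: %s",
              min(x$absorbance), max(x$absorbance),
              if (x$pathlength_corrected) "yes" else "no"))
  if (x$n_negative > 0) {
    cat(sprintf("; %d negative readings (blanked export?)", x$n_negative))
  }
  cat("\n")
  invisible(x)
}

#' Long-format view of a plate time series
#'
#' @param series A `plate_ts`.
#' @return A tibble with columns `well`, `time_min`, `od411`, ordered by
#'   well (plate order) then time.
#' @export
plate_to_long <- function(series) {
  stopifnot(inherits(series, "plate_ts"))
  tibble::tibble(
    well = rep(series$wells, each = length(series$times)),
    time_min = rep(series$times, times = length(series$wells)),
    od411 = as.vector(t(series$absorbance))
  )
}

#' Read a plate-reader kinetic export
#'
#' Parses a delimited text export (separator autodetected) in either dialect
#' into a validated [plate_timeseries()]. The grid must be rectangular:
#' every well read at every time point. Duplicate `(well, time)` rows and
#' missing cells are errors.
#'
#' @param path Path to the export file.
#' @param dialect `"wide"` (first column time in minutes, remaining columns
#'   wells) or `"long"` (columns `well`, `time_min`, `od411`).
#' @param plate_id Plate label; defaults to the file name without extension.
#' @param pathlength_corrected Whether the export is already standardised to
#'   a 1 cm path (the usual case when the reader applies its own correction).
#' @param quiet Suppress the parsed-plate summary message.
#' @return A `plate_ts`.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("well\ttime_min\tod411",
#'              "A1\t0\t0.5", "A1\t1\t0.5",
#'              "A2\t0\t0.5", "A2\t1\t0.5"), f)
#' read_plate_timeseries(f, dialect = "long", quiet = TRUE)
#' @export
read_plate_timeseries <- function(path, dialect = c("wide", "long"),
                                  plate_id = NULL,
                                  pathlength_corrected = TRUE,
                                  quiet = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_parse(sprintf("file not found: %s", path))
  if (is.null(plate_id)) plate_id <- sub("\\.[^.]*$", "", basename(path))
  dt <- data.table::fread(path, data.table = FALSE, na.strings = NULL)
  if (nrow(dt) == 0) stop_parse(sprintf("empty plate file: %s", path))

  long <- switch(dialect,
    wide = parse_wide(dt),
    long = parse_long(dt)
  )

  # rectangularity: every well at every time, no duplicates
  wells <- order_wells(unique(long$well))
  times <- sort(unique(long$time_min))
  key <- paste(long$well, long$time_min)
  if (anyDuplicated(key)) {
    d <- long[duplicated(key), ][1, ]
    stop_parse(sprintf("duplicate reading for well %s at time %g",
                       d$well, d$time_min))
  }
  if (nrow(long) != length(wells) * length(times)) {
    full <- paste(rep(wells, each = length(times)),
                  rep(times, times = length(wells)))
    miss <- setdiff(full, key)[[1]]
    ms <- strsplit(miss, " ", fixed = TRUE)[[1]]
    stop_parse(sprintf(
      "ragged grid: well %s has no reading at time %s min", ms[1], ms[2]))
  }

  m <- matrix(NA_real_, nrow = length(wells), ncol = length(times),
              dimnames = list(wells, NULL))
  m[cbind(match(long$well, wells), match(long$time_min, times))] <- long$od411
  out <- plate_timeseries(m, times, plate_id = plate_id,
                          pathlength_corrected = pathlength_corrected)
  if (!quiet) {
    message(sprintf(
      "parsed plate '%s': %d wells, %d reads spanning %g-%g min, OD [%.4g, %.4g]%s",
      out$plate_id, length(out$wells), length(out$times),
      min(out$times), max(out$times), min(out$absorbance), max(out$absorbance),
      if (out$n_negative > 0)
        sprintf(" (%d negative readings)", out$n_negative) else ""))
  }
  out
}

parse_numeric_col <- function(x, what) {
  if (is.numeric(x)) return(as.numeric(x))
  y <- suppressWarnings(as.numeric(x))
  if (any(is.na(y))) {
    row <- which(is.na(y))[[1]]
    stop_parse(sprintf("non-numeric %s '%s' at data row %d", what, x[row], row))
  }
  y
}

parse_wide <- function(dt) {
  if (ncol(dt) < 2) stop_parse("wide dialect needs a time column plus wells")
  time <- parse_numeric_col(dt[[1]], "time value")
  wells <- normalize_well(names(dt)[-1])
  od <- lapply(seq_along(wells), function(j) {
    parse_numeric_col(dt[[j + 1]], sprintf("OD value in column %s", wells[j]))
  })
  data.frame(
    well = rep(wells, each = nrow(dt)),
    time_min = rep(time, times = length(wells)),
    od411 = unlist(od),
    stringsAsFactors = FALSE
  )
}

parse_long <- function(dt) {
  need <- c("well", "time_min", "od411")
  if (!all(need %in% names(dt))) {
    stop_parse(sprintf("long dialect needs columns %s; found %s",
                       paste(need, collapse = ", "),
                       paste(names(dt), collapse = ", ")))
  }
  data.frame(
    well = normalize_well(dt$well),
    time_min = parse_numeric_col(dt$time_min, "time value"),
    od411 = parse_numeric_col(dt$od411, "OD value"),
    stringsAsFactors = FALSE
  )
}

#' Write a plate time series
#'
#' Serialises at full double precision (17 significant digits) so a
#' write-then-read round trip reproduces every value bit-for-bit.
#'
#' @param series A `plate_ts`.
#' @param path Output path.
#' @param dialect `"wide"` or `"long"`.
#' @param sep Field separator (default tab).
#' @return `path`, invisibly.
#' @export
write_plate_timeseries <- function(series, path, dialect = c("wide", "long"),
                                   sep = "\t") {
  stopifnot(inherits(series, "plate_ts"))
  dialect <- match.arg(dialect)
  fmt <- function(x) formatC(x, digits = 17, format = "g")
  lines <- if (dialect == "wide") {
    header <- paste(c("time_min", series$wells), collapse = sep)
    rows <- vapply(seq_along(series$times), function(j) {
      paste(c(fmt(series$times[j]), fmt(series$absorbance[, j])),
            collapse = sep)
    }, character(1))
    c(header, rows)
  } else {
    long <- plate_to_long(series)
    c(paste(c("well", "time_min", "od411"), collapse = sep),
      paste(long$well, fmt(long$time_min), fmt(long$od411), sep = sep))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Standardise absorbance to a 1 cm optical path
#'
#' Divides every OD reading by its path length. Most plate readers apply
#' this internally; use only on uncorrected exports. Calling it twice on the
#' same series is an error.
#'
#' @param series A `plate_ts` with `pathlength_corrected = FALSE`.
#' @param factor Path length in cm: a positive scalar, or a named numeric
#'   vector giving one path length per well.
#' @return The corrected `plate_ts` with `pathlength_corrected = TRUE`.
#' @export
apply_pathlength_correction <- function(series, factor) {
  stopifnot(inherits(series, "plate_ts"))
  if (series$pathlength_corrected) {
    stop_state("series is already path-length corrected")
  }
  if (!is.numeric(factor) || any(!is.finite(factor)) || any(factor <= 0)) {
    stop_domain("path-length factor must be finite and > 0")
  }
  if (length(factor) == 1 && is.null(names(factor))) {
    series$absorbance <- series$absorbance / factor
  } else {
    if (is.null(names(factor)) ||
        !setequal(normalize_well(names(factor)), series$wells)) {
      stop_domain("per-well factor must be named with every well address")
    }
    names(factor) <- normalize_well(names(factor))
    series$absorbance <- series$absorbance / factor[series$wells]
  }
  series$pathlength_corrected <- TRUE
  series$n_negative <- sum(series$absorbance < 0)
  series
}
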