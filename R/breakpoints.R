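# Piecewise-linear air-quality index conversion (AQI and WAQA) and the
# EPA NowCast hourly aggregate.
#
# Both indices map PM2.5 concentration bands to index-value bands; within a
# band the index is linear in concentration. Washington's WAQA uses lower
# PM2.5 cut-points than the federal AQI for the same index values, which is
# why the state's "encouraged" rule threshold of 20.5 µg/m³ reads WAQA 101
# but only AQI 69.

# Printed equivalences every table for a scheme must reproduce; a user table
# that fails one of these is rejected at load.
scheme_anchors <- list(
  AQI  = data.frame(pm25 = c(20.5, 35.5, 55.5), index = c(69L, 101L, 151L)),
  WAQA = data.frame(pm25 = c(20.5, 55.5), index = c(101L, 173L))
)

#' Construct and validate a breakpoint table
#'
#' A breakpoint table is an ordered set of contiguous concentration bands,
#' each mapped to a contiguous index-value band with a level-of-concern
#' label. Validation enforces the structural invariants (bands contiguous at
#' 0.1 µg/m³ granularity, index ranges contiguous, first band starting at
#' concentration 0 and index 0, monotone mapping) and, for the `"AQI"` and
#' `"WAQA"` schemes, checks the table against the published rule-threshold
#' equivalences (e.g. 20.5 µg/m³ -> AQI 69, WAQA 101; 55.5 µg/m³ ->
#' AQI 151, WAQA 173): a table that contradicts one is rejected.
#'
#' @param scheme `"AQI"` or `"WAQA"`.
#' @param bands data frame with columns `conc_lo`, `conc_hi` (µg/m³ at 0.1
#'   precision), `index_lo`, `index_hi` (integers), `label` (level of
#'   concern, e.g. `"good"`, `"unhealthy for sensitive groups"`).
#' @param check_anchors check the printed equivalences for known schemes
#'   (default `TRUE`).
#' @return an object of class `breakpoint_table`.
#' @seealso [default_breakpoints()], [concentration_to_index()]
#' @export
breakpoint_table <- function(scheme, bands, check_anchors = TRUE) {
  scheme <- match.arg(toupper(scheme), c("AQI", "WAQA"))
  required <- c("conc_lo", "conc_hi", "index_lo", "index_hi", "label")
  missing_cols <- setdiff(required, names(bands))
  if (length(missing_cols)) {
    stop("bands is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  bands <- tibble::as_tibble(bands)[required]
  bands$index_lo <- as.integer(bands$index_lo)
  bands$index_hi <- as.integer(bands$index_hi)

  if (nrow(bands) < 1) stop("breakpoint table needs at least one band")
  if (any(bands$conc_lo > bands$conc_hi)) stop("conc_lo > conc_hi in some band")
  if (any(bands$index_lo > bands$index_hi)) stop("index_lo > index_hi in some band")
  if (abs(bands$conc_lo[1]) > 1e-9 || bands$index_lo[1] != 0L) {
    stop("first band must start at concentration 0.0 and index 0")
  }
  n <- nrow(bands)
  if (n > 1) {
    conc_gap <- bands$conc_lo[-1] - bands$conc_hi[-n]
    if (any(abs(conc_gap - 0.1) > 1e-9)) {
      stop("concentration bands must be contiguous at 0.1 µg/m³ granularity")
    }
    if (any(bands$index_lo[-1] != bands$index_hi[-n] + 1L)) {
      stop("index ranges of successive bands must be contiguous")
    }
  }

  tbl <- structure(list(scheme = scheme, bands = bands), class = "breakpoint_table")

  if (check_anchors && scheme %in% names(scheme_anchors)) {
    anchors <- scheme_anchors[[scheme]]
    got <- concentration_to_index(anchors$pm25, tbl)
    bad <- got != anchors$index
    if (any(bad)) {
      stop(
        scheme, " table rejected: fails published anchor(s) ",
        paste(sprintf("%.1f µg/m³ -> %d (got %d)",
                      anchors$pm25[bad], anchors$index[bad], got[bad]),
              collapse = "; ")
      )
    }
  }
  tbl
}

#' @export
print.breakpoint_table <- function(x, ...) {
  cat("<breakpoint_table>", x$scheme, "with", nrow(x$bands), "bands\n")
  print(x$bands)
  invisible(x)
}

#' Default PM2.5 breakpoint tables
#'
#' Ships the pre-2024 federal AQI PM2.5 breakpoints (the table in force over
#' the 2011-2020 study window) and the Washington Air Quality Advisory
#' (WAQA) PM2.5 breakpoints. Both reproduce the rule-threshold equivalences
#' used by Washington's emergency wildfire-smoke rule. Users with a
#' different advisory table can load their own with [read_breakpoints()].
#'
#' @param scheme `"AQI"` or `"WAQA"`.
#' @return a [breakpoint_table()].
#' @examples
#' concentration_to_index(20.5, default_breakpoints("AQI")) # 69
#' @export
default_breakpoints <- function(scheme = c("AQI", "WAQA")) {
  scheme <- match.arg(toupper(scheme[1]), c("AQI", "WAQA"))
  bands <- if (scheme == "AQI") {
    tibble::tribble(
      ~conc_lo, ~conc_hi, ~index_lo, ~index_hi, ~label,
      0.0,   12.0,     0L,  50L, "good",
      12.1,  35.4,    51L, 100L, "moderate",
      35.5,  55.4,   101L, 150L, "unhealthy for sensitive groups",
      55.5,  150.4,  151L, 200L, "unhealthy",
      150.5, 250.4,  201L, 300L, "very unhealthy",
      250.5, 350.4,  301L, 400L, "hazardous",
      350.5, 500.4,  401L, 500L, "hazardous"
    )
  } else {
    tibble::tribble(
      ~conc_lo, ~conc_hi, ~index_lo, ~index_hi, ~label,
      0.0,   12.0,     0L,  50L, "good",
      12.1,  20.4,    51L, 100L, "moderate",
      20.5,  35.4,   101L, 150L, "unhealthy for sensitive groups",
      35.5,  80.4,   151L, 200L, "unhealthy",
      80.5,  140.4,  201L, 300L, "very unhealthy",
      140.5, 250.4,  301L, 500L, "hazardous"
    )
  }
  breakpoint_table(scheme, bands)
}

#' Read breakpoint tables from a plain-text configuration file
#'
#' The format is line-oriented: a block starts with `scheme: <name>` and is
#' followed by one comma-separated row per band
#' (`conc_lo,conc_hi,index_lo,index_hi,label`). Blank lines and lines
#' starting with `#` are ignored. Every parsed table passes full validation,
#' including the published anchor checks for known schemes.
#'
#' @param path file path.
#' @return named list of [breakpoint_table()] objects, one per block.
#' @export
read_breakpoints <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  scheme <- NULL
  rows <- list()
  flush <- function() {
    if (is.null(scheme)) return()
    if (!length(rows)) stop("scheme block '", scheme, "' has no band rows")
    bands <- do.call(rbind, rows)
    out[[scheme]] <<- breakpoint_table(scheme, bands)
  }
  for (ln in lines) {
    if (grepl("^scheme\\s*:", ln)) {
      flush()
      scheme <- toupper(trimws(sub("^scheme\\s*:", "", ln)))
      rows <- list()
    } else {
      if (is.null(scheme)) stop("band row before any 'scheme:' header: ", ln)
      parts <- trimws(strsplit(ln, ",")[[1]])
      if (length(parts) != 5) stop("expected 5 comma-separated fields: ", ln)
      rows[[length(rows) + 1]] <- data.frame(
        conc_lo = as.numeric(parts[1]), conc_hi = as.numeric(parts[2]),
        index_lo = as.integer(parts[3]), index_hi = as.integer(parts[4]),
        label = parts[5], stringsAsFactors = FALSE
      )
    }
  }
  flush()
  out
}

#' Convert PM2.5 concentration to an index value
#'
#' Truncates the concentration to 0.1 µg/m³, locates the containing band and
#' interpolates linearly:
#' `index = index_lo + (index_hi - index_lo) / (conc_hi - conc_lo) * (c - conc_lo)`,
#' rounded half-up to the nearest integer. Concentrations above the table's
#' top band saturate at the maximum index with a warning (extreme smoke
#' events can exceed the tabulated range).
#'
#' @param pm25 numeric vector of concentrations in µg/m³ (>= 0).
#' @param table a [breakpoint_table()].
#' @return integer vector of index values.
#' @examples
#' concentration_to_index(55.5, default_breakpoints("WAQA")) # 173
#' @export
concentration_to_index <- function(pm25, table) {
  stopifnot(inherits(table, "breakpoint_table"))
  conc <- truncate_concentration(pm25)
  bands <- table$bands
  top <- bands$conc_hi[nrow(bands)]
  sat <- conc > top + 1e-9
  if (any(sat)) {
    warning(sum(sat), " concentration(s) above the top band (",
            top, " µg/m³); index saturated at ",
            bands$index_hi[nrow(bands)])
    conc[sat] <- top
  }
  # band lookup on the truncated 0.1 grid
  idx <- findInterval(conc + 1e-9, bands$conc_lo)
  lo_c <- bands$conc_lo[idx]; hi_c <- bands$conc_hi[idx]
  lo_i <- bands$index_lo[idx]; hi_i <- bands$index_hi[idx]
  frac <- ifelse(hi_c > lo_c, (conc - lo_c) / (hi_c - lo_c), 0)
  as.integer(round_half_up(lo_i + (hi_i - lo_i) * frac))
}

#' Minimum concentration reaching a given index value
#'
#' The inverse mapping used to express rule thresholds as concentrations:
#' the smallest concentration on the 0.1 µg/m³ grid whose index value is at
#' least `index`. Round trip: `concentration_to_index(result) >= index`, and
#' one grid step lower falls below `index`.
#'
#' @param index integer index value within the table's range.
#' @param table a [breakpoint_table()].
#' @return concentration in µg/m³ at 0.1 precision.
#' @examples
#' index_to_min_concentration(151, default_breakpoints("AQI")) # 55.5
#' @export
index_to_min_concentration <- function(index, table) {
  stopifnot(inherits(table, "breakpoint_table"))
  bands <- table$bands
  max_index <- bands$index_hi[nrow(bands)]
  if (any(index < 0 | index > max_index)) {
    stop("index out of table range [0, ", max_index, "]")
  }
  vapply(as.integer(index), function(i) {
    if (i == 0L) return(0.0)
    b <- which(bands$index_lo <= i & i <= bands$index_hi)[1]
    # analytic inverse, then walk the 0.1 grid to the exact minimum
    # (rounding makes the analytic point off by at most one grid step)
    span_i <- bands$index_hi[b] - bands$index_lo[b]
    span_c <- bands$conc_hi[b] - bands$conc_lo[b]
    guess <- bands$conc_lo[b] +
      if (span_i > 0) (i - bands$index_lo[b]) / span_i * span_c else 0
    c0 <- truncate_concentration(max(guess, 0))
    # walk down to the last grid point still reaching i, then up if short
    while (c0 > 0 &&
           concentration_to_index(round(c0 - 0.1, 1), table) >= i) {
      c0 <- round(c0 - 0.1, 1)
    }
    while (concentration_to_index(c0, table) < i) {
      c0 <- round(c0 + 0.1, 1)
    }
    c0
  }, numeric(1))
}

#' Level-of-concern label for an index value
#'
#' @param index integer index value within the table's range.
#' @param table a [breakpoint_table()].
#' @return character vector of labels (e.g. `"good"`, `"moderate"`,
#'   `"unhealthy"`).
#' @export
category_label <- function(index, table) {
  stopifnot(inherits(table, "breakpoint_table"))
  bands <- table$bands
  index <- as.integer(index)
  max_index <- bands$index_hi[nrow(bands)]
  if (any(is.na(index)) || any(index < 0 | index > max_index)) {
    stop("index out of table range [0, ", max_index, "]")
  }
  band <- findInterval(index, bands$index_lo)
  bands$label[band]
}

#' EPA NowCast of recent hourly PM2.5 concentrations
#'
#' The NowCast is the EPA's weighted average of up to 12 recent hourly
#' concentrations used to report "current" air quality. The weight factor
#' shrinks toward its floor of 0.5 as hourly variability grows:
#' `w = max(1 - (max - min)/max, 0.5)` over the hours present, and the
#' result is `sum(w^i * c_i) / sum(w^i)` for hour lags `i = 0..11`
#' (`i = 0` newest), truncated to 0.1 µg/m³. Following the EPA convention,
#' the result is missing unless at least 2 of the 3 most recent hours are
#' present.
#'
#' The retrospective analysis pipeline uses calendar-day means, not the
#' NowCast; this function covers rules worded in terms of current NowCast
#' AQI when hourly data are at hand.
#'
#' @param hours numeric vector of up to 12 hourly concentrations in µg/m³,
#'   ordered newest first; `NA` marks a missing hour.
#' @return the NowCast concentration in µg/m³, or `NA` if the recency
#'   requirement is not met.
#' @examples
#' nowcast(c(10, 20, 30)) # 15.7
#' @export
nowcast <- function(hours) {
  if (length(hours) > 12) stop("at most 12 hourly values allowed")
  if (any(hours < 0, na.rm = TRUE)) stop("hourly concentrations must be >= 0")
  if (length(hours) < 3) return(NA_real_)
  if (sum(!is.na(hours[1:3])) < 2) return(NA_real_)
  present <- which(!is.na(hours))
  vals <- hours[present]
  w <- if (max(vals) > 0) max(1 - (max(vals) - min(vals)) / max(vals), 0.5) else 1

  lag <- present - 1L
  truncate_concentration(sum(w^lag * vals) / sum(w^lag))
}
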