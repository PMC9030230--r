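# QCEW-style monthly employment ingestion, NAICS filtering, the seasonal
# workforce index, and industry subsector share / outdoor-work-potential
# summaries.

#' Read monthly employment records
#'
#' Accepts either the package's canonical long CSV
#' (`county_key,naics,year,month,workers`) or a QCEW quarterly layout in
#' which each row carries a quarter with three month-level employment
#' columns (`month1_employment`, `month2_employment`, `month3_employment`),
#' which are unpivoted to calendar months. Blank (suppressed) month cells
#' are dropped and logged; negative worker counts and duplicate
#' (county, NAICS, year, month) keys are errors.
#'
#' @param source path to a CSV file.
#' @return tibble `county_key, naics, year, month, workers`.
#' @export
read_qcew_monthly <- function(source) {
  df <- readr::read_csv(source, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(naics = readr::col_character(),
                                                .default = readr::col_guess()))
  qcew_cols <- c("month1_employment", "month2_employment", "month3_employment")
  if (all(qcew_cols %in% names(df))) {
    if (!all(c("county_key", "naics", "year", "quarter") %in% names(df))) {
      stop("QCEW layout requires columns county_key, naics, year, quarter")
    }
    long <- tidyr::pivot_longer(df, dplyr::all_of(qcew_cols),
                                names_to = "month_in_quarter",
                                values_to = "workers")
    long$month <- (as.integer(long$quarter) - 1L) * 3L +
      as.integer(sub("month(\\d)_employment", "\\1", long$month_in_quarter))
    out <- tibble::tibble(
      county_key = as.character(long$county_key),
      naics = as.character(long$naics),
      year = as.integer(long$year),
      month = long$month,
      workers = long$workers
    )
  } else {
    required <- c("county_key", "naics", "year", "month", "workers")
    miss <- setdiff(required, names(df))
    if (length(miss)) stop("missing mandatory column(s): ", paste(miss, collapse = ", "))
    out <- tibble::tibble(
      county_key = as.character(df$county_key),
      naics = as.character(df$naics),
      year = as.integer(df$year),
      month = as.integer(df$month),
      workers = df$workers
    )
  }

  n_blank <- sum(is.na(out$workers))
  if (n_blank) {
    log_event("suppressed/blank employment cells dropped", n = n_blank)
    out <- out[!is.na(out$workers), , drop = FALSE]
  }
  if (any(out$workers < 0)) stop("negative worker counts are not allowed")
  out$workers <- as.integer(round(out$workers))

  key <- paste(out$county_key, out$naics, out$year, out$month, sep = "|")
  if (anyDuplicated(key)) {
    stop("duplicate (county, naics, year, month) keys: ",
         paste(utils::head(unique(key[duplicated(key)]), 5), collapse = "; "))
  }
  out
}

#' Filter employment records to a NAICS hierarchy branch
#'
#' NAICS codes are hierarchical by prefix: sector 23 (construction)
#' contains subsector 236, which contains national industry 236220. A
#' record matches when its code starts with `prefix`.
#'
#' @param records employment tibble.
#' @param prefix NAICS code prefix of 2-6 digits.
#' @return the matching subset.
#' @export
filter_naics <- function(records, prefix) {
  prefix <- as.character(prefix)
  if (nchar(prefix) < 2 || nchar(prefix) > 6) stop("prefix must be 2-6 digits")
  records[startsWith(records$naics, prefix), , drop = FALSE]
}

#' Seasonal workforce index for one county
#'
#' Monthly worker counts are averaged over the years of the study window
#' into a 12-point climatology; the index is the percent change of each
#' calendar month relative to the month with the smallest mean workforce
#' (the baseline — January for most construction-sector counties). Ties
#' for the minimum break to the earliest calendar month.
#'
#' @param records employment tibble for a single county, already restricted
#'   to the NAICS level of interest (counts are summed over any remaining
#'   codes per month).
#' @param years years to average over (default: all years present).
#' @return tibble `month, mean_workers, pct_change` with attributes
#'   `baseline_month` and `county_key`.
#' @export
seasonal_index <- function(records, years = NULL) {
  if (!is.null(years)) records <- records[records$year %in% years, , drop = FALSE]
  if (!nrow(records)) stop("no employment records in the requested years")
  if (length(unique(records$county_key)) > 1) {
    stop("seasonal_index expects records for a single county")
  }
  monthly <- records |>
    dplyr::summarise(workers = sum(workers), .by = c(year, month)) |>
    dplyr::summarise(mean_workers = mean(workers), .by = month) |>
    dplyr::arrange(month)
  baseline <- monthly$month[which.min(monthly$mean_workers)]
  base_val <- monthly$mean_workers[monthly$month == baseline]
  if (base_val == 0) stop("degenerate baseline: mean workforce is 0 in month ", baseline)
  monthly$pct_change <- 100 * (monthly$mean_workers - base_val) / base_val
  attr(monthly, "baseline_month") <- baseline
  attr(monthly, "county_key") <- records$county_key[1]
  monthly
}

#' Subsector employment shares within a sector
#'
#' For each NAICS code present, computes the period-mean worker count (the
#' mean of its monthly values over the records supplied) and expresses it
#' as a percent of the 2-digit sector total and, for codes of 4+ digits, of
#' their 3-digit subsector total. Denominators prefer an explicitly
#' reported aggregate row (e.g. a "23" record) and fall back to the sum of
#' the children at the next level down. Shares are rounded half-up to one
#' decimal, the convention of published QCEW summary tables.
#'
#' @param records employment tibble restricted to one sector and period.
#' @return tibble `naics, workers, pct_of_sector, pct_of_subsector`
#'   (subsector share `NA` for codes of fewer than 4 digits).
#' @export
subsector_shares <- function(records) {
  if (!nrow(records)) stop("no employment records supplied")
  sector_codes <- unique(substr(records$naics, 1, 2))
  if (length(sector_codes) > 1) {
    stop("records span multiple 2-digit sectors: ", paste(sector_codes, collapse = ", "))
  }
  by_code <- records |>
    dplyr::summarise(workers = sum(workers), .by = c(naics, year, month)) |>
    dplyr::summarise(workers = mean(workers), .by = naics)

  level_total <- function(prefix, level_nchar) {
    own <- by_code$workers[by_code$naics == prefix]
    if (length(own)) return(own[1])
    children <- by_code[startsWith(by_code$naics, prefix) &
                          nchar(by_code$naics) == level_nchar, , drop = FALSE]
    sum(children$workers)
  }
  sector_total <- level_total(sector_codes, 3L)
  if (!length(sector_total) || sector_total == 0) stop("sector total employment is 0")

  out <- by_code[by_code$naics != sector_codes, , drop = FALSE]
  out$pct_of_sector <- round_half_up(100 * out$workers / sector_total, 1)
  out$pct_of_subsector <- NA_real_
  deep <- nchar(out$naics) >= 4
  for (i in which(deep)) {
    sub_total <- level_total(substr(out$naics[i], 1, 3), 6L)
    if (length(sub_total) && sub_total > 0) {
      out$pct_of_subsector[i] <- round_half_up(100 * out$workers[i] / sub_total, 1)
    }
  }
  dplyr::arrange(out, naics)
}

#' Load the shipped outdoor-work-potential classification
#'
#' A judgement-based mapping from construction NAICS codes to the potential
#' for outdoor work (`high`, `medium`, `mixed`), editable by users. Codes
#' may be given at any depth; the longest matching prefix wins when
#' classifying a record.
#'
#' @param path optional path to a replacement CSV (`naics,potential`).
#' @return tibble `naics, potential`.
#' @export
outdoor_potential_map <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "outdoor_potential.csv", package = "smokepolicy")
  }
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(naics = readr::col_character(),
                                          potential = readr::col_character()))
}

#' Percent of sector workers by outdoor-work potential class
#'
#' Classifies each leaf NAICS code present (codes with no finer-grained
#' code beneath them in the records) by the longest matching prefix in the
#' map and reports each class's share of the sector total. Codes matched by
#' no map entry are reported as `"unclassified"`.
#'
#' @param records employment tibble restricted to one sector and period.
#' @param map tibble `naics, potential` (default the shipped
#'   classification, see [outdoor_potential_map()]).
#' @return tibble `potential, workers, pct_of_sector`.
#' @export
outdoor_potential_summary <- function(records, map = outdoor_potential_map()) {
  by_code <- records |>
    dplyr::summarise(workers = sum(workers), .by = c(naics, year, month)) |>
    dplyr::summarise(workers = mean(workers), .by = naics)
  # leaves only: drop aggregate rows that have children present
  is_leaf <- vapply(by_code$naics, function(code) {
    !any(startsWith(by_code$naics, code) & by_code$naics != code)
  }, logical(1))
  leaves <- by_code[is_leaf, , drop = FALSE]
  total <- sum(leaves$workers)
  if (total == 0) stop("sector total employment is 0")

  classify <- function(code) {
    hits <- map$naics[startsWith(code, map$naics)]
    if (!length(hits)) return("unclassified")
    map$potential[map$naics == hits[which.max(nchar(hits))]]
  }
  leaves$potential <- vapply(leaves$naics, classify, character(1),
                             USE.NAMES = FALSE)
  leaves |>
    dplyr::summarise(workers = sum(workers), .by = potential) |>
    dplyr::mutate(pct_of_sector = round_half_up(100 * workers / total, 1)) |>
    dplyr::arrange(dplyr::desc(workers))
}
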