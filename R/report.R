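# Report service: the three summary views over a patient list — baseline
# characteristics, longitudinal trend, and hierarchical attrition.

#' Round half away from zero
#'
#' Decimal rounding with ties going up (`0.5 -> 1`), as clinical reports
#' conventionally print percentages, rather than R's round-half-even.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5 + sqrt(.Machine$double.eps)) / f
}

#' Format a count as a percentage string
#'
#' `100 * numerator / denominator`, rounded half-up at the requested decimals
#' and suffixed `%` — the arithmetic behind printed figures such as
#' `"82.44%"` for 1808 of 2193.
#'
#' @param numerator,denominator Counts; `denominator > 0`.
#' @param decimals 0, 1 or 2.
#' @return Character vector.
#' @examples
#' format_percent(1808, 2193, 2)
#' format_percent(1, 3, 1)
#' @export
format_percent <- function(numerator, denominator, decimals = 2) {
  if (any(denominator <= 0)) stop("denominator must be positive")
  if (!all(decimals %in% 0:2)) stop("decimals must be 0, 1 or 2")
  pct <- round_half_up(100 * numerator / denominator, decimals)
  paste0(formatC(pct, format = "f", digits = decimals), "%")
}

#' Baseline characteristics of a patient list
#'
#' The demographic summary view: mean, sample standard deviation (n-1) and
#' non-missing count for age at the index date and BMI; count and percent of
#' `n` per level for sex, marital status, income level and occupation
#' (missing occupation reported as `"unknown"`).
#'
#' @param ds An [ehr_dataset()].
#' @param list A `patient_list` whose members resolve in `ds`.
#' @return A `characteristics_report`: list with `n`, `continuous` tibble
#'   (`variable`, `mean`, `sd`, `n_nonmissing`) and `categorical` tibble
#'   (`variable`, `level`, `count`, `percent`).
#' @export
summarize_characteristics <- function(ds, list) {
  stopifnot(inherits(ds, "ehr_dataset"), inherits(list, "patient_list"))
  m <- list$members
  n <- nrow(m)
  if (n == 0) {
    return(structure(list(
      n = 0L,
      continuous = tibble::tibble(variable = character(), mean = numeric(),
                                  sd = numeric(), n_nonmissing = integer()),
      categorical = tibble::tibble(variable = character(), level = character(),
                                   count = integer(), percent = numeric())),
      class = "characteristics_report"))
  }
  p <- ds$patients[match(m$patient_id, ds$patients$patient_id), , drop = FALSE]
  if (anyNA(p$patient_id)) stop("patient list members missing from dataset")
  age <- age_at(p$birth_date, m$index_date)

  cont1 <- function(variable, x) {
    x <- x[!is.na(x)]
    tibble::tibble(variable = variable,
                   mean = if (length(x)) mean(x) else NA_real_,
                   sd = if (length(x) > 1) stats::sd(x) else NA_real_,
                   n_nonmissing = length(x))
  }
  cat1 <- function(variable, x) {
    x[is.na(x)] <- "unknown"
    tab <- table(x)
    tibble::tibble(variable = variable, level = names(tab),
                   count = as.integer(tab),
                   percent = 100 * as.integer(tab) / n)
  }
  structure(list(
    n = n,
    continuous = dplyr::bind_rows(cont1("age", age), cont1("bmi", p$bmi)),
    categorical = dplyr::bind_rows(cat1("sex", p$sex),
                                   cat1("marital_status", p$marital_status),
                                   cat1("income_level", p$income_level),
                                   cat1("occupation", p$occupation))),
    class = "characteristics_report")
}

#' @export
print.characteristics_report <- function(x, ...) {
  cat(sprintf("<characteristics_report> n=%d\n", x$n))
  print(x$continuous)
  print(x$categorical, n = 30)
  invisible(x)
}

bucket_floor <- function(dates, interval) {
  lt <- as.POSIXlt(dates)
  lt$mday <- 1L
  if (interval == "quarterly") lt$mon <- (lt$mon %/% 3L) * 3L
  if (interval == "yearly") lt$mon <- 0L
  as.Date(lt)
}

bucket_label <- function(starts, interval) {
  switch(interval,
    monthly = format(starts, "%Y-%m"),
    quarterly = paste0(format(starts, "%Y"), " Q",
                       (as.POSIXlt(starts)$mon %/% 3L) + 1L),
    yearly = format(starts, "%Y"))
}

bucket_seq <- function(window, interval) {
  by <- switch(interval, monthly = "month", quarterly = "3 months",
               yearly = "year")
  seq(bucket_floor(window$start, interval), bucket_floor(window$end, interval),
      by = by)
}

# stratum value per member: sex from demographics, fracture_type from which
# fracture templates the index-day diagnosis codes matched (hip, vertebral,
# both, or unclassified)
stratum_values <- function(ds, members, strata, templates) {
  if (is.null(strata)) return(rep("all", nrow(members)))
  if (strata == "sex") {
    return(ds$patients$sex[match(members$patient_id, ds$patients$patient_id)])
  }
  if (strata == "fracture_type") {
    hip <- get_template(templates, "hip_fracture")
    vert <- get_template(templates, "vertebral_fracture")
    dx <- ds$events[ds$events$dimension == "diagnosis", , drop = FALSE]
    dx <- dplyr::inner_join(dx, members, by = "patient_id")
    dx <- dx[dx$event_date == dx$index_date, , drop = FALSE]
    dx$is_hip <- match_code(dx$code, hip)
    dx$is_vert <- match_code(dx$code, vert)
    per <- dx |>
      dplyr::group_by(.data$patient_id) |>
      dplyr::summarise(hip = any(.data$is_hip), vert = any(.data$is_vert),
                       .groups = "drop")
    lab <- ifelse(per$hip & per$vert, "both",
                  ifelse(per$hip, "hip",
                         ifelse(per$vert, "vertebral", "unclassified")))
    out <- lab[match(members$patient_id, per$patient_id)]
    out[is.na(out)] <- "unclassified"
    return(out)
  }
  stop("unknown stratum variable '", strata, "'")
}

#' Longitudinal incidence trend of a patient list
#'
#' Buckets the members by index date into calendar-aligned monthly, quarterly
#' (Jan--Mar, Apr--Jun, Jul--Sep, Oct--Dec) or yearly buckets spanning the
#' list's observation window, optionally stratified by `sex` or by
#' `fracture_type` (hip / vertebral / both, from which fracture templates the
#' index-day codes matched). Every member lands in exactly one bucket; empty
#' buckets are reported with a zero count.
#'
#' @param ds An [ehr_dataset()].
#' @param list A `patient_list`.
#' @param interval `"monthly"`, `"quarterly"` or `"yearly"`.
#' @param strata `NULL`, `"sex"` or `"fracture_type"`.
#' @param templates Template library (for fracture-type classification).
#' @return A `trend_series` tibble with columns `bucket`, `stratum`, `n`.
#' @export
incidence_trend <- function(ds, list, interval = c("quarterly", "monthly",
                                                   "yearly"),
                            strata = NULL, templates = builtin_templates()) {
  interval <- match.arg(interval)
  stopifnot(inherits(list, "patient_list"))
  starts <- bucket_seq(list$observation, interval)
  m <- list$members
  m$stratum <- stratum_values(ds, m, strata, templates)
  m$bucket <- bucket_label(bucket_floor(m$index_date, interval), interval)
  strata_levels <- if (nrow(m)) sort(unique(m$stratum)) else "all"
  grid <- tidyr::expand_grid(bucket = bucket_label(starts, interval),
                             stratum = strata_levels)
  counts <- m |>
    dplyr::count(.data$bucket, .data$stratum, name = "n")
  out <- dplyr::left_join(grid, counts, by = c("bucket", "stratum")) |>
    dplyr::mutate(n = ifelse(is.na(.data$n), 0L, .data$n))
  structure(out, class = c("trend_series", class(out)),
            interval = interval, strata = strata %||% "none")
}

#' Treatment-proportion trend between nested patient lists
#'
#' For each calendar bucket (and optional stratum), the proportion of the
#' denominator list's members indexed in that bucket who also belong to the
#' numerator list — e.g. newly fractured patients per quarter and the share
#' of them starting treatment within a year. The numerator members must be a
#' subset of the denominator members; buckets with an empty denominator
#' report `NA`.
#'
#' @param ds An [ehr_dataset()].
#' @param numerator_list,denominator_list `patient_list`s with
#'   `numerator members` a subset of `denominator` members.
#' @param interval `"monthly"`, `"quarterly"` or `"yearly"`.
#' @param strata `NULL`, `"sex"` or `"fracture_type"`.
#' @param templates Template library.
#' @return A `trend_series` tibble with columns `bucket`, `stratum`,
#'   `numerator`, `denominator`, `proportion`.
#' @export
proportion_trend <- function(ds, numerator_list, denominator_list,
                             interval = c("quarterly", "monthly", "yearly"),
                             strata = NULL, templates = builtin_templates()) {
  interval <- match.arg(interval)
  stopifnot(inherits(numerator_list, "patient_list"),
            inherits(denominator_list, "patient_list"))
  if (!all(numerator_list$members$patient_id %in%
           denominator_list$members$patient_id)) {
    stop("numerator members are not a subset of denominator members")
  }
  count_by <- function(m) {
    m$stratum <- stratum_values(ds, m, strata, templates)
    m$bucket <- bucket_label(bucket_floor(m$index_date, interval), interval)
    dplyr::count(m, .data$bucket, .data$stratum, name = "n")
  }
  den <- count_by(denominator_list$members)
  num <- count_by(numerator_list$members)
  starts <- bucket_seq(denominator_list$observation, interval)
  strata_levels <- if (nrow(den)) sort(unique(den$stratum)) else "all"
  grid <- tidyr::expand_grid(bucket = bucket_label(starts, interval),
                             stratum = strata_levels)
  out <- grid |>
    dplyr::left_join(dplyr::rename(den, denominator = "n"),
                     by = c("bucket", "stratum")) |>
    dplyr::left_join(dplyr::rename(num, numerator = "n"),
                     by = c("bucket", "stratum")) |>
    dplyr::mutate(
      denominator = ifelse(is.na(.data$denominator), 0L, .data$denominator),
      numerator = ifelse(is.na(.data$numerator), 0L, .data$numerator),
      proportion = ifelse(.data$denominator > 0,
                          .data$numerator / .data$denominator, NA_real_)) |>
    dplyr::select("bucket", "stratum", "numerator", "denominator",
                  "proportion")
  structure(out, class = c("trend_series", class(out)),
            interval = interval, strata = strata %||% "none")
}

#' Hierarchical attrition report
#'
#' The source-record view: walks a list's parent links back to the root and
#' concatenates each list's attrition record, root first, giving the full
#' flowchart from the initial index set down to the requested leaf.
#'
#' @param mart A `patient_mart`.
#' @param case Case number (or topic) of the leaf list.
#' @return An `attrition_report` tibble with columns `case_number`, `topic`,
#'   `parent`, `step`, `excluded`, `remaining`.
#' @export
attrition_report <- function(mart, case) {
  chain <- list()
  ref <- case
  seen <- character()
  repeat {
    pl <- mart_get(mart, ref)
    if (pl$case_number %in% seen) stop("cycle in patient-list hierarchy")
    seen <- c(seen, pl$case_number)
    chain <- c(list(pl), chain)
    if (is.null(pl$parent)) break
    ref <- pl$parent
  }
  rows <- lapply(chain, function(pl) {
    tibble::tibble(case_number = pl$case_number, topic = pl$topic,
                   parent = pl$parent %||% NA_character_,
                   step = pl$attrition$label,
                   excluded = pl$attrition$excluded,
                   remaining = pl$attrition$remaining)
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("attrition_report", class(out)))
}
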