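#' @importFrom rlang %||%
NULL

#' Observation window
#'
#' The inclusive calendar interval a study draws its index events from.
#'
#' @param start,end Dates (or ISO-8601 strings), `start <= end`.
#' @return An `observation_window`.
#' @export
observation_window <- function(start, end) {
  start <- as_iso_date(start, "observation start")
  end <- as_iso_date(end, "observation end")
  stopifnot(length(start) == 1, length(end) == 1, !is.na(start), !is.na(end))
  if (start > end) stop("observation window start is after its end")
  structure(list(start = start, end = end), class = "observation_window")
}

#' Index rule: how a study picks its index date
#'
#' The index date is the date of the qualifying event from which all relative
#' windows are measured — here always the first occurrence of a diagnosis
#' matching the named template, within the observation window, optionally
#' restricted to a subset of care settings.
#'
#' `first_ever` controls the washout against pre-window history: if `TRUE`
#' (the default), a patient with any matching diagnosis before the window
#' start is not indexed at all ("first-ever in database"); if `FALSE`, the
#' first in-window occurrence indexes regardless of earlier history, leaving
#' incident-user screening to an explicit lookback exclusion criterion. The
#' packaged fracture study uses the latter so that prior-fracture attrition is
#' attributed to its named exclusion step.
#'
#' @param template Name of a diagnosis-dimension template.
#' @param settings Care settings considered, subset of
#'   `c("outpatient", "admission", "emergency")`.
#' @param first_ever Logical; see Details.
#' @return An `index_rule`.
#' @export
index_rule <- function(template, settings = SETTINGS, first_ever = TRUE) {
  stopifnot(is.character(template), length(template) == 1)
  if (!all(settings %in% SETTINGS)) {
    stop("unknown setting(s): ",
         paste(setdiff(settings, SETTINGS), collapse = ", "))
  }
  structure(list(template = template, settings = settings,
                 rule = "first-occurrence", first_ever = isTRUE(first_ever)),
            class = "index_rule")
}

#' Inclusion/exclusion criterion with an index-relative window
#'
#' A criterion screens the current members against events in an inclusive
#' day-offset window relative to each member's index date: `window = c(-365,
#' -1)` is the year before the index (the index day itself belongs to neither
#' lookback nor follow-up), `c(1, 90)` the three months after. Exactly one
#' target must be given:
#'
#' * `template` — clinical events matching a named template (on the
#'   template's own dimension);
#' * `encounter = TRUE` — any hospital encounter;
#' * `age_minimum` — completed years at the index date; no window applies.
#'
#' `action` is `"exclude_if_present"` (drop members with at least one matching
#' event in the window) or `"require_presence"` (keep only members with one).
#' Age criteria always keep members at or above the threshold.
#'
#' @param label Unique step label, reported in the attrition record.
#' @param action `"exclude_if_present"` or `"require_presence"`; ignored for
#'   age criteria.
#' @param template Template name, or `NULL`.
#' @param encounter `TRUE` to target encounters.
#' @param age_minimum Minimum age in completed years, or `NULL`.
#' @param window Length-2 integer vector of inclusive day offsets,
#'   `window[1] <= window[2]`.
#' @param settings Optional care-setting filter.
#' @return A `criterion`.
#' @export
criterion <- function(label, action = c("exclude_if_present",
                                        "require_presence"),
                      template = NULL, encounter = FALSE, age_minimum = NULL,
                      window = NULL, settings = NULL) {
  stopifnot(is.character(label), length(label) == 1, nzchar(label))
  action <- match.arg(action)
  targets <- c(!is.null(template), isTRUE(encounter), !is.null(age_minimum))
  if (sum(targets) != 1) {
    stop("criterion '", label,
         "' must target exactly one of template, encounter, age_minimum")
  }
  if (!is.null(age_minimum)) {
    if (!is.null(window)) {
      stop("age criterion '", label, "' must not carry a window")
    }
    age_minimum <- as.integer(age_minimum)
    action <- "require_presence"
  } else {
    if (is.null(window)) stop("criterion '", label, "' needs a window")
    window <- as.integer(window)
    stopifnot(length(window) == 2, !anyNA(window))
    if (window[1] > window[2]) {
      stop("criterion '", label, "' window low exceeds high")
    }
  }
  if (!is.null(settings) && !all(settings %in% SETTINGS)) {
    stop("unknown setting(s) in criterion '", label, "'")
  }
  structure(list(label = label, action = action, template = template,
                 encounter = isTRUE(encounter), age_minimum = age_minimum,
                 window = window, settings = settings),
            class = "criterion")
}

#' Declarative cohort definition
#'
#' Bundles everything one identification run needs: a topic, the observation
#' window, the index rule, the ordered criteria, and optionally the case
#' number (or topic) of a previously identified patient list to draw candidate
#' patients from — which is how hierarchical sub-cohorts chain.
#'
#' @param topic Human-readable study topic.
#' @param observation An [observation_window()].
#' @param index An [index_rule()].
#' @param criteria List of [criterion()] objects, applied in order; labels
#'   must be unique.
#' @param source_list Optional case number or topic of a parent list in the
#'   data mart.
#' @return An `identification_spec`.
#' @export
identification_spec <- function(topic, observation, index, criteria = list(),
                                source_list = NULL) {
  stopifnot(is.character(topic), length(topic) == 1,
            inherits(observation, "observation_window"),
            inherits(index, "index_rule"), is.list(criteria))
  for (cr in criteria) {
    if (!inherits(cr, "criterion")) stop("criteria must be criterion objects")
  }
  labels <- vapply(criteria, `[[`, "", "label")
  if (anyDuplicated(labels)) {
    stop("duplicate criterion label(s): ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  structure(list(topic = topic, source_list = source_list,
                 observation = observation, index = index,
                 criteria = criteria),
            class = "identification_spec")
}

#' Age in completed years at a date
#'
#' Birthday-anniversary arithmetic: the age increments on the month/day
#' anniversary of the birth date (a 29 February birthday increments on
#' 1 March in non-leap years). Vectorised; both arguments recycle.
#'
#' @param birth_date,on_date Dates (or ISO-8601 strings); every
#'   `birth_date <= on_date`.
#' @return Integer vector of completed years.
#' @examples
#' age_at("1960-03-01", "2010-02-28")  # 49: day before the 50th birthday
#' age_at("1960-03-01", "2010-03-01")  # 50: on the birthday
#' @export
age_at <- function(birth_date, on_date) {
  birth_date <- as_iso_date(birth_date, "birth_date")
  on_date <- as_iso_date(on_date, "on_date")
  n <- max(length(birth_date), length(on_date))
  birth_date <- rep_len(birth_date, n)
  on_date <- rep_len(on_date, n)
  if (any(birth_date > on_date, na.rm = TRUE)) {
    stop("birth_date after on_date")
  }
  b <- as.POSIXlt(birth_date)
  o <- as.POSIXlt(on_date)
  not_yet <- (o$mon < b$mon) | (o$mon == b$mon & o$mday < b$mday)
  as.integer(o$year - b$year - not_yet)
}

# events matching a template, vectorised over the (typically few) distinct
# codes rather than every row
matched_events <- function(ds, template, settings = NULL) {
  e <- ds$events[ds$events$dimension == template$dimension, , drop = FALSE]
  if (!is.null(settings)) e <- e[e$setting %in% settings, , drop = FALSE]
  if (!nrow(e)) return(e)
  codes <- unique(e$code)
  hits <- codes[match_code(codes, template)]
  e[e$code %in% hits, , drop = FALSE]
}

#' Find index dates for a cohort
#'
#' For every candidate patient (all patients, or the members of a source
#' list), the earliest diagnosis matching the index rule's template within the
#' observation window — subject, when `rule$first_ever` is `TRUE`, to no
#' matching diagnosis existing before the window start. Patients with no
#' qualifying date are absent from the result. Several qualifying codes on the
#' same earliest day collapse to the one index date.
#'
#' @param ds An [ehr_dataset()].
#' @param rule An [index_rule()].
#' @param window An [observation_window()].
#' @param templates A `template_library` resolving the rule's template.
#' @param source Optional parent `patient_list` restricting candidates.
#' @return Tibble with columns `patient_id`, `index_date`.
#' @export
find_index_dates <- function(ds, rule, window, templates = builtin_templates(),
                             source = NULL) {
  stopifnot(inherits(ds, "ehr_dataset"), inherits(rule, "index_rule"),
            inherits(window, "observation_window"))
  tpl <- get_template(templates, rule$template)
  if (tpl$dimension != "diagnosis") {
    stop("index rule template '", rule$template, "' is not diagnosis-dimension")
  }
  e <- matched_events(ds, tpl, rule$settings)
  if (!is.null(source)) {
    e <- e[e$patient_id %in% source$members$patient_id, , drop = FALSE]
  }
  inw <- e[e$event_date >= window$start & e$event_date <= window$end, ,
           drop = FALSE]
  if (!nrow(inw)) {
    return(tibble::tibble(patient_id = character(),
                          index_date = as.Date(character())))
  }
  idx <- inw |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(index_date = min(.data$event_date), .groups = "drop")
  if (rule$first_ever) {
    prior <- unique(e$patient_id[e$event_date < window$start])
    idx <- idx[!idx$patient_id %in% prior, , drop = FALSE]
  }
  dplyr::arrange(idx, .data$patient_id)
}

#' Apply one criterion to a member set
#'
#' Evaluates the criterion's target over each member's inclusive day-offset
#' window relative to their index date and returns the survivors together
#' with the number excluded at this step.
#'
#' @param ds An [ehr_dataset()].
#' @param members Tibble with `patient_id`, `index_date` (as returned by
#'   [find_index_dates()]).
#' @param criterion A [criterion()].
#' @param templates Template library resolving any template target.
#' @return List with `members` (surviving tibble) and `excluded` (integer).
#' @export
apply_criterion <- function(ds, members, criterion,
                            templates = builtin_templates()) {
  stopifnot(inherits(criterion, "criterion"))
  n0 <- nrow(members)
  if (!n0) return(list(members = members, excluded = 0L))

  if (!is.null(criterion$age_minimum)) {
    birth <- ds$patients$birth_date[match(members$patient_id,
                                          ds$patients$patient_id)]
    ok <- !is.na(birth) &
      age_at(birth, members$index_date) >= criterion$age_minimum
    keep <- members[ok, , drop = FALSE]
    return(list(members = keep, excluded = n0 - nrow(keep)))
  }

  if (criterion$encounter) {
    tab <- ds$encounters
    if (!is.null(criterion$settings)) {
      tab <- tab[tab$setting %in% criterion$settings, , drop = FALSE]
    }
    dates <- tab$encounter_date
  } else {
    tpl <- get_template(templates, criterion$template)
    tab <- matched_events(ds, tpl, criterion$settings)
    dates <- tab$event_date
  }
  hits <- tibble::tibble(patient_id = tab$patient_id, date = dates) |>
    dplyr::inner_join(members, by = "patient_id") |>
    dplyr::mutate(offset = as.integer(.data$date - .data$index_date)) |>
    dplyr::filter(.data$offset >= criterion$window[1],
                  .data$offset <= criterion$window[2])
  hit_ids <- unique(hits$patient_id)
  keep <- if (criterion$action == "exclude_if_present") {
    members[!members$patient_id %in% hit_ids, , drop = FALSE]
  } else {
    members[members$patient_id %in% hit_ids, , drop = FALSE]
  }
  list(members = keep, excluded = n0 - nrow(keep))
}
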