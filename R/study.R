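# The packaged worked example: a new-user cohort of adults newly diagnosed
# with a hip or vertebral fracture 2010-2014, screened for treatment
# eligibility, then chained into follow-up and treated sub-cohorts.

#' The packaged osteoporotic-fracture study chain
#'
#' Three identification specs run in order as a queue:
#'
#' 1. *Incident fracture cohort* — first in-window hip/vertebral fracture
#'    diagnosis (ICD-9 820, 805, 806; any care setting) between 2010-01-01
#'    and 2014-12-31 is the index date; then, in order: keep patients aged 50
#'    or over at index; exclude malignant neoplasm (140--208), osteoporotic
#'    fracture, Paget disease (731.0), and anti-osteoporosis dispensings in
#'    the 1-year lookback `[-365, -1]`. The index rule is first-in-window
#'    (`first_ever = FALSE`): incident-user screening is carried by the
#'    explicit prior-fracture exclusion so its attrition is attributed to
#'    that named step.
#' 2. *Continued follow-up* — chained from cohort 1; requires an encounter
#'    within `[+1, +90]` days of the index.
#' 3. *Treated with an AOM* — chained from cohort 1 (treatment proportions
#'    are reported against the full incident cohort); requires an
#'    anti-osteoporosis dispensing within `[+1, +365]` days of the index.
#'
#' @return List of three [identification_spec()] objects.
#' @export
fracture_study_chain <- function() {
  obs <- observation_window("2010-01-01", "2014-12-31")
  idx <- index_rule("osteoporotic_fracture", SETTINGS, first_ever = FALSE)
  incident <- identification_spec(
    topic = "incident_osteoporotic_fracture",
    observation = obs, index = idx,
    criteria = list(
      criterion("age 50 or over at index", age_minimum = 50),
      criterion("no malignant neoplasm in prior year", "exclude_if_present",
                template = "malignancy", window = c(-365, -1)),
      criterion("no osteoporotic fracture in prior year", "exclude_if_present",
                template = "osteoporotic_fracture", window = c(-365, -1)),
      criterion("no Paget disease in prior year", "exclude_if_present",
                template = "paget", window = c(-365, -1)),
      criterion("no AOM dispensing in prior year", "exclude_if_present",
                template = "aom", window = c(-365, -1))
    ))
  followup <- identification_spec(
    topic = "continued_followup",
    source_list = "incident_osteoporotic_fracture",
    observation = obs, index = idx,
    criteria = list(
      criterion("encounter within 90 days post index", "require_presence",
                encounter = TRUE, window = c(1, 90))
    ))
  treated <- identification_spec(
    topic = "aom_treated",
    source_list = "incident_osteoporotic_fracture",
    observation = obs, index = idx,
    criteria = list(
      criterion("AOM dispensing within 1 year post index", "require_presence",
                template = "aom", window = c(1, 365))
    ))
  list(incident, followup, treated)
}

criterion_to_list <- function(cr) {
  out <- list(label = cr$label, action = cr$action)
  if (!is.null(cr$template)) out$template <- cr$template
  if (cr$encounter) out$encounter <- TRUE
  if (!is.null(cr$age_minimum)) out$age_minimum <- cr$age_minimum
  if (!is.null(cr$window)) out$window <- as.integer(cr$window)
  if (!is.null(cr$settings)) out$settings <- cr$settings
  out
}

criterion_from_list <- function(x) {
  criterion(label = x$label,
            action = x$action %||% "exclude_if_present",
            template = x$template,
            encounter = isTRUE(x$encounter),
            age_minimum = x$age_minimum,
            window = if (!is.null(x$window)) unlist(x$window),
            settings = if (!is.null(x$settings)) unlist(x$settings))
}

#' Save or load a study-spec queue as a YAML document
#'
#' Schema: `{version, studies: [{topic, source_list?, observation: {start,
#' end}, index: {template, settings, first_ever}, criteria: [{label, action,
#' template | encounter | age_minimum, window: [low, high], settings?}]}]}`.
#' The packaged fracture study ships as
#' `system.file("extdata", "fracture_study.yaml", package = "cohortforge")`.
#'
#' @param specs List of [identification_spec()] objects.
#' @param path File path.
#' @return `load_study_specs` returns the list of specs; `save_study_specs`
#'   its path, invisibly.
#' @export
save_study_specs <- function(specs, path) {
  doc <- list(version = 1L, studies = lapply(specs, function(s) {
    out <- list(topic = s$topic)
    if (!is.null(s$source_list)) out$source_list <- s$source_list
    out$observation <- list(start = format(s$observation$start),
                            end = format(s$observation$end))
    out$index <- list(template = s$index$template,
                      settings = s$index$settings,
                      first_ever = s$index$first_ever)
    out$criteria <- lapply(s$criteria, criterion_to_list)
    out
  }))
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' @rdname save_study_specs
#' @export
load_study_specs <- function(path) {
  if (!file.exists(path)) stop("missing study spec file: ", path)
  doc <- yaml::read_yaml(path)
  if (is.null(doc$studies)) stop("not a study spec document: ", path)
  lapply(doc$studies, function(s) {
    identification_spec(
      topic = s$topic,
      source_list = s$source_list,
      observation = observation_window(s$observation$start,
                                       s$observation$end),
      index = index_rule(s$index$template,
                         settings = unlist(s$index$settings) %||% SETTINGS,
                         first_ever = s$index$first_ever %||% TRUE),
      criteria = lapply(s$criteria, criterion_from_list))
  })
}

#' Canonical dispensing durations for long-acting osteoporosis drugs
#'
#' Per-drug default durations used by [normalize_durations()]: annual
#' zolendronate infusions, six-monthly denosumab injections and quarterly
#' intravenous ibandronate are commonly recorded as 1-day prescriptions even
#' though they cover months of exposure.
#'
#' @return Tibble with columns `code`, `duration_days`.
#' @export
aom_default_durations <- function() {
  tibble::tibble(code = c("zolendronate", "denosumab", "ibandronate"),
                 duration_days = c(365L, 180L, 90L))
}

#' Correct recorded dispensing durations against drug properties
#'
#' Opt-in exposure-measurement correction: where a pharmacy row records a
#' duration of 1 day but the drug's canonical duration exceeds 30 days (long
#' effect-duration products recorded as single-day prescriptions), the
#' canonical duration replaces the recorded one. All other rows are
#' untouched.
#'
#' @param ds An [ehr_dataset()].
#' @param durations Tibble with columns `code`, `duration_days`; defaults to
#'   [aom_default_durations()].
#' @return The corrected [ehr_dataset()].
#' @export
normalize_durations <- function(ds, durations = aom_default_durations()) {
  stopifnot(inherits(ds, "ehr_dataset"))
  e <- ds$events
  canon <- durations$duration_days[match(e$code, durations$code)]
  fix <- e$dimension == "pharmacy" & !is.na(e$duration_days) &
    e$duration_days == 1L & !is.na(canon) & canon > 30L
  e$duration_days[fix] <- canon[fix]
  ds$events <- e
  ds
}

fixture_spec_from_yaml <- function(doc) {
  counts <- doc$counts %||% list()
  do.call(fixture_spec, c(
    counts,
    list(observation = if (!is.null(doc$observation)) {
      observation_window(doc$observation$start, doc$observation$end)
    } else observation_window("2010-01-01", "2014-12-31"),
    seed = doc$seed %||% 1L)))
}

population_params_from_yaml <- function(doc) {
  args <- doc[setdiff(names(doc), c("mode", "observation"))]
  if (!is.null(doc$observation)) {
    args$observation <- observation_window(doc$observation$start,
                                           doc$observation$end)
  }
  do.call(population_params, args)
}

#' Read a generator spec file (fixture or population mode)
#'
#' YAML schema: `{mode: fixture, counts: {...}, observation: {start, end},
#' seed}` or `{mode: population, n_patients, incidence, p_treat, p_fu, ...,
#' seed}`.
#'
#' @param path YAML file path.
#' @return A [fixture_spec()] or [population_params()].
#' @export
load_generator_spec <- function(path) {
  if (!file.exists(path)) stop("missing generator spec file: ", path)
  doc <- yaml::read_yaml(path)
  mode <- doc$mode %||% stop("generator spec lacks a 'mode' field")
  switch(mode,
         fixture = fixture_spec_from_yaml(doc),
         population = population_params_from_yaml(doc),
         stop("unknown generator mode '", mode, "'"))
}
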