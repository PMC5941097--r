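# Independent brute-force oracles. These deliberately share no code with the
# package: matching is regex-based, ages walk anniversaries year by year, and
# the cohort interpreter is a per-patient loop in base R.

`%||%` <- function(x, y) if (is.null(x)) y else x

regex_escape <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)

# regex equivalent of a template's pattern list
oracle_match_code <- function(codes, tpl) {
  res <- rep(FALSE, length(codes))
  for (p in tpl$patterns) {
    rx <- switch(p$kind,
      exact = paste0("^", regex_escape(p$value), "$"),
      prefix = paste0("^", regex_escape(p$value), "(\\.|$)"),
      range = paste0("^(", paste(sprintf("%03d", p$low:p$high),
                                 collapse = "|"), ")"))
    res <- res | grepl(rx, codes)
  }
  res & nzchar(codes)
}

# completed years by walking birthday anniversaries (29 Feb -> 1 Mar in
# non-leap years)
oracle_age <- function(birth, on) {
  birth <- as.Date(birth); on <- as.Date(on)
  mapply(function(b, o) {
    lt <- as.POSIXlt(b)
    age <- -1L
    y <- lt$year + 1900L
    repeat {
      ann <- as.Date(sprintf("%d-%02d-%02d", y + age + 1L, lt$mon + 1L,
                             lt$mday), optional = TRUE)
      if (is.na(ann)) ann <- as.Date(sprintf("%d-03-01", y + age + 1L))
      if (ann > o) break
      age <- age + 1L
    }
    age
  }, birth, on)
}

# naive per-patient interpreter of a full identification run; returns the
# member table and the per-step exclusion counts
oracle_identify <- function(ds, spec, templates, parent_ids = NULL) {
  tpl_index <- templates$templates[[spec$index$template]]
  ids <- ds$patients$patient_id
  if (!is.null(parent_ids)) ids <- intersect(ids, parent_ids)
  excl <- setNames(rep(0L, length(spec$criteria)),
                   vapply(spec$criteria, `[[`, "", "label"))
  members <- character(); index_dates <- as.Date(character())
  for (pid in ids) {
    e <- ds$events[ds$events$patient_id == pid &
                   ds$events$dimension == "diagnosis" &
                   ds$events$setting %in% spec$index$settings, ]
    e <- e[oracle_match_code(e$code, tpl_index), ]
    cand <- e$event_date[e$event_date >= spec$observation$start &
                         e$event_date <= spec$observation$end]
    if (!length(cand)) next
    if (spec$index$first_ever &&
        any(e$event_date < spec$observation$start)) next
    index <- min(cand)
    survived <- TRUE
    for (cr in spec$criteria) {
      if (!is.null(cr$age_minimum)) {
        b <- ds$patients$birth_date[ds$patients$patient_id == pid]
        keep <- !is.na(b) && oracle_age(b, index) >= cr$age_minimum
      } else {
        if (cr$encounter) {
          t <- ds$encounters[ds$encounters$patient_id == pid, ]
          if (!is.null(cr$settings)) t <- t[t$setting %in% cr$settings, ]
          dates <- t$encounter_date
        } else {
          tpl <- templates$templates[[cr$template]]
          t <- ds$events[ds$events$patient_id == pid &
                         ds$events$dimension == tpl$dimension, ]
          if (!is.null(cr$settings)) t <- t[t$setting %in% cr$settings, ]
          dates <- t$event_date[oracle_match_code(t$code, tpl)]
        }
        off <- as.integer(dates - index)
        hit <- any(off >= cr$window[1] & off <= cr$window[2])
        keep <- if (cr$action == "exclude_if_present") !hit else hit
      }
      if (!keep) {
        excl[[cr$label]] <- excl[[cr$label]] + 1L
        survived <- FALSE
        break
      }
    }
    if (survived) {
      members <- c(members, pid)
      index_dates <- c(index_dates, index)
    }
  }
  list(members = tibble::tibble(patient_id = members,
                                index_date = index_dates),
       excluded = excl)
}

# independent row-by-row invariant checker: counts violations with plain loops
oracle_count_violations <- function(ds) {
  n <- 0L
  p <- ds$patients
  seen <- character()
  for (i in seq_len(nrow(p))) {
    r <- p[i, ]
    if (r$patient_id %in% seen) n <- n + 1L
    seen <- c(seen, r$patient_id)
    if (!is.na(r$death_date) && r$death_date < r$birth_date) n <- n + 1L
    if (!is.na(r$bmi) && (r$bmi <= 5 || r$bmi >= 100)) n <- n + 1L
    if (!r$sex %in% c("female", "male", "unknown")) n <- n + 1L
    if (!r$marital_status %in% c("married", "unmarried", "unknown")) n <- n + 1L
    if (!r$income_level %in% c("normal", "low", "unknown")) n <- n + 1L
    if (is.na(r$birth_date)) n <- n + 1L
  }
  e <- ds$events
  keys <- character()
  for (i in seq_len(nrow(e))) {
    r <- e[i, ]
    if (!r$patient_id %in% p$patient_id) n <- n + 1L
    if (!r$dimension %in% c("diagnosis", "pharmacy", "procedure",
                            "laboratory")) n <- n + 1L
    if (!r$setting %in% c("outpatient", "admission", "emergency")) n <- n + 1L
    if (is.na(r$code) || r$code == "") n <- n + 1L
    if (!is.na(r$duration_days) && r$dimension != "pharmacy") n <- n + 1L
    if (!is.na(r$duration_days) && r$duration_days <= 0) n <- n + 1L
    k <- paste(r$patient_id, r$event_date, r$dimension, r$code, r$setting)
    if (k %in% keys) n <- n + 1L
    keys <- c(keys, k)
  }
  for (i in seq_len(nrow(ds$encounters))) {
    r <- ds$encounters[i, ]
    if (!r$patient_id %in% p$patient_id) n <- n + 1L
    if (!r$setting %in% c("outpatient", "admission", "emergency")) n <- n + 1L
  }
  n
}

# small hand-built dataset helpers -----------------------------------------

mini_patients <- function(ids, birth = "1940-06-15", sex = "female") {
  tibble::tibble(patient_id = ids, birth_date = as.Date(birth), sex = sex,
                 bmi = 23, marital_status = "married",
                 income_level = "normal", occupation = "retired",
                 death_date = as.Date(NA))
}

mini_event <- function(pid, date, dim = "diagnosis", code = "820.21",
                       setting = "outpatient", dur = NA_integer_) {
  tibble::tibble(patient_id = pid, event_date = as.Date(date),
                 dimension = dim, code = code, setting = setting,
                 duration_days = as.integer(dur))
}

mini_encounter <- function(pid, date, setting = "outpatient") {
  tibble::tibble(patient_id = pid, encounter_date = as.Date(date),
                 setting = setting)
}

# a random identification spec over the built-in templates, for oracle
# equivalence sweeps
random_spec <- function(first_ever = sample(c(TRUE, FALSE), 1)) {
  pool <- list(
    criterion("age50", age_minimum = 50),
    criterion("age65", age_minimum = 65),
    criterion("ex malignancy", "exclude_if_present", template = "malignancy",
              window = c(-365, -1)),
    criterion("ex prior fracture", "exclude_if_present",
              template = "osteoporotic_fracture", window = c(-365, -1)),
    criterion("ex paget", "exclude_if_present", template = "paget",
              window = c(-365, -1)),
    criterion("ex prior aom", "exclude_if_present", template = "aom",
              window = c(-400, -1)),
    criterion("req followup", "require_presence", encounter = TRUE,
              window = c(1, 90)),
    criterion("req treatment", "require_presence", template = "aom",
              window = c(1, 365)),
    criterion("req outpatient fu", "require_presence", encounter = TRUE,
              window = c(1, 180), settings = "outpatient")
  )
  k <- sample(0:4, 1)
  crits <- if (k) sample(pool, k) else list()
  settings <- sample(c("outpatient", "admission", "emergency"),
                     sample(1:3, 1))
  identification_spec(
    topic = "random",
    observation = observation_window(
      as.Date("2010-01-01") + sample(0:200, 1),
      as.Date("2014-12-31") - sample(0:200, 1)),
    index = index_rule(sample(c("osteoporotic_fracture", "hip_fracture",
                                "vertebral_fracture"), 1),
                       settings = settings, first_ever = first_ever),
    criteria = crits)
}

random_population <- function(seed, n = NULL) {
  n <- n %||% sample(60:200, 1)
  generate_population(population_params(
    n_patients = n,
    incidence = runif(1, 0.05, 0.3),
    p_treat = runif(1, 0.1, 0.5),
    p_fu = runif(1, 0.4, 0.95),
    age_mean = runif(1, 55, 80),
    age_sd = runif(1, 8, 15),
    p_prior_malignancy = runif(1, 0, 0.15),
    p_prior_fracture = runif(1, 0, 0.15),
    p_prior_aom = runif(1, 0, 0.15),
    p_paget = runif(1, 0, 0.05),
    seed = seed))
}
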