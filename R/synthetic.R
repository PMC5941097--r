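# Synthetic longitudinal claims generation: a deterministic fixture mode that
# forces exact attrition counts by construction, and a stochastic population
# mode with stated distributions for property tests and parameter recovery.

# run code under a fixed seed without disturbing the caller's RNG stream
with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

FRACTURE_CODES <- c("820.21", "805.4", "806.00", "820.8", "805.2")
MALIGNANCY_CODES <- c("151.9", "174.9", "185", "162.3")
AOM_DRUGS <- c("alendronate", "zolendronate", "ibandronate", "denosumab",
               "raloxifene", "teriparatide", "estradiol valerate",
               "conjugated estrogens", "calcitonin")

cycle <- function(values, i) values[((i - 1L) %% length(values)) + 1L]

#' Fixture specification: per-category patient counts
#'
#' Each category seeds patients built to satisfy exactly one qualifying or
#' disqualifying condition of the packaged fracture study, so that running
#' the study chain on the generated dataset yields attrition counts equal to
#' the construction:
#'
#' * `eligible_untreated` — indexed, followed up within 90 days, never
#'   treated;
#' * `eligible_treated` — indexed, followed up, anti-osteoporosis dispensing
#'   within 1--365 days after the index;
#' * `no_followup` — indexed but no encounter in the 90 days after the index;
#' * `prior_malignancy` / `prior_fracture` / `prior_aom` / `paget_history` —
#'   indexed but carrying the corresponding disqualifying history in the
#'   1-year lookback;
#' * `under_50` — indexed but younger than 50 at the index date;
#' * `outside_window` — fracture diagnosed only outside the observation
#'   window, never indexed.
#'
#' Index dates are allocated round-robin over the calendar quarters of the
#' observation window; `prior_fracture` patients are confined to the first
#' two quarters so their prior fracture (180 days earlier) predates the
#' window start — otherwise it would itself become the index date.
#'
#' @param eligible_untreated,eligible_treated,no_followup,prior_malignancy,prior_fracture,prior_aom,under_50,paget_history,outside_window
#'   Non-negative patient counts per category.
#' @param observation An [observation_window()].
#' @param seed Integer seed; the fixture is bit-identical given the seed.
#' @return A `fixture_spec`.
#' @export
fixture_spec <- function(eligible_untreated = 0, eligible_treated = 0,
                         no_followup = 0, prior_malignancy = 0,
                         prior_fracture = 0, prior_aom = 0, under_50 = 0,
                         paget_history = 0, outside_window = 0,
                         observation = observation_window("2010-01-01",
                                                          "2014-12-31"),
                         seed = 1L) {
  counts <- c(eligible_untreated = eligible_untreated,
              eligible_treated = eligible_treated,
              no_followup = no_followup,
              prior_malignancy = prior_malignancy,
              prior_fracture = prior_fracture,
              prior_aom = prior_aom,
              under_50 = under_50,
              paget_history = paget_history,
              outside_window = outside_window)
  counts <- vapply(counts, as.integer, 0L)
  if (any(is.na(counts)) || any(counts < 0)) {
    stop("fixture counts must be non-negative integers")
  }
  stopifnot(inherits(observation, "observation_window"))
  structure(list(counts = counts, observation = observation,
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

demographics <- function(pid, birth, young = FALSE) {
  n <- length(pid)
  bmi <- pmin(pmax(rnorm(n, 23, 3.9), 13), 45)
  bmi[runif(n) < 0.05] <- NA_real_
  tibble::tibble(
    patient_id = pid,
    birth_date = birth,
    sex = ifelse(runif(n) < 0.75, "female", "male"),
    bmi = bmi,
    marital_status = sample(c("married", "unmarried", "unknown"), n,
                            replace = TRUE, prob = c(0.70, 0.27, 0.03)),
    income_level = sample(c("normal", "low"), n, replace = TRUE,
                          prob = c(0.99, 0.01)),
    occupation = sample(c("retired", "manual", "office", "unknown"), n,
                        replace = TRUE),
    death_date = as.Date(NA)
  )
}

#' Generate a deterministic fixture dataset
#'
#' Builds the dataset described by the [fixture_spec()]: categories are
#' mutually exclusive by construction, so sequential attrition attribution is
#' unambiguous and every per-step exclusion of the packaged fracture study
#' equals the corresponding category count. Deterministic given the spec's
#' seed; the caller's RNG stream is left untouched.
#'
#' @param spec A [fixture_spec()].
#' @return An [ehr_dataset()].
#' @export
generate_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  obs <- spec$observation
  quarters <- bucket_seq(obs, "quarterly")
  with_local_seed(spec$seed, {
    patients <- list(); events <- list(); encounters <- list()
    add_ev <- function(pid, date, dim, code, setting, dur = NA_integer_) {
      events[[length(events) + 1]] <<- tibble::tibble(
        patient_id = pid, event_date = date, dimension = dim, code = code,
        setting = setting, duration_days = as.integer(dur))
    }
    add_enc <- function(pid, date, setting) {
      encounters[[length(encounters) + 1]] <<- tibble::tibble(
        patient_id = pid, encounter_date = date, setting = setting)
    }

    build <- function(category, prefix) {
      n <- spec$counts[[category]]
      if (n == 0) return(invisible())
      i <- seq_len(n)
      pid <- sprintf("%s%05d", prefix, i)
      qs <- if (category == "prior_fracture") quarters[cycle(1:2, i)]
            else quarters[cycle(seq_along(quarters), i)]
      anchor <- qs + (i * 7L) %% 84L   # index date (or sole dx date)
      if (category == "outside_window") anchor <- obs$end + 100L + (i %% 120L)

      age <- if (category == "under_50") runif(n, 25, 45)
             else pmin(pmax(rnorm(n, 76, 10), 52), 95)
      birth <- anchor - round(age * 365.25)
      patients[[length(patients) + 1]] <<- demographics(pid, birth)

      fx <- cycle(FRACTURE_CODES, i)
      st <- cycle(SETTINGS, i)
      add_ev(pid, anchor, "diagnosis", fx, st)
      add_enc(pid, anchor, st)

      if (category %in% c("eligible_untreated", "eligible_treated")) {
        add_enc(pid, anchor + 30L, "outpatient")
      }
      if (category == "eligible_treated") {
        add_ev(pid, anchor + 100L, "pharmacy", cycle(AOM_DRUGS, i),
               "outpatient", 30L)
      }
      if (category == "prior_malignancy") {
        add_ev(pid, anchor - 180L, "diagnosis", cycle(MALIGNANCY_CODES, i),
               "outpatient")
      }
      if (category == "prior_fracture") {
        add_ev(pid, anchor - 180L, "diagnosis", cycle(FRACTURE_CODES, i + 1L),
               "outpatient")
      }
      if (category == "prior_aom") {
        add_ev(pid, anchor - 100L, "pharmacy", cycle(AOM_DRUGS, i),
               "outpatient", 30L)
      }
      if (category == "paget_history") {
        add_ev(pid, anchor - 100L, "diagnosis", "731.0", "outpatient")
      }
      invisible()
    }

    build("eligible_untreated", "EU")
    build("eligible_treated", "ET")
    build("no_followup", "NF")
    build("prior_malignancy", "PM")
    build("prior_fracture", "PF")
    build("prior_aom", "PA")
    build("under_50", "U5")
    build("paget_history", "PG")
    build("outside_window", "OW")

    ehr_dataset(dplyr::bind_rows(patients), dplyr::bind_rows(events),
                dplyr::bind_rows(encounters), quiet = TRUE)
  })
}

#' Population-mode generation parameters
#'
#' The stochastic counterpart of the fixture: `n_patients` independent
#' patients with ages drawn from a normal distribution anchored at the
#' observation start, a yearly first-fracture incidence probability, and —
#' conditional on a fracture — independent Bernoulli treatment (an
#' anti-osteoporosis dispensing uniform in days 1--365 after the index) and
#' follow-up (an encounter uniform in days 1--90). Lookback comorbidity
#' history (malignancy, prior fracture, prior drug, Paget disease) occurs at
#' the stated background rates, independently of treatment and follow-up, so
#' the engine-estimated treated/follow-up proportions are unbiased for
#' `p_treat` and `p_fu`.
#'
#' @param n_patients Number of patients.
#' @param incidence Yearly probability of a first fracture.
#' @param p_treat Probability of treatment given a fracture.
#' @param p_fu Probability of a follow-up encounter given a fracture.
#' @param age_mean,age_sd Age distribution (years) at observation start.
#' @param p_female Probability of female sex.
#' @param bmi_mean,bmi_sd,p_bmi_missing BMI distribution and missingness.
#' @param p_prior_malignancy,p_prior_fracture,p_prior_aom,p_paget Background
#'   lookback-history rates given a fracture.
#' @param observation An [observation_window()].
#' @param seed Integer seed.
#' @return A `population_params`.
#' @export
population_params <- function(n_patients = 2000, incidence = 0.05,
                              p_treat = 0.21, p_fu = 0.82,
                              age_mean = 76, age_sd = 10, p_female = 0.75,
                              bmi_mean = 23, bmi_sd = 3.9,
                              p_bmi_missing = 0.05,
                              p_prior_malignancy = 0.03,
                              p_prior_fracture = 0.02,
                              p_prior_aom = 0.03, p_paget = 0.005,
                              observation = observation_window("2010-01-01",
                                                               "2014-12-31"),
                              seed = 1L) {
  probs <- c(incidence, p_treat, p_fu, p_female, p_bmi_missing,
             p_prior_malignancy, p_prior_fracture, p_prior_aom, p_paget)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (n_patients <= 0) stop("n_patients must be positive")
  stopifnot(inherits(observation, "observation_window"))
  structure(list(n_patients = as.integer(n_patients), incidence = incidence,
                 p_treat = p_treat, p_fu = p_fu, age_mean = age_mean,
                 age_sd = age_sd, p_female = p_female, bmi_mean = bmi_mean,
                 bmi_sd = bmi_sd, p_bmi_missing = p_bmi_missing,
                 p_prior_malignancy = p_prior_malignancy,
                 p_prior_fracture = p_prior_fracture,
                 p_prior_aom = p_prior_aom, p_paget = p_paget,
                 observation = observation, seed = as.integer(seed)),
            class = "population_params")
}

#' Generate a stochastic population dataset
#'
#' Draws the population described by [population_params()]: per-patient
#' yearly Bernoulli trials decide the first-fracture year, the fracture day
#' is uniform within that year, and treatment, follow-up and lookback
#' comorbidity history are drawn independently. Non-fractured patients
#' contribute background encounters and non-fracture diagnoses so datasets
#' exercise code matching. Deterministic given the seed.
#'
#' @param params A [population_params()].
#' @return An [ehr_dataset()].
#' @export
generate_population <- function(params) {
  stopifnot(inherits(params, "population_params"))
  obs <- params$observation
  with_local_seed(params$seed, {
    n <- params$n_patients
    pid <- sprintf("P%06d", seq_len(n))
    age <- pmin(pmax(rnorm(n, params$age_mean, params$age_sd), 30), 100)
    birth <- obs$start - round(age * 365.25)
    bmi <- pmin(pmax(rnorm(n, params$bmi_mean, params$bmi_sd), 13), 45)
    bmi[runif(n) < params$p_bmi_missing] <- NA_real_
    patients <- tibble::tibble(
      patient_id = pid, birth_date = birth,
      sex = ifelse(runif(n) < params$p_female, "female", "male"),
      bmi = bmi,
      marital_status = sample(c("married", "unmarried", "unknown"), n,
                              replace = TRUE, prob = c(0.70, 0.27, 0.03)),
      income_level = sample(c("normal", "low"), n, replace = TRUE,
                            prob = c(0.99, 0.01)),
      occupation = sample(c("retired", "manual", "office", "unknown"), n,
                          replace = TRUE),
      death_date = as.Date(NA))

    years <- seq(as.integer(format(obs$start, "%Y")),
                 as.integer(format(obs$end, "%Y")))
    trial <- matrix(runif(n * length(years)) < params$incidence, nrow = n)
    first_year <- apply(trial, 1, function(r) {
      w <- which(r); if (length(w)) w[1] else NA_integer_
    })
    has_fx <- !is.na(first_year)
    events <- list(); encounters <- list()

    if (any(has_fx)) {
      f_pid <- pid[has_fx]
      nf <- length(f_pid)
      ystart <- as.Date(sprintf("%d-01-01", years[first_year[has_fx]]))
      ylen <- as.integer(as.Date(sprintf("%d-12-31",
                                         years[first_year[has_fx]])) - ystart)
      fx_date <- pmin(ystart + floor(runif(nf) * (ylen + 1)), obs$end)
      events[[1]] <- tibble::tibble(
        patient_id = f_pid, event_date = fx_date, dimension = "diagnosis",
        code = sample(FRACTURE_CODES, nf, replace = TRUE),
        setting = sample(SETTINGS, nf, replace = TRUE),
        duration_days = NA_integer_)
      encounters[[1]] <- tibble::tibble(
        patient_id = f_pid, encounter_date = fx_date,
        setting = sample(SETTINGS, nf, replace = TRUE))

      draw <- function(p) runif(nf) < p
      treated <- draw(params$p_treat)
      if (any(treated)) {
        events[[length(events) + 1]] <- tibble::tibble(
          patient_id = f_pid[treated],
          event_date = fx_date[treated] + sample(1:365, sum(treated),
                                                 replace = TRUE),
          dimension = "pharmacy",
          code = sample(AOM_DRUGS, sum(treated), replace = TRUE),
          setting = "outpatient", duration_days = 30L)
      }
      fu <- draw(params$p_fu)
      if (any(fu)) {
        encounters[[length(encounters) + 1]] <- tibble::tibble(
          patient_id = f_pid[fu],
          encounter_date = fx_date[fu] + sample(1:90, sum(fu), replace = TRUE),
          setting = "outpatient")
      }
      lookback <- function(p, codes, dim, back, dur = NA_integer_) {
        sel <- draw(p)
        if (!any(sel)) return(NULL)
        tibble::tibble(
          patient_id = f_pid[sel],
          event_date = fx_date[sel] - sample(back, sum(sel), replace = TRUE),
          dimension = dim, code = sample(codes, sum(sel), replace = TRUE),
          setting = "outpatient", duration_days = dur)
      }
      events <- c(events, list(
        lookback(params$p_prior_malignancy, MALIGNANCY_CODES, "diagnosis",
                 1:365),
        lookback(params$p_prior_fracture, FRACTURE_CODES, "diagnosis",
                 180:365),
        lookback(params$p_prior_aom, AOM_DRUGS, "pharmacy", 1:365, 30L),
        lookback(params$p_paget, "731.0", "diagnosis", 1:365)))
    }

    # background noise for everyone: an encounter and a non-fracture dx
    span <- as.integer(obs$end - obs$start)
    noise_date <- obs$start + floor(runif(n) * (span + 1))
    encounters[[length(encounters) + 1]] <- tibble::tibble(
      patient_id = pid, encounter_date = noise_date,
      setting = sample(SETTINGS, n, replace = TRUE))
    events[[length(events) + 1]] <- tibble::tibble(
      patient_id = pid, event_date = noise_date, dimension = "diagnosis",
      code = sample(c("401.9", "250.00", "715.90", "496"), n, replace = TRUE),
      setting = sample(SETTINGS, n, replace = TRUE),
      duration_days = NA_integer_)

    ehr_dataset(patients, dplyr::bind_rows(events),
                dplyr::bind_rows(encounters), quiet = TRUE)
  })
}
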