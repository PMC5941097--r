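lib <- builtin_templates()

# build a patient_list directly around hand-chosen members
manual_list <- function(ids, index_dates,
                        observation = observation_window("2010-01-01",
                                                         "2014-12-31")) {
  spec <- identification_spec("manual", observation,
                              index_rule("osteoporotic_fracture",
                                         first_ever = FALSE))
  ds <- ehr_dataset(mini_patients(ids),
                    mini_event(ids, index_dates), NULL)
  run_identification(ds, spec, new_patient_mart(), lib)
}

test_that("percent formatting reproduces report-style strings", {
  expect_equal(format_percent(1808, 2193, 2), "82.44%")
  expect_equal(format_percent(464, 2193, 2), "21.16%")
  expect_equal(format_percent(1, 3, 1), "33.3%")
  expect_equal(format_percent(1, 2, 0), "50%")
  expect_equal(format_percent(125, 1000, 1), "12.5%")
  expect_equal(format_percent(5, 1000, 1), "0.5%")
  # ties round up, not to even
  expect_equal(format_percent(345, 1000, 1), "34.5%")
  expect_equal(format_percent(125, 1000, 0), "13%")
  expect_error(format_percent(1, 0, 1), "positive")
  expect_error(format_percent(1, 10, 3), "decimals")
})

test_that("characteristics summarise age and BMI with sample SD", {
  ds <- ehr_dataset(
    dplyr::bind_rows(
      mini_patients("P1", birth = "1951-12-31"),  # 60 at 2012-06-15
      mini_patients("P2", birth = "1931-12-31")), # 80
    mini_event(c("P1", "P2"), "2012-06-15"), NULL)
  spec <- identification_spec("two", observation_window("2012-01-01",
                                                        "2012-12-31"),
                              index_rule("osteoporotic_fracture",
                                         first_ever = FALSE))
  pl <- run_identification(ds, spec, new_patient_mart(), lib)
  rep <- summarize_characteristics(ds, pl)
  age <- rep$continuous[rep$continuous$variable == "age", ]
  expect_equal(rep$n, 2)
  expect_equal(age$mean, 70)
  expect_equal(age$sd, sqrt(200), tolerance = 1e-10)  # = 14.142...
  expect_equal(age$n_nonmissing, 2)
})

test_that("missing BMI is excluded with n_nonmissing reported", {
  ds <- ehr_dataset(
    dplyr::bind_rows(mini_patients(c("P1", "P2", "P3"))),
    mini_event(c("P1", "P2", "P3"), "2012-06-15"), NULL)
  ds$patients$bmi <- c(20, NA, 30)
  pl <- manual_list(c("P1", "P2", "P3"), "2012-06-15")
  rep <- summarize_characteristics(ds, pl)
  bmi <- rep$continuous[rep$continuous$variable == "bmi", ]
  expect_equal(bmi$mean, 25)
  expect_equal(bmi$n_nonmissing, 2)
})

test_that("a 464-member cohort with 384 women reports 82.76% female", {
  ids <- sprintf("P%03d", 1:464)
  ds <- ehr_dataset(mini_patients(ids,
                                  sex = rep(c("female", "male"),
                                            c(384, 80))),
                    mini_event(ids, "2012-06-15"), NULL)
  pl <- manual_list(ids, "2012-06-15")
  rep <- summarize_characteristics(ds, pl)
  fem <- rep$categorical[rep$categorical$variable == "sex" &
                         rep$categorical$level == "female", ]
  expect_equal(fem$count, 384)
  expect_equal(format_percent(fem$count, rep$n, 2), "82.76%")
  # categorical counts partition n for every variable
  tot <- tapply(rep$categorical$count, rep$categorical$variable, sum)
  expect_true(all(tot == rep$n))
})

test_that("cohort mean age recovers the generating normal within sampling error", {
  set.seed(5)
  n <- 2000
  ids <- sprintf("P%04d", 1:n)
  index <- as.Date("2012-06-15")
  target_age <- round(rnorm(n, 76, 10))
  # birthday ~half a year before the index so completed years == target
  birth <- index - round(target_age * 365.25) - 120
  ds <- ehr_dataset(mini_patients(ids, birth = birth),
                    mini_event(ids, index), NULL)
  pl <- manual_list(ids, index)
  rep <- summarize_characteristics(ds, pl)
  age <- rep$continuous[rep$continuous$variable == "age", ]
  expect_lt(abs(age$mean - 76), 3 * 10 / sqrt(n))
})

test_that("characteristics mean/sd match an independent two-pass computation", {
  set.seed(17)
  ds <- random_population(seed = 23, n = 150)
  spec <- fracture_study_chain()[[1]]
  pl <- run_identification(ds, spec, new_patient_mart(), lib)
  rep <- summarize_characteristics(ds, pl)
  p <- ds$patients[match(pl$members$patient_id, ds$patients$patient_id), ]
  x <- age_at(p$birth_date, pl$members$index_date)
  m <- sum(x) / length(x)
  s <- sqrt(sum((x - m)^2) / (length(x) - 1))
  age <- rep$continuous[rep$continuous$variable == "age", ]
  expect_equal(age$mean, m, tolerance = 1e-10)
  expect_equal(age$sd, s, tolerance = 1e-10)
})

test_that("an empty list summarises to n = 0", {
  spec <- identification_spec("none", observation_window("2010-01-01",
                                                         "2010-12-31"),
                              index_rule("osteoporotic_fracture"))
  pl <- run_identification(ehr_dataset(), spec, new_patient_mart(), lib)
  rep <- summarize_characteristics(ehr_dataset(), pl)
  expect_equal(rep$n, 0)
  expect_equal(nrow(rep$continuous), 0)
})

test_that("quarter bucketing respects calendar boundaries", {
  pl <- manual_list(c("A1", "A2", "A3"),
                    c("2014-10-01", "2014-12-31", "2015-01-01"),
                    observation_window("2014-01-01", "2015-03-31"))
  ds <- ehr_dataset(mini_patients(c("A1", "A2", "A3")),
                    mini_event(c("A1", "A2", "A3"),
                               c("2014-10-01", "2014-12-31", "2015-01-01")),
                    NULL)
  tr <- incidence_trend(ds, pl, "quarterly")
  expect_equal(tr$n[tr$bucket == "2014 Q4"], 2)
  expect_equal(tr$n[tr$bucket == "2015 Q1"], 1)
  expect_equal(sum(tr$n), 3)
  expect_equal(tr$bucket[1:5],
               c("2014 Q1", "2014 Q2", "2014 Q3", "2014 Q4", "2015 Q1"))
})

test_that("bucketing is a partition and strata re-sum to the unstratified counts", {
  set.seed(7)
  for (interval in c("monthly", "quarterly", "yearly")) {
    ds <- random_population(seed = 51, n = 150)
    pl <- run_identification(ds, fracture_study_chain()[[1]],
                             new_patient_mart(), lib)
    tr <- incidence_trend(ds, pl, interval)
    expect_equal(sum(tr$n), nrow(pl$members), info = interval)
    for (strat in c("sex", "fracture_type")) {
      trs <- incidence_trend(ds, pl, interval, strata = strat)
      agg <- tapply(trs$n, trs$bucket, sum)
      expect_equal(as.integer(agg[tr$bucket]), as.integer(tr$n),
                   info = paste(interval, strat))
    }
  }
})

test_that("proportions divide nested bucket counts: 42 of 130 is 0.323", {
  obs <- observation_window("2014-10-01", "2014-12-31")
  ids <- sprintf("Q%03d", 1:130)
  den <- manual_list(ids, "2014-11-15", obs)
  num <- den
  num$members <- den$members[1:42, ]
  num$parent <- den$case_number
  ds <- ehr_dataset(mini_patients(ids), mini_event(ids, "2014-11-15"), NULL)
  tr <- proportion_trend(ds, num, den, "quarterly")
  q4 <- tr[tr$bucket == "2014 Q4", ]
  expect_equal(q4$numerator, 42)
  expect_equal(q4$denominator, 130)
  expect_equal(round(q4$proportion, 3), 0.323)
  expect_equal(format_percent(q4$numerator, q4$denominator, 1), "32.3%")
})

test_that("numerator equal to denominator gives proportion 1 everywhere occupied", {
  ds <- random_population(seed = 61, n = 100)
  pl <- run_identification(ds, fracture_study_chain()[[1]],
                           new_patient_mart(), lib)
  tr <- proportion_trend(ds, pl, pl, "quarterly")
  expect_true(all(tr$proportion[tr$denominator > 0] == 1))
  expect_true(all(is.na(tr$proportion[tr$denominator == 0])))
})

test_that("a numerator outside the denominator is fatal", {
  a <- manual_list(c("P1", "P2"), "2012-06-15")
  b <- manual_list(c("P3"), "2012-06-15")
  ds <- ehr_dataset(mini_patients(c("P1", "P2", "P3")),
                    mini_event(c("P1", "P2", "P3"), "2012-06-15"), NULL)
  expect_error(proportion_trend(ds, b, a), "subset")
})

test_that("proportions equal brute-force per-bucket ratios on random nested lists", {
  set.seed(83)
  for (i in 1:5) {
    ds <- random_population(seed = 600 + i, n = 150)
    mart <- new_patient_mart()
    res <- run_batch(fracture_study_chain(), ds, mart, lib)
    tr <- proportion_trend(ds, res[[3]], res[[1]], "quarterly")
    qtr <- function(d) paste0(format(d, "%Y"), " Q",
                              (as.POSIXlt(d)$mon %/% 3) + 1)
    for (j in seq_len(nrow(tr))) {
      den <- sum(qtr(res[[1]]$members$index_date) == tr$bucket[j])
      num <- sum(qtr(res[[3]]$members$index_date) == tr$bucket[j])
      expect_equal(tr$denominator[j], den)
      expect_equal(tr$numerator[j], num)
      if (den > 0) expect_equal(tr$proportion[j], num / den)
    }
  }
})

test_that("attrition report walks the hierarchy root to leaf", {
  ds <- generate_fixture(fixture_spec(eligible_untreated = 5,
                                      eligible_treated = 3, no_followup = 2,
                                      prior_aom = 1, seed = 13))
  mart <- new_patient_mart()
  res <- run_batch(fracture_study_chain(), ds, mart, lib)

  root_only <- attrition_report(mart, res[[1]]$case_number)
  expect_equal(unique(root_only$case_number), res[[1]]$case_number)
  expect_equal(root_only$step[1], "index")

  leaf <- attrition_report(mart, res[[2]]$case_number)
  expect_equal(unique(leaf$case_number),
               c(res[[1]]$case_number, res[[2]]$case_number))
  # remaining counts never increase inside a list, and each list's rows
  # reproduce its own attrition record
  expect_equal(leaf$remaining[leaf$case_number == res[[1]]$case_number],
               res[[1]]$attrition$remaining)
  expect_equal(leaf$remaining[leaf$case_number == res[[2]]$case_number],
               res[[2]]$attrition$remaining)
  expect_error(attrition_report(mart, "no-such-case"), "no patient list")

  # forced by construction: 5 + 3 eligible members keep follow-up
  expect_equal(leaf$remaining[nrow(leaf)], 8)
})

test_that("a three-deep chain reports in topological order", {
  ds <- generate_fixture(fixture_spec(eligible_untreated = 4,
                                      eligible_treated = 4, seed = 19))
  obs <- observation_window("2010-01-01", "2014-12-31")
  idx <- index_rule("osteoporotic_fracture", first_ever = FALSE)
  mart <- new_patient_mart()
  s1 <- identification_spec("root", obs, idx)
  s2 <- identification_spec("mid", obs, idx, source_list = "root",
                            criteria = list(
                              criterion("fu", "require_presence",
                                        encounter = TRUE, window = c(1, 90))))
  s3 <- identification_spec("leaf", obs, idx, source_list = "mid",
                            criteria = list(
                              criterion("rx", "require_presence",
                                        template = "aom", window = c(1, 365))))
  res <- run_batch(list(s1, s2, s3), ds, mart, lib)
  rep <- attrition_report(mart, res[[3]]$case_number)
  expect_equal(unique(rep$topic), c("root", "mid", "leaf"))
  expect_equal(rep$remaining[nrow(rep)], 4)
})
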