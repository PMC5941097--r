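# Patient-level data mart: a reference-semantics collection of identified
# patient lists, keyed by case number, plus the append-only audit log of
# identification runs.

#' Create an empty patient-level data mart
#'
#' The mart collects every identified patient list under its case number so
#' later identifications can chain from earlier results (hierarchical
#' sub-cohorts), and accumulates an audit log of runs. It has reference
#' semantics: [run_identification()] and [run_batch()] store their results in
#' place.
#'
#' @return A `patient_mart`.
#' @export
new_patient_mart <- function() {
  env <- new.env(parent = emptyenv())
  env$lists <- list()
  env$audit <- empty_audit()
  structure(list(env = env), class = "patient_mart")
}

empty_audit <- function() {
  tibble::tibble(timestamp = character(), case_number = character(),
                 topic = character(), cost_seconds = numeric(),
                 n_identified = integer(), status = character(),
                 message = character())
}

#' @export
print.patient_mart <- function(x, ...) {
  cat(sprintf("<patient_mart> %d list(s)\n", length(x$env$lists)))
  for (pl in x$env$lists) {
    cat(sprintf("  %s  n=%d  topic=%s%s\n", pl$case_number,
                nrow(pl$members), pl$topic,
                if (is.null(pl$parent)) "" else paste0("  parent=", pl$parent)))
  }
  invisible(x)
}

mart_add <- function(mart, pl) {
  stopifnot(inherits(mart, "patient_mart"), inherits(pl, "patient_list"))
  mart$env$lists[[pl$case_number]] <- pl
  invisible(mart)
}

#' Retrieve a patient list from the mart
#'
#' `ref` may be a case number or a topic; a topic resolves to the most
#' recently stored list with that topic (which is how queued study files
#' chain by topic before case numbers exist).
#'
#' @param mart A `patient_mart`.
#' @param ref Case number or topic.
#' @return The `patient_list`; error if unresolvable.
#' @export
mart_get <- function(mart, ref) {
  stopifnot(inherits(mart, "patient_mart"))
  pl <- mart$env$lists[[ref]]
  if (!is.null(pl)) return(pl)
  topics <- vapply(mart$env$lists, `[[`, "", "topic")
  hit <- which(topics == ref)
  if (!length(hit)) stop("no patient list with case number or topic '",
                         ref, "'")
  mart$env$lists[[hit[length(hit)]]]
}

#' @rdname mart_get
#' @export
mart_cases <- function(mart) names(mart$env$lists)

#' Audit log of identification runs
#'
#' One row per queued task, in execution order: timestamp, case number,
#' topic, elapsed cost in seconds, number of patients identified, and status
#' (`ok` or `error` with the message).
#'
#' @param mart A `patient_mart`.
#' @return A tibble.
#' @export
mart_audit <- function(mart) mart$env$audit

mart_log <- function(mart, row) {
  mart$env$audit <- dplyr::bind_rows(mart$env$audit, row)
  invisible(mart)
}

# version-4 UUID; uniqueness within a session is the contract, member sets
# (not identifiers) carry the determinism guarantee
uuid4 <- function() {
  h <- sample(c(0:9, letters[1:6]), 32, replace = TRUE)
  h[13] <- "4"
  h[17] <- sample(c("8", "9", "a", "b"), 1)
  paste0(paste(h[1:8], collapse = ""), "-", paste(h[9:12], collapse = ""),
         "-", paste(h[13:16], collapse = ""), "-",
         paste(h[17:20], collapse = ""), "-",
         paste(h[21:32], collapse = ""))
}

new_patient_list <- function(case_number, topic, parent, members, attrition,
                             observation, cost_seconds) {
  structure(list(case_number = case_number, topic = topic, parent = parent,
                 members = members, attrition = attrition,
                 observation = observation,
                 created_at = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                 cost_seconds = cost_seconds),
            class = "patient_list")
}

#' @export
print.patient_list <- function(x, ...) {
  cat(sprintf("<patient_list> %s  topic='%s'  n=%d%s\n", x$case_number,
              x$topic, nrow(x$members),
              if (is.null(x$parent)) "" else paste0("  parent=", x$parent)))
  print(x$attrition)
  invisible(x)
}

#' Run one cohort identification
#'
#' Executes the pipeline: resolve the source list (if chained), find index
#' dates under the index rule, then apply the criteria in declared order,
#' recording an attrition entry per step. A patient removable by several
#' criteria is counted only under the first one that removes it (sequential
#' attribution). The result — a `patient_list` with a fresh version-4 UUID
#' case number, the attrition record and the elapsed cost — is stored in the
#' mart and returned. An empty index set is a valid empty list, with the
#' attrition still recorded.
#'
#' @param ds An [ehr_dataset()].
#' @param spec An [identification_spec()].
#' @param mart A [new_patient_mart()]; the result is stored into it.
#' @param templates Template library resolving all template references.
#' @return The `patient_list`.
#' @export
run_identification <- function(ds, spec, mart = new_patient_mart(),
                               templates = builtin_templates()) {
  stopifnot(inherits(spec, "identification_spec"))
  t0 <- proc.time()[["elapsed"]]

  # fail before any evaluation if a reference does not resolve
  get_template(templates, spec$index$template)
  for (cr in spec$criteria) {
    if (!is.null(cr$template)) get_template(templates, cr$template)
  }
  source <- if (!is.null(spec$source_list)) mart_get(mart, spec$source_list)

  members <- find_index_dates(ds, spec$index, spec$observation, templates,
                              source = source)
  attrition <- tibble::tibble(label = "index", excluded = NA_integer_,
                              remaining = nrow(members))
  for (cr in spec$criteria) {
    res <- apply_criterion(ds, members, cr, templates)
    members <- res$members
    attrition <- dplyr::bind_rows(
      attrition, tibble::tibble(label = cr$label,
                                excluded = as.integer(res$excluded),
                                remaining = nrow(members)))
  }
  stopifnot(attrition$remaining[1] - sum(attrition$excluded, na.rm = TRUE) ==
              nrow(members))

  pl <- new_patient_list(
    case_number = uuid4(), topic = spec$topic,
    parent = if (!is.null(source)) source$case_number,
    members = members, attrition = attrition,
    observation = spec$observation,
    cost_seconds = proc.time()[["elapsed"]] - t0
  )
  mart_add(mart, pl)
  pl
}

#' Run a queue of identifications first-in-first-out
#'
#' Executes the specs strictly in submission order against the same dataset
#' and mart, appending one audit-log entry per task. A failing spec is logged
#' with its error message and skipped; subsequent specs still run (so a
#' chained spec whose parent failed will itself fail and be logged, not abort
#' the queue).
#'
#' @param specs List of [identification_spec()] objects (the queue).
#' @param ds An [ehr_dataset()].
#' @param mart A [new_patient_mart()].
#' @param templates Template library.
#' @return List of the successful `patient_list` results, in execution order;
#'   inspect [mart_audit()] for the full log.
#' @export
run_batch <- function(specs, ds, mart = new_patient_mart(),
                      templates = builtin_templates()) {
  results <- list()
  for (spec in specs) {
    started <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    topic <- if (inherits(spec, "identification_spec")) spec$topic
             else NA_character_
    res <- tryCatch(run_identification(ds, spec, mart, templates),
                    error = function(e) e)
    if (inherits(res, "error")) {
      mart_log(mart, tibble::tibble(
        timestamp = started, case_number = NA_character_, topic = topic,
        cost_seconds = NA_real_, n_identified = NA_integer_,
        status = "error", message = conditionMessage(res)))
    } else {
      mart_log(mart, tibble::tibble(
        timestamp = started, case_number = res$case_number, topic = res$topic,
        cost_seconds = res$cost_seconds, n_identified = nrow(res$members),
        status = "ok", message = NA_character_))
      results[[length(results) + 1]] <- res
    }
  }
  results
}
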