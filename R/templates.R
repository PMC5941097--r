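#' Code-matching patterns
#'
#' A code pattern is the atom of a clinical-order template. Three kinds are
#' supported:
#'
#' * `exact` — the code equals the stored value (string equality). This is the
#'   only kind allowed outside the diagnosis dimension; drug identifiers are
#'   matched against a controlled vocabulary of canonical lowercase names.
#' * `prefix` — an ICD-9 category prefix such as `"820"`: matches the bare
#'   category itself or any dotted subcode (`"820"`, `"820.21"`), but never a
#'   code whose category merely shares leading digits (`"8200"` does not
#'   match).
#' * `range` — an inclusive range of 3-digit ICD-9 categories such as
#'   140--208: the code's leading 3-character category, parsed as an integer,
#'   must lie in `[low, high]`. Non-numeric categories (V and E codes) never
#'   match a numeric range.
#'
#' @param value Code string (exact) or category prefix (prefix).
#' @param low,high Inclusive integer 3-digit ICD-9 category bounds.
#' @return A `code_pattern` list.
#' @export
pattern_exact <- function(value) {
  stopifnot(is.character(value), length(value) == 1, nzchar(value))
  structure(list(kind = "exact", value = value), class = "code_pattern")
}

#' @rdname pattern_exact
#' @export
pattern_prefix <- function(value) {
  stopifnot(is.character(value), length(value) == 1, nzchar(value))
  structure(list(kind = "prefix", value = value), class = "code_pattern")
}

#' @rdname pattern_exact
#' @export
pattern_range <- function(low, high) {
  low <- as.integer(low); high <- as.integer(high)
  stopifnot(!is.na(low), !is.na(high), low <= high)
  structure(list(kind = "range", low = low, high = high),
            class = "code_pattern")
}

#' Define a reusable clinical-order template
#'
#' A template is a named, shareable set of code patterns on one clinical
#' dimension — the unit a cohort definition refers to when it says "a
#' diagnosis of malignant neoplasm" or "a dispensing of an anti-osteoporosis
#' medication". Range patterns are only meaningful for ICD-9 diagnosis codes
#' and are rejected elsewhere; pharmacy templates must use exact drug-name
#' patterns.
#'
#' @param name Unique template name.
#' @param dimension One of `diagnosis`, `pharmacy`, `procedure`, `laboratory`.
#' @param patterns Non-empty list of [pattern_exact()], [pattern_prefix()],
#'   [pattern_range()] objects.
#' @param description Free-text description.
#' @param public Whether the template is flagged as publicly shared.
#' @return A `template` object.
#' @export
template <- function(name, dimension, patterns, description = "",
                     public = TRUE) {
  stopifnot(is.character(name), length(name) == 1, nzchar(name))
  if (!dimension %in% DIMENSIONS) {
    stop("unknown dimension '", dimension, "' for template '", name, "'")
  }
  if (!is.list(patterns) || !length(patterns)) {
    stop("template '", name, "' needs a non-empty pattern list")
  }
  patterns <- lapply(patterns, function(p) {
    if (!inherits(p, "code_pattern")) stop("not a code_pattern")
    p
  })
  kinds <- vapply(patterns, `[[`, "", "kind")
  if (dimension != "diagnosis" && any(kinds == "range")) {
    stop("range patterns are only valid for diagnosis templates ('",
         name, "')")
  }
  if (dimension == "pharmacy" && any(kinds != "exact")) {
    stop("pharmacy templates use exact drug-identifier patterns only ('",
         name, "')")
  }
  structure(list(name = name, dimension = dimension, patterns = patterns,
                 description = description, public = isTRUE(public)),
            class = "template")
}

#' @export
print.template <- function(x, ...) {
  cat(sprintf("<template> %s [%s], %d pattern(s)\n", x$name, x$dimension,
              length(x$patterns)))
  invisible(x)
}

#' Match a clinical code against a template
#'
#' Returns `TRUE` iff any of the template's patterns matches the code. Exact
#' patterns use string equality; prefix patterns match the bare ICD-9
#' category or the category followed by a dotted subcode; range patterns
#' compare the integer value of the code's leading 3-character category
#' against the inclusive bounds, and never match codes whose category is not
#' an integer (V/E codes).
#'
#' @param code Code string (vectorised).
#' @param template A [template()].
#' @return Logical vector, one element per code.
#' @examples
#' lib <- builtin_templates()
#' match_code(c("820.21", "8200", "807.0"), lib$templates$hip_fracture)
#' match_code(c("151.9", "209.0", "V10.3"), lib$templates$malignancy)
#' @export
match_code <- function(code, template) {
  stopifnot(inherits(template, "template"))
  code <- as.character(code)
  out <- rep(FALSE, length(code))
  cat3 <- substr(code, 1, 3)
  cat_int <- suppressWarnings(
    ifelse(grepl("^[0-9]{3}", code), as.integer(cat3), NA_integer_))
  for (p in template$patterns) {
    hit <- switch(p$kind,
      exact = code == p$value,
      prefix = code == p$value | startsWith(code, paste0(p$value, ".")),
      range = !is.na(cat_int) & cat_int >= p$low & cat_int <= p$high,
      stop("unknown pattern kind: ", p$kind)
    )
    out <- out | hit
  }
  out & nzchar(code)
}

#' Built-in template library for the osteoporotic-fracture study
#'
#' The packaged study's code sets: hip fracture (ICD-9 category 820),
#' vertebral fracture (805, 806), their union, malignant neoplasm (categories
#' 140--208), Paget disease of bone (731.0), and the nine anti-osteoporosis
#' medications (AOMs) ascertained as treatment — alendronate, zolendronate,
#' ibandronate, denosumab, raloxifene, teriparatide, estradiol valerate,
#' conjugated estrogens, calcitonin — as canonical lowercase drug names.
#'
#' @return A `template_library`.
#' @export
builtin_templates <- function() {
  aom_drugs <- c("alendronate", "zolendronate", "ibandronate", "denosumab",
                 "raloxifene", "teriparatide", "estradiol valerate",
                 "conjugated estrogens", "calcitonin")
  template_library(list(
    template("hip_fracture", "diagnosis", list(pattern_prefix("820")),
             "Hip fracture (ICD-9 820)"),
    template("vertebral_fracture", "diagnosis",
             list(pattern_prefix("805"), pattern_prefix("806")),
             "Vertebral fracture (ICD-9 805, 806)"),
    template("osteoporotic_fracture", "diagnosis",
             list(pattern_prefix("820"), pattern_prefix("805"),
                  pattern_prefix("806")),
             "Hip or vertebral fracture (ICD-9 820, 805, 806)"),
    template("malignancy", "diagnosis", list(pattern_range(140, 208)),
             "Malignant neoplasm (ICD-9 140-208)"),
    template("paget", "diagnosis", list(pattern_exact("731.0")),
             "Paget disease of bone (ICD-9 731.0)"),
    template("aom", "pharmacy", lapply(aom_drugs, pattern_exact),
             "Anti-osteoporosis medications (9 drugs)")
  ))
}

#' Template library: a name-keyed collection of templates
#'
#' @param templates List of [template()] objects; names must be unique.
#' @return A `template_library` with a name-keyed `templates` list.
#' @export
template_library <- function(templates = list()) {
  nms <- vapply(templates, `[[`, "", "name")
  if (anyDuplicated(nms)) {
    stop("duplicate template name(s): ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  }
  structure(list(templates = setNames(templates, nms)),
            class = "template_library")
}

#' @export
print.template_library <- function(x, ...) {
  cat(sprintf("<template_library> %d template(s): %s\n", length(x$templates),
              paste(names(x$templates), collapse = ", ")))
  invisible(x)
}

#' Look up a template by name
#' @param lib A `template_library`.
#' @param name Template name.
#' @return The [template()]; error if absent.
#' @export
get_template <- function(lib, name) {
  stopifnot(inherits(lib, "template_library"))
  tpl <- lib$templates[[name]]
  if (is.null(tpl)) stop("template '", name, "' not found in library")
  tpl
}

pattern_to_list <- function(p) {
  if (p$kind == "range") list(kind = "range", low = p$low, high = p$high)
  else list(kind = p$kind, value = p$value)
}

pattern_from_list <- function(x, where) {
  kind <- x$kind
  if (is.null(kind)) stop("pattern without kind in template '", where, "'")
  switch(kind,
    exact = pattern_exact(x$value),
    prefix = pattern_prefix(x$value),
    range = pattern_range(x$low, x$high),
    stop("unknown pattern kind '", kind, "' in template '", where, "'")
  )
}

#' Save or load a template library as a YAML document
#'
#' One schema-versioned YAML document per library:
#' `{version, templates: [{name, dimension, description, public,
#' patterns: [{kind, value | low, high}]}]}`. Loading is the exact inverse of
#' saving; duplicate template names or unknown dimensions abort with the
#' offending name.
#'
#' @param lib A `template_library`.
#' @param path File path.
#' @return `load_library` returns the library; `save_library` its path,
#'   invisibly.
#' @export
save_library <- function(lib, path) {
  stopifnot(inherits(lib, "template_library"))
  doc <- list(
    version = 1L,
    templates = lapply(unname(lib$templates), function(t) {
      list(name = t$name, dimension = t$dimension,
           description = t$description, public = t$public,
           patterns = lapply(t$patterns, pattern_to_list))
    })
  )
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' @rdname save_library
#' @export
load_library <- function(path) {
  if (!file.exists(path)) stop("missing template library file: ", path)
  doc <- yaml::read_yaml(path)
  if (is.null(doc$templates)) stop("not a template library document: ", path)
  tpls <- lapply(doc$templates, function(t) {
    template(name = t$name, dimension = t$dimension,
             patterns = lapply(t$patterns, pattern_from_list, where = t$name),
             description = t$description %||% "",
             public = t$public %||% TRUE)
  })
  template_library(tpls)
}
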