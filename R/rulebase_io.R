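# Reader/writer for the rule-base document format.
#
# A rule-base document is YAML or JSON with two top-level keys: `conditions`
# (the catalogue) and `rules`. The normative structural description ships at
# inst/schema/rulebase-schema.json; parse_rulebase() enforces the same
# constraints and reports every violation with the offending rule id and path.

#' Parse a rule-base document
#'
#' Validates and converts an already-deserialized document (a nested list as
#' produced by [yaml::read_yaml()] or `jsonlite::fromJSON(simplifyVector =
#' FALSE)`) into a rule base. Premise sets are de-duplicated; union order is
#' preserved as written. `default_code` in documents is a 1-based index.
#'
#' @param doc Nested list with top-level `conditions` and `rules`.
#' @return A validated [rule_base()].
#' @seealso [read_rulebase()] to parse directly from a file.
#' @export
parse_rulebase <- function(doc) {
  if (!is.list(doc))
    rf_abort("document must be a mapping with 'conditions' and 'rules'",
             "rf_error_malformed")
  conds <- doc$conditions %||% list()
  rules <- doc$rules %||% list()
  extra <- setdiff(names(doc), c("conditions", "rules"))
  if (length(extra))
    rf_abort(sprintf("unknown top-level key(s): %s", paste(extra, collapse = ", ")),
             "rf_error_malformed")
  if (!is.list(conds) || !is.list(rules))
    rf_abort("'conditions' and 'rules' must be lists", "rf_error_malformed")

  conditions <- lapply(seq_along(conds), function(i) {
    c_ <- conds[[i]]
    path <- sprintf("conditions[%d]", i)
    if (!is.list(c_) || is.null(c_$id) || is.null(c_$kind))
      rf_abort(sprintf("%s: each condition needs 'id' and 'kind'", path),
               "rf_error_malformed")
    if (!as.character(c_$kind)[1] %in% c("clinical", "nonclinical"))
      rf_abort(sprintf("%s (id '%s'): kind must be 'clinical' or 'nonclinical'",
                       path, c_$id), "rf_error_malformed")
    codes <- unlist(c_$codes) %||% character(0)
    condition(as.character(c_$id), c_$kind,
              label = c_$label %||% as.character(c_$id),
              category = c_$category %||% "general and other",
              codes = codes,
              default_code = c_$default_code %||%
                (if (length(codes)) 1L else NA_integer_))
  })

  parsed_rules <- lapply(seq_along(rules), function(i) {
    r <- rules[[i]]
    path <- sprintf("rules[%d]", i)
    if (!is.list(r) || is.null(r$id))
      rf_abort(sprintf("%s: each rule needs an 'id'", path), "rf_error_malformed")
    known <- c("id", "present_clinical", "present_nonclinical",
               "absent_clinical", "absent_nonclinical", "unions", "action")
    extra <- setdiff(names(r), known)
    if (length(extra))
      rf_abort(sprintf("%s (id '%s'): unknown key(s) %s", path, r$id,
                       paste(extra, collapse = ", ")), "rf_error_malformed")
    unions <- lapply(r$unions %||% list(), function(u) {
      if (!is.list(u))
        rf_abort(sprintf("%s (id '%s'): each union must be a mapping with 'clinical'/'nonclinical'",
                         path, r$id), "rf_error_malformed")
      list(clinical = unlist(u$clinical) %||% character(0),
           nonclinical = unlist(u$nonclinical) %||% character(0))
    })
    clinical_rule(as.character(r$id),
                  present_clinical = unlist(r$present_clinical) %||% character(0),
                  present_nonclinical = unlist(r$present_nonclinical) %||% character(0),
                  absent_clinical = unlist(r$absent_clinical) %||% character(0),
                  absent_nonclinical = unlist(r$absent_nonclinical) %||% character(0),
                  unions = unions,
                  action = r$action %||% "")
  })
  rule_base(conditions, parsed_rules)
}

#' Serialize a rule base to a document
#'
#' Inverse of [parse_rulebase()]: `parse_rulebase(serialize_rulebase(rb))`
#' reproduces `rb` up to set ordering.
#'
#' @param rb A rule base.
#' @return A nested list ready for [yaml::write_yaml()] or
#'   [jsonlite::toJSON()].
#' @export
serialize_rulebase <- function(rb) {
  list(
    conditions = lapply(unname(rb$catalogue), function(c_) {
      out <- list(id = c_$id, kind = c_$kind, label = c_$label,
                  category = c_$category)
      if (length(c_$codes)) {
        out$codes <- as.list(c_$codes)
        out$default_code <- c_$default_code
      }
      out
    }),
    rules = lapply(unname(rb$rules), function(r) {
      out <- list(id = r$id)
      for (slot in c("present_clinical", "present_nonclinical",
                     "absent_clinical", "absent_nonclinical"))
        if (length(r[[slot]])) out[[slot]] <- as.list(r[[slot]])
      if (length(r$unions))
        out$unions <- lapply(r$unions, function(u) {
          uu <- list()
          if (length(u$clinical)) uu$clinical <- as.list(u$clinical)
          if (length(u$nonclinical)) uu$nonclinical <- as.list(u$nonclinical)
          uu
        })
      out$action <- r$action
      out
    })
  )
}

#' Read and write rule-base files
#'
#' The format is chosen from the file extension: `.yaml`/`.yml` for YAML,
#' `.json` for JSON.
#'
#' @param path File path.
#' @return `read_rulebase()` returns a validated [rule_base()];
#'   `write_rulebase()` returns `path` invisibly.
#' @examples
#' rb <- load_fixture("stoppstart_demo")
#' f <- tempfile(fileext = ".yaml")
#' write_rulebase(rb, f)
#' identical_sets <- read_rulebase(f)$m == rb$m
#' @export
read_rulebase <- function(path) {
  if (!file.exists(path))
    rf_abort(sprintf("no such file: %s", path), "rf_error_malformed")
  doc <- switch(tolower(tools::file_ext(path)),
    "yaml" = , "yml" = yaml::read_yaml(path),
    "json" = jsonlite::fromJSON(path, simplifyVector = FALSE),
    rf_abort(sprintf("unsupported extension for '%s' (use .yaml/.yml/.json)", path),
             "rf_error_malformed"))
  parse_rulebase(doc)
}

#' @rdname read_rulebase
#' @param rb A rule base.
#' @export
write_rulebase <- function(rb, path) {
  doc <- serialize_rulebase(rb)
  switch(tolower(tools::file_ext(path)),
    "yaml" = , "yml" = yaml::write_yaml(doc, path),
    "json" = writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE,
                                         null = "null"), path),
    rf_abort(sprintf("unsupported extension for '%s' (use .yaml/.yml/.json)", path),
             "rf_error_malformed"))
  invisible(path)
}

#' Serialize compiled display rules
#'
#' Display rules use the same document dialect as clinical rules, with three
#' added per-rule fields: `target` (the clinical condition the rule displays),
#' `generator` (which of the five compilation formulas produced it) and
#' `source_rule` (the originating clinical rule id).
#'
#' @param drules List of display rules from [compile_all()].
#' @return A list with one entry per display rule.
#' @export
serialize_display_rules <- function(drules) {
  lapply(drules, function(r) {
    out <- list(id = r$id)
    for (slot in c("present_clinical", "present_nonclinical",
                   "absent_clinical", "absent_nonclinical"))
      if (length(r[[slot]])) out[[slot]] <- as.list(r[[slot]])
    if (length(r$unions))
      out$unions <- lapply(r$unions, function(u) {
        uu <- list()
        if (length(u$clinical)) uu$clinical <- as.list(u$clinical)
        if (length(u$nonclinical)) uu$nonclinical <- as.list(u$nonclinical)
        uu
      })
    out$target <- r$target
    out$generator <- r$generator
    out$source_rule <- r$source_rule
    out
  })
}
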