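# Domain types for conditions and clinical rules, and the rule-base document
# format (YAML or JSON).
#
# A clinical rule is the 6-element tuple (Cp, Dp, Ca, Da, U, A): clinical and
# non-clinical conditions that must be present, clinical and non-clinical
# conditions that must be absent, a list of disjunctive unions (each a pair of
# a clinical set and a non-clinical set, at least one member of which must be
# true), and an opaque action. Condition identity is the id token; terminology
# codes (ICD10/ATC/LOINC) are carried as opaque display metadata and never
# used in rule evaluation.

# The 13 default anatomical/etiological grouping categories used to organize
# the questionnaire.
#' @rdname condition
#' @export
default_categories <- c(
  "cardiology", "vascular", "respiratory", "digestive system", "urogenital",
  "endocrinology and metabolism", "neurology", "psychiatry",
  "musculoskeletal", "dermatology", "ophthalmology and ENT",
  "infectious diseases", "general and other"
)

#' Conditions and the condition catalogue
#'
#' A condition is either *clinical* (a diagnosis or symptom, entered manually
#' through the questionnaire, typically coded with ICD10) or *non-clinical*
#' (a drug prescription or lab result, assumed already known and coded, ATC or
#' LOINC). A condition may carry several terminology codes; `default_code` is
#' the 1-based index of the most general one, preselected when the user checks
#' the condition.
#'
#' @param id Unique token identifying the condition within a catalogue.
#' @param kind `"clinical"` or `"nonclinical"`.
#' @param label Free-text label shown to the user.
#' @param category Grouping category name (see `default_categories`).
#' @param codes Character vector of terminology code strings (possibly empty).
#' @param default_code 1-based index into `codes` of the most general code.
#' @return An object of class `rf_condition`.
#' @examples
#' condition("constipation", "clinical", "History of constipation",
#'           category = "digestive system", codes = "ICD10:K59.0")
#' @export
condition <- function(id, kind = c("clinical", "nonclinical"), label = id,
                      category = "general and other", codes = character(0),
                      default_code = if (length(codes)) 1L else NA_integer_) {
  kind <- match.arg(kind)
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    rf_abort("condition id must be a non-empty string", "rf_error_malformed")
  codes <- as.character(codes)
  if (length(codes)) {
    default_code <- as.integer(default_code)
    if (is.na(default_code) || default_code < 1L || default_code > length(codes))
      rf_abort(sprintf("condition '%s': default_code out of range", id),
               "rf_error_malformed")
  } else {
    default_code <- NA_integer_
  }
  structure(
    list(id = id, kind = kind, label = as.character(label)[1],
         category = as.character(category)[1], codes = codes,
         default_code = default_code),
    class = "rf_condition"
  )
}

#' Clinical rules as 6-element tuples
#'
#' Constructs one guideline rule: the conjunction of all `present_*`
#' conditions, the negations of all `absent_*` conditions, and, for every
#' union, the disjunction of its members, concluding in `action`. All premise
#' slots are sets of condition ids; unions are identified by their list index
#' within the rule.
#'
#' @param id Rule id token.
#' @param present_clinical,present_nonclinical Ids that must be present.
#' @param absent_clinical,absent_nonclinical Ids that must be absent.
#' @param unions List of unions, each `list(clinical = ids, nonclinical = ids)`
#'   with at least one member; a union is satisfied when at least one member is
#'   true.
#' @param action Opaque action descriptor, e.g. `"start(fibre)"`.
#' @return An object of class `rf_rule`.
#' @examples
#' clinical_rule("D2",
#'   present_clinical = c("constipation", "diverticulosis"),
#'   absent_nonclinical = "fibre", action = "start(fibre)")
#' @export
clinical_rule <- function(id, present_clinical = character(0),
                          present_nonclinical = character(0),
                          absent_clinical = character(0),
                          absent_nonclinical = character(0),
                          unions = list(), action = "") {
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    rf_abort("rule id must be a non-empty string", "rf_error_malformed")
  unions <- lapply(unions, function(u) {
    list(clinical = as_id_set(u$clinical), nonclinical = as_id_set(u$nonclinical))
  })
  structure(
    list(id = id,
         present_clinical = as_id_set(present_clinical),
         present_nonclinical = as_id_set(present_nonclinical),
         absent_clinical = as_id_set(absent_clinical),
         absent_nonclinical = as_id_set(absent_nonclinical),
         unions = unions,
         action = as.character(action)[1]),
    class = "rf_rule"
  )
}

#' Rule bases
#'
#' A rule base bundles a condition catalogue with a list of clinical rules and
#' validates every cross-reference: each id mentioned by a rule must exist in
#' the catalogue with the matching kind, no id may occupy two roles within one
#' rule, every union must have at least one member, and every rule premise
#' must be non-empty.
#'
#' @param conditions List of [condition()] objects (the catalogue).
#' @param rules List of [clinical_rule()] objects.
#' @return An object of class `rf_rulebase` with elements `catalogue`,
#'   `rules`, `n` (number of clinical conditions) and `m` (number of rules).
#' @seealso [read_rulebase()], [load_fixture()]
#' @export
rule_base <- function(conditions = list(), rules = list()) {
  if (inherits(conditions, "rf_condition")) conditions <- list(conditions)
  if (inherits(rules, "rf_rule")) rules <- list(rules)
  ids <- vapply(conditions, function(x) x$id, character(1))
  if (anyDuplicated(ids))
    rf_abort(sprintf("duplicate condition id(s): %s",
                     paste(unique(ids[duplicated(ids)]), collapse = ", ")),
             "rf_error_malformed")
  kinds <- vapply(conditions, function(x) x$kind, character(1))
  names(kinds) <- ids
  rule_ids <- vapply(rules, function(r) r$id, character(1))
  if (anyDuplicated(rule_ids))
    rf_abort(sprintf("duplicate rule id(s): %s",
                     paste(unique(rule_ids[duplicated(rule_ids)]), collapse = ", ")),
             "rf_error_malformed")
  for (r in rules) validate_rule(r, kinds)
  names(conditions) <- ids
  names(rules) <- rule_ids
  structure(
    list(catalogue = conditions, rules = rules,
         n = sum(kinds == "clinical"), m = length(rules)),
    class = "rf_rulebase"
  )
}

# Validate one rule against the catalogue kind map (named chr id -> kind).
#' @keywords internal
#' @noRd
validate_rule <- function(rule, kinds) {
  where <- function(slot) sprintf("rule '%s', %s", rule$id, slot)
  check_refs <- function(ids, want, slot) {
    unknown <- setdiff(ids, names(kinds))
    if (length(unknown))
      rf_abort(sprintf("%s: unknown condition id(s) %s", where(slot),
                       paste(unknown, collapse = ", ")),
               "rf_error_unknown_ref")
    bad <- ids[kinds[ids] != want]
    if (length(bad))
      rf_abort(sprintf("%s: id(s) %s are not %s conditions", where(slot),
                       paste(bad, collapse = ", "), want),
               "rf_error_kind_mismatch")
  }
  check_refs(rule$present_clinical, "clinical", "present_clinical")
  check_refs(rule$absent_clinical, "clinical", "absent_clinical")
  check_refs(rule$present_nonclinical, "nonclinical", "present_nonclinical")
  check_refs(rule$absent_nonclinical, "nonclinical", "absent_nonclinical")
  for (k in seq_along(rule$unions)) {
    u <- rule$unions[[k]]
    check_refs(u$clinical, "clinical", sprintf("unions[%d].clinical", k))
    check_refs(u$nonclinical, "nonclinical", sprintf("unions[%d].nonclinical", k))
    if (length(u$clinical) + length(u$nonclinical) == 0L)
      rf_abort(sprintf("%s: union has no members", where(sprintf("unions[%d]", k))),
               "rf_error_empty_premise")
  }
  all_ids <- c(rule$present_clinical, rule$present_nonclinical,
               rule$absent_clinical, rule$absent_nonclinical,
               unlist(lapply(rule$unions, function(u) c(u$clinical, u$nonclinical))))
  if (anyDuplicated(all_ids))
    rf_abort(sprintf("rule '%s': condition id(s) %s appear in more than one role",
                     rule$id,
                     paste(unique(all_ids[duplicated(all_ids)]), collapse = ", ")),
             "rf_error_duplicate_role")
  if (length(all_ids) == 0L)
    rf_abort(sprintf("rule '%s': premise is empty", rule$id),
             "rf_error_empty_premise")
  invisible(rule)
}

#' @rdname rule_base
#' @param rb A rule base.
#' @export
clinical_ids <- function(rb) {
  ids <- names(rb$catalogue)
  ids[vapply(rb$catalogue, function(x) x$kind, character(1)) == "clinical"]
}

#' @rdname rule_base
#' @export
nonclinical_ids <- function(rb) {
  ids <- names(rb$catalogue)
  ids[vapply(rb$catalogue, function(x) x$kind, character(1)) == "nonclinical"]
}

#' @rdname rule_base
#' @param rule_ids Rule ids to keep.
#' @export
rulebase_subset <- function(rb, rule_ids) {
  missing <- setdiff(rule_ids, names(rb$rules))
  if (length(missing))
    rf_abort(sprintf("unknown rule id(s): %s", paste(missing, collapse = ", ")),
             "rf_error_unknown_ref")
  rule_base(unname(rb$catalogue), unname(rb$rules[rule_ids]))
}

#' @export
print.rf_rulebase <- function(x, ...) {
  cat(sprintf("Rule base: %d clinical conditions, %d non-clinical, %d rules\n",
              x$n, length(x$catalogue) - x$n, x$m))
  for (r in x$rules) cat("  ", format_rule(r), "\n", sep = "")
  invisible(x)
}

#' @keywords internal
#' @noRd
format_premise <- function(r) {
  parts <- c(
    r$present_clinical, r$present_nonclinical,
    if (length(r$absent_clinical)) paste0("¬", r$absent_clinical),
    if (length(r$absent_nonclinical)) paste0("¬", r$absent_nonclinical),
    vapply(r$unions, function(u)
      paste0("(", paste(c(u$clinical, u$nonclinical), collapse = " ∨ "), ")"),
      character(1))
  )
  if (!length(parts)) "True" else paste(parts, collapse = " ∧ ")
}

#' @keywords internal
#' @noRd
format_rule <- function(r) {
  concl <- if (!is.null(r$target)) sprintf("display(%s)", r$target) else r$action
  sprintf("%s: %s → %s", r$id %||% "", format_premise(r), concl)
}

#' @keywords internal
#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
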