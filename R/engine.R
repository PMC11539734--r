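# Closed-world rule evaluation and interactive questionnaire sessions.
#
# Evaluation is two-valued and closed-world: a condition absent from the
# profile's truth sets is false. This mirrors routine clinical reasoning - a
# patient is considered not to have a disorder unless it is recorded - and is
# what makes an unordered questionnaire workable: unanswered questions simply
# count as "no".

#' Patient profiles
#'
#' A profile is a closed-world truth assignment: `nonclinical_true` lists the
#' drugs/lab facts that hold, `clinical_checked` the clinical conditions
#' currently asserted true; everything else is false. `code_choice`
#' optionally maps a clinical id to the terminology code selected in its
#' drop-down; it never affects rule evaluation, which is id-based.
#'
#' @param rb A rule base (for id/kind validation).
#' @param nonclinical_true Non-clinical ids that are true.
#' @param clinical_checked Clinical ids asserted true.
#' @param code_choice Named list mapping clinical ids to a code string.
#' @return An object of class `rf_profile`.
#' @export
patient_profile <- function(rb, nonclinical_true = character(0),
                            clinical_checked = character(0),
                            code_choice = list()) {
  nonclinical_true <- as_id_set(nonclinical_true)
  clinical_checked <- as_id_set(clinical_checked)
  bad_nc <- setdiff(nonclinical_true, nonclinical_ids(rb))
  bad_cl <- setdiff(clinical_checked, clinical_ids(rb))
  if (length(bad_nc))
    rf_abort(sprintf("not non-clinical condition id(s): %s",
                     paste(bad_nc, collapse = ", ")), "rf_error_unknown_id")
  if (length(bad_cl))
    rf_abort(sprintf("not clinical condition id(s): %s",
                     paste(bad_cl, collapse = ", ")), "rf_error_unknown_id")
  structure(list(nonclinical_true = nonclinical_true,
                 clinical_checked = clinical_checked,
                 code_choice = code_choice),
            class = "rf_profile")
}

#' Evaluate a rule premise against a profile
#'
#' A premise holds when every present condition is true, no absent condition
#' is true, and each union has at least one true member (clinical or
#' non-clinical). The empty premise is vacuously true. Total function: never
#' errors on a valid premise/profile pair.
#'
#' @param premise A clinical or display rule (the six premise slots are read).
#' @param profile A [patient_profile()].
#' @return `TRUE` or `FALSE`.
#' @export
premise_satisfied <- function(premise, profile) {
  cl <- profile$clinical_checked
  nc <- profile$nonclinical_true
  if (!all(premise$present_clinical %in% cl)) return(FALSE)
  if (!all(premise$present_nonclinical %in% nc)) return(FALSE)
  if (any(premise$absent_clinical %in% cl)) return(FALSE)
  if (any(premise$absent_nonclinical %in% nc)) return(FALSE)
  for (u in premise$unions)
    if (!any(u$clinical %in% cl) && !any(u$nonclinical %in% nc)) return(FALSE)
  TRUE
}

#' Clinical rules triggered by a profile
#'
#' @param rb A rule base.
#' @param profile A [patient_profile()].
#' @return Character vector of the ids of the rules whose premise is
#'   satisfied.
#' @export
triggered_rules <- function(rb, profile) {
  ids <- names(rb$rules)
  ids[vapply(rb$rules, premise_satisfied, logical(1), profile = profile)]
}

#' Conditions the questionnaire must display
#'
#' The displayed set is the union over all satisfied display rules of their
#' target conditions: a pure recomputation with no fixpoint (display-rule
#' conclusions never feed premises).
#'
#' @param display_rules Display rules from [compile_all()].
#' @param profile A [patient_profile()].
#' @return Character vector of clinical ids to display.
#' @export
displayed_conditions <- function(display_rules, profile) {
  sat <- vapply(display_rules, premise_satisfied, logical(1), profile = profile)
  unique(vapply(display_rules[sat], function(r) r$target, character(1)))
}

#' Interactive questionnaire sessions
#'
#' `new_session()` initializes the questionnaire state for a profile;
#' [step_session()] applies one user event. The state records the displayed
#' set, which conditions newly appeared or disappeared at the last step (the
#' interface highlights appearances), the displayed conditions grouped by
#' catalogue category, and every condition ever displayed.
#'
#' @param rb A rule base.
#' @param display_rules Display rules compiled from `rb`.
#' @param profile Starting [patient_profile()] (default: empty, no drugs).
#' @return An object of class `rf_session`.
#' @export
new_session <- function(rb, display_rules, profile = patient_profile(rb)) {
  displayed <- displayed_conditions(display_rules, profile)
  structure(
    list(profile = profile, displayed = displayed,
         newly_appeared = character(0), disappeared_last_step = character(0),
         by_category = group_by_category(rb, displayed),
         ever_displayed = displayed),
    class = "rf_session"
  )
}

#' @keywords internal
#' @noRd
group_by_category <- function(rb, ids) {
  if (!length(ids)) return(list())
  cats <- vapply(rb$catalogue[ids], function(x) x$category, character(1))
  split(ids, cats)
}

#' Apply one user event to a session
#'
#' Events: `check`/`uncheck` a *currently displayed* clinical condition (a
#' checked condition that is hidden keeps its value silently; it can only
#' change through explicit profile edits, mirroring EHR-import corrections),
#' `set_drug`/`unset_drug` a non-clinical condition, or `choose_code` to pick
#' a terminology code for a checked condition (never affects evaluation).
#' After the profile update the display rules are re-executed and the
#' appeared/disappeared diffs recomputed.
#'
#' @param rb A rule base.
#' @param display_rules Display rules compiled from `rb`.
#' @param session An `rf_session` from [new_session()].
#' @param event One of `"check"`, `"uncheck"`, `"set_drug"`, `"unset_drug"`,
#'   `"choose_code"`.
#' @param id Condition id the event refers to.
#' @param code Code string (for `choose_code` only).
#' @return The updated `rf_session`.
#' @export
step_session <- function(rb, display_rules, session,
                         event = c("check", "uncheck", "set_drug",
                                   "unset_drug", "choose_code"),
                         id, code = NULL) {
  event <- match.arg(event)
  if (!id %in% names(rb$catalogue))
    rf_abort(sprintf("unknown condition id '%s'", id), "rf_error_unknown_id")
  kind <- rb$catalogue[[id]]$kind
  profile <- session$profile
  if (event %in% c("check", "uncheck", "choose_code")) {
    if (kind != "clinical")
      rf_abort(sprintf("'%s' is not a clinical condition", id),
               "rf_error_kind_mismatch")
  } else if (kind != "nonclinical") {
    rf_abort(sprintf("'%s' is not a non-clinical condition", id),
             "rf_error_kind_mismatch")
  }
  if (event %in% c("check", "uncheck") && !id %in% session$displayed)
    rf_abort(sprintf("condition '%s' is not currently displayed", id),
             "rf_error_not_displayed")

  if (event == "check") {
    profile$clinical_checked <- union(profile$clinical_checked, id)
    cc <- rb$catalogue[[id]]
    if (length(cc$codes) && is.null(profile$code_choice[[id]]))
      profile$code_choice[[id]] <- cc$codes[[cc$default_code]]
  } else if (event == "uncheck") {
    profile$clinical_checked <- setdiff(profile$clinical_checked, id)
    profile$code_choice[[id]] <- NULL
  } else if (event == "set_drug") {
    profile$nonclinical_true <- union(profile$nonclinical_true, id)
  } else if (event == "unset_drug") {
    profile$nonclinical_true <- setdiff(profile$nonclinical_true, id)
  } else if (event == "choose_code") {
    cc <- rb$catalogue[[id]]
    if (is.null(code) || !code %in% cc$codes)
      rf_abort(sprintf("'%s' is not a code of condition '%s'", code %||% "", id),
               "rf_error_unknown_id")
    profile$code_choice[[id]] <- code
  }

  before <- session$displayed
  displayed <- displayed_conditions(display_rules, profile)
  structure(
    list(profile = profile, displayed = displayed,
         newly_appeared = setdiff(displayed, before),
         disappeared_last_step = setdiff(before, displayed),
         by_category = group_by_category(rb, displayed),
         ever_displayed = union(session$ever_displayed, displayed)),
    class = "rf_session"
  )
}

#' Ground-truth patients and full-knowledge profiles
#'
#' `ground_truth_profile()` turns a complete ground-truth assignment (as from
#' [gen_patient()]) into the profile of a fully informed user: every true
#' clinical condition checked, every true non-clinical condition set.
#'
#' @param rb A rule base.
#' @param truth A ground truth: list with `clinical_true` and
#'   `nonclinical_true` character vectors (closed world: unlisted ids are
#'   false).
#' @return A [patient_profile()].
#' @export
ground_truth_profile <- function(rb, truth) {
  patient_profile(rb, nonclinical_true = truth$nonclinical_true,
                  clinical_checked = truth$clinical_true)
}

#' Simulate a full data-entry session
#'
#' Starting from the patient's known drugs/labs and an empty clinical
#' checklist, repeatedly answers the questionnaire truthfully according to a
#' ground-truth assignment until the displayed set stabilizes. The default
#' `"greedy"` policy checks, in each round, every displayed unchecked
#' condition that is true (re-verifying visibility before each check, since a
#' check can hide other conditions); `"single"` checks one condition per
#' round (first in catalogue order), exposing any order sensitivity. A custom
#' policy is a `function(session, truth)` returning the clinical ids to check
#' next (empty to stop); custom policies are guarded by `step_cap`.
#'
#' The trace's `questions_asked` counts the distinct clinical conditions ever
#' displayed - the evaluation metric for questionnaire size - and `triggered`
#' holds the clinical rules that fire on the final profile.
#'
#' @param rb A rule base.
#' @param display_rules Display rules compiled from `rb` (default: compile
#'   under declaration order).
#' @param truth Ground truth (see [ground_truth_profile()]).
#' @param policy `"greedy"`, `"single"`, or a function.
#' @param step_cap Maximum number of events (default `10 * n` clinical
#'   conditions); exceeding it raises an error.
#' @return An object of class `rf_trace`: `events` (list of
#'   event/displayed-set snapshots), `final_profile`, `questions_asked`,
#'   `triggered`.
#' @examples
#' rb <- rulebase_subset(load_fixture("stoppstart_demo"), c("D2", "D6"))
#' tr <- simulate_session(rb, compile_all(rb),
#'   truth = list(clinical_true = c("constipation", "diverticulosis"),
#'                nonclinical_true = character(0)))
#' tr$questions_asked  # 2
#' tr$triggered        # "D2"
#' @export
simulate_session <- function(rb, display_rules = compile_all(rb), truth,
                             policy = "greedy",
                             step_cap = 10L * max(1L, rb$n)) {
  truth$clinical_true <- as_id_set(truth$clinical_true)
  truth$nonclinical_true <- as_id_set(truth$nonclinical_true)
  session <- new_session(rb, display_rules,
                         patient_profile(rb, nonclinical_true = truth$nonclinical_true))
  pick <- if (is.function(policy)) {
    policy
  } else if (identical(policy, "greedy")) {
    function(session, truth)
      setdiff(intersect(session$displayed, truth$clinical_true),
              session$profile$clinical_checked)
  } else if (identical(policy, "single")) {
    function(session, truth) {
      cand <- setdiff(intersect(session$displayed, truth$clinical_true),
                      session$profile$clinical_checked)
      # first candidate in catalogue order
      cand <- cand[order(match(cand, clinical_ids(rb)))]
      utils::head(cand, 1L)
    }
  } else {
    rf_abort("policy must be 'greedy', 'single', or a function",
             "rf_error_malformed")
  }

  events <- list()
  n_events <- 0L
  repeat {
    to_check <- pick(session, truth)
    if (!length(to_check)) break
    progressed <- FALSE
    for (x in to_check) {
      # a check earlier in this round may have hidden x or (custom policy)
      # it may already be checked
      if (!x %in% session$displayed ||
          x %in% session$profile$clinical_checked) next
      n_events <- n_events + 1L
      if (n_events > step_cap)
        rf_abort(sprintf("session exceeded the step cap of %d events", step_cap),
                 "rf_error_step_cap")
      session <- step_session(rb, display_rules, session, "check", x)
      events[[length(events) + 1L]] <-
        list(event = "check", id = x, displayed = session$displayed)
      progressed <- TRUE
    }
    if (!progressed) break
  }
  structure(
    list(events = events, final_profile = session$profile,
         questions_asked = length(session$ever_displayed),
         ever_displayed = session$ever_displayed,
         triggered = triggered_rules(rb, session$profile)),
    class = "rf_trace"
  )
}

#' @export
print.rf_trace <- function(x, ...) {
  cat(sprintf("Session: %d events, %d condition(s) asked, %d rule(s) triggered\n",
              length(x$events), x$questions_asked, length(x$triggered)))
  if (length(x$triggered))
    cat("  triggered:", paste(x$triggered, collapse = ", "), "\n")
  invisible(x)
}
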