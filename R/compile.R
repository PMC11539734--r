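# Display-rule generation.
#
# A display rule concludes display(x) for a clinical condition x: x must be
# shown in the questionnaire whenever the rule's premise is satisfied. Five
# generators translate each clinical rule, given a strict total priority
# order over the clinical conditions (earlier conditions are asked first and
# gate the display of later ones):
#
#   p  - per present clinical condition: show x once every strictly preceding
#        present condition is true and the rest of the premise (drugs, absent
#        conditions, fully-preceding unions) holds.
#   a1 - per absent clinical condition: show x once all other premise parts
#        hold (absent conditions are asked last, since conditions are more
#        likely false than true).
#   a2 - per absent clinical condition: show x when x itself is true, so a
#        value imported from outside the questionnaire (e.g. an EHR extract)
#        can be reviewed and unchecked.
#   u1 - per clinical union member: show x while no member of its union is
#        true and the preceding premise parts hold.
#   u2 - per clinical union member: show x when x itself is true (same
#        review rationale as a2).

#' Condition priority orders
#'
#' A condition order is a character vector listing every clinical condition of
#' the rule base exactly once; `c1` precedes `c2` in the questionnaire
#' whenever `c1` comes earlier in the vector. `condition_order()` validates a
#' sequence (default: catalogue declaration order).
#'
#' @param rb A rule base.
#' @param sequence Permutation of the clinical condition ids, or `NULL` for
#'   declaration order.
#' @return The validated character vector.
#' @export
condition_order <- function(rb, sequence = NULL) {
  cl <- clinical_ids(rb)
  if (is.null(sequence)) return(cl)
  sequence <- as.character(sequence)
  if (length(sequence) != length(cl) || !setequal(sequence, cl) ||
      anyDuplicated(sequence))
    rf_abort("order must list every clinical condition exactly once",
             "rf_error_incomplete_order")
  sequence
}

#' @keywords internal
#' @noRd
order_pos <- function(order) stats::setNames(seq_along(order), order)

#' @keywords internal
#' @noRd
new_display_rule <- function(source_rule, generator, target,
                             present_clinical = character(0),
                             present_nonclinical = character(0),
                             absent_clinical = character(0),
                             absent_nonclinical = character(0),
                             unions = list()) {
  structure(
    list(id = paste(source_rule, generator, target, sep = "."),
         present_clinical = as_id_set(present_clinical),
         present_nonclinical = as_id_set(present_nonclinical),
         absent_clinical = as_id_set(absent_clinical),
         absent_nonclinical = as_id_set(absent_nonclinical),
         unions = unions,
         target = target, generator = generator, source_rule = source_rule),
    class = "rf_display_rule"
  )
}

# Unions whose clinical members all strictly precede x; a union with no
# clinical member is retained (the universal guard is vacuously true).
#' @keywords internal
#' @noRd
fully_preceding_unions <- function(unions, x, pos, exclude_index = 0L) {
  keep <- vapply(seq_along(unions), function(k) {
    if (k == exclude_index) return(FALSE)
    cl <- unions[[k]]$clinical
    length(cl) == 0L || all(pos[cl] < pos[x])
  }, logical(1))
  unions[keep]
}

#' Compile one present clinical condition
#'
#' Generator `p`: the display rule for `x` in the rule's present set keeps the
#' strictly preceding present clinical conditions, the full drug premise, the
#' full absent premise, and only those unions whose clinical members all
#' precede `x`.
#'
#' @param rule A clinical rule.
#' @param x A clinical condition id in the rule's `present_clinical`.
#' @param order A condition order (see [condition_order()]).
#' @return A display rule.
#' @examples
#' rb <- load_fixture("stoppstart_demo")
#' compile_present(rb$rules$D2, "diverticulosis", condition_order(rb))
#' @export
compile_present <- function(rule, x, order) {
  if (!x %in% rule$present_clinical)
    rf_abort(sprintf("rule '%s': '%s' is not in present_clinical", rule$id, x),
             "rf_error_unknown_ref")
  pos <- order_pos(order)
  new_display_rule(rule$id, "p", x,
    present_clinical = rule$present_clinical[pos[rule$present_clinical] < pos[x]],
    present_nonclinical = rule$present_nonclinical,
    absent_clinical = rule$absent_clinical,
    absent_nonclinical = rule$absent_nonclinical,
    unions = fully_preceding_unions(rule$unions, x, pos))
}

#' Compile one absent clinical condition
#'
#' Generators `a1` and `a2`. `a1` shows `x` once every other premise part of
#' the rule holds (absent conditions are asked last). `a2` shows `x` whenever
#' `x` is already true and the preceding absent conditions hold, so that a
#' value set outside the questionnaire can be reviewed and removed.
#'
#' @inheritParams compile_present
#' @param x A clinical condition id in the rule's `absent_clinical`.
#' @return A list of two display rules, `a1` and `a2`.
#' @export
compile_absent <- function(rule, x, order) {
  if (!x %in% rule$absent_clinical)
    rf_abort(sprintf("rule '%s': '%s' is not in absent_clinical", rule$id, x),
             "rf_error_unknown_ref")
  pos <- order_pos(order)
  a1 <- new_display_rule(rule$id, "a1", x,
    present_clinical = rule$present_clinical,
    present_nonclinical = rule$present_nonclinical,
    absent_clinical = setdiff(rule$absent_clinical, x),
    absent_nonclinical = rule$absent_nonclinical,
    unions = rule$unions)
  a2 <- new_display_rule(rule$id, "a2", x,
    present_clinical = x,
    present_nonclinical = rule$present_nonclinical,
    absent_clinical = rule$absent_clinical[pos[rule$absent_clinical] < pos[x]],
    absent_nonclinical = rule$absent_nonclinical,
    unions = list())
  list(a1 = a1, a2 = a2)
}

#' Compile one clinical union member
#'
#' Generators `u1` and `u2` for a clinical condition `x` in union `k`. `u1`
#' shows `x` while no member of union `k` is true (the union's members move to
#' the absent slots) and the preceding premise parts hold; `u2` shows `x`
#' whenever `x` itself is true. Other unions are kept only when all their
#' clinical members strictly precede `x`; "other" is decided by union index,
#' not set equality. The self-negation of `x` is omitted from `u1`'s absent
#' set: it is redundant, because whenever `x` is true the `u2` companion rule
#' displays `x` under a weaker premise, so the displayed set is unchanged and
#' no display rule's premise mentions its own target negatively.
#'
#' @inheritParams compile_present
#' @param k Union index (1-based) within the rule.
#' @param x A clinical condition id in the clinical part of union `k`.
#' @return A list of two display rules, `u1` and `u2`.
#' @export
compile_union_member <- function(rule, k, x, order) {
  if (k < 1L || k > length(rule$unions))
    rf_abort(sprintf("rule '%s': no union with index %d", rule$id, k),
             "rf_error_unknown_ref")
  u <- rule$unions[[k]]
  if (!x %in% u$clinical)
    rf_abort(sprintf("rule '%s': '%s' is not a clinical member of union %d",
                     rule$id, x, k), "rf_error_unknown_ref")
  pos <- order_pos(order)
  pre_p <- rule$present_clinical[pos[rule$present_clinical] < pos[x]]
  others <- fully_preceding_unions(rule$unions, x, pos, exclude_index = k)
  u1 <- new_display_rule(rule$id, "u1", x,
    present_clinical = pre_p,
    present_nonclinical = rule$present_nonclinical,
    absent_clinical = union(rule$absent_clinical, setdiff(u$clinical, x)),
    absent_nonclinical = union(rule$absent_nonclinical, u$nonclinical),
    unions = others)
  u2 <- new_display_rule(rule$id, "u2", x,
    present_clinical = c(pre_p, x),
    present_nonclinical = rule$present_nonclinical,
    absent_clinical = rule$absent_clinical,
    absent_nonclinical = rule$absent_nonclinical,
    unions = others)
  list(u1 = u1, u2 = u2)
}

#' Compile a whole rule base into display rules
#'
#' Applies every generator to every clinical rule: one `p` rule per present
#' clinical condition, one `a1`/`a2` pair per absent clinical condition, and
#' one `u1`/`u2` pair per clinical member of every union. The total count is
#' therefore `sum(|Cp| + 2 |Ca| + 2 * sum_k |Cuk|)` over the rules; rules
#' whose premises mention no clinical condition produce no display rules.
#' Duplicate display rules from different sources are kept, with provenance.
#'
#' @param rb A rule base.
#' @param order A condition order covering all clinical conditions of `rb`
#'   (default: declaration order).
#' @return A list of display rules (class `rf_display_rules`).
#' @examples
#' rb <- rulebase_subset(load_fixture("stoppstart_demo"), c("D2", "D6"))
#' length(compile_all(rb, condition_order(rb)))  # 6
#' @export
compile_all <- function(rb, order = condition_order(rb)) {
  order <- condition_order(rb, order)
  out <- vector("list", 0L)
  for (rule in rb$rules) {
    for (x in rule$present_clinical)
      out[[length(out) + 1L]] <- compile_present(rule, x, order)
    for (x in rule$absent_clinical) {
      pair <- compile_absent(rule, x, order)
      out[[length(out) + 1L]] <- pair$a1
      out[[length(out) + 1L]] <- pair$a2
    }
    for (k in seq_along(rule$unions))
      for (x in rule$unions[[k]]$clinical) {
        pair <- compile_union_member(rule, k, x, order)
        out[[length(out) + 1L]] <- pair$u1
        out[[length(out) + 1L]] <- pair$u2
      }
  }
  structure(out, class = "rf_display_rules")
}

#' @export
print.rf_display_rules <- function(x, ...) {
  cat(sprintf("%d display rules\n", length(x)))
  for (r in x) cat("  ", format_rule(r), "\n", sep = "")
  invisible(x)
}

#' @export
`[.rf_display_rules` <- function(x, i) {
  structure(unclass(x)[i], class = "rf_display_rules")
}
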