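# Shared fixtures and oracles, all built in code.

# The two published example rules, alone.
demo_rb <- function() rulebase_subset(load_fixture("stoppstart_demo"), c("D2", "D6"))

# Compact builder: conditions from ids, rules from premise lists.
# rules: named list, each element list(pc=, pn=, ac=, an=, unions=list(list(cl=, nc=)))
tiny_rb <- function(clinical, nonclinical = character(0), rules = list()) {
  conds <- c(lapply(clinical, condition, kind = "clinical"),
             lapply(nonclinical, condition, kind = "nonclinical"))
  rl <- lapply(names(rules), function(id) {
    r <- rules[[id]]
    clinical_rule(id,
      present_clinical = r$pc %||% character(0),
      present_nonclinical = r$pn %||% character(0),
      absent_clinical = r$ac %||% character(0),
      absent_nonclinical = r$an %||% character(0),
      unions = lapply(r$unions %||% list(), function(u)
        list(clinical = u$cl %||% character(0),
             nonclinical = u$nc %||% character(0))),
      action = "act")
  })
  rule_base(conds, rl)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Restricted rule base (pure present-clinical conjunctions) over c1..cn.
restricted_rb <- function(n, rule_sets) {
  conds <- lapply(paste0("c", seq_len(n)), condition, kind = "clinical")
  rl <- lapply(seq_along(rule_sets), function(i)
    clinical_rule(paste0("r", i), present_clinical = rule_sets[[i]], action = "act"))
  rule_base(conds, rl)
}

# Normal form for rule-base equality up to set ordering.
normalize_rb <- function(rb) {
  list(
    conditions = lapply(rb$catalogue[order(names(rb$catalogue))], function(c_)
      list(id = c_$id, kind = c_$kind, label = c_$label, category = c_$category,
           codes = c_$codes, default_code = c_$default_code)),
    rules = lapply(rb$rules[order(names(rb$rules))], function(r)
      list(id = r$id,
           pc = sort(r$present_clinical), pn = sort(r$present_nonclinical),
           ac = sort(r$absent_clinical), an = sort(r$absent_nonclinical),
           unions = lapply(r$unions, function(u)
             list(cl = sort(u$clinical), nc = sort(u$nonclinical))),
           action = r$action))
  )
}

expect_rb_equal <- function(a, b) expect_equal(normalize_rb(a), normalize_rb(b))

# Premise structure of a display rule as sorted sets, for structural
# comparison against hand-written expectations.
premise_of <- function(r) {
  list(pc = sort(r$present_clinical), pn = sort(r$present_nonclinical),
       ac = sort(r$absent_clinical), an = sort(r$absent_nonclinical),
       unions = lapply(r$unions, function(u)
         list(cl = sort(u$clinical), nc = sort(u$nonclinical))))
}

expect_display_rule <- function(dr, target, generator, pc = character(0),
                                pn = character(0), ac = character(0),
                                an = character(0), unions = list()) {
  expect_equal(dr$target, target)
  expect_equal(dr$generator, generator)
  expect_equal(premise_of(dr),
               list(pc = sort(pc), pn = sort(pn), ac = sort(ac), an = sort(an),
                    unions = unions))
}

# Independent premise evaluator used as an oracle against the engine: a
# literal transcription of "present true, absent false, each union has a true
# member" that shares no code with premise_satisfied().
oracle_premise <- function(r, clinical_true, nonclinical_true) {
  truths <- c(clinical_true, nonclinical_true)
  ok <- all(c(r$present_clinical, r$present_nonclinical) %in% truths) &&
    !any(c(r$absent_clinical, r$absent_nonclinical) %in% truths)
  for (u in r$unions)
    ok <- ok && any(c(u$clinical, u$nonclinical) %in% truths)
  ok
}

# Run a cli_main() call muffling both streams, returning its status.
capture_status <- function(expr) {
  status <- NULL
  suppressMessages(utils::capture.output(
    utils::capture.output(status <- expr, type = "message")))
  status
}

with_seed_shuffle <- function(seed, x) {
  set.seed(seed)
  sample(x)
}

# Closed-form display-rule count.
display_count_formula <- function(rb) {
  sum(vapply(rb$rules, function(r)
    length(r$present_clinical) + 2L * length(r$absent_clinical) +
      2L * sum(vapply(r$unions, function(u) length(u$clinical), integer(1))),
    integer(1)))
}
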