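# The printed worked example: compiling the two demo rules under
# constipation before diverticulosis yields six display rules.
test_that("compiling the demo rules reproduces the printed display rules", {
  rb <- demo_rb()
  ord <- condition_order(rb)  # catalogue order: constipation first
  expect_lt(match("constipation", ord), match("diverticulosis", ord))
  drules <- compile_all(rb, ord)
  expect_length(drules, 6)
  by_id <- setNames(unclass(drules), vapply(drules, `[[`, "", "id"))

  expect_display_rule(by_id[["D2.p.constipation"]], "constipation", "p",
                      an = "fibre")
  expect_display_rule(by_id[["D2.p.diverticulosis"]], "diverticulosis", "p",
                      pc = "constipation", an = "fibre")
  expect_display_rule(by_id[["D6.u1.parkinsonism"]], "parkinsonism", "u1",
                      pn = "antipsychotic", ac = "lewy_body")
  expect_display_rule(by_id[["D6.u2.parkinsonism"]], "parkinsonism", "u2",
                      pc = "parkinsonism", pn = "antipsychotic")
  expect_display_rule(by_id[["D6.u1.lewy_body"]], "lewy_body", "u1",
                      pn = "antipsychotic", ac = "parkinsonism")
  expect_display_rule(by_id[["D6.u2.lewy_body"]], "lewy_body", "u2",
                      pc = "lewy_body", pn = "antipsychotic")
})

test_that("absent-condition compilation follows the two generator formulas", {
  # drugD present, heartFailure must be absent
  rb <- tiny_rb("heart_failure", "drugD",
                rules = list(r = list(pn = "drugD", ac = "heart_failure")))
  pair <- compile_absent(rb$rules$r, "heart_failure", condition_order(rb))
  expect_display_rule(pair$a1, "heart_failure", "a1", pn = "drugD")
  expect_display_rule(pair$a2, "heart_failure", "a2",
                      pc = "heart_failure", pn = "drugD")

  # ask first for the likely-absent present condition, then the absent one
  rb2 <- tiny_rb(c("ankle_edema", "heart_failure"),
                 rules = list(r = list(pc = "ankle_edema", ac = "heart_failure")))
  pair2 <- compile_absent(rb2$rules$r, "heart_failure", condition_order(rb2))
  expect_display_rule(pair2$a1, "heart_failure", "a1", pc = "ankle_edema")

  # singleton absent set: a1 premise is empty, x always displayed
  rb3 <- tiny_rb("x", rules = list(r = list(ac = "x")))
  pair3 <- compile_absent(rb3$rules$r, "x", "x")
  expect_display_rule(pair3$a1, "x", "a1")
  expect_true(premise_satisfied(pair3$a1, patient_profile(rb3)))
})

test_that("single-condition present rules compile to an always-true premise", {
  rb <- tiny_rb("x", rules = list(r = list(pc = "x")))
  dr <- compile_present(rb$rules$r, "x", "x")
  expect_display_rule(dr, "x", "p")
  expect_true(premise_satisfied(dr, patient_profile(rb)))
})

test_that("a singleton clinical union degenerates to self-gated display", {
  rb <- tiny_rb("x", "d",
                rules = list(r = list(pn = "d", unions = list(list(cl = "x")))))
  pair <- compile_union_member(rb$rules$r, 1L, "x", "x")
  # u1: remaining premise, no self-negation (u2 covers the x-true case)
  expect_display_rule(pair$u1, "x", "u1", pn = "d")
  expect_display_rule(pair$u2, "x", "u2", pc = "x", pn = "d")
})

test_that("unions with no clinical member are always retained in premises", {
  rb <- tiny_rb(c("a", "b"), c("d1", "d2"),
                rules = list(r = list(pc = c("a", "b"),
                                      unions = list(list(nc = c("d1", "d2"))))))
  ord <- c("a", "b")
  dr_a <- compile_present(rb$rules$r, "a", ord)
  expect_length(dr_a$unions, 1)  # drug-only union kept even for the first target
  expect_setequal(dr_a$unions[[1]]$nonclinical, c("d1", "d2"))
})

test_that("compilation errors name the misplaced target", {
  rb <- demo_rb()
  ord <- condition_order(rb)
  expect_error(compile_present(rb$rules$D6, "parkinsonism", ord),
               class = "rf_error_unknown_ref")
  expect_error(compile_absent(rb$rules$D2, "constipation", ord),
               class = "rf_error_unknown_ref")
  expect_error(compile_union_member(rb$rules$D6, 2L, "parkinsonism", ord),
               class = "rf_error_unknown_ref")
  expect_error(compile_all(rb, "constipation"),
               class = "rf_error_incomplete_order")
})

test_that("rules without clinical premises generate no display rules", {
  rb <- tiny_rb("c1", c("d1", "d2"),
                rules = list(r = list(pn = "d1", an = "d2")))
  expect_length(compile_all(rb), 0)
})

test_that("the display-rule count obeys its closed form on random bases", {
  for (seed in 0:99) {
    rb <- gen_rulebase(n_clinical = 9, n_nonclinical = 6, m = 5, seed = seed)
    expect_length(compile_all(rb), display_count_formula(rb))
  }
})

test_that("premises are gated monotonically by the priority order", {
  for (seed in 1:20) {
    rb <- gen_rulebase(n_clinical = 8, n_nonclinical = 5, m = 5, seed = seed)
    ord <- with_seed_shuffle(seed, clinical_ids(rb))
    pos <- setNames(seq_along(ord), ord)
    for (dr in compile_all(rb, ord)) {
      src <- rb$rules[[dr$source_rule]]
      if (dr$generator == "p") {
        expect_setequal(dr$present_clinical,
                        src$present_clinical[pos[src$present_clinical] < pos[dr$target]])
        for (u in dr$unions)
          expect_true(length(u$clinical) == 0 || all(pos[u$clinical] < pos[dr$target]))
      }
      # the target never appears in its own premise, except positively in a2/u2
      neg <- c(dr$absent_clinical,
               unlist(lapply(dr$unions, `[[`, "clinical")))
      expect_false(dr$target %in% neg)
      if (dr$generator %in% c("a2", "u2"))
        expect_true(dr$target %in% dr$present_clinical)
      else
        expect_false(dr$target %in% dr$present_clinical)
    }
  }
})
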