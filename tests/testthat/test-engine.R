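test_that("premise evaluation is closed-world over all six slots", {
  rb <- demo_rb()
  d2 <- rb$rules$D2
  d6 <- rb$rules$D6
  # fibre already prescribed violates the absent-drug slot
  expect_false(premise_satisfied(d2, patient_profile(rb, "fibre")))
  expect_false(premise_satisfied(d2, patient_profile(rb)))  # Cp unchecked
  expect_true(premise_satisfied(
    d2, patient_profile(rb, clinical_checked = c("constipation", "diverticulosis"))))
  # one true member satisfies a union
  expect_true(premise_satisfied(
    d6, patient_profile(rb, "antipsychotic", "lewy_body")))
  expect_false(premise_satisfied(d6, patient_profile(rb, "antipsychotic")))
  # empty premise is vacuously true
  empty <- list(present_clinical = character(0), present_nonclinical = character(0),
                absent_clinical = character(0), absent_nonclinical = character(0),
                unions = list())
  expect_true(premise_satisfied(empty, patient_profile(rb, "fibre", "constipation")))
})

test_that("triggered_rules returns exactly the satisfied rules", {
  rb <- demo_rb()
  expect_equal(triggered_rules(rb, patient_profile(
    rb, clinical_checked = c("constipation", "diverticulosis"))), "D2")
  expect_length(triggered_rules(rb, patient_profile(rb)), 0)
  expect_equal(triggered_rules(rb, patient_profile(
    rb, "antipsychotic", "parkinsonism")), "D6")
})

test_that("the displayed set matches the printed interaction behavior", {
  rb <- demo_rb()
  dr <- compile_all(rb)
  expect_equal(displayed_conditions(dr, patient_profile(rb)), "constipation")
  expect_length(displayed_conditions(dr, patient_profile(rb, "fibre")), 0)
  expect_setequal(
    displayed_conditions(dr, patient_profile(rb, clinical_checked = "constipation")),
    c("constipation", "diverticulosis"))
  expect_setequal(
    displayed_conditions(dr, patient_profile(rb, "antipsychotic")),
    c("constipation", "parkinsonism", "lewy_body"))
})

test_that("displayed_conditions agrees with an independent per-rule oracle", {
  for (seed in 1:30) {
    rb <- gen_rulebase(n_clinical = 8, n_nonclinical = 5, m = 5, seed = seed)
    dr <- compile_all(rb)
    truth <- gen_patient(rb, p = 0.4, q = 0.5, seed = seed + 1000)
    profile <- patient_profile(rb, truth$nonclinical_true, truth$clinical_true)
    oracle <- unique(unlist(lapply(dr, function(r)
      if (oracle_premise(r, truth$clinical_true, truth$nonclinical_true)) r$target)))
    expect_setequal(displayed_conditions(dr, profile), oracle %||% character(0))
  }
})

test_that("stepping tracks appearances and disappearances", {
  rb <- demo_rb()
  dr <- compile_all(rb)
  s <- new_session(rb, dr)
  expect_equal(s$displayed, "constipation")
  expect_length(s$newly_appeared, 0)

  s <- step_session(rb, dr, s, "check", "constipation")
  expect_equal(s$newly_appeared, "diverticulosis")
  expect_setequal(s$displayed, c("constipation", "diverticulosis"))
  expect_setequal(s$by_category[["digestive system"]],
                  c("constipation", "diverticulosis"))

  s <- step_session(rb, dr, s, "uncheck", "constipation")
  expect_equal(s$disappeared_last_step, "diverticulosis")
  s <- step_session(rb, dr, s, "check", "constipation")
  expect_true("diverticulosis" %in% s$displayed)  # re-check restores it
})

test_that("checking one union member hides the other but keeps itself shown", {
  rb <- demo_rb()
  dr <- compile_all(rb)
  s <- new_session(rb, dr, patient_profile(rb, "antipsychotic"))
  expect_true(all(c("parkinsonism", "lewy_body") %in% s$displayed))
  s <- step_session(rb, dr, s, "check", "parkinsonism")
  expect_true("lewy_body" %in% s$disappeared_last_step)
  expect_true("parkinsonism" %in% s$displayed)  # sticky via its u2 rule
  # and it stays displayed while its u2 premise (drug present) holds
  s <- step_session(rb, dr, s, "unset_drug", "antipsychotic")
  expect_false("parkinsonism" %in% s$displayed)
})

test_that("hidden conditions silently keep their checked value", {
  rb <- demo_rb()
  dr <- compile_all(rb)
  s <- new_session(rb, dr)
  s <- step_session(rb, dr, s, "check", "constipation")
  s <- step_session(rb, dr, s, "check", "diverticulosis")
  s <- step_session(rb, dr, s, "uncheck", "constipation")
  expect_false("diverticulosis" %in% s$displayed)
  expect_true("diverticulosis" %in% s$profile$clinical_checked)
  # a checked-but-hidden condition still counts toward triggering
  s <- step_session(rb, dr, s, "check", "constipation")
  expect_equal(triggered_rules(rb, s$profile), "D2")
})

test_that("events are validated with distinct error classes", {
  rb <- demo_rb()
  dr <- compile_all(rb)
  s <- new_session(rb, dr)
  expect_error(step_session(rb, dr, s, "check", "ghost"),
               class = "rf_error_unknown_id")
  expect_error(step_session(rb, dr, s, "check", "diverticulosis"),
               class = "rf_error_not_displayed")
  expect_error(step_session(rb, dr, s, "check", "fibre"),
               class = "rf_error_kind_mismatch")
  expect_error(step_session(rb, dr, s, "set_drug", "constipation"),
               class = "rf_error_kind_mismatch")
})

test_that("code choice defaults to the most general term, never affects display", {
  rb <- demo_rb()
  dr <- compile_all(rb)
  s <- new_session(rb, dr, patient_profile(rb, "antipsychotic"))
  s <- step_session(rb, dr, s, "check", "parkinsonism")
  # catalogue lists ICD10:G20 first as the most general term
  expect_equal(s$profile$code_choice[["parkinsonism"]], "ICD10:G20")
  before <- s$displayed
  s <- step_session(rb, dr, s, "choose_code", "parkinsonism", code = "ICD10:G21")
  expect_equal(s$profile$code_choice[["parkinsonism"]], "ICD10:G21")
  expect_setequal(s$displayed, before)
  expect_error(step_session(rb, dr, s, "choose_code", "parkinsonism", code = "nope"),
               class = "rf_error_unknown_id")
})

test_that("simulated sessions reproduce the printed questionnaire sizes", {
  rb <- demo_rb()
  dr <- compile_all(rb)
  tr <- simulate_session(rb, dr, truth = list(
    clinical_true = c("constipation", "diverticulosis"),
    nonclinical_true = character(0)))
  expect_equal(tr$questions_asked, 2L)
  expect_equal(tr$triggered, "D2")

  tr0 <- simulate_session(rb, dr, truth = list(
    clinical_true = character(0), nonclinical_true = character(0)))
  expect_equal(tr0$questions_asked, 1L)  # only constipation ever shown
  expect_length(tr0$triggered, 0)

  trf <- simulate_session(rb, dr, truth = list(
    clinical_true = character(0), nonclinical_true = "fibre"))
  expect_equal(trf$questions_asked, 0L)  # fibre already prescribed
})

test_that("identical event sequences yield identical traces", {
  rb <- gen_rulebase(n_clinical = 8, n_nonclinical = 5, m = 6, seed = 3)
  dr <- compile_all(rb)
  truth <- gen_patient(rb, seed = 4)
  t1 <- simulate_session(rb, dr, truth)
  t2 <- simulate_session(rb, dr, truth)
  expect_identical(t1, t2)
})

test_that("greedy sessions recover full-knowledge triggering on random pairs", {
  for (seed in 1:200) {
    rb <- gen_rulebase(n_clinical = 8, n_nonclinical = 5, m = 6, seed = seed)
    dr <- compile_all(rb)
    truth <- gen_patient(rb, seed = seed + 5000)
    tr <- simulate_session(rb, dr, truth)
    expect_setequal(tr$triggered,
                    triggered_rules(rb, ground_truth_profile(rb, truth)))
  }
})

test_that("the priority order never changes which rules fire", {
  for (seed in 1:50) {
    rb <- gen_rulebase(n_clinical = 7, n_nonclinical = 4, m = 5, seed = seed)
    truth <- gen_patient(rb, seed = seed + 9000)
    ord2 <- with_seed_shuffle(seed, clinical_ids(rb))
    t1 <- simulate_session(rb, compile_all(rb), truth)
    t2 <- simulate_session(rb, compile_all(rb, ord2), truth)
    expect_setequal(t1$triggered, t2$triggered)
  }
})

test_that("single-step policy reaches the same final triggering as greedy", {
  for (seed in 1:25) {
    rb <- gen_rulebase(n_clinical = 7, n_nonclinical = 4, m = 5, seed = seed)
    dr <- compile_all(rb)
    truth <- gen_patient(rb, seed = seed + 400)
    tg <- simulate_session(rb, dr, truth, policy = "greedy")
    ts <- simulate_session(rb, dr, truth, policy = "single")
    expect_setequal(tg$triggered, ts$triggered)
  }
})

test_that("custom policies stall cleanly or hit the step cap", {
  rb <- demo_rb()
  dr <- compile_all(rb)
  # a policy that keeps proposing an already-checked condition stalls cleanly
  tr <- simulate_session(rb, dr, truth = list(
    clinical_true = "constipation", nonclinical_true = character(0)),
    policy = function(session, truth) "constipation")
  expect_equal(tr$final_profile$clinical_checked, "constipation")
  expect_error(
    simulate_session(rb, dr,
      truth = list(clinical_true = "constipation", nonclinical_true = character(0)),
      step_cap = 0L),
    class = "rf_error_step_cap")
})
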