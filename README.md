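# ruleform

Rule-based clinical decision support systems (CDSS) — STOPP/START-style
medication-review guidelines in particular — need patient data that is rarely
available in coded form to the people who run them: community pharmacists do
not have the GP's record, and conditions like "history of constipation" are
seldom coded anywhere. Asking for everything up front produces a form with
dozens of checkboxes, most of them irrelevant for any given patient.

`ruleform` turns such a rule base into an **unordered exhaustive adaptive
questionnaire**: a checklist that starts small, can be answered in any order,
grows only when an answer makes further questions decision-relevant, and is
still guaranteed to surface every condition that can change which rules fire.
It is aimed at health-informatics developers building data-entry front ends
for rule-based CDSS, and at researchers studying questionnaire-size
optimization.

## The model

A clinical rule is a 6-element tuple
`R = (Cp, Dp, Ca, Da, U, A)`: clinical (`C*`) and non-clinical (`D*`, drugs
and lab results, assumed already known and coded) conditions that must be
*present* or *absent*, a set `U` of disjunctive unions (each needing at least
one true member), and an action `A`, e.g.

```
R_D2 = constipation ∧ diverticulosis ∧ ¬fibre → start(fibre)
R_D6 = antipsychotic ∧ (parkinsonism ∨ lewy_body) → stop(antipsychotic)
```

Given a strict priority order `≺` over the clinical conditions, each rule is
compiled into *display rules*, whose conclusion `display(x)` means "clinical
condition `x` must be shown as a checkbox". Five generators cover the three
roles a clinical condition can play (present: `p`; absent: `a1`, `a2`; union
member: `u1`, `u2`); for a present condition `x`,

```
Rp(R, x) = {c ∈ Cp | c ≺ x} ∧ Dp ∧ ¬Ca ∧ ¬Da ∧ {unions entirely ≺ x} → display(x)
```

so earlier conditions gate later ones, drug facts gate everything, and the
`a2`/`u2` variants keep a condition visible once it is true so that values
imported from an EHR can be reviewed and unchecked. The questionnaire shows
the union of all satisfied display rules, re-evaluated (closed-world: an
unanswered question counts as "no") after every user event.

Choosing `≺` to minimize the number of conditions shown before anything is
entered is NP-hard — the package includes the reformulation as a Generalized
Traveling Salesman Problem over the `2^n` subsets of conditions, used as an
exact cross-check — so `ruleform` offers an occurrence-count heuristic, exact
brute force on small instances, and a seeded stochastic permutation search.

## Worked example

```r
library(ruleform)
rb <- rulebase_subset(load_fixture("stoppstart_demo"), c("D2", "D6"))
drules <- compile_all(rb)   # catalogue order: constipation ≺ diverticulosis ≺ ...
print(drules)
#> 6 display rules
#>   D2.p.constipation: ¬fibre → display(constipation)
#>   D2.p.diverticulosis: constipation ∧ ¬fibre → display(diverticulosis)
#>   D6.u1.parkinsonism: antipsychotic ∧ ¬lewy_body → display(parkinsonism)
#>   D6.u2.parkinsonism: parkinsonism ∧ antipsychotic → display(parkinsonism)
#>   D6.u1.lewy_body: antipsychotic ∧ ¬parkinsonism → display(lewy_body)
#>   D6.u2.lewy_body: lewy_body ∧ antipsychotic → display(lewy_body)
```

For a patient with an empty drug order, the initial questionnaire shows a
single checkbox out of 13 clinical conditions; checking it reveals the next
gated condition:

```r
s <- new_session(rb, drules)
s$displayed
#> [1] "constipation"
s <- step_session(rb, drules, s, "check", "constipation")
s$newly_appeared
#> [1] "diverticulosis"
```

A truthful data-entry session for a patient who really has both conditions
asks 2 of the 13 questions and fires exactly the fibre-supplement rule — the
same rules that full knowledge of the patient would fire:

```r
tr <- simulate_session(rb, drules,
  truth = list(clinical_true = c("constipation", "diverticulosis"),
               nonclinical_true = character(0)))
print(tr)
#> Session: 2 events, 2 condition(s) asked, 1 rule(s) triggered
#>   triggered: D2
```

`occurrence_order()`, `brute_force_order()` and `stochastic_order()` compute
priority orders; `initial_display_count()` is the objective they minimize.

## Command line

A thin CLI wraps the same functions:

```sh
inst/exec/ruleform validate --rules base.yaml
inst/exec/ruleform compile  --rules base.yaml --order heuristic
inst/exec/ruleform order    --rules base.yaml --method stochastic --seed 1
inst/exec/ruleform simulate --rules base.yaml --patients 10 --seed 1
inst/exec/ruleform gen      --out base.yaml --m 6 --seed 1
```

All commands emit JSON reports embedding their configuration and seed.

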