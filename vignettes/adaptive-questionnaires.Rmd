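---
title: "Compiling rule bases into adaptive questionnaires: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compiling rule bases into adaptive questionnaires: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ruleform)
```

## The problem

A rule-based clinical decision support system can only run once the
patient's conditions are entered. Drug prescriptions and lab results are
usually available in coded form (ATC, LOINC); diagnoses and symptoms usually
are not, and have to be asked. A fixed checklist of every condition any rule
might need quickly becomes unusable. `ruleform` compiles the rule base
itself into the logic of an *adaptive* checklist that is:

* **unordered** — clinicians can answer in any sequence, and the form stays
  organized by anatomical category rather than by an algorithmic ranking;
* **exhaustive** — every condition that could still change which rules fire
  is eventually shown, so the triggered recommendations after a truthful
  session are exactly those a fully informed run would produce.

## Rule model and working assumptions

Rules are 6-element tuples `(Cp, Dp, Ca, Da, U, A)` over a catalogue of
*clinical* conditions (asked in the questionnaire) and *non-clinical*
conditions (drugs/labs, assumed known). Three assumptions shape the
compilation:

1. fewer visible conditions is better;
2. non-clinical conditions are already coded, so they gate everything and
   are never asked;
3. a clinical condition is more likely false than true in the target
   population, so conditions that must be *present* are asked before
   conditions that must be *absent* (asking "ankle edema?" first and "heart
   failure?" only if edema is present minimizes expected questions).

Lab-test conditions can be modelled on either side: the packaged demo keeps
them non-clinical (e.g. a coded eGFR threshold), but a deployment without a
lab feed can simply declare them clinical.

Evaluation is two-valued and closed-world: unanswered means false. No
three-valued "unknown" state exists; this matches how clinicians read a
record, and it is what makes an unordered form coherent — the displayed set
is a pure function of the current profile.

## The five display-rule generators

Given a strict total priority order `≺` over clinical conditions, each rule
yields, per clinical condition it mentions:

* `p` (present member `x`): keep the strictly `≺`-preceding present
  conditions, the full drug premise, the full absent premise, and the unions
  whose clinical members all precede `x`. Unions with no clinical member are
  always kept — their "all members precede `x`" guard is vacuous.
* `a1` (absent member `x`): every other premise part, absent conditions
  asked last.
* `a2` (absent member `x`): `x` itself plus the `≺`-preceding absent
  conditions — needed so that a value set *outside* the questionnaire (an
  EHR import) keeps its checkbox visible and can be unchecked.
* `u1` (union member `x`): shown while no member of its union is true; the
  union's other members move into the absent slots. We omit the redundant
  self-negation `¬x`: whenever `x` is true its `u2` companion displays `x`
  under a weaker premise, so the displayed set is identical and no display
  rule mentions its own target negatively. This follows the worked examples
  rather than a literal reading of the tuple formula, which includes `¬x`;
  the two compilations are observationally equivalent.
* `u2` (union member `x`): `x` itself plus the preceding premise parts, the
  review/uncheck counterpart of `u1`.

"Other unions" are identified by list index, not set equality — two unions
with the same clinical part but different drug parts would otherwise be
conflated. Duplicate display rules arising from different source rules are
kept: the displayed set is a union, so duplicates are harmless, and the
provenance fields (`source_rule`, `generator`, `target`) make every visible
checkbox explainable. Compilation is eager; only *evaluation* is repeated
when the profile changes. The total count is exactly
`sum(|Cp| + 2|Ca| + 2 Σ_k |Cuk|)` over the rules, which the tests verify on
100 generated bases.

## Sessions

`step_session()` applies one event (check/uncheck a displayed condition,
set/unset a drug, choose a terminology code) and recomputes the displayed
set, recording appearances and disappearances for highlighting. Two policy
decisions the formalism leaves open:

* **Hidden values persist.** Unchecking a gating condition hides its
  dependents but does not clear them; the `a2`/`u2` generators exist
  precisely because values can live outside the visible form. Consequently a
  checked-but-hidden condition still counts toward rule triggering — it is
  in the profile.
* **Code choice is cosmetic.** Checking a multi-code condition selects its
  most general code by default; evaluation is id-based, so the choice never
  changes what is displayed or triggered.

`simulate_session()` drives a whole session against a complete ground-truth
assignment. The default greedy-truthful policy checks every displayed true
condition each round; because a check can hide other conditions (union
members), visibility is re-verified before each individual check. Checked
sets grow monotonically under truthful policies, so termination is
structural; custom policies are guarded by a step cap of `10 n` events. The
central property — exhaustiveness — is tested on 1000 seeded (rule base,
patient) pairs: the rules triggered on the final session profile equal those
triggered under full knowledge, with zero tolerated failures. A companion
property checks that the priority order changes only *how many* questions
are asked, never *which rules fire*.

## The ordering problem

The objective is the number of distinct clinical conditions displayed when
no clinical condition is entered yet (drugs known). Three solvers:

* `occurrence_order()` sorts conditions by decreasing number of rules
  mentioning them (a rule counts once however many slots it uses — roles are
  disjoint by validation anyway), ties by catalogue declaration order. It is
  patient-independent and, in guideline bases whose rules are largely
  independent, already optimal in practice.
* `brute_force_order()` enumerates permutations of the conditions that occur
  in rules (others can never be displayed and are appended), capped at 9
  occurring conditions (≈3.6e5 permutations, seconds on one CPU thanks to a
  precompiled integer objective). Tie-break: lexicographically smallest
  optimal permutation by declaration index. The precompiled objective is
  checked against the definitional compile-and-evaluate route on random
  bases, orders and drug profiles.
* `stochastic_order()` is seeded random-restart hill climbing over adjacent
  transpositions (defaults: 8 restarts, 25 sweeps each). The first restart
  starts at the heuristic order, so its value never exceeds the heuristic's.
  The search stands in for fancier permutation metaheuristics behind the
  same interface; on bases small enough to verify, it finds the exact
  optimum in ≥95% of seeded runs, and on independent-rule bases it ties the
  heuristic exactly — the regime where a metaheuristic has nothing to
  improve.

### The GTSP oracle

For rule bases restricted to pure present-clinical conjunctions (and an
all-false patient), the problem maps to a Generalized TSP: towns are the
`2^n` subsets of conditions (a town = the set already placed in the order),
areas group towns by cardinality, and appending a condition costs 1 exactly
when it newly "gates" some rule. One subtlety: the distance matrix alone
also admits area-respecting travels between *non-nested* towns, whose set
difference can straddle two rules and evade the cost; such travels do not
correspond to any order (a town is, by definition, the set of conditions
placed so far, which only grows one condition at a time). The solver
therefore enumerates nested travels only, which correspond one-to-one to
permutations. `build_gtsp()` materializes towns explicitly and refuses more
than 6 conditions rather than approximate. The reduction is exercised both
ways: on random restricted bases with ≤5 conditions, the GTSP tour cost
equals the direct brute-force optimum and the recovered order attains it
through the real compiler.

Re-ordering mid-session is deliberately not implemented: the objective is
defined on the empty questionnaire, and silently reshuffling a form the user
is filling in would defeat the unordered design.

## Synthetic data

`gen_rulebase()` draws rule shapes from uniform ranges (defaults per rule:
0–3 present clinical, 0–2 absent clinical, 0–2 unions of 1–3 clinical and
0–1 non-clinical members, 0–2 present and 0–1 absent drugs), clipping each
draw to what remains of the catalogue and refusing specs whose minima cannot
fit. `drug_gated_fraction` reproduces the structural signature of
stop-medication rules, all of which carry a present-drug gate: at 1.0 every
rule is drug-gated, at 0.0 none is. `gen_patient()` assigns each clinical
condition true with probability 0.2 — the "more likely false than true"
assumption — and each drug with probability 0.5, as expected in a
polypharmacy population. Those defaults are the study conditions of the test
suite; sparse drug profiles (q = 0.2) are used only where the drug-gated vs
present-driven contrast is the point, and that contrast is asserted
directionally (drug-gated bases open far smaller), not at any particular
magnitude.

What the generator does *not* emulate: the skewed co-occurrence structure of
real guidelines (shared gate conditions across many rules), terminology
subsumption between conditions, and realistic per-condition prevalences.
Passing tests therefore demonstrate the correctness of compilation,
evaluation and optimization — not the questionnaire-size reductions any
particular guideline would achieve.

The packaged `stoppstart_demo` fixture contains the two published example
rule formalizations from STOPP/START v2 (D2, D6) verbatim, plus eight
illustrative rules authored for this package (marked non-normative in the
file) so that every generator kind appears in a realistic catalogue of 13
clinical and 8 non-clinical conditions.

## Degenerate inputs and validation

* A condition in two roles of one rule is rejected, not resolved — no
  published rule exhibits this, and silent resolution would mask encoding
  errors. Every malformation maps to one classed error carrying the rule id.
* Empty premises are rejected for clinical rules but arise legitimately in
  *display* rules (a singleton present or absent set compiles to an
  always-true premise) and evaluate to true.
* Rules mentioning no clinical condition compile to nothing; rule bases with
  no rules yield empty questionnaires and objective 0 everywhere.
* Terminology codes are opaque: evaluation is pinned to id tokens for
  determinism, and hierarchy reasoning ("is-a" collapse) is out of scope.

## Known limitations

* Cardinality premises ("at least x of y conditions") are not compilable.
* The action slot is an opaque label; nothing executes actions.
* No user interface is provided — the session state (categories,
  appeared/disappeared flags) is exactly what a front end needs, but
  rendering is out of scope.
* Exhaustiveness is proven by property testing at scale, not formally.
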