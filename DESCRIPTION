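Package: ruleform
Title: Adaptive Questionnaires Compiled from Rule-Based Clinical Guidelines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Turns a rule-based clinical guideline (STOPP/START-style rules
    over clinical conditions, drugs and lab results) into an unordered
    exhaustive adaptive questionnaire. Clinical rules expressed as 6-element
    tuples are compiled into display rules that decide which clinical
    conditions a data-entry form must show; a closed-world engine evaluates
    rules against patient profiles and drives interactive sessions; and the
    priority order of clinical conditions is optimized to minimize the size
    of the initial questionnaire, with an occurrence-count heuristic, exact
    brute force, a seeded stochastic permutation search, and a generalized
    traveling salesman reformulation used as a verification oracle. Includes
    seeded generators for synthetic rule bases and patients, a packaged demo
    rule base, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
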