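# Seeded generators for rule bases and ground-truth patients, plus packaged
# fixtures. Generated artifacts always pass rule-base validation and are
# reproducible from their seed.

#' Generate a random rule base
#'
#' Draws `m` rules over synthetic catalogues (`c001`, `c002`, ... clinical;
#' `d001`, ... non-clinical; categories assigned round-robin over
#' `default_categories`). Per-rule slot sizes are drawn uniformly from the
#' given inclusive ranges, each draw clipped to what is left of the catalogue
#' for that rule (a union that cannot reach its minimum clinical size is
#' dropped); ids within a rule are sampled without replacement, so roles are
#' disjoint by construction, and a rule that would come out empty is given
#' one present clinical condition. Specs whose range minima cannot fit the
#' catalogue are refused.
#'
#' `drug_gated_fraction` models the structural contrast between guideline
#' families: with probability `drug_gated_fraction` a rule is forced to have
#' at least one present drug (as STOPP-style rules do), otherwise it gets
#' none. Left as `NA`, `dp_range` alone governs the draw.
#'
#' @param n_clinical,n_nonclinical Catalogue sizes.
#' @param m Number of rules.
#' @param present_range,absent_range Ranges for the number of present/absent
#'   clinical conditions per rule.
#' @param union_count_range Range for the number of unions per rule.
#' @param union_size_range Range (min >= 1) for clinical members per union.
#' @param union_nonclinical_range Range for non-clinical members per union.
#' @param dp_range,da_range Ranges for present/absent non-clinical conditions.
#' @param drug_gated_fraction `NA`, or a probability in `[0, 1]`.
#' @param seed Integer seed.
#' @return A validated [rule_base()].
#' @export
gen_rulebase <- function(n_clinical = 8L, n_nonclinical = 6L, m = 6L,
                         present_range = c(0L, 3L), absent_range = c(0L, 2L),
                         union_count_range = c(0L, 2L),
                         union_size_range = c(1L, 3L),
                         union_nonclinical_range = c(0L, 1L),
                         dp_range = c(0L, 2L), da_range = c(0L, 1L),
                         drug_gated_fraction = NA, seed = 1L) {
  if (union_size_range[1] < 1L)
    rf_abort("union_size_range minimum must be >= 1 (unions cannot be empty)",
             "rf_error_infeasible_spec")
  need_cl <- present_range[1] + absent_range[1] +
    union_count_range[1] * union_size_range[1]
  need_nc <- dp_range[1] + da_range[1] +
    union_count_range[1] * union_nonclinical_range[1]
  if (!is.na(drug_gated_fraction) && drug_gated_fraction > 0)
    need_nc <- max(need_nc, 1L)
  if (max(need_cl, 1L) > n_clinical || need_nc > n_nonclinical)
    rf_abort("catalogue too small for the requested minimum per-rule slot sizes",
             "rf_error_infeasible_spec")

  cl_ids <- sprintf("c%03d", seq_len(n_clinical))
  nc_ids <- sprintf("d%03d", seq_len(n_nonclinical))
  conditions <- c(
    lapply(seq_len(n_clinical), function(i)
      condition(cl_ids[i], "clinical", label = sprintf("clinical condition %d", i),
                category = default_categories[(i - 1L) %% length(default_categories) + 1L])),
    lapply(seq_len(n_nonclinical), function(i)
      condition(nc_ids[i], "nonclinical", label = sprintf("drug/lab %d", i),
                category = "general and other"))
  )

  draw <- function(range) {
    if (range[1] >= range[2]) range[1]
    else range[1] + sample.int(range[2] - range[1] + 1L, 1L) - 1L
  }

  rules <- with_rng_seed(seed, lapply(seq_len(m), function(i) {
    avail_cl <- n_clinical
    avail_nc <- n_nonclinical
    n_p <- min(draw(present_range), avail_cl); avail_cl <- avail_cl - n_p
    n_a <- min(draw(absent_range), avail_cl); avail_cl <- avail_cl - n_a
    n_dp <- if (!is.na(drug_gated_fraction)) {
      if (stats::runif(1) < drug_gated_fraction) max(1L, draw(dp_range)) else 0L
    } else {
      draw(dp_range)
    }
    n_dp <- min(n_dp, avail_nc); avail_nc <- avail_nc - n_dp
    n_da <- min(draw(da_range), avail_nc); avail_nc <- avail_nc - n_da
    u_sizes <- integer(0)
    u_nc_sizes <- integer(0)
    for (k in seq_len(draw(union_count_range))) {
      if (avail_cl < union_size_range[1]) break
      s <- min(draw(union_size_range), avail_cl); avail_cl <- avail_cl - s
      snc <- min(draw(union_nonclinical_range), avail_nc); avail_nc <- avail_nc - snc
      u_sizes <- c(u_sizes, s)
      u_nc_sizes <- c(u_nc_sizes, snc)
    }
    n_u <- length(u_sizes)
    if (n_p + n_a + n_u + n_dp + n_da == 0L) n_p <- 1L

    cl_pool <- sample_ids(cl_ids, n_p + n_a + sum(u_sizes))
    nc_pool <- sample_ids(nc_ids, n_dp + n_da + sum(u_nc_sizes))
    take <- function(pool, k, off) if (k) pool[off + seq_len(k)] else character(0)
    off_cl <- 0L
    off_nc <- 0L
    p_cl <- take(cl_pool, n_p, off_cl); off_cl <- off_cl + n_p
    a_cl <- take(cl_pool, n_a, off_cl); off_cl <- off_cl + n_a
    p_nc <- take(nc_pool, n_dp, off_nc); off_nc <- off_nc + n_dp
    a_nc <- take(nc_pool, n_da, off_nc); off_nc <- off_nc + n_da
    unions <- lapply(seq_len(n_u), function(k) {
      ucl <- take(cl_pool, u_sizes[k], off_cl); off_cl <<- off_cl + u_sizes[k]
      unc <- take(nc_pool, u_nc_sizes[k], off_nc); off_nc <<- off_nc + u_nc_sizes[k]
      list(clinical = ucl, nonclinical = unc)
    })
    clinical_rule(sprintf("r%03d", i),
                  present_clinical = p_cl, present_nonclinical = p_nc,
                  absent_clinical = a_cl, absent_nonclinical = a_nc,
                  unions = unions, action = sprintf("act(r%03d)", i))
  }))
  rule_base(conditions, rules)
}

#' Generate a rule base of mutually independent rules
#'
#' Builds `n_rules` pure present-clinical rules over pairwise disjoint
#' condition sets (no condition shared between rules). Under any priority
#' order each rule contributes exactly its order-first condition to the
#' initial questionnaire, so every order is optimal - the regime in which a
#' metaheuristic cannot improve on the occurrence heuristic.
#'
#' @param n_rules Number of rules.
#' @param rule_size Present clinical conditions per rule.
#' @param n_nonclinical Extra non-clinical conditions in the catalogue
#'   (unused by the rules).
#' @param seed Integer seed (shuffles which conditions land in which rule).
#' @return A validated [rule_base()].
#' @export
gen_independent_rulebase <- function(n_rules = 4L, rule_size = 2L,
                                     n_nonclinical = 0L, seed = 1L) {
  n_clinical <- n_rules * rule_size
  cl_ids <- sprintf("c%03d", seq_len(n_clinical))
  nc_ids <- sprintf("d%03d", seq_len(n_nonclinical))
  conditions <- c(
    lapply(seq_along(cl_ids), function(i)
      condition(cl_ids[i], "clinical",
                category = default_categories[(i - 1L) %% length(default_categories) + 1L])),
    lapply(nc_ids, condition, kind = "nonclinical")
  )
  assignment <- with_rng_seed(seed, sample(cl_ids))
  rules <- lapply(seq_len(n_rules), function(i) {
    members <- assignment[(i - 1L) * rule_size + seq_len(rule_size)]
    clinical_rule(sprintf("r%03d", i), present_clinical = members,
                  action = sprintf("act(r%03d)", i))
  })
  rule_base(conditions, rules)
}

#' Generate a complete ground-truth patient
#'
#' Assigns each clinical condition true independently with probability `p`
#' and each non-clinical condition with probability `q`. The defaults encode
#' the working assumptions about the target population: clinical conditions
#' are more likely false than true (`p = 0.2`), while drugs are common in a
#' polypharmacy population (`q = 0.5`).
#'
#' @param rb A rule base.
#' @param p Clinical condition prevalence, in `[0, 1]`.
#' @param q Non-clinical condition prevalence, in `[0, 1]`.
#' @param seed Integer seed.
#' @return A list with `clinical_true` and `nonclinical_true` (closed world:
#'   unlisted ids are false), usable as `truth` in [simulate_session()].
#' @export
gen_patient <- function(rb, p = 0.2, q = 0.5, seed = 1L) {
  if (p < 0 || p > 1 || q < 0 || q > 1)
    rf_abort("prevalences must lie in [0, 1]", "rf_error_infeasible_spec")
  cl <- clinical_ids(rb)
  nc <- nonclinical_ids(rb)
  with_rng_seed(seed, {
    list(clinical_true = cl[stats::runif(length(cl)) < p],
         nonclinical_true = nc[stats::runif(length(nc)) < q])
  })
}

#' Load a packaged demo rule base
#'
#' `"stoppstart_demo"` contains the two published example rules of the
#' STOPP/START v2 guideline formalization - START D2 (start fibre supplements
#' for diverticulosis with a history of constipation) and STOPP D6 (stop
#' antipsychotics in those with parkinsonism or Lewy Body disease) - plus
#' eight additional illustrative rules, authored for this package and
#' non-normative, that exercise every display-rule generator.
#'
#' @param name Fixture name.
#' @return A validated [rule_base()].
#' @examples
#' rb <- load_fixture("stoppstart_demo")
#' rb$rules$D2$present_clinical
#' @export
load_fixture <- function(name = "stoppstart_demo") {
  path <- system.file("extdata", paste0(name, ".yaml"), package = "ruleform")
  if (!nzchar(path))
    rf_abort(sprintf("unknown fixture '%s'", name), "rf_error_unknown_fixture")
  read_rulebase(path)
}
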