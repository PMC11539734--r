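# Condition-ordering optimization.
#
# The ordering problem: choose the priority order over clinical conditions
# that minimizes the number of distinct clinical conditions displayed when no
# clinical condition has been entered yet (drugs/labs already known). The
# problem is NP-hard (see gtsp.R for the reduction used as a verification
# oracle), so three solvers are provided: a patient-independent occurrence
# heuristic, exact brute force on small instances, and a seeded stochastic
# permutation search for patient-specific near-optimal orders.

#' Occurrence-count heuristic order
#'
#' Sorts clinical conditions by decreasing number of occurrences in the
#' rules, a rule contributing once per condition it mentions (in its present
#' set, absent set, or any union). Ties - and conditions absent from every
#' rule - fall back to catalogue declaration order, making the result
#' deterministic and patient-independent.
#'
#' @param rb A rule base.
#' @return A condition order (character vector).
#' @export
occurrence_order <- function(rb) {
  cl <- clinical_ids(rb)
  counts <- stats::setNames(integer(length(cl)), cl)
  for (r in rb$rules) {
    mentioned <- unique(c(r$present_clinical, r$absent_clinical,
                          unlist(lapply(r$unions, `[[`, "clinical"))))
    counts[mentioned] <- counts[mentioned] + 1L
  }
  cl[order(-counts, seq_along(cl))]
}

#' Size of the initial questionnaire under an order
#'
#' Compiles the rule base under `order`, evaluates the display rules against
#' a profile with the given drugs/labs and no clinical condition checked, and
#' counts the distinct conditions displayed. This is the objective the
#' ordering solvers minimize.
#'
#' @param rb A rule base.
#' @param order A condition order.
#' @param nonclinical Non-clinical ids true for this patient.
#' @return Integer count, between 0 and `rb$n`.
#' @export
initial_display_count <- function(rb, order = condition_order(rb),
                                  nonclinical = character(0)) {
  drules <- compile_all(rb, order)
  profile <- patient_profile(rb, nonclinical_true = nonclinical)
  length(displayed_conditions(drules, profile))
}

# ---- fast direct objective --------------------------------------------------
# With no clinical condition checked, which display rules can fire is fully
# determined by the drug profile and the order, so the objective can be read
# off the clinical rules without materializing display rules:
#   p : only the order-first member of Cp can show; it does unless some
#       drug-unsatisfied union has all clinical members before it.
#   a1: shows every Ca member iff Cp is empty and every union is satisfied by
#       a drug member.
#   a2/u2: never fire (their positive clinical premise is unchecked).
#   u1: members of a union with no drug member present show, unless a present
#       clinical condition or a blocking union precedes them.
# brute_force_order() and stochastic_order() evaluate thousands of
# permutations, so the rules are precompiled to integer indices over the
# conditions that occur in rules; equality with the compile+evaluate route is
# asserted by the test suite.

#' @keywords internal
#' @noRd
occurring_ids <- function(rb) {
  cl <- clinical_ids(rb)
  mentioned <- unique(unlist(lapply(rb$rules, function(r)
    c(r$present_clinical, r$absent_clinical,
      unlist(lapply(r$unions, `[[`, "clinical"))))))
  cl[cl %in% mentioned]
}

# Returns list(occurring, fixed (ids always displayed via a1), fn(pos) ->
# integer count). pos[i] = rank of occurring[i] in the order.
#' @keywords internal
#' @noRd
precompile_objective <- function(rb, nonclinical = character(0)) {
  occ <- occurring_ids(rb)
  idx <- stats::setNames(seq_along(occ), occ)
  fixed <- logical(length(occ))
  compiled <- list()
  for (r in rb$rules) {
    if (!all(r$present_nonclinical %in% nonclinical)) next
    if (any(r$absent_nonclinical %in% nonclinical)) next
    drug_ok <- vapply(r$unions, function(u) any(u$nonclinical %in% nonclinical),
                      logical(1))
    has_cl <- vapply(r$unions, function(u) length(u$clinical) > 0L, logical(1))
    # a union with no clinical member and no present drug member can never be
    # satisfied in the initial form: the whole rule is inert
    if (any(!has_cl & !drug_ok)) next
    pc <- unname(idx[r$present_clinical])
    # unions not satisfied by a drug: these block when fully preceding, and
    # only their clinical members can be displayed through u1
    bad_ucl <- lapply(r$unions[has_cl & !drug_ok], function(u) unname(idx[u$clinical]))
    if (!length(pc) && !length(bad_ucl) && length(r$absent_clinical))
      fixed[idx[r$absent_clinical]] <- TRUE
    if (length(pc) || length(bad_ucl))
      compiled[[length(compiled) + 1L]] <- list(pc = pc, bad_ucl = bad_ucl)
  }
  force(fixed)
  fn <- function(pos) {
    disp <- fixed
    for (cr in compiled) {
      pmin <- if (length(cr$pc)) min(pos[cr$pc]) else Inf
      bad_max <- vapply(cr$bad_ucl, function(cl) max(pos[cl]), numeric(1))
      if (length(cr$pc)) {
        x <- cr$pc[which.min(pos[cr$pc])]
        if (!length(bad_max) || min(bad_max) > pos[x]) disp[x] <- TRUE
      }
      for (k in seq_along(cr$bad_ucl)) {
        other_min <- if (length(bad_max) > 1L) min(bad_max[-k]) else Inf
        for (x in cr$bad_ucl[[k]]) {
          px <- pos[x]
          if (pmin < px || other_min < px) next
          disp[x] <- TRUE
        }
      }
    }
    sum(disp)
  }
  list(occurring = occ, fn = fn)
}

# Direct (compiler-free) evaluation of the objective for a full order.
#' @keywords internal
#' @noRd
initial_display_direct <- function(rb, order, nonclinical = character(0)) {
  obj <- precompile_objective(rb, nonclinical)
  if (!length(obj$occurring)) return(0L)
  pos <- rank(match(obj$occurring, order))
  obj$fn(pos)
}

# All permutations of 1..n in lexicographic order, one per row.
#' @keywords internal
#' @noRd
perms_lex <- function(n) {
  if (n == 0L) return(matrix(integer(0), 1L, 0L))
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- perms_lex(n - 1L)
  blocks <- lapply(seq_len(n), function(i) {
    rest <- setdiff(seq_len(n), i)
    cbind(i, matrix(rest[sub], nrow = nrow(sub)))
  })
  do.call(rbind, blocks)
}

#' Exact optimal order by enumeration
#'
#' Enumerates every permutation of the clinical conditions that occur in at
#' least one rule (conditions occurring in no rule can never be displayed and
#' are appended in declaration order without enumeration) and returns a
#' global minimizer of [initial_display_count()]. Ties are broken by taking
#' the lexicographically smallest optimal permutation in declaration-index
#' terms.
#'
#' @param rb A rule base.
#' @param nonclinical Non-clinical ids true for this patient.
#' @param cap Maximum number of occurring conditions to enumerate (default 9,
#'   about 3.6e5 permutations); beyond it an error is raised.
#' @return A list with `order` (full condition order) and `value` (the
#'   minimum objective).
#' @export
brute_force_order <- function(rb, nonclinical = character(0), cap = 9L) {
  obj <- precompile_objective(rb, nonclinical)
  occ <- obj$occurring
  rest <- setdiff(clinical_ids(rb), occ)
  if (length(occ) > cap)
    rf_abort(sprintf("%d occurring conditions exceed the brute-force cap of %d",
                     length(occ), cap), "rf_error_cap_exceeded")
  if (!length(occ))
    return(list(order = condition_order(rb), value = 0L))
  pm <- perms_lex(length(occ))
  best <- Inf
  best_perm <- pm[1L, ]
  pos <- integer(length(occ))
  for (i in seq_len(nrow(pm))) {
    pos[pm[i, ]] <- seq_along(occ)
    v <- obj$fn(pos)
    if (v < best) {
      best <- v
      best_perm <- pm[i, ]
    }
  }
  list(order = c(occ[best_perm], rest), value = as.integer(best))
}

#' Seeded stochastic order search
#'
#' Random-restart hill climbing over adjacent transpositions of the occurring
#' conditions. The first restart starts from the occurrence heuristic (so the
#' returned value never exceeds the heuristic's); later restarts start from
#' random permutations. Each restart sweeps the adjacent transpositions in
#' random order, accepting strict improvements, until a sweep yields none or
#' the per-restart sweep budget is exhausted. Fully reproducible for a fixed
#' seed. The optimizer interface is deliberately minimal so that alternative
#' seeded permutation metaheuristics can be swapped in.
#'
#' @param rb A rule base.
#' @param nonclinical Non-clinical ids true for this patient (unlike
#'   [occurrence_order()], the result may be patient-specific).
#' @param iterations Sweep budget per restart.
#' @param restarts Number of restarts.
#' @param seed Integer seed.
#' @return A list with `order` and `value`, as [brute_force_order()].
#' @export
stochastic_order <- function(rb, nonclinical = character(0), iterations = 25L,
                             restarts = 8L, seed = 1L) {
  if (iterations < 1L)
    rf_abort("iterations must be >= 1", "rf_error_malformed")
  obj <- precompile_objective(rb, nonclinical)
  occ <- obj$occurring
  rest <- setdiff(clinical_ids(rb), occ)
  n <- length(occ)
  heur <- occurrence_order(rb)
  if (n <= 1L)
    return(list(order = condition_order(rb, heur),
                value = initial_display_direct(rb, heur, nonclinical)))
  heur_perm <- match(heur[heur %in% occ], occ)

  with_rng_seed(seed, {
    best <- Inf
    best_perm <- heur_perm
    for (r in seq_len(restarts)) {
      perm <- if (r == 1L) heur_perm else sample.int(n)
      pos <- integer(n)
      pos[perm] <- seq_len(n)
      v <- obj$fn(pos)
      for (sweep in seq_len(iterations)) {
        improved <- FALSE
        for (i in sample.int(n - 1L)) {
          cand <- perm
          cand[c(i, i + 1L)] <- cand[c(i + 1L, i)]
          pos[cand] <- seq_len(n)
          v2 <- obj$fn(pos)
          if (v2 < v) {
            perm <- cand
            v <- v2
            improved <- TRUE
          } else {
            pos[perm] <- seq_len(n)  # undo
          }
        }
        if (!improved) break
      }
      if (v < best) {
        best <- v
        best_perm <- perm
      }
    }
    list(order = c(occ[best_perm], rest), value = as.integer(best))
  })
}
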