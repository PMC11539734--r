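# Generalized-TSP reformulation of the ordering problem.
#
# For rule bases restricted to pure conjunctions of present clinical
# conditions (and all patient conditions false), the ordering problem maps to
# a GTSP: towns are the 2^n subsets of the clinical conditions - a town is
# the set of conditions already placed in the order under construction -
# grouped into areas by cardinality; the travel visits one town per area in
# area order and its length counts the conditions displayed in the initial
# form. Appending one condition costs 1 exactly when some rule contains it
# and none of the rule's other conditions is already placed (a new "gate"
# condition becomes visible), else 0; the edge from the full set back to the
# empty set closes the loop for free. Since a town stands for the set of
# conditions placed so far, consecutive towns on a meaningful travel are
# nested (each adds exactly one condition), and the brute-force solver only
# enumerates such travels - which correspond one-to-one to condition orders.
# This module exists as a verification oracle for the direct solvers, not as
# a production solver.

#' Build a GTSP instance from a restricted rule base
#'
#' Requires every rule to be a pure present-clinical conjunction (all other
#' premise slots empty). Towns are materialized explicitly, so the number of
#' clinical conditions is capped (default 6, i.e. 64 towns); beyond the cap
#' the function refuses rather than approximates.
#'
#' @param rb A rule base whose rules all have the restricted form.
#' @param cap Maximum number of clinical conditions.
#' @return An object of class `rf_gtsp`: `conditions` (clinical ids, the bit
#'   order of town masks), `towns` (list of id vectors), `masks`, `areas`
#'   (town cardinalities) and the asymmetric distance matrix `M` (entries 0,
#'   1 or `Inf`).
#' @export
build_gtsp <- function(rb, cap = 6L) {
  for (r in rb$rules) {
    if (length(r$present_nonclinical) || length(r$absent_clinical) ||
        length(r$absent_nonclinical) || length(r$unions) ||
        !length(r$present_clinical))
      rf_abort(sprintf("rule '%s' is not of the restricted present-clinical form",
                       r$id), "rf_error_restricted_form")
  }
  conds <- clinical_ids(rb)
  n <- length(conds)
  if (n > cap)
    rf_abort(sprintf("%d clinical conditions exceed the GTSP cap of %d", n, cap),
             "rf_error_cap_exceeded")
  n_towns <- bitwShiftL(1L, n)
  masks <- seq_len(n_towns) - 1L
  popcount <- vapply(masks, function(m) sum(bitwAnd(m, bitwShiftL(1L, 0:(max(n, 1) - 1))) > 0L),
                     integer(1))
  if (n == 0L) popcount <- 0L
  towns <- lapply(masks, function(m) conds[bitwAnd(m, bitwShiftL(1L, seq_len(n) - 1L)) > 0L])
  rule_masks <- vapply(rb$rules, function(r)
    Reduce(bitwOr, bitwShiftL(1L, match(r$present_clinical, conds) - 1L), 0L),
    integer(1))

  M <- matrix(Inf, n_towns, n_towns)
  labels <- vapply(towns, function(t) paste0("{", paste(t, collapse = ","), "}"),
                   character(1))
  dimnames(M) <- list(labels, labels)
  for (i in seq_len(n_towns)) {
    for (j in seq_len(n_towns)) {
      if (popcount[i] == n && popcount[j] == 0L) {
        M[i, j] <- 0
      } else if (popcount[j] == popcount[i] + 1L) {
        new_conds <- bitwAnd(masks[j], bitwNot(masks[i]))
        gated <- any(bitwAnd(bitwNot(rule_masks), new_conds) == 0L &
                     bitwAnd(masks[i], rule_masks) == 0L)
        M[i, j] <- if (length(rule_masks) && gated) 1 else 0
      }
    }
  }
  structure(list(conditions = conds, towns = towns, masks = masks,
                 areas = popcount, M = M),
            class = "rf_gtsp")
}

#' Solve a GTSP instance exactly
#'
#' Enumerates every travel that starts at the empty town and visits one town
#' per area in area order, consecutive towns nested (each adding one
#' condition), plus the free closing edge back to the empty town, and returns
#' a minimum-cost travel. The condition order is recovered from the
#' successive set differences along the travel. Ties are broken by the
#' lexicographically smallest order in declaration-index terms.
#'
#' @param instance An `rf_gtsp` from [build_gtsp()].
#' @return A list with `tour` (list of towns, starting and ending at the
#'   empty set), `cost`, and `order` (the recovered condition order).
#' @export
gtsp_bruteforce <- function(instance) {
  conds <- instance$conditions
  n <- length(conds)
  M <- instance$M
  if (n == 0L)
    return(list(tour = list(character(0), character(0)), cost = 0,
                order = character(0)))
  pm <- perms_lex(n)
  best <- Inf
  best_perm <- pm[1L, ]
  bits <- bitwShiftL(1L, seq_len(n) - 1L)
  for (i in seq_len(nrow(pm))) {
    mask <- 0L
    cost <- 0
    for (k in seq_len(n)) {
      nxt <- bitwOr(mask, bits[pm[i, k]])
      cost <- cost + M[mask + 1L, nxt + 1L]
      mask <- nxt
    }
    cost <- cost + M[mask + 1L, 1L]  # closing edge, always 0
    if (cost < best) {
      best <- cost
      best_perm <- pm[i, ]
    }
  }
  ordered <- conds[best_perm]
  tour <- c(list(character(0)),
            lapply(seq_len(n), function(k) ordered[seq_len(k)]),
            list(character(0)))
  list(tour = tour, cost = best, order = ordered)
}
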