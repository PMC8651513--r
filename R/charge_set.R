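## ChargeSet: named per-atom partial charges with equivalence groups,
## a regularization reference set, and a frozen mask.

#' Construct a charge set
#'
#' A `charge_set` holds the per-atom partial charges of one molecule together
#' with the structure the refinement protocol must preserve: equivalence
#' groups (atoms forced to share one charge value, e.g. chemically identical
#' acyl chains), a frozen mask (atoms excluded from optimization, e.g. acyl
#' chains and the alcohol group), the reference charges the regularization
#' pulls toward, and the declared molecular net charge.
#'
#' @param atom_names Character vector of unique atom identifiers, in file
#'   order.
#' @param charges Numeric vector of partial charges in elementary-charge
#'   units (e), one per atom.
#' @param reference_charges Charges the regularization penalty is anchored to
#'   (defaults to `charges`).
#' @param groups Integer vector, one entry per atom, labelling equivalence
#'   groups: atoms sharing a label are constrained to identical charge.
#'   Defaults to one singleton group per atom.
#' @param frozen Logical vector, one entry per atom; `TRUE` marks atoms whose
#'   charge is never altered by the optimizer.
#' @param net_charge Declared molecular net charge in e (0 for neutral
#'   lipids).
#' @param annotations Optional data.frame of opaque per-atom columns (type,
#'   mass, ...) retained for topology round-trips.
#' @param validate Check invariants (equivalence equality to 1e-12 e,
#'   neutrality to `net_tol`, frozen == reference).
#' @param net_tol Net-charge tolerance in e.
#' @return An object of class `charge_set`.
#' @seealso [read_itp_charges()], [delta_charges()], [project_constraints()]
#' @export
charge_set <- function(atom_names, charges, reference_charges = charges,
                       groups = seq_along(atom_names),
                       frozen = rep(FALSE, length(atom_names)),
                       net_charge = 0, annotations = NULL,
                       validate = TRUE, net_tol = 1e-9) {
  atom_names <- as.character(atom_names)
  n <- length(atom_names)
  charges <- as.numeric(charges)
  reference_charges <- as.numeric(reference_charges)
  groups <- as.integer(groups)
  frozen <- as.logical(frozen)
  if (length(charges) != n || length(reference_charges) != n ||
      length(groups) != n || length(frozen) != n) {
    stop("charge_set: all per-atom fields must have one entry per atom name")
  }
  if (anyDuplicated(atom_names)) {
    stop("charge_set: duplicate atom names: ",
         paste(unique(atom_names[duplicated(atom_names)]), collapse = ", "))
  }
  cs <- structure(
    list(atom_names = atom_names, charges = charges,
         reference_charges = reference_charges, groups = groups,
         frozen = frozen, net_charge = as.numeric(net_charge),
         annotations = annotations),
    class = "charge_set")
  if (validate) validate_charge_set(cs, net_tol = net_tol)
  cs
}

#' Validate charge-set invariants
#'
#' Checks that all atoms in one equivalence group carry the same charge (to
#' 1e-12 e), that the total charge matches the declared net charge within
#' `net_tol`, and that frozen atoms sit exactly at their reference charge.
#'
#' @param cs A `charge_set`.
#' @param net_tol Net-charge tolerance in e.
#' @return `cs`, invisibly; errors on violation.
#' @export
validate_charge_set <- function(cs, net_tol = 1e-9) {
  stopifnot(inherits(cs, "charge_set"))
  spread <- tapply(cs$charges, cs$groups, function(x) diff(range(x)))
  if (any(spread > 1e-12)) {
    bad <- names(spread)[spread > 1e-12]
    stop("charge_set: equivalence groups with unequal charges: ",
         paste(bad, collapse = ", "))
  }
  net <- sum(cs$charges)
  if (abs(net - cs$net_charge) > net_tol) {
    stop(sprintf(
      "charge_set: net charge %.12g differs from declared %.12g (tol %g)",
      net, cs$net_charge, net_tol))
  }
  if (any(cs$frozen & cs$charges != cs$reference_charges)) {
    stop("charge_set: frozen atoms must keep their reference charge: ",
         paste(cs$atom_names[cs$frozen &
                             cs$charges != cs$reference_charges],
               collapse = ", "))
  }
  invisible(cs)
}

#' @export
print.charge_set <- function(x, ...) {
  n_free <- sum(!x$frozen)
  cat(sprintf(
    "<charge_set> %d atoms (%d free, %d frozen), %d free groups, net %+.4f e\n",
    length(x$atom_names), n_free, sum(x$frozen),
    length(free_group_ids(x)), sum(x$charges)))
  invisible(x)
}

#' @export
length.charge_set <- function(x) length(x$atom_names)

## group ids carrying at least one non-frozen atom, in first-appearance order
free_group_ids <- function(cs) {
  g <- cs$groups[!cs$frozen]
  unique(g)
}

#' Extract the free optimization parameters of a charge set
#'
#' One parameter per equivalence group containing non-frozen atoms; the value
#' is the shared group charge. Names are `"g<id>"`.
#'
#' @param cs A `charge_set`.
#' @return Named numeric vector theta, with attributes `group_ids` and
#'   `multiplicity` (number of atoms represented by each parameter).
#' @export
free_parameters <- function(cs) {
  ids <- free_group_ids(cs)
  theta <- vapply(ids, function(g) cs$charges[cs$groups == g][1], numeric(1))
  mult <- vapply(ids, function(g) sum(cs$groups == g & !cs$frozen), integer(1))
  names(theta) <- paste0("g", ids)
  attr(theta, "group_ids") <- ids
  attr(theta, "multiplicity") <- mult
  theta
}

#' Rebuild a charge set from free parameters
#'
#' Inverse of [free_parameters()]: writes each group parameter back onto its
#' non-frozen atoms. Frozen atoms keep their reference charge.
#'
#' @param cs Template `charge_set`.
#' @param theta Numeric vector in the order returned by [free_parameters()].
#' @param validate Validate the result.
#' @return A new `charge_set`.
#' @export
set_free_parameters <- function(cs, theta, validate = TRUE) {
  ids <- free_group_ids(cs)
  if (length(theta) != length(ids)) {
    stop("set_free_parameters: expected ", length(ids), " parameters, got ",
         length(theta))
  }
  q <- cs$charges
  for (k in seq_along(ids)) {
    sel <- cs$groups == ids[k] & !cs$frozen
    q[sel] <- theta[k]
  }
  out <- cs
  out$charges <- q
  if (validate) validate_charge_set(out)
  out
}

#' Per-atom charge differences between two charge sets
#'
#' Computes `b - a` per atom, the quantity plotted as the change in partial
#' charges between two parameterizations of the same molecule. The sum of
#' the differences equals the difference of net charges (zero for
#' neutral-to-neutral comparisons).
#'
#' @param a,b `charge_set` objects with identical atom orderings.
#' @return Named numeric vector of charge differences in e.
#' @export
delta_charges <- function(a, b) {
  stopifnot(inherits(a, "charge_set"), inherits(b, "charge_set"))
  if (!identical(a$atom_names, b$atom_names)) {
    stop("delta_charges: atom orderings differ")
  }
  stats::setNames(b$charges - a$charges, a$atom_names)
}

#' Project a charge vector onto the optimization constraints
#'
#' Applies, cyclically until joint convergence: (i) equivalence-group
#' averaging, (ii) net-charge conservation by removing the uniform per-atom
#' shift over free atoms, and (iii) an optional per-atom box cap
#' `|q - q_anchor| <= cap`. Frozen atoms are never moved; the free-atom total
#' absorbs the entire neutrality correction.
#'
#' @param cs `charge_set` whose charges are to be projected.
#' @param cap Per-atom cap in e, or `NULL` for no cap.
#' @param anchor Charges the cap is measured from (default: `cs`'s reference
#'   charges; the optimizer passes the cycle-start charges).
#' @param max_iter,tol Iteration controls for the alternating projection.
#' @return A new, validated `charge_set`.
#' @export
project_constraints <- function(cs, cap = NULL, anchor = NULL,
                                max_iter = 200, tol = 1e-12) {
  q <- cs$charges
  q[cs$frozen] <- cs$reference_charges[cs$frozen]
  if (is.null(anchor)) anchor <- cs$reference_charges
  free <- !cs$frozen
  n_free <- sum(free)
  if (n_free == 0) {
    out <- cs; out$charges <- q
    return(validate_charge_set(out))
  }
  target_free_sum <- cs$net_charge - sum(q[!free])
  for (it in seq_len(max_iter)) {
    ## equivalence: average within each group over its free atoms
    for (g in unique(cs$groups[free])) {
      sel <- cs$groups == g & free
      q[sel] <- mean(q[sel])
    }
    ## neutrality: uniform shift across free atoms
    q[free] <- q[free] - (sum(q[free]) - target_free_sum) / n_free
    ## cap: per-atom clip relative to the anchor
    if (!is.null(cap)) {
      lo <- anchor[free] - cap
      hi <- anchor[free] + cap
      q[free] <- pmin(pmax(q[free], lo), hi)
    }
    ok_net <- abs(sum(q) - cs$net_charge) <= tol
    ok_grp <- all(tapply(q[free], cs$groups[free],
                         function(x) diff(range(x))) <= tol)
    if (ok_net && ok_grp) break
  }
  if (!(ok_net && ok_grp)) {
    stop("project_constraints: cap and neutrality constraints are jointly ",
         "infeasible for this charge set")
  }
  ## snap group members to exact equality for the 1e-12 invariant
  for (g in unique(cs$groups[free])) {
    sel <- cs$groups == g & free
    q[sel] <- q[sel][1]
  }
  q[free] <- q[free] - (sum(q) - cs$net_charge) / n_free
  out <- cs
  out$charges <- q
  validate_charge_set(out)
}

#' Spread a small net-charge residual over the non-frozen atoms
#'
#' Optional repair for published topologies whose printed charges do not sum
#' exactly to the declared net charge because of rounding.
#'
#' @param cs A `charge_set` (possibly failing the neutrality invariant).
#' @param max_residual Largest residual the repair will accept, in e.
#' @return A validated `charge_set`.
#' @export
repair_net_charge <- function(cs, max_residual = 1e-3) {
  residual <- sum(cs$charges) - cs$net_charge
  if (abs(residual) > max_residual) {
    stop(sprintf("repair_net_charge: residual %.6g e exceeds %.3g e",
                 residual, max_residual))
  }
  free <- !cs$frozen
  if (!any(free)) stop("repair_net_charge: no non-frozen atoms to adjust")
  cs$charges[free] <- cs$charges[free] - residual / sum(free)
  ## keep equivalence exact
  for (g in unique(cs$groups[free])) {
    sel <- cs$groups == g & free
    cs$charges[sel] <- mean(cs$charges[sel])
  }
  cs$charges[free] <- cs$charges[free] - (sum(cs$charges) - cs$net_charge) /
    sum(free)
  validate_charge_set(cs)
}
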