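# Molecular dating of gene loss from the mixed dN/dS observed on a loss
# branch.  A loss branch spends T_f Myr under purifying selection
# (dN/dS = omega_f, with both synonymous and nonsynonymous rates scaled by
# c <= 1 relative to fully neutral sequence) and T_p Myr as a neutral
# pseudogene (dN/dS = 1).  The observed branch-wide ratio is then
#
#   omega_mixed = (c * omega_f * T_f + T_p) / (c * T_f + T_p)
#
# which is inverted in closed form to partition the branch and convert the
# functional span into a calendar-date interval for the inactivation event.

#' Forward mixed dN/dS of a partially pseudogenic branch
#'
#' @param t_functional Time (Myr) the gene evolved under selection.
#' @param t_pseudogenic Time (Myr) the gene evolved neutrally.
#' @param omega_functional dN/dS of the functional regime (0 < omega_f < 1).
#' @param syn_scaling Ratio c of the functional synonymous rate to the
#'   fully-neutral rate (default 0.7).
#' @return The branch-wide dN/dS, a value in `[omega_functional, 1]`.
#' @export
mixed_omega_forward <- function(t_functional, t_pseudogenic,
                                omega_functional, syn_scaling = 0.7) {
  stopifnot(t_functional >= 0, t_pseudogenic >= 0,
            omega_functional > 0, syn_scaling > 0, syn_scaling <= 1)
  if (t_functional == 0 && t_pseudogenic == 0) {
    stop("mixed_omega_forward: both time spans are zero; omega undefined")
  }
  c <- syn_scaling
  (c * omega_functional * t_functional + t_pseudogenic) /
    (c * t_functional + t_pseudogenic)
}

#' Inputs for dating a gene-loss event
#'
#' Bundles the observed loss-branch dN/dS, the functional-class dN/dS, the
#' synonymous-rate scaling and the date bounds of the two ends of the loss
#' branch.  Each end may carry an (older, younger) bound pair from divergence
#' time estimates; a point-dated end is the degenerate case with equal bounds.
#'
#' @param omega_mixed Observed dN/dS of the loss branch.
#' @param omega_functional dN/dS of the functional branch class.
#' @param syn_scaling Functional-to-neutral synonymous rate ratio c.
#' @param start_older,start_younger Date bounds (Mya) of the branch start
#'   (the older node).
#' @param end_older,end_younger Date bounds (Mya) of the branch end.
#' @param parsimony_floor Optional minimum loss age (Mya) implied by shared
#'   inactivating mutations deeper in the clade.
#' @return An object of class `dating_inputs`.
#' @export
dating_inputs <- function(omega_mixed, omega_functional, syn_scaling = 0.7,
                          start_older, start_younger = start_older,
                          end_older, end_younger = end_older,
                          parsimony_floor = NULL) {
  stopifnot(omega_functional > 0, syn_scaling > 0, syn_scaling <= 1,
            start_older >= start_younger, end_older >= end_younger,
            start_older >= end_older, start_younger >= end_younger)
  if (omega_mixed < omega_functional) {
    stop("dating_inputs: observed selection stronger than functional class; ",
         "loss branch is undateable (omega_mixed < omega_functional)")
  }
  structure(list(omega_mixed = omega_mixed,
                 omega_functional = omega_functional,
                 syn_scaling = syn_scaling,
                 start_older = start_older, start_younger = start_younger,
                 end_older = end_older, end_younger = end_younger,
                 parsimony_floor = parsimony_floor),
            class = "dating_inputs")
}

# Fraction of the loss branch spent pseudogenic; scale-free in T.
pseudogenic_fraction <- function(omega_mixed, omega_functional, syn_scaling) {
  if (omega_mixed >= 1) return(1)
  c <- syn_scaling
  num <- c * (omega_mixed - omega_functional)
  num / ((1 - omega_mixed) + num)
}

#' Date a gene-loss event from a mixed loss-branch dN/dS
#'
#' Inverts the forward mixture formula to split the loss branch into its
#' functional span `T_f` and pseudogenic span `T_p`
#' (`T_p = T * c * (omega_mixed - omega_f) /
#' [(1 - omega_mixed) + c * (omega_mixed - omega_f)]`), then maps the loss
#' time onto the calendar at both the older and younger date-bound pairs.
#' `omega_mixed >= 1` dates the loss at the branch start.  If a parsimony
#' floor is supplied, the younger date bound is clamped up to it.
#'
#' @param inputs A [dating_inputs()] object.
#' @return An object of class `loss_dating_result` with the spans at the
#'   older and younger bound pairs (`t_functional`, `t_pseudogenic`,
#'   vectors `c(older, younger)`), the loss-date interval
#'   (`loss_date_older`, `loss_date_younger`, Mya) and
#'   `clamped_by_parsimony`.
#' @export
date_loss <- function(inputs) {
  stopifnot(inherits(inputs, "dating_inputs"))
  k <- pseudogenic_fraction(inputs$omega_mixed, inputs$omega_functional,
                            inputs$syn_scaling)
  spans <- c(older = inputs$start_older - inputs$end_older,
             younger = inputs$start_younger - inputs$end_younger)
  t_p <- k * spans
  t_f <- spans - t_p
  starts <- c(older = inputs$start_older, younger = inputs$start_younger)
  loss_dates <- starts - t_f
  clamped <- FALSE
  if (!is.null(inputs$parsimony_floor) &&
      loss_dates[["younger"]] < inputs$parsimony_floor) {
    if (inputs$parsimony_floor > inputs$start_older) {
      stop("date_loss: parsimony floor is older than the loss branch start")
    }
    loss_dates[["younger"]] <- inputs$parsimony_floor
    clamped <- TRUE
  }
  structure(list(t_functional = t_f, t_pseudogenic = t_p,
                 loss_date_older = loss_dates[["older"]],
                 loss_date_younger = loss_dates[["younger"]],
                 pseudogenic_fraction = k,
                 inputs = inputs,
                 clamped_by_parsimony = clamped),
            class = "loss_dating_result")
}

#' @export
print.loss_dating_result <- function(x, ...) {
  cat(sprintf(
    "Gene-loss dating: %.1f-%.1f Mya (T_p = %.2f/%.2f Myr, T_f = %.2f/%.2f Myr)%s\n",
    x$loss_date_older, x$loss_date_younger,
    x$t_pseudogenic[["older"]], x$t_pseudogenic[["younger"]],
    x$t_functional[["older"]], x$t_functional[["younger"]],
    if (x$clamped_by_parsimony) " [clamped by shared-mutation parsimony]" else ""))
  invisible(x)
}

#' Clamp a dating result by a shared-mutation parsimony placement
#'
#' Shared inactivating mutations place the loss no later than the split of
#' the species carrying them.  This tightens the younger bound of the
#' molecular date interval to the date of the node below the placement
#' branch.
#'
#' @param result A [date_loss()] result.
#' @param placement A loss placement (from [place_loss_events()]) whose
#'   `event_branch` must be the dated branch.
#' @param tree The [time_tree()] the placement refers to.
#' @param branch Child-node label identifying the dated branch (defaults to
#'   the placement's branch, in which case no check is possible).
#' @return The result with `loss_date_younger` clamped up to the split date
#'   and `clamped_by_parsimony` set when the clamp binds.
#' @export
apply_parsimony_constraint <- function(result, placement, tree,
                                       branch = placement$event_branch) {
  stopifnot(inherits(result, "loss_dating_result"))
  if (!identical(placement$event_branch, branch)) {
    stop("apply_parsimony_constraint: placement is on branch '",
         placement$event_branch, "', not the dated branch '", branch, "'")
  }
  split_date <- node_date(tree, placement$event_branch)
  if (split_date > result$inputs$start_older) {
    stop("apply_parsimony_constraint: split date older than the branch start")
  }
  if (result$loss_date_younger < split_date) {
    result$loss_date_younger <- split_date
    result$clamped_by_parsimony <- TRUE
  }
  result
}
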