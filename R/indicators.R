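#' Column schema of per-timestep operational records
#'
#' Names and meaning of the columns expected in a timestep record table:
#' one row per timestep per alternative, counts of exams executed, queued
#' for faults, requiring or not requiring repetition, effective tests and
#' errors, side effects, incoming requests, ethically refused exams
#' (surgeon- and patient-side), financials (net profit, net operating
#' margin MON, net revenues), staffing, and planned vs executed daily
#' exam loads.
#'
#' @return Character vector of required column names.
#' @export
timestep_columns <- function() {
  c("timestep", "alternative",
    "executed_exams", "queued_exams_for_faults",
    "exams_no_additional_withdrawals", "exams_no_further_investigation",
    "exams_requiring_further_withdrawals",
    "effective_tests", "effective_exams_with_error",
    "exams_with_side_effects", "incoming_requests",
    "refused_exams_surgeon", "refused_exams_patient",
    "net_profit", "mon", "net_revenues",
    "medical_specialists", "biologists",
    "planned_daily_exams", "executed_daily_exams")
}

#' Static score panel for safety and legal indicators
#'
#' Safety is scored on five 1-10 variables where 10 is best (visual
#' evaluation, safety-standard compliance, manual availability,
#' alarm/control systems, room status); legal compliance on six 1-10
#' variables where 1 is best (noise, electromagnetic pollution, respect
#' for the value of life, health risk, mandatory-standard compliance,
#' lawsuits).  Investment and purchase cost feed the investments ratio.
#'
#' @param safety Numeric vector of five scores in \code{[1, 10]}.
#' @param legal Numeric vector of six scores in \code{[1, 10]}.
#' @param investment,purchase_cost Positive currency amounts.
#' @return An object of class \code{score_panel}.
#' @export
score_panel <- function(safety, legal, investment, purchase_cost) {
  if (length(safety) != 5 || any(safety < 1 | safety > 10)) {
    stop("safety must be five scores in [1, 10]", call. = FALSE)
  }
  if (length(legal) != 6 || any(legal < 1 | legal > 10)) {
    stop("legal must be six scores in [1, 10]", call. = FALSE)
  }
  if (purchase_cost <= 0) stop("purchase cost must be positive", call. = FALSE)
  if (investment < 0) stop("investment must be non-negative", call. = FALSE)
  structure(list(safety = safety, legal = legal, investment = investment,
                 purchase_cost = purchase_cost),
            class = "score_panel")
}

# orientation of each sub-criterion indicator: "benefit" = larger is
# better, "cost" = larger is worse
.indicator_orientation <- function() {
  c("Reliability" = "cost",
    "Technological Efficiency" = "benefit",
    "Technological Safety" = "benefit",
    "Procedural Complexity" = "cost",
    "Human Resources" = "benefit",
    "Investments" = "benefit",
    "Usefulness" = "benefit",
    "ROS" = "benefit",
    "Clinical Efficiency" = "benefit",
    "Effectiveness" = "benefit",
    "Side Effects" = "cost",
    "Respect for social aspects" = "benefit",
    "Respect for legal issues" = "cost",
    "Respect for ethical principles" = "cost")
}

#' Compute the sub-criterion indicator panel for one alternative
#'
#' Aggregates a window of per-timestep operational records into the
#' fourteen sub-criterion indicators: window sums for technological
#' efficiency (executed exams), reliability (exams queued for faults),
#' usefulness (net profit), social respect (examinations), ethical
#' respect (refused exams, surgeon + patient) and side effects (exams
#' with side effects + effective exams with error); window ratios for
#' procedural complexity (executed/planned daily exams), ROS (MON / net
#' revenues) and effectiveness (effective tests / incoming requests);
#' clinical efficiency as (no-additional-withdrawals +
#' no-further-investigation) - requiring-further-withdrawals; staffing
#' (specialists + biologists, window mean); and the static score-panel
#' indicators: technological safety (sum of five safety scores), legal
#' respect (sum of six legal scores) and investments
#' (investment / purchase cost).
#'
#' Ratios aggregate over the whole window first (sums of numerator and
#' denominator), then divide once.
#'
#' @param records Data frame of per-timestep rows for a single
#'   alternative, with the columns of [timestep_columns()] (minus
#'   \code{alternative}, which is ignored if present).
#' @param scores A [score_panel()].
#' @return Named numeric vector of 14 indicator values with an
#'   \code{orientation} attribute (\code{"benefit"}/\code{"cost"} per
#'   indicator).
#' @examples
#' rec <- data.frame(timestep = 1, executed_exams = 8,
#'   queued_exams_for_faults = 1, exams_no_additional_withdrawals = 6,
#'   exams_no_further_investigation = 1, exams_requiring_further_withdrawals = 1,
#'   effective_tests = 7, effective_exams_with_error = 1,
#'   exams_with_side_effects = 0, incoming_requests = 10,
#'   refused_exams_surgeon = 0, refused_exams_patient = 1,
#'   net_profit = 50, mon = 20, net_revenues = 100,
#'   medical_specialists = 2, biologists = 1,
#'   planned_daily_exams = 10, executed_daily_exams = 8)
#' sp <- score_panel(rep(8, 5), rep(2, 6), 1e4, 5e4)
#' compute_indicator_panel(rec, sp)[["ROS"]]  # 0.2
#' @export
compute_indicator_panel <- function(records, scores) {
  stopifnot(inherits(scores, "score_panel"))
  need <- setdiff(timestep_columns(), c("alternative"))
  miss <- setdiff(need, names(records))
  if (length(miss) > 0) {
    stop("records missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(records) == 0) stop("empty timestep series", call. = FALSE)
  counts <- setdiff(need, c("timestep", "net_profit", "mon", "net_revenues"))
  for (cc in counts) {
    if (any(records[[cc]] < 0)) {
      stop("negative count in column ", cc, call. = FALSE)
    }
  }
  s <- function(col) sum(records[[col]])
  ratio <- function(num, den, name) {
    if (s(den) <= 0) {
      stop("zero denominator computing ", name, " (column ", den, ")",
           call. = FALSE)
    }
    s(num) / s(den)
  }
  out <- c(
    "Reliability" = s("queued_exams_for_faults"),
    "Technological Efficiency" = s("executed_exams"),
    "Technological Safety" = sum(scores$safety),
    "Procedural Complexity" = ratio("executed_daily_exams",
                                    "planned_daily_exams",
                                    "procedural complexity"),
    "Human Resources" = mean(records$medical_specialists +
                               records$biologists),
    "Investments" = scores$investment / scores$purchase_cost,
    "Usefulness" = s("net_profit"),
    "ROS" = ratio("mon", "net_revenues", "ROS"),
    "Clinical Efficiency" = s("exams_no_additional_withdrawals") +
      s("exams_no_further_investigation") -
      s("exams_requiring_further_withdrawals"),
    "Effectiveness" = ratio("effective_tests", "incoming_requests",
                            "effectiveness"),
    "Side Effects" = s("exams_with_side_effects") +
      s("effective_exams_with_error"),
    "Respect for social aspects" = s("executed_exams"),
    "Respect for legal issues" = sum(scores$legal),
    "Respect for ethical principles" = s("refused_exams_surgeon") +
      s("refused_exams_patient")
  )
  attr(out, "orientation") <- .indicator_orientation()
  out
}

#' Local alternative weights from one indicator across alternatives
#'
#' Converts one sub-criterion's indicator values for all alternatives into
#' unit-sum local weights.  Benefit-type indicators are normalized
#' proportionally (\eqn{w_i = v_i / \sum v}); cost-type indicators are
#' inverted by reciprocal first (zeros floored at \code{eps}), so the
#' least-burdened alternative gets the largest weight.
#'
#' @param values Non-negative numeric vector, one per alternative (named
#'   or not), not all zero.
#' @param orientation \code{"benefit"} or \code{"cost"}.
#' @param eps Floor applied before reciprocal inversion of cost values
#'   (default 1e-9).
#' @return Unit-sum numeric weights, same names as \code{values}.
#' @examples
#' local_alternative_weights(c(2, 3, 5), "benefit")  # 0.2 0.3 0.5
#' local_alternative_weights(c(1, 1, 1), "cost")     # 1/3 each
#' @export
local_alternative_weights <- function(values, orientation = c("benefit", "cost"),
                                      eps = 1e-9) {
  orientation <- match.arg(orientation)
  if (length(values) < 2) stop("need at least two alternatives", call. = FALSE)
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("indicator values must be finite and non-negative", call. = FALSE)
  }
  if (all(values == 0)) {
    stop("degenerate input: all indicator values are zero", call. = FALSE)
  }
  v <- if (orientation == "cost") 1 / pmax(values, eps) else values
  v / sum(v)
}

#' Per-sub-criterion local alternative weights from indicator panels
#'
#' @param panels Named list of indicator vectors (one
#'   [compute_indicator_panel()] result per alternative; identical
#'   indicator names required).
#' @return Matrix of local weights, sub-criteria in rows, alternatives in
#'   columns; each row sums to 1.
#' @export
indicator_local_weights <- function(panels) {
  if (length(panels) < 2 || is.null(names(panels))) {
    stop("panels must be a named list with one panel per alternative",
         call. = FALSE)
  }
  nm <- names(panels[[1]])
  for (p in panels) {
    if (!identical(names(p), nm)) {
      stop("all panels must share the same indicator names", call. = FALSE)
    }
  }
  orient <- attr(panels[[1]], "orientation")[nm]
  out <- t(vapply(nm, function(k) {
    local_alternative_weights(
      vapply(panels, function(p) p[[k]], numeric(1)),
      orientation = unname(orient[k]))
  }, numeric(length(panels))))
  dimnames(out) <- list(nm, names(panels))
  out
}
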