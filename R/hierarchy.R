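#' Build a decision hierarchy
#'
#' Constructs the goal / criteria / sub-criteria / alternatives tree used
#' by the assessment.  Weights are unset at construction; they are filled
#' in from pairwise matrices (see [assess_node()]) or set directly with
#' [set_local_weights()] and then propagated with [propagate_weights()].
#'
#' @param config A list with elements \code{goal} (character scalar),
#'   \code{criteria} (named list: criterion label -> character vector of
#'   sub-criterion labels), and \code{alternatives} (character vector of
#'   at least two labels).  Typically produced by
#'   [read_hierarchy_config()].
#' @return An object of class \code{decision_hierarchy}.
#' @examples
#' h <- build_hierarchy(list(
#'   goal = "Choose assay",
#'   criteria = list(Clinical = c("Efficacy", "Safety"),
#'                   Economic = c("Cost")),
#'   alternatives = c("A", "B")
#' ))
#' h
#' @export
build_hierarchy <- function(config) {
  if (is.null(config$goal) || !nzchar(config$goal[1])) {
    stop("config must name a goal", call. = FALSE)
  }
  crit <- config$criteria
  if (is.null(crit) || length(crit) < 1L || is.null(names(crit)) ||
      any(!nzchar(names(crit)))) {
    stop("config must define at least one named criterion", call. = FALSE)
  }
  crit <- lapply(crit, function(x) as.character(unlist(x)))
  if (any(vapply(crit, length, integer(1)) < 1L)) {
    empty <- names(crit)[vapply(crit, length, integer(1)) < 1L]
    stop("criterion with no sub-criteria: ", paste(empty, collapse = ", "),
         call. = FALSE)
  }
  alts <- as.character(config$alternatives)
  if (length(alts) < 2L) stop("need at least two alternatives", call. = FALSE)
  all_labels <- c(names(crit), unlist(crit, use.names = FALSE), alts)
  dup <- unique(all_labels[duplicated(all_labels)])
  if (length(dup) > 0L) {
    stop("duplicate labels in hierarchy: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  structure(
    list(
      goal = as.character(config$goal[1]),
      criteria = crit,
      alternatives = alts,
      # local weights: one vector over criteria (node = goal) plus one per
      # criterion over its sub-criteria; NA until set
      local = c(
        list(goal = rep(NA_real_, length(crit))),
        stats::setNames(
          lapply(crit, function(x) rep(NA_real_, length(x))),
          names(crit)
        )
      ),
      consistency = list(),
      global = NULL
    ),
    class = "decision_hierarchy"
  )
}

#' @export
print.decision_hierarchy <- function(x, ...) {
  cat("Decision hierarchy: ", x$goal, "\n", sep = "")
  cat("  ", length(x$criteria), " criteria, ", n_leaves(x), " sub-criteria, ",
      length(x$alternatives), " alternatives\n", sep = "")
  for (cr in names(x$criteria)) {
    w <- x$local$goal[match(cr, names(x$criteria))]
    cat("  - ", cr,
        if (!is.na(w)) sprintf(" (local %.4f)", w) else "", "\n", sep = "")
    for (i in seq_along(x$criteria[[cr]])) {
      lw <- x$local[[cr]][i]
      cat("      * ", x$criteria[[cr]][i],
          if (!is.na(lw)) sprintf(" (local %.4f)", lw) else "", "\n", sep = "")
    }
  }
  cat("  alternatives: ", paste(x$alternatives, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Number of leaves (sub-criteria) in a hierarchy
#' @param h A \code{decision_hierarchy}.
#' @return Integer leaf count.
#' @export
n_leaves <- function(h) {
  sum(vapply(h$criteria, length, integer(1)))
}

#' Leaf (sub-criterion) labels, in hierarchy order
#' @param h A \code{decision_hierarchy}.
#' @return Character vector of sub-criterion labels.
#' @export
leaf_labels <- function(h) {
  unlist(h$criteria, use.names = FALSE)
}

# Internal: node name -> child labels. "goal" is the criteria level.
.node_children <- function(h, node) {
  if (identical(node, "goal")) return(names(h$criteria))
  if (!node %in% names(h$criteria)) {
    stop("unknown hierarchy node: ", node, call. = FALSE)
  }
  h$criteria[[node]]
}

#' Set the local weights of one node's children
#'
#' @param h A \code{decision_hierarchy}.
#' @param node \code{"goal"} (weights over criteria) or a criterion label
#'   (weights over its sub-criteria).
#' @param w Numeric weights, one per child, non-negative and summing to 1
#'   within 1e-9.  May be named; names must then match the child labels.
#' @return The updated hierarchy.
#' @export
set_local_weights <- function(h, node, w) {
  children <- .node_children(h, node)
  if (length(w) != length(children)) {
    stop("expected ", length(children), " weights for node '", node, "'",
         call. = FALSE)
  }
  if (!is.null(names(w))) {
    if (!setequal(names(w), children)) {
      stop("weight names do not match children of '", node, "'", call. = FALSE)
    }
    w <- w[children]
  }
  if (any(w < 0) || abs(sum(w) - 1) > 1e-9) {
    stop("local weights must be non-negative and sum to 1", call. = FALSE)
  }
  h$local[[node]] <- unname(as.numeric(w))
  h$global <- NULL  # stale
  h
}

#' Propagate local weights to global leaf weights
#'
#' The global weight of each sub-criterion is its local weight multiplied
#' by its parent criterion's local weight; because every sibling set is
#' unit-sum, the global leaf weights also sum to 1.
#'
#' @param h A \code{decision_hierarchy} with local weights set at every
#'   node (goal and each criterion).
#' @return The hierarchy with a \code{global} element: a named numeric
#'   vector of leaf global weights in hierarchy order.
#' @examples
#' h <- build_hierarchy(list(goal = "g",
#'   criteria = list(A = c("a1", "a2"), B = c("b1")),
#'   alternatives = c("x", "y")))
#' h <- set_local_weights(h, "goal", c(0.7, 0.3))
#' h <- set_local_weights(h, "A", c(0.5, 0.5))
#' h <- set_local_weights(h, "B", 1)
#' propagate_weights(h)$global
#' @export
propagate_weights <- function(h) {
  unset <- names(h$local)[vapply(h$local, anyNA, logical(1))]
  if (length(unset) > 0L) {
    stop("local weights unset at node(s): ", paste(unset, collapse = ", "),
         call. = FALSE)
  }
  crit_w <- stats::setNames(h$local$goal, names(h$criteria))
  glob <- unlist(lapply(names(h$criteria), function(cr) {
    stats::setNames(h$local[[cr]] * crit_w[[cr]], h$criteria[[cr]])
  }))
  h$global <- glob
  h
}

#' The worked-example hierarchy: HTA of a thyroglobulin assay
#'
#' The five-criterion, fourteen-sub-criterion hierarchy used to assess a
#' thyroglobulin (Tg) assay technology, with three alternatives: the
#' incumbent cytological analysis and two fibre-optic biosensors (LOF,
#' lab-on-fibre tip sensor; LPG, long-period-grating sensor).
#'
#' @return A \code{decision_hierarchy} with weights unset.
#' @export
paper_hierarchy <- function() {
  build_hierarchy(list(
    goal = "Assessment of healthcare technology",
    criteria = list(
      "Technical aspects" = c("Reliability", "Technological Efficiency",
                              "Technological Safety"),
      "Organizational aspects" = c("Procedural Complexity", "Human Resources"),
      "Economic aspects" = c("Investments", "Usefulness", "ROS"),
      "Clinical aspects" = c("Clinical Efficiency", "Effectiveness",
                             "Side Effects"),
      "Social, ethical and legal aspects" = c("Respect for social aspects",
                                              "Respect for legal issues",
                                              "Respect for ethical principles")
    ),
    alternatives = c("Cytological Analysis", "Biosensor LOF", "Biosensor LPG")
  ))
}
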