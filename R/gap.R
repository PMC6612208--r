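#' Rank sub-criteria by global importance ("hierarchy of needs")
#'
#' Sorts global leaf weights descending — the user-importance ranking of
#' the sub-criteria.  Ties keep their input (hierarchy/config) order.
#'
#' @param weights Named numeric vector of unit-sum global leaf weights.
#' @return A data frame with columns \code{sub_criterion}, \code{weight}
#'   and \code{rank}, sorted descending.
#' @examples
#' hierarchy_of_needs(c(ROS = 0.237, Usefulness = 0.200, Safety = 0.0058))
#' @export
hierarchy_of_needs <- function(weights) {
  if (is.null(names(weights)) || any(!nzchar(names(weights)))) {
    stop("weights must be named by sub-criterion", call. = FALSE)
  }
  ord <- order(-weights)  # stable: ties stay in input order
  data.frame(sub_criterion = names(weights)[ord],
             weight = unname(weights[ord]),
             rank = seq_along(weights),
             stringsAsFactors = FALSE)
}

#' Importance-satisfaction gap analysis
#'
#' Pairs each sub-criterion's AHP global importance with its Likert
#' satisfaction index, assigns a quadrant (high/low importance times
#' high/low satisfaction, cut at the medians unless thresholds are
#' given), and ranks improvement priority by the score
#' \code{importance * (1 - satisfaction)}.  Sub-criteria in the
#' high-importance / low-satisfaction quadrant are flagged for
#' improvement: users weight them heavily but are not satisfied.
#'
#' @param importance Named numeric vector of global AHP weights.
#' @param satisfaction Named numeric vector of satisfaction indices in
#'   \code{[0, 1]}; names must match \code{importance} (order free;
#'   extras in either input are an error).
#' @param thresholds Optional list with elements \code{importance} and
#'   \code{satisfaction} overriding the median cutoffs.
#' @return A data frame of class \code{gap_table}: one row per
#'   sub-criterion with columns \code{sub_criterion}, \code{importance},
#'   \code{satisfaction}, \code{importance_rank}, \code{satisfaction_rank},
#'   \code{quadrant}, \code{priority_score}, \code{priority_rank} and
#'   \code{improve}, sorted by descending priority score.  The cutoffs
#'   used are attached as attribute \code{"thresholds"}.
#' @examples
#' importance_satisfaction(c(a = 0.6, b = 0.3, c = 0.1),
#'                         c(a = 0.4, b = 0.9, c = 0.7))
#' @export
importance_satisfaction <- function(importance, satisfaction,
                                    thresholds = NULL) {
  if (is.null(names(importance)) || is.null(names(satisfaction))) {
    stop("importance and satisfaction must be named", call. = FALSE)
  }
  if (!setequal(names(importance), names(satisfaction))) {
    only_i <- setdiff(names(importance), names(satisfaction))
    only_s <- setdiff(names(satisfaction), names(importance))
    stop("label mismatch between importance and satisfaction",
         if (length(only_i)) paste0("; importance only: ",
                                    paste(only_i, collapse = ", ")),
         if (length(only_s)) paste0("; satisfaction only: ",
                                    paste(only_s, collapse = ", ")),
         call. = FALSE)
  }
  satisfaction <- satisfaction[names(importance)]
  cut_i <- if (!is.null(thresholds$importance)) thresholds$importance
           else stats::median(importance)
  cut_s <- if (!is.null(thresholds$satisfaction)) thresholds$satisfaction
           else stats::median(satisfaction)
  hi_i <- importance >= cut_i
  hi_s <- satisfaction >= cut_s
  quadrant <- paste0(ifelse(hi_i, "high", "low"), " importance / ",
                     ifelse(hi_s, "high", "low"), " satisfaction")
  score <- importance * (1 - satisfaction)
  out <- data.frame(
    sub_criterion = names(importance),
    importance = unname(importance),
    satisfaction = unname(satisfaction),
    importance_rank = rank(-importance, ties.method = "first"),
    satisfaction_rank = rank(-satisfaction, ties.method = "first"),
    quadrant = quadrant,
    priority_score = unname(score),
    priority_rank = rank(-score, ties.method = "first"),
    improve = unname(hi_i & !hi_s),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$priority_rank), ]
  rownames(out) <- NULL
  attr(out, "thresholds") <- list(importance = unname(cut_i),
                                  satisfaction = unname(cut_s))
  class(out) <- c("gap_table", "data.frame")
  out
}

#' @export
print.gap_table <- function(x, digits = 4, ...) {
  th <- attr(x, "thresholds")
  cat(sprintf(
    "Importance-satisfaction gap (cutoffs: importance %.4f, satisfaction %.3f)\n",
    th$importance, th$satisfaction))
  y <- as.data.frame(x)
  y$importance <- round(y$importance, digits)
  y$satisfaction <- round(y$satisfaction, 3)
  y$priority_score <- round(y$priority_score, digits)
  print(y[, c("sub_criterion", "importance", "satisfaction",
              "priority_rank", "improve")], row.names = FALSE)
  invisible(x)
}

#' Bar chart of the hierarchy of needs
#'
#' @param needs A [hierarchy_of_needs()] data frame.
#' @param ... Further arguments passed to [graphics::barplot()].
#' @return Invisibly, the bar midpoints.
#' @export
plot_hierarchy_of_needs <- function(needs, ...) {
  op <- graphics::par(mar = c(10, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::barplot(needs$weight, names.arg = needs$sub_criterion,
                    las = 2, ylab = "global weight",
                    main = "Hierarchy of needs", cex.names = 0.7, ...)
}
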