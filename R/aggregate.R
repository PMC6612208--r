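#' Weighted geometric mean of ratio judgments
#'
#' Aggregates N respondents' ratio judgments for one comparison into a
#' single group judgment, \eqn{\prod_k a_k^{\beta_k}}.  With equal weights
#' \eqn{\beta_k = 1/N} this is the N-th root of the product; it is
#' evaluated in the log domain for numerical stability, and the three
#' formulations (weighted product, N-th root, exponentiated mean log)
#' agree to machine precision.
#'
#' @param values Positive numeric vector of ratio judgments.
#' @param weights Respondent weights \eqn{\beta_k}, positive and summing
#'   to 1 within 1e-9; default equal weights \code{1/N}.
#' @return The aggregated ratio (scalar).
#' @examples
#' wgmm(c(1, 9))        # 3
#' wgmm(c(3, 3, 3))     # 3
#' @export
wgmm <- function(values, weights = NULL) {
  if (length(values) == 0) stop("no values to aggregate", call. = FALSE)
  if (any(!is.finite(values)) || any(values <= 0)) {
    stop("judgment ratios must be finite and positive", call. = FALSE)
  }
  if (is.null(weights)) weights <- rep(1 / length(values), length(values))
  if (length(weights) != length(values)) {
    stop("values and weights must have equal length", call. = FALSE)
  }
  if (any(weights <= 0) || abs(sum(weights) - 1) > 1e-9) {
    stop("weights must be positive and sum to 1", call. = FALSE)
  }
  exp(sum(weights * log(values)))
}

#' Build a group pairwise matrix from respondent judgments
#'
#' For every unordered child pair of \code{node}, the respondents' ratios
#' are aggregated by [wgmm()] on the \eqn{\ge 1} side of the comparison,
#' rounded to the nearest Saaty value (unless \code{rounding = FALSE}),
#' and mirrored exactly into the lower triangle, so the result is always a
#' valid reciprocal matrix.
#'
#' Respondents missing a pair are dropped for that pair and the remaining
#' weights renormalized; a pair no respondent judged is an error.
#'
#' @param judgments A data frame with columns \code{respondent_id},
#'   \code{node}, \code{child_a}, \code{child_b}, \code{answer} (numeric
#'   ratio, a fraction string like \code{"1/7"}, or a Saaty/questionnaire
#'   label understood by [saaty_value()]), as read by
#'   [read_judgments_csv()].  An \code{answer} is the importance of
#'   \code{child_a} relative to \code{child_b}.
#' @param node Node label to aggregate (matched against the \code{node}
#'   column).
#' @param labels Child labels in output order.  Defaults to order of first
#'   appearance in the data.
#' @param weights Optional named vector of respondent weights
#'   \eqn{\beta_k} (names = respondent ids); default equal.
#' @param rounding Round aggregated entries to the Saaty scale (default
#'   \code{TRUE}, matching how printed group matrices are built); set
#'   \code{FALSE} to keep raw geometric means.
#' @return A [pairwise_matrix()].
#' @export
build_group_matrix <- function(judgments, node, labels = NULL,
                               weights = NULL, rounding = TRUE) {
  need <- c("respondent_id", "node", "child_a", "child_b", "answer")
  miss <- setdiff(need, names(judgments))
  if (length(miss) > 0) {
    stop("judgments missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  d <- judgments[judgments$node == node, , drop = FALSE]
  if (nrow(d) == 0) stop("no judgments for node '", node, "'", call. = FALSE)
  ans <- d$answer
  if (is.numeric(ans)) {
    val <- as.numeric(ans)
  } else {
    ans <- as.character(ans)
    numeric_like <- grepl("^\\s*[0-9.,/]+\\s*$", ans)
    val <- numeric(length(ans))
    val[numeric_like] <- .parse_ratio(ans[numeric_like])
    if (any(!numeric_like)) val[!numeric_like] <- saaty_value(ans[!numeric_like])
  }
  if (any(!is.finite(val)) || any(val <= 0)) {
    stop("judgment answers must be positive ratios", call. = FALSE)
  }
  if (is.null(labels)) {
    labels <- unique(c(rbind(as.character(d$child_a), as.character(d$child_b))))
  }
  n <- length(labels)
  if (n < 2) stop("need at least two children at node '", node, "'",
                  call. = FALSE)
  M <- diag(n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      fwd <- d$child_a == labels[i] & d$child_b == labels[j]
      rev <- d$child_a == labels[j] & d$child_b == labels[i]
      ids <- c(as.character(d$respondent_id[fwd]),
               as.character(d$respondent_id[rev]))
      ratios <- c(val[fwd], 1 / val[rev])
      if (length(ratios) == 0) {
        stop("no respondent judged pair (", labels[i], ", ", labels[j],
             ") at node '", node, "'", call. = FALSE)
      }
      if (is.null(weights)) {
        bk <- rep(1 / length(ratios), length(ratios))
      } else {
        bk <- weights[ids]
        if (anyNA(bk)) {
          stop("weights missing for respondent(s): ",
               paste(unique(ids[is.na(bk)]), collapse = ", "), call. = FALSE)
        }
        bk <- bk / sum(bk)  # renormalize over respondents present
      }
      g <- wgmm(ratios, bk)
      # round on the >= 1 side only, then mirror, preserving reciprocity
      if (rounding) g <- round_to_saaty(g)
      M[i, j] <- g
      M[j, i] <- 1 / g
    }
  }
  pairwise_matrix(M, labels = labels)
}
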