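#' Likert answer categories
#'
#' Canonical agreement categories for a k-point scale; for the default 5
#' points: strongly agree, agree, uncertain, disagree, strongly disagree.
#'
#' @param points Scale width, 4-7 (default 5).
#' @return Character vector of category labels, most-agreeing first.
#' @export
likert_categories <- function(points = 5) {
  if (!points %in% 4:7) stop("scale width must be 4..7", call. = FALSE)
  switch(as.character(points),
    "4" = c("strongly agree", "agree", "disagree", "strongly disagree"),
    "5" = c("strongly agree", "agree", "uncertain", "disagree",
            "strongly disagree"),
    "6" = c("strongly agree", "agree", "somewhat agree", "somewhat disagree",
            "disagree", "strongly disagree"),
    "7" = c("strongly agree", "agree", "somewhat agree", "uncertain",
            "somewhat disagree", "disagree", "strongly disagree"))
}

#' The 13-item satisfaction questionnaire codebook
#'
#' Items, their wording, the sub-criteria each item informs, and the
#' scoring direction.  Direct items score strongly agree = 5 down to
#' strongly disagree = 1; reverse-coded items (4, 8, 12, 13) score
#' strongly agree = 1 up to strongly disagree = 5.  Items may inform more
#' than one sub-criterion (item 9, on cost adequacy, informs all three
#' economic sub-criteria; items 5 and 6 both inform human resources).
#'
#' @return A data frame of class \code{likert_codebook} with columns
#'   \code{item} (integer id), \code{text}, \code{subcriteria}
#'   (list-column of sub-criterion labels) and \code{reverse} (logical).
#' @export
likert_codebook <- function() {
  cb <- data.frame(
    item = 1:13,
    text = c(
      "The reliability of the medical equipment is satisfactory",
      "The technological efficiency is appropriate for the type of treatment",
      "The technological safety is high to reduce any danger",
      "The procedural complexity is quite easy and well organized",
      "The preparation of the medical staff is adequate",
      "The staff is adequately available",
      "The possible side effects of the treatment are not very dangerous for the patients",
      "The clinical efficacy of the treatment is evaluated as good",
      "The cost of the treatment is appropriate for the quality offered",
      "The duration of the treatment is not long in relation to the type of disease",
      "In the hospital, there is a good respect for social principles",
      "The legal issues are respected",
      "The ethical principles are respected"),
    reverse = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, TRUE,
                FALSE, FALSE, FALSE, TRUE, TRUE),
    stringsAsFactors = FALSE
  )
  cb$subcriteria <- list(
    "Reliability", "Technological Efficiency", "Technological Safety",
    "Procedural Complexity", "Human Resources", "Human Resources",
    "Side Effects", "Clinical Efficiency",
    c("Investments", "Usefulness", "ROS"), "Effectiveness",
    "Respect for social aspects", "Respect for legal issues",
    "Respect for ethical principles")
  class(cb) <- c("likert_codebook", "data.frame")
  cb
}

#' Score raw Likert answers
#'
#' Maps category labels to numeric scores per the codebook direction:
#' direct items strongly agree = k ... strongly disagree = 1 on a k-point
#' scale; reverse items the mirror image, so a reverse score always equals
#' \code{k + 1 - direct score}.
#'
#' @param answers Data frame with columns \code{respondent_id},
#'   \code{item_id} and \code{answer} (category labels,
#'   case-insensitive).  Missing answers (\code{NA} or empty) stay
#'   \code{NA} and are excluded item-wise downstream.
#' @param codebook A [likert_codebook()] (or a data frame with columns
#'   \code{item} and \code{reverse}).
#' @param points Scale width (default 5).
#' @return A respondents-by-items numeric matrix of scores; row names are
#'   respondent ids, column names item ids.
#' @examples
#' a <- data.frame(respondent_id = 1, item_id = c(1, 4),
#'                 answer = "strongly agree")
#' score_responses(a)  # item 1 -> 5, item 4 (reverse) -> 1
#' @export
score_responses <- function(answers, codebook = likert_codebook(), points = 5) {
  need <- c("respondent_id", "item_id", "answer")
  miss <- setdiff(need, names(answers))
  if (length(miss) > 0) {
    stop("answers missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  cats <- likert_categories(points)
  items <- sort(unique(answers$item_id))
  unknown <- setdiff(items, codebook$item)
  if (length(unknown) > 0) {
    stop("item(s) not in codebook: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  key <- tolower(trimws(as.character(answers$answer)))
  key[!nzchar(key)] <- NA
  pos <- match(key, cats)  # 1 = most agreeing
  bad <- !is.na(key) & is.na(pos)
  if (any(bad)) {
    stop("unknown answer categor(ies): ",
         paste(unique(answers$answer[bad]), collapse = ", "), call. = FALSE)
  }
  direct <- points + 1L - pos              # strongly agree -> k
  rev_item <- codebook$reverse[match(answers$item_id, codebook$item)]
  score <- ifelse(rev_item, points + 1L - direct, direct)
  resp <- unique(answers$respondent_id)
  m <- matrix(NA_real_, nrow = length(resp), ncol = length(items),
              dimnames = list(as.character(resp), as.character(items)))
  m[cbind(match(answers$respondent_id, resp),
          match(answers$item_id, items))] <- score
  m
}

#' Summarize scored Likert responses
#'
#' Per item: the percentage of respondents in each score category, the
#' mean score, and a satisfaction index rescaled to \code{[0, 1]} as
#' \code{(mean - 1) / (k - 1)}.  Missing answers are excluded item-wise
#' and the per-item respondent count is reported.
#'
#' @param scored Respondents-by-items score matrix from
#'   [score_responses()].
#' @param points Scale width (default 5).
#' @return A data frame of class \code{satisfaction_table}: one row per
#'   item with columns \code{item}, \code{n}, \code{pct_1} ..
#'   \code{pct_k} (percentages by score value), \code{mean} and
#'   \code{index}.
#' @export
summarize_likert <- function(scored, points = 5) {
  if (!is.matrix(scored) || nrow(scored) == 0) {
    stop("scored matrix must have at least one respondent", call. = FALSE)
  }
  out <- do.call(rbind, lapply(colnames(scored), function(it) {
    x <- scored[, it]
    x <- x[!is.na(x)]
    if (length(x) == 0) {
      stop("item ", it, " has no answers", call. = FALSE)
    }
    pct <- 100 * vapply(seq_len(points), function(v) mean(x == v), numeric(1))
    data.frame(item = it, n = length(x),
               t(stats::setNames(pct, paste0("pct_", seq_len(points)))),
               mean = mean(x), index = (mean(x) - 1) / (points - 1),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("satisfaction_table", "data.frame")
  out
}

#' Satisfaction index per sub-criterion
#'
#' Maps item-level satisfaction indices onto sub-criteria via the
#' codebook; a sub-criterion informed by several items gets their mean
#' index.
#'
#' @param summary A [summarize_likert()] table.
#' @param codebook A [likert_codebook()].
#' @return Named numeric vector of satisfaction indices in \code{[0, 1]},
#'   one per sub-criterion covered by the codebook.
#' @export
satisfaction_by_subcriterion <- function(summary, codebook = likert_codebook()) {
  idx <- stats::setNames(summary$index, summary$item)
  pairs <- do.call(rbind, lapply(seq_len(nrow(codebook)), function(i) {
    data.frame(item = codebook$item[i], sub = codebook$subcriteria[[i]],
               stringsAsFactors = FALSE)
  }))
  pairs <- pairs[as.character(pairs$item) %in% names(idx), , drop = FALSE]
  vals <- tapply(idx[as.character(pairs$item)], pairs$sub, mean)
  # keep codebook order, not alphabetical
  ord <- unique(unlist(codebook$subcriteria))
  out <- vals[ord[ord %in% names(vals)]]
  stats::setNames(as.numeric(out), names(out))
}
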