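#' The Saaty 1-9 judgment scale
#'
#' Returns the fundamental pairwise-comparison scale used throughout the
#' analytic hierarchy process: integer intensities 1 (equal importance) to
#' 9 (extreme importance), with even intensities as intermediate grades.
#' Comparisons in the mirrored direction take the exact reciprocal \code{1/v}.
#'
#' @return A data frame with columns \code{intensity} (integer 1-9) and
#'   \code{label} (the canonical degree-of-preference wording).
#' @examples
#' saaty_scale()
#' @export
saaty_scale <- function() {
  data.frame(
    intensity = 1:9,
    label = c(
      "Equal importance",
      "Weak",
      "Moderate importance",
      "Moderate plus",
      "Strong importance",
      "Strong plus",
      "Very strong or demonstrated importance",
      "Very, very strong",
      "Extreme importance"
    ),
    stringsAsFactors = FALSE
  )
}

# Questionnaire answer categories: symmetric 9-point wording used when a
# respondent may favour either side of a comparison.  "less important"
# categories map to reciprocals of the odd intensities.
.saaty_mirror <- function() {
  data.frame(
    label = c(
      "Extremely less important",
      "Much less important",
      "Less important",
      "Slightly less important",
      "Equally Important",
      "Slightly more important",
      "More important",
      "Much more important",
      "Extremely more important"
    ),
    value = c(1 / 9, 1 / 7, 1 / 5, 1 / 3, 1, 3, 5, 7, 9),
    stringsAsFactors = FALSE
  )
}

#' Convert a Saaty-scale label or intensity to its ratio value
#'
#' Accepts integer intensities 1-9, the canonical scale labels (e.g.
#' \code{"Strong importance"} is 5), or the mirrored questionnaire answer
#' categories (e.g. \code{"Much less important"} is 1/7).  Matching is
#' case-insensitive and tolerant of surrounding whitespace.
#'
#' @param x A character vector of labels, or a numeric vector of
#'   intensities in \code{1:9} (reciprocals \code{1/9..1} are passed
#'   through unchanged).
#' @return A numeric vector of ratio values in \code{[1/9, 9]}.
#' @examples
#' saaty_value("Strong importance")      # 5
#' saaty_value("Much less important")    # 1/7
#' saaty_value(c(1, 7))
#' @export
saaty_value <- function(x) {
  if (is.numeric(x)) {
    ok <- is.finite(x) &
      ((x >= 1 & x <= 9 & abs(x - round(x)) < 1e-9) |
         vapply(x, function(v) {
           v > 0 && v < 1 && abs(1 / v - round(1 / v)) < 1e-9 && 1 / v <= 9
         }, logical(1)))
    if (!all(ok)) {
      stop("numeric Saaty values must be integers 1..9 or their reciprocals; bad: ",
           paste(x[!ok], collapse = ", "), call. = FALSE)
    }
    return(as.numeric(x))
  }
  key <- tolower(trimws(as.character(x)))
  scale <- saaty_scale()
  mirror <- .saaty_mirror()
  lut <- c(
    stats::setNames(as.numeric(scale$intensity), tolower(scale$label)),
    stats::setNames(mirror$value, tolower(mirror$label))
  )
  out <- unname(lut[key])
  if (anyNA(out)) {
    stop("unknown Saaty label(s): ",
         paste(unique(x[is.na(out)]), collapse = ", "), call. = FALSE)
  }
  out
}

#' Round an aggregated ratio to the nearest Saaty value
#'
#' Group-aggregated geometric means are generally non-integer; the group
#' matrix entry is the nearest scale integer.  Values \eqn{\ge 1} round to
#' the nearest integer in 1..9 (halves round up, values above 9 clamp to 9);
#' values \eqn{< 1} are rounded on their reciprocal side and mirrored back,
#' so that \code{round_to_saaty(1/g) == 1/round_to_saaty(g)} always holds
#' and reciprocity of the rounded matrix is preserved.
#'
#' @param g Positive numeric vector of aggregated ratios.
#' @return Numeric vector of values in \code{\{1/9..1/2, 1..9\}}.
#' @examples
#' round_to_saaty(3.4)        # 3
#' round_to_saaty(2.5)        # 3 (half rounds up)
#' round_to_saaty(1 / 3.4)    # 1/3
#' @export
round_to_saaty <- function(g) {
  if (!is.numeric(g) || any(!is.finite(g)) || any(g <= 0)) {
    stop("ratios must be finite and positive", call. = FALSE)
  }
  round_up <- function(v) pmin(pmax(floor(v + 0.5), 1), 9)
  ifelse(g >= 1, round_up(g), 1 / round_up(1 / g))
}
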