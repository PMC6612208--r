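#' Principal eigenvalue and eigenvector of a comparison matrix
#'
#' For a positive reciprocal matrix the Perron-Frobenius theorem
#' guarantees a unique largest eigenvalue \eqn{\lambda_{max} \ge n} with a
#' strictly positive eigenvector; that eigenvector, suitably normalized,
#' is the AHP priority vector.  The dense eigen-decomposition is used
#' (matrices here are tiny); if it fails to deliver a real positive
#' principal pair, a power iteration with tolerance 1e-10 is used instead.
#'
#' @param M A [pairwise_matrix()] (or plain valid reciprocal matrix).
#' @return A list with \code{lambda_max} and \code{vector}, the positive
#'   principal eigenvector scaled to unit Euclidean norm, named by the
#'   matrix labels.
#' @examples
#' M <- pairwise_matrix(matrix(c(1, 2, 4, 1/2, 1, 2, 1/4, 1/2, 1), 3, 3,
#'                             byrow = TRUE))
#' principal_eigen(M)  # lambda_max = 3 exactly: the matrix is consistent
#' @export
principal_eigen <- function(M) {
  v <- validate_pairwise_matrix(M)
  if (!v) {
    stop("not a valid pairwise matrix: ",
         paste(attr(v, "problems"), collapse = "; "), call. = FALSE)
  }
  A <- unclass(M)
  e <- eigen(A)
  i <- which.max(Re(e$values))
  lambda <- e$values[i]
  vec <- e$vectors[, i]
  if (abs(Im(lambda)) > 1e-8 || any(abs(Im(vec)) > 1e-8)) {
    res <- .power_iteration(A)
    lambda <- res$lambda
    vec <- res$vector
  }
  lambda <- Re(lambda)
  vec <- Re(vec)
  if (all(vec <= 0)) vec <- -vec
  if (any(vec <= 0)) {
    # principal eigenvector of a positive matrix is one-signed; mixed signs
    # indicate numerical trouble -> fall back to power iteration
    res <- .power_iteration(A)
    lambda <- res$lambda
    vec <- res$vector
  }
  vec <- vec / sqrt(sum(vec^2))
  list(lambda_max = lambda,
       vector = stats::setNames(vec, rownames(M)))
}

# Power iteration on a positive matrix; independent of eigen() and also
# used as an oracle in the tests.
.power_iteration <- function(A, tol = 1e-10, max_iter = 10000L) {
  x <- rep(1, nrow(A))
  lambda <- NA_real_
  for (it in seq_len(max_iter)) {
    y <- drop(A %*% x)
    lambda_new <- sqrt(sum(y^2)) / sqrt(sum(x^2))
    y <- y / sqrt(sum(y^2))
    if (it > 1 && max(abs(y - x)) < tol && abs(lambda_new - lambda) < tol) {
      return(list(lambda = lambda_new, vector = y))
    }
    x <- y
    lambda <- lambda_new
  }
  stop("power iteration did not converge within ", max_iter, " steps",
       call. = FALSE)
}

#' Normalize a raw priority eigenvector to unit sum
#'
#' @param raw Positive numeric vector (a principal eigenvector in any
#'   scaling).
#' @return An object of class \code{weight_vector}: list with
#'   \code{labels}, \code{raw} (input rescaled to unit Euclidean norm) and
#'   \code{weights} (unit-sum).  Output is invariant to positive scaling
#'   of the input.
#' @examples
#' normalize_weights(c(a = 2, b = 1, c = 1))$weights  # 0.5 0.25 0.25
#' @export
normalize_weights <- function(raw) {
  if (!is.numeric(raw) || length(raw) == 0 || any(!is.finite(raw))) {
    stop("raw vector must be finite numeric", call. = FALSE)
  }
  if (all(raw == 0)) stop("all-zero vector cannot be normalized", call. = FALSE)
  if (any(raw < 0)) stop("priority components must be positive", call. = FALSE)
  labels <- names(raw)
  if (is.null(labels)) labels <- paste0("C", seq_along(raw))
  structure(
    list(labels = labels,
         raw = unname(raw / sqrt(sum(raw^2))),
         weights = stats::setNames(unname(raw / sum(raw)), labels)),
    class = "weight_vector"
  )
}

#' @export
print.weight_vector <- function(x, digits = 4, ...) {
  cat("Priority weights (unit sum):\n")
  print(round(x$weights, digits))
  invisible(x)
}

#' Saaty's random consistency index
#'
#' Mean consistency index of randomly filled reciprocal matrices, used as
#' the denominator of the consistency ratio.  Standard tabled values;
#' \code{RI(5) = 1.12}.
#'
#' @param n Matrix dimension(s), 1-10.
#' @return Numeric RI value(s).
#' @export
random_index <- function(n) {
  ri <- c(0, 0, 0.58, 0.90, 1.12, 1.24, 1.32, 1.41, 1.45, 1.49)
  if (any(n < 1 | n > length(ri) | n != round(n))) {
    stop("random index tabled only for integer n in 1..", length(ri),
         call. = FALSE)
  }
  ri[n]
}

#' Consistency statistics of a comparison matrix
#'
#' Computes \eqn{\lambda_{max}}, the consistency index
#' \eqn{CI = (\lambda_{max} - n) / (n - 1)} and the consistency ratio
#' \eqn{CR = CI / RI(n)}.  Judgments with \eqn{CR \le 0.1} are
#' conventionally acceptable; a perfectly consistent matrix has
#' \eqn{CR = 0}.  For \eqn{n \le 2} a reciprocal matrix is always
#' consistent and CR is defined as 0.
#'
#' @param M A [pairwise_matrix()].
#' @param threshold Acceptability cutoff on CR (default 0.1).
#' @return An object of class \code{consistency_report}: list with
#'   \code{lambda_max}, \code{n}, \code{CI}, \code{RI}, \code{CR},
#'   \code{threshold}, \code{acceptable}.
#' @examples
#' M <- pairwise_matrix(matrix(c(1, 2, 1/2, 1), 2, 2, byrow = TRUE))
#' consistency(M)$CR  # 0
#' @export
consistency <- function(M, threshold = 0.1) {
  pe <- principal_eigen(M)
  n <- nrow(M)
  if (n <= 2) {
    ci <- 0
    ri <- random_index(n)
    cr <- 0
  } else {
    ci <- (pe$lambda_max - n) / (n - 1)
    ri <- random_index(n)
    cr <- ci / ri
  }
  structure(
    list(lambda_max = pe$lambda_max, n = n, CI = ci, RI = ri, CR = cr,
         threshold = threshold, acceptable = cr <= threshold),
    class = "consistency_report"
  )
}

#' @export
print.consistency_report <- function(x, ...) {
  cat(sprintf(
    "lambda_max = %.4f (n = %d)  CI = %.4f  RI = %.2f  CR = %.4f (%.2f%%) -> %s\n",
    x$lambda_max, x$n, x$CI, x$RI, x$CR, 100 * x$CR,
    if (x$acceptable) "acceptable" else
      sprintf("exceeds %.0f%% threshold", 100 * x$threshold)))
  invisible(x)
}

#' Derive one node's local weights from its comparison matrix
#'
#' Runs the eigenvector method on \code{M}, screens consistency, and
#' writes the unit-sum weights into the hierarchy at \code{node}.  An
#' inconsistent matrix (CR above threshold) warns and is annotated by
#' default; with \code{strict = TRUE} it is an error, reflecting that
#' ratios above 0.1 are sometimes tolerated in practice.
#'
#' @param h A \code{decision_hierarchy}.
#' @param node \code{"goal"} or a criterion label.
#' @param M A [pairwise_matrix()] over that node's children (labels, if
#'   present, must match).
#' @param threshold CR acceptability cutoff (default 0.1).
#' @param strict Reject inconsistent matrices instead of warning.
#' @return The updated hierarchy; consistency reports accumulate in
#'   \code{h$consistency[[node]]}.
#' @export
assess_node <- function(h, node, M, threshold = 0.1, strict = FALSE) {
  children <- .node_children(h, node)
  if (nrow(M) != length(children)) {
    stop("matrix dimension ", nrow(M), " does not match the ",
         length(children), " children of '", node, "'", call. = FALSE)
  }
  if (!is.null(rownames(M)) && !all(rownames(M) == paste0("C", seq_len(nrow(M)))) &&
      !setequal(rownames(M), children)) {
    stop("matrix labels do not match children of '", node, "'", call. = FALSE)
  }
  rep <- consistency(M, threshold = threshold)
  if (!rep$acceptable) {
    msg <- sprintf("node '%s': CR = %.4f exceeds threshold %.2f", node,
                   rep$CR, threshold)
    if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  pe <- principal_eigen(M)
  w <- normalize_weights(pe$vector)$weights
  h <- set_local_weights(h, node, unname(w))
  h$consistency[[node]] <- rep
  h
}

#' Synthesize final alternative priorities from leaf contributions
#'
#' Each alternative's total priority is the sum of its per-leaf
#' contributions (global leaf weight times the alternative's local weight
#' under that leaf).  Totals are reported as-is — they are not renormalized
#' to unit sum by default, so printed contribution lists can be audited
#' directly; set \code{normalize = TRUE} for a unit-sum view.
#'
#' @param contributions A named list, one element per alternative, each a
#'   numeric vector of non-negative contributions (lengths may differ).
#' @param normalize Rescale totals to sum to 1 (default \code{FALSE}).
#' @return An object of class \code{alternative_priorities}: list with
#'   \code{totals} (named, input order), \code{ranking} (labels sorted by
#'   descending total, ties kept in input order), and \code{unit_sum}
#'   (whether the raw totals sum to 1 within 1e-6).
#' @examples
#' synthesize_priorities(list(A = c(0.2, 0.3), B = c(0.1, 0.15)))
#' @export
synthesize_priorities <- function(contributions, normalize = FALSE) {
  if (is.null(names(contributions)) || any(!nzchar(names(contributions)))) {
    stop("contributions must be a named list (one element per alternative)",
         call. = FALSE)
  }
  bad <- vapply(contributions,
                function(x) any(!is.finite(x)) || any(x < 0), logical(1))
  if (any(bad)) {
    stop("negative or non-finite contribution for: ",
         paste(names(contributions)[bad], collapse = ", "), call. = FALSE)
  }
  totals <- vapply(contributions, sum, numeric(1))
  unit_sum <- abs(sum(totals) - 1) <= 1e-6
  if (normalize) totals <- totals / sum(totals)
  ord <- order(-totals)  # stable: ties stay in input order
  structure(
    list(totals = totals, ranking = names(totals)[ord], unit_sum = unit_sum,
         normalized = normalize),
    class = "alternative_priorities"
  )
}

#' @export
print.alternative_priorities <- function(x, digits = 4, ...) {
  cat("Alternative priorities",
      if (x$normalized) " (normalized)", ":\n", sep = "")
  for (i in seq_along(x$ranking)) {
    cat(sprintf("  %d. %s  %.*f\n", i, x$ranking[i], digits,
                x$totals[[x$ranking[i]]]))
  }
  if (!x$normalized && !x$unit_sum) {
    cat(sprintf("  (totals sum to %.4f, not renormalized)\n", sum(x$totals)))
  }
  invisible(x)
}
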