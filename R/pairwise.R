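#' Construct a pairwise comparison matrix
#'
#' A pairwise comparison matrix holds, for the children of one hierarchy
#' node, the ratio judgments \eqn{a_{ij}} of how much more important child
#' \eqn{i} is than child \eqn{j}.  It must be square, strictly positive,
#' have a unit diagonal and be reciprocal (\eqn{a_{ij} a_{ji} = 1}).
#'
#' @param x A square numeric matrix of positive ratios.
#' @param labels Optional character vector of child labels (defaults to
#'   existing dimnames or \code{C1..Cn}).
#' @param check If \code{TRUE} (default) the matrix is validated and
#'   invalid input is an error.
#' @return A matrix of class \code{pairwise_matrix} with label dimnames.
#' @examples
#' pairwise_matrix(matrix(c(1, 2, 1/2, 1), 2, 2, byrow = TRUE),
#'                 labels = c("cost", "benefit"))
#' @seealso [validate_pairwise_matrix()], [principal_eigen()]
#' @export
pairwise_matrix <- function(x, labels = NULL, check = TRUE) {
  x <- as.matrix(x)
  if (nrow(x) != ncol(x)) {
    stop("pairwise comparison matrix must be square, got ",
         nrow(x), "x", ncol(x), call. = FALSE)
  }
  if (is.null(labels)) {
    labels <- rownames(x)
    if (is.null(labels)) labels <- paste0("C", seq_len(nrow(x)))
  }
  if (length(labels) != nrow(x)) {
    stop("labels length must equal matrix dimension", call. = FALSE)
  }
  storage.mode(x) <- "double"
  dimnames(x) <- list(labels, labels)
  class(x) <- c("pairwise_matrix", "matrix", "array")
  if (check) {
    v <- validate_pairwise_matrix(x)
    if (!v) {
      stop("invalid pairwise matrix: ",
           paste(attr(v, "problems"), collapse = "; "), call. = FALSE)
    }
  }
  x
}

#' Validate a pairwise comparison matrix
#'
#' Checks the structural requirements of a comparison matrix: finite,
#' strictly positive entries, unit diagonal, and reciprocity
#' \eqn{a_{ij} a_{ji} = 1} within \code{tol}.
#'
#' @param M A square numeric matrix.
#' @param tol Numerical tolerance for diagonal and reciprocity checks.
#' @return \code{TRUE} if valid, otherwise \code{FALSE} with a
#'   \code{"problems"} attribute listing each violated requirement.
#'   A non-square input is an error, not a verdict.
#' @examples
#' validate_pairwise_matrix(matrix(c(1, 2, 0.5, 1), 2, 2))      # TRUE
#' validate_pairwise_matrix(matrix(c(1, 2, 2, 1), 2, 2))        # FALSE
#' @export
validate_pairwise_matrix <- function(M, tol = 1e-9) {
  M <- as.matrix(M)
  if (nrow(M) != ncol(M)) {
    stop("matrix must be square, got ", nrow(M), "x", ncol(M), call. = FALSE)
  }
  problems <- character(0)
  if (!is.numeric(M) || any(!is.finite(M))) {
    problems <- c(problems, "entries must be finite numbers")
  } else {
    if (any(M <= 0)) problems <- c(problems, "entries must be strictly positive")
    if (any(abs(diag(M) - 1) > tol)) problems <- c(problems, "diagonal must be 1")
    if (any(abs(M * t(M) - 1) > tol)) {
      problems <- c(problems, "reciprocity a_ij * a_ji = 1 violated")
    }
  }
  out <- length(problems) == 0L
  attr(out, "problems") <- problems
  out
}

#' @export
print.pairwise_matrix <- function(x, digits = 4, ...) {
  cat("Pairwise comparison matrix (", nrow(x), "x", ncol(x), ")\n", sep = "")
  y <- x
  class(y) <- "matrix"
  print(round(y, digits), ...)
  invisible(x)
}

# Parse a ratio that may be written as a fraction ("1/7") or a decimal,
# accepting both "." and "," decimal marks.  Fractions are evaluated from
# integer parts so 1/3 is bit-identical to R's 1/3.
.parse_ratio <- function(s) {
  s <- gsub(",", ".", trimws(as.character(s)), fixed = TRUE)
  vapply(s, function(v) {
    if (grepl("/", v, fixed = TRUE)) {
      parts <- strsplit(v, "/", fixed = TRUE)[[1]]
      if (length(parts) != 2) stop("malformed ratio: ", v, call. = FALSE)
      num <- suppressWarnings(as.numeric(parts[1]))
      den <- suppressWarnings(as.numeric(parts[2]))
      if (is.na(num) || is.na(den) || den == 0) {
        stop("malformed ratio: ", v, call. = FALSE)
      }
      num / den
    } else {
      out <- suppressWarnings(as.numeric(v))
      if (is.na(out)) stop("malformed ratio: ", v, call. = FALSE)
      out
    }
  }, numeric(1), USE.NAMES = FALSE)
}

# Render a ratio as "1/n" when it is (within tolerance) a unit fraction,
# else as a plain decimal; used when writing matrices so printed tables
# round-trip exactly.
.format_ratio <- function(x) {
  vapply(x, function(v) {
    if (v < 1 && abs(1 / v - round(1 / v)) < 1e-9) {
      paste0("1/", format(round(1 / v)))
    } else {
      format(v, digits = 15)
    }
  }, character(1))
}

#' Read a pairwise comparison matrix from CSV
#'
#' The expected layout mirrors a printed comparison table: a header row of
#' child labels, one row per child with its label in the first column, and
#' ratio entries that may be decimals (either \code{.} or \code{,} decimal
#' mark) or exact fractions such as \code{1/7}.
#'
#' @param path Path to the CSV file.
#' @param check Validate the matrix after reading (default \code{TRUE}).
#' @return A [pairwise_matrix()].
#' @export
read_pairwise_csv <- function(path, check = TRUE) {
  raw <- utils::read.csv(path, header = TRUE, check.names = FALSE,
                         colClasses = "character")
  labels <- raw[[1]]
  vals <- as.matrix(raw[, -1, drop = FALSE])
  M <- matrix(.parse_ratio(vals), nrow = nrow(vals), ncol = ncol(vals))
  pairwise_matrix(M, labels = labels, check = check)
}

#' Write a pairwise comparison matrix to CSV
#'
#' Entries below 1 that are exact unit fractions are written as
#' \code{"1/n"} so they re-read bit-identically; all other entries are
#' written with full precision and a \code{.} decimal mark.
#'
#' @param M A [pairwise_matrix()].
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_pairwise_csv <- function(M, path) {
  labels <- rownames(M)
  body <- matrix(.format_ratio(as.numeric(M)), nrow = nrow(M))
  df <- data.frame(label = labels, body, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df) <- c("", labels)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
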