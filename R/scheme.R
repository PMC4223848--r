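#' Define a categorical rating scheme
#'
#' A rating scheme declares the set of category codes a survey item can
#' take, display labels, and which codes are informative (substantive
#' scale points) as opposed to indefinite ("cannot say") or missing
#' answers, which are carried along as categories of their own.
#'
#' @param codes Integer vector of distinct category codes (length >= 2).
#' @param labels Character labels, one per code.
#' @param informative Logical vector flagging substantive codes.
#'
#' @return An object of class `rating_scheme`.
#' @examples
#' rating_scheme(1:3, c("low", "high", "missing"), c(TRUE, TRUE, FALSE))
#' @export
rating_scheme <- function(codes,
                          labels = as.character(codes),
                          informative = rep(TRUE, length(codes))) {
  codes <- as.integer(codes)
  if (anyNA(codes) || anyDuplicated(codes) > 0L) {
    abort("`codes` must be distinct non-missing integers.")
  }
  if (length(codes) < 2L) {
    abort("A rating scheme needs at least 2 categories.")
  }
  if (length(labels) != length(codes) || length(informative) != length(codes)) {
    abort("`labels` and `informative` must match `codes` in length.")
  }
  structure(
    list(codes = codes, labels = as.character(labels),
         informative = as.logical(informative)),
    class = "rating_scheme"
  )
}

#' Four-graded agreement scale with indefinite and missing categories
#'
#' The scheme used throughout the package examples: an ordinal
#' Disagree-to-Agree scale (codes 1-4), plus "Cannot say" (5) and
#' "Not answered" (6) kept as separate, non-informative categories.
#'
#' @return A [rating_scheme].
#' @export
green_score_scheme <- function() {
  rating_scheme(
    codes = 1:6,
    labels = c("Disagree completely", "Disagree", "Agree",
               "Agree completely", "Cannot say", "Not answered"),
    informative = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE)
  )
}

#' @export
print.rating_scheme <- function(x, ...) {
  cat("<rating_scheme> ", length(x$codes), " categories\n", sep = "")
  flag <- ifelse(x$informative, "", " (non-informative)")
  cat(paste0("  ", x$codes, " = ", x$labels, flag, collapse = "\n"), "\n")
  invisible(x)
}

# Infer a scheme from the codes actually present in one or more rating columns.
infer_scheme <- function(values) {
  codes <- sort(unique(as.integer(values)))
  rating_scheme(codes)
}

check_scheme <- function(scheme) {
  if (!inherits(scheme, "rating_scheme")) {
    abort("`scheme` must be a `rating_scheme` object.")
  }
  scheme
}
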