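#' Rank-based tertile assignment with a deterministic tie rule
#'
#' Splits a numeric vector into three rank-based groups. Cutpoints sit at the
#' `floor(n/3)`-th and `floor(2n/3)`-th order statistics; every observation
#' less than or equal to a cutpoint value falls in the lower group, so ties at
#' a boundary all receive the lower label and the assignment is deterministic.
#'
#' @param x Numeric vector, no missing values.
#' @param labels Character vector of three labels, low to high.
#' @return Factor of the same length as `x` with levels `labels` and an
#'   attribute `"cutpoints"`: a tibble with the observed min and max per group.
#' @examples
#' tertile_assign(1:9)
#' @export
tertile_assign <- function(x, labels = c("T1", "T2", "T3")) {
  if (anyNA(x)) abort("`x` must not contain missing values.")
  n <- length(x)
  if (n < 3) abort("Need at least 3 observations to form tertiles.")
  if (length(unique(x)) == 1L) {
    abort("All values are identical; no tertile split is possible.")
  }
  xs <- sort(x)
  cut1 <- xs[floor(n / 3)]
  cut2 <- xs[floor(2 * n / 3)]
  lab <- ifelse(x <= cut1, labels[1], ifelse(x <= cut2, labels[2], labels[3]))
  f <- factor(lab, levels = labels)
  present <- levels(droplevels(f))
  if (length(present) < 2L) {
    abort("Ties collapse the split to a single group; no tertile split is possible.")
  }
  cp <- dplyr::group_by(tibble::tibble(group = f, x = x), .data$group)
  cp <- dplyr::summarise(cp, min = min(.data$x), max = max(.data$x), n = dplyr::n(),
                         .groups = "drop")
  attr(f, "cutpoints") <- cp
  f
}

#' Format tertile cutpoints the way cohort papers print them
#'
#' @param f A factor produced by [tertile_assign()].
#' @return Character scalar like `"T1: 1.7-3.3, T2: 3.5-4.3, T3: 4.4-8.0"`.
#' @export
format_cutpoints <- function(f) {
  cp <- attr(f, "cutpoints")
  if (is.null(cp)) abort("`f` carries no cutpoint attribute.")
  paste(sprintf("%s: %s-%s", cp$group, signif(cp$min, 3), signif(cp$max, 3)),
        collapse = ", ")
}

# yes/no/dont_know helpers for survey booleans
is_yes <- function(x) x == "yes"
has_dk <- function(...) {
  cols <- list(...)
  Reduce(`|`, lapply(cols, function(v) !is.na(v) & v == "dont_know"))
}
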