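#' Prey-importance statistics for one group
#'
#' For every prey category observed in a group's diet matrix, computes the
#' triplet of Amundsen-style importance statistics, all on the percent
#' scale:
#' \describe{
#'   \item{frequency of occurrence}{\eqn{F_i = 100 \, N_i / N}, where
#'     \eqn{N_i} is the number of fish whose gut contains prey \eqn{i} and
#'     \eqn{N} the number of fish with gut contents of any kind (empty guts
#'     are excluded from the denominator).}
#'   \item{relative abundance}{\eqn{A_i = 100 \, S_i / S_t}: weight of prey
#'     \eqn{i} over the total content weight of all examined guts.}
#'   \item{prey-specific abundance}{\eqn{P_i = 100 \, S_i / St_i}: weight of
#'     prey \eqn{i} over the total content weight of only those guts that
#'     contain it. Always \eqn{\ge A_i}.}
#' }
#' Unobserved prey are absent from the result, not zero rows.
#'
#' @param matrix a `diet_matrix` from [build_diet_matrix()].
#' @return a tibble with columns `prey_category`, `n_occurrence`,
#'   `weight_g`, `frequency_occurrence`, `relative_abundance`,
#'   `prey_specific_abundance`, plus the group key columns; the group key is
#'   also attached as attribute `"group"`.
#' @export
#' @examples
#' recs <- tibble::tibble(
#'   fish_id = c("f1", "f2", "f2", "f3"),
#'   species = "sp", season = "spring", standard_length = 150,
#'   prey_category = c("A", "A", "B", "B"),
#'   prey_weight = c(2, 1, 1, 3))
#' dm <- build_diet_matrix(recs)[[1]]
#' prey_importance(dm)
prey_importance <- function(matrix) {
  stopifnot(inherits(matrix, "diet_matrix"))
  W <- matrix$weights
  nonempty <- matrix$fish_totals > 0
  N <- sum(nonempty)
  if (N == 0) {
    abort_data("group has no fish with gut contents; indices are undefined",
               class = "gutdiet_empty_group")
  }
  W <- W[nonempty, , drop = FALSE]
  present <- W > 0
  N_i <- colSums(present)
  observed <- N_i > 0
  W <- W[, observed, drop = FALSE]
  present <- present[, observed, drop = FALSE]
  N_i <- N_i[observed]

  S_i <- colSums(W)                       # total weight of prey i
  S_t <- sum(W)                           # total content weight, all guts
  # St_i: total content weight of the guts containing prey i
  St_i <- colSums(present * rowSums(W))

  out <- tibble::tibble(
    prey_category = colnames(W),
    n_occurrence = as.integer(N_i),
    weight_g = unname(S_i),
    frequency_occurrence = 100 * unname(N_i) / N,
    relative_abundance = 100 * unname(S_i) / S_t,
    prey_specific_abundance = 100 * unname(S_i) / unname(St_i)
  )
  for (nm in rev(names(matrix$group))) {
    out <- tibble::add_column(out, !!nm := matrix$group[[nm]], .before = 1)
  }
  attr(out, "group") <- matrix$group
  attr(out, "N") <- N
  out
}

#' Percent-by-weight diet proportions
#'
#' Converts a diet matrix, a prey-importance table, or a named numeric
#' vector of relative abundances into a named proportion vector on the
#' percent scale. By default the vector is renormalised to sum exactly 100,
#' which absorbs the ±0.01 drift of 2-decimal published tables and makes
#' the two algebraic forms of Schoener's index coincide; set
#' `renormalize = FALSE` to audit raw values.
#'
#' @param x a `diet_matrix`, a data frame with `prey_category` and
#'   `relative_abundance` columns, or a named non-negative numeric vector.
#' @param renormalize scale the vector to sum exactly 100?
#' @return a named numeric vector of class `diet_proportions`.
#' @export
diet_proportions <- function(x, renormalize = TRUE) {
  UseMethod("diet_proportions")
}

#' @export
diet_proportions.diet_matrix <- function(x, renormalize = TRUE) {
  imp <- prey_importance(x)
  diet_proportions(setNames(imp$relative_abundance, imp$prey_category),
                   renormalize = renormalize)
}

#' @export
diet_proportions.data.frame <- function(x, renormalize = TRUE) {
  cols <- c("prey_category", "relative_abundance")
  if (!all(cols %in% names(x))) {
    abort_data("data frame must have prey_category and relative_abundance columns")
  }
  if (anyDuplicated(x$prey_category)) {
    abort_data("one proportion per prey category expected; did you forget to split by group?")
  }
  diet_proportions(setNames(x$relative_abundance, x$prey_category),
                   renormalize = renormalize)
}

#' @export
diet_proportions.numeric <- function(x, renormalize = TRUE) {
  if (is.null(names(x)) || any(names(x) == "")) {
    abort_data("proportion vectors must be named by prey category")
  }
  if (any(!is.finite(x) | x < 0)) {
    abort_data("proportions must be finite and non-negative")
  }
  total <- sum(x)
  if (total <= 0) {
    abort_data("all-zero proportion vector")
  }
  if (renormalize) x <- x / total * 100
  structure(x, class = c("diet_proportions", "numeric"))
}

#' @export
diet_proportions.diet_proportions <- function(x, renormalize = TRUE) {
  diet_proportions(unclass(x), renormalize = renormalize)
}

check_proportions <- function(p, arg, tol = 0.5) {
  p <- diet_proportions(p, renormalize = FALSE)
  if (abs(sum(p) - 100) > tol) {
    abort_data(sprintf("%s sums to %.4f, not 100 (tolerance %.2f)",
                       arg, sum(p), tol))
  }
  p
}

#' Schoener's diet-overlap index
#'
#' \eqn{D = 100 - 0.5 \sum_i |p_i - q_i|} on percent-by-weight diet
#' proportions, aligned on the union of the two prey sets (absent prey
#' contribute 0). When both vectors sum to 100 this equals
#' \eqn{\sum_i \min(p_i, q_i)}. D ranges from 0 (no shared diet) to 100
#' (identical diets); overlap above 60 is conventionally called
#' biologically significant.
#'
#' @param p,q named percent-by-weight proportion vectors (see
#'   [diet_proportions()]); each must sum to 100 within `tol`.
#' @param tol allowed deviation of each input sum from 100.
#' @return the overlap D, a scalar percent.
#' @export
#' @examples
#' p <- diet_proportions(c(mussel = 80, detritus = 20))
#' q <- diet_proportions(c(mussel = 60, insect = 40))
#' schoener_overlap(p, q)  # 60
schoener_overlap <- function(p, q, tol = 0.5) {
  p <- check_proportions(p, "p", tol)
  q <- check_proportions(q, "q", tol)
  prey <- union(names(p), names(q))
  pp <- setNames(numeric(length(prey)), prey)
  qq <- pp
  pp[names(p)] <- p
  qq[names(q)] <- q
  d <- 100 - 0.5 * sum(abs(pp - qq))
  min(max(d, 0), 100)  # clamp floating-point dust at the bounds
}

#' Pairwise diet-overlap matrix
#'
#' All pairwise Schoener overlaps among two or more groups, with the
#' diagonal fixed at 100 and pairs exceeding the significance threshold
#' flagged.
#'
#' @param groups a named list of proportion vectors ([diet_proportions()]).
#' @param threshold percent overlap above which a pair is flagged
#'   biologically significant (default 60).
#' @inheritParams schoener_overlap
#' @return a symmetric numeric matrix of class `overlap_matrix` with a
#'   logical `"significant"` attribute of the same shape.
#' @export
overlap_matrix <- function(groups, threshold = 60, tol = 0.5) {
  if (length(groups) < 2) {
    abort_data("at least two groups are needed for an overlap matrix")
  }
  if (is.null(names(groups)) || any(names(groups) == "")) {
    abort_data("groups must be a named list")
  }
  k <- length(groups)
  D <- matrix(100, k, k, dimnames = list(names(groups), names(groups)))
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      D[i, j] <- D[j, i] <- schoener_overlap(groups[[i]], groups[[j]], tol = tol)
    }
  }
  sig <- D > threshold
  diag(sig) <- NA
  structure(D, significant = sig, threshold = threshold,
            class = c("overlap_matrix", "matrix", "array"))
}

#' @export
print.overlap_matrix <- function(x, digits = 2, ...) {
  cat(sprintf("<overlap_matrix> Schoener's D (%%), significance threshold %s\n",
              format(attr(x, "threshold"))))
  m <- unclass(x)
  attr(m, "significant") <- NULL
  attr(m, "threshold") <- NULL
  print(round_half_up(m, digits))
  invisible(x)
}

#' Levins' dietary niche breadth
#'
#' \eqn{B = 1 / \sum_i p_i^2} with \eqn{p_i} the fraction of prey \eqn{i}
#' in the diet (by weight). B runs from 1 (a single prey: monophagy) to S,
#' the number of prey used, attained only by the uniform diet. The input
#' may be on the percent or fraction scale; it is normalised internally, so
#' the index is scale-invariant.
#'
#' @param p a non-negative named or unnamed numeric vector of diet
#'   proportions.
#' @return an object of class `niche_breadth`: a list with `B` (breadth)
#'   and `S` (number of prey with positive proportion).
#' @export
#' @examples
#' levins_breadth(c(25, 25, 25, 25))$B  # 4, the uniform maximum
levins_breadth <- function(p) {
  p <- as.numeric(p)
  if (length(p) == 0 || any(!is.finite(p) | p < 0) || sum(p) <= 0) {
    abort_data("diet proportions must be non-negative with a positive sum")
  }
  f <- p / sum(p)
  structure(list(B = 1 / sum(f^2), S = sum(f > 0)), class = "niche_breadth")
}

#' @export
print.niche_breadth <- function(x, ...) {
  cat(sprintf("Levins' niche breadth B = %.3f over S = %d prey\n", x$B, x$S))
  invisible(x)
}
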