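#' Graded information-theoretic measures of monotonicity and quantity
#'
#' All measures place the uniform distribution on the \eqn{2^n} structures
#' and compare the entropy of the quantifier's truth value \eqn{1_Q} with
#' its conditional entropy given an auxiliary variable:
#' \describe{
#'   \item{upward degree}{auxiliary variable = "the structure has a
#'     (reflexive) substructure that the quantifier verifies", i.e. the
#'     upward closure of the true-set.}
#'   \item{downward degree}{same with superstructures.}
#'   \item{quantity degree}{auxiliary variable = the number of T bits.}
#' }
#' Each degree is \eqn{1 - H(1_Q | V) / H(1_Q)}, a normalized mutual
#' information in `[0, 1]`; it equals 1 exactly when the truth value is a
#' function of the auxiliary variable, which for the directional variables
#' happens precisely for monotone (or constant) quantifiers and for the
#' count variable precisely for quantitative (or constant) quantifiers.
#' Entropies are computed in base 2 with the convention 0 log 0 = 0; the
#' degrees are entropy ratios and therefore base-invariant.
#'
#' When \eqn{H(1_Q) = 0} (a degenerate quantifier) every degree is defined
#' as 1: a constant meaning is trivially monotone and quantitative. This
#' convention lives only here and can be changed in one place.
#'
#' @section Combining the two directions:
#' `monotonicity_degree()` reports as overall `value` the maximum of the
#' directional degrees evaluated on the quantifier *and on its negation*
#' (four numbers). A quantifier and its 0/1-switched variants share the
#' same monotone structure, and the substructure indicator of the negated
#' table is not redundant with the superstructure indicator of the original
#' one: for the parity quantifier at n = 10 the plain directional degrees
#' are all 0 while the negated-table degrees are 0.000977, and this
#' four-way maximum is the rule that reproduces the package's worked
#' reference values (see the methods vignette). The maximum is 1 if and
#' only if the quantifier is upward monotone, downward monotone, or
#' constant.
#'
#' @param Q a quantifier (see [as_quantifier()]).
#' @return `upward_monotonicity_degree()`, `downward_monotonicity_degree()`
#'   and `quantity_degree()` return a single number in `[0, 1]`.
#'   `monotonicity_degree()` returns an object of class `"measure_result"`:
#'   a list with `value` (the overall degree), `upward`, `downward` (the
#'   directional degrees of the table as given), `upward_neg`,
#'   `downward_neg` (of the negated table) and `entropy_H` (the entropy of
#'   \eqn{1_Q} in bits).
#' @examples
#' monotonicity_degree(named_quantifier("some", 10))$value        # 1
#' quantity_degree(named_quantifier("between", 10, lo = 2, hi = 4)) # 1
#' @name measures
NULL

# binary entropy (base 2) of a Bernoulli probability, with 0 log 0 = 0
.entropy_bin <- function(p) {
  h <- 0
  if (p > 0 && p < 1) h <- -p * log2(p) - (1 - p) * log2(1 - p)
  h
}

# H(q | y) for logical q and a small-alphabet integer/logical y,
# uniform weights over positions
.cond_entropy <- function(q, y) {
  tot <- length(q)
  h <- 0
  for (v in unique(y)) {
    sel <- y == v
    h <- h + sum(sel) / tot * .entropy_bin(mean(q[sel]))
  }
  h
}

.degree <- function(q, y) {
  hq <- .entropy_bin(mean(q))
  if (hq == 0) return(1)                    # degenerate-quantifier convention
  max(0, min(1, 1 - .cond_entropy(q, y) / hq))
}

#' @rdname measures
#' @export
upward_monotonicity_degree <- function(Q) {
  qn <- .check_quantifier(Q)
  .degree(qn$table, .has_true_sub(qn$table, qn$n))
}

#' @rdname measures
#' @export
downward_monotonicity_degree <- function(Q) {
  qn <- .check_quantifier(Q)
  .degree(qn$table, .has_true_sup(qn$table, qn$n))
}

#' @rdname measures
#' @export
monotonicity_degree <- function(Q) {
  qn <- .check_quantifier(Q)
  q <- qn$table
  nq <- !q
  up <- .degree(q, .has_true_sub(q, qn$n))
  down <- .degree(q, .has_true_sup(q, qn$n))
  up_neg <- .degree(nq, .has_true_sub(nq, qn$n))
  down_neg <- .degree(nq, .has_true_sup(nq, qn$n))
  structure(list(
    value = max(up, down, up_neg, down_neg),
    upward = up, downward = down,
    upward_neg = up_neg, downward_neg = down_neg,
    entropy_H = .entropy_bin(mean(q))
  ), class = "measure_result")
}

#' @export
print.measure_result <- function(x, ...) {
  cat(sprintf(
    "<measure_result> monotonicity %.4f (up %.4f, down %.4f; negated up %.4f, down %.4f), H = %.4f bits\n",
    x$value, x$upward, x$downward, x$upward_neg, x$downward_neg,
    x$entropy_H))
  invisible(x)
}

#' @rdname measures
#' @export
quantity_degree <- function(Q) {
  qn <- .check_quantifier(Q)
  .degree(qn$table, .structure_counts(qn$n))
}

#' All measures of one quantifier as a one-row table
#'
#' Convenience wrapper returning the directional monotonicity degrees, the
#' overall monotonicity, the quantity degree and the degeneracy of a
#' quantifier in one row, as used in chain snapshots and batch scoring.
#'
#' @param Q a quantifier.
#' @return A one-row [tibble::tibble] with columns `quantifier`, `upward`,
#'   `downward`, `monotonicity`, `quantity`, `degeneracy`.
#' @export
quantifier_measures <- function(Q) {
  qn <- .check_quantifier(Q)
  m <- monotonicity_degree(Q)
  tibble::tibble(
    quantifier = paste(as.integer(qn$table), collapse = ""),
    upward = m$upward,
    downward = m$downward,
    monotonicity = m$value,
    quantity = quantity_degree(Q),
    degeneracy = degeneracy(Q)
  )
}
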