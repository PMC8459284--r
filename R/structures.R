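#' Structures: Boolean models of a quantified sentence
#'
#' A *structure* is an ordered vector of n Booleans. Bit i records whether
#' object \eqn{o_i} of the fixed restrictor set A belongs to the scope set B,
#' so a structure encodes \eqn{A \cap B} for one possible B. Structures are
#' ordered lexicographically with F < T and the leftmost bit most
#' significant, so index 0 is the all-F structure and index \eqn{2^n - 1}
#' the all-T structure: the index is simply the binary expansion of the
#' bit vector.
#'
#' @param i structure index, an integer in `[0, 2^n)`.
#' @param n structure size (number of objects in A), a positive integer.
#' @return `structure_from_index()` returns a logical vector of length `n`;
#'   `index_of_structure()` its 0-based lexicographic index;
#'   `all_structures()` a `2^n x n` logical matrix whose row `i + 1` is the
#'   structure with index `i`.
#' @examples
#' structure_from_index(7, 3)   # the all-T structure [T,T,T]
#' structure_from_index(5, 3)   # [T,F,T]
#' index_of_structure(c(TRUE, FALSE, TRUE))
#' @export
structure_from_index <- function(i, n) {
  n <- .check_n(n)
  if (length(i) != 1L || is.na(i) || i != floor(i) || i < 0 || i >= 2^n) {
    stop("structure index must be a single integer in [0, 2^", n, ")",
         call. = FALSE)
  }
  bitwAnd(as.integer(i), bitwShiftL(1L, (n - 1L):0L)) != 0L
}

#' @param M a structure (logical or 0/1 vector).
#' @rdname structure_from_index
#' @export
index_of_structure <- function(M) {
  M <- .check_structure(M)
  n <- length(M)
  sum(2^((n - 1L):0L)[M])
}

#' @rdname structure_from_index
#' @export
all_structures <- function(n) {
  n <- .check_n(n)
  key <- as.character(n)
  cached <- .structure_cache[[key]]
  if (!is.null(cached)) return(cached)
  idx <- 0:(2^n - 1L)
  m <- matrix(FALSE, length(idx), n)
  for (b in seq_len(n)) {
    m[, b] <- bitwAnd(idx, bitwShiftL(1L, n - b)) != 0L
  }
  .structure_cache[[key]] <- m
  m
}

.structure_cache <- new.env(parent = emptyenv())

# number of T bits of every structure, in index order
.structure_counts <- function(n) {
  key <- paste0("cnt", n)
  cached <- .structure_cache[[key]]
  if (!is.null(cached)) return(cached)
  cnt <- as.integer(rowSums(all_structures(n)))
  .structure_cache[[key]] <- cnt
  cnt
}

.check_n <- function(n) {
  if (length(n) != 1L || is.na(n) || n != floor(n) || n < 1 || n > 20) {
    stop("structure size n must be a single integer in [1, 20]", call. = FALSE)
  }
  as.integer(n)
}

.check_structure <- function(M) {
  if (is.numeric(M)) {
    if (!all(M %in% c(0, 1))) stop("structure bits must be 0/1", call. = FALSE)
    M <- M != 0
  }
  if (!is.logical(M) || length(M) < 1L || anyNA(M)) {
    stop("a structure is a non-empty logical (or 0/1) vector", call. = FALSE)
  }
  M
}

#' Substructure relation between two structures
#'
#' `M1` is a substructure of `M2` when `M1` is F everywhere `M2` is F;
#' equivalently, the true-set of `M1` is contained in the true-set of `M2`.
#' Moving objects out of B produces substructures. The relation is a partial
#' order (reflexive, antisymmetric, transitive) and every structure is a
#' substructure of itself.
#'
#' @param M1,M2 structures of equal length.
#' @return A single logical.
#' @examples
#' is_substructure(c(FALSE, TRUE, TRUE, FALSE, FALSE),
#'                 c(FALSE, TRUE, TRUE, TRUE, TRUE))  # TRUE
#' @export
is_substructure <- function(M1, M2) {
  M1 <- .check_structure(M1)
  M2 <- .check_structure(M2)
  if (length(M1) != length(M2)) {
    stop("structures must have equal length", call. = FALSE)
  }
  !any(M1 & !M2)
}

#' Quantifiers as Boolean truth tables
#'
#' A quantifier over structures of size n is a logical vector of length
#' \eqn{2^n}: entry `i + 1` is the truth value the quantifier assigns to the
#' structure with lexicographic index `i`. `as_quantifier()` validates a
#' vector (or a '0'/'1' string) and stamps it with the class `"quantifier"`;
#' `make_quantifier()` tabulates an arbitrary truth condition.
#'
#' @param x a logical or 0/1 vector of length `2^n`, or a single string of
#'   '0'/'1' characters.
#' @param truth_condition a function taking one structure (logical vector)
#'   and returning a single logical.
#' @param n structure size.
#' @return A logical vector of class `"quantifier"` with attribute `n`.
#' @examples
#' make_quantifier(function(M) all(M), 3)  # "all": F,F,F,F,F,F,F,T
#' as_quantifier("0111")                   # "some" at n = 2
#' @export
as_quantifier <- function(x, n = NULL) {
  if (is.character(x)) {
    if (length(x) != 1L || !grepl("^[01]+$", x)) {
      stop("quantifier strings must consist of '0'/'1' characters",
           call. = FALSE)
    }
    x <- strsplit(x, "")[[1]] == "1"
  }
  if (is.numeric(x)) x <- x != 0
  if (!is.logical(x) || anyNA(x)) {
    stop("a quantifier is a logical truth table", call. = FALSE)
  }
  len <- length(x)
  n_inferred <- as.integer(round(log2(len)))
  if (len < 2L || 2^n_inferred != len) {
    stop("quantifier length must be a power of two (2^n)", call. = FALSE)
  }
  if (!is.null(n) && .check_n(n) != n_inferred) {
    stop("quantifier length ", len, " does not match n = ", n, call. = FALSE)
  }
  structure(as.logical(x), n = n_inferred, class = "quantifier")
}

#' @rdname as_quantifier
#' @export
make_quantifier <- function(truth_condition, n) {
  n <- .check_n(n)
  stopifnot(is.function(truth_condition))
  S <- all_structures(n)
  tab <- vapply(seq_len(nrow(S)), function(r) {
    isTRUE(as.logical(truth_condition(S[r, ])))
  }, logical(1))
  as_quantifier(tab, n)
}

#' @export
print.quantifier <- function(x, ...) {
  n <- attr(x, "n")
  cat(sprintf("<quantifier> n = %d, %d/%d structures true\n",
              n, sum(x), length(x)))
  cat(" table: ", quantifier_to_string(x), "\n", sep = "")
  invisible(x)
}

#' @param Q a quantifier.
#' @rdname as_quantifier
#' @export
quantifier_to_string <- function(Q) {
  paste(as.integer(.check_quantifier(Q)$table), collapse = "")
}

# returns list(table = logical, n = integer)
.check_quantifier <- function(Q) {
  if (inherits(Q, "quantifier")) {
    return(list(table = as.logical(Q), n = attr(Q, "n")))
  }
  q <- as_quantifier(Q)
  list(table = as.logical(q), n = attr(q, "n"))
}

#' Named quantifier constructors
#'
#' Builds the truth tables of the standard fixture quantifiers:
#' \describe{
#'   \item{`some`, `all`, `none`}{at least one / all / no T bits.}
#'   \item{`at_least`, `at_most`}{count threshold, parameter `k`.}
#'   \item{`between`}{`lo <= count <= hi` (both bounds inclusive).}
#'   \item{`even`}{the number of T bits is even (0 counts as even).}
#'   \item{`ultrafilter`}{true iff bit `i` is T: the quantifier names
#'     object \eqn{o_i} and behaves like a proper noun.}
#'   \item{`conj_ultrafilter`}{true iff bits `i` and `j` are both T.}
#'   \item{`const`}{degenerate quantifier, constant `value`.}
#' }
#' Bit positions `i`, `j` are 1-based (1..n); count parameters satisfy
#' `0 <= k <= n` and `0 <= lo <= hi <= n`.
#'
#' @param name one of `"some"`, `"all"`, `"none"`, `"at_least"`,
#'   `"at_most"`, `"between"`, `"even"`, `"ultrafilter"`,
#'   `"conj_ultrafilter"`, `"const"`.
#' @param n structure size.
#' @param k count threshold for `at_least` / `at_most`.
#' @param lo,hi inclusive count bounds for `between`.
#' @param i,j 1-based bit positions for `ultrafilter` / `conj_ultrafilter`.
#' @param value constant truth value for `const`.
#' @return A `"quantifier"`.
#' @examples
#' named_quantifier("some", 2)            # [F,T,T,T]
#' named_quantifier("ultrafilter", 3, i = 3)
#' named_quantifier("between", 10, lo = 2, hi = 4)
#' @export
named_quantifier <- function(name, n, k = NULL, lo = NULL, hi = NULL,
                             i = NULL, j = NULL, value = TRUE) {
  n <- .check_n(n)
  name <- match.arg(name, c("some", "all", "none", "at_least", "at_most",
                            "between", "even", "ultrafilter",
                            "conj_ultrafilter", "const"))
  cnt <- .structure_counts(n)
  chk_count <- function(x, what) {
    if (is.null(x) || length(x) != 1L || is.na(x) || x != floor(x) ||
        x < 0 || x > n) {
      stop(sprintf("'%s' must be an integer in [0, %d]", what, n),
           call. = FALSE)
    }
    as.integer(x)
  }
  chk_bit <- function(x, what) {
    if (is.null(x) || length(x) != 1L || is.na(x) || x != floor(x) ||
        x < 1 || x > n) {
      stop(sprintf("'%s' must be a bit position in [1, %d]", what, n),
           call. = FALSE)
    }
    as.integer(x)
  }
  tab <- switch(name,
    some = cnt >= 1L,
    all = cnt == n,
    none = cnt == 0L,
    at_least = cnt >= chk_count(k, "k"),
    at_most = cnt <= chk_count(k, "k"),
    between = {
      lo <- chk_count(lo, "lo"); hi <- chk_count(hi, "hi")
      if (lo > hi) stop("'lo' must not exceed 'hi'", call. = FALSE)
      cnt >= lo & cnt <= hi
    },
    even = cnt %% 2L == 0L,
    ultrafilter = all_structures(n)[, chk_bit(i, "i")],
    conj_ultrafilter = {
      i <- chk_bit(i, "i"); j <- chk_bit(j, "j")
      if (i == j) stop("'i' and 'j' must differ", call. = FALSE)
      all_structures(n)[, i] & all_structures(n)[, j]
    },
    const = rep(isTRUE(value), 2^n)
  )
  as_quantifier(tab, n)
}

#' Degeneracy of a quantifier
#'
#' The maximum of the proportion of T entries and the proportion of F
#' entries in the truth table: 1 for a constant (degenerate) quantifier,
#' 0.5 for a perfectly balanced one.
#'
#' @param Q a quantifier.
#' @return A number in `[0.5, 1]`.
#' @export
degeneracy <- function(Q) {
  q <- .check_quantifier(Q)$table
  max(mean(q), 1 - mean(q))
}

# indicator of "has a true substructure (reflexively)": the upward closure
# of the true-set, computed with a subset-OR (zeta) transform in O(n 2^n)
.has_true_sub <- function(q, n) {
  f <- q
  for (b in 0:(n - 1L)) {
    step <- 2^b
    has <- which(bitwAnd(seq_along(q) - 1L, bitwShiftL(1L, b)) != 0L)
    f[has] <- f[has] | f[has - step]
  }
  f
}

# indicator of "has a true superstructure (reflexively)"
.has_true_sup <- function(q, n) {
  f <- q
  for (b in 0:(n - 1L)) {
    step <- 2^b
    no <- which(bitwAnd(seq_along(q) - 1L, bitwShiftL(1L, b)) == 0L)
    f[no] <- f[no] | f[no + step]
  }
  f
}

#' Binary monotonicity and quantity of a quantifier
#'
#' `is_monotone()` checks the classical all-or-nothing property: upward
#' monotone means truth is preserved when moving to superstructures (adding
#' objects to B), downward when moving to substructures. `is_quantitative()`
#' checks permutation invariance: the truth value depends only on the
#' number of T bits, never on which bits they are.
#'
#' @param Q a quantifier.
#' @param direction `"up"` or `"down"`.
#' @return A single logical.
#' @examples
#' is_monotone(named_quantifier("at_least", 10, k = 4), "up")   # TRUE
#' is_monotone(named_quantifier("even", 10), "up")              # FALSE
#' is_quantitative(named_quantifier("ultrafilter", 4, i = 1))   # FALSE
#' @export
is_monotone <- function(Q, direction = c("up", "down")) {
  direction <- match.arg(direction)
  qn <- .check_quantifier(Q)
  cl <- if (direction == "up") .has_true_sub(qn$table, qn$n)
        else .has_true_sup(qn$table, qn$n)
  # monotone iff the true-set equals its own (reflexive) closure
  all(cl == qn$table)
}

#' @rdname is_monotone
#' @export
is_quantitative <- function(Q) {
  qn <- .check_quantifier(Q)
  cnt <- .structure_counts(qn$n)
  per_class_true <- tabulate(cnt[qn$table] + 1L, nbins = qn$n + 1L)
  class_size <- tabulate(cnt + 1L, nbins = qn$n + 1L)
  all(per_class_true == 0L | per_class_true == class_size)
}

#' Enumerate quantitative quantifiers and their monotone subset
#'
#' A quantitative quantifier is determined by a truth value per count class
#' k = 0..n, so there are \eqn{2^{n+1}} of them; exactly \eqn{2n + 2} of
#' those are (upward or downward) monotone, i.e. have a count table of the
#' shape 0..01..1 or 1..10..0 (constants included). Computed by exhaustive
#' enumeration of the count tables.
#'
#' @param n structure size, `1 <= n <= 16`.
#' @return A list with integer components `total` and `monotone`.
#' @examples
#' count_quantitative(10)  # total 2048, monotone 22 (ratio ~ 1.07%)
#' @export
count_quantitative <- function(n) {
  if (length(n) != 1L || is.na(n) || n != floor(n) || n < 1 || n > 16) {
    stop("count_quantitative() enumerates count tables for n in [1, 16]",
         call. = FALSE)
  }
  n <- as.integer(n)
  tabs <- all_structures(n + 1L) # rows = all 0/1 count tables of length n+1
  d <- tabs[, -1L, drop = FALSE] - tabs[, -(n + 1L), drop = FALSE]
  nondec <- rowSums(d < 0) == 0
  noninc <- rowSums(d > 0) == 0
  list(total = nrow(tabs), monotone = as.integer(sum(nondec | noninc)))
}
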