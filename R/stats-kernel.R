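#' Upper-tail hypergeometric overlap probability
#'
#' Probability of drawing at least `k` marked elements when `n` elements are
#' sampled without replacement from a universe of `N` containing `K` marked
#' ones: `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`. This is the overlap
#' statistic used throughout the pipeline to score the co-occurrence of two
#' gene sets in a shared universe ("at least as many overlapping genes as
#' observed").
#'
#' All arguments are vectorized and recycled to a common length. The tail is
#' inclusive of `k` itself, so `k = 0` always returns 1.
#'
#' @param k Observed overlap count(s).
#' @param K Size of the first (marked) set.
#' @param n Size of the second (sampled) set.
#' @param N Universe size.
#' @return Numeric vector of tail probabilities in `(0, 1]`.
#' @examples
#' hyper_upper_tail(4, 5, 8, 20)
#' @export
hyper_upper_tail <- function(k, K, n, N) {
  args <- vctrs_recycle(k = k, K = K, n = n, N = N)
  with(args, {
    check_counts(k, K, n, N)
    if (any(K > N) || any(n > N)) {
      abort("set sizes `K` and `n` cannot exceed the universe size `N`")
    }
    if (any(k > pmin(K, n))) {
      abort("overlap `k` cannot exceed min(K, n)")
    }
    if (any(k < pmax(0, K + n - N))) {
      abort("overlap `k` below the minimum forced by the margins")
    }
    phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  })
}

#' One-sided Fisher's exact test for a 2x2 table
#'
#' Tests for positive association: the probability, under fixed margins, of
#' an `a` cell at least as large as observed. Equivalent to
#' [hyper_upper_tail()] applied to the `a` cell with margins `(a + b)`,
#' `(a + c)` and total `a + b + c + d`.
#'
#' @param a,b,c,d Cell counts; `a` counts joint occurrence, `d` joint
#'   absence. Vectorized.
#' @return Numeric vector of one-sided p-values.
#' @examples
#' fisher_one_sided(3, 1, 1, 3)  # 17/70
#' @export
fisher_one_sided <- function(a, b, c, d) {
  args <- vctrs_recycle(a = a, b = b, c = c, d = d)
  with(args, {
    check_counts(a, b, c, d)
    if (any(a + b + c + d == 0)) abort("table total must be positive")
    hyper_upper_tail(a, a + b, a + c, a + b + c + d)
  })
}

#' Odds ratio of a 2x2 table
#'
#' `OR = (a * d) / (b * c)`. When any cell is zero the Haldane-Anscombe
#' correction (add 0.5 to every cell) is applied by default and flagged in
#' the `corrected` column; with `zero_cell = "strict"` a zero `b * c`
#' product is an error instead.
#'
#' @inheritParams fisher_one_sided
#' @param zero_cell Either `"haldane"` (default) or `"strict"`.
#' @return A tibble with columns `estimate` and `corrected`.
#' @examples
#' odds_ratio(20, 5, 5, 20)
#' odds_ratio(3, 0, 2, 5)
#' @export
odds_ratio <- function(a, b, c, d, zero_cell = c("haldane", "strict")) {
  zero_cell <- match.arg(zero_cell)
  args <- vctrs_recycle(a = a, b = b, c = c, d = d)
  with(args, {
    check_counts(a, b, c, d)
    if (any(a + b + c + d == 0)) abort("table total must be positive")
    has_zero <- a == 0 | b == 0 | c == 0 | d == 0
    if (zero_cell == "strict") {
      if (any(b * c == 0)) {
        abort("odds ratio undefined: zero `b * c` with zero_cell = \"strict\"")
      }
      tibble(estimate = (a * d) / (b * c), corrected = FALSE)
    } else {
      shift <- ifelse(has_zero, 0.5, 0)
      tibble(
        estimate = ((a + shift) * (d + shift)) / ((b + shift) * (c + shift)),
        corrected = has_zero
      )
    }
  })
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard BH false-discovery-rate adjustment. Input order is preserved,
#' values are capped at 1, and ties are handled by a stable sort so the
#' output is deterministic.
#'
#' @param p Numeric vector of raw p-values in `[0, 1]`.
#' @return Numeric vector of adjusted p-values, same length and order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) abort("`p` must be non-empty")
  if (anyNA(p) || any(p < 0 | p > 1)) {
    abort("all p-values must lie in [0, 1]")
  }
  p.adjust(p, method = "BH")
}

#' Pearson chi-square test for a 2x2 table
#'
#' The closed-form statistic `N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))` with
#' its df = 1 upper-tail p-value. Yates' continuity correction (subtract
#' `N/2` from `|ad - bc|`, floored at 0) is available via `correct = TRUE`
#' but off by default.
#'
#' @inheritParams fisher_one_sided
#' @param correct Apply Yates' continuity correction? Default `FALSE`.
#' @return A tibble with columns `statistic` and `p_value`.
#' @examples
#' chisq_2x2(5, 5, 5, 85)
#' @export
chisq_2x2 <- function(a, b, c, d, correct = FALSE) {
  args <- vctrs_recycle(a = a, b = b, c = c, d = d)
  with(args, {
    check_counts(a, b, c, d)
    tot <- a + b + c + d
    m1 <- a + b; m2 <- c + d; m3 <- a + c; m4 <- b + d
    if (any(m1 == 0 | m2 == 0 | m3 == 0 | m4 == 0)) {
      abort("degenerate 2x2 table: a zero margin")
    }
    num <- abs(a * d - b * c)
    if (correct) num <- pmax(0, num - tot / 2)
    stat <- tot * num^2 / (m1 * m2 * m3 * m4)
    tibble(statistic = stat, p_value = pchisq(stat, df = 1, lower.tail = FALSE))
  })
}

#' Two-sided normal-tail p-value
#'
#' `p = 2 * min(Phi(z), 1 - Phi(z))` with `z = (x - mu) / sigma`: the
#' probability of a statistic at least as extreme as `x` under a
#' `N(mu, sigma^2)` null. Used by the differential-expression stage, whose
#' null mean and standard deviation are estimated from control arrays.
#'
#' @param x Observed statistic(s).
#' @param mu Null mean.
#' @param sigma Null standard deviation (must be positive).
#' @return Numeric vector of p-values in `(0, 1]`.
#' @examples
#' normal_two_sided_p(1.959964, 0, 1)
#' @export
normal_two_sided_p <- function(x, mu = 0, sigma = 1) {
  if (any(!is.finite(sigma)) || any(sigma <= 0)) {
    abort("`sigma` must be positive and finite")
  }
  z <- (x - mu) / sigma
  pmin(1, 2 * pnorm(-abs(z)))
}

# recycle scalar/vector arguments to a common length; doubles throughout so
# products of large count margins cannot overflow integer arithmetic
vctrs_recycle <- function(...) {
  args <- list(...)
  len <- max(lengths(args))
  bad <- lengths(args) != 1L & lengths(args) != len
  if (any(bad)) abort("arguments must have length 1 or a common length")
  lapply(args, function(x) rep_len(as.double(x), length.out = len))
}

check_counts <- function(...) {
  vals <- unlist(list(...), use.names = FALSE)
  if (anyNA(vals) || any(!is.finite(vals))) abort("counts must be finite")
  if (any(vals < 0)) abort("counts must be non-negative")
  if (any(vals != floor(vals))) abort("counts must be whole numbers")
  invisible(TRUE)
}
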