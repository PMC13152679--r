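#' Two-sample / paired test result
#'
#' Light container returned by [paired_t()] and [mann_whitney()].
#'
#' @param statistic test statistic.
#' @param df degrees of freedom, or `NA` for rank tests.
#' @param p_one_sided,p_two_sided tail probabilities.
#' @param method label (`"student_t"`, `"exact"`, `"permutation"`,
#'   `"normal_approx"`).
#' @param extra optional named list of method-specific detail.
#' @return An object of class `test_result`.
#' @keywords internal
test_result <- function(statistic, df = NA_real_, p_one_sided, p_two_sided,
                        method, extra = list()) {
  structure(c(list(statistic = statistic, df = df,
                   p_one_sided = p_one_sided, p_two_sided = p_two_sided,
                   method = method), extra),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<test_result> statistic %.6g%s; p one-sided %.4g, two-sided %.4g (%s)\n",
              x$statistic,
              if (is.finite(x$df)) sprintf(" (df %g)", x$df) else "",
              x$p_one_sided, x$p_two_sided, x$method))
  invisible(x)
}

#' Paired Student t test
#'
#' `t = mean(d) / (sd(d) / sqrt(n))` on the differences `d = x - y`,
#' with `df = n - 1` and p-values from the Student-t distribution. At
#' `df = 2` the two-sided p has the closed form
#' `1 - |t| / sqrt(t^2 + 2)`. All-zero-variance differences are rejected
#' (t is undefined).
#'
#' @param x,y equal-length paired samples (n >= 2).
#' @return a `test_result` with fields `statistic` (t), `df`,
#'   `p_one_sided` (smaller tail), `p_two_sided`, and `mean_diff`.
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y)) stopf("paired samples must have equal length")
  n <- length(x)
  if (n < 2L) stopf("need at least 2 pairs")
  d <- x - y
  s <- stats::sd(d)
  if (s == 0)
    stopf("differences have zero variance; the paired t statistic is undefined")
  tstat <- mean(d) / (s / sqrt(n))
  p1 <- stats::pt(abs(tstat), df = n - 1, lower.tail = FALSE)
  test_result(statistic = tstat, df = n - 1,
              p_one_sided = p1, p_two_sided = 2 * p1,
              method = "student_t", extra = list(mean_diff = mean(d)))
}

# Exact null distribution of U (number of x-over-y pairs) by full
# enumeration of the C(nx+ny, nx) assignments of ranks to x.
mw_exact_tail <- function(u_obs, nx, ny) {
  N <- nx + ny
  comb <- utils::combn(N, nx)
  u_all <- colSums(comb) - nx * (nx + 1) / 2
  list(p_greater = mean(u_all >= u_obs),
       p_less = mean(u_all <= u_obs),
       n_assignments = ncol(comb))
}

#' Mann-Whitney U test with exact small-sample enumeration
#'
#' The statistic is `U` for the first sample: the rank sum of `x` (using
#' midranks for ties) minus `nx (nx + 1) / 2`, i.e. the number of `(x, y)`
#' pairs with `x > y` (ties counted 1/2). For `nx + ny <= exact_limit`
#' with no ties, the full null distribution is enumerated over all
#' `choose(nx + ny, nx)` group assignments and tail probabilities are
#' exact. With ties on a small sample, a seeded permutation null
#' (`n_perm` draws) is used; otherwise the normal approximation with
#' continuity and tie corrections. Both one-sided (smaller tail) and
#' two-sided (twice the smaller tail, capped at 1) p-values are
#' reported, and the method is labelled.
#'
#' @param x,y non-empty numeric samples.
#' @param exact_limit maximum `nx + ny` for enumeration (default 12).
#' @param n_perm permutation draws when ties block enumeration.
#' @param seed seed for the permutation null.
#' @return a `test_result` with fields `statistic` (U for `x`), `df = NA`,
#'   `p_one_sided`, `p_two_sided`, `method`, plus `p_greater`, `p_less`,
#'   `n_x`, `n_y`.
#' @export
mann_whitney <- function(x, y, exact_limit = 12L, n_perm = 1e5L, seed = 1L) {
  if (!length(x) || !length(y)) stopf("both samples must be non-empty")
  nx <- length(x); ny <- length(y)
  N <- nx + ny
  r <- rank(c(x, y))
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0L

  if (!ties && N <= exact_limit) {
    tail <- mw_exact_tail(u, nx, ny)
    method <- "exact"
  } else if (ties && N <= 30L) {
    tail <- with_seed(seed, {
      u_perm <- vapply(seq_len(n_perm), function(i) {
        rp <- r[sample.int(N)]
        sum(rp[seq_len(nx)]) - nx * (nx + 1) / 2
      }, numeric(1))
      list(p_greater = mean(u_perm >= u), p_less = mean(u_perm <= u))
    })
    method <- "permutation"
  } else {
    mu <- nx * ny / 2
    tie_tab <- table(r)
    sig2 <- nx * ny / 12 * (N + 1 - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
    sig <- sqrt(sig2)
    tail <- list(
      p_greater = stats::pnorm((u - 0.5 - mu) / sig, lower.tail = FALSE),
      p_less = stats::pnorm((u + 0.5 - mu) / sig))
    method <- "normal_approx"
  }
  p1 <- min(tail$p_greater, tail$p_less)
  test_result(statistic = u, df = NA_real_,
              p_one_sided = p1, p_two_sided = min(1, 2 * p1),
              method = method,
              extra = list(p_greater = tail$p_greater, p_less = tail$p_less,
                           n_x = nx, n_y = ny))
}

#' Ordinary least-squares line with R-squared
#'
#' @param x,y numeric samples, `n >= 3`; `x` must not be constant.
#' @return list with `slope`, `intercept`, `r_squared`, `n`.
#' @export
linreg <- function(x, y) {
  if (length(x) != length(y)) stopf("'x' and 'y' must have equal length")
  if (length(x) < 3L) stopf("need at least 3 points")
  if (stats::var(x) == 0) stopf("'x' is constant; slope is undefined")
  fit <- stats::lm(y ~ x)
  co <- stats::coef(fit)
  list(slope = unname(co[2L]), intercept = unname(co[1L]),
       r_squared = summary(fit)$r.squared, n = length(x))
}
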