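## Standard tests used across the package, with exactly stated
## conventions. Where base R provides the test (Kruskal-Wallis omnibus,
## BH adjustment, OLS) it is called directly; Mann-Whitney, Spearman and
## the summary-statistic Welch test are written out so their tie and
## approximation conventions are explicit (base equivalents serve as
## independent checks in the test suite).

#' Welch t-test from group summaries
#'
#' Recomputes a two-sample comparison from printed mean / SD / n triples:
#' unequal-variance t with Welch-Satterthwaite degrees of freedom and a
#' two-sided p from the central t distribution. With both SDs zero and
#' equal means, p = 1 by convention.
#'
#' @param mean_a,sd_a,n_a,mean_b,sd_b,n_b group summaries (`sd >= 0`,
#'   `n >= 2`).
#' @return list with `t`, `df`, `pvalue`.
#' @export
welch_from_summary <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b) {
  if (sd_a < 0 || sd_b < 0) stop("sd must be >= 0")
  if (n_a < 2 || n_b < 2) stop("n must be >= 2")
  va <- sd_a^2 / n_a
  vb <- sd_b^2 / n_b
  if (va + vb == 0) {
    return(list(t = 0, df = n_a + n_b - 2,
                pvalue = if (mean_a == mean_b) 1 else 0))
  }
  t <- (mean_b - mean_a) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (n_a - 1) + vb^2 / (n_b - 1))
  list(t = t, df = df, pvalue = 2 * stats::pt(-abs(t), df))
}

#' Mann-Whitney U test
#'
#' Midrank ties; U reported for the first sample (so U + U' = nx * ny).
#' For `min(n) <= 8` (and a feasible enumeration) the p-value is exact
#' over all assignments of the pooled midranks; otherwise a normal
#' approximation with tie correction is used (no continuity correction).
#'
#' @param x,y numeric samples.
#' @return list with `U`, `pvalue`, `method`.
#' @export
mann_whitney <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) stop("empty sample")
  nx <- length(x)
  ny <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  if (min(nx, ny) <= 8L && choose(nx + ny, nx) <= 2e5) {
    # exact: enumerate all placements of x among the pooled midranks
    combs <- utils::combn(nx + ny, nx)
    Us <- colSums(matrix(r[combs], nrow = nx)) - nx * (nx + 1) / 2
    mu <- nx * ny / 2
    p <- mean(abs(Us - mu) >= abs(U - mu) - 1e-9)
    return(list(U = U, pvalue = p, method = "exact"))
  }
  n <- nx + ny
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma <- sqrt(nx * ny / 12 * ((n + 1) - tie_term))
  z <- (U - nx * ny / 2) / sigma
  list(U = U, pvalue = min(1, 2 * stats::pnorm(-abs(z))),
       method = "normal")
}

#' Kruskal-Wallis omnibus with Dunn's pairwise post hoc
#'
#' The omnibus H (tie-corrected, chi-square reference) comes from
#' `stats::kruskal.test`. Dunn z statistics use pooled midranks with the
#' standard tie correction; pairwise p-values are two-sided and
#' unadjusted by default (`p_adjust = "BH"` applies Benjamini-Hochberg).
#'
#' @param groups named list of numeric vectors (>= 2 nonempty groups).
#' @param p_adjust `"none"` (default) or `"BH"`.
#' @return list with `omnibus` (`H`, `df`, `pvalue`) and `pairwise`
#'   (data.frame `group1`, `group2`, `z`, `pvalue`).
#' @export
kruskal_dunn <- function(groups, p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  groups <- groups[lengths(groups) > 0L]
  if (length(groups) < 2L) stop("need at least 2 nonempty groups")
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  kw <- stats::kruskal.test(x, g)
  N <- length(x)
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  n <- tapply(r, g, length)
  ties <- table(r)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  pairs <- utils::combn(names(groups), 2L)
  z <- apply(pairs, 2L, function(p) {
    se <- sqrt((N * (N + 1) / 12 - tie_corr) * (1 / n[[p[1]]] + 1 / n[[p[2]]]))
    if (se == 0) 0 else (rbar[[p[1]]] - rbar[[p[2]]]) / se
  })
  pv <- 2 * stats::pnorm(-abs(z))
  if (p_adjust == "BH") pv <- stats::p.adjust(pv, method = "BH")
  omnibus <- if (all(x == x[1])) {
    # fully tied data: H is 0 by convention (kruskal.test yields 0/0)
    list(H = 0, df = length(groups) - 1L, pvalue = 1)
  } else {
    list(H = unname(kw$statistic), df = unname(kw$parameter),
         pvalue = kw$p.value)
  }
  list(omnibus = omnibus,
       pairwise = data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                             z = as.numeric(z), pvalue = pmin(1, pv),
                             stringsAsFactors = FALSE))
}

#' Spearman rank correlation
#'
#' Pearson correlation on midranks; two-sided p via the t approximation
#' with n - 2 degrees of freedom. Constant input is an error (rho is
#' undefined).
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list with `rho`, `pvalue`, `n`.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3L) stop("need at least 3 observations")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    stop("constant input: rank correlation undefined")
  }
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) {
    p <- 2 * stats::pt(-Inf, n - 2)  # 0; degenerate perfect ordering
    p <- max(p, .Machine$double.xmin)
  } else {
    t <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(t), n - 2)
  }
  list(rho = rho, pvalue = p, n = n)
}

#' Linear trend test over ordered levels
#'
#' Ordinary least squares of the response on the level index (1, 2, ...),
#' with a two-sided t test on the slope.
#'
#' @param samples ordered list of numeric vectors (>= 3 levels).
#' @return list with `slope`, `t`, `df`, `pvalue`.
#' @export
linear_trend_test <- function(samples) {
  if (length(samples) < 3L) stop("need at least 3 ordered levels")
  y <- unlist(samples, use.names = FALSE)
  x <- rep(seq_along(samples), lengths(samples))
  fit <- stats::lm(y ~ x)
  s <- summary(fit)$coefficients
  list(slope = unname(s["x", "Estimate"]), t = unname(s["x", "t value"]),
       df = fit$df.residual, pvalue = unname(s["x", "Pr(>|t|)"]))
}
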