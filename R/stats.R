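# Cohort statistics: Spearman with exact small-sample p-values, Kaplan-Meier
# with first-crossing median and log(-log) interval, log-rank and
# Gehan-Breslow tests over a shared weighted risk-set walk, Mann-Whitney U
# with exact enumeration under ties, and the noncentral-t sample-size
# calculation. Mid-ranks are used for ties throughout; p-values are
# two-sided and unadjusted.

# All n! permutations of 1..n (n small), one per row.
.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .permutations(n - 1L)
  fs <- nrow(sub)
  res <- matrix(0L, n * fs, n)
  for (i in seq_len(n)) {
    rows <- ((i - 1L) * fs + 1L):(i * fs)
    res[rows, 1L] <- i
    rest <- seq_len(n)[-i]
    res[rows, -1L] <- matrix(rest[sub], fs)
  }
  res
}

#' Spearman rank correlation with exact small-sample p-value
#'
#' The coefficient is the Pearson correlation of mid-ranks (so ties are
#' handled conventionally). For `n <= 9` the two-sided p-value is computed
#' by full enumeration of all `n!` permutations of one margin; for larger n
#' it uses the t approximation with `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length `n >= 3`.
#' @return A list with `rho`, `p`, `n` and `method`.
#' @export
spearman_test <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input: Spearman correlation is undefined")
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= 9L) {
    P <- .permutations(n)
    M <- matrix(ry[P], nrow(P))
    S <- as.vector(M %*% rx)
    E <- n * mean(rx) * mean(ry)
    S_obs <- sum(rx * ry)
    p <- mean(abs(S - E) >= abs(S_obs - E) - 1e-9)
    method <- "exact permutation"
  } else {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tt), n - 2)
    method <- "t approximation"
  }
  list(rho = rho, p = min(p, 1), n = n, method = method)
}

#' Mann-Whitney U test
#'
#' U is computed from mid-rank sums. When the smaller group has at most 8
#' observations (and the enumeration is tractable) the two-sided p-value is
#' exact, by enumerating all assignments of the pooled ranks to the groups;
#' otherwise the tie-corrected normal approximation with continuity
#' correction is used.
#'
#' @param a,b Numeric vectors, both non-empty.
#' @return A list with `U` (for group `a`), `p`, `method`.
#' @export
mann_whitney_u <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  na <- length(a); nb <- length(b)
  if (na == 0L || nb == 0L) stop("both groups must be non-empty")
  n <- na + nb
  r <- rank(c(a, b))
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  mu <- na * nb / 2
  if (min(na, nb) <= 8L && choose(n, na) <= 2e6) {
    cmb <- utils::combn(n, na)
    Us <- colSums(matrix(r[cmb], nrow = na)) - na * (na + 1) / 2
    p <- mean(abs(Us - mu) >= abs(U - mu) - 1e-9)
    method <- "exact enumeration"
  } else {
    if (min(na, nb) <= 8L)
      warning("exact enumeration too large; using normal approximation")
    tie <- table(r)
    sigma2 <- na * nb / 12 * ((n + 1) - sum(tie^3 - tie) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
      p <- min(2 * stats::pnorm(-abs(z)), 1)
    }
    method <- "normal approximation"
  }
  list(U = U, p = p, method = method)
}

#' Kaplan-Meier survival curve with median and 95% interval
#'
#' Product-limit estimate via [survival::survfit()] with log(-log)
#' (Greenwood-based) confidence intervals. The median is the first time at
#' which the survival estimate drops to 0.5 or below; its 95% bounds come
#' from the log(-log) interval crossing 0.5. Censored subjects leave the
#' risk set at their censoring time and their times are exported for curve
#' annotation.
#'
#' @param time Follow-up times (days).
#' @param event Logical or 0/1; `TRUE` = death observed, `FALSE` = censored.
#' @return A list of class `km_curve`: `times` (event times), `n_risk`,
#'   `n_event`, `surv`, `greenwood_var`, `median`, `median_ci`,
#'   `censor_times`, and the underlying `fit`.
#' @export
km_estimate <- function(time, event) {
  event <- as.integer(event)
  stopifnot(length(time) == length(event), all(time > 0))
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           conf.type = "log-log")
  sm <- summary(fit, censored = FALSE)
  times <- sm$time; surv <- sm$surv
  med <- if (any(surv <= 0.5)) min(times[surv <= 0.5]) else NA_real_
  tab <- summary(fit)$table
  ci <- c(unname(tab["0.95LCL"]), unname(tab["0.95UCL"]))
  structure(list(times = times, n_risk = sm$n.risk, n_event = sm$n.event,
                 surv = surv, greenwood_var = sm$std.err^2,
                 median = med, median_ci = ci,
                 censor_times = time[event == 0L], fit = fit),
            class = "km_curve")
}

#' Survival probability at a time point
#'
#' Step-function evaluation of a [km_estimate()] curve; with no events the
#' curve is identically 1.
#'
#' @param curve A `km_curve`.
#' @param t Time(s) at which to evaluate S(t).
#' @return Numeric survival probabilities.
#' @export
km_surv_at <- function(curve, t) {
  vapply(t, function(tt) {
    i <- which(curve$times <= tt)
    if (length(i)) curve$surv[max(i)] else 1
  }, numeric(1L))
}

# Shared machinery: weighted two-sample survival test.
# weight "logrank" -> w_j = 1; "gehan" -> w_j = number at risk.
.weighted_survtest <- function(time_a, event_a, time_b, event_b, weight) {
  event_a <- as.integer(event_a); event_b <- as.integer(event_b)
  if (length(time_a) == 0L || length(time_b) == 0L)
    stop("both groups must be non-empty")
  if (sum(event_a) + sum(event_b) == 0L)
    stop("need at least one observed event")
  all_t <- c(time_a, time_b); all_e <- c(event_a, event_b)
  ut <- sort(unique(all_t[all_e == 1L]))
  n1 <- vapply(ut, function(t) sum(time_a >= t), numeric(1L))
  n2 <- vapply(ut, function(t) sum(time_b >= t), numeric(1L))
  d1 <- vapply(ut, function(t) sum(time_a == t & event_a == 1L), numeric(1L))
  d2 <- vapply(ut, function(t) sum(time_b == t & event_b == 1L), numeric(1L))
  nn <- n1 + n2; dd <- d1 + d2
  e1 <- dd * n1 / nn
  v <- dd * (n1 / nn) * (n2 / nn) * (nn - dd) / pmax(nn - 1, 1)
  w <- if (weight == "gehan") nn else rep(1, length(nn))
  OE <- sum(w * (d1 - e1))
  V <- sum(w^2 * v)
  stat <- if (V > 0) OE^2 / V else 0
  p <- if (V > 0) stats::pchisq(stat, df = 1L, lower.tail = FALSE) else 1
  list(statistic = stat, p = p, observed_minus_expected = OE, variance = V)
}

#' Log-rank and Gehan tests for two survival curves
#'
#' At each distinct event time the observed events in group A are compared
#' with their hypergeometric expectation given the pooled risk set; the
#' weighted sums give a chi-square statistic on 1 df. `logrank_test()`
#' weights every event time equally; `gehan_test()` uses Gehan-Breslow
#' weights (the pooled number at risk), which emphasises early differences.
#'
#' @param time_a,event_a Times and event indicators for group A.
#' @param time_b,event_b Times and event indicators for group B.
#' @return A list with `statistic` (chi-square, 1 df), `p`,
#'   `observed_minus_expected` (weighted, group A) and `variance`.
#' @export
logrank_test <- function(time_a, event_a, time_b, event_b)
  .weighted_survtest(time_a, event_a, time_b, event_b, "logrank")

#' @rdname logrank_test
#' @export
gehan_test <- function(time_a, event_a, time_b, event_b)
  .weighted_survtest(time_a, event_a, time_b, event_b, "gehan")

#' Sample size for a two-sample t comparison
#'
#' Smallest integer group size `n` such that a two-sided two-sample t-test
#' at level `alpha` with `n` per group and noncentrality `d * sqrt(n/2)`
#' attains at least the target power, computed by iterating the
#' noncentral-t power function. A 10% difference in mean lifespan with an
#' assumed 20% standard deviation corresponds to `d = 0.5` and reproduces
#' the canonical 64 per group at `alpha = 0.05`, power 0.8; that 20%-SD
#' assumption is a documented default, not a hidden constant.
#'
#' @param effect_size_d Standardised difference (Cohen's d), > 0.
#' @param alpha Two-sided significance level.
#' @param power Target power in (0, 1).
#' @param n_max Search cap.
#' @return Integer group size.
#' @examples
#' power_sample_size(0.5, 0.05, 0.8) # 64
#' @export
power_sample_size <- function(effect_size_d, alpha = 0.05, power = 0.8,
                              n_max = 1e5L) {
  if (effect_size_d <= 0) stop("effect_size_d must be > 0")
  stopifnot(alpha > 0, alpha < 1, power > 0, power < 1)
  n <- 2L
  while (n <= n_max) {
    if (.t_power(n, effect_size_d, alpha) >= power) return(n)
    n <- n + 1L
  }
  stop("no n <= n_max reaches the target power")
}

# Power of the two-sided two-sample t-test at n per group.
.t_power <- function(n, d, alpha) {
  df <- 2 * n - 2
  ncp <- d * sqrt(n / 2)
  tc <- stats::qt(1 - alpha / 2, df)
  1 - stats::pt(tc, df, ncp) + stats::pt(-tc, df, ncp)
}
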