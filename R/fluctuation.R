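#' Mutant-count distribution of the Luria--Delbrueck fluctuation assay
#'
#' Probability mass function of the number of resistant colonies observed per
#' culture under the Lea--Coulson formulation: mutational events per culture
#' are Poisson(`m`), each event founds a clone whose size follows
#' `P(Y = y) = 1/(y (y + 1))`, and a fraction `epsilon` of the culture is
#' plated so each clone contributes `Binomial(Y, epsilon)` colonies.
#'
#' For `epsilon = 1` this is the Ma--Sandri--Sarkar distribution, computed by
#' the exact recursion `p_0 = exp(-m)`,
#' `p_n = (m/n) * sum_{i=0}^{n-1} p_i / (n - i + 1)`.
#' For `epsilon < 1` the clone-size law is binomially thinned (numerically,
#' with an analytic bound on the truncated tail of the `1/(y(y+1))` series)
#' and the same compound-Poisson recursion is applied to the thinned law.
#'
#' @param m expected number of mutational events per culture (>= 0).
#' @param epsilon plating fraction in `(0, 1]`.
#' @param n_max largest count for which the probability is returned.
#' @return numeric vector `p[0..n_max]` (length `n_max + 1`).  Entries are
#'   non-negative and sum to at most 1; the deficit is the mass above
#'   `n_max`.
#' @seealso [ld_fit()] for maximum-likelihood estimation.
#' @export
ld_pmf <- function(m, epsilon = 1, n_max) {
  check_m_eps(m, epsilon)
  n_max <- as.integer(n_max)
  if (n_max < 0) stop("`n_max` must be >= 0")
  h <- ld_clone_law(epsilon, n_max)
  panjer_pmf(m, h)
}

check_m_eps <- function(m, epsilon) {
  if (!is.numeric(m) || length(m) != 1L || is.na(m) || m < 0)
    stop("`m` must be a single non-negative number")
  if (!is.numeric(epsilon) || length(epsilon) != 1L || is.na(epsilon) ||
      epsilon <= 0 || epsilon > 1)
    stop("`epsilon` must be in (0, 1]")
  invisible(TRUE)
}

## Observed-clone-size law h_0..h_nmax after Binomial(epsilon) thinning of
## q_y = 1/(y(y+1)).  The y-series is truncated at ymax chosen so that the
## neglected relative tail mass over k <= nmax is below ~1e-10 (Hoeffding
## bound on P(Bin(y, eps) <= nmax) for y > ymax, times the q tail 1/ymax).
ld_clone_law <- function(epsilon, n_max) {
  if (epsilon == 1) {
    if (n_max == 0L) return(0)
    j <- seq_len(n_max)
    return(c(0, 1 / (j * (j + 1))))
  }
  ymax <- max(1000, ceiling((2 * n_max + 20) / epsilon))
  repeat {
    slack <- ymax * epsilon - n_max
    bound <- if (slack > 0) exp(-2 * slack^2 / ymax) / ymax else 1
    if (bound < 1e-10 || ymax >= 1e8) break
    ymax <- 2 * ymax
  }
  thin_clone_law(epsilon, as.integer(n_max), as.integer(ymax))
}

## Log-likelihood (and analytic score) of observed counts under ld_pmf.
## `tab` is a two-column matrix [count, multiplicity] of uncensored counts;
## `n_cens` counts were right-censored at `cap` (observed as >= cap).
## The score uses the compound-Poisson identity
##   d p_n / dm = (h * p)_n - p_n   (discrete convolution),
## so d log p_n / dm = conv_n / p_n - 1.
ld_lik <- function(m, h, tab, n_cens, cap) {
  nmax <- length(h) - 1L
  p <- panjer_pmf(m, h)
  ll <- 0; sc <- 0
  if (nrow(tab)) {
    pc <- p[tab[, 1L] + 1L]
    if (any(pc <= 0)) return(list(ll = -Inf, score = Inf))
    conv <- vapply(tab[, 1L], function(cc)
      sum(h[seq_len(cc + 1L)] * p[(cc + 1L):1L]), numeric(1))
    ll <- sum(tab[, 2L] * log(pc))
    sc <- sum(tab[, 2L] * (conv / pc - 1))
  }
  if (n_cens > 0L) {
    S <- max(1 - sum(p[seq_len(cap)]), 1e-300)  # P(X >= cap)
    ll <- ll + n_cens * log(S)
    convs <- vapply(0:(cap - 1L), function(cc)
      sum(h[seq_len(cc + 1L)] * p[(cc + 1L):1L]), numeric(1))
    dS <- -sum(convs - p[seq_len(cap)])
    sc <- sc + n_cens * dS / S
  }
  list(ll = ll, score = sc)
}

#' Fit the Luria--Delbrueck model to fluctuation-assay counts
#'
#' Maximum-likelihood estimation of the expected number of mutations per
#' culture, `m`, from per-culture resistant-colony counts, with a profile
#' likelihood 95% confidence interval and (when the final population size
#' `Nt` is given) the mutation rate `mu = m / Nt` per cell per generation.
#'
#' The MLE solves the score equation `dl/dm = 0` by safeguarded
#' Brent root-finding started from `m0 = -log(zero-count fraction)` (or 1
#' when no culture is mutant-free); confidence bounds are the two solutions
#' of `l(m) = l(m_hat) - qchisq(0.95, 1)/2` (= 1.9207).  Counts above
#' `max_count` are treated as right-censored at `max_count` ("too numerous
#' to count"); their likelihood contribution is `P(X >= max_count)`, which
#' keeps the likelihood exact while bounding the length of the pmf
#' recursion in the presence of jackpot cultures.
#'
#' @param counts non-negative integer vector, one resistant-colony count per
#'   culture.
#' @param epsilon plating fraction in `(0, 1]` shared by all cultures.
#' @param Nt mean final cells per culture (positive), used to convert `m` to
#'   a rate; may be `NULL`.
#' @param label optional strain identifier.
#' @param max_count censoring threshold for jackpot counts.
#' @param conf_level confidence level of the reported profile interval.
#' @return an object of class `ld_fit` with components `m` (the MLE),
#'   `ci_m`, `loglik`, `rate`, `ci_rate`, `epsilon`, `Nt`, `label`,
#'   `counts`, `n_censored`.  Supports [print()], [summary()], [coef()],
#'   [confint()], [logLik()], [simulate()], [plot()] and [anova()] (the
#'   likelihood-ratio strain comparison).
#' @examples
#' cfg <- sim_config(seed = 7, n_cultures = 25, m_true = 1.5)
#' fit <- ld_fit(simulate_fluctuation_counts(cfg), epsilon = 1, Nt = 2e8)
#' fit
#' coef(fit)
#' confint(fit)
#' @export
ld_fit <- function(counts, epsilon = 1, Nt = NULL, label = NULL,
                   max_count = 1000L, conf_level = 0.95) {
  if (!length(counts)) stop("`counts` must be non-empty")
  if (any(is.na(counts)) || any(counts < 0) ||
      any(abs(counts - round(counts)) > 1e-8))
    stop("`counts` must be non-negative integers")
  check_m_eps(0, epsilon)
  if (!is.null(Nt) && (!is.numeric(Nt) || Nt <= 0))
    stop("`Nt` must be positive")
  counts <- as.numeric(round(counts))
  cap <- as.integer(max_count)
  if (cap < 1L) stop("`max_count` must be >= 1")
  n_cens <- sum(counts >= cap)
  obs <- counts[counts < cap]
  tb <- table(obs)
  tab <- cbind(as.integer(names(tb)), as.integer(tb))
  if (!nrow(tab)) tab <- tab[0, , drop = FALSE]
  nmax <- max(0L, if (nrow(tab)) max(tab[, 1L]), if (n_cens > 0L) cap - 1L)
  h <- ld_clone_law(epsilon, nmax)

  lik <- function(m) ld_lik(m, h, tab, n_cens, cap)
  all_zero <- all(counts == 0)
  if (all_zero) {
    m_hat <- 0
    ll_hat <- 0
  } else {
    m0 <- if (any(counts == 0)) -log(mean(counts == 0)) else 1
    lo <- m0 / 8; hi <- max(2 * m0, 1)
    while (lik(lo)$score < 0 && lo > 1e-12) lo <- lo / 8
    while (lik(hi)$score > 0 && hi < 500) hi <- hi * 2
    m_hat <- uniroot(function(m) lik(m)$score, c(lo, hi), tol = 1e-10)$root
    ll_hat <- lik(m_hat)$ll
  }
  ci_m <- ld_profile_ci(lik, m_hat, ll_hat, conf_level, h0 = h[1L],
                        n = length(counts), all_zero = all_zero)
  rate <- if (!is.null(Nt)) m_hat / Nt
  ci_rate <- if (!is.null(Nt)) ci_m / Nt
  structure(
    list(m = m_hat, ci_m = ci_m, loglik = ll_hat,
         rate = rate, ci_rate = ci_rate,
         epsilon = epsilon, Nt = Nt,
         label = if (is.null(label)) "experiment" else label,
         counts = as.integer(counts), n_censored = n_cens,
         max_count = cap, conf_level = conf_level,
         call = match.call()),
    class = "ld_fit")
}

## Profile-likelihood interval: solutions of l(m) = l(m_hat) - cutoff.
ld_profile_ci <- function(lik, m_hat, ll_hat, conf_level, h0, n, all_zero) {
  cut <- qchisq(conf_level, df = 1) / 2
  target <- ll_hat - cut
  if (all_zero) {
    ## l(m) = -n * m * (1 - h0), strictly decreasing: closed-form upper bound
    return(c(0, cut / (n * (1 - h0))))
  }
  f <- function(m) lik(m)$ll - target
  lo_bracket <- m_hat * 1e-9
  lower <- if (f(lo_bracket) >= 0) 0 else
    uniroot(f, c(lo_bracket, m_hat), tol = 1e-9)$root
  hi <- m_hat * 2 + 0.5
  while (f(hi) > 0 && hi < 1e4) hi <- hi * 2
  upper <- uniroot(f, c(m_hat, hi), tol = 1e-9)$root
  c(lower, upper)
}

#' Convert a fitted number of mutations per culture into a mutation rate
#'
#' `rate = m / Nt` per cell per generation; confidence bounds divide
#' identically, preserving their ordering.
#'
#' @param m_hat estimated mutations per culture.
#' @param ci length-2 confidence bounds on `m_hat`.
#' @param Nt mean final cells per culture (> 0).
#' @return list with components `rate`, `ci_low`, `ci_high`.
#' @export
rate_from_m <- function(m_hat, ci, Nt) {
  if (!is.numeric(Nt) || length(Nt) != 1L || Nt <= 0)
    stop("`Nt` must be positive")
  list(rate = m_hat / Nt, ci_low = min(ci) / Nt, ci_high = max(ci) / Nt)
}

#' Likelihood-ratio comparison of two fluctuation experiments
#'
#' Tests the null hypothesis of a common mutation rate `mu` against the
#' alternative of experiment-specific rates (`m_i = mu_i * Nt_i`).  The
#' statistic `2 * (l_alt - l_null)` is referred to the upper tail of a
#' chi-squared distribution with 1 degree of freedom.  When both fits carry
#' the same `Nt` (or none), the null reduces to a common `m` and is fitted
#' on the pooled counts.
#'
#' @param fit1,fit2 `ld_fit` objects, or raw count vectors (then `epsilon`,
#'   `Nt` apply to both).
#' @param epsilon,Nt used only when raw counts are supplied.
#' @return an object of class `htest` with `statistic`, `parameter` (df) and
#'   `p.value`.
#' @export
ld_lrt <- function(fit1, fit2, epsilon = 1, Nt = NULL) {
  if (!inherits(fit1, "ld_fit")) fit1 <- ld_fit(fit1, epsilon, Nt)
  if (!inherits(fit2, "ld_fit")) fit2 <- ld_fit(fit2, epsilon, Nt)
  ll_alt <- fit1$loglik + fit2$loglik
  same_nt <- (is.null(fit1$Nt) && is.null(fit2$Nt)) ||
    (!is.null(fit1$Nt) && !is.null(fit2$Nt) && fit1$Nt == fit2$Nt)
  if (same_nt && fit1$epsilon == fit2$epsilon) {
    pooled <- ld_fit(c(fit1$counts, fit2$counts), epsilon = fit1$epsilon,
                     Nt = fit1$Nt, max_count = min(fit1$max_count,
                                                   fit2$max_count))
    ll_null <- pooled$loglik
  } else {
    if (is.null(fit1$Nt) || is.null(fit2$Nt))
      stop("both fits need `Nt` to share a rate across different cultures")
    part <- function(fit) {
      cap <- fit$max_count
      n_cens <- sum(fit$counts >= cap)
      obs <- fit$counts[fit$counts < cap]
      tb <- table(obs)
      tab <- cbind(as.integer(names(tb)), as.integer(tb))
      nmax <- max(0L, if (nrow(tab)) max(tab[, 1L]), if (n_cens) cap - 1L)
      list(h = ld_clone_law(fit$epsilon, nmax), tab = tab, n_cens = n_cens,
           cap = cap, Nt = fit$Nt)
    }
    p1 <- part(fit1); p2 <- part(fit2)
    nll <- function(log_mu) {
      mu <- exp(log_mu)
      -(ld_lik(mu * p1$Nt, p1$h, p1$tab, p1$n_cens, p1$cap)$ll +
        ld_lik(mu * p2$Nt, p2$h, p2$tab, p2$n_cens, p2$cap)$ll)
    }
    mu_alt <- c(fit1$m / fit1$Nt, fit2$m / fit2$Nt)
    mu_alt <- mu_alt[mu_alt > 0]
    ctr <- if (length(mu_alt)) log(mean(mu_alt)) else log(1e-9)
    opt <- optimize(nll, ctr + c(-8, 8), tol = 1e-10)
    ll_null <- -opt$objective
  }
  stat <- max(0, 2 * (ll_alt - ll_null))
  structure(
    list(statistic = c(LRT = stat), parameter = c(df = 1),
         p.value = pchisq(stat, df = 1, lower.tail = FALSE),
         method = "Likelihood-ratio test of equal mutation rates",
         data.name = paste(fit1$label, "vs", fit2$label)),
    class = "htest")
}

#' Benjamini--Hochberg adjustment of p-values
#'
#' Step-up false-discovery-rate adjustment, returned in input order.
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, capped at 1.
#' @export
bh_adjust <- function(pvalues) {
  if (!is.numeric(pvalues) || any(is.na(pvalues)) ||
      any(pvalues < 0 | pvalues > 1))
    stop("p-values must be numbers in [0, 1]")
  p.adjust(pvalues, method = "BH")
}

## ---- ld_fit methods ------------------------------------------------------

#' @export
print.ld_fit <- function(x, ...) {
  cat("Luria-Delbruck fluctuation fit:", x$label, "\n")
  cat(sprintf("  cultures: %d   plating fraction: %g   censored: %d\n",
              length(x$counts), x$epsilon, x$n_censored))
  cat(sprintf("  m = %.4g  (%d%% CI %.4g - %.4g)\n", x$m,
              round(100 * x$conf_level), x$ci_m[1], x$ci_m[2]))
  if (!is.null(x$rate))
    cat(sprintf("  rate = %.3g per cell per generation (CI %.3g - %.3g)\n",
                x$rate, x$ci_rate[1], x$ci_rate[2]))
  invisible(x)
}

#' @export
summary.ld_fit <- function(object, ...) {
  out <- list(fit = object,
              n = length(object$counts),
              zero_fraction = mean(object$counts == 0),
              median_count = stats::median(object$counts),
              max_count_obs = max(object$counts))
  class(out) <- "summary.ld_fit"
  out
}

#' @export
print.summary.ld_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  zero-count fraction: %.3f   median count: %g   max: %g\n",
              x$zero_fraction, x$median_count, x$max_count_obs))
  cat(sprintf("  log-likelihood: %.4f\n", x$fit$loglik))
  invisible(x)
}

#' @export
coef.ld_fit <- function(object, ...) {
  if (is.null(object$rate)) c(m = object$m)
  else c(m = object$m, rate = object$rate)
}

#' @export
logLik.ld_fit <- function(object, ...) {
  structure(object$loglik, df = 1L, nobs = length(object$counts),
            class = "logLik")
}

#' @export
confint.ld_fit <- function(object, parm = c("m", "rate"), level = 0.95, ...) {
  parm <- match.arg(parm)
  ci_m <- if (abs(level - object$conf_level) < 1e-12) object$ci_m else {
    refit <- ld_fit(object$counts, object$epsilon, object$Nt, object$label,
                    object$max_count, conf_level = level)
    refit$ci_m
  }
  ci <- if (parm == "m") ci_m else {
    if (is.null(object$Nt)) stop("fit has no `Nt`; rate interval undefined")
    ci_m / object$Nt
  }
  out <- matrix(ci, nrow = 1,
                dimnames = list(parm, sprintf("%g %%",
                                              100 * c((1 - level) / 2,
                                                      1 - (1 - level) / 2))))
  out
}

#' @export
simulate.ld_fit <- function(object, nsim = 1, seed = NULL, ...) {
  cfg <- sim_config(seed = if (is.null(seed)) 1L else seed,
                    n_cultures = length(object$counts),
                    m_true = object$m, epsilon = object$epsilon,
                    Nt = if (is.null(object$Nt)) 1e9 else object$Nt)
  out <- lapply(seq_len(nsim), function(i)
    simulate_fluctuation_counts(cfg, seed = cfg$seed + i - 1L))
  as.data.frame(setNames(out, paste0("sim_", seq_len(nsim))))
}

#' @export
plot.ld_fit <- function(x, n_show = NULL, ...) {
  if (is.null(n_show)) n_show <- min(max(x$counts) + 1L, 30L)
  obs <- tabulate(pmin(x$counts, n_show) + 1L, nbins = n_show + 1L) /
    length(x$counts)
  p <- ld_pmf(x$m, x$epsilon, n_show)
  bp <- barplot(obs, names.arg = 0:n_show, xlab = "mutant colonies",
                ylab = "relative frequency",
                main = paste("Fluctuation fit:", x$label), ...)
  points(bp, p, pch = 19, col = "firebrick")
  legend("topright", legend = c("observed", "fitted pmf"),
         pch = c(15, 19), col = c("grey", "firebrick"), bty = "n")
  invisible(x)
}

#' @export
anova.ld_fit <- function(object, ...) {
  others <- Filter(function(o) inherits(o, "ld_fit"), list(...))
  if (length(others) != 1L)
    stop("supply exactly two `ld_fit` objects to compare")
  ld_lrt(object, others[[1L]])
}
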