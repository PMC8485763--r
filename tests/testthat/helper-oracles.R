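## Independent reference implementations used as oracles.  These are kept
## deliberately naive (plain R, direct formulas) and separate from the code
## paths they check.

## Ma-Sandri-Sarkar recursion for the whole-culture-plated mutant-count pmf,
## written directly from p_0 = exp(-m), p_n = (m/n) sum_i p_i / (n - i + 1).
oracle_mss_pmf <- function(m, n_max) {
  p <- numeric(n_max + 1)
  p[1] <- exp(-m)
  for (n in seq_len(n_max)) {
    i <- 0:(n - 1)
    p[n + 1] <- (m / n) * sum(p[i + 1] / (n - i + 1))
  }
  p
}

## Log-likelihood of counts (censored at `cap`, like ld_fit) under a pmf
## function pmf_fun(m, n_max) -> p[0..n_max].
oracle_loglik <- function(m, counts, pmf_fun, cap = 1000L) {
  n_cens <- sum(counts >= cap)
  obs <- counts[counts < cap]
  nmax <- max(0L, obs, if (n_cens) cap - 1L)
  p <- pmf_fun(m, nmax)
  ll <- sum(log(p[obs + 1L]))
  if (n_cens) ll <- ll + n_cens * log(max(1 - sum(p[seq_len(cap)]), 1e-300))
  ll
}

## Iteratively refined grid search for the maximum-likelihood m.
oracle_grid_mle <- function(counts, pmf_fun, cap = 1000L,
                            lo = 1e-4, hi = 20, rounds = 7, pts = 81) {
  grid <- exp(seq(log(lo), log(hi), length.out = 200))
  for (r in seq_len(rounds)) {
    ll <- vapply(grid, oracle_loglik, numeric(1),
                 counts = counts, pmf_fun = pmf_fun, cap = cap)
    k <- which.max(ll)
    lo2 <- grid[max(1L, k - 2L)]
    hi2 <- grid[min(length(grid), k + 2L)]
    grid <- seq(lo2, hi2, length.out = pts)
  }
  grid[which.max(vapply(grid, oracle_loglik, numeric(1),
                        counts = counts, pmf_fun = pmf_fun, cap = cap))]
}

## Welch statistic, Welch-Satterthwaite df and two-sided p, by hand.
oracle_welch <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- var(x); vy <- var(y)
  se2 <- vx / nx + vy / ny
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

## Benjamini-Hochberg step-up adjustment, by hand.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  adj <- pmin(cummin(p[o] * n / rank(p, ties.method = "max")[o]), 1)
  adj[order(o)]
}

## Build a substitution-call table with a prescribed number of calls in each
## of the six base-pair classes (positions cycled through the window).
calls_from_class_counts <- function(counts,
                                    classes = c("CG>GC", "CG>AT", "CG>TA",
                                                "AT>TA", "AT>CG", "AT>GC"),
                                    window = c(1516L, 1717L)) {
  rep_class <- rep(classes, counts)
  ra <- list("CG>GC" = c("C", "G"), "CG>AT" = c("C", "A"),
             "CG>TA" = c("C", "T"), "AT>TA" = c("A", "T"),
             "AT>CG" = c("A", "C"), "AT>GC" = c("A", "G"))
  n <- length(rep_class)
  pos <- window[1L] + (seq_len(n) - 1L) %% (window[2L] - window[1L] + 1L)
  data.frame(isolate = sprintf("i%04d", seq_len(n)),
             position = as.integer(pos),
             ref = vapply(rep_class, function(cl) ra[[cl]][1L], character(1)),
             alt = vapply(rep_class, function(cl) ra[[cl]][2L], character(1)),
             stringsAsFactors = FALSE)
}

## Render a complete synthetic alkaline gel (sample lanes plus ladders) and
## quantify it; returns the ribo_quant object plus the realized nick counts.
synthetic_gel <- function(seed, rho_wt = 5e-5, rho_mut = 1e-4,
                          n_wt = 4, n_mut = 1,
                          ladder = c(1e3, 2e3, 5e3, 1e4, 2e4, 5e4, 1e5)) {
  cfg <- sim_config(seed = seed)
  lanes <- list(); realized <- list(wt = numeric(), mut = numeric())
  for (i in seq_len(n_wt)) {
    c2 <- cfg; c2$rho <- rho_wt
    fr <- simulate_nicked_fragments(c2, seed = seed * 100 + i)
    realized$wt <- c(realized$wt, length(fr) - 1L)
    lanes[[length(lanes) + 1L]] <-
      render_gel_lane(fr, cfg, label = paste0("wt", i), rnhB = "wt",
                      seed = seed * 100 + 50 + i)
  }
  for (i in seq_len(n_mut)) {
    c2 <- cfg; c2$rho <- rho_mut
    fr <- simulate_nicked_fragments(c2, seed = seed * 100 + 10 + i)
    realized$mut <- c(realized$mut, length(fr) - 1L)
    lanes[[length(lanes) + 1L]] <-
      render_gel_lane(fr, cfg, label = paste0("mut", i), rnhB = "drnhB",
                      dnaE = "dnaE_mut", seed = seed * 100 + 60 + i)
  }
  lcnt <- round(max(ladder) / ladder)
  markers <- lapply(1:2, function(k)
    render_gel_lane(ladder, cfg, counts = lcnt, label = paste0("lad", k),
                    seed = seed * 100 + 90 + k))
  rq <- ribo_quant(lanes, markers, ladder, sz_min = 500, G = cfg$G)
  list(rq = rq, realized = realized, G = cfg$G)
}
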