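#' Construct a gel lane densitometry profile
#'
#' @param distances strictly increasing migration distances (arbitrary units).
#' @param intensities non-negative staining intensities, same length.
#' @param label lane identifier.
#' @param rnhB RNase HII status of the sample, `"wt"` or `"drnhB"`.
#' @param dnaE polymerase allele label (free text).
#' @return an object of class `lane_profile`.
#' @export
lane_profile <- function(distances, intensities, label = "lane",
                         rnhB = c("wt", "drnhB"), dnaE = "dnaE_wt") {
  rnhB <- match.arg(rnhB)
  if (length(distances) != length(intensities))
    stop("`distances` and `intensities` must have equal length")
  if (length(distances) < 3L) stop("a lane profile needs >= 3 samples")
  if (any(diff(distances) <= 0))
    stop("`distances` must be strictly increasing")
  if (any(!is.finite(distances)) || any(!is.finite(intensities)))
    stop("profile values must be finite")
  structure(list(distances = as.numeric(distances),
                 intensities = as.numeric(intensities),
                 label = label, rnhB = rnhB, dnaE = dnaE),
            class = "lane_profile")
}

#' @export
print.lane_profile <- function(x, ...) {
  cat(sprintf("<lane_profile> %s (%s, %s): %d points, distance %.4g-%.4g\n",
              x$label, x$dnaE, x$rnhB, length(x$distances),
              min(x$distances), max(x$distances)))
  invisible(x)
}

#' Background-subtract and smooth a lane profile
#'
#' A single constant background is subtracted from the whole lane (by
#' default the 2nd-percentile intensity, standing in for the empty-lane
#' staining level), negatives are clipped to zero, and a cubic smoothing
#' spline targeting `df` effective degrees of freedom is fitted to suppress
#' densitometry noise.
#'
#' @param profile a [lane_profile()].
#' @param df target effective degrees of freedom of the smoothing spline
#'   (>= 2); reduced with a warning when the lane has too few points.
#' @param background `"quantile"` (default) or `"constant"`.
#' @param bg_value background level when `background = "constant"`.
#' @param bg_quantile quantile used when `background = "quantile"`.
#' @return a new [lane_profile()] with processed intensities.
#' @export
preprocess_lane <- function(profile, df = 40,
                            background = c("quantile", "constant"),
                            bg_value = NULL, bg_quantile = 0.02) {
  stopifnot(inherits(profile, "lane_profile"))
  background <- match.arg(background)
  if (df < 2) stop("`df` must be >= 2")
  bg <- switch(background,
    quantile = as.numeric(quantile(profile$intensities, bg_quantile)),
    constant = {
      if (is.null(bg_value)) stop("`bg_value` required for constant background")
      bg_value
    })
  y <- pmax(profile$intensities - bg, 0)
  if (all(y == 0))
    stop("lane is empty after background subtraction")
  n <- length(y)
  if (df > n - 1) {
    warning(sprintf("reducing spline df from %g to %d (lane has %d points)",
                    df, n - 1L, n))
    df <- n - 1L
  }
  sm <- smooth.spline(profile$distances, y, df = df)
  out <- profile
  out$intensities <- pmax(predict(sm, profile$distances)$y, 0)
  out
}

## Local maxima of y with their topographic prominence: for each candidate
## peak, scan outward on each side until a strictly higher point (or the
## profile end); the prominence is the peak height minus the higher of the
## two minima encountered.
find_peaks <- function(y, min_prominence = 0) {
  n <- length(y)
  if (n < 3L) return(integer())
  cand <- which(y[2:(n - 1L)] > y[1:(n - 2L)] &
                y[2:(n - 1L)] >= y[3:n]) + 1L
  keep <- logical(length(cand))
  for (k in seq_along(cand)) {
    i <- cand[k]; yp <- y[i]
    left <- if (i > 1L) y[1:(i - 1L)] else numeric()
    j <- which(left > yp)
    lmin <- if (length(j)) min(left[(max(j) ):(i - 1L)]) else min(left)
    right <- if (i < n) y[(i + 1L):n] else numeric()
    j <- which(right > yp)
    rmin <- if (length(j)) min(right[1:min(j)]) else min(right)
    keep[k] <- (yp - max(lmin, rmin)) >= min_prominence
  }
  cand[keep]
}

#' Fit a distance-to-size calibration from molecular-weight marker lanes
#'
#' Ladder peaks are detected as local maxima whose topographic prominence
#' exceeds `prominence` times the lane maximum, paired to the ladder sizes
#' in order (largest fragment = smallest migration distance), averaged
#' across marker lanes band by band, and regressed as
#' `distance = a + b * log(size)` by least squares.
#'
#' @param marker_lanes a [lane_profile()] or list of them.
#' @param marker_sizes ladder fragment sizes in nucleotides (>= 2 distinct).
#' @param peak_positions optional manual peak distances (vector, ordered by
#'   increasing distance, one per ladder band; or a list per lane),
#'   bypassing detection -- the equivalent of supervised peak picking.
#' @param prominence prominence threshold as a fraction of the lane maximum.
#' @return an object of class `gel_calibration` with components `a`, `b`,
#'   `marker_sizes`, `marker_positions`, `r2` and the underlying `lm` fit.
#' @export
fit_calibration <- function(marker_lanes, marker_sizes,
                            peak_positions = NULL, prominence = 0.05) {
  if (inherits(marker_lanes, "lane_profile")) marker_lanes <- list(marker_lanes)
  sizes <- sort(unique(as.numeric(marker_sizes)), decreasing = TRUE)
  if (length(sizes) < 2L) stop("need >= 2 distinct marker sizes")
  nb <- length(sizes)
  if (is.null(peak_positions)) {
    pos <- vapply(marker_lanes, function(ln) {
      idx <- find_peaks(ln$intensities,
                        min_prominence = prominence * max(ln$intensities))
      if (length(idx) != nb)
        stop(sprintf(
          "lane '%s': detected %d peaks but ladder has %d bands; %s",
          ln$label, length(idx), nb,
          "supply `peak_positions` to identify bands manually"))
      sort(ln$distances[idx])
    }, numeric(nb))
    pos <- if (nb == 1L) matrix(pos, nrow = 1L) else pos
    mean_pos <- rowMeans(pos)
  } else {
    if (!is.list(peak_positions)) peak_positions <- list(peak_positions)
    if (any(lengths(peak_positions) != nb))
      stop("each `peak_positions` vector must have one entry per ladder band")
    mean_pos <- rowMeans(vapply(peak_positions, function(p) sort(p),
                                numeric(nb)))
  }
  fit <- lm(mean_pos ~ log(sizes))
  a <- unname(coef(fit)[1L]); b <- unname(coef(fit)[2L])
  if (!is.finite(b) || b >= 0)
    stop("calibration slope must be negative (larger fragments migrate less)")
  r2 <- if (nb > 2L) summary(fit)$r.squared else 1
  structure(list(a = a, b = b, marker_sizes = sizes,
                 marker_positions = mean_pos, r2 = r2, fit = fit),
            class = "gel_calibration")
}

#' @export
print.gel_calibration <- function(x, ...) {
  cat(sprintf("<gel_calibration> d = %.4g + %.4g * log(size), r2 = %.4f (%d bands)\n",
              x$a, x$b, x$r2, length(x$marker_sizes)))
  invisible(x)
}

#' Construct a fragment-size distribution directly
#'
#' Builds the per-interval size/count container produced by
#' [fragment_count_profile()] from explicit values, e.g. to apply the mean
#' fragment-size correction to distributions obtained outside the
#' densitometry pipeline.
#'
#' @param sz per-interval fragment sizes (nt, > 0).
#' @param n_sz per-interval fragment counts (>= 0), same length.
#' @param sz_min minimum resolvable fragment size at the cut-off (nt).
#' @param d_max cut-off electrophoretic distance (optional bookkeeping).
#' @param label sample identifier.
#' @return an object of class `fragment_size_distribution`.
#' @export
fragment_size_distribution <- function(sz, n_sz, sz_min, d_max = NA_real_,
                                       label = "sample") {
  if (length(sz) != length(n_sz))
    stop("`sz` and `n_sz` must have equal length")
  if (any(sz <= 0)) stop("fragment sizes must be positive")
  if (any(n_sz < 0)) stop("fragment counts must be non-negative")
  if (!is.numeric(sz_min) || sz_min < 0) stop("`sz_min` must be >= 0")
  structure(list(sz = as.numeric(sz), n_sz = as.numeric(n_sz),
                 intensity = as.numeric(sz) * as.numeric(n_sz),
                 d_max = d_max, sz_min = sz_min, label = label),
            class = "fragment_size_distribution")
}

#' Convert a lane profile into a fragment-size distribution
#'
#' Applies the calibration to map each distance interval to a fragment size
#' `sz = exp((d - a)/b)` and estimates the fragment count per interval as
#' `n_sz = I_sz / sz` (staining intensity is proportional to fragment mass).
#' Intervals beyond the cut-off distance `d_max` are discarded to avoid the
#' noise-amplified small-fragment region at the bottom of the gel; the size
#' at `d_max` is the minimum resolvable fragment size `sz_min`.
#'
#' @param profile a preprocessed [lane_profile()].
#' @param calib a [fit_calibration()] result.
#' @param d_max cut-off electrophoretic distance, inside the profile range.
#' @return an object of class `fragment_size_distribution` with fields `sz`,
#'   `n_sz`, `intensity`, `d_max`, `sz_min`, `label`.
#' @export
fragment_count_profile <- function(profile, calib, d_max) {
  stopifnot(inherits(profile, "lane_profile"),
            inherits(calib, "gel_calibration"))
  rng <- range(profile$distances)
  if (!is.numeric(d_max) || d_max < rng[1L] || d_max > rng[2L])
    stop("`d_max` must lie within the profile distance range")
  keep <- profile$distances <= d_max
  d <- profile$distances[keep]
  I <- profile$intensities[keep]
  sz <- exp((d - calib$a) / calib$b)
  structure(list(sz = sz, n_sz = I / sz, intensity = I,
                 d_max = d_max, sz_min = exp((d_max - calib$a) / calib$b),
                 label = profile$label),
            class = "fragment_size_distribution")
}

#' Mean fragment size, raw and corrected for sub-threshold fragments
#'
#' `mean_raw = sum(sz * n_sz) / sum(n_sz)` over the retained intervals; the
#' corrected mean `mean_corr = mean_raw * exp(-sz_min / mean_raw)` accounts
#' for fragments smaller than `sz_min` that migrated beyond the cut-off
#' (exponential fragment-size approximation).
#'
#' @param dist a [fragment_count_profile()] result.
#' @return named numeric vector `c(mean_raw, mean_corr)` in nucleotides.
#' @export
mean_fragment_size <- function(dist) {
  stopifnot(inherits(dist, "fragment_size_distribution"))
  tot_n <- sum(dist$n_sz)
  if (!(tot_n > 0)) stop("empty fragment-size distribution")
  mean_raw <- sum(dist$sz * dist$n_sz) / tot_n
  c(mean_raw = mean_raw,
    mean_corr = mean_raw * exp(-dist$sz_min / mean_raw))
}

#' Number of strand breakpoints per genome
#'
#' `N = G / mean_corr` for a single-strand genome of `G` nucleotides.
#'
#' @param mean_corr corrected mean fragment size (> 0), nucleotides.
#' @param G single-strand genome length in nucleotides.
#' @return breakpoints per genome.
#' @export
genome_breakpoints <- function(mean_corr, G = 9.28e6) {
  if (any(mean_corr <= 0)) stop("`mean_corr` must be positive")
  G / mean_corr
}

#' Embedded ribonucleotides per genome
#'
#' Breakpoints in RNase HII-deficient DNA in excess of the wild-type mean on
#' the same gel: `n_ribo = N_mut - mean(N_wt_samples)`.  A negative result
#' is returned (with a warning) rather than clamped, preserving the
#' differencing semantics for quality control.
#'
#' @param N_mut breakpoints per genome in the RER-deficient sample.
#' @param N_wt_samples breakpoint counts of all RNase HII-proficient samples
#'   on the same gel.
#' @return estimated embedded ribonucleotides per genome.
#' @export
embedded_ribos <- function(N_mut, N_wt_samples) {
  if (!length(N_wt_samples)) stop("need >= 1 wild-type sample")
  out <- N_mut - mean(N_wt_samples)
  if (any(out < 0))
    warning("negative ribonucleotide estimate: mutant below wild-type mean")
  out
}

#' Welch two-sample t test
#'
#' Unpaired two-sided t test with Welch's correction (unequal variances,
#' Welch--Satterthwaite degrees of freedom).
#'
#' @param x,y numeric samples, each of size >= 2.
#' @return list with components `t`, `df`, `p`.
#' @export
welch_t <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L)
    stop("each sample needs >= 2 observations")
  tt <- t.test(x, y, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}

#' Summarize per-genome embedded-ribonucleotide estimates across strains
#'
#' Produces the standard reporting table for embedded-ribonucleotide
#' quantification: per strain, the mean +/- SD of ribonucleotides per
#' genome, per megabase (`per_genome / (G/1e6)`, computed per replicate and
#' then averaged), kilobases per ribonucleotide (`(G/1e3) / per_genome`,
#' per replicate then averaged), the fold difference of strain mean over the
#' reference mean, and a Welch t-test of the per-genome values against the
#' reference (NA when either strain has a single replicate).
#'
#' @param per_genome named list of numeric vectors: per-strain replicate
#'   values of ribonucleotides per genome.
#' @param G single-strand genome length in nucleotides.
#' @param reference name of the reference (wild-type) strain in `per_genome`.
#' @return a data frame of class `ribo_summary` with columns `strain`, `n`,
#'   `per_genome`, `per_genome_sd`, `per_mb`, `per_mb_sd`, `kb_per_rn`,
#'   `kb_per_rn_sd`, `fold`, `p_value`.  The print method rounds for
#'   display (integers for per-genome/per-Mb, 1 decimal for kb-per-rN,
#'   2 for folds).
#' @export
summarize_ribo <- function(per_genome, G = 9.28e6, reference = "dnaE_wt") {
  if (!is.list(per_genome) || is.null(names(per_genome)) ||
      any(!nzchar(names(per_genome))))
    stop("`per_genome` must be a named list of replicate vectors")
  if (any(lengths(per_genome) == 0L)) stop("replicate lists must be non-empty")
  if (!reference %in% names(per_genome))
    stop(sprintf("reference strain '%s' missing from `per_genome`", reference))
  ref <- per_genome[[reference]]
  rows <- lapply(names(per_genome), function(s) {
    v <- as.numeric(per_genome[[s]])
    per_mb <- v / (G / 1e6)
    kb <- (G / 1e3) / v
    p <- if (identical(s, reference)) 1
         else if (length(v) >= 2L && length(ref) >= 2L) welch_t(v, ref)$p
         else NA_real_
    data.frame(strain = s, n = length(v),
               per_genome = mean(v), per_genome_sd = sd(v),
               per_mb = mean(per_mb), per_mb_sd = sd(per_mb),
               kb_per_rn = mean(kb), kb_per_rn_sd = sd(kb),
               fold = mean(v) / mean(ref), p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "G") <- G
  attr(out, "reference") <- reference
  class(out) <- c("ribo_summary", "data.frame")
  out
}

#' @export
print.ribo_summary <- function(x, ...) {
  disp <- data.frame(
    strain = x$strain, n = x$n,
    `rN_per_genome` = sprintf("%.0f ± %.0f", x$per_genome,
                              ifelse(is.na(x$per_genome_sd), 0,
                                     x$per_genome_sd)),
    `rN_per_Mb` = round(x$per_mb),
    `kb_per_rN` = round(x$kb_per_rn, 1),
    fold = sprintf("%.2f", x$fold),
    p_value = ifelse(is.na(x$p_value), "NA",
                     ifelse(x$p_value < 1e-4, "<0.0001",
                            sprintf("%.4f", x$p_value))),
    check.names = FALSE)
  cat(sprintf("Embedded ribonucleotides per genome (G = %.3g nt, reference: %s)\n",
              attr(x, "G"), attr(x, "reference")))
  print(disp, row.names = FALSE)
  invisible(x)
}
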