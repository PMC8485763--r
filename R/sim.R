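#' Simulation configuration for the synthetic-data generators
#'
#' Bundles the ground-truth parameters shared by the three generators:
#' fluctuation-assay mutant counts, nicked-genome gel lanes, and
#' base-substitution call sets.  Defaults describe a typical rifampicin
#' forward-mutation experiment in *E. coli*: around 2 mutational events per
#' culture, the whole culture plated, ~2e8 cells per overnight culture, a
#' 9.28e6-nt single-strand genome, and a nick density giving a few hundred
#' alkali-labile sites per genome.
#'
#' @param seed integer seed; every generator derives its randomness from an
#'   explicit seed, never from global RNG state.
#' @param n_cultures number of parallel cultures in a fluctuation experiment.
#' @param m_true expected number of mutational events per culture (>= 0).
#' @param epsilon plating fraction in `[0, 1]`.
#' @param Nt final number of cells per culture (>= 1).
#' @param G single-strand genome length in nucleotides.
#' @param rho nick density per nucleotide in `[0, 1)`.
#' @param calib_a,calib_b electrophoretic calibration intercept and slope of
#'   the migration model `d = calib_a + calib_b * log(sz)`; `calib_b < 0`
#'   because larger fragments migrate less.
#' @param band_sd Gaussian band spread of a gel band, in distance units.
#' @param noise_sd standard deviation of additive intensity noise.
#' @param background constant lane background intensity.
#' @param class_probs probabilities of the six base-pair substitution classes
#'   in the order CG>GC, CG>AT, CG>TA, AT>TA, AT>CG, AT>GC; must sum to 1.
#' @param position_weights named non-negative vector of relative weights over
#'   the reporting-window positions; names are 1-based gene coordinates.
#' @param window integer length-2 closed reporting window (1-based).
#'
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed = 1L,
                       n_cultures = 30L,
                       m_true = 2,
                       epsilon = 1,
                       Nt = 2e8,
                       G = 9.28e6,
                       rho = 5e-5,
                       calib_a = 450,
                       calib_b = -25,
                       band_sd = 2,
                       noise_sd = 10,
                       background = 200,
                       class_probs = c(2, 8, 9, 89, 174, 20) / 302,
                       position_weights = NULL,
                       window = c(1516L, 1717L)) {
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon < 0 || epsilon > 1)
    stop("`epsilon` must be a single number in [0, 1]")
  if (!is.numeric(m_true) || length(m_true) != 1L || m_true < 0)
    stop("`m_true` must be a single non-negative number")
  if (!is.numeric(rho) || rho < 0 || rho >= 1)
    stop("`rho` must be in [0, 1)")
  if (!is.numeric(G) || G < 1) stop("`G` must be a positive genome length")
  if (!is.numeric(Nt) || Nt < 1) stop("`Nt` must be >= 1")
  if (!is.numeric(calib_b) || calib_b >= 0)
    stop("`calib_b` must be negative: larger fragments migrate less")
  if (length(class_probs) != 6L || any(class_probs < 0))
    stop("`class_probs` must be 6 non-negative probabilities")
  if (abs(sum(class_probs) - 1) > 1e-9)
    stop("`class_probs` must sum to 1 (within 1e-9)")
  window <- as.integer(window)
  if (length(window) != 2L || window[1] > window[2])
    stop("`window` must be an ordered pair of positions")
  if (is.null(position_weights)) {
    pos <- window[1]:window[2]
    position_weights <- setNames(rep(1, length(pos)), pos)
    ## mutagenic peaks observed for this reporter: strong hotspot at 1714,
    ## secondary peaks at 1547, 1577, 1687, 1715
    hot <- c(`1547` = 10, `1577` = 10, `1687` = 10, `1714` = 25, `1715` = 10)
    position_weights[names(hot)] <- position_weights[names(hot)] + hot
  } else {
    if (is.null(names(position_weights)))
      stop("`position_weights` must be named by window position")
    if (any(position_weights < 0)) stop("`position_weights` must be >= 0")
    pw_pos <- as.integer(names(position_weights))
    if (any(is.na(pw_pos)) || any(pw_pos < window[1]) || any(pw_pos > window[2]))
      stop("`position_weights` names must be positions inside `window`")
  }
  names(class_probs) <- SUB_CLASSES
  structure(
    list(seed = as.integer(seed), n_cultures = as.integer(n_cultures),
         m_true = m_true, epsilon = epsilon, Nt = Nt, G = G, rho = rho,
         calib_a = calib_a, calib_b = calib_b, band_sd = band_sd,
         noise_sd = noise_sd, background = background,
         class_probs = class_probs, position_weights = position_weights,
         window = window),
    class = "sim_config")
}

#' Simulate mutant-colony counts for a fluctuation experiment
#'
#' Realizes the Lea--Coulson model that the mutation-rate estimator assumes:
#' the number of mutational events per culture is Poisson(`m_true`); each
#' event founds a clone of size `Y = min(floor(1/U), Nt)` with `U` uniform
#' (deterministic exponential-growth approximation); a `Binomial(Y, epsilon)`
#' subset of each clone is recovered on the selective plate.
#'
#' @param cfg a [sim_config()].
#' @param seed integer seed (defaults to `cfg$seed`).
#' @return integer vector of length `cfg$n_cultures` of per-culture counts.
#' @export
simulate_fluctuation_counts <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- cfg$n_cultures
  with_seed(seed, {
    counts <- numeric(n)
    M <- rpois(n, cfg$m_true)
    tot <- sum(M)
    if (tot > 0 && cfg$epsilon > 0) {
      Y <- pmin(floor(1 / runif(tot)), cfg$Nt)
      obs <- rbinom(tot, size = Y, prob = cfg$epsilon)
      agg <- rowsum(obs, rep.int(seq_len(n), M))
      counts[as.integer(rownames(agg))] <- agg
    }
    as.integer(counts)
  })
}

#' Simulate inter-nick fragment sizes of a nicked single-strand genome
#'
#' Places `K ~ Binomial(G, rho)` nicks uniformly (without replacement) on a
#' linear single-strand molecule of length `G` and returns the `K + 1`
#' inter-nick segment lengths, which sum to `G` exactly.
#'
#' @inheritParams simulate_fluctuation_counts
#' @return numeric vector of fragment sizes in nucleotides.
#' @export
simulate_nicked_fragments <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "sim_config"))
  G <- cfg$G
  with_seed(seed, {
    K <- rbinom(1L, size = G, prob = cfg$rho)
    if (K == 0L) return(G)
    cuts <- sort(sample(G - 1, min(K, G - 1)))
    diff(c(0, cuts, G))
  })
}

#' Render a densitometry lane profile from fragment sizes
#'
#' Inverse model of the gel-quantification pipeline: each fragment of size
#' `sz` migrates to `d = calib_a + calib_b * log(sz)` and deposits staining
#' intensity proportional to its *mass* (i.e. to `sz`, which is why the
#' analysis divides intensity by size to count fragments).  Band mass is
#' binned onto a fixed distance grid, spread with a Gaussian kernel of width
#' `band_sd`, and overlaid with constant background plus Gaussian noise.
#'
#' @param fragments numeric vector of fragment sizes (> 0), in nucleotides.
#' @param cfg a [sim_config()].
#' @param counts number of molecules of each size (same length as
#'   `fragments`, default 1 each); a band's mass is `counts * size`.  Useful
#'   for rendering marker-ladder lanes, which load roughly equal mass per
#'   band rather than one molecule per band.
#' @param grid strictly increasing vector of migration distances; defaults to
#'   a grid spanning sizes from ~50 nt up to twice the genome length.
#' @param label,rnhB,dnaE lane annotations carried into the profile.
#' @param seed integer seed for the noise (defaults to `cfg$seed`).
#' @return a [lane_profile()].
#' @export
render_gel_lane <- function(fragments, cfg, counts = NULL, grid = NULL,
                            label = "lane", rnhB = "wt", dnaE = "dnaE_wt",
                            seed = cfg$seed) {
  stopifnot(inherits(cfg, "sim_config"))
  if (length(fragments) && any(fragments <= 0))
    stop("fragment sizes must be positive")
  if (is.null(counts)) counts <- rep(1, length(fragments))
  if (length(counts) != length(fragments) || any(counts < 0))
    stop("`counts` must be non-negative, one per fragment size")
  a <- cfg$calib_a; b <- cfg$calib_b
  if (is.null(grid)) {
    d_lo <- a + b * log(2 * cfg$G)
    d_hi <- a + b * log(50)
    grid <- seq(d_lo, d_hi, by = cfg$band_sd / 4)
  }
  step <- grid[2L] - grid[1L]
  mass <- numeric(length(grid))
  if (length(fragments)) {
    centre <- a + b * log(fragments)
    idx <- pmin(pmax(round((centre - grid[1L]) / step) + 1L, 1L), length(grid))
    agg <- rowsum(counts * fragments, idx)
    mass[as.integer(rownames(agg))] <- agg
  }
  ## Gaussian band spread, discretized so total deposited mass is conserved
  ## up to quadrature error
  half <- seq(0, 4 * cfg$band_sd, by = step)
  kern <- dnorm(c(-rev(half[-1L]), half), sd = cfg$band_sd) * step
  smeared <- convolve_open(mass, kern)
  intens <- smeared + cfg$background
  if (cfg$noise_sd > 0)
    intens <- intens + with_seed(seed, rnorm(length(grid), sd = cfg$noise_sd))
  lane_profile(grid, pmax(intens, 0), label = label, rnhB = rnhB, dnaE = dnaE)
}

## symmetric open convolution trimmed back to the length of `x`
convolve_open <- function(x, kern) {
  full <- stats::convolve(x, rev(kern), type = "open")
  off <- (length(kern) - 1L) %/% 2L
  full[(off + 1L):(off + length(x))]
}

#' Simulate base-substitution calls with known class and position structure
#'
#' Draws one substitution per isolate: the base-pair class from
#' `cfg$class_probs`, the position from `cfg$position_weights`, and the
#' strand representation of the class (e.g. `CG>TA` recorded as C>T or G>A)
#' uniformly at random.
#'
#' @param cfg a [sim_config()].
#' @param n_isolates number of isolates to draw.
#' @param seed integer seed (defaults to `cfg$seed`).
#' @return data frame with columns `isolate`, `position`, `ref`, `alt`.
#' @export
simulate_substitution_calls <- function(cfg, n_isolates, seed = cfg$seed) {
  stopifnot(inherits(cfg, "sim_config"))
  n_isolates <- as.integer(n_isolates)
  if (n_isolates < 0) stop("`n_isolates` must be >= 0")
  ## the two strand-level representations of each pair class
  strands <- list(
    "CG>GC" = rbind(c("C", "G"), c("G", "C")),
    "CG>AT" = rbind(c("C", "A"), c("G", "T")),
    "CG>TA" = rbind(c("C", "T"), c("G", "A")),
    "AT>TA" = rbind(c("A", "T"), c("T", "A")),
    "AT>CG" = rbind(c("A", "C"), c("T", "G")),
    "AT>GC" = rbind(c("A", "G"), c("T", "C")))
  if (n_isolates == 0L)
    return(data.frame(isolate = character(), position = integer(),
                      ref = character(), alt = character(),
                      stringsAsFactors = FALSE))
  with_seed(seed, {
    cls <- sample(SUB_CLASSES, n_isolates, replace = TRUE,
                  prob = cfg$class_probs)
    pos <- as.integer(sample(names(cfg$position_weights), n_isolates,
                             replace = TRUE, prob = cfg$position_weights))
    strand <- sample(1:2, n_isolates, replace = TRUE)
    ref <- alt <- character(n_isolates)
    for (i in seq_len(n_isolates)) {
      ra <- strands[[cls[i]]][strand[i], ]
      ref[i] <- ra[1L]; alt[i] <- ra[2L]
    }
    data.frame(isolate = sprintf("iso%04d", seq_len(n_isolates)),
               position = pos, ref = ref, alt = alt,
               stringsAsFactors = FALSE)
  })
}
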