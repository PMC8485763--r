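#' Call base substitutions between a reference and an isolate sequence
#'
#' Compares two pre-aligned, ungapped sequences position by position and
#' emits one call per mismatch.  Positions where either sequence carries an
#' ambiguous base (anything other than A, C, G, T) are skipped.
#'
#' @param ref_seq,isolate_seq character strings (or objects coercible with
#'   `as.character`) of equal length; case-insensitive.
#' @param offset 1-based gene coordinate of the first aligned base.
#' @param isolate isolate identifier recorded in the calls.
#' @return data frame with columns `isolate`, `position`, `ref`, `alt`.
#' @export
call_substitutions <- function(ref_seq, isolate_seq, offset = 1L,
                               isolate = "isolate") {
  r <- toupper(as.character(ref_seq))
  s <- toupper(as.character(isolate_seq))
  if (length(r) != 1L || length(s) != 1L)
    stop("supply a single reference and a single isolate sequence")
  rb <- strsplit(r, "")[[1L]]
  sb <- strsplit(s, "")[[1L]]
  if (length(rb) != length(sb))
    stop("reference and isolate sequences must have equal length")
  ok <- rb %in% c("A", "C", "G", "T") & sb %in% c("A", "C", "G", "T")
  hit <- which(ok & rb != sb)
  data.frame(isolate = rep(isolate, length(hit)),
             position = as.integer(offset) + hit - 1L,
             ref = rb[hit], alt = sb[hit], stringsAsFactors = FALSE)
}

#' Classify base substitutions into the six base-pair classes
#'
#' A substitution is recorded on one strand but expressed as a base-*pair*
#' change by Watson--Crick complementation: a change at a G or T reference
#' is collapsed onto its complement, so e.g. G>A and C>T are the same class
#' (`CG>TA`).  Transitions are `CG>TA` and `AT>GC`; the other four classes
#' are transversions.
#'
#' @param ref,alt vectors of single uppercase bases (A/C/G/T), `alt != ref`.
#' @return data frame with columns `class` (one of
#'   `CG>GC, CG>AT, CG>TA, AT>TA, AT>CG, AT>GC`) and `type`
#'   (`"transition"` or `"transversion"`).
#' @export
classify_substitution <- function(ref, alt) {
  ref <- toupper(as.character(ref)); alt <- toupper(as.character(alt))
  if (length(ref) != length(alt)) stop("`ref` and `alt` lengths differ")
  bad <- !(ref %in% c("A", "C", "G", "T")) | !(alt %in% c("A", "C", "G", "T"))
  if (any(bad)) stop("non-canonical base in substitution call")
  if (any(ref == alt)) stop("`alt` must differ from `ref`")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  flip <- ref %in% c("G", "T")
  r <- ifelse(flip, comp[ref], ref)
  a <- ifelse(flip, comp[alt], alt)
  pair <- c(A = "AT", C = "CG")
  cls <- paste0(pair[r], ">", a, comp[a])
  if (!all(cls %in% SUB_CLASSES)) stop("internal: unknown class")  # nocov
  data.frame(class = cls,
             type = ifelse(cls %in% TRANSITION_CLASSES,
                           "transition", "transversion"),
             stringsAsFactors = FALSE)
}

#' Restrict substitution calls to the reporting window
#'
#' Keeps calls with `lo <= position <= hi` (closed interval, 1-based).  The
#' default window is the sequenced rifampicin-resistance-determining region
#' of *rpoB*.
#'
#' @param calls data frame with a `position` column.
#' @param lo,hi window bounds.
#' @return the filtered data frame.
#' @export
filter_window <- function(calls, lo = 1516L, hi = 1717L) {
  if (lo > hi) stop("`lo` must be <= `hi`")
  calls[calls$position >= lo & calls$position <= hi, , drop = FALSE]
}

#' Tabulate a base-substitution spectrum
#'
#' Counts window-filtered substitution calls by base-pair class and by
#' position, and derives totals, transition/transversion splits, and
#' percentages of the total.
#'
#' @param calls data frame with columns `position`, `ref`, `alt` (e.g. from
#'   [call_substitutions()] or [simulate_substitution_calls()]).
#' @return an object of class `spectrum_table`: a list with `counts` (named
#'   by the six classes), `total`, `transitions`, `transversions`,
#'   `percents` (per class; `NA` when the table is empty),
#'   `percent_transitions`, `percent_transversions`, and `per_position`
#'   (long data frame position/class/count).
#' @export
tabulate_spectrum <- function(calls) {
  if (!all(c("position", "ref", "alt") %in% names(calls)))
    stop("`calls` needs columns position, ref, alt")
  n <- nrow(calls)
  if (n) {
    cls <- classify_substitution(calls$ref, calls$alt)$class
    counts <- table(factor(cls, levels = SUB_CLASSES))
    counts <- setNames(as.integer(counts), SUB_CLASSES)
    pp <- as.data.frame(table(position = calls$position,
                              class = factor(cls, levels = SUB_CLASSES)),
                        stringsAsFactors = FALSE)
    pp <- pp[pp$Freq > 0, ]
    per_position <- data.frame(position = as.integer(pp$position),
                               class = pp$class, count = pp$Freq,
                               stringsAsFactors = FALSE)
    per_position <- per_position[order(per_position$position), ]
    rownames(per_position) <- NULL
  } else {
    counts <- setNames(integer(6L), SUB_CLASSES)
    per_position <- data.frame(position = integer(), class = character(),
                               count = integer(), stringsAsFactors = FALSE)
  }
  transitions <- sum(counts[TRANSITION_CLASSES])
  total <- sum(counts)
  percents <- if (total > 0) 100 * counts / total else
    setNames(rep(NA_real_, 6L), SUB_CLASSES)
  structure(list(counts = counts, total = total,
                 transitions = transitions,
                 transversions = total - transitions,
                 percents = percents,
                 percent_transitions =
                   if (total > 0) 100 * transitions / total else NA_real_,
                 percent_transversions =
                   if (total > 0) 100 * (total - transitions) / total
                   else NA_real_,
                 per_position = per_position),
            class = "spectrum_table")
}

#' @export
print.spectrum_table <- function(x, ...) {
  cat("Base-pair substitution spectrum\n")
  fmt <- function(k, p) if (is.na(p)) sprintf("%d", k)
                        else sprintf("%d (%.1f%%)", k, p)
  for (cl in SUB_CLASSES)
    cat(sprintf("  %-6s %s\n", cl, fmt(x$counts[[cl]], x$percents[[cl]])))
  cat(sprintf("  %-6s %s\n", "Ts", fmt(x$transitions, x$percent_transitions)))
  cat(sprintf("  %-6s %s\n", "Tv", fmt(x$transversions,
                                       x$percent_transversions)))
  cat(sprintf("  Total  %d\n", x$total))
  invisible(x)
}

#' Mutational hotspots of a spectrum
#'
#' Positions carrying at least `min_fraction` of all calls, ordered by
#' descending count then ascending position.
#'
#' @param table a [tabulate_spectrum()] result.
#' @param min_fraction threshold in `(0, 1]`.
#' @return integer vector of hotspot positions (possibly empty).
#' @export
find_hotspots <- function(table, min_fraction = 0.05) {
  stopifnot(inherits(table, "spectrum_table"))
  if (!is.numeric(min_fraction) || min_fraction <= 0 || min_fraction > 1)
    stop("`min_fraction` must be in (0, 1]")
  if (table$total == 0L) return(integer())
  tot <- rowsum(table$per_position$count, table$per_position$position)
  pos <- as.integer(rownames(tot)); cnt <- as.vector(tot)
  keep <- cnt >= min_fraction * table$total
  pos[keep][order(-cnt[keep], pos[keep])]
}

#' Monte-Carlo comparison of two substitution spectra
#'
#' Contingency test of the six-class counts of two spectra with a simulated
#' null distribution (useful when counts are small).  This is auxiliary
#' plumbing for exploratory comparison, not part of the core reporting.
#'
#' @param t1,t2 [tabulate_spectrum()] results.
#' @param B number of Monte-Carlo replicates.
#' @return an `htest` object.
#' @export
spectrum_compare <- function(t1, t2, B = 2000L) {
  stopifnot(inherits(t1, "spectrum_table"), inherits(t2, "spectrum_table"))
  m <- rbind(t1$counts, t2$counts)
  keep <- colSums(m) > 0
  chisq.test(m[, keep, drop = FALSE], simulate.p.value = TRUE, B = B)
}
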