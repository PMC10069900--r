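#' Windowed read coverage of a compartment
#'
#' Counts reads by leftmost aligned position into windows tiling
#' `[0, compartment length)` (the last, possibly partial window is kept and
#' flagged), then normalises to CPM — counts per million mapped reads. By
#' default the CPM denominator is all reads assigned to the nuclear +
#' mitochondrial compartments after plastid exclusion; `"all"` uses every
#' input read and `"nuclear"` only the nuclear-assigned ones. Counting by
#' leftmost position (rather than by overlap) makes window counts sum exactly
#' to the compartment's assigned reads, which every downstream ratio relies
#' on.
#'
#' @param aln An `alignment_set`.
#' @param compartment Compartment to window.
#' @param window_bp Window width (bp), default 500.
#' @param step_bp Window step; the default (`= window_bp`) tiles the
#'   compartment, smaller values give sliding windows.
#' @param cpm_denominator One of `"assigned"`, `"all"`, `"nuclear"`.
#' @return A `window_coverage` data.frame: `compartment`, `start`, `end`
#'   (0-based half-open), `raw`, `cpm`, `partial`; the CPM denominator is
#'   kept as an attribute.
#' @export
window_coverage <- function(aln, compartment, window_bp = 500L,
                            step_bp = window_bp,
                            cpm_denominator = c("assigned", "all", "nuclear")) {
  stopifnot(inherits(aln, "alignment_set"))
  cpm_denominator <- match.arg(cpm_denominator)
  ref_len <- attr(aln, "ref_lengths")
  if (!compartment %in% names(ref_len))
    stopf("unknown compartment '%s'", compartment)
  if (window_bp <= 0) stopf("window_bp must be positive")
  if (step_bp > window_bp || step_bp <= 0)
    stopf("step_bp must lie in (0, window_bp]")
  L <- ref_len[[compartment]]

  denom <- switch(cpm_denominator,
    assigned = sum(aln$compartment %in% c("nuclear", "mitochondrial")),
    all = nrow(aln),
    nuclear = sum(aln$compartment == "nuclear"))

  starts <- seq(0L, L - 1L, by = step_bp)
  ends <- pmin(starts + window_bp, L)
  pos <- sort(aln$pos[aln$compartment == compartment])
  # half-open interval counts from the sorted position vector
  raw <- findInterval(ends - 1L, pos, left.open = FALSE) -
    findInterval(starts - 1L, pos, left.open = FALSE)
  cpm <- if (denom > 0) raw * 1e6 / denom else rep(0, length(raw))
  structure(data.frame(compartment = compartment, start = starts, end = ends,
                       raw = raw, cpm = cpm, partial = (ends - starts) < window_bp,
                       stringsAsFactors = FALSE),
            class = c("window_coverage", "data.frame"),
            cpm_denominator = cpm_denominator, denom_reads = denom,
            window_bp = as.integer(window_bp), step_bp = as.integer(step_bp))
}

#' Windowed coverage of a sample relative to a reference sample
#'
#' Computes `rel = (cpm_sample + p) / (cpm_reference + p)` per window, where
#' `p` is a pseudocount of `pseudocount` reads converted to each sample's own
#' CPM scale. The pseudocount keeps ratios defined over zero-coverage
#' reference windows; a sample relative to itself is exactly 1 everywhere.
#'
#' @param sample,reference [window_coverage()] results on identical grids.
#' @param pseudocount Pseudocount in read units (default 0.5).
#' @return The `sample` windows with an added `rel` column.
#' @export
relative_coverage <- function(sample, reference, pseudocount = 0.5) {
  stopifnot(inherits(sample, "window_coverage"),
            inherits(reference, "window_coverage"))
  if (nrow(sample) != nrow(reference) ||
      any(sample$start != reference$start) ||
      any(sample$end != reference$end) ||
      sample$compartment[1] != reference$compartment[1])
    stopf("sample and reference window grids differ")
  ps <- pseudocount * 1e6 / max(attr(sample, "denom_reads"), 1)
  pr <- pseudocount * 1e6 / max(attr(reference, "denom_reads"), 1)
  out <- sample
  out$rel <- (sample$cpm + ps) / (reference$cpm + pr)
  out
}

#' Estimate organelle genome copies per cell from read depth
#'
#' The per-cell copy number of a region is its length-normalised read depth
#' over the length-normalised nuclear depth, scaled by the nuclear copies per
#' cell:
#' `copies = (reads_region / length_region) / (reads_nuclear / length_nuclear)
#'  * nuclear_copies_per_cell`.
#' `nuclear_copies_per_cell` defaults to 2 (a 2C diploid cell) and accepts a
#' measured mean C-value so endoreduplicating tissue can be put on a true
#' per-cell scale.
#'
#' @param aln An `alignment_set`.
#' @param region A compartment name, or `list(compartment =, start =, end =)`
#'   with a 0-based half-open interval.
#' @param nuclear_copies_per_cell Nuclear genome copies per cell.
#' @param reference Optional `copy_number_estimate` of a reference sample;
#'   when given, `rel_to_reference = copies / reference copies` is added
#'   (reference vs itself is exactly 1).
#' @return A `copy_number_estimate`.
#' @export
estimate_copy_number <- function(aln, region = "mitochondrial",
                                 nuclear_copies_per_cell = 2,
                                 reference = NULL) {
  stopifnot(inherits(aln, "alignment_set"))
  ref_len <- attr(aln, "ref_lengths")
  reads_nuclear <- sum(aln$compartment == "nuclear")
  if (reads_nuclear == 0) stopf("nuclear depth zero")
  if (is.character(region)) {
    if (!region %in% names(ref_len)) stopf("unknown compartment '%s'", region)
    reads_region <- sum(aln$compartment == region)
    len_region <- ref_len[[region]]
    region_label <- region
  } else {
    comp <- region$compartment
    if (!comp %in% names(ref_len)) stopf("unknown compartment '%s'", comp)
    reads_region <- sum(aln$compartment == comp & aln$pos >= region$start &
                          aln$pos < region$end)
    len_region <- region$end - region$start
    region_label <- sprintf("%s:%d-%d", comp, region$start, region$end)
  }
  copies <- (reads_region / len_region) /
    (reads_nuclear / ref_len[["nuclear"]]) * nuclear_copies_per_cell
  out <- structure(list(region = region_label, reads_region = reads_region,
                        reads_nuclear = reads_nuclear,
                        length_region = len_region,
                        length_nuclear = ref_len[["nuclear"]],
                        nuclear_copies_per_cell = nuclear_copies_per_cell,
                        copies_per_cell = copies,
                        rel_to_reference = NA_real_),
                   class = "copy_number_estimate")
  if (!is.null(reference)) {
    stopifnot(inherits(reference, "copy_number_estimate"))
    out$rel_to_reference <- copies / reference$copies_per_cell
  }
  out
}

#' @export
print.copy_number_estimate <- function(x, ...) {
  cat(sprintf("Copy number estimate for %s\n", x$region))
  cat(sprintf("  reads: %d region / %d nuclear; lengths: %d / %d bp\n",
              x$reads_region, x$reads_nuclear, x$length_region,
              x$length_nuclear))
  cat(sprintf("  copies per cell: %.3f (nuclear = %.3g)\n",
              x$copies_per_cell, x$nuclear_copies_per_cell))
  if (!is.na(x$rel_to_reference))
    cat(sprintf("  relative to reference: %.3f\n", x$rel_to_reference))
  invisible(x)
}

# Exhaustive run scan used by call_deletions: indices of low windows are
# grouped into runs separated by at most max_gap high windows.
low_runs <- function(low_idx, min_windows, max_gap) {
  if (length(low_idx) == 0L) return(list())
  breaks <- which(diff(low_idx) > max_gap + 1L)
  grp <- cumsum(c(1L, seq_along(low_idx)[-1] %in% (breaks + 1L)))
  runs <- split(low_idx, grp)
  Filter(function(r) length(r) >= min_windows, runs)
}

#' Call deletions from relative windowed coverage
#'
#' Flags maximal runs of windows whose coverage relative to the reference
#' sample falls below `rel_threshold`, allowing up to `max_gap_windows`
#' interspersed high windows and requiring at least `min_windows` low
#' windows. The default threshold of 0.2 sits between the residual coverage
#' a NUMT leaves over a truly deleted region (a few percent of wild type) and
#' ordinary biological copy-number variation (roughly 0.5–3 fold). On
#' circular compartments a run may wrap the origin and is flagged.
#'
#' @param rel_windows A [relative_coverage()] result.
#' @param rel_threshold Windows with `rel` below this are low.
#' @param min_windows Minimum low windows per call.
#' @param max_gap_windows High windows tolerated inside a call.
#' @param circular Treat the compartment as circular.
#' @return A `deletion_calls` data.frame: `compartment`, `start`, `end`
#'   (0-based half-open), `length_bp`, `n_windows`, `mean_rel`, `wrapped`.
#' @export
call_deletions <- function(rel_windows, rel_threshold = 0.2,
                           min_windows = 3L, max_gap_windows = 1L,
                           circular = FALSE) {
  if (is.null(rel_windows$rel)) stopf("windows carry no 'rel' column")
  n <- nrow(rel_windows)
  low <- which(rel_windows$rel < rel_threshold)
  runs <- low_runs(low, min_windows, max_gap_windows)

  wrapped <- logical(length(runs))
  if (circular && length(runs) >= 2L) {
    first <- runs[[1]]; last <- runs[[length(runs)]]
    # merge across the origin when the terminal runs nearly touch it
    if (first[1] <= max_gap_windows + 1L &&
        last[length(last)] >= n - max_gap_windows) {
      runs[[1]] <- c(last, first)
      runs <- runs[-length(runs)]
      wrapped <- c(TRUE, logical(length(runs) - 1L))
    }
  }

  calls <- lapply(seq_along(runs), function(i) {
    r <- runs[[i]]
    span <- min(r):max(r)
    data.frame(compartment = rel_windows$compartment[1],
               start = rel_windows$start[min(r)],
               end = rel_windows$end[max(r)],
               length_bp = rel_windows$end[max(r)] - rel_windows$start[min(r)],
               n_windows = length(span),
               mean_rel = mean(rel_windows$rel[span]),
               wrapped = wrapped[i],
               stringsAsFactors = FALSE)
  })
  out <- if (length(calls)) do.call(rbind, calls) else
    data.frame(compartment = character(0), start = integer(0),
               end = integer(0), length_bp = integer(0),
               n_windows = integer(0), mean_rel = numeric(0),
               wrapped = logical(0), stringsAsFactors = FALSE)
  structure(out, class = c("deletion_calls", "data.frame"),
            rel_threshold = rel_threshold, min_windows = min_windows,
            max_gap_windows = max_gap_windows)
}

#' Write deletion calls as BED
#'
#' 0-based half-open intervals, one line per call, score = mean relative
#' coverage inside the call.
#'
#' @param calls A [call_deletions()] result.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_deletions_bed <- function(calls, path) {
  df <- data.frame(chrom = calls$compartment, start = calls$start,
                   end = calls$end,
                   name = sprintf("del%d", seq_len(nrow(calls))),
                   score = signif(calls$mean_rel, 4),
                   strand = ".")
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
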