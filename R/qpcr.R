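#' Simulate a qPCR Ct table from known relative quantities
#'
#' Generates cycle-threshold records for a target gene normalised against a
#' nuclear control gene. Under amplification efficiency `E`, a template
#' quantity `q` crosses threshold at `Ct = Ct0 - log_E(q) + noise`, so the
#' delta-Ct machinery downstream recovers the planted quantities exactly when
#' `ct_noise_sd = 0`.
#'
#' @param truth Data.frame with `sample_id`, `group`, `quantity` (relative
#'   target quantity, > 0) and optionally `target`, `control_quantity`
#'   (default 1).
#' @param efficiency Amplification efficiency per cycle (default 2, perfect
#'   doubling).
#' @param ct_noise_sd SD of independent Gaussian noise added to each Ct.
#' @param ct0_target,ct0_control Baseline cycle thresholds at quantity 1.
#' @param target,control Gene labels for the output table.
#' @param seed Integer seed.
#' @return A data.frame of Ct records: `sample_id`, `group`, `target`,
#'   `control`, `ct_target`, `ct_control`.
#' @export
simulate_ct <- function(truth, efficiency = 2, ct_noise_sd = 0,
                        ct0_target = 24, ct0_control = 20,
                        target = "mt_gene", control = "TUA6", seed) {
  stopifnot(is.data.frame(truth), all(c("sample_id", "group", "quantity")
                                      %in% names(truth)))
  if (any(truth$quantity <= 0)) stopf("quantities must be positive")
  if (efficiency <= 1) stopf("efficiency must exceed 1")
  cq <- truth$control_quantity %||% rep(1, nrow(truth))
  if (any(cq <= 0)) stopf("control quantities must be positive")
  with_seed(seed, {
    n <- nrow(truth)
    data.frame(
      sample_id = truth$sample_id,
      group = truth$group,
      target = if (!is.null(truth$target)) truth$target else target,
      control = control,
      ct_target = ct0_target - log(truth$quantity) / log(efficiency) +
        stats::rnorm(n, 0, ct_noise_sd),
      ct_control = ct0_control - log(cq) / log(efficiency) +
        stats::rnorm(n, 0, ct_noise_sd),
      stringsAsFactors = FALSE)
  })
}

#' Per-record delta-Ct
#'
#' `delta_ct = ct_target - ct_control`; records with a missing Ct are
#' excluded with a message rather than propagated.
#'
#' @param records Ct table as produced by [simulate_ct()] (columns
#'   `ct_target`, `ct_control`).
#' @return The records with a `delta_ct` column; excluded-row count kept as
#'   attribute `n_excluded`.
#' @export
delta_ct <- function(records) {
  stopifnot(all(c("ct_target", "ct_control") %in% names(records)))
  bad <- is.na(records$ct_target) | is.na(records$ct_control)
  if (any(bad))
    message(sum(bad), " record(s) with missing Ct excluded")
  out <- records[!bad, , drop = FALSE]
  out$delta_ct <- out$ct_target - out$ct_control
  attr(out, "n_excluded") <- sum(bad)
  out
}

#' Relative quantification against a reference group
#'
#' Classic delta-delta-Ct: per target,
#' `rel = efficiency^-(delta_ct - mean(delta_ct of the reference group))`.
#' Centering on the arithmetic mean of the reference delta-Ct makes the
#' reference group's *geometric* mean fold change exactly 1. Technical
#' replicates (duplicate `sample_id` x `target` rows) are averaged on the Ct
#' scale before the delta is taken; biological replicates stay separate.
#'
#' @param records Ct table (columns `sample_id`, `group`, `target`,
#'   `ct_target`, `ct_control`).
#' @param reference_group Group label normalised to 1.
#' @param efficiency Amplification efficiency (default 2).
#' @return A `relative_quant` data.frame (`sample_id`, `group`, `target`,
#'   `delta_ct`, `rel`) with a per-group-x-target summary (mean, sd — `NA`
#'   when n = 1 — and n) as attribute `summary`.
#' @export
relative_quant <- function(records, reference_group, efficiency = 2) {
  records <- delta_ct(records)
  if (!reference_group %in% records$group)
    stopf("unknown reference group '%s'", reference_group)
  # average technical replicates on the Ct scale
  agg <- stats::aggregate(delta_ct ~ sample_id + group + target,
                          data = records, FUN = mean)
  out <- do.call(rbind, lapply(split(agg, agg$target), function(d) {
    ref <- d$delta_ct[d$group == reference_group]
    if (length(ref) == 0L)
      stopf("reference group has no records for target '%s'", d$target[1])
    d$rel <- efficiency^(-(d$delta_ct - mean(ref)))
    d
  }))
  rownames(out) <- NULL
  summ <- do.call(rbind, lapply(split(out, list(out$group, out$target),
                                      drop = TRUE), function(d) {
    data.frame(group = d$group[1], target = d$target[1],
               mean_rel = mean(d$rel),
               sd_rel = if (nrow(d) > 1) stats::sd(d$rel) else NA_real_,
               n = nrow(d), stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  structure(out, class = c("relative_quant", "data.frame"),
            summary = summ, reference_group = reference_group,
            efficiency = efficiency)
}

#' @export
print.relative_quant <- function(x, ...) {
  cat("Relative quantification (reference group: ",
      attr(x, "reference_group"), ", efficiency ", attr(x, "efficiency"),
      ")\n", sep = "")
  print(attr(x, "summary"), row.names = FALSE)
  invisible(x)
}

#' Two-group comparison of relative quantities
#'
#' Welch's two-sided t test on the per-sample relative values of two groups.
#' When both groups are constant and identical the comparison degenerates to
#' statistic 0 and p = 1.
#'
#' @param rel A [relative_quant()] result.
#' @param groupA,groupB Group labels.
#' @param target Restrict to one target (required when several are present).
#' @return List with `statistic`, `p.value`, `df`, the group means and n.
#' @export
compare_groups <- function(rel, groupA, groupB, target = NULL) {
  d <- rel
  if (!is.null(target)) d <- d[d$target == target, , drop = FALSE]
  if (length(unique(d$target)) > 1L)
    stopf("several targets present; pick one with 'target ='")
  a <- d$rel[d$group == groupA]
  b <- d$rel[d$group == groupB]
  if (length(a) < 2L || length(b) < 2L)
    stopf("each group needs at least 2 samples")
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    same <- isTRUE(all.equal(mean(a), mean(b)))
    return(list(statistic = if (same) 0 else Inf,
                p.value = if (same) 1 else 0,
                df = NA_real_, mean_A = mean(a), mean_B = mean(b),
                n_A = length(a), n_B = length(b)))
  }
  tt <- stats::t.test(a, b, var.equal = FALSE)
  list(statistic = unname(tt$statistic), p.value = tt$p.value,
       df = unname(tt$parameter), mean_A = mean(a), mean_B = mean(b),
       n_A = length(a), n_B = length(b))
}
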