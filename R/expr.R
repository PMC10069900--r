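#' Partition genes into induced / suppressed / null
#'
#' A gene is *induced* when `log2fc > lfc_threshold` and
#' `fdr < fdr_threshold`, *suppressed* when `log2fc < -lfc_threshold` and
#' `fdr < fdr_threshold`, otherwise *null*. All inequalities are strict, so a
#' gene sitting exactly on a threshold is null. Records with a missing FDR
#' are excluded with a message.
#'
#' @param table DEG table with `gene_id`, `log2fc`, `fdr` (and optionally
#'   `genome`).
#' @param lfc_threshold,fdr_threshold Thresholds (defaults 1 and 0.05).
#' @return The table with a `status` column; excluded-row count in attribute
#'   `n_excluded`.
#' @export
filter_degs <- function(table, lfc_threshold = 1, fdr_threshold = 0.05) {
  stopifnot(all(c("gene_id", "log2fc", "fdr") %in% names(table)))
  bad <- is.na(table$fdr) | is.na(table$log2fc)
  if (any(bad))
    message(sum(bad), " record(s) with missing log2fc/fdr excluded")
  out <- table[!bad, , drop = FALSE]
  out$status <- "null"
  out$status[out$log2fc > lfc_threshold & out$fdr < fdr_threshold] <- "induced"
  out$status[out$log2fc < -lfc_threshold & out$fdr < fdr_threshold] <-
    "suppressed"
  attr(out, "n_excluded") <- sum(bad)
  attr(out, "lfc_threshold") <- lfc_threshold
  attr(out, "fdr_threshold") <- fdr_threshold
  out
}

#' DEG proportions stratified by encoding genome
#'
#' For each genome (and a pooled `total` row), the number and proportion of
#' induced and suppressed genes among all genes annotated to that genome.
#' The denominator is the full supplied table — every annotated gene —
#' so restrict the input first if a protein-coding-only denominator is
#' wanted.
#'
#' @param partition A [filter_degs()] result.
#' @param genome_map Named character vector `gene_id -> genome`; omit when
#'   the table already has a `genome` column.
#' @return A `genome_deg_proportions` data.frame with `genome`, `n_total`,
#'   `n_induced`, `n_suppressed`, `prop_induced`, `prop_suppressed`.
#' @export
genome_proportions <- function(partition, genome_map = NULL) {
  stopifnot(!is.null(partition$status))
  if (is.null(partition$genome)) {
    if (is.null(genome_map)) stopf("no 'genome' column and no genome_map")
    unmapped <- setdiff(partition$gene_id, names(genome_map))
    if (length(unmapped))
      stopf("gene(s) not mapped to a genome: %s",
            paste(utils::head(unmapped, 10), collapse = ", "))
    partition$genome <- unname(genome_map[partition$gene_id])
  }
  one <- function(d, label = "x") {
    data.frame(genome = label, n_total = nrow(d),
               n_induced = sum(d$status == "induced"),
               n_suppressed = sum(d$status == "suppressed"),
               prop_induced = sum(d$status == "induced") / nrow(d),
               prop_suppressed = sum(d$status == "suppressed") / nrow(d),
               stringsAsFactors = FALSE)
  }
  parts <- split(partition, partition$genome)
  out <- do.call(rbind, Map(one, parts, names(parts)))
  out <- rbind(out, one(partition, "total"))
  rownames(out) <- NULL
  structure(out, class = c("genome_deg_proportions", "data.frame"))
}

#' Fisher exact contrast of DEG proportions between two genomes
#'
#' Two-sided Fisher exact test on the 2x2 table
#' `[[A_dir, A_total - A_dir], [B_dir, B_total - B_dir]]`, where `dir` counts
#' the induced (or suppressed) genes of each genome.
#'
#' @param props A [genome_proportions()] result.
#' @param genomeA,genomeB Genome labels to contrast.
#' @param direction `"induced"` or `"suppressed"`.
#' @return List with `p.value`, `odds_ratio`, the 2x2 `table`, `genomes` and
#'   `direction`.
#' @export
fisher_contrast <- function(props, genomeA, genomeB,
                            direction = c("induced", "suppressed")) {
  direction <- match.arg(direction)
  row_of <- function(g) {
    r <- props[props$genome == g, , drop = FALSE]
    if (nrow(r) != 1L) stopf("genome '%s' not in proportions table", g)
    if (r$n_total == 0L) stopf("genome '%s' has zero total genes", g)
    r
  }
  a <- row_of(genomeA); b <- row_of(genomeB)
  col <- paste0("n_", direction)
  tab <- matrix(c(a[[col]], a$n_total - a[[col]],
                  b[[col]], b$n_total - b[[col]]),
                nrow = 2, byrow = TRUE,
                dimnames = list(c(genomeA, genomeB), c(direction, "rest")))
  ft <- stats::fisher.test(tab, alternative = "two.sided")
  list(p.value = ft$p.value, odds_ratio = unname(ft$estimate), table = tab,
       genomes = c(genomeA, genomeB), direction = direction)
}

# DESeq-style median-of-ratios size factors.
size_factors <- function(counts) {
  lg <- rowMeans(log(counts))
  ok <- is.finite(lg)
  if (!any(ok)) return(rep(1, ncol(counts)))
  apply(counts, 2, function(cj) {
    s <- stats::median((log(cj) - lg)[ok & cj > 0])
    if (is.finite(s)) exp(s) else 1
  })
}

#' Stand-in differential-expression caller for synthetic counts
#'
#' A deliberately simple DEG caller used to make synthetic end-to-end tests
#' self-contained: median-of-ratios size factors, log2 fold change from
#' normalised group means with a pseudocount of 1, a per-gene moderated t
#' test on `log2(normalised + 1)` and Benjamini-Hochberg FDR. Per-gene
#' variances are shrunk toward the genome-wide trend with
#' [limma::squeezeVar()] — at the 3-replicate designs this caller targets,
#' raw per-gene variances are far too noisy for a plain t test to retain
#' power after FDR adjustment. It is **not** a substitute for a dedicated
#' negative-binomial framework on real data — pipelines on real experiments
#' should ingest an externally produced DEG table instead.
#'
#' @param counts Integer matrix, genes x samples.
#' @param groupA,groupB Column names or indices of the two groups (at least
#'   2 replicates each); fold changes are B over A.
#' @return A DEG table: `gene_id`, `log2fc`, `pvalue`, `fdr`.
#' @export
call_degs_standin <- function(counts, groupA, groupB) {
  a <- counts[, groupA, drop = FALSE]
  b <- counts[, groupB, drop = FALSE]
  if (ncol(a) < 2L || ncol(b) < 2L)
    stopf("each group needs at least 2 replicates")
  all_ <- cbind(a, b)
  sf <- size_factors(all_)
  norm <- sweep(all_, 2, sf, `/`)
  na <- ncol(a)
  normA <- norm[, seq_len(na), drop = FALSE]
  normB <- norm[, na + seq_len(ncol(b)), drop = FALSE]

  log2fc <- log2((rowMeans(normB) + 1) / (rowMeans(normA) + 1))

  la <- log2(normA + 1); lb <- log2(normB + 1)
  ma <- rowMeans(la); mb <- rowMeans(lb)
  va <- apply(la, 1, stats::var); vb <- apply(lb, 1, stats::var)
  nA <- ncol(la); nB <- ncol(lb)
  df_resid <- nA + nB - 2
  s2 <- ((nA - 1) * va + (nB - 1) * vb) / df_resid
  # all-zero or otherwise constant genes have zero sample variance; limma
  # offsets these internally, no need to warn about it here
  sq <- suppressWarnings(limma::squeezeVar(s2, df = df_resid))
  se2 <- sq$var.post * (1 / nA + 1 / nB)
  tstat <- ifelse(se2 > 0, (mb - ma) / sqrt(se2), 0)
  df_total <- sq$df.prior + df_resid
  if (!is.finite(df_total)) df_total <- 1e6
  p <- ifelse(se2 > 0, 2 * stats::pt(-abs(tstat), df_total), 1)

  zero <- rowSums(all_) == 0
  log2fc[zero] <- 0
  p[zero] <- 1
  fdr <- stats::p.adjust(p, method = "BH")
  data.frame(gene_id = rownames(counts) %||% sprintf("g%d", seq_len(nrow(counts))),
             log2fc = log2fc, pvalue = p, fdr = fdr,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Association between copy number and expression (or phenotype)
#'
#' Pearson product-moment correlation with the usual two-sided t transform on
#' `n - 2` degrees of freedom. Incomplete pairs are dropped and counted; a
#' zero-variance margin yields `r = NA` rather than an error.
#'
#' @param x,y Paired observations (e.g. per-gene relative copy number and
#'   relative transcript abundance).
#' @param labels Optional per-pair labels carried into the result.
#' @return An `association_result`: `r`, `n`, `p.value`, `n_dropped`.
#' @export
associate <- function(x, y, labels = NULL) {
  if (length(x) != length(y)) stopf("x and y differ in length")
  ok <- is.finite(x) & is.finite(y)
  n_dropped <- sum(!ok)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stopf("need at least 3 complete pairs")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    res <- list(r = NA_real_, n = length(x), p.value = NA_real_,
                n_dropped = n_dropped, note = "zero variance")
  } else {
    ct <- stats::cor.test(x, y, method = "pearson")
    res <- list(r = unname(ct$estimate), n = length(x),
                p.value = ct$p.value, n_dropped = n_dropped, note = NULL)
  }
  if (!is.null(labels)) res$labels <- labels[ok]
  structure(res, class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  if (is.na(x$r)) {
    cat("Pearson association: r not available (", x$note, "), n = ", x$n,
        "\n", sep = "")
  } else {
    cat(sprintf("Pearson association: r = %.3f, n = %d, p = %.3g\n",
                x$r, x$n, x$p.value))
  }
  if (x$n_dropped > 0) cat("  (", x$n_dropped, "incomplete pairs dropped)\n")
  invisible(x)
}
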