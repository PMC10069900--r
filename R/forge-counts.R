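#' Configuration for the RNA-seq count simulator
#'
#' Negative-binomial counts for genes encoded on the three genomes, with a
#' genome-level induction (and optionally suppression) effect: a fixed
#' fraction of each genome's genes — `floor(fraction * n_genes)` of them —
#' receives a log2 fold change drawn from a normal distribution in the
#' treated condition. The defaults emulate a mitochondrial-genome-wide
#' induction (80% of 30 mitochondrial genes at log2FC around 1.5) against a
#' quiet nuclear background, the structure the genome-stratified DEG
#' statistics are designed to detect.
#'
#' @param n_genes Named integer vector of genes per genome.
#' @param meanlog,sdlog Log-normal baseline mean expression parameters.
#' @param dispersion NB dispersion (size = 1/dispersion); scalar or
#'   per-gene vector.
#' @param induced_fraction,suppressed_fraction Named fractions in `[0, 1]`
#'   per genome.
#' @param effect_log2fc_mean,effect_log2fc_sd Normal distribution of planted
#'   |log2FC|; suppressed genes get the negated draw.
#' @param n_replicates Replicates per condition.
#' @param lib_factors Library-size factors, length `2 * n_replicates`
#'   (control then treated); default all 1.
#' @return An `expr_sim_config`.
#' @export
expr_sim_config <- function(n_genes = c(nuclear = 200L, mitochondrial = 30L,
                                        plastid = 20L),
                            meanlog = 4, sdlog = 1, dispersion = 0.05,
                            induced_fraction = c(nuclear = 0,
                                                 mitochondrial = 0.8,
                                                 plastid = 0),
                            suppressed_fraction = c(nuclear = 0,
                                                    mitochondrial = 0,
                                                    plastid = 0),
                            effect_log2fc_mean = 1.5,
                            effect_log2fc_sd = 0.3,
                            n_replicates = 3L,
                            lib_factors = NULL) {
  genomes <- names(n_genes)
  if (is.null(genomes) || !all(genomes %in% COMPARTMENTS))
    stopf("n_genes must be named with genomes: %s",
          paste(COMPARTMENTS, collapse = ", "))
  if (any(induced_fraction < 0 | induced_fraction > 1) ||
      any(suppressed_fraction < 0 | suppressed_fraction > 1))
    stopf("fractions must lie in [0, 1]")
  if (any(induced_fraction[genomes] + suppressed_fraction[genomes] > 1))
    stopf("induced + suppressed fractions exceed 1 for some genome")
  if (any(dispersion <= 0)) stopf("dispersion must be positive")
  if (!is_count(n_replicates) || n_replicates < 1)
    stopf("n_replicates must be a positive integer")
  lib_factors <- lib_factors %||% rep(1, 2L * n_replicates)
  if (length(lib_factors) != 2L * n_replicates || any(lib_factors <= 0))
    stopf("lib_factors must be %d positive values", 2L * n_replicates)
  structure(list(n_genes = n_genes, meanlog = meanlog, sdlog = sdlog,
                 dispersion = dispersion,
                 induced_fraction = induced_fraction,
                 suppressed_fraction = suppressed_fraction,
                 effect_log2fc_mean = effect_log2fc_mean,
                 effect_log2fc_sd = effect_log2fc_sd,
                 n_replicates = as.integer(n_replicates),
                 lib_factors = lib_factors),
            class = "expr_sim_config")
}

#' Simulate an RNA-seq count matrix with genome-level effects
#'
#' Counts are drawn as `NB(mean * lib_factor, size = 1/dispersion)`; the
#' treated condition multiplies the baseline mean of each affected gene by
#' `2^log2FC`. The returned truth table records every gene's genome, its true
#' log2 fold change and its planted status.
#'
#' @param cfg An [expr_sim_config()].
#' @param seed Integer seed.
#' @return A `sim_counts` list: `counts` (genes x samples integer matrix),
#'   `truth` (`gene_id`, `genome`, `true_log2fc`, `status`, `base_mean`),
#'   `groups` (condition label per column).
#' @export
simulate_counts <- function(cfg, seed) {
  stopifnot(inherits(cfg, "expr_sim_config"))
  with_seed(seed, {
    prefix <- c(nuclear = "nuc", mitochondrial = "mt", plastid = "pt")
    truth <- do.call(rbind, lapply(names(cfg$n_genes), function(g) {
      n <- cfg$n_genes[[g]]
      if (n == 0L) return(NULL)
      n_ind <- floor(cfg$induced_fraction[[g]] * n)
      n_sup <- floor(cfg$suppressed_fraction[[g]] * n)
      status <- rep("null", n)
      aff <- sample.int(n, n_ind + n_sup)
      status[aff[seq_len(n_ind)]] <- "induced"
      if (n_sup > 0) status[aff[n_ind + seq_len(n_sup)]] <- "suppressed"
      lfc <- numeric(n)
      lfc[status == "induced"] <-
        stats::rnorm(n_ind, cfg$effect_log2fc_mean, cfg$effect_log2fc_sd)
      lfc[status == "suppressed"] <-
        -stats::rnorm(n_sup, cfg$effect_log2fc_mean, cfg$effect_log2fc_sd)
      data.frame(gene_id = sprintf("%s_g%03d", prefix[[g]], seq_len(n)),
                 genome = g, true_log2fc = lfc, status = status,
                 stringsAsFactors = FALSE)
    }))
    ng <- nrow(truth)
    nr <- cfg$n_replicates
    base <- stats::rlnorm(ng, cfg$meanlog, cfg$sdlog)
    truth$base_mean <- base
    mu <- cbind(matrix(base, ng, nr),
                matrix(base * 2^truth$true_log2fc, ng, nr))
    mu <- sweep(mu, 2, cfg$lib_factors, `*`)
    counts <- matrix(stats::rnbinom(ng * 2L * nr, mu = mu,
                                    size = 1 / cfg$dispersion),
                     ng, 2L * nr)
    rownames(counts) <- truth$gene_id
    groups <- rep(c("control", "treated"), each = nr)
    colnames(counts) <- sprintf("%s_%d", groups, c(seq_len(nr), seq_len(nr)))
    structure(list(counts = counts, truth = truth, groups = groups,
                   cfg = cfg, seed = as.integer(seed)),
              class = "sim_counts")
  })
}

#' @export
print.sim_counts <- function(x, ...) {
  cat("Simulated count matrix:", nrow(x$counts), "genes x",
      ncol(x$counts), "samples\n")
  print(table(x$truth$genome, x$truth$status))
  invisible(x)
}
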