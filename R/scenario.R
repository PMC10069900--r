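#' Override a compartment's per-cell copy number
#'
#' Returns a copy of the model whose compartment carries a new copy number;
#' sequences and annotations are untouched. Used to derive, from one set of
#' reference sequences, cells that differ only in organelle genome dosage
#' (e.g. a mutant whose mitochondrial genome is amplified relative to wild
#' type).
#'
#' @param model A `cell_model`.
#' @param compartment Compartment name.
#' @param copies_per_cell New copies per cell (>= 0; 0 removes the
#'   compartment from read sampling).
#' @return The modified `cell_model`.
#' @export
set_copy_number <- function(model, compartment, copies_per_cell) {
  stopifnot(inherits(model, "cell_model"),
            compartment %in% COMPARTMENTS, copies_per_cell >= 0)
  model$compartments[[compartment]]$copies_per_cell <- copies_per_cell
  model
}

#' Simulate per-gene copy-number / expression coupling
#'
#' Draws a relative copy number `x` per gene around a genome-level fold
#' change and a relative transcript abundance `y = x * noise`, the planted
#' positive coupling used to exercise [associate()].
#'
#' @param n_genes Number of genes.
#' @param fold Genome-level copy-number fold change.
#' @param x_sdlog Log-scale SD of per-gene copy number around `fold`.
#' @param noise_sdlog Log-scale SD of the multiplicative expression noise.
#' @param seed Integer seed.
#' @return Data.frame with `gene`, `copy_number`, `expression`.
#' @export
simulate_cn_expression <- function(n_genes = 30L, fold = 2.3,
                                   x_sdlog = 0.4, noise_sdlog = 0.3, seed) {
  with_seed(seed, {
    x <- stats::rlnorm(n_genes, log(fold), x_sdlog)
    y <- x * stats::rlnorm(n_genes, 0, noise_sdlog)
    data.frame(gene = sprintf("mt_g%03d", seq_len(n_genes)),
               copy_number = x, expression = y)
  })
}

#' Scenario configuration for the end-to-end pipeline
#'
#' Bundles a forge configuration, read-simulation parameters and analysis
#' parameters into one serialisable object; [run_scenario()] executes it.
#' Every parameter has an explicit value here — reports echo the full
#' configuration so no default stays hidden.
#'
#' @param name Scenario label.
#' @param forge A [forge_config()].
#' @param sample_genotype `"wild_type"` or `"mutant"` — the mitochondrial
#'   genome the test sample's reads are drawn from (the reference sample is
#'   always wild type, and mapping always uses the wild-type references).
#' @param sample_mt_copies Mitochondrial copies per cell of the test sample
#'   (the reference sample uses the forge value).
#' @param n_pairs,read_len,insert_mean,insert_sd,error_rate Read simulation
#'   parameters (applied to both samples).
#' @param window_bp,rel_threshold,min_windows,max_gap_windows,pseudocount
#'   Windowed-coverage and deletion-calling parameters.
#' @param cpm_denominator CPM denominator rule, see [window_coverage()].
#' @param nuclear_copies_per_cell Per-cell nuclear copies for
#'   [estimate_copy_number()].
#' @param self_reference When `TRUE` the test sample *is* the reference
#'   sample (same reads): relative coverage and copy-number ratios are then
#'   exactly 1 everywhere, the degenerate baseline case.
#' @param expr Optional [expr_sim_config()] for the expression stage.
#' @param association Optional list for the copy-number/expression coupling
#'   stage: `n_genes`, `fold`, `x_sdlog`, `noise_sdlog`.
#' @param seed Integer master seed; stage seeds are derived from it.
#' @return A `scenario_config`.
#' @export
scenario_config <- function(name, forge = forge_config(),
                            sample_genotype = c("wild_type", "mutant"),
                            sample_mt_copies = NULL,
                            n_pairs = 50000L, read_len = 150L,
                            insert_mean = 400, insert_sd = 60,
                            error_rate = 0,
                            window_bp = 500L, rel_threshold = 0.2,
                            min_windows = 3L, max_gap_windows = 1L,
                            pseudocount = 0.5,
                            cpm_denominator = "assigned",
                            nuclear_copies_per_cell = 2,
                            self_reference = FALSE,
                            expr = NULL, association = NULL,
                            seed = 1L) {
  sample_genotype <- match.arg(sample_genotype)
  stopifnot(inherits(forge, "forge_config"))
  structure(list(name = name, forge = forge,
                 sample_genotype = sample_genotype,
                 sample_mt_copies = sample_mt_copies,
                 n_pairs = as.integer(n_pairs), read_len = as.integer(read_len),
                 insert_mean = insert_mean, insert_sd = insert_sd,
                 error_rate = error_rate, window_bp = as.integer(window_bp),
                 rel_threshold = rel_threshold,
                 min_windows = as.integer(min_windows),
                 max_gap_windows = as.integer(max_gap_windows),
                 pseudocount = pseudocount,
                 cpm_denominator = cpm_denominator,
                 nuclear_copies_per_cell = nuclear_copies_per_cell,
                 self_reference = isTRUE(self_reference),
                 expr = expr, association = association,
                 seed = as.integer(seed)),
            class = "scenario_config")
}

#' Packaged scenario: wild-type baseline
#'
#' The wild-type sample analysed against itself: relative coverage and
#' copy-number ratios are exactly 1 everywhere and no deletion is called —
#' the sanity baseline for the whole pipeline.
#'
#' @param seed Master seed.
#' @param n_pairs Read pairs per sample.
#' @return A `scenario_config`.
#' @export
scenario_wildtype_baseline <- function(seed = 1L, n_pairs = 50000L) {
  scenario_config("wildtype-baseline", self_reference = TRUE,
                  seed = seed, n_pairs = n_pairs)
}

#' Packaged scenario: mitochondrial gene knockout
#'
#' A knockout-like cell: the mitochondrial genome carries the forge's 5.5 kb
#' deletion (repaired by a junction), and its per-cell copy number is raised
#' 2.3-fold over wild type — the copy-number response accompanying loss of a
#' respiratory-chain gene. Expected outcome: one deletion call over the
#' planted interval, an elevated mitochondrial copy-number ratio, and
#' NUMT-type residual reads over the deleted region.
#'
#' @param seed Master seed.
#' @param n_pairs Read pairs per sample.
#' @return A `scenario_config`.
#' @export
scenario_nad7_ko <- function(seed = 1L, n_pairs = 200000L) {
  scenario_config("nad7-ko", sample_genotype = "mutant",
                  sample_mt_copies = 230, seed = seed, n_pairs = n_pairs)
}

#' Packaged scenario: copy-number increase with mitochondrial induction
#'
#' A cell whose intact mitochondrial genome is amplified 2.3-fold, paired
#' with an RNA-seq simulation in which 80% of mitochondrial genes are induced
#' against a quiet nuclear background, plus a planted per-gene
#' copy-number/expression coupling.
#'
#' @param seed Master seed.
#' @param n_pairs Read pairs per sample.
#' @return A `scenario_config`.
#' @export
scenario_cn_induction <- function(seed = 1L, n_pairs = 50000L) {
  scenario_config("cn-induction",
                  forge = forge_config(deletion_start = NULL),
                  sample_genotype = "wild_type", sample_mt_copies = 230,
                  expr = expr_sim_config(),
                  association = list(n_genes = 30L, fold = 2.3,
                                     x_sdlog = 0.4, noise_sdlog = 0.3),
                  seed = seed, n_pairs = n_pairs)
}

#' Serialise / restore a scenario configuration
#'
#' Round-trips a [scenario_config()] through JSON so a scenario can be
#' re-run byte-identically from a file.
#'
#' @param cfg A `scenario_config`.
#' @param path JSON file path.
#' @return `write_scenario_config` returns `path` invisibly;
#'   `read_scenario_config` returns the restored `scenario_config`.
#' @export
write_scenario_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "scenario_config"))
  out <- unclass(cfg)
  out$forge <- unclass(out$forge)
  # named vectors must become JSON objects, not bare arrays
  for (nm in c("lengths", "copies", "gc", "n_genes"))
    out$forge[[nm]] <- as.list(out$forge[[nm]])
  if (!is.null(out$expr)) {
    out$expr <- unclass(out$expr)
    for (nm in c("n_genes", "induced_fraction", "suppressed_fraction"))
      out$expr[[nm]] <- as.list(out$expr[[nm]])
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_scenario_config
#' @export
read_scenario_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  f <- j$forge
  forge <- forge_config(
    nuclear_length = f$lengths[["nuclear"]],
    mitochondrial_length = f$lengths[["mitochondrial"]],
    plastid_length = f$lengths[["plastid"]],
    nuclear_copies = f$copies[["nuclear"]],
    mitochondrial_copies = f$copies[["mitochondrial"]],
    plastid_copies = f$copies[["plastid"]],
    gc = unlist(f$gc),
    numt_source_start = f$numt$source_start,
    numt_source_end = f$numt$source_end %||% 0L,
    numt_insertion_pos = f$numt$insertion_pos %||% 0L,
    numt_snp_offsets = f$numt$snp_offsets %||% integer(0),
    numt_copies_per_haploid = f$numt$copies_per_haploid %||% 0L,
    deletion_start = f$deletion$start,
    deletion_end = f$deletion$end %||% 0L,
    junction_mode = f$deletion$junction_mode %||% "simple_join",
    n_genes = unlist(f$n_genes),
    gene_length = f$gene_length)
  expr <- NULL
  if (!is.null(j$expr)) {
    e <- j$expr
    expr <- expr_sim_config(
      n_genes = unlist(e$n_genes), meanlog = e$meanlog, sdlog = e$sdlog,
      dispersion = e$dispersion,
      induced_fraction = unlist(e$induced_fraction),
      suppressed_fraction = unlist(e$suppressed_fraction),
      effect_log2fc_mean = e$effect_log2fc_mean,
      effect_log2fc_sd = e$effect_log2fc_sd,
      n_replicates = e$n_replicates, lib_factors = e$lib_factors)
  }
  scenario_config(
    name = j$name, forge = forge, sample_genotype = j$sample_genotype,
    sample_mt_copies = j$sample_mt_copies, n_pairs = j$n_pairs,
    read_len = j$read_len, insert_mean = j$insert_mean,
    insert_sd = j$insert_sd, error_rate = j$error_rate,
    window_bp = j$window_bp, rel_threshold = j$rel_threshold,
    min_windows = j$min_windows, max_gap_windows = j$max_gap_windows,
    pseudocount = j$pseudocount, cpm_denominator = j$cpm_denominator,
    nuclear_copies_per_cell = j$nuclear_copies_per_cell,
    self_reference = j$self_reference,
    expr = expr, association = j$association, seed = j$seed)
}

stage <- function(label, expr) {
  tryCatch(expr, error = function(e) {
    stopf("scenario stage '%s' failed: %s", label, conditionMessage(e))
  })
}

#' Run an end-to-end scenario
#'
#' Executes forge, read simulation (reference and test sample), plastid-first
#' assignment, windowed relative coverage, deletion calling, copy-number
#' estimation, SNP-origin classification and — when configured — the
#' expression and association stages. When `out_dir` is given every stage's
#' tabular output is written as TSV/BED, the report as JSON, and MD5
#' checksums of all written files are recorded in the report.
#'
#' @param cfg A [scenario_config()].
#' @param out_dir Optional output directory.
#' @return A `scenario_report` list with all stage results.
#' @export
run_scenario <- function(cfg, out_dir = NULL) {
  stopifnot(inherits(cfg, "scenario_config"))
  s <- cfg$seed

  model <- stage("forge", build_cell_model(cfg$forge, seed = s))
  refs <- model_refs(model, "wild_type")

  smp_model <- model
  if (!is.null(cfg$sample_mt_copies))
    smp_model <- set_copy_number(model, "mitochondrial", cfg$sample_mt_copies)

  sim <- function(m, genotype, seed) {
    simulate_reads(m, genotype, n_pairs = cfg$n_pairs,
                   read_len = cfg$read_len, insert_mean = cfg$insert_mean,
                   insert_sd = cfg$insert_sd, error_rate = cfg$error_rate,
                   seed = seed)
  }
  reads_ref <- stage("simulate-reference-reads",
                     sim(model, "wild_type", s + 1L))
  aln_ref <- stage("assign-reference", assign_reads(reads_ref, refs))
  if (cfg$self_reference) {
    reads_smp <- reads_ref
    aln_smp <- aln_ref
  } else {
    reads_smp <- stage("simulate-sample-reads",
                       sim(smp_model, cfg$sample_genotype, s + 2L))
    aln_smp <- stage("assign-sample", assign_reads(reads_smp, refs))
  }

  wc <- function(aln) window_coverage(aln, "mitochondrial",
                                      window_bp = cfg$window_bp,
                                      cpm_denominator = cfg$cpm_denominator)
  rel <- stage("relative-coverage",
               relative_coverage(wc(aln_smp), wc(aln_ref),
                                 pseudocount = cfg$pseudocount))
  dels <- stage("call-deletions",
                call_deletions(rel, rel_threshold = cfg$rel_threshold,
                               min_windows = cfg$min_windows,
                               max_gap_windows = cfg$max_gap_windows))

  cn <- stage("copy-number", {
    lapply(c("mitochondrial", "plastid"), function(comp) {
      ref_est <- estimate_copy_number(aln_ref, comp,
                                      cfg$nuclear_copies_per_cell)
      estimate_copy_number(aln_smp, comp, cfg$nuclear_copies_per_cell,
                           reference = ref_est)
    }) |> stats::setNames(c("mitochondrial", "plastid"))
  })

  snp <- NULL
  if (!is.null(model$numt)) {
    snp <- stage("snp-origin",
                 classify_snp_origin(aln_smp, reads_smp, snp_sites(model)))
  }

  expr_res <- NULL
  if (!is.null(cfg$expr)) {
    expr_res <- stage("expression", {
      sim_c <- simulate_counts(cfg$expr, seed = s + 3L)
      degs <- call_degs_standin(sim_c$counts,
                                which(sim_c$groups == "control"),
                                which(sim_c$groups == "treated"))
      degs$genome <- sim_c$truth$genome
      part <- filter_degs(degs)
      props <- genome_proportions(part)
      contrast <- fisher_contrast(props, "mitochondrial", "nuclear",
                                  "induced")
      list(truth = sim_c$truth, degs = part, proportions = props,
           fisher_mito_vs_nuclear = contrast)
    })
  }

  assoc <- NULL
  if (!is.null(cfg$association)) {
    assoc <- stage("association", {
      d <- simulate_cn_expression(cfg$association$n_genes,
                                  cfg$association$fold,
                                  cfg$association$x_sdlog,
                                  cfg$association$noise_sdlog,
                                  seed = s + 4L)
      list(data = d, result = associate(d$copy_number, d$expression))
    })
  }

  report <- structure(list(
    scenario = cfg$name, seed = s, config = cfg,
    counts = list(reference = attr(aln_ref, "counts"),
                  sample = attr(aln_smp, "counts")),
    copy_number = lapply(cn, function(e) {
      list(copies_per_cell = e$copies_per_cell,
           rel_to_reference = e$rel_to_reference)
    }),
    windows = rel, deletion_calls = dels, snp_origin = snp,
    expression = expr_res, association = assoc), class = "scenario_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    written <- c(write_cell_model(model, file.path(out_dir, "model")))
    written["windows"] <- write_tsv(as.data.frame(rel),
                                    file.path(out_dir, "windows.tsv"))
    written["deletions_bed"] <-
      write_deletions_bed(dels, file.path(out_dir, "deletions.bed"))
    cn_df <- do.call(rbind, lapply(names(cn), function(nm) {
      data.frame(region = nm, copies_per_cell = cn[[nm]]$copies_per_cell,
                 rel_to_reference = cn[[nm]]$rel_to_reference)
    }))
    written["copy_number"] <- write_tsv(cn_df,
                                        file.path(out_dir, "copy_number.tsv"))
    if (!is.null(snp))
      written["snp_origin"] <- write_tsv(snp$sites,
                                         file.path(out_dir, "snp_origin.tsv"))
    if (!is.null(expr_res)) {
      written["degs"] <- write_tsv(expr_res$degs,
                                   file.path(out_dir, "degs.tsv"))
      written["deg_proportions"] <-
        write_tsv(as.data.frame(expr_res$proportions),
                  file.path(out_dir, "deg_proportions.tsv"))
    }
    if (!is.null(assoc))
      written["association"] <- write_tsv(assoc$data,
                                          file.path(out_dir, "association.tsv"))
    report$checksums <- as.list(tools::md5sum(unname(written)))
    json <- report
    json$windows <- NULL  # bulky; the TSV carries it
    json$config$forge <- unclass(json$config$forge)
    json$config <- unclass(json$config)
    if (!is.null(json$expression)) {
      json$expression$truth <- NULL
      json$expression$degs <- NULL
      json$expression$fisher_mito_vs_nuclear$table <- NULL
    }
    jsonlite::write_json(unclass(json), file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null", force = TRUE)
  }
  report
}

#' @export
print.scenario_report <- function(x, ...) {
  cat("Scenario report:", x$scenario, "(seed", x$seed, ")\n")
  cat(sprintf("  mitochondrial copies/cell: %.2f (rel %.3f); plastid: %.2f (rel %.3f)\n",
              x$copy_number$mitochondrial$copies_per_cell,
              x$copy_number$mitochondrial$rel_to_reference,
              x$copy_number$plastid$copies_per_cell,
              x$copy_number$plastid$rel_to_reference))
  cat("  deletion calls:", nrow(x$deletion_calls), "\n")
  if (nrow(x$deletion_calls))
    print(as.data.frame(x$deletion_calls), row.names = FALSE)
  if (!is.null(x$snp_origin) && !is.na(x$snp_origin$pooled$fraction_mt))
    cat(sprintf("  SNP origin (pooled): %.1f%% mitochondrial-type\n",
                100 * x$snp_origin$pooled$fraction_mt))
  if (!is.null(x$expression))
    cat(sprintf("  mito-vs-nuclear induced-DEG Fisher p = %.3g\n",
                x$expression$fisher_mito_vs_nuclear$p.value))
  if (!is.null(x$association))
    cat(sprintf("  CN-expression association r = %.3f (p = %.3g)\n",
                x$association$result$r, x$association$result$p.value))
  invisible(x)
}
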