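test_that("DEG thresholds are strict inequalities", {
  tab <- data.frame(gene_id = sprintf("g%d", 1:6),
                    log2fc = c(1.0, 1.01, -1.0, -1.01, 2, 2),
                    fdr = c(0.01, 0.01, 0.01, 0.01, 0.05, 0.049))
  part <- filter_degs(tab)
  expect_equal(part$status,
               c("null", "induced", "null", "suppressed", "null", "induced"))
  # missing fdr rows are excluded, not silently kept
  tab$fdr[2] <- NA
  expect_message(part2 <- filter_degs(tab), "1 record")
  expect_equal(attr(part2, "n_excluded"), 1)
  expect_equal(nrow(part2), 5)
})

test_that("a truth table fed directly through the filter recovers itself", {
  cfg <- expr_sim_config(n_genes = c(nuclear = 50L, mitochondrial = 20L,
                                     plastid = 0L),
                         effect_log2fc_mean = 3, effect_log2fc_sd = 0)
  sim <- simulate_counts(cfg, seed = 5)
  tab <- data.frame(gene_id = sim$truth$gene_id,
                    genome = sim$truth$genome,
                    log2fc = sim$truth$true_log2fc,
                    fdr = ifelse(sim$truth$status == "null", 1, 1e-6))
  part <- filter_degs(tab)
  expect_identical(part$status == "induced", sim$truth$status == "induced")
})

test_that("genome proportions and the pooled total row are consistent", {
  tab <- data.frame(
    gene_id = sprintf("g%d", 1:50),
    genome = rep(c("mitochondrial", "nuclear"), c(35, 15)),
    log2fc = c(rep(3, 32), rep(0, 3), rep(0, 15)),
    fdr = 0.001)
  props <- genome_proportions(filter_degs(tab))
  mt <- props[props$genome == "mitochondrial", ]
  expect_equal(mt$n_induced, 32)
  expect_equal(round(mt$prop_induced, 3), 0.914)   # 32 / 35
  tot <- props[props$genome == "total", ]
  expect_equal(tot$n_total, 50)
  expect_equal(tot$n_induced, 32)
  # conservation: induced + suppressed + null = total per genome
  for (g in c("mitochondrial", "nuclear", "total")) {
    r <- props[props$genome == g, ]
    expect_lte(r$n_induced + r$n_suppressed, r$n_total)
  }
})

test_that("degenerate proportion tables behave", {
  none <- data.frame(gene_id = c("a", "b"), genome = c("nuclear", "plastid"),
                     log2fc = 0, fdr = 1)
  p0 <- genome_proportions(filter_degs(none))
  expect_true(all(p0$prop_induced == 0 & p0$prop_suppressed == 0))
  all_up <- data.frame(gene_id = c("a", "b"), genome = c("nuclear", "plastid"),
                       log2fc = 5, fdr = 1e-9)
  p1 <- genome_proportions(filter_degs(all_up))
  expect_true(all(p1$prop_induced == 1))
  # gene -> genome map path, with unmapped genes as errors
  tab <- data.frame(gene_id = c("a", "b"), log2fc = 0, fdr = 1)
  expect_error(genome_proportions(filter_degs(tab),
                                  genome_map = c(a = "nuclear")), "b")
  pm <- genome_proportions(filter_degs(tab),
                           genome_map = c(a = "nuclear", b = "plastid"))
  expect_equal(sort(pm$genome), c("nuclear", "plastid", "total"))
})

test_that("Fisher contrasts match hypergeometric enumeration", {
  props <- data.frame(genome = c("A", "B"), n_total = c(5, 5),
                      n_induced = c(3, 1), n_suppressed = c(0, 0))
  fc <- fisher_contrast(props, "A", "B")
  expect_equal(fc$p.value, 0.524, tolerance = 1e-3)
  expect_equal(fc$p.value, fisher_enum(fc$table), tolerance = 1e-9)

  props2 <- data.frame(genome = c("A", "B"), n_total = c(20, 20),
                       n_induced = c(10, 10), n_suppressed = c(0, 0))
  expect_equal(fisher_contrast(props2, "A", "B")$p.value, 1)

  props3 <- data.frame(genome = c("A", "B"), n_total = c(10, 10),
                       n_induced = c(10, 0), n_suppressed = c(0, 0))
  p3 <- fisher_contrast(props3, "A", "B")$p.value
  expect_equal(p3, 1.082e-5, tolerance = 1e-3)
  expect_equal(p3, fisher_enum(matrix(c(10, 0, 0, 10), 2, byrow = TRUE)),
               tolerance = 1e-9)

  propsz <- data.frame(genome = c("A", "B"), n_total = c(0, 5),
                       n_induced = c(0, 1), n_suppressed = c(0, 0))
  expect_error(fisher_contrast(propsz, "A", "B"), "zero total")
})

test_that("Fisher p equals enumeration for every table with margins <= 12", {
  for (r1 in c(1, 3, 5, 8, 12)) {
    for (r2 in c(1, 4, 7, 12)) {
      for (a in 0:r1) {
        for (c_ in 0:r2) {
          tab <- matrix(c(a, r1 - a, c_, r2 - c_), 2, byrow = TRUE)
          if (any(colSums(tab) > 12)) next
          expect_equal(stats::fisher.test(tab)$p.value, fisher_enum(tab),
                       tolerance = 1e-7,
                       label = paste(a, r1 - a, c_, r2 - c_))
        }
      }
    }
  }
})

test_that("the stand-in DEG caller is calibrated on null data", {
  cfg <- expr_sim_config(n_genes = c(nuclear = 2000L, mitochondrial = 0L,
                                     plastid = 0L),
                         induced_fraction = c(nuclear = 0, mitochondrial = 0,
                                              plastid = 0),
                         n_replicates = 5L)
  sim <- simulate_counts(cfg, seed = 11)
  degs <- call_degs_standin(sim$counts, 1:5, 6:10)
  frac <- mean(degs$fdr < 0.05)
  se <- sqrt(0.05 * 0.95 / 2000)
  expect_lte(frac, 0.05 + 3 * se)
  # raw p-values approximately uniform under the null
  ks <- suppressWarnings(stats::ks.test(degs$pvalue, "punif"))
  expect_gt(ks$p.value, 0.01)
  # permuting labels within the null leaves calibration intact
  perm <- call_degs_standin(sim$counts, c(1, 7, 3, 9, 5), c(6, 2, 8, 4, 10))
  ks2 <- suppressWarnings(stats::ks.test(perm$pvalue, "punif"))
  expect_gt(ks2$p.value, 0.01)
})

test_that("the stand-in caller recovers strong planted inductions", {
  cfg <- expr_sim_config(n_genes = c(nuclear = 400L, mitochondrial = 30L,
                                     plastid = 0L),
                         induced_fraction = c(nuclear = 0,
                                              mitochondrial = 0.8,
                                              plastid = 0),
                         effect_log2fc_mean = 3, effect_log2fc_sd = 0.1,
                         dispersion = 0.05, n_replicates = 5L)
  sim <- simulate_counts(cfg, seed = 13)
  degs <- call_degs_standin(sim$counts, 1:5, 6:10)
  part <- filter_degs(degs)
  truth_ind <- sim$truth$gene_id[sim$truth$status == "induced"]
  called_ind <- part$gene_id[part$status == "induced"]
  recall <- mean(truth_ind %in% called_ind)
  expect_gt(recall, 0.9)
  # BH adjustment: monotone in raw-p order and never below raw p
  o <- order(degs$pvalue)
  expect_true(all(diff(degs$fdr[o]) >= -1e-12))
  expect_true(all(degs$fdr >= degs$pvalue - 1e-12))
})

test_that("an all-zero gene is reported as null, not an error", {
  counts <- rbind(matrix(rpois(40, 50), 4, 10), rep(0L, 10))
  rownames(counts) <- sprintf("g%d", 1:5)
  degs <- call_degs_standin(counts, 1:5, 6:10)
  expect_equal(degs$log2fc[5], 0)
  expect_equal(degs$fdr[5], 1)
})

test_that("mitochondrial induction separates genomes significantly", {
  sim <- simulate_counts(expr_sim_config(), seed = 17)
  degs <- call_degs_standin(sim$counts, 1:3, 4:6)
  degs$genome <- sim$truth$genome
  props <- genome_proportions(filter_degs(degs))
  mt <- props$prop_induced[props$genome == "mitochondrial"]
  nuc <- props$prop_induced[props$genome == "nuclear"]
  expect_gt(mt, nuc)
  fc <- fisher_contrast(props, "mitochondrial", "nuclear", "induced")
  expect_lt(fc$p.value, 0.05)
})

test_that("associations behave on exact, noisy and degenerate inputs", {
  x <- 1:10
  expect_equal(associate(x, 2 * x + 1)$r, 1)
  expect_equal(associate(x, -x)$r, -1)
  z <- associate(rep(2, 5), 1:5)
  expect_true(is.na(z$r))
  expect_error(associate(1:2, 1:2), "at least 3")
  withna <- associate(c(x, NA), c(2 * x, 5))
  expect_equal(withna$n_dropped, 1)
  expect_equal(withna$n, 10)
  # planted copy-number/expression coupling: r > 0.5 in at least 95% of seeds
  rs <- vapply(1:200, function(s) {
    d <- simulate_cn_expression(n_genes = 30, seed = s)
    associate(d$copy_number, d$expression)$r
  }, numeric(1))
  expect_gte(mean(rs > 0.5), 0.95)
})
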