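make_ct <- function(ratios, groups, seed = 1, noise = 0, efficiency = 2) {
  truth <- data.frame(sample_id = sprintf("s%d", seq_along(ratios)),
                      group = groups, quantity = ratios)
  simulate_ct(truth, efficiency = efficiency, ct_noise_sd = noise, seed = seed)
}

test_that("delta-Ct is exact subtraction and missing records are excluded", {
  rec <- data.frame(sample_id = c("a", "b", "c"), group = "g",
                    target = "t", control = "c",
                    ct_target = c(20, 22, NA), ct_control = c(22, 22, 20))
  expect_message(out <- delta_ct(rec), "1 record")
  expect_equal(out$delta_ct, c(-2, 0))
  expect_equal(attr(out, "n_excluded"), 1)
})

test_that("noise-free planted ratios are recovered exactly", {
  # ratio 2 at efficiency 2: delta-delta-Ct is exactly -1
  ct <- make_ct(c(1, 1, 2, 2), c("WT", "WT", "KO", "KO"))
  dct <- delta_ct(ct)
  ddct <- mean(dct$delta_ct[dct$group == "KO"]) -
    mean(dct$delta_ct[dct$group == "WT"])
  expect_equal(ddct, -1)

  rq <- relative_quant(ct, reference_group = "WT")
  expect_equal(rq$rel[rq$group == "WT"], c(1, 1))
  expect_equal(rq$rel[rq$group == "KO"], c(2, 2))

  # arbitrary ratio inverts exactly through efficiency^-ddCt
  ct23 <- make_ct(c(1, 1, 2.3, 2.3), c("WT", "WT", "KO", "KO"))
  rq23 <- relative_quant(ct23, reference_group = "WT")
  expect_equal(unique(rq23$rel[rq23$group == "KO"]), 2.3)

  # ratio 1 stays 1 and identical Ct everywhere gives rel 1
  ct1 <- make_ct(rep(1, 4), c("WT", "WT", "KO", "KO"))
  rq1 <- relative_quant(ct1, reference_group = "WT")
  expect_equal(rq1$rel, rep(1, 4))
})

test_that("a non-default efficiency propagates through quantification", {
  ct <- make_ct(c(1, 1, 4, 4), c("WT", "WT", "KO", "KO"), efficiency = 1.9)
  rq <- relative_quant(ct, reference_group = "WT", efficiency = 1.9)
  expect_equal(unique(round(rq$rel[rq$group == "KO"], 10)), 4)
})

test_that("the reference group is geometric-mean centred at exactly one", {
  ct <- make_ct(exp(rnorm(6, 0, 0.5)), rep(c("WT", "KO"), each = 3),
                noise = 0.3, seed = 9)
  rq <- relative_quant(ct, reference_group = "WT")
  gm <- exp(mean(log(rq$rel[rq$group == "WT"])))
  expect_equal(gm, 1)
  expect_error(relative_quant(ct, reference_group = "mock"),
               "unknown reference group")
})

test_that("delta-delta-Ct is antisymmetric under group swap", {
  ct <- make_ct(c(1, 1.2, 2.6, 2.1), c("A", "A", "B", "B"), noise = 0.2,
                seed = 4)
  dct <- delta_ct(ct)
  dd <- function(x, y) mean(dct$delta_ct[dct$group == x]) -
    mean(dct$delta_ct[dct$group == y])
  expect_equal(dd("A", "B"), -dd("B", "A"))
})

test_that("group summaries report n = 1 dispersion as unavailable", {
  ct <- make_ct(c(1, 1, 2), c("WT", "WT", "KO"))
  rq <- relative_quant(ct, reference_group = "WT")
  s <- attr(rq, "summary")
  expect_true(is.na(s$sd_rel[s$group == "KO"]))
  expect_equal(s$n[s$group == "KO"], 1)
  expect_false(is.na(s$sd_rel[s$group == "WT"]))
})

test_that("technical replicates average on the Ct scale before the delta", {
  rec <- data.frame(sample_id = c("s1", "s1", "s2"), group = c("WT", "WT", "KO"),
                    target = "t", control = "c",
                    ct_target = c(20, 22, 19), ct_control = c(20, 20, 20))
  rq <- relative_quant(rec, reference_group = "WT")
  expect_equal(nrow(rq), 2)   # s1 collapsed to one biological sample
  expect_equal(rq$delta_ct[rq$sample_id == "s1"], 1)
})

test_that("identical groups compare as statistic zero, p one", {
  ct <- make_ct(rep(2, 6), rep(c("A", "B"), each = 3))
  rq <- relative_quant(ct, reference_group = "A")
  cmp <- compare_groups(rq, "A", "B")
  expect_equal(cmp$statistic, 0)
  expect_equal(cmp$p.value, 1)
  expect_error(compare_groups(rq[-1, ], "A", "B"), NA)
  expect_error(compare_groups(rq[rq$group == "A", ][1, ], "A", "B"),
               "at least 2")
})

test_that("the two-group test is calibrated and powered", {
  # type-I error at alpha = 0.05 over 1,000 null simulations
  set.seed(314)
  rej <- mean(replicate(1000, {
    d <- data.frame(target = "t", group = rep(c("A", "B"), each = 6),
                    rel = exp(rnorm(12, 0, 0.3)))
    compare_groups(d, "A", "B")$p.value < 0.05
  }))
  expect_gte(rej, 0.03)
  expect_lte(rej, 0.07)
  # power > 0.9 for a 3 SD mean shift at n = 8, via the package's comparison
  set.seed(2718)
  hits <- mean(replicate(500, {
    truth <- data.frame(sample_id = sprintf("s%d", 1:16),
                        group = rep(c("A", "B"), each = 8),
                        quantity = exp(c(rnorm(8, 0, 0.2),
                                         rnorm(8, 0.6, 0.2))))
    ct <- simulate_ct(truth, seed = sample.int(1e6, 1))
    rq <- relative_quant(ct, reference_group = "A")
    compare_groups(rq, "A", "B")$p.value < 0.05
  }))
  expect_gt(hits, 0.9)
})
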