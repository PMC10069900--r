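test_that("windows tile the compartment and conserve read counts", {
  aln <- fake_aln(pos = c(0, 499, 500, 49999, 25000, 25000),
                  extra_nuclear = 4L)
  wc <- window_coverage(aln, "mitochondrial")
  expect_equal(nrow(wc), 100)           # 50 kb / 500 bp
  expect_equal(sum(wc$raw), 6)          # leftmost-position conservation
  expect_equal(wc$raw[1], 2)            # 0 and 499 in [0, 500)
  expect_equal(wc$raw[2], 1)            # 500 in [500, 1000)
  expect_equal(wc$raw[100], 1)          # 49999 in the last window
  expect_false(any(wc$partial))
  # CPM denominator: nuclear + mitochondrial assigned reads
  expect_equal(attr(wc, "denom_reads"), 10)
  expect_equal(wc$cpm, wc$raw * 1e6 / 10)
})

test_that("a ragged final window is kept and flagged", {
  aln <- fake_aln(pos = c(100, 49900),
                  ref_lengths = c(nuclear = 10000, mitochondrial = 50100,
                                  plastid = 1000))
  wc <- window_coverage(aln, "mitochondrial")
  expect_equal(nrow(wc), 101)
  expect_equal(wc$end[101] - wc$start[101], 100)
  expect_true(wc$partial[101])
  expect_equal(sum(wc$raw), 2)
})

test_that("window counts conserve reads across simulated samples", {
  model <- small_model()
  rs <- small_reads(n_pairs = 4000, seed = 5)
  aln <- assign_reads(rs, model_refs(model))
  for (comp in c("mitochondrial", "nuclear", "plastid")) {
    wc <- window_coverage(aln, comp)
    expect_equal(sum(wc$raw), sum(aln$compartment == comp), label = comp)
  }
})

test_that("uniform coverage behaves like Poisson-thinned window counts", {
  set.seed(101)
  n <- 20000
  aln <- fake_aln(pos = floor(runif(n) * 50000), extra_nuclear = 0L)
  wc <- window_coverage(aln, "mitochondrial", cpm_denominator = "all")
  lambda <- n / 100
  frac_in <- mean(abs(wc$raw - lambda) <= 4 * sqrt(lambda))
  expect_gte(frac_in, 0.95)
})

test_that("zero assigned reads give zero CPM without division errors", {
  aln <- fake_aln(pos = integer(0), extra_nuclear = 0L)
  wc <- window_coverage(aln, "mitochondrial")
  expect_true(all(wc$cpm == 0))
  expect_error(window_coverage(aln, "chromoplast"), "unknown compartment")
})

test_that("relative coverage of a sample against itself is exactly one", {
  model <- small_model()
  rs <- small_reads(n_pairs = 3000, seed = 5)
  aln <- assign_reads(rs, model_refs(model))
  wc <- window_coverage(aln, "mitochondrial")
  rel <- relative_coverage(wc, wc)
  expect_equal(rel$rel, rep(1, nrow(rel)))
})

test_that("split-half wild-type relative coverage stays near one", {
  model <- small_model()
  a <- assign_reads(small_reads(n_pairs = 6000, seed = 51), model_refs(model))
  b <- assign_reads(small_reads(n_pairs = 6000, seed = 52), model_refs(model))
  rel <- relative_coverage(window_coverage(a, "mitochondrial"),
                           window_coverage(b, "mitochondrial"))
  expect_gt(median(rel$rel), 0.9)
  expect_lt(median(rel$rel), 1.1)
})

test_that("the pseudocount keeps zero-coverage windows finite and small", {
  s <- fake_aln(pos = integer(0), extra_nuclear = 1000L)
  r <- fake_aln(pos = rep(250, 100), extra_nuclear = 900L)
  ws <- window_coverage(s, "mitochondrial")
  wr <- window_coverage(r, "mitochondrial")
  rel <- relative_coverage(ws, wr)
  # sample raw = 0 over a covered reference window: rel ~ pseudocount/cpm_r
  expect_lt(rel$rel[1], 0.01)
  expect_gt(rel$rel[1], 0)
  # grids must match
  wr2 <- window_coverage(r, "mitochondrial", window_bp = 1000)
  expect_error(relative_coverage(ws, wr2), "grids")
})

test_that("copy number is recovered and self-normalises on the nuclear genome", {
  model <- small_model()
  rs <- small_reads(n_pairs = 20000, seed = 29)
  aln <- assign_reads(rs, model_refs(model))
  est <- estimate_copy_number(aln, "mitochondrial")
  expect_lt(abs(est$copies_per_cell - 100) / 100, 0.1)
  nuc <- estimate_copy_number(aln, "nuclear", nuclear_copies_per_cell = 2)
  expect_equal(nuc$copies_per_cell, 2)
  # a whole-compartment interval region gives the same answer
  est2 <- estimate_copy_number(
    aln, list(compartment = "mitochondrial", start = 0L, end = 20000L))
  expect_equal(est2$copies_per_cell, est$copies_per_cell)
  # reference identity
  self_rel <- estimate_copy_number(aln, "mitochondrial", reference = est)
  expect_equal(self_rel$rel_to_reference, 1)
})

test_that("zero nuclear depth is a hard error", {
  aln <- fake_aln(pos = rep(1, 10), extra_nuclear = 0L)
  expect_error(estimate_copy_number(aln, "mitochondrial"), "nuclear depth")
})

test_that("doubling the read depth leaves CPM and copy number stable", {
  model <- small_model()
  a1 <- assign_reads(small_reads(n_pairs = 5000, seed = 61), model_refs(model))
  a2 <- assign_reads(small_reads(n_pairs = 10000, seed = 62), model_refs(model))
  c1 <- estimate_copy_number(a1, "mitochondrial")$copies_per_cell
  c2 <- estimate_copy_number(a2, "mitochondrial")$copies_per_cell
  expect_lt(abs(c1 - c2) / c2, 0.15)
  m1 <- mean(window_coverage(a1, "mitochondrial")$cpm)
  m2 <- mean(window_coverage(a2, "mitochondrial")$cpm)
  expect_lt(abs(m1 - m2) / m2, 0.1)
})
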