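test_that("default fixture carries a 5.5 kb deletion and valid geometry", {
  model <- build_cell_model(forge_config(), seed = 1)
  expect_equal(model$deletion$end - model$deletion$start, 5500L)
  expect_equal(model$compartments$nuclear$length, 200000L)
  expect_equal(nchar(model$mt_mutant),
               model$compartments$mitochondrial$length - 5500L)
  # SNP positions sit inside the deletion so residual coverage is NUMT-only
  ss <- snp_sites(model)
  expect_true(all(ss$position >= model$deletion$start &
                    ss$position < model$deletion$end))
  expect_true(all(ss$mt_allele != ss$numt_allele))
  # the NUMT segment differs from its mitochondrial source exactly at the SNPs
  src <- substr(model$compartments$mitochondrial$seq,
                model$numt$source_start + 1, model$numt$source_end)
  seg <- model$numt$segment
  diffs <- which(charToRaw(src) != charToRaw(seg))
  expect_equal(diffs - 1L, model$numt$snps$offset)
})

test_that("gene annotations lie inside their compartments and off the NUMT", {
  model <- small_model()
  ann <- model$annotations
  lens <- vapply(model$compartments, `[[`, numeric(1), "length")
  expect_true(all(ann$start >= 0 & ann$end <= lens[ann$compartment]))
  nuc <- ann[ann$compartment == "nuclear", ]
  expect_true(all(nuc$end <= model$numt$insertion_start |
                    nuc$start >= model$numt$insertion_end))
  # non-overlap within each compartment
  for (comp in unique(ann$compartment)) {
    d <- ann[ann$compartment == comp, ]
    d <- d[order(d$start), ]
    expect_true(all(d$start[-1] >= d$end[-nrow(d)]))
  }
})

test_that("a zero-copy NUMT leaves the nuclear sequence untouched", {
  cfg0 <- small_config(numt_copies_per_haploid = 0L)
  cfg_none <- forge_config(nuclear_length = 60000L,
                           mitochondrial_length = 20000L,
                           plastid_length = 12000L,
                           numt_source_start = NULL, deletion_start = NULL,
                           n_genes = c(nuclear = 12L, mitochondrial = 8L,
                                       plastid = 6L),
                           gene_length = 400L)
  m0 <- build_cell_model(cfg0, seed = 5)
  mn <- build_cell_model(cfg_none, seed = 5)
  expect_identical(m0$compartments$nuclear$seq, mn$compartments$nuclear$seq)
})

test_that("model building and serialisation are deterministic", {
  m1 <- build_cell_model(small_config(), seed = 11)
  m2 <- build_cell_model(small_config(), seed = 11)
  expect_identical(m1$compartments, m2$compartments)
  expect_identical(m1$annotations, m2$annotations)

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- write_cell_model(m1, d1)
  p2 <- write_cell_model(m2, d2)
  for (nm in names(p1)) {
    expect_identical(unname(tools::md5sum(p1[[nm]])),
                     unname(tools::md5sum(p2[[nm]])), label = nm)
  }
  # truth JSON records the planted deletion length
  truth <- jsonlite::read_json(file.path(d1, "truth.json"))
  expect_equal(truth$deletion$length, 2500L)
  # annotations survive a GFF3 round trip with coordinates intact
  gr <- rtracklayer::import(file.path(d1, "annotations.gff3"))
  expect_equal(length(gr), nrow(m1$annotations))
  expect_setequal(gr$ID, m1$annotations$gene_id)
})

test_that("junction repair modes alter only the expected bases", {
  ms <- build_cell_model(small_config(), seed = 3)
  mh <- build_cell_model(small_config(junction_mode = "microhomology_join"),
                         seed = 3)
  expect_identical(ms$compartments$mitochondrial$seq,
                   mh$compartments$mitochondrial$seq)
  del_start <- ms$deletion$start
  # simple join: mutant = left flank + right flank verbatim
  expect_identical(substr(ms$mt_mutant, 1, del_start),
                   substr(ms$compartments$mitochondrial$seq, 1, del_start))
  # microhomology join: 20 bp immediately after the junction copy the 20 bp
  # immediately before it
  expect_identical(substr(mh$mt_mutant, del_start + 1, del_start + 20),
                   substr(mh$mt_mutant, del_start - 19, del_start))
  # beyond the patch both modes agree
  expect_identical(substr(mh$mt_mutant, del_start + 21, nchar(mh$mt_mutant)),
                   substr(ms$mt_mutant, del_start + 21, nchar(ms$mt_mutant)))
})

test_that("invalid forge configurations are rejected", {
  expect_error(forge_config(deletion_start = 100L, deletion_end = 50L),
               "positive length")
  expect_error(forge_config(numt_snp_offsets = c(100L, 99999L)),
               "inside the NUMT")
  # deletion that misses every SNP breaks the knockout construction
  expect_error(forge_config(deletion_start = 30000L, deletion_end = 35500L),
               "SNP")
})
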