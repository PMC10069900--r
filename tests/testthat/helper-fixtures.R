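# Small desk fixture: same geometry as the default forge configuration but
# ~3x smaller, so simulation-heavy tests stay fast. The deletion interval is
# window-aligned (multiples of 500) and contains both diagnostic SNPs.
small_config <- function(...) {
  forge_config(nuclear_length = 60000L, mitochondrial_length = 20000L,
               plastid_length = 12000L,
               numt_source_start = 5000L, numt_source_end = 8000L,
               numt_insertion_pos = 30000L,
               numt_snp_offsets = c(1200L, 1800L),
               deletion_start = 5000L, deletion_end = 7500L,
               n_genes = c(nuclear = 12L, mitochondrial = 8L, plastid = 6L),
               gene_length = 400L, ...)
}

small_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_cell_model(small_config(), seed = 42)
    cache
  }
})

small_reads <- function(n_pairs = 5000, genotype = "wild_type", seed = 7,
                        error_rate = 0, model = small_model()) {
  simulate_reads(model, genotype, n_pairs = n_pairs, read_len = 100L,
                 insert_mean = 250, insert_sd = 30, error_rate = error_rate,
                 seed = seed)
}

# Independent brute-force aligner over full references via Biostrings
# pattern matching: minimum mismatch count and number of equally good
# placements per compartment, on either strand.
brute_force_best <- function(seq, refs, budget) {
  res <- list()
  for (comp in names(refs)) {
    ref <- Biostrings::DNAString(refs[[comp]])
    best_mm <- NA_integer_
    n_best <- 0L
    for (s in c(seq, as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(seq))))) {
      for (mm in 0:budget) {
        cnt <- Biostrings::countPattern(s, ref, max.mismatch = mm)
        if (cnt > 0) {
          if (is.na(best_mm) || mm < best_mm) {
            best_mm <- mm
            n_best <- cnt
          } else if (mm == best_mm) {
            n_best <- n_best + cnt
          }
          break
        }
      }
    }
    res[[comp]] <- list(mm = best_mm, n = n_best)
  }
  res
}

# The paper-style assignment rule applied to brute-force scores: plastid
# first, then best of mitochondrial/nuclear with ties to mitochondrial.
brute_force_assign <- function(seq, refs, budget) {
  b <- brute_force_best(seq, refs, budget)
  if (!is.na(b$plastid$mm)) return("plastid")
  mm_mt <- b$mitochondrial$mm
  mm_nu <- b$nuclear$mm
  if (is.na(mm_mt) && is.na(mm_nu)) return("unassigned")
  if (is.na(mm_nu) || (!is.na(mm_mt) && mm_mt <= mm_nu)) return("mitochondrial")
  "nuclear"
}

# Exhaustive two-sided Fisher p for a 2x2 table by hypergeometric point
# probability summation (ties at the observed probability included with a
# small tolerance factor).
fisher_enum <- function(tab) {
  a <- tab[1, 1]; r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1]); n <- sum(tab)
  supp <- max(0, c1 - r2):min(r1, c1)
  pr <- stats::dhyper(supp, r1, r2, c1)
  p_obs <- stats::dhyper(a, r1, r2, c1)
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

# Exhaustive run scan over a logical low-coverage vector: maximal groups of
# low windows separated by at most max_gap high windows, with at least
# min_windows low members. Returns list of index vectors.
scan_runs <- function(low, min_windows, max_gap) {
  idx <- which(low)
  runs <- list()
  cur <- integer(0)
  for (i in idx) {
    if (length(cur) == 0L || i - cur[length(cur)] <= max_gap + 1L) {
      cur <- c(cur, i)
    } else {
      runs[[length(runs) + 1L]] <- cur
      cur <- i
    }
  }
  if (length(cur)) runs[[length(runs) + 1L]] <- cur
  Filter(function(r) length(r) >= min_windows, runs)
}

# Construct a bare alignment_set from positions, for window/CN unit tests.
fake_aln <- function(pos, compartment = "mitochondrial",
                     ref_lengths = c(nuclear = 200000, mitochondrial = 50000,
                                     plastid = 30000),
                     extra_nuclear = 0L) {
  n_tot <- length(pos) + extra_nuclear
  df <- data.frame(
    read_id = sprintf("f%d", seq_len(n_tot)),
    mate = rep(1L, n_tot),
    compartment = c(rep(compartment, length(pos)),
                    rep("nuclear", extra_nuclear)),
    pos = c(pos, rep(0L, extra_nuclear)),
    strand = rep("+", n_tot), n_mismatches = rep(0L, n_tot),
    unique = rep(TRUE, n_tot),
    mt_pos = rep(NA_integer_, n_tot), mt_strand = rep(NA_character_, n_tot),
    mt_mm = rep(NA_integer_, n_tot),
    read_len = rep(100L, n_tot), stringsAsFactors = FALSE)
  counts <- c(plastid = sum(df$compartment == "plastid"),
              mitochondrial = sum(df$compartment == "mitochondrial"),
              nuclear = sum(df$compartment == "nuclear"),
              unassigned = 0L)
  structure(df, class = c("alignment_set", "data.frame"),
            ref_lengths = ref_lengths, mismatch_budget = 2L, counts = counts)
}
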