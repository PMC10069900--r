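#' Simulate labelled paired-end reads from a cell model
#'
#' Draws read pairs from the cell's compartments with sampling weights
#' proportional to `copies_per_cell * sequence length`, so the expected read
#' fraction of compartment *i* is `weight_i / sum(weights)`. The NUMT segment
#' travels inside the nuclear sequence (one embedded copy per haploid genome,
#' i.e. weight `2 * copies_per_haploid` for a diploid cell when
#' `copies_per_haploid = 1`); reads falling entirely inside the NUMT interval
#' are truth-labelled `"numt"` even though they are physically nuclear.
#' For `genotype = "mutant"` mitochondrial fragments are drawn from the
#' deletion-bearing genome, so reads from the deleted interval cannot occur.
#'
#' Base qualities are constant Q30 — downstream stages never consult them.
#'
#' @param model A [build_cell_model()] result.
#' @param genotype `"wild_type"` or `"mutant"`.
#' @param n_pairs Number of read pairs.
#' @param read_len Read length (bp); default 150.
#' @param insert_mean,insert_sd Fragment-length distribution (bp); fragments
#'   are clamped to `[read_len, compartment length]`.
#' @param error_rate Per-base substitution probability in `[0, 1)`.
#' @param seed Integer seed.
#' @return A `read_set`: a data.frame with one row per mate (`read_id`,
#'   `mate`, `seq`, `true_compartment`, `true_pos` 0-based leftmost on the
#'   source sequence, `true_strand`), with simulation parameters as
#'   attributes.
#' @export
simulate_reads <- function(model, genotype = c("wild_type", "mutant"),
                           n_pairs, read_len = 150L, insert_mean = 400,
                           insert_sd = 60, error_rate = 0, seed) {
  stopifnot(inherits(model, "cell_model"))
  genotype <- match.arg(genotype)
  if (!is_count(n_pairs)) stopf("n_pairs must be a positive integer")
  if (insert_mean < read_len) stopf("insert_mean must be >= read_len")
  if (error_rate < 0 || error_rate >= 1) stopf("error_rate must lie in [0, 1)")
  lens <- vapply(model$compartments, `[[`, numeric(1), "length")
  if (any(lens < 10 * read_len))
    stopf("every compartment must be at least 10x the read length")

  mt_seq <- if (genotype == "mutant") {
    if (is.null(model$mt_mutant)) stopf("model has no mutant genome")
    model$mt_mutant
  } else {
    model$compartments$mitochondrial$seq
  }

  comp_seq <- c(nuclear = model$compartments$nuclear$seq,
                mitochondrial = mt_seq,
                plastid = model$compartments$plastid$seq)
  comp_len <- nchar(comp_seq)
  copies <- vapply(model$compartments, `[[`, numeric(1), "copies_per_cell")
  weights <- copies * comp_len

  # extra NUMT copies beyond the one embedded per haploid genome: sampled
  # from the nuclear sequence restricted to the insertion interval
  numt_extra_w <- 0
  if (!is.null(model$numt) && model$numt$copies_per_haploid > 1) {
    seg_len <- model$numt$source_end - model$numt$source_start
    numt_extra_w <- 2 * (model$numt$copies_per_haploid - 1) * seg_len
  }
  wt <- c(weights, numt_extra = numt_extra_w)
  if (sum(wt) <= 0) stopf("all sampling weights are zero")

  with_seed(seed, {
    comp <- sample(names(wt), n_pairs, replace = TRUE, prob = wt)
    src_comp <- ifelse(comp == "numt_extra", "nuclear", comp)
    L <- comp_len[src_comp]
    ins <- pmin(pmax(round(stats::rnorm(n_pairs, insert_mean, insert_sd)),
                     read_len), L)
    # fragment start, uniform over valid placements (or over the NUMT
    # interval for extra NUMT copies)
    lo <- rep(0L, n_pairs)
    hi <- L - ins
    if (numt_extra_w > 0) {
      ex <- comp == "numt_extra"
      lo[ex] <- model$numt$insertion_start
      hi[ex] <- pmax(lo[ex], model$numt$insertion_end - ins[ex])
    }
    start <- lo + floor(stats::runif(n_pairs) * (hi - lo + 1L))

    frag <- substring(comp_seq[src_comp], start + 1L, start + ins)
    r1 <- substring(frag, 1L, read_len)
    r2 <- revcomp(substring(frag, ins - read_len + 1L, ins))
    pos1 <- start
    pos2 <- start + ins - read_len

    seqs <- c(r1, r2)
    n_mates <- 2L * n_pairs
    if (error_rate > 0) {
      n_err <- stats::rbinom(n_mates, read_len, error_rate)
      for (i in which(n_err > 0L)) {
        p <- sample.int(read_len, n_err[i])
        for (j in p) {
          b <- substr(seqs[i], j, j)
          substr(seqs[i], j, j) <- sample(setdiff(c("A", "C", "G", "T"), b), 1L)
        }
      }
    }

    lab <- src_comp
    if (!is.null(model$numt) && !is.null(model$numt$insertion_start) &&
        model$numt$copies_per_haploid > 0) {
      i0 <- model$numt$insertion_start
      i1 <- model$numt$insertion_end
      in1 <- src_comp == "nuclear" & pos1 >= i0 & pos1 + read_len <= i1
      in2 <- src_comp == "nuclear" & pos2 >= i0 & pos2 + read_len <= i1
    } else {
      in1 <- in2 <- rep(FALSE, n_pairs)
    }

    ids <- sprintf("r%07d", seq_len(n_pairs))
    rs <- data.frame(
      read_id = c(ids, ids),
      mate = rep(1:2, each = n_pairs),
      seq = seqs,
      true_compartment = c(ifelse(in1, "numt", lab), ifelse(in2, "numt", lab)),
      true_pos = c(pos1, pos2),
      true_strand = rep(c("+", "-"), each = n_pairs),
      stringsAsFactors = FALSE)
    structure(rs, class = c("read_set", "data.frame"),
              genotype = genotype, read_len = as.integer(read_len),
              n_pairs = as.integer(n_pairs), error_rate = error_rate,
              insert_mean = insert_mean, insert_sd = insert_sd,
              seed = as.integer(seed))
  })
}

#' Write a read set as paired FASTQ plus a truth table
#'
#' @param reads A [simulate_reads()] result.
#' @param dir Output directory.
#' @param prefix File name prefix.
#' @param gzip Compress the FASTQ files.
#' @return Invisibly, the vector of written paths.
#' @export
write_fastq <- function(reads, dir, prefix = "reads", gzip = FALSE) {
  stopifnot(inherits(reads, "read_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rl <- attr(reads, "read_len")
  ext <- if (gzip) ".fastq.gz" else ".fastq"
  paths <- character(0)
  for (m in 1:2) {
    sub <- reads[reads$mate == m, ]
    ss <- Biostrings::DNAStringSet(sub$seq)
    names(ss) <- sub$read_id
    q <- Biostrings::BStringSet(rep(strrep("?", rl), nrow(sub)))  # Q30
    p <- file.path(dir, paste0(prefix, "_R", m, ext))
    Biostrings::writeXStringSet(ss, p, format = "fastq", qualities = q,
                                compress = gzip)
    paths <- c(paths, p)
  }
  pt <- file.path(dir, paste0(prefix, "_truth.tsv"))
  write_tsv(reads[, c("read_id", "mate", "true_compartment", "true_pos",
                      "true_strand")], pt)
  invisible(c(paths, pt))
}

#' Read paired FASTQ files into a read set
#'
#' Truth columns are `NA`; use this to feed externally produced reads into
#' [assign_reads()].
#'
#' @param r1,r2 Paths to the mate FASTQ files (optionally gzipped).
#' @return A `read_set` data.frame.
#' @export
read_fastq <- function(r1, r2) {
  s1 <- Biostrings::readDNAStringSet(r1, format = "fastq")
  s2 <- Biostrings::readDNAStringSet(r2, format = "fastq")
  if (length(s1) != length(s2)) stopf("mate files differ in read count")
  ids <- sub("\\s.*$", "", names(s1))
  rs <- data.frame(
    read_id = c(ids, ids),
    mate = rep(1:2, each = length(s1)),
    seq = c(as.character(s1), as.character(s2)),
    true_compartment = NA_character_, true_pos = NA_integer_,
    true_strand = NA_character_, stringsAsFactors = FALSE)
  structure(rs, class = c("read_set", "data.frame"),
            read_len = max(nchar(rs$seq)), n_pairs = length(s1))
}
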