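#' @import data.table
NULL

# data.table non-standard evaluation columns
utils::globalVariables(c(
  ".", "comp", "compartment", "fpos", "kmer", "mate", "mm", "mm_min",
  "mt_pos", "mt_strand", "off", "pos", "rdseq", "read_id", "refsub", "rid",
  "seq", "strand"))

# Build the exact k-mer index over both strands of the references.
# Rows: kmer, comp, strand ("+" indexes the forward sequence, "-" its
# reverse complement), pos (0-based on the indexed strand string).
kmer_index <- function(refs, k) {
  idx <- rbindlist(lapply(names(refs), function(cn) {
    out <- list()
    for (strand in c("+", "-")) {
      s <- if (strand == "+") refs[[cn]] else revcomp(refs[[cn]])
      L <- nchar(s)
      if (L < k) next
      out[[strand]] <- data.table(
        kmer = substring(s, 1:(L - k + 1L), k:L),
        comp = cn, strand = strand, pos = 0:(L - k))
    }
    rbindlist(out)
  }))
  setkey(idx, kmer)
  idx
}

mm_count <- function(a, b) {
  mapply(function(x, y) sum(charToRaw(x) != charToRaw(y)), a, b,
         USE.NAMES = FALSE)
}

#' Assign reads to cell compartments with plastid-first exclusion
#'
#' A minimal exact-k-mer-seeded, ungapped read mapper tailored to organelle
#' copy-number work. Each read is seeded with k-mers (k = 21 by default,
#' taken every `seed_step` positions plus the final one), candidate ungapped
#' placements on either strand of each reference are verified by mismatch
#' counting, and the read is assigned following the plastid-exclusion order
#' used throughout the package: a read that places on the plastid genome
#' within the mismatch budget is assigned `plastid` and excluded from all
#' further consideration; remaining reads take their best-scoring placement
#' among the mitochondrial and nuclear references, with score ties broken in
#' favour of `mitochondrial` and flagged `unique = FALSE`. This tie-break
#' deliberately routes NUMT-derived reads to the mitochondrial reference —
#' the residual coverage they create over a deleted region is a feature of
#' the analysis, not an artefact to suppress.
#'
#' Every read additionally records its best mitochondrial placement
#' (`mt_pos`, `mt_strand`, `mt_mm`) whether or not mitochondrial won the
#' final assignment; the SNP-origin classifier consumes these placements,
#' mirroring a map-everything-to-the-mitochondrial-reference protocol.
#'
#' @param reads A `read_set` (from [simulate_reads()] or [read_fastq()]) or
#'   any data.frame with `read_id`, `mate`, `seq`.
#' @param refs Named character vector or `DNAStringSet` of reference
#'   sequences; names among `nuclear`, `mitochondrial`, `plastid`.
#' @param k Seed k-mer length.
#' @param seed_step Spacing of seed start positions along the read.
#' @param mismatch_budget Maximum mismatches for a valid placement; default
#'   `max(2, ceiling(0.04 * read_len))`.
#' @return An `alignment_set`: a data.frame with one row per input read
#'   (`read_id`, `mate`, `compartment` in
#'   `{plastid, mitochondrial, nuclear, unassigned}`, `pos` 0-based leftmost,
#'   `strand`, `n_mismatches`, `unique`, `mt_pos`, `mt_strand`, `mt_mm`,
#'   `read_len`), with reference lengths, the budget and assignment counts as
#'   attributes.
#' @export
assign_reads <- function(reads, refs, k = 21L, seed_step = 10L,
                         mismatch_budget = NULL) {
  if (inherits(refs, "DNAStringSet")) {
    refs <- stats::setNames(as.character(refs), names(refs))
  }
  if (is.null(names(refs)) || !all(names(refs) %in% COMPARTMENTS))
    stopf("refs must be named with compartments: %s",
          paste(COMPARTMENTS, collapse = ", "))
  ref_len <- nchar(refs)

  empty <- data.frame(read_id = character(0), mate = integer(0),
                      compartment = character(0), pos = integer(0),
                      strand = character(0), n_mismatches = integer(0),
                      unique = logical(0), mt_pos = integer(0),
                      mt_strand = character(0), mt_mm = integer(0),
                      read_len = integer(0), stringsAsFactors = FALSE)
  n <- nrow(reads)
  if (n == 0L) {
    return(structure(empty, class = c("alignment_set", "data.frame"),
                     ref_lengths = ref_len, mismatch_budget = NA_integer_,
                     counts = c(plastid = 0L, mitochondrial = 0L,
                                nuclear = 0L, unassigned = 0L)))
  }

  seqs <- reads$seq
  rl <- nchar(seqs)
  budget <- as.integer(mismatch_budget %||% max(2L, ceiling(0.04 * max(rl))))

  idx <- kmer_index(refs, k)

  # seeds: every seed_step-th start plus the last valid one, per read length
  seeds <- rbindlist(lapply(unique(rl), function(len) {
    if (len < k) return(NULL)
    offs <- unique(c(seq(1L, len - k + 1L, by = seed_step), len - k + 1L))
    rid <- which(rl == len)
    rbindlist(lapply(offs, function(o) {
      data.table(rid = rid, off = o, kmer = substring(seqs[rid], o, o + k - 1L))
    }))
  }))

  cand <- if (nrow(seeds)) {
    idx[seeds, on = "kmer", nomatch = 0L, allow.cartesian = TRUE]
  } else data.table()
  if (nrow(cand)) {
    cand[, diag := pos - (off - 1L)]
    cand <- unique(cand[, .(rid, comp, strand, diag)])
    cand <- cand[diag >= 0L & diag + rl[rid] <= ref_len[comp]]
  }

  res <- data.table(read_id = reads$read_id, mate = reads$mate,
                    compartment = "unassigned", pos = NA_integer_,
                    strand = NA_character_, n_mismatches = NA_integer_,
                    unique = NA, mt_pos = NA_integer_,
                    mt_strand = NA_character_, mt_mm = NA_integer_,
                    read_len = rl)

  if (nrow(cand)) {
    # verify: compare the read to the indexed-strand substring
    strand_seq <- c("+" = 1L, "-" = 2L)
    ss <- rbind(refs, vapply(refs, revcomp, character(1)))
    cand[, refsub := substring(ss[cbind(strand_seq[strand], match(comp, colnames(ss)))],
                               diag + 1L, diag + rl[rid])]
    cand[, rdseq := seqs[rid]]
    cand[, mm := 0L]
    nx <- which(cand$refsub != cand$rdseq)
    if (length(nx))
      cand[nx, mm := mm_count(refsub, rdseq)]
    cand[, c("refsub", "rdseq") := NULL]
    cand <- cand[mm <= budget]
  }

  if (nrow(cand)) {
    # forward-strand leftmost coordinate of each placement
    cand[, fpos := ifelse(strand == "+", diag,
                          ref_len[comp] - diag - rl[rid])]
    cand[, mm_min := min(mm), by = .(rid, comp)]
    bb <- cand[mm == mm_min]
    setorder(bb, rid, comp, fpos, strand)
    rep_ <- bb[, .(pos = fpos[1L], strand = strand[1L], mm = mm_min[1L],
                   nbest = .N), by = .(rid, comp)]

    pick <- function(cn) rep_[comp == cn]
    pl <- pick("plastid"); mt <- pick("mitochondrial"); nu <- pick("nuclear")
    i_pl <- match(seq_len(n), pl$rid)
    i_mt <- match(seq_len(n), mt$rid)
    i_nu <- match(seq_len(n), nu$rid)

    # record the best mitochondrial placement for every read that has one
    res[!is.na(i_mt), `:=`(mt_pos = mt$pos[i_mt[!is.na(i_mt)]],
                           mt_strand = mt$strand[i_mt[!is.na(i_mt)]],
                           mt_mm = mt$mm[i_mt[!is.na(i_mt)]])]

    has_pl <- !is.na(i_pl)
    has_mt <- !is.na(i_mt)
    has_nu <- !is.na(i_nu)
    mt_mm_v <- ifelse(has_mt, mt$mm[i_mt], NA_integer_)
    nu_mm_v <- ifelse(has_nu, nu$mm[i_nu], NA_integer_)

    # plastid first
    w <- which(has_pl)
    if (length(w))
      res[w, `:=`(compartment = "plastid", pos = pl$pos[i_pl[w]],
                  strand = pl$strand[i_pl[w]], n_mismatches = pl$mm[i_pl[w]],
                  unique = pl$nbest[i_pl[w]] == 1L)]

    rest <- which(!has_pl & (has_mt | has_nu))
    if (length(rest)) {
      tie <- has_mt[rest] & has_nu[rest] & mt_mm_v[rest] == nu_mm_v[rest]
      mt_wins <- has_mt[rest] &
        (!has_nu[rest] | mt_mm_v[rest] <= nu_mm_v[rest])
      wmt <- rest[mt_wins]
      wnu <- rest[!mt_wins]
      if (length(wmt))
        res[wmt, `:=`(compartment = "mitochondrial", pos = mt$pos[i_mt[wmt]],
                      strand = mt$strand[i_mt[wmt]],
                      n_mismatches = mt$mm[i_mt[wmt]],
                      unique = mt$nbest[i_mt[wmt]] == 1L &
                        !tie[match(wmt, rest)])]
      if (length(wnu))
        res[wnu, `:=`(compartment = "nuclear", pos = nu$pos[i_nu[wnu]],
                      strand = nu$strand[i_nu[wnu]],
                      n_mismatches = nu$mm[i_nu[wnu]],
                      unique = nu$nbest[i_nu[wnu]] == 1L)]
    }
  }

  out <- as.data.frame(res)
  counts <- c(plastid = sum(out$compartment == "plastid"),
              mitochondrial = sum(out$compartment == "mitochondrial"),
              nuclear = sum(out$compartment == "nuclear"),
              unassigned = sum(out$compartment == "unassigned"))
  structure(out, class = c("alignment_set", "data.frame"),
            ref_lengths = ref_len, mismatch_budget = budget, counts = counts)
}

#' Ingest external SAM/BAM alignments as an alignment set
#'
#' Lets a production aligner stand in for the internal mapper. Only primary,
#' non-supplementary records are kept; unmapped reads are counted as
#' `unassigned`; `MAPQ == 0` is flagged `unique = FALSE`. SAM input is
#' converted on the fly through Rsamtools.
#'
#' @param path Path to a `.sam` or `.bam` file.
#' @param compartment_map Named character vector mapping reference names in
#'   the file header to compartments, e.g. `c(chrM = "mitochondrial")`.
#' @return An `alignment_set` (positions converted to 0-based).
#' @export
ingest_alignments <- function(path, compartment_map) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    path <- Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                             indexDestination = FALSE)
  }
  hdr <- Rsamtools::scanBamHeader(path)[[1]]$targets
  unknown <- setdiff(names(hdr), names(compartment_map))
  if (length(unknown))
    stopf("reference name(s) not resolvable to a compartment: %s",
          paste(unknown, collapse = ", "))
  bad <- compartment_map[!compartment_map %in% COMPARTMENTS]
  if (length(bad))
    stopf("compartment_map values must be compartments; offending: %s",
          paste(unique(bad), collapse = ", "))

  fl <- Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                               isSupplementaryAlignment = FALSE)
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "strand", "pos", "mapq", "qwidth"),
    flag = fl)
  b <- Rsamtools::scanBam(path, param = p)[[1]]

  mapped <- !is.na(b$rname) & !is.na(b$pos)
  comp <- rep("unassigned", length(b$qname))
  comp[mapped] <- unname(compartment_map[as.character(b$rname[mapped])])
  mate <- ifelse(bitwAnd(b$flag, 0x40L) > 0L, 1L,
                 ifelse(bitwAnd(b$flag, 0x80L) > 0L, 2L, 1L))
  pos0 <- ifelse(mapped, b$pos - 1L, NA_integer_)
  strand <- ifelse(mapped, as.character(b$strand), NA_character_)
  uniq <- ifelse(mapped, b$mapq > 0L, NA)

  out <- data.frame(
    read_id = b$qname, mate = mate, compartment = comp, pos = pos0,
    strand = strand, n_mismatches = NA_integer_, unique = uniq,
    mt_pos = ifelse(comp == "mitochondrial", pos0, NA_integer_),
    mt_strand = ifelse(comp == "mitochondrial", strand, NA_character_),
    mt_mm = NA_integer_,
    read_len = ifelse(is.na(b$qwidth), NA_integer_, b$qwidth),
    stringsAsFactors = FALSE)
  ref_len <- numeric(0)
  for (rn in names(hdr)) ref_len[compartment_map[[rn]]] <- hdr[[rn]]
  counts <- c(plastid = sum(out$compartment == "plastid"),
              mitochondrial = sum(out$compartment == "mitochondrial"),
              nuclear = sum(out$compartment == "nuclear"),
              unassigned = sum(out$compartment == "unassigned"))
  structure(out, class = c("alignment_set", "data.frame"),
            ref_lengths = ref_len, mismatch_budget = NA_integer_,
            counts = counts)
}

#' @export
print.alignment_set <- function(x, ...) {
  cnt <- attr(x, "counts")
  cat("Alignment set:", nrow(x), "reads\n")
  for (nm in names(cnt))
    cat(sprintf("  %-14s %9d (%.2f%%)\n", nm, cnt[[nm]],
                if (nrow(x)) 100 * cnt[[nm]] / nrow(x) else 0))
  invisible(x)
}

#' Classify read origin at diagnostic SNP sites
#'
#' For every read with a mitochondrial placement spanning a diagnostic SNP
#' site, tallies the observed base as mitochondrial-type, NUMT-type or other.
#' Reads assigned to the nuclear compartment still contribute through their
#' recorded mitochondrial placement, so the profile reflects what a
#' map-to-the-mitochondrial-reference protocol observes. Sites spanned by no
#' read are reported missing and excluded from the pooled denominator; bases
#' matching neither allele are counted as `other` and never imputed.
#'
#' @param aln An [assign_reads()] result.
#' @param reads The read set that produced `aln` (supplies sequences).
#' @param sites Data.frame of SNP sites: `position` (0-based, mitochondrial),
#'   `mt_allele`, `numt_allele`, optional `label`; see [snp_sites()].
#' @return A `snp_origin_profile`: per-site counts and fractions plus pooled
#'   fractions (`fraction_mt = mt / (mt + numt)`).
#' @export
classify_snp_origin <- function(aln, reads, sites) {
  stopifnot(inherits(aln, "alignment_set"))
  ref_len <- attr(aln, "ref_lengths")
  if (!"mitochondrial" %in% names(ref_len))
    stopf("alignment set has no mitochondrial reference")
  if (any(sites$position < 0 | sites$position >= ref_len[["mitochondrial"]]))
    stopf("SNP site outside the mitochondrial reference")
  if (is.null(sites$label))
    sites$label <- sprintf("snp%d", seq_len(nrow(sites)))

  a <- as.data.table(aln)[!is.na(mt_pos) & compartment != "plastid"]
  rd <- as.data.table(reads)[, .(read_id, mate, seq)]
  a <- rd[a, on = c("read_id", "mate")]

  per_site <- lapply(seq_len(nrow(sites)), function(i) {
    p <- sites$position[i]
    sp <- a[mt_pos <= p & p < mt_pos + nchar(seq)]
    if (nrow(sp) == 0L) {
      return(data.frame(label = sites$label[i], position = p,
                        n_mt = 0L, n_numt = 0L, n_other = 0L,
                        fraction_mt = NA_real_, fraction_numt = NA_real_,
                        missing = TRUE))
    }
    oriented <- sp$seq
    neg <- sp$mt_strand == "-"
    if (any(neg)) oriented[neg] <- revcomp(oriented[neg])
    off <- p - sp$mt_pos + 1L
    base <- substring(oriented, off, off)
    n_mt <- sum(base == sites$mt_allele[i])
    n_numt <- sum(base == sites$numt_allele[i])
    n_other <- length(base) - n_mt - n_numt
    den <- n_mt + n_numt
    data.frame(label = sites$label[i], position = p, n_mt = n_mt,
               n_numt = n_numt, n_other = n_other,
               fraction_mt = if (den > 0) n_mt / den else NA_real_,
               fraction_numt = if (den > 0) n_numt / den else NA_real_,
               missing = FALSE)
  })
  per_site <- do.call(rbind, per_site)

  ok <- !per_site$missing
  pooled_mt <- sum(per_site$n_mt[ok])
  pooled_numt <- sum(per_site$n_numt[ok])
  den <- pooled_mt + pooled_numt
  structure(list(
    sites = per_site,
    pooled = list(n_mt = pooled_mt, n_numt = pooled_numt,
                  n_other = sum(per_site$n_other[ok]),
                  fraction_mt = if (den > 0) pooled_mt / den else NA_real_,
                  fraction_numt = if (den > 0) pooled_numt / den else NA_real_),
    n_sites_missing = sum(per_site$missing)),
    class = "snp_origin_profile")
}

#' @export
print.snp_origin_profile <- function(x, ...) {
  cat("SNP origin profile (", nrow(x$sites), " sites, ",
      x$n_sites_missing, " missing)\n", sep = "")
  print(x$sites, row.names = FALSE)
  if (!is.na(x$pooled$fraction_mt))
    cat(sprintf("pooled: %.2f%% mitochondrial-type, %.2f%% NUMT-type (n = %d)\n",
                100 * x$pooled$fraction_mt, 100 * x$pooled$fraction_numt,
                x$pooled$n_mt + x$pooled$n_numt))
  invisible(x)
}
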