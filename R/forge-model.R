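#' Configuration for the synthetic cell forge
#'
#' Describes a multi-compartment plant cell: a diploid nuclear genome, a
#' high-copy mitochondrial genome and a plastid genome, plus (optionally) a
#' NUMT — a near-identical nuclear insertion of a mitochondrial segment
#' distinguished from the organellar original by diagnostic SNPs — and a
#' mitochondrial deletion whose ends are rejoined by a recombination-style
#' junction. The defaults are a desk-scale cell: compartment lengths are
#' scaled down roughly sevenfold from Arabidopsis so that 1e5 read pairs
#' already give deep organellar coverage, while per-cell copy numbers keep
#' realistic magnitudes (2 nuclear, 100 mitochondrial, 50 plastid copies).
#'
#' @param nuclear_length,mitochondrial_length,plastid_length Compartment
#'   lengths in bp. The nuclear length is the final length including the NUMT
#'   insertion.
#' @param nuclear_copies,mitochondrial_copies,plastid_copies Copies per cell.
#'   Nuclear defaults to 2 (a 2C diploid cell). `mitochondrial_copies = 0`
#'   models a cell whose intact mitochondrial genomes are entirely lost.
#' @param gc Named numeric of GC fractions per compartment.
#' @param numt_source_start,numt_source_end 0-based half-open interval on the
#'   mitochondrial sequence that the NUMT copies.
#' @param numt_insertion_pos 0-based insertion point on the nuclear backbone.
#' @param numt_snp_offsets Offsets (bp, within the copied segment) of the
#'   diagnostic SNPs that distinguish NUMT from mitochondrial sequence.
#' @param numt_copies_per_haploid Integer >= 0; per-cell NUMT copy number is
#'   twice this for the diploid nucleus. 0 disables the NUMT.
#' @param deletion_start,deletion_end 0-based half-open deletion interval on
#'   the mitochondrial sequence, or `NULL` for no mutant derivative.
#' @param junction_mode `"simple_join"` (ends fused directly) or
#'   `"microhomology_join"` (a 20 bp patch from the left flank is copied over
#'   the right flank, mimicking repair through a short homologous tract).
#' @param n_genes Named integer vector: annotated genes per compartment.
#' @param gene_length Length of each annotated gene (bp).
#'
#' @return An object of class `forge_config`.
#' @export
forge_config <- function(nuclear_length = 200000L,
                         mitochondrial_length = 50000L,
                         plastid_length = 30000L,
                         nuclear_copies = 2,
                         mitochondrial_copies = 100,
                         plastid_copies = 50,
                         gc = c(nuclear = 0.36, mitochondrial = 0.45,
                                plastid = 0.36),
                         numt_source_start = 20000L,
                         numt_source_end = 26000L,
                         numt_insertion_pos = 100000L,
                         numt_snp_offsets = c(2500L, 3500L),
                         numt_copies_per_haploid = 1L,
                         deletion_start = 20000L,
                         deletion_end = 25500L,
                         junction_mode = c("simple_join", "microhomology_join"),
                         n_genes = c(nuclear = 40L, mitochondrial = 30L,
                                     plastid = 20L),
                         gene_length = 600L) {
  junction_mode <- match.arg(junction_mode)
  lens <- c(nuclear = nuclear_length, mitochondrial = mitochondrial_length,
            plastid = plastid_length)
  copies <- c(nuclear = nuclear_copies, mitochondrial = mitochondrial_copies,
              plastid = plastid_copies)
  if (any(lens < 1500)) stopf("compartment lengths must be >= 1500 bp")
  if (any(copies < 0)) stopf("copies per cell must be >= 0")
  if (any(gc <= 0 | gc >= 1)) stopf("gc fractions must lie in (0, 1)")

  numt <- NULL
  if (!is.null(numt_source_start)) {
    seg_len <- numt_source_end - numt_source_start
    if (seg_len <= 0) stopf("NUMT source interval must have positive length")
    if (numt_source_end > mitochondrial_length)
      stopf("NUMT source interval exceeds the mitochondrial length")
    if (any(numt_snp_offsets < 0 | numt_snp_offsets >= seg_len))
      stopf("SNP offsets must lie inside the NUMT source interval")
    numt <- list(source_start = as.integer(numt_source_start),
                 source_end = as.integer(numt_source_end),
                 insertion_pos = as.integer(numt_insertion_pos),
                 snp_offsets = as.integer(sort(numt_snp_offsets)),
                 copies_per_haploid = as.integer(numt_copies_per_haploid))
  }

  deletion <- NULL
  if (!is.null(deletion_start)) {
    if (deletion_end <= deletion_start)
      stopf("deletion interval must have positive length")
    if (deletion_end - deletion_start >= mitochondrial_length)
      stopf("deletion cannot span the whole mitochondrial genome")
    if (!is.null(numt)) {
      snp_pos <- numt$source_start + numt$snp_offsets
      if (!any(snp_pos >= deletion_start & snp_pos < deletion_end))
        stopf(paste("the deletion interval must contain at least one",
                    "diagnostic SNP position when a NUMT is present"))
    }
    deletion <- list(start = as.integer(deletion_start),
                     end = as.integer(deletion_end),
                     junction_mode = junction_mode)
  }

  structure(list(lengths = lens, copies = copies, gc = gc, numt = numt,
                 deletion = deletion, n_genes = n_genes,
                 gene_length = as.integer(gene_length)),
            class = "forge_config")
}

# Place n non-overlapping genes of length gl on [0, L), avoiding `avoid`
# (a 0-based half-open interval or NULL). Starts are drawn in a reduced
# coordinate system with the forbidden start interval excised and mapped
# back, so genes are repositioned around the avoided interval and slots stay
# non-overlapping; errors only when the compartment genuinely lacks room.
place_genes <- function(n, L, gl, avoid = NULL, prefix) {
  if (n == 0L) {
    return(data.frame(gene_id = character(0), start = integer(0),
                      end = integer(0), strand = character(0)))
  }
  # starts s with s + gl > avoid[1] and s < avoid[2] would overlap
  forb_lo <- if (!is.null(avoid)) max(0L, avoid[1] - gl + 1L) else 0L
  forb_w <- if (!is.null(avoid)) avoid[2] - forb_lo else 0L
  L_red <- (L - gl + 1L) - forb_w
  slot <- floor(L_red / n)
  if (slot <= gl + 2L)
    stopf(paste("cannot place %d non-overlapping genes of %d bp on a %d bp",
                "compartment%s"), n, gl, L,
          if (forb_w > 0)
            sprintf(" while avoiding the NUMT insertion [%d, %d)",
                    avoid[1], avoid[2]) else "")
  starts <- integer(n)
  for (i in seq_len(n)) {
    lo <- (i - 1L) * slot
    u <- lo + sample.int(slot - gl, 1L)
    starts[i] <- if (u < forb_lo) u else u + forb_w
  }
  data.frame(gene_id = sprintf("%s_g%02d", prefix, seq_len(n)),
             start = starts, end = starts + gl,
             strand = sample(c("+", "-"), n, replace = TRUE))
}

#' Build a synthetic cell model
#'
#' Generates the compartment sequences, applies the NUMT insertion to the
#' nuclear sequence and the deletion + junction repair to a mutant copy of
#' the mitochondrial sequence, and annotates genes on every compartment.
#' Deterministic given `(config, seed)`.
#'
#' The NUMT is constructed by copying the configured mitochondrial segment,
#' editing the diagnostic SNP positions to a different base, and inserting the
#' edited segment into the nuclear backbone; the nuclear backbone is generated
#' shorter by the segment length so the final nuclear length equals
#' `config$lengths["nuclear"]`.
#'
#' @param config A [forge_config()].
#' @param seed Integer seed; the only source of randomness.
#' @return An object of class `cell_model` with elements `compartments`
#'   (per-compartment `seq`, `length`, `copies_per_cell`), `numt` (with the
#'   realised SNP table), `deletion`, `mt_mutant` (mutant mitochondrial
#'   sequence, if a deletion is configured) and `annotations`.
#' @export
build_cell_model <- function(config = forge_config(), seed) {
  stopifnot(inherits(config, "forge_config"))
  with_seed(seed, {
    lens <- config$lengths
    mt_seq <- random_dna(lens["mitochondrial"], config$gc["mitochondrial"])
    pt_seq <- random_dna(lens["plastid"], config$gc["plastid"])

    numt <- config$numt
    has_numt <- !is.null(numt) && numt$copies_per_haploid > 0
    seg_len <- if (!is.null(numt)) numt$source_end - numt$source_start else 0L

    backbone_len <- lens["nuclear"] - if (has_numt) seg_len else 0L
    if (!is.null(numt) && numt$insertion_pos > backbone_len)
      stopf("NUMT insertion position exceeds the nuclear backbone length")
    nuc_backbone <- random_dna(backbone_len, config$gc["nuclear"])

    numt_out <- NULL
    if (!is.null(numt)) {
      segment <- substr(mt_seq, numt$source_start + 1L, numt$source_end)
      mt_bases <- substring(segment, numt$snp_offsets + 1L,
                            numt$snp_offsets + 1L)
      numt_alleles <- other_base(mt_bases)
      for (j in seq_along(numt$snp_offsets)) {
        substr(segment, numt$snp_offsets[j] + 1L,
               numt$snp_offsets[j] + 1L) <- numt_alleles[j]
      }
      snps <- data.frame(
        label = sprintf("snp%d", seq_along(numt$snp_offsets)),
        offset = numt$snp_offsets,
        mt_pos = numt$source_start + numt$snp_offsets,
        mt_allele = mt_bases,
        numt_allele = numt_alleles,
        stringsAsFactors = FALSE)
      numt_out <- c(numt, list(segment = segment, snps = snps))
      if (has_numt) {
        nuc_seq <- paste0(substr(nuc_backbone, 1L, numt$insertion_pos),
                          segment,
                          substr(nuc_backbone, numt$insertion_pos + 1L,
                                 backbone_len))
        numt_out$insertion_start <- numt$insertion_pos
        numt_out$insertion_end <- numt$insertion_pos + seg_len
        snps$nuc_pos <- numt_out$insertion_start + numt$snp_offsets
        numt_out$snps <- snps
      } else {
        nuc_seq <- nuc_backbone
      }
    } else {
      nuc_seq <- nuc_backbone
    }

    mt_mutant <- NULL
    if (!is.null(config$deletion)) {
      d <- config$deletion
      left <- substr(mt_seq, 1L, d$start)
      right <- substr(mt_seq, d$end + 1L, lens["mitochondrial"])
      if (d$junction_mode == "microhomology_join" && d$start >= 20L) {
        # repair through a 20 bp homologous tract: the tract left of the
        # break is duplicated over the start of the right flank
        patch <- substr(left, nchar(left) - 19L, nchar(left))
        if (nchar(right) >= 20L)
          substr(right, 1L, 20L) <- patch
      }
      mt_mutant <- paste0(left, right)
    }

    avoid <- if (has_numt) {
      c(numt_out$insertion_start, numt_out$insertion_end)
    } else NULL
    ann <- rbind(
      cbind(place_genes(config$n_genes[["nuclear"]], nchar(nuc_seq),
                        config$gene_length, avoid, "nuc"),
            compartment = "nuclear"),
      cbind(place_genes(config$n_genes[["mitochondrial"]],
                        lens[["mitochondrial"]],
                        config$gene_length, NULL, "mt"),
            compartment = "mitochondrial"),
      cbind(place_genes(config$n_genes[["plastid"]], lens[["plastid"]],
                        config$gene_length, NULL, "pt"),
            compartment = "plastid"))
    ann <- ann[, c("gene_id", "compartment", "start", "end", "strand")]

    structure(list(
      compartments = list(
        nuclear = list(seq = nuc_seq, length = nchar(nuc_seq),
                       copies_per_cell = config$copies[["nuclear"]]),
        mitochondrial = list(seq = mt_seq, length = nchar(mt_seq),
                             copies_per_cell = config$copies[["mitochondrial"]]),
        plastid = list(seq = pt_seq, length = nchar(pt_seq),
                       copies_per_cell = config$copies[["plastid"]])),
      numt = numt_out,
      deletion = config$deletion,
      mt_mutant = mt_mutant,
      annotations = ann,
      config = config,
      seed = as.integer(seed)), class = "cell_model")
  })
}

#' Diagnostic SNP sites of a cell model
#'
#' @param model A [build_cell_model()] result with a NUMT.
#' @return A data.frame of SNP sites on the mitochondrial compartment
#'   (0-based `position`, `mt_allele`, `numt_allele`, `label`).
#' @export
snp_sites <- function(model) {
  stopifnot(inherits(model, "cell_model"))
  if (is.null(model$numt)) stopf("model has no NUMT, hence no SNP sites")
  s <- model$numt$snps
  data.frame(compartment = "mitochondrial", position = s$mt_pos,
             mt_allele = s$mt_allele, numt_allele = s$numt_allele,
             label = s$label, stringsAsFactors = FALSE)
}

#' Reference sequences of a cell model
#'
#' @param model A `cell_model`.
#' @param genotype Which mitochondrial sequence to return for the
#'   `mitochondrial` entry of a sample's own genome; references used for
#'   mapping are always the wild type.
#' @return Named character vector of compartment sequences.
#' @export
model_refs <- function(model, genotype = c("wild_type", "mutant")) {
  genotype <- match.arg(genotype)
  mt <- if (genotype == "mutant") {
    if (is.null(model$mt_mutant)) stopf("model has no deletion / mutant genome")
    model$mt_mutant
  } else {
    model$compartments$mitochondrial$seq
  }
  c(nuclear = model$compartments$nuclear$seq,
    mitochondrial = mt,
    plastid = model$compartments$plastid$seq)
}

#' Write a cell model to disk
#'
#' Writes one FASTA per compartment (plus the mutant mitochondrial FASTA when
#' a deletion is present), a GFF3 of the gene annotations and a `truth.json`
#' recording copy numbers, NUMT coordinates, the SNP table and the deletion
#' interval. Outputs are byte-identical across runs for the same model.
#'
#' @param model A `cell_model`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
write_cell_model <- function(model, dir) {
  stopifnot(inherits(model, "cell_model"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  for (comp in COMPARTMENTS) {
    p <- file.path(dir, paste0(comp, ".fasta"))
    ss <- Biostrings::DNAStringSet(model$compartments[[comp]]$seq)
    names(ss) <- comp
    Biostrings::writeXStringSet(ss, p)
    paths[comp] <- p
  }
  if (!is.null(model$mt_mutant)) {
    p <- file.path(dir, "mitochondrial_mutant.fasta")
    ss <- Biostrings::DNAStringSet(model$mt_mutant)
    names(ss) <- "mitochondrial_mutant"
    Biostrings::writeXStringSet(ss, p)
    paths["mitochondrial_mutant"] <- p
  }

  ann <- model$annotations
  gr <- GenomicRanges::GRanges(
    seqnames = ann$compartment,
    ranges = IRanges::IRanges(start = ann$start + 1L, end = ann$end),
    strand = ann$strand)
  S4Vectors::mcols(gr)$type <- "gene"
  S4Vectors::mcols(gr)$ID <- ann$gene_id
  pg <- file.path(dir, "annotations.gff3")
  rtracklayer::export(gr, pg, format = "gff3")
  paths["annotations"] <- pg

  truth <- list(
    seed = model$seed,
    copies_per_cell = as.list(model$config$copies),
    lengths = lapply(model$compartments, `[[`, "length"),
    numt = if (!is.null(model$numt)) list(
      source_start = model$numt$source_start,
      source_end = model$numt$source_end,
      insertion_start = model$numt$insertion_start,
      insertion_end = model$numt$insertion_end,
      copies_per_haploid = model$numt$copies_per_haploid,
      snps = model$numt$snps),
    deletion = if (!is.null(model$deletion)) list(
      start = model$deletion$start,
      end = model$deletion$end,
      length = model$deletion$end - model$deletion$start,
      junction_mode = model$deletion$junction_mode))
  pj <- file.path(dir, "truth.json")
  jsonlite::write_json(truth, pj, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  paths["truth"] <- pj
  invisible(paths)
}

#' @export
print.cell_model <- function(x, ...) {
  cat("Synthetic cell model (seed ", x$seed, ")\n", sep = "")
  for (comp in COMPARTMENTS) {
    c_ <- x$compartments[[comp]]
    cat(sprintf("  %-14s %7d bp, %6.4g copies/cell\n", comp, c_$length,
                c_$copies_per_cell))
  }
  if (!is.null(x$numt)) {
    cat(sprintf("  NUMT: mt[%d,%d) -> nuclear @%s, %d cop(y/ies)/haploid, %d SNP(s)\n",
                x$numt$source_start, x$numt$source_end,
                x$numt$insertion_start %||% "not inserted",
                x$numt$copies_per_haploid, nrow(x$numt$snps)))
  }
  if (!is.null(x$deletion)) {
    cat(sprintf("  deletion: mt[%d,%d) (%d bp, %s)\n", x$deletion$start,
                x$deletion$end, x$deletion$end - x$deletion$start,
                x$deletion$junction_mode))
  }
  cat("  annotations:", nrow(x$annotations), "genes\n")
  invisible(x)
}
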