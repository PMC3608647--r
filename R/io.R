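# Standard-format readers and writers. Coordinate conventions, stated once
# and enforced here: FASTA/SAM/VCF are 1-based; BED (mask, BED12 gene
# models) is 0-based half-open. Writers emit deterministic, sorted output
# so a fixed simulation config produces byte-identical files.
#
# Reading goes through the established Bioconductor stack (Biostrings for
# FASTA, Rsamtools for SAM via BAM conversion, VariantAnnotation for VCF,
# rtracklayer for BED), which keeps the writers honest in round-trip tests.

#' Write a reference FASTA
#' @param ref a `ref_model`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_reference_fasta <- function(ref, path) {
  dss <- Biostrings::DNAStringSet(ref$contigs)
  Biostrings::writeXStringSet(dss, filepath = path, width = 70L)
  invisible(path)
}

#' Read a reference FASTA into contig sequences
#' @param path FASTA file.
#' @return named character vector of contig sequences.
#' @export
read_reference_fasta <- function(path) {
  dss <- Biostrings::readDNAStringSet(path)
  setNames(as.character(dss), sub("\\s.*$", "", names(dss)))
}

# ---- gene models -----------------------------------------------------------

#' Write gene models as a refFlat-style table
#'
#' Eleven-column refFlat: geneName, name, chrom, strand, txStart, txEnd,
#' cdsStart, cdsEnd, exonCount, exonStarts, exonEnds, with 0-based
#' half-open transcript/exon coordinates and trailing-comma lists. The CDS
#' is set equal to the transcript (the simulator has no UTR model).
#'
#' @param genes exon `data.table` from a `ref_model`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gene_models_refflat <- function(genes, path) {
  genes <- as.data.table(genes)
  rows <- genes[order(gene_id, exon_rank),
                .(chrom = contig[1L], strand = strand[1L],
                  tx_start0 = min(start) - 1L, tx_end0 = max(end),
                  n_exon = .N,
                  starts0 = paste0(paste(start - 1L, collapse = ","), ","),
                  ends0 = paste0(paste(end, collapse = ","), ",")),
                by = "gene_id"]
  lines <- if (nrow(rows) == 0L) character(0) else
    sprintf("%s\t%s\t%s\t%s\t%d\t%d\t%d\t%d\t%d\t%s\t%s",
            rows$gene_id, rows$gene_id, rows$chrom, rows$strand,
            rows$tx_start0, rows$tx_end0, rows$tx_start0, rows$tx_end0,
            rows$n_exon, rows$starts0, rows$ends0)
  writeLines(lines, path)
  invisible(path)
}
utils::globalVariables(c("tx_start0", "tx_end0", "n_exon", "starts0", "ends0"))

#' Read a refFlat-style gene model table
#' @param path refFlat file.
#' @return exon `data.table` (`gene_id`, `contig`, `strand`, `exon_rank`,
#'   `start`, `end`; 1-based closed).
#' @export
read_gene_models_refflat <- function(path) {
  cols <- c("gene_id", "name", "contig", "strand", "tx_start", "tx_end",
            "cds_start", "cds_end", "n_exon", "starts", "ends")
  raw <- utils::read.delim(path, header = FALSE, col.names = cols,
                           colClasses = "character")
  if (nrow(raw) == 0L) {
    return(data.table(gene_id = character(), contig = character(),
                      strand = character(), exon_rank = integer(),
                      start = integer(), end = integer()))
  }
  out <- lapply(seq_len(nrow(raw)), function(i) {
    s0 <- as.integer(strsplit(raw$starts[i], ",")[[1]])
    e0 <- as.integer(strsplit(raw$ends[i], ",")[[1]])
    data.table(gene_id = raw$gene_id[i], contig = raw$contig[i],
               strand = raw$strand[i], exon_rank = seq_along(s0),
               start = s0 + 1L, end = e0)
  })
  data.table::rbindlist(out)
}

#' Write gene models as BED12
#' @inheritParams write_gene_models_refflat
#' @export
write_gene_models_bed12 <- function(genes, path) {
  genes <- as.data.table(genes)
  rows <- genes[order(gene_id, exon_rank),
                .(chrom = contig[1L], strand = strand[1L],
                  tx_start0 = min(start) - 1L, tx_end0 = max(end),
                  n_exon = .N,
                  sizes = paste0(paste(end - start + 1L, collapse = ","), ","),
                  rel0 = paste0(paste(start - min(start), collapse = ","), ",")),
                by = "gene_id"]
  lines <- if (nrow(rows) == 0L) character(0) else
    sprintf("%s\t%d\t%d\t%s\t0\t%s\t%d\t%d\t0\t%d\t%s\t%s",
            rows$chrom, rows$tx_start0, rows$tx_end0, rows$gene_id,
            rows$strand, rows$tx_start0, rows$tx_end0,
            rows$n_exon, rows$sizes, rows$rel0)
  writeLines(lines, path)
  invisible(path)
}
utils::globalVariables(c("sizes", "rel0"))

# ---- SAM -------------------------------------------------------------------

#' Write ungapped single-end alignments as a sorted SAM file
#'
#' Emits a coordinate-sorted SAM with mandatory `@HD`/`@SQ` headers.
#' FLAG carries strand (0x10) and the duplicate mark (0x400); CIGAR is
#' all-match since the simulator produces ungapped alignments.
#'
#' @param alignments alignment `data.table`.
#' @param ref a `ref_model` (for `@SQ` lengths).
#' @param path output SAM file.
#' @return `path`, invisibly.
#' @export
write_alignments_sam <- function(alignments, ref, path) {
  al <- as.data.table(alignments)
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(ref$contigs),
                   nchar(ref$contigs)))
  body <- character(0)
  if (nrow(al) > 0L) {
    ord <- order(match(al$contig, names(ref$contigs)), al$start, al$read_id)
    al <- al[ord]
    flag <- ifelse(al$strand == "-", 16L, 0L) +
      ifelse(isTRUE_vec(al$is_dup), 1024L, 0L)
    body <- sprintf("%s\t%d\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t%s",
                    al$read_id, flag, al$contig, al$start,
                    nchar(al$bases), al$bases, al$quals)
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

isTRUE_vec <- function(x) if (is.null(x)) FALSE else x %in% TRUE

#' Read a SAM file of ungapped single-end alignments
#'
#' Converts through BAM with Rsamtools and recovers the package's
#' alignment-table representation (strand from FLAG 0x10, duplicate mark
#' from 0x400).
#'
#' @param path SAM file.
#' @return alignment `data.table`.
#' @export
read_alignments_sam <- function(path) {
  bam <- Rsamtools::asBam(path, destination = tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  on.exit(unlink(c(bam, paste0(bam, ".bai"))), add = TRUE)
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "qwidth", "seq", "qual"),
    flag = Rsamtools::scanBamFlag()
  )
  x <- Rsamtools::scanBam(bam, param = p)[[1]]
  n <- length(x$qname)
  if (n == 0L) return(empty_reads())
  data.table(
    read_id = x$qname,
    contig = as.character(x$rname),
    start = x$pos,
    end = x$pos + x$qwidth - 1L,
    strand = ifelse(bitwAnd(x$flag, 16L) > 0L, "-", "+"),
    bases = as.character(x$seq),
    quals = as.character(x$qual),
    is_dup = bitwAnd(x$flag, 1024L) > 0L
  )
}

# ---- VCF -------------------------------------------------------------------

vcf_header <- function(ref, info = FALSE, sample = "sample1") {
  c("##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", names(ref$contigs),
            nchar(ref$contigs)),
    if (info) c(
      "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
      "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Alternate allele fraction\">"
    ),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", sample))
}

#' Write a truth-variant table as VCF
#'
#' Biallelic SNVs with a single sample whose GT is `0/1` (het) or `1/1`
#' (hom_alt).
#'
#' @param truth truth-variant table.
#' @param ref a `ref_model` (for contig header lines).
#' @param path output VCF file.
#' @return `path`, invisibly.
#' @export
write_truth_vcf <- function(truth, ref, path) {
  truth <- as.data.table(truth)
  body <- character(0)
  if (nrow(truth) > 0L) {
    # NB: compute the order outside `[` - `ref` is also a column name
    ord <- order(match(truth$contig, names(ref$contigs)), truth$pos)
    truth <- truth[ord]
    gt <- ifelse(truth$zygosity == "het", "0/1", "1/1")
    body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tGT\t%s",
                    truth$contig, truth$pos, truth$ref, truth$alt, gt)
  }
  writeLines(c(vcf_header(ref), body), path)
  invisible(path)
}

#' Write a call set as VCF
#'
#' INFO carries DP and AF; the FILTER column carries `PASS` or the filter
#' tags assigned by the filter stages.
#'
#' @param calls call set `data.table`.
#' @inheritParams write_truth_vcf
#' @export
write_calls_vcf <- function(calls, ref, path) {
  calls <- as.data.table(calls)
  body <- character(0)
  if (nrow(calls) > 0L) {
    ord <- order(match(calls$contig, names(ref$contigs)), calls$pos)
    calls <- calls[ord]
    gt <- ifelse(calls$genotype == "het", "0/1", "1/1")
    body <- sprintf("%s\t%d\t.\t%s\t%s\t.\t%s\tDP=%d;AF=%.6g\tGT\t%s",
                    calls$contig, calls$pos, calls$ref, calls$alt,
                    calls$filter, calls$depth, calls$alt_fraction, gt)
  }
  writeLines(c(vcf_header(ref, info = TRUE), body), path)
  invisible(path)
}

gt_to_zygosity <- function(gt) {
  z <- rep(NA_character_, length(gt))
  z[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- "het"
  z[gt %in% c("1/1", "1|1")] <- "hom_alt"
  z
}

read_vcf_table <- function(path) {
  vcf <- VariantAnnotation::readVcf(path, genome = "synthetic")
  rr <- SummarizedExperiment::rowRanges(vcf)
  n <- length(rr)
  if (n == 0L) {
    return(data.table(contig = character(), pos = integer(),
                      ref = character(), alt = character(),
                      gt = character(), filter = character()))
  }
  alt <- vapply(as.list(VariantAnnotation::alt(vcf)), function(a) {
    as.character(a)[1]
  }, character(1))
  gt <- as.character(VariantAnnotation::geno(vcf)$GT[, 1])
  data.table(
    contig = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    ref = as.character(VariantAnnotation::ref(vcf)),
    alt = alt,
    gt = gt,
    filter = as.character(VariantAnnotation::filt(vcf))
  )
}

#' Read a truth VCF
#' @param path VCF file with a single sample and GT genotypes.
#' @return truth-variant `data.table` (`contig`, `pos`, `ref`, `alt`,
#'   `zygosity`).
#' @export
read_truth_vcf <- function(path) {
  x <- read_vcf_table(path)
  x[, .(contig, pos, ref, alt, zygosity = gt_to_zygosity(gt))]
}
utils::globalVariables("gt")

#' Read a call-set VCF written by [write_calls_vcf()]
#' @param path VCF file.
#' @return call set `data.table`.
#' @export
read_calls_vcf <- function(path) {
  x <- read_vcf_table(path)
  if (nrow(x) == 0L) {
    return(data.table(contig = character(), pos = integer(),
                      ref = character(), alt = character(),
                      genotype = character(), depth = integer(),
                      alt_fraction = numeric(), filter = character()))
  }
  vcf <- VariantAnnotation::readVcf(path, genome = "synthetic")
  info <- VariantAnnotation::info(vcf)
  x[, .(contig, pos, ref, alt, genotype = gt_to_zygosity(gt),
        depth = as.integer(info$DP), alt_fraction = as.numeric(info$AF),
        filter)]
}

# ---- BED (mask) ------------------------------------------------------------

#' Write mask intervals as BED3
#' @param mask mask `data.table` (`contig`, `start` 0-based, `end`
#'   exclusive).
#' @param path output BED file.
#' @export
write_mask_bed <- function(mask, path) {
  mask <- as.data.table(mask)
  lines <- if (nrow(mask) == 0L) character(0) else {
    mask <- mask[order(contig, start)]
    sprintf("%s\t%d\t%d", mask$contig, mask$start, mask$end)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED3 mask file
#' @param path BED file.
#' @return mask `data.table` with 0-based half-open intervals.
#' @export
read_mask_bed <- function(path) {
  if (length(readLines(path, n = 1L)) == 0L) {
    return(data.table(contig = character(), start = integer(),
                      end = integer()))
  }
  gr <- rtracklayer::import(path, format = "bed")
  out <- data.table(
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,     # back to BED 0-based
    end = GenomicRanges::end(gr)
  )
  validate_mask(out)
  out
}

# ---- fixture bundle --------------------------------------------------------

#' Write a complete fixture-file bundle
#'
#' Writes the reference FASTA, gene models (refFlat and BED12), truth VCF,
#' RNA and evidence SAM, and mask BED to `outdir`. Reading the files back
#' with the package's readers reproduces the in-memory objects.
#'
#' @param ref a `ref_model`.
#' @param truth truth-variant table.
#' @param rna,evidence alignment tables.
#' @param mask mask interval table.
#' @param outdir output directory (created if needed).
#' @return named character vector of written paths (the manifest).
#' @export
emit_fixture_files <- function(ref, truth, rna, evidence, mask, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    reference_fasta = file.path(outdir, "reference.fa"),
    genes_refflat = file.path(outdir, "genes.refflat"),
    genes_bed12 = file.path(outdir, "genes.bed12"),
    truth_vcf = file.path(outdir, "truth.vcf"),
    rna_sam = file.path(outdir, "rna.sam"),
    evidence_sam = file.path(outdir, "evidence.sam"),
    mask_bed = file.path(outdir, "mask.bed")
  )
  wrap_io <- function(path, expr) {
    tryCatch(expr, error = function(e) {
      stop("failed writing ", path, ": ", conditionMessage(e))
    })
  }
  wrap_io(paths["reference_fasta"],
          write_reference_fasta(ref, paths["reference_fasta"]))
  wrap_io(paths["genes_refflat"],
          write_gene_models_refflat(ref$genes, paths["genes_refflat"]))
  wrap_io(paths["genes_bed12"],
          write_gene_models_bed12(ref$genes, paths["genes_bed12"]))
  wrap_io(paths["truth_vcf"], write_truth_vcf(truth, ref, paths["truth_vcf"]))
  wrap_io(paths["rna_sam"], write_alignments_sam(rna, ref, paths["rna_sam"]))
  wrap_io(paths["evidence_sam"],
          write_alignments_sam(evidence, ref, paths["evidence_sam"]))
  wrap_io(paths["mask_bed"], write_mask_bed(mask, paths["mask_bed"]))
  paths
}
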