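# Shared fixture builders. Everything is generated in code; no binary or
# stored test data.

library(data.table)

tiny_config <- function(seed = 1L, ...) {
  args <- list(seed = seed, n_contigs = 1L, contig_length = 20000L,
               n_genes = 6L, exons_per_gene = c(2L, 4L), n_reads = 2000L)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(sim_config, args)
}

# a bare reference with no gene models, for hand-built alignments
flat_ref <- function(seqs) {
  structure(list(
    contigs = seqs,
    genes = data.table(gene_id = character(), contig = character(),
                       strand = character(), exon_rank = integer(),
                       start = integer(), end = integer())
  ), class = "ref_model")
}

random_flat_ref <- function(len = 5000L, contigs = "chr1") {
  seqs <- vapply(contigs, function(x) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
  flat_ref(seqs)
}

make_read <- function(contig, start, bases, strand = "+", q = 30L,
                      read_id = NULL, is_dup = FALSE) {
  data.table(
    read_id = if (is.null(read_id)) sprintf("r_%s_%d_%s", contig, start,
                                            substr(bases, 1, 4)) else read_id,
    contig = contig, start = as.integer(start),
    end = as.integer(start + nchar(bases) - 1L), strand = strand,
    bases = bases, quals = strrep(intToUtf8(q + 33L), nchar(bases)),
    is_dup = is_dup)
}

make_reads <- function(...) rbindlist(list(...))

# reads copied straight from a reference (error-free), for pileup tests
ref_read <- function(ref, contig, start, len, ...) {
  make_read(contig, start,
            substring(ref$contigs[[contig]], start, start + len - 1L), ...)
}

random_calls <- function(n, contigs = c("chr1", "chr2"), pos_max = 10000L) {
  data.table(
    contig = sample(contigs, n, replace = TRUE),
    pos = sample.int(pos_max, n, replace = TRUE),
    ref = sample(c("A", "C", "G", "T"), n, replace = TRUE),
    alt = sample(c("A", "C", "G", "T"), n, replace = TRUE),
    genotype = sample(c("het", "hom_alt"), n, replace = TRUE),
    depth = sample(3:40, n, replace = TRUE),
    alt_fraction = runif(n, 0.2, 1),
    filter = "PASS"
  )[!duplicated(paste(contig, pos))]
}
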