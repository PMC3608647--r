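# Generator behavior: seeded determinism, empty cases, placement
# constraints, and distributional checks against exact binomial /
# multinomial expectations.

test_that("build_reference handles empty and deterministic cases", {
  cfg0 <- tiny_config(n_genes = 0L)
  ref0 <- build_reference(cfg0)
  expect_length(ref0$contigs, 1L)
  expect_identical(nrow(ref0$genes), 0L)

  cfg <- tiny_config(seed = 5L)
  expect_identical(build_reference(cfg), build_reference(cfg))

  # sizing error names the constraint
  cfg_big <- tiny_config(n_genes = 200L, contig_length = 5000L)
  expect_error(build_reference(cfg_big), "contig too short")
})

test_that("exon geometry: counts match the emitted gene-model file and every exon hosts a read", {
  cfg <- sim_config(seed = 3L, n_genes = 50L, exons_per_gene = c(1L, 8L))
  ref <- build_reference(cfg)
  expect_true(all(ref$genes$end - ref$genes$start + 1L >= cfg$read_length))
  # exons within a gene sorted, non-overlapping, inside the contig
  by_gene <- split(ref$genes, ref$genes$gene_id)
  for (g in by_gene) {
    expect_true(all(diff(g$start) > 0))
    expect_true(all(g$start[-1] > g$end[-nrow(g)]))
    expect_true(all(g$end <= nchar(ref$contigs[[g$contig[1]]])))
  }
  # re-count exon records from the emitted refFlat file
  f <- tempfile(fileext = ".refflat")
  write_gene_models_refflat(ref$genes, f)
  reread <- read_gene_models_refflat(f)
  expect_identical(nrow(reread), nrow(ref$genes))
  expect_identical(length(unique(reread$gene_id)), cfg$n_genes)
})

test_that("plant_truth_variants respects density, zygosity and mask exclusion", {
  cfg <- tiny_config(variants_per_kb = 0)
  ref <- build_reference(cfg)
  expect_identical(nrow(plant_truth_variants(ref, cfg)), 0L)

  cfg1 <- tiny_config(het_fraction = 1, variants_per_kb = 5)
  tr1 <- plant_truth_variants(build_reference(cfg1), cfg1)
  expect_true(all(tr1$zygosity == "het"))

  # ref alleles match the reference; alt differs; sites unique and exonic
  cfg2 <- tiny_config(seed = 9L, variants_per_kb = 3)
  ref2 <- build_reference(cfg2)
  tr2 <- plant_truth_variants(ref2, cfg2)
  expect_false(any(duplicated(paste(tr2$contig, tr2$pos))))
  expect_identical(tr2$ref,
                   unname(substring(ref2$contigs[tr2$contig], tr2$pos,
                                    tr2$pos)))
  expect_true(all(tr2$alt != tr2$ref))
  in_exon <- logical(nrow(tr2))
  for (i in seq_len(nrow(tr2))) {
    in_exon[i] <- any(ref2$genes$contig == tr2$contig[i] &
                        ref2$genes$start <= tr2$pos[i] &
                        ref2$genes$end >= tr2$pos[i])
  }
  expect_true(all(in_exon))

  # masked positions never carry a planted variant
  mask <- simulate_mask(ref2, tiny_config(seed = 9L, mask_fraction = 0.3))
  tr3 <- plant_truth_variants(ref2, cfg2, mask = mask)
  expect_true(nrow(tr3) < nrow(tr2))
  hit <- mapply(function(ctg, p) {
    any(mask$contig == ctg & mask$start <= p - 1L & p - 1L < mask$end)
  }, tr3$contig, tr3$pos)
  expect_false(any(hit))
})

test_that("planted-variant count matches the exact binomial expectation", {
  # density 2/kb over the exonic footprint; pooled over 20 seeds the total
  # is Binomial(20 * N_exonic, p): check against its 99.99% interval
  counts <- integer(20)
  nex <- integer(20)
  for (i in 1:20) {
    cfg <- tiny_config(seed = 1000L + i, variants_per_kb = 2)
    ref <- build_reference(cfg)
    nex[i] <- sum(ref$genes$end - ref$genes$start + 1L)
    counts[i] <- nrow(plant_truth_variants(ref, cfg))
  }
  p <- 2 / 1000
  n_tot <- sum(nex)
  bounds <- qbinom(c(5e-5, 1 - 5e-5), n_tot, p)
  expect_gte(sum(counts), bounds[1])
  expect_lte(sum(counts), bounds[2])
})

test_that("error-free variant-free reads reproduce the reference exactly", {
  cfg <- tiny_config(seed = 2L, error_rate = 0, variants_per_kb = 0,
                     pcr_duplicate_rate = 0, off_exon_fraction = 0,
                     n_reads = 500L)
  ref <- build_reference(cfg)
  truth <- plant_truth_variants(ref, cfg)
  rna <- simulate_rna_alignments(ref, truth, cfg)
  expect_identical(nrow(rna), 500L)
  expect_identical(rna$bases,
                   unname(substring(ref$contigs[rna$contig], rna$start,
                                    rna$end)))
})

test_that("duplicate emission: rate 0 collides only by chance; with-errors copies share coordinates", {
  # sparse configuration: collisions bounded by the enumerated expectation
  cfg <- tiny_config(seed = 21L, pcr_duplicate_rate = 0, n_reads = 300L,
                     off_exon_fraction = 0, variants_per_kb = 0,
                     expression_weights = rep(1, 6))
  ref <- build_reference(cfg)
  rna <- simulate_rna_alignments(ref, plant_truth_variants(ref, cfg), cfg)
  keys <- paste(rna$contig, rna$start, rna$end, rna$strand)
  n_dup_pairs <- nrow(rna) - length(unique(keys))
  # uniform weights: per-slot probability = 1/(2 * total start positions)
  n_pos <- sum(ref$genes$end - ref$genes$start + 1L - cfg$read_length + 1L)
  lambda <- choose(nrow(rna), 2) / (2 * n_pos)     # expected collision pairs
  expect_lte(n_dup_pairs, qpois(0.9999, lambda))

  cfg2 <- tiny_config(seed = 22L, pcr_duplicate_rate = 1,
                      duplicate_error_mode = "with_errors", n_reads = 200L)
  ref2 <- build_reference(cfg2)
  tr2 <- plant_truth_variants(ref2, cfg2)
  rna2 <- simulate_rna_alignments(ref2, tr2, cfg2)
  expect_gt(nrow(rna2), 2L * 200L - 1L)   # every fragment emitted >= twice
  frag <- sub("_c\\d+$", "", rna2$read_id)
  key_by_frag <- split(paste(rna2$contig, rna2$start, rna2$end, rna2$strand),
                       frag)
  expect_true(all(vapply(key_by_frag,
                         function(k) length(unique(k)) == 1L, logical(1))))
})

test_that("read counts per gene follow expression weights (exact multinomial margin)", {
  cfg <- tiny_config(seed = 31L, n_genes = 2L, exons_per_gene = c(1L, 1L),
                     n_reads = 10000L, off_exon_fraction = 0,
                     variants_per_kb = 0, error_rate = 0,
                     pcr_duplicate_rate = 0, expression_weights = c(9, 1))
  ref <- build_reference(cfg)
  rna <- simulate_rna_alignments(ref, plant_truth_variants(ref, cfg), cfg)
  g1 <- ref$genes[gene_id == "gene001"]
  n_g1 <- sum(rna$contig == g1$contig & rna$start >= g1$start &
                rna$end <= g1$end)
  bounds <- qbinom(c(5e-5, 1 - 5e-5), 10000L, 0.9)
  expect_gte(n_g1, bounds[1])
  expect_lte(n_g1, bounds[2])
})

test_that("het allele balance in reads matches Binomial(n, 1/2)", {
  alt_n <- 0L; tot_n <- 0L
  for (s in 41:45) {
    cfg <- tiny_config(seed = s, error_rate = 0, pcr_duplicate_rate = 0,
                       variants_per_kb = 2, het_fraction = 1,
                       n_reads = 3000L, off_exon_fraction = 0)
    ref <- build_reference(cfg)
    tr <- plant_truth_variants(ref, cfg)
    rna <- simulate_rna_alignments(ref, tr, cfg)
    pile <- build_pileup(rna, ref)
    at <- pile[tr, on = c("contig", "pos"), nomatch = NULL]
    m <- as.matrix(at[, .(A, C, G, T)])
    alt_n <- alt_n + sum(m[cbind(seq_len(nrow(at)), match(at$alt, c("A","C","G","T")))])
    tot_n <- tot_n + sum(at$depth)
  }
  bounds <- qbinom(c(5e-5, 1 - 5e-5), tot_n, 0.5)
  expect_gte(alt_n, bounds[1])
  expect_lte(alt_n, bounds[2])
})

test_that("evidence alignments: empty at depth 0, pure alt at hom sites, binomial at het sites", {
  cfg0 <- tiny_config(evidence_depth = 0)
  ref <- build_reference(cfg0)
  tr <- plant_truth_variants(ref, cfg0)
  expect_identical(nrow(simulate_evidence_alignments(ref, tr, cfg0)), 0L)

  cfg <- tiny_config(seed = 51L, evidence_depth = 25, error_rate = 0,
                     variants_per_kb = 2, het_fraction = 0)
  ref <- build_reference(cfg)
  tr <- plant_truth_variants(ref, cfg)
  ev <- simulate_evidence_alignments(ref, tr, cfg)
  pile <- build_pileup(ev, ref)
  at <- pile[tr, on = c("contig", "pos"), nomatch = NULL]
  m <- as.matrix(at[, .(A, C, G, T)])
  altc <- m[cbind(seq_len(nrow(at)), match(at$alt, c("A","C","G","T")))]
  expect_identical(as.integer(altc), at$depth)   # 100% alt at hom_alt sites

  # het: pooled alt count over seeds is Binomial(total, 1/2)
  alt_n <- 0L; tot_n <- 0L
  for (s in 61:64) {
    cfg <- tiny_config(seed = s, evidence_depth = 30, error_rate = 0,
                       variants_per_kb = 2, het_fraction = 1)
    ref <- build_reference(cfg)
    tr <- plant_truth_variants(ref, cfg)
    ev <- simulate_evidence_alignments(ref, tr, cfg)
    pile <- build_pileup(ev, ref)
    at <- pile[tr, on = c("contig", "pos"), nomatch = NULL]
    m <- as.matrix(at[, .(A, C, G, T)])
    alt_n <- alt_n + sum(m[cbind(seq_len(nrow(at)), match(at$alt, c("A","C","G","T")))])
    tot_n <- tot_n + sum(at$depth)
  }
  bounds <- qbinom(c(5e-5, 1 - 5e-5), tot_n, 0.5)
  expect_gte(alt_n, bounds[1])
  expect_lte(alt_n, bounds[2])
})

test_that("mask covers the configured fraction of the exonic footprint", {
  cfg <- tiny_config(seed = 71L, mask_fraction = 0.1)
  ref <- build_reference(cfg)
  mask <- simulate_mask(ref, cfg)
  target <- 0.1 * sum(ref$genes$end - ref$genes$start + 1L)
  covered <- sum(mask$end - mask$start)          # merged, so a plain sum
  expect_gte(covered, target - 1)
  expect_lte(covered, target + 250)              # one interval of overshoot
})

test_that("identical configs give byte-identical fixture files", {
  cfg <- tiny_config(seed = 81L, n_reads = 400L)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  o1 <- emit_fixture_files(d1$ref, d1$truth, d1$rna, d1$evidence, d1$mask,
                           tempfile("fixA"))
  o2 <- emit_fixture_files(d2$ref, d2$truth, d2$rna, d2$evidence, d2$mask,
                           tempfile("fixB"))
  expect_identical(unname(tools::md5sum(o1)), unname(tools::md5sum(o2)))
})
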