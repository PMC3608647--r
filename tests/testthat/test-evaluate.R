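# Expected-call set, TP/FP/FN classification, stratified metrics and
# call-set overlap, each against brute-force oracles.

mk_truth <- function(contig, pos, ref = "A", alt = "G", zyg = "het") {
  data.table(contig = contig, pos = as.integer(pos), ref = ref, alt = alt,
             zygosity = zyg)
}

empty_reads_tbl <- function() {
  data.table(read_id = character(), contig = character(), start = integer(),
             end = integer(), strand = character(), bases = character(),
             quals = character(), is_dup = logical())
}

test_that("truth_site_depth counts covering unflagged reads", {
  tr <- mk_truth("chr1", c(50, 500))
  expect_identical(truth_site_depth(tr, empty_reads_tbl())$depth, c(0L, 0L))
  r <- make_read("chr1", 41, strrep("A", 40))
  expect_identical(truth_site_depth(tr, r)$depth, c(1L, 0L))
  rd <- copy(r)[, is_dup := TRUE]
  expect_identical(truth_site_depth(tr, rd)$depth, c(0L, 0L))
})

test_that("truth_site_depth equals the pileup oracle on random alignments", {
  for (s in 1:3) {
    set.seed(400 + s)
    n <- 800L
    reads <- data.table(
      read_id = sprintf("r%04d", 1:n),
      contig = sample(c("chr1", "chr2"), n, replace = TRUE),
      start = sample.int(2000L, n, replace = TRUE),
      strand = "+", bases = strrep("A", 30), quals = strrep("I", 30),
      is_dup = sample(c(TRUE, FALSE), n, replace = TRUE, prob = c(0.2, 0.8))
    )
    reads[, end := start + 29L]
    tr <- mk_truth(sample(c("chr1", "chr2"), 200L, replace = TRUE),
                   sample.int(2100L, 200L))
    got <- truth_site_depth(tr, reads)$depth
    want <- vapply(seq_len(nrow(tr)), function(i) {
      sum(!reads$is_dup & reads$contig == tr$contig[i] &
            reads$start <= tr$pos[i] & reads$end >= tr$pos[i])
    }, integer(1))
    expect_identical(got, want)
  }
})

test_that("expected_call_set keeps exactly the sites at or above the floor", {
  tr <- mk_truth("chr1", 1:5)
  tr[, depth := c(0L, 2L, 3L, 4L, 10L)]
  expect_identical(expected_call_set(tr)$pos, c(3L, 4L, 5L))  # 3x inclusive
  expect_identical(nrow(expected_call_set(copy(tr)[, depth := 0L])), 0L)
  set.seed(1); d <- sample(0:20, 5, replace = TRUE)
  tr[, depth := d]
  expect_identical(expected_call_set(tr)$pos, tr$pos[d >= 3])
})

test_that("call classification follows the truth-then-catalog rule", {
  truth <- mk_truth("chr1", c(10, 20), zyg = c("het", "het"))
  cat_dt <- allele_catalog(truth,
                           extra = data.table(contig = "chr1", pos = 30L,
                                              alleles = "A,G"))
  calls <- data.table(contig = "chr1", pos = c(10L, 20L, 30L, 40L),
                      ref = "A", alt = "G",
                      genotype = c("het", "hom_alt", "hom_alt", "het"),
                      depth = 10L, alt_fraction = 0.5, filter = "PASS")
  lab <- classify_calls(calls, truth, cat_dt)
  # exact truth match; genotype mismatch at truth site is FP even though
  # the alleles are catalogued; catalog-only allele match; novel site
  expect_identical(lab$label, c("TP", "FP", "TP", "FP"))
  wrong_alt <- copy(calls)[2, `:=`(genotype = "het", alt = "T")]
  expect_identical(classify_calls(wrong_alt, truth, cat_dt)$label[2], "FP")
})

test_that("classification matches the three-way lookup oracle on random data", {
  for (s in 1:3) {
    set.seed(500 + s)
    calls <- random_calls(700L, pos_max = 1500L)
    truth <- mk_truth(sample(c("chr1", "chr2"), 400L, replace = TRUE),
                      sample.int(1500L, 400L),
                      ref = sample(c("A", "C"), 400L, replace = TRUE),
                      alt = sample(c("G", "T"), 400L, replace = TRUE),
                      zyg = sample(c("het", "hom_alt"), 400L, replace = TRUE))
    truth <- truth[!duplicated(paste(contig, pos))]
    cat_dt <- allele_catalog(
      truth[1:100],
      extra = data.table(contig = sample(c("chr1", "chr2"), 150L, TRUE),
                         pos = sample.int(1500L, 150L),
                         alleles = replicate(150L, paste(
                           sample(c("A", "C", "G", "T"), 2), collapse = ","))))
    got <- classify_calls(calls, truth, cat_dt)$label
    want <- vapply(seq_len(nrow(calls)), function(i) {
      ti <- which(truth$contig == calls$contig[i] & truth$pos == calls$pos[i])
      if (length(ti)) {
        if (truth$zygosity[ti] == calls$genotype[i] &&
            truth$alt[ti] == calls$alt[i] && truth$ref[ti] == calls$ref[i])
          "TP" else "FP"
      } else {
        ci <- which(cat_dt$contig == calls$contig[i] &
                      cat_dt$pos == calls$pos[i])
        if (length(ci)) {
          al <- strsplit(cat_dt$alleles[ci[1]], ",")[[1]]
          if (calls$ref[i] %in% al && calls$alt[i] %in% al) "TP" else "FP"
        } else "FP"
      }
    }, character(1))
    expect_identical(got, want)

    # truth-side labels against the same oracle logic
    expected <- copy(truth)[, depth := sample(3:30, .N, replace = TRUE)]
    tgot <- classify_truth(expected, calls)$label
    twant <- vapply(seq_len(nrow(expected)), function(i) {
      ci <- which(calls$contig == expected$contig[i] &
                    calls$pos == expected$pos[i])
      if (length(ci) && calls$genotype[ci[1]] == expected$zygosity[i] &&
          calls$alt[ci[1]] == expected$alt[i]) "TP" else "FN"
    }, character(1))
    expect_identical(tgot, twant)
  }
})

test_that("classify_truth covers the stated edge cases", {
  expected <- mk_truth("chr1", c(10, 20), zyg = c("het", "het"))
  expected[, depth := 5L]
  no_calls <- data.table(contig = character(), pos = integer(),
                         ref = character(), alt = character(),
                         genotype = character(), depth = integer(),
                         alt_fraction = numeric(), filter = character())
  expect_identical(classify_truth(expected, no_calls)$label, c("FN", "FN"))
  hom_call <- data.table(contig = "chr1", pos = 10L, ref = "A", alt = "G",
                         genotype = "hom_alt", depth = 10L,
                         alt_fraction = 1, filter = "PASS")
  expect_identical(classify_truth(expected, hom_call)$label, c("FN", "FN"))
  match_calls <- data.table(contig = "chr1", pos = c(10L, 20L), ref = "A",
                            alt = "G", genotype = "het", depth = 10L,
                            alt_fraction = 0.5, filter = "PASS")
  expect_identical(classify_truth(expected, match_calls)$label, c("TP", "TP"))
})

test_that("stratified metrics: ratios, undefined bins, and additivity across bins", {
  call_labels <- data.table(depth = c(rep(5L, 10), rep(12L, 4)),
                            genotype = "het",
                            label = c(rep("TP", 8), "FP", "FP", rep("TP", 4)))
  truth_labels <- data.table(depth = rep(5L, 10), zygosity = "het",
                             label = c(rep("TP", 7), rep("FN", 3)))
  m <- compute_metrics(call_labels, truth_labels, breaks = c(3, 10, Inf),
                       zygosity_split = FALSE)
  expect_identical(m$specificity, c(0.8, 1))
  expect_identical(m$sensitivity, c(0.7, NA_real_))   # empty denominator: NA
  expect_identical(m$fp, c(2L, 0L))
  # pooled counts across bins equal unstratified totals
  expect_identical(sum(m$tp) + sum(m$fp), nrow(call_labels))
  expect_identical(sum(m$tp_truth) + sum(m$fn), nrow(truth_labels))

  # per-zygosity strata add up to "all"
  set.seed(7)
  cl <- data.table(depth = sample(3:30, 300L, replace = TRUE),
                   genotype = sample(c("het", "hom_alt"), 300L, TRUE),
                   label = sample(c("TP", "FP"), 300L, TRUE))
  tl <- data.table(depth = sample(3:30, 200L, replace = TRUE),
                   zygosity = sample(c("het", "hom_alt"), 200L, TRUE),
                   label = sample(c("TP", "FN"), 200L, TRUE))
  mm <- compute_metrics(cl, tl)
  tot <- mm[zygosity == "all", .(tp = sum(tp), fp = sum(fp), fn = sum(fn))]
  byz <- mm[zygosity != "all", .(tp = sum(tp), fp = sum(fp), fn = sum(fn))]
  expect_equal(as.list(tot), as.list(byz))
  expect_identical(tot$tp + tot$fp, sum(cl$depth >= 3))
})

test_that("callset overlap matches brute-force set intersection", {
  a <- random_calls(200L)
  expect_identical(callset_overlap(a, a)[c("frac_a", "frac_b")],
                   list(frac_a = 1, frac_b = 1))
  b <- copy(a)[, pos := pos + 100000L]
  ov0 <- callset_overlap(a, b)
  expect_identical(ov0$frac_a, 0); expect_identical(ov0$frac_b, 0)
  set.seed(9)
  b2 <- rbind(a[sample.int(nrow(a), 50L)], random_calls(100L))
  b2 <- b2[!duplicated(paste(contig, pos))]
  ov <- callset_overlap(a, b2)
  keys <- function(x) unique(paste(x$contig, x$pos, x$alt, x$genotype))
  ni <- length(intersect(keys(a), keys(b2)))
  expect_identical(ov$n_intersect, ni)
  expect_equal(ov$frac_a, ni / length(keys(a)))
  expect_equal(ov$frac_b, ni / length(keys(b2)))
})
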