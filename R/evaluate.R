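# Concordance evaluation: expected-call set, TP/FP/FN classification
# against a truth genotype set and an allele catalog, and specificity /
# sensitivity stratified by coverage depth and zygosity.
#
# Conventions (matching the glossary used throughout the package):
#  * specificity = TP / (TP + FP) over calls (fraction of calls that are
#    true variants; elsewhere called precision);
#  * sensitivity = TP / (TP + FN) over expected truth sites (truth sites
#    covered at >= min_depth).

#' Depth of coverage at truth sites
#'
#' Counts unflagged reads covering each truth-variant position (post-dedup
#' pipeline depth - the same depth the caller sees). Sites with no
#' overlapping read get depth 0.
#'
#' @param truth truth-variant table.
#' @param alignments alignment table; rows with `is_dup == TRUE` are
#'   excluded.
#' @return the truth table with a `depth` column appended.
#' @export
truth_site_depth <- function(truth, alignments) {
  truth <- data.table::copy(as.data.table(truth))
  if (nrow(truth) == 0L) {
    truth[, depth := integer(0)]
    return(truth)
  }
  al <- drop_duplicates(alignments)
  if (nrow(al) == 0L) {
    truth[, depth := 0L]
    return(truth)
  }
  frags <- data.table(contig = al$contig, fstart = al$start, fend = al$end)
  data.table::setkey(frags, contig, fstart, fend)
  tr <- data.table(contig = truth$contig, tstart = truth$pos,
                   tend = truth$pos, site = seq_len(nrow(truth)))
  ov <- data.table::foverlaps(tr, frags,
                              by.x = c("contig", "tstart", "tend"),
                              type = "within", nomatch = NULL)
  cnt <- ov[, .N, by = "site"]
  truth[, depth := 0L]
  truth[cnt$site, depth := cnt$N]
  truth[]
}
utils::globalVariables(c("site", "N"))

#' Expected-call set
#'
#' The truth sites eligible for detection: those covered at
#' `>= min_depth` (default 3x) in the RNA-seq alignment. This set is the
#' sensitivity denominator.
#'
#' @param truth truth table with a `depth` column (see
#'   [truth_site_depth()]).
#' @param min_depth coverage floor (inclusive).
#' @return subset of `truth`.
#' @export
expected_call_set <- function(truth, min_depth = 3L) {
  truth <- as.data.table(truth)
  stopifnot("depth" %in% names(truth))
  truth[depth >= min_depth]
}

#' Build an allele catalog
#'
#' A site -> allele-set table standing in for a population allele catalog
#' (dbSNP-like). The default construction lists `{ref, alt}` at each truth
#' site; additional sites can be appended.
#'
#' @param truth truth-variant table.
#' @param extra optional `data.table(contig, pos, alleles)` rows to append
#'   (`alleles` comma-separated).
#' @return `data.table` with columns `contig`, `pos`, `alleles`.
#' @export
allele_catalog <- function(truth, extra = NULL) {
  truth <- as.data.table(truth)
  cat_dt <- if (nrow(truth)) {
    truth[, .(contig, pos, alleles = paste(ref, alt, sep = ","))]
  } else {
    data.table(contig = character(), pos = integer(), alleles = character())
  }
  if (!is.null(extra)) cat_dt <- rbind(cat_dt, as.data.table(extra))
  unique(cat_dt, by = c("contig", "pos"))
}

#' Classify calls as true or false positives
#'
#' A call at a truth site is TP iff its genotype matches the truth
#' (zygosity and alternate allele); a wrong genotype at a truth site is FP
#' even if the alleles are catalogued. A call at a catalog-only site is TP
#' iff both its ref and alt alleles appear in the catalog's allele set.
#' Everything else is FP.
#'
#' @param calls filtered call set.
#' @param truth truth-variant table.
#' @param catalog optional allele catalog from [allele_catalog()].
#' @return `calls` with `label` (`"TP"`/`"FP"`), `at_truth` (logical) and
#'   the truth zygosity joined in where present.
#' @export
classify_calls <- function(calls, truth, catalog = NULL) {
  calls <- data.table::copy(as.data.table(calls))
  if (nrow(calls) == 0L) {
    calls[, `:=`(label = character(0), at_truth = logical(0))]
    return(calls)
  }
  truth <- as.data.table(truth)
  calls[, `:=`(label = "FP", at_truth = FALSE)]
  if (nrow(truth)) {
    calls[truth, on = c("contig", "pos"),
          `:=`(at_truth = TRUE,
               label = ifelse(genotype == i.zygosity & alt == i.alt &
                                ref == i.ref, "TP", "FP"))]
  }
  if (!is.null(catalog) && nrow(catalog)) {
    cat_dt <- as.data.table(catalog)
    calls[cat_dt, on = c("contig", "pos"),
          label := ifelse(at_truth, label, {
            sets <- strsplit(i.alleles, ",", fixed = TRUE)
            ok <- mapply(function(r, a, s) r %in% s && a %in% s,
                         ref, alt, sets)
            ifelse(ok, "TP", label)
          })]
  }
  calls[]
}
utils::globalVariables(c("i.alleles"))

#' Classify expected truth sites as detected or missed
#'
#' An expected site is TP iff an (unfiltered) call exists at the site with
#' matching genotype and alternate allele; otherwise it is a false
#' negative - either no call was made there, or the genotype did not
#' match.
#'
#' @param expected expected-call set from [expected_call_set()].
#' @param calls filtered call set.
#' @return `expected` with a `label` (`"TP"`/`"FN"`) column.
#' @export
classify_truth <- function(expected, calls) {
  expected <- data.table::copy(as.data.table(expected))
  if (nrow(expected) == 0L) {
    expected[, label := character(0)]
    return(expected)
  }
  expected[, label := "FN"]
  calls <- as.data.table(calls)
  if (nrow(calls)) {
    expected[calls, on = c("contig", "pos"),
             label := ifelse(zygosity == i.genotype & alt == i.alt, "TP", "FN")]
  }
  expected[]
}

#' Default depth bin boundaries
#'
#' Half-open bins `[3,4) [4,5) [5,6) [6,8) [8,10) [10,15) [15,20) [20,Inf)`
#' resolving the 3-10x region where accuracy changes fastest and the >10x
#' plateau.
#' @return numeric vector of bin breaks.
#' @export
default_depth_breaks <- function() c(3, 4, 5, 6, 8, 10, 15, 20, Inf)

bin_label <- function(lo, hi) {
  ifelse(is.infinite(hi), sprintf("[%g,Inf)", lo), sprintf("[%g,%g)", lo, hi))
}

#' Stratified specificity and sensitivity
#'
#' Cross-tabulates TP/FP (from call labels, binned by call depth) and
#' TP/FN (from truth labels, binned by truth-site depth) by depth bin and
#' zygosity, and computes the two ratios. `tp` counts call-side true
#' positives (the specificity numerator); `tp_truth` counts detected
#' expected sites (the sensitivity numerator). Undefined ratios
#' (denominator 0) are reported as `NA`, never 0 or 1.
#'
#' @param call_labels output of [classify_calls()].
#' @param truth_labels output of [classify_truth()].
#' @param breaks increasing depth-bin boundaries (last may be `Inf`).
#' @param zygosity_split if `TRUE`, per-zygosity strata are emitted in
#'   addition to the pooled `"all"` stratum.
#' @param cumulative if `TRUE`, bins are cumulative `[b, Inf)` for each
#'   break instead of half-open exact bins.
#' @return long `data.table`: `depth_bin`, `bin_lo`, `bin_hi`, `zygosity`,
#'   `tp`, `fp`, `tp_truth`, `fn`, `specificity`, `sensitivity`.
#' @export
compute_metrics <- function(call_labels, truth_labels,
                            breaks = default_depth_breaks(),
                            zygosity_split = TRUE, cumulative = FALSE) {
  breaks <- as.numeric(breaks)
  if (any(diff(breaks) <= 0)) {
    stop("depth bins must be strictly increasing (overlapping bins)")
  }
  calls <- as.data.table(call_labels)
  tru <- as.data.table(truth_labels)
  nb <- if (cumulative) length(breaks[is.finite(breaks)]) else
    length(breaks) - 1L
  lo <- if (cumulative) breaks[is.finite(breaks)] else breaks[-length(breaks)]
  hi <- if (cumulative) rep(Inf, nb) else breaks[-1L]
  zygs <- if (zygosity_split) c("all", "het", "hom_alt") else "all"
  grid <- data.table::CJ(bin = seq_len(nb), zyg = zygs)
  res <- grid[, {
    b_lo <- lo[bin]; b_hi <- hi[bin]
    cin <- calls[depth >= b_lo & depth < b_hi]
    tin <- tru[depth >= b_lo & depth < b_hi]
    if (zyg != "all") {
      cin <- cin[genotype == zyg]
      tin <- tin[zygosity == zyg]
    }
    tp_c <- sum(cin$label == "TP")
    fp_c <- sum(cin$label == "FP")
    tp_t <- sum(tin$label == "TP")
    fn_t <- sum(tin$label == "FN")
    .(depth_bin = bin_label(b_lo, b_hi), bin_lo = b_lo, bin_hi = b_hi,
      zygosity = zyg, tp = tp_c, fp = fp_c, tp_truth = tp_t, fn = fn_t,
      specificity = if (tp_c + fp_c > 0) tp_c / (tp_c + fp_c) else NA_real_,
      sensitivity = if (tp_t + fn_t > 0) tp_t / (tp_t + fn_t) else NA_real_)
  }, by = .(bin, zyg)][, c("bin", "zyg") := NULL]
  res[]
}
utils::globalVariables(c("bin", "zyg"))

#' Overlap between two call sets
#'
#' Intersection keyed on (contig, pos, alt allele, genotype), reported as
#' the fraction of each set found in the other.
#'
#' @param a,b call sets.
#' @return list with `n_intersect`, `frac_a` (`|a n b| / |a|`) and
#'   `frac_b`; fractions are `NA` for an empty set.
#' @export
callset_overlap <- function(a, b) {
  a <- as.data.table(a); b <- as.data.table(b)
  key_of <- function(x) {
    if (nrow(x) == 0L) character(0) else
      paste(x$contig, x$pos, x$alt, x$genotype, sep = "\r")
  }
  ka <- unique(key_of(a)); kb <- unique(key_of(b))
  ni <- length(intersect(ka, kb))
  list(n_intersect = ni,
       frac_a = if (length(ka)) ni / length(ka) else NA_real_,
       frac_b = if (length(kb)) ni / length(kb) else NA_real_)
}
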