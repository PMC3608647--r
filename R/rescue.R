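# Orthogonal-evidence rescue: putative false positives are re-examined in
# an independent DNA alignment of the same individual. A heterozygous call
# is corroborated when the alternate allele occurs in 20-80% (inclusive)
# of evidence reads at the site; a homozygous-alternate call when strictly
# more than 90% of evidence reads carry it.

#' Rescue putative false positives with DNA evidence
#'
#' For each call, computes the fraction of unflagged evidence reads at the
#' site that carry the call's alternate allele, and flags the call:
#' * `"yes"` - het call with alt fraction in `het_band` (inclusive), or
#'   hom_alt call with alt fraction strictly above `hom_min`;
#' * `"no"` - assessable but not corroborated;
#' * `"unassessable"` - fewer than `min_evidence_depth` evidence reads.
#'
#' @param fp_calls call set (typically the FP-labelled subset from
#'   [classify_calls()]).
#' @param evidence DNA evidence alignment table.
#' @param het_band inclusive alt-fraction band corroborating a het call.
#' @param hom_min alt fraction strictly above which a hom_alt call is
#'   corroborated.
#' @param min_evidence_depth minimum evidence reads for an assessment
#'   (default 4; below this the 20-80% band is nearly unfalsifiable).
#' @return `fp_calls` with `evidence_depth`, `evidence_alt_fraction` and
#'   `rescue` columns appended.
#' @export
rescue_false_positives <- function(fp_calls, evidence,
                                   het_band = c(0.20, 0.80),
                                   hom_min = 0.90,
                                   min_evidence_depth = 4L) {
  calls <- data.table::copy(as.data.table(fp_calls))
  if (nrow(calls) == 0L) {
    calls[, `:=`(evidence_depth = integer(0),
                 evidence_alt_fraction = numeric(0),
                 rescue = character(0))]
    return(calls)
  }
  ev <- drop_duplicates(evidence)
  calls[, `:=`(evidence_depth = 0L, evidence_alt_fraction = NA_real_)]
  if (nrow(ev) > 0L) {
    frags <- data.table(contig = ev$contig, fstart = ev$start,
                        fend = ev$end, bases = ev$bases)
    data.table::setkey(frags, contig, fstart, fend)
    sites <- data.table(contig = calls$contig, tstart = calls$pos,
                        tend = calls$pos, alt = calls$alt,
                        site = seq_len(nrow(calls)))
    ov <- data.table::foverlaps(sites, frags,
                                by.x = c("contig", "tstart", "tend"),
                                type = "within", nomatch = NULL)
    if (nrow(ov) > 0L) {
      ov[, obs := substring(bases, tstart - fstart + 1L,
                            tstart - fstart + 1L)]
      stat <- ov[, .(d = .N, a = sum(obs == alt)), by = "site"]
      calls[stat$site, `:=`(evidence_depth = stat$d,
                            evidence_alt_fraction = stat$a / stat$d)]
    }
  }
  calls[, rescue := "no"]
  calls[evidence_depth < min_evidence_depth, rescue := "unassessable"]
  calls[rescue == "no" & genotype == "het" &
          evidence_alt_fraction >= het_band[1] &
          evidence_alt_fraction <= het_band[2], rescue := "yes"]
  calls[rescue == "no" & genotype == "hom_alt" &
          evidence_alt_fraction > hom_min, rescue := "yes"]
  calls[]
}
utils::globalVariables(c("obs", "d", "a"))

#' Summarise a rescue run
#'
#' @param rescued output of [rescue_false_positives()].
#' @return one-row `data.table` with counts per status and the rescued
#'   percentage of all assessed-or-not FP calls.
#' @export
rescue_summary <- function(rescued) {
  rescued <- as.data.table(rescued)
  n <- nrow(rescued)
  n_yes <- sum(rescued$rescue == "yes")
  data.table(
    n_fp = n,
    n_rescued = n_yes,
    n_not_rescued = sum(rescued$rescue == "no"),
    n_unassessable = sum(rescued$rescue == "unassessable"),
    rescued_pct = if (n > 0) 100 * n_yes / n else NA_real_
  )
}
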