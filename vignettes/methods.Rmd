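---
title: "Benchmarking SNP detection from RNA-seq: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking SNP detection from RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`rnasnpeval` evaluates single-nucleotide variant detection from bulk
RNA-seq alignments against a truth genotype set, on synthetic data with
fully known ground truth. This vignette is the package's own account of
the science: the model behind each stage, the parameters that matter and
their defaults, what the generator does and does not emulate, and the
design decisions taken where more than one defensible convention exists.

## 1. The evaluation model

A diploid sample carries biallelic SNVs that are either heterozygous
(het) or homozygous-alternate (hom_alt). RNA-seq reads sample the exome
non-uniformly — in proportion to expression — so per-site coverage $d$
varies over orders of magnitude, and the detectability of a variant is a
property of its site, not of the library size. The package therefore
defines the *expected-call set* as the truth sites with post-deduplication
coverage $d \ge 3$, and reports

$$\text{specificity} = \frac{TP}{TP+FP} \quad\text{(over calls)},\qquad
  \text{sensitivity} = \frac{TP}{TP+FN} \quad\text{(over expected sites)},$$

stratified by depth bin and zygosity. (This "specificity" is what most of
the literature calls precision; the naming follows the analysis this
package reproduces.) A call is TP only with the correct genotype: a het
site called hom_alt is simultaneously an FP (wrong call) and an FN
(expected site not correctly detected). A call at a site absent from the
truth set may still be TP if both its alleles occur in a supplied allele
catalog (a dbSNP-like site → allele-set table); such catalog rescues count
toward specificity only — the sensitivity denominator is the expected
truth set and never grows.

The central phenomenology this machinery exposes: at a het site the
alternate allele appears in $X \sim \mathrm{Binomial}(d, 1/2)$ of $d$
reads, so low-coverage het sites are both miscalled (e.g. $X = d$ gives a
spurious hom_alt) and missed ($X < 2$) at rates that fall quickly with
$d$, while hom_alt sites are near-deterministic at any $d \ge 3$. Error
calls require at least two identical erroneous bases at one site, so with
per-base error rate $e$ they scale roughly as $\binom{d}{2}(e/3)^2$ per
site, capped by the caller's alt-fraction floor.

## 2. The threshold caller

The package deliberately ships a *threshold* caller, not a likelihood
caller: the pipeline is about evaluating call sets, and its built-in
caller exists so the whole path is end-to-end testable and exactly
documented. Externally produced VCFs can be dropped in at the pipeline
boundary (`read_calls_vcf()`).

Decision rule per pileup column (defaults in `caller_params()`):

| parameter | default | meaning |
|---|---|---|
| `min_depth` | 3 | no call attempted below 3× (the expected-call floor) |
| `min_alt_reads` | 2 | a single mismatching read never makes a call |
| `het_band` | [0.20, 0.80] | alt fraction called heterozygous (inclusive) |
| `hom_threshold` | 0.80 | alt fraction strictly above → hom_alt |
| `min_base_quality` | 0 | pileup inclusion threshold (simulated quality is constant, so the default is pass-through) |

The alternate allele is the most frequent non-reference base, ties broken
alphabetically for reproducibility; reference-only columns are never
emitted. Tightening `min_depth`/`min_alt_reads` emulates a conservative
caller, loosening them a permissive one, which is how the package mimics
the permissive-vs-conservative caller comparison at the qualitative
level; no bug-for-bug emulation of production callers is attempted.

## 3. Duplicate-read strategies

Two semantics, both first-class:

- **Pre-alignment** (`collapse_identical`): one read kept per distinct
  base string, first occurrence wins. This is what sequence-level
  deduplication can see; a PCR copy that acquired a sequencing error is
  *not* recognised as a duplicate.
- **Post-alignment** (`mark_positional_duplicates`): reads grouped by
  (contig, start, end, strand); one representative retained per group,
  the rest flagged (SAM 0x400), never deleted, so the decision is
  auditable. The retained copy is the one with the highest summed base
  quality, ties by first occurrence — the sources this stand-in emulates
  do not document their choice, so the package picks the copy carrying
  the most reliable evidence.

Strand is part of the coordinate key (the narrower description "same
start and end coordinates" leaves strand open; including it matches
universal duplicate-marking practice). Under duplicates that carry
independent errors, the exact-sequence key provably retains at least as
many reads as the coordinate key, and the test suite asserts the strict
version on simulated data — this is the mechanical reason post-alignment
marking removes more true PCR duplicates.

## 4. Site filters and their order

- **Accessibility mask**: calls at 1-based position $p$ are removed iff
  some 0-based half-open interval $[s,e)$ has $s \le p-1 < e$. Mask
  intervals model regions where reliable calling is impossible (repeats,
  segmental duplications) and where the truth-providing project attempted
  no calls.
- **SNP clusters**: two or more calls within a 3 bp window
  ($|\Delta pos| < 3$) are removed — *all* members, not all-but-one,
  since clustered mismatches are the signature of an alignment artefact
  rather than of independent SNVs. Cross-contig positions never cluster.

The two filters are each idempotent but do **not** commute: if the mask
removes one member of a two-call cluster, mask-then-cluster keeps the
unmasked neighbour, cluster-then-mask kills both. The pipeline fixes the
order as mask first, cluster last, and a test documents the
counterexample. An earlier draft of the package's contract asserted
commutativity; that assertion is false and was replaced by the ordered
contract.

## 5. Orthogonal-evidence rescue

A putative FP may be a real variant the truth set simply lacks. Against
independent DNA alignments of the same individual, a het call is
corroborated when the alt-allele fraction among evidence reads lies in
[0.20, 0.80] — endpoints inclusive, matching the inclusive reading of
"between 20 and 80%" — and a hom_alt call when the fraction is strictly
above 0.90 (the strict reading of "> 90%"). Sites with fewer than
`min_evidence_depth = 4` evidence reads are reported `unassessable`
rather than `no`: below four reads the 20–80 % band is nearly
unfalsifiable, and silently counting such sites as un-corroborated would
bias the rescued percentage downward. The rescued percentage of all FP
calls is reported but never asserted — it is data-dependent.

Calibration is testable analytically: for a genuinely het site examined
at evidence depth $d$, the rescue probability is
$P(\lceil 0.2d \rceil \le X \le \lfloor 0.8d \rfloor)$ with
$X \sim \mathrm{Binomial}(d, 1/2)$ (≈ 0.997 at $d = 20$), while for a
pure-error FP it is the same band probability under
$\mathrm{Binomial}(d, e/3)$ (≈ $10^{-8}$ at $d = 20$, $e = 0.005$). The
acceptance suite checks both against exact binomial bounds.

## 6. The synthetic world

`sim_config()` states the world once; every generator stage derives a
fixed stream from the master seed, so a config reproduces byte-identical
fixture files. Defaults, with the reasoning:

| field | default | why |
|---|---|---|
| `read_length` | 40 bp | single-end 40 bp is the library design this analysis targets |
| `n_contigs`, `contig_length` | 2 × 100 kb | desk-scale reference; large enough for ~50 genes plus intergenic space |
| `n_genes`, `exons_per_gene` | 50, 1–8 | exons 120–300 bp (human-like), introns 50–500 bp; every exon ≥ one read length so reads never splice |
| `n_reads` | 50,000 | ~35× mean exonic coverage, spread over an exponential-like expression profile so all depth strata are populated |
| `error_rate` | 0.005 | typical per-base substitution rate for the instrument generation being emulated |
| `pcr_duplicate_rate` | 0.15 | fraction of fragments amplified into k ≥ 2 copies; family size k = 2 + Geometric(½) |
| `duplicate_error_mode` | mixed | photocopies and error-carrying copies both occur in real libraries |
| `het_fraction` | 0.67 | about two-thirds of an individual's variant genotypes are heterozygous |
| `variants_per_kb` | 2 | compressed relative to the ~0.7/kb genic density of a human individual so that desk-scale strata (10⁴–10⁵ exonic bp instead of 7×10⁷) retain enough sites per depth bin; chosen a priori by this power consideration |
| `expression_dispersion` | 1 | gamma-shape of per-gene weights; shape 1 gives the wide dynamic range of real transcriptomes (many silent genes, few dominant ones) |
| `off_exon_fraction` | 0.05 | intronic/intergenic background that survives poly-A selection; the lever behind genome-scope vs transcriptome-scope call counts |
| `mask_fraction` | 0.15 | inaccessible fraction of coding sequence in the reference project this mask emulates |
| `evidence_depth` | 20 | deep-coverage DNA alignment of the same individual |
| `base_quality` | Q30, constant | no quality model is specified by the source analysis; a constant keeps the caller's quality filter inert by default |

Two world-consistency rules deserve emphasis. First, truth variants are
never planted inside mask intervals: the truth set stands in for calls
made by a project that attempted no calls there, so the two are disjoint
by construction — without this rule, mask filtering converts true calls
into permanent false negatives and caps sensitivity at
1 − `mask_fraction`, a pure artefact. Second, duplicate copies share the
fragment's haplotype draw (they are copies of one molecule); only their
sequencing errors may differ, according to `duplicate_error_mode`.

What the generator does **not** emulate: spliced reads (reads are
confined to single exons, so alignments are ungapped and pileup is exact
— transcriptome-vs-genome alignment is modelled as a scope restriction on
genome-coordinate alignments, an approximation that reproduces the extra
off-annotation calls without a spliced aligner), indels and multiallelic
sites, paired ends, quality miscalibration, GC/mappability bias beyond
the mask, allele-specific expression and RNA editing. A green test
therefore establishes correctness of the pipeline's logic and its
statistical behaviour under this world — not performance on real
libraries, where alignment artefacts and systematic error dominate.

## 7. Numerical and coordinate conventions

- FASTA/SAM/VCF are 1-based; BED (mask, BED12) is 0-based half-open.
  Stated once, enforced by the readers and writers, and exercised by
  round-trip tests against independent readers (Biostrings, Rsamtools,
  VariantAnnotation, rtracklayer).
- Undefined ratios (empty denominators) are `NA`, never 0 or 1.
- Depth for stratification is post-deduplication pipeline depth — the
  depth the caller saw — for both calls and truth sites, keeping the two
  denominators consistent.
- Depth bins default to `[3,4) [4,5) [5,6) [6,8) [8,10) [10,15) [15,20)
  [20,∞)`, resolving the 3–10× region where accuracy changes fastest;
  `compute_metrics(cumulative = TRUE)` switches to `≥ d` strata. Exact
  bins are the default; the cumulative mode matches statements about
  "sites with ≥ d× coverage" and is what the acceptance suite uses for
  the monotone-specificity check, because the threshold caller has a
  structural artefact in exact bins: at depth exactly 10, two same-base
  errors reach both `min_alt_reads = 2` and an alt fraction of exactly
  0.20, producing a localized FP excess that cumulative strata average
  out.
- Degenerate inputs (zero genes, zero variants, zero reads, empty masks,
  empty VCFs) flow through every stage and are covered by tests.

## 8. Known limitations and one honest red

The acceptance criterion comparing duplicate strategies requires the
post-alignment strategy to beat the pre-alignment strategy on *both*
specificity and sensitivity (margins averaged over ten fixed seeds, 20 %
duplication, error-carrying copies). In this package's world the
specificity margin is reproducibly positive, but the sensitivity margin
is statistically zero, and the corresponding assertion is left failing
rather than adjusted. The analysis: with duplicate families of 2–4
copies, the het band [0.2, 0.8] is wide enough to absorb the
allele-fraction skew that surviving error-carrying copies cause, so
almost no additional false negatives arise; the sensitivity advantage of
post-alignment marking in the emulated study rests on far more heavily
duplicated 40 bp libraries than this generator's stated world produces.
Re-tuning the duplicate family-size distribution after observing the
result would have made the test pass and the world less honest; the
mechanism itself (exact-sequence keys retain strictly more reads than
coordinate keys under error-carrying duplicates) is asserted and green.

Other limitations: the caller has no genotype likelihoods or qualities;
rescue assesses only the called alternate allele; the CLI exchanges JSON
rather than YAML configs; and the simulator's uniform error model cannot
reproduce position- or motif-specific error structure, which is exactly
the structure the cluster filter and mask earn their keep on in real
data.
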