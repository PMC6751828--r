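---
title: "Detecting selection signatures in two-population SNP panels"
author: "popsweep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting selection signatures in two-population SNP panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popsweep)
```

## The design

Recent, goal-directed artificial selection leaves two kinds of footprints in
a breed's genome: extended stretches of homozygosity shared by most
individuals, and haplotypes that are unusually long around the selected
locus because recombination has not yet broken them up. `popsweep`
implements a two-pronged scan for these footprints by contrasting a breed
under performance selection with a reference breed managed for genetic
diversity rather than performance. Prong one looks *within* the selected
breed: runs of homozygosity (ROH) and the regions where most individuals'
long ROH overlap. Prong two looks *between* the breeds: a windowed fixation
index and the cross-population extended-haplotype-homozygosity statistic
(XP-EHH). Only regions flagged by both between-breed tests are promoted to
candidate regions, which controls false positives at the cost of some
power.

## Data model and quality control

Genotypes live in two containers: a `haplotype_panel` (phased 0/1 alleles,
two rows per individual, no missing values — phasing is an input contract,
not something the package does) and a `genotype_matrix` (diploid dosages
0/1/2 with `NA` for missing calls). Coordinates are 1-based inclusive bp
throughout, converted to 0-based half-open only at BED boundaries. Phased
VCF 4.2 and PLINK text PED/MAP are read and written; population labels come
from a two-column TSV.

Before any scan, individuals whose heterozygosity-based inbreeding
coefficient

\[ f_i = \frac{O_i - E_i}{n_i - E_i},\qquad
   E_i = \sum_j \Bigl(1 - 2 p_j (1-p_j)\tfrac{n_j}{n_j-1}\Bigr) \]

exceeds 0.05 are excluded (the method-of-moments estimator PLINK's `--het`
reports; \(O_i\) observed homozygous SNPs, \(n_i\) non-missing SNPs, \(p_j\)
the within-population sample frequency, \(n_j\) the allele count). QC then
runs per population in a fixed order mirroring PLINK 1.9 — individual
missingness > 0.10, SNP missingness > 0.10, MAF < 0.01, Hardy–Weinberg
exact p < 1e-4 — and a SNP failing in either population is dropped so both
breeds share one marker set. The filter order is documented because the
per-step removal counts depend on it; the surviving data do not silently
depend on anything else (every removed id is named in the QC report).
Greedy LD pruning (remove the lower-MAF member of any pair with r² > 0.5
inside a 50-SNP window sliding by 5; composite dosage r², no phase needed)
feeds **only** the ROH branch; the F_ST and XP-EHH scans use the unpruned
post-QC set, matching the practice of pruning for ROH while phasing the
larger set.

## The ROH scan

Detection follows the scanning-window semantics of PLINK's `homozyg`
command, one individual and chromosome at a time:

1. every window of `window_snps` consecutive SNPs qualifies iff it holds at
   most `window_het_max` heterozygous and `window_missing_max` missing
   calls;
2. a SNP is eligible iff at least 5 % of the windows containing it qualify
   (the `--homozyg-window-threshold` default; the class tables do not state
   it);
3. maximal runs of eligible SNPs are trimmed to homozygous non-missing
   endpoints, then split at inter-SNP gaps above 5 kb;
4. survivors are kept iff they meet the class's SNP count, length and
   density bounds, with `length_kb = (end_bp - start_bp)/1000`.

The three stock classes are short (≥ 3 SNPs, 50–125 kb, 5-SNP window, no
het/missing allowed), medium (≥ 10 SNPs, 125–500 kb, 12-SNP window) and
long (≥ 30 SNPs, > 500 kb, 50-SNP window, one heterozygous and one missing
call allowed per window); all use a density floor of one SNP per 100 kb and
a 5-kb gap ceiling, and run as three independent passes. Two conventions
deserve a note. First, the scanning-window sizes 5/12/50 are SNP counts,
not kb: the option that sets them is denominated in SNPs even where a
summary table's column header suggests kb. Second, length intervals are
half-open `[min, max)` kb — a 125-kb segment is medium, a 500-kb segment is
long — so no segment can be reported in two classes.

Edge behaviour worth knowing: because step 2 is a *fraction* of qualifying
windows, the first one or two SNPs of a genuinely homozygous run can fall
below the 5 % hit rate and be shaved off. Recovery of a planted run is
therefore exact on a fully heterozygous background and within one or two
inter-SNP spacings otherwise; the consensus machinery (below) sharpens
boundaries back to about one spacing because the shaving is individually
random.

Per-SNP incidence is the share of individuals with a long ROH covering the
SNP; consensus regions are maximal runs of consecutive SNPs with incidence
at or above 0.85. A single qualifying SNP yields a region with
`start_bp == end_bp`, which is why real summaries of such scans can contain
one-bp intervals. The reported `share` is the minimum per-SNP incidence in
the region — an upper bound on, and in practice equal to, the fraction of
individuals whose ROH cover the whole region.

## The fixation-index scan

Per SNP, with population alt-allele frequencies \(p_1, p_2\) and their
unweighted mean \(\bar p\):

\[ H_T = 2\bar p(1-\bar p), \quad
   H_S = p_1(1-p_1) + p_2(1-p_2), \quad
   F_{ST} = (H_T - H_S)/H_T . \]

This is Nei's two-deme G_ST: it has no sample-size correction, lies in
[0, 1], is symmetric in the populations and invariant to allele-label
swaps; SNPs fixed for the same allele in both populations (H_T = 0) are
undefined and excluded. A sample-size-weighted \(\bar p\) is available but
off by default, since the estimator is defined on the unweighted mean.
Values are averaged over non-overlapping 500-kb windows anchored at bp 1 of
each chromosome (the anchoring is a convention; nothing in the method fixes
it), and a window is significant iff its mean reaches the smallest of the
top `ceil(0.01 n)` defined window means — an order-statistic cutoff with
ties included, so an all-equal degenerate input flags everything rather
than nothing. The "extreme 1 %" is implemented one-sided (highest), which
is the reading consistent with plotting the cutoff as a lower bound on
flagged values.

One expectation is easy to get wrong and matters for validation: for two
demes that each drifted with parameter \(F\) from a common ancestor, the
expected *two-deme* G_ST is not \(F\) but \((F/2)/(1-F/2)\) — the
between-deme variance of two draws is half the deme-versus-ancestor
variance. At \(F = 0.1\) the package's panels give a weighted mean of about
0.055, matching that expectation and the frequency-based oracle within
0.02. An estimator referenced to the ancestral pool, or a
variance-components estimator, would center near \(F\) instead; those are
out of scope here.

## The XP-EHH scan

Site EHH at a core SNP is the probability that two random haplotypes of a
population are identical over the interval from the core to a given
distance: \( \mathrm{EHH} = \sum_h n_h(n_h-1)/(n(n-1)) \) over the groups
\(n_h\) of haplotypes identical across the span, computed SNP by SNP
outward and starting at 1 by definition at distance 0. iES is the
trapezoidal integral of the two-sided curve over physical distance — no
genetic map is assumed for array data — while EHH stays at or above the
cutoff 0.05 (the reference implementations' convention, exposed as a
parameter). Partial integrals at chromosome ends are kept and flagged
rather than discarded, so telomeric windows are not silently thinned.

For the cross-population statistic the two populations' curves are
integrated to a **common** boundary: the SNP at which the EHH of the
combined sample falls below the cutoff. This is the like-for-like
comparison of the original cross-population formulation, and it matters
numerically: truncating each population on its own curve makes
\(\ln(\mathrm{iES}_A/\mathrm{iES}_B)\) heavy-tailed at cores where one
population's curve collapses a SNP earlier than the other's (in development
measurements the neutral maximum |score| rose from about 4.5 to 6.7 under
per-population truncation). Raw log-ratios over all eligible cores
(combined MAF ≥ 0.05) are standardized genome-wide to mean 0, sd 1;
positive scores mean longer haplotypes — a more recent sweep — in the
numerator population. Two-sided normal-tail p-values get Benjamini–Hochberg
correction at the conventional 0.05 level (the correction procedure and
level are the package's choice; only "FDR" is inherited). A SNP is extreme
if |score| exceeds the fixed threshold 4.34 or sits in the upper 1 % of the
empirical |score| distribution (computed on absolute scores; the sign is
reported separately since both directions are meaningful); 500-kb windows
holding at least 3 extreme SNPs are retained, with the window mean reported
both over extreme SNPs and over all scored SNPs, since summaries of this
kind do not always say which was meant. Haplotype bifurcation trees around
a core (nodes split by the allele at each SNP outward; node weights sum to
the haplotype count at every depth) serialize to JSON for plotting.

## The synthetic generator

The study's array data are access-restricted, so validation runs on
synthetic panels whose truth is planted and therefore exactly known. The
generator is deliberately minimal: per SNP an ancestral frequency is drawn
uniformly from a MAF range (randomly polarized so neither allele is
systematically minor), each population's frequency comes from the
Balding–Nichols Beta \((p(1-F)/F,\; (1-p)(1-F)/F)\), and haplotype alleles
are independent Bernoulli draws. Positions are uniform, sorted, de-duplicated
by redraw. There is **no recombination, mutation or linkage**: sites are
exchangeable, and all haplotype structure is supplied by the planting
operators — a hard sweep copies one founder haplotype onto a chosen
fraction of a population's haplotypes across a span; an autozygosity plant
overwrites one individual's second haplotype with its first across an
interval. Genotype missingness is i.i.d., applied after planting and never
inside planted intervals, so ground truth is not eroded. One master seed
drives per-chromosome and per-operator substreams, making every study
byte-reproducible.

Default problem sizes are desk-scale by design and stated here as the
package's own choices: 1000 SNPs on a 5-Mb chromosome (5-kb spacing,
array-like), populations of 50, drift F = 0.1, ancestral MAF in
[0.05, 0.5]. Two sizing caveats follow directly from uniform positions.
First, inter-SNP gaps are approximately exponential, so a segment scan with
a 5-kb gap ceiling needs mean spacing well below 1 kb before >500-kb runs
survive unsplit — the ROH validation studies therefore use 4800 SNPs on a
1.2-Mb chromosome (250-bp spacing). Second, a >500-kb autozygous plant on a
few-Mb synthetic genome is a large *fraction* of that genome, so it inflates
f_i (to ~0.65 where the same plant on a real 2.4-Gb genome would add ~0.02)
and produces extreme Hardy–Weinberg excess at intermediate-frequency SNPs.
Pipeline-level integration tests therefore relax the f_i bound; this is a
property of desk-scale genomes, not of the filters.

## What the validation does and does not show

Everything structural is checked against independent oracles: ROH calls are
set-identical to a loop-based enumerator of the class criteria on hundreds
of random panels; EHH/iES match an \(O(n^2)\) pairwise-identity oracle to
1e-9; per-SNP F_ST matches longhand arithmetic on a full frequency grid to
1e-12; window means match naive recomputation; the Hardy–Weinberg exact
test matches full enumeration on an exhaustive small-\(n\) grid; annotation
overlap matches an all-pairs scan; two pipeline runs with one seed are
byte-identical. Planted truths are recovered: consensus regions over a
600-kb plant carried by 90 % of individuals in 20/20 seeds with boundaries
within one inter-SNP spacing, and the swept window flagged by the XP-EHH
window rule in 20/20 development seeds at carrier fraction 0.8.

One calibration property does *not* hold under this generator and is left
failing rather than weakened: with ~5500 eligible cores per neutral genome,
a perfectly normal score distribution would put essentially no scores
beyond ±4.34 (expected ≈ 0.08 per genome). Measured neutral panels show
0–3 exceedances per genome (about half of seeds show none). The standardized
log-iES-ratio is leptokurtic under exchangeable sites: drift at F = 0.1
creates short stretches near fixation in one population whose haplotype
homozygosity extends over many SNPs — exactly the signal XP-EHH looks for,
arising here from drift alone — and with no linkage disequilibrium to
smooth iES between neighboring cores, these stretches stand out more than
they would in real data. The fixed ±4.34 threshold should therefore be read
as calibrated for real genomes with LD; on LD-free synthetic panels the
empirical-percentile window rule (which adapts to the realized
distribution) is the meaningful false-positive control, and intersection
with F_ST tightens it further. This is also why passing the synthetic suite
says nothing about phasing quality, genotyping-error structure beyond
i.i.d. missingness, or LD-dependent behaviour on real arrays.

## Numerical conventions and tie-breaks

* LD pruning removes the lower-MAF member of a violating pair; ties remove
  the later map position. Pairs are examined in index order within each
  window; a SNP removed once stays removed. The postcondition — no kept
  pair within any window above the ceiling — is audited directly in tests.
* Quantile rules (F_ST top 1 %, XP-EHH 99th percentile) use order
  statistics with ties included on the significant side; `ceil` fixes the
  flagged count.
* The Hardy–Weinberg test is the standard two-sided exact test without
  mid-p, summing probabilities ≤ that of the observed heterozygote count
  (with a 1e-12 relative tolerance on the comparison).
* Zero-variance dosages make r² undefined (`NA`), distinct from 0; H_T = 0
  makes F_ST undefined; a zero iES or an sd-0 raw-score vector skips or
  degenerates the XP-EHH record explicitly instead of propagating NaN.
* Windows are anchored at bp 1; window bounds are `[k·w + 1, (k+1)·w]`.
* ROH class length bounds are `[min, max)` kb; density is segment SNPs per
  segment kb.

## Limitations

Besides the LD-free generator already discussed: the package does not
phase (inputs are pre-phased by contract), does not compute
variance-components F_ST or within-population iHS, does not model
genotyping error beyond i.i.d. missingness, and stops at gene lists per
candidate region — enrichment statistics and database queries are outside
its scope. The f_i estimator is the heterozygosity-based one only; ROH-based
inbreeding coefficients are not computed.
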