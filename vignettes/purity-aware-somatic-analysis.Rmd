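---
title: "Purity-aware somatic analysis: model, thresholds and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Purity-aware somatic analysis: model, thresholds and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somaticsift)
```

# The problem

A tumor specimen sequenced in bulk is a mixture of malignant cells at
fraction $p$ (the tumor purity, or tumor content) and normal cells at
fraction $1-p$. Every somatic signal is diluted by that mixture:

* a region at tumor copy number $c_t$ produces coverage proportional to
  $p\,c_t + (1-p)\,2$ rather than $c_t$;
* a germline heterozygous site that has lost one allele in the tumor
  shows a variant allele fraction pulled back toward $0.5$ by the
  remaining normal cells;
* a methylation difference of $\Delta$ percentage points between tumor
  and normal cells is observed as $p\,\Delta$;
* the read-count ratio between two HLA alleles shifts by $p/2$ under
  full copy-neutral loss, not by $1/2$.

`somaticsift` makes this mixture explicit: a single `purity_model(p,
normal_ploidy)` object feeds every caller, so all thresholds are
interpreted on the observed (diluted) scale while all reported states are
on the tumor-compartment scale.

# The mixture model

`expected_observed_cn()` implements
$\mathrm{CN}_{obs} = p\,c_t + (1-p)\,\pi$ with normal ploidy $\pi$
(default 2). `calibrate_tumor_cn()` inverts it on integer states,
$\hat c_t = \mathrm{round}\!\big((\mathrm{CN}_{obs} - (1-p)\pi)/p\big)$,
clamped at zero. Because the forward map is affine, the inverse is exact
on integer states at any $p>0$; rounding ties (residual exactly one half)
are resolved *away* from the normal ploidy, preferring to report an event
over no event. This is a deliberate, testable tie-break.

For allele fractions, a site with $a_t$ of $c_t$ alternate copies in the
tumor compartment and $a_n$ of $c_n$ in the normal one is expected at

$$\mathrm{VAF} = \frac{p\,a_t + (1-p)\,a_n}{p\,c_t + (1-p)\,c_n}.$$

For a germline het ($a_n = 1$, $c_n = 2$) under copy-neutral LoH the two
homozygous-adjusted bands sit at $(1\pm p)/2$; a deletion-LoH mode (one
retained copy) is exposed as an option. These formulas are the standard
allele-specific mixture; they are adopted here because they exactly
reproduce the observed-CN behavior of a diluted triplication (CN=4 seen
as CN=3 at 50% purity) and the VAF bands a diluted LoH region occupies.

## Site classification and its separability limits

`classify_site()` assigns each tumor site to the nearest of the three
expected bands — ref-retained LoH, persistent het ($0.5$), alt-retained
LoH — when that band is *uniquely* within a tolerance (default 0.10 VAF).
Three guards make the classification honest about what the data support:

* **Unique band.** If no band, or more than one band, lies strictly
  within tolerance, the site is `ambiguous`. At low purity the bands
  crowd together and a fraction near one band is also near another;
  picking the nearest would manufacture confidence that is not there.
* **Band-separation collapse.** When the hom-to-het separation $p/2$
  falls below the tolerance the LoH classes are unresolvable at any VAF,
  and every site is `ambiguous`. With the default tolerance this places
  the hard floor at $p = 0.2$, which is why LoH detection collapses at
  the bottom of the titration ladder.
* **Binomial noise floor.** An adjusted-hom call additionally requires
  the VAF to sit outside $0.5 \pm 2\sqrt{0.25/\mathrm{depth}}$, two
  binomial standard errors of a true het. At 30x this margin is about
  0.18, which in practice moves the usable LoH range to purities of
  roughly 0.5 and above — matching the observed behavior that LoH calling
  degrades sharply below 50% tumor content while remaining reliable at
  50–90%. Deeper data relax the guard automatically.

# Copy-number calling

Coverage enters as fixed 1 kb binned depth. Each bin's ratio is
$(d_T/\tilde d_T)\,/\,(d_N/\tilde d_N)$ with $\tilde d$ the genome-wide
median, so a flat diploid genome sits at ratio 1; blacklisted bins and
bins with zero normal depth are dropped. Tumor-only mode self-normalizes
against the tumor median.

Segmentation is recursive binary splitting on $\log_2$ ratio: a split is
accepted when it reduces the within-segment sum of squares by more than a
penalty, by default $10\hat\sigma^2$ where $\hat\sigma$ is a MAD estimate
of per-bin noise from adjacent-bin differences (the factor of $\sqrt 2$
between difference noise and bin noise is absorbed into the constant).
The exhaustive minimum-SSE placement is the test oracle for this
procedure. Two post-passes keep calls clean: segments shorter than the
size floor merge into the neighbor with the nearer mean, and adjacent
segments that calibrate to the same integer copy state are re-joined —
a spurious breakpoint inside one event otherwise splits it into two
calls, each of which would fail a 70%-overlap benchmark match.

Per segment, the mean ratio is computed as the ratio of segment mean
normalized depths (not the mean of per-bin ratios, whose reciprocal
denominator inflates it by several percent at 30x). Calls require
$|\log_2 r|$ outside a neutral band (default 0.1), a calibrated state
different from the normal ploidy, and a minimum span: 100 kb in paired
mode, 1 Mb in tumor-only mode where only large events are prioritized.

# LoH detection

Germline het sites (normal genotype het, normal VAF in $[0.30, 0.70]$)
are matched by position into the tumor and classified as above. A
per-chromosome scan grows candidate regions from adjusted-hom support:
ambiguous sites are neither support nor interruption; persistent-het
sites interrupt, and a region closes when the cumulative het fraction
would exceed a cap (default 0.15) or when a short consecutive het run
(default 8) marks the return to normal het background. A region must hold
at least 25 adjusted-hom sites and span the minimum size; it extends from
its first to its last supporting site, so trailing background never
stretches a boundary. Overlapping CNV calls populate `concurrent_cn`,
distinguishing copy-neutral LoH from deletion-LoH. Sex chromosomes are
excluded by default (ploidy ambiguity). Tumor-only mode classifies all
tumor sites against the bands and applies the 1 Mb floor.

# Methylation

Per-CpG modified/valid counts are pooled over non-overlapping 10 kb
windows anchored at coordinate zero; the window fraction is the pooled
proportion (robust to per-site depth variation), defined only at five or
more valid calls. A cancer DMR is a window whose tumor and control
fractions differ by at least 33 percentage points, inclusive, in either
direction. The 33 comes from cohort calibration: `calibrate_threshold()`
counts, over all pairs of normal samples, windows exceeding each integer
threshold and returns the smallest threshold whose mean per-pair count
drops to the target (~50 candidate windows) — the expected
between-individual difference scale for the same tissue. The procedure is
monotone in the target by construction.

Without a matched normal, two per-sample routes exist: extreme-state
classification (hypermethylated at $\ge 90\%$, hypomethylated at
$\le 10\%$, both inclusive) and comparison against a panel-of-normals
reference, the per-window median across panel samples (even counts: mean
of the central pair; windows defined in fewer than 3 samples are
unassessed). `constitutive_regions()` intersects per-sample DMR sets to
the windows shared by every sample in a cohort with the same direction.

Allele-specific methylation restricts haplotype-tagged pileups to a gene
panel padded by 2 kb (covering promoters), builds up to four series per
gene (tumor/normal x H1/H2) on a 1 kb window grid, and compares all six
unordered pairs; the ASM flag is reserved for within-sample haplotype
pairs reaching the same 33-pp scale. A series needs 5 haplotagged valid
calls to be assessable — after LoH the lost haplotype typically fails
this floor, and the pair is reported not-assessable rather than silently
skipped. All pairs among present series are emitted with their
assessability, so the count of assessable results per gene is
$\binom{k}{2}$ for $k$ assessable series.

# HLA loss of heterozygosity

Typing is consumed at two-field resolution. Per gene, the allele-1 read
share $r = c_1/(c_1+c_2)$ is compared between normal and tumor;
$\Delta r = r_T - r_N$ is thresholded at $p/4$ — the midpoint between no
loss ($\Delta r = 0$) and full copy-neutral loss ($\Delta r = p/2$) — so
sensitivity scales with the stated purity. Germline-homozygous genes
short-circuit; fewer than 10 reads in either sample gives `no_call`. A
two-sided binomial test of the tumor counts against the normal ratio is
emitted as an auxiliary column only. In tumor-only mode, homozygous
typings are flagged as candidate-loss *hints*, never calls, since typing
alone cannot distinguish germline homozygosity from somatic loss.

# Somatic SVs

Paired mode subtracts normal from tumor SVs by greedy nearest-first
breakpoint matching (each normal record consumable once): same
chromosome, breakpoints within 1 kb (inclusive), same type, and length
similarity $\min/\max \ge 0.7$ (skipped for breakends). Unmatched tumor
records are somatic. The greedy matcher is validated against brute-force
all-pairs matching on small instances. Tumor-only mode classifies records
absent from a population SV index (zero hits) as *pseudo-somatic*;
records whose lookup is missing are labeled unknown and conservatively
excluded.

# The synthetic-data generator

`simulate_pair()` emits the same summary substrates the real pipeline
consumes, with a truth ledger. Its defaults are the study conditions the
package is tested under:

* genome 10 chromosomes x 10 Mb — large enough for $\ge 1$ Mb events and
  10 kb windows, small enough for fast tests;
* depth 30x, Poisson per bin (an overdispersion-free default; real
  nanopore coverage is modestly overdispersed);
* germline het SNVs at 0.5/kb with binomial allele counts; inside an LoH
  event the same parental haplotype is retained at every site, so each
  site lands in the $(1\pm p)/2$ band according to the phase of its alt
  allele;
* CpG sites at 2/kb with binomial methylation calls; the baseline
  landscape is a three-part mixture (20% island-like windows near zero,
  60% methylated bulk, 20% intermediate) so per-sample extreme states
  exist, as they do in real genomes; planted DMR windows are set
  symmetric around 0.5 at $\pm\Delta/2$;
* shared germline SVs with up-to-100 bp breakpoint jitter between the
  two samples, somatic SVs only in the tumor, population hit counts
  attached (germline $\ge 1$, somatic 0);
* HLA counts binomial from copy proportions at 200 reads/gene.

`mix_titration()` mixes a pure tumor with its matched normal at fraction
$\alpha$: coverage as the exact convex combination, and SNV, methylation
and HLA *counts* by binomial thinning of each compartment's reads — so
allele fractions mix at the read level rather than by averaging
fractions, and the mixture's effective purity is exactly $\alpha$. All
randomness derives from a user seed through fixed per-stream offsets;
regeneration is bit-identical.

What the generator does not emulate: GC and mappability waves in
coverage, segmental-duplication artifacts, subclonal heterogeneity
(every somatic event is clonal), error-driven false SNVs, and read-level
phasing errors. Passing recovery tests therefore demonstrates the
correctness of the calling logic under the stated noise model, not
performance on real nanopore data.

# Problem sizes and numerical choices

The test suite exercises recovery on 100 Mb genomes with ten planted
$\ge 1$ Mb events across the titration ladder $\{0.9, 0.7, 0.5, 0.3,
0.1\}$ over five seeds, cDMR recovery on 20 Mb genomes, and HLA
classification over 100 replicates per purity — sizes chosen so the whole
suite runs in well under a minute per component. Other numerical
decisions, each pinned by a test: threshold comparisons at 33 pp and the
90%/10% extreme cuts are inclusive; the 70% benchmark overlap is measured
on the truth interval and inclusive at the boundary; VCF output is
1-based with symbolic ALTs and a `SOMATIC=1` INFO flag, while all
in-memory intervals are 0-based half-open, converted only at the VCF
boundary; multi-allelic SNV records are rejected rather than decomposed;
contigs are processed in input order with no karyotype sorting; writers
are byte-stable given identical input.

# Known limitations

Purity is consumed, never estimated; a wrong stated purity biases
calibration correspondingly. CNV calls below 100 kb are out of contract.
The LoH scan is a deterministic run-length heuristic, not an HMM; very
fragmented LoH with persistent-het contamination above the cap will be
split or missed. The binomial-noise guard makes 30x LoH calling
conservative below ~50% purity by design. The ASM module consumes
haplotype tags and cannot recover from upstream phasing errors.
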