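---
title: "Cross-platform SNP array curation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-platform SNP array curation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Breeding programs that genotyped germplasm on two different SNP array
platforms — here a 50-mer Infinium-style chemistry and a 35-mer Axiom-style
chemistry — need one integrated, curated dataset. Naively merging the calls
is unsafe: each platform's probes fail in their own ways (secondary
polymorphisms under the probe, null alleles, paralogous binding sites,
poor cluster separation), and default auto-calling hides these failures as
plausible-looking genotypes. `arraybridge` implements the curation
workflow end to end: duplicate-sample concordance screening, Mendelian
error analysis over a pedigree, null-allele inference from cluster
intensities, cluster-plot analytics, genetic-map revision against physical
coordinates, probe off-target QC, and a rule ladder that fuses all of this
into a per-SNP verdict — plus a synthetic generator that plants each
artifact so every stage can be tested against ground truth.

# The signal model behind the generator

Real array software reports, per individual and SNP, a normalized allelic
contrast Theta in [0, 1] (AA near 0, BB near 1, AB intermediate) and a
normalized total intensity R. The generator reproduces this geometry from
a dosage-proportional signal model: each of an individual's two alleles
contributes unit signal to its channel, scaled by

* the **secondary-polymorphism retention** `1 - exp(-d / lambda)` for
  haplotypes carrying a polymorphism at distance `d` from the probe's 3'
  end (`d = 1` is the base adjacent to the target SNP). `lambda` is 3 for
  the 50-mer platform and 8 for the 35-mer platform, so the short-probe
  chemistry is more sensitive near the 3' end. These values are tunable
  configuration, chosen to reproduce the qualitative platform asymmetry;
  no quantitative per-mismatch penalty is published for either chemistry.
* the **null factor** (0.05) for null (N) alleles, whose faint
  non-specific background is split over both channels — so an AN
  heterozygote looks like AA at roughly half R, and an NN individual
  collapses to near-zero R;
* a **paralog term**: a fixed non-target locus contributing a fraction
  `s` of total signal on one allele, which compresses the usable cluster
  space. Platform exposure differs (`paralog_sensitivity` 0.35 vs 1.0 for
  the 50- and 35-mer models).

Raw contrast is `(2/pi)·atan2(b, a)`, mapped piecewise-linearly onto the
platform's cluster centers (0.05, 0.5, 0.95 by default) so that noise-free
AA/AB/BB individuals sit exactly on the centers. Gaussian noise (SD 0.03
on the contrast axis, 0.08 on R) is platform- and artifact-scalable.

Inheritance is standard: founders are drawn from Hardy-Weinberg
proportions at a per-SNP B-allele frequency uniform on (0.3, 0.5) in the
class-recovery scenario (low-frequency SNPs make several geometry
statistics degenerate at cohort sizes of ~100, which is a property of the
statistics, not of the biology we want to probe); gametes recombine with
crossover probability given by Haldane's map function of the cM gap.
Haldane (no interference) was chosen over Kosambi for simplicity; a
consequence worth knowing is that close double-crossovers — and therefore
a small genuine background of "consistent errors" — occur more often than
in real meiosis.

Auto-calling is emulated by a per-SNP 1-D Gaussian mixture on Theta (1-3
components, BIC selection, deterministic initialization at the platform
centers; components map to genotype classes by nearest center, ties broken
toward the heavier component). Calls below a 0.85 posterior or below 25%
of the SNP's reference R are set missing; the reference R is the SNP
median floored at half the experiment-wide median, because a SNP where
most of the cohort has failed hybridization would otherwise gate nothing.
A per-call error rate of 5e-4 (between the two platforms' published
repeatability discordance rates, 1.6e-5 and 3.2e-3) models residual
miscalls.

# What each planted class is

`simulate_scenario()` assigns every SNP one mechanism (see
`?plantable_classes`): no artifact (A); a few calls displaced between
clusters (B); a 3'-proximal polymorphism linked to the B allele that
collapses the 35-mer heterozygous cluster into AA (C); two moved
duplicate calls (D); paralog compression plus noise (J); an A-linked
polymorphism merging the heterozygous cluster into BB (K); heterozygote
hybridization dropout (O); and three first-platform exclusions
(monomorphic, poor clustering, common null). The mechanisms were chosen
so that each class's *definition* is unambiguous in the truth — e.g. K's
merged cluster sits under two within-mode SDs from its host class, while
C's sub-cluster is over four away — because a classifier cannot be
expected to separate classes that the world itself does not separate.

# Curation methods

**Duplicates and repeatability.** Concordance is the fraction of loci
with identical visible calls over loci called in both samples; duplicates
require strictly more than 97% over at least 500 jointly-called loci
(the spec's source workflow is silent on a minimum; 500 avoids spurious
duplicates from sparse overlap). Accessions replicated k times contribute
the mean of their choose(k, 2) pairwise discordances once, before the
across-accession mean. Curated null alleles are exempt from discordance
tallies.

**Mendelian errors.** Duo and trio checks are allele-set logic (a duo is
inconsistent exactly when parent and offspring share no allele; a trio
when the offspring's alleles cannot be drawn one from each parent), with
N handled as a transmissible allele. The uncallable double null is
treated as missing during scanning — scanning it as a literal {N, N}
genotype would manufacture errors against any called relative.
"Consistent errors" are operationalized as singleton double-recombinants:
per parent and linkage group, transmitted-allele states are converted to
haplotype-origin states by minimum-recombinant majority phasing across
the parent's offspring (at least 4 informative offspring; a single
meiosis cannot distinguish phase from recombination), and a one-SNP
origin flip flanked by 3 concordant informative SNPs within 10 cM on
both sides is flagged. The source workflow delegates this to FlexQTL
without printing its rule; the singleton-flip operationalization is this
package's own and is validated only against the simulator's ground truth.

**Null inference.** An opposing-homozygote duo whose two members both sit
below 0.6 of their called cluster's *upper-quartile* R is recoded to
AN/BN (the upper quartile, not the median, because a common null
contaminates its own cluster's R distribution); individuals below 0.1 of
the SNP median R become NN, forcing visibly homozygous low-R parents to
carrier status. SNPs with at most 3 carriers are flagged rare and remain
includable, mirroring the source workflow's unquantified "rare" rule.

**Cluster analytics.** Cluster space is the 5-95% Theta quantile range
under linear-interpolation (type 7) quantiles — stated explicitly because
the 0.90 worked example depends on the quantile definition. Modes are KDE
local maxima (Silverman bandwidth) carrying at least 2% of mass.
Between-cluster calls are called points beyond 3 robust SDs (MAD floored
at 0.03) of every class mean and strictly between the outermost class
means; uncalled points do not count, and the between points are excluded
from the class interval summaries they would otherwise inflate. The
heterozygous sub-cluster detector demands separability (mode gap of at
least 0.08 and at least 3 member-MADs), evidence enrichment of at least
0.5 — duplicate discordance when available, which is sharper than
Mendelian errors because errors also name the innocent relatives of
miscalled individuals — and that the recode accounts for at least 80% of
the SNP's discordant individuals; the pipeline additionally verifies the
recode creates no new errors or discordances.

**Map revision.** Probe BLAST hits below E = 1e-12 on the expected
chromosome and inside the flanking-SNP interval anchor each SNP
physically, lowest E winning. Per linkage group, the longest
cM-non-decreasing subsequence along physical order is kept; conflicting
SNPs move to positions linearly interpolated on relative physical
distance from the nearest kept flanks (fallback: alternative adjacent
flank, then midpoint), capped at 2 cM of displacement and vetoed if a
supplied hook reports more consistent errors. The revision is idempotent.
"Linear algebra approach" is read as 1-D linear interpolation on relative
physical distance — the only reading consistent with interpolation from
the nearest flanking SNPs. SNPs are never moved across linkage groups.

**Classification.** The first-platform ladder (monomorphic; poor
clustering; overlapping null and homozygous clusters; extra clusters with
illogical segregation; illogical segregation; else included) and the
second-platform class ladder (R, C, J, K, O, B, I/G, E, L, N, D, P, Q, M,
A — see `?classify_axiom`) are quantitative operationalizations of
originally manual, visual classifications; every trigger is exposed in
`default_thresholds()`. Order matters and is part of the design: a
verified class-C rescue is claimed before the geometry classes it would
otherwise trip; J precedes K because global poor differentiation
subsumes a single merged class; D demands otherwise-clean geometry
("only 1 to 2 discordant calls" as the *only* issue); the error-count
class P comes after all geometry classes ("normal clustering but...").
Class M has no operational definition in the source classification and
is implemented as the residual for heavy unresolved discordance. Classes
E/H are founder-lineage-specific discordance where the lineage is an
input (`founder_lineage`), never inferred. Clone-group consensus at
integration is unanimity among non-missing calls, else missing —
zero-tolerance, matching the curation stance throughout.

# What a green test run does and does not establish

The synthetic world emulates pedigreed inheritance, three-cluster Theta
geometry, platform-specific probe chemistry and the artifact mechanisms
above. It does not model bead/image-level chemistry, GC effects,
polyploid dosage, population structure beyond the configured pedigree, or
the long-tailed intensity distributions of real arrays. Green acceptance
tests therefore establish that the implementations are mutually
consistent, match their closed-form or enumeration oracles, and recover
artifacts whose mechanisms are the stated ones — not that the default
thresholds are optimal for any particular real dataset. The headline
figures of the motivating study (97.1% duplicate concordance, 81.7%
compatible) derive from its real 20K/480K apple arrays and are not
reproducible at desk scale; no test here claims them.

# Numerical choices and degenerate inputs

* EM for calling: 60 iterations, tolerance 1e-7, SD floor 1e-3 (guards
  the zero-variance clusters a noise-free simulation produces).
* Theta is clipped to [0, 1]; clipping piles mass onto a cluster center
  at the boundary, which is why sub-cluster separability uses MADs of
  mode-assigned members rather than mixture SDs (a boundary spike
  collapses a fitted component's SD and corrupts the ratio).
* Fewer than 2 Theta values: cluster space is NA; fewer than 20: flagged
  low-n/unstable rather than refused.
* `interpolate_cm` with a zero physical span warns and falls back to the
  midpoint.
* All generators and the caller are deterministic under a fixed seed;
  ties between equal-mean mixture components resolve toward the heavier
  component.

# Scale of the shipped acceptance scenarios

The acceptance suite runs the stated scenarios at desk scale — 2000 SNPs
for null recovery, 240 SNPs by 105 individuals for class recovery, 220
individuals by 1000 SNPs for duplicate screening — which complete in
seconds to a couple of minutes on one CPU. The 3'-distance experiment
isolates the secondary-polymorphism mechanism by switching other noise
sources off (call error 0), because the monotone-rate criterion concerns
that mechanism, not sampling noise; its distance grid avoids the exact
retention value at which a component mean ties between two cluster
centers, where the call is a coin flip by construction.
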