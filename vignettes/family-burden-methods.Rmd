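---
title: "Methods: family burden scores, APOE diplotypes and gene-level methylation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: family burden scores, APOE diplotypes and gene-level methylation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famgbs)
```

## The setting and the model

famgbs analyzes small multi-generational families in which a handful of
blood relatives have array genotypes and CpG methylation profiles. The
central quantity is the **genetic burden score**,

$$\mathrm{GBS}_i \;=\; \sum_{j=1}^{m} G_{ij}, \qquad G_{ij} \in \{0,1,2\},$$

the unweighted count of designated risk alleles over a fixed
candidate-gene SNP panel. The deliberate absence of effect-size weights
is a modelling position, not a simplification of convenience: within a
single family, weights estimated in external populations (usually of
different ancestry) import biases from allele-frequency and LD
differences and imply a precision that a seven-person pedigree cannot
support. The score's only valid use is *relative comparison among the
scored relatives*; it is not a probability of disease and has no
interpretation against population polygenic-score distributions. The
package's reporting functions are built around that boundary: every
statistic is descriptive (means, sample SDs, ranges, within-family
correlations), and nothing converts a score to a risk.

Assumptions baked into the scoring path:

- SNPs are biallelic and autosomal; each is scored independently (no
  phasing, no interaction terms).
- The panel's risk-allele designations are taken as given on the VCF
  reference strand; the package never strand-flips (A/T and C/G SNPs
  pass through untouched, since flipping would require external
  frequency data).
- Genotypes entering the score are complete: the QC chain removes any
  SNP with a missing call, and `compute_gbs()` treats a missing call as
  a contract violation (an error), never as a silent zero.

## Pedigree semantics

Generations are ordinal: founders (no in-pedigree parents) are
generation 1 and every child sits one level below its deepest
in-pedigree parent; a child with a single in-pedigree parent is that
parent's generation + 1. The assignment is a longest-ancestor-path
computation, deterministic and independent of file row order, and its
failure modes (cycles, no founder) are hard errors.

"Blood relatives of a proband set" is implemented as *shares an
in-pedigree common ancestor with some proband* (ancestors include
self, so ancestors and descendants qualify). Plain graph connectivity
over parent–child edges would be wrong in an instructive way: a
marry-in is connected to their spouse's family *through their own
children*, yet shares no genetic background with the spouse's side.
Under the common-ancestor rule marry-ins drop out, while a spouse who
is also a cousin (a genuine blood path) is retained.

The Mendelian checker enumerates parental gamete pairs: a (child, SNP)
pair is flagged iff no choice of one allele from each parent's genotype
reproduces the child's genotype. With one genotyped parent the check
weakens to allele sharing with that parent; missing child genotypes are
never flagged. X/Y inheritance is not special-cased because the
candidate panel is autosomal.

## Variant QC

The filter chain runs in a fixed order so removal reports are
reproducible: (1) multi-allelic records, (2) no clear risk-allele
designation (the `risk_allele` entry must be one of REF/ALT), (3)
monomorphic across the scored samples (one observed allele), (4) any
missing call. Each removed SNP is attributed to the *first* rule it
fails. The chain is monotone and idempotent; the order itself is a
package convention, chosen so that structural defects (rules 1–2) are
reported before sample-dependent ones (rules 3–4).

Coordinates are 1-based inclusive everywhere (VCF convention), and
region extraction keeps a SNP iff `start − flank ≤ pos ≤ end + flank`
with both boundaries inclusive. Flanked regions that overlap on a
chromosome would make gene assignment ambiguous and are rejected
outright rather than resolved by precedence.

## APOE ε diplotypes

The two canonical APOE-defining SNPs jointly define the ε haplotypes
(rs429358, rs7412): ε2 = (T,T), ε3 = (T,C), ε4 = (C,C), plus the
vanishingly rare ε1 = (C,T). `call_apoe()` enumerates all haplotype
pairs consistent with the two unphased genotypes. Eight of the nine
genotype combinations resolve uniquely; the double heterozygote is
consistent with both ε2/ε4 and ε1/ε3 and is reported as ε2/ε4 — the
standard clinical convention, since ε1 is negligible in every surveyed
population — with `ambiguous = TRUE` and the alternative attached, so
downstream code can surface the caveat. ε4 carrier status is
possession of at least one ε4 allele. In the burden score itself,
rs429358 and rs7412 are ordinary panel SNPs with their own designated
risk alleles, independent of the diplotype call. Because some arrays
omit these two SNPs, the pipeline accepts a side TSV of directly typed
genotypes; if the VCF also covers them the two sources must agree, and
a conflict is an error rather than a precedence rule.

## Statistics and reporting conventions

- **Sample SD everywhere** (n − 1 denominator); SD of a singleton group
  is reported as absent, not 0.
- **Rounding only at display**: full precision internally, halves
  rounded *away from zero* at 1 decimal for burden statistics and 3
  decimals for correlations. Base R's round-half-even would misreport
  values such as a mean of 45.75.
- **Sibling discordance** is |Δ| and the relative percentage with the
  *smaller* total as denominator (so a 37-vs-61 pair is a 64.9%
  difference). The per-gene decomposition is signed (b − a) and sums
  exactly to the total difference.
- **Contribution percentages** divide each gene's family mean count by
  the family mean total.
- **ICC** is the one-way random-effects form ICC(1) =
  (MSB − MSW)/(MSB + (k₀ − 1)·MSW) with the unbalanced-design average
  group size k₀ = (N − Σnᵢ²/N)/(a − 1), grouping by generation. The
  grouping factor and model form are package assumptions: familial
  clustering is named as an analysis in this setting without a stated
  model, and generation is the only natural grouping in a single
  pedigree.
- **Generational trend** is OLS of the total on the ordinal generation
  code.
- Hierarchical clustering of methylation profiles uses Euclidean
  distance with complete linkage via `stats::hclust()`; the test suite
  checks it against a naive O(n³) agglomerator. On continuous data ties
  are measure-zero; with ties the `hclust` ordering convention decides,
  deterministically for a given input order.

## Methylation processing

β = M/(M + U) with no stabilizing offset by default (an offset argument
exists for pipelines that use one). Probe filtering drops, in order:
detection p-value above 0.01 in *any* sample (strict, because with
seven samples a single unreliable measurement moves a gene mean),
SNP-overlapping probes, cross-reactive probes, and sex-chromosome
probes. SNP-overlap and cross-reactivity are taken from manifest flags
and/or user-supplied mask lists — the package does not compute
population overlap itself. Gene-level summaries average kept probes
inside gene body ± 10 kb; the flank is read as a symmetric extension of
the same region table used for variants (a separate promoter definition
would need annotation the pipeline does not require). A gene with no
probe in range is *absent* from the summary, never reported as β = 0.
Genotype–methylation coupling is the per-gene Pearson correlation
between risk-allele count and mean β across individuals; a gene whose
count vector is constant (legitimately possible after QC) is flagged
undefined rather than erroring.

## The synthetic family generator

The generator exists so that every stage — parsing, region extraction,
QC, scoring, the Mendelian checker, methylation summarization — can be
exercised on data with known truth. Its defaults are a statement of the
world it emulates, fixed once:

| parameter | default | rationale |
|---|---|---|
| pedigree | 3 founders, 2 parents, 2 sibs | the three-generation, seven-member blood core: one single founder (affected), a founder couple, one second-generation child of each line, two full sibs |
| SNPs per gene | ABCA7 101, PICALM 89, CR1 84, CLU 29, BIN1 8, APOE 9 | the candidate panel's per-gene composition, incl. rs429358/rs7412 at their real GRCh37 positions |
| risk-allele frequency | U(0.01, 0.15) per SNP | E[GBS] = 2·m·E[p] ≈ 51, the realistic tens scale for unweighted counts |
| LD persistence ρ | 0.8 | strong local LD, as expected of proxy panels chosen for LD with lead SNPs |
| recombination | 0.01 per adjacent interval | few crossovers per gene block per meiosis |
| missingness / error injection | 0 | clean world by default; both injectable and logged |
| probe noise | SD 0.05, logit scale | keeps β in (0,1) by construction; spread comparable to reported within-family β ranges |
| affected offset | −0.1 logit | mild hypomethylation of the affected founder, emulating the observed lowest-β pattern without any causal claim |

LD uses a latent-uniform copy chain: each SNP's latent U(0,1) value is
copied from its left neighbour with probability ρ (within a gene
block), else redrawn, and the haplotype carries the risk allele iff the
latent value is below the SNP's frequency. Two properties motivated
this over a state-copying chain: marginals are *exactly* Bernoulli(p)
at every ρ (a state-copy chain biases marginals toward neighbouring
frequencies), and for equal frequencies the adjacent-state correlation
is exactly ρ, giving a closed form the tests can check. Gene blocks are
mutually in linkage equilibrium and assort independently in meiosis,
as for genes on different chromosomes.

Meiosis starts from a uniformly chosen parental haplotype and switches
source with the recombination probability at each interval. Mendelian
error injection picks leaf-child SNPs where an infeasible genotype
exists and logs every change; restricting injection to leaves is
necessary for "exactly k violations detected" to be well-defined,
since corrupting an individual who is also a parent can cascade into
violations at their children.

What a green test on synthetic data does establish: the counting,
filtering and statistical machinery is correct against independent
oracles, transmission respects Mendelian constraints, and planted
defects are found exactly. What it does not establish: anything about
real LD structure (the copy chain is one-parameter, not a coalescent),
real methylation biology (probe βs are conditionally independent given
the gene mean; no CpG-island structure, batch effects or cell-type
composition), array measurement error, or any clinical claim.

Two statistical facts about this world are worth recording because
they contradict first intuitions. First, sibling burden discordance
*grows* with ρ: positive LD makes haplotype block sums more variable,
so the gamete a sib inherits is closer to all-or-nothing
(measured mean |ΔGBS| ≈ 6, 8, 16.5 at ρ = 0.2, 0.5, 0.9). Second,
per-SNP frequency recovery from 500 founders has a binomial standard
error up to ~0.011 at p = 0.15, so isolated deviations slightly above
0.03 are expected from an exactly unbiased generator; the property
suite therefore checks a Bonferroni-safe 4·SE envelope per SNP plus a
mean absolute deviation below 0.01, while the stricter fixed band is
kept, as specified, in the acceptance suite.

At n = 7, null Pearson correlations are wide (SD ≈ 0.41, so |r| ≥ 0.5
occurs about a quarter of the time per null gene). Coupling-recovery
checks therefore require the coupled gene to exceed |r| > 0.8 with the
right sign in ≥ 18/20 seeded replicates, while null genes are required
to stay below 0.5 *on average* — a per-replicate bound on five null
genes simultaneously would fail for any correct implementation.

## Worked-example fixture

`fixture_core_family()` packages the printed per-individual totals,
generations, carrier and affected flags, per-gene family means, the
sibling pair, and the three printed individual APOE β values. One
total (J-011 = 41) is not printed as a literal anywhere; it is forced
by the generation-II summary (n = 2, range 41–45) together with
J-025 = 45. The remaining four individual APOE β values and the exact
panel genotypes are unpublished, so the family-mean β (reported as
0.523) and the per-gene genotype–methylation correlations of the
source analysis are *not* recomputable and are asserted nowhere;
the fixture's ε genotypes are back-derived from the stated diplotypes,
which is unambiguous for ε3/ε3 and ε3/ε4.

## Degenerate inputs and numerical choices

- Empty region table → empty extraction; empty post-QC panel → the
  pipeline completes with a warning and no burden block.
- `group_summary()` of a singleton reports SD as `NA`; of an empty
  vector, errors.
- Correlations require n ≥ 3 and nonzero variance; constant vectors are
  errors (or flagged, in the per-gene path, where constancy is a
  legitimate data outcome).
- Relative discordance requires positive totals (a zero total would
  make the percentage undefined).
- Display rounding uses half-away-from-zero with a machine-epsilon
  guard against representation error (so 45.75 → 45.8 reliably).

## Limitations

The package scores only what it is given: risk designations are inputs,
not derived; no imputation, phasing, kinship estimation or
Hardy–Weinberg testing (meaningless within one family) is performed;
methylation normalization is assumed done upstream of the β matrix.
All statistics are descriptive instruments for families of a handful of
members — the package deliberately offers no p-values for its headline
comparisons, because at these sample sizes they would be decoration.
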