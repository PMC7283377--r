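---
title: "Substitution mapping of SER QTLs with single-segment substitution lines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Substitution mapping of SER QTLs with single-segment substitution lines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sslmap)
```

## The problem and the design

Stigma exsertion rate (SER) — the percentage of rice spikelets whose
stigmas remain exserted after flowering — determines how well a
male-sterile line outcrosses in hybrid seed production. Cultivated rice
lost much of this trait under domestication; wild *Oryza* species retain
it. A single-segment substitution line (SSSL) library makes the trait
genetically tractable: each line carries exactly one donor chromosome
segment from a wild accession in an otherwise uniform recurrent-parent
(recipient) background, so any reproducible phenotypic displacement of a
line can be attributed to a locus inside its segment.

`sslmap` implements the complete analysis for such a library: segment
inference from codominant marker genotypes, the phenotypic screen against
the recipient, interval delimitation by primary and secondary substitution
mapping, and genetic-effect estimation. A synthetic-data module generates
whole studies with known ground truth so every stage is testable without
field data.

## Segment model

A segment is observed only through markers. With physical marker positions
in kb, a maximal run of donor-genotype calls bounded by recipient-genotype
flanking markers gives

$$L_{min} = x_{last\,donor} - x_{first\,donor}, \qquad
  L_{max} = x_{right\,flank} - x_{left\,flank}, \qquad
  L_{est} = \tfrac{1}{2}(L_{min} + L_{max}),$$

and the *estimated interval* places each end halfway between the outermost
donor marker and the adjacent flank, so its width equals $L_{est}$ exactly.
Missing calls inside a run are bridged (a donor segment cannot be
interrupted by an unknown call without independent evidence); missing
calls at run edges do not extend $L_{min}$ — the inner bound stays
conservative. A run reaching a chromosome end takes its outer bound from
the chromosome extent. Heterozygous calls default to an error for SSSL QC
(finished SSSLs are homozygous by construction); `as_donor` is available
for secondary-line intermediates, which segregate.

Coordinates are 1-based kb, closed intervals, reported to 0.1 kb with
halves rounded away from zero (`round_kb()`); BED export multiplies by
1000, floors the start (shifted to 0-based) and ceils the end, so the bp
interval always covers the kb interval.

## The screen and post-hoc machinery

Lines are screened against the recipient with Fisher's LSD on a pooled
one-way ANOVA: $t = (\bar y_i - \bar y_c)/\sqrt{MSE(1/n_i + 1/n_c)}$ on
the pooled error df, two-tailed. The default detection rule requires
$p \le 0.001$ with the line above the control **in every cropping season**
— the conservative rule a multi-season screen uses to exclude
season-specific artifacts; a pooled mode exists for small designs. The
screen applies no further multiplicity correction beyond the stringent
per-test $\alpha$; tests are two-tailed throughout even though selection
is one-directional, matching standard practice for these designs.

Letter displays come from Duncan's multiple range test: ordered means, a
span of $p$ means declared heterogeneous when its range exceeds
$q\!\left(1-(1-\alpha)^{p-1};\, p,\, df_e\right)\sqrt{MSE/n_h}$ with
$n_h$ the harmonic mean group size; a span that fails to exceed its
critical range is homogeneous and is never subdivided. At $p = 2$ the
critical value reduces to $\sqrt2\,t_{1-\alpha/2}$, so Duncan's decision
coincides with LSD's for adjacent pairs — a property the test suite checks
numerically. The studentized-range quantiles come from `stats::qtukey`;
the multiple-range protocol and compact letter display are implemented
here.

The line-by-season structure is summarized by a balanced fixed-effect
two-way ANOVA (`stats::aov`); unbalanced or incomplete designs are
rejected rather than silently refitted with adjusted sums of squares. The
panicle is the replicate unit; per-line-per-season values default to the
mean of panicle SERs, with pooled spikelet counts as an alternative.

## Primary and secondary mapping

Segments of detected lines on one chromosome are clustered by overlap of
their estimated intervals (transitive closure). Each cluster becomes one
QTL whose interval is the **intersection** of its members' intervals: for
nested segments this equals the shortest member — the classical
substitution-mapping argument — and it generalizes to staggered overlaps.
A staggered chain with an empty common intersection cannot be explained by
one shared locus; the call then falls back to the shortest member's
interval and carries an explicit flag. Names follow rice QTL convention
(`qSER-3b`: trait, chromosome, positional suffix when a chromosome hosts
several QTLs; ties broken by supporting-line ids).

Secondary (fine) mapping classifies recombinant sub-lines of a parent SSSL
from the Duncan letter display at $\alpha = 0.001$: recipient-like lines
(sharing a letter with the control only) are LOW, parent-like lines HIGH,
anything ambiguous UNCLASSIFIED and excluded with a report — the
conservative choice, since an ambiguous line cannot veto marker
placements. The QTL must sit at a marker that is homozygous donor in every
HIGH line and carries no donor dose in any LOW line; the delimited
interval is the estimated interval of the candidate-marker run. An empty
candidate set raises an inconsistency error ("no single-QTL placement
explains the classes") instead of returning a guess. The implementation is
checked against an independent brute-force per-marker placement oracle on
1,000 random configurations.

## Genetic effects

A homozygous substitution displaces the phenotype by $2a$, so the additive
effect is estimated per season as $A_j = (\bar y_{line,j} -
\bar y_{control,j})/2$ (supporting lines of a multi-line QTL are averaged
per season first), reported as the season mean with its standard error
over seasons — the season-level S.E., matching how multi-season SSSL
effects are conventionally reported. F$_2$ genotype classes at a focal
marker are tested against 1:2:1 with the plain Pearson $\chi^2$ (no
continuity correction; the published decision rule compares the raw
statistic to $\chi^2_{0.01,2} = 9.21$). Dominance uses $a = (\bar y_{AA} -
\bar y_{aa})/2$, $d = \bar y_{Aa} - (\bar y_{AA}+\bar y_{aa})/2$; the
$|d/a|$ class boundaries 0.2 / 0.8 / 1.2 (additive / incomplete /
complete / overdominance) are conventional cut points and are exposed as
configuration, since only the qualitative label depends on them.

## What the generator emulates

`sim_config()` defaults describe the study design the package targets:

* genome: 12 chromosomes of 43,000 kb (rice-scale), 60 markers each on a
  jittered regular grid. A jittered grid rather than sorted uniform draws:
  at this density sorted uniforms violate any useful minimum spacing with
  probability near one, while the grid keeps positions strictly
  increasing with a guaranteed floor and the same large-scale uniformity.
* library: 168 lines, one donor segment each; background segment lengths
  uniform on 1,500–12,000 kb, the observed range of such libraries.
* planted QTLs (`default_planted_qtls()`): seven loci on five chromosomes
  with additive effects 10.6–14.8 pp — the magnitude reported for major
  wild-rice SER loci — one of them supported by three nested carriers so
  clustering is exercised.
* phenotypes: baseline $\mu = 29.6$% (a typical *indica* recipient), five
  seasons with zero-mean offsets $(-2,-1,0,1,2)$ pp (seasons differ, but
  first- and second-cropping-season means balance), line-by-season
  interaction sd 2 pp, panicle residual sd 5 pp, 10 panicles per
  line-season.

Two observation models are provided. `"normal"` (default) emits panicle
SER values with Gaussian residual sd 5 pp, clamped to $[0,100]$ — the
scale on which the screen's calibration properties are stated.
`"binomial"` is the biologically faithful alternative: Poisson spikelet
counts (mean 150) and binomial exserted counts at the latent rate, split
into single/dual exsertion 0.75/0.25 (the split is cosmetic; only total
SER feeds the pipeline).

Three generator rules keep the ground truth exact rather than
probabilistic. Carrier segments are centered on their planted locus and
minimally widened so the locus is flanked by donor markers — the analogue
of marker-assisted selection, under which a carrier whose locus is not
bracketed by markers of its own segment would never have been selected;
this also makes every carrier's estimated interval provably contain the
locus. Background segments containing no marker are resampled (a
marker-invisible segment cannot enter a marker-genotyped library). And by
default background segments are resampled away from planted loci
(`exclusive_carriers`), so each QTL's carrier set is exactly its
designated carriers; disable it to study chance co-carriers. Secondary
lines express a QTL iff their donor run includes the parent-run marker
nearest the planted locus, because one marker is the intrinsic resolution
of substitution mapping — tying expression to an off-marker position can
generate class patterns no single-marker placement explains.

What passing tests therefore show: the pipeline's inference, statistics
and interval logic are correct *under this generative model*. They do not
show robustness to genotyping error, segregation distortion, multi-segment
lines, shared QTL between "distinct" loci, or unbalanced field designs —
real-data features the generator deliberately omits (multi-donor-segment
lines and meiosis-accurate recombination are out of scope).

## Numerical choices and degenerate inputs

* Constant data in ANOVA: $F = 0/0$ is reported as $F = 0$, $p = 1$;
  zero within-group variance with real separation as $F = \infty$,
  $p = 0$.
* Zero pooled variance in the season t-test: $p = 1$ if means agree,
  otherwise $p = 0$ with a `degenerate` flag.
* `verify_single_segment` failures drop a detected line from mapping with
  a warning in the run report rather than aborting the run.
* Reports round kb to 0.1 (halves away from zero); in-memory values stay
  full precision, and the identity $2L_{est} = L_{min} + L_{max}$ holds
  exactly.
* The run report omits wall-clock timing and output paths from its JSON
  form so identical inputs produce byte-identical report files.
* Two published reference rows (`qser_reference()`, qSER-1b and qSER-5)
  are internally inconsistent by 0.1 kb between endpoints and printed
  estimated length — an upstream rounding artifact. The package follows
  its own rounding rule and flags those rows (`width_consistent`) rather
  than matching the printed cells.

## Problem sizes used by the test suite

The packaged checks run the full pipeline on 50 replicate simulated
studies (168 lines, 5 seasons, 10 panicles), 2,000 null datasets for LSD
calibration, 5,000 multinomial draws for $\chi^2$ calibration, 1,000
random fine-mapping configurations against the brute-force oracle, and
200 F$_2$ populations of n = 80 for effect recovery — sizes chosen so each
property is measured with a standard error well below its acceptance
margin while the whole suite stays interactive.

## A small worked run

```{r, eval = FALSE}
st <- simulate_study(sim_config(seed = 7))
res <- run_pipeline(st$map, st$geno, st$pheno,
                    run_config(control_id = "HJX74"))
res$qtls[, c("name", "chromosome", "est_length_kb",
             "additive_effect", "se", "supporting_lines")]
```

The QTL table lists, per call, the delimited interval and estimated
length, the minimum screen p among supporting lines, and the additive
effect with its season-level standard error; `st$truth` holds the planted
positions and effects for comparison.
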