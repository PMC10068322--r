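---
title: "Quantifying PAS cleavage efficiency from windowed read counts: models and design"
author: "pascleave"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying PAS cleavage efficiency from windowed read counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pascleave)
```

## The measurement

Cleavage of a pre-mRNA at its polyadenylation site (PAS) removes the
transcript's 3'-flanking region. In nuclear RNA-seq, sequence immediately
*downstream* of the PAS is therefore present only on transcripts that have
not (yet) been cleaved, while sequence immediately *upstream* is present on
every transcript, cleaved or not. Counting reads in two equal windows
flanking the PAS turns this into a per-gene readout:

$$\hat r_g = \frac{\text{normalized reads in } [\mathrm{PAS},\,
\mathrm{PAS}+w)}{\text{normalized reads in } [\mathrm{PAS}-w,\,
\mathrm{PAS})}$$

the *uncleaved/total ratio*, an inverse proxy for 3'-end processing
efficiency. The window width defaults to $w = 500$ nt: wide enough to
collect reads at typical nuclear RNA-seq depth, narrow enough that the
downstream window usually stays inside the gene's own 3'-flanking region.

Gene models are built by merging all transcripts that share a symbol; the
PAS is the 3'-most end of the merged span. Internal or alternative PAS
isoforms are deliberately not modeled — the method asks about the terminal
cleavage site of the merged gene. Genes whose downstream window overlaps
*another gene's span* are discarded, because reads there are ambiguous
between readthrough and the neighbour's expression. The overlap test is
strand-agnostic by default (`overlap_stranded = FALSE` equivalent): under
imperfect library strandedness, an antisense neighbour still contaminates
the window. Nothing in the data can adjudicate this choice, so it is a
documented switch rather than a hidden constant.

## Counting rules

An alignment is assigned to a window if its full aligned reference span
(including splice gaps) overlaps the window by at least one base, its MAPQ
is at least 20, and its strand is compatible with the library type
(`reverse` by default, matching dUTP-type stranded protocols where the read
maps antisense to the transcript). Secondary and supplementary records are
excluded before any of this, so one sequenced fragment counts at most once.
A read that straddles the PAS touches both windows and is ambiguous between
"total" and "uncleaved"; the default drops it, `count_both` keeps it in
both and is provided for sensitivity analysis. The 5'-end assignment
dialect used by some feature counters is a legitimate alternative; span
overlap was chosen because it is the common convention and because with
terminal 500-nt windows the two dialects differ only for boundary reads.

A gene enters the differential analysis only if, in at least one condition,
both of its regional sums across replicates reach 10 reads. Without
downstream reads somewhere, the ratio under test is unobservable.

## The interaction model

The question is not whether downstream counts change between conditions —
expression changes do that — but whether they change *more than the
upstream counts do*. Per gene, counts $y_{ij}$ (region $i \in \{up,
down\}$, sample $j$ with size factor $s_j$) are modeled as negative
binomial, $\mathrm{Var} = \mu + \alpha\mu^2$, with log-linear mean

$$\log \mu = \beta_0 + \beta_1\,\mathrm{cond} + \beta_2\,\mathrm{region}
+ \beta_3\,\mathrm{cond}\times\mathrm{region} + \log s_j .$$

$\beta_3/\ln 2$ is `delta_log2`, identically equal to
$\log_2\mathrm{FC}_{down} - \log_2\mathrm{FC}_{up}$ — the change in the
uncleaved/total ratio on the log2 scale. The fit is Fisher-scoring IRLS
with weights $\mu/(1+\alpha\mu)$, initialized from a linear fit to
log-shifted normalized counts, iterated to a $10^{-10}$ coefficient
tolerance (cap 100 iterations). The covariance comes from the inverse
Fisher information; the Wald statistic $\beta_3/\mathrm{se}$ is referred to
a standard normal, as the test's name implies — with two replicates per
condition this is optimistic in the extreme tails, which is the standard
caveat of this test family and is stated here rather than patched with an
ad hoc $t$ reference.

Genes in which an entire condition-by-region cell is zero cannot support
the saturated mean model without inventing infinite fold changes; they are
reported unconverged with missing p-values. A `pseudo_count` option adds a
constant to every observation of such genes for users who prefer a finite,
biased answer.

Classification follows the raw p-value at $\alpha = 0.05$: positive
`delta_log2` and $p < \alpha$ is *repressed cleavage* (more readthrough
under treatment), the mirror case *increased cleavage*. No multiplicity
adjustment is applied to the calls — that matches the classification rule
this pipeline implements — but Benjamini–Hochberg q-values are always
emitted, and the recovery numbers below show why a user screening for
candidates should prefer them.

## Normalization and dispersion

Size factors are median-of-ratios, computed from the *upstream windows
only*. Downstream counts are excluded from normalization because they are
near zero for efficiently cleaved genes and, more importantly, they carry
the signal under test; normalizing on them would absorb part of any global
readthrough shift. `features = "all"` restores the pooled behaviour.

Dispersion is estimated per gene by method of moments on normalized
counts, pooled over the four design cells, floored at $10^{-8}$, then
shrunk (weight 0.8 by default) toward a parametric trend $\alpha(\mu) =
a_0 + a_1/\mu$ fitted across genes. With two replicates per condition the
per-gene estimate is mostly noise, so the trend carries the weight; a
single $\alpha_g$ is shared between a gene's two regions for the same
reason. A known dispersion can be supplied directly (`fixed =`), which is
how the calibration studies below are run. No fold-change shrinkage is
applied anywhere: reported coefficients are plain MLEs.

## What the generators emulate

The count generator draws upstream means from a log-normal (default
$e^{\mu_{\log}} = 200$, $\sigma_{\log} = 1$, a typical nuclear RNA-seq
window-depth spread), applies per-sample library scalars, and sets the
expected downstream/upstream ratio exactly equal to a readthrough fraction
$r$, by default 0.3 — downstream signal detectable but substoichiometric,
as the expression filter presupposes. Two conditions with two biological
replicates each and $\alpha = 0.05$ are the default design. Regulated
genes multiply $r$ under treatment by `effect_fold`, capped at 1 (a
readthrough fraction cannot exceed complete non-cleavage). Every gene has
its own deterministic substream, so enlarging a simulation never perturbs
existing genes.

The read-level generator emits 100-nt single-end alignment records
antisense to their gene, uniform over the gene body (plus a 1-kb extension
for the uncleaved fraction), with a two-point MAPQ distribution; its truth
table is produced by an independent brute-force per-read assignment, so
the production counter can be checked cell-for-cell. No sequence content,
GC/3'-bias, or error model is simulated — the counting contract depends
only on span, strand and MAPQ — so passing tests validate the counting and
testing machinery, not robustness to alignment artefacts in real data.
Likewise the Ct generator ($C_t = c_0 - \log_E q + \varepsilon$) validates
the ratio algebra, not qPCR chemistry.

## Calibration, recovery, and an honest bound

Problem sizes were chosen to make the checks sharp but quick: 5,000 genes
for calibration and recovery, 200 genes x ~10,000 reads for counting
equivalence, 1,000 random primer walks, 10-kb scan sequences.

Under the null (equal $r$ in both conditions, known $\alpha = 0.05$) the
test rejects at $p < 0.05$ at a rate of ~0.051-0.059 across seeds with a
Kolmogorov–Smirnov distance from uniformity of ~0.01-0.03. With 10% of
genes at a 4-fold readthrough increase and deep counts (cell means
$\ge 500$), the mean estimated `delta_log2` among regulated genes lands
within a few hundredths of the true 2.0, and sensitivity of the
directional call at raw $p < 0.05$ exceeds 0.99.

Precision at raw $p < 0.05$, however, is arithmetically capped in this
design: a calibrated test yields about $0.05 \times 0.9 \times 5000 = 225$
false rejections, roughly half in the positive direction, against ~500
true ones — precision $\approx 0.8$, and no correct implementation can do
better without breaking null calibration. The same call set under BH
$q < 0.05$ reaches precision ~0.97 at sensitivity ~0.92. This is the
quantitative form of the advice above: classify at raw p to mirror the
reference analysis, screen with q-values.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open everywhere internally; GTF is
  converted on input, BED passes through.
* Windows that would cross coordinate 0 raise an error rather than being
  truncated silently.
* Offset invariance: multiplying *all* counts by $k$ with size factors
  rescaled by $k$ reproduces every point estimate exactly in the Poisson
  limit, and that is what the tests assert. Rescaling a *single* library is
  not an invariance of any count likelihood — it changes that library's
  weight in the pooled cell means and everyone's information content — so
  standard errors and p-values legitimately move; this is a property of
  count models, not an implementation artefact.
* The AT-rich scanner reports connected components of the union of
  qualifying 100-nt windows (threshold 0.65 A/T; `N` counts against). A
  run-of-windows definition would emit overlapping "elements" whenever two
  runs sit closer than one window width; the footprint-union definition
  keeps elements disjoint and sorted. Window and threshold have no
  canonical published values and are exposed as parameters.
* Primer-walk inference never repairs a non-monotone profile (an amplified
  probe beyond a lost one); it flags the profile inconsistent, since that
  pattern indicates an experimental failure the user must see.
* qPCR ratios fix amplification efficiency at 2 (the formulas are defined
  in base 2); an efficiency in $(1, 2]$ is accepted for generality.
  Replicates aggregate on the $\Delta C_t$ scale, i.e. geometric mean of
  ratios.

## Known limitations

Replicate counts are taken as given (the design is replicate-agnostic,
$\ge 2$ per condition); no fragment-level paired-end logic (the target
libraries are single-end); no alternative-PAS isoform testing, which is a
different question from terminal-PAS cleavage efficiency; and the normal
Wald reference is anti-conservative at very low counts — the expression
filter is the main guard, and q-values are provided.
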