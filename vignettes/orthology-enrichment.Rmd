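---
title: "Ortholog-aware gene-set enrichment: models, calibration and design"
author: "orthoenrich"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ortholog-aware gene-set enrichment: models, calibration and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orthoenrich)
```

## The problem

Zebrafish (*Danio rerio*) is a standard vertebrate model for human
development, toxicology and disease, but its functional annotation is far
sparser than human annotation: KEGG annotates roughly half as many
pathways for zebrafish as for human, and KEGG disease networks exist for
human only. An enrichment analysis of a zebrafish experiment run against
zebrafish gene sets alone is therefore blind to a large slice of testable
biology. The remedy implemented here is annotation transfer through
orthology: project human-annotated gene sets into zebrafish gene space by
replacing each human member with all of its zebrafish orthologs, then test
the projected sets exactly like native ones, keeping track of which
results rest on transferred annotation.

Orthology between the two species is many-to-many. The teleost lineage
underwent a whole-genome duplication, so one human gene frequently has two
retained zebrafish co-orthologs; conversely a zebrafish gene can map to
several human genes. All mapping functions in this package therefore emit
*every* ortholog of an input gene (with a one-to-many count in the
result), and set projection takes the union over members. Roughly 65% of
human protein-coding genes have at least one zebrafish ortholog in current
genome builds, which bounds what projection can recover; sets whose
projected membership falls below `min_size` (default 5) are dropped from
orthologized collections because both tests below become degenerate or
wildly unstable on near-empty sets.

## The two enrichment tests

Let the *universe* be the deduplicated gene list of the
differential-expression (DE) table, of size $N$.

**Overrepresentation (Fisher's exact test).** Genes are dichotomized at a
raw DE p-value cut-off (default $p < 0.05$; the cut-off is a tunable
argument, unitless, on the raw p scale). With $a$ = in-set and
significant, $b$ = out-of-set and significant, $c$ = in-set and not
significant, $d$ = neither, the point probability of the observed table
under the hypergeometric null is

$$p = \frac{\binom{a+b}{a}\binom{c+d}{d}}{\binom{N}{a+c}},$$

and the one-sided test sums these over $a' \ge a$ (enrichment) or
$a' \le a$ (depletion) at fixed margins. Both are computed in log space
from `lchoose` plus a log-sum-exp reduction, so they remain exact to
near machine precision for any universe size.

**Cut-off-free logistic regression.** Dichotomization discards most of
the DE evidence. The second test instead regresses set membership on the
continuous evidence $x = -\log(p_{\mathrm{DE}})$:

$$\log\frac{p}{1-p} = \alpha + \beta x,$$

where $p$ is the probability of set membership, and tests
$H_0\colon \beta = 0$ with the Wald statistic
$W = \hat\beta / s(\hat\beta)$, comparing $W^2$ to $\chi^2_1$. A positive
$\beta$ means set members carry systematically stronger DE evidence —
enrichment; the Wald p-value alone is two-sided, so interpretation (and
the calibration harness) always pairs it with the sign of $\beta$.

The natural log is used for $x$; any other base only rescales $\beta$ and
leaves $W$ and its p-value unchanged (an invariance the test suite checks
to 1e-10). DE p-values of exactly zero are clamped to 1e-300 so $x$ stays
finite.

### Fitting and numerical choices

The logistic model is fit by iteratively reweighted least squares on the
2-parameter design, with step halving so the log-likelihood never
decreases — without it, the heavy-tailed $x$ produced by strong signal
makes plain IRLS overshoot and diverge. Iteration stops when the relative
log-likelihood change falls below 1e-12 (IRLS converges quadratically, so
this costs one or two extra iterations and lands on the MLE to near
machine precision) or at 100 iterations. The standard error comes from
the observed information. Complete separation — a diverging slope that
perfectly classifies membership — is detected and reported as a failed
fit with a diagnostic rather than a spuriously huge $W$; such sets are
skipped by `enrich_collection()` and listed in its `skipped` attribute,
as are sets with no gene in the universe.

**Directional testing.** For "upregulated" tests, Fisher's significance
indicator additionally requires $\log_2\mathrm{FC} > 0$ (symmetrically
for down; a fold change of exactly 0 counts as neither). The logistic
model as written is nondirectional, so the directional variant masks the
evidence: $x_i = -\log p_i$ when the fold change has the tested sign,
otherwise $x_i = 0$, i.e. genes moving the other way contribute only
null-level evidence. This masking is a design decision of this package —
a defensible member of the cut-off-free family rather than the only
possible one — and `direction = "both"` simply stacks the up and down
analyses.

**Other fixed choices.** Duplicate DE genes collapse to their minimum
p-value (conservative and explicit; the count is reported). Unmapped IDs
are reported, never silently dropped, to prevent invisible universe
shrinkage. Multiple-testing adjustment defaults to Benjamini–Hochberg and
is applied across exactly the tested sets, separately per direction;
`correction = "none"` reproduces raw-p reporting. Output rows sort by
p-value with ties broken by set id, and GMT serialization sorts members
lexicographically, so all outputs are byte-stable. Fisher's effect size
is the sample odds ratio, with the Haldane–Anscombe 0.5 correction
applied only when a zero cell would make it 0 or infinite.

## Orthology projection and the novel-only merge

`orthologize_collection()` maps each human set through the orthology
table and tags it `HUMAN_VIA_ORTHOLOGY`. `merge_collections()` then
combines native and projected annotation in two modes. `all` keeps both
versions of every pathway, disambiguated by annotation organism. The
`novel_only` mode treats zebrafish annotation as ground truth: a
projected set is added only when its *counterpart key* — the KEGG map
number with the organism prefix stripped (`dre04010` and `hsa04010` are
both map `04010`), GO ids and human-only KEGG disease ids taken verbatim
— matches no native set. Counterpart matching is deliberately by id, not
by member overlap: overlap-based matching would be a different method
with its own thresholds. KEGG disease sets, existing only for human, are
always retained in novel-only mode by construction.

## What the synthetic data emulates

The generators in `sim_config()` and friends produce the full input
suite — mapping tables, orthology, collections, DE tables — with known
ground truth, because the statistical guarantees of the two tests can
only be verified against data whose answer is known:

* the mapping table is a bijection over four namespaces, so conversion
  round trips are exact by construction;
* each human gene draws 0 orthologs with probability `p_no_ortholog`
  (default 0.35, matching the observed ~65% coverage of human genes),
  2 with probability `p_two_orthologs` (default 0.30, the retained
  duplication signature), else 1;
* collections draw `n_sets` (default 200) sets with sizes uniform on
  `set_size_range` (default 10–100, typical KEGG pathway sizes scaled to
  the default 2000-gene universe) from the universe without replacement;
* null DE p-values are Uniform(0,1) with fair-coin fold-change signs;
  planted sets draw $p \sim \mathrm{Beta}(a, 1)$ — the canonical
  one-parameter stochastically small family, with shape $a \in (0,1]$ as
  the effect strength and $a = 1$ recovering the null exactly — and match
  the planted fold-change direction with probability 0.9.

One user seed drives separate substreams per artifact, so changing the
number of sets never perturbs the gene-level draws and every output is
byte-reproducible. Replicate draws inside `calibration_run()` use
subseeds drawn once from a dedicated stream.

What this synthesis does *not* emulate: negative-binomial count noise and
the DE-testing step itself (p-values are drawn directly, not computed
from reads), correlation between genes, set overlap structure beyond what
uniform sampling induces, and annotation bias. Passing calibration here
therefore shows the tests do what they claim *given* well-behaved
per-gene p-values; it does not certify behaviour under correlated genes,
where all marginal enrichment methods are known to be optimistic.

## Calibration results and problem sizes

`calibration_run()` measures the type-I rate as the fraction of
non-planted set tests rejecting at raw $p < \alpha$, with a Monte-Carlo
standard error taken from the spread of per-replicate rejection
fractions (which respects the dependence among set tests sharing one DE
draw). The reference study conditions used by the acceptance checks are
a 2000-gene universe, 200 sets and 500 replicates; the routine test suite
uses scaled-down versions of the same conditions (a few hundred genes,
tens of sets) chosen so the whole suite runs in minutes while the
full-scale run lives in the acceptance layer.

Two findings are worth stating as properties of the methods, both
reproduced by the suite. The logistic/Wald test is close to nominal at
these sizes — measured rates cluster a few thousandths below $\alpha$,
the mild finite-sample conservatism expected of an asymptotic Wald test
on sets of 10–100 members, and can land marginally outside a strict
two-standard-error band around $\alpha$. Fisher's exact
test rejects clearly *below* its nominal level — the familiar conservatism of
discrete exact tests, whose attainable p-values below $\alpha$ carry
total mass less than $\alpha$; it is a property of the test itself, and
the implementation is verified separately against independent
hypergeometric enumeration to 1e-12 relative error. Power over a planted
effect grid $a \in \{0.2, 0.4, 0.6\}$ is compared on equal-size sets
(`equal_size_sets()`), because set size otherwise dominates the
comparison.

## Known limitations

* Orthology projection transfers annotation, not function: a projected
  disease set is a hypothesis generator, and a hit means "the zebrafish
  orthologs of this human set moved", no more.
* Counterpart detection relies on KEGG id structure; bespoke set ids fall
  back to verbatim keys.
* The logistic model has a single explanatory variable by design;
  covariate adjustment is out of scope.
* GO sets are taken as given — no ontology-graph propagation is applied
  before projection.
* Symbol matching is exact and case-sensitive by default (zebrafish
  symbols are conventionally lower case); an opt-in case-insensitive flag
  exists, but alias/history resolution does not.
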