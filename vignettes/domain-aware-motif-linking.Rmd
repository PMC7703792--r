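---
title: "Domain-aware linking of motifs to transcription factors: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Domain-aware linking of motifs to transcription factors: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dbdlink)
```

# The model

## Motifs and hits

A motif is a position frequency matrix (PFM): L probability columns over
(A, C, G, T). A *hit* of motif X at a sequence position is the event that the
log-odds score of the local word,

$$s(w) = \sum_i \ln\frac{p_{i, w_i}}{b_{w_i}},$$

reaches a threshold $t_X$. Scores are discretized once: every per-column,
per-letter contribution is rounded to a grid of width `bin_width` (default
0.01 on the natural-log-odds scale) and all word scores are exact integer
sums of those binned contributions. The threshold, the hit probability
$\alpha_X = P_{bg}(s \ge t_X)$, the overlap probabilities below, the dynamic
programs and the brute-force test oracle all share this single discrete score
definition, which is why the exact DP and plain word enumeration agree to
floating-point accuracy rather than "up to binning".

The default threshold rule is *balanced*: $t_X$ minimizes
$|FPR(t) - FNR(t)|$, where the false-positive rate is the background tail
probability and the false-negative rate is the probability that a word
generated by the motif itself scores below $t$ (ties prefer the larger,
more specific threshold, and $\alpha_X > 0$ is guaranteed by falling back to
the highest bin the background can reach). A fixed-FPR rule
(`hit_model(..., rule = "fpr", target_fpr = ...)`) is available for users who
want a common specificity across motifs. When a PFM contains zero
frequencies, a pseudo-frequency of `1e-6` is folded in so log-odds stay
finite; matrices without zeros are used as-is.

## Overlap similarity

Two motifs describe a similar binding site if they tend to hit the *same*
place in random sequence far more often than independence predicts. For an
offset $k$ of Y relative to X the overlap probability
$\gamma_{X,Y}(k)$ is the probability, under one iid background sequence
covering both windows, that X and Y both hit. The similarity is the log
enrichment over independent hits,

$$S_{X,Y}(k) = \ln\frac{\gamma_{X,Y}(k)}{\alpha_X\,\alpha_Y},$$

and $S^{\max}$ maximizes over every offset sharing at least one column and
over the reverse complement of Y (disjoint placements would contribute
exactly $S = 0$ and are excluded). $S^{\max}$ is symmetric, invariant under
reverse-complementing either argument, and $-\infty$ exactly when no word can
be a hit of both motifs (for example, incompatible near-deterministic
consensus motifs). Ties in the maximization resolve toward the forward
orientation, then the smaller $|k|$, then the smaller $k$, making reported
alignments deterministic.

$\gamma$ is computed exactly: a joint dynamic program over the overlap
columns tracks the pair of partial integer scores, pruning states that can no
longer reach either threshold (an exact integer bound, not an approximation),
while the non-overlap columns of each motif enter as precomputed
tail-probability tables of their independent score distributions. For short
overlaps the joint distribution is enumerated by a depth-first sweep with the
same pruning; for long overlaps a hashed DP merges states that collide on the
score grid. Computing all offsets of a pair of typical motifs takes
milliseconds; cost grows with the overlap window (roughly with the number of
distinct reachable score pairs), which is the intrinsic price of an exact
fine-grained joint distribution — coarser grids would be faster but would
change the score definition.

## The DBD collection

Motifs annotated with the same DNA-binding domain (DBD) family are clustered
greedily under $S^{\max}$: all motifs start as singleton clusters; the best
pair of consensus motifs at or above `merge_threshold` (default 3 on the
natural-log scale, i.e. overlapping hits at least $e^3 \approx 20$ times more
likely than independent ones) is merged, provided every member of the
tentative cluster still reaches the threshold against the new consensus;
rejected pairs are cached so each pair is considered at most once per
consensus state. Consensus columns are member-count-weighted averages over
the aligned windows; flanks covered by only one side are averaged against the
background so a consensus never sharpens beyond its support. The default
threshold was chosen so that identical short motifs always merge and
consensus-incompatible motifs never do; it is exposed because no single value
suits every database.

The collection maps each DBD name (free-form, whitespace-normalized,
case-sensitive; TFClass family names are the recommended vocabulary) to its
clusters. Motifs without annotation are reported as skipped, never silently
dropped; multiply-annotated motifs go to every listed family by default.
Archives are plain text (JASPAR matrices + membership TSV + key=value
metadata) and carry a fingerprint over the consensus matrices and clustering
parameters, so a stale Monte-Carlo null can never be applied to a changed
collection.

## Domain score and its p-value

For a candidate PFM $P$ the per-family similarity is
$\max_k S^{\max}(P, M_{cl_k})$ over the family's consensus motifs, and the
domain score normalizes across families:

$$I_D(P, D_l) = \frac{\mathrm{clip}(\max sim(P, D_l))}
                     {\sum_m \mathrm{clip}(\max sim(P, D_m))}.$$

$S^{\max}$ is a log-ratio and can be negative or $-\infty$, which a ratio of
similarities cannot absorb; the default clip is $\max(s, 0)$, the minimal
repair. (An alternative, `clip = "exp"`, uses the raw probability ratio
$e^s$.) If every clipped similarity is zero the score falls back to the
uniform $1/|D|$ and is flagged. Scores always sum to 1 across families, so a
score is only meaningful *relative to the other families in the collection* —
small collections (few DBDs) have intrinsically coarse resolution.

Because no analytic null is available, p-values are empirical: a shared
sample of `n = 100000` random PFMs — length uniform on 6–21 (the usual TF
binding-site range), columns from a flat Dirichlet(1,1,1,1), whole matrices
redrawn until the mean per-column Shannon entropy reaches 0.6 bits — is scored
once against the collection (the normalizing denominator is shared across
families, so one pass serves every DBD), and

$$p(x, D_l) = \frac{\max(\#\{r : I_D(r, D_l) \ge x\},\, 1)}{|R|}.$$

Counting ties upward makes the p-value conservative; the $\max(\cdot, 1)$
floor makes the smallest attainable p-value exactly $1/|R| = 10^{-5}$ at the
default sample size, which is the package's stated convention. Entropy is
measured in bits (base 2); the sampler and its constraints are parameters of
`build_null()` and are recorded, together with the seed and the collection
fingerprint, in the persisted null.

## Meta-analysis and filtering

Given per-method enrichment p-values $p_1, \dots, p_m$ for a motif, Fisher's
method refers $X = -2\sum_i \ln p_i$ to the $\chi^2$ distribution with $2m$
degrees of freedom; the survival function is evaluated with the closed form
for even degrees of freedom, $e^{-X/2}\sum_{j<m} (X/2)^j/j!$. The domain
p-value either joins that combination (variants `MCP`) or acts first as a
hard filter (variants `M_C`, `M_P`, `M_CP`): motifs with domain p-value
strictly above `pi` (default 0.001) are excluded, and the ranking is computed
on the survivors. Equality at `pi` keeps the motif. A filtered table can
become empty — with de novo candidate motifs this is an expected, explicitly
reported outcome meaning none of them resembles any known motif of the TF's
DBD. One caveat the package inherits from the statistics: the domain
p-value's floor ($10^{-5}$) is far larger than enrichment tools' floors, and
Fisher's method is more sensitive to the smaller p-values, so the
meta-analysis variant can be dominated by the enrichment terms; the filter
variants avoid that resolution mismatch, and no rescaling is applied.

## Evaluation

Per dataset the top-1 motif of a variant is scored cluster-aware: a
prediction in the same cluster as the true motif counts as correct, so
near-duplicate database motifs are not penalized. For de novo candidates the
"true" candidate is designated as the one most similar (by $S^{\max}$) to the
TF's known motif. Precision–recall curves sweep a threshold over the top-1
confidences: at threshold $\theta$, TP are correct predictions with
$p \le \theta$, FP incorrect ones, and FN $= n - TP$ (datasets whose motif is
not yet correctly linked, including datasets the filter emptied). The AUC is
the trapezoid over the achieved recall range with the curve anchored at
(recall 0, precision of the first sweep point). Top-1-per-dataset is the
construction under which "how many TFs got the right motif" and a PR curve
coexist.

# The synthetic data generator

Real benchmarks need external enrichment tools and genome-scale ChIP-seq
data; the generator instead builds the smallest world in which every claim is
testable.

* `make_toy_collection()` draws one random *anchor* PFM per synthetic DBD and
  perturbs it (per-column Dirichlet noise, mixing weight 0.05) into members.
  Anchors use peaked columns (Dirichlet concentration 0.1, no entropy floor)
  because real TF motifs are information-rich, and are rejection-sampled
  until every anchor pair has $S^{\max} \le 1.5$ — about the median
  similarity of two unrelated random motifs — so no two synthetic families
  accidentally share a binding preference. That is what makes the generator's
  central invariant ("within-DBD similarity exceeds between-DBD similarity")
  hold by construction rather than by luck of the seed. Anchor lengths
  default to 6–10: the exact joint DP's cost grows with the overlap window,
  and short anchors keep collection-scale Monte-Carlo cheap without changing
  any statistical property being tested.
* `implant_sequences()` emulates peak-centered ChIP-seq sequence sets:
  iid background with a motif-sampled word implanted centered (optional
  jitter) in a chosen fraction of sequences, names carrying synthetic signal
  values.
* `mock_method_table()` stands in for an enrichment tool's output; its
  adversarial mode gives one foreign-DBD decoy a better p-value than the true
  motif — the precise failure mode the domain filter is designed to repair.
* `make_adversarial_scenario()` combines these: 10 TF datasets over 2 DBD
  families, each with one true candidate (a lightly perturbed copy of a
  consensus of the TF's own family, perturbation 0.01) and three foreign-DBD
  decoys; in 60% of datasets the mock enrichment ranks a decoy first. One
  extra dataset contains only foreign decoys, which the filter is expected to
  empty. The anchors are fixed at length 10 so the true candidates' domain
  scores sit clearly above the null's 99.9th percentile across seeds.

What passing these tests does *not* show: the generator draws independent
columns (no dinucleotide structure, no flanking GC bias), its "enrichment
tool" is a stipulated p-value table rather than a sequence scan, and two or
five synthetic families are far from the ~30 DBD families of a real
collection, where the domain score's resolution is higher (the denominator
averages over many families) but annotation noise and family overlap are
real. Results on synthetic scenarios bound correctness of the machinery, not
performance on ENCODE-scale data.

# Numerical choices and degenerate inputs

* Natural logarithms throughout; `bin_width = 0.01` on the log-odds grid.
* Columns are renormalized on load (parsers differ in rounding); a column
  summing to zero is an error unless a pseudo-count is requested.
* Deterministic tie-breaks everywhere: thresholds prefer the more specific
  grid point, $S^{\max}$ prefers forward/small offsets, clustering resolves
  equal similarities lexicographically on representative member ids, rankings
  break p-value ties by motif id. Identical inputs give bit-identical
  clusterings and null archives.
* A candidate incompatible with every family gets the flagged uniform score;
  p-values of 0 from enrichment tables are clipped to 1e-300 with a warning
  (Fisher needs $p > 0$); BED records with `start >= end` and unknown
  chromosomes are errors, clipped extraction windows warn.
* Monte-Carlo sizes in the tests are scaled to the quantity under test: the
  minimum-p-value convention is exercised at the full `n = 100000` (it *is*
  a statement about that sample size), calibration and the scenario at
  `n = 2000` (floor 5e-4, well below `pi = 0.001`).

# Known limitations

* Exact fine-binned $\gamma$ for two long, moderately informative motifs is
  expensive (the joint state space is intrinsic); clustering hundreds of long
  database motifs is an offline computation. Published overlap-similarity
  implementations use coarser score grids for exactly this reason.
* The domain score cannot help when the TF's DBD is absent from the
  collection, and with very few families its resolution is coarse.
* The Monte-Carlo null treats the collection as fixed; changing clustering
  parameters requires rebuilding the null (the fingerprint enforces this).
* Single-nucleotide iid background only; no higher-order background models.
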