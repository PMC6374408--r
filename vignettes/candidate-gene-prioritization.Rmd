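---
title: "Prioritizing pathway candidate genes from co-expression networks and differential expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritizing pathway candidate genes from co-expression networks and differential expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coexcand)
```

## The problem

A recurring situation in plant secondary-metabolite genetics: a biosynthetic
pathway (here, the phenylpropanoid route from phenylalanine through daidzein
toward coumestrol in soybean) is known only in part, two genotypes differ
strongly and reproducibly in the end metabolite, and the goal is to nominate
the genes that complete the pathway. Neither differential expression nor
network proximity alone is convincing: many genes respond to the genotype
contrast for unrelated reasons, and many genes sit near the pathway in a
co-expression network without being differentially expressed. The productive
signal is their intersection — genes that are both close to the known
pathway in a functional network and differentially expressed in the right
direction between the contrasting genotypes.

`coexcand` implements that workflow as a reusable, fully testable pipeline:

1. **DEG calling** on a replicated two-genotype FPKM matrix,
2. **three network prioritization approaches** over a weighted
   co-functional network,
3. **integration** into a multi-approach candidate table, and
4. **qRT-PCR concordance validation** via the 2^-ddCt method.

A planted-module synthetic generator stands in for the original sequencing
data, so every stage has a ground truth to be scored against.

## DEG calling

Expression is taken as given FPKM (no re-normalization). For each gene,
every FPKM value below 1 is raised to 1 *before* averaging within a
genotype ("value-level flooring"), and the fold change is

$$\mathrm{log_2FC} = \log_2 \frac{\overline{\max(\mathrm{FPKM}_{case}, 1)}}
                                {\overline{\max(\mathrm{FPKM}_{control}, 1)}}.$$

Flooring prevents ratios between barely-detected transcripts from
dominating the DEG list; a side effect worth knowing is that a gene whose
case samples fall entirely below 1 FPKM reports the (floored) control
abundance as its magnitude, not the unobservable true ratio, and a gene
below 1 FPKM in *both* genotypes reports exactly 0.

Significance uses a two-sided two-sample Student's t-test with pooled
variance on log2 floored FPKM, with no multiple-testing correction. Both
choices are deliberate and exposed:

* The replicated design (3 vs 3) with multiplicative noise is the textbook
  setting for a pooled t on the log scale; Welch and count-model
  alternatives exist, but the pooled t is the simplest test consistent with
  the design, and the `transform` argument lets a user test raw FPKM
  instead.
* Candidate discovery here ranks and intersects evidence rather than
  controlling a genome-wide error rate; DEG status feeds a candidate
  filter, not a final inference. `hub_predict` still emits a
  Benjamini–Hochberg column for reporting.

Degenerate replicates (zero pooled variance) return p = 1 for equal means
and p = 0 otherwise, so constant measurements never propagate NaN.

A gene is a DEG at threshold $t \in \{2, 3, 4, 5\}$ when
$|\mathrm{log_2FC}| \ge t$ and $p < 0.05$; the four flags are nested by
construction. "Up" means up in the case genotype (the high-metabolite
line).

## The three prediction approaches

The network is an undirected simple graph whose edge weights are
log-likelihood scores (LLS) of co-functionality, read from a 3-column edge
list (`read_network`). Duplicate pairs collapse to the maximum weight with
a warning; self-loops and non-positive weights are hard errors.

**Guide prediction.** The known pathway members that are connected to at
least one other pathway member (`connected_pathway_subset`) act as guides;
every other gene is scored by the *sum of LLS over its direct edges to
guides* and ranked by descending score. "Closely connected" is interpreted
as direct (1-hop) neighbors only, because a sum of edge scores is defined
only over direct links; diffusion-style propagation is out of scope.

**DEG-seeded prediction.** The same scorer, seeded instead with the guides
that are themselves DEGs at the base threshold — the pathway members with
expression evidence. By default the seeds are excluded from their own
ranking, mirroring the guide approach (the target is *new* members).

**Hub prediction.** Every gene with degree at least `min_degree` (default
5; smaller neighborhoods give degenerate p-values) is treated as the
central hub of its direct neighborhood, and the overlap between the
neighborhood and the DEG set is scored with a one-sided upper-tail
hypergeometric test: with $N$ background genes, $K$ DEGs, a neighborhood
of size $n$ and overlap $k$,

$$p = P(X \ge k), \quad X \sim \mathrm{Hypergeom}(N, K, n).$$

Hubs rank by ascending p. The background $N$ defaults to all network genes
but is a parameter (`universe`), since whether such databases screen
against all genes or only annotated ones is generally not recoverable; the
default is the most conservative choice available from the data itself.

Ties are broken deterministically everywhere: by statistic, then (hub
only) by larger overlap, then by lexicographic gene id. `top_n_ranking`
is therefore a simple prefix.

## Integration

Each approach contributes its top 20 genes; a gene becomes a candidate
when it appears in at least one top list *and* is a DEG at the base
threshold (log2FC >= 2, p < 0.05). Filtering happens *after* top-N
selection — the per-approach DEG counts answer "how many of this
approach's top 20 are DEGs", which is the natural audit of each approach.
Support is the number of approaches listing the gene; the table sorts by
support, then best rank, then gene id. Up-regulation is *not* enforced:
in the motivating use case all final candidates happened to be
up-regulated, but that is an observation to be checked (`require_up`
exists for users who want the stricter filter).

## qRT-PCR validation

Relative quantification follows the Livak 2^-ddCt method with
amplification efficiency fixed at 2: per sample,
$\Delta Ct = Ct_{target} - Ct_{reference}$; then
$\Delta\Delta Ct = \overline{\Delta Ct}_{case} -
\overline{\Delta Ct}_{control}$ and $rq = 2^{-\Delta\Delta Ct}$.
Technical replicates of a sample are averaged to one Ct first, so the
t-test on dCt values stays at the biological-replicate level. Validation
asks whether sign(log2 rq) matches sign(RNA-seq log2FC) per gene
(`concordance`); the reference gene self-normalizes to rq = 1 exactly.
Efficiency correction from dilution series is a non-goal.

## The synthetic generator

`sim_config()` fixes the study conditions; the defaults are the
conditions under which the package's recovery properties are tested:

| parameter | default | why |
|---|---|---|
| `n_genes` | 2000 | large enough for realistic sparsity, small enough to simulate in seconds |
| `n_pathway`, `n_guides` | 30, 15 | a module the size of a typical partially-known pathway, half designated as known guides |
| `p_within`, `p_background` | 0.6, 0.003 | dense planted module over a sparse background, matching the edge densities of curated co-functional networks |
| `lls_within_range`, `lls_background_range` | [2,4], [0.5,1.5] | planted edges carry higher log-likelihood scores, overlapping nothing |
| `n_replicates` | 3 | the standard RNA-seq design emulated |
| `n_deg` | 200 | 10% of genes differential, a strong two-genotype contrast |
| `deg_log2fc_range` | [2,6] | planted effects at or above the base calling threshold |
| `frac_deg_in_pathway` | 0.1 | 20 of 200 DEGs inside the 30-gene module: DEG density 2/3 within vs ~9% outside, i.e. DEGs concentrated in the module |
| `base_log2fpkm_mean`, `sd` | 6, 1.5 | baselines centered at 64 FPKM, the scale of well-expressed genes |
| `noise_sd` | 0.25 | ~19% coefficient of variation between replicates, typical for bulk RNA-seq of expressed genes |
| `ct_intercept` (qPCR) | 35 | cycles at 1 FPKM, placing Ct values in the usual 20–35 band |

Mechanics: the planted pathway occupies the first `n_pathway` gene ids
(labels are arbitrary in a synthetic benchmark, and deterministic
placement keeps the generator simple and reproducible); every gene pair
gets an independent Bernoulli edge; effects are signed uniformly at
random; noise is Gaussian on the log2 scale, i.e. log-normal FPKM — the
simplest model of multiplicative sequencing noise. Planted hubs are
recorded *post hoc* as pathway genes whose realized degree reaches
`hub_min_degree`, so hub-recovery tests are well-posed even when the
random draw leaves a pathway gene sparsely connected. All randomness
derives from `seed` (network and truth), `seed + 1` (expression), and an
explicit seed argument for qPCR; identical configuration gives
byte-identical outputs.

What the generator does **not** emulate: read-level sampling (no FASTQ,
no length bias), the many near-zero genes of a genome-wide FPKM matrix,
batch effects, correlated noise between replicates, or a scale-free
degree distribution in the background graph. Passing recovery tests
therefore demonstrates that the algorithms are implemented correctly and
behave as designed under their stated model — not that the model captures
every property of real RNA-seq or of curated co-functional networks.

## Numerical conventions and degenerate inputs

* Flooring is idempotent; all-sub-1 input gives log2FC exactly 0.
* Zero-variance t-tests return p in {0, 1} as described above.
* Hypergeometric tails come from `phyper` (verified against exhaustive
  subset enumeration to 1e-12 in the test suite).
* An empty DEG set short-circuits: DEG-seeded and hub rankings are empty,
  the candidate table is empty with all counts 0, and qPCR validation is
  skipped.
* A hub overlap of zero has p = 1 (the upper tail includes the observed
  count).
* Guide scores of exactly 0 (no edge to any guide) are omitted from
  rankings rather than reported as ties at the bottom.

## Problem sizes in the test suite

The recovery tests run the generator defaults over 10 seeds (DEG
sensitivity/precision) and 20 seeds (guide/hub/integration recovery), and
the oracle-equivalence tests use 100 random graphs of up to 50 nodes plus
exhaustive hypergeometric enumeration for universes up to 12 genes —
sizes chosen so the full suite runs in well under a minute per property
while keeping the binomial noise on the averaged metrics small.

## Known limitations

* The guide scorer is strictly 1-hop; genes two steps from every guide
  score 0 regardless of topology.
* The hypergeometric hub test treats neighborhoods as simple random draws
  from the universe, ignoring degree correlation between hubs.
* The pooled t-test with n = 3 per group has little power for effects
  below ~1.5 on the log2 scale at typical noise; the pipeline is designed
  for the large-effect regime its thresholds (log2FC >= 2) imply.
* With a noisy reference gene, 2^-ddCt inherits that noise in every
  target gene's rq; the generator's qPCR noise model is independent
  Gaussian cycles and does not emulate pipetting covariance.
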