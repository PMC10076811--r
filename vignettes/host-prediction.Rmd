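---
title: "Staged ensemble prediction of bacteriophage hosts"
author: "phagehost"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Staged ensemble prediction of bacteriophage hosts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phagehost)
```

## The problem

Phage therapy needs a fast answer to a narrow question: given the
genome of a bacteriophage, which bacterial strain from a reference
collection does it infect? No single signal answers it reliably.
Close relatives of the query phage with known hosts are decisive when
they exist; shared sequence between phage and host genomes
(prophage-like fragments) is decisive when it exists; CRISPR spacers
are near-certain evidence of past infection but are present in only a
minority of host genomes; and alignment-free composition similarity is
always available but noisy. `phagehost` combines all four in a staged
cascade and scores the result at five taxonomic ranks (genus, family,
order, class, phylum): a strain-level call counts as correct at rank
*r* when the predicted and true hosts share the rank-*r* taxon.

## The model

**Reference data.** A `ref_bundle` fixes the problem instance: the
reference phages with known hosts (the training interactions, one host
strain per phage), the *M* reference host genomes, and the host
taxonomy. The host order is pinned at load time and checksummed; every
per-host vector in the package indexes by it, and models refuse
bundles whose order changed.

**Alignment-based predictors.** Three predictors assign the host of a
top alignment hit, each thresholded on the hit's e-value: similarity
to a reference phage (assign that phage's host), similarity to a host
genome directly, and short-query similarity to CRISPR spacers pooled
from the host genomes (assign the spacer's host). Top-hit selection is
a total order — bit score, then e-value, then lexicographic ID — so
predictions are deterministic. Either BLAST+ `blastn` (when on the
PATH) or a built-in exact-seed aligner serves as backend; the built-in
aligner anchors on shared words (11 bp, or 7 bp in short-query mode),
extends ungapped, scores 2 bits per matched base and converts to an
e-value through the Karlin–Altschul form \(E = m\,n\,2^{-S}\). It
searches the given strand only, which is sufficient for its role:
preserving top-hit ordering and threshold semantics on forward-strand
homology.

**Alignment-free classifier.** Each phage genome is represented by its
modified k-mer frequency vector: for every k-mer \(w\),
\[
f_m(w) = f_o(w) - P_w\,\{L-(k-1)\}, \qquad P_w=\prod_{i=1}^{k}p_i ,
\]
where \(f_o\) is the overlapping-window count, \(p_i\) the probability
of the i-th base of \(w\) estimated from the same sequence, and \(L\)
the number of unambiguous bases. The correction removes the length and
composition bias of raw counts; for N-free input the vector sums to
zero exactly, a property the tests exploit. Windows containing N are
skipped and N is excluded from \(L\); no reverse-complement collapsing
is applied (genomes are used as given). The default k = 6 gives 4096
features. A multi-class classifier maps this vector to a probability
simplex over the M hosts; multinomial ridge logistic regression is the
default base model, with seven alternatives (linear SVM, KNN, MLP,
random forest, gradient boosting, Gaussian naive Bayes, decision tree)
behind the same surface. Labels are host strain IDs; rank-level calls
come from aggregating the strain call through the taxonomy afterwards,
not from per-rank models. Hyperparameters are library defaults with a
fixed seed, recorded in the model object; margin classifiers without
native probabilities are calibrated by a softmax over decision values
so every algorithm can feed the hybrid score. Singleton classes (a
host with one training phage — common with strain-level labels) are
duplicated before the ridge fit, which the fit treats as observation
weighting.

**Hybrid score.** The base probabilities are mixed with two similarity
rows,
\[
Pr_o \;=\; (1-\gamma)\,Pr_b \;+\; \gamma\,\bigl[(1-\alpha)\,
\mathrm{SIM}_{PH}(v_q,H) \;+\; \alpha\,\mathrm{SIM}_{HH}(h_s,H)\bigr],
\]
where \(v_q\) is the query, \(H\) the ordered hosts, and \(h_s\) the
*support host*: the host of the training phage most similar to the
query (ties to the smaller phage ID; if the query has no phage-phage
similarity at all, the host-host term contributes a zero vector).
Similarity values are best bit scores per pair, max-normalized per row
so that all three terms live on [0, 1]; raw bit scores grow with
genome length and would swamp the probabilities. The predicted host is
the argmax. The combination is read as a convex mixture because the
weights are searched on [0, 1] and because only then is a fixed
probability threshold on the top score meaningful; an alternative
exponent reading (`form = "exponent"`) is provided for comparison but
is not the default. The defaults \(\alpha = 0.9\), \(\gamma = 0.6\)
are the operating point reported for this family of models;
`grid_search_weights()` re-derives them on any bundle by exhaustive
search on an 11 × 11 grid (step 0.1), scoring leave-one-out genus
accuracy on the training interactions with the query's self-match
excluded from the phage-phage row (otherwise every training phage
trivially supports itself). Ties go to the smaller \(\gamma\), then
the smaller \(\alpha\) — prefer the simpler model when the data cannot
distinguish.

**CRISPR detection.** Host genomes are scanned for arrays in the style
of the CRISPR Recognition Tool: at least 3 near-identical repeats of
19–38 bp separated by spacers of 19–48 bp, nominated by a repeated
8 bp seed word at a compatible period. The chain of repeat copies is
grown by re-seeding from the last copy (so each copy may carry its own
point mutations) and scored by exact-match extension so random word
collisions do not misalign it; boundaries are refined column by column
across copies — a column is accepted when all copies agree, and a run
of at most two disagreeing columns is bridged when a unanimous column
closes it, within a budget of 2 mismatches per copy against the
column-majority consensus. Copies that no exact word reaches are
rescued by consensus matching at a compatible spacing, and extension
and trimming alternate to a fixed point so a spurious trailing copy
cannot cap the repeat length. Arrays never overlap; coordinates are
0-based half-open.

**The cascade.** Stages run strictly in order: phage-phage alignment
(e ≤ 1e-10), phage-host alignment (e ≤ 1e-20), hybrid score (top score
≥ 0.6), CRISPR spacers (e ≤ 1e-2). The first stage passing its
threshold supplies the call; a phage failing all four is reported as
an explicit no-prediction unless `force_call` asks for the hybrid
argmax regardless. The strict-to-permissive ordering means every added
stage can only add calls, so cascade coverage dominates each stage
alone. Two derived modes reuse the machinery: interaction mode
predicts the query phage's host and then asks whether the query
bacterium is (or aligns at e ≤ 1e-10 to) that host; phage-for-host
mode aligns a bacterium against the reference hosts and returns the
training phage of the top hit.

**Evaluation.** Per rank: accuracy = 100·correct/total, coverage =
100·called/total, and the probability of correct prediction PCP =
100·correct/called. No-predictions count against accuracy but not
against PCP; with zero calls PCP is undefined and reported as NA. The
identity accuracy = PCP × coverage / 100 holds row by row, and
accuracy is monotone from genus up to phylum since coarser ranks only
merge correct calls. An unknown taxon name (token `"NA"`) never
matches, not even itself — unknown-vs-unknown agreement is no evidence
of a correct call. Reports print percentages to one decimal; full
precision is retained internally. `threshold_sweep()` re-thresholds
one predictor over a descending e-value list from a single permissive
search, so its coverage column is monotone by construction.

## The synthetic benchmark

`simulate_bundle()` generates complete, deterministic benchmark
instances so that every stage is testable offline. What it emulates,
and how:

* **Taxonomy** — a nested hierarchy: configurable phyla, genera per
  phylum and hosts per genus; families group genera in pairs within a
  phylum, order and class follow the phylum. Defaults: 3 × 2 × 3 = 18
  hosts.
* **Composition signal** — each genus draws a first-order Markov
  transition matrix (rows Dirichlet-distributed), and host and phage
  backgrounds are generated from their genus's chain. A genus-specific
  *marginal* composition alone would be invisible to the classifier,
  because the modified-frequency transform subtracts exactly the
  independent-base expectation; the transition structure is what
  leaves a learnable residue in \(f_m\).
* **Phage-host homology** — each training phage carries an 800 bp
  fragment copied verbatim from its host at a random position (the
  prophage-like signal for the phage-host stage and the similarity
  rows).
* **Test phages** — 40 of the 60 training phages are re-emitted with
  independent per-base substitutions at rate 0.05 (the divergence
  signal for the phage-phage stage). `mutate_sequence(rate = 1)`
  changes every base; `rate = 0` is the identity.
* **CRISPR arrays** — half the hosts receive an R–S1–R–S2–R array
  (28 bp repeat × 3, 32 bp spacers) whose second spacer is a verbatim
  protospacer from the host's own phage. The generator keeps the three
  columns flanking each repeat boundary non-unanimous across copies,
  so the planted boundaries are the unique stopping point of consensus
  extension and detection can be verified against exact coordinates;
  this mirrors how real repeat boundaries are defined by flanking
  divergence, and without it a coordinate-exact check would be
  ill-posed.
* **Truth log** — every planted coordinate (fragments, parentage and
  substitution counts, arrays, protospacer provenance) is recorded for
  verification.

The default sizes (18 hosts of 20 kb, 60 + 40 phages of 5 kb) keep a
full fit-predict-evaluate cycle under a minute on one CPU while
leaving each planted signal unambiguous.

What passing the benchmark does **not** show: real phage-host pairs
differ by mosaic rearrangements, horizontal transfer across genera,
uneven taxon sampling, and CRISPR arrays with cas-gene context and
degenerate terminal repeats — none of which the generator models. The
benchmark validates the machinery (signal recovery, thresholds,
ordering, scoring), not field accuracy on natural genomes. Likewise,
the mutation-tolerance fixtures for array detection place point
mutations in repeat interiors at separated columns with a surviving
seed word; a detector of this family cannot, even in principle,
nominate a locus in which no word is shared between any two copies.

## Numerical and design choices

* E-values from the internal aligner are floored at 1e-300 (blastn
  prints 0 for overwhelming hits); all alignment thresholds therefore
  operate on strictly positive values.
* Argmax ties in score vectors resolve to the first host in bundle
  order; all other ties (top hits, support hosts, phage-for-host) are
  documented lexicographic tie-breaks, making every prediction path
  deterministic. Two runs with identical inputs and seeds produce
  byte-identical prediction TSVs.
* The grid search evaluates \(\gamma\) ascending in the outer loop and
  \(\alpha\) ascending in the inner loop, keeping the first strict
  improvement — the stated tie-break falls out of the loop order.
* Evaluation of a test set against a bundle whose training hosts do
  not cover a test genus is not meaningful;
  `filter_test_by_training_genera()` implements that restriction and
  is idempotent.
* Model persistence is a binary file plus a JSON manifest carrying the
  algorithm, k, seed and host-order checksum; loading verifies the
  checksum.

## Known limitations

* The internal aligner is ungapped and plus-strand; indel-rich or
  inverted homology requires the external backend (the default
  whenever `blastn` is on the PATH).
* Hybrid scores inherit the coarseness of row max-normalization: a
  query whose best hit is weak still gets a 1.0 somewhere in its
  similarity row. The cascade mitigates this by trying alignment
  stages first and by the 0.6 threshold, and a query with an all-zero
  phage-phage row contributes no host-host term at all, but
  hybrid-stage calls on weak-similarity queries are the least reliable
  of the four stages.
* Archaea-infecting phages receive no special handling; their hosts
  are reference entries like any other.
* The α/γ grid search reuses the base model fitted on the full
  training set when scoring leave-one-out accuracy (only the
  similarity self-match is excluded); with small training sets a fully
  nested refit would be preferable but is disproportionate here.

## A worked session

```{r example, eval = FALSE}
library(phagehost)

sim <- simulate_bundle(sim_config(seed = 42))
fit <- host_ensemble(sim$bundle, algorithm = "lr", k = 6, seed = 1)
pred <- predict_hosts(fit, sim$test_phages)
table(pred$stage)
evaluate_predictions(pred, sim$test, sim$bundle$taxonomy)
```
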