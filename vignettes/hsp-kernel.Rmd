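---
title: "The hash subgraph pairwise kernel: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The hash subgraph pairwise kernel: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hspkernel)
```

## The task and the model

Drug–drug interaction (DDI) extraction is cast as binary classification of
candidate entity pairs: given a sentence, a dependency parse, and two
annotated drug mentions, decide whether the sentence asserts an interaction
between them. The classifier never sees the drug names — the candidate
mentions are blinded to `DRUG1`/`DRUG2` and every other drug mention in the
sentence to `DRUG` — so all discriminative information lives in the
sentence's structure.

A sentence is represented as a directed vertex-labeled graph with two
disconnected components:

* the **dependency component**: one node per token labeled
  `form/pos` (lowercased), plus one node per dependency relation labeled by
  the relation string, wired governor → relation → dependent. Materializing
  relations as nodes keeps the graph vertex-labeled (no edge labels) while
  the relation vocabulary stays visible to the kernel;
* the **linear component**: the same token nodes chained left to right,
  capturing surface word order.

The hash subgraph pairwise (HSP) kernel compares two such graphs through
three ingredients.

**Hierarchical neighborhood hash labels.** Every distinct label string gets
a unique D-bit code (D = 24 by default) from a persistent vocabulary. The
hash update

$$h_{k+1}(v) \;=\; \mathrm{ROT}_{o_c}\!\big(h_k(v)\big)
 \;\oplus\; \bigoplus_{u \to v} \mathrm{ROT}_{o_i}\!\big(h_k(u)\big)
 \;\oplus\; \bigoplus_{v \to u} \mathrm{ROT}_{o_o}\!\big(h_k(u)\big)$$

(cyclic bit rotation, bitwise XOR; distinct offsets $o_c, o_i, o_o$ for the
node itself, in-neighbors and out-neighbors, so direction matters) gives a
level-k label that summarizes the labeled neighborhood of radius k. Two
nodes with isomorphic, identically labeled radius-k neighborhoods receive
the same level-k value, and the whole labeling costs a constant number of
word operations per edge and level.

**Walk-weighted subgraph pairs.** With the (symmetrized) adjacency matrix
$A$ and decay $\gamma$, the Neumann series
$W = (I - \gamma A)^{-1} = \sum_{n \ge 0} \gamma^n A^n$ accumulates the
weight of all walks between every node pair, discounted geometrically in
length; it exists exactly when $\rho(\gamma A) < 1$ and costs one matrix
inversion. The level-k feature map sends a graph to the sparse vector
indexed by ordered label pairs,
$\phi_k(g)[a,b] = \sum_{\ell_k(i)=a,\,\ell_k(j)=b} W_{ij}$:
each entry measures how strongly two radius-k subgraphs co-occur, weighted
by their proximity in the graph. Diagonal self-pairs (the $n = 0$ identity
term of the series) contribute plain bag-of-subgraphs mass.

**The kernel.** Levels are combined with a second decay,
$K(g_1, g_2) = \sum_{k=0}^{R} \beta^k \langle \phi_k(g_1), \phi_k(g_2)\rangle$,
optionally cosine-normalized. The result is an inner product in an explicit
feature space, hence positive semidefinite, and is consumed by a
maximum-margin classifier through its precomputed Gram matrix.

**Pruning.** Whole-sentence structure is noisy for pair classification, so
before kernel computation the graph is restricted to the candidate pair's
neighborhood: in the dependency component, the tokens on the shortest path
between the candidates, tokens one relation hop away, and the relations
among kept tokens; in the linear component, the candidates, everything
between them, and one token on each side. Unrelated clauses (e.g. a leading
"however, …" clause) disappear from both components.

## Parameters

| parameter | default | meaning and rationale |
|---|---|---|
| `D` | 24 bits | hash-label width; the vocabulary must stay below $2^D$, and at desk scale ($\le 10^3$ labels) level-0 codes are collision-free by construction. Capped at 31 by R's integer arithmetic. |
| `R` | 2 | hierarchy bound: levels 0..R. Larger R matches ever larger subgraphs and over-fits quickly; 2 keeps features at radius ≤ 2. |
| `beta` | 0.6 | per-level decay $\beta^k$; balances small against large subgraph pairs. Values up to 2 are meaningful (large subgraph pairs emphasized); 0.6 is the operating point used throughout. |
| `gamma` | 0.25 | walk decay $\gamma^n$. Must satisfy $\gamma\,\rho(A) < 1$ per graph — checked, with a classed error on divergence. Pruned sentence graphs have small spectral radius (chains and shallow trees, $\rho \lesssim 3$), so 0.25 leaves a comfortable margin; dense random graphs need a smaller value. |
| `w` | 1.0 | uniform edge weight: all edges carry the same weight. |
| `rot_center, rot_in, rot_out` | 1, 2, 3 | rotation offsets; only pairwise distinctness matters (that is what separates edge directions), the specific values are a reproducibility convention. |
| `normalize` | TRUE | cosine normalization, removing sentence-length effects. |
| `symmetrize_walks` | TRUE | walks run over the undirected skeleton. On directed dependency trees most node pairs are mutually unreachable, which would empty the pairwise feature space; direction information is preserved by the hash labels instead. |
| `tag_components` | TRUE | dependency-side and linear-side features live in disjoint index sets; subgraph pairs never straddle components. |
| `include_identity_walks` | TRUE | keep the $n = 0$ term of the walk series (bag features on the diagonal). |
| `C` | 1.0 | SVM box constraint for the precomputed-kernel solver. |

Vocabulary codes are assigned sequentially from 1 in first-seen order (0 is
reserved as null, $2^D - 1$ as the unknown-label code after freezing a
training vocabulary): sequential assignment guarantees uniqueness and
reproducibility where random codes would only give them with high
probability.

## Numerical and degenerate-input choices

* **Divergence.** `walk_matrix()` computes $\rho(\gamma A)$ explicitly and
  raises a classed numerical error (CLI exit code 3) when it is ≥ 1, rather
  than returning a misleading inverse.
* **Shortest-path ties.** Among equal-length dependency paths the one with
  the lexicographically smallest node-id sequence is used; node ids are
  assigned in construction order, so the choice is deterministic.
* **Disconnected candidates.** If the parse leaves the candidates in
  different weakly connected dependency components, the dependency
  component is kept unpruned (fallback, flagged in the pruning provenance)
  instead of dropping the instance.
* **Dangling relations.** A relation node with exactly one kept endpoint is
  dropped during pruning; keeping it would violate the one-in/one-out
  relation-node invariant.
* **Multi-token mentions** collapse to the span's dependency head (the span
  token whose head lies outside the span; first token if unresolvable);
  external dependencies re-attach to the collapsed node, internal ones
  vanish. Spans that cross token boundaries are aligned by maximal overlap
  with a recorded warning.
* **Zero-denominator metrics** (precision with no positive predictions,
  MCC with an empty margin) are reported as 0; AUC uses the rank statistic
  with ties counted one half, over raw decision values.
* **Degenerate settings** are exact: $\gamma = 0$, $R = 0$, $\beta = 1$
  reduces the kernel to the bag-of-labels product
  $\sum_a n_a(g_1)\, n_a(g_2)$, which the tests pin down.

## Open design points and how they were resolved

* The hash update's treatment of the center label is not fixed by the
  method's lineage; we rotate it by `rot_center`, with offset 0 allowed to
  disable the rotation.
* "Direct neighbor tokens" in the pruning rule is read as *neighbors of any
  shortest-path token* (default); a stricter candidates-only reading is
  available via `neighbor_scope = "candidates"`.
* Whether the two candidate token nodes in the dependency and linear
  components share identity is unspecified; they are distinct nodes (the
  block structure forbids cross-component edges).
* The level weights of the walk series include $n = 0$; `--exclude-identity-walks`
  (or `include_identity_walks = FALSE`) removes the identity term.
* Cross-validation folds are split at **document** level so sentences of one
  document never appear on both sides of a split; pooled (micro) metrics are
  reported alongside macro-averaged F and per-fold standard deviations.
* No SVM implementation with a precomputed-kernel interface is available in
  the target environment, so the package carries its own sequential-minimal-
  optimization dual solver with deterministic maximal-violating-pair
  selection. Its KKT conditions are verified in the test suite; the decision
  function follows the standard contract
  $f(x) = \sum_j \alpha_j y_j K(x, j) + b$.

## What the synthetic corpus does and does not establish

`toy_corpus()` emulates the structure of a DDI corpus: documents of five
sentences, sentences with ≥ 2 drug mentions and exhaustively enumerated
candidate pairs, inclusive-offset XML entities, and CoNLL-style parses. The
planted signal is syntactic, not lexical: in positive frames an interaction
trigger verb *governs the candidate pair on its dependency path*; negative
frames express co-administration or explicit non-interaction, and one
three-entity frame places the trigger on the path of a *negative* pair
without governing it, so co-occurrence with a trigger verb is not
sufficient. Two frames carry a distractor leading clause that pruning must
remove, and two frames use a multi-token mention ("vitamin k") to exercise
span collapse.

```{r, eval = FALSE}
tc <- toy_corpus(seed = 7, n = 200, positive_rate = 0.3, dir = tempdir())
instances <- make_instances(read_ddi_corpus(tc$xml),
                            read_conll_parses(tc$conll))
cfg <- kernel_config()
built <- instances_to_graphs(instances, cfg, prune = TRUE)
vocab <- label_vocab(cfg$D)
K <- gram_matrix(built$graphs, vocab, cfg)
cross_validate(K, built$meta$label, built$meta$doc_id, k = 10, seed = 7)
```

A green end-to-end test (cross-validated F ≥ 0.90 on this corpus; the suite
observes perfect recovery, F = AUC = 1.0) establishes that the pipeline —
blinding, graph construction, pruning, hashing, walk weighting, kernel,
solver, document-level evaluation — transmits a purely syntactic signal
without leaking labels. It does **not** establish performance on real
corpora: the generator has a ~10-frame grammar, a 12-name lexicon, perfect
parses and a noiseless label function, none of which hold for real
biomedical text, where the same method is reported in the
low-60s F range. Published headline numbers on the 2011 DDI challenge
corpus require that external corpus and its parses and are out of scope
here; the evaluator is instead pinned to the published worked example
(TP = 508, FP = 297, FN = 248, TN = 5973 → P = 63.1, R = 67.2, F = 65.1,
Acc = 92.2, MCC = 60.8, in percent).

## Known limitations

* `D` ≤ 31 (32-bit integer arithmetic); the default 24 is unaffected.
* Hash collisions above level 0 are monitored only by the width of `D`
  (sparseness), not resolved — the classical trade-off of neighborhood
  hashing.
* The Gram matrix is dense and quadratic in the number of instances;
  corpora here are desk-scale, and no landmark/approximate path is
  provided.
* Tokenization is taken from the parse file verbatim; there is no parser
  integration.
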