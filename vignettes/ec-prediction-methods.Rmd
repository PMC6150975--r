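---
title: "Hierarchical EC number prediction: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical EC number prediction: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(echier)
```

## The problem

Enzyme Commission (EC) numbers classify enzymatic reactions in a
four-level hierarchy: main class, subclass, sub-subclass and substrate
(e.g. EC 1.1.2.4), with `-` marking unspecified trailing components.
`echier` predicts the EC number of a protein from its amino-acid
sequence alone.  Each EC class gets its own binary model, and a query
descends the hierarchy top-down through the models it clears, ending
with a full or partial EC path, the label `non-enzyme`, or — for
ambiguous scores — `no prediction`.

## The per-class ensemble

Every class model combines three base predictors with complementary
views of the sequence:

1. **Subsequence profile map (SPMap).**  All length-$l$ windows of the
   positive training proteins (default $l = 5$) are clustered online:
   a window joins the best-scoring existing cluster if its ungapped
   BLOSUM62 similarity to the cluster representative,
   $s(x,y)=\sum_{i=1}^{l} M(x_i, y_i)$, reaches the threshold $t = 8$,
   otherwise it founds a new cluster.  Clusters smaller than 10% of the
   positive-set size are discarded; the rest become probabilistic
   profiles $PP_c(i,j) = \ln\frac{\mathrm{count}(i,j) + 0.01}{S_c}$
   with a 0.01 pseudo-count against zero probabilities.  A query's
   feature for profile $c$ is $\exp\big(\max_{ss} \sum_i PP_c(i,
   ss_i)\big)$ — the best window wins — so the feature dimension equals
   the number of retained profiles.  An RBF-kernel SVM is trained on
   these features.
2. **Similarity vote (kNN).**  The query is aligned (Smith–Waterman,
   BLOSUM62, affine gaps open 11 / extend 1) against every training
   protein; among the $k = 5$ highest-scoring neighbours across the
   positive and negative sets combined, the signed vote is
   $O_B = (S_p - S_n)/(S_p + S_n)$, where $S_p$ and $S_n$ sum the
   similarities of positive and negative neighbours.  $O_B$ is $+1$
   when every neighbour is positive and $-1$ when every neighbour is
   negative; it is rescaled to $[0,1]$ as $(O_B+1)/2$ so the three
   predictors share one range.
3. **Physicochemical descriptors.**  A 37-dimensional composition
   summary in the spirit of the EMBOSS peptide-statistics report:
   20 amino-acid mole percentages, 9 residue-class mole percentages
   (tiny, small, aliphatic, aromatic, non-polar, polar, charged, basic,
   acidic), molecular weight, residue count, average residue weight,
   net charge at pH 7, isoelectric point (bisection on the monotone
   Henderson–Hasselbalch charge curve to $|q| < 10^{-4}$), and three
   extinction-coefficient descriptors.  Features are min-max scaled on
   the training set (test values clipped into $[0,1]$; constant
   columns map to 0) and fed to a second RBF SVM.  The original
   tool's exact 37 features are not published; this composition-based
   reconstruction sums to 37 and preserves the method's character.

Each predictor's reliability for the class is measured by stratified
5-fold cross-validated AUROC $R_m$ (rank/Mann–Whitney formulation,
half-credit for ties), and the ensemble score is the weighted mean
with sharp fourth-power weights

$$W(m) = \frac{R_m^4}{\sum_{m'} R_{m'}^4},$$

which concentrates weight on the best-ranked predictor for that class
while keeping all three in play.

## Cutoffs and traversal

A per-class *positive cutoff* is chosen by sweeping a 0.01-step grid
over the held-out validation scores of the weighted ensemble and
keeping the F1-maximizing cutoff (ties resolved toward the largest,
most conservative value; "above" is strict).  A single global
*negative cutoff* of 0.3 applies at the enzyme/non-enzyme gate.
Traversal: at the top level the query is scored by every main-class
model; the best class strictly above its positive cutoff is accepted
and the query descends into its children; if every main-class score is
below 0.3 the query is a non-enzyme; anything in between is `no
prediction`.  At deeper levels the query either descends further or
finalizes with the previously accepted EC number when no child clears
its cutoff (the negative rule is not re-checked below the gate, per
the stated decision rules).  Ties at equal score go to the
lexicographically smallest EC number, for determinism.

## Dataset construction

Annotations are propagated to all ancestors in the EC tree;
multi-functional proteins (more than one distinct EC number) are
discarded; classes with at least 50 members are trainable (50 is the
default of `min_class_size`; the toy tests lower it).  Negative sets
are hierarchy-aware: for class $e$ the candidates are (i) proteins
under siblings of $e$ and their descendants, (ii) proteins under other
EC main classes, and (iii) reliable non-enzymes — proteins with no
enzymatic annotation and an annotation-reliability score of at least
4 stars.  Proteins under $e$ itself are excluded everywhere.
Negatives are drawn balanced to the positive count: at the main-class
level half enzymes from the other main classes and half non-enzymes;
below the main level the split is 1/2 sibling-branch enzymes, 1/4
other-main-class enzymes and 1/4 non-enzymes — the sibling share is
largest because discriminating a class from its siblings is the
hardest sub-problem.  A `wne` flag removes the non-enzyme share (for
ablation), redistributing it to the enzyme partitions.

Redundancy is handled UniRef50-style: greedy longest-first clustering
in which a sequence joins the first cluster whose representative
shares at least 50% identity (matches / alignment length of a global
BLOSUM62 alignment, gap open 10 / extend 1), and whole clusters go to
one side of the 90/10 train/validation split, so no near-duplicate
pair straddles the split.  The split is made once, globally (per main
class plus the non-enzyme pool), and every class dataset intersects it:
a design choice that prevents a protein from serving as a training
negative for one class model and a validation query for another, which
would leak information into the hierarchical evaluation.  By default
only cluster representatives enter the datasets.

## Numerical and degenerate-input choices

* Non-canonical residues (B, Z, J, U, O, `*`) are masked to X under the
  default policy; X-containing windows never enter profiles, and X
  contributes nothing to masses, charges or class percentages (it does
  count toward the residue total).  A `strict` policy errors instead.
* Sequences shorter than $l$ yield an all-zero profile feature vector,
  with a warning.
* The pseudo-count makes a perfectly conserved profile column score
  $\exp(l \ln(1.01)) > 1$; features are clipped to 1 to honour the
  $[0,1]$ contract.
* The SVM margin is mapped to $[0,1]$ by a logistic (Platt-style)
  calibration fitted on the training decision values; perfect
  separation drives the calibrated scores to 0/1, which is accepted.
  Training avoids libsvm's internal probability machinery, whose
  shuffling cannot be seeded from R, so scorers are deterministic.
* The SVM kernel width defaults to $1/(d \cdot \mathrm{var}(X))$ and
  the cost to 1; both are exposed in `ec_config()`.
* Alignment scoring uses integer Gotoh kernels whose scores are tested
  for exact equality against an independent aligner; global-alignment
  identity follows one optimal-score path with a deterministic
  tie-break (diagonal first), so co-optimal paths may differ from
  other implementations in identity, never in score.
* Cluster-vs-window similarity uses the founding representative by
  default (O(#clusters) per pass, deterministic); comparison against
  all members is available via `cluster_comparison = "members"`.
* A degenerate cutoff sweep (best F1 below 0.5, or a cutoff under
  every validation score) and an F1-optimal cutoff at or below the
  negative cutoff are both flagged with warnings; the latter is
  clamped strictly above 0.3.

## What the synthetic benchmark emulates — and what it does not

`generate_benchmark()` builds protein families that share conserved
motifs implanted into random background sequence, organized in a toy
EC hierarchy, plus motif-free non-enzymes: this is exactly the signal
structure all three predictors exploit (conserved active-site and
binding regions).  Defaults: six main-class families of 80 members,
two motifs of length 12 per family, per-residue motif mutation rate
0.05, lengths uniform in 120–400 (long enough for stable composition
statistics and profile windows), uniform background composition, 480
non-enzymes with annotation score 5.  Child families inherit parent
motifs and add their own, keeping deeper levels separable.

Real proteomes differ in ways the generator deliberately ignores:
biased residue composition, indels and domain shuffling, homology
*between* classes, annotation noise, and class imbalance.  Passing the
recovery tests therefore demonstrates that the pipeline's machinery —
dataset construction, featurization, weighting, cutoffs, traversal —
is implemented correctly and can recover a motif-defined signal; it
does not certify performance on natural sequence data.

## Problem sizes used by the test suite

The end-to-end recovery tests train the full pipeline on the default
benchmark (960 proteins) for three generation seeds at mutation rate
0.05 plus one run at rate 0, evaluating level-0 and level-1 F1 on the
held-out 10%; module tests use families of 16–24 members so that each
test file runs in seconds.  These sizes were chosen as the smallest
that exercise every code path with stable statistics.

## Known limitations

* Multi-functional enzymes are out of scope by construction (discarded
  in training; single-label traversal at prediction).
* The kNN predictor's default backend is the internal Smith–Waterman
  scorer; an external search tool can be adapted behind the same
  contract (non-negative scores, monotone in alignment quality) but no
  adapter ships here.
* The 37-descriptor set is a reconstruction (see above), not a copy of
  the original tool's undocumented feature list.
* Positive cutoffs are selected on validation scores; with very small
  validation sets the F1 sweep is coarse and the tie-break toward the
  largest cutoff makes the models conservative.
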