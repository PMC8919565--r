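# famtrio

Per-family ensemble classification of protein sequences, built for the
**twilight zone** — queries that share at most 40% (often under 30%)
sequence identity with any annotated reference, where single-method
homology transfer becomes unreliable.

## What it does

For each family in a catalogue of $N$ families, famtrio trains a trio of
weighted linear SVMs (squared hinge loss, L2 regularization) on
homology-derived features:

* **alignment block** (3 per family, $3N$ total): bit-score,
  $-\log_{10}$ E-value and percent identity of the best local-alignment
  hit against a database of 10 reference sequences per family — the target
  family's triple is a *similarity* feature, every other family's a
  *dissimilarity* feature;
* **profile block** (2 per profile, $2M$ total): bit-score and
  $-\log_{10}$ E-value against $M$ position-specific profiles.

Model 1 sees all $2M+3N$ features, model 2 the target triple plus the
profile block ($2M+3$), model 3 the target triple alone (3). Class
imbalance is tamed by sampling only 10 negatives per non-target family and
weighting each positive 9× a negative. A family is predicted iff at least
two of the three classifiers vote for it:

$$\hat{y} = \mathrm{mode}\{C_1(x),\, C_2(x),\, C_3(x)\},$$

and the score used for ROC analysis is the probability that at least two
of three independent base classifiers fire,

$$\Pr(\text{ensemble}) = p_1p_2p_3 + p_1p_2q_3 + p_1q_2p_3 + q_1p_2p_3,
\qquad q_i = 1-p_i .$$

A sequence can receive several families (`pred_count` > 1), exactly one,
or none — `pred_count = 0` is how members of never-seen families are
rejected. Because real benchmark corpora are large downloads, the package
ships a synthetic family generator (randomized emission profiles +
substitution/indel divergence) whose mixture is tuned so ~12% of members
fall in the twilight zone, plus parsers for BLAST tabular (`-outfmt 6`)
and HMMER `hmmscan --domtblout` output so precomputed searches can replace
the internal scorers.

## Worked example

```r
library(famtrio)

res <- run_benchmark(n_families = 12, members_per_family = 30,
                     n_novel_families = 3, n_profile_models = 3,
                     min_aln_len = 60, seed = 1)

res$accuracy$overall        # 0.925   true family recovered for 111/120
mean(res$family_auc)        # 0.983   mean one-vs-rest AUC over 12 families
mean(res$novel_auc)         # 0.972   members vs novel-family rejection AUC

bins <- res$identity_bins[names(res$accuracy$correct)]
mean(res$accuracy$correct[bins %in% c("(0,30]", "(30,40]")])
# 0.609   accuracy inside the twilight zone (23 of 120 test sequences)
mean(res$accuracy$correct[bins %in% c("(40,70]", "(70,100]")])
# 1.000   accuracy above 40% identity
```

The run simulates 12 families of 30 members under a mixed-divergence
process, holds out one of three stratified folds, builds the 10-per-family
reference database and 3 calibrated profiles, trains 12 trios, and
evaluates the ensemble. The numbers show the expected shape: essentially
perfect assignment above 40% identity to the training set, degraded but
far-above-chance accuracy in the twilight zone, and strong rejection of
the three held-out novel families.

The same pipeline is scriptable from a shell via `inst/bin/famtrio`
(`simulate → featurize → train → predict → evaluate`), each stage reading
and writing plain FASTA/TSV/JSON artifacts.

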