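# mirstart

Prediction of the 5' mature miRNA start position within a pre-miRNA
hairpin.

A pre-miRNA stem-loop of length *L* contains *L − w + 1* candidate start
positions for its ~22 nt mature product, only one of which is correct —
an intrinsically class-imbalanced problem (roughly 1 positive per 60
negatives). `mirstart` implements a rebalanced ensemble classifier for
this task:

* every candidate window is encoded as a **110-dimensional feature
  vector** built around the miRNA:miRNA\* duplex alignment derived from
  the dot-bracket structure (paired-nucleotide types of the 25 duplex
  columns, per-position nucleotide/pairing-state codes of the duplex and
  its flanks, stacking energies of duplex sub-regions, distance to the
  terminal loop, gap counts, first nucleotide, first-column pairing
  state);
* the training set is rebalanced by **k-means undersampling**: negatives
  are clustered into 10 groups and each group contributes its
  centroid-nearest members, one negative per positive;
* up to 10 **RBF-SVM rounds** are combined AdaBoost-style: round *m* is
  fit on the current subset, scored on the full window set under the
  boosting distribution *D<sub>m</sub>*, weighted by
  *α<sub>m</sub> = ½ log((1 − e<sub>m</sub>)/e<sub>m</sub>)*, and the
  next subset grows with the examples it misclassified;
* test candidates are ranked by the **α-weighted sum of calibrated
  per-round probabilities**, and evaluated by position deviation (PD):
  accuracy at PD 0–5 nt, top-k accuracy, and the average PD (APD).

A seeded synthetic stem-loop generator with a planted, feature-expressible
start signature makes the whole pipeline trainable and testable offline.

## Worked example

Simulate 60 hairpins (90/10 train/test split), fit a 3-round ensemble,
and score the held-out hairpins:

```r
library(mirstart)

ds  <- simulate_dataset(60, seed = 42, signal_strength = 0.9)
fit <- mirstart(ds$train, rounds = 3, seed = 42)
fit
#> Boosted SVM mature-start model (boosted)
#>   rounds: 3, window: 22 nt
#>   round log:
#>  round subset_size n_incorrect          e_m  alpha_m C   g
#>      1         108          82 0.0223616035 1.888897 2 0.1
#>      2         190           0 0.0001363512 4.450070 2 0.1
#>      3         190           0 0.0001363512 4.450070 2 0.1

pred <- predict(fit, ds$test, k = 3)
head(pred, 6)
#>   hairpin_id rank start end     score
#> 1  synth0049    1    15  36 10.788165
#> 2  synth0049    2    16  37  5.196652
#> 3  synth0049    3    17  38  1.980484
#> 4  synth0037    1    11  32 10.788212
#> 5  synth0037    2    12  33  1.887509
#> 6  synth0037    3    10  31  1.194880
```

The round log shows the rebalancing at work: round 1 trains on a balanced
subset of 108 windows (54 positives + 54 centroid-nearest negatives) out
of ~3,300, misclassifies 82 windows of the full set (weighted error
0.022, weight α₁ = 1.89), and those 82 join the round-2 subset; by round
2 the ensemble classifies every training window correctly. For each test
hairpin the top-ranked `start` is the predicted 5' mature start
(`end = start + 21`), and the score is the α-weighted probability sum.

```r
truth <- data.frame(id = names(ds$test),
                    mature_start = sapply(ds$test, `[[`, "mature_start"))
eval_report(pred, truth, ks = c(1, 3))
#> Mature-start evaluation over 6 hairpins
#> Cumulative accuracy by position deviation:
#> 0nt 1nt 2nt 3nt 4nt 5nt
#>   1   1   1   1   1   1
#> ...
#> APD: 0 nt
```

Here every held-out start is recovered exactly (accuracy 1.0 at 0 nt
deviation, APD 0): the generator's planted signature — a 5' U and a fully
paired lower duplex — is expressible in the feature set, and the ensemble
finds it.

A command-line wrapper with `simulate` / `train` / `predict` /
`evaluate` subcommands is installed under `inst/cli/mirstart.R`:

```sh
Rscript inst/cli/mirstart.R simulate --out-dir data --n 200 --seed 7
Rscript inst/cli/mirstart.R train --fasta data/train.fa \
    --structures data/train.vienna --mature data/train_mature.tsv \
    --model model.rds --log rounds.tsv --seed 7
```

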