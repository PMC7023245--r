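# ddgsampler

Prediction of protein stability changes (ddG, kcal/mol) caused by single
and double amino-acid substitutions, for structural bioinformaticians who
need both a point estimate and an honest uncertainty statement per mutant.

## The method

The package assumes that every substitution type *m* (an ordered
wild-type/mutant residue pair such as A>S; 380 exist) carries its own
distribution of energy changes, independent of protein and position. Two
stages turn that landscape into predictions:

**1. Holdout random sampler.** The dataset is divided into 100 random
75/25 train/test bags. Per bag, the empirical CDF of observed ddG is
learned for every substitution type with enough observations, each test
mutant's energy change `E_MC,k` is sampled from its type's CDF by
Monte-Carlo (doubles sum independent draws from both types), and a
residual distribution `Omega_k` with damping weight `k_omega` is fitted so
that

    E_real,k  ≈  E_MC,k + k_omega · Omega_k

Each bag is scored by the sign accuracy of its corrected medians,

    S_k = median(E_pred,k) / |median(E_pred,k)| ∈ {-1, +1},
    Acc = (1/n) · Σ [S_k,pred = S_k,obs]

and bags with `Acc ≥ 0.99 · max(Acc)` form an ensemble that predicts a
corrected energy-change CDF `E_pred,k = E_MC,k + mean(k_omega) · Omega` for
every record.

**2. Neural regression.** The 100-quantile discretization of each
predicted CDF, plus mutation-type and protein codes, feeds a one-hidden-
layer network (10 ReLU neurons, linear output) trained by
Levenberg-Marquardt with early stopping; 100 repeats of a random 70/15/15
train/test/blind-validation split yield distributions of Pearson r, RMSE
and sign accuracy.

A synthetic ProTherm-like data generator with known ground truth
(per-type Gaussian effects, protein offsets, epistasis and measurement
noise) makes the whole pipeline testable offline. See the methods
vignette (`vignettes/holdout-sampler-methods.Rmd`) for assumptions,
parameter meanings and limitations.

## Worked example

```r
library(ddgsampler)

cfg <- synthetic_config(n_substitution_types = 12, n_single_records = 200,
                        seed = 42)
gen <- generate_dataset(cfg)
gen$dataset
#> <ddg_dataset> 200 records (single)
#> provenance: synthetic(seed=42)
head(gen$dataset$records, 3)
#>   record_id protein_id mutation        ddg
#> 1    R00001       P004    E197V -0.9655323
#> 2    R00002       P002    E215V -1.8490647
#> 3    R00003       P005    D130N  2.7527715

res <- run_sampler(gen$dataset, n_bags = 50, n_mc = 500, seed = 42)
res
#> <sampler_result> 50/50 usable holdouts, 37 selected, 200 records
#> predicted, 0 uncovered

med <- sampler_medians(res)   # per-record point prediction (kcal/mol)
obs <- gen$dataset$records$ddg
sprintf("sampler median: Pearson %.3f, RMSE %.3f, sign accuracy %.3f",
        pearson_cor(med, obs), rmse(med, obs), holdout_accuracy(med, obs))
#> "sampler median: Pearson 0.933, RMSE 0.578, sign accuracy 0.995"

reports <- repeated_split_experiment(gen$dataset$records, res$predictions,
                                     n_repeats = 10, seed = 42,
                                     baseline = med)
aggregate_reports(reports)
#> <aggregate_summary> 10 repeats | Pearson 0.9376 (sd 0.0140) |
#> RMSE 0.5638 | sign accuracy 0.9933
```

The sampler's 50 bags all pass the usability check, 37 survive the
0.99-of-best selection, and every record's substitution types are covered.
The median of each corrected predictive CDF already classifies the sign of
199/200 mutations correctly in this synthetic world; the repeated-split
network experiment reports blind-validation Pearson ≈ 0.94 with RMSE ≈
0.56 kcal/mol against a generator noise floor of ≈ 0.5 kcal/mol.

## Command line

Every stage is reachable through one entry point (exit status 0 = ok,
2 = validation error):

```sh
Rscript -e 'quit(status = ddgsampler::ddg_cli())' \
  run-all --seed 7 --out-dir out --bags 100 --n-mc 1000 --repeats 100
```

Subcommands `simulate`, `sample`, `train`, `evaluate`, `predict` and
`tune` chain through files (`dataset.tsv`, `quantiles.tsv`, `model.json`,
`reports.tsv`, ...); `--config config.json` overrides any default in
`default_config()`, and every run writes a `manifest.json` with the seed
and config echo. Runs with the same seed are byte-identical.

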