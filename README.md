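# emrimpute

Race and ethnicity imputation from anonymized disease histories with a deep
multilayer perceptron, interpreted through DeepLIFT contribution scores.

## The problem

Anonymized electronic medical record (EMR) datasets routinely lack race and
ethnicity labels, which are strong confounders for disease incidence,
treatment outcomes and access to care. Because clinical histories correlate
with race and ethnicity — through socioeconomic structure, differential
access to prophylactic care, lifestyle and background genetic variation —
the missing label can be treated as a supervised imputation target: estimate
a posterior distribution over four mutually exclusive classes (Other, White,
Hispanic, Black) from the features that anonymized records do retain: ICD9
diagnosis codes, integer age and quinary gender.

`emrimpute` is for epidemiologists and biostatisticians who need those
posteriors (or a systematic description of which diagnoses carry
race/ethnicity signal) and cannot use census-based Bayesian imputation
because geolocation and surname data are absent.

## The model

Patients are binary-encoded: one column per distinct ICD9 code, one per
observed integer age (`age_k`), one per gender level (`gender_g`), giving a
sparse 0/1 matrix **X** ∈ {0,1}^(n×F). A multilayer perceptron

&nbsp;&nbsp;&nbsp;&nbsp;**h₁** = f(**x**W₁+b₁), **h₂** = f(**h₁**W₂+b₂), **p** = softmax(**h₂**W₃+b₃)

with rectifier activations f(x) = x for x > 0 and f(x) = αx otherwise
(α = 0 gives ReLU; otherwise α is a learned PReLU slope per hidden layer)
is trained by minibatch Adam on categorical cross-entropy, with inverted
dropout on the hidden layers and early stopping with model caching: the
weights from the epoch of minimal validation loss are kept. Hyperparameters
can be chosen by randomized grid search on a validation subsample.

Trained networks are interpreted with **DeepLIFT** (rescale rule). With an
all-zeros input reference — no diseases observed — each class output's
difference-from-reference Δt is decomposed exactly over input features,

&nbsp;&nbsp;&nbsp;&nbsp;Δt = Σᵢ C_{Δxᵢ,Δt}&nbsp;&nbsp;(summation-to-delta),

and the per-feature scores, summed over all test samples of every
cross-validation fold, yield a descending **class ordering** per feature —
e.g. a score vector (Other −500, White −100, Hispanic +200, Black +500)
orders Black > Hispanic > White > Other, reading "this diagnosis predicts
for Black and against Other".

Since real multi-million-patient EMR extracts are private, the package
ships a synthetic-EMR generator with known class-conditional structure
(planted marker features, background features, optional feature-pair
interactions invisible to linear models) plus an exact enumeration of the
Bayes-optimal accuracy, so every claim the package makes is testable.

## Worked example

```r
library(emrimpute)

spec   <- cohort_spec(n_patients = 6000, seed = 11)   # 8 planted markers, 100 background features
cohort <- generate_cohort(spec)
summarize_dataset(cohort$records)
#>      class count percent
#> 1    Other  3158    52.6
#> 2    White  1159    19.3
#> 3 Hispanic   957    15.9
#> 4    Black   726    12.1

bayes_optimal_accuracy(spec)   # analytic ceiling: 0.861

ec <- experiment_config(spec, k = 3, master_seed = 2026,
                        config = train_config(max_epochs = 40, patience = 5))
bundle <- run_experiment(ec)
round(bundle$mean_metrics, 3)
#>             accuracy                 loss            precision               recall
#>                0.845                0.461                0.843                0.845
#>                   f1            micro_auc   macro_weighted_auc macro_unweighted_auc
#>                0.843                0.963                0.955                0.954

head(bundle$orderings[, c("feature", "class_1", "class_2", "class_3", "class_4")], 4)
#>   feature class_1 class_2  class_3 class_4
#> 1  250.00   Other   Black Hispanic   White
#> 2   401.9   Other   Black Hispanic   White
#> 3  282.60   White   Black Hispanic   Other
#> 4     042   White Hispanic    Black   Other

marker_recovery(bundle)$rate   # 1: every planted marker ranks its true class first
```

The cross-fold accuracy (0.845) sits just under the enumerated Bayes
ceiling (0.861) — the network has extracted essentially all the signal the
generative model put in — and the aggregate DeepLIFT orderings rank the
true target class first for all eight planted markers (`250.00` and
`401.9` were planted for Other, `282.60`/`042` for White, and so on).

A command-line front end over the same functions lives at
`inst/cli/emrimpute.R` (`synth`, `encode`, `train`, `evaluate`,
`interpret`, `run`, `compare` subcommands).

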