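---
title: "Uncertainty-aware bacteremia risk modelling: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Uncertainty-aware bacteremia risk modelling: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Emergency-department physicians order blood cultures liberally because a
missed bacteremia can be fatal, yet culture yields are low (roughly 7-15%)
and results arrive a day later. A risk model available at the time the
culture decision is made — before laboratory results exist — can support
that decision, but only if the physician can tell *when to trust it*. This
package implements a complete, fully synthetic re-analysis pipeline for
that setting: a Bayesian neural network (BNN) that reports not just a
bacteremia probability but a predictive interval; a taxonomy that labels
each prediction as certain or uncertain, and each physician assessment as
confident or not; and the multi-reader multi-case (MRMC) statistics needed
to ask whether showing the model's output changes physician performance,
and for whom.

Because the hospital data behind this problem are not publicly available,
the package's first-class module is a synthetic cohort generator with a
*known* generative risk. Everything downstream is exercised against data
whose Bayes-optimal behaviour is computable, which is what makes honest
end-to-end testing possible.

# The synthetic cohort

`generate_cohort()` draws structured variables from marginals typical of an
adult urban tertiary-care ED blood-culture population: age 62.3 (SD 15.9)
years, 45.1% female, triage levels concentrated at level 3, vital signs
around SBP 136/DBP 77, HR 100, RR 20, BT 37.4 C, symptom histories of
chills (24.7%), vomiting (10.4%) and abdominal pain (17.1%), and a
bacteremia prevalence of 10.9%. Missingness (default 2%, always below 3%)
is confined to the five vital signs; all other fields are complete.

Each case additionally carries:

* an **infection-site latent class** (respiratory / intra-abdominal /
  other) that drives which tokens appear in the free-text note and adds a
  modest log-odds shift (respiratory sites are *less* likely to be
  bacteremic, which is how "sputum", "cough" and "dyspnea" become
  risk-lowering words without per-token hand-tuning);
* a **note** assembled from a token vocabulary with site- and
  symptom-dependent inclusion probabilities, plus injected punctuation and
  case noise so the text pipeline is genuinely exercised;
* a **generative risk**: a single logistic model over the structured
  variables, the site class, and the tokens present in the note. The
  intercept is root-found on the sampled covariates so the mean risk equals
  the target prevalence to within 1e-6, and the label is a Bernoulli draw
  from that risk.

A single logistic generative model was chosen deliberately: it makes the
Bayes-optimal AUC computable from `true_risk`, giving the model-recovery
tests a hard, known ceiling. With the default effect sizes that ceiling is
about 0.80. The per-variable effects are stipulated, not fitted — no public
per-variable bacteremia effect estimates exist for this variable set — and
were fixed once to place the achievable AUC near that of published
ED bacteremia models while leaving signal in both the structured and the
text block.

What the generator does **not** emulate: realistic clinical language
(notes are bags of tokens with filler words), correlated vital signs,
informative missingness, temporal drift between cohorts, or
site-to-symptom correlations beyond the single latent class. Passing tests
therefore demonstrate correctness of the machinery under a well-specified
risk model, not performance on real clinical text.

# Preprocessing

Continuous variables are mean-imputed (vitals only can be missing) and
standardized to zero mean and unit variance with statistics computed on
training data only; the population-SD convention is used, so a two-point
column `{0, 2}` maps to exactly `{-1, +1}` and an imputed cell maps to
exactly 0. Categorical variables are one-hot encoded over closed level
sets with no reference level dropped (the network has no collinearity
constraint, and grouping one-hot blocks for feature importance is
simpler); an unknown level is an error naming the variable and level.

Notes are lowercased, split on any non-alphanumeric character
(Unicode-aware), filtered against injected stopword lists, and passed
through a pluggable token-wise lemmatizer (identity by default; bilingual
morphology is out of scope and reduces to these two plug-in points).
TF-IDF uses raw term counts times the smoothed inverse document frequency
`ln((1+N)/(1+df)) + 1`, followed by per-document L2 normalization;
vocabulary admission requires a document frequency of at least 1% of
training documents, ties kept. These conventions are stated exactly
because the test suite recomputes them by hand.

# The Bayesian network

The model is a two-branch multilayer perceptron: structured features feed
a 100-node hidden layer, the TF-IDF vector a 15-node hidden layer; the two
are concatenated into a single sigmoid output node. Every weight and bias
carries a fully factorized Gaussian variational posterior with an N(0, 1)
prior, trained by stochastic gradient ascent on the evidence lower bound
(ELBO) using the reparameterization trick — one weight draw per minibatch —
and Adam. The per-example objective is the mean binary cross-entropy plus
`kl_weight * KL(q || prior) / N`. Flipout-style perturbation sharing is a
variance-reduction refinement of the same unbiased estimator; the plain
estimator defines the same model and keeps the implementation exactly
hand-checkable (the ELBO is verified against two-dimensional quadrature in
the tests).

Numerical choices that matter:

* **KL annealing**: linear warm-up over the first 25% of epochs; the
  recorded per-epoch history always reports the objective at the *full*
  KL weight, so the training curve is interpretable and decreases on a
  smoothed basis.
* **Learning-rate decay**: the Adam learning rate (default 0.01) is
  multiplied by 0.2 for the final 30% of epochs. Constant-rate Adam leaves
  the variational state in a wide stationary distribution, which makes
  run-to-run predictive-interval widths noisy; the decay tightens the
  final state without changing what is being estimated.
* **Initialization**: weight means use He-style scaling; variational SDs
  start at softplus(-3) (about 0.05).
* **Two-stage protocol**: with a multi-entry hyperparameter grid the
  development data are split 80/20, candidates are scored by validation
  AUC, and the winner is refit on 100% of the development data with
  preprocessing refitted as well (no leakage of validation statistics into
  the tuning stage).

Prediction draws 25 weight realizations (configurable), passes the case
through each realized network, and summarizes the sigmoid outputs by their
mean (the point prediction), sample SD, and the clipped normal interval
`mean +/- 1.96 * sd`. A percentile interval is a one-line change but the
normal form matches how the interval is defined from the SD here.

**Problem sizes.** The shipped tests train at 1,000 / 5,000 / 15,000
development cases with 8,000 held-out cases, using step-matched budgets
(885 / 177 / 60 epochs, i.e. a constant number of gradient steps).
Step-matching is essential for the posterior-contraction comparison: at a
fixed epoch count the small-cohort run gets 15 times fewer gradient steps
and its variational SDs simply have not equilibrated, so interval widths
would reflect the optimization budget rather than the data.

# Uncertainty taxonomy

A prediction is binarized at a 5% threshold (10% as the secondary
analysis), with the boundary counted positive — only risks strictly below
the threshold are "low risk". A prediction carries **high AI uncertainty**
when the threshold lies inside the closed 95% predictive interval: this
couples the point estimate and its dispersion in a single clinically
interpretable rule (a 50% prediction with a wide interval is still
"certain" about exceeding a 5% threshold). A case carries **high physician
uncertainty** when at least one of its two reviewers scored confidence
below 4 of 5. Both boundary closures are stated explicitly because they
are floating-point-relevant in tests.

# Evaluation machinery

AUCs use the Mann-Whitney statistic with half credit for ties, computed in
rank-sum form so small-sample values agree bit-for-bit with brute-force
pair counting. Variance and confidence intervals come from DeLong's
structural components. Proportions (sensitivity, specificity, PPV, NPV,
calibration bins) use Wilson score intervals — the AUC method does not
apply to proportions, and Wilson behaves well at the prevalences involved;
zero-denominator metrics are flagged rather than raised. Calibration uses
ten equal-width bins with empty bins omitted. Global feature importance is
permutation-sampling Shapley attribution with one-hot blocks grouped per
variable and each vocabulary token its own group; the Monte-Carlo
prediction inside the value function runs at a fixed seed so Shapley noise
is decoupled from posterior noise.

# The reader study

Simulated readers implement a noisy-gestalt / anchor-and-adjust model.
Reader r's pre-AI impression of case i is, on the log-odds scale,
`logit(true_risk) + u_i + b_r + e_ri`, where `u_i` is a per-case
"difficulty" component shared by the two reviewers of the case, `b_r` a
per-reader bias, and `e_ri` individual noise. The impression is binned on
the ordinal scale [0,5%), [5,10%), [10,20%), [20,50%), [50,100%], and a
Likert confidence is derived from the magnitude of the evidence. The
post-AI probability is a convex combination of the reader's probability
and the AI point estimate with a weight that increases when the reader is
unsure and when the AI is certain (the CI-enclosure class); this is the
simplest mechanism consistent with how readers revise toward a trusted
advisor.

The shared case component deserves a note: without it, two readers agree
only through the generative risk and their chance-corrected agreement is
far below what human readers show at the same AUC. The default parameters
(individual noise SD 2.0, shared case SD 1.0, reader bias SD 0.4,
confidence cuts 0.9/1.8/2.6/3.4, adoption weights scaled by 0.75 when the
AI is certain and 0.25 when not) were calibrated once so the simulator
reproduces the reported human operating point — pre-AI reader AUC in the
mid-0.60s improving by roughly 0.05 after AI exposure, linearly weighted
kappa around 0.3 pre-AI, and roughly four of five case reviews carrying
high physician uncertainty — and then frozen.

The pre- vs post-AI comparison uses the Obuchowski-Rockette ANOVA on the
reader-by-modality AUC matrix with case-jackknife error covariances and
the Hillis denominator degrees of freedom,
`F = MS(T) / (MS(T*R) + r * max(Cov2 - Cov3, 0))`. The study allocation is
split-plot — ten disjoint 100-case sets, two readers each — so jackknife
covariances are computed only for reader pairs sharing a set, set to zero
across disjoint sets, and averaged over all pairs. For two modalities this
convention makes the crossed-design denominator exactly unbiased for the
numerator's expectation under the null (the expectation algebra is in the
test suite's null simulation, which checks the empirical type-I error at
the 5% level). Random-reader random-case inference was chosen because the
Hillis denominator degrees of freedom *are* the random-reader form and the
reference implementations of this method default to it; fixed-reader
inference would additionally require the reader-by-modality interaction to
vanish. Ordinal bins enter ROC analysis as raw scores 1-5; AUC is
rank-invariant, so any monotone relabelling gives identical results.
Degenerate designs fail loudly: a single reader, a missing phase, a reader
subset without both label classes, or a set too small to jackknife all
raise rather than return approximations; subgroup analyses convert those
errors to warnings and skip the subgroup.

# Known limitations

* Mean-field variational posteriors understate weight correlations; the
  predictive intervals are approximate and their absolute width should not
  be over-interpreted. The taxonomy consumes them only through the
  CI-enclosure rule.
* The Monte-Carlo mean of a sigmoid is slightly inflated toward 0.5
  relative to the plug-in prediction; with wide posteriors this produces a
  small systematic over-prediction in the lowest risk bins, visible at
  large test sizes. Decile calibration slope stays near 1.
* Simulated readers respond to the AI point estimate and interval only;
  the explanation display a real deployment would show is not modelled,
  so the simulator cannot distinguish trust changes due to explanations
  from those due to uncertainty disclosure.
* All claims are conditional on the generator's assumptions; in
  particular, tokens act through presence/absence while the model consumes
  TF-IDF weights, a deliberate mild mismatch that keeps the recovery task
  non-trivial.
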