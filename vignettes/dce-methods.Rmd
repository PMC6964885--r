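---
title: "Methods: preference estimation and treatment ranking for a discrete-choice experiment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: preference estimation and treatment ranking for a discrete-choice experiment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcepref)
```

## The problem

`dcepref` implements the full analysis pipeline of a discrete-choice
experiment (DCE) in health preference research, shaped around a concrete
application: preferences of patients with Crohn's disease over maintenance
therapies. Respondents repeatedly choose one of three hypothetical
treatments, each described by six attributes — chance of maintaining
remission for a year, chance of withdrawal due to adverse events (WDAE),
dosing regimen, need for a course of prednisone, possible low blood counts or
liver reaction, and a small risk of serious infection / possible cancer risk.
From roughly 2,000 observed choices (155 respondents times 13 tasks) the
pipeline estimates individual-level part-worth utilities, summarises them in
interpretable units, explores preference heterogeneity, audits response
quality, and finally fuses the estimated preferences with treatment outcome
distributions from a network meta-analysis (NMA) to rank real treatments by
preference-weighted benefit-risk.

Because no respondent-level data ship with the package, a first-class
synthetic-data module generates cohorts with *known* preference structure;
every downstream claim the package makes is tested against that ground truth.

## Utility model and coding

Alternative $j$ in a task has utility $U_j = x_j^\top \beta + \varepsilon_j$
with extreme-value errors, giving the multinomial logit (MNL) choice rule
$P(j) = \exp(x_j^\top\beta) / \sum_k \exp(x_k^\top\beta)$. The covariate
vector $x_j$ is produced by `coding_map()`:

* the two outcome attributes (remission, WDAE) enter **linearly**, one column
  each, as `level - center` with centers 50 and 15.5, so their coefficients
  are utilities **per percentage point**;
* the 6-level dosing attribute gets 5 **effects-coded** columns (the last
  level is $-1$ on all of them), so level utilities sum to zero within the
  attribute;
* the three Yes/No risk attributes get one effects column each
  ($+1$ = Yes, $-1$ = No).

This yields $p = 10$ part-worth columns. Centering the linear attributes at
mid-range makes the remission slope directly usable as the denominator of
marginal rates of substitution.

## Choice-design generation

`generate_design()` approximates a *balanced overlap* fractional-factorial
design: within each survey version every attribute's levels are dealt from a
balanced multiset (level counts within one of each other by construction),
and a count-preserving swap search then steers the fraction of tasks in which
two or more alternatives share a level toward `overlap_target`. Deliberate
overlap trades some statistical efficiency for simpler tasks. Two numerical
facts matter:

* attributes with fewer levels than alternatives (the three binary risks in a
  3-alternative design) overlap in **every** task by pigeonhole, so with the
  default schema the global overlap rate cannot fall below 0.5; the default
  target 0.7 sits between that floor and the ~0.83 of a purely random design;
* tasks whose alternatives coincide on *all* attributes are repaired by
  count-preserving swaps; accidentally dominated alternatives in main tasks
  are allowed but counted in the audit (forbidding them would bias level
  balance).

`audit_design()` recomputes balance, overlap, duplicates and accidental
dominance by exhaustive scan, and the test-suite cross-checks it with an
independent recount. Warm-up tasks (`make_warmups()`) embed exactly one
alternative that is weakly worse than another on every ordered attribute and
strictly worse on at least one; unordered attributes are held equal across
that pair so "dominated" is unambiguous. Warm-ups never enter estimation.

## The synthetic cohort

`default_population_spec()` encodes the qualitative structure the pipeline is
designed to detect: a 55% benefit-driven class whose utility is dominated by
the remission slope, and a 45% risk-averse class with strong aversions to
prednisone and to the infection/cancer risk. The magnitudes are package
choices on the per-percentage-point scale, chosen so that the implied scaled
utilities and importance ranking are qualitatively realistic (remission
dominant, WDAE second); they are deliberately *not* presented as estimates of
any real cohort. Pathological respondents can be injected: straight-liners
(fixed screen position) and attribute-dominant respondents (always pick the
best available level of one attribute, ties broken uniformly from the same
RNG stream). What the generator does **not** emulate: learning and fatigue
over tasks, response times, covariate-dependent preferences, or attribute
non-attendance. Passing recovery tests therefore demonstrates correctness of
the estimation machinery under the model's own assumptions, not robustness to
real-world response behaviour.

## Hierarchical Bayes estimation

`fit_hb()` estimates the hierarchical model
$$\beta_i \sim N(\mu, \Sigma), \qquad y_{it} \mid \beta_i \sim \mathrm{MNL},$$
by Metropolis-within-Gibbs: a per-respondent random-walk Metropolis step on
$\beta_i$, then conjugate Gibbs draws of $\mu$ (normal) and $\Sigma$
(inverse-Wishart). Priors are $\mu \sim N(0, 100\,I)$ and
$\Sigma \sim IW(p+3,\; 0.01\,I)$.

Three numerical choices deserve explanation:

* **Inverse-Wishart scale.** The IW scale matrix enters the posterior as
  additive prior scatter. On the per-percentage-point coding, realistic
  part-worth variances are of order $10^{-4}$ to $10^{-1}$; an identity scale
  would contribute more pseudo-scatter than the entire cohort's data,
  inflating $\Sigma$, under-shrinking the individual $\beta_i$ (whose
  few-task logit MLEs are biased away from zero) and thereby inflating
  $\mu$. The default $0.01\,I$ keeps the prior proper but small relative to
  even a few dozen respondents; recovery simulations in the test suite
  confirm the population mean is then recovered without systematic scale
  inflation.
* **Proposal shaping.** Proposals are $N(0, s_i^2 V)$ with
  $V = (\bar H + \Sigma^{-1})^{-1}$, where $\bar H$ is the average
  per-respondent Fisher information at the pooled MNL estimate — the
  approximate conditional posterior covariance of a $\beta_i$. A spherical
  or $\Sigma$-shaped proposal forces likelihood-dominated directions
  (remission) and prior-dominated directions (dosing contrasts) to share one
  step size and mixes the latter an order of magnitude more slowly. The
  scalar $s_i$ adapts during burn-in toward the classic 23% random-walk
  acceptance target.
* **Translation move.** When heterogeneity is small, $\mu$ and all
  $\beta_i$ are strongly coupled (the hierarchical "funnel") and
  per-respondent updates move the population location very slowly. Each
  iteration therefore also proposes a joint shift $\delta$ of $\mu$ *and*
  every $\beta_i$, shaped by the pooled information $(n\bar H)^{-1}$ and
  accepted by Metropolis against the pooled likelihood. Chains warm-start at
  the pooled MNL estimate plus chain-specific jitter.

The documented full-scale profile is 3 chains of 350,000 monitoring
iterations after 150,000 burn-in (draws thinned to 1,000 stored per chain);
the test suite and the acceptance script use desk-scale profiles (3 chains,
5,000 monitored after 2,500 burn-in for the recovery study; 2,000 after
1,000 for the cohort run), which the convergence diagnostic itself validates.

**Convergence** is assessed by the multi-chain potential scale reduction
factor: $W$ the mean within-chain variance, $B/n$ the variance of chain
means, $\hat R = \sqrt{\big(\tfrac{n-1}{n}W + B/n\big)/W}$, floored at 1
(with no between-chain spread the unbiased numerator slightly underestimates
$W$; values below 1 are estimator noise). The threshold is the conventional
1.10. `gelman_rubin()` monitors $\mu$ and the diagonal of $\Sigma$;
parameters with zero within-chain variance are flagged degenerate rather
than given an undefined ratio. Chain-splitting is available behind
`split = TRUE` but off by default, matching the era of the cited diagnostic.

### Recovery-study design

The parameter-recovery simulation (150 respondents, 13 tasks, the full
schema) uses a population mean with clearly nonzero entries in **all ten**
columns, e.g. dosing contrasts of magnitude 0.15–0.30. This is a power
consideration, not a claim about real cohorts: with 13 tasks the posterior
standard error of a dosing contrast is ~0.07, so a truth vector whose dosing
entries are near zero measures noise, not recovery. With the chosen truth the
posterior median of $\mu$ correlates with the truth above 0.97 and all
$\hat R$ fall below 1.2 at the desk-scale profile.

## Reporting scales

* **Scaled utilities** (`scale_utilities()`): per posterior draw of $\mu$,
  zero-centred level utilities for every attribute are rescaled so the
  largest absolute level utility in that draw equals 10; medians and
  equal-tailed 95% credible intervals are then taken across draws. Scaling
  per draw (rather than scaling the posterior medians once) keeps the
  reported extreme at exactly ±10 whenever one level dominates the
  posterior, and being a positive monotone transform it preserves the level
  ordering within every attribute.
* **Relative importance** (`relative_importance()`): per draw, an
  attribute's importance is its level-utility range, normalised to sum to
  100 across attributes. Point estimates are means across draws — means,
  not medians, so the reported column itself sums to exactly 100.
* **Marginal rate of substitution** (`mrs()`): the remission increase (in
  percentage points) that offsets an undesirable level, computed per draw as
  (utility of avoiding the level − utility of having it) / remission slope;
  for an effects-coded binary this is $2|\beta|/\beta_{\text{rem}}$. The
  ratio is summarised by median and equal-tailed 95% CrI. Draws with a
  non-positive remission slope make the ratio unstable; their share is
  reported and a warning attaches above 1%. All three summaries are
  computed on population-mean draws (the cohort-level quantities); this is a
  committed choice where per-respondent pooling would also have been
  defensible.

## Latent-class analysis

`fit_lc()` fits a finite mixture of within-class homogeneous MNL models over
respondents by EM: responsibilities $r_{ik} \propto \pi_k \prod_t
P_{\mathrm{MNL}}(y_{it} \mid \beta_k)$, then $\pi_k = \bar r_{\cdot k}$ and
$\beta_k$ by responsibility-weighted MNL maximum likelihood (BFGS with
analytic gradients, warm-started). Multi-start (default 20) guards against
local optima; a class collapsing below $1/(10N)$ is reinitialised from a
perturbed copy of the largest class. Model comparison uses
$\mathrm{BIC} = -2\,\mathrm{LL} + q \ln N$ with $q = Kp + (K-1)$ and $N$ the
number of **respondents** — the mixture is over respondents, not choice
observations. Respondents are assigned to their maximum-probability class
(ties to the lowest index, flagged), and the share with maximum probability
below 0.90 is reported as an assignment-certainty summary. Respondent
covariates are not used in class membership.

## Internal-validity audits

* **Dominated warm-ups**: a respondent fails if they chose the dominated
  alternative in at least one warm-up; missing answers are "not assessable".
* **Straight-lining**: position counts per respondent; flagged when one
  position exceeds 9/13 of tasks (configurable). The false-positive rate of
  this rule under uniform random responding has a closed trinomial form that
  the test suite verifies by exact enumeration.
* **Attribute dominance**: a respondent is dominant on an ordered attribute
  when their chosen alternative attains the task's best available level of
  that attribute in every main task. Shared-best levels count as attaining —
  under a balanced-overlap design strict uniqueness would under-count.
  Dosing is excluded: with no preference ordering there is no "best" level.

## Treatment-scenario engine

Published NMA summaries (median and 95% CrI of remission and WDAE
probabilities per treatment) are reconstructed as **logit-normal** sampling
distributions: mean `logit(median)`, sd `(logit(hi) - logit(lo)) / (2 x
1.959964)`. This respects the (0,1) support and the asymmetry of printed
intervals; the reconstruction, not the original NMA posterior, is what the
engine samples, and remission and WDAE are sampled independently within and
across treatments because the joint NMA posterior is not available.

`simulate_menu()` runs, per simulation draw, one fresh outcome draw per
treatment (shared across patients within the iteration — a committed choice
where independent per-patient outcome draws would also have been possible)
and one posterior draw of each patient's own part-worth vector; each patient
picks the highest-utility treatment, ties broken uniformly. Outcomes sampled
beyond the designed level range (e.g. a WDAE draw above 30%) are linearly
extrapolated and counted, with a clamp mode available. Cohort preference is
reported **both** as the share of patients whose modal treatment is each
option and as the mean choice probability, because "preferred by X% of
patients" is ambiguous between the two. `simulate_pairs()` applies the same
engine to every unordered pair and enforces $P(A \succ B) + P(B \succ A) = 1$
by construction. Sensitivity scenarios flip the documented flags: prednisone
to "No" for the four biologic-based treatments, or blood/liver risk to "Yes"
for the two anti-TNF agents. In the base scenario prednisone is "Yes" for
all six treatments, so that attribute provably cancels from every
comparison.

## Determinism and problem sizes

Every stochastic function takes a seed and restores the caller's RNG state;
`run_pipeline()` spawns per-stage seeds from one global seed, so a repeated
run reproduces every output file byte for byte. The test suite runs
everything at desk scale — cohorts of 40–300 respondents, chains of a few
thousand iterations, 10,000-draw scenario simulations — sizes chosen so the
whole suite completes in minutes while leaving each statistical check
adequately powered; the same code scales to the documented full-size
profiles unchanged.

## Known limitations

* The balanced-overlap generator is a documented heuristic, not a
  reimplementation of any proprietary design engine, and does not optimise
  D-efficiency.
* Linear entry of the two outcome attributes is an input assumption; no
  basis-expansion check is performed.
* The logit-normal reconstruction of NMA posteriors ignores between-outcome
  and between-treatment correlation.
* MRS and importance summaries on population-mean draws understate
  individual-level heterogeneity by design; per-respondent variants exist
  behind flags.
* EM for latent classes guarantees monotone likelihood but not the global
  optimum; BIC comparisons inherit multi-start variability.
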