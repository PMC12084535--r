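---
title: "Uncertainty-gated sepsis alerting: models, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Uncertainty-gated sepsis alerting: models, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edsepsis)
```

## The problem

Hourly sepsis risk scores computed from structured EHR data (vitals, labs,
demographics, medications) are good at ranking patients but poorly calibrated
in the middle of their range: scores just above a single decision threshold
are dominated by false alarms, which drive alert fatigue. The idea
implemented here is to split the score range with two thresholds. Scores at
or above a primary threshold `theta1` fire an alert directly. Scores in the
intermediate band `[theta2, theta1)` — the *uncertainty zone* — are
adjudicated by a second, independent source of evidence: the free-text
clinical notes. Clinical signs are extracted from the notes, a differential
diagnosis over severe sepsis and 18 sepsis-mimics is computed, and the alert
fires only when severe sepsis ranks in the top 5 differentials *and* a
suspicion of bacterial infection was extracted. Scores below `theta2` take
no action.

`edsepsis` implements the full decision pipeline, the Sepsis-3 encounter
phenotype used to define ground truth, the evaluation policy (truth windows,
silencing, false alarms per patient-hour), and a synthetic
emergency-department cohort generator so that every stage is testable
without access to protected health data.

## The differential diagnosis model

Extraction yields a binary vector over a catalog of 51 clinical signs
(`symptom_catalog()`). For each disease $D$ in the 19-condition set, a
likelihood table stores $P(CS_i = 1 \mid D)$ for the signs mapped to $D$,
and the posterior is Bayes' rule over the closed disease set:

$$P(D \mid CS) = \frac{P(D)\, P(CS \mid D)}{\sum_{D'} P(D')\, P(CS \mid D')}$$

**Absence factors (a deliberate design choice).** A strictly
"present-signs-only" product, $P(CS\mid D)=\prod_{i \in \text{present}}
P(CS_i{=}1\mid D)$, is not usable for cross-disease ranking when diseases
map different sign subsets: a disease sharing *no* sign with the extraction
keeps the empty product 1 and outranks every disease that actually explains
the findings. We therefore score each disease against the *whole* catalog as
a binary naive Bayes: present mapped signs contribute $P(CS_i{=}1\mid D)$,
absent mapped signs contribute $1 - P(CS_i{=}1\mid D)$, and signs outside
the disease's map contribute a small background probability (0.05 when
present, 0.95 when absent). The background term is what penalizes a disease
for present findings it cannot explain. The strict present-only semantics
remain available (`likelihood_table(use_absence = FALSE)`) and
`joint_likelihood()` always computes the present-only log product, but the
default posterior uses the full model; with present-only semantics the
empty extraction returns the prior, with the full model it does not.

**Priors** default to uniform (1/19): no published prior vector exists for
this differential set, and the closed-set normalization makes the ranking
insensitive to a common scaling. The prior is a plain configuration field.

**The likelihood values** are configuration, not ground truth. The default
table ranks each disease's mapped signs by specificity and decays
geometrically (0.90, 0.81, 0.73, ...). The severe-sepsis row is curated
instead of decayed, because it is the decision-critical row and the clinical
picture is well characterized: suspicion of bacterial infection (0.95) and
organ dysfunction (0.85) are near-definitional for Sepsis-3 septic patients
(cultures and antibiotics were ordered; a SOFA rise occurred), elevated
inflammatory markers are nearly universal (0.85), while a positive blood
culture is present in well under half of septic patients (0.40).

**Calibration.** `calibrate_likelihoods()` searches tables constrained to
(0.01, 0.99) for the one maximizing the F1 of the downstream alert decision
on a labeled development cohort, with the mean log-posterior of the true
diagnosis as a smooth tie-breaker (F1 is a step function; many tables tie).
The candidate pool contains the initial table, a moment-matched table
(Laplace-smoothed per-disease sign frequencies), and seeded random
perturbations of both, so the procedure is deterministic given its seed,
never returns a table scoring below the initial one, and recovers the
orderings of a generative table when the development cohort is drawn from
one. Budget 0 returns the initial table untouched.

## Sepsis-3 phenotyping

Suspicion of infection is a blood-culture draw paired with a
non-prophylactic IV antibiotic course of at least 4 days (96 continuous
hours from start): culture first requires the antibiotic start within 72 h,
antibiotic first requires the culture within 24 h; the suspicion time is the
earlier of the pair. Organ dysfunction is a rise of 2+ SOFA points inside
the closed window from 48 h before to 24 h after suspicion. Choices the
consensus papers leave open, fixed here so tests can be exact:

* **Baseline for the SOFA rise**: the running minimum over the window up to
  the candidate hour. This is the common operationalization and is monotone
  in the window width (shrinking any window can only remove septic labels).
* **Window edges**: closed on both ends ("within 72 h" read as $\le$ 72).
* **Onset** is the first qualifying dysfunction hour, not the suspicion
  hour: dysfunction is the binding event in the definition.

One structural note: a 4-day antibiotic course necessarily extends past an
ED stay of 12–25 h, so order events (unlike vitals, labs, SOFA and notes)
are not bounded by the discharge hour — they continue on the inpatient side.

## Note retrieval and extraction

The extractor is pluggable behind a 4-argument backend interface
`(prompt, context, temperature, seed)`. The tested path is a deterministic
mock that answers "Yes" iff the queried sign's canonical phrase occurs
verbatim in the retrieved context; a production LLM backend slots into the
same interface. Pipeline parameters follow the deployed configuration:
chunks of 1000 tokens with 300-token overlap, top-5 retrieval by cosine
similarity, temperature 0.3, and 3-run majority voting with one retry and a
fail-safe "no" for unparseable output (failing toward *not* alerting).
A token is a whitespace-delimited word — the production tokenizer is
model-internal and unspecified, and a model-free definition keeps the
chunker exactly testable. The test embedder is a hashed bag-of-words; ties
in retrieval keep input order, so the whole path is deterministic.

## The alert loop and evaluation policy

Predictions run at integer hours over the closed-open interval from hour 2
after triage to the earlier of sepsis onset and ED discharge. An hour is
eligible iff there is at least one vital and one lab in the half-open
24-hour lookback, no antibiotics have started, and a qualifying note type
exists (incomplete notes still qualify, mirroring prospective deployment).
Boundary conventions: score $\ge \theta_1$ fires directly;
$\theta_2 \le$ score $< \theta_1$ is the uncertainty zone. After a fired
alarm, firing (not scoring) is suppressed for 6 h; the silencing clock is
shared across the direct and gated pathways.

Evaluation is encounter-level: an alarm within the closed 48-h window before
onset with severe sepsis in its top-5 (or any direct fire) makes a septic
encounter a true positive; a non-septic encounter becomes a false positive
on any direct fire, but a gated alarm counts against it only when severe
sepsis is the *top-1* differential. Gated alarms with sepsis in top-5 but
not top-1 on non-septic encounters are ignored — the asymmetric policy is
reproduced as published, since it shapes the reported PPV. FAPH divides
total false alarms by the total count of hourly prediction time points.
The SLT variant (sepsis likelihood alone, threshold $\alpha$ with strict
exceedance) and a note-only baseline are provided for comparison; $\alpha$
is calibrated by grid search on the development split because no published
value exists.

## The synthetic cohort: what it emulates, and what it does not

`generate_cohort()` produces the stated world the pipeline assumes:

* septic prevalence 16.6% (the retrospective cohort's rate);
* onset delays log-normal with median 3.2 h, truncated below at 2.5 h —
  encounters septic before the hour-2 prediction start are excluded from
  the emulated cohort by the study design, so the generator produces only
  encounters the pipeline could in principle detect;
* ED length of stay log-normal, median 22 h septic / 12 h non-septic;
* hourly vitals, 4-hourly labs, an ED provider note and an H&P note within
  the first two hours;
* orders satisfying (septic) or failing (non-septic) the
  suspicion-of-infection windows, and a planted SOFA jump of +3 at onset,
  so Sepsis-3 labels round-trip exactly;
* truly present signs drawn Bernoulli from the likelihood table row of the
  true diagnosis, with canonical phrases planted into the ED note; a
  symptom-noise parameter (default 0.02) drops true phrases and introduces
  decoys;
* 70% of non-septic encounters carry a uniformly drawn sepsis-mimic with
  its signature planted (the cohort emulated is pre-filtered to clinically
  concerning presentations); the mimic prevalence is a stand-in, as no
  published value exists.

The surrogate risk score is a logistic function
`plogis(6*(severity - 0.45) + jitter)` of a planted per-encounter severity
(Beta-distributed: septic 5/2, mimics 2.5/4, benign 1.5/8) plus stored
per-hour noise, calibrated by construction so scores straddle both decision
thresholds. It stands in for the out-of-scope upstream neural network.

What the generator does **not** emulate: physiological waveforms, realistic
prose, demographic confounding, correlated sign noise, or distribution
shift. A green mechanism test therefore establishes that the gating logic,
differential ranking and evaluation policy interact as designed under the
stated world — it does not establish clinical performance, and the
published cohort metrics are not reproducible at desk scale. The package's
acceptance checks accordingly verify (a) every closed-form published number
(care-unit conversions, F1 identities, prevalence arithmetic) exactly, and
(b) the *direction* of the mechanism on synthetic data: gating strictly
lowers FAPH and raises PPV at a sensitivity cost of at most 5 points.

## Numerical choices

* Posteriors are computed in log space with a max-shift before
  exponentiation; normalization is exact to 1e-9 and matches the direct
  product to 1e-12 on small tables.
* All ranking ties break by table order, retrieval ties by chunk order, and
  every stochastic component (generator, calibration, per-run backend
  seeds derived from encounter, symptom and run index) is seeded, so equal
  seeds give byte-identical artifacts.
* Degenerate inputs surface as `NA` metrics (never silent zeros) or typed
  errors naming the violated constraint.

## Known limitations

* The disease–symptom map and likelihood defaults are curated
  configuration; other curations will shift rankings, which is why both are
  plain editable objects.
* The phenotype does not implement comfort-care censoring beyond truncating
  monitoring at discharge, nor ICD-based definitions.
* The mock extractor's exact-phrase contract makes extraction noise purely
  a generator property; real-note linguistic variability is out of scope.
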