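# panometry

Rule-based classification of esophageal motility from **FLIP panometry**
(functional lumen imaging probe), and concordance analysis against
high-resolution manometry (HRM) diagnoses, for clinicians and researchers
working on esophageal motility disorders.

FLIP panometry records luminal diameters from 16 impedance sensors at 1-cm
spacing, together with bag pressure, while the bag is filled stepwise from
40 to 70 mL during sedated endoscopy. Two things are read off the diameter
topography:

* the **contractile response (CR)** to distension (secondary peristalsis),
  classified under scheme v2.0 as *normal* (> 1 distinct antegrade
  contraction of ≥ 6 cm axial length with a pressure rise > 10 mmHg),
  *diminished* or *disordered* (contractility failing the normal criteria,
  split by whether the 60-mL pressure is ≤ 40 or > 40 mmHg), *absent*, or
  *spastic* (sustained occluding or sustained LES contractions);
* **EGJ opening**, from the EGJ distensibility index at 60 mL
  (EGJ-DI = narrowest EGJ cross-sectional area / bag pressure, mm²/mmHg) and
  the maximum EGJ diameter at 60–70 mL: *normal* (EGJ-DI ≥ 2.0 and
  diameter ≥ 16 mm), *reduced* (EGJ-DI < 2.0 and diameter < 12 mm), else
  *inconclusive*.

A total decision table maps each (CR, EGJ opening) pair to one of seven
motility classes (normal, hypocontractility, non-spastic obstruction,
spastic obstruction, possible spasm, possible obstruction, obstruction with
normal CR). The older v1.0 scheme (merged impaired/disordered CR,
"borderline" opening) ships as a second table for reclassification studies.

The package provides:

* a **synthetic topography simulator** (`simulate_topography()`) producing
  full FLIP exams with known ground-truth phenotypes;
* **feature extraction** (`extract_metrics()`): contraction-event detection
  in the time-by-channel grid, EGJ-DI, maximum EGJ diameter;
* the **classifiers** (`classify_cr_v2()`, `classify_cr_v1()`,
  `classify_egj_opening()`, `classify_motility()`) with auditable,
  provenance-tagged decision tables;
* an **HRM/TBE adjudicator** (`adjudicate_diagnosis()`): Chicago
  Classification v4.0 labels resolved against timed-barium-esophagram rules
  into conclusive/inconclusive EGJ-outflow status (plus IRP threshold
  checks);
* a **calibrated cohort generator** (`calibrate_joint_from_counts()`,
  `sample_cohort()`, `attach_metrics()`) and a packaged plain-text fixture
  of the published 805-patient FLIP × HRM contingency table;
* **concordance analysis** (`concordance_report()`, `build_crosstab()`,
  `proportion_within()`, `predictive_values()`,
  `version_reclassification()`, `group_comparison_tests()`).

Everything is data-frame-first: functions take a tibble and return a
tibble, so stages chain with the pipe; results have `tidy()`/`glance()`
methods and `autoplot()` views.

## Worked example

Simulate a spastic-obstruction exam, extract its metrics, and classify it:

```r
library(panometry)

study <- simulate_topography(topography_spec("disordered", "reduced"))
metrics <- extract_metrics(study)
classify_flip(metrics, scheme = "both")[
  , c("egj_opening", "cr_v2", "motility_v2", "cr_v1", "motility_v1")]
#> # A tibble: 1 × 5
#>   egj_opening cr_v2      motility_v2         cr_v1               motility_v1
#>   <fct>       <fct>      <fct>               <fct>               <fct>
#> 1 REDUCED     DISORDERED SPASTIC_OBSTRUCTION IMPAIRED_DISORDERED OBSTRUCTION_WEAK_CR
```

The disordered contractile response (retrograde contractions with 60-mL
pressure > 40 mmHg) combined with reduced EGJ opening yields *spastic
obstruction* under v2.0; under v1.0 the same exam is *obstruction with
weak CR* — exactly the reclassification the v2.0 revision introduced to
sharpen achalasia subtyping.

Run the concordance analysis on the packaged cohort fixture:

```r
rep <- concordance_report(cohort_fixture())
rep
#> <concordance_report> 805 patients: 704 conclusive, 101 excluded
```

Among the 704 patients with a conclusive CCv4.0 diagnosis, the report
computes (numerator/denominator → integer percent): 127/137 → 93% of
normal-FLIP patients with normal motility or IEM on HRM; NPV 135/137 → 99%
of normal FLIP for disorders of EGJ outflow; PPV 148/163 → 91% of
non-spastic obstruction for a conclusive outflow disorder; 126/163 → 77%
type I/II achalasia within non-spastic obstruction; 56/78 → 72%
absent/IEM within hypocontractility; and 16/37 → 43% of type III achalasia
classified as spastic obstruction.

## Package layout

* `R/` — simulator, feature extraction, classifiers, adjudicator, cohort
  generator, concordance, I/O, plotting
* `inst/extdata/` — the published contingency-count fixture (plain CSV)
* `vignettes/panometry-methods.Rmd` — models, parameters, design choices
  and limitations
* `tests/testthat/` — unit, property and end-to-end acceptance tests
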