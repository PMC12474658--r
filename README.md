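# laolink

Deduplication ("patient matching") of child health registries recorded in
Lao script or Latin transliteration. Registries without a shared patient
identifier accumulate duplicate records for the same child; in the Lao
setting this is aggravated by a tonal script with confusable vowel-length
marks (ສຸກສັນ vs ສູກສັນ, both *Souksan*), inconsistent romanization, and
temporary placeholder names such as ແອນ້ອຍ (*Eanoi*, "baby") recorded
before a child is permanently named. `laolink` is aimed at health
information exchange teams and researchers who need to resolve such
registries against a gold standard, and at methodologists who want a fully
testable, synthetic-data-driven benchmark of the standard matching
strategies.

The package implements, from a common Lao-aware normalized representation:

* **Deterministic matching** — blocking on exact (date of birth, sex,
  village), then a total decision table over the agreement states
  (MATCH / NONMATCH / NOT AVAILABLE) of the child's and parents' names.
  The table is the majority rule `count(MATCH) > count(NONMATCH)`, which
  reproduces the 21 published review criteria (10 match, 11 nonmatch)
  exactly, and is overridable from CSV.
* **Probabilistic matching** — the Fellegi–Sunter model, implemented from
  scratch: per-field agreement levels (exact / Jaro–Winkler ≥ 0.88 /
  ≥ 0.70 / else), match weight
  `w(γ) = Σ_f log2(m_f[γ_f] / u_f[γ_f])`,
  m/u estimated by expectation–maximization with a monotone
  log-likelihood, prior match probability λ estimated from a
  recall-adjusted deterministic proxy (default recall 0.7), pairs linked
  at posterior ≥ 0.5 and closed transitively. Jaro–Winkler operates on
  Unicode code points, so Lao names are scored natively.
* **Hybrid matching** — probabilistic matching applied only to records the
  deterministic stage left unmatched, link union, and a rule-table audit
  of probabilistic links (non-destructive by default, strict mode
  available).
* **Record-level evaluation** — confusion counts (a record is positive iff
  it sits in a cluster of size ≥ 2), precision/recall/F1, PR curves with
  trapezoidal AUC, cluster-size and completeness/name-frequency profiling.
* **A calibrated synthetic registry generator** — known truth partition;
  duplicate fraction 15.62%, cluster sizes 2–5 in the observed 86.9 / 11.4
  / 1.4 / 0.3 % mix, family-name completeness 32%, contact 13%,
  placeholder-name rates, Lao spelling corruption operators, and twin
  entities sharing quasi-identifiers.

See the vignette (`vignettes/lao-patient-matching.Rmd`) for the model
details and design rationale.

## Worked example

```r
library(laolink)

gen <- generate_registry(generator_config(n_records = 2000, seed = 42))
rec <- normalize_records(gen$records)

det <- deterministic_match(rec)
hyb <- hybrid_match(rec, pipeline_config(seed = 42))

metrics(record_confusion(det, gen$truth))
#> <metrics> precision=0.9593 recall=0.7564 f1=0.8459
metrics(record_confusion(hyb, gen$truth))
#> <metrics> precision=0.9685 recall=0.9840 f1=0.9762

cluster_size_table(gen$truth)
#>   size clusters  pct records
#> 1    2      121 84.0     242
#> 2    3       22 15.3      66
#> 3    4        1  0.7       4
```

The deterministic matcher loses recall (0.76) because Lao spelling variants
break exact name equality while the majority rule demands more matching
than non-matching name fields; the hybrid matcher recovers those records
through Jaro–Winkler partial agreement on the deterministic residual
(recall 0.98) at essentially the same precision. The cluster-size table
shows the truth structure the generator emitted: mostly 2-record clusters,
as in real registries of this kind.

A thin command-line wrapper over the same functions ships in
`inst/cli/laolink.R`:

```sh
Rscript inst/cli/laolink.R simulate --n 5000 --seed 7 --out records.csv --truth truth.csv
Rscript inst/cli/laolink.R match-hybrid --input records.csv --output pred.csv
Rscript inst/cli/laolink.R evaluate --pred pred.csv --gold truth.csv
```

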