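---
title: "Patient matching for Lao-script child health registries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Patient matching for Lao-script child health registries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(laolink)
```

## The problem

Child health information systems in Lao PDR exchange records between
immunization registries and hospital systems without a shared patient
identifier. The same child is routinely registered several times, and the
Lao language makes the resulting duplicates hard to detect: the script is
tonal, vowel-length marks are easily confused (ສຸກສັນ and ສູກສັນ are the
same name, Souksan, spelled two ways), names circulate both in Lao script
and in inconsistent Latin transliterations, and many infants are recorded
under a temporary placeholder name — ແອນ້ອຍ ("Eanoi", *baby*) — before
receiving a permanent name. `laolink` implements and compares three
deduplication strategies for this setting, evaluated at the record level
against a gold-standard partition.

## Normalization

All comparisons operate on canonical text (`normalize_text()`): Unicode NFC,
Latin accent folding, an ordered substitution table (`charmap`), removal of
all whitespace (Lao is written without spaces; transliterations space names
inconsistently), upper-casing, and removal of characters outside the Lao
block (U+0E80–U+0EFF) and printable ASCII. The bundled base table maps Lao
digit forms to ASCII and expands the ໜ/ໝ ligature code points; an optional
*phonetic-merge* layer additionally collapses the confusable short/long
vowel marks (◌ຸ/◌ູ, ◌ິ/◌ີ) and the four tone marks into one class, so the
two spellings of Souksan above compare equal. The table contents are a
package choice: the goals of normalization (upper-casing, space removal,
canonicalizing special characters) are standard for this kind of registry,
but no authoritative substitution list exists, so the table ships as data
(`inst/extdata/charmap_*.csv`) rather than code, and users can supply their
own. The map is validated at load time to be idempotent, which also rules
out rule cycles.

Placeholder names are detected (`placeholder_flag()`) but by default compare
as ordinary values, because that is how registry systems behave in practice
— two "Eanoi" records agree on the name field, which is precisely one of the
documented failure modes. An opt-in flag demotes placeholder agreement to
"not available".

## Deterministic matching

Records are blocked on exact (date of birth, sex, village); only
within-block pairs are compared. Each pair's evidence is the agreement state
of the child's name, the father's name and the mother's name, each one of
MATCH / NONMATCH / NOT_AVAILABLE (missing on either side). The decision
table over the 27 state triples is the majority rule

> match ⇔ count(MATCH) > count(NONMATCH),

which reproduces exactly the 21 review criteria (10 match, 11 nonmatch)
used by human reviewers in this domain; the 6 remaining triples all lack a
single matching field and resolve to FALSE. The table is overridable from a
CSV, and a strict variant requires all three names to agree exactly.
Matched pairs are closed transitively into clusters (entities can appear
three or more times).

## Probabilistic matching (Fellegi–Sunter)

For the probabilistic stage the blocking key is the conjunction of exact
date of birth and village — sex is deliberately left out of the key so that
sex-discrepant duplicates remain comparable, and instead enters the
comparison vector. Each within-block pair gets one agreement level per
field: names at four levels (exact / Jaro–Winkler ≥ 0.88 / ≥ 0.70 / else)
and sex at two (exact / else); a field missing on either side gets no level
and is ignored by the model (missing at random). The thresholds 0.88/0.70
are the conventional partial-agreement cut-offs for name fields in
record-linkage tooling and are configurable (`comparison_spec()`).

Jaro–Winkler similarity is implemented from scratch on Unicode code points
(prefix scaling 0.1, prefix cap 4), so Lao script and Latin transliterations
are scored alike; it is verified in the test suite against an independent
from-definition implementation on random Lao/ASCII strings.

Under conditional independence of fields given the latent match class, a
pair's match weight is

$$w(\gamma) = \sum_f \log_2 \frac{m_f[\gamma_f]}{u_f[\gamma_f]},$$

where $m$ and $u$ are the level probabilities given match and non-match.
They are estimated by a standard two-class EM (`em_estimate()`) whose
observed-data log-likelihood is asserted non-decreasing at every iteration;
estimates are clamped to $[10^{-6}, 1-10^{-6}]$ so weights stay finite.
Initialization puts 0.9 of the $m$ mass on the top level and starts $u$ at
the empirical level frequencies (true matches are rare among comparable
pairs, so the overall frequencies approximate $u$ well).

The prior match probability $\lambda$ is estimated from a deterministic
proxy: the number of rule-table matches among comparable pairs, divided by
an assumed proxy recall $r$ (default 0.7, the value reported optimal for
registries of this kind after sweeping 0.65–0.95; `recall_sweep()`
reproduces that sensitivity analysis), divided by the number of comparable
pairs. In the
standalone probabilistic matcher $\lambda$ stays fixed at this estimate, so
the recall parameter has its intended effect on the prior; EM re-estimation
of $\lambda$ is available as an option. A pair is linked when its posterior
$\lambda 2^w / (\lambda 2^w + 1 - \lambda)$ reaches the threshold (default
0.5, configurable — there is no canonical choice), and links are closed
transitively.

Identifiability note: a two-class mixture over a *single* categorical field
is not identifiable (any one-field marginal admits a ridge of equivalent
$(m, u, \lambda)$ solutions), so parameter-recovery guarantees are stated
and tested for three or more conditionally independent fields, which is the
regime the matcher actually runs in.

## Hybrid matching

The hybrid combiner runs the deterministic matcher first; every record in a
deterministic cluster of size ≥ 2 is withheld, and the probabilistic
matcher runs on the residual only. Because the residual's own deterministic
proxy is empty by construction, $\lambda$ is estimated on the full registry
and EM may refine it on residual pairs. The final partition is the
transitive closure of the union of both link sets, and each link carries
its provenance.

Probabilistic links are audited against the rule table. "Validation" of
probabilistic links by deterministic criteria is ambiguous between
filtering and flagging; the default is a non-destructive audit (links whose
rule evidence actively conflicts — differing sex, or a FALSE decision with
at least one NONMATCH among the names — are flagged but kept), because in
the hybrid design every deterministically-acceptable residual link would
already have been matched deterministically, so destructive filtering would
empty the probabilistic stage. The published behaviour of this pipeline
family (hybrid true positives slightly *above* probabilistic) likewise
indicates validation did not remove links. A `strict_audit` mode removes
flagged links for users who want the conservative variant.

## Evaluation

Evaluation is at the record level: a record is positive iff it belongs to a
cluster of size ≥ 2, and the confusion matrix compares that status between
predicted and gold partitions. This unit is forced by the way results are
reported in this domain (per-method confusion counts summing to the number
of records). Precision, recall and F1 use zero-division-to-zero rules;
quoted integer percentages use half-away-from-zero rounding. `pr_curve()`
sweeps a per-record score (maximum incident-link posterior for the
probabilistic/hybrid matchers; for the deterministic matcher the count of
agreeing name fields within the block, 0–3, a package choice since no
deterministic sweep score is standard) and reports trapezoidal area under
the recall-sorted (recall, precision) points. Pair-level rates are
available in the test suite but the headline numbers are record-level.

## The synthetic registry generator

Real registries of this kind are access-controlled, so `generate_registry()`
produces registries with a known truth partition that reproduce the
structural features the matchers are sensitive to:

* 15.62% of records belong to duplicate clusters, with multi-record cluster
  sizes distributed 86.9 / 11.4 / 1.4 / 0.3 % over sizes 2–5;
* field completeness: family name 32%, contact 13%, other matching fields
  complete (unquoted fields default to fully complete and are
  config-exposed);
* placeholder names at their observed rates (Eanoi ≈ 2.4% of entities, Mr.
  and Miss at ≈ 110 and 80 per 20,433);
* duplicates derive from a base record via spelling operators — tone-mark
  swap, confusable vowel length, romanization variants, adjacent
  transposition — or a temporary-name replacement that models the
  pre-naming record (name becomes ແອນ້ອຍ, truth link retained);
* twins: distinct entities sharing date of birth, village, family and
  parent names, same sex half the time, and both still under the
  placeholder name 15% of the time.

Values not reported for the real registry are package choices, fixed once:
35 villages and a four-year birth-date window (together these set the
coincidental key-collision rate so that the share of records flagged for
review on synthetic data, ≈ 30%, is of the same order as the ≈ 28% observed
in the field); a 50/50 split between Lao-script and Latin-transliteration
entities; corruption rates of 0.35 (child name), 0.30 (each parent name)
and 0.05 (temporary-name replacement) per duplicate record; a twin rate of
1% of entities. Per-duplicate name corruption at these rates makes roughly
a quarter of true pairs fail the majority rule (two or more NONMATCH
fields) while remaining within Jaro–Winkler reach, which is what gives the
deterministic matcher its characteristic recall deficit.

What the generator does **not** emulate: realistic Lao name frequency
distributions (the bundled pool is 200 synthetic two-syllable names, marked
as synthetic in its filename), seasonal or village-level birth clustering,
correlated missingness, cross-script duplicates of the same entity, or
clerical date-of-birth errors (duplicates always share DOB and village, so
blocking recall is 1 on synthetic data). Passing tests therefore demonstrate
correct mechanics and the expected *ordering* of the three matchers under
Lao-like name noise, not field performance on real registries.

`emit_gold_review()` simulates the three-reviewer gold-standard process:
each reviewer is the rule table with independent decision flips at a given
error rate, and the consensus keeps links all three agree on — reproducing
the observed property that the consensus match count is below every
individual reviewer's.

## Numerical and testing choices

* EM: tolerance $10^{-6}$ on the log-likelihood, at most 100 iterations,
  probabilities clamped to $[10^{-6}, 1-10^{-6}]$; `tol = Inf` performs
  exactly one parameter update (stopping-rule contract).
* Degenerate inputs: a registry with no comparable pairs yields all
  singletons; EM on identical comparison vectors raises an
  "unidentifiable" error; an empty threshold sweep is an error; a
  single-point PR curve degenerates to the rectangle under that point.
* Determinism: every stochastic routine takes a seed (`withr::with_seed`),
  and partitions use order-invariant canonical labels (smallest member id).
* Test problem sizes were chosen to keep the default suite fast while
  leaving sampling noise well inside the asserted tolerances: EM recovery
  at 20,000 vectors (±0.03), the fixed-point check at 50,000, hybrid
  superset checks on twenty registries of 2,000 records, and one
  full-scale registry of 20,433 records for end-to-end ordering and
  generator calibration.

## Known limitations

* The conditional-independence Fellegi–Sunter model ignores term
  frequencies (a pair agreeing on a rare name scores the same as one
  agreeing on a common one) and level correlations.
* Cross-script duplicates (Lao vs Latin spelling of the same entity) defeat
  Jaro–Winkler entirely and are only recoverable through parent names; a
  Lao phonetic encoding (Soundex-style) is the natural extension and is out
  of scope here.
* Twins sharing all quasi-identifiers are structurally indistinguishable
  from duplicates for every matcher in this package; the synthetic
  generator reproduces this failure mode rather than solving it.
* The λ proxy assumes the deterministic rules have known recall on
  comparable pairs; on registries where the rules are badly miscalibrated
  the prior (and hence the posterior threshold) shifts accordingly.
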