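---
title: "Querying phenotype-genotype relationships under open-world semantics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Querying phenotype-genotype relationships under open-world semantics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenoquery)
library(dplyr)
```

## The problem

Genetic catalogs and mutation databases describe disease at the level of
abstract phenotype descriptions ("childhood-onset chronic diarrhea"), while
clinical records store the same information as low-level fields spread over
several columns ("diarrhea onset age", "diarrhea duration"). Asking either
direction of the phenotype-genotype question — *which variants occur in
patients with this trait?* or *which traits occur in carriers of this
variant?* — therefore needs two steps: first interpret the abstract
description against the raw fields, then map the query onto the dataset,
expanding broad phenotype classes to their narrower subclasses.

phenoquery implements this two-step machinery for tabular patient data,
with cerebrotendinous xanthomatosis (CTX, a rare autosomal-recessive
CYP27A1 disease) as the worked domain: an is-a phenotype ontology, a
three-valued patient model, a monotone Horn-rule layer for phenotype
abstraction, and a query engine for set-valued and aggregate answers.

## The patient model and its three truth values

Clinical datasets are chronically incomplete, so the model is open-world:
for any patient and any phenotype term the answer is one of *present*,
*absent* or *unknown*. Both presence **and** absence are asserted facts; a
blank is never read as "does not have". Each phenotype therefore behaves
like a pair of instances — presence-of-X and absence-of-X — and a patient
may be linked to either, or to neither.

`phenotype_status()` computes the value for any ontology term:

* **present** if the patient has a presence assertion on the term or (with
  `hierarchy = TRUE`, the default) on any descendant — ataxia counts as an
  abnormality of the cerebellum;
* **absent** if an absence assertion sits literally on the queried term.
  Absence never propagates, in either direction: knowing a patient has no
  tendon xanthomas says nothing about xanthomas elsewhere, and knowing
  a class is absent is only usable where an explicit rule says so;
* **unknown** otherwise.

Presence is checked first, so a presence on a descendant beats an absence
propagated query-side onto the same ancestor; `validate_cohort()` flags
such cohorts with a warning rather than rejecting them. An optional
`closed_world = TRUE` collapses unknown into absent, reproducing the
"a blank means not(trait)" reading for comparison; it is never the default.

## The ontology

`parse_ontology()` reads a small OBO 1.2 subset (`[Term]` stanzas with
`id:`, `name:`, `is_a:`, `synonym:`) or an equivalent 4-column table. The
hierarchy is a DAG — multiple parents are allowed, as concept systems
reuse terms across axes (tendon xanthomas sit under both xanthoma and
musculoskeletal abnormality) — and is validated at load: duplicate ids,
dangling parents and cycles are hard errors, with one witness cycle named.
Subsumption is reflexive (`subsumes(x, x)` is true); `ancestors()` and
`descendants()` exclude the term itself. Synonyms are stored but play no
role in matching — terminology mapping is out of scope, and all references
are by exact term id.

The bundled CTX ontology (`ctx_ontology()`, ~60 terms) covers the four
hierarchies (phenotype, anatomical structure, diagnostic study, qualifier
value) and every concept the CTX queries touch. The structure *between*
the named concepts is a curated implementation choice; the package makes
no claim to reconstruct a complete disease ontology.

## The abstraction rule layer

Rules deduce catalog-level descriptions from raw fields. The language is
deliberately a small fragment of general Horn rules: a conjunction of
atoms over one patient implying one explicit assertion. Three atom kinds
exist — a three-valued status check, a numeric attribute comparison, and a
class-membership check (some presence assertion under a class). There is
no negation-as-failure (absence atoms read asserted negatives only) and no
variable ranging over several patients. Every derivation the engine must
reproduce fits this fragment, and it buys a strong guarantee: forward
chaining is monotone over a finite fact space, so the fixpoint is unique,
reached regardless of rule order, and idempotent. All three properties are
exercised on random cohorts in the test suite.

The bundled ruleset (`ctx_ruleset()`) contains the childhood-onset chronic
diarrhea presence rule, its downward absence counterpart (no diarrhea at
all implies no childhood-onset chronic form — needed so that "patients
*without* the trait" has asserted-absence evidence to find), and three
property-group link rules attaching neurological / extra-neurological /
diagnostic-study manifestation markers. Two thresholds parameterize it:

| parameter | default | why |
|---|---|---|
| `childhood_onset_max_age` | 16 years (strict `<`) | covers pediatric-onset classes in common phenotype catalogs |
| `chronic_min_duration` | 4 weeks (`>=`) | the standard chronic-diarrhea definition |

Neither cutoff is defined in the source material; both are policy values,
so comparisons are exact (no numeric tolerance) and both can be overridden
in the rule file. Rule numeric atoms read the patient *attribute* table
(`diarrhea_onset_age`, `diarrhea_duration_weeks`, decimal years at 0.1
resolution / decimal weeks); assertion-level onset fields are descriptive
and kept consistent with the attributes in the shipped data.

Every firing is recorded with its supporting facts; `explain_derivations()`
reconstructs full chains, one per distinct rule path, and returns nothing
for assertions that were asserted rather than derived.

## The query patterns

Nine patterns cover the competency questions described in the main text;
`evaluate_query()` dispatches a `query_spec()` and guarantees rules are
applied exactly once beforehand. Conventions that matter:

* **Floor percentages.** Frequencies print as truncated integers (4 of 7
  carriers is 57%, not 57.1 or 58) — matching how the study reports 6/14
  as 42%. Means print at 0.1 precision, rounded half up.
* **Denominators include unknowns.** `trait_frequency()` divides by *all*
  carriers of the variant, informative or not; this is what the original
  set-based aggregate program computes.
* **Same-patient co-occurrence.** `variants_with_all_traits()` requires
  one patient to have every trait; variants whose carriers have the traits
  scattered across different people do not qualify.
* **"Never" is not "don't know".** `variants_never_associated()` returns
  variants with asserted-absence evidence and no presence; variants whose
  carriers are all uninformative go to a separate do-not-know list. An
  empty denominator yields a distinct `empty-denominator` note, never 0 —
  open-world "do not know" must stay distinguishable from "0%".
* Patients are counted individually, never per family, and a patient
  carrying two variants counts toward both carrier sets.

## The synthetic cohort

The original 25-patient dataset lives in a dissertation and is not
deposited, so the package ships a *constraint-level* emulation rather than
a reconstruction: `build_canonical_fixture()` returns a deterministic
cohort of 25 patients, 19 families and 14 CYP27A1 variants (the eight
labels quoted in the study plus six placeholders in an unmistakably
synthetic `p.SYN00x` namespace) that satisfies every printed aggregate —
the 44% / 32% / 52% cohort frequencies, the 7-variant and 6-variant
association sets, the single mixed-evidence variant p.R395C, the
never-associated p.Q525X, the 57% ataxia frequency among p.R395C carriers,
the cerebellar trait set, and the 23 / 16 / 31 / 23.4 / 12.7-year onset
means with the 7-year diarrhea-to-neurological interval. The raw cohort
contains *no* asserted presence of childhood-onset chronic diarrhea: all
eleven presences exist only through rule derivation, which is the point of
the abstraction layer.

Where the aggregates under-determine the records (who carries which
placeholder, individual onset ages), values were fixed once by hand; any
constraint-satisfying choice reproduces the same aggregates, because the
aggregates are exactly what is constrained. `verify_constraints()` checks
all of this through the query engine on every build and in the test suite;
`build_canonical_fixture()` refuses to return a cohort violating any
constraint.

One published tension is worth recording: the overview example lists
p.Q525X under "do not know", while the full-study results name it the one
variant *never* associated with childhood-onset chronic diarrhea. These
are different datasets — a worked mini-scenario versus the full cohort —
so the package gives p.Q525X an absence-asserting carrier in the canonical
cohort and an uninformative carrier in the mini-scenario
(`build_mini_scenario()`). The mini-scenario carries seven patients:
four presence carriers of the four quoted variants, the asserted-absence
patient 564385-1 (p.R395C), and two uninformative carriers supplying the
do-not-know answers.

## The random generator

`generate_random_cohort()` exists for property-based testing, not realism.
It draws, per patient, one or two variants uniformly; per leaf phenotype,
presence with its prevalence, else asserted absence with `absence_rate`,
else nothing; then drops assertions with `missingness`. Onset ages are
uniform on 0.5–60 years at 0.1 resolution, durations uniform on 1–104
weeks. Identical configurations (including seed) give identical cohorts.
What it deliberately does **not** emulate: comorbidity correlation,
penetrance/expressivity, family structure, or any temporal process beyond
a single onset age — so green property tests certify the engine's logic
(oracle equivalence, fixpoint laws, hierarchy monotonicity, open-world
stability, binomial calibration of prevalence), not fidelity to real
clinical data.

Problem sizes used by the shipped suites: oracle-equivalence runs 200
random cohorts of up to 10 patients, 6 variants and 15 terms against an
independent nested-loop evaluator; fixpoint laws run on 50 cohorts;
calibration uses 100 seeds at n = 400 with prevalence 0.5, requiring the
observed frequency within three binomial standard errors of 50% in at
least 95 seeds.

## A worked example

```{r example}
fx <- build_canonical_fixture()
enriched <- apply_rules(fx$cohort, fx$ruleset, fx$ontology)

cohort_frequency(enriched, "ChildhoodOnsetChronicDiarrhea", fx$ontology)
variants_with_all_traits(enriched, c("Epilepsy", "Dementia"), fx$ontology)
trait_frequency(enriched, "p.R395C", "Ataxia", fx$ontology)
mean_attribute(enriched, "neurological_symptom_onset_age",
               list(filter_term("Xanthoma", "present"),
                    filter_variant("p.R395C")), fx$ontology)
```

```{r plot, fig.width = 6, fig.height = 3}
plot_status_breakdown(enriched,
                      c("ChildhoodOnsetChronicDiarrhea", "Epilepsy",
                        "Dementia", "Xanthoma"), fx$ontology)
```

## Known limitations

* The rule language cannot express cross-patient joins, disjunction or
  probabilistic conclusions; richer abstractions need a different engine.
* Temporal modelling is limited to onset ages and durations; timelines and
  event ordering are out of scope.
* The bundled ruleset is representative of the described derivations, not
  a reconstruction of the full 28-rule catalog (which is not available in
  the main text); likewise only the query patterns described in the text
  are implemented as named patterns.
* Zygosity and phasing are not modelled; variant observations are opaque
  labels, and a patient's two variants are treated independently.
* The synthetic cohort matches the published aggregates, not the real
  patients; per-patient conclusions drawn from it are meaningless by
  construction.
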