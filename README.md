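# phenoquery

Bidirectional phenotype–genotype querying of patient cohorts under
open-world semantics, with an is-a phenotype ontology, Horn-rule phenotype
abstraction, and set/aggregate query patterns — demonstrated on a
constraint-verified synthetic cohort for cerebrotendinous xanthomatosis
(CTX), a rare autosomal-recessive CYP27A1 disease.

## Who this is for

Clinical geneticists and registry builders ask two symmetric questions:
*which genetic variants occur in patients with this (combination of)
trait(s)?* and *which traits occur in carriers of this variant?* Answering
them on real records is hard for two reasons this package addresses
head-on:

1. **Abstraction gap.** Catalogs say "childhood-onset chronic diarrhea";
   records store `diarrhea_onset_age` and `diarrhea_duration_weeks`.
   phenoquery bridges the gap with a forward-chained, monotone Horn-rule
   layer: `Diarrhea present ∧ onset < 16 y ∧ duration ≥ 4 wk ⇒
   ChildhoodOnsetChronicDiarrhea present`, with full derivation
   provenance.
2. **Missing data.** A blank is not a "no". Every patient has one of three
   statuses per phenotype term — present, absent, unknown — and absence
   counts only when asserted. Queries distinguish "never associated" from
   "do not know", and an optional closed-world mode shows what changes if
   blanks are read as negatives.

Phenotype terms live in an is-a DAG (OBO-subset or tabular), and presence
propagates upward: a query for *Abnormality of the cerebellum* finds
patients asserted only with *Ataxia* or *Arnold-Chiari type I
malformation*.

## Core model

For patient $p$ and term $t$ with descendant set $D(t)$:

$$
\mathrm{status}(p,t)=
\begin{cases}
\text{present} & \exists\, \text{presence assertion on } t' \in \{t\}\cup D(t)\\
\text{absent} & \exists\, \text{absence assertion literally on } t\\
\text{unknown} & \text{otherwise}
\end{cases}
$$

Aggregates follow the conventions of the source study: percentages are
floored to integers ($\lfloor 100 \cdot 4/7\rfloor = 57\%$ with *all*
carriers in the denominator, unknowns included), means are reported at
0.1-year precision rounded half up, and empty denominators return a
distinct `empty-denominator` outcome, never 0.

## Worked example

```r
library(phenoquery)

fx <- build_canonical_fixture()      # 25 patients, 19 families, 14 variants
enriched <- apply_rules(fx$cohort, fx$ruleset, fx$ontology)

cohort_frequency(enriched, "ChildhoodOnsetChronicDiarrhea", fx$ontology)
#> # A tibble: 1 × 5
#>   value numerator denominator unit    note
#>   <dbl>     <int>       <int> <chr>   <chr>
#> 1    44        11          25 percent ok
```

44% of patients have the derived abstraction (11 of 25) — none of these
presences exists in the raw data; all are rule derivations from onset age
and duration. Which variants accompany epilepsy *and* dementia in the same
patient?

```r
variants_with_all_traits(enriched, c("Epilepsy", "Dementia"), fx$ontology)
#> # A tibble: 6 × 1
#>   variant_id
#>   <chr>
#> 1 c.844+1G>T
#> 2 p.N403K
#> 3 p.R395C
#> 4 p.R405W
#> 5 p.T339M
#> 6 p.T343R
```

Open-world negatives stay separate from ignorance:

```r
nv <- variants_never_associated(enriched, "ChildhoodOnsetChronicDiarrhea", fx$ontology)
nv$variant_id            # "p.Q525X"  — asserted-absence evidence, no presence
attr(nv, "do_not_know")  # "p.SYN001" ... "p.SYN006" — carriers uninformative
```

And the aggregate patterns:

```r
trait_frequency(enriched, "p.R395C", "Ataxia", fx$ontology)
#>   value numerator denominator unit    note
#> 1    57         4           7 percent ok

mean_attribute(enriched, "neurological_symptom_onset_age",
               list(filter_term("Xanthoma", "present"),
                    filter_variant("p.R395C")), fx$ontology)
#>   value numerator denominator unit  note
#> 1  23.4         5           5 years ok
```

So p.R395C carriers show ataxia in 57% of cases, and xanthoma-positive
p.R395C carriers develop neurological symptoms at a mean of 23.4 years.

A command-line wrapper covers the same pipeline (`validate`, `infer`,
`query`, `fixture build`, `fixture random`):

```sh
cli=$(Rscript -e 'cat(system.file("cli", "phenoquery", package = "phenoquery"))')
Rscript "$cli" fixture build --out-dir data/
Rscript "$cli" query --ontology data/ctx_ontology.obo \
  --cohort data/ctx_cohort.csv --attributes data/ctx_cohort_attributes.csv \
  --rules data/ctx_rules.yml \
  --pattern trait_frequency --variant p.R395C --term Ataxia
```

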