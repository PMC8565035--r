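---
title: "Mapping SDTM registry data to the OMOP CDM: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping SDTM registry data to the OMOP CDM: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdtm2omop)
```

This vignette is the package's account of what the transformation does,
which behaviours are fixed methodology and which are configurable, the
design choices made where the design was genuinely open, and what the
validation on synthetic data does and does not demonstrate.

## The transformation model

A registry study arrives as one delimited file per SDTM domain. The
pipeline runs six stages, in a fixed order that matters:

1. **Sample selection** over DM records;
2. **reference-timeline construction** per patient (drug intervals,
   enrollment, last available information, study end);
3. **non-event filtering** (`--OCCUR` of N or U, `--STAT` of NOT DONE);
4. **date completion** (the record is dropped as *undatable* only if every
   strategy fails);
5. **source-to-standard resolution** (failure puts the record in the
   *unmapped* log);
6. **routing, fact linking, death reconciliation and observation periods.**

Because dating precedes resolution, a record that is both undatable and
unmappable is counted once, as undatable. The four fates — mapped,
non-event, unmapped, undatable (death-details records form a fifth,
consumed by the DEATH table) — partition the input records exactly; this
"no silent loss" property is asserted by the test suite on every synthetic
fixture.

### Sample selection semantics

The exclusion report mirrors a three-row accounting table: patients in the
database, protocol violators, and records excluded during mapping. The
unit is the *DM record*, which makes the identity
`n_mapped = n_in_database − n_violators − n_mapping_excluded` exact even
with duplicates: a duplicated DM row is one excluded record while its
patient remains mapped, whereas a missing birth year (or treatment start
and end dates both missing) excludes the patient outright. Violators are
supplied as an input flag set (`VIOLATORS.csv`); re-deriving eligibility
criteria is out of scope. The treatment-date rule applies only when the
study has an EX table, so vocabulary- or imputation-only fixtures are not
spuriously emptied.

## Date imputation

`PartialDate` is an ISO-8601 prefix: year, optional month, optional day.
Generic completion maps a missing day to the first of the month and a
missing day and month to 1 January. All other strategies reduce to this
completion plus a reference comparison:

* **Free text** (strategy i): a fixed dialect list — ISO prefixes,
  `DD Mon YYYY`, `Mon YYYY`, `MM/DD/YYYY` — scanned in that order, first
  full match wins. A bare year must stand as its own token within
  1900–2099. Anything else is *not* a date; the list is deliberately
  closed, because silent acceptance of ambiguous text (is `04/05/2016`
  April or May?) is worse than an undatable record. `DD/MM/YYYY` is
  intentionally absent: the supported dialect is month-first.
* **Timepoints** (ii): labels such as `BEFORE DISCONTINUATION` are study
  vocabulary, so the label→anchor table is configuration
  (`default_timepoints()`), each entry an anchor plus an integer day
  offset. The offset for windowed labels ("within 3 months of baseline")
  defaults to 0 — the anchor date itself — since no principled point
  inside the window exists; a study that prefers the window midpoint
  configures `offset_days = 45`.
* **Previous drug interval** (iii): a completed drug start that does not
  fall after the previous interval's end becomes that end + 1 day. If the
  shifted date contradicts the recorded components (different year, or
  different month when one was recorded), the shift is refused, the
  generic candidate kept, and the conflict flagged in the audit log. The
  rule is applied to EX study-drug intervals, where interval order is
  well-defined by the sequence number; concomitant medications complete
  generically because their interval structure in registry data is too
  irregular to trust.
* **Reference comparison** (iv): lab dates anchor at drug initiation when
  the recorded month/year agree with it, or at min(drug end, study end)
  for last-available timepoints — the timepoint rule deliberately precedes
  generic completion, so a partial date with a last-available label takes
  the anchor. Death dates select the candidate with the fewest missing
  components; ties break by source (CRF death details, then fatal AEs,
  then the safety database), then by completed date, making the result
  invariant under candidate reordering. A selected partial candidate is
  completed generically and floored at the date of last available
  information; a recorded complete date is never moved.

Two open points were decided as follows. First, candidate selection
prefers the *more complete* date outright and applies the source
hierarchy only on ties — the strict-inequality case is an inference from
the tie rule, consistent with gathering the most complete information.
Second, a single source's date is selected rather than assembling a
composite from day/month parts across sources; a composite of fragments
from conflicting sources could manufacture a date no source attests.
"Last available information" is the latest complete date among the
patient's non-death records and enrollment, capped at the study end.

Records with no year and no applicable strategy are dropped with a logged
reason: an OMOP event without a date is not representable, and inventing
one without any anchor would be fabrication.

## Vocabulary handling

Resolution order is: exact crosswalk entry (free text is lower-cased and
whitespace-normalised first), then a direct `Maps to` relationship from a
source concept, then unmapped. The crosswalk is shipped as data, not code:
the upstream automated UMLS-assisted mapping plus expert review is a
curation process whose *product* is the table; re-running it is neither
possible nor useful offline. MedDRA terms are classification concepts and
can never be an event row's `concept_id`; they ride along in
`source_concept_id`.

Custom concepts are allocated sequentially from 2,000,000,000 (the OMOP
local-concept convention), deterministically given registration order, and
registration is idempotent on (name, domain) so a concept introduced for
one registry is reused for the next. `build_ancestor_closure()` computes
the exact transitive closure of the `Is a` DAG with
`min_levels_of_separation` the shortest and `max_levels_of_separation` the
longest path length (well-defined because the graph must be acyclic — a
cycle aborts naming the concepts involved), plus `(c, c, 0, 0)` self rows
for every concept, following OMOP convention; whether self rows belong in
a local closure is not universally agreed, but including them keeps
`descendant-of` queries uniform. The test suite checks the closure against
a brute-force path-enumeration oracle on random DAGs of up to 50 nodes.

Disease subgroups with no single concept are expressed two ways: a custom
concept (drug- and toxin-induced PAH) or a *combination* of standard
concepts (PAH plus connective tissue disease overlap syndrome). A
combination is just a one-to-many crosswalk entry with `custom`
provenance: the fan-out rows are emitted like any other, and additionally
linked pairwise through `FACT_RELATIONSHIP` so the qualifier is not
mistaken for an independent diagnosis. Ordinary one-to-many mappings
(`manual`/`automated` provenance, e.g. a catheter-site-discharge code
mapping to both a catheter complication and a skin discharge) fan out
*without* links — the two rows are genuinely separate facts.

## Routing and fact links

A concept's domain dictates its table; a domain outside the routable set
is a vocabulary bug and fails fast at `lint_vocabulary()`. Event
characteristics (severity, causality, measurement method) and non-fatal
outcomes become observation rows linked to the event by mirrored
`FACT_RELATIONSHIP` pairs — both directions are emitted, sharing one
relationship concept, since the vocabulary fixture does not model inverse
relationship pairs. The measurement-method link uses the standard
measurement-method concept (4152892); characteristic links use a metadata
link concept, as the CDM has no specific one. The table ids for the
observation and measurement tables follow the CDM metadata vocabulary
(1147304, 1147330); ids for the remaining tables are fixture metadata
allocated in the same range.

Fatal outcomes are not event attachments: they divert into the death
pathway as `crf_fatal_ae` candidates (the adverse event row itself is
still mapped). Disposition records map to config-chosen observation
concepts, because the CDM offers interchangeable alternatives per category
and a run must commit to one set. Hospitalizations arriving as dated
free-text events route to `visit_occurrence`. `person_id` and event ids
are sequential surrogates assigned in sorted source order, so identical
inputs give byte-identical outputs; source identifiers survive in the
`*_source_value` columns.

## Quality assessment

The counting keys are explicit because the tallies are meaningless
without them: a *unique source record* is a distinct (patient, domain,
sequence) triple; a *unique CDM record* is a distinct event row counted
after fan-out (which is why mapped CDM records can exceed source records
in a registry with few non-events); a *unique source value* is a distinct
(vocabulary, code-or-normalised-text) pair. Concept and CDM-record counts
include only rows emitted from the source code itself, not attachment
observations. Redundancy is reported to the whole percent, exclusion
percentages to one decimal, both half-up, matching how such tables are
conventionally printed; on very small studies fan-out can exceed
consolidation and redundancy is then reported as not applicable rather
than negative. The demographic consistency check recomputes age at
enrollment (enrollment year minus birth year — month-level precision
would claim more than a year-of-birth field supports) and the gender
distribution on both sides, flagging count differences exactly and mean
differences beyond 0.01.

## The synthetic generator

The generator emulates the *mechanics* of registry data, not the disease:
MedDRA-coded checklists with non-occurrence flags (prospective mode only;
retrospective charts record only conditions that occurred), WHODrug-coded
and free-text medications, partial and missing dates at configurable
rates, free-text dates in the recognised dialects, duplicate DM rows,
flagged violators, deliberately unmappable codes, and deaths recorded in
up to three conflicting sources. Lab values are uniform noise; clinical
plausibility of values and trajectories is explicitly out of scope, so
passing tests say nothing about statistical properties of real data —
only about the data mechanics the pipeline must survive.

Default rates (per written date: 10% missing day, 5% missing day+month,
2% fully missing; 50% checklist non-occurrence; 1% duplicates, 2%
violators, 8% deaths of which 30% multi-source, 10% free text) were
chosen once as representative of a multi-centre drug registry with a
retrospective-chart component — missingness concentrated at the day
level, non-occurrence dominating prospective checklists, and exclusions
in the low percent — and are not tuned thereafter. The fully-missing rate
also drives missing birth years, which is what produces
mapping-excluded patients.

Determinism uses one seeded substream per (patient, domain) with a fixed
field draw order inside each, so records for one patient never perturb
another's and identical config+seed give byte-identical files.

Every generated record carries a ledger row with its true date, fate and
expected resolution targets. `expected_qa()` recomputes the full QA
report from the ledger alone — pure arithmetic, independent of the
pipeline — and the test suite asserts exact agreement
("oracle closure") at 500 patients across three seeds in both designs,
alongside the no-silent-loss and byte-identical-rerun properties. The
500-patient scale was chosen as the package's standard validation size:
large enough that every rare pathway (conflicting death sources,
undatable records, combination fan-outs) is exercised many times per
run, small enough to keep the whole suite interactive. A dedicated test
pins the generator's dictionary to the bundled crosswalk, so the ledger's
expectations and the vocabulary fixture cannot drift apart.

## Known limitations

* The SDTM column conventions (`--PTCD` for codes, `--METHOD`, `--SRC`)
  are a documented house dialect with config overrides; real registry
  exports will need `var_overrides` or column renaming.
* WHODrug is represented only through the crosswalk; there are no
  WHODrug source concepts in the store, so `source_concept_id` is empty
  for drug records.
* Inverse relationship concepts in `FACT_RELATIONSHIP` mirrors are not
  modelled; both rows carry the same relationship id.
* Drug/condition era derivation, cost tables and visit detail are out of
  scope, as is any analysis of the mapped data.
* The bundled vocabulary is a ~70-concept miniature for self-contained
  operation and testing; production use requires a full Athena
  distribution in the same file layout.
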