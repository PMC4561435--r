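# radtex

Ontology-driven information extraction from narrative knee MRI reports.

Radiology reports describe the findings of an MRI scan in short, highly
regular free text: each clinically relevant statement pairs a **finding**
(tear, oedema, intact structure, ...) with the **anatomy** it affects
(meniscus, ligament, condyle, ...), plus qualifiers, certainty and negation.
radtex turns such text into structured, ontology-coded templates so that
collections of reports can be queried and used in epidemiologic studies of
knee pathology. It is a rule-based system driven by an OBO ontology: the
ontology's vocabulary powers soft dictionary matching and its is-a structure
powers semantic slot typing and finding/anatomy compatibility checks.

The core pieces:

* **Soft dictionary matching** (`match_dictionary()`): candidate token
  windows are scored with SoftTFIDF — a cosine-style TF-IDF similarity over
  one-to-one token pairs weighted by Jaro-Winkler similarity
  (`jaro_winkler()`, `soft_tfidf()`) — and resolved longest-match-first, so
  inflectional and typographical variants of ontology terms are still
  recognised.
* **Pattern rules** for coordination ("medial and lateral meniscus"),
  enumeration ("peripheral vertical longitudinal tear"), implicit anatomy
  ("medial meniscectomy"), and negation (*no*, *not*, *without*, *rather
  than*, with the "no further" exception).
* **Disambiguation**: hyponym coreference ("... the ligament is intact"),
  co-occurrence-based polysemy resolution ("rupture" of a cyst vs of a
  ligament), and pruning of nested quality mentions.
* **Two-pass clause segmentation** and **template filling** with qualifier
  linking through shallow noun-phrase structure, anatomy backtracking across
  segments, and filler sharing over "or".
* **Evaluation**: per-slot (vertical) and per-record (horizontal)
  micro-averaged precision/recall/F (`compare_records()`, `prf()`),
  chance-corrected inter-annotator agreement (`kappa()`,
  `agreement_from_annotations()`), and concept-ablation experiments
  (`run_ablation()`).
* **Synthetic fixtures**: a toy knee ontology and a deterministic report
  generator (`generate_corpus()`) that emits gold-annotated corpora with
  the documented shape of real reports (≈9.5 sentences and ≈111 tokens per
  report, 0.83 typos per document).

With precision `P = TP/(TP+FP)`, recall `R = TP/(TP+FN)` and
`F = 2PR/(P+R)`, slot fillers are compared at the conceptual level (by
ontology identifier) after aligning predicted and gold records on their
finding concepts; agreement uses `k = (Ao − Ae)/(1 − Ae)`.

## Worked example

```r
library(radtex)
cfg <- toy_pipeline_config()
res <- process_report(
  "There is a small undisplaced vertical radial tear of the posterior horn of the lateral meniscus.",
  cfg)
res$mentions[, c("text", "concept_id", "score", "source", "slot")]
#>               text   concept_id score           source              slot
#> 1            small  TOY:0000101     1       dictionary finding_qualifier
#> 2      undisplaced  TOY:0000112     1       dictionary finding_qualifier
#> 3      radial tear  TOY:0000158     1       dictionary           finding
#> 4   posterior horn  TOY:0000172     1       dictionary anatomy_qualifier
#> 5 lateral meniscus TRAK:0001089     1       dictionary           anatomy
#> 6         vertical TRAK:0001388     1 rule:enumeration           finding
cat(res$json)
```

The sentence yields one record: the finding is the matched compound *radial
tear*; "small" and "undisplaced" fill the finding-qualifier slot together
with the enumerated satellite *vertical tear* (anchored on "vertical");
"posterior horn" is linked as an anatomy qualifier of the *lateral meniscus*
anatomy through the "of the" noun-phrase pattern. The JSON carries, for every
filler, its text, 0-based start offset, length, concept id and preferred
name:

```json
{
  "finding": {"text": "radial tear", "start": 38, "offset": 11,
              "id": "TOY:0000158", "name": "radial tear"},
  "anatomy": {"text": "lateral meniscus", "start": 79, "offset": 16,
              "id": "TRAK:0001089", "name": "lateral meniscus"},
  ...
}
```

A thin command-line front end lives at `inst/cli/radtex.R`
(`extract`, `evaluate`, `simulate` subcommands).

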