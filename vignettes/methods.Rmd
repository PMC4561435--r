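---
title: "Ontology-driven template extraction from knee MRI reports: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ontology-driven template extraction from knee MRI reports: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radtex)
```

## The problem

Narrative knee MRI reports compress a radiologist's interpretation of a scan
into a handful of short, highly regular sentences. Each clinically relevant
statement pairs a *finding* (what was observed: a tear, oedema, an intact
structure) with the *anatomy* it affects (where: a meniscus, a ligament, a
condyle), possibly decorated with qualifiers, a certainty judgement and a
negation. radtex converts such free text into filled templates with six
slots — finding, finding qualifiers, negation, certainty, anatomy, anatomy
qualifiers — where every filler carries its extracted text, 0-based character
offset, length, an ontology concept identifier and the concept's preferred
name. Output is JSON, one record per observation.

The pipeline is ontology-driven and rule-based rather than statistical: a
domain ontology in OBO format supplies both the vocabulary (for recognising
mentions) and the is-a structure (for typing them into slots and checking
finding/anatomy compatibility). This exploits the regularity of the
sublanguage; no part-of-speech tagging or parsing is performed, and the only
syntactic analysis is a shallow noun-phrase pattern used to link anatomy
qualifiers to their anatomy.

## Pipeline stages

`process_report()` runs a fixed stage order:

1. **Tokenisation and sectioning.** Alphanumeric runs (hyphenated words and
   internal apostrophes kept whole) and single punctuation marks become
   tokens with exact character offsets. A maximal run of upper-case tokens
   drawn from a fifteen-token heading vocabulary — and confined to one line —
   is a section heading (scanner line, indication, history, findings,
   conclusion). Sentences break at final punctuation and around headings.

2. **Soft dictionary matching.** The ontology's names and synonyms are
   compiled into a matcher dictionary (`compile_dictionary()`), after
   applying overrides: whole branches holding composite terms (e.g. a class
   that bundles an anatomical entity with an injury) are not exported, since
   recognising their components separately is what makes slot filling
   direct; surface forms may be remapped to the concept they actually denote
   in this sublanguage; informal variants ("ruptured", "collaterals") are
   added as unofficial entries without polluting the ontology. Candidate
   token windows (up to six tokens, never crossing punctuation) are scored
   with SoftTFIDF: a cosine-style TF-IDF similarity over token pairs whose
   Jaro-Winkler similarity reaches an internal threshold θ, each pair
   weighted by that similarity. Pairing is one-to-one; see *Numerical
   choices*. Windows scoring at least the acceptance threshold become
   mentions, resolved longest-first so mentions never overlap.

3. **Pattern rules** (additive only): coordination ("medial and lateral
   meniscus" adds the sibling concept *medial meniscus* anchored on the
   modifier), enumeration (stacked modifiers of a matched compound such as
   "peripheral vertical longitudinal tear" add the corresponding sibling
   findings as satellites of the base compound), implicit anatomy (a
   derivation table maps "medial meniscectomy" to *medial meniscus*,
   "prepatellar bursitis" to *prepatellar bursa*), and negation cue
   detection (*no*, *not*, *without*, *rather than*; *no* is ignored inside
   the phrase "no further", which asserts a positive finding).

4. **Disambiguation.** Hyponym coreference: a mention of a hypernym trigger
   (meniscus, ligament, tendon) is retargeted to the nearest preceding
   mention of a strict descendant, across the whole preceding report text.
   Polysemy: co-occurrence rules fire within a sentence (the shipped rule
   reinterprets "rupture" from the injury reading to the morphologic one
   when any cyst descendant co-occurs). Nested pruning: a mention wholly
   contained in another's span is removed iff its concept descends from the
   quality branch; other nested mentions (true references, like a coordinated
   sibling) survive.

5. **Segmentation, two passes.** Pass one is lexical: history and conclusion
   sentences are comma-separated lists and split at commas; elsewhere a
   segment opens before each clue word (*but*, *which*, *consistent with*,
   *although*, *though*, *suggesting*, *in keeping with*). A clue inside a
   mention span never splits. Pass two is finding-aware and runs after slot
   typing: a segment splits at *and*/*with* iff both halves contain a
   finding candidate; *or* never splits because its fillers are shared.

6. **Template filling.** Mentions are typed into slots by their semantic
   ancestry (`semantic_slot()`), with one override: when cartilage co-occurs
   with other anatomy candidates in a segment, the others become anatomy
   qualifier candidates (the finding applies to the cartilage as object).
   A single-finding segment attaches all its fillers to the finding; a
   negation cue attaches only if it precedes the finding; anatomy qualifiers
   link to anatomy through the pattern ⟨qualifier⟩ (aspect|part|portion)?
   (of|to) (the)? ⟨anatomy⟩ or adjacency, falling back to the nearest
   anatomy. If a segment holds no anatomy and the finding is not
   self-contained, preceding segments are searched nearest-first for an
   anatomy passing the compatibility rules (a tear or rupture requires soft
   tissue). Two findings divide the remaining fillers at the end of the
   first finding, unless joined by *or*, in which case fillers are shared.

## Design choices at genuinely open points

Several behaviours were underdetermined and fixed as follows.

* **Enumerated compound findings produce one record.** For "small
  undisplaced vertical radial tear", the base compound (*radial tear*) fills
  the finding slot and the enumeration satellites (*vertical tear*) attach
  as finding qualifiers. The alternative — one record per enumerated tear
  type — would break the one-observation-one-record reading of such
  sentences and triple-count qualifiers.
* **One record per anatomy.** A segment whose single finding co-occurs with
  several anatomy candidates ("the medial and lateral meniscus are intact")
  emits one record per anatomy sharing the other fillers, because the
  template holds exactly one anatomy.
* **Cartilage override scope.** The cartilage/anatomy-qualifier
  co-occurrence rule is scoped to the clause-level segment, not the whole
  sentence: comma-separated conclusion lists routinely mention cartilage in
  one item and an unrelated bone in another, and sentence scope would
  cross-link them.
* **Coordination over "or"** is enabled by default (configurable): "medial
  or lateral meniscus" carries the same implicit sibling reference as the
  conjunctive form.
* **Self-contained findings** (no anatomical localisation required) cover
  Osgood-Schlatter disease plus the physical-examination and accident
  branches, whose members are intrinsically non-localised; the list is a
  configuration file.
* **Backtracking depth** for missing anatomy is unbounded within the report,
  nearest segment first, filtered by the compatibility table.
* **Certainty** is left absent when no cue is found rather than filled with
  an "asserted" pseudo-value, and negation and certainty attach
  independently when both precede a finding.
* **Unlinkable anatomy qualifiers** are kept on the record with a warning
  rather than dropped, favouring recall.

## Numerical choices

* Matching thresholds: acceptance threshold 0.90, internal Jaro-Winkler
  pairing threshold θ = 0.90, Winkler prefix scale 0.1, maximum window six
  tokens. The thresholds follow the SoftTFIDF literature convention and are
  exposed in `match_config()`. At these values the morphological variants
  seen in the sublanguage ("lateral menisci" for *lateral meniscus*) score
  above threshold while unrelated windows stay far below it.
* **One-to-one pairing in SoftTFIDF.** Classic formulations let every
  phrase token pair with its closest entry token, reusing entry tokens. With
  single-token entries this degenerates: the window "patella and the
  patellar" outscores the true compound *patellar tendon* against the entry
  "patella", because both "patella" and "patellar" consume the same entry
  token. radtex therefore pairs tokens one-to-one, greedily from the most
  similar pair down. Identical token sequences score exactly 1, which also
  realises the exact-name guarantee.
* IDF reference collection: the dictionary entries themselves, one document
  per entry; tokens unseen in the dictionary receive the maximal weight
  `log(N)`. Token weights are `(1 + log tf) · idf`, L2-normalised.
* Ties between concepts scoring equally on one span prefer official entries
  over informal additions, then the lexicographically smaller identifier,
  making extraction deterministic. Overlap resolution orders candidates by
  span length (longest first), then start position, then score.
* Percentages are rounded half-up to two decimals; the reported F-measure is
  computed from the rounded precision and recall, which is how such tables
  are conventionally printed. Raw-precision values are kept alongside. A
  metric with a zero denominator is reported as not applicable (`NA`),
  never as zero.

## The synthetic corpus: what it does and does not show

Real knee MRI reports are confidential and cannot ship with the package, so
`generate_corpus()` builds reports from a sentence grammar over the toy
ontology's surface forms. The defaults reproduce the documented shape of the
real data: a mean of 9.53 sentences and 110.81 tokens per report and 0.83
typographical errors per document, alongside sectioned structure
(scanner-line, optional indication, history list, findings, conclusion
list), qualifier chains, the four negation cues with the "no further"
exception, coordinated siblings, enumerated tear compounds, two-finding
statements, *or*-sharing, and anatomy backtracking pairs. Gold templates are
derived from the generation-time choices, never from the pipeline, so
end-to-end recovery is a genuine correctness check: on a zero-perturbation
corpus the pipeline must reproduce the gold exactly (F = 1.0). Typos are
injected as single-character substitutions that keep all offsets valid and,
by default, avoid gold filler spans and function words the rules depend on.

What passing these checks does *not* show: robustness to radiologist style
variation beyond the grammar's constructions, to misspelled domain terms
(exercised separately via `typos_in_spans = TRUE` and the soft matcher's
unit tests), to section layouts outside the heading vocabulary, or to
vocabulary missing from the ontology — the ablation experiment
(`run_ablation()`) quantifies exactly that last failure mode, and recall
degrades monotonically as concepts are removed from the dictionary.

Problem sizes used by the shipped checks: 200 synthetic reports for
end-to-end recovery, 60 reports for the ablation grid k ∈ {0, 10, …, 50}
over 50 removable concepts, 20 random sentences for the brute-force matcher
oracle, 120 reports for the corpus-shape statistics.

## Known limitations

* Soft matching trades precision for recall by design: at permissive
  thresholds "patella tends" is confused with *patellar tendon* (the
  regression suite pins this behaviour down).
* Negation cues are assumed to precede their finding; a sentence-final
  "absent" is not recognised.
* Coreference fires only on bare hypernym triggers: the modifier inside
  "meniscal cyst" is not resolved to a previously named meniscus.
* The Mixup-style rule layer implements the four documented rule families
  behaviourally, not a reimplementation of any particular rule inventory;
  the derivation, co-occurrence, compatibility and self-contained tables are
  deliberately small and user-extensible TSVs.
* Horizontal (whole-record) evaluation aligns records greedily by finding
  concept and nearest span; no optimal assignment is attempted.

## A worked example

```{r example}
cfg <- toy_pipeline_config()
res <- process_report(
  "There is a small undisplaced vertical radial tear of the posterior horn of the lateral meniscus.",
  cfg)
res$mentions[, c("text", "concept_id", "score", "source", "slot")]
cat(to_json(res$records, pretty = TRUE))
```
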