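#' Toy knee ontology as OBO text
#'
#' A ~100-concept miniature of the knee-domain taxonomy, sufficient to run
#' every worked example: meniscus/ligament/tendon/bone anatomy, the quality
#' branch with all descriptor classes, findings (injuries, cysts, effusions,
#' surgery, physical examinations, accidents), meniscus zones and general
#' anatomical terms. Where an identifier for a concept has been published
#' the published `TRAK:` id is reused so examples are citable; fixture-local
#' concepts use a `TOY:` namespace.
#'
#' @return Character scalar: the OBO document.
#' @export
build_toy_ontology <- function() {
  path <- system.file("extdata", "toy_knee.obo", package = "radtex",
                      mustWork = TRUE)
  paste(readLines(path, warn = FALSE, encoding = "UTF-8"), collapse = "\n")
}

#' Parsed toy ontology
#' @return An `ontology`.
#' @export
toy_ontology <- function() {
  parse_obo(build_toy_ontology())
}

#' Dictionary overrides shipped with the toy ontology
#'
#' Mirrors the override families the extraction approach relies on: the
#' composite "ACL rupture" branch is not exported; "joint effusion" is
#' remapped to knee effusion; informal variants (ruptured, meniscal,
#' collaterals, tib-fib joint, subluxed, torn) are added as unofficial
#' entries.
#' @return A `dict_overrides`.
#' @export
toy_overrides <- function() {
  read_overrides(system.file("extdata", "toy_overrides.tsv",
                             package = "radtex", mustWork = TRUE))
}

#' Pipeline configuration for the toy fixture
#'
#' @param ... Overrides passed through to [pipeline_config()] (e.g.
#'   `match`, `rules_enabled`).
#' @return A `pipeline_config` wired to the shipped toy ontology, override,
#'   derivation, co-occurrence, compatibility and self-contained tables,
#'   with the cartilage branch registered for the anatomy-qualifier
#'   co-occurrence rule.
#' @export
toy_pipeline_config <- function(...) {
  ext <- function(f) system.file("extdata", f, package = "radtex",
                                 mustWork = TRUE)
  args <- list(...)
  base <- list(
    ontology = toy_ontology(),
    overrides = toy_overrides(),
    derivation_table = ext("toy_derivations.tsv"),
    cooccurrence_rules = ext("toy_cooccurrence.tsv"),
    compatibility_rules = ext("toy_compatibility.tsv"),
    self_contained = ext("toy_self_contained.tsv"),
    cartilage_id = "TOY:0000017")
  base[names(args)] <- args
  do.call(pipeline_config, base)
}

#' Worked-example corpus
#'
#' The printed example sentences of the knee MRI sublanguage, each paired
#' with the behaviour the pipeline must show on it: mentions added or
#' retargeted, negation marks, segment counts, and filled-template content.
#' Fields of `expect` (all optional): `mentions_include` (data.frame
#' `text`/`concept_id`), `mentions_absent` (concept ids that must not
#' survive), `negation_cues` (character vector, possibly empty),
#' `n_segments`, `records` (list of partial record specs with any of
#' `finding_id`, `negated`, `anatomy_id`, `anatomy_text`, `fq_ids`,
#' `aq_ids`, `certainty_id`).
#'
#' @return List of cases: `name`, `text`, `expect`.
#' @export
worked_examples <- function() {
  list(
    list(name = "composite term split into anatomy and finding",
         text = "HISTORY Twisting injury, ACL rupture and medial meniscal tear.",
         expect = list(
           mentions_include = data.frame(
             text = c("ACL", "rupture"),
             concept_id = c("TRAK:0000049", "TRAK:0000211")),
           mentions_absent = "TRAK:0000513",
           n_segments = 3,
           records = list(
             list(finding_id = "TOY:0000156", negated = FALSE),
             list(finding_id = "TRAK:0000211", anatomy_id = "TRAK:0000049",
                  negated = FALSE),
             list(finding_id = "TOY:0000157", anatomy_id = "TRAK:0001090",
                  negated = FALSE)))),
    list(name = "coordination: medial and lateral meniscus",
         text = "There is some peripheral signal in both the medial and lateral meniscus posteriorly.",
         expect = list(
           mentions_include = data.frame(
             text = c("medial", "lateral meniscus"),
             concept_id = c("TRAK:0001090", "TRAK:0001089")),
           mentions_absent = "TRAK:0000031")),
    list(name = "coordination: cruciate and collateral ligaments",
         text = "The cruciate and collateral ligaments are intact.",
         expect = list(
           mentions_include = data.frame(
             text = c("cruciate", "collateral ligaments"),
             concept_id = c("TOY:0000013", "TOY:0000011")),
           n_segments = 1,
           records = list(
             list(finding_id = "TOY:0000123", anatomy_id = "TOY:0000013"),
             list(finding_id = "TOY:0000123", anatomy_id = "TOY:0000011")))),
    list(name = "enumeration: tiny peripheral vertical longitudinal tear",
         text = "This possibly represents a tiny peripheral vertical longitudinal tear.",
         expect = list(
           mentions_include = data.frame(
             text = c("vertical", "peripheral", "longitudinal tear"),
             concept_id = c("TRAK:0001388", "TRAK:0001389", "TRAK:0001390")),
           mentions_absent = c("TRAK:0000077", "TOY:0000141"),
           records = list(
             list(finding_id = "TRAK:0001390", negated = FALSE,
                  certainty_id = "TOY:0000119")))),
    list(name = "enumeration: small undisplaced vertical radial tear",
         text = "There is a small undisplaced vertical radial tear of the posterior horn of the lateral meniscus.",
         expect = list(
           mentions_include = data.frame(
             text = c("vertical", "radial tear"),
             concept_id = c("TRAK:0001388", "TOY:0000158")),
           mentions_absent = "TRAK:0000077",
           records = list(
             list(finding_id = "TOY:0000158", negated = FALSE,
                  anatomy_id = "TRAK:0001089",
                  fq_ids = c("TOY:0000101", "TOY:0000112", "TRAK:0001388"),
                  aq_ids = "TOY:0000172")))),
    list(name = "equivalent zone phrases map to one concept",
         text = "A peripheral tear involving the body of the lateral meniscus extending into the posterior third is seen.",
         expect = list(
           mentions_include = data.frame(
             text = c("body", "posterior third"),
             concept_id = c("TRAK:0001346", "TOY:0000172")))),
    list(name = "implicit anatomy: medial meniscectomy",
         text = "He has previously undergone medial meniscectomy.",
         expect = list(
           mentions_include = data.frame(
             text = c("medial", "meniscectomy"),
             concept_id = c("TRAK:0001090", "TRAK:0001511")),
           mentions_absent = "TRAK:0000031",
           records = list(
             list(finding_id = "TRAK:0001511", anatomy_id = "TRAK:0001090")))),
    list(name = "implicit anatomy: prepatellar bursitis",
         text = "There is prepatellar bursitis.",
         expect = list(
           mentions_include = data.frame(
             text = c("prepatellar", "bursitis"),
             concept_id = c("TRAK:0001054", "TRAK:0000225")),
           records = list(
             list(finding_id = "TRAK:0000225", anatomy_id = "TRAK:0001054")))),
    list(name = "implicit anatomy: patellar tendinitis",
         text = "Appearances are consistent with patellar tendinitis.",
         expect = list(
           mentions_include = data.frame(
             text = c("patellar", "tendinitis"),
             concept_id = c("TRAK:0000053", "TRAK:0000229")))),
    list(name = "bursitis alone adds no anatomy",
         text = "There is bursitis.",
         expect = list(
           mentions_absent = "TRAK:0001054",
           records = list(list(finding_id = "TRAK:0000225")))),
    list(name = "negation: no",
         text = "No bone marrow lesion identified.",
         expect = list(
           negation_cues = "No",
           records = list(list(finding_id = "TOY:0000152",
                               negated = TRUE)))),
    list(name = "negation: not",
         text = "His patella lies tilted laterally though it has not subluxed.",
         expect = list(
           negation_cues = "not",
           n_segments = 2,
           records = list(
             list(finding_id = "TOY:0000129", negated = FALSE),
             list(finding_id = "TOY:0000164", negated = TRUE)))),
    list(name = "negation: without",
         text = "There is general attenuation of the body of the medial meniscus without a discrete tear.",
         expect = list(
           negation_cues = "without",
           records = list(
             list(finding_id = "TOY:0000128", negated = FALSE),
             list(finding_id = "TOY:0000157", negated = TRUE,
                  anatomy_id = "TRAK:0001090", aq_ids = "TRAK:0001346")))),
    list(name = "negation: rather than",
         text = "This represents residual vascularity rather than a tear.",
         expect = list(
           negation_cues = "rather than",
           records = list(list(finding_id = "TOY:0000157",
                               negated = TRUE)))),
    list(name = "no-further exception keeps the finding positive",
         text = "There is no further cartilage defect.",
         expect = list(
           negation_cues = character(),
           records = list(list(finding_id = "TOY:0000163",
                               negated = FALSE)))),
    list(name = "hyponym coreference: the ligament is intact",
         text = "There is oedema superficial to the medial collateral ligament consistent with a sprain but the ligament is intact.",
         expect = list(
           mentions_include = data.frame(
             text = c("medial collateral ligament", "ligament"),
             concept_id = c("TRAK:0000051", "TRAK:0000051")),
           n_segments = 3)),
    list(name = "hyponym without antecedent stays general",
         text = "The menisci are intact.",
         expect = list(
           mentions_include = data.frame(
             text = "menisci", concept_id = "TRAK:0000045"),
           records = list(list(finding_id = "TOY:0000123",
                               anatomy_id = "TRAK:0000045")))),
    list(name = "polysemy: rupture of the popliteal cyst",
         text = "There is oedema in the soft tissues suggesting rupture of the popliteal cyst.",
         expect = list(
           mentions_include = data.frame(
             text = c("rupture", "popliteal cyst"),
             concept_id = c("TRAK:0001461", "TRAK:0000222")))),
    list(name = "polysemy: rupture of the MCL stays an injury",
         text = "There is grade 3 rupture of the MCL.",
         expect = list(
           mentions_include = data.frame(
             text = "rupture", concept_id = "TRAK:0000211"),
           records = list(list(finding_id = "TRAK:0000211",
                               anatomy_id = "TRAK:0000051")))),
    list(name = "history list splits at commas",
         text = "HISTORY Twisting injury, tender medial joint line, positive McMurray's.",
         expect = list(n_segments = 3)),
    list(name = "lexical clues split findings sentences",
         text = "There is oedema in the soft tissues at the posterolateral corner but the popliteal tendon is intact consistent with a sprain.",
         expect = list(n_segments = 3)),
    list(name = "finding-aware split at and",
         text = "There is no oedema in the lateral femoral condyle and the ACL is intact.",
         expect = list(
           n_segments = 2,
           records = list(
             list(finding_id = "TOY:0000150", negated = TRUE,
                  anatomy_id = "TRAK:0001037"),
             list(finding_id = "TOY:0000123", negated = FALSE,
                  anatomy_id = "TRAK:0000049")))),
    list(name = "cartilage co-occurrence claims the anatomy slot",
         text = "There is early fissuring of the hyaline cartilage of the lateral patellar facet.",
         expect = list(
           records = list(
             list(finding_id = "TOY:0000130", anatomy_id = "TOY:0000018",
                  aq_ids = "TOY:0000029")))),
    list(name = "noun-phrase linking of anatomy qualifiers",
         text = "There is marrow oedema at the medial aspect of the patella and the lateral aspect of the lateral femoral condyle.",
         expect = list(
           records = list(
             list(finding_id = "TOY:0000150", anatomy_id = "TOY:0000022",
                  aq_ids = "TRAK:0000031"),
             list(finding_id = "TOY:0000150", anatomy_id = "TRAK:0001037",
                  aq_ids = "TOY:0000135")))),
    list(name = "anatomy backtracking across sentences",
         text = "There is a vertical longitudinal tear of the peripheral aspect of the posterior third of the medial meniscus. The tear does not appear significant.",
         expect = list(
           records = list(
             list(finding_id = "TRAK:0001390", anatomy_id = "TRAK:0001090"),
             list(finding_id = "TOY:0000157", anatomy_id = "TRAK:0001090",
                  negated = FALSE)))),
    list(name = "run-on history divides fillers at the finding boundary",
         text = "HISTORY Lateral joint line tenderness meniscal tear.",
         expect = list(
           records = list(
             list(finding_id = "TOY:0000151", anatomy_id = "TOY:0000028"),
             list(finding_id = "TOY:0000157", anatomy_id = "TRAK:0000045")))),
    list(name = "or shares fillers between findings",
         text = "There is bone bruising or subchondral marrow oedema at the inferior patella.",
         expect = list(
           records = list(
             list(finding_id = "TOY:0000154", anatomy_id = "TOY:0000022",
                  aq_ids = "TOY:0000137"),
             list(finding_id = "TOY:0000150", anatomy_id = "TOY:0000022",
                  aq_ids = "TOY:0000137")))),
    list(name = "informal verb form maps to the injury concept",
         text = "The ACL appears chronically ruptured.",
         expect = list(
           mentions_include = data.frame(
             text = "ruptured", concept_id = "TRAK:0000211"),
           records = list(list(finding_id = "TRAK:0000211",
                               anatomy_id = "TRAK:0000049"))))
  )
}
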