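#' Configuration for the synthetic report generator
#'
#' Defaults emulate the shape of real knee MRI reports: short sectioned
#' documents averaging 9.53 sentences and 110.81 tokens, a finding/anatomy
#' sublanguage with qualifier chains, negation, coordinated and enumerated
#' terms, and a low typographical error rate of 0.83 errors per document.
#'
#' @param n_reports Number of reports.
#' @param seed Integer seed; the corpus is deterministic given the config.
#' @param mean_sentences,sd_sentences Target per-report sentence count.
#' @param mean_tokens,sd_tokens Target per-report token count.
#' @param p_negation Probability that an eligible statement is negated.
#' @param p_no_further Probability that a negated statement instead uses the
#'   positive "no further" construction.
#' @param p_coordination,p_enumeration,p_two_finding,p_or,p_backtrack
#'   Weights of the corresponding sentence constructions among findings
#'   sentences.
#' @param qualifier_probs Probabilities of 0, 1, 2 finding qualifiers.
#' @param typo_rate Mean typographical errors per document (Poisson).
#' @param typos_in_spans When `TRUE`, typos may corrupt gold filler words
#'   (exercising soft matching); by default they only touch filler-free
#'   function words so that zero-noise recovery is exact.
#' @param p_indication Probability of an INDICATION section.
#' @return List of class `corpus_config`.
#' @export
corpus_config <- function(n_reports = 100, seed = 42,
                          mean_sentences = 9.53, sd_sentences = 5.13,
                          mean_tokens = 110.81, sd_tokens = 64.60,
                          p_negation = 0.22, p_no_further = 0.15,
                          p_coordination = 0.08, p_enumeration = 0.08,
                          p_two_finding = 0.12, p_or = 0.06,
                          p_backtrack = 0.06,
                          qualifier_probs = c(0.25, 0.50, 0.25),
                          typo_rate = 0.83, typos_in_spans = FALSE,
                          p_indication = 0.35) {
  rates <- c(p_negation, p_no_further, p_coordination, p_enumeration,
             p_two_finding, p_or, p_backtrack, p_indication)
  stopifnot(all(rates >= 0), all(rates <= 1), n_reports >= 0,
            abs(sum(qualifier_probs) - 1) < 1e-9)
  structure(as.list(environment()), class = "corpus_config")
}

# ---- vocabulary pools (surfaces must be dictionary entries) ----------------

.POOL <- list(
  soft_anat = list(
    c("TRAK:0001089", "lateral meniscus"), c("TRAK:0001090", "medial meniscus"),
    c("TRAK:0000051", "medial collateral ligament"), c("TRAK:0000051", "MCL"),
    c("TRAK:0000049", "ACL"), c("TRAK:0000049", "anterior cruciate ligament"),
    c("TOY:0000014", "PCL"), c("TRAK:0000053", "patellar tendon"),
    c("TOY:0000015", "popliteal tendon")),
  bone_anat = list(
    c("TOY:0000022", "patella"), c("TOY:0000023", "tibia"),
    c("TRAK:0001037", "lateral femoral condyle"),
    c("TOY:0000021", "medial femoral condyle")),
  cart_anat = list(c("TOY:0000018", "hyaline cartilage")),
  menisci = list(
    c("TRAK:0001089", "lateral meniscus"), c("TRAK:0001090", "medial meniscus")),
  zone_aq = list(
    c("TOY:0000172", "posterior horn"), c("TOY:0000172", "posterior third"),
    c("TOY:0000173", "anterior horn"), c("TRAK:0001346", "body")),
  loc_aq = list(
    c("TRAK:0000031", "medial"), c("TOY:0000135", "lateral"),
    c("TOY:0000137", "inferior"), c("TOY:0000138", "superior")),
  patho = list(
    c("TOY:0000157", "tear"), c("TRAK:0000211", "rupture"),
    c("TOY:0000160", "sprain")),
  general = list(
    c("TOY:0000150", "oedema"), c("TOY:0000153", "swelling"),
    c("TOY:0000152", "lesion"), c("TOY:0000163", "defect"),
    c("TOY:0000166", "chondromalacia"), c("TRAK:0001411", "joint effusion")),
  fq = list(
    c("TOY:0000101", "small"), c("TOY:0000102", "large"),
    c("TOY:0000103", "tiny"), c("TOY:0000115", "acute"),
    c("TOY:0000116", "chronic"), c("TOY:0000111", "severe"),
    c("TOY:0000114", "mild"), c("TOY:0000106", "focal"),
    c("TOY:0000107", "diffuse")),
  norm = list(
    c("TOY:0000123", "intact"), c("TOY:0000124", "unremarkable"),
    c("TOY:0000125", "normal")),
  tear_mods = list(
    c("TRAK:0001388", "vertical"), c("TRAK:0001389", "peripheral"),
    c("TOY:0000158", "radial"), c("TRAK:0001390", "longitudinal")),
  tear_base = list(
    c("TOY:0000158", "radial tear"), c("TRAK:0001390", "longitudinal tear"),
    c("TRAK:0001388", "vertical tear")))

.pick <- function(pool) pool[[sample.int(length(pool), 1)]]
.tail <- function() {
  sample(c("at this level", "on these images", "as described previously",
           "at the time of this study"), 1, prob = c(0.2, 0.2, 0.25, 0.35))
}
.tail2 <- function() {
  sample(c(", unchanged from the previous study",
           ", better appreciated on these images"), 1)
}
.art <- function(word) if (grepl("^[aeiou]", word)) "an" else "a"

# ---- sentence builder ------------------------------------------------------

.sb <- function() list(pieces = list(), nrec = 0L)

.p <- function(sb, text, fills = NULL, pre = " ") {
  sb$pieces[[length(sb$pieces) + 1L]] <- list(text = text, fills = fills,
                                              pre = pre)
  sb
}

.fill <- function(rec, slot, id) list(list(rec = rec, slot = slot, id = id))

.fills <- function(...) do.call(c, list(...))

.end <- function(sb) .p(sb, ".", pre = "")

.fq_chain <- function(sb, rec, n) {
  for (i in seq_len(n)) {
    fq <- .pick(.POOL$fq)
    sb <- .p(sb, fq[2], .fill(rec, "finding_qualifier", fq[1]))
  }
  sb
}

.n_quals <- function(cfg) sample.int(3, 1, prob = cfg$qualifier_probs) - 1L

# every .gen_* returns a builder whose record indices are local (1..nrec)

.gen_plain_patho <- function(cfg) {
  sb <- .sb(); sb$nrec <- 1L
  anat <- .pick(.POOL$soft_anat)
  pf <- .pick(.POOL$patho)
  neg <- stats::runif(1) < cfg$p_negation
  sb <- .p(sb, "There is", pre = "")
  if (stats::runif(1) < 0.4) sb <- .p(sb, "evidence of")
  if (neg) {
    # "evidence of no tear" reads badly; drop the padding again
    if (sb$pieces[[length(sb$pieces)]]$text == "evidence of") {
      sb$pieces <- sb$pieces[-length(sb$pieces)]
    }
    if (stats::runif(1) < cfg$p_no_further) {
      sb <- .p(sb, "no further")
    } else {
      sb <- .p(sb, "no", .fill(1, "negation", ""))
    }
    sb <- .p(sb, pf[2], .fill(1, "finding", pf[1]))
  } else {
    nq <- .n_quals(cfg)
    fqs <- sample(.POOL$fq, nq)
    lead <- if (nq > 0) fqs[[1]][2] else pf[2]
    sb <- .p(sb, .art(lead))
    for (fq in fqs) sb <- .p(sb, fq[2], .fill(1, "finding_qualifier", fq[1]))
    sb <- .p(sb, pf[2], .fill(1, "finding", pf[1]))
  }
  sb <- .p(sb, "of the")
  if (anat[1] %in% c("TRAK:0001089", "TRAK:0001090")) {
    if (stats::runif(1) < 0.7) {
      z <- .pick(.POOL$zone_aq)
      sb <- .p(sb, z[2], .fill(1, "anatomy_qualifier", z[1]))
      sb <- .p(sb, "of the")
    }
  } else if (stats::runif(1) < 0.5) {
    loc <- .pick(.POOL$loc_aq)
    sb <- .p(sb, loc[2], .fill(1, "anatomy_qualifier", loc[1]))
    sb <- .p(sb, "aspect of the")
  }
  sb <- .p(sb, anat[2], .fill(1, "anatomy", anat[1]))
  if (stats::runif(1) < 0.8) sb <- .p(sb, .tail())
  if (stats::runif(1) < 0.65) sb <- .p(sb, .tail2(), pre = "")
  .end(sb)
}

.gen_plain_general <- function(cfg) {
  sb <- .sb(); sb$nrec <- 1L
  anat <- .pick(c(.POOL$bone_anat, .POOL$soft_anat, .POOL$cart_anat))
  gf <- .pick(.POOL$general)
  neg <- stats::runif(1) < cfg$p_negation
  sb <- .p(sb, "There is", pre = "")
  if (!neg && stats::runif(1) < 0.4) sb <- .p(sb, "evidence of")
  if (neg) {
    sb <- .p(sb, "no", .fill(1, "negation", ""))
    sb <- .p(sb, gf[2], .fill(1, "finding", gf[1]))
  } else {
    nq <- .n_quals(cfg)
    fqs <- sample(.POOL$fq, nq)
    for (fq in fqs) sb <- .p(sb, fq[2], .fill(1, "finding_qualifier", fq[1]))
    sb <- .p(sb, gf[2], .fill(1, "finding", gf[1]))
  }
  sb <- .p(sb, "in the")
  if (stats::runif(1) < 0.4 && !(anat[1] %in% "TOY:0000018")) {
    loc <- .pick(.POOL$loc_aq)
    sb <- .p(sb, loc[2], .fill(1, "anatomy_qualifier", loc[1]))
    sb <- .p(sb, "aspect of the")
  }
  sb <- .p(sb, anat[2], .fill(1, "anatomy", anat[1]))
  if (stats::runif(1) < 0.8) sb <- .p(sb, .tail())
  if (stats::runif(1) < 0.65) sb <- .p(sb, .tail2(), pre = "")
  .end(sb)
}

.gen_normality <- function(cfg) {
  sb <- .sb(); sb$nrec <- 1L
  anat <- .pick(c(.POOL$bone_anat, .POOL$soft_anat, .POOL$cart_anat))
  nm <- .pick(.POOL$norm)
  sb <- .p(sb, "The", pre = "")
  sb <- .p(sb, anat[2], .fill(1, "anatomy", anat[1]))
  u <- stats::runif(1)
  if (u < cfg$p_negation) {
    sb <- .p(sb, "is")
    sb <- .p(sb, "not", .fill(1, "negation", ""))
    sb <- .p(sb, nm[2], .fill(1, "finding", nm[1]))
  } else if (u < cfg$p_negation + 0.3) {
    sb <- .p(sb, "appears", .fill(1, "certainty", "TOY:0000122"))
    sb <- .p(sb, nm[2], .fill(1, "finding", nm[1]))
  } else {
    sb <- .p(sb, "is")
    sb <- .p(sb, nm[2], .fill(1, "finding", nm[1]))
  }
  if (stats::runif(1) < 0.8) sb <- .p(sb, .tail())
  .end(sb)
}

.gen_two_finding <- function(cfg) {
  sb <- .sb(); sb$nrec <- 2L
  a1 <- .pick(c(.POOL$bone_anat, .POOL$soft_anat))
  a2 <- .pick(c(.POOL$bone_anat, .POOL$soft_anat))
  gf <- .pick(.POOL$general)
  nm <- .pick(.POOL$norm)
  neg <- stats::runif(1) < 0.6
  sb <- .p(sb, "There is", pre = "")
  if (neg) sb <- .p(sb, "no", .fill(1, "negation", ""))
  sb <- .p(sb, gf[2], .fill(1, "finding", gf[1]))
  sb <- .p(sb, "in the")
  if (stats::runif(1) < 0.5) {
    loc <- .pick(.POOL$loc_aq)
    sb <- .p(sb, loc[2], .fill(1, "anatomy_qualifier", loc[1]))
    sb <- .p(sb, "aspect of the")
  }
  sb <- .p(sb, a1[2], .fill(1, "anatomy", a1[1]))
  sb <- .p(sb, "and the")
  sb <- .p(sb, a2[2], .fill(2, "anatomy", a2[1]))
  sb <- .p(sb, "is")
  sb <- .p(sb, nm[2], .fill(2, "finding", nm[1]))
  if (stats::runif(1) < 0.6) sb <- .p(sb, .tail())
  .end(sb)
}

.gen_or_share <- function(cfg) {
  sb <- .sb(); sb$nrec <- 2L
  anat <- .pick(.POOL$bone_anat)
  gs <- sample(.POOL$general, 2)
  with_loc <- stats::runif(1) < 0.5
  sb <- .p(sb, "There is", pre = "")
  sb <- .p(sb, gs[[1]][2], .fill(1, "finding", gs[[1]][1]))
  sb <- .p(sb, "or")
  sb <- .p(sb, gs[[2]][2], .fill(2, "finding", gs[[2]][1]))
  sb <- .p(sb, "at the")
  if (with_loc) {
    loc <- .pick(.POOL$loc_aq)
    sb <- .p(sb, loc[2], .fills(.fill(1, "anatomy_qualifier", loc[1]),
                                .fill(2, "anatomy_qualifier", loc[1])))
    # a bare qualifier right before a multi-token anatomy name invites a
    # spurious longest match; insert the "aspect of" construction instead
    if (grepl(" ", anat[2], fixed = TRUE)) {
      sb <- .p(sb, "aspect of the")
    }
  }
  sb <- .p(sb, anat[2], .fills(.fill(1, "anatomy", anat[1]),
                               .fill(2, "anatomy", anat[1])))
  if (stats::runif(1) < 0.6) sb <- .p(sb, .tail())
  .end(sb)
}

.gen_coordination <- function(cfg) {
  sb <- .sb(); sb$nrec <- 2L
  kind <- sample.int(3, 1)
  if (kind == 1) {      # the medial and lateral meniscus are intact
    nm <- .pick(.POOL$norm)
    sb <- .p(sb, "The", pre = "")
    sb <- .p(sb, "medial", .fill(1, "anatomy", "TRAK:0001090"))
    sb <- .p(sb, "and")
    sb <- .p(sb, "lateral meniscus", .fill(2, "anatomy", "TRAK:0001089"))
    sb <- .p(sb, "are")
    sb <- .p(sb, nm[2], .fills(.fill(1, "finding", nm[1]),
                               .fill(2, "finding", nm[1])))
  } else if (kind == 2) {  # the cruciate and collateral ligaments are intact
    nm <- .pick(.POOL$norm)
    sb <- .p(sb, "The", pre = "")
    sb <- .p(sb, "cruciate", .fill(1, "anatomy", "TOY:0000013"))
    sb <- .p(sb, "and")
    sb <- .p(sb, "collateral ligaments", .fill(2, "anatomy", "TOY:0000011"))
    sb <- .p(sb, "are")
    sb <- .p(sb, nm[2], .fills(.fill(1, "finding", nm[1]),
                               .fill(2, "finding", nm[1])))
  } else {               # there is oedema in both the medial and lateral meniscus
    gf <- .pick(.POOL$general)
    sb <- .p(sb, "There is", pre = "")
    sb <- .p(sb, gf[2], .fills(.fill(1, "finding", gf[1]),
                               .fill(2, "finding", gf[1])))
    sb <- .p(sb, "in both the")
    sb <- .p(sb, "medial", .fill(1, "anatomy", "TRAK:0001090"))
    sb <- .p(sb, "and")
    sb <- .p(sb, "lateral meniscus", .fill(2, "anatomy", "TRAK:0001089"))
  }
  if (stats::runif(1) < 0.6) sb <- .p(sb, .tail())
  .end(sb)
}

.gen_enumeration <- function(cfg) {
  sb <- .sb(); sb$nrec <- 1L
  base <- .pick(.POOL$tear_base)
  mod <- .pick(.POOL$tear_mods)
  while (mod[1] == base[1]) mod <- .pick(.POOL$tear_mods)
  anat <- .pick(.POOL$menisci)
  fq <- .pick(.POOL$fq)
  sb <- .p(sb, "There is", pre = "")
  sb <- .p(sb, .art(fq[2]))
  sb <- .p(sb, fq[2], .fill(1, "finding_qualifier", fq[1]))
  sb <- .p(sb, mod[2], .fill(1, "finding_qualifier", mod[1]))
  sb <- .p(sb, base[2], .fill(1, "finding", base[1]))
  sb <- .p(sb, "of the")
  if (stats::runif(1) < 0.7) {
    z <- .pick(.POOL$zone_aq)
    sb <- .p(sb, z[2], .fill(1, "anatomy_qualifier", z[1]))
    sb <- .p(sb, "of the")
  }
  sb <- .p(sb, anat[2], .fill(1, "anatomy", anat[1]))
  if (stats::runif(1) < 0.6) sb <- .p(sb, .tail())
  if (stats::runif(1) < 0.65) sb <- .p(sb, .tail2(), pre = "")
  .end(sb)
}

# returns a list of TWO builders (a sentence pair)
.gen_backtrack <- function(cfg) {
  a <- .sb(); a$nrec <- 1L
  anat <- .pick(.POOL$soft_anat)
  fq <- .pick(.POOL$fq)
  a <- .p(a, "There is", pre = "")
  a <- .p(a, .art(fq[2]))
  a <- .p(a, fq[2], .fill(1, "finding_qualifier", fq[1]))
  a <- .p(a, "tear", .fill(1, "finding", "TOY:0000157"))
  a <- .p(a, "of the")
  a <- .p(a, anat[2], .fill(1, "anatomy", anat[1]))
  a <- .end(a)
  b <- .sb(); b$nrec <- 1L
  b <- .p(b, "The", pre = "")
  b <- .p(b, "tear", .fill(1, "finding", "TOY:0000157"))
  b <- .p(b, "does not")
  b <- .p(b, "appear", .fill(1, "certainty", "TOY:0000122"))
  b <- .p(b, "significant", .fill(1, "finding_qualifier", "TOY:0000113"))
  b <- .p(b, "on these images")
  b <- .end(b)
  # record 1 of sentence B inherits the anatomy mention from sentence A
  attr(b, "inherit_anatomy_from") <- anat
  list(a, b)
}

# summary statement whose anatomy (if any) comes from the most recent
# preceding anatomy mention; `last_anat` is c(id, surface) or NULL
.gen_remainder <- function(cfg, last_anat) {
  sb <- .sb(); sb$nrec <- 1L
  nm <- .pick(.POOL$norm)
  sb <- .p(sb, "The remainder of the examination is", pre = "")
  sb <- .p(sb, nm[2], .fill(1, "finding", nm[1]))
  if (stats::runif(1) < 0.5) sb <- .p(sb, "at this level")
  if (!is.null(last_anat)) attr(sb, "inherit_anatomy_from") <- last_anat
  sb
  .end(sb)
}

# last anatomy filler surface of a builder, or NULL
.last_anat_of <- function(sb) {
  inherited <- attr(sb, "inherit_anatomy_from")
  out <- NULL
  for (pc in sb$pieces) {
    for (f in pc$fills) {
      if (f$slot == "anatomy") out <- c(f$id, pc$text)
    }
  }
  if (is.null(out)) inherited else out
}

.gen_history <- function(cfg) {
  sb <- .sb()
  firsts <- list(
    list(text = "Twisting injury",
         fills = function(r) .fill(r, "finding", "TOY:0000156"), rec = TRUE),
    list(text = "Squash", text2 = "injury", rec = TRUE,
         fills = function(r) .fill(r, "finding_qualifier", "TOY:0000147"),
         fills2 = function(r) .fill(r, "finding", "TOY:0000155")),
    list(text = "Football", text2 = "injury", rec = TRUE,
         fills = function(r) .fill(r, "finding_qualifier", "TOY:0000148"),
         fills2 = function(r) .fill(r, "finding", "TOY:0000155")),
    list(text = "ACL", text2 = "rupture", rec = TRUE, anat_first = TRUE,
         fills = function(r) .fill(r, "anatomy", "TRAK:0000049"),
         fills2 = function(r) .fill(r, "finding", "TRAK:0000211")))
  rests <- list(
    list(text = "positive", text2 = "McMurray's", rec = TRUE,
         fills = function(r) .fill(r, "finding_qualifier", "TOY:0000145"),
         fills2 = function(r) .fill(r, "finding", "TOY:0000169")),
    list(text = "positive", text2 = "Lachman's", rec = TRUE,
         fills = function(r) .fill(r, "finding_qualifier", "TOY:0000145"),
         fills2 = function(r) .fill(r, "finding", "TOY:0000170")),
    list(text = "tender", text2 = "medial joint line", rec = FALSE,
         ctx2 = function(r) .fill(NA_integer_, "anatomy", "TOY:0000027")),
    list(text = "tender", text2 = "lateral joint line", rec = FALSE,
         ctx2 = function(r) .fill(NA_integer_, "anatomy", "TOY:0000028")),
    list(text = "locking and giving way", rec = FALSE),
    list(text = "recurrent pain on exercise", rec = FALSE))
  sb <- .p(sb, "HISTORY", pre = "")
  items <- c(sample(firsts, 1), sample(rests, 3))
  first <- TRUE
  for (it in items) {
    if (!first) sb <- .p(sb, ",", pre = "")
    r <- if (isTRUE(it$rec)) sb$nrec + 1L else NA
    if (isTRUE(it$rec)) sb$nrec <- sb$nrec + 1L
    f1 <- if (isTRUE(it$rec)) it$fills(r) else NULL
    sb <- .p(sb, it$text, f1)
    if (!is.null(it$text2)) {
      f2 <- if (isTRUE(it$rec)) it$fills2(r) else
        if (!is.null(it$ctx2)) it$ctx2(NA) else NULL
      sb <- .p(sb, it$text2, f2)
    }
    first <- FALSE
  }
  .end(sb)
}

.gen_conclusion <- function(cfg) {
  sb <- .sb()
  sb <- .p(sb, "CONCLUSION", pre = "")
  n_items <- sample(1:2, 1, prob = c(0.1, 0.9))
  for (i in seq_len(n_items)) {
    if (i > 1) sb <- .p(sb, ",", pre = "")
    r <- sb$nrec + 1L
    sb$nrec <- sb$nrec + 1L
    kind <- sample.int(3, 1)
    if (kind == 1) {
      fq <- .pick(.POOL$fq); pf <- .pick(.POOL$patho)
      anat <- .pick(.POOL$soft_anat)
      fq_txt <- if (i == 1) paste0(toupper(substr(fq[2], 1, 1)),
                                   substr(fq[2], 2, nchar(fq[2]))) else fq[2]
      sb <- .p(sb, fq_txt, .fill(r, "finding_qualifier", fq[1]))
      sb <- .p(sb, pf[2], .fill(r, "finding", pf[1]))
      sb <- .p(sb, "of the")
      if (anat[1] %in% c("TRAK:0001089", "TRAK:0001090") &&
          stats::runif(1) < 0.6) {
        z <- .pick(.POOL$zone_aq)
        sb <- .p(sb, z[2], .fill(r, "anatomy_qualifier", z[1]))
        sb <- .p(sb, "of the")
      }
      sb <- .p(sb, anat[2], .fill(r, "anatomy", anat[1]))
    } else if (kind == 2) {
      gf <- .pick(.POOL$general)
      anat <- .pick(c(.POOL$bone_anat, .POOL$soft_anat))
      sb <- .p(sb, if (i == 1) "No" else "no", .fill(r, "negation", ""))
      sb <- .p(sb, gf[2], .fill(r, "finding", gf[1]))
      sb <- .p(sb, "in the")
      sb <- .p(sb, anat[2], .fill(r, "anatomy", anat[1]))
    } else {
      anat <- .pick(c(.POOL$bone_anat, .POOL$soft_anat, .POOL$cart_anat))
      sb <- .p(sb, if (i == 1) "Normal" else "normal",
               .fill(r, "finding", "TOY:0000125"))
      sb <- .p(sb, "appearance", .fill(r, "certainty", "TOY:0000122"))
      sb <- .p(sb, "of the")
      sb <- .p(sb, anat[2], .fill(r, "anatomy", anat[1]))
    }
  }
  if (stats::runif(1) < 0.8) sb <- .p(sb, .tail())
  .end(sb)
}

# ---- report assembly -------------------------------------------------------

.render_report <- function(sentences, ontology) {
  text <- ""
  fillers <- list()   # per global record index: list of slot fillers
  rec_offset <- 0L
  for (sb in sentences) {
    if (nzchar(text)) text <- paste0(text, "\n")
    line_start <- nchar(text)
    line <- ""
    for (pc in sb$pieces) {
      pre <- if (nzchar(line)) pc$pre else ""
      start <- line_start + nchar(line) + nchar(pre)
      line <- paste0(line, pre, pc$text)
      for (f in pc$fills) {
        if (is.na(f$rec)) next  # context-only span, not a gold filler
        gr <- rec_offset + f$rec
        key <- as.character(gr)
        fillers[[key]] <- c(fillers[[key]], list(list(
          slot = f$slot, text = pc$text, start = start,
          offset = nchar(pc$text), id = f$id)))
      }
    }
    inherit <- attr(sb, "inherit_anatomy_from")
    if (!is.null(inherit)) {
      # anatomy filler reuses the span of the most recent occurrence of the
      # surface in the preceding text (backtracking construction)
      pos <- gregexpr(inherit[2], text, fixed = TRUE)[[1]]
      if (pos[[1]] != -1) {
        key <- as.character(rec_offset + 1L)
        fillers[[key]] <- c(fillers[[key]], list(list(
          slot = "anatomy", text = inherit[2],
          start = max(as.integer(pos)) - 1L,
          offset = nchar(inherit[2]), id = inherit[1])))
      }
    }
    text <- paste0(text, line)
    rec_offset <- rec_offset + sb$nrec
  }
  records <- list()
  for (key in as.character(sort(as.integer(names(fillers))))) {
    rec <- .empty_record()
    fl <- fillers[[key]]
    ord <- order(vapply(fl, `[[`, 0, "start"))
    for (f in fl[ord]) {
      sf <- .slot_filler(ontology, f$text, f$start, f$offset, f$id)
      switch(f$slot,
             finding = { rec$finding <- sf },
             negation = { rec$negation <- .slot_filler(ontology, f$text,
                                                       f$start, f$offset,
                                                       "", "") },
             certainty = { rec$certainty <- sf },
             anatomy = { rec$anatomy <- sf },
             finding_qualifier = {
               rec$finding_qualifiers[[length(rec$finding_qualifiers) + 1L]] <- sf
             },
             anatomy_qualifier = {
               rec$anatomy_qualifiers[[length(rec$anatomy_qualifiers) + 1L]] <- sf
             })
    }
    records[[length(records) + 1L]] <- rec
  }
  list(text = text, records = records)
}

.TYPO_SAFE <- c("There", "is", "are", "This", "has", "does", "evidence",
                "level", "Query", "internal", "derangement", "study",
                "images", "these", "throughout", "described", "previously",
                "time", "recent", "trauma", "following", "unchanged",
                "previous", "better", "appreciated")

.inject_typos <- function(text, records, cfg) {
  n <- stats::rpois(1, cfg$typo_rate)
  if (n == 0) return(text)
  toks <- tokenize(text)
  spans <- do.call(rbind, lapply(records, function(r) {
    fl <- c(list(r$finding, r$negation, r$certainty, r$anatomy),
            r$finding_qualifiers, r$anatomy_qualifiers)
    fl <- Filter(Negate(is.null), fl)
    do.call(rbind, lapply(fl, function(s) c(s$start, s$start + s$offset)))
  }))
  in_span <- function(st, en) {
    !is.null(spans) && nrow(spans) > 0 &&
      any(spans[, 1] < en & spans[, 2] > st)
  }
  cand <- which(if (cfg$typos_in_spans) {
    nchar(toks$text) >= 6 &
      vapply(seq_len(nrow(toks)), function(i)
        in_span(toks$start[i], toks$start[i] + toks$length[i]), logical(1))
  } else {
    toks$text %in% .TYPO_SAFE &
      !vapply(seq_len(nrow(toks)), function(i)
        in_span(toks$start[i], toks$start[i] + toks$length[i]), logical(1))
  })
  if (!length(cand)) return(text)
  for (i in sample(cand, min(n, length(cand)))) {
    w <- toks$text[i]
    pos <- sample.int(nchar(w), 1)
    repl <- sample(setdiff(letters, tolower(substr(w, pos, pos))), 1)
    w2 <- paste0(substr(w, 1, pos - 1), repl,
                 substr(w, pos + 1, nchar(w)))
    substr(text, toks$start[i] + 1, toks$start[i] + nchar(w)) <- w2
  }
  text
}

#' Generate a synthetic gold-annotated report corpus
#'
#' Reports are built from a sentence grammar over the toy-ontology surface
#' forms (sectioned structure, findings with qualifier chains, negation
#' cues, coordinated and enumerated terms, two-finding statements, anatomy
#' backtracking pairs). Gold templates derive from the generating choices,
#' never from the extraction pipeline. Typographical errors are injected as
#' single-character substitutions that keep all character offsets valid.
#'
#' @param cfg A [corpus_config()].
#' @param ontology Ontology used for preferred names (the toy ontology).
#' @return Object of class `gold_corpus`: list with `reports` (named list
#'   id -> `list(text, records)`) and `cfg`.
#' @export
generate_corpus <- function(cfg = corpus_config(), ontology = toy_ontology()) {
  set.seed(cfg$seed)
  reports <- list()
  if (cfg$n_reports == 0) {
    return(structure(list(reports = reports, cfg = cfg),
                     class = "gold_corpus"))
  }
  weights <- c(plain_patho = 0.20, plain_general = 0.18, normality = 0.12,
               remainder = 0.08,
               two_finding = cfg$p_two_finding, or_share = cfg$p_or,
               coordination = cfg$p_coordination,
               enumeration = cfg$p_enumeration, backtrack = cfg$p_backtrack)
  for (r in seq_len(cfg$n_reports)) {
    id <- sprintf("r%03d", r)
    target <- max(7L, min(24L, round(stats::rnorm(1, cfg$mean_sentences - 0.2,
                                                  cfg$sd_sentences))))
    has_ind <- stats::runif(1) < cfg$p_indication
    n_f <- max(1L, target - 6L - if (has_ind) 2L else 0L)
    sents <- list()
    title <- .p(.sb(), paste("MRI REPORT OF THE",
                             sample(c("LEFT", "RIGHT"), 1), "KNEE"),
                pre = "")
    sents[[length(sents) + 1L]] <- title
    if (has_ind) {
      sents[[length(sents) + 1L]] <-
        .end(.p(.sb(),
                "INDICATION Query internal derangement following recent trauma",
                pre = ""))
    }
    hist <- .gen_history(cfg)
    sents[[length(sents) + 1L]] <- hist
    last_anat <- .last_anat_of(hist)
    sents[[length(sents) + 1L]] <- .p(.sb(), "FINDINGS", pre = "")
    k <- 0L
    while (k < n_f) {
      kind <- sample(names(weights), 1, prob = weights)
      if (kind == "backtrack" && k + 2L <= n_f) {
        pair <- .gen_backtrack(cfg)
        sents <- c(sents, pair)
        la <- .last_anat_of(pair[[1]])
        if (!is.null(la)) last_anat <- la
        k <- k + 2L
      } else if (kind == "backtrack") {
        next
      } else {
        gen <- switch(kind,
                      plain_patho = .gen_plain_patho,
                      plain_general = .gen_plain_general,
                      normality = .gen_normality,
                      two_finding = .gen_two_finding,
                      or_share = .gen_or_share,
                      coordination = .gen_coordination,
                      enumeration = .gen_enumeration)
        sb <- if (kind == "remainder") .gen_remainder(cfg, last_anat) else
          gen(cfg)
        sents[[length(sents) + 1L]] <- sb
        la <- .last_anat_of(sb)
        if (!is.null(la)) last_anat <- la
        k <- k + 1L
      }
    }
    sents[[length(sents) + 1L]] <- .gen_conclusion(cfg)
    reports[[id]] <- .render_report(sents, ontology)
  }
  # typos are injected in a second pass so that the underlying reports (and
  # the random draws that shaped them) are identical across typo rates
  for (id in names(reports)) {
    reports[[id]]$text <- .inject_typos(reports[[id]]$text,
                                        reports[[id]]$records, cfg)
  }
  structure(list(reports = reports, cfg = cfg), class = "gold_corpus")
}

#' @export
print.gold_corpus <- function(x, ...) {
  cat(sprintf("<gold_corpus> %d report(s), %d gold record(s)\n",
              length(x$reports),
              sum(vapply(x$reports, function(r) length(r$records), 0L))))
  invisible(x)
}

#' Report texts of a gold corpus
#' @param gc A `gold_corpus`.
#' @return Named character vector id -> text.
#' @export
corpus_texts <- function(gc) {
  vapply(gc$reports, `[[`, "", "text")
}

#' Gold records of a gold corpus
#' @param gc A `gold_corpus`.
#' @return Named list id -> list of records.
#' @export
corpus_gold <- function(gc) {
  lapply(gc$reports, `[[`, "records")
}

#' Write a gold corpus to disk (report .txt files plus gold JSON)
#' @param gc A `gold_corpus`.
#' @param dir Output directory.
#' @export
write_corpus <- function(gc, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (id in names(gc$reports)) {
    writeLines(gc$reports[[id]]$text, file.path(dir, paste0(id, ".txt")),
               useBytes = TRUE)
    writeLines(to_json(gc$reports[[id]]$records, report_id = id),
               file.path(dir, paste0(id, ".gold.json")), useBytes = TRUE)
  }
  invisible(dir)
}
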