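# Seeded synthetic lexicons and PubTator corpora. The generator emulates the
# structures every pipeline stage needs: multi-word disease names with
# synonyms, "long form (ABBR)" definitions followed by bare abbreviation
# mentions, concepts repeated within one abstract, distractor noun phrases,
# and "trap" tokens that occur both inside and outside entities.

DISEASE_MODIFIERS <- c("acute", "chronic", "severe", "congenital",
                       "recurrent", "transient", "familial", "idiopathic",
                       "systemic", "focal", "progressive", "refractory",
                       "juvenile", "malignant", "bilateral")

DISEASE_SITES <- c("renal", "cardiac", "hepatic", "pulmonary", "gastric",
                   "neural", "dermal", "ocular", "spinal", "vascular",
                   "bronchial", "splenic", "adrenal", "cranial",
                   "intestinal")

DISEASE_HEADS <- c("fibrosis", "anemia", "carcinoma", "dermatitis",
                   "nephropathy", "sclerosis", "neuropathy", "myopathy",
                   "arthritis", "hepatitis", "melanoma", "lymphoma",
                   "glaucoma", "psychosis", "delirium", "asthma",
                   "epilepsy", "migraine", "sepsis", "cirrhosis",
                   "leukemia", "thrombosis", "embolism", "stenosis",
                   "aneurysm", "hypertension", "hypotension", "tachycardia",
                   "bradycardia", "dystrophy", "atrophy", "hyperplasia",
                   "ischemia", "edema", "ulceration", "gangrene",
                   "meningitis", "encephalitis", "colitis", "gastritis")

DRUG_SYLLABLES <- c("dor", "mel", "tra", "vex", "zan", "cor", "fin", "lud",
                    "pra", "sol", "bex", "tam", "rol", "vin", "dex")

# intensifiers prepended to some gold mentions but absent from every lexicon
# term: they give gold spans that a pure dictionary match cuts short, the
# dominant boundary-error mode of gazetteer taggers on real abstracts
INTENSIFIERS <- c("marked", "notable", "profound", "persistent", "prominent")

#' Generator configuration
#'
#' @param seed Master RNG seed.
#' @param n_docs Number of documents to generate.
#' @param lexicon_size Number of concepts (at most `length(DISEASE_HEADS)`,
#'   each concept gets a unique head word).
#' @param synonyms_range Min/max synonyms per concept (the derived
#'   abbreviation counts as one).
#' @param abbrev_prob Probability that a document introduces one of its
#'   concepts as "long form (ABBR)" with later bare "ABBR" mentions.
#' @param repeat_prob Probability that a document repeats one concept's
#'   surface in at least two sentences.
#' @param mention_density Mean number of mention-bearing sentences per
#'   document concept.
#' @param n_distractors Size of the distractor (pseudo-drug) vocabulary.
#' @param boundary_noise Probability that a (non-abbreviation) mention is
#'   rendered with a leading intensifier that belongs to the gold span but to
#'   no lexicon term, so that dictionary matching alone truncates the span.
#' @param label_noise Fraction of gold mentions dropped from the annotations
#'   (annotation-noise robustness option).
#' @return A `generator_config` list.
#' @export
generator_config <- function(seed = 1L, n_docs = 100L, lexicon_size = 20L,
                             synonyms_range = c(1L, 3L), abbrev_prob = 0.5,
                             repeat_prob = 0.5, mention_density = 1.5,
                             n_distractors = 25L, boundary_noise = 0.25,
                             label_noise = 0) {
  stopifnot(n_docs >= 0, lexicon_size >= 1,
            lexicon_size <= length(DISEASE_HEADS),
            abbrev_prob >= 0, abbrev_prob <= 1,
            repeat_prob >= 0, repeat_prob <= 1,
            label_noise >= 0, label_noise <= 1,
            boundary_noise >= 0, boundary_noise <= 1,
            n_distractors >= 1, mention_density > 0)
  structure(list(seed = as.integer(seed), n_docs = as.integer(n_docs),
                 lexicon_size = as.integer(lexicon_size),
                 synonyms_range = as.integer(synonyms_range),
                 abbrev_prob = abbrev_prob, repeat_prob = repeat_prob,
                 mention_density = mention_density,
                 n_distractors = as.integer(n_distractors),
                 boundary_noise = boundary_noise,
                 label_noise = label_noise), class = "generator_config")
}

initials <- function(name)
  paste(toupper(substring(strsplit(name, " ")[[1]], 1, 1)), collapse = "")

#' Generate a synthetic disease lexicon
#'
#' Concepts get synthetic IDs (T0001, ...), 2-3-word names built from a
#' modifier/site/head morpheme inventory with a unique head word per concept,
#' synonym variants (word re-ordering, "syndrome"/"disorder" suffixes) and
#' the abbreviation formed from the name's initial letters. Abbreviations are
#' unique across concepts by construction. Deterministic given the seed.
#'
#' @param config A [generator_config()].
#' @return A `dner_lexicon`; each entry carries an `abbrev` field.
#' @export
make_lexicon <- function(config = generator_config()) {
  with_seed(derive_seed(config$seed, 23L), {
    heads <- sample(DISEASE_HEADS, config$lexicon_size)
    used_abbrev <- character(0)
    entries <- list()
    for (i in seq_len(config$lexicon_size)) {
      name <- NULL
      for (try in 1:100) {
        nw <- sample(2:3, 1)
        words <- if (nw == 2)
          c(sample(c(DISEASE_MODIFIERS, DISEASE_SITES), 1), heads[i])
        else
          c(sample(DISEASE_MODIFIERS, 1), sample(DISEASE_SITES, 1), heads[i])
        cand <- paste(words, collapse = " ")
        ab <- initials(cand)
        # uniqueness on the stemmed form: normalization must never conflate
        # two concepts' abbreviations (e.g. "PHS" stems to "ph")
        if (!(porter_stem(tolower(ab)) %in% used_abbrev)) {
          name <- cand
          break
        }
      }
      if (is.null(name)) stop("could not build a unique abbreviation")
      ab <- initials(name)
      used_abbrev <- c(used_abbrev, porter_stem(tolower(ab)))
      pool <- c(paste(rev(strsplit(name, " ")[[1]]), collapse = " "),
                paste(name, "syndrome"), paste(name, "disorder"))
      n_syn <- sample(config$synonyms_range[1]:config$synonyms_range[2], 1)
      syn <- unique(c(ab, sample(pool, min(max(n_syn - 1, 0), length(pool)))))
      entries[[sprintf("T%04d", i)]] <-
        list(name = name, synonyms = syn, abbrev = ab)
    }
    dner_lexicon(entries)
  })
}

# fill a "... {M1} ... {D1} ..." template; returns text plus relative
# 0-based mention offsets
fill_template <- function(template, fills) {
  m <- gregexpr("\\{[A-Z0-9]+\\}", template)[[1]]
  pieces <- character(0)
  if (m[1] == -1) pieces <- template else {
    pos <- 1L
    for (k in seq_along(m)) {
      if (m[k] > pos)
        pieces <- c(pieces, substring(template, pos, m[k] - 1L))
      pieces <- c(pieces, substring(template, m[k],
                                    m[k] + attr(m, "match.length")[k] - 1L))
      pos <- m[k] + attr(m, "match.length")[k]
    }
    if (pos <= nchar(template))
      pieces <- c(pieces, substring(template, pos))
  }
  text <- ""
  mentions <- list()
  for (p in pieces) {
    if (grepl("^\\{.*\\}$", p)) {
      key <- gsub("[{}]", "", p)
      f <- fills[[key]]
      if (is.null(f)) stop("unfilled template slot ", key)
      if (!is.null(f$concept))
        mentions[[length(mentions) + 1L]] <- data.frame(
          start = nchar(text), end = nchar(text) + nchar(f$text),
          surface = f$text, concept = f$concept, stringsAsFactors = FALSE)
      text <- paste0(text, f$text)
    } else text <- paste0(text, p)
  }
  # sentence-initial capitalization (kept in gold surfaces)
  first <- toupper(substring(text, 1, 1))
  if (length(mentions) && mentions[[1]]$start == 0)
    mentions[[1]]$surface <- paste0(first,
                                    substring(mentions[[1]]$surface, 2))
  text <- paste0(first, substring(text, 2))
  list(text = text,
       mentions = if (length(mentions)) do.call(rbind, mentions) else NULL)
}

MENTION_TEMPLATES <- c(
  "We studied {N} patients with {M}.",
  "{M} was observed in the treatment group.",
  "Patients with {M} received {D} therapy.",
  "The incidence of {M} increased after {D} administration.",
  "No association between {D} and {M} was found.",
  "Severity of {M} was assessed at baseline.",
  "Follow up revealed persistent {M} in {N} cases.")

FILLER_TEMPLATES <- c(
  "All subjects provided informed consent.",
  "Data were analysed with standard statistical methods.",
  "{D} was administered daily for {N} weeks.",
  "Patients in the {T} group improved rapidly.",
  "The {T} care unit reported {N} admissions.",
  "Baseline characteristics were similar across groups.")

TITLE_TEMPLATES <- c(
  "Clinical features of {M}.",
  "A case of {M} after {D} treatment.",
  "{M} associated with {D} exposure.",
  "Incidence of {M} in a hospital cohort.")

#' Generate a synthetic PubTator corpus
#'
#' Documents are built from sentence templates with injected gold mentions
#' carrying offsets and concept IDs. With probability `abbrev_prob` a
#' document introduces one concept as "long form (ABBR)" (both the long form
#' and the parenthesized abbreviation are gold mentions) followed by later
#' bare "ABBR" mentions; with probability `repeat_prob` one concept's surface
#' repeats in at least two sentences. Deterministic given the seed.
#'
#' @param lexicon A lexicon from [make_lexicon()].
#' @param config The same [generator_config()].
#' @return List of `dner_document` objects.
#' @export
generate_corpus <- function(lexicon, config = generator_config()) {
  if (config$n_docs == 0) return(list())
  with_seed(derive_seed(config$seed, 29L), {
    distractors <- unique(replicate(config$n_distractors * 2, paste0(
      paste(sample(DRUG_SYLLABLES, 2), collapse = ""),
      sample(c("in", "ol", "ide", "ate"), 1))))[seq_len(config$n_distractors)]
    rnum <- function() as.character(sample(10:499, 1))
    rdist <- function() sample(distractors, 1)
    rtrap <- function() sample(c(DISEASE_MODIFIERS, DISEASE_SITES), 1)

    docs <- vector("list", config$n_docs)
    for (d in seq_len(config$n_docs)) {
      ids <- sample(names(lexicon$entries), sample(2:3, 1))
      abbrev_id <- if (stats::runif(1) < config$abbrev_prob) ids[1] else NULL
      repeat_id <- if (stats::runif(1) < config$repeat_prob)
        ids[length(ids)] else NULL

      surface_for <- function(id, allow_abbrev = FALSE) {
        e <- lexicon$entries[[id]]
        pool <- c(e$name, setdiff(e$synonyms, e$abbrev))
        if (allow_abbrev) pool <- c(pool, e$abbrev)
        s <- sample(pool, 1)
        if (stats::runif(1) < config$boundary_noise)
          s <- paste(sample(INTENSIFIERS, 1), s)
        s
      }

      # title sentence
      tfill <- list(M = list(text = surface_for(ids[1]),
                             concept = ids[1]),
                    D = list(text = rdist()), N = list(text = rnum()))
      title <- fill_template(sample(TITLE_TEMPLATES, 1), tfill)

      # abstract sentence plan
      sents <- list()
      add_sentence <- function(template, fills) {
        sents[[length(sents) + 1L]] <<- fill_template(template, fills)
      }
      for (id in ids) {
        n_ment <- max(1L, stats::rpois(1, config$mention_density))
        if (identical(id, repeat_id)) n_ment <- max(2L, n_ment)
        surf <- surface_for(id)
        for (j in seq_len(n_ment)) {
          if (identical(id, abbrev_id) && j == 1L) {
            e <- lexicon$entries[[id]]
            long <- e$name
            combo <- fill_template(
              sample(MENTION_TEMPLATES[1:6], 1),
              list(M = list(text = paste0(long, " (", e$abbrev, ")"),
                            concept = NULL),
                   D = list(text = rdist()), N = list(text = rnum())))
            # re-annotate: long form and ABBR are separate gold mentions
            whole_start <- regexpr(paste0(long, " (", e$abbrev, ")"),
                                   combo$text, fixed = TRUE)
            if (whole_start < 0) { # capitalized at sentence start
              long <- paste0(toupper(substring(long, 1, 1)),
                             substring(long, 2))
              whole_start <- regexpr(paste0(long, " (", e$abbrev, ")"),
                                     combo$text, fixed = TRUE)
            }
            s0 <- as.integer(whole_start) - 1L
            combo$mentions <- rbind(
              data.frame(start = s0, end = s0 + nchar(long), surface = long,
                         concept = id, stringsAsFactors = FALSE),
              data.frame(start = s0 + nchar(long) + 2L,
                         end = s0 + nchar(long) + 2L + nchar(e$abbrev),
                         surface = e$abbrev, concept = id,
                         stringsAsFactors = FALSE))
            sents[[length(sents) + 1L]] <- combo
          } else {
            use <- if (identical(id, abbrev_id))
              lexicon$entries[[id]]$abbrev
            else if (identical(id, repeat_id)) surf
            else surface_for(id)
            add_sentence(sample(MENTION_TEMPLATES, 1),
                         list(M = list(text = use, concept = id),
                              D = list(text = rdist()),
                              N = list(text = rnum())))
          }
        }
      }
      n_fill <- sample(1:2, 1)
      for (j in seq_len(n_fill))
        add_sentence(sample(FILLER_TEMPLATES, 1),
                     list(D = list(text = rdist()), N = list(text = rnum()),
                          T = list(text = rtrap())))
      sents <- sents[sample(length(sents))]

      # assemble: full text = title + " " + abstract
      title_text <- title$text
      abstract <- ""
      mentions <- list()
      if (!is.null(title$mentions)) {
        m <- title$mentions; m$offset <- 0L
        mentions[[length(mentions) + 1L]] <- m
      }
      base <- nchar(title_text) + 1L
      for (s in sents) {
        if (nchar(abstract)) { abstract <- paste0(abstract, " ") }
        off <- base + nchar(abstract)
        if (!is.null(s$mentions)) {
          m <- s$mentions; m$offset <- off
          mentions[[length(mentions) + 1L]] <- m
        }
        abstract <- paste0(abstract, s$text)
      }
      mdf <- NULL
      if (length(mentions)) {
        mm <- do.call(rbind, mentions)
        mdf <- data.frame(start = mm$start + mm$offset,
                          end = mm$end + mm$offset, surface = mm$surface,
                          type = "Disease", concept_id = mm$concept,
                          stringsAsFactors = FALSE)
        if (config$label_noise > 0) {
          keep <- stats::runif(nrow(mdf)) >= config$label_noise
          mdf <- mdf[keep, , drop = FALSE]
        }
      }
      docs[[d]] <- dner_document(sprintf("%d", 10000L + d), title_text,
                                 abstract, mdf)
    }
    docs
  })
}

#' Split a corpus into train/dev/test
#'
#' Document-level, disjoint, exhaustive and seed-deterministic.
#'
#' @param docs List of documents.
#' @param fractions Numeric length-3 vector summing to 1.
#' @param seed RNG seed.
#' @return `list(train = , dev = , test = )`.
#' @export
split_corpus <- function(docs, fractions = c(0.6, 0.2, 0.2), seed = 1L) {
  if (length(fractions) != 3 || abs(sum(fractions) - 1) > 1e-8)
    stop("fractions must be three numbers summing to 1")
  n <- length(docs)
  ord <- with_seed(derive_seed(seed, 31L), sample.int(n))
  n1 <- round(fractions[1] * n)
  n2 <- round(fractions[2] * n)
  n2 <- min(n2, n - n1)
  list(train = docs[ord[seq_len(n1)]],
       dev = docs[ord[seq_len(n2) + n1]],
       test = docs[ord[setdiff(seq_len(n), seq_len(n1 + n2))]])
}

#' Write a corpus bundle to disk
#'
#' Emits `corpus.txt` (PubTator), `lexicon.tsv` and `manifest.json` (seed,
#' config, counts).
#'
#' @param dir Output directory (created if needed).
#' @param docs Document list.
#' @param lexicon A `dner_lexicon`.
#' @param config The `generator_config` used.
#' @return Invisibly, the manifest list.
#' @export
write_corpus_bundle <- function(dir, docs, lexicon, config) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_pubtator(docs, file.path(dir, "corpus.txt"))
  write_lexicon(lexicon, file.path(dir, "lexicon.tsv"))
  manifest <- list(
    seed = config$seed,
    config = unclass(config),
    n_docs = length(docs),
    n_mentions = sum(vapply(docs, function(d) nrow(d$mentions), integer(1))),
    n_concepts = length(lexicon$entries))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
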