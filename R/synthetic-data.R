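#' Synthetic corpus and knowledge-base generation
#'
#' The live pipeline mined PubMed abstracts against a curated
#' neuro-endocrine-immune gene dictionary, a STRING-derived protein-relation
#' knowledge base, and GenCliP-style symptom-gene hit counts. None of those
#' services is reproducible offline, so this module generates data with the
#' statistical properties the pipeline assumes: abstracts with planted gene
#' mentions, elevated co-mention rates for knowledge-base pairs, lexical
#' relation cues on true-relation sentences, and Poisson symptom-gene hit
#' structure with a zero-inflated fraction of unmapped symptoms. Every
#' generator is deterministic for a fixed seed and draws from its own stream
#' derived by stable sub-seeding, so adding one generator never perturbs
#' another. Abstracts are templated English sentences (subject-verb-object
#' with gene slots plus filler sentences): the recognition and
#' relation-extraction stages only need token streams, not fluent prose.
#'
#' @name synthetic_data
NULL

#' Relation-cue lexicon used by the generator and featurizer
#'
#' Verbs that signal a true gene-gene relation in a co-mention sentence.
#'
#' @return character vector of cue tokens.
#' @export
cue_lexicon <- function() {
  c("activates", "inhibits", "regulates", "binds", "phosphorylates")
}

neutral_verbs <- function() {
  c("accompanies", "precedes", "follows", "parallels")
}

filler_words <- function() {
  c("patients", "tissue", "cohort", "samples", "clinical", "baseline",
    "expression", "levels", "observed", "analysis", "myocardial", "cerebral",
    "outcome", "therapy", "treatment", "group", "control", "study",
    "measured", "reported", "significant", "serum", "plasma", "chronic")
}

#' Configuration for the synthetic study conditions
#'
#' Defaults are the standard conditions used throughout the test-bed: 20
#' genes, 400 abstracts, knowledge-base pairs co-mentioned in 30% of
#' abstracts against a 2% background, and a 90% chance that a true-relation
#' co-mention sentence carries a cue verb.
#'
#' @param n_genes number of dictionary genes (>= 2).
#' @param n_abstracts number of abstracts to generate.
#' @param kb_density fraction of gene pairs placed in the knowledge base.
#' @param comention_rate_kb per-abstract probability that a knowledge-base
#'   pair is planted as a co-mention sentence.
#' @param comention_rate_bg the same for a non-knowledge-base pair.
#' @param cue_rate probability a true-relation co-mention sentence carries a
#'   relation cue token.
#' @param n_symptoms number of symptom terms.
#' @param hits_lambda Poisson mean of symptom-gene hit counts.
#' @param seed master integer seed.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_genes = 20, n_abstracts = 400,
                             kb_density = 0.2, comention_rate_kb = 0.3,
                             comention_rate_bg = 0.02, cue_rate = 0.9,
                             n_symptoms = 12, hits_lambda = 2, seed = 1) {
  rates <- c(kb_density = kb_density, comention_rate_kb = comention_rate_kb,
             comention_rate_bg = comention_rate_bg, cue_rate = cue_rate)
  if (any(rates < 0 | rates > 1)) {
    stop_invalid(paste0("rates must lie in [0,1]; got ",
                        paste(names(rates)[rates < 0 | rates > 1], collapse = ", ")))
  }
  if (comention_rate_kb < comention_rate_bg) {
    stop_invalid("comention_rate_kb must be >= comention_rate_bg (planted signal)")
  }
  counts <- c(n_genes = n_genes, n_abstracts = n_abstracts, n_symptoms = n_symptoms)
  if (any(counts < 1) || n_genes < 2) {
    stop_invalid("n_genes must be >= 2 and all counts positive")
  }
  if (hits_lambda < 0) stop_invalid("hits_lambda must be nonnegative")
  structure(list(n_genes = as.integer(n_genes),
                 n_abstracts = as.integer(n_abstracts),
                 kb_density = kb_density,
                 comention_rate_kb = comention_rate_kb,
                 comention_rate_bg = comention_rate_bg,
                 cue_rate = cue_rate,
                 n_symptoms = as.integer(n_symptoms),
                 hits_lambda = hits_lambda,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate a gene dictionary
#'
#' Symbols are synthetic gene-style identifiers (three letters plus digits),
#' globally unique across symbols and synonyms; each entry carries 0-2
#' synonyms. The identifier alphabet is disjoint from the generator's filler
#' vocabulary, so a dictionary surface never appears in an abstract
#' unplanned.
#'
#' @param n_genes number of entries (>= 2).
#' @param seed integer seed.
#' @return a tibble with `symbol` and list-column `synonyms`.
#' @export
gen_gene_dictionary <- function(n_genes, seed = 1) {
  if (n_genes < 2) stop_invalid("n_genes must be >= 2")
  set.seed(sub_seed(seed, "dictionary"))
  pool <- character(0)
  while (length(pool) < n_genes * 3) {
    cand <- paste0(
      apply(matrix(sample(LETTERS, 3 * n_genes * 4, replace = TRUE), ncol = 3), 1, paste, collapse = ""),
      sample(1:99, n_genes * 4, replace = TRUE)
    )
    pool <- unique(c(pool, cand))
  }
  symbols <- pool[seq_len(n_genes)]
  syn_pool <- pool[(n_genes + 1):length(pool)]
  n_syn <- sample(0:2, n_genes, replace = TRUE)
  offsets <- cumsum(c(0, n_syn[-n_genes]))
  dict <- tibble(
    symbol = symbols,
    synonyms = map(seq_len(n_genes), function(i) {
      if (n_syn[i] == 0) character() else syn_pool[offsets[i] + seq_len(n_syn[i])]
    })
  )
  validate_dictionary(dict)
  dict
}

#' Generate a knowledge base of gene-gene relations
#'
#' Each unordered pair of dictionary symbols enters the knowledge base
#' independently with probability `kb_density`, with a uniform confidence
#' score; expected size is `kb_density * choose(n_genes, 2)`.
#'
#' @param dictionary tibble from [gen_gene_dictionary()].
#' @param kb_density inclusion probability in \[0,1\].
#' @param seed integer seed.
#' @return a tibble with `gene_a`, `gene_b`, `score`.
#' @export
gen_knowledge_base <- function(dictionary, kb_density, seed = 1) {
  validate_dictionary(dictionary)
  if (kb_density < 0 || kb_density > 1) stop_invalid("kb_density must lie in [0,1]")
  set.seed(sub_seed(seed, "kb"))
  syms <- sort(dictionary$symbol)
  pairs <- utils::combn(syms, 2)
  keep <- stats::runif(ncol(pairs)) < kb_density
  tibble(gene_a = pairs[1, keep], gene_b = pairs[2, keep],
         score = round(stats::runif(sum(keep), 0.4, 0.99), 3))
}

# one templated co-mention sentence; surfaces may be synonyms
comention_sentence <- function(surf_a, verb, surf_b) {
  ctx <- sample(filler_words(), 2)
  paste0(surf_a, " ", verb, " ", surf_b, " in ", ctx[1], " ", ctx[2], ".")
}

filler_sentence <- function() {
  w <- sample(filler_words(), 5)
  paste0(str_to_upper(substr(w[1], 1, 1)), substr(w[1], 2, nchar(w[1])), " ",
         paste(w[2:5], collapse = " "), ".")
}

pick_surface <- function(dictionary, symbol) {
  i <- match(symbol, dictionary$symbol)
  syns <- dictionary$synonyms[[i]]
  if (length(syns) > 0 && stats::runif(1) < 0.25) sample(syns, 1) else symbol
}

#' Generate an abstract corpus with planted gene co-mentions
#'
#' For every abstract, each knowledge-base pair is planted as a co-mention
#' sentence with probability `comention_rate_kb` and each remaining pair
#' with probability `comention_rate_bg`. Planted knowledge-base sentences
#' carry a relation-cue verb with probability `cue_rate`; background
#' sentences never do. Each abstract also receives 1-3 gene-free filler
#' sentences and at most one solo gene mention, so an abstract contains two
#' distinct genes only through planted co-mentions when both rates are zero.
#'
#' @param dictionary tibble from [gen_gene_dictionary()].
#' @param knowledge_base tibble from [gen_knowledge_base()].
#' @param config a [synthetic_config()].
#' @return a list with `corpus` (tibble: `record_id`, `title`, `abstract`,
#'   `keywords`) and `truth` (tibble of planted co-mentions: `record_id`,
#'   `gene_a`, `gene_b`, `sentence_index`, `is_kb`, `has_cue`).
#' @export
gen_abstract_corpus <- function(dictionary, knowledge_base, config) {
  validate_dictionary(dictionary)
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(sub_seed(config$seed, "corpus"))
  syms <- sort(dictionary$symbol)
  syns <- dictionary$synonyms[match(syms, dictionary$symbol)]
  all_pairs <- utils::combn(syms, 2)
  n_pairs <- ncol(all_pairs)
  kb_keys <- pair_key(knowledge_base$gene_a, knowledge_base$gene_b)
  is_kb <- pair_key(all_pairs[1, ], all_pairs[2, ]) %in% kb_keys
  rate <- ifelse(is_kb, config$comention_rate_kb, config$comention_rate_bg)
  fw <- filler_words(); cl <- cue_lexicon(); nv <- neutral_verbs()

  # one Bernoulli draw per (pair, abstract); rate recycles down columns
  plant <- matrix(stats::runif(n_pairs * config$n_abstracts), nrow = n_pairs) < rate
  n_truth <- sum(plant)
  t_rid <- character(n_truth); t_a <- character(n_truth); t_b <- character(n_truth)
  t_kb <- logical(n_truth); t_cue <- logical(n_truth); t_idx <- integer(n_truth)
  titles <- character(config$n_abstracts)
  abstracts <- character(config$n_abstracts)
  keywords <- vector("list", config$n_abstracts)
  rids <- sprintf("SYN%05d", seq_len(config$n_abstracts))
  # surface chooser: canonical symbol, or a synonym 25% of the time
  surf_of <- function(gidx) {
    s <- syms[gidx]
    use_syn <- stats::runif(length(gidx)) < 0.25
    for (k in which(use_syn)) {
      sy <- syns[[gidx[k]]]
      if (length(sy) > 0) s[k] <- sy[sample.int(length(sy), 1)]
    }
    s
  }
  row <- 0L
  for (i in seq_len(config$n_abstracts)) {
    pl <- which(plant[, i])
    np <- length(pl)
    sent <- character(0)
    if (np > 0) {
      cued <- is_kb[pl] & stats::runif(np) < config$cue_rate
      verbs <- ifelse(cued, sample(cl, np, replace = TRUE),
                      sample(nv, np, replace = TRUE))
      sa <- surf_of(match(all_pairs[1, pl], syms))
      sb <- surf_of(match(all_pairs[2, pl], syms))
      ctx <- matrix(sample(fw, 2 * np, replace = TRUE), nrow = 2)
      sent <- paste0(sa, " ", verbs, " ", sb, " in ", ctx[1, ], " ", ctx[2, ], ".")
    }
    n_fill <- sample(1:3, 1)
    fwm <- matrix(sample(fw, 5 * n_fill, replace = TRUE), nrow = 5)
    fill <- paste0(str_to_upper(substr(fwm[1, ], 1, 1)),
                   substr(fwm[1, ], 2, nchar(fwm[1, ])), " ",
                   fwm[2, ], " ", fwm[3, ], " ", fwm[4, ], " ", fwm[5, ], ".")
    solo <- character(0)
    if (stats::runif(1) < 0.1) {
      g <- sample.int(length(syms), 1)
      solo <- paste0("Expression of ", surf_of(g), " was ",
                     sample(fw, 1), ".")
    }
    body <- c(sent, fill, solo)
    perm <- sample.int(length(body))
    abstracts[i] <- paste(body[perm], collapse = " ")
    titles[i] <- paste0("Study ", i, " of ", paste(sample(fw, 2), collapse = " "))
    keywords[[i]] <- sample(fw, 2)
    if (np > 0) {
      ix <- row + seq_len(np)
      t_rid[ix] <- rids[i]
      t_a[ix] <- all_pairs[1, pl]; t_b[ix] <- all_pairs[2, pl]
      t_kb[ix] <- is_kb[pl]; t_cue[ix] <- cued
      t_idx[ix] <- match(seq_len(np), perm) - 1L
      row <- row + np
    }
  }
  corpus <- tibble(record_id = rids, title = titles, abstract = abstracts,
                   keywords = keywords)
  truth <- tibble(record_id = t_rid, gene_a = t_a, gene_b = t_b,
                  is_kb = t_kb, has_cue = t_cue, sentence_index = t_idx)
  list(corpus = corpus, truth = truth)
}

#' Generate symptom terms, symptom-gene hit counts, and a term map
#'
#' Each symptom-gene cell gets a Poisson(`hits_lambda`) hit count, except
#' that a fixed 20% of symptoms are forced to all-zero rows ("unmapped"
#' symptoms), reproducing the pruning path for symptoms with no associated
#' genes. Every modern symptom term is covered by a synthetic TCM term in
#' the returned map.
#'
#' @param dictionary tibble from [gen_gene_dictionary()].
#' @param n_symptoms number of symptoms (>= 1).
#' @param hits_lambda Poisson mean (>= 0).
#' @param seed integer seed.
#' @return a list with `symptoms` (tibble: `symptom`, `unmapped`), `hits`
#'   (tibble: `symptom`, `gene`, `hits`) and `term_map`.
#' @export
gen_symptom_structure <- function(dictionary, n_symptoms, hits_lambda, seed = 1) {
  validate_dictionary(dictionary)
  if (n_symptoms < 1) stop_invalid("n_symptoms must be >= 1")
  if (hits_lambda < 0) stop_invalid("hits_lambda must be nonnegative")
  set.seed(sub_seed(seed, "symptoms"))
  base_terms <- c("dizziness", "headache", "palpitation", "chest pain",
                  "lassitude", "sweating", "hemiplegia", "ecchymoses",
                  "constipation", "xerostomia", "irritability", "insomnia",
                  "glossitis", "sputum", "numbness", "anemia", "fever",
                  "chills", "thirst", "fatigue")
  terms <- if (n_symptoms <= length(base_terms)) base_terms[seq_len(n_symptoms)] else
    c(base_terms, paste0("symptom ", seq_len(n_symptoms - length(base_terms))))
  n_zero <- floor(0.2 * n_symptoms)
  unmapped <- rep(FALSE, n_symptoms)
  if (n_zero > 0) unmapped[sample(n_symptoms, n_zero)] <- TRUE
  genes <- sort(dictionary$symbol)
  grid <- tidyr::expand_grid(symptom = terms, gene = genes)
  grid$hits <- stats::rpois(nrow(grid), hits_lambda)
  grid$hits[grid$symptom %in% terms[unmapped]] <- 0L
  term_map <- tibble(
    tcm_term = paste0("tcm_", gsub(" ", "_", terms)),
    modern_terms = as.list(terms)
  )
  list(symptoms = tibble(symptom = terms, unmapped = unmapped),
       hits = grid, term_map = term_map)
}

#' Generate a full two-syndrome synthetic study bundle
#'
#' Builds one shared dictionary and knowledge base, then per syndrome an
#' abstract corpus, a symptom structure, and an automatically derived
#' symptom classification (main / Qi-deficiency / blood-stasis groups over
#' the mapped symptoms). A set of planted shared genes is guaranteed
#' recoverable by construction: they are chained into knowledge-base pairs,
#' each chained pair receives three extra cue-bearing co-mention abstracts
#' in every corpus, and every planted gene gets at least one hit for every
#' mapped symptom.
#'
#' @param config a [synthetic_config()].
#' @param syndromes character vector of syndrome names (length >= 1).
#' @param n_planted_shared number of genes planted as shared signal.
#' @return a list with `dictionary`, `knowledge_base`, `planted_shared`,
#'   and per-syndrome lists (`corpus`, `truth`, `symptoms`,
#'   `classification`).
#' @export
gen_syndrome_bundle <- function(config,
                                syndromes = c("syndrome_a", "syndrome_b"),
                                n_planted_shared = 4) {
  stopifnot(inherits(config, "synthetic_config"), length(syndromes) >= 1)
  if (n_planted_shared > config$n_genes) {
    stop_invalid("n_planted_shared cannot exceed n_genes")
  }
  if (config$n_symptoms < 5) {
    stop_invalid("bundle classifications need n_symptoms >= 5")
  }
  dictionary <- gen_gene_dictionary(config$n_genes, seed = config$seed)
  kb <- gen_knowledge_base(dictionary, config$kb_density, seed = config$seed)
  set.seed(sub_seed(config$seed, "planted"))
  planted <- sort(sample(dictionary$symbol, n_planted_shared))
  if (n_planted_shared >= 2) {
    chain <- canonical_pair(planted[-length(planted)], planted[-1])
    chain$score <- 0.9
    new_pairs <- !(pair_key(chain$gene_a, chain$gene_b) %in%
                     pair_key(kb$gene_a, kb$gene_b))
    kb <- bind_rows(kb, chain[new_pairs, ]) |> arrange(.data$gene_a, .data$gene_b)
  }
  out <- list(dictionary = dictionary, knowledge_base = kb,
              planted_shared = planted, syndromes = list())
  for (s in syndromes) {
    cfg_s <- config
    cfg_s$seed <- sub_seed(config$seed, paste0("corpus_", s))
    gen <- gen_abstract_corpus(dictionary, kb, cfg_s)
    # guaranteed planted-pair evidence: three cue abstracts per chained pair
    if (n_planted_shared >= 2) {
      set.seed(sub_seed(config$seed, paste0("force_", s)))
      extra <- list(); etruth <- list()
      for (ci in seq_len(nrow(chain))) {
        for (k in 1:3) {
          rid <- sprintf("PLT%02d_%d_%s", ci, k, s)
          sentence <- comention_sentence(chain$gene_a[ci], sample(cue_lexicon(), 1),
                                         chain$gene_b[ci])
          extra[[length(extra) + 1]] <- tibble(
            record_id = rid,
            title = paste0("Planted study ", rid),
            abstract = paste(sentence, filler_sentence()),
            keywords = list(character())
          )
          etruth[[length(etruth) + 1]] <- tibble(
            record_id = rid, gene_a = chain$gene_a[ci], gene_b = chain$gene_b[ci],
            is_kb = TRUE, has_cue = TRUE, sentence_index = 0L)
        }
      }
      gen$corpus <- bind_rows(gen$corpus, bind_rows(extra))
      gen$truth <- bind_rows(gen$truth, bind_rows(etruth))
    }
    sym <- gen_symptom_structure(dictionary, config$n_symptoms,
                                 config$hits_lambda,
                                 seed = sub_seed(config$seed, paste0("sym_", s)))
    sym$hits <- sym$hits |>
      mutate(hits = ifelse(.data$gene %in% planted &
                             !(.data$symptom %in% sym$symptoms$symptom[sym$symptoms$unmapped]),
                           pmax(.data$hits, 1L), .data$hits))
    mapped <- sym$symptoms$symptom[!sym$symptoms$unmapped]
    if (length(mapped) < 4) stop_validation("too few mapped symptoms for a classification")
    n_qi <- max(1, ceiling((length(mapped) - 2) / 2))
    classification <- symptom_classification(
      syndrome_name = s,
      main = list(mapped[1]),
      qi_deficiency = as.list(mapped[2 + seq_len(n_qi)]),
      blood_stasis = as.list(mapped[(2 + n_qi + 1):length(mapped)]),
      fixed_terms = mapped[2]
    )
    out$syndromes[[s]] <- list(corpus = gen$corpus, truth = gen$truth,
                               symptoms = sym, classification = classification)
  }
  out
}

#' Write a planted-truth record as JSON
#'
#' @param truth truth tibble from [gen_abstract_corpus()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
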