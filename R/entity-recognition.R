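#' Dictionary-based gene named-entity recognition
#'
#' Abstracts are segmented into sentences, tokenized with a rule-based
#' English tokenizer (whitespace and punctuation split, internal hyphens
#' preserved), and token n-grams are matched against the gene dictionary,
#' longest match first. Matching is case-insensitive by default, except
#' that short all-caps surfaces (up to `exact_short_max` characters)
#' require an exact-case match: 2-3-letter symbols such as "INS", "MET",
#' "AR" or "C3" collide with ordinary English words, and the exact-case
#' exception keeps precision high while staying configurable.
#'
#' @name entity_recognition
NULL

sentence_abbreviations <- function() {
  c("Fig", "fig", "Figs", "eg", "e.g", "ie", "i.e", "al", "Dr", "Mr", "Ms",
    "vs", "No", "approx", "cf", "St", "Ref")
}

#' Split text into sentences
#'
#' Boundaries are terminal punctuation (`.`, `!`, `?`) followed by
#' whitespace, guarded by an abbreviation blocklist (so "Fig. 2" does not
#' split). Total function: empty input yields an empty vector, and the
#' sentences concatenated with single spaces reconstruct a
#' single-space-separated input.
#'
#' @param text a character scalar.
#' @return character vector of sentences (no empty sentences).
#' @export
split_sentences <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  if (is.na(text) || !nzchar(str_trim(text))) return(character(0))
  m <- gregexpr("[.!?]+(?=\\s)", text, perl = TRUE)[[1]]
  bounds <- integer(0)
  if (m[1] != -1) {
    ends <- as.integer(m) + attr(m, "match.length") - 1L
    for (e in ends) {
      # word immediately before the punctuation
      before <- sub(".*?([A-Za-z.]+)$", "\\1", substr(text, 1, e - 1))
      before <- sub("\\.+$", "", before)
      if (!(before %in% sentence_abbreviations())) bounds <- c(bounds, e)
    }
  }
  starts <- c(1L, bounds + 1L)
  stops <- c(bounds, nchar(text))
  sents <- str_trim(substring(text, starts, stops))
  sents[nzchar(sents)]
}

#' Tokenize a sentence with character offsets
#'
#' Tokens are maximal runs of alphanumerics (internal hyphens and
#' apostrophes preserved, so "IL-10" is one token) or single punctuation
#' characters. Offsets are half-open `[start, end)`, 0-based, strictly
#' increasing and non-overlapping.
#'
#' @param sentence a character scalar.
#' @return a tibble with `token`, `start`, `end`.
#' @export
tokenize <- function(sentence) {
  stopifnot(is.character(sentence), length(sentence) == 1)
  m <- gregexpr("[A-Za-z0-9]+(?:[-'][A-Za-z0-9]+)*|[^A-Za-z0-9[:space:]]",
                sentence, perl = TRUE)[[1]]
  if (m[1] == -1) return(tibble(token = character(), start = integer(), end = integer()))
  start <- as.integer(m)
  len <- attr(m, "match.length")
  tibble(token = substring(sentence, start, start + len - 1L),
         start = start - 1L,
         end = .data$start + len)
}

# vectorized tokenizer: one regex pass over many texts, plain-list output
# (token / start / end vectors per text, 0-based half-open offsets)
tokenize_many <- function(texts) {
  ms <- gregexpr("[A-Za-z0-9]+(?:[-'][A-Za-z0-9]+)*|[^A-Za-z0-9[:space:]]",
                 texts, perl = TRUE)
  map2(as.list(texts), ms, function(txt, m) {
    if (m[1] == -1) {
      return(list(token = character(), start = integer(), end = integer()))
    }
    start <- as.integer(m)
    len <- attr(m, "match.length")
    list(token = substring(txt, start, start + len - 1L),
         start = start - 1L, end = start - 1L + len)
  })
}

# surface table: one row per surface form (symbol or synonym)
surface_table <- function(dictionary) {
  validate_dictionary(dictionary)
  syn <- tidyr::unnest(dictionary[c("symbol", "synonyms")], "synonyms")
  tibble(
    surface = c(dictionary$symbol, syn$synonyms),
    symbol = c(dictionary$symbol, syn$symbol)
  )
}

#' Match dictionary genes in one sentence
#'
#' Longest-match-first over token n-grams; overlapping candidates resolve
#' to the longer match, then the leftmost. Each matched surface maps to its
#' canonical symbol.
#'
#' @param sentence a character scalar.
#' @param dictionary gene dictionary tibble.
#' @param case_insensitive fold case when matching (default `TRUE`).
#' @param exact_short_max with case-insensitive matching, all-caps surfaces
#'   of at most this many characters still require exact case (default 3;
#'   set 0 to disable).
#' @return a tibble with `start`, `end` (0-based half-open character span),
#'   `surface`, `symbol`.
#' @export
match_genes <- function(sentence, dictionary, case_insensitive = TRUE,
                        exact_short_max = 3) {
  matcher <- build_matcher(dictionary, case_insensitive, exact_short_max)
  match_genes_impl(sentence, matcher)
}

# precompiled lookup structure shared across sentences
build_matcher <- function(dictionary, case_insensitive = TRUE,
                          exact_short_max = 3) {
  surf <- surface_table(dictionary)
  surf$n_tok <- map_int(surf$surface, function(s) nrow(tokenize(s)))
  exact_req <- !case_insensitive |
    (nchar(surf$surface) <= exact_short_max &
       surf$surface == str_to_upper(surf$surface))
  key <- ifelse(exact_req, surf$surface, str_to_upper(surf$surface))
  lut <- split(seq_len(nrow(surf)), paste0(surf$n_tok, "\r", key))
  # fast-path maps for single-token surfaces
  one <- surf$n_tok == 1
  exact_map <- stats::setNames(which(one & exact_req),
                               surf$surface[one & exact_req])
  folded_map <- stats::setNames(which(one & !exact_req),
                                str_to_upper(surf$surface[one & !exact_req]))
  list(surf = surf, exact_req = exact_req, lut = lut,
       exact_map = exact_map, folded_map = folded_map,
       max_n = max(surf$n_tok))
}

match_genes_impl <- function(sentence, matcher) {
  toks <- tokenize(sentence)
  empty <- tibble(start = integer(), end = integer(),
                  surface = character(), symbol = character())
  if (nrow(toks) == 0) return(empty)
  surf <- matcher$surf
  consumed <- rep(FALSE, nrow(toks))
  hits <- list()
  for (n in seq(min(matcher$max_n, nrow(toks)), 1)) {
    for (i in seq_len(nrow(toks) - n + 1)) {
      span <- i:(i + n - 1)
      if (any(consumed[span])) next
      cand <- substr(sentence, toks$start[i] + 1L, toks$end[i + n - 1])
      js <- unique(c(matcher$lut[[paste0(n, "\r", cand)]],
                     matcher$lut[[paste0(n, "\r", str_to_upper(cand))]]))
      # exact-case surfaces must match verbatim; folded surfaces fold
      ok <- map_lgl(js, function(j) {
        if (matcher$exact_req[j]) cand == surf$surface[j]
        else str_to_upper(cand) == str_to_upper(surf$surface[j])
      })
      js <- js[ok]
      if (length(js) == 0) next
      j <- js[1]
      hits[[length(hits) + 1]] <- tibble(
        start = toks$start[i], end = toks$end[i + n - 1],
        surface = cand, symbol = surf$symbol[j])
      consumed[span] <- TRUE
    }
  }
  if (length(hits) == 0) return(empty)
  bind_rows(hits) |> arrange(.data$start)
}

#' Annotate a corpus with gene mentions
#'
#' Runs sentence splitting and dictionary matching over every record.
#' Titles are excluded by default (`include_title = TRUE` prepends title
#' sentences). Deterministic; record order preserved; idempotent.
#'
#' @param corpus corpus tibble (`record_id`, `title`, `abstract`).
#' @param dictionary gene dictionary tibble.
#' @inheritParams match_genes
#' @param include_title also search the title.
#' @return an `annotated_corpus`: a tibble of mentions (`record_id`,
#'   `sentence_index`, `start`, `end`, `surface`, `symbol`) with the
#'   sentence table and record ids attached as attributes.
#' @export
annotate_corpus <- function(corpus, dictionary, case_insensitive = TRUE,
                            exact_short_max = 3, include_title = FALSE) {
  validate_corpus(corpus)
  sent_rows <- vector("list", nrow(corpus))
  for (i in seq_len(nrow(corpus))) {
    sents <- c(if (include_title) split_sentences(corpus$title[i]),
               split_sentences(corpus$abstract[i]))
    if (length(sents) > 0) {
      sent_rows[[i]] <- tibble(record_id = corpus$record_id[i],
                               sentence_index = seq_along(sents) - 1L,
                               sentence = sents)
    }
  }
  sentences <- bind_rows(sent_rows)
  if (nrow(sentences) == 0) {
    sentences <- tibble(record_id = character(), sentence_index = integer(),
                        sentence = character())
  }
  matcher <- build_matcher(dictionary, case_insensitive, exact_short_max)
  if (matcher$max_n == 1 && nrow(sentences) > 0) {
    # vectorized single-token path: one tokenizer pass, hashed lookup
    toks <- tokenize_many(sentences$sentence)
    nt <- map_int(toks, function(t) length(t$token))
    sent_of <- rep(seq_along(toks), nt)
    token <- unlist(map(toks, "token"), use.names = FALSE)
    start <- unlist(map(toks, "start"), use.names = FALSE)
    end <- unlist(map(toks, "end"), use.names = FALSE)
    j <- unname(matcher$exact_map[token])
    fj <- unname(matcher$folded_map[str_to_upper(token)])
    j[is.na(j)] <- fj[is.na(j)]
    hit <- !is.na(j)
    mentions <- tibble(
      record_id = sentences$record_id[sent_of[hit]],
      sentence_index = sentences$sentence_index[sent_of[hit]],
      start = start[hit], end = end[hit],
      surface = token[hit],
      symbol = matcher$surf$symbol[j[hit]]
    )
  } else {
    mention_rows <- vector("list", nrow(sentences))
    for (i in seq_len(nrow(sentences))) {
      m <- match_genes_impl(sentences$sentence[i], matcher)
      if (nrow(m) > 0) {
        m$record_id <- sentences$record_id[i]
        m$sentence_index <- sentences$sentence_index[i]
        mention_rows[[i]] <- m
      }
    }
    mentions <- bind_rows(mention_rows)
  }
  if (nrow(mentions) == 0) {
    mentions <- tibble(start = integer(), end = integer(), surface = character(),
                       symbol = character(), record_id = character(),
                       sentence_index = integer())
  }
  mentions <- mentions[c("record_id", "sentence_index", "start", "end",
                         "surface", "symbol")]
  structure(mentions,
            class = c("annotated_corpus", class(tibble())),
            sentences = sentences,
            record_ids = corpus$record_id)
}
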