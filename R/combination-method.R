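#' The gene-symptom-syndrome combination method
#'
#' A syndrome's symptoms are classified into main symptoms, Qi-deficiency
#' symptoms and blood-stasis symptoms. Symptom combinations are enumerated
#' as the Cartesian product of one option from each variable group, with
#' fixed terms appended to every combination. Per symptom, gene "hits"
#' count the documents in which the gene and the symptom co-occur; a
#' combination's gene set is the union of its symptoms' gene sets, and the
#' syndrome's core genes are the intersection of those sets across all
#' combinations ("the genes existing in each combination"). Symptoms with
#' no mapped genes are pruned before enumeration.
#'
#' Groups are lists of *options*; an option is one or more symptom terms
#' that enter a combination together (published combination lists pair
#' some terms, e.g. a respiratory-abnormality option that carries
#' lassitude with it).
#'
#' @name combination_method
NULL

#' Construct a symptom classification
#'
#' @param syndrome_name syndrome label.
#' @param main list of main-symptom options (each a character vector).
#' @param qi_deficiency list of Qi-deficiency options.
#' @param blood_stasis list of blood-stasis options.
#' @param fixed_terms character vector of terms included in every
#'   combination.
#' @param removed_terms character vector of pruned terms (normally filled
#'   by [prune_unmapped_symptoms()]).
#' @return a `symptom_classification`.
#' @export
symptom_classification <- function(syndrome_name, main, qi_deficiency,
                                   blood_stasis, fixed_terms = character(),
                                   removed_terms = character()) {
  as_opts <- function(x) {
    if (is.character(x)) x <- as.list(x)
    stopifnot(is.list(x), all(map_lgl(x, is.character)))
    map(x, unique)
  }
  main <- as_opts(main); qi_deficiency <- as_opts(qi_deficiency)
  blood_stasis <- as_opts(blood_stasis)
  groups <- list(main = unlist(main), qi = unlist(qi_deficiency),
                 blood = unlist(blood_stasis), fixed = fixed_terms)
  all_terms <- unlist(groups)
  if (anyDuplicated(all_terms) > 0) {
    stop_validation(paste0("symptom groups must be disjoint; duplicated: ",
                           paste(unique(all_terms[duplicated(all_terms)]), collapse = ", ")))
  }
  if (length(intersect(removed_terms, all_terms)) > 0) {
    stop_validation("removed_terms must not overlap the active groups")
  }
  structure(list(syndrome_name = syndrome_name, main = main,
                 qi_deficiency = qi_deficiency, blood_stasis = blood_stasis,
                 fixed_terms = fixed_terms, removed_terms = removed_terms),
            class = "symptom_classification")
}

#' @export
print.symptom_classification <- function(x, ...) {
  cat("<symptom_classification> ", x$syndrome_name, "\n",
      "  main: ", length(x$main), " option(s); Qi deficiency: ",
      length(x$qi_deficiency), "; blood stasis: ", length(x$blood_stasis),
      "; fixed: ", length(x$fixed_terms), " term(s); removed: ",
      length(x$removed_terms), "\n", sep = "")
  invisible(x)
}

#' Read / write a symptom classification as YAML
#'
#' @param path YAML file path.
#' @return `read_classification()`: a `symptom_classification`.
#' @export
read_classification <- function(path) {
  y <- yaml::read_yaml(path)
  need <- c("syndrome_name", "main", "qi_deficiency", "blood_stasis")
  miss <- setdiff(need, names(y))
  if (length(miss) > 0) {
    stop_validation(paste0("classification lacks field(s): ", paste(miss, collapse = ", ")))
  }
  symptom_classification(
    syndrome_name = y$syndrome_name,
    main = y$main, qi_deficiency = y$qi_deficiency,
    blood_stasis = y$blood_stasis,
    fixed_terms = unlist(y$fixed_terms) %||% character(),
    removed_terms = unlist(y$removed_terms) %||% character()
  )
}

#' @rdname read_classification
#' @param classification a `symptom_classification`.
#' @export
write_classification <- function(classification, path) {
  stopifnot(inherits(classification, "symptom_classification"))
  yaml::write_yaml(unclass(classification), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# case-insensitive token-subsequence match of a symptom term in a text
term_in_text <- function(term, text_tokens) {
  term_toks <- str_to_lower(tokenize(term)$token)
  k <- length(term_toks)
  if (k == 0) return(FALSE)
  n <- length(text_tokens)
  if (n < k) return(FALSE)
  for (i in seq_len(n - k + 1)) {
    if (all(text_tokens[i:(i + k - 1)] == term_toks)) return(TRUE)
  }
  FALSE
}

#' Count symptom-gene document hits in a corpus
#'
#' `hit(s, g)` is the number of records whose text contains symptom term
#' `s` (case-insensitive contiguous token match over title and abstract)
#' and at least one mention of gene `g`. The full symptom-by-gene grid over
#' the dictionary is returned, so absent genes give zero columns.
#'
#' @param corpus corpus tibble.
#' @param dictionary gene dictionary tibble.
#' @param symptom_terms character vector of symptom terms.
#' @inheritParams match_genes
#' @return a `symptom_gene_hits` tibble: `symptom`, `gene`, `hits`.
#' @export
count_symptom_gene_hits <- function(corpus, dictionary, symptom_terms,
                                    case_insensitive = TRUE,
                                    exact_short_max = 3) {
  validate_corpus(corpus)
  if (length(symptom_terms) == 0) stop_invalid("symptom_terms must be nonempty")
  ann <- annotate_corpus(corpus, dictionary, case_insensitive = case_insensitive,
                         exact_short_max = exact_short_max, include_title = TRUE)
  rec_genes <- distinct(as_tibble(ann), .data$record_id, .data$symbol)
  toks <- map(seq_len(nrow(corpus)), function(i) {
    str_to_lower(tokenize(paste(corpus$title[i], corpus$abstract[i]))$token)
  })
  sym_rec <- bind_rows(map(symptom_terms, function(s) {
    present <- map_lgl(toks, function(tt) term_in_text(s, tt))
    tibble(symptom = s, record_id = corpus$record_id[present])
  }))
  grid <- tidyr::expand_grid(symptom = symptom_terms,
                             gene = sort(dictionary$symbol))
  counts <- inner_join(sym_rec, rec_genes, by = "record_id",
                       relationship = "many-to-many") |>
    count(.data$symptom, .data$symbol, name = "hits") |>
    rename(gene = "symbol")
  out <- left_join(grid, counts, by = c("symptom", "gene")) |>
    mutate(hits = tidyr::replace_na(.data$hits, 0L))
  structure(out, class = c("symptom_gene_hits", class(tibble())))
}

as_hits <- function(hits) {
  stopifnot(is.data.frame(hits), all(c("symptom", "gene", "hits") %in% names(hits)))
  if (any(hits$hits < 0)) stop_validation("hit counts must be nonnegative")
  hits
}

#' Genes related to one symptom
#'
#' @param hits a symptom-gene hits tibble (`symptom`, `gene`, `hits`).
#' @param symptom a symptom term present in `hits`.
#' @param min_hits minimum document count to keep a gene (default 1).
#' @return sorted character vector of gene symbols.
#' @export
genes_for_symptom <- function(hits, symptom, min_hits = 1) {
  hits <- as_hits(hits)
  if (!symptom %in% hits$symptom) {
    stop_lookup(paste0("symptom '", symptom, "' not present in hits"))
  }
  sort(unique(hits$gene[hits$symptom == symptom & hits$hits >= min_hits]))
}

#' Prune symptoms with no mapped genes
#'
#' Symptoms whose gene set is empty move to `removed_terms`; an option all
#' of whose terms are pruned is dropped. Emptying a whole group is a
#' validation error naming the group.
#'
#' @param classification a `symptom_classification`.
#' @param hits symptom-gene hits covering all classification terms.
#' @param min_hits minimum hits for a gene to count as mapped.
#' @return the pruned `symptom_classification`.
#' @export
prune_unmapped_symptoms <- function(classification, hits, min_hits = 1) {
  stopifnot(inherits(classification, "symptom_classification"))
  hits <- as_hits(hits)
  mapped <- function(term) {
    length(genes_for_symptom(hits, term, min_hits = min_hits)) > 0
  }
  removed <- character(0)
  prune_opts <- function(opts, group) {
    kept <- list()
    for (o in opts) {
      keep <- map_lgl(o, mapped)
      removed <<- c(removed, o[!keep])
      if (any(keep)) kept[[length(kept) + 1]] <- o[keep]
    }
    if (length(kept) == 0) {
      stop_validation(paste0("pruning emptied the '", group, "' group"))
    }
    kept
  }
  main <- prune_opts(classification$main, "main")
  qi <- prune_opts(classification$qi_deficiency, "qi_deficiency")
  blood <- prune_opts(classification$blood_stasis, "blood_stasis")
  fixed_keep <- map_lgl(classification$fixed_terms, mapped)
  removed <- c(removed, classification$fixed_terms[!fixed_keep])
  symptom_classification(
    syndrome_name = classification$syndrome_name,
    main = main, qi_deficiency = qi, blood_stasis = blood,
    fixed_terms = classification$fixed_terms[fixed_keep],
    removed_terms = unique(c(classification$removed_terms, removed))
  )
}

#' Enumerate symptom combinations
#'
#' Cartesian product of one main option, one Qi-deficiency option and one
#' blood-stasis option, with fixed terms inserted between the Qi and
#' blood-stasis parts (matching the published combination layout:
#' main + Qi + fixed + blood). Combinations are deduplicated (as term
#' sets) and ordered main-major, then Qi, then blood stasis.
#'
#' @param classification a pruned `symptom_classification`; every group
#'   must be nonempty.
#' @return a tibble `combination` (integer id), `label` ("A + B + ..."),
#'   and list-column `terms`.
#' @export
enumerate_combinations <- function(classification) {
  stopifnot(inherits(classification, "symptom_classification"))
  for (g in c("main", "qi_deficiency", "blood_stasis")) {
    if (length(classification[[g]]) == 0) {
      stop_validation(paste0("group '", g, "' has no options"))
    }
  }
  rows <- list()
  for (m in classification$main) {
    for (q in classification$qi_deficiency) {
      for (b in classification$blood_stasis) {
        terms <- c(m, q, classification$fixed_terms, b)
        rows[[length(rows) + 1]] <- tibble(label = paste(terms, collapse = " + "),
                                           terms = list(terms))
      }
    }
  }
  out <- bind_rows(rows)
  key <- map_chr(out$terms, function(t) paste(sort(t), collapse = "\r"))
  out <- out[!duplicated(key), ]
  out$combination <- seq_len(nrow(out))
  out[c("combination", "label", "terms")]
}

#' Core genes across symptom combinations
#'
#' Each combination's gene set is the union of [genes_for_symptom()] over
#' its terms ("within = union"); the result is the intersection of those
#' sets over all combinations. `within = "intersection"` instead intersects
#' gene sets inside each combination.
#'
#' @param combinations tibble from [enumerate_combinations()].
#' @param hits symptom-gene hits covering all combination terms.
#' @param min_hits minimum document count per symptom-gene link.
#' @param within how genes aggregate inside one combination.
#' @return sorted character vector of core gene symbols (possibly empty).
#' @export
core_genes <- function(combinations, hits, min_hits = 1,
                       within = c("union", "intersection")) {
  within <- match.arg(within)
  stopifnot(nrow(combinations) >= 1)
  hits <- as_hits(hits)
  sets <- map(combinations$terms, function(terms) {
    gsets <- map(terms, function(s) genes_for_symptom(hits, s, min_hits = min_hits))
    if (within == "union") Reduce(union, gsets, character(0)) else
      Reduce(intersect, gsets)
  })
  sort(Reduce(intersect, sets))
}
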