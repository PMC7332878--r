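#' Readers and writers for pipeline exchange formats
#'
#' The pipeline touches a small set of plain-text formats: MEDLINE-style
#' PubMed XML and a TSV corpus (one abstract per row), a TSV gene dictionary
#' (symbol plus synonyms), a TSV gene-gene edge list (the knowledge base),
#' a CSV map from traditional-Chinese-medicine symptom terms to modern
#' symptom terms, and Pajek `.net` network files. All readers are total over
#' their declared dialects: any failure raises a typed condition, never a
#' silent truncation. TSV files are UTF-8 and unquoted; CSV files use
#' RFC-style quoting.
#'
#' @name io_formats
NULL

validate_corpus <- function(corpus) {
  stopifnot(is.data.frame(corpus))
  need <- c("record_id", "title", "abstract")
  miss <- setdiff(need, names(corpus))
  if (length(miss) > 0) {
    stop_validation(paste0("corpus lacks column(s): ", paste(miss, collapse = ", ")))
  }
  dup <- corpus$record_id[duplicated(corpus$record_id)]
  if (length(dup) > 0) {
    stop_validation(paste0("duplicate record_id: ", paste(unique(dup), collapse = ", ")))
  }
  if (anyNA(corpus$abstract)) {
    stop_validation("abstract may be empty but not absent (NA found)")
  }
  invisible(corpus)
}

#' Read a MEDLINE-style PubMed XML corpus
#'
#' Parses `PubmedArticle` elements into one record per article. A missing
#' `AbstractText` yields an empty abstract with a warning; duplicate record
#' identifiers are a validation error.
#'
#' @param path path to an XML file.
#' @return a tibble with columns `record_id`, `title`, `abstract` and a
#'   list-column `keywords`.
#' @export
read_medline_xml <- function(path) {
  doc <- tryCatch(
    xml2::read_xml(path),
    error = function(e) stop_parse(paste0("malformed XML in '", path, "': ", conditionMessage(e)))
  )
  arts <- xml2::xml_find_all(doc, ".//PubmedArticle")
  if (length(arts) == 0) {
    return(tibble(record_id = character(), title = character(),
                  abstract = character(), keywords = list()))
  }
  recs <- map(arts, function(a) {
    pmid <- xml2::xml_text(xml2::xml_find_first(a, ".//MedlineCitation/PMID"))
    title <- xml2::xml_text(xml2::xml_find_first(a, ".//ArticleTitle"))
    abs_node <- xml2::xml_find_first(a, ".//Abstract/AbstractText")
    abstract <- if (inherits(abs_node, "xml_missing")) NA_character_ else xml2::xml_text(abs_node)
    kw <- xml2::xml_text(xml2::xml_find_all(a, ".//KeywordList/Keyword"))
    list(record_id = pmid, title = title, abstract = abstract, keywords = kw)
  })
  out <- tibble(
    record_id = map_chr(recs, "record_id"),
    title = map_chr(recs, "title"),
    abstract = map_chr(recs, "abstract"),
    keywords = map(recs, "keywords")
  )
  if (anyNA(out$abstract)) {
    warn(paste0(sum(is.na(out$abstract)), " article(s) lack an abstract; using empty string"))
    out$abstract[is.na(out$abstract)] <- ""
  }
  validate_corpus(out)
  out
}

#' Write a corpus as MEDLINE-style PubMed XML
#'
#' @param corpus tibble with `record_id`, `title`, `abstract` and optionally
#'   a `keywords` list-column.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_medline_xml <- function(corpus, path) {
  validate_corpus(corpus)
  root <- xml2::xml_new_root("PubmedArticleSet")
  for (i in seq_len(nrow(corpus))) {
    art <- xml2::xml_add_child(root, "PubmedArticle")
    cit <- xml2::xml_add_child(art, "MedlineCitation")
    xml2::xml_add_child(cit, "PMID", corpus$record_id[i])
    a <- xml2::xml_add_child(cit, "Article")
    xml2::xml_add_child(a, "ArticleTitle", corpus$title[i])
    ab <- xml2::xml_add_child(a, "Abstract")
    xml2::xml_add_child(ab, "AbstractText", corpus$abstract[i])
    kws <- if ("keywords" %in% names(corpus)) corpus$keywords[[i]] else character()
    if (length(kws) > 0) {
      kl <- xml2::xml_add_child(cit, "KeywordList")
      for (k in kws) xml2::xml_add_child(kl, "Keyword", k)
    }
  }
  xml2::write_xml(root, path)
  invisible(path)
}

#' Read / write a TSV corpus (id, title, abstract)
#'
#' @param path file path.
#' @return `read_corpus_tsv()`: a corpus tibble; `write_corpus_tsv()`:
#'   `path`, invisibly.
#' @export
read_corpus_tsv <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) == 0) stop_validation(paste0("empty corpus file: ", path))
  parts <- str_split(lines, "\t")
  bad <- which(lengths(parts) < 3)
  if (length(bad) > 0) {
    stop_parse(paste0("corpus TSV line ", bad[1], " has fewer than 3 fields"))
  }
  out <- tibble(
    record_id = map_chr(parts, 1),
    title = map_chr(parts, 2),
    abstract = map_chr(parts, 3),
    keywords = map(parts, function(p) if (length(p) > 3 && nzchar(p[4])) strsplit(p[4], ";", fixed = TRUE)[[1]] else character())
  )
  validate_corpus(out)
  out
}

#' @rdname read_corpus_tsv
#' @param corpus a corpus tibble.
#' @export
write_corpus_tsv <- function(corpus, path) {
  validate_corpus(corpus)
  kws <- if ("keywords" %in% names(corpus)) {
    map_chr(corpus$keywords, paste, collapse = ";")
  } else rep("", nrow(corpus))
  lines <- paste(corpus$record_id, corpus$title, corpus$abstract, kws, sep = "\t")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

validate_dictionary <- function(dict) {
  stopifnot(is.data.frame(dict), all(c("symbol", "synonyms") %in% names(dict)))
  if (nrow(dict) == 0) stop_validation("gene dictionary is empty")
  if (any(!nzchar(dict$symbol))) stop_validation("empty gene symbol in dictionary")
  folded <- str_to_upper(dict$symbol)
  dup <- unique(dict$symbol[duplicated(folded)])
  if (length(dup) > 0) {
    stop_validation(paste0("duplicate symbols after case-folding: ",
                           paste(dup, collapse = ", ")))
  }
  # a synonym may never collide with another entry's symbol or synonyms:
  # silent merging would corrupt downstream counts.
  syn_tbl <- tidyr::unnest(dict[c("symbol", "synonyms")], "synonyms")
  if (nrow(syn_tbl) > 0) {
    syn_folded <- str_to_upper(syn_tbl$synonyms)
    hit <- syn_folded %in% folded
    if (any(hit)) {
      stop_validation(paste0("synonym collides with a symbol: ",
                             paste(unique(syn_tbl$synonyms[hit]), collapse = ", ")))
    }
    if (anyDuplicated(syn_folded) > 0) {
      stop_validation(paste0("synonym shared by multiple entries: ",
                             paste(unique(syn_tbl$synonyms[duplicated(syn_folded)]), collapse = ", ")))
    }
  }
  invisible(dict)
}

#' Read a gene dictionary from ragged TSV
#'
#' Each line holds a canonical symbol followed by zero or more synonym
#' fields. Synonyms identical to their own symbol after case-folding are
#' dropped; a synonym colliding with another entry's symbol (or synonym) is
#' a validation error, as are duplicate symbols.
#'
#' @param path file path.
#' @return a tibble with `symbol` and list-column `synonyms`.
#' @export
read_gene_dictionary <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(str_trim(lines))]
  if (length(lines) == 0) stop_validation(paste0("empty dictionary file: ", path))
  parts <- str_split(lines, "\t")
  dict <- tibble(
    symbol = map_chr(parts, 1),
    synonyms = map(parts, function(p) {
      syn <- p[-1]
      syn <- syn[nzchar(syn)]
      # drop synonyms equal to own symbol after case-folding
      unique(syn[str_to_upper(syn) != str_to_upper(p[1])])
    })
  )
  validate_dictionary(dict)
  dict
}

#' @rdname read_gene_dictionary
#' @param dict a gene dictionary tibble.
#' @export
write_gene_dictionary <- function(dict, path) {
  validate_dictionary(dict)
  lines <- map_chr(seq_len(nrow(dict)), function(i) {
    paste(c(dict$symbol[i], dict$synonyms[[i]]), collapse = "\t")
  })
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a gene-gene knowledge base (TSV edge list)
#'
#' Two symbol columns plus an optional numeric score. Pairs are stored
#' unordered (lexicographic canonical order); self-pairs are skipped with a
#' warning; duplicates collapse keeping the maximum score.
#'
#' @param path file path.
#' @return a tibble with `gene_a`, `gene_b`, `score` (NA when absent).
#' @export
read_knowledge_base <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(str_trim(lines))]
  parts <- str_split(lines, "\t")
  bad <- which(lengths(parts) < 2)
  if (length(bad) > 0) {
    stop_parse(paste0("knowledge-base line ", bad[1], " has fewer than 2 fields"))
  }
  a <- map_chr(parts, 1)
  b <- map_chr(parts, 2)
  sc_raw <- map_chr(parts, function(p) if (length(p) >= 3) p[3] else NA_character_)
  score <- suppressWarnings(as.numeric(sc_raw))
  nonnum <- !is.na(sc_raw) & nzchar(sc_raw) & is.na(score)
  if (any(nonnum)) {
    stop_validation(paste0("non-numeric score on line ", which(nonnum)[1],
                           ": '", sc_raw[nonnum][1], "'"))
  }
  self <- a == b
  if (any(self)) {
    warn(paste0("skipping ", sum(self), " self-pair row(s), e.g. (",
                a[self][1], ", ", a[self][1], ")"))
  }
  kb <- canonical_pair(a[!self], b[!self])
  kb$score <- score[!self]
  kb |>
    group_by(.data$gene_a, .data$gene_b) |>
    summarise(score = if (all(is.na(.data$score))) NA_real_ else max(.data$score, na.rm = TRUE),
              .groups = "drop")
}

#' @rdname read_knowledge_base
#' @param kb a knowledge-base tibble (`gene_a`, `gene_b`, optional `score`).
#' @export
write_knowledge_base <- function(kb, path) {
  stopifnot(all(c("gene_a", "gene_b") %in% names(kb)))
  sc <- if ("score" %in% names(kb)) ifelse(is.na(kb$score), "", format(kb$score)) else NULL
  lines <- if (is.null(sc)) paste(kb$gene_a, kb$gene_b, sep = "\t") else
    paste(kb$gene_a, kb$gene_b, sc, sep = "\t")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Write / read a gene network in Pajek .net format
#'
#' Standard Pajek dialect: a `*Vertices n` section with 1-based indices and
#' quoted labels, then `*Edges` with index pairs. Node identity is the gene
#' symbol; indices exist only inside the file. `read_pajek(write_pajek(g))`
#' reproduces labels and the edge set exactly.
#'
#' @param network a `gene_network` (see [build_network()]) or a list with
#'   `nodes` (character) and `edges` (tibble `gene_a`, `gene_b`).
#' @param path file path.
#' @return `write_pajek()`: `path` invisibly; `read_pajek()`: a
#'   `gene_network`.
#' @export
write_pajek <- function(network, path) {
  nodes <- sort(network$nodes)
  if (length(nodes) == 0) stop_validation("cannot write a network with no nodes")
  idx <- stats::setNames(seq_along(nodes), nodes)
  lines <- c(
    paste0("*Vertices ", length(nodes)),
    paste0(seq_along(nodes), ' "', nodes, '"'),
    "*Edges"
  )
  if (nrow(network$edges) > 0) {
    lines <- c(lines, paste(idx[network$edges$gene_a], idx[network$edges$gene_b]))
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_pajek
#' @export
read_pajek <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  vhead <- grep("^\\*Vertices", lines, ignore.case = TRUE)
  ehead <- grep("^\\*Edges", lines, ignore.case = TRUE)
  if (length(vhead) != 1 || length(ehead) != 1) {
    stop_parse("expected one *Vertices and one *Edges section")
  }
  n <- as.integer(sub("^\\*Vertices\\s+", "", lines[vhead], ignore.case = TRUE))
  vlines <- lines[(vhead + 1):(ehead - 1)]
  m <- regmatches(vlines, regexec('^\\s*(\\d+)\\s+"(.*)"\\s*$', vlines))
  bad <- which(lengths(m) != 3)
  if (length(bad) > 0) {
    stop_parse(paste0("cannot parse vertex line ", vhead + bad[1], ": '",
                      vlines[bad[1]], "'"))
  }
  vidx <- as.integer(map_chr(m, 2))
  labels <- map_chr(m, 3)
  if (length(labels) != n || any(sort(vidx) != seq_len(n))) {
    stop_parse("vertex indices do not form 1..n")
  }
  labels <- labels[order(vidx)]
  edges <- tibble(gene_a = character(), gene_b = character())
  if (ehead < length(lines)) {
    elines <- lines[(ehead + 1):length(lines)]
    elines <- elines[nzchar(str_trim(elines))]
    if (length(elines) > 0) {
      em <- regmatches(elines, regexec("^\\s*(\\d+)\\s+(\\d+)", elines))
      bad <- which(lengths(em) != 3)
      if (length(bad) > 0) {
        stop_parse(paste0("cannot parse edge line ", ehead + bad[1], ": '",
                          elines[bad[1]], "'"))
      }
      ia <- as.integer(map_chr(em, 2)); ib <- as.integer(map_chr(em, 3))
      out_of_range <- which(ia < 1 | ia > n | ib < 1 | ib > n)
      if (length(out_of_range) > 0) {
        stop_parse(paste0("unknown vertex index on line ", ehead + out_of_range[1]))
      }
      edges <- distinct(canonical_pair(labels[ia], labels[ib]))
    }
  }
  new_gene_network(labels, edges)
}

#' Read a TCM-to-modern symptom term map (CSV)
#'
#' Expects columns `tcm_term` and `modern_term`; rows are grouped so each
#' source term carries all its modern translations, deduplicated.
#'
#' @param path CSV file path.
#' @return a tibble with `tcm_term` and list-column `modern_terms`.
#' @export
read_term_map <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  need <- c("tcm_term", "modern_term")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop_validation(paste0("term map lacks column(s): ", paste(miss, collapse = ", ")))
  }
  as_tibble(df) |>
    distinct(.data$tcm_term, .data$modern_term) |>
    group_by(.data$tcm_term) |>
    summarise(modern_terms = list(.data$modern_term), .groups = "drop")
}

#' @rdname read_term_map
#' @param term_map a term-map tibble as returned by [read_term_map()].
#' @export
write_term_map <- function(term_map, path) {
  long <- tidyr::unnest(term_map, "modern_terms") |>
    rename(modern_term = "modern_terms")
  utils::write.csv(long, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Translate a TCM symptom term through a term map
#'
#' @param term_map tibble from [read_term_map()].
#' @param term a TCM term to translate.
#' @return character vector of modern terms.
#' @export
map_term <- function(term_map, term) {
  i <- match(term, term_map$tcm_term)
  if (is.na(i)) stop_lookup(paste0("no mapping for term '", term, "'"))
  term_map$modern_terms[[i]]
}
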