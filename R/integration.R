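#' Integrating decomposition and combination results
#'
#' Per syndrome, the decomposition track (relation extraction plus network
#' scoring) and the combination track (symptom combinations plus core
#' genes) each yield a gene set; "matching" the two methods is their exact
#' intersection. Matched sets are then intersected across diseases to find
#' the genes shared by syndromes of different diseases, optionally followed
#' by hypergeometric over-representation analysis against a gene-set
#' collection.
#'
#' @name integration
NULL

#' A syndrome gene set with provenance
#'
#' @param syndrome_name syndrome label.
#' @param method one of "decomposition", "combination", "matched".
#' @param genes character vector of gene symbols.
#' @return a `syndrome_gene_set`.
#' @export
syndrome_gene_set <- function(syndrome_name,
                              method = c("decomposition", "combination", "matched"),
                              genes) {
  method <- match.arg(method)
  structure(list(syndrome_name = syndrome_name, method = method,
                 genes = sort(unique(genes))),
            class = "syndrome_gene_set")
}

#' @export
print.syndrome_gene_set <- function(x, ...) {
  cat("<syndrome_gene_set> ", x$syndrome_name, " [", x$method, "]: ",
      length(x$genes), " genes\n", sep = "")
  invisible(x)
}

#' Match decomposition and combination results for one syndrome
#'
#' @param decomposition_set,combination_set `syndrome_gene_set`s for the
#'   same syndrome.
#' @return a matched `syndrome_gene_set` (exact intersection).
#' @export
intersect_method_results <- function(decomposition_set, combination_set) {
  stopifnot(inherits(decomposition_set, "syndrome_gene_set"),
            inherits(combination_set, "syndrome_gene_set"))
  if (decomposition_set$syndrome_name != combination_set$syndrome_name) {
    stop_validation(paste0("syndrome mismatch: '", decomposition_set$syndrome_name,
                           "' vs '", combination_set$syndrome_name, "'"))
  }
  syndrome_gene_set(decomposition_set$syndrome_name, "matched",
                    intersect(decomposition_set$genes, combination_set$genes))
}

#' Genes shared across two diseases
#'
#' @param set_a,set_b matched `syndrome_gene_set`s (or character vectors).
#' @return sorted character vector of shared gene symbols.
#' @export
shared_across_diseases <- function(set_a, set_b) {
  ga <- if (inherits(set_a, "syndrome_gene_set")) set_a$genes else set_a
  gb <- if (inherits(set_b, "syndrome_gene_set")) set_b$genes else set_b
  sort(intersect(ga, gb))
}

#' Hypergeometric over-representation analysis
#'
#' Per gene set, the upper-tail hypergeometric probability of observing at
#' least the overlap between the query and the set within the universe,
#' with Benjamini-Hochberg adjustment across sets.
#'
#' @param query_genes character vector of query genes (subset of the
#'   universe).
#' @param gene_set_collection named list of character vectors, or a GMT
#'   tibble from [read_gmt()].
#' @param universe character vector of all eligible genes.
#' @return a tibble `set_name`, `set_size`, `overlap_size`, `overlap`
#'   (list-column), `p_value`, `adjusted_p`, sorted by p-value.
#' @export
enrich <- function(query_genes, gene_set_collection, universe) {
  if (is.data.frame(gene_set_collection)) {
    gene_set_collection <- stats::setNames(gene_set_collection$members,
                                           gene_set_collection$set_name)
  }
  stopifnot(is.list(gene_set_collection), !is.null(names(gene_set_collection)))
  universe <- unique(universe)
  query_genes <- unique(query_genes)
  off <- setdiff(query_genes, universe)
  if (length(off) > 0) {
    stop_validation(paste0("query genes outside the universe: ",
                           paste(off, collapse = ", ")))
  }
  for (nm in names(gene_set_collection)) {
    off <- setdiff(gene_set_collection[[nm]], universe)
    if (length(off) > 0) {
      stop_validation(paste0("gene set '", nm, "' outside the universe: ",
                             paste(off, collapse = ", ")))
    }
  }
  N <- length(universe); n <- length(query_genes)
  rows <- imap(gene_set_collection, function(set, nm) {
    set <- unique(set)
    K <- length(set)
    ov <- intersect(query_genes, set)
    k <- length(ov)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    tibble(set_name = nm, set_size = K, overlap_size = k,
           overlap = list(sort(ov)), p_value = p)
  })
  out <- bind_rows(rows)
  out$adjusted_p <- stats::p.adjust(out$p_value, method = "BH")
  arrange(out, .data$p_value, .data$set_name)
}

#' Read / write GMT gene-set collections
#'
#' GMT lines are `set_name<TAB>description<TAB>member...`.
#'
#' @param path GMT file path.
#' @return `read_gmt()`: a tibble `set_name`, `description`, `members`
#'   (list-column).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(str_trim(lines))]
  parts <- str_split(lines, "\t")
  bad <- which(lengths(parts) < 3)
  if (length(bad) > 0) {
    stop_parse(paste0("GMT line ", bad[1], " has fewer than 3 fields"))
  }
  tibble(set_name = map_chr(parts, 1),
         description = map_chr(parts, 2),
         members = map(parts, function(p) unique(p[-(1:2)])))
}

#' @rdname read_gmt
#' @param collection a GMT tibble.
#' @export
write_gmt <- function(collection, path) {
  lines <- map_chr(seq_len(nrow(collection)), function(i) {
    paste(c(collection$set_name[i], collection$description[i],
            collection$members[[i]]), collapse = "\t")
  })
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("pipeline stage '", stage, "' failed: ", conditionMessage(e)),
          class = c("syndromine_stage_error", "syndromine_error"),
          stage = stage, parent = e)
  })
}

#' Assemble a pipeline configuration
#'
#' Either `synthetic` (a [synthetic_config()]; corpora, knowledge base and
#' symptom structures are generated) or `data` (explicit inputs: a
#' `dictionary`, a `knowledge_base`, and per-syndrome lists with `corpus`,
#' `hits` and `classification`) must be supplied.
#'
#' @param synthetic optional [synthetic_config()].
#' @param data optional explicit-input list (see above).
#' @param syndromes syndrome names for synthetic mode.
#' @param n_planted_shared planted shared genes in synthetic mode.
#' @param threshold relation decision threshold.
#' @param edges_from take network edges from model predictions or raw
#'   knowledge-base flags.
#' @param min_hits minimum symptom-gene document count.
#' @param zjw optional named ZJW vector by subnet id (applied per syndrome).
#' @param gene_sets optional named list (or GMT tibble) for enrichment of
#'   the shared gene set.
#' @param mil_hyperparams passed to [train_mil()].
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(synthetic = NULL, data = NULL,
                            syndromes = c("syndrome_a", "syndrome_b"),
                            n_planted_shared = 4, threshold = 0.5,
                            edges_from = c("model", "flags"), min_hits = 1,
                            zjw = NULL, gene_sets = NULL,
                            mil_hyperparams = list()) {
  edges_from <- match.arg(edges_from)
  if (is.null(synthetic) && is.null(data)) {
    stop_invalid("pipeline_config needs `synthetic` or `data`")
  }
  structure(list(synthetic = synthetic, data = data, syndromes = syndromes,
                 n_planted_shared = n_planted_shared, threshold = threshold,
                 edges_from = edges_from, min_hits = min_hits, zjw = zjw,
                 gene_sets = gene_sets, mil_hyperparams = mil_hyperparams),
            class = "pipeline_config")
}

#' Run the full two-track pipeline
#'
#' Per syndrome: annotation, bag generation, multi-instance relation
#' extraction, network construction, community decomposition and gene
#' ranking (decomposition track); symptom pruning, combination enumeration
#' and core-gene intersection (combination track); then per-syndrome
#' matching and the cross-disease shared gene set, with optional
#' enrichment. Fully deterministic given the seeds in the configuration;
#' any stage failure aborts with the stage name.
#'
#' @param config a `pipeline_config`.
#' @return an `integration_report`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  timings <- list()
  clock <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- with_stage(stage, expr)
    timings[[stage]] <<- proc.time()[["elapsed"]] - t0
    out
  }
  if (!is.null(config$synthetic)) {
    bundle <- clock("simulate", gen_syndrome_bundle(
      config$synthetic, syndromes = config$syndromes,
      n_planted_shared = config$n_planted_shared))
    dictionary <- bundle$dictionary
    kb <- bundle$knowledge_base
    inputs <- map(bundle$syndromes, function(s) {
      list(corpus = s$corpus, hits = s$symptoms$hits,
           classification = s$classification)
    })
    seed <- config$synthetic$seed
    planted <- bundle$planted_shared
  } else {
    dictionary <- config$data$dictionary
    kb <- config$data$knowledge_base
    inputs <- config$data$syndromes
    seed <- config$data$seed %||% 1L
    planted <- character(0)
    if (is.null(dictionary)) stop_invalid("explicit data needs a dictionary")
  }

  syn_results <- list()
  for (s in names(inputs)) {
    inp <- inputs[[s]]
    ann <- clock(paste0(s, "/ner"), annotate_corpus(inp$corpus, dictionary))
    bags <- clock(paste0(s, "/relations"), {
      if (is.null(kb)) stop_invalid("no knowledge base configured")
      generate_bags(ann, kb)
    })
    preds <- clock(paste0(s, "/relations"), {
      if (config$edges_from == "model") {
        model <- train_mil(bags, hyperparams = config$mil_hyperparams,
                           seed = sub_seed(seed, paste0("mil_", s)))
        predict_relations(model, bags, threshold = config$threshold)
      } else {
        tibble(gene_a = bags$gene_a, gene_b = bags$gene_b,
               score = as.numeric(bags$flag), label = bags$flag,
               n_instances = bags$n_instances)
      }
    })
    net <- clock(paste0(s, "/network"), build_network(preds))
    ranking <- clock(paste0(s, "/network"), {
      partition <- detect_communities(net, seed = sub_seed(seed, paste0("net_", s)))
      list(partition = partition,
           ranking = rank_genes(net, partition, zjw_map = config$zjw))
    })
    comb <- clock(paste0(s, "/combine"), {
      pruned <- prune_unmapped_symptoms(inp$classification, inp$hits,
                                        min_hits = config$min_hits)
      combos <- enumerate_combinations(pruned)
      list(combinations = combos,
           genes = core_genes(combos, inp$hits, min_hits = config$min_hits))
    })
    dec_set <- syndrome_gene_set(s, "decomposition", net$nodes)
    com_set <- syndrome_gene_set(s, "combination", comb$genes)
    syn_results[[s]] <- list(
      decomposition = dec_set, combination = com_set,
      matched = intersect_method_results(dec_set, com_set),
      ranking = ranking$ranking,
      n_subnets = nrow(ranking$partition$subnets),
      combinations = comb$combinations$label)
  }

  shared <- clock("integrate", {
    Reduce(function(a, b) sort(intersect(a, b)),
           map(syn_results, function(r) r$matched$genes))
  })
  enrichment <- NULL
  if (!is.null(config$gene_sets) && length(shared) > 0) {
    enrichment <- clock("enrich",
                        enrich(shared, config$gene_sets, sort(dictionary$symbol)))
  }
  cfg_hash <- rlang::hash(unclass(config))
  report <- structure(list(
    syndromes = syn_results,
    shared = shared,
    enrichment = enrichment,
    planted_shared = planted,
    metadata = list(seed = seed, config_hash = cfg_hash,
                    n_genes = nrow(dictionary),
                    syndrome_names = names(inputs))
  ), class = "integration_report")
  attr(report, "timings") <- timings
  report
}

#' @export
print.integration_report <- function(x, ...) {
  cat("<integration_report> ", length(x$syndromes), " syndrome(s); shared genes: ",
      length(x$shared), "\n", sep = "")
  for (s in names(x$syndromes)) {
    r <- x$syndromes[[s]]
    cat("  ", s, ": decomposition ", length(r$decomposition$genes),
        " | combination ", length(r$combination$genes),
        " | matched ", length(r$matched$genes),
        " | subnets ", r$n_subnets, "\n", sep = "")
  }
  invisible(x)
}

#' Write an integration report as JSON
#'
#' Stage timings (carried as an attribute) are excluded, so reports from
#' identical configurations and seeds are byte-identical.
#'
#' @param report an `integration_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_integration_report <- function(report, path) {
  stopifnot(inherits(report, "integration_report"))
  ser <- list(
    metadata = report$metadata,
    shared = report$shared,
    planted_shared = report$planted_shared,
    syndromes = map(report$syndromes, function(r) {
      list(decomposition = r$decomposition$genes,
           combination = r$combination$genes,
           matched = r$matched$genes,
           n_subnets = r$n_subnets,
           combinations = r$combinations,
           ranking = as.data.frame(r$ranking))
    }),
    enrichment = if (!is.null(report$enrichment)) {
      as.data.frame(select(report$enrichment, -"overlap"))
    }
  )
  jsonlite::write_json(ser, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}
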