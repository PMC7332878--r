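#' Distant-supervision multi-instance relation extraction
#'
#' Gene pairs co-mentioned anywhere in the corpus form bags of evidence
#' sentences, labeled 1 when the pair exists in the protein-relation
#' knowledge base (distant supervision) and 0 otherwise. A sparse
#' multi-instance classifier then scores each bag: an L1-regularised
#' logistic instance scorer is pooled with a log-sum-exp smooth maximum and
#' trained on the bag-level flags by proximal gradient descent. The bag
#' construction follows the classical generate-bag scheme: one bag per
#' distinct unordered pair, globally deduplicated, instances aggregated
#' across the whole corpus. Instances are sentence-level co-mentions; when
#' a pair is co-mentioned only at abstract level (the two genes never share
#' a sentence anywhere), a document-level instance is built from each
#' gene's mention sentence.
#'
#' @name relation_extraction
NULL

#' Build labeled bags from an annotated corpus
#'
#' @param annotated an `annotated_corpus` from [annotate_corpus()].
#' @param knowledge_base tibble with `gene_a`, `gene_b`.
#' @return a `bag_set` tibble: `gene_a`, `gene_b`, `flag` (1 if the pair is
#'   in the knowledge base), `n_instances`, and a list-column `instances`
#'   (each a tibble `record_id`, `sentence_index`, `text`, `start_a`,
#'   `end_a`, `start_b`, `end_b`, `doc_level`).
#' @export
generate_bags <- function(annotated, knowledge_base) {
  if (!inherits(annotated, "annotated_corpus")) {
    stop_invalid("`annotated` must come from annotate_corpus()")
  }
  stopifnot(all(c("gene_a", "gene_b") %in% names(knowledge_base)))
  sentences <- attr(annotated, "sentences")
  m <- as_tibble(annotated)
  empty <- structure(
    tibble(gene_a = character(), gene_b = character(), flag = integer(),
           n_instances = integer(), instances = list()),
    class = c("bag_set", class(tibble()))
  )
  if (nrow(m) == 0) return(empty)

  # first mention of each symbol per (record, sentence)
  sm <- m |>
    group_by(.data$record_id, .data$sentence_index, .data$symbol) |>
    slice_min(.data$start, n = 1, with_ties = FALSE) |>
    ungroup()

  # sentence-level co-mentions
  sl <- inner_join(sm, sm, by = c("record_id", "sentence_index"),
                   relationship = "many-to-many", suffix = c("_x", "_y")) |>
    filter(.data$symbol_x < .data$symbol_y) |>
    left_join(sentences, by = c("record_id", "sentence_index")) |>
    transmute(gene_a = .data$symbol_x, gene_b = .data$symbol_y,
              record_id = .data$record_id, sentence_index = .data$sentence_index,
              text = .data$sentence,
              start_a = .data$start_x, end_a = .data$end_x,
              start_b = .data$start_y, end_b = .data$end_y,
              doc_level = FALSE)

  # record-level distinct pairs (the bag universe)
  rg <- distinct(m, .data$record_id, .data$symbol)
  rl <- inner_join(rg, rg, by = "record_id", relationship = "many-to-many",
                   suffix = c("_x", "_y")) |>
    filter(.data$symbol_x < .data$symbol_y) |>
    rename(gene_a = "symbol_x", gene_b = "symbol_y")

  pairs <- distinct(rl, .data$gene_a, .data$gene_b)
  has_sentence <- pair_key(pairs$gene_a, pairs$gene_b) %in%
    pair_key(sl$gene_a, sl$gene_b)

  # document-level fallback for pairs never sharing a sentence:
  # first mention sentence of each gene in the record, concatenated
  fallback_pairs <- pairs[!has_sentence, ]
  dl <- NULL
  if (nrow(fallback_pairs) > 0) {
    fm <- sm |>
      group_by(.data$record_id, .data$symbol) |>
      slice_min(.data$sentence_index, n = 1, with_ties = FALSE) |>
      ungroup() |>
      left_join(sentences, by = c("record_id", "sentence_index"))
    need <- semi_join(rl, fallback_pairs, by = c("gene_a", "gene_b"))
    dl <- need |>
      inner_join(fm, by = c("record_id", "gene_a" = "symbol")) |>
      inner_join(fm, by = c("record_id", "gene_b" = "symbol"),
                 suffix = c("_x", "_y")) |>
      transmute(gene_a = .data$gene_a, gene_b = .data$gene_b,
                record_id = .data$record_id,
                sentence_index = NA_integer_,
                text = paste(.data$sentence_x, .data$sentence_y),
                start_a = .data$start_x, end_a = .data$end_x,
                start_b = nchar(.data$sentence_x) + 1L + .data$start_y,
                end_b = nchar(.data$sentence_x) + 1L + .data$end_y,
                doc_level = TRUE)
  }

  inst <- bind_rows(sl, dl) |>
    arrange(.data$gene_a, .data$gene_b, .data$record_id, .data$sentence_index)
  kb_keys <- pair_key(knowledge_base$gene_a, knowledge_base$gene_b)
  bags <- inst |>
    tidyr::nest(instances = c("record_id", "sentence_index", "text",
                              "start_a", "end_a", "start_b", "end_b",
                              "doc_level")) |>
    mutate(flag = as.integer(pair_key(.data$gene_a, .data$gene_b) %in% kb_keys),
           n_instances = map_int(.data$instances, nrow)) |>
    select("gene_a", "gene_b", "flag", "n_instances", "instances") |>
    arrange(.data$gene_a, .data$gene_b)
  structure(bags, class = c("bag_set", class(tibble())))
}

distance_bucket <- function(d, doc_level) {
  ifelse(doc_level, "doc",
         ifelse(d <= 2, "d1_2",
                ifelse(d <= 5, "d3_5",
                       ifelse(d <= 10, "d6_10", "d11p"))))
}

# window tokens and mention distance for one instance
instance_features <- function(text, start_a, end_a, start_b, end_b,
                              doc_level, window = 3, cue = cue_lexicon()) {
  toks <- tokenize(text)
  feats_from_tokens(list(token = toks$token, start = toks$start, end = toks$end),
                    start_a, end_a, start_b, end_b, doc_level, window, cue)
}

feats_from_tokens <- function(tk, start_a, end_a, start_b, end_b,
                              doc_level, window, cue) {
  ia <- which(tk$start < end_a & tk$end > start_a)
  ib <- which(tk$start < end_b & tk$end > start_b)
  mention <- c(ia, ib)
  lo <- min(mention); hi <- max(mention)
  keep <- setdiff(seq(max(1, lo - window), min(length(tk$token), hi + window)),
                  mention)
  words <- str_to_lower(tk$token[keep])
  words <- words[grepl("[a-z0-9]", words)]
  d <- abs(min(ib) - min(ia))
  feats <- c(paste0("tok:", unique(words)),
             paste0("dist:", distance_bucket(d, doc_level)))
  if (any(words %in% cue)) feats <- c(feats, "cue")
  feats
}

# one tokenizer pass over every instance of every bag; returns the flat
# instance table, its bag index, and the per-instance feature-name lists
compute_bag_features <- function(bags, window = 3, cue = cue_lexicon()) {
  flat <- tidyr::unnest(
    mutate(as_tibble(bags)[c("instances")], .bag = row_number()), "instances")
  n_inst <- nrow(flat)
  feats <- vector("list", n_inst)
  if (n_inst > 0) {
    toks <- tokenize_many(flat$text)
    for (i in seq_len(n_inst)) {
      feats[[i]] <- feats_from_tokens(toks[[i]], flat$start_a[i], flat$end_a[i],
                                      flat$start_b[i], flat$end_b[i],
                                      flat$doc_level[i], window, cue)
    }
  }
  list(bag_index = flat$.bag, feats = feats)
}

#' Fit the instance featurizer on training bags
#'
#' The vocabulary (windowed bag-of-words around and between the two
#' mentions, token-distance bucket, relation-cue presence) is fit on
#' training data only; tokens unseen at prediction time hash to a reserved
#' out-of-vocabulary feature.
#'
#' @param bags a `bag_set`.
#' @param window tokens kept either side of the mention pair.
#' @return a `mil_featurizer` (feature index map plus cue lexicon).
#' @export
fit_featurizer <- function(bags, window = 3) {
  stopifnot(inherits(bags, "bag_set"))
  cb <- compute_bag_features(bags, window = window)
  featurizer_from_feats(cb$feats, window)
}

featurizer_from_feats <- function(feats, window) {
  vocab <- sort(unique(unlist(feats, use.names = FALSE)))
  vocab <- c(vocab, "tok:<OOV>")
  structure(list(features = stats::setNames(seq_along(vocab), vocab),
                 window = window, cue = cue_lexicon()),
            class = "mil_featurizer")
}

#' Featurize bags into a sparse instance design matrix
#'
#' @param bags a `bag_set`.
#' @param featurizer a `mil_featurizer` from [fit_featurizer()].
#' @return a list with `X` (instances x features 0/1 matrix), `bag_index`
#'   (instance-to-bag map) and `flag` (bag labels).
#' @export
featurize <- function(bags, featurizer) {
  stopifnot(inherits(bags, "bag_set"), inherits(featurizer, "mil_featurizer"))
  cb <- compute_bag_features(bags, window = featurizer$window,
                             cue = featurizer$cue)
  design_from_feats(cb, featurizer, bags$flag)
}

design_from_feats <- function(cb, featurizer, flag) {
  fmap <- featurizer$features
  n_inst <- length(cb$feats)
  X <- matrix(0, nrow = n_inst, ncol = length(fmap),
              dimnames = list(NULL, names(fmap)))
  oov_col <- fmap[["tok:<OOV>"]]
  for (i in seq_len(n_inst)) {
    idx <- fmap[cb$feats[[i]]]
    oov <- is.na(idx)
    if (any(oov)) idx <- c(idx[!oov], oov_col)
    X[i, unique(idx)] <- 1
  }
  list(X = X, bag_index = cb$bag_index, flag = flag)
}

logsumexp_by_bag <- function(z, bag_index, n_bags) {
  grp <- split(seq_along(z), factor(bag_index, levels = seq_len(n_bags)))
  vapply(grp, function(ix) {
    m <- max(z[ix]); m + log(sum(exp(z[ix] - m)))
  }, numeric(1))
}

#' Train the sparse multi-instance relation classifier
#'
#' L1-regularised logistic instance scorer with log-sum-exp bag pooling,
#' trained on bag flags by proximal gradient descent (ISTA) from a zero
#' initialisation. Training is deterministic: it consumes no randomness,
#' and the `seed` argument exists for interface stability with stochastic
#' bag classifiers plugged in behind the same surface.
#'
#' @param bags a `bag_set` with at least one positive and one negative bag.
#' @param hyperparams list with `lambda` (L1 penalty), `lr` (step size) and
#'   `epochs` (iterations).
#' @param seed integer, unused by the deterministic default trainer.
#' @param featurizer optional frozen `mil_featurizer`; fit on `bags` when
#'   `NULL`.
#' @return a `mil_model`: learned weights, intercept, frozen featurizer and
#'   training metadata.
#' @export
train_mil <- function(bags, hyperparams = list(), seed = 1, featurizer = NULL) {
  stopifnot(inherits(bags, "bag_set"))
  hp <- utils::modifyList(list(lambda = 0.005, lr = 0.5, epochs = 250), hyperparams)
  if (length(unique(bags$flag)) < 2) {
    stop_validation("training needs both positive and negative bags")
  }
  if (is.null(featurizer)) {
    cb <- compute_bag_features(bags)
    featurizer <- featurizer_from_feats(cb$feats, window = 3)
    d <- design_from_feats(cb, featurizer, bags$flag)
  } else {
    d <- featurize(bags, featurizer)
  }
  n_bags <- nrow(bags)
  grp <- split(seq_along(d$bag_index),
               factor(d$bag_index, levels = seq_len(n_bags)))
  y <- d$flag
  w <- rep(0, ncol(d$X))
  b <- 0
  loss <- NA_real_
  for (it in seq_len(hp$epochs)) {
    z <- drop(d$X %*% w) + b
    L <- vapply(grp, function(ix) {
      m <- max(z[ix]); m + log(sum(exp(z[ix] - m)))
    }, numeric(1))
    p <- stats::plogis(L)
    loss <- -mean(y * log(pmax(p, 1e-12)) + (1 - y) * log(pmax(1 - p, 1e-12))) +
      hp$lambda * sum(abs(w))
    g_bag <- (p - y) / n_bags
    soft <- exp(z - L[d$bag_index])            # within-bag softmax weights
    g_inst <- g_bag[d$bag_index] * soft
    grad_w <- drop(crossprod(d$X, g_inst))
    grad_b <- sum(g_inst)
    w_new <- w - hp$lr * grad_w
    w <- sign(w_new) * pmax(abs(w_new) - hp$lr * hp$lambda, 0)
    b <- b - hp$lr * grad_b
  }
  structure(list(weights = stats::setNames(w, colnames(d$X)), intercept = b,
                 featurizer = featurizer, hyperparams = hp,
                 n_bags = n_bags, n_positive = sum(y == 1),
                 final_loss = loss, seed = seed),
            class = "mil_model")
}

#' Score bags with a trained relation model
#'
#' @param model a `mil_model` from [train_mil()].
#' @param bags a `bag_set`.
#' @param threshold decision threshold on the bag score (default 0.5).
#' @return a tibble `gene_a`, `gene_b`, `score`, `label`, `n_instances`,
#'   sorted by descending score.
#' @export
predict_relations <- function(model, bags, threshold = 0.5) {
  stopifnot(inherits(model, "mil_model"), inherits(bags, "bag_set"))
  d <- featurize(bags, model$featurizer)
  if (ncol(d$X) != length(model$weights)) {
    stop_validation("featurizer/model version mismatch: feature maps differ")
  }
  z <- drop(d$X %*% model$weights) + model$intercept
  L <- logsumexp_by_bag(z, d$bag_index, nrow(bags))
  score <- stats::plogis(L)
  tibble(gene_a = bags$gene_a, gene_b = bags$gene_b,
         score = score, label = as.integer(score >= threshold),
         n_instances = bags$n_instances) |>
    arrange(desc(.data$score), .data$gene_a, .data$gene_b)
}

#' Measure planted-relation recovery on synthetic corpora
#'
#' For each seed, generates a dictionary, knowledge base and corpus under
#' `config`, builds bags, holds out a stratified fraction of bags, trains
#' the multi-instance classifier on the rest, and reports the held-out AUC
#' of bag scores against the planted knowledge-base truth.
#'
#' @param config a [synthetic_config()].
#' @param n_seeds number of replicate seeds (consecutive from
#'   `config$seed`).
#' @param holdout held-out fraction of bags.
#' @param hyperparams passed to [train_mil()].
#' @return a tibble `seed`, `auc`, `n_bags`, `n_test`.
#' @export
assess_relation_recovery <- function(config, n_seeds = 10, holdout = 0.3,
                                     hyperparams = list()) {
  stopifnot(inherits(config, "synthetic_config"))
  res <- vector("list", n_seeds)
  for (k in seq_len(n_seeds)) {
    cfg <- config
    cfg$seed <- config$seed + k - 1L
    dict <- gen_gene_dictionary(cfg$n_genes, seed = cfg$seed)
    kb <- gen_knowledge_base(dict, cfg$kb_density, seed = cfg$seed)
    gen <- gen_abstract_corpus(dict, kb, cfg)
    ann <- annotate_corpus(gen$corpus, dict)
    bags <- generate_bags(ann, kb)
    set.seed(sub_seed(cfg$seed, "holdout"))
    pos <- which(bags$flag == 1); neg <- which(bags$flag == 0)
    test <- c(sample(pos, max(1, round(holdout * length(pos)))),
              sample(neg, max(1, round(holdout * length(neg)))))
    train_bags <- bags[-test, ]
    test_bags <- bags[test, ]
    class(train_bags) <- class(bags); class(test_bags) <- class(bags)
    model <- train_mil(train_bags, hyperparams = hyperparams, seed = cfg$seed)
    pred <- predict_relations(model, test_bags)
    truth <- tibble(gene_a = test_bags$gene_a, gene_b = test_bags$gene_b,
                    flag = test_bags$flag)
    scored <- left_join(pred, truth, by = c("gene_a", "gene_b"))
    res[[k]] <- tibble(seed = cfg$seed, auc = rank_auc(scored$score, scored$flag),
                       n_bags = nrow(bags), n_test = nrow(test_bags))
  }
  bind_rows(res)
}
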