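# corpus builders for controlled bag fixtures -------------------------------

fixture_dict <- function(symbols) {
  tibble::tibble(symbol = symbols,
                 synonyms = rep(list(character()), length(symbols)))
}

fixture_corpus <- function(abstracts, ids = sprintf("r%d", seq_along(abstracts))) {
  tibble::tibble(record_id = ids, title = paste("title", seq_along(abstracts)),
                 abstract = abstracts,
                 keywords = rep(list(character()), length(abstracts)))
}

fixture_kb <- function(pairs) {
  if (length(pairs) == 0) {
    return(tibble::tibble(gene_a = character(), gene_b = character()))
  }
  m <- t(vapply(pairs, sort, character(2)))
  tibble::tibble(gene_a = m[, 1], gene_b = m[, 2])
}

# positives carry a cue verb in every co-mention; negatives never do
separable_bags <- function(n_pos = 6, n_neg = 6) {
  genes <- sprintf("GN%02d", seq_len(2 * (n_pos + n_neg)))
  dict <- fixture_dict(genes)
  abs_pos <- vapply(seq_len(n_pos), function(i) {
    a <- genes[2 * i - 1]; b <- genes[2 * i]
    paste0(a, " activates ", b, " in cohort samples.")
  }, "")
  abs_neg <- vapply(seq_len(n_neg), function(i) {
    a <- genes[2 * n_pos + 2 * i - 1]; b <- genes[2 * n_pos + 2 * i]
    paste0(a, " parallels ", b, " in cohort samples.")
  }, "")
  corpus <- fixture_corpus(c(abs_pos, abs_neg))
  kb <- fixture_kb(lapply(seq_len(n_pos), function(i) genes[c(2 * i - 1, 2 * i)]))
  bags <- generate_bags(annotate_corpus(corpus, dict), kb)
  list(bags = bags, dict = dict, corpus = corpus, kb = kb)
}

test_that("bag generation enumerates co-mentioned pairs with knowledge-base flags", {
  d <- fixture_dict(c("AAA1", "BBB2", "CCC3"))
  corpus <- fixture_corpus("AAA1 binds BBB2 here. CCC3 was measured.")
  kb <- fixture_kb(list(c("AAA1", "BBB2")))
  bags <- generate_bags(annotate_corpus(corpus, d), kb)
  expect_equal(nrow(bags), 3)   # (A,B), (A,C), (B,C)
  flags <- setNames(bags$flag, paste(bags$gene_a, bags$gene_b))
  expect_equal(unname(flags["AAA1 BBB2"]), 1L)
  expect_equal(unname(flags["AAA1 CCC3"]), 0L)
  expect_equal(unname(flags["BBB2 CCC3"]), 0L)
  # sentence-level instance for the co-mention, doc-level for the others
  ab <- bags[bags$gene_a == "AAA1" & bags$gene_b == "BBB2", ]
  expect_false(any(ab$instances[[1]]$doc_level))
  ac <- bags[bags$gene_a == "AAA1" & bags$gene_b == "CCC3", ]
  expect_true(all(ac$instances[[1]]$doc_level))
})

test_that("bags deduplicate globally and aggregate instances across abstracts", {
  d <- fixture_dict(c("AAA1", "BBB2"))
  corpus <- fixture_corpus(c("AAA1 binds BBB2 now.", "BBB2 meets AAA1 again."))
  bags <- generate_bags(annotate_corpus(corpus, d), fixture_kb(list()))
  expect_equal(nrow(bags), 1)
  expect_equal(bags$n_instances, 2)
  expect_setequal(bags$instances[[1]]$record_id, c("r1", "r2"))

  empty <- generate_bags(annotate_corpus(fixture_corpus(character()), d),
                         fixture_kb(list()))
  expect_equal(nrow(empty), 0)

  expect_error(generate_bags(tibble::tibble(), fixture_kb(list())),
               class = "syndromine_invalid_parameter")
})

test_that("bag flags and pair counts equal brute-force enumeration on random corpora", {
  for (s in 1:20) {
    d <- gen_gene_dictionary(sample(4:8, 1), seed = s)
    kb <- gen_knowledge_base(d, runif(1, 0.1, 0.6), seed = s)
    cfg <- small_config(seed = s, n_genes = nrow(d),
                        n_abstracts = sample(10:25, 1))
    gen <- gen_abstract_corpus(d, kb, cfg)
    bags <- generate_bags(annotate_corpus(gen$corpus, d), kb)
    oracle <- oracle_comentioned_pairs(gen$corpus, d)
    expect_equal(nrow(bags), nrow(oracle))
    if (nrow(oracle) > 0) {
      ok <- apply(oracle, 1, function(r) paste(sort(r), collapse = " "))
      expect_setequal(paste(bags$gene_a, bags$gene_b), unname(ok))
      kb_keys <- paste(kb$gene_a, kb$gene_b)
      expect_equal(bags$flag,
                   as.integer(paste(bags$gene_a, bags$gene_b) %in% kb_keys))
    }
  }
})

test_that("featurization captures cues deterministically with a frozen vocabulary", {
  fx <- separable_bags(3, 3)
  fz <- fit_featurizer(fx$bags)
  des <- featurize(fx$bags, fz)
  cue_col <- des$X[, "cue"]
  # positive bags' instances carry the cue feature, negative bags' never
  pos_rows <- des$bag_index %in% which(fx$bags$flag == 1)
  expect_true(all(cue_col[pos_rows] == 1))
  expect_true(all(cue_col[!pos_rows] == 0))

  # identical sentences give identical rows
  d <- fixture_dict(c("AAA1", "BBB2"))
  corpus <- fixture_corpus(c("AAA1 binds BBB2 now.", "AAA1 binds BBB2 now."))
  bags <- generate_bags(annotate_corpus(corpus, d), fixture_kb(list()))
  fz2 <- fit_featurizer(bags)
  des2 <- featurize(bags, fz2)
  expect_equal(des2$X[1, ], des2$X[2, ])

  # unseen tokens at prediction time hash to the reserved OOV feature
  corpus_new <- fixture_corpus("AAA1 obliterates BBB2 zzz.")
  bags_new <- generate_bags(annotate_corpus(corpus_new, d), fixture_kb(list()))
  des_new <- featurize(bags_new, fz2)
  expect_equal(unname(des_new$X[1, "tok:<OOV>"]), 1)
  expect_false("tok:obliterates" %in% colnames(des_new$X))
})

test_that("training separates cue-bearing bags and is deterministic", {
  fx <- separable_bags(6, 6)
  m1 <- train_mil(fx$bags, seed = 1)
  m2 <- train_mil(fx$bags, seed = 1)
  expect_identical(m1$weights, m2$weights)

  pred <- predict_relations(m1, fx$bags, threshold = 0.5)
  joined <- dplyr::left_join(pred,
                             tibble::tibble(gene_a = fx$bags$gene_a,
                                            gene_b = fx$bags$gene_b,
                                            flag = fx$bags$flag),
                             by = c("gene_a", "gene_b"))
  expect_equal(joined$label, joined$flag)  # training accuracy 1.0 at 0.5

  # single-class training set is rejected
  pos_only <- fx$bags[fx$bags$flag == 1, ]
  class(pos_only) <- class(fx$bags)
  expect_error(train_mil(pos_only), class = "syndromine_validation_error")
})

test_that("threshold endpoints and score monotonicity in the cue behave", {
  fx <- separable_bags(4, 4)
  m <- train_mil(fx$bags)
  expect_true(all(predict_relations(m, fx$bags, threshold = 0)$label == 1))
  expect_true(all(predict_relations(m, fx$bags, threshold = 1 + 1e-9)$label == 0))

  # learned cue weight is nonnegative on the separable fixture, so adding
  # the cue token to a bag's instances never decreases its score
  expect_gte(m$weights[["cue"]], 0)
  neg_bag <- fx$bags[fx$bags$flag == 0, ][1, ]
  class(neg_bag) <- class(fx$bags)
  cued <- neg_bag
  cued$instances[[1]]$text <- sub("\\.$", " activates.",
                                  cued$instances[[1]]$text)
  class(cued) <- class(fx$bags)
  s0 <- predict_relations(m, neg_bag)$score
  s1 <- predict_relations(m, cued)$score
  expect_gte(s1, s0)
})

test_that("planted relations are recovered on held-out bags", {
  rec <- assess_relation_recovery(small_config(seed = 3, n_abstracts = 60),
                                  n_seeds = 2)
  expect_true(all(rec$auc >= 0.8))
})
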