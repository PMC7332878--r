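hits_fixture <- function(...) {
  rows <- list(...)
  tibble::tibble(
    symptom = unlist(lapply(rows, `[[`, 1)),
    gene = unlist(lapply(rows, `[[`, 2)),
    hits = as.integer(unlist(lapply(rows, `[[`, 3)))
  )
}

test_that("symptom-gene hits count co-occurring documents exactly", {
  dict <- tibble::tibble(symbol = c("AAA1", "BBB2"),
                         synonyms = list(character(), character()))
  corpus <- tibble::tibble(
    record_id = sprintf("r%d", 1:5),
    title = c("t", "t", "t", "t", "dizziness note"),
    abstract = c("Patient dizziness with AAA1 signal.",
                 "Severe dizziness and AAA1 again.",
                 "dizziness but no gene.",
                 "AAA1 without the symptom.",
                 "AAA1 in the title record."),
    keywords = rep(list(character()), 5)
  )
  h <- count_symptom_gene_hits(corpus, dict, c("dizziness", "headache"))
  get <- function(s, g) h$hits[h$symptom == s & h$gene == g]
  # brute-force: records 1, 2 and 5 (title) contain both
  expect_equal(get("dizziness", "AAA1"), 3L)
  expect_equal(get("dizziness", "BBB2"), 0L)     # absent gene: zero column
  expect_true(all(h$hits[h$symptom == "headache"] == 0))  # absent symptom

  expect_error(count_symptom_gene_hits(corpus, dict, character()),
               class = "syndromine_invalid_parameter")
})

test_that("per-symptom gene selection filters on the hit threshold", {
  h <- hits_fixture(list("dizzy", "A", 3), list("dizzy", "B", 0))
  expect_equal(genes_for_symptom(h, "dizzy", min_hits = 1), "A")
  expect_equal(genes_for_symptom(h, "dizzy", min_hits = 4), character(0))
  expect_error(genes_for_symptom(h, "nope"), class = "syndromine_lookup_error")

  # random table equals a direct filter
  set.seed(17)
  h <- tibble::tibble(symptom = rep(c("s1", "s2"), each = 30),
                      gene = rep(paste0("G", 1:30), 2),
                      hits = rpois(60, 1))
  for (mh in 1:3) {
    expect_equal(genes_for_symptom(h, "s1", mh),
                 sort(h$gene[h$symptom == "s1" & h$hits >= mh]))
  }
})

test_that("pruning removes exactly the unmapped symptoms", {
  counts <- symptom_gene_counts()
  pruned <- prune_unmapped_symptoms(chd_classification(),
                                    counts_to_hits(counts))
  expect_setequal(pruned$removed_terms,
                  c("Chest heaviness", "Insomnia", "Tongue disorder"))
  expect_equal(unlist(pruned$main), "Chest pain")
  expect_length(pruned$qi_deficiency, 5)
  expect_length(pruned$blood_stasis, 2)
  expect_equal(pruned$fixed_terms, "Palpitation")

  # fully mapped classification passes through unchanged
  cls <- symptom_classification("toy", list("a"), list("b"), list("c"),
                                fixed_terms = "f")
  h <- hits_fixture(list("a", "G", 1), list("b", "G", 1), list("c", "G", 2),
                    list("f", "G", 1))
  expect_equal(prune_unmapped_symptoms(cls, h)$removed_terms, character(0))

  # emptying a whole group is an error naming the group
  h0 <- hits_fixture(list("a", "G", 1), list("b", "G", 0), list("c", "G", 2),
                     list("f", "G", 1))
  expect_error(prune_unmapped_symptoms(cls, h0), "qi_deficiency",
               class = "syndromine_validation_error")
})

test_that("the CHD classification enumerates its ten published combinations", {
  pruned <- prune_unmapped_symptoms(chd_classification(),
                                    counts_to_hits(symptom_gene_counts()))
  combos <- enumerate_combinations(pruned)
  expect_equal(nrow(combos), 10)
  expect_equal(combos$label, c(
    "Chest pain + Respiratory abnormality + Palpitation + Hemiplegia",
    "Chest pain + Respiratory abnormality + Palpitation + Ecchymoses",
    "Chest pain + Lassitude + Palpitation + Hemiplegia",
    "Chest pain + Lassitude + Palpitation + Ecchymoses",
    "Chest pain + Sweating + Palpitation + Hemiplegia",
    "Chest pain + Sweating + Palpitation + Ecchymoses",
    "Chest pain + Dizziness + Palpitation + Hemiplegia",
    "Chest pain + Dizziness + Palpitation + Ecchymoses",
    "Chest pain + Typhoid fever + Palpitation + Hemiplegia",
    "Chest pain + Typhoid fever + Palpitation + Ecchymoses"))
})

test_that("the stroke classification enumerates its six published combinations", {
  combos <- enumerate_combinations(stroke_classification())
  expect_equal(nrow(combos), 6)
  expect_equal(combos$label[1], paste(
    "Hemiplegia + Stroke + Respiratory abnormality + Lassitude +",
    "Constipation + Xerostomia + Headache + Sputum + Ecchymoses +",
    "Extremity numbness"))
  expect_equal(combos$label[6], paste(
    "Hemiplegia + Stroke + Anemic + Constipation + Xerostomia +",
    "Headache + Sputum + Glossitis + Irritability"))
})

test_that("combination counts multiply the variable group sizes", {
  one <- symptom_classification("t", list("m"), list("q"), list("b"))
  expect_equal(nrow(enumerate_combinations(one)), 1)

  set.seed(23)
  for (k in 1:10) {
    nm <- sample(1:3, 1); nq <- sample(1:4, 1); nb <- sample(1:3, 1)
    cls <- symptom_classification(
      "r", as.list(paste0("m", seq_len(nm))),
      as.list(paste0("q", seq_len(nq))), as.list(paste0("b", seq_len(nb))))
    expect_equal(nrow(enumerate_combinations(cls)), nm * nq * nb)
  }

  empty_q <- symptom_classification("t", list("m"), list(), list("b"))
  expect_error(enumerate_combinations(empty_q),
               class = "syndromine_validation_error")
})

test_that("core genes intersect per-combination unions", {
  h <- hits_fixture(list("s1", "A", 2), list("s1", "B", 1), list("s2", "B", 3),
                    list("s2", "C", 1), list("s3", "D", 5))
  single <- tibble::tibble(combination = 1L, label = "s1 + s2",
                           terms = list(c("s1", "s2")))
  expect_equal(core_genes(single, h), c("A", "B", "C"))  # union over one set

  disjoint <- tibble::tibble(combination = 1:2, label = c("s1", "s3"),
                             terms = list("s1", "s3"))
  expect_equal(core_genes(disjoint, h), character(0))

  # random fixtures equal a brute-force union-then-intersect evaluation
  set.seed(29)
  for (k in 1:10) {
    sympt <- paste0("s", 1:6)
    genes <- paste0("G", 1:12)
    h <- tidyr::expand_grid(symptom = sympt, gene = genes)
    h$hits <- rpois(nrow(h), 0.7)
    combos <- tibble::tibble(
      combination = 1:5, label = as.character(1:5),
      terms = lapply(1:5, function(i) sample(sympt, sample(2:4, 1))))
    got <- core_genes(combos, h)
    oracle <- Reduce(intersect, lapply(combos$terms, function(ts) {
      Reduce(union, lapply(ts, function(s) h$gene[h$symptom == s & h$hits >= 1]))
    }))
    expect_equal(got, sort(oracle))
    # intersection is anti-monotone in the number of combinations
    expect_true(all(core_genes(combos[1:3, ], h) %in%
                      core_genes(combos[1:2, ], h)))
    # every core gene lies in every per-combination union
    for (ts in combos$terms) {
      u <- Reduce(union, lapply(ts, function(s) genes_for_symptom(h, s)))
      expect_true(all(got %in% u))
    }
  }
})

test_that("pruning zero-gene symptoms never changes the core genes", {
  set.seed(37)
  sympt <- paste0("s", 1:5)
  genes <- paste0("G", 1:10)
  h <- tidyr::expand_grid(symptom = c(sympt, "dead"), gene = genes)
  h$hits <- ifelse(h$symptom == "dead", 0L, rpois(nrow(h), 1))
  # the zero-gene symptom rides inside a multi-term option: pruning drops
  # the term but keeps the option, so unions are unchanged combination by
  # combination and the core genes cannot move
  cls <- symptom_classification("t", list("s1"), list("s2", c("s3", "dead")),
                                list("s4", "s5"))
  pruned <- prune_unmapped_symptoms(cls, h)
  expect_equal(pruned$removed_terms, "dead")
  with_dead <- enumerate_combinations(cls)
  without_dead <- enumerate_combinations(pruned)
  expect_equal(nrow(with_dead), nrow(without_dead))
  expect_equal(core_genes(with_dead, h), core_genes(without_dead, h))
})

test_that("classification YAML round-trips", {
  f <- withr::local_tempfile(fileext = ".yaml")
  cls <- stroke_classification()
  write_classification(cls, f)
  rt <- read_classification(f)
  expect_equal(rt$main, cls$main)
  expect_equal(rt$qi_deficiency, cls$qi_deficiency)
  expect_equal(rt$blood_stasis, cls$blood_stasis)
  expect_equal(rt$fixed_terms, cls$fixed_terms)
})
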