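test_that("network construction uses set semantics over positive pairs", {
  tri <- tibble::tibble(gene_a = c("A", "B", "C"), gene_b = c("B", "C", "A"),
                        label = 1L)
  net <- build_network(tri)
  expect_length(net$nodes, 3)
  expect_equal(nrow(net$edges), 3)

  dup <- tibble::tibble(gene_a = c("A", "B"), gene_b = c("B", "A"), label = 1L)
  expect_equal(nrow(build_network(dup)$edges), 1)

  # only positive labels enter; negatives excluded entirely
  mixed <- tibble::tibble(gene_a = c("A", "C"), gene_b = c("B", "D"),
                          label = c(1L, 0L))
  net <- build_network(mixed)
  expect_setequal(net$nodes, c("A", "B"))

  expect_warning(empty <- build_network(mixed[mixed$label == 0, ]),
                 "no positive")
  expect_length(empty$nodes, 0)

  # 109 distinct synthetic pairs with duplicated rows -> 109 edges
  set.seed(77)
  pool <- t(combn(paste0("G", 1:30), 2))
  pick <- pool[sample(nrow(pool), 109), ]
  rows <- rbind(pick, pick[sample(109, 40), ])
  preds <- tibble::tibble(gene_a = rows[, 1], gene_b = rows[, 2], label = 1L)
  expect_equal(nrow(build_network(preds)$edges),
               nrow(unique(t(apply(pick, 1, sort)))))
})

test_that("centralities hit the documented extremal and degenerate cases", {
  star <- build_network(tibble::tibble(gene_a = "HUB",
                                       gene_b = c("L1", "L2", "L3"),
                                       label = 1L))
  cent <- compute_centralities(star)
  hub <- cent[cent$gene == "HUB", ]
  expect_equal(unlist(hub[c("CD", "CB", "CC", "CE")]),
               c(CD = 1, CB = 1, CC = 1, CE = 1))

  path3 <- build_network(tibble::tibble(gene_a = c("A", "B"),
                                        gene_b = c("B", "C"), label = 1L))
  cent <- compute_centralities(path3)
  expect_equal(cent$CB[cent$gene == "A"], 0)  # endpoints carry no paths

  single <- syndromine:::new_gene_network("X",
                                          tibble::tibble(gene_a = character(),
                                                         gene_b = character()))
  cent <- compute_centralities(single)
  expect_equal(unlist(cent[c("CD", "CB", "CC", "CE")]),
               c(CD = 0, CB = 0, CC = 0, CE = 1))
})

test_that("centralities agree with exhaustive path enumeration", {
  rn <- random_network(10, 0.35, seed = 3)
  net <- build_network(rn$preds)
  keep <- match(net$nodes, rn$nodes)   # isolated nodes are excluded
  adj <- rn$adj[keep, keep]
  cent <- compute_centralities(net)

  ob <- oracle_betweenness(adj)
  oc <- oracle_closeness(adj)
  oe <- oracle_eigenvector(adj)
  expect_equal(cent$CB, if (max(ob) > 0) ob / max(ob) else ob, tolerance = 1e-10)
  expect_equal(cent$CC, oc / max(oc), tolerance = 1e-10)
  expect_equal(cent$CE, oe, tolerance = 1e-6)
})

test_that("community decomposition finds modular structure deterministically", {
  two_tri <- build_network(tibble::tibble(
    gene_a = c("A", "B", "C", "X", "Y", "Z"),
    gene_b = c("B", "C", "A", "Y", "Z", "X"), label = 1L))
  part <- detect_communities(two_tri, seed = 1)
  expect_equal(nrow(part$subnets), 2)
  expect_equal(sort(part$subnets$N), c(3, 3))

  # brute-force modularity over all partitions of the 6 nodes confirms the
  # two triangles are the unique optimum
  nodes <- two_tri$nodes
  adj <- matrix(0L, 6, 6, dimnames = list(nodes, nodes))
  for (i in seq_len(nrow(two_tri$edges))) {
    a <- two_tri$edges$gene_a[i]; b <- two_tri$edges$gene_b[i]
    adj[a, b] <- adj[b, a] <- 1L
  }
  best <- -Inf; best_p <- NULL
  for (p in oracle_all_partitions(6)) {
    q <- oracle_modularity(adj, p)
    if (q > best) { best <- q; best_p <- p }
  }
  groups <- split(nodes, best_p)
  expect_setequal(vapply(part$subnets$members,
                         function(m) paste(sort(m), collapse = ","), ""),
                  vapply(unname(groups),
                         function(m) paste(sort(m), collapse = ","), ""))

  k4 <- build_network(tibble::tibble(gene_a = c("A", "A", "A", "B", "B", "C"),
                                     gene_b = c("B", "C", "D", "C", "D", "D"),
                                     label = 1L))
  expect_equal(nrow(detect_communities(k4, seed = 2)$subnets), 1)

  p1 <- detect_communities(two_tri, seed = 9)
  p2 <- detect_communities(two_tri, seed = 9)
  expect_identical(p1, p2)
})

test_that("the composite indicator follows its formula and guards", {
  expect_equal(compute_cmi(0.8, 0.29, 0.92, 0.5), 0.752174, tolerance = 5e-7)
  expect_equal(compute_cmi(1, 0.29, 1, 1), 1.29)
  expect_equal(compute_cmi(0.6, 0, 0.69, 0.7), 0.7)   # zero-betweenness limit
  expect_equal(compute_cmi(0.4, 0, 0, 0.7), 0.7)      # CB=0 makes CC=0 legal
  expect_error(compute_cmi(0.4, 0.2, 0, 0.7),
               class = "syndromine_invalid_parameter")
})

test_that("subnet weighting and normalisation follow SW = N + ZJW", {
  net <- build_network(tibble::tibble(
    gene_a = c("A", "B", "C", "P", "Q", "X"),
    gene_b = c("B", "C", "A", "Q", "R", "Y"), label = 1L))
  part <- detect_communities(net, seed = 1)
  part <- score_subnets(part)
  expect_equal(part$subnets$SW, part$subnets$N)   # default ZJW = 0

  zjw <- setNames(2.5, as.character(part$subnets$subnet_id[1]))
  part2 <- score_subnets(part, zjw)
  expect_equal(part2$subnets$SW[1], part2$subnets$N[1] + 2.5)
  expect_error(score_subnets(part, setNames(-1, "1")),
               class = "syndromine_validation_error")

  # min-max normalisation on a constructed SW spread
  part3 <- part
  part3$subnets$SW <- c(2, 4, 6)[seq_len(nrow(part3$subnets))]
  part3$sw_min <- min(part3$subnets$SW); part3$sw_max <- max(part3$subnets$SW)
  norm <- normalize_subnet_weights(part3)
  expect_equal(sort(norm$subnets$ZSW), c(0, 0.5, 1)[seq_len(nrow(part3$subnets))])

  # degenerate MAX = MIN: every ZSW is 1
  part4 <- part
  part4$subnets$SW <- rep(5, nrow(part4$subnets))
  part4$sw_min <- 5; part4$sw_max <- 5
  expect_true(all(normalize_subnet_weights(part4)$subnets$ZSW == 1))

  expect_equal(compute_gw(1.29, 1), 2.29)
  expect_equal(compute_gw(1.70, 0.88), 2.58)
  expect_equal(compute_gw(0, 0), 0)
})

test_that("gene ranking satisfies its construction identities", {
  star <- build_network(tibble::tibble(gene_a = "HUB",
                                       gene_b = c("L1", "L2", "L3", "L4"),
                                       label = 1L))
  r <- rank_genes(star, seed = 1)
  expect_equal(r$gene[1], "HUB")
  expect_true(all(abs(r$GW - r$CMI - r$ZSW) < 1e-9))

  # full recomputation from first principles on a synthetic network
  d <- gen_gene_dictionary(20, seed = 13)
  kb <- gen_knowledge_base(d, 0.25, seed = 13)
  preds <- dplyr::mutate(kb, label = 1L)
  net <- build_network(preds)
  part <- detect_communities(net, seed = 4)
  r <- rank_genes(net, part, seed = 4)

  keep <- match(net$nodes, net$nodes)
  adj <- matrix(0L, length(net$nodes), length(net$nodes),
                dimnames = list(net$nodes, net$nodes))
  for (i in seq_len(nrow(net$edges))) {
    a <- net$edges$gene_a[i]; b <- net$edges$gene_b[i]
    adj[a, b] <- adj[b, a] <- 1L
  }
  deg <- rowSums(adj)
  cd <- deg / max(deg)
  cb_raw <- oracle_betweenness(adj)
  cb <- if (max(cb_raw) > 0) cb_raw / max(cb_raw) else cb_raw
  cc_raw <- oracle_closeness(adj)
  cc <- cc_raw / max(cc_raw)
  ce <- oracle_eigenvector(adj)
  sw <- part$subnets$N
  zsw_sub <- if (max(sw) == min(sw)) rep(1, length(sw)) else
    (sw - min(sw)) / (max(sw) - min(sw))
  for (i in seq_len(nrow(r))) {
    g <- r$gene[i]
    j <- match(g, net$nodes)
    sub <- which(vapply(part$subnets$members, function(m) g %in% m, TRUE))
    cmi <- ifelse(cb[j] == 0, 0, cd[j] * cb[j] / cc[j]) + ce[j]
    expect_equal(r$CMI[i], unname(cmi), tolerance = 1e-6)
    expect_equal(r$ZSW[i], zsw_sub[sub], tolerance = 1e-12)
    expect_equal(r$GW[i], unname(cmi + zsw_sub[sub]), tolerance = 1e-6)
  }
  # sorted by GW descending, ties by symbol
  expect_true(all(diff(r$GW) <= 1e-12))
})

test_that("CMI is monotone in each centrality under random perturbation", {
  set.seed(99)
  for (k in 1:50) {
    cd <- runif(1); cb <- runif(1, 0.01, 1); cc <- runif(1, 0.1, 1); ce <- runif(1)
    eps <- runif(1, 0.01, 0.2)
    base <- compute_cmi(cd, cb, cc, ce)
    expect_gte(compute_cmi(min(cd + eps, 1), cb, cc, ce), base)
    expect_gte(compute_cmi(cd, min(cb + eps, 1), cc, ce), base)
    expect_gte(compute_cmi(cd, cb, cc, min(ce + eps, 1)), base)
    expect_lte(compute_cmi(cd, cb, min(cc + eps, 1), ce), base)
  }
})
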