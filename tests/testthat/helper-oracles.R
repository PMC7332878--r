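# Independent oracles used across the suite. Each one recomputes a quantity
# by brute force (enumeration, direct summation, dense linear algebra) with
# no calls into the package's own implementation paths.

# distinct co-mentioned unordered pairs of a corpus, by direct text scan
# against the dictionary surfaces (record-level co-mention)
oracle_comentioned_pairs <- function(corpus, dictionary) {
  surf <- c(dictionary$symbol,
            unlist(dictionary$synonyms, use.names = FALSE))
  sym_of <- c(dictionary$symbol,
              rep(dictionary$symbol, lengths(dictionary$synonyms)))
  out <- list()
  for (i in seq_len(nrow(corpus))) {
    toks <- unlist(strsplit(corpus$abstract[i], "[^A-Za-z0-9'-]+"))
    found <- sort(unique(sym_of[match(toks, surf, nomatch = 0)]))
    if (length(found) >= 2) {
      cmb <- t(combn(found, 2))
      out[[length(out) + 1]] <- data.frame(record_id = corpus$record_id[i],
                                           gene_a = cmb[, 1], gene_b = cmb[, 2])
    }
  }
  if (length(out) == 0) {
    return(data.frame(gene_a = character(), gene_b = character()))
  }
  unique(do.call(rbind, out)[c("gene_a", "gene_b")])
}

# binomial 99% acceptance interval for k successes out of n at rate p,
# by direct tail summation (no qbinom)
oracle_binom_interval <- function(n, p, conf = 0.99) {
  pmf <- vapply(0:n, function(k) choose(n, k) * p^k * (1 - p)^(n - k), 0)
  cdf <- cumsum(pmf)
  lo <- min(which(cdf > (1 - conf) / 2)) - 1
  hi <- min(which(cdf >= 1 - (1 - conf) / 2)) - 1
  c(lo, hi)
}

# all simple undirected graphs handled as an edge matrix over n nodes
oracle_bfs_dist <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n); diag(d) <- 0
  for (s in seq_len(n)) {
    frontier <- s; dist <- 0
    while (length(frontier) > 0) {
      nxt <- integer(0)
      for (v in frontier) {
        nb <- which(adj[v, ] == 1 & d[s, ] == Inf & seq_len(n) != s)
        nb <- setdiff(nb, which(d[s, ] <= dist))
        d[s, nb] <- dist + 1
        nxt <- c(nxt, nb)
      }
      frontier <- unique(nxt)
      dist <- dist + 1
    }
  }
  d
}

# geodesic-counting betweenness by exhaustive simple-path enumeration
oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  d <- oracle_bfs_dist(adj)
  btw <- numeric(n)
  # enumerate all simple paths between every pair with DFS, keep geodesics
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      if (!is.finite(d[s, t])) next
      paths <- list()
      dfs <- function(v, path) {
        if (length(path) - 1 > d[s, t]) return()
        if (v == t) {
          if (length(path) - 1 == d[s, t]) paths[[length(paths) + 1]] <<- path
          return()
        }
        for (w in which(adj[v, ] == 1)) {
          if (!(w %in% path)) dfs(w, c(path, w))
        }
      }
      dfs(s, s)
      sigma <- length(paths)
      if (sigma == 0) next
      inner <- unlist(lapply(paths, function(p) p[-c(1, length(p))]))
      if (length(inner) > 0) {
        tb <- table(inner)
        idx <- as.integer(names(tb))
        btw[idx] <- btw[idx] + as.numeric(tb) / sigma
      }
    }
  }
  btw
}

# Freeman-normalised closeness per connected component
oracle_closeness <- function(adj) {
  n <- nrow(adj)
  d <- oracle_bfs_dist(adj)
  vapply(seq_len(n), function(v) {
    reach <- which(is.finite(d[v, ]) & seq_len(n) != v)
    if (length(reach) == 0) return(0)
    length(reach) / sum(d[v, reach])
  }, 0)
}

# principal-eigenvector centrality per component via dense eigen(),
# scaled to component max 1
oracle_eigenvector <- function(adj) {
  n <- nrow(adj)
  comp <- rep(NA_integer_, n)
  cid <- 0
  d <- oracle_bfs_dist(adj)
  for (v in seq_len(n)) {
    if (is.na(comp[v])) {
      cid <- cid + 1
      comp[is.finite(d[v, ])] <- cid
    }
  }
  ce <- numeric(n)
  for (ci in seq_len(cid)) {
    vs <- which(comp == ci)
    if (length(vs) == 1) { ce[vs] <- 1; next }
    sub <- adj[vs, vs, drop = FALSE]
    ev <- eigen(sub, symmetric = TRUE)
    vec <- abs(ev$vectors[, which.max(ev$values)])
    ce[vs] <- vec / max(vec)
  }
  ce
}

# modularity of a partition (list of integer membership) of adjacency adj
oracle_modularity <- function(adj, membership) {
  m <- sum(adj) / 2
  if (m == 0) return(0)
  deg <- rowSums(adj)
  q <- 0
  for (i in seq_len(nrow(adj))) {
    for (j in seq_len(nrow(adj))) {
      if (membership[i] == membership[j]) {
        q <- q + adj[i, j] - deg[i] * deg[j] / (2 * m)
      }
    }
  }
  q / (2 * m)
}

# all set partitions of 1..n (n small), as membership vectors
oracle_all_partitions <- function(n) {
  if (n == 1) return(list(1L))
  rest <- oracle_all_partitions(n - 1)
  out <- list()
  for (p in rest) {
    k <- max(p)
    for (g in seq_len(k + 1)) out[[length(out) + 1]] <- c(p, g)
  }
  out
}

# random graph as gene_network plus adjacency, over LETTERS nodes
random_network <- function(n, p, seed) {
  set.seed(seed)
  nodes <- paste0("G", sprintf("%02d", seq_len(n)))
  adj <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (runif(1) < p) adj[i, j] <- adj[j, i] <- 1L
    }
  }
  ed <- which(upper.tri(adj) & adj == 1, arr.ind = TRUE)
  edges <- tibble::tibble(gene_a = nodes[ed[, 1]], gene_b = nodes[ed[, 2]])
  preds <- dplyr::mutate(edges, label = 1L)
  list(nodes = nodes, adj = adj, edges = edges, preds = preds)
}

# hypergeometric upper tail by direct summation of choose() terms
oracle_hyper_tail <- function(k, K, N, n) {
  ks <- k:min(K, n)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

small_config <- function(seed = 1, ...) {
  args <- modifyList(list(n_genes = 8, n_abstracts = 40, kb_density = 0.3,
                          comention_rate_kb = 0.3, comention_rate_bg = 0.02,
                          cue_rate = 0.9, n_symptoms = 8, hits_lambda = 2,
                          seed = seed), list(...))
  do.call(synthetic_config, args)
}
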