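#' Gene network construction, decomposition and composite scoring
#'
#' Positive relation predictions become an undirected gene network. The
#' network is decomposed into sub-networks with Louvain modularity
#' maximisation, four centrality indexes are computed per gene (degree CD,
#' betweenness CB, closeness CC, eigenvector/hub CE, each max-scaled so top
#' genes score exactly 1), and genes are ranked by the composite scores
#'
#' \deqn{CMI = CD \cdot CB \cdot (1/CC) + CE}
#' \deqn{SW = N + ZJW, \quad ZSW = (SW - \min SW)/(\max SW - \min SW)}
#' \deqn{GW = CMI + ZSW}
#'
#' where N is the sub-network size and ZJW an expert-assigned relevance
#' score for the sub-network (default 0). When CB = 0 the product term of
#' CMI is taken as 0 regardless of CC; when all sub-networks share one SW
#' value, every ZSW is 1.
#'
#' @name network_scoring
NULL

new_gene_network <- function(nodes, edges) {
  structure(list(nodes = sort(unique(nodes)),
                 edges = distinct(as_tibble(edges[c("gene_a", "gene_b")]))),
            class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  cat("<gene_network> ", length(x$nodes), " nodes, ", nrow(x$edges),
      " edges\n", sep = "")
  invisible(x)
}

as_igraph <- function(network) {
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(network$nodes), name = network$nodes)
  if (nrow(network$edges) > 0) {
    g <- igraph::add_edges(g, rbind(match(network$edges$gene_a, network$nodes),
                                    match(network$edges$gene_b, network$nodes)))
  }
  g
}

#' Build the gene network from relation predictions
#'
#' Nodes are the genes of positively labeled pairs; edges the positive
#' pairs themselves (set semantics, self-loops excluded); genes appearing
#' in no positive pair are excluded.
#'
#' @param predictions tibble with `gene_a`, `gene_b` and a 0/1 `label`
#'   column (absent `label` treats every row as positive).
#' @return a `gene_network`.
#' @export
build_network <- function(predictions) {
  stopifnot(all(c("gene_a", "gene_b") %in% names(predictions)))
  pos <- if ("label" %in% names(predictions)) {
    filter(predictions, .data$label == 1)
  } else predictions
  pos <- filter(pos, .data$gene_a != .data$gene_b)
  if (nrow(pos) == 0) {
    warn("no positive predictions; returning an empty network")
    return(new_gene_network(character(), tibble(gene_a = character(), gene_b = character())))
  }
  edges <- distinct(canonical_pair(pos$gene_a, pos$gene_b))
  new_gene_network(c(edges$gene_a, edges$gene_b), edges)
}

#' Compute the four centrality indexes per gene
#'
#' CD is degree over the maximum degree. CC is Freeman-normalised closeness
#' within each connected component, then divided by the network maximum.
#' CB is normalised betweenness divided by its maximum (0 when no shortest
#' path passes any node). CE is the eigenvector centrality of each
#' component, scaled so each component's maximum is 1. Consequently every
#' top-scoring gene gets exactly 1.0 in each index. For a single-node
#' network the documented degenerate contract is CD = CB = CC = 0, CE = 1.
#'
#' @param network a `gene_network`.
#' @return a tibble `gene`, `CD`, `CB`, `CC`, `CE`.
#' @export
compute_centralities <- function(network) {
  stopifnot(inherits(network, "gene_network"))
  n <- length(network$nodes)
  if (n == 0) stop_invalid("network has no nodes")
  if (n == 1) {
    return(tibble(gene = network$nodes, CD = 0, CB = 0, CC = 0, CE = 1))
  }
  g <- as_igraph(network)
  deg <- igraph::degree(g)
  CD <- if (max(deg) > 0) deg / max(deg) else rep(0, n)
  # raw geodesic-counting betweenness; the max-scaling below absorbs any
  # normalisation constant (and stays defined for two-node graphs)
  btw <- igraph::betweenness(g, normalized = FALSE)
  CB <- if (max(btw) > 0) btw / max(btw) else rep(0, n)
  comp <- igraph::components(g)
  CC <- numeric(n); CE <- numeric(n)
  for (ci in seq_len(comp$no)) {
    vs <- which(comp$membership == ci)
    sub <- igraph::induced_subgraph(g, vs)
    nc <- length(vs)
    if (nc == 1) {
      CC[vs] <- 0
      CE[vs] <- 1
    } else {
      d <- igraph::distances(sub)
      CC[vs] <- (nc - 1) / rowSums(d)          # Freeman-normalised closeness
      ev <- igraph::eigen_centrality(sub)$vector
      CE[vs] <- ev / max(ev)
    }
  }
  if (max(CC) > 0) CC <- CC / max(CC)
  tibble(gene = network$nodes, CD = unname(CD), CB = unname(CB),
         CC = unname(CC), CE = unname(CE))
}

#' Decompose a network into sub-networks (communities)
#'
#' Louvain modularity maximisation with node-sorted, seeded deterministic
#' tie-breaking; singleton components become singleton sub-networks.
#' Sub-network ids are assigned in decreasing size, ties by smallest member
#' symbol.
#'
#' @param network a `gene_network`.
#' @param seed integer seed fixing tie-breaks.
#' @return a `subnet_partition`: list with `subnets` (tibble `subnet_id`,
#'   `members` list-column, `N`, `ZJW`, `SW`, `ZSW`) and the `sw_min` /
#'   `sw_max` bounds (filled by [score_subnets()]).
#' @export
detect_communities <- function(network, seed = 1) {
  stopifnot(inherits(network, "gene_network"))
  if (length(network$nodes) == 0) stop_invalid("network has no nodes")
  g <- as_igraph(network)   # vertices already in sorted node order
  set.seed(sub_seed(seed, "louvain"))
  cl <- igraph::cluster_louvain(g)
  membership <- igraph::membership(cl)
  subs <- tibble(gene = network$nodes, community = as.integer(membership)) |>
    group_by(.data$community) |>
    summarise(members = list(sort(.data$gene)), N = n(), .groups = "drop") |>
    arrange(desc(.data$N), map_chr(.data$members, 1)) |>
    mutate(subnet_id = row_number(), ZJW = 0, SW = NA_real_, ZSW = NA_real_) |>
    select("subnet_id", "members", "N", "ZJW", "SW", "ZSW")
  structure(list(subnets = subs, sw_min = NA_real_, sw_max = NA_real_),
            class = "subnet_partition")
}

#' @export
print.subnet_partition <- function(x, ...) {
  cat("<subnet_partition> ", nrow(x$subnets), " sub-networks over ",
      sum(x$subnets$N), " genes\n", sep = "")
  invisible(x)
}

#' Composite measurement indicator (CMI)
#'
#' `CMI = CD * CB * (1/CC) + CE`. When `CB = 0` the product term is taken
#' as 0 regardless of CC; `CC = 0` with `CB > 0` is an arithmetic-guard
#' error (closeness is computed within components, so CC can only vanish
#' for an isolated node, where CB is 0 too).
#'
#' @param CD,CB,CC,CE centrality indexes (vectors recycle).
#' @return numeric CMI.
#' @export
compute_cmi <- function(CD, CB, CC, CE) {
  if (any(CC == 0 & CB > 0)) {
    stop_invalid("CC = 0 with CB > 0: the closeness reciprocal is undefined")
  }
  prod_term <- ifelse(CB == 0, 0, CD * CB / CC)
  prod_term + CE
}

#' Gene weight (GW)
#'
#' `GW = CMI + ZSW`.
#'
#' @param cmi composite measurement indicator.
#' @param zsw normalised sub-network weight.
#' @return numeric GW.
#' @export
compute_gw <- function(cmi, zsw) {
  stopifnot(all(is.finite(cmi)), all(is.finite(zsw)),
            all(cmi >= 0), all(zsw >= 0))
  cmi + zsw
}

#' Fill sub-network weights SW = N + ZJW
#'
#' @param partition a `subnet_partition`.
#' @param zjw_map named numeric vector of expert scores keyed by
#'   `subnet_id` (missing sub-networks default to 0).
#' @return the partition with `SW`, `sw_min`, `sw_max` filled.
#' @export
score_subnets <- function(partition, zjw_map = NULL) {
  stopifnot(inherits(partition, "subnet_partition"))
  zjw <- rep(0, nrow(partition$subnets))
  if (!is.null(zjw_map)) {
    if (any(zjw_map < 0)) stop_validation("ZJW scores must be nonnegative")
    hit <- match(as.character(partition$subnets$subnet_id), names(zjw_map))
    zjw[!is.na(hit)] <- zjw_map[hit[!is.na(hit)]]
  }
  partition$subnets$ZJW <- zjw
  partition$subnets$SW <- partition$subnets$N + zjw
  partition$sw_min <- min(partition$subnets$SW)
  partition$sw_max <- max(partition$subnets$SW)
  partition
}

#' Min-max normalise sub-network weights (ZSW)
#'
#' `ZSW = (SW - MIN)/(MAX - MIN)` across the sub-networks of one network;
#' when MAX = MIN (including a single sub-network) every ZSW is 1.
#'
#' @param partition a `subnet_partition` with SW filled.
#' @return the partition with `ZSW` filled.
#' @export
normalize_subnet_weights <- function(partition) {
  stopifnot(inherits(partition, "subnet_partition"))
  if (anyNA(partition$subnets$SW)) {
    stop_invalid("SW not filled; call score_subnets() first")
  }
  rng <- partition$sw_max - partition$sw_min
  partition$subnets$ZSW <- if (rng == 0) rep(1, nrow(partition$subnets)) else
    (partition$subnets$SW - partition$sw_min) / rng
  partition
}

#' Rank genes by composite weight
#'
#' Runs the full scoring chain over a network and its partition: the four
#' centralities, CMI, sub-network ZSW, and GW = CMI + ZSW, returning one
#' row per gene sorted by descending GW (ties by symbol).
#'
#' @param network a `gene_network`.
#' @param partition optional `subnet_partition`; computed with
#'   [detect_communities()] when `NULL`.
#' @param zjw_map optional named ZJW vector (see [score_subnets()]).
#' @param seed seed for community detection when `partition` is `NULL`.
#' @return a `gene_ranking` tibble: `gene`, `CD`, `CC`, `CB`, `CE`,
#'   `CMI`, `subnet_id`, `ZSW`, `GW`.
#' @export
rank_genes <- function(network, partition = NULL, zjw_map = NULL, seed = 1) {
  stopifnot(inherits(network, "gene_network"))
  if (is.null(partition)) partition <- detect_communities(network, seed = seed)
  partition <- normalize_subnet_weights(score_subnets(partition, zjw_map))
  cent <- compute_centralities(network)
  member_map <- tidyr::unnest(partition$subnets[c("subnet_id", "members", "ZSW")],
                              "members") |>
    rename(gene = "members")
  out <- cent |>
    left_join(member_map, by = "gene") |>
    mutate(CMI = compute_cmi(.data$CD, .data$CB, .data$CC, .data$CE),
           GW = compute_gw(.data$CMI, .data$ZSW)) |>
    select("gene", "CD", "CC", "CB", "CE", "CMI", "subnet_id", "ZSW", "GW") |>
    arrange(desc(.data$GW), .data$gene)
  structure(out, class = c("gene_ranking", class(tibble())))
}
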