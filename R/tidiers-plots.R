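#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_point geom_segment
#'   coord_flip labs theme_minimal scale_fill_brewer geom_histogram
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' Tidy a trained relation model
#'
#' One row per nonzero feature weight, largest magnitude first.
#'
#' @param x a `mil_model`.
#' @param ... unused.
#' @return a tibble `feature`, `weight`.
#' @export
tidy.mil_model <- function(x, ...) {
  out <- tibble(feature = names(x$weights), weight = unname(x$weights)) |>
    filter(.data$weight != 0) |>
    arrange(desc(abs(.data$weight)))
  out
}

#' @rdname tidy.mil_model
#' @return `glance()`: a one-row tibble with bag counts, feature counts,
#'   sparsity and final training loss.
#' @export
glance.mil_model <- function(x, ...) {
  tibble(n_bags = x$n_bags, n_positive = x$n_positive,
         n_features = length(x$weights),
         n_nonzero = sum(x$weights != 0),
         lambda = x$hyperparams$lambda,
         epochs = x$hyperparams$epochs,
         final_loss = x$final_loss)
}

#' Tidy a sub-network partition
#'
#' @param x a `subnet_partition`.
#' @param ... unused.
#' @return a tibble `subnet_id`, `N`, `ZJW`, `SW`, `ZSW`.
#' @export
tidy.subnet_partition <- function(x, ...) {
  select(x$subnets, "subnet_id", "N", "ZJW", "SW", "ZSW")
}

#' @rdname tidy.subnet_partition
#' @export
glance.subnet_partition <- function(x, ...) {
  tibble(n_subnets = nrow(x$subnets), n_genes = sum(x$subnets$N),
         sw_min = x$sw_min, sw_max = x$sw_max)
}

#' Tidy an integration report
#'
#' @param x an `integration_report`.
#' @param ... unused.
#' @return a long tibble `syndrome`, `method`, `gene`.
#' @export
tidy.integration_report <- function(x, ...) {
  bind_rows(imap(x$syndromes, function(r, s) {
    bind_rows(map(c("decomposition", "combination", "matched"), function(m) {
      g <- r[[m]]$genes
      if (length(g) == 0) return(NULL)
      tibble(syndrome = s, method = m, gene = g)
    }))
  }))
}

#' @rdname tidy.integration_report
#' @export
glance.integration_report <- function(x, ...) {
  tibble(
    n_syndromes = length(x$syndromes),
    n_shared = length(x$shared),
    seed = x$metadata$seed,
    config_hash = x$metadata$config_hash
  )
}

#' Plot a gene ranking
#'
#' Stacked contributions of CMI and ZSW to the gene weight GW for the top
#' genes.
#'
#' @param object a `gene_ranking` from [rank_genes()].
#' @param top_n number of genes to show.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.gene_ranking <- function(object, top_n = 15, ...) {
  df <- utils::head(as_tibble(object), top_n) |>
    tidyr::pivot_longer(c("CMI", "ZSW"), names_to = "component",
                        values_to = "value") |>
    mutate(gene = factor(.data$gene, levels = rev(utils::head(object$gene, top_n))))
  ggplot(df, aes(x = .data$gene, y = .data$value, fill = .data$component)) +
    geom_col() +
    coord_flip() +
    scale_fill_brewer(palette = "Set2") +
    labs(x = NULL, y = "gene weight GW = CMI + ZSW",
         title = "Top-ranked genes by composite weight") +
    theme_minimal()
}

#' Plot sub-network sizes of a partition
#'
#' @param object a `subnet_partition`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.subnet_partition <- function(object, ...) {
  df <- tidy(object)
  ggplot(df, aes(x = factor(.data$subnet_id), y = .data$N)) +
    geom_col(fill = "steelblue") +
    labs(x = "sub-network", y = "genes",
         title = "Community decomposition of the gene network") +
    theme_minimal()
}

#' Histogram of relation scores by bag label
#'
#' @param predictions tibble from [predict_relations()], joined with a
#'   `flag` column if available.
#' @param bins histogram bins.
#' @return a ggplot.
#' @export
plot_relation_scores <- function(predictions, bins = 30) {
  p <- ggplot(predictions, aes(x = .data$score))
  if ("flag" %in% names(predictions)) {
    p <- p + geom_histogram(aes(fill = factor(.data$flag)), bins = bins,
                            position = "identity", alpha = 0.6) +
      labs(fill = "knowledge-base flag")
  } else {
    p <- p + geom_histogram(bins = bins, fill = "grey40")
  }
  p + labs(x = "bag relation score", y = "pairs") + theme_minimal()
}
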