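#' @importFrom rlang abort warn .data :=
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom purrr map map_chr map_int map_dbl map_lgl map2 pmap imap keep
#' @importFrom stringr str_detect str_split str_trim str_to_upper str_to_lower
NULL

# Typed conditions used across the package. Every reader/validator failure is
# one of these classes, never a silent truncation.
stop_invalid <- function(msg, ...) {
  abort(msg, class = c("syndromine_invalid_parameter", "syndromine_error"), ...)
}

stop_validation <- function(msg, ...) {
  abort(msg, class = c("syndromine_validation_error", "syndromine_error"), ...)
}

stop_parse <- function(msg, ...) {
  abort(msg, class = c("syndromine_parse_error", "syndromine_error"), ...)
}

stop_lookup <- function(msg, ...) {
  abort(msg, class = c("syndromine_lookup_error", "syndromine_error"), ...)
}

#' Derive a stable sub-seed from a master seed
#'
#' Each generator draws from its own stream, derived from the master seed and
#' a stream label, so adding one generator never perturbs the draws of
#' another. The derivation is a small deterministic hash kept below 2^31.
#'
#' @param seed master integer seed.
#' @param stream character label of the stream.
#' @return an integer seed.
#' @keywords internal
sub_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((abs(seed) * 7919 + h * 104729) %% .Machine$integer.max)
}

# Canonical (lexicographic) ordering of an unordered gene pair.
canonical_pair <- function(a, b) {
  swap <- a > b
  tibble(gene_a = ifelse(swap, b, a), gene_b = ifelse(swap, a, b))
}

pair_key <- function(a, b) {
  p <- canonical_pair(a, b)
  paste(p$gene_a, p$gene_b, sep = "\r")
}

# Rank-based AUC (Mann-Whitney), ties counted half.
rank_auc <- function(score, label) {
  pos <- score[label == 1]
  neg <- score[label == 0]
  if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}
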