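#' Published worked examples for the two target syndromes
#'
#' Small reference tables transcribed from the published study of the
#' Qi-deficiency-and-blood-stasis syndromes of coronary heart disease
#' (CHD) and stroke: the top-ten gene ranking of each syndrome network
#' (centrality indexes, CMI, ZSW and GW), the symptom classifications with
#' their enumerated combinations, the per-symptom gene counts returned by
#' the literature-mining tool, and the 46 genes shared by the two
#' syndromes. They serve as worked examples and regression fixtures for
#' the scoring formulas; the corpus-scale counts behind them are not
#' reproducible offline.
#'
#' @name reference_data
NULL

#' @rdname reference_data
#' @return `chd_reference_ranking()` / `stroke_reference_ranking()`: a
#'   tibble `gene`, `CD`, `CC`, `CB`, `CE`, `CMI`, `ZSW`, `GW` with the
#'   published (rounded) values.
#' @export
chd_reference_ranking <- function() {
  tibble(
    gene = c("CHRNA4", "BDNF", "CHRNB4", "CHRNA5", "CHRNB3", "CHRNA6",
             "COMT", "CHRNA3", "CHRNB2", "MAOA"),
    CD = c(1, 0.8, 0.6, 0.5, 0.5, 0.4, 0.5, 0.5, 0.4, 0.4),
    CC = c(1, 0.92, 0.69, 0.62, 0.62, 0.62, 0.77, 0.62, 0.62, 0.77),
    CB = c(0.29, 0.29, 0, 0, 0, 0, 0.14, 0, 0, 0.14),
    CE = c(1, 0.5, 0.7, 0.64, 0.62, 0.54, 0.44, 0.52, 0.5, 0.38),
    CMI = c(1.29, 0.752174, 0.7, 0.64, 0.62, 0.54, 0.530909, 0.52, 0.5,
            0.452727),
    ZSW = rep(1, 10),
    GW = c(2.29, 1.75, 1.70, 1.64, 1.62, 1.54, 1.53, 1.52, 1.5, 1.45)
  )
}

#' @rdname reference_data
#' @export
stroke_reference_ranking <- function() {
  tibble(
    gene = c("CXCR4", "CXCL13", "CCR7", "CCL2", "CXCL1", "CCR4", "CXCL9",
             "CCL5", "CCR2", "CCR1"),
    CD = c(1, 0.92, 0.85, 0.69, 0.77, 0.62, 0.62, 0.69, 0.54, 0.54),
    CC = c(0.99, 0.94, 0.88, 0.87, 0.75, 0.87, 0.75, 0.72, 0.72, 0.72),
    CB = c(0.91, 0.65, 0.27, 0.4, 0.05, 0.16, 0.04, 0.08, 0.02, 0.01),
    CE = c(0.78, 0.88, 1, 0.83, 1.01, 0.93, 0.88, 0.83, 0.87, 0.86),
    CMI = c(1.70, 1.52, 1.06, 1.26, 0.91, 0.85, 0.85, 1.04, 0.75, 0.55),
    ZSW = c(0.88, 0.88, 0.88, 0.63, 0.88, 0.88, 0.88, 0.63, 0.88, 1),
    GW = c(2.58, 2.40, 1.94, 1.89, 1.79, 1.73, 1.73, 1.67, 1.63, 1.55)
  )
}

#' @rdname reference_data
#' @return `chd_classification()` / `stroke_classification()`: the
#'   published `symptom_classification` (before pruning): single-term
#'   options for CHD; the stroke Qi-deficiency and blood-stasis options
#'   pair terms as published.
#' @export
chd_classification <- function() {
  symptom_classification(
    syndrome_name = "CHD Qi deficiency and blood stasis",
    main = list("Chest pain", "Chest heaviness"),
    qi_deficiency = list("Respiratory abnormality", "Lassitude", "Sweating",
                         "Dizziness", "Typhoid fever", "Insomnia"),
    blood_stasis = list("Hemiplegia", "Ecchymoses", "Tongue disorder"),
    fixed_terms = "Palpitation"
  )
}

#' @rdname reference_data
#' @export
stroke_classification <- function() {
  symptom_classification(
    syndrome_name = "Stroke Qi deficiency and blood stasis",
    main = list(c("Hemiplegia", "Stroke")),
    qi_deficiency = list(c("Respiratory abnormality", "Lassitude"),
                         "Sweating", "Anemic"),
    blood_stasis = list(c("Ecchymoses", "Extremity numbness"),
                        c("Glossitis", "Irritability")),
    fixed_terms = c("Constipation", "Xerostomia", "Headache", "Sputum")
  )
}

#' @rdname reference_data
#' @return `symptom_gene_counts()`: a tibble `symptom`, `count` with the
#'   published number of genes the literature-mining tool associated with
#'   each symptom keyword (0 for chest heaviness, tongue disorder and
#'   insomnia, which were therefore pruned).
#' @export
symptom_gene_counts <- function() {
  tibble(
    symptom = c("Dizziness", "Constipation", "Headache", "Xerostomia",
                "Irritability", "Glossitis", "Extremity numbness",
                "Hemiplegia", "Sputum", "Stroke", "Respiratory abnormality",
                "Anemic", "Lassitude", "Ecchymoses", "Sweating", "Chest pain",
                "Palpitation", "Typhoid fever", "Chest heaviness",
                "Tongue disorder", "Insomnia"),
    count = c(166L, 210L, 338L, 87L, 122L, 19L, 4L, 65L, 4L, 699L, 76L,
              169L, 31L, 24L, 129L, 225L, 49L, 82L, 0L, 0L, 0L)
  )
}

#' @rdname reference_data
#' @param counts a tibble `symptom`, `count` (aggregate gene counts per
#'   symptom, as published by the mining tool).
#' @return `counts_to_hits()`: a symptom-gene hits tibble with a single
#'   aggregate pseudo-gene column, sufficient for pruning decisions when
#'   only per-symptom totals are available.
#' @export
counts_to_hits <- function(counts) {
  stopifnot(all(c("symptom", "count") %in% names(counts)))
  tibble(symptom = counts$symptom, gene = "(aggregate)",
         hits = as.integer(counts$count))
}

#' @rdname reference_data
#' @return `shared_syndrome_genes()`: the published 46 genes common to the
#'   matched sets of the two syndromes.
#' @export
shared_syndrome_genes <- function() {
  sort(c("CXCR4", "HGF", "EGF", "BDNF", "IL10", "INS", "IL12B", "IL13",
         "IGF2", "IGF1R", "CTNNB1", "IFNG", "HTR3A", "EGFR", "HLA-B",
         "HLA-DQB1", "HLA-DRB1", "IFNGR1", "IGF1", "CRLF1", "GDNF", "FOXP3",
         "AKT1", "F3", "BMP2", "AR", "CNTF", "BCL2", "IL6", "COMT", "CHRNA4",
         "CLCF1", "CNTFR", "MET", "MUC1", "MAOA", "LEP", "CCK", "IL4",
         "BRCA1", "C3", "IL18", "IL2", "IL1B", "INSR", "IL17A"))
}
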