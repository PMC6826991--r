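# GO-term analysis of interaction results: hypergeometric cluster
# enrichment (a GO Term Finder-style test) and GO-term averaging (GTA).

#' Hypergeometric GO-term enrichment of a gene cluster
#'
#' For every term with at least one gene in the cluster, computes the
#' upper-tail hypergeometric probability of drawing `k` or more term genes
#' in a cluster of size `n` from a background of `N` genes of which `M`
#' carry the term — the ratio-of-ratios comparison between cluster and
#' tested background. Bonferroni-adjusted p-values across the tested terms
#' are reported alongside the raw values.
#'
#' @param cluster_genes character vector, a subset of `background_genes`.
#' @param background_genes all genes tested in the experiment (the
#'   enrichment background is the screened set, not the whole genome).
#' @param annotations data.frame/data.table with columns `gene`, `term`;
#'   annotations outside the background are ignored.
#' @return data.table: `term, k, n, M, N, p_value, adjusted_p`, ordered by
#'   `p_value`. Terms with no cluster gene are excluded.
#' @export
hypergeom_enrichment <- function(cluster_genes, background_genes,
                                 annotations) {
  cluster_genes <- unique(cluster_genes)
  background_genes <- unique(background_genes)
  outside <- setdiff(cluster_genes, background_genes)
  if (length(outside))
    stop("cluster gene(s) absent from background: ",
         paste(outside, collapse = ", "))
  ann <- data.table::as.data.table(annotations)
  ann <- unique(ann[gene %in% background_genes, .(gene, term)])
  N <- length(background_genes)
  n <- length(cluster_genes)
  tab <- ann[, .(M = .N, k = sum(gene %in% cluster_genes)), by = term]
  tab <- tab[k > 0]
  if (!nrow(tab))
    return(data.table::data.table(term = character(), k = integer(),
                                  n = integer(), M = integer(),
                                  N = integer(), p_value = numeric(),
                                  adjusted_p = numeric()))
  tab[, `:=`(n = n, N = N)]
  tab[, p_value := stats::phyper(k - 1, M, N - M, n, lower.tail = FALSE)]
  tab[, adjusted_p := pmin(1, p_value * .N)]
  data.table::setcolorder(tab, c("term", "k", "n", "M", "N", "p_value",
                                 "adjusted_p"))
  data.table::setorder(tab, p_value, term)
  tab[]
}

#' GO-term averaging (GTA) for one term
#'
#' The GTA value is the mean interaction z-score over the term's genes
#' present in the score table; `gta_sd` is their sample SD (0 for a single
#' gene); the GTA score is `|GTA value| - gta_sd`. A term passes the GTA
#' filter when `|GTA value| > 2` and GTA score `> 2` (both strict).
#'
#' @param term_genes genes annotated to the term.
#' @param scores named numeric vector of interaction z-scores (names =
#'   genes) for one drug and CPP.
#' @param term term identifier copied into the result.
#' @param threshold GTA filter threshold (default 2).
#' @return one-row data.table: `term, gta_value, gta_sd, gta_score,
#'   n_genes, n_missing, passes_filter`.
#' @export
gta <- function(term_genes, scores, term = NA_character_, threshold = 2) {
  present <- intersect(unique(term_genes), names(scores))
  if (!length(present))
    stop("no gene of the term is present in the score table")
  n_missing <- length(unique(term_genes)) - length(present)
  x <- scores[present]
  value <- mean(x)
  s <- if (length(x) > 1) stats::sd(x) else 0
  score <- abs(value) - s
  data.table::data.table(term = term, gta_value = value, gta_sd = s,
                         gta_score = score, n_genes = length(x),
                         n_missing = n_missing,
                         passes_filter = abs(value) > threshold &
                           score > threshold)
}

#' GTA over every annotated term
#'
#' @param scores named numeric vector of interaction z-scores for one drug
#'   and CPP (e.g. one z column of [profile_matrix()], named by strain).
#' @param annotations data.frame/data.table with columns `gene`, `term`.
#' @param drug,cpp labels copied into the result.
#' @param threshold GTA filter threshold (default 2).
#' @return data.table with one [gta()] row per term having at least one
#'   scored gene, plus `drug` and `cpp` columns.
#' @export
gta_table <- function(scores, annotations, drug = NA_character_,
                      cpp = NA_character_, threshold = 2) {
  ann0 <- unique(data.table::as.data.table(annotations)[, .(gene, term)])
  sizes <- ann0[, .(total = .N), by = term]
  ann <- ann0[gene %in% names(scores)]
  if (!nrow(ann))
    return(data.table::data.table(term = character(), gta_value = numeric(),
                                  gta_sd = numeric(), gta_score = numeric(),
                                  n_genes = integer(), n_missing = integer(),
                                  passes_filter = logical(),
                                  drug = character(), cpp = character()))
  out <- ann[, {
    x <- scores[unique(gene)]
    v <- mean(x)
    s <- if (length(x) > 1) stats::sd(x) else 0
    list(gta_value = v, gta_sd = s, gta_score = abs(v) - s,
         n_genes = length(x),
         passes_filter = abs(v) > threshold & (abs(v) - s) > threshold)
  }, by = term]
  out[sizes, n_missing := i.total - n_genes, on = "term"]
  out[, `:=`(drug = drug, cpp = cpp)]
  out[order(-abs(gta_value))]
}

#' Filter GTA results
#'
#' Retains terms passing both GTA filters (`|GTA value| > 2` and GTA score
#' `> 2`), sorted by `|GTA value|` descending.
#'
#' @param results data.table from [gta_table()] (or rbind of [gta()] rows).
#' @return the filtered, sorted data.table.
#' @export
gta_filter <- function(results) {
  out <- data.table::as.data.table(results)[passes_filter == TRUE]
  out[order(-abs(gta_value))]
}
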