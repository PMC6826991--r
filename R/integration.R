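# Integration of yeast interaction classes with cancer cell-line
# pharmacogenomics via yeast-human homology: expression-sensitivity
# association per gene, then UES/OES calls.

#' Per-gene expression-sensitivity association in a tissue stratum
#'
#' For each gene, a simple linear model of drug sensitivity on expression,
#' both standardized to zero mean and unit SD within the stratum, so the
#' standardized coefficient equals the Pearson correlation: negative means
#' the gene is underexpressed in drug-sensitive lines, positive
#' overexpressed. Two-sided p-values come from the t distribution with
#' n - 2 df. Genes with constant expression in the stratum are skipped
#' (reported in the `skipped` attribute).
#'
#' @param expression genes x cell-lines numeric matrix (dimnames required).
#' @param sensitivity data.frame/data.table with columns `cell_line`,
#'   `drug`, `value` (a continuous sensitivity metric, e.g. AAC).
#' @param tissues data.frame/data.table with columns `cell_line`, `tissue`.
#' @param stratum `"all"` or a tissue label (e.g. `"HaL"`, `"lung"`).
#' @param drug drug whose sensitivity values to use.
#' @param min_lines minimum cell lines required in the stratum.
#' @return data.table: `gene, drug, tissue, standardized_coefficient,
#'   p_value, n`; attribute `skipped` lists constant-expression genes.
#' @export
associate_expression <- function(expression, sensitivity, tissues,
                                 stratum = "all", drug, min_lines = 10L) {
  dg <- drug
  sens <- data.table::as.data.table(sensitivity)
  sens <- sens[drug == dg]
  tis <- data.table::as.data.table(tissues)
  lines <- intersect(colnames(expression), sens$cell_line)
  if (stratum != "all")
    lines <- intersect(lines, tis[tissue == stratum]$cell_line)
  if (length(lines) < min_lines)
    stop("stratum '", stratum, "' has ", length(lines),
         " cell lines; need >= ", min_lines)
  y <- sens[match(lines, cell_line)]$value
  X <- expression[, lines, drop = FALSE]
  n <- length(lines)

  sds <- apply(X, 1, stats::sd)
  skipped <- rownames(X)[sds == 0 | is.na(sds)]
  keep <- sds > 0 & !is.na(sds)
  X <- X[keep, , drop = FALSE]
  if (length(skipped))
    message(length(skipped), " gene(s) with constant expression skipped")

  ys <- as.numeric(scale(y))
  Xs <- t(scale(t(X)))
  r <- as.numeric(Xs %*% ys) / (n - 1)
  r <- pmin(pmax(r, -1), 1)
  tstat <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  out <- data.table::data.table(gene = rownames(X), drug = drug,
                                tissue = stratum,
                                standardized_coefficient = r,
                                p_value = p, n = n)
  data.table::setattr(out, "skipped", skipped)
  out[]
}

#' Call UES/OES hits by intersecting yeast classes with associations
#'
#' Cross-joins yeast interaction classes with the homology map and the
#' expression-sensitivity associations, keeping pairs where a yeast
#' deletion enhancer matches a human homolog underexpressed in
#' drug-sensitive lines (negative standardized coefficient, p < `alpha`;
#' direction `"UES"`), or a deletion suppressor matches an overexpressed
#' homolog (positive coefficient, p < `alpha`; `"OES"`). Duplicate homolog
#' rows are deduplicated; homolog rows naming unknown yeast genes are
#' skipped with a warning.
#'
#' @param yeast_results data.frame/data.table with one row per yeast gene
#'   and drug: columns `strain` (yeast gene), `drug`, `class`, and
#'   optionally z-score and cluster columns carried into the output.
#' @param homolog_map data.frame/data.table with columns `yeast`, `human`,
#'   `class` (homology class).
#' @param associations data.table from [associate_expression()] (rbind
#'   several strata/drugs as needed).
#' @param alpha association significance threshold (default 0.05).
#' @return data.table: `yeast, human, homology_class, drug, tissue,
#'   direction, standardized_coefficient, p_value, yeast_class` plus any
#'   carried columns; one row per (yeast, human, drug, tissue).
#' @export
call_hits <- function(yeast_results, homolog_map, associations,
                      alpha = 0.05) {
  yr <- data.table::as.data.table(yeast_results)
  hm <- unique(data.table::as.data.table(homolog_map)[, .(yeast, human, class)])
  data.table::setnames(hm, "class", "homology_class")
  as_ <- data.table::as.data.table(associations)

  unknown <- setdiff(hm$yeast, yr$strain)
  if (length(unknown)) {
    warning("homolog rows reference unknown yeast gene(s): ",
            paste(head(unknown, 5), collapse = ", "),
            if (length(unknown) > 5) ", ...")
    hm <- hm[!yeast %in% unknown]
  }

  j <- merge(yr[, .(yeast = strain, drug, yeast_class = class)],
             hm, by = "yeast", allow.cartesian = TRUE)
  j <- merge(j, as_[, .(human = gene, drug, tissue,
                        standardized_coefficient, p_value)],
             by = c("human", "drug"), allow.cartesian = TRUE)
  j[, direction := data.table::fcase(
    yeast_class == "enhancer" & standardized_coefficient < 0 &
      p_value < alpha, "UES",
    yeast_class == "suppressor" & standardized_coefficient > 0 &
      p_value < alpha, "OES",
    default = NA_character_)]
  hits <- j[!is.na(direction)]
  data.table::setcolorder(hits, c("yeast", "human", "homology_class",
                                  "drug", "tissue", "direction",
                                  "standardized_coefficient", "p_value",
                                  "yeast_class"))
  data.table::setorder(hits, drug, tissue, yeast, human)
  unique(hits)[]
}

#' Conservation summary: yeast calls with concordant human homologs
#'
#' Per drug and tissue stratum, the fraction of yeast deletion enhancers
#' with at least one UES homolog hit, and of deletion suppressors with at
#' least one OES hit — a descriptive estimate of how often a yeast
#' drug-gene interaction is mirrored in the cell-line data.
#'
#' @param hits data.table from [call_hits()].
#' @param yeast_results the yeast classification table given to
#'   [call_hits()].
#' @return data.table: `drug, tissue, direction, n_called, n_with_hit,
#'   fraction`.
#' @export
summarize_conservation <- function(hits, yeast_results) {
  yr <- data.table::as.data.table(yeast_results)
  hits <- data.table::as.data.table(hits)
  strata <- unique(hits[, .(drug, tissue)])
  if (!nrow(strata))
    strata <- data.table::CJ(drug = unique(yr$drug), tissue = "all")
  out <- strata[, {
    dg <- drug; tt <- tissue
    enh <- unique(yr[drug == dg & class == "enhancer"]$strain)
    sup <- unique(yr[drug == dg & class == "suppressor"]$strain)
    hu <- unique(hits[drug == dg & tissue == tt & direction == "UES"]$yeast)
    ho <- unique(hits[drug == dg & tissue == tt & direction == "OES"]$yeast)
    data.table::data.table(
      direction = c("UES", "OES"),
      n_called = c(length(enh), length(sup)),
      n_with_hit = c(sum(enh %in% hu), sum(sup %in% ho)),
      fraction = c(
        if (length(enh)) sum(enh %in% hu) / length(enh) else 0,
        if (length(sup)) sum(sup %in% ho) / length(sup) else 0))
  }, by = .(drug, tissue)]
  out[]
}
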