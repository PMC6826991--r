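# Synthetic phenomic experiment generator.
#
# Emulates Q-HTCP: 384-culture agar arrays imaged over time, 768 replicate
# reference cultures, logistic growth with additive Gaussian intensity
# noise, gene-specific baseline shifts, dose-proportional drug-gene
# interaction effects, and occasional no-growth cultures. Ground truth is
# returned alongside the time series for recovery testing.

#' Logistic growth model
#'
#' `G(t) = K / (1 + exp(-r (t - l)))`: `K` is the carrying capacity
#' (intensity units), `r` the maximum specific growth rate (per hour) and
#' `l` the time (hours) at which half carrying capacity is reached, i.e.
#' `G(l) = K/2`.
#'
#' @param t time vector, hours.
#' @param K,r,l logistic parameters (scalars or vectors recycled against `t`).
#' @return predicted intensity.
#' @export
logistic_growth <- function(t, K, r, l) K / (1 + exp(-r * (t - l)))

#' Configuration for a synthetic plate experiment
#'
#' Defaults reproduce the study conditions of the screen being emulated:
#' gemcitabine dose series 0, 5, 10, 20, 30 ug/mL; cytarabine 0, 10, 25, 50,
#' 100 ug/mL; 768 replicate reference cultures; imaging every 2.5 h from 0
#' to 48 h. Reference-strain logistic parameters default to K = 200
#' intensity units, r = 0.3 / h, l = 10 h, with per-drug dose responses that
#' slow growth (L increases, K decreases with dose), gemcitabine more
#' strongly per unit dose than cytarabine.
#'
#' @param seed integer; every random draw in the generators derives from it.
#' @param n_mutant_strains number of knockout strains to simulate.
#' @param n_knockdown_strains number of knockdown (DAmP) strains; these are
#'   standardized downstream against their own stratum.
#' @param n_reference_cultures replicate reference cultures per dose
#'   (>= 2 so the reference score SD is defined).
#' @param doses_by_drug named list, drug -> strictly increasing dose vector
#'   starting at 0 (ug/mL).
#' @param timepoints imaging times in hours, strictly increasing.
#' @param reference_params named vector `c(K=, r=, l=)` for the untreated
#'   reference strain.
#' @param ref_dose_response named list, drug -> `c(K=, L=)` giving the change
#'   in the reference K and L per ug/mL of drug.
#' @param noise_sd SD of additive Gaussian intensity noise (intensity units).
#' @param planted_effects `NULL` (all-null strains) or a list with elements
#'   `shifts` (data.frame strain, cpp, value: dose-independent CPP
#'   displacement) and `slopes` (data.frame strain, drug, cpp, value: CPP
#'   displacement per ug/mL).
#' @param no_growth_fraction proportion of mutant strains that never grow.
#' @return a validated `simulation_config` list.
#' @export
simulation_config <- function(seed = 1L,
                              n_mutant_strains = 100L,
                              n_knockdown_strains = 0L,
                              n_reference_cultures = 768L,
                              doses_by_drug = list(
                                gemcitabine = c(0, 5, 10, 20, 30),
                                cytarabine = c(0, 10, 25, 50, 100)),
                              timepoints = seq(0, 48, by = 2.5),
                              reference_params = c(K = 200, r = 0.3, l = 10),
                              ref_dose_response = list(
                                gemcitabine = c(K = -1.5, L = 0.35),
                                cytarabine = c(K = -0.40, L = 0.10)),
                              noise_sd = 5,
                              planted_effects = NULL,
                              no_growth_fraction = 0) {
  config <- list(seed = as.integer(seed),
                 n_mutant_strains = as.integer(n_mutant_strains),
                 n_knockdown_strains = as.integer(n_knockdown_strains),
                 n_reference_cultures = as.integer(n_reference_cultures),
                 doses_by_drug = doses_by_drug,
                 timepoints = as.numeric(timepoints),
                 reference_params = reference_params,
                 ref_dose_response = ref_dose_response,
                 noise_sd = noise_sd,
                 planted_effects = planted_effects,
                 no_growth_fraction = no_growth_fraction)
  errs <- validate_simulation_config(config)
  if (length(errs)) stop("invalid simulation config: ",
                         paste(errs, collapse = "; "))
  class(config) <- c("simulation_config", "list")
  config
}

#' @rdname simulation_config
#' @param config a `simulation_config` list.
#' @return `validate_simulation_config` returns a character vector of
#'   problems (empty when valid).
#' @export
validate_simulation_config <- function(config) {
  errs <- character()
  for (drug in names(config$doses_by_drug)) {
    d <- config$doses_by_drug[[drug]]
    if (length(d) < 2 || d[1] != 0 || any(diff(d) <= 0))
      errs <- c(errs, sprintf(
        "dose list for %s must start at 0 and be strictly increasing", drug))
  }
  if (config$n_reference_cultures < 2)
    errs <- c(errs, "n_reference_cultures must be >= 2")
  if (is.na(config$noise_sd) || config$noise_sd < 0)
    errs <- c(errs, "noise_sd must be non-negative")
  if (config$no_growth_fraction < 0 || config$no_growth_fraction > 1)
    errs <- c(errs, "no_growth_fraction must be in [0, 1]")
  if (any(diff(config$timepoints) <= 0) || length(config$timepoints) < 4)
    errs <- c(errs, "timepoints must be strictly increasing, length >= 4")
  if (!all(c("K", "r", "l") %in% names(config$reference_params)))
    errs <- c(errs, "reference_params must name K, r, l")
  errs
}

# expand planted effect tables to a full (strain x drug x cpp) lookup
.effect_lookup <- function(strains, drugs, planted) {
  grid <- data.table::CJ(strain = strains, drug = drugs,
                         cpp = c("K", "r", "L"))
  grid[, `:=`(shift = 0, slope = 0)]
  if (!is.null(planted$shifts) && nrow(planted$shifts)) {
    sh <- data.table::as.data.table(planted$shifts)
    data.table::setnames(sh, c("strain", "cpp", "value"))
    grid[sh, shift := i.value, on = c("strain", "cpp")]
  }
  if (!is.null(planted$slopes) && nrow(planted$slopes)) {
    sl <- data.table::as.data.table(planted$slopes)
    data.table::setnames(sl, c("strain", "drug", "cpp", "value"))
    grid[sl, slope := i.value, on = c("strain", "drug", "cpp")]
  }
  grid
}

#' Generate a synthetic plate experiment with ground truth
#'
#' Produces one intensity time series per (culture, drug, dose): every
#' mutant strain once and `n_reference_cultures` reference replicates, each
#' occupying a fixed 384-array position (16 rows x 24 columns) that is
#' shared across the dose plates of a drug. Mutant logistic parameters are
#' the reference parameters at that dose displaced by the strain's planted
#' shift (all doses) and by `slope * dose` (interaction). No-growth strains
#' emit pure noise around zero intensity.
#'
#' @param config a [simulation_config()].
#' @return list with `timeseries` (data.table: plate, row, col, strain,
#'   strain_class, drug, dose, time_h, intensity) and `truth` (data.table:
#'   strain, drug, cpp, shift, slope, true_int, true_class, no_growth).
#'   `true_int = slope * max(dose)` is the interaction value a noiseless
#'   pipeline recovers; `true_class` applies the enhancer/suppressor sign
#'   convention to the planted L and K slopes.
#' @export
generate_plate_experiment <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, {
    mutants <- character()
    if (config$n_mutant_strains > 0)
      mutants <- sprintf("yko_%04d", seq_len(config$n_mutant_strains))
    kds <- character()
    if (config$n_knockdown_strains > 0)
      kds <- sprintf("kd_%04d", seq_len(config$n_knockdown_strains))
    all_mut <- c(mutants, kds)
    drugs <- names(config$doses_by_drug)

    n_ng <- floor(config$no_growth_fraction * length(all_mut))
    ng_strains <- if (n_ng > 0) sample(all_mut, n_ng) else character()

    eff <- .effect_lookup(all_mut, drugs, config$planted_effects)

    ref <- config$reference_params
    ts_parts <- vector("list", length(drugs))
    for (di in seq_along(drugs)) {
      dg <- drugs[di]
      doses <- config$doses_by_drug[[dg]]
      dres <- config$ref_dose_response[[dg]] %||% c(K = 0, L = 0)

      # array layout: references first, then mutants, row-major over
      # 16 x 24 positions; plate id identifies the source-array position
      # block (constant across the dose plates of a drug)
      n_ref <- config$n_reference_cultures
      strain_col <- c(rep("ref", n_ref), all_mut)
      idx <- seq_along(strain_col) - 1L
      cultures <- data.table::data.table(
        strain = strain_col,
        plate = sprintf("%s_p%03d", dg, idx %/% 384L + 1L),
        row = LETTERS[(idx %% 384L) %/% 24L + 1L],
        col = (idx %% 24L) + 1L)

      grid <- cultures[, data.table::CJ(dose = doses), by = names(cultures)]
      grid[, drug := dg]
      # reference parameters at this dose
      grid[, `:=`(K = ref[["K"]] + dres[["K"]] * dose,
                  r = ref[["r"]],
                  L = ref[["l"]] + dres[["L"]] * dose)]
      # planted strain effects
      egg <- eff[list(dg), on = "drug"]
      for (cp in c("K", "r", "L")) {
        e <- egg[cpp == cp]
        grid[e, (cp) := get(cp) + i.shift + i.slope * dose, on = "strain"]
      }
      grid[, K := pmax(K, 0)]
      grid[, r := pmax(r, 1e-3)]
      grid[, no_growth := strain %in% ng_strains | K <= 0]
      ts_parts[[di]] <- grid
    }
    grid <- data.table::rbindlist(ts_parts)

    tp <- config$timepoints
    long <- grid[rep(seq_len(.N), each = length(tp))]
    long[, time_h := rep(tp, times = nrow(grid))]
    long[, intensity := ifelse(no_growth, 0,
                               logistic_growth(time_h, K, r, L))]
    if (config$noise_sd > 0)
      long[, intensity := intensity + rnorm(.N, 0, config$noise_sd)]
    long[, intensity := pmax(intensity, 0)]
    long[, strain_class := infer_strain_class(strain)]
    ts <- long[, .(plate, row, col, strain, strain_class, drug, dose,
                   time_h, intensity)]
    data.table::setkey(ts, drug, plate, row, col, dose, time_h)

    truth <- eff[, .(strain, drug, cpp, shift, slope)]
    truth[, true_int := slope * vapply(drug, function(d)
      max(config$doses_by_drug[[d]]), numeric(1))]
    cls <- truth[cpp != "r",
                 .(enh = any((cpp == "L" & slope > 0) | (cpp == "K" & slope < 0)),
                   sup = any((cpp == "L" & slope < 0) | (cpp == "K" & slope > 0))),
                 by = .(strain, drug)]
    cls[, true_class := data.table::fcase(enh & sup, "conflict",
                                          enh, "enhancer",
                                          sup, "suppressor",
                                          default = "none")]
    truth[cls, true_class := i.true_class, on = c("strain", "drug")]
    truth[, no_growth := strain %in% ng_strains]
    data.table::setkey(truth, strain, drug, cpp)
    list(timeseries = ts, truth = truth[])
  })
}

#' Generate a synthetic gene-to-GO-term annotation table
#'
#' Each term annotates a unique random gene subset whose size is uniform in
#' `term_size_range`; genes may belong to any number of terms (including
#' none).
#'
#' @param genes character vector of gene names, or a single integer `n`
#'   expanded to `g0001..g<n>`.
#' @param n_terms number of GO terms.
#' @param term_size_range integer pair `c(min, max)` genes per term.
#' @param seed integer seed.
#' @return data.table with columns `gene`, `term`.
#' @export
generate_go_annotations <- function(genes, n_terms,
                                    term_size_range = c(3L, 30L),
                                    seed = 1L) {
  if (is.numeric(genes) && length(genes) == 1)
    genes <- sprintf("g%04d", seq_len(genes))
  if (term_size_range[1] > term_size_range[2])
    stop("term_size_range must be (min, max) with min <= max")
  if (n_terms == 0)
    return(data.table::data.table(gene = character(), term = character()))
  if (term_size_range[2] > length(genes))
    stop("term sizes cannot exceed the number of genes")
  with_seed(seed, {
    size_pool <- seq.int(term_size_range[1], term_size_range[2])
    sizes <- size_pool[sample.int(length(size_pool), n_terms,
                                  replace = TRUE)]
    seen <- character()
    rows <- vector("list", n_terms)
    for (i in seq_len(n_terms)) {
      repeat {
        gs <- sort(sample(genes, sizes[i]))
        key <- paste(gs, collapse = ";")
        if (!key %in% seen) break
      }
      seen <- c(seen, key)
      rows[[i]] <- data.table::data.table(gene = gs,
                                          term = sprintf("T%04d", i))
    }
    data.table::rbindlist(rows)
  })
}

#' Generate a synthetic yeast-to-human homology map
#'
#' Yeast genes are assigned a homology class by multinomial draw from
#' `class_mix`: one-to-one genes pair with a single dedicated human gene;
#' one-to-many genes receive 2-4 dedicated human partners; many-to-many
#' genes are grouped in pairs sharing 2 human partners each (full cross
#' product), so labels are consistent with realized mapping cardinalities.
#'
#' @param yeast_genes non-empty character vector.
#' @param class_mix named proportions over
#'   `c("one-to-one","one-to-many","many-to-many")`, summing to 1.
#' @param seed integer seed.
#' @return data.table with columns `yeast`, `human`, `class`.
#' @export
generate_homology_map <- function(yeast_genes,
                                  class_mix = c("one-to-one" = 0.6,
                                                "one-to-many" = 0.25,
                                                "many-to-many" = 0.15),
                                  seed = 1L) {
  if (!length(yeast_genes)) stop("yeast_genes must be non-empty")
  if (abs(sum(class_mix) - 1) > 1e-8) stop("class_mix must sum to 1")
  with_seed(seed, {
    classes <- sample(names(class_mix), length(yeast_genes),
                      replace = TRUE, prob = class_mix)
    counter <- 0L
    next_human <- function(n) {
      out <- sprintf("HG%05d", counter + seq_len(n))
      counter <<- counter + n
      out
    }
    rows <- list()
    o2o <- yeast_genes[classes == "one-to-one"]
    if (length(o2o))
      rows$o2o <- data.table::data.table(
        yeast = o2o, human = next_human(length(o2o)), class = "one-to-one")
    o2m <- yeast_genes[classes == "one-to-many"]
    for (g in o2m) {
      m <- sample(2:4, 1)
      rows[[paste0("o2m_", g)]] <- data.table::data.table(
        yeast = g, human = next_human(m), class = "one-to-many")
    }
    m2m <- yeast_genes[classes == "many-to-many"]
    # group in pairs; a leftover singleton joins the last pair
    if (length(m2m) == 1) {
      # cannot form a many-to-many group of one; fall back to one-to-many
      rows$m2m_single <- data.table::data.table(
        yeast = m2m, human = next_human(2), class = "one-to-many")
    } else if (length(m2m) > 1) {
      grp <- rep(seq_len(length(m2m) %/% 2), each = 2, length.out = length(m2m))
      if (length(m2m) %% 2 == 1) grp[length(m2m)] <- max(grp)
      for (g in unique(grp)) {
        ys <- m2m[grp == g]
        hs <- next_human(2)
        rows[[paste0("m2m_", g)]] <- data.table::CJ(yeast = ys, human = hs)[
          , class := "many-to-many"]
      }
    }
    out <- data.table::rbindlist(rows, use.names = TRUE)
    data.table::setkey(out, yeast, human)
    out[]
  })
}

#' Generate a synthetic cell-line expression / drug-sensitivity dataset
#'
#' Drug sensitivity is a continuous AAC-like value in [0, 1]. Planted
#' underexpression-sensitivity (UES) genes get expression negatively related
#' to sensitivity, overexpression-sensitivity (OES) genes positively, and
#' null genes independent: `expr = baseline + s * effect_size * z(sens) +
#' N(0, 1)` with `s = -1` (UES), `+1` (OES) or `0` (null).
#'
#' @param n_cell_lines number of cell lines (>= 10).
#' @param human_genes character vector of gene names (rows of the matrix).
#' @param tissues tissue labels to sample cell lines from.
#' @param planted `NULL` or data.frame with columns `gene`,
#'   `direction` in `{"UES","OES","null"}`, `effect_size`.
#' @param drug drug name recorded in the sensitivity table.
#' @param seed integer seed.
#' @return list with `expression` (genes x cell lines matrix), `sensitivity`
#'   (data.table: cell_line, drug, value), `tissues` (data.table: cell_line,
#'   tissue).
#' @export
generate_pharmaco_dataset <- function(n_cell_lines, human_genes,
                                      tissues = c("HaL", "lung", "other"),
                                      planted = NULL,
                                      drug = "gemcitabine",
                                      seed = 1L) {
  if (n_cell_lines < 10) stop("n_cell_lines must be >= 10")
  if (!is.null(planted)) {
    bad <- setdiff(unique(planted$direction), c("UES", "OES", "null"))
    if (length(bad)) stop("unknown direction label(s): ",
                          paste(bad, collapse = ", "))
  }
  with_seed(seed, {
    lines <- sprintf("CL%04d", seq_len(n_cell_lines))
    tlab <- sample(tissues, n_cell_lines, replace = TRUE)
    sens <- pmin(pmax(rnorm(n_cell_lines, 0.3, 0.1), 0), 1)
    zs <- as.numeric(scale(sens))
    expr <- matrix(rnorm(length(human_genes) * n_cell_lines, 7, 1),
                   nrow = length(human_genes),
                   dimnames = list(human_genes, lines))
    if (!is.null(planted)) {
      for (i in seq_len(nrow(planted))) {
        g <- planted$gene[i]
        if (!g %in% human_genes) next
        s <- switch(planted$direction[i], UES = -1, OES = 1, null = 0)
        expr[g, ] <- expr[g, ] + s * planted$effect_size[i] * zs
      }
    }
    list(expression = expr,
         sensitivity = data.table::data.table(cell_line = lines, drug = drug,
                                              value = sens),
         tissues = data.table::data.table(cell_line = lines, tissue = tlab))
  })
}
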