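# End-to-end orchestration: simulate (or load) -> fit -> score -> cluster
# -> enrich/GTA -> integrate, with one config, per-stage logging and a
# manifest of hashed outputs.

#' Pipeline configuration
#'
#' Defaults carry the screen's stated constants: gemcitabine doses
#' 0/5/10/20/30 and cytarabine doses 0/10/25/50/100 ug/mL, 768 replicate
#' reference cultures, z threshold 2, association alpha 0.05, GTA threshold
#' 2. `sim` entries override [simulation_config()] arguments (the top-level
#' `seed` is injected); set `paths$timeseries` etc. to analyze existing
#' tables instead of simulating.
#'
#' @param seed master seed for every stage.
#' @param sim named list of overrides for [simulation_config()].
#' @param z_threshold enhancer/suppressor threshold on interaction z-scores.
#' @param alpha expression-sensitivity association significance level.
#' @param gta_threshold GTA filter threshold.
#' @param remc named list: `max_k`, `n_init`, `min_size`, `max_depth`.
#' @param annotations named list for [generate_go_annotations()]:
#'   `n_terms`, `term_size_range`.
#' @param homology named list for [generate_homology_map()]: `class_mix`.
#' @param pharmaco named list: `n_cell_lines`, `effect_size`,
#'   `conservation_fraction` (probability that a classified yeast gene's
#'   homologs get a concordant planted expression effect), `tissues`.
#' @param paths named list of optional input files (`timeseries`,
#'   `annotations`, `homology`); when given they are read instead of
#'   simulated.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L,
                            sim = list(),
                            z_threshold = 2,
                            alpha = 0.05,
                            gta_threshold = 2,
                            remc = list(max_k = 10L, n_init = 5L,
                                        min_size = 8L, max_depth = 4L),
                            annotations = list(n_terms = 50L,
                                               term_size_range = c(3L, 30L)),
                            homology = list(class_mix = c(
                              "one-to-one" = 0.6, "one-to-many" = 0.25,
                              "many-to-many" = 0.15)),
                            pharmaco = list(n_cell_lines = 200L,
                                            effect_size = 0.6,
                                            conservation_fraction = 0.5,
                                            tissues = c("HaL", "lung",
                                                        "other")),
                            paths = list()) {
  config <- list(seed = as.integer(seed), sim = sim,
                 z_threshold = z_threshold, alpha = alpha,
                 gta_threshold = gta_threshold, remc = remc,
                 annotations = annotations, homology = homology,
                 pharmaco = pharmaco, paths = paths)
  class(config) <- c("pipeline_config", "list")
  config
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [pipeline_config()]; absent keys keep their
#' defaults.
#'
#' @param path YAML file path.
#' @return a `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  args <- raw[intersect(names(raw), names(formals(pipeline_config)))]
  do.call(pipeline_config, args)
}

#' Validate a pipeline configuration
#'
#' Checks every structural invariant (dose lists start at 0 and increase,
#' alpha in (0,1), thresholds positive, referenced input files exist) and
#' returns all problems at once rather than failing mid-pipeline.
#'
#' @param config a [pipeline_config()].
#' @return character vector of problems; empty when the config is valid.
#' @export
validate_config <- function(config) {
  errs <- character()
  sim_args <- config$sim
  sim_args$seed <- config$seed
  sim <- tryCatch(do.call(simulation_config, sim_args),
                  error = function(e) conditionMessage(e))
  if (is.character(sim)) errs <- c(errs, sim)
  if (!is.numeric(config$alpha) || config$alpha <= 0 || config$alpha >= 1)
    errs <- c(errs, "alpha must be in (0, 1)")
  if (!is.numeric(config$z_threshold) || config$z_threshold <= 0)
    errs <- c(errs, "z_threshold must be positive")
  if (!is.numeric(config$gta_threshold) || config$gta_threshold <= 0)
    errs <- c(errs, "gta_threshold must be positive")
  for (p in names(config$paths)) {
    f <- config$paths[[p]]
    if (!is.null(f) && !file.exists(f))
      errs <- c(errs, sprintf("input file for '%s' does not exist: %s", p, f))
  }
  errs
}

.stage <- function(name, expr) {
  message(sprintf("[%s] start", name))
  out <- tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
  message(sprintf("[%s] done", name))
  out
}

#' Run the full pipeline
#'
#' Executes simulate (or load) -> fit -> score -> cluster -> enrich/GTA ->
#' integrate, writing one TSV per stage into `output_dir` and returning a
#' manifest with an MD5 hash per artifact (identical config and seed give
#' identical hashes).
#'
#' @param config a validated [pipeline_config()].
#' @param output_dir directory for stage outputs (created if needed).
#' @return list with `manifest` (data.table: file, md5) and the in-memory
#'   stage results (`truth`, `cpp`, `interactions`, `membership`,
#'   `enrichment`, `gta`, `hits`, `conservation`).
#' @export
run_pipeline <- function(config, output_dir) {
  errs <- validate_config(config)
  if (length(errs))
    stop("invalid pipeline config:\n  - ", paste(errs, collapse = "\n  - "))
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  emit <- function(x, name) {
    path <- file.path(output_dir, name)
    write_tsv_table(x, path)
    written <<- c(written, path)
    path
  }

  # --- simulate or load -------------------------------------------------
  truth <- NULL
  if (!is.null(config$paths$timeseries)) {
    ts <- .stage("load", read_tsv_table(config$paths$timeseries))
  } else {
    sim_args <- config$sim
    sim_args$seed <- config$seed
    simc <- do.call(simulation_config, sim_args)
    simdata <- .stage("simulate", generate_plate_experiment(simc))
    ts <- simdata$timeseries
    truth <- simdata$truth
    emit(ts, "timeseries.tsv")
    emit(truth, "ground_truth.tsv")
  }
  drugs <- unique(ts$drug)

  # --- fit growth curves ------------------------------------------------
  cpp <- .stage("fit", fit_cpp_table(ts))
  message(sprintf("  %d cultures fitted, %d no-growth",
                  nrow(cpp), sum(cpp$no_growth)))
  emit(cpp, "cpp.tsv")

  # --- interaction scores ----------------------------------------------
  ints <- .stage("score", {
    out <- lapply(drugs, function(d)
      score_interactions(cpp, d, threshold = config$z_threshold))
    data.table::rbindlist(out)
  })
  emit(ints, "interactions.tsv")

  # --- REMc -------------------------------------------------------------
  prof <- profile_matrix(split(ints, ints$drug))
  tree <- .stage("cluster", remc(
    prof, k_candidates = seq_len(config$remc$max_k %||% 10L),
    n_init = config$remc$n_init %||% 5L,
    min_size = config$remc$min_size %||% 8L,
    max_depth = config$remc$max_depth %||% 4L, seed = config$seed))
  membership <- remc_membership(tree)
  emit(prof, "profiles.tsv")
  emit(membership, "clusters.tsv")

  # --- enrichment + GTA -------------------------------------------------
  genes <- prof$strain
  if (!is.null(config$paths$annotations)) {
    ann <- read_tsv_table(config$paths$annotations)
  } else {
    ann <- generate_go_annotations(
      genes, n_terms = config$annotations$n_terms %||% 50L,
      term_size_range = config$annotations$term_size_range %||% c(3L, 30L),
      seed = config$seed + 1L)
    emit(ann, "annotations.tsv")
  }
  enr <- .stage("enrich", {
    res <- lapply(unique(membership$cluster_name), function(cl) {
      cg <- membership[cluster_name == cl]$gene
      if (length(cg) < 2) return(NULL)
      e <- hypergeom_enrichment(cg, genes, ann)
      if (nrow(e)) e[, cluster_name := cl]
      e
    })
    data.table::rbindlist(res[!vapply(res, is.null, logical(1))])
  })
  emit(enr, "enrichment.tsv")

  gtas <- .stage("gta", {
    res <- list()
    for (d in drugs) for (cp in c("K", "L")) {
      zc <- paste0("z_", d, "_", cp)
      if (!zc %in% names(prof)) next
      sc <- setNames(prof[[zc]], prof$strain)
      res[[paste(d, cp)]] <- gta_table(sc, ann, drug = d, cpp = cp,
                                       threshold = config$gta_threshold)
    }
    data.table::rbindlist(res)
  })
  emit(gtas, "gta.tsv")

  # --- pharmacogenomic integration -------------------------------------
  if (!is.null(config$paths$homology)) {
    hom <- read_tsv_table(config$paths$homology)
  } else {
    hom <- generate_homology_map(genes,
                                 class_mix = config$homology$class_mix,
                                 seed = config$seed + 2L)
    emit(hom, "homology.tsv")
  }
  yeast_cls <- unique(ints[strain_class %in% c("knockout", "knockdown"),
                           .(strain, drug, class)])
  hits_all <- list()
  for (d in drugs) {
    planted <- NULL
    cls_d <- yeast_cls[drug == d & class %in% c("enhancer", "suppressor")]
    if (nrow(cls_d)) {
      ph <- merge(cls_d, hom[, .(strain = yeast, human)], by = "strain")
      keep <- with_seed(config$seed + 3L,
                        runif(nrow(ph)) <
                          (config$pharmaco$conservation_fraction %||% 0.5))
      ph <- ph[keep]
      if (nrow(ph))
        planted <- data.frame(
          gene = ph$human,
          direction = ifelse(ph$class == "enhancer", "UES", "OES"),
          effect_size = config$pharmaco$effect_size %||% 0.6)
    }
    pd <- generate_pharmaco_dataset(
      n_cell_lines = config$pharmaco$n_cell_lines %||% 200L,
      human_genes = unique(hom$human),
      tissues = config$pharmaco$tissues %||% c("HaL", "lung", "other"),
      planted = planted, drug = d, seed = config$seed + 10L + match(d, drugs))
    assoc <- associate_expression(pd$expression, pd$sensitivity,
                                  pd$tissues, stratum = "all", drug = d)
    hits_all[[d]] <- call_hits(yeast_cls[drug == d], hom, assoc,
                               alpha = config$alpha)
  }
  hits <- .stage("integrate", data.table::rbindlist(hits_all))
  emit(hits, "hits.tsv")
  conservation <- summarize_conservation(hits, yeast_cls)
  emit(conservation, "conservation.tsv")

  manifest <- data.table::data.table(
    file = basename(written),
    md5 = unname(tools::md5sum(written)))
  emit(manifest, "manifest.tsv")
  list(manifest = manifest, truth = truth, cpp = cpp, interactions = ints,
       profiles = prof, membership = membership, enrichment = enr,
       gta = gtas, hits = hits, conservation = conservation)
}
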