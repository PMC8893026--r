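#' Pipeline configuration
#'
#' Assembles and validates the configuration consumed by [runPipeline()].
#' Either construct it in R or load it from a YAML/JSON file with
#' [readPipelineConfig()].
#'
#' @param table path to an OTU table (TSV or BIOM v1 JSON) or an
#'   [OtuExperiment-class] / samples x OTUs matrix.
#' @param metadata path to a metadata TSV or a data.frame.
#' @param tree path to a newick file, an \code{ape::phylo}, or NULL (the
#'   beta stage then falls back to Bray-Curtis only).
#' @param negctrl path to a one-sample TSV, a named count vector, or NULL
#'   (contaminant screening skipped).
#' @param rarefaction_depth target depth; NULL = minimum sample total.
#' @param seed global integer seed, expanded to per-stage seeds by fixed
#'   offsets so stages can be re-run in isolation.
#' @param n_perm permutations for all permutation tests.
#' @param group_vars metadata columns used as grouping factors.
#' @param env_vars metadata columns used as environmental predictors.
#' @param contaminant_factor fold threshold of the contaminant screen.
#' @param unifrac_normalized,chao1_bias_corrected,permdisp_center flags
#'   forwarded to the respective stages.
#' @param alpha forward-selection significance threshold.
#' @param output_dir directory for the per-stage artifacts and report; NULL
#'   disables file output.
#' @return list of class \code{"PipelineConfig"}.
#' @export
pipelineConfig <- function(table, metadata, tree = NULL, negctrl = NULL,
                           rarefaction_depth = NULL, seed = 1,
                           n_perm = 999,
                           group_vars = c("region", "depth_category"),
                           env_vars = c("temperature", "salinity", "nitrate",
                                        "chla", "depth_m",
                                        "sargassum_density"),
                           contaminant_factor = 10,
                           unifrac_normalized = TRUE,
                           chao1_bias_corrected = FALSE,
                           permdisp_center = "centroid",
                           alpha = 0.05,
                           output_dir = NULL) {
  cfg <- as.list(environment())
  stopifnot(is.numeric(seed), length(seed) == 1)
  structure(cfg, class = "PipelineConfig")
}

#' Read a pipeline configuration file (YAML or JSON)
#'
#' @param path configuration file; keys mirror the arguments of
#'   [pipelineConfig()] (paths are interpreted relative to the file).
#' @return list of class \code{"PipelineConfig"}.
#' @export
readPipelineConfig <- function(path) {
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  for (k in c("table", "metadata", "tree", "negctrl"))
    if (!is.null(cfg[[k]]) && is.character(cfg[[k]]) &&
        !file.exists(cfg[[k]]))
      cfg[[k]] <- file.path(base, cfg[[k]])
  do.call(pipelineConfig, cfg)
}

.stage_log <- function(log, stage, ...) {
  msg <- paste0("[", stage, "] ", ...)
  message(msg)
  c(log, msg)
}

.load_table <- function(x) if (is.character(x)) readOtuTable(x) else .counts(x)

#' Run the full analysis pipeline
#'
#' Orchestrates contaminant screening, single rarefaction, alpha-diversity
#' with group tests, beta-diversity (weighted UniFrac when a tree is
#' supplied, otherwise Bray-Curtis, with an explicit notice), PCoA,
#' PERMANOVA / PERMDISP / pairwise tests per grouping variable, two-way
#' SIMPER, distance-decay, PCNM construction, partial db-RDA with forward
#' selection, variation partitioning, and neutral-model fits per depth
#' stratum. Deterministic given the configured seed: per-stage seeds are
#' derived from the global seed by fixed offsets. When \code{output_dir} is
#' set, per-stage TSVs and a machine-readable JSON report are written; the
#' report body excludes wall-clock metadata so that repeated runs are
#' byte-identical.
#'
#' @param config a [pipelineConfig()] list or path to a YAML/JSON file.
#' @return list of class \code{"PipelineReport"} with one element per stage
#'   and a \code{log} character vector.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- readPipelineConfig(config)
  cfg <- config
  log <- character()
  report <- list(schema = "seabiome-report/1")
  seeds <- list(rarefy = cfg$seed + 101, beta = cfg$seed + 202,
                spatial = cfg$seed + 303, ordination = cfg$seed + 404)

  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  ## ingest
  m <- run_stage("ingest", .load_table(cfg$table))
  md <- run_stage("ingest", {
    md <- if (is.character(cfg$metadata)) readSampleMetadata(cfg$metadata)
          else as.data.frame(cfg$metadata)
    md[rownames(m), , drop = FALSE]
  })
  tree <- run_stage("ingest", {
    if (is.character(cfg$tree)) ape::read.tree(cfg$tree) else cfg$tree
  })
  log <- .stage_log(log, "ingest", nrow(m), " samples x ", ncol(m), " OTUs",
                    if (is.null(tree)) "; no tree (Bray-Curtis beta only)"
                    else "")

  ## contaminant screen
  if (!is.null(cfg$negctrl)) {
    neg <- if (is.character(cfg$negctrl)) {
      nm <- readOtuTable(cfg$negctrl)
      stats::setNames(as.vector(nm[1, ]), colnames(nm))
    } else cfg$negctrl
    fl <- run_stage("contaminants",
                    removeContaminants(m, neg, cfg$contaminant_factor))
    m <- .counts(fl$table)
    report$contaminants <- list(n_removed = nrow(fl$report),
                                removed = fl$report)
    log <- .stage_log(log, "contaminants", nrow(fl$report), " OTU(s) removed")
  }

  ## rarefaction
  m <- run_stage("rarefy", suppressWarnings(
    rarefyTable(m, depth = cfg$rarefaction_depth, seed = seeds$rarefy)))
  md <- md[rownames(m), , drop = FALSE]
  report$rarefaction <- list(depth = unname(rowSums(m)[1]),
                             n_samples = nrow(m))
  log <- .stage_log(log, "rarefy", "depth ", rowSums(m)[1], ", ",
                    nrow(m), " samples retained")

  ## alpha diversity
  alpha_tab <- run_stage("alpha", alphaDiversity(
    m, chao1_bias_corrected = cfg$chao1_bias_corrected))
  tests <- list()
  for (gv in intersect(cfg$group_vars, names(md)))
    for (metric in c("observed_otus", "shannon", "chao1", "heip_evenness"))
      if (length(unique(stats::na.omit(md[[gv]]))) >= 2)
        tests[[paste(metric, gv, sep = "~")]] <-
          kruskalWallis(alpha_tab[[metric]], md[[gv]])
  report$alpha <- list(table = alpha_tab, kruskal_wallis = tests)
  log <- .stage_log(log, "alpha", "4 metrics, ", length(tests), " group tests")

  ## beta diversity
  dm <- run_stage("beta", {
    if (!is.null(tree)) weightedUnifrac(m, tree,
                                        normalized = cfg$unifrac_normalized)
    else brayCurtis(m)
  })
  beta_metric <- if (is.null(tree)) "bray_curtis" else "weighted_unifrac"
  pc <- pcoaOrdination(dm)
  report$beta <- list(metric = beta_metric,
                      pcoa_eigenvalues = pc$eigenvalues,
                      prop_explained = pc$prop_explained)
  perma <- list(); disp <- list(); pairwise <- list()
  for (gv in intersect(cfg$group_vars, names(md))) {
    g <- md[[gv]]
    if (length(unique(stats::na.omit(g))) < 2) next
    perma[[gv]] <- run_stage("permanova",
      permanova(dm, g, n_perm = cfg$n_perm, seed = seeds$beta))
    disp[[gv]] <- tryCatch(
      permdisp(dm, g, n_perm = cfg$n_perm, seed = seeds$beta + 1,
               center = cfg$permdisp_center),
      error = function(e) NULL)
    if (perma[[gv]]$p <= 0.05 && length(unique(stats::na.omit(g))) > 2)
      pairwise[[gv]] <- pairwisePermanova(dm, g, n_perm = cfg$n_perm,
                                          seed = seeds$beta + 2)
  }
  report$permanova <- perma
  report$permdisp <- lapply(disp, function(x)
    if (is.null(x)) NULL else x[c("F", "p", "df")])
  report$pairwise_permanova <- pairwise
  log <- .stage_log(log, "beta", beta_metric, ", ", length(perma),
                    " PERMANOVA tests")

  ## SIMPER (two-way where both grouping variables exist)
  gvs <- intersect(cfg$group_vars, names(md))
  if (length(gvs) >= 1 && length(unique(stats::na.omit(md[[gvs[1]]]))) >= 2) {
    crossed <- if (length(gvs) >= 2) md[[gvs[2]]] else NULL
    simp <- run_stage("simper",
                      suppressWarnings(simperAnalysis(m, md[[gvs[1]]], crossed)))
    report$simper <- lapply(simp, function(s) list(
      overall_dissimilarity = s$overall_dissimilarity,
      top_taxa = utils::head(s$contributions, 10)))
    log <- .stage_log(log, "simper", length(simp), " group pairs")
  }

  ## spatial: distance decay, Mantel, PCNM
  spatial_ok <- all(c("latitude", "longitude") %in% names(md)) &&
    all(stats::complete.cases(md[, c("latitude", "longitude")]))
  if (spatial_ok) {
    geo <- haversineMatrix(md)
    report$distance_decay <- run_stage("distance_decay", {
      dd <- list(all = distanceDecay(dm, geo))
      if ("depth_category" %in% names(md))
        for (s in unique(md$depth_category)) {
          keep <- md$depth_category == s
          if (sum(keep) >= 3)
            dd[[s]] <- distanceDecay(dm[keep, keep], geo[keep, keep])
        }
      dd
    })
    if ("temperature" %in% names(md)) {
      tdm <- as.matrix(stats::dist(md$temperature))
      dimnames(tdm) <- list(rownames(md), rownames(md))
      report$mantel_temperature_geo <- run_stage("mantel",
        mantelTest(tdm, geo, n_perm = cfg$n_perm, seed = seeds$spatial))
    }
    pcnm <- run_stage("pcnm", pcnmBasis(geo))
    report$pcnm <- list(n_axes = ncol(pcnm$vectors),
                        threshold_km = pcnm$threshold)
    log <- .stage_log(log, "spatial", ncol(pcnm$vectors),
                      " PCNM axes, truncation ",
                      round(pcnm$threshold, 1), " km")

    ## constrained ordination + variation partitioning
    env <- md[, intersect(cfg$env_vars, names(md)), drop = FALSE]
    env <- env[, vapply(env, function(v)
      is.numeric(v) && length(unique(stats::na.omit(v))) > 1, TRUE),
      drop = FALSE]
    if (ncol(env) >= 1) {
      S <- as.data.frame(pcnm$vectors)
      fs <- run_stage("forward_selection",
        forwardSelect(dm, env, Z = S, alpha = cfg$alpha,
                      n_perm = cfg$n_perm, seed = seeds$ordination))
      best_env <- if (length(fs$selected)) env[, fs$selected, drop = FALSE]
                  else env
      partial <- run_stage("dbrda",
        dbRda(dm, best_env, Z = S, n_perm = cfg$n_perm,
              seed = seeds$ordination + 1))
      vp <- run_stage("varpart",
        variationPartition(dm, best_env, S, n_perm = min(cfg$n_perm, 199),
                           seed = seeds$ordination + 2))
      report$dbrda <- list(
        selected = fs$selected, forward_steps = fs$steps,
        global_adj_r_squared = fs$global_adj_r_squared,
        partial_model = partial[c("pseudo_F", "p", "r_squared",
                                  "adj_r_squared", "m", "q", "n")])
      report$variation_partition <- vp[c("a", "b", "c", "d", "apportioned",
                                         "a_prime", "b_prime", "c_prime",
                                         "adj_r_squared")]
      log <- .stage_log(log, "dbrda", "selected: ",
                        paste(fs$selected, collapse = ", "))
    }
  } else {
    log <- .stage_log(log, "spatial", "skipped: incomplete coordinates")
  }

  ## neutral community model
  strata <- c("all",
              if ("depth_category" %in% names(md))
                intersect(c("surface", "DCM"), unique(md$depth_category)))
  ncm <- run_stage("ncm", {
    fits <- ncmByStratum(m, md, strata = strata)
    lapply(fits, function(f) f[c("m", "Nm", "N", "d", "r_squared",
                                 "n_samples", "n_below", "n_within",
                                 "n_above")])
  })
  report$ncm <- ncm
  log <- .stage_log(log, "ncm", "fitted strata: ",
                    paste(names(ncm), collapse = ", "))

  report$log <- log
  out <- structure(report, class = "PipelineReport")
  if (!is.null(cfg$output_dir)) writePipelineReport(out, cfg$output_dir,
                                                    alpha_tab, dm)
  out
}

#' Write pipeline artifacts
#'
#' Writes the alpha table and distance matrix as TSV plus the JSON report
#' (fixed-precision serialization; no timestamps, so repeated runs of the
#' same configuration are byte-identical).
#'
#' @param report a \code{PipelineReport}.
#' @param dir output directory (created if needed).
#' @param alpha_tab,dm optional per-stage artifacts to serialize alongside.
#' @return \code{dir}, invisibly.
#' @export
writePipelineReport <- function(report, dir, alpha_tab = NULL, dm = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(alpha_tab))
    utils::write.table(alpha_tab, file.path(dir, "alpha_diversity.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(dm))
    utils::write.table(data.frame(sample_id = rownames(dm), dm,
                                  check.names = FALSE),
                       file.path(dir, "distance_matrix.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  body <- unclass(report)
  body$log <- NULL
  jsonlite::write_json(body, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = 10, null = "null",
                       dataframe = "rows", force = TRUE)
  writeLines(report$log, file.path(dir, "pipeline.log"))
  invisible(dir)
}
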