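#' Generate a metacommunity source pool
#'
#' Draws metacommunity relative abundances from a lognormal rank-abundance
#' distribution and a random bifurcating phylogeny over the taxa. The pool
#' plays the role of the regional species pool whose relative abundances
#' \eqn{p_i} drive both the Dirichlet-multinomial sampler and the neutral
#' community model fitted downstream.
#'
#' @param n_taxa number of taxa (>= 2).
#' @param abundance_sd lognormal sigma of the abundance distribution; 0 gives
#'   a perfectly even pool.
#' @param seed integer seed; the pool is deterministic given the seed.
#' @return a list of class \code{"SourcePool"} with elements
#'   \code{taxon_ids}, \code{p} (sums to 1) and \code{tree} (rooted
#'   \code{ape::phylo} with exponential(1) branch lengths).
#' @examples
#' pool <- generateSourcePool(50, 1, seed = 1)
#' sum(pool$p)
#' @export
generateSourcePool <- function(n_taxa, abundance_sd = 1, seed = NULL) {
  if (n_taxa < 2) stop("n_taxa must be >= 2")
  if (abundance_sd < 0) stop("abundance_sd must be >= 0")
  .with_seed(seed, {
    ids <- sprintf("OTU%04d", seq_len(n_taxa))
    p <- if (abundance_sd == 0) rep(1, n_taxa) else
      stats::rlnorm(n_taxa, meanlog = 0, sdlog = abundance_sd)
    p <- p / sum(p)
    tree <- ape::rtree(n_taxa, rooted = TRUE, tip.label = ids,
                       br = function(n) stats::rexp(n, rate = 1))
    structure(list(taxon_ids = ids, p = p, tree = tree),
              class = "SourcePool")
  })
}

#' Simulate one local community under neutral assembly
#'
#' Generative inverse of the Sloan neutral model: the local relative-abundance
#' vector is Dirichlet with concentration \eqn{Nm \cdot p}, then reads are
#' drawn multinomially. The marginal of taxon \eqn{i} is approximately
#' Beta(\eqn{Nm\,p_i}, \eqn{Nm(1-p_i)}), the distribution the fitted model
#' assumes.
#'
#' @param pool a \code{SourcePool} (or any list with a \code{p} element) giving
#'   source relative abundances.
#' @param Nm product of local community size and immigration probability
#'   (> 0); small \code{Nm} means strong drift.
#' @param reads library size of the simulated sample (>= 1).
#' @param seed integer seed or NULL.
#' @return named integer count vector summing to \code{reads}.
#' @export
simulateNeutralSample <- function(pool, Nm, reads, seed = NULL) {
  p <- if (is.list(pool)) pool$p else pool
  if (is.null(p) || anyNA(p)) stop("pool relative abundances are undefined")
  if (Nm <= 0) stop("Nm must be > 0")
  if (reads < 1) stop("reads must be >= 1")
  .with_seed(seed, {
    # Dirichlet via independent gammas; taxa with p = 0 stay exactly 0.
    g <- numeric(length(p))
    pos <- p > 0
    g[pos] <- stats::rgamma(sum(pos), shape = Nm * p[pos], rate = 1)
    if (sum(g) == 0) g[pos] <- p[pos]  # extreme-shape underflow guard
    counts <- as.vector(stats::rmultinom(1, size = reads, prob = g / sum(g)))
    names(counts) <- if (is.list(pool)) pool$taxon_ids else names(p)
    counts
  })
}

#' Simulate one local community under mixed niche/neutral assembly
#'
#' Applies a Gaussian environmental filter to the source pool before neutral
#' sampling: \eqn{q_i \propto p_i \exp(-w (x - o_i)^2 / (2 t_i^2))} where
#' \eqn{x} is the local environmental value, \eqn{o_i} and \eqn{t_i} the
#' taxon's optimum and tolerance, and \eqn{w \in [0,1]} the niche weight
#' (0 = pure neutral, 1 = full niche filtering).
#'
#' @param pool a \code{SourcePool}.
#' @param traits list with numeric \code{optimum} and \code{tolerance}
#'   vectors matching the pool (tolerance > 0).
#' @param env_value local environmental value (same units as the optima).
#' @param w mixture weight in [0, 1].
#' @inheritParams simulateNeutralSample
#' @return named integer count vector summing to \code{reads}.
#' @export
simulateNicheSample <- function(pool, traits, env_value, w, Nm, reads,
                                seed = NULL) {
  if (w < 0 || w > 1) stop("w must lie in [0, 1]")
  p <- pool$p
  if (length(traits$optimum) != length(p) ||
      length(traits$tolerance) != length(p))
    stop("trait lengths do not match the pool")
  if (any(traits$tolerance <= 0)) stop("tolerances must be > 0")
  q <- p * exp(-w * (env_value - traits$optimum)^2 /
                 (2 * traits$tolerance^2))
  if (sum(q) == 0) stop("degenerate pool: all filtered abundances are zero")
  q <- q / sum(q)
  simulateNeutralSample(list(taxon_ids = pool$taxon_ids, p = q),
                        Nm = Nm, reads = reads, seed = seed)
}

#' Gaussian niche traits for a source pool
#'
#' Random environmental optima (uniform over a range) and a common tolerance,
#' in the units of the driving covariate (degrees C by default usage).
#'
#' @param pool a \code{SourcePool}.
#' @param optimum_range length-2 numeric range for the optima.
#' @param tolerance positive Gaussian breadth (single value or per taxon).
#' @param seed integer seed or NULL.
#' @return list with \code{optimum} and \code{tolerance} vectors.
#' @export
generateNicheTraits <- function(pool, optimum_range = c(15, 30),
                                tolerance = 3, seed = NULL) {
  n <- length(pool$p)
  if (any(tolerance <= 0)) stop("tolerance must be > 0")
  .with_seed(seed, list(
    optimum = stats::runif(n, optimum_range[1], optimum_range[2]),
    tolerance = rep_len(tolerance, n)))
}

#' Simulation configuration
#'
#' Bundles the transect geometry and assembly parameters for
#' [generateMetadata()] and [simulateDataset()]. Defaults describe a
#' subtropical open-ocean transect: 20 stations spanning ~14 degrees of
#' latitude, two depth strata (surface and deep chlorophyll maximum) per
#' station, 15,000 reads per sample after rarefaction, immigration
#' probability m = 0.1, and a temperature field declining with latitude.
#'
#' @param n_stations stations along the transect.
#' @param n_depth_strata 1 (surface only) or 2 (surface + DCM).
#' @param reads_per_sample reads per simulated community (>= 1).
#' @param migration_m Sloan immigration probability, in (0, 1].
#' @param niche_weight w in [0, 1]: 0 pure neutral, 1 full niche filtering.
#' @param transect list with numeric \code{lat} and \code{lon} endpoints
#'   (degrees), south to north.
#' @param temp_intercept,temp_slope,temp_noise_sd linear temperature model
#'   temperature = intercept + slope * latitude + N(0, sd) (degrees C;
#'   slope in degrees C per degree latitude).
#' @param dcm_temp_offset additive temperature offset of the DCM stratum
#'   (degrees C, typically negative).
#' @param region_breaks latitude break points (southmost to northmost)
#'   delimiting the region labels AC / SSS / NSS / NA.
#' @param dispersal_drift_sd station-to-station standard deviation of the
#'   log-pool random walk used by the dispersal-limited assembly mode; 0
#'   disables dispersal limitation.
#' @param seed integer seed.
#' @return a list of class \code{"SimConfig"}.
#' @export
simConfig <- function(n_stations = 20, n_depth_strata = 2,
                      reads_per_sample = 15000, migration_m = 0.1,
                      niche_weight = 0,
                      transect = list(lat = c(22, 36), lon = c(-65, -63)),
                      temp_intercept = 35, temp_slope = -0.35,
                      temp_noise_sd = 0.5, dcm_temp_offset = -2.8,
                      region_breaks = c(24, 28, 33),
                      dispersal_drift_sd = 0, seed = 1) {
  if (reads_per_sample < 1) stop("reads_per_sample must be >= 1")
  if (migration_m <= 0 || migration_m > 1) stop("migration_m must be in (0, 1]")
  if (niche_weight < 0 || niche_weight > 1) stop("niche_weight must be in [0, 1]")
  if (!n_depth_strata %in% 1:2) stop("n_depth_strata must be 1 or 2")
  structure(as.list(environment()), class = "SimConfig")
}

#' Generate transect sample metadata
#'
#' Places stations evenly along the transect, builds a latitude-driven
#' temperature field with Gaussian noise, assigns oceanographic region labels
#' by latitude break points, and emits one row per station x depth stratum
#' with the covariate vocabulary used throughout the package (latitude,
#' longitude, depth_m, temperature, salinity, nitrate, chla,
#' sargassum_density, date, region, depth_category).
#'
#' @param config a [simConfig()] list.
#' @return \code{data.frame} with row names = sample ids.
#' @export
generateMetadata <- function(config) {
  stopifnot(inherits(config, "SimConfig") || is.list(config))
  ns <- config$n_stations
  .with_seed(config$seed, {
    lat <- seq(config$transect$lat[1], config$transect$lat[2], length.out = ns)
    lon <- seq(config$transect$lon[1], config$transect$lon[2], length.out = ns)
    temp_surface <- config$temp_intercept + config$temp_slope * lat +
      stats::rnorm(ns, 0, config$temp_noise_sd)
    # "NAtl" (not "NA") so region labels survive TSV round trips
    region <- cut(lat, breaks = c(-Inf, config$region_breaks, Inf),
                  labels = c("AC", "SSS", "NSS", "NAtl"))
    strata <- if (config$n_depth_strata == 2) c("surface", "DCM") else "surface"
    rows <- expand.grid(stratum = strata, station = seq_len(ns),
                        stringsAsFactors = FALSE)
    is_dcm <- rows$stratum == "DCM"
    st <- rows$station
    md <- data.frame(
      station = sprintf("ST%02d", st),
      region = as.character(region)[st],
      depth_category = rows$stratum,
      latitude = lat[st],
      longitude = lon[st],
      depth_m = ifelse(is_dcm, 100, 2),
      temperature = temp_surface[st] + ifelse(is_dcm, config$dcm_temp_offset, 0),
      salinity = 36.5 + 0.02 * (lat[st] - mean(lat)) + stats::rnorm(nrow(rows), 0, 0.05),
      nitrate = ifelse(is_dcm, 1.5, 0.02) * exp(stats::rnorm(nrow(rows), 0, 0.3)),
      chla = ifelse(is_dcm, 0.30, 0.05) * exp(stats::rnorm(nrow(rows), 0, 0.3)),
      sargassum_density = ifelse(is_dcm, 0,
        round(exp(stats::rnorm(nrow(rows), log(5), 1)), 2)),
      date = as.Date("2017-05-01") + st - 1,
      stringsAsFactors = FALSE)
    rownames(md) <- paste0(md$station, "_", ifelse(is_dcm, "D", "S"))
    md$sample_id <- rownames(md)
    md[, c("sample_id", setdiff(names(md), "sample_id"))]
  })
}

#' Simulate a full ground-truthed dataset
#'
#' Composes [generateMetadata()] with one community per metadata row, using
#' that row's temperature as the environmental value for the niche filter.
#' Three assembly regimes are available through the configuration:
#' \itemize{
#'   \item pure neutral (\code{niche_weight = 0, dispersal_drift_sd = 0}):
#'     every sample drawn from the same source pool;
#'   \item niche filtered (\code{niche_weight > 0}): Gaussian temperature
#'     filter applied to the pool before sampling;
#'   \item dispersal limited (\code{dispersal_drift_sd > 0}): the log source
#'     pool performs a random walk from station to station along the
#'     transect, so nearby stations share similar effective pools
#'     (neighborhood mixing) while the environment plays no role.
#' }
#' Optionally appends contaminant taxa seen mainly in a negative-control
#' sample, for exercising the contaminant screen.
#'
#' @param config a [simConfig()] list.
#' @param pool a \code{SourcePool}; defaults to a fresh 500-taxon pool.
#' @param traits niche traits (required when \code{niche_weight > 0}).
#' @param n_contaminants number of contaminant taxa to append (with a
#'   negative-control count vector in the result).
#' @return list of class \code{"SimulatedDataset"} with \code{table} (an
#'   [OtuExperiment-class]), \code{metadata}, \code{tree}, \code{negctrl}
#'   (named counts or NULL) and \code{truth} (config, pool and per-sample
#'   effective pools).
#' @export
simulateDataset <- function(config, pool = NULL, traits = NULL,
                            n_contaminants = 0) {
  stopifnot(inherits(config, "SimConfig") || is.list(config))
  .with_seed(config$seed, {
    if (is.null(pool))
      pool <- generateSourcePool(500, 1, seed = NULL)
    if (config$niche_weight > 0 && is.null(traits))
      traits <- generateNicheTraits(pool,
        optimum_range = range(config$temp_intercept +
                                config$temp_slope * config$transect$lat) + c(-3, 3),
        tolerance = 3, seed = NULL)
    md <- generateMetadata(config)
    nt <- length(pool$p)

    # Station-level effective pools under dispersal limitation: random walk
    # on log p along the transect.
    station_pools <- NULL
    if (config$dispersal_drift_sd > 0) {
      lp <- log(pool$p)
      station_pools <- matrix(NA_real_, config$n_stations, nt)
      for (s in seq_len(config$n_stations)) {
        lp <- lp + stats::rnorm(nt, 0, config$dispersal_drift_sd)
        q <- exp(lp - max(lp)); station_pools[s, ] <- q / sum(q)
      }
    }

    counts <- matrix(0, nrow(md), nt,
                     dimnames = list(rownames(md), pool$taxon_ids))
    eff_pools <- counts
    for (i in seq_len(nrow(md))) {
      st <- as.integer(sub("ST", "", md$station[i]))
      base_p <- if (is.null(station_pools)) pool$p else station_pools[st, ]
      row_pool <- list(taxon_ids = pool$taxon_ids, p = base_p)
      if (config$niche_weight > 0) {
        q <- base_p * exp(-config$niche_weight *
                            (md$temperature[i] - traits$optimum)^2 /
                            (2 * traits$tolerance^2))
        if (sum(q) == 0) stop("degenerate pool at sample ", rownames(md)[i])
        row_pool$p <- q / sum(q)
      }
      eff_pools[i, ] <- row_pool$p
      counts[i, ] <- simulateNeutralSample(
        row_pool, Nm = config$migration_m * config$reads_per_sample,
        reads = config$reads_per_sample, seed = NULL)
    }

    negctrl <- NULL
    tree <- pool$tree
    if (n_contaminants > 0) {
      cid <- sprintf("CONTAM%02d", seq_len(n_contaminants))
      # contaminants: abundant in the negative control, sparse in samples
      extra <- matrix(stats::rpois(nrow(md) * n_contaminants, 5),
                      nrow(md), n_contaminants, dimnames = list(rownames(md), cid))
      counts <- cbind(counts, extra)
      negctrl <- stats::setNames(numeric(ncol(counts)), colnames(counts))
      negctrl[cid] <- 100 + stats::rpois(n_contaminants, 20)
      ctree <- ape::rtree(max(2, n_contaminants),
                          br = function(n) stats::rexp(n, 1))
      ctree$tip.label <- c(cid, sprintf("PAD%02d",
        seq_len(max(0, 2 - n_contaminants))))[seq_along(ctree$tip.label)]
      # graft the contaminant clade into a root edge to keep the tree rooted
      tree$root.edge <- 1
      tree <- ape::bind.tree(tree, ctree, position = 0.5)
    }

    oe <- OtuExperiment(counts, metadata = md, tree = tree)
    structure(list(table = oe, metadata = md, tree = tree, negctrl = negctrl,
                   truth = list(config = config, pool = pool, traits = traits,
                                effective_pools = eff_pools)),
              class = "SimulatedDataset")
  })
}
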