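#' Read an OTU table
#'
#' Reads the two interchange formats used by the pipeline: a TSV matrix
#' (first column OTU id, header row of sample ids, tab-separated, UTF-8) or
#' BIOM v1 JSON. Counts are validated as non-negative integers.
#'
#' @param path file path.
#' @param format \code{"tsv"} or \code{"biom-json"}; default guessed from the
#'   file extension.
#' @return samples x OTUs numeric matrix with dimnames.
#' @seealso [writeOtuTable()]
#' @export
readOtuTable <- function(path, format = c("auto", "tsv", "biom-json")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.biom$|\\.json$", path)) "biom-json" else "tsv"
  if (!file.exists(path)) stop("file not found: ", path)
  m <- switch(format,
    "tsv" = {
      df <- utils::read.table(path, header = TRUE, sep = "\t",
                              check.names = FALSE, row.names = 1,
                              quote = "", comment.char = "")
      t(as.matrix(df))  # file is OTUs x samples
    },
    "biom-json" = .read_biom_json(path))
  if (nrow(m) == 0 || ncol(m) == 0)
    stop("parse error: table in ", path, " has no samples or no OTUs")
  if (!is.numeric(m) || any(!is.finite(m)))
    stop("validation error: non-numeric counts in ", path)
  if (any(abs(m - round(m)) > 1e-8) || any(m < 0))
    stop("validation error: counts must be non-negative integers in ", path)
  m
}

# BIOM v1 (JSON) reader/writer. jsonlite is used directly so that sparse and
# dense matrix types round-trip without an HDF5 dependency.
.read_biom_json <- function(path) {
  b <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(b$rows) || is.null(b$columns) || is.null(b$data))
    stop("parse error: not a BIOM v1 JSON file: ", path)
  otus <- vapply(b$rows, function(r) r$id, "")
  samples <- vapply(b$columns, function(r) r$id, "")
  m <- matrix(0, length(otus), length(samples), dimnames = list(otus, samples))
  if (identical(b$matrix_type, "dense")) {
    for (i in seq_along(b$data)) m[i, ] <- unlist(b$data[[i]])
  } else {
    for (trip in b$data)
      m[trip[[1]] + 1, trip[[2]] + 1] <- trip[[3]]
  }
  t(m)
}

#' Write an OTU table
#'
#' @param table [OtuExperiment-class] or samples x OTUs matrix.
#' @param path output file path.
#' @param format \code{"tsv"} or \code{"biom-json"}.
#' @return \code{path}, invisibly.
#' @export
writeOtuTable <- function(table, path, format = c("tsv", "biom-json")) {
  format <- match.arg(format)
  m <- .counts(table)
  if (format == "tsv") {
    out <- t(m)  # OTUs x samples on disk
    df <- data.frame("#OTU ID" = rownames(out), out, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                       fileEncoding = "UTF-8")
  } else {
    om <- t(m)
    trip <- which(om != 0, arr.ind = TRUE)
    b <- list(
      id = "seabiome", format = "Biological Observation Matrix 1.0.0",
      format_url = "http://biom-format.org",
      type = "OTU table", generated_by = "seabiome",
      date = "1970-01-01T00:00:00",
      matrix_type = "sparse", matrix_element_type = "int",
      shape = c(nrow(om), ncol(om)),
      rows = lapply(rownames(om), function(id) list(id = id, metadata = NULL)),
      columns = lapply(colnames(om), function(id) list(id = id, metadata = NULL)),
      data = lapply(seq_len(nrow(trip)), function(k)
        list(trip[k, 1] - 1, trip[k, 2] - 1, om[trip[k, 1], trip[k, 2]])))
    jsonlite::write_json(b, path, auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}

#' Read / write sample metadata TSV
#'
#' Metadata TSV uses a \code{sample_id} first column and the covariate
#' vocabulary documented in [generateMetadata()].
#' @param path file path.
#' @return \code{data.frame} with row names = sample ids.
#' @export
readSampleMetadata <- function(path) {
  md <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          quote = "", comment.char = "", stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(md)) stop("metadata must have a sample_id column")
  rownames(md) <- md$sample_id
  if ("date" %in% names(md)) md$date <- as.Date(md$date)
  md
}

#' @rdname readSampleMetadata
#' @param metadata \code{data.frame} of per-sample covariates.
#' @export
writeSampleMetadata <- function(metadata, path) {
  md <- as.data.frame(metadata)
  if (!"sample_id" %in% names(md)) md$sample_id <- rownames(md)
  md <- md[, c("sample_id", setdiff(names(md), "sample_id"))]
  utils::write.table(md, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Remove contaminant OTUs flagged by a negative control
#'
#' An OTU observed in the negative control (count \eqn{c > 0}) is treated as
#' a contaminant and removed unless at least one real sample carries at least
#' \code{factor} times the control count, i.e. it is removed iff
#' \eqn{\max_s \mathrm{count}_{s} < \mathrm{factor} \cdot c}. OTUs absent
#' from the control are always kept.
#'
#' @param table [OtuExperiment-class] or samples x OTUs matrix.
#' @param negctrl named count vector for the negative-control sample, indexed
#'   by OTU id (ids absent from the vector are treated as 0).
#' @param factor fold threshold (> 0); default 10.
#' @return list with \code{table} (filtered, same class as the input matrix
#'   orientation) and \code{report} (data.frame of removed OTUs with their
#'   control and maximum sample counts).
#' @export
removeContaminants <- function(table, negctrl, factor = 10) {
  if (factor <= 0) stop("factor must be > 0")
  m <- .counts(table)
  c0 <- stats::setNames(numeric(ncol(m)), colnames(m))
  shared <- intersect(names(negctrl), colnames(m))
  c0[shared] <- negctrl[shared]
  maxs <- apply(m, 2, max)
  removed <- c0 > 0 & maxs < factor * c0
  report <- data.frame(otu_id = colnames(m)[removed],
                       negctrl_count = unname(c0[removed]),
                       max_sample_count = unname(maxs[removed]))
  out <- m[, !removed, drop = FALSE]
  if (methods::is(table, "OtuExperiment")) {
    out <- OtuExperiment(out, metadata = sampleData(table), tree = otuTree(table))
  }
  list(table = out, report = report)
}

#' Rarefy an OTU table to even depth
#'
#' Single rarefaction: each sample is subsampled without replacement
#' (hypergeometric) to exactly \code{depth} reads. Samples with fewer reads
#' than \code{depth} are dropped with a warning.
#'
#' @param table [OtuExperiment-class] or samples x OTUs matrix.
#' @param depth target reads per sample (>= 1); default: minimum sample total.
#' @param seed integer seed; the subsample is deterministic given the seed.
#' @return rarefied table of the same kind as the input.
#' @export
rarefyTable <- function(table, depth = NULL, seed = NULL) {
  m <- .counts(table)
  .check_integer_counts(m)
  tot <- rowSums(m)
  if (is.null(depth)) depth <- min(tot)
  if (depth < 1) stop("depth must be >= 1")
  keep <- tot >= depth
  if (!any(keep)) stop("empty result: no sample reaches depth ", depth)
  if (any(!keep))
    warning("dropped ", sum(!keep), " sample(s) below depth ", depth, ": ",
            paste(rownames(m)[!keep], collapse = ", "))
  sub <- round(m[keep, , drop = FALSE])
  # rrarefy's "observed counts" heuristic warning is spurious here
  out <- .with_seed(seed, suppressWarnings(vegan::rrarefy(sub, depth)))
  if (methods::is(table, "OtuExperiment")) {
    md <- sampleData(table)[rownames(out), , drop = FALSE]
    return(OtuExperiment(out, metadata = md, tree = otuTree(table)))
  }
  out
}

#' Shared and unique OTU counts across sample groups
#'
#' Presence/absence set algebra over sample categories: an OTU belongs to a
#' category iff any sample of that category has a positive count. Returns the
#' full intersection lattice (one cell per non-empty membership pattern),
#' which partitions the observed OTUs, plus the per-category unique counts
#' and the all-category shared count.
#'
#' @param table [OtuExperiment-class] or samples x OTUs matrix.
#' @param groups sample-to-category factor (named by sample id, or in table
#'   order).
#' @return list with \code{lattice} (data.frame: membership pattern, count),
#'   \code{unique} (named vector), \code{shared_all} (scalar) and
#'   \code{per_category} (total observed per category).
#' @export
sharedUniqueCounts <- function(table, groups) {
  m <- .counts(table)
  g <- .groups_factor(groups, nrow(m), rownames(m))
  if (nlevels(g) < 2) stop("need >= 2 categories")
  if (any(table(g) == 0)) stop("category with zero samples")
  pres <- vapply(levels(g), function(lv)
    colSums(m[g == lv, , drop = FALSE]) > 0, logical(ncol(m)))
  observed <- rowSums(pres) > 0
  pat <- apply(pres[observed, , drop = FALSE], 1, function(z)
    paste(levels(g)[z], collapse = "&"))
  lattice <- as.data.frame(table(pattern = pat), stringsAsFactors = FALSE)
  names(lattice)[2] <- "n_otus"
  uniq <- vapply(levels(g), function(lv) sum(pat == lv), 0)
  list(lattice = lattice,
       unique = uniq,
       shared_all = sum(pat == paste(levels(g), collapse = "&")),
       per_category = colSums(pres))
}

#' Group-mean relative abundances at an aggregation level
#'
#' Per-sample relative abundances are aggregated to labels (e.g. phylum or
#' family) via \code{level_map}, averaged within each sample group, and
#' labels that stay below \code{min_frac} in every group are suppressed.
#' Retained columns therefore need not sum to 1.
#'
#' @param table [OtuExperiment-class] or samples x OTUs matrix.
#' @param groups sample-to-group factor.
#' @param level_map named character: OTU id to label; default identity.
#' @param min_frac suppression threshold in [0, 1).
#' @return labels x groups matrix of mean relative abundances.
#' @export
groupRelativeAbundance <- function(table, groups, level_map = NULL,
                                   min_frac = 0) {
  if (min_frac < 0 || min_frac >= 1) stop("min_frac must be in [0, 1)")
  m <- .counts(table)
  g <- .groups_factor(groups, nrow(m), rownames(m))
  rel <- .rel_abund(m)
  lab <- if (is.null(level_map)) colnames(m) else {
    unname(level_map[colnames(m)])
  }
  if (anyNA(lab)) stop("level_map does not cover all OTU ids")
  agg <- t(rowsum(t(rel), lab))                      # samples x labels
  gm <- rowsum(agg, g) / as.vector(table(g))         # groups x labels
  out <- t(gm)                                       # labels x groups
  keep <- apply(out, 1, max) >= min_frac
  out[keep, , drop = FALSE]
}
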