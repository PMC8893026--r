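#' OtuExperiment: an OTU count table with sample metadata and a phylogeny
#'
#' The single data currency passed between pipeline stages. Extends
#' \linkS4class{SummarizedExperiment}: the \code{"counts"} assay holds
#' non-negative integer OTU counts (OTUs as rows, samples as columns, the
#' Bioconductor convention), \code{colData} holds the per-sample environmental
#' and spatial covariates, and a rooted \code{\link[ape]{phylo}} tree whose
#' tips cover the OTU identifiers may be attached for phylogenetic
#' beta-diversity.
#'
#' @slot tree a rooted \code{ape::phylo} object or \code{NULL}.
#'
#' @seealso [OtuExperiment()] (constructor), [otuCounts()], [sampleData()],
#'   [otuTree()]
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @exportClass OtuExperiment
setClass("OtuExperiment",
  contains = "SummarizedExperiment",
  slots = c(tree = "ANY"))

setValidity("OtuExperiment", function(object) {
  msg <- character()
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'counts' is required")
  else {
    m <- SummarizedExperiment::assay(object, "counts")
    if (any(!is.finite(m)) || any(m < 0))
      msg <- c(msg, "counts must be finite and non-negative")
    else if (any(abs(m - round(m)) > 1e-8))
      msg <- c(msg, "counts must be integral")
  }
  if (anyDuplicated(colnames(object))) msg <- c(msg, "sample ids must be unique")
  if (anyDuplicated(rownames(object))) msg <- c(msg, "OTU ids must be unique")
  tr <- object@tree
  if (!is.null(tr)) {
    if (!inherits(tr, "phylo")) msg <- c(msg, "tree must be an ape 'phylo' or NULL")
    else {
      if (!ape::is.rooted(tr)) msg <- c(msg, "tree must be rooted")
      if (is.null(tr$edge.length) || any(!is.finite(tr$edge.length)) ||
          any(tr$edge.length < 0))
        msg <- c(msg, "tree must have finite non-negative branch lengths")
      missing <- setdiff(rownames(object), tr$tip.label)
      if (length(missing))
        msg <- c(msg, paste0("OTUs absent from tree tips: ",
                             paste(utils::head(missing, 5), collapse = ", "),
                             if (length(missing) > 5) " ..."))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct an OtuExperiment
#'
#' @param counts samples x OTUs (or OTUs x samples, see \code{samples_as_rows})
#'   non-negative integer matrix with dimnames.
#' @param metadata \code{data.frame} or \code{DataFrame} of per-sample
#'   covariates, one row per sample; row names (or a \code{sample_id} column)
#'   must match the sample ids of \code{counts}.
#' @param tree optional rooted \code{ape::phylo} whose tips cover the OTU ids.
#' @param samples_as_rows logical; \code{TRUE} (default) when \code{counts}
#'   has samples as rows, as emitted by the simulator and the TSV reader.
#' @return an [OtuExperiment-class] object.
#' @examples
#' m <- matrix(rpois(12, 5), 3, 4,
#'             dimnames = list(paste0("S", 1:3), paste0("OTU", 1:4)))
#' oe <- OtuExperiment(m, data.frame(row.names = rownames(m),
#'                                   depth_category = c("surface", "DCM", "surface")))
#' otuCounts(oe)
#' @export
OtuExperiment <- function(counts, metadata = NULL, tree = NULL,
                          samples_as_rows = TRUE) {
  counts <- .counts(counts)
  if (samples_as_rows) counts <- t(counts)
  .check_integer_counts(counts)
  storage.mode(counts) <- "double"
  if (is.null(metadata)) {
    metadata <- S4Vectors::DataFrame(row.names = colnames(counts))
  } else {
    metadata <- S4Vectors::DataFrame(metadata)
    if (is.null(rownames(metadata)) && "sample_id" %in% colnames(metadata))
      rownames(metadata) <- metadata$sample_id
    if (!setequal(rownames(metadata), colnames(counts)))
      stop("metadata sample ids do not match the count table")
    metadata <- metadata[colnames(counts), , drop = FALSE]
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts), colData = metadata)
  methods::new("OtuExperiment", se, tree = tree)
}
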