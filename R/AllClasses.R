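#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<- queryHits subjectHits split
#' @importFrom IRanges IRanges
#' @importFrom BiocGenerics sort strand strand<- start end width
#' @importFrom GenomicRanges GRanges granges seqnames findOverlaps
#'   pintersect reduce countOverlaps isDisjoint
#' @importFrom GenomeInfoDb seqlengths seqlevels
#' @importFrom data.table data.table as.data.table fread dcast setorderv .N := shift
#' @importFrom yaml read_yaml
#' @importFrom glmnet glmnet
NULL

#' Simulation configuration for the synthetic annotation bundle
#'
#' Holds every knob of the synthetic-genome generator: genome geometry, gene
#' architecture, the TE type catalog, and the planted effects (exonic
#' enrichment, sense-strand bias, exonic conservation excess, per-copy
#' localization shifts, rare-allele excess). All randomness downstream is
#' driven by \code{seed}.
#'
#' @slot seed integer; master RNG seed.
#' @slot nChroms,chromLength genome geometry (nt).
#' @slot nGenes number of non-overlapping lncRNA-like genes to place.
#' @slot exonsPerTranscript,transcriptsPerGene integer ranges (min, max).
#' @slot exonLength,intronLength sampling ranges (nt) for gene architecture.
#' @slot teCatalog data.frame with columns te_type, te_family, te_class,
#'   consensus_length, n_instances.
#' @slot enrichedTypes,enrichedFold planted exonic-enrichment types and the
#'   exon/intron coverage fold they realize in expectation.
#' @slot strandBiasedTypes,senseFraction planted sense-biased types and their
#'   genic sense-placement probability.
#' @slot conservedTypes,exonicConsFraction,intronicConsFraction planted
#'   conserved types: per-instance probability that an exonic (resp. intronic)
#'   instance is covered by a conserved element.
#' @slot localizationEffects named numeric; per-TE-type per-copy RCI shift
#'   (log2 units) applied to host transcripts.
#' @slot cellLines character; simulated cell lines.
#' @slot rciSigma baseline RCI standard deviation (log2 units).
#' @slot rpkmSigma per-fraction lognormal noise sd (log2 units).
#' @slot dropoutRate probability a fraction RPKM is zeroed.
#' @slot dafRareRidl,dafRareBackground rare-allele (DAF < 0.1) fractions for
#'   the RIDL SNP class and all other classes.
#' @slot consensusBias per-type 3' insertion bias in (-1, 1); 0 = uniform
#'   fragment sampling along the consensus.
#' @exportClass SimulationConfig
setClass("SimulationConfig",
  representation(
    seed = "integer",
    nChroms = "integer", chromLength = "integer",
    nGenes = "integer",
    exonsPerTranscript = "integer", transcriptsPerGene = "integer",
    exonLength = "integer", intronLength = "integer",
    teCatalog = "data.frame",
    enrichedTypes = "character", enrichedFold = "numeric",
    strandBiasedTypes = "character", senseFraction = "numeric",
    conservedTypes = "character",
    exonicConsFraction = "numeric", intronicConsFraction = "numeric",
    localizationEffects = "numeric",
    cellLines = "character",
    rciSigma = "numeric", rpkmSigma = "numeric", dropoutRate = "numeric",
    dafRareRidl = "numeric", dafRareBackground = "numeric",
    consensusBias = "numeric"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character()
  cat <- object@teCatalog
  need <- c("te_type", "te_family", "te_class", "consensus_length",
            "n_instances")
  if (!all(need %in% names(cat)))
    msg <- c(msg, paste("teCatalog must have columns:",
                        paste(need, collapse = ", ")))
  planted <- c(object@enrichedTypes, object@strandBiasedTypes,
               object@conservedTypes, names(object@localizationEffects))
  if (length(planted) && !all(planted %in% cat$te_type))
    msg <- c(msg, "all planted type names must be drawn from the te catalog")
  if (object@enrichedFold <= 0) msg <- c(msg, "enrichedFold must be > 0")
  fr <- c(object@senseFraction, object@exonicConsFraction,
          object@intronicConsFraction, object@dropoutRate,
          object@dafRareRidl, object@dafRareBackground)
  if (any(fr < 0 | fr > 1)) msg <- c(msg, "fractions must lie in [0, 1]")
  if (length(object@exonsPerTranscript) != 2L ||
      diff(object@exonsPerTranscript) < 0L)
    msg <- c(msg, "exonsPerTranscript must be an increasing (min, max) pair")
  if (length(msg)) msg else TRUE
})

#' Synthetic annotation bundle
#'
#' File paths of one generated dataset (chromosome sizes, gene GTF, TE BED,
#' conserved-element BEDs, expression table, SNP table, functional gene
#' lists) plus the truth tables of planted effects, and the config that
#' produced them.
#'
#' @slot dir output directory.
#' @slot files named character vector of file paths.
#' @slot truth named list of data.frames describing the planted effects.
#' @slot config the \linkS4class{SimulationConfig} used.
#' @exportClass SyntheticBundle
setClass("SyntheticBundle",
  representation(dir = "character", files = "character", truth = "list",
                 config = "SimulationConfig")
)

setValidity("SyntheticBundle", function(object) {
  if (is.null(names(object@files)) || any(names(object@files) == ""))
    return("files must be a named character vector")
  TRUE
})

#' Per-TE-type screen results with empirical null
#'
#' One selection screen's output: per-type observed statistic, empirical
#' p-value against a shuffle null, direction, BH FDR and candidate flag,
#' plus the null matrix and the metadata needed to reproduce it.
#'
#' @slot screen one of "enrichment", "strand_bias", "conservation".
#' @slot results DataFrame, one row per TE type.
#' @slot nullValues numeric matrix (type x simulation) of null statistics;
#'   zero columns for the analytic enrichment screen.
#' @slot nSim number of shuffle simulations.
#' @slot seed RNG seed used for the shuffles (NA for analytic screens).
#' @exportClass ScreenResult
setClass("ScreenResult",
  representation(screen = "character", results = "DataFrame",
                 nullValues = "matrix", nSim = "integer", seed = "integer")
)

setValidity("ScreenResult", function(object) {
  msg <- character()
  if (!object@screen %in% c("enrichment", "strand_bias", "conservation"))
    msg <- c(msg, "unknown screen kind")
  if (!"te_type" %in% colnames(object@results))
    msg <- c(msg, "results must carry a te_type column")
  p <- object@results$p_empirical
  if (!is.null(p)) {
    ok <- is.na(p) | (p >= 1 / (1 + object@nSim) - 1e-12 & p <= 1)
    if (!all(ok))
      msg <- c(msg, "empirical p-values must lie in [1/(1+nSim), 1]")
  }
  if (length(msg)) msg else TRUE
})

#' The merged RIDL annotation
#'
#' Repeat insertion domains of lncRNAs: merged exonic TE fragments carrying
#' selection evidence. Fragments shorter than 10 nt are discarded at
#' construction and instances are non-overlapping after the merge.
#'
#' @slot ranges GRanges with metadata columns te_type, gene_id (CharacterList),
#'   evidence (CharacterList) and source_instances (IntegerList).
#' @exportClass RIDLSet
setClass("RIDLSet", representation(ranges = "GRanges"))

setValidity("RIDLSet", function(object) {
  gr <- object@ranges
  msg <- character()
  need <- c("te_type", "gene_id", "evidence", "source_instances")
  if (!all(need %in% names(mcols(gr))))
    msg <- c(msg, paste("ranges must carry metadata columns:",
                        paste(need, collapse = ", ")))
  if (length(gr)) {
    if (any(width(gr) < 10L))
      msg <- c(msg, "all RIDL instances must be >= 10 nt")
    if ("evidence" %in% names(mcols(gr)) &&
        any(lengths(mcols(gr)$evidence) == 0L))
      msg <- c(msg, "every RIDL must carry at least one evidence label")
    if (!isDisjoint(gr))
      msg <- c(msg, "RIDL instances must be non-overlapping after merging")
  }
  if (length(msg)) msg else TRUE
})

#' @importFrom GenomicRanges isDisjoint
NULL

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig\n")
  cat("  seed:", object@seed, "\n")
  cat("  genome:", object@nChroms, "chromosome(s) x",
      object@chromLength, "nt\n")
  cat("  genes:", object@nGenes, "| TE types:",
      nrow(object@teCatalog), "\n")
  cat("  planted: enrichment [", paste(object@enrichedTypes, collapse = ", "),
      "] fold", object@enrichedFold, "\n")
  cat("           strand bias [",
      paste(object@strandBiasedTypes, collapse = ", "),
      "] sense fraction", object@senseFraction, "\n")
  cat("           conservation [",
      paste(object@conservedTypes, collapse = ", "), "] exonic",
      object@exonicConsFraction, "vs intronic",
      object@intronicConsFraction, "\n")
  if (length(object@localizationEffects))
    cat("           localization shifts:",
        paste(names(object@localizationEffects),
              sprintf("%+.2f", object@localizationEffects), collapse = "; "),
        "(log2/copy)\n")
})

setMethod("show", "SyntheticBundle", function(object) {
  cat("SyntheticBundle in", object@dir, "\n")
  cat("  files:", paste(names(object@files), collapse = ", "), "\n")
  cat("  truth tables:", paste(names(object@truth), collapse = ", "), "\n")
})

setMethod("show", "ScreenResult", function(object) {
  res <- object@results
  cat("ScreenResult <", object@screen, ">:", nrow(res), "TE types")
  if (object@nSim > 0L) cat(",", object@nSim, "simulations")
  cat("\n")
  if ("candidate" %in% colnames(res))
    cat("  candidates:", sum(res$candidate, na.rm = TRUE), "\n")
})

setMethod("show", "RIDLSet", function(object) {
  gr <- object@ranges
  cat("RIDLSet:", length(gr), "instances,",
      length(unique(mcols(gr)$te_type)), "TE types\n")
  if (length(gr)) {
    ev <- sort(table(unlist(mcols(gr)$evidence)), decreasing = TRUE)
    cat("  evidence:", paste(names(ev), ev, sep = "=", collapse = ", "), "\n")
  }
})

# ---- accessors ----

#' @rdname accessors
#' @param x a ScreenResult or RIDLSet.
#' @export
setGeneric("resultsTable", function(x) standardGeneric("resultsTable"))

#' Accessors for screen and RIDL objects
#'
#' \code{resultsTable} returns the per-type result table of a screen as a
#' data.frame; \code{candidateTypes} the TE types flagged as RIDL candidates;
#' \code{ridlRanges} the underlying GRanges of a RIDLSet; \code{nullMatrix}
#' the type x simulation matrix of null statistics.
#'
#' @name accessors
#' @rdname accessors
#' @export
setMethod("resultsTable", "ScreenResult",
          function(x) as.data.frame(x@results))

#' @rdname accessors
#' @export
setGeneric("candidateTypes", function(x) standardGeneric("candidateTypes"))

#' @rdname accessors
#' @export
setMethod("candidateTypes", "ScreenResult", function(x) {
  res <- x@results
  as.character(res$te_type[!is.na(res$candidate) & res$candidate])
})

#' @rdname accessors
#' @export
setGeneric("ridlRanges", function(x) standardGeneric("ridlRanges"))

#' @rdname accessors
#' @export
setMethod("ridlRanges", "RIDLSet", function(x) x@ranges)

#' @rdname accessors
#' @export
setGeneric("nullMatrix", function(x) standardGeneric("nullMatrix"))

#' @rdname accessors
#' @export
setMethod("nullMatrix", "ScreenResult", function(x) x@nullValues)

#' @rdname accessors
#' @export
setGeneric("bundleFile", function(x, name) standardGeneric("bundleFile"))

#' @rdname accessors
#' @param name file key, e.g. "gtf", "te_bed", "chrom_sizes".
#' @export
setMethod("bundleFile", "SyntheticBundle", function(x, name) {
  if (!name %in% names(x@files))
    stop("no bundle file named '", name, "'; available: ",
         paste(names(x@files), collapse = ", "))
  unname(x@files[name])
})

#' @rdname accessors
#' @export
setGeneric("truthTables", function(x) standardGeneric("truthTables"))

#' @rdname accessors
#' @export
setMethod("truthTables", "SyntheticBundle", function(x) x@truth)
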