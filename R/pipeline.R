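#' Run the full RIDL discovery pipeline on annotation files
#'
#' Reads the gene models, TE annotation and conserved-element sets, merges
#' exons and derives single-gene introns, runs the three selection screens
#' (exonic enrichment; strand bias against a gene-shuffling null; REIC
#' against a conserved-element-shuffling null, once per conserved set),
#' applies the per-evidence instance filters and assembles the merged RIDL
#' annotation.
#'
#' @param gtf path to the gene GTF.
#' @param teBed path to the RepeatMasker-style TE BED.
#' @param conservedBeds named character vector of conserved-element BED
#'   paths (each becomes one conservation screen, named cons_<name>).
#' @param chromSizes path to the chromosome-size table, or a named vector.
#' @param nSim shuffle simulations per empirical null.
#' @param seed RNG seed (the strand screen uses \code{seed}, the k-th
#'   conservation screen \code{seed + k}).
#' @param biotypeFilter optional GTF biotype filter.
#' @param foldCutoff enrichment candidacy cutoff.
#' @return list with exons, merged, introns, tes, types, exonCov,
#'   intronCov, screens (named list of ScreenResult), selected, ridls
#'   (a \linkS4class{RIDLSet}).
#' @export
runRidlPipeline <- function(gtf, teBed, conservedBeds, chromSizes,
                            nSim = 1000L, seed = 1L,
                            biotypeFilter = NULL, foldCutoff = 2.0) {
  if (is.character(chromSizes) && length(chromSizes) == 1L)
    chromSizes <- readChromSizes(chromSizes)
  exons <- readGeneModels(gtf, biotypeFilter)
  tes <- readTeBed(teBed)
  merged <- mergeExons(exons)
  introns <- deriveIntrons(exons, merged)
  types <- screenEligibleTypes(tes, merged, introns)
  exonCov <- coverageByType(merged, tes, types)
  intronCov <- coverageByType(introns, tes, types)
  screens <- list(
    enrichment = enrichmentScreen(exonCov, intronCov, foldCutoff),
    strand_bias = strandBiasScreen(merged, tes, chromSizes, nSim = nSim,
                                   seed = seed, types = types))
  consSets <- list()
  for (k in seq_along(conservedBeds)) {
    nm <- paste0("cons_", names(conservedBeds)[k])
    consSets[[nm]] <- readBed(conservedBeds[k])
    screens[[nm]] <- conservationScreen(
      merged, introns, tes, consSets[[nm]], chromSizes, nSim = nSim,
      seed = seed + k, types = types)
  }
  selected <- selectInstances(screens, merged, tes, consSets)
  ridls <- assembleRidls(selected)
  list(exons = exons, merged = merged, introns = introns, tes = tes,
       types = types, exonCov = exonCov, intronCov = intronCov,
       screens = screens, selected = selected, ridls = ridls)
}

#' Run the pipeline on a synthetic bundle
#'
#' Convenience wrapper of [runRidlPipeline()] over the file paths of a
#' \linkS4class{SyntheticBundle} (conserved sets phast and ecs).
#'
#' @param bundle a \linkS4class{SyntheticBundle}.
#' @param nSim,seed as in [runRidlPipeline()].
#' @return the [runRidlPipeline()] result list.
#' @export
runRidlPipelineOnBundle <- function(bundle, nSim = 1000L,
                                    seed = bundle@config@seed) {
  runRidlPipeline(
    gtf = bundleFile(bundle, "gtf"),
    teBed = bundleFile(bundle, "te_bed"),
    conservedBeds = c(phast = bundleFile(bundle, "cons_phast"),
                      ecs = bundleFile(bundle, "cons_ecs")),
    chromSizes = bundleFile(bundle, "chrom_sizes"),
    nSim = nSim, seed = seed)
}
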