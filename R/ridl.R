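#' Select TE instances carrying each kind of selection evidence
#'
#' Applies the per-evidence instance filters to the screen candidates:
#' \describe{
#'   \item{enrichment}{all exonic instances of a candidate type;}
#'   \item{strand_bias}{only instances in sense orientation to a host
#'     transcript;}
#'   \item{conservation}{only instances intersecting (>= 1 nt) an element of
#'     the specific conserved set that flagged the type.}
#' }
#' An exonic instance is a TE instance overlapping the merged exons of at
#' least one gene.
#'
#' @param screens named list of \linkS4class{ScreenResult} objects; names
#'   starting with "cons" must have a matching entry in
#'   \code{conservedSets}.
#' @param merged merged exon GRanges.
#' @param tes TE annotation GRanges.
#' @param conservedSets named list of conserved-element GRanges, one per
#'   conservation screen.
#' @return GRanges of selected instances, one row per (instance, evidence),
#'   with metadata te_type, instance_id, evidence, gene_id (CharacterList).
#' @export
selectInstances <- function(screens, merged, tes,
                            conservedSets = list()) {
  records <- classifyExonicTEs(merged, tes)
  if (nrow(records) == 0L) {
    out <- GRanges()
    mcols(out) <- DataFrame(te_type = character(), instance_id = integer(),
                            evidence = character(),
                            gene_id = S4Vectors::SimpleList())
    return(out)
  }
  exIdx <- unique(records$te_idx)
  hostGenes <- split(records$gene_id, records$te_idx)
  senseIdx <- unique(records$te_idx[!is.na(records$relative_strand) &
                                    records$relative_strand == "sense"])
  pick <- function(idx, evidence) {
    if (length(idx) == 0L) return(NULL)
    sel <- tes[idx]
    gl <- lapply(as.character(idx), function(i)
      sort(unique(hostGenes[[i]])))
    mcols(sel) <- DataFrame(te_type = tes$te_type[idx],
                            instance_id = tes$instance_id[idx],
                            evidence = evidence,
                            gene_id = S4Vectors::SimpleList(gl))
    sel
  }
  out <- list()
  for (nm in names(screens)) {
    cand <- candidateTypes(screens[[nm]])
    if (length(cand) == 0L) next
    kind <- screens[[nm]]@screen
    if (kind == "enrichment") {
      idx <- exIdx[tes$te_type[exIdx] %in% cand]
      out[[nm]] <- pick(idx, nm)
    } else if (kind == "strand_bias") {
      idx <- senseIdx[tes$te_type[senseIdx] %in% cand]
      out[[nm]] <- pick(idx, nm)
    } else if (kind == "conservation") {
      if (!nm %in% names(conservedSets))
        stop("no conserved-element set supplied for screen '", nm, "'")
      idx <- exIdx[tes$te_type[exIdx] %in% cand]
      hit <- GenomicRanges::countOverlaps(tes[idx], conservedSets[[nm]],
                                          ignore.strand = TRUE) > 0
      out[[nm]] <- pick(idx[hit], nm)
    } else stop("unknown screen kind: ", kind)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0L) {
    res <- GRanges()
    mcols(res) <- DataFrame(te_type = character(), instance_id = integer(),
                            evidence = character(),
                            gene_id = S4Vectors::SimpleList())
    return(res)
  }
  suppressWarnings(do.call(c, unname(out)))
}

#' Assemble the merged RIDL annotation
#'
#' Overlapping selected fragments are merged genome-wide (strand-ignorant,
#' bookended intervals merge); evidence labels and host gene ids are unioned
#' on merge; the dominant te_type (largest contributing fragment) labels the
#' merged record; merged instances shorter than 10 nt are discarded
#' (strictly: length 10 survives).
#'
#' @param selected output of [selectInstances()].
#' @param minLength minimum merged length retained (default 10 nt).
#' @return a \linkS4class{RIDLSet}.
#' @export
assembleRidls <- function(selected, minLength = 10L) {
  if (length(selected) == 0L) {
    gr <- GRanges()
    mcols(gr) <- DataFrame(
      te_type = character(), gene_id = S4Vectors::SimpleList(),
      evidence = S4Vectors::SimpleList(),
      source_instances = S4Vectors::SimpleList())
    return(new("RIDLSet", ranges = gr))
  }
  red <- reduce(granges(selected), ignore.strand = TRUE,
                with.revmap = TRUE, min.gapwidth = 1L)
  keep <- width(red) >= minLength
  red <- red[keep]
  revmap <- mcols(red)$revmap
  teType <- character(length(red))
  evid <- vector("list", length(red))
  gids <- vector("list", length(red))
  srcs <- vector("list", length(red))
  for (i in seq_along(red)) {
    idx <- revmap[[i]]
    contrib <- width(pintersect(granges(selected)[idx],
                                rep(granges(red)[i], length(idx)),
                                ignore.strand = TRUE))
    teType[i] <- selected$te_type[idx][which.max(contrib)]
    evid[[i]] <- sort(unique(selected$evidence[idx]))
    gids[[i]] <- sort(unique(unlist(selected$gene_id[idx])))
    srcs[[i]] <- sort(unique(selected$instance_id[idx]))
  }
  gr <- granges(red)
  mcols(gr) <- DataFrame(te_type = teType,
                         gene_id = S4Vectors::SimpleList(gids),
                         evidence = S4Vectors::SimpleList(evid),
                         source_instances = S4Vectors::SimpleList(srcs))
  new("RIDLSet", ranges = gr)
}

#' Write a RIDLSet as BED6+ (te_type, evidence, gene_id extra columns)
#' @param x RIDLSet. @param path output file.
#' @export
writeRidlBed <- function(x, path) {
  gr <- ridlRanges(x)
  mcols(gr)$name <- mcols(gr)$te_type
  writeBed(gr, path, extraCols = c("te_type", "evidence", "gene_id"))
}

#' Count RIDL instances per transcript
#'
#' A transcript carries a RIDL when a RIDL instance overlaps one of its
#' exons; counts are per (transcript, te_type).
#'
#' @param x RIDLSet. @param exons exon GRanges with transcript_id/gene_id.
#' @return data.frame transcript_id, gene_id, te_type, n.
#' @export
countRidlsPerTranscript <- function(x, exons) {
  gr <- ridlRanges(x)
  ov <- findOverlaps(gr, exons, ignore.strand = TRUE)
  if (length(ov) == 0L)
    return(data.frame(transcript_id = character(), gene_id = character(),
                      te_type = character(), n = integer()))
  dt <- data.table::data.table(
    ridl = queryHits(ov),
    transcript_id = exons$transcript_id[subjectHits(ov)],
    gene_id = exons$gene_id[subjectHits(ov)],
    te_type = mcols(gr)$te_type[queryHits(ov)])
  dt <- unique(dt)  # a RIDL spanning two exons of one transcript counts once
  out <- dt[, list(n = .N), by = c("transcript_id", "gene_id", "te_type")]
  as.data.frame(out)
}

#' Insertion profile of TE instances along their consensus
#'
#' profile[pos] = fraction of instances whose consensus interval
#' [consensus_start, consensus_end] covers position pos (1-based).
#'
#' @param tes GRanges with consensus_start/consensus_end metadata.
#' @param consensusLength length of the consensus (nt).
#' @return numeric vector of length \code{consensusLength} in [0, 1].
#' @export
insertionProfile <- function(tes, consensusLength) {
  tes <- tes[!is.na(tes$consensus_start)]
  if (length(tes) == 0L)
    stop("undefined profile: no instances with consensus coordinates")
  if (any(tes$consensus_end > consensusLength))
    stop("rejected record: consensus_end exceeds consensus length")
  inc <- tabulate(tes$consensus_start, nbins = consensusLength + 1L)
  dec <- tabulate(tes$consensus_end + 1L, nbins = consensusLength + 1L)
  cumsum(inc - dec)[seq_len(consensusLength)] / length(tes)
}

#' Compare two insertion profiles by rank correlation
#'
#' CC is Spearman's correlation of the two equal-length profiles; a CC below
#' 0.9 flags a possible difference in selective forces between the two
#' instance sets. Constant profiles make the rank correlation undefined and
#' are flagged degenerate.
#'
#' @param ridlProfile,intronicProfile equal-length numeric profiles.
#' @param ccCutoff flagging threshold (default 0.9).
#' @return list with cc, flagged, degenerate.
#' @export
compareProfiles <- function(ridlProfile, intronicProfile, ccCutoff = 0.9) {
  if (length(ridlProfile) != length(intronicProfile))
    stop("profiles must have equal length")
  if (stats::sd(ridlProfile) == 0 || stats::sd(intronicProfile) == 0)
    return(list(cc = NA_real_, flagged = TRUE, degenerate = TRUE))
  cc <- stats::cor(ridlProfile, intronicProfile, method = "spearman")
  list(cc = cc, flagged = cc < ccCutoff, degenerate = FALSE)
}
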