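#' Merge exons of all transcripts per gene
#'
#' Exons of every transcript of a gene are unioned into a non-overlapping,
#' sorted set of merged exonic intervals; bookended intervals (distance 0)
#' merge. The merged set carries the gene strand.
#'
#' @param exons GRanges of exons with gene_id metadata (see
#'   [readGeneModels()]).
#' @return GRanges of merged exonic intervals with a gene_id column.
#' @export
mergeExons <- function(exons) {
  if (length(exons) == 0L) return(GRanges(gene_id = character()))
  dt <- data.table::data.table(chrom = as.character(seqnames(exons)),
                               start = start(exons), end = end(exons),
                               strand = as.character(strand(exons)),
                               gene_id = exons$gene_id)
  nStr <- dt[, list(n = length(unique(strand))), by = "gene_id"]
  if (any(nStr$n > 1L))
    stop("annotation error: transcripts of gene ",
         nStr$gene_id[nStr$n > 1L][1], " lie on conflicting strands")
  data.table::setorderv(dt, c("gene_id", "start", "end"))
  prevmax <- dt[, list(v = data.table::shift(cummax(end), 1L)),
                by = "gene_id"]$v
  dt$newg <- is.na(prevmax) | dt$start > prevmax + 1L
  dt[, `:=`(grp, cumsum(newg)), by = "gene_id"]
  m <- dt[, list(chrom = chrom[1], start = min(start), end = max(end),
                 strand = strand[1]), by = c("gene_id", "grp")]
  out <- GRanges(m$chrom, IRanges(m$start, m$end), strand = m$strand,
                 gene_id = m$gene_id)
  sort(out, ignore.strand = TRUE)
}

#' Gene spans (min start to max end over a gene's exons)
#' @param exons GRanges of exons with gene_id metadata.
#' @return GRanges, one span per gene, with gene_id.
#' @export
geneSpans <- function(exons) {
  if (length(exons) == 0L) return(GRanges(gene_id = character()))
  dt <- data.table::data.table(chrom = as.character(seqnames(exons)),
                               start = start(exons), end = end(exons),
                               strand = as.character(strand(exons)),
                               gene_id = exons$gene_id)
  agg <- dt[, list(chrom = chrom[1], s = min(start), e = max(end),
                   strand = strand[1]), by = "gene_id"]
  spans <- GRanges(agg$chrom, IRanges(agg$s, agg$e), strand = agg$strand,
                   gene_id = agg$gene_id)
  sort(spans, ignore.strand = TRUE)
}

#' Derive single-gene introns
#'
#' Introns are the gene span minus the merged exons, assigned the host gene's
#' strand; any intron overlapping a second gene's span is discarded so every
#' retained intron belongs to exactly one gene.
#'
#' @param exons GRanges of exons with gene_id.
#' @param merged optional pre-computed [mergeExons()] output.
#' @return GRanges of introns with a gene_id column.
#' @export
deriveIntrons <- function(exons, merged = mergeExons(exons)) {
  spans <- geneSpans(exons)
  if (length(spans) == 0L) return(GRanges(gene_id = character()))
  # merged is sorted and non-bookended within a gene, so introns are the
  # gaps between consecutive merged intervals of the same gene
  dt <- data.table::data.table(chrom = as.character(seqnames(merged)),
                               start = start(merged), end = end(merged),
                               strand = as.character(strand(merged)),
                               gene_id = merged$gene_id)
  data.table::setorderv(dt, c("gene_id", "start"))
  gaps <- dt[, if (.N > 1L)
    list(chrom = chrom[-.N], start = end[-.N] + 1L,
         end = start[-1L] - 1L, strand = strand[-.N]),
    by = "gene_id"]
  if (nrow(gaps) == 0L) return(GRanges(gene_id = character()))
  introns <- GRanges(gaps$chrom, IRanges(gaps$start, gaps$end),
                     strand = gaps$strand, gene_id = gaps$gene_id)
  nSpans <- GenomicRanges::countOverlaps(introns, spans,
                                         ignore.strand = TRUE)
  sort(introns[nSpans < 2L], ignore.strand = TRUE)
}

.geneTerminalNts <- function(merged) {
  dt <- data.table::data.table(start = start(merged), end = end(merged),
                               strand = as.character(strand(merged)),
                               gene_id = merged$gene_id)
  agg <- dt[, list(s = min(start), e = max(end), strand = strand[1]),
            by = "gene_id"]
  minus <- agg$strand == "-"
  list(first = stats::setNames(ifelse(minus, agg$e, agg$s), agg$gene_id),
       last = stats::setNames(ifelse(minus, agg$s, agg$e), agg$gene_id),
       strand = stats::setNames(agg$strand, agg$gene_id))
}

#' Intersect TE instances with merged exons and classify them
#'
#' Every (TE instance, merged exon interval) overlapping pair yields one
#' record, classified into one of six structural categories relative to the
#' host gene: \code{TSS} (TE covers the first exonic nucleotide of the gene),
#' \code{TTS} (covers the last), \code{encompassing} (exon entirely within
#' the TE), \code{acceptor} (TE crosses the exon 5' boundary into the
#' intron), \code{donor} (crosses the 3' boundary), \code{inside} (TE
#' entirely within the exon). When several definitions match, precedence is
#' TSS > TTS > encompassing > acceptor > donor > inside. The relative strand
#' is \code{sense} when TE and gene strands agree, \code{antisense}
#' otherwise, and NA (flagged) for unstranded TEs.
#'
#' @param merged merged exon GRanges from [mergeExons()].
#' @param tes TE GRanges from [readTeBed()].
#' @return DataFrame with columns te_idx (index into \code{tes}),
#'   instance_id, te_type, gene_id, category, relative_strand, overlap_nt,
#'   unstranded.
#' @export
classifyExonicTEs <- function(merged, tes) {
  core <- .classifyCore(merged, tes)
  DataFrame(te_idx = core$te_idx,
            instance_id = tes$instance_id[core$te_idx],
            te_type = core$te_type, gene_id = core$gene_id,
            category = core$category,
            relative_strand = core$relative_strand,
            overlap_nt = core$overlap_nt, unstranded = core$unstranded)
}

# Plain-vector classification core shared with the shuffle-null loops.
.classifyCore <- function(merged, tes) {
  empty <- list(te_idx = integer(), te_type = character(),
                gene_id = character(), category = character(),
                relative_strand = character(), overlap_nt = integer(),
                unstranded = logical())
  if (length(merged) == 0L || length(tes) == 0L) return(empty)
  ov <- findOverlaps(tes, merged, ignore.strand = TRUE)
  if (length(ov) == 0L) return(empty)
  ti <- queryHits(ov); ei <- subjectHits(ov)
  ts <- start(tes)[ti]; te <- end(tes)[ti]
  es <- start(merged)[ei]; ee <- end(merged)[ei]
  gid <- merged$gene_id[ei]
  term <- .geneTerminalNts(merged)
  firstNt <- term$first[gid]; lastNt <- term$last[gid]
  gstr <- term$strand[gid]
  plus <- gstr != "-"
  crossesLeft <- ts < es & te >= es     # TE extends beyond exon start
  crossesRight <- ts <= ee & te > ee    # TE extends beyond exon end
  category <- rep("inside", length(ti))
  category[(plus & crossesRight) | (!plus & crossesLeft)] <- "donor"
  category[(plus & crossesLeft) | (!plus & crossesRight)] <- "acceptor"
  category[crossesLeft & crossesRight] <- "encompassing"
  coversFirst <- ts <= firstNt & te >= firstNt & es <= firstNt & ee >= firstNt
  coversLast <- ts <= lastNt & te >= lastNt & es <= lastNt & ee >= lastNt
  category[coversLast] <- "TTS"
  category[coversFirst] <- "TSS"
  tstr <- as.character(strand(tes))[ti]
  unstranded <- tstr == "*"
  rel <- ifelse(unstranded, NA_character_,
                ifelse(tstr == gstr, "sense", "antisense"))
  list(te_idx = ti, te_type = tes$te_type[ti], gene_id = gid,
       category = category, relative_strand = rel,
       overlap_nt = pmin(te, ee) - pmax(ts, es) + 1L,
       unstranded = unstranded)
}

#' Per-TE-type nucleotide coverage of an interval set
#'
#' For each TE type, the number of nucleotides of the interval union covered
#' by at least one instance of that type (same-type overlaps counted once)
#' and the covered fraction.
#'
#' @param intervals GRanges (e.g. merged exons or introns); the union is the
#'   denominator.
#' @param tes TE GRanges with te_type metadata.
#' @param types optional character vector fixing the set (and order) of
#'   reported types; defaults to types present in \code{tes}.
#' @return data.frame with columns te_type, covered_nt, total_nt, fraction.
#' @export
coverageByType <- function(intervals, tes,
                           types = sort(unique(tes$te_type))) {
  pooled <- reduce(intervals, ignore.strand = TRUE)
  total <- sum(width(pooled))
  if (total == 0L)
    stop("undefined fraction: interval set has zero total length")
  covered <- stats::setNames(numeric(length(types)), types)
  if (length(tes)) {
    tesIn <- tes[tes$te_type %in% types]
    if (length(tesIn)) {
      red <- reduce(split(granges(tesIn), tesIn$te_type),
                    ignore.strand = TRUE)
      ur <- unlist(red)
      ov <- findOverlaps(ur, pooled, ignore.strand = TRUE)
      if (length(ov)) {
        w <- width(pintersect(ur[queryHits(ov)], pooled[subjectHits(ov)],
                              ignore.strand = TRUE))
        agg <- rowsum(w, names(ur)[queryHits(ov)])
        covered[rownames(agg)] <- agg[, 1]
      }
    }
  }
  data.frame(te_type = types, covered_nt = as.numeric(covered),
             total_nt = as.numeric(total),
             fraction = as.numeric(covered) / total,
             row.names = NULL, stringsAsFactors = FALSE)
}
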