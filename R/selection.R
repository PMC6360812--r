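#' Empirical p-value from a shuffle null
#'
#' p = rank/(1 + n_sim), where rank is the 1-based rank of the observed
#' statistic among the observed value plus the null values, in the direction
#' tested: rank = 1 + #\{null >= observed\} for direction "greater",
#' 1 + #\{null <= observed\} for "less". A statistic more extreme than every
#' null replicate (rank 1) is conservatively assigned p = 1/n_sim (0.001 at
#' n_sim = 1000): the raw 1/(1 + n_sim) is rounded up, and p is never 0.
#'
#' @param observed observed statistic.
#' @param nullValues numeric vector of null statistics (NA/NaN entries count
#'   as never more extreme).
#' @param direction "greater" or "less".
#' @return list with rank, p (conservatively floored), p_raw
#'   (rank/(1+n_sim)), n_sim, direction.
#' @export
empiricalPvalue <- function(observed, nullValues,
                            direction = c("greater", "less")) {
  direction <- match.arg(direction)
  nSim <- length(nullValues)
  if (nSim == 0L) stop("empty null distribution")
  extreme <- if (direction == "greater") nullValues >= observed
             else nullValues <= observed
  rank <- 1L + sum(extreme, na.rm = TRUE)
  praw <- rank / (1 + nSim)
  list(rank = rank, p = if (rank == 1L) 1 / nSim else praw,
       p_raw = praw, n_sim = nSim, direction = direction)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Thin wrapper over \code{p.adjust(..., method = "fdr")} with an input
#' range check; q-values are returned in the input order.
#'
#' @param pvals numeric p-values in [0, 1] (NAs passed through).
#' @return numeric q-values.
#' @export
adjustFdr <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "fdr")
}

#' Relative exonic-intronic conservation (REIC)
#'
#' REIC = (Ce/(Ce+Ne)) / (Ci/(Ci+Ni)): the conserved fraction of exonic TE
#' nucleotides over the conserved fraction of intronic TE nucleotides of the
#' same type. Because both terms are fractional overlaps, the statistic
#' normalizes for the different total lengths of exons and introns.
#'
#' @param ce,ne conserved / non-conserved exonic TE nucleotides.
#' @param ci,ni conserved / non-conserved intronic TE nucleotides.
#' @return numeric; NA when undefined (Ce+Ne = 0, Ci+Ni = 0, or Ci = 0).
#' @export
computeReic <- function(ce, ne, ci, ni) {
  bad <- (ce + ne) <= 0 | (ci + ni) <= 0 | ci <= 0
  out <- (ce / (ce + ne)) / (ci / (ci + ni))
  out[bad] <- NA_real_
  out
}

#' TE types eligible for the selection screens
#'
#' A type must have at least one instance overlapping the exonic space and
#' one overlapping the intronic space to enter any screen.
#'
#' @param tes TE GRanges.
#' @param merged merged exon GRanges; @param introns intron GRanges.
#' @return character vector of eligible type names, sorted.
#' @export
screenEligibleTypes <- function(tes, merged, introns) {
  exTypes <- unique(tes$te_type[GenomicRanges::countOverlaps(
    tes, merged, ignore.strand = TRUE) > 0])
  inTypes <- unique(tes$te_type[GenomicRanges::countOverlaps(
    tes, introns, ignore.strand = TRUE) > 0])
  sort(intersect(exTypes, inTypes))
}

#' Exonic-enrichment screen
#'
#' Per TE type, the ratio of exonic to intronic per-nucleotide coverage
#' fractions. Types with ratio strictly greater than \code{foldCutoff}
#' (default twofold) are candidates. Types with zero intronic coverage have
#' an undefined ratio and are flagged, never candidates.
#'
#' @param exonCov,intronCov coverage tables from [coverageByType()] over the
#'   same type set.
#' @param foldCutoff candidacy cutoff on the ratio (strict inequality).
#' @return a \linkS4class{ScreenResult} (screen = "enrichment"; analytic, no
#'   null simulations).
#' @export
enrichmentScreen <- function(exonCov, intronCov, foldCutoff = 2.0) {
  stopifnot(identical(exonCov$te_type, intronCov$te_type))
  ef <- exonCov$fraction; inf_ <- intronCov$fraction
  ratio <- ifelse(inf_ > 0, ef / inf_, ifelse(ef > 0, NA_real_, 0))
  flag <- ifelse(inf_ == 0 & ef > 0, "undefined_ratio", "")
  res <- DataFrame(te_type = exonCov$te_type,
                   exonic_fraction = ef, intronic_fraction = inf_,
                   observed = ratio,
                   candidate = !is.na(ratio) & ratio > foldCutoff,
                   flag = flag)
  new("ScreenResult", screen = "enrichment", results = res,
      nullValues = matrix(numeric(), nrow(res), 0,
                          dimnames = list(exonCov$te_type, NULL)),
      nSim = 0L, seed = NA_integer_)
}

#' Rigidly reposition gene structures in the genome
#'
#' Each gene (group of intervals sharing gene_id) is translated as a rigid
#' body — internal exon/intron structure, lengths and strand preserved — to
#' a uniform random start on a chromosome chosen with probability
#' proportional to its length, among chromosomes that can hold the gene
#' span. Shuffled genes may overlap each other.
#'
#' @param gr GRanges with gene_id metadata (exons or merged exons).
#' @param chromSizes named vector from [readChromSizes()].
#' @param seed optional RNG seed.
#' @return GRanges with identical per-gene structure at new positions.
#' @export
shuffleGeneStructures <- function(gr, chromSizes, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (length(gr) == 0L) return(gr)
  genes <- unique(gr$gene_id)
  geneIdx <- split(seq_along(gr), gr$gene_id)[genes]
  spanStart <- vapply(geneIdx, function(i) min(start(gr)[i]), numeric(1))
  spanLen <- vapply(geneIdx, function(i)
    max(end(gr)[i]) - min(start(gr)[i]) + 1, numeric(1))
  chromNames <- names(chromSizes)
  if (any(spanLen > max(chromSizes)))
    stop("capacity error: gene ",
         genes[which(spanLen > max(chromSizes))[1]],
         " is longer than every chromosome")
  nG <- length(genes)
  sizes <- as.numeric(chromSizes)
  ci <- sample.int(length(sizes), nG, replace = TRUE,
                   prob = sizes / sum(sizes))
  # redraw genes that landed on a chromosome too short to hold them
  while (any(sizes[ci] < spanLen)) {
    bad <- which(sizes[ci] < spanLen)
    ci[bad] <- sample.int(length(sizes), length(bad), replace = TRUE,
                          prob = sizes / sum(sizes))
  }
  newChrom <- chromNames[ci]
  newStart <- floor(stats::runif(nG) * (sizes[ci] - spanLen + 1)) + 1
  off <- stats::setNames(newStart - spanStart, genes)
  chrMap <- stats::setNames(newChrom, genes)
  gid <- gr$gene_id
  out <- GRanges(chrMap[gid], IRanges(start(gr) + off[gid],
                                      end(gr) + off[gid]),
                 strand = strand(gr))
  mcols(out) <- mcols(gr)
  out
}

#' Positionally shuffle intervals, preserving lengths
#'
#' Each interval is moved independently to a uniform random position on a
#' chromosome chosen proportional to its length (among chromosomes that can
#' hold it); shuffled intervals may overlap one another.
#'
#' @param gr GRanges. @param chromSizes named sizes. @param seed RNG seed.
#' @return GRanges of equal widths at random positions.
#' @export
shuffleIntervals <- function(gr, chromSizes, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(gr)
  if (n == 0L) return(gr)
  w <- width(gr)
  sizes <- as.numeric(chromSizes)
  probs <- sizes / sum(sizes)
  if (any(w > max(sizes)))
    stop("capacity error: an interval is longer than every chromosome")
  chromIdx <- sample.int(length(sizes), n, replace = TRUE, prob = probs)
  room <- sizes[chromIdx] - w + 1
  # redraw elements that landed on a chromosome too short to hold them
  while (any(room < 1)) {
    bad <- which(room < 1)
    chromIdx[bad] <- sample.int(length(sizes), length(bad), replace = TRUE,
                                prob = probs)
    room <- sizes[chromIdx] - w + 1
  }
  newStart <- floor(stats::runif(n) * room) + 1
  GRanges(names(chromSizes)[chromIdx], IRanges(newStart, width = w),
          strand = strand(gr))
}


# ---- fast shuffle-null internals ------------------------------------------
# The shuffle nulls re-randomize thousands of intervals per simulation; to
# avoid per-simulation S4 container construction they operate on plain
# vectors in a single global coordinate axis (chromosomes laid end to end
# with a spacer wider than any interval).

.globalOffsets <- function(chromSizes, spacer = 10000) {
  sizes <- as.numeric(chromSizes)
  off <- cumsum(c(0, utils::head(sizes + spacer, -1)))
  stats::setNames(off, names(chromSizes))
}

.sampleChromFit <- function(n, sizes, probs, need) {
  ci <- sample.int(length(sizes), n, replace = TRUE, prob = probs)
  while (any(sizes[ci] < need)) {
    bad <- which(sizes[ci] < need)
    ci[bad] <- sample.int(length(sizes), length(bad), replace = TRUE,
                          prob = probs)
  }
  ci
}

# Per-simulation sense/antisense ratios for repositioned gene structures.
.strandNullRatios <- function(prep, types, statistic) {
  newStart <- floor(stats::runif(prep$nG) *
                    (prep$sizes[prep$ci] - prep$spanLen + 1)) + 1
  base <- prep$off[prep$ci] + newStart
  esG <- base[prep$ivGene] + prep$esRel
  eeG <- base[prep$ivGene] + prep$eeRel
  ov <- findOverlaps(prep$teIR, IRanges(esG, eeG))
  ti <- queryHits(ov); ei <- subjectHits(ov)
  gidI <- prep$ivGene[ei]
  ts <- prep$teS[ti]; te <- prep$teE[ti]
  es <- esG[ei]; ee <- eeG[ei]
  firstG <- base[gidI] + prep$firstRel[gidI]
  lastG <- base[gidI] + prep$lastRel[gidI]
  crossesLeft <- ts < es
  crossesRight <- te > ee
  coversFirst <- ts <= firstG & te >= firstG & es <= firstG & ee >= firstG
  coversLast <- ts <= lastG & te >= lastG & es <= lastG & ee >= lastG
  noSJ <- !coversFirst & !coversLast & (crossesLeft == crossesRight) &
    !prep$teUnstranded[ti]
  sense <- prep$teStrand[ti] == prep$gStrand[gidI]
  val <- if (statistic == "coverage")
    as.numeric(pmin(te, ee) - pmax(ts, es) + 1) else rep(1, length(ti))
  senseNt <- stats::setNames(numeric(length(types)), types)
  antiNt <- senseNt
  tt <- prep$teType[ti]
  kS <- noSJ & sense; kA <- noSJ & !sense
  if (any(kS)) {
    a <- rowsum(val[kS], tt[kS]); hit <- rownames(a) %in% types
    senseNt[rownames(a)[hit]] <- a[hit, 1]
  }
  if (any(kA)) {
    a <- rowsum(val[kA], tt[kA]); hit <- rownames(a) %in% types
    antiNt[rownames(a)[hit]] <- a[hit, 1]
  }
  ifelse(antiNt > 0, senseNt / antiNt, ifelse(senseNt > 0, Inf, NA_real_))
}

.strandNullPrep <- function(merged, tes, chromSizes) {
  off <- .globalOffsets(chromSizes)
  sizes <- as.numeric(chromSizes)
  gid <- merged$gene_id
  genes <- unique(gid)
  gIdx <- match(gid, genes)
  spanStart <- as.numeric(tapply(start(merged), gIdx, min))
  spanEnd <- as.numeric(tapply(end(merged), gIdx, max))
  gStrand <- as.character(strand(merged))[match(genes, gid)]
  firstNt <- ifelse(gStrand == "-", spanEnd, spanStart)
  lastNt <- ifelse(gStrand == "-", spanStart, spanEnd)
  teChrom <- as.character(seqnames(tes))
  teOff <- off[teChrom]
  list(nG = length(genes), sizes = sizes, off = unname(off),
       probs = sizes / sum(sizes),
       spanLen = spanEnd - spanStart + 1,
       ivGene = gIdx,
       esRel = start(merged) - spanStart[gIdx],
       eeRel = end(merged) - spanStart[gIdx],
       firstRel = firstNt - spanStart, lastRel = lastNt - spanStart,
       gStrand = gStrand,
       teS = unname(teOff) + start(tes), teE = unname(teOff) + end(tes),
       teIR = IRanges(unname(teOff) + start(tes),
                      unname(teOff) + end(tes)),
       teStrand = as.character(strand(tes)),
       teUnstranded = as.character(strand(tes)) == "*",
       teType = tes$te_type)
}

.strandRatios <- function(core, types, statistic) {
  keep <- core$category %in% c("inside", "encompassing") & !core$unstranded
  val <- if (statistic == "coverage") as.numeric(core$overlap_nt[keep])
         else rep(1, sum(keep))
  tt <- core$te_type[keep]; rel <- core$relative_strand[keep]
  sense <- stats::setNames(numeric(length(types)), types)
  anti <- sense
  if (length(val)) {
    s <- rowsum(val[rel == "sense"], tt[rel == "sense"])
    a <- rowsum(val[rel == "antisense"], tt[rel == "antisense"])
    sHit <- rownames(s) %in% types; aHit <- rownames(a) %in% types
    sense[rownames(s)[sHit]] <- s[sHit, 1]
    anti[rownames(a)[aHit]] <- a[aHit, 1]
  }
  list(sense = sense, anti = anti,
       ratio = ifelse(anti > 0, sense / anti,
                      ifelse(sense > 0, Inf, NA_real_)))
}

#' Strand-bias screen with a gene-shuffling empirical null
#'
#' Restricted to non-splice-junction (noSJ) exonic TE records (categories
#' inside and encompassing), computes per type the ratio of sense to
#' antisense nucleotide coverage relative to the host gene. The null
#' repositions entire gene structures uniformly in the genome
#' (\code{nSim} times), re-intersects against the full TE annotation and
#' recomputes the ratios. A type is a candidate when its observed ratio
#' exceeds all null values (p = 1/(1+nSim), direction greater). Types
#' significant in the antisense direction are flagged
#' (\code{antisense_significant}) but never become candidates.
#'
#' @param merged merged exon GRanges (with gene_id).
#' @param tes full TE annotation GRanges.
#' @param chromSizes named chromosome sizes.
#' @param nSim number of shuffles (default 1000).
#' @param seed RNG seed.
#' @param types type set to test; defaults to all types in \code{tes}.
#' @param statistic "coverage" (nucleotide, default) or "count" (instances).
#' @return a \linkS4class{ScreenResult} (screen = "strand_bias").
#' @export
strandBiasScreen <- function(merged, tes, chromSizes, nSim = 1000L,
                             seed = NULL,
                             types = sort(unique(tes$te_type)),
                             statistic = c("coverage", "count")) {
  statistic <- match.arg(statistic)
  stopifnot(nSim >= 1L)
  if (!is.null(seed)) set.seed(seed)
  obs <- .strandRatios(.classifyCore(merged, tes), types, statistic)
  prep <- .strandNullPrep(merged, tes, chromSizes)
  nullMat <- matrix(NA_real_, length(types), nSim,
                    dimnames = list(types, NULL))
  for (s in seq_len(nSim)) {
    prep$ci <- .sampleChromFit(prep$nG, prep$sizes, prep$probs,
                               prep$spanLen)
    nullMat[, s] <- .strandNullRatios(prep, types, statistic)
  }
  pG <- pL <- rankG <- rep(NA_real_, length(types))
  for (i in seq_along(types)) {
    if (is.na(obs$ratio[i])) next
    eg <- empiricalPvalue(obs$ratio[i], nullMat[i, ], "greater")
    el <- empiricalPvalue(obs$ratio[i], nullMat[i, ], "less")
    pG[i] <- eg$p; pL[i] <- el$p; rankG[i] <- eg$rank
  }
  floorP <- 1 / nSim
  res <- DataFrame(te_type = types,
                   sense_nt = as.numeric(obs$sense),
                   antisense_nt = as.numeric(obs$anti),
                   observed = obs$ratio, rank = rankG,
                   p_empirical = pG, direction = "greater",
                   p_less = pL,
                   antisense_significant = !is.na(pL) & pL <= floorP,
                   fdr_q = adjustFdr(pG),
                   candidate = !is.na(pG) & pG <= floorP)
  new("ScreenResult", screen = "strand_bias", results = res,
      nullValues = nullMat, nSim = as.integer(nSim),
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}

.typeCompartmentFragments <- function(merged, introns, tes, types) {
  exPool <- reduce(merged, ignore.strand = TRUE)
  inPool <- reduce(introns, ignore.strand = TRUE)
  tesUse <- tes[tes$te_type %in% types]
  red <- reduce(split(granges(tesUse), tesUse$te_type),
                ignore.strand = TRUE)
  ur <- unlist(red, use.names = TRUE)
  urType <- names(ur)
  names(ur) <- NULL
  clip <- function(pool, comp) {
    ov <- findOverlaps(ur, pool, ignore.strand = TRUE)
    if (length(ov) == 0L) return(NULL)
    fr <- pintersect(ur[queryHits(ov)], pool[subjectHits(ov)],
                     ignore.strand = TRUE)
    mcols(fr) <- NULL
    mcols(fr)$te_type <- urType[queryHits(ov)]
    mcols(fr)$comp <- comp
    fr
  }
  fe <- clip(exPool, "e"); fi <- clip(inPool, "i")
  if (is.null(fe) && is.null(fi)) {
    out <- GRanges()
    mcols(out)$te_type <- character()
    mcols(out)$comp <- character()
    return(out)
  }
  if (is.null(fe)) return(fi)
  if (is.null(fi)) return(fe)
  c(fe, fi)
}

.reicPrecompute <- function(frags, types) {
  key <- paste(frags$te_type, frags$comp, sep = "\r")
  tot <- rowsum(as.numeric(width(frags)), key)
  lookup <- function(x, t, comp) {
    v <- x[paste(t, comp, sep = "\r")]
    v[is.na(v)] <- 0
    unname(v)
  }
  list(key = key, tot = stats::setNames(tot[, 1], rownames(tot)),
       lookup = lookup)
}

.reicFromFragments <- function(frags, conserved, types,
                               pre = .reicPrecompute(frags, types)) {
  consNt <- numeric(0)
  consRed <- reduce(conserved, ignore.strand = TRUE)
  ov <- findOverlaps(frags, consRed, ignore.strand = TRUE)
  if (length(ov)) {
    w <- width(pintersect(frags[queryHits(ov)], consRed[subjectHits(ov)],
                          ignore.strand = TRUE))
    agg <- rowsum(as.numeric(w), pre$key[queryHits(ov)])
    consNt <- stats::setNames(agg[, 1], rownames(agg))
  }
  ce <- pre$lookup(consNt, types, "e")
  te <- pre$lookup(pre$tot, types, "e")
  ci <- pre$lookup(consNt, types, "i")
  ti <- pre$lookup(pre$tot, types, "i")
  list(ce = ce, ne = te - ce, ci = ci, ni = ti - ci,
       reic = computeReic(ce, te - ce, ci, ti - ci))
}


# Per-simulation REIC values for positionally shuffled conserved elements.
.consNullPrep <- function(frags, conserved, chromSizes, types, pre) {
  off <- .globalOffsets(chromSizes)
  sizes <- as.numeric(chromSizes)
  fOff <- off[as.character(seqnames(frags))]
  list(sizes = sizes, off = unname(off), probs = sizes / sum(sizes),
       w = as.numeric(width(conserved)), n = length(conserved),
       fragIR = IRanges(unname(fOff) + start(frags),
                        unname(fOff) + end(frags)),
       key = pre$key, tot = pre$tot, lookup = pre$lookup)
}

.consNullReic <- function(prep, types) {
  ci <- .sampleChromFit(prep$n, prep$sizes, prep$probs, prep$w)
  newStart <- floor(stats::runif(prep$n) *
                    (prep$sizes[ci] - prep$w + 1)) + 1
  gs <- prep$off[ci] + newStart
  consIR <- IRanges::reduce(IRanges(gs, gs + prep$w - 1))
  ov <- findOverlaps(prep$fragIR, consIR)
  consNt <- numeric(0)
  if (length(ov)) {
    q <- queryHits(ov); sj <- subjectHits(ov)
    w <- pmin(end(prep$fragIR)[q], end(consIR)[sj]) -
      pmax(start(prep$fragIR)[q], start(consIR)[sj]) + 1
    agg <- rowsum(as.numeric(w), prep$key[q])
    consNt <- stats::setNames(agg[, 1], rownames(agg))
  }
  ce <- prep$lookup(consNt, types, "e")
  te <- prep$lookup(prep$tot, types, "e")
  ci_ <- prep$lookup(consNt, types, "i")
  ti <- prep$lookup(prep$tot, types, "i")
  computeReic(ce, te - ce, ci_, ti - ci_)
}

#' Conservation screen: REIC with a conserved-element-shuffling null
#'
#' Per TE type, the observed REIC from per-nucleotide overlap of exonic and
#' intronic TE fragments by conserved elements, against a null in which the
#' conserved elements are positionally randomized \code{nSim} times (lengths
#' preserved). Conserved elements, not TEs, are shuffled: conserved elements
#' are themselves enriched in exons, so shuffling TEs would overestimate the
#' background exonic conservation. Both directions are reported; only
#' direction greater yields candidates, depleted types are flagged.
#'
#' @param merged merged exon GRanges; @param introns intron GRanges.
#' @param tes TE annotation GRanges.
#' @param conserved conserved-element GRanges (one evidence set).
#' @param chromSizes named chromosome sizes.
#' @param nSim shuffles (default 1000). @param seed RNG seed.
#' @param types type set to test.
#' @param shuffleTes if TRUE, shuffle TEs instead of conserved elements
#'   (comparison mode only; biased toward long TEs).
#' @return a \linkS4class{ScreenResult} (screen = "conservation").
#' @export
conservationScreen <- function(merged, introns, tes, conserved, chromSizes,
                               nSim = 1000L, seed = NULL,
                               types = screenEligibleTypes(tes, merged,
                                                           introns),
                               shuffleTes = FALSE) {
  stopifnot(nSim >= 1L)
  if (!is.null(seed)) set.seed(seed)
  frags <- .typeCompartmentFragments(merged, introns, tes, types)
  pre <- .reicPrecompute(frags, types)
  obs <- .reicFromFragments(frags, conserved, types, pre)
  nullMat <- matrix(NA_real_, length(types), nSim,
                    dimnames = list(types, NULL))
  prepN <- .consNullPrep(frags, conserved, chromSizes, types, pre)
  for (s in seq_len(nSim)) {
    if (shuffleTes) {
      shufTes <- shuffleIntervals(granges(tes), chromSizes)
      mcols(shufTes)$te_type <- tes$te_type
      fr <- .typeCompartmentFragments(merged, introns, shufTes, types)
      nullMat[, s] <- .reicFromFragments(fr, conserved, types)$reic
    } else {
      nullMat[, s] <- .consNullReic(prepN, types)
    }
  }
  pG <- pL <- rep(NA_real_, length(types))
  for (i in seq_along(types)) {
    if (is.na(obs$reic[i])) next
    pG[i] <- empiricalPvalue(obs$reic[i], nullMat[i, ], "greater")$p
    pL[i] <- empiricalPvalue(obs$reic[i], nullMat[i, ], "less")$p
  }
  floorP <- 1 / nSim
  res <- DataFrame(te_type = types,
                   ce = obs$ce, ne = obs$ne, ci = obs$ci, ni = obs$ni,
                   observed = obs$reic,
                   p_empirical = pG, direction = "greater", p_less = pL,
                   depleted = !is.na(pL) & pL <= floorP,
                   fdr_q = adjustFdr(pG),
                   candidate = !is.na(pG) & pG <= floorP,
                   flag = ifelse(is.na(obs$reic), "undefined_reic", ""))
  new("ScreenResult", screen = "conservation", results = res,
      nullValues = nullMat, nSim = as.integer(nSim),
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}

#' Element-level true-positive fraction for an evidence type
#'
#' Compares how often candidate-type TE instances overlap an evidence set in
#' exons versus introns: TP fraction = 1 - (intronic overlap frequency /
#' exonic overlap frequency), floored at 0.
#'
#' @param exonicTes GRanges of exonic instances of candidate types.
#' @param intronicTes GRanges of intronic instances of the same types.
#' @param evidence GRanges of the evidence elements.
#' @return list with exonic_freq, intronic_freq, tp_fraction (NA and a flag
#'   when the exonic frequency is zero).
#' @export
elementLevelFdr <- function(exonicTes, intronicTes, evidence) {
  fe <- if (length(exonicTes))
    mean(GenomicRanges::countOverlaps(exonicTes, evidence,
                                      ignore.strand = TRUE) > 0) else 0
  fi <- if (length(intronicTes))
    mean(GenomicRanges::countOverlaps(intronicTes, evidence,
                                      ignore.strand = TRUE) > 0) else 0
  if (fe == 0)
    return(list(exonic_freq = 0, intronic_freq = fi, tp_fraction = NA_real_,
                flag = "zero_exonic_frequency"))
  list(exonic_freq = fe, intronic_freq = fi,
       tp_fraction = max(0, 1 - fi / fe), flag = "")
}

#' Write a screen's per-type results as TSV
#'
#' Deterministic column order and row order (by te_type); list-columns are
#' comma-joined.
#'
#' @param x a \linkS4class{ScreenResult}. @param path output file.
#' @export
writeScreenTsv <- function(x, path) {
  df <- resultsTable(x)
  df <- df[order(df$te_type), , drop = FALSE]
  for (j in seq_along(df))
    if (is.list(df[[j]]))
      df[[j]] <- vapply(df[[j]], paste, character(1), collapse = ",")
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
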