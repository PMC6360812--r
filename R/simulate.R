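#' Build a TE type catalog for simulation
#'
#' @param nTypes number of repeat types.
#' @param nInstances instances per type.
#' @param consensusLength range (nt) to sample consensus lengths from.
#' @return data.frame with columns te_type, te_family, te_class,
#'   consensus_length, n_instances.
#' @export
makeTeCatalog <- function(nTypes = 30L, nInstances = 150L,
                          consensusLength = c(200L, 1500L)) {
  fams <- c("L1", "L2", "MIR", "Alu", "ERVL", "hAT-Charlie")
  cls <- c("LINE", "LINE", "SINE", "SINE", "LTR", "DNA")
  i <- seq_len(nTypes)
  data.frame(te_type = sprintf("TE%03d", i),
             te_family = fams[(i - 1L) %% length(fams) + 1L],
             te_class = cls[(i - 1L) %% length(cls) + 1L],
             consensus_length = as.integer(round(seq(consensusLength[1],
                                                     consensusLength[2],
                                                     length.out = nTypes))),
             n_instances = as.integer(nInstances),
             stringsAsFactors = FALSE)
}

#' Construct a SimulationConfig
#'
#' Defaults define the package's standard study conditions: a 2 x 1 Mb
#' genome densely covered by 300 multi-exon genes, a 30-type TE catalog
#' (150 instances per background type, 600 per planted type, ~40% of the
#' genome TE-covered as in the human genome), and planted effects of
#' fourfold exonic enrichment (TE001, TE002),
#' 90/10 sense-strand bias (TE003, TE004), exonic conservation 0.5 versus an
#' intronic baseline of 0.25 (TE005, TE006; REIC 2 in expectation), a
#' +0.5 log2 per-copy nuclear shift for TE001 and TE005, and a rare-allele
#' excess (0.6 vs 0.4) in the RIDL SNP class.
#'
#' @param seed master RNG seed.
#' @param ... any slot of \linkS4class{SimulationConfig} to override.
#' @return a validated \linkS4class{SimulationConfig}.
#' @export
simulationConfig <- function(seed = 1L, ...) {
  cat <- makeTeCatalog()
  # planted types are abundant (as the real exapted repeats are), so that
  # per-type screen statistics rest on tens of exonic instances
  cat$n_instances[cat$te_type %in% sprintf("TE%03d", 1:6)] <- 600L
  defaults <- list(
    seed = as.integer(seed),
    nChroms = 2L, chromLength = 1000000L,
    nGenes = 300L,
    exonsPerTranscript = c(2L, 5L), transcriptsPerGene = c(1L, 3L),
    exonLength = c(150L, 400L), intronLength = c(300L, 1500L),
    teCatalog = cat,
    enrichedTypes = c("TE001", "TE002"), enrichedFold = 4,
    strandBiasedTypes = c("TE003", "TE004"), senseFraction = 0.9,
    conservedTypes = c("TE005", "TE006"),
    exonicConsFraction = 0.5, intronicConsFraction = 0.25,
    localizationEffects = c(TE001 = 0.5, TE005 = 0.5),
    cellLines = paste0("cell", LETTERS[1:4]),
    rciSigma = 1, rpkmSigma = 0.25, dropoutRate = 0,
    dafRareRidl = 0.6, dafRareBackground = 0.4,
    consensusBias = 0)
  over <- list(...)
  bad <- setdiff(names(over), names(defaults))
  if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
  defaults[names(over)] <- over
  int <- c("seed", "nChroms", "chromLength", "nGenes", "exonsPerTranscript",
           "transcriptsPerGene", "exonLength", "intronLength")
  for (f in int) defaults[[f]] <- as.integer(defaults[[f]])
  do.call(new, c(list("SimulationConfig"), defaults))
}

#' Read a SimulationConfig from a YAML file
#'
#' Scalar fields and planted-effect lists use the slot names of
#' \linkS4class{SimulationConfig}; the TE catalog may be given inline as a
#' list of records under \code{teCatalog}.
#'
#' @param path YAML file.
#' @return a \linkS4class{SimulationConfig}.
#' @export
readSimulationConfigYaml <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$teCatalog) && !is.data.frame(y$teCatalog))
    y$teCatalog <- do.call(rbind, lapply(y$teCatalog, as.data.frame))
  if (!is.null(y$localizationEffects))
    y$localizationEffects <- unlist(y$localizationEffects)
  seed <- if (is.null(y$seed)) 1L else y$seed
  y$seed <- NULL
  do.call(simulationConfig, c(list(seed = seed), y))
}

# Place genes sequentially on the chromosomes; returns exon table plus the
# master (merged) exon chain and intron chain per gene.
.placeGenes <- function(cfg) {
  chromNames <- paste0("chr", seq_len(cfg@nChroms))
  exons <- list(); master <- list(); introns <- list()
  gi <- 0L
  for (ch in chromNames) {
    cursor <- sample(500:2500, 1L)
    while (gi < cfg@nGenes) {
      nE <- sample(cfg@exonsPerTranscript[1]:cfg@exonsPerTranscript[2], 1L)
      exLens <- sample(cfg@exonLength[1]:cfg@exonLength[2], nE,
                       replace = TRUE)
      inLens <- if (nE > 1L)
        sample(cfg@intronLength[1]:cfg@intronLength[2], nE - 1L,
               replace = TRUE) else integer()
      span <- sum(exLens) + sum(inLens)
      if (cursor + span > cfg@chromLength - 2000L) break
      gi <- gi + 1L
      gid <- sprintf("G%04d", gi)
      strand <- sample(c("+", "-"), 1L)
      exStart <- cursor + cumsum(c(0L, exLens[-nE] + inLens))
      exEnd <- exStart + exLens - 1L
      master[[gid]] <- data.frame(chrom = ch, start = exStart, end = exEnd,
                                  strand = strand, gene_id = gid)
      if (nE > 1L)
        introns[[gid]] <- data.frame(chrom = ch, start = exEnd[-nE] + 1L,
                                     end = exStart[-1L] - 1L,
                                     strand = strand, gene_id = gid)
      nT <- sample(cfg@transcriptsPerGene[1]:cfg@transcriptsPerGene[2], 1L)
      txs <- list(seq_len(nE))
      if (nT > 1L) for (t in 2:nT) {
        len <- sample(seq(min(cfg@exonsPerTranscript[1], nE), nE), 1L)
        a <- sample(seq_len(nE - len + 1L), 1L)
        txs[[t]] <- a:(a + len - 1L)
      }
      for (t in seq_along(txs)) {
        idx <- txs[[t]]
        exons[[length(exons) + 1L]] <- data.frame(
          chrom = ch, start = exStart[idx], end = exEnd[idx],
          strand = strand, gene_id = gid,
          transcript_id = sprintf("%s.T%d", gid, t))
      }
      cursor <- cursor + span + sample(500:2500, 1L)
    }
    if (gi >= cfg@nGenes) break
  }
  if (gi < cfg@nGenes)
    stop("capacity error: chromosomes too short for ", cfg@nGenes,
         " genes (placed ", gi, ")")
  list(exons = do.call(rbind, exons),
       master = do.call(rbind, master),
       introns = if (length(introns)) do.call(rbind, introns)
                 else data.frame())
}

.poolFromDf <- function(df) {
  if (nrow(df) == 0L)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      gene_id = character(), width = integer()))
  df$width <- df$end - df$start + 1L
  df
}

# Sample one interval index from a pool, probability proportional to width.
.sampleIntervals <- function(pool, n) {
  sample.int(nrow(pool), n, replace = TRUE,
             prob = pool$width / sum(pool$width))
}

.placeTes <- function(cfg, pools) {
  exPool <- .poolFromDf(pools$master)
  inPool <- .poolFromDf(pools$introns)
  geneLen <- c(ex = sum(exPool$width), intr = sum(inPool$width))
  # intergenic pool: complement of gene spans, per chromosome
  chromNames <- paste0("chr", seq_len(cfg@nChroms))
  spans <- data.table::as.data.table(pools$master)[
    , list(s = min(start), e = max(end)), by = c("gene_id", "chrom")]
  igRows <- list()
  for (ch in chromNames) {
    sp <- spans[spans$chrom == ch][order(s)]
    bounds <- c(1L, if (nrow(sp)) as.vector(rbind(sp$s - 1L, sp$e + 1L)),
                cfg@chromLength)
    m <- matrix(bounds, ncol = 2, byrow = TRUE)
    keep <- m[, 2] > m[, 1]
    if (any(keep))
      igRows[[ch]] <- data.frame(chrom = ch, start = m[keep, 1],
                                 end = m[keep, 2], strand = "*",
                                 gene_id = NA_character_)
  }
  igPool <- .poolFromDf(do.call(rbind, igRows))
  pools2 <- list(exon = exPool, intron = inPool, intergenic = igPool)
  flip <- c("+" = "-", "-" = "+")
  cat <- cfg@teCatalog
  rows <- list()
  for (k in seq_len(nrow(cat))) {
    tt <- cat$te_type[k]; consLen <- cat$consensus_length[k]
    n <- cat$n_instances[k]
    fold <- if (tt %in% cfg@enrichedTypes) cfg@enrichedFold else 1
    sf <- if (tt %in% cfg@strandBiasedTypes) cfg@senseFraction else 0.5
    w <- c(fold * geneLen["ex"], geneLen["intr"], sum(igPool$width))
    comp <- sample(c("exon", "intron", "intergenic"), n, replace = TRUE,
                   prob = w / sum(w))
    L <- pmin(sample(60:180, n, replace = TRUE), consLen)
    iv <- data.frame(chrom = character(n), start = integer(n),
                     width = integer(n), strand = character(n),
                     gene_id = character(n), stringsAsFactors = FALSE)
    for (cp in names(pools2)) {
      j <- which(comp == cp)
      if (!length(j)) next
      pool <- pools2[[cp]]
      pi_ <- .sampleIntervals(pool, length(j))
      iv$chrom[j] <- pool$chrom[pi_]; iv$start[j] <- pool$start[pi_]
      iv$width[j] <- pool$width[pi_]
      iv$strand[j] <- pool$strand[pi_]
      iv$gene_id[j] <- if (cp == "intergenic") NA_character_
                       else pool$gene_id[pi_]
    }
    len <- pmin(L, iv$width)
    gStart <- iv$start + floor(stats::runif(n) * (iv$width - len + 1))
    genic <- comp != "intergenic"
    sense <- stats::runif(n) < sf
    strand <- ifelse(genic, ifelse(sense, iv$strand, flip[iv$strand]),
                     sample(c("+", "-"), n, replace = TRUE))
    # consensus fragment, optionally 3'-biased
    maxS <- consLen - len + 1L
    u <- stats::runif(n)
    b <- cfg@consensusBias
    if (b > 0) u <- u^(1 / (1 + 2 * b))
    if (b < 0) u <- 1 - (1 - u)^(1 / (1 - 2 * b))
    cs <- pmin(floor(u * maxS) + 1L, maxS)
    rows[[k]] <- data.frame(
      chrom = iv$chrom, start = as.integer(gStart),
      end = as.integer(gStart + len - 1L),
      strand = strand, te_type = tt, te_class = cat$te_class[k],
      te_family = cat$te_family[k], consensus_start = as.integer(cs),
      consensus_end = as.integer(cs + len - 1L),
      consensus_length = consLen,
      compartment = comp,
      host_gene = ifelse(is.na(iv$gene_id), "", iv$gene_id),
      stringsAsFactors = FALSE)
  }
  te <- do.call(rbind, rows)
  rownames(te) <- NULL
  te$instance_id <- seq_len(nrow(te))
  te
}

.makeConservedSets <- function(cfg, te, setNames = c(phast = 12L, ecs = 15L),
                               nBackground = 300L) {
  # every TE instance is tiled with short windows; each window becomes a
  # conserved element independently, with probability equal to the target
  # conserved fraction of its compartment. The planted exonic/intronic
  # conserved fractions therefore hold exactly in expectation, and the
  # element-level granularity matches what a positional shuffle resamples.
  out <- list()
  for (sn in names(setNames)) {
    wlen <- setNames[[sn]]
    planted <- te$te_type %in% cfg@conservedTypes
    p <- ifelse(planted & te$compartment == "exon", cfg@exonicConsFraction,
                cfg@intronicConsFraction)
    L <- te$end - te$start + 1L
    nW <- L %/% wlen
    idx <- rep(seq_len(nrow(te)), nW)
    off <- unlist(lapply(nW, function(k) seq_len(k) - 1L)) * wlen
    keep <- stats::runif(length(idx)) < p[idx]
    idx <- idx[keep]; off <- off[keep]
    rows <- data.frame(chrom = te$chrom[idx], start = te$start[idx] + off,
                       end = te$start[idx] + off + wlen - 1L)
    # background elements independent of TEs
    bgLen <- sample(wlen:(3L * wlen), nBackground, replace = TRUE)
    bgChrom <- sample(paste0("chr", seq_len(cfg@nChroms)), nBackground,
                      replace = TRUE)
    bgStart <- floor(stats::runif(nBackground) *
                     (cfg@chromLength - bgLen)) + 1L
    df <- rbind(rows, data.frame(chrom = bgChrom, start = bgStart,
                                 end = bgStart + bgLen - 1L))
    df$start <- as.integer(df$start); df$end <- as.integer(df$end)
    out[[sn]] <- df[order(df$chrom, df$start, df$end), ]
  }
  out
}

# Truth RIDL instances: exonic instances of planted types passing the
# per-evidence instance filter (sense-only for strand types; conserved-set
# overlap for conserved types).
.truthRidls <- function(cfg, te, consSets, master) {
  ex <- te[te$compartment == "exon", , drop = FALSE]
  if (nrow(ex) == 0L) return(ex[0, ])
  hostStrand <- stats::setNames(master$strand, master$gene_id)[
    ex$host_gene]
  rows <- list()
  enr <- ex[ex$te_type %in% cfg@enrichedTypes, , drop = FALSE]
  if (nrow(enr)) { enr$evidence <- "enrichment"; rows$enr <- enr }
  sb <- ex[ex$te_type %in% cfg@strandBiasedTypes &
           ex$strand == hostStrand, , drop = FALSE]
  if (nrow(sb)) { sb$evidence <- "strand_bias"; rows$sb <- sb }
  cons <- ex[ex$te_type %in% cfg@conservedTypes, , drop = FALSE]
  if (nrow(cons)) {
    cgr <- GRanges(consSets[[1]]$chrom,
                   IRanges(consSets[[1]]$start, consSets[[1]]$end))
    tgr <- GRanges(cons$chrom, IRanges(cons$start, cons$end))
    keep <- GenomicRanges::countOverlaps(tgr, cgr) > 0
    cons <- cons[keep, , drop = FALSE]
    if (nrow(cons)) { cons$evidence <- "conservation"; rows$cons <- cons }
  }
  if (length(rows) == 0L) {
    ex0 <- ex[0, , drop = FALSE]
    ex0$evidence <- character(0)
    return(ex0)
  }
  do.call(rbind, rows)
}

.sampleSnpPositions <- function(regions, n) {
  # regions: data.frame chrom/start/end; sample n positions uniformly
  if (nrow(regions) == 0L || n == 0L)
    return(data.frame(chrom = character(), pos = integer()))
  w <- regions$end - regions$start + 1L
  idx <- sample.int(nrow(regions), n, replace = TRUE, prob = w / sum(w))
  off <- vapply(idx, function(i) sample.int(w[i], 1L), integer(1))
  data.frame(chrom = regions$chrom[idx],
             pos = regions$start[idx] + off - 1L)
}

#' Generate a complete synthetic annotation bundle
#'
#' Writes a chromosome-size table, a GENCODE-style lncRNA GTF, a
#' RepeatMasker-style TE BED, two conserved-element BED sets, a SNP table
#' with a planted rare-allele excess in the RIDL class, and functional gene
#' lists, together with truth tables of all planted effects. Byte-identical
#' for identical configs (all randomness flows from \code{config@seed}).
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param outDir output directory (created if needed).
#' @param nSnpsPerClass SNPs sampled per region class.
#' @return a \linkS4class{SyntheticBundle}.
#' @export
generateAnnotationBundle <- function(config, outDir,
                                     nSnpsPerClass = 400L) {
  validObject(config)
  set.seed(config@seed)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  chromSizes <- stats::setNames(rep(config@chromLength, config@nChroms),
                                paste0("chr", seq_len(config@nChroms)))
  genes <- .placeGenes(config)
  te <- .placeTes(config, genes)
  consSets <- .makeConservedSets(config, te)
  truthRidl <- .truthRidls(config, te, consSets, genes$master)

  files <- c(chrom_sizes = file.path(outDir, "genome.chrom.sizes"),
             gtf = file.path(outDir, "genes.gtf"),
             te_bed = file.path(outDir, "te.bed"),
             cons_phast = file.path(outDir, "cons_phast.bed"),
             cons_ecs = file.path(outDir, "cons_ecs.bed"),
             snps = file.path(outDir, "snps.tsv"),
             functional_db = file.path(outDir, "functional_db.txt"),
             disease = file.path(outDir, "disease.txt"),
             trait_snp_genes = file.path(outDir, "trait_snp_genes.txt"))
  writeLines(paste(names(chromSizes), chromSizes, sep = "\t"),
             files["chrom_sizes"])
  exGr <- GRanges(genes$exons$chrom,
                  IRanges(genes$exons$start, genes$exons$end),
                  strand = genes$exons$strand,
                  gene_id = genes$exons$gene_id,
                  transcript_id = genes$exons$transcript_id,
                  biotype = "lncRNA")
  writeGtf(exGr, files["gtf"])
  teOrd <- te[order(te$chrom, te$start, te$end), ]
  writeLines(sprintf("%s\t%d\t%d\t%s\t0\t%s\t%s\t%s\t%d\t%d\t%d",
                     teOrd$chrom, teOrd$start - 1L, teOrd$end,
                     teOrd$te_type, teOrd$strand, teOrd$te_class,
                     teOrd$te_family, teOrd$consensus_start,
                     teOrd$consensus_end, teOrd$consensus_length),
             files["te_bed"])
  for (sn in names(consSets))
    writeLines(sprintf("%s\t%d\t%d\t%s\t0\t.", consSets[[sn]]$chrom,
                       consSets[[sn]]$start - 1L, consSets[[sn]]$end,
                       paste0(sn, "_el", seq_len(nrow(consSets[[sn]])))),
               files[paste0("cons_", sn)])

  # SNP classes from the planted annotation
  ridlReg <- unique(truthRidl[, c("chrom", "start", "end")])
  exTe <- te[te$compartment == "exon", ]
  exTeNon <- exTe[!exTe$instance_id %in% truthRidl$instance_id,
                  c("chrom", "start", "end")]
  inTe <- te[te$compartment == "intron", c("chrom", "start", "end")]
  igTe <- te[te$compartment == "intergenic", ]
  flank <- data.frame(chrom = igTe$chrom,
                      start = pmax(1L, igTe$start - 200L),
                      end = igTe$start - 1L)
  flank <- flank[flank$end >= flank$start, ]
  # exonic non-TE space: merged exons minus TEs
  exPoolGr <- reduce(GRanges(genes$master$chrom,
                             IRanges(genes$master$start, genes$master$end)))
  teGrAll <- GRanges(te$chrom, IRanges(te$start, te$end))
  exNonTe <- GenomicRanges::setdiff(exPoolGr, teGrAll, ignore.strand = TRUE)
  exNonTeDf <- data.frame(chrom = as.character(seqnames(exNonTe)),
                          start = start(exNonTe), end = end(exNonTe))
  classes <- list(RIDL = ridlReg, exonic_TE_nonRIDL = exTeNon,
                  intronic_TE = inTe, exonic_nonRIDL = exNonTeDf,
                  ancestral_repeat_flank = flank)
  snpRows <- list()
  for (cl in names(classes)) {
    pos <- .sampleSnpPositions(classes[[cl]], nSnpsPerClass)
    if (nrow(pos) == 0L) next
    pRare <- if (cl == "RIDL") config@dafRareRidl
             else config@dafRareBackground
    rare <- stats::runif(nrow(pos)) < pRare
    daf <- ifelse(rare, stats::runif(nrow(pos), 0.001, 0.0999),
                  stats::runif(nrow(pos), 0.1, 1))
    snpRows[[cl]] <- data.frame(chrom = pos$chrom, pos = pos$pos,
                                daf = round(daf, 4), region_class = cl)
  }
  snps <- do.call(rbind, snpRows)
  utils::write.table(snps, files["snps"], sep = "\t", quote = FALSE,
                     row.names = FALSE)

  # functional gene lists, enriched among RIDL host genes
  allGenes <- unique(genes$master$gene_id)
  ridlGenes <- unique(truthRidl$host_gene)
  memb <- function(pRidl, pOther) {
    inR <- allGenes %in% ridlGenes
    keep <- stats::runif(length(allGenes)) < ifelse(inR, pRidl, pOther)
    sort(allGenes[keep])
  }
  writeLines(memb(0.30, 0.15), files["functional_db"])
  writeLines(memb(0.20, 0.10), files["disease"])
  writeLines(memb(0.15, 0.08), files["trait_snp_genes"])

  truth <- list(
    planted_types = data.frame(
      te_type = c(config@enrichedTypes, config@strandBiasedTypes,
                  config@conservedTypes),
      effect = c(rep("enrichment", length(config@enrichedTypes)),
                 rep("strand_bias", length(config@strandBiasedTypes)),
                 rep("conservation", length(config@conservedTypes))),
      stringsAsFactors = FALSE),
    te_instances = te,
    ridl_instances = truthRidl,
    ridl_genes = data.frame(gene_id = sort(ridlGenes)))
  new("SyntheticBundle", dir = outDir, files = files, truth = truth,
      config = config)
}

#' Generate per-fraction expression tables with planted localization shifts
#'
#' For every transcript and cell line, a baseline RCI is drawn from
#' N(0, rciSigma) and shifted by sum(copies x delta) over the planted
#' localization types (copies = exonic TE instances of the type overlapping
#' the transcript's exons). Whole-cell RPKM is lognormal; nuclear and
#' cytoplasmic RPKM are back-computed so that log2(N/C) equals the intended
#' RCI exactly before per-fraction lognormal noise.
#'
#' @param bundle a \linkS4class{SyntheticBundle}.
#' @param config the same \linkS4class{SimulationConfig}.
#' @return the bundle, with an \code{expression} file and
#'   \code{localization_truth} truth table added.
#' @export
generateLocalizationData <- function(bundle, config) {
  if (!all(names(config@localizationEffects) %in%
           config@teCatalog$te_type))
    stop("config error: unknown te_type in localizationEffects")
  set.seed(config@seed + 104729L)  # independent stream from the same seed
  exons <- readGeneModels(bundleFile(bundle, "gtf"))
  tes <- readTeBed(bundleFile(bundle, "te_bed"))
  txIds <- sort(unique(exons$transcript_id))
  txGene <- stats::setNames(exons$gene_id[!duplicated(exons$transcript_id)],
                            exons$transcript_id[
                              !duplicated(exons$transcript_id)])
  # copies per transcript of each localization-effect type
  shift <- stats::setNames(numeric(length(txIds)), txIds)
  effTypes <- names(config@localizationEffects)
  sel <- tes[tes$te_type %in% effTypes]
  copies <- data.frame(transcript_id = character(), te_type = character(),
                       copies = integer(), delta = numeric())
  if (length(sel)) {
    ov <- findOverlaps(sel, exons, ignore.strand = TRUE)
    if (length(ov)) {
      dt <- unique(data.table::data.table(
        inst = sel$instance_id[queryHits(ov)],
        te_type = sel$te_type[queryHits(ov)],
        transcript_id = exons$transcript_id[subjectHits(ov)]))
      cnt <- dt[, list(copies = .N), by = c("transcript_id", "te_type")]
      cnt$delta <- unname(config@localizationEffects[cnt$te_type])
      copies <- as.data.frame(cnt)
      perTx <- rowsum(copies$copies * copies$delta, copies$transcript_id)
      shift[rownames(perTx)] <- perTx[, 1]
    }
  }
  rows <- list(); truthRows <- list()
  for (cl in config@cellLines) {
    base <- stats::rnorm(length(txIds), 0, config@rciSigma)
    rci <- base + shift
    W <- 2^stats::rnorm(length(txIds), log2(10), 1)
    nN <- 2^stats::rnorm(length(txIds), 0, config@rpkmSigma)
    nC <- 2^stats::rnorm(length(txIds), 0, config@rpkmSigma)
    nuc <- W * 2^(rci / 2) * nN
    cyt <- W * 2^(-rci / 2) * nC
    if (config@dropoutRate > 0) {
      nuc[stats::runif(length(nuc)) < config@dropoutRate] <- 0
      cyt[stats::runif(length(cyt)) < config@dropoutRate] <- 0
    }
    rows[[cl]] <- data.frame(
      transcript_id = rep(txIds, 3L),
      gene_id = rep(unname(txGene[txIds]), 3L),
      cell_line = cl,
      fraction = rep(c("nuclear", "cytoplasmic", "whole_cell"),
                     each = length(txIds)),
      rpkm = round(c(nuc, cyt, W), 6))
    truthRows[[cl]] <- data.frame(transcript_id = txIds, cell_line = cl,
                                  rci_true = rci,
                                  ridl_shift = unname(shift))
  }
  expr <- do.call(rbind, rows)
  path <- file.path(bundle@dir, "expression.tsv")
  utils::write.table(expr, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  bundle@files <- c(bundle@files, expression = path)
  bundle@truth$localization_truth <- do.call(rbind, truthRows)
  bundle@truth$localization_copies <- copies
  bundle
}

#' Generate a full synthetic bundle (annotation + expression)
#' @inheritParams generateAnnotationBundle
#' @return a \linkS4class{SyntheticBundle} with all files written.
#' @export
simulateBundle <- function(config, outDir) {
  b <- generateAnnotationBundle(config, outDir)
  generateLocalizationData(b, config)
}
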