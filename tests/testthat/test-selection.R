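test_that("empirical p-values follow rank/(1+n_sim) with a floor", {
  set.seed(1)
  nulls <- runif(1000)
  r <- empiricalPvalue(2, nulls, "greater")
  expect_equal(r$p, 0.001)       # exceeds all 1000 nulls -> floor
  expect_equal(r$rank, 1L)

  # exceeded by 49 of 999 nulls -> rank 50, p = 0.05
  nulls2 <- c(seq(0.5, 0.99, length.out = 49), runif(950, 0, 0.4))
  r2 <- empiricalPvalue(0.45, nulls2, "greater")
  expect_equal(r2$rank, 50L)
  expect_equal(r2$p, 0.05)

  # below all nulls, direction greater -> p = 1
  r3 <- empiricalPvalue(-1, nulls, "greater")
  expect_equal(r3$p, 1)

  expect_error(empiricalPvalue(1, numeric()), "empty null")
})

test_that("empirical p-values are super-uniform under the null", {
  set.seed(20)
  nRep <- 400L
  p <- vapply(seq_len(nRep), function(i) {
    nulls <- rnorm(99)
    empiricalPvalue(rnorm(1), nulls, "greater")$p
  }, numeric(1))
  for (alpha in c(0.01, 0.05, 0.1)) {
    slack <- 3 * sqrt(alpha * (1 - alpha) / nRep)
    expect_lte(mean(p <= alpha), alpha + slack)
  }
})

test_that("BH adjustment matches hand-computed q-values", {
  expect_equal(adjustFdr(c(0.001, 0.002, 0.003)), rep(0.003, 3))
  expect_equal(adjustFdr(0.04), 0.04)
  expect_equal(adjustFdr(c(0.02, 0.01)), c(0.02, 0.02))
  expect_error(adjustFdr(c(0.5, 1.2)), "0, 1")
})

test_that("REIC evaluates its defining ratio of conserved fractions", {
  expect_equal(computeReic(50, 50, 25, 75), 2.0)
  expect_equal(computeReic(30, 70, 15, 35), 1.0)  # equal fractions
  expect_equal(computeReic(0, 100, 10, 90), 0.0)
  expect_true(is.na(computeReic(50, 50, 0, 100)))  # Ci = 0 undefined
  expect_true(is.na(computeReic(0, 0, 10, 90)))
})

test_that("REIC from interval overlap matches a per-nucleotide oracle", {
  set.seed(3)
  ex <- GRanges("chr1", IRanges(c(101, 501), c(300, 800)), strand = "+",
                gene_id = "G", transcript_id = "G.T1")
  merged <- mergeExons(ex)
  introns <- deriveIntrons(ex)
  st <- c(sample(120:250, 6), sample(320:750, 8))
  tes <- makeTeGr(st, st + sample(20:40, 14, replace = TRUE))
  cons <- GRanges("chr1", IRanges(sample(100:800, 25),
                                  width = sample(5:15, 25, replace = TRUE)))
  scr <- conservationScreen(merged, introns, tes, cons,
                            c(chr1 = 10000L), nSim = 3, seed = 5,
                            types = "T1")
  res <- resultsTable(scr)
  # oracle: count conserved/unconserved TE nucleotides per compartment
  pos <- function(gr) unique(unlist(mapply(seq, start(gr), end(gr),
                                           SIMPLIFY = FALSE)))
  teP <- pos(GenomicRanges::reduce(tes)); consP <- pos(cons)
  exP <- intersect(teP, pos(merged)); inP <- intersect(teP, pos(introns))
  ce <- sum(exP %in% consP); ci <- sum(inP %in% consP)
  expect_equal(res$ce, ce)
  expect_equal(res$ci, ci)
  expect_equal(res$observed,
               (ce / length(exP)) / (ci / length(inP)))
})

test_that("enrichment screen applies the strict twofold cutoff", {
  mk <- function(fr) data.frame(te_type = c("A", "B", "C", "D"),
                                covered_nt = fr * 100, total_nt = 100,
                                fraction = fr)
  scr <- enrichmentScreen(mk(c(0.04, 0.02, 0, 0.03)),
                          mk(c(0.01, 0.01, 0.02, 0)))
  res <- resultsTable(scr)
  expect_equal(res$observed[res$te_type == "A"], 4.0)
  expect_true(res$candidate[res$te_type == "A"])
  # ratio exactly 2 is NOT a candidate (strictly greater than twofold)
  expect_equal(res$observed[res$te_type == "B"], 2.0)
  expect_false(res$candidate[res$te_type == "B"])
  # zero exonic coverage -> ratio 0
  expect_equal(res$observed[res$te_type == "C"], 0)
  expect_false(res$candidate[res$te_type == "C"])
  # zero intronic coverage -> undefined, flagged, not a candidate
  expect_true(is.na(res$observed[res$te_type == "D"]))
  expect_equal(res$flag[res$te_type == "D"], "undefined_ratio")
  expect_false(res$candidate[res$te_type == "D"])
})

test_that("gene shuffling is rigid, seeded and in bounds", {
  merged <- mergeExons(makeExonFixture())
  cs <- c(chr1 = 100000L, chr2 = 50000L)
  s1 <- shuffleGeneStructures(merged, cs, seed = 9)
  s2 <- shuffleGeneStructures(merged, cs, seed = 9)
  expect_identical(start(s1), start(s2))
  expect_identical(as.character(seqnames(s1)), as.character(seqnames(s2)))
  # per-gene interval count, widths and gaps preserved
  for (g in unique(merged$gene_id)) {
    m0 <- merged[merged$gene_id == g]; m1 <- s1[s1$gene_id == g]
    expect_equal(width(m1), width(m0))
    expect_equal(diff(start(m1)), diff(start(m0)))
    expect_equal(as.character(strand(m1)), as.character(strand(m0)))
    expect_equal(length(unique(as.character(seqnames(m1)))), 1L)
  }
  expect_true(all(start(s1) >= 1))
  expect_true(all(end(s1) <= cs[as.character(seqnames(s1))]))
  expect_error(shuffleGeneStructures(merged, c(chr1 = 50L)),
               "capacity error")
})

test_that("interval shuffling preserves element counts and exact lengths", {
  set.seed(2)
  gr <- GRanges("chr1", IRanges(sample(1:900, 40),
                                width = sample(5:50, 40, replace = TRUE)))
  cs <- c(chr1 = 1000L, chr2 = 3000L)
  sh <- shuffleIntervals(gr, cs, seed = 4)
  expect_equal(length(sh), length(gr))
  expect_equal(sort(width(sh)), sort(width(gr)))
  expect_true(all(start(sh) >= 1))
  expect_true(all(end(sh) <= cs[as.character(seqnames(sh))]))
  expect_identical(start(shuffleIntervals(gr, cs, seed = 4)), start(sh))
})

test_that("fast strand-bias null equals the reference shuffle-classify path", {
  set.seed(31)
  ex <- generateAnnotationBundle(
    simulationConfig(seed = 17, nGenes = 40L,
                     teCatalog = makeTeCatalog(6, 40L)),
    file.path(tempdir(), "fastcheck"))
  exons <- readGeneModels(bundleFile(ex, "gtf"))
  tes <- readTeBed(bundleFile(ex, "te_bed"))
  merged <- mergeExons(exons)
  cs <- readChromSizes(bundleFile(ex, "chrom_sizes"))
  types <- sort(unique(tes$te_type))
  # reference: explicit gene shuffle + full classification
  set.seed(77)
  shuf <- shuffleGeneStructures(merged, cs)
  ref <- ridlscan:::.strandRatios(ridlscan:::.classifyCore(shuf, tes),
                                  types, "coverage")$ratio
  # fast path consumes the RNG identically
  set.seed(77)
  prep <- ridlscan:::.strandNullPrep(merged, tes, cs)
  prep$ci <- ridlscan:::.sampleChromFit(prep$nG, prep$sizes, prep$probs,
                                        prep$spanLen)
  fast <- ridlscan:::.strandNullRatios(prep, types, "coverage")
  expect_equal(unname(fast), unname(ref))
})

test_that("strand-bias screen computes ratios and flags planted bias", {
  # fixture: one gene, 4 sense noSJ TEs of 75 nt, 1 antisense of 100 nt
  ex <- GRanges("chr1", IRanges(1001, 2000), strand = "+", gene_id = "G",
                transcript_id = "G.T1")
  merged <- mergeExons(ex)
  tes <- c(makeTeGr(c(1101, 1201, 1301, 1401), c(1175, 1275, 1375, 1475),
                    strand = "+", type = "S"),
           makeTeGr(1601, 1700, strand = "-", type = "S"))
  tes$instance_id <- 1:5
  scr <- strandBiasScreen(merged, tes, c(chr1 = 100000L), nSim = 99,
                          seed = 12, types = "S")
  res <- resultsTable(scr)
  expect_equal(res$sense_nt, 300)
  expect_equal(res$antisense_nt, 100)
  expect_equal(res$observed, 3.0)
  expect_equal(res$direction, "greater")
  # p respects the floor contract
  expect_gte(res$p_empirical, 1 / 100)
})

test_that("strand screen null calibration flags almost nothing", {
  # no planted strand bias: strands assigned at random by the generator
  cfg <- simulationConfig(seed = 23, nGenes = 150L,
                          teCatalog = makeTeCatalog(40, 60L),
                          enrichedTypes = character(),
                          strandBiasedTypes = character(),
                          conservedTypes = character(),
                          localizationEffects = setNames(numeric(), character()))
  b <- generateAnnotationBundle(cfg, file.path(tempdir(), "nullstrand"))
  exons <- readGeneModels(bundleFile(b, "gtf"))
  tes <- readTeBed(bundleFile(b, "te_bed"))
  merged <- mergeExons(exons)
  cs <- readChromSizes(bundleFile(b, "chrom_sizes"))
  scr <- strandBiasScreen(merged, tes, cs, nSim = 200, seed = 5)
  expect_lte(length(candidateTypes(scr)), 2L)
})

test_that("planted screen effects are recovered across replicate bundles", {
  # reduced catalog (planted types + 6 background types) so that 20
  # replicate bundles with shuffle nulls stay fast; planted effect sizes
  # are the package defaults
  nRep <- 20L
  missedAny <- 0L
  for (i in seq_len(nRep)) {
    cat12 <- makeTeCatalog(12, 150L)
    cat12$n_instances[1:6] <- 600L
    cfg <- simulationConfig(seed = 1000L + i, teCatalog = cat12)
    b <- generateAnnotationBundle(cfg, file.path(tempdir(),
                                                 paste0("rep", i)))
    exons <- readGeneModels(bundleFile(b, "gtf"))
    tes <- readTeBed(bundleFile(b, "te_bed"))
    merged <- mergeExons(exons)
    introns <- deriveIntrons(exons, merged)
    cs <- readChromSizes(bundleFile(b, "chrom_sizes"))
    types <- screenEligibleTypes(tes, merged, introns)
    enr <- enrichmentScreen(coverageByType(merged, tes, types),
                            coverageByType(introns, tes, types))
    sb <- strandBiasScreen(merged, tes, cs, nSim = 100, seed = i,
                           types = types)
    cons <- conservationScreen(merged, introns, tes,
                               readBed(bundleFile(b, "cons_phast")),
                               cs, nSim = 100, seed = 100 + i,
                               types = types)
    ok <- all(c("TE001", "TE002") %in% candidateTypes(enr)) &&
      all(c("TE003", "TE004") %in% candidateTypes(sb)) &&
      all(c("TE005", "TE006") %in% candidateTypes(cons))
    if (!ok) missedAny <- missedAny + 1L
  }
  expect_lte(missedAny, 2L)  # zero planted types missed in >= 18/20
})

test_that("element-level true-positive fraction follows its definition", {
  ex <- makeTeGr(c(1, 101, 201, 301), c(50, 150, 250, 350))
  intr <- makeTeGr(c(1001, 1101, 1201, 1301, 1401),
                   c(1050, 1150, 1250, 1350, 1450))
  ev <- GRanges("chr1", IRanges(c(10, 110, 1010), width = 5))
  r <- elementLevelFdr(ex, intr, ev)
  expect_equal(r$exonic_freq, 0.5)
  expect_equal(r$intronic_freq, 0.2)
  expect_equal(r$tp_fraction, 1 - 0.2 / 0.5)
  # equal frequencies -> 0
  r2 <- elementLevelFdr(ex[1:2], intr[1:2],
                        GRanges("chr1", IRanges(c(10, 1010), width = 5)))
  expect_equal(r2$tp_fraction, 0)
  # zero intronic frequency -> upper bound 1
  r3 <- elementLevelFdr(ex, intr, GRanges("chr1", IRanges(10, 14)))
  expect_equal(r3$tp_fraction, 1)
  # zero exonic frequency -> undefined, flagged
  r4 <- elementLevelFdr(ex, intr, GRanges("chr1", IRanges(1010, 1014)))
  expect_true(is.na(r4$tp_fraction))
  expect_equal(r4$flag, "zero_exonic_frequency")
})
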