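test_that("instance filters follow the per-evidence selection rules", {
  # one gene, merged exon 1001-2000
  ex <- GRanges("chr1", IRanges(1001, 2000), strand = "+", gene_id = "G",
                transcript_id = "G.T1")
  merged <- mergeExons(ex)

  # conservation evidence: 3 exonic MIR instances, only 1 overlaps a
  # conserved element -> exactly 1 RIDL instance
  mir <- makeTeGr(c(1101, 1301, 1501), c(1180, 1380, 1580), type = "MIR")
  cons <- GRanges("chr1", IRanges(1150, 1160))
  sel <- selectInstances(list(cons_a = fakeScreen("conservation", "MIR")),
                         merged, mir, conservedSets = list(cons_a = cons))
  expect_equal(length(sel), 1L)
  expect_equal(start(sel), 1101L)
  expect_equal(sel$evidence, "cons_a")

  # strand-bias evidence: 2 sense + 1 antisense -> 2 selected
  sb <- c(makeTeGr(c(1101, 1301), c(1180, 1380), strand = "+", type = "S"),
          makeTeGr(1501, 1580, strand = "-", type = "S"))
  sb$instance_id <- 1:3
  sel2 <- selectInstances(list(strand_bias = fakeScreen("strand_bias", "S")),
                          merged, sb)
  expect_equal(length(sel2), 2L)
  expect_setequal(start(sel2), c(1101L, 1301L))

  # enrichment evidence: all 5 exonic instances selected
  enr <- makeTeGr(seq(1101, 1901, by = 200), seq(1150, 1950, by = 200),
                  type = "E")
  sel3 <- selectInstances(list(enrichment = fakeScreen("enrichment", "E")),
                          merged, enr)
  expect_equal(length(sel3), 5L)

  # a candidate type with zero qualifying instances contributes nothing
  sel4 <- selectInstances(list(cons_a = fakeScreen("conservation", "MIR")),
                          merged, mir,
                          conservedSets = list(cons_a = GRanges("chr1",
                                                IRanges(5000, 5010))))
  expect_equal(length(sel4), 0L)
})

test_that("RIDL assembly merges, unions evidence and drops <10 nt", {
  ex <- GRanges("chr1", IRanges(1001, 2000), strand = "+", gene_id = "G",
                transcript_id = "G.T1")
  merged <- mergeExons(ex)
  # same fragment selected by two conservation sets -> one instance with
  # both labels
  te <- makeTeGr(1101, 1180, type = "MIR")
  consA <- GRanges("chr1", IRanges(1110, 1120))
  sel <- selectInstances(
    list(cons_a = fakeScreen("conservation", "MIR"),
         cons_b = fakeScreen("conservation", "MIR")),
    merged, te, conservedSets = list(cons_a = consA, cons_b = consA))
  r <- assembleRidls(sel)
  gr <- ridlRanges(r)
  expect_equal(length(gr), 1L)
  expect_setequal(unlist(gr$evidence), c("cons_a", "cons_b"))

  # merged length 9 discarded, 10 retained (strict <10 filter)
  short <- c(makeTeGr(100, 108, type = "A"), makeTeGr(200, 209, type = "A"))
  short$instance_id <- 1:2
  selShort <- selectInstances(list(enrichment = fakeScreen("enrichment",
                                                           "A")),
                              mergeExons(GRanges("chr1", IRanges(50, 400),
                                                 strand = "+",
                                                 gene_id = "H",
                                                 transcript_id = "H.T1")),
                              short)
  rs <- ridlRanges(assembleRidls(selShort))
  expect_equal(length(rs), 1L)
  expect_equal(width(rs), 10L)

  # overlapping selections merge into non-overlapping output
  ov <- c(makeTeGr(1101, 1180, type = "A"), makeTeGr(1150, 1260, type = "B"))
  ov$instance_id <- 1:2
  scr <- list(enrichment = fakeScreen("enrichment", c("A", "B")))
  rOv <- ridlRanges(assembleRidls(selectInstances(scr, merged, ov)))
  expect_equal(length(rOv), 1L)
  expect_true(GenomicRanges::isDisjoint(rOv))
  # dominant type labels the merge (B contributes 111 nt, A 80 nt)
  expect_equal(rOv$te_type, "B")
  expect_setequal(unlist(rOv$source_instances), 1:2)
})

test_that("re-assembling an assembled RIDL set is idempotent", {
  ex <- GRanges("chr1", IRanges(1001, 2000), strand = "+", gene_id = "G",
                transcript_id = "G.T1")
  merged <- mergeExons(ex)
  tes <- makeTeGr(c(1101, 1150, 1501), c(1180, 1260, 1580), type = "A")
  tes$instance_id <- 1:3
  r1 <- assembleRidls(selectInstances(
    list(enrichment = fakeScreen("enrichment", "A")), merged, tes))
  gr1 <- ridlRanges(r1)
  # feed the assembled ranges back through assembly
  again <- gr1
  mcols(again) <- DataFrame(te_type = gr1$te_type,
                            instance_id = seq_along(gr1),
                            evidence = "enrichment",
                            gene_id = gr1$gene_id)
  r2 <- assembleRidls(again)
  expect_equal(granges(ridlRanges(r2)), granges(gr1))
})

test_that("insertion profiles count consensus coverage fractions", {
  mk <- function(cs, ce, len) {
    gr <- makeTeGr(seq_along(cs) * 1000, seq_along(cs) * 1000 + 50)
    gr$consensus_start <- as.integer(cs)
    gr$consensus_end <- as.integer(ce)
    gr$consensus_length <- as.integer(len)
    gr
  }
  # all instances spanning the full consensus -> constant 1
  p <- insertionProfile(mk(c(1, 1), c(100, 100), 100), 100)
  expect_equal(p, rep(1, 100))
  # 1-100 and 51-150 of a 150 nt consensus -> 0.5 / 1.0 / 0.5
  p2 <- insertionProfile(mk(c(1, 51), c(100, 150), 150), 150)
  expect_equal(unique(p2[1:50]), 0.5)
  expect_equal(unique(p2[51:100]), 1.0)
  expect_equal(unique(p2[101:150]), 0.5)
  # degenerate and invalid inputs
  expect_error(insertionProfile(mk(1, 50, 100)[0], 100), "no instances")
  expect_error(insertionProfile(mk(1, 200, 150), 150), "exceeds")
})

test_that("profile comparison uses rank correlation with a 0.9 flag", {
  x <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  r <- compareProfiles(x, x)
  expect_equal(r$cc, 1.0)
  expect_false(r$flagged)
  # strictly increasing transform leaves the rank correlation at 1
  r2 <- compareProfiles(x, x^3 + 2)
  expect_equal(r2$cc, 1.0)
  # constant profile is degenerate
  r3 <- compareProfiles(x, rep(0.5, 5))
  expect_true(r3$degenerate)
  expect_true(r3$flagged)
  # opposed 3' vs 5' biased profiles are flagged
  pos <- 1:200
  ridlProf <- pos / 200          # 3'-weighted
  intrProf <- rev(pos) / 200     # 5'-weighted
  r4 <- compareProfiles(ridlProf, intrProf)
  expect_lt(r4$cc, 0.9)
  expect_true(r4$flagged)
})

test_that("consensus bias knob shifts generated insertion profiles", {
  cfg3 <- simulationConfig(seed = 40, nGenes = 60L,
                           teCatalog = makeTeCatalog(4, 150L),
                           enrichedTypes = character(),
                           strandBiasedTypes = character(),
                           conservedTypes = character(),
                           localizationEffects = setNames(numeric(),
                                                          character()),
                           consensusBias = 0.9)
  b3 <- generateAnnotationBundle(cfg3, file.path(tempdir(), "bias3"))
  tes3 <- readTeBed(bundleFile(b3, "te_bed"))
  cfg5 <- simulationConfig(seed = 41, nGenes = 60L,
                           teCatalog = makeTeCatalog(4, 150L),
                           enrichedTypes = character(),
                           strandBiasedTypes = character(),
                           conservedTypes = character(),
                           localizationEffects = setNames(numeric(),
                                                          character()),
                           consensusBias = -0.9)
  b5 <- generateAnnotationBundle(cfg5, file.path(tempdir(), "bias5"))
  tes5 <- readTeBed(bundleFile(b5, "te_bed"))
  len <- tes3$consensus_length[tes3$te_type == "TE001"][1]
  p3 <- insertionProfile(tes3[tes3$te_type == "TE001"], len)
  p5 <- insertionProfile(tes5[tes5$te_type == "TE001"], len)
  cmp <- compareProfiles(p3, p5)
  expect_lt(cmp$cc, 0.9)
  expect_true(cmp$flagged)
})

test_that("RIDL counts per transcript deduplicate multi-exon overlaps", {
  ex <- c(GRanges("chr1", IRanges(c(101, 301), c(200, 400)), strand = "+",
                  gene_id = "G", transcript_id = "G.T1"),
          GRanges("chr1", IRanges(101, 200), strand = "+", gene_id = "G",
                  transcript_id = "G.T2"))
  ridlGr <- GRanges("chr1", IRanges(c(150, 190), c(170, 320)))
  mcols(ridlGr) <- DataFrame(
    te_type = c("A", "A"),
    gene_id = S4Vectors::SimpleList(list("G", "G")),
    evidence = S4Vectors::SimpleList(list("enrichment", "enrichment")),
    source_instances = S4Vectors::SimpleList(list(1L, 2L)))
  rs <- new("RIDLSet", ranges = GenomicRanges::sort(ridlGr))
  cnt <- countRidlsPerTranscript(rs, ex)
  # T1 overlaps both instances (one spans exon1-exon2 boundary region)
  expect_equal(cnt$n[cnt$transcript_id == "G.T1"], 2L)
  expect_equal(cnt$n[cnt$transcript_id == "G.T2"], 2L)
})

test_that("RIDLSet validity enforces its invariants", {
  bad <- GRanges("chr1", IRanges(1, 5))  # 5 nt < 10
  mcols(bad) <- DataFrame(
    te_type = "A", gene_id = S4Vectors::SimpleList(list("G")),
    evidence = S4Vectors::SimpleList(list("enrichment")),
    source_instances = S4Vectors::SimpleList(list(1L)))
  expect_error(new("RIDLSet", ranges = bad), ">= 10 nt")
  noEv <- GRanges("chr1", IRanges(1, 50))
  mcols(noEv) <- DataFrame(
    te_type = "A", gene_id = S4Vectors::SimpleList(list("G")),
    evidence = S4Vectors::SimpleList(list(character())),
    source_instances = S4Vectors::SimpleList(list(1L)))
  expect_error(new("RIDLSet", ranges = noEv), "evidence")
})
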