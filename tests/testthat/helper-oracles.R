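suppressPackageStartupMessages({
  library(S4Vectors)
  library(IRanges)
  library(GenomicRanges)
})

# Brute-force oracles and hand-built fixtures shared across tests.
# The oracles enumerate nucleotides or tables directly and never call the
# package functions they are used to check.

# Per-nucleotide coverage oracle: fraction of interval-set positions covered
# by >= 1 TE of each type. Intervals are GRanges; positions enumerated.
bruteCoverageByType <- function(intervals, tes, types) {
  posOf <- function(gr) {
    if (length(gr) == 0L) return(character())
    unique(unlist(lapply(seq_along(gr), function(i)
      paste0(as.character(GenomicRanges::seqnames(gr)[i]), ":",
             seq(GenomicRanges::start(gr)[i], GenomicRanges::end(gr)[i])))))
  }
  ivPos <- posOf(intervals)
  out <- data.frame(te_type = types, covered_nt = 0, total_nt = length(ivPos),
                    fraction = 0, stringsAsFactors = FALSE)
  for (k in seq_along(types)) {
    tePos <- posOf(tes[tes$te_type == types[k]])
    out$covered_nt[k] <- sum(ivPos %in% tePos)
  }
  out$fraction <- out$covered_nt / out$total_nt
  out
}

# All-pairs overlap oracle: number of (TE, interval) pairs sharing >= 1 nt
# on the same chromosome.
bruteOverlapPairs <- function(tes, intervals) {
  n <- 0L
  for (i in seq_along(tes)) for (j in seq_along(intervals)) {
    if (as.character(GenomicRanges::seqnames(tes)[i]) !=
        as.character(GenomicRanges::seqnames(intervals)[j])) next
    if (GenomicRanges::start(tes)[i] <= GenomicRanges::end(intervals)[j] &&
        GenomicRanges::end(tes)[i] >= GenomicRanges::start(intervals)[j])
      n <- n + 1L
  }
  n
}

# Exact Wilcoxon rank-sum p (two-sided) by full enumeration of group
# assignments; assumes no ties.
exactWilcoxP <- function(x, y) {
  all_ <- c(x, y)
  stopifnot(!anyDuplicated(all_))
  r <- rank(all_)
  n1 <- length(x)
  obsW <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(length(all_), n1)
  W <- apply(combs, 2, function(idx) sum(r[idx])) - n1 * (n1 + 1) / 2
  pl <- mean(W <= obsW); pu <- mean(W >= obsW)
  min(1, 2 * min(pl, pu))
}

# Exact Fisher p (two-sided) by hypergeometric enumeration: sum of
# probabilities of tables no more likely than the observed one.
exactFisherP <- function(tab, tol = 1e-7) {
  a <- tab[1, 1]
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  d <- stats::dhyper(support, m, n, k)
  sum(d[d <= stats::dhyper(a, m, n, k) * (1 + tol)])
}

# Hand-built gene fixture: one plus-strand and one minus-strand gene.
makeExonFixture <- function() {
  GenomicRanges::GRanges(
    c("chr1", "chr1", "chr1", "chr1", "chr1"),
    IRanges::IRanges(start = c(101, 301, 501, 2001, 2501),
                     end = c(200, 400, 600, 2100, 2600)),
    strand = c("+", "+", "+", "-", "-"),
    gene_id = c("GA", "GA", "GA", "GB", "GB"),
    transcript_id = c("GA.T1", "GA.T1", "GA.T1", "GB.T1", "GB.T1"),
    biotype = "lncRNA")
}

makeTeGr <- function(starts, ends, strand = "+", type = "T1",
                     chrom = "chr1") {
  n <- length(starts)
  gr <- GenomicRanges::GRanges(rep(chrom, n)[seq_len(n)],
                               IRanges::IRanges(starts, ends),
                               strand = rep(strand, length.out = n))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    te_type = rep(type, length.out = n),
    te_class = "X", te_family = "X",
    consensus_start = rep(NA_integer_, n),
    consensus_end = rep(NA_integer_, n),
    consensus_length = rep(NA_integer_, n),
    instance_id = seq_len(n))
  gr
}

# Minimal ScreenResult with a given candidate list, for instance-filter
# tests.
fakeScreen <- function(kind, candidates, allTypes = candidates) {
  res <- S4Vectors::DataFrame(te_type = allTypes,
                              observed = rep(1, length(allTypes)),
                              candidate = allTypes %in% candidates)
  new("ScreenResult", screen = kind, results = res,
      nullValues = matrix(numeric(), length(allTypes), 0,
                          dimnames = list(allTypes, NULL)),
      nSim = 0L, seed = NA_integer_)
}

writeTempGtf <- function(lines) {
  f <- tempfile(fileext = ".gtf")
  writeLines(lines, f)
  f
}

gtfExonLine <- function(chrom, start, end, strand, gid, tid,
                        type = "lncRNA") {
  sprintf(paste0('%s\tsrc\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; ',
                 'transcript_id "%s"; gene_type "%s";'),
          chrom, start, end, strand, gid, tid, type)
}
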