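#' Relative concentration index (RCI) per transcript and cell line
#'
#' RCI = log2(nuclear RPKM / cytoplasmic RPKM). Only transcripts with
#' nonzero values in both fractions get an RCI; others are excluded with a
#' reason. Positive RCI means nuclear enrichment.
#'
#' @param expr long-format expression data.frame from
#'   [readExpressionTable()] (fractions: nuclear, cytoplasmic, whole_cell).
#' @return data.frame with one row per (transcript, cell line):
#'   transcript_id, gene_id (if present), cell_line, nuclear_rpkm,
#'   cytoplasmic_rpkm, whole_cell_rpkm, rci, excluded_reason.
#' @export
computeRci <- function(expr) {
  if (any(expr$rpkm < 0)) stop("data error: negative RPKM")
  dt <- data.table::as.data.table(expr)
  keys <- intersect(c("transcript_id", "gene_id", "cell_line"), names(dt))
  wide <- data.table::dcast(dt, paste(paste(keys, collapse = " + "),
                                      "~ fraction"),
                            value.var = "rpkm", fun.aggregate = mean)
  for (cc in c("nuclear", "cytoplasmic", "whole_cell"))
    if (!cc %in% names(wide)) wide[[cc]] <- NA_real_
  ok <- !is.na(wide$nuclear) & !is.na(wide$cytoplasmic) &
    wide$nuclear > 0 & wide$cytoplasmic > 0
  out <- as.data.frame(wide)
  names(out)[names(out) == "nuclear"] <- "nuclear_rpkm"
  names(out)[names(out) == "cytoplasmic"] <- "cytoplasmic_rpkm"
  names(out)[names(out) == "whole_cell"] <- "whole_cell_rpkm"
  out$rci <- ifelse(ok, log2(out$nuclear_rpkm) - log2(out$cytoplasmic_rpkm),
                    NA_real_)
  out$excluded_reason <- ifelse(ok, "", "zero_or_missing_fraction")
  out
}

#' Representative transcript per gene (largest exon count)
#'
#' One transcript per gene: the one with the largest number of exons, ties
#' broken by lexicographically smallest transcript_id.
#'
#' @param exons exon GRanges with gene_id/transcript_id metadata.
#' @return named character vector, gene_id -> transcript_id.
#' @export
pickRepresentativeTranscript <- function(exons) {
  dt <- data.table::data.table(gene_id = exons$gene_id,
                               transcript_id = exons$transcript_id)
  cnt <- dt[, list(n = .N), by = c("gene_id", "transcript_id")]
  data.table::setorderv(cnt, c("gene_id", "n", "transcript_id"),
                        order = c(1L, -1L, 1L))
  rep_ <- cnt[!duplicated(cnt$gene_id)]
  stats::setNames(rep_$transcript_id, rep_$gene_id)
}

#' Localization screen: Wilcoxon test per (RIDL type, cell line)
#'
#' For each RIDL type and cell line, compares the RCI distribution of
#' RIDL-carrying representative transcripts against representative
#' transcripts not carrying that type (two-sided Wilcoxon rank-sum test).
#' A type is tested only if it has at least three RIDL transcripts with
#' defined RCI in at least one cell line; within an eligible type, each cell
#' line with >= 3 RIDL transcripts and a non-empty background is tested.
#' P-values are adjusted globally (BH) across all tests; significance at
#' q < 0.01.
#'
#' @param ridlCounts data.frame from [countRidlsPerTranscript()].
#' @param rci data.frame from [computeRci()].
#' @param representative named vector from [pickRepresentativeTranscript()];
#'   if NULL all transcripts in \code{rci} are used.
#' @param minRidl minimum RIDL-transcript group size (default 3).
#' @param alphaQ significance threshold on q (default 0.01).
#' @return data.frame, one row per performed test: te_type, cell_line,
#'   n_ridl, n_background, median_rci_ridl, median_rci_background,
#'   p_wilcoxon, q_bh, significant.
#' @export
localizationScreen <- function(ridlCounts, rci, representative = NULL,
                               minRidl = 3L, alphaQ = 0.01) {
  loc <- rci[!is.na(rci$rci), , drop = FALSE]
  if (!is.null(representative))
    loc <- loc[loc$transcript_id %in% representative, , drop = FALSE]
  types <- sort(unique(ridlCounts$te_type))
  cells <- sort(unique(loc$cell_line))
  rows <- list()
  for (tp in types) {
    carriers <- unique(ridlCounts$transcript_id[ridlCounts$te_type == tp])
    perCell <- lapply(cells, function(cl) {
      sub <- loc[loc$cell_line == cl, , drop = FALSE]
      list(ridl = sub$rci[sub$transcript_id %in% carriers],
           bg = sub$rci[!sub$transcript_id %in% carriers])
    })
    names(perCell) <- cells
    if (max(vapply(perCell, function(x) length(x$ridl), integer(1))) <
        minRidl) next
    for (cl in cells) {
      g <- perCell[[cl]]
      if (length(g$ridl) < minRidl || length(g$bg) == 0L) next
      p <- suppressWarnings(
        stats::wilcox.test(g$ridl, g$bg, alternative = "two.sided")$p.value)
      rows[[length(rows) + 1L]] <- data.frame(
        te_type = tp, cell_line = cl,
        n_ridl = length(g$ridl), n_background = length(g$bg),
        median_rci_ridl = stats::median(g$ridl),
        median_rci_background = stats::median(g$bg),
        p_wilcoxon = p, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(te_type = character(), cell_line = character(),
                      n_ridl = integer(), n_background = integer(),
                      median_rci_ridl = numeric(),
                      median_rci_background = numeric(),
                      p_wilcoxon = numeric(), q_bh = numeric(),
                      significant = logical()))
  out <- do.call(rbind, rows)
  out$q_bh <- adjustFdr(out$p_wilcoxon)
  out$significant <- out$q_bh < alphaQ
  out
}

#' Dose-response of localization on RIDL copy number
#'
#' Spearman correlation (two-sided) between per-transcript RIDL copy number
#' and RCI.
#'
#' @param rciValues numeric RCI per transcript.
#' @param counts integer RIDL copies per transcript (same order).
#' @return list with rho, p, n, flag ("" or "degenerate").
#' @export
doseResponse <- function(rciValues, counts) {
  keep <- !is.na(rciValues) & !is.na(counts)
  x <- counts[keep]; y <- rciValues[keep]
  if (length(x) < 3L) stop("need at least 3 transcripts with defined RCI")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = length(x),
                flag = "degenerate"))
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         alternative = "two.sided"))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(x), flag = "")
}

.vifs <- function(X) {
  vapply(seq_len(ncol(X)), function(j) {
    if (ncol(X) == 1L) return(1)
    r2 <- summary(stats::lm(X[, j] ~ X[, -j, drop = FALSE]))$r.squared
    1 / (1 - r2)
  }, numeric(1))
}

#' Linear model of localization on RIDL copies with confounder control
#'
#' Ordinary least squares of RCI on RIDL copy number, transcript length and
#' whole-cell expression; variance inflation factors are reported per term
#' as a multicollinearity check.
#'
#' @param rciValues RCI per transcript.
#' @param counts RIDL copies.
#' @param lengths transcript (exonic) lengths, nt.
#' @param expression whole-cell RPKM.
#' @param logExpression log2-transform expression before fitting.
#' @return list with coefficients, p_values, vifs, n, fit (the lm object).
#' @export
fitLocalizationModel <- function(rciValues, counts, lengths, expression,
                                 logExpression = FALSE) {
  df <- data.frame(rci = rciValues, ridl = counts, length = lengths,
                   expression = if (logExpression) log2(expression + 1)
                                else expression)
  df <- df[stats::complete.cases(df), , drop = FALSE]
  if (nrow(df) < 10L) stop("need at least 10 complete observations")
  X <- as.matrix(df[, c("ridl", "length", "expression")])
  if (qr(cbind(1, X))$rank < ncol(X) + 1L) {
    cors <- stats::cor(X)
    diag(cors) <- 0
    worst <- which(abs(cors) == max(abs(cors)), arr.ind = TRUE)[1, ]
    stop("rank-deficient design: collinear terms ",
         colnames(X)[worst[1]], " and ", colnames(X)[worst[2]])
  }
  fit <- stats::lm(rci ~ ridl + length + expression, data = df)
  sm <- summary(fit)$coefficients
  list(coefficients = sm[, "Estimate"],
       p_values = sm[, "Pr(>|t|)"],
       vifs = stats::setNames(.vifs(X), colnames(X)),
       n = nrow(df), fit = fit)
}

#' Rank-based partial correlation with confounder control
#'
#' Spearman partial correlation of RCI and RIDL copy number given the
#' control covariates, computed from the inverse of the rank-scale
#' correlation matrix; two-sided p from the t approximation with
#' n - 2 - k degrees of freedom (k controls).
#'
#' @param rciValues,counts the two variables of interest.
#' @param controls data.frame of control covariates (e.g. length,
#'   expression).
#' @return list with rho_partial, p, n.
#' @export
partialCorrelation <- function(rciValues, counts, controls) {
  df <- data.frame(y = rciValues, x = counts, controls)
  df <- df[stats::complete.cases(df), , drop = FALSE]
  n <- nrow(df)
  k <- ncol(controls)
  if (n < k + 4L) stop("too few observations for partial correlation")
  if (any(vapply(df, function(v) stats::sd(v) == 0, logical(1))))
    stop("undefined partial correlation: constant column")
  R <- stats::cor(apply(df, 2, rank))
  P <- solve(R)
  rho <- -P[1, 2] / sqrt(P[1, 1] * P[2, 2])
  tstat <- rho * sqrt((n - 2 - k) / (1 - rho^2))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2 - k)
  list(rho_partial = rho, p = p, n = n)
}

#' Intra-gene isoform contrast of localization
#'
#' For every gene expressing, in a given cell line, at least one
#' RIDL-carrying and at least one non-RIDL transcript (all with defined
#' RCI), computes Delta = mean RCI(RIDL isoforms) - mean RCI(non-RIDL
#' isoforms). Per cell line, reports the median Delta and a one-sided
#' t-test of Delta > 0.
#'
#' @param rci data.frame from [computeRci()] with gene_id.
#' @param ridlTranscripts character vector of transcript ids carrying a
#'   RIDL (of the type set under study).
#' @return list with \code{perGene} (gene_id, cell_line, delta, n_ridl,
#'   n_nonridl) and \code{perCell} (cell_line, n_genes, median_delta,
#'   p_t_onesided).
#' @export
isoformContrast <- function(rci, ridlTranscripts) {
  loc <- rci[!is.na(rci$rci), , drop = FALSE]
  loc$is_ridl <- loc$transcript_id %in% ridlTranscripts
  dt <- data.table::as.data.table(loc)
  per <- dt[, list(n_ridl = sum(is_ridl), n_nonridl = sum(!is_ridl),
                   delta = mean(rci[is_ridl]) - mean(rci[!is_ridl])),
            by = c("gene_id", "cell_line")]
  per <- per[per$n_ridl >= 1L & per$n_nonridl >= 1L]
  perGene <- as.data.frame(per)
  cells <- sort(unique(perGene$cell_line))
  perCell <- do.call(rbind, lapply(cells, function(cl) {
    d <- perGene$delta[perGene$cell_line == cl]
    if (length(d) < 2L) return(NULL)
    data.frame(cell_line = cl, n_genes = length(d),
               median_delta = stats::median(d),
               p_t_onesided = stats::t.test(d, mu = 0,
                                            alternative = "greater")$p.value,
               stringsAsFactors = FALSE)
  }))
  if (is.null(perCell))
    perCell <- data.frame(cell_line = character(), n_genes = integer(),
                          median_delta = numeric(),
                          p_t_onesided = numeric())
  list(perGene = perGene, perCell = perCell)
}
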