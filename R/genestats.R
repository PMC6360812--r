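#' RIDL clustering test across host genes
#'
#' Compares the observed per-gene RIDL-count histogram to a null in which
#' each RIDL is independently reassigned to a gene with probability
#' proportional to the gene's merged exonic length (a positional shuffle
#' across the lncRNA annotation, in expectation). Reports, per count value,
#' the observed number of genes and the empirical 95% band over \code{nSim}
#' reassignments; every replicate conserves the total number of RIDLs.
#'
#' @param ridlGeneIds character; host gene of each RIDL instance (one entry
#'   per RIDL; multi-gene RIDLs contribute their first host).
#' @param geneExonicLengths named numeric; merged exonic length per gene
#'   (the weight and the gene universe).
#' @param nSim number of reassignment replicates.
#' @param seed RNG seed.
#' @param uniformWeights if TRUE, genes are drawn uniformly instead of
#'   length-weighted.
#' @return data.frame: count, observed_genes, null_lo, null_hi, null_mean.
#' @export
clusteringTest <- function(ridlGeneIds, geneExonicLengths, nSim = 1000L,
                           seed = NULL, uniformWeights = FALSE) {
  stopifnot(length(ridlGeneIds) >= 1L)
  if (!is.null(seed)) set.seed(seed)
  genes <- names(geneExonicLengths)
  nR <- length(ridlGeneIds)
  obsCounts <- table(factor(ridlGeneIds, levels = genes))
  maxC <- max(obsCounts)
  w <- if (uniformWeights) rep(1, length(genes))
       else as.numeric(geneExonicLengths)
  nullHist <- matrix(0L, nSim, 0)
  histos <- vector("list", nSim)
  for (s in seq_len(nSim)) {
    asg <- sample.int(length(genes), nR, replace = TRUE, prob = w / sum(w))
    cnt <- tabulate(tabulate(asg, nbins = length(genes)) + 1L)
    histos[[s]] <- cnt  # cnt[k] = number of genes with k-1 RIDLs
    maxC <- max(maxC, length(cnt) - 1L)
  }
  counts <- 0:maxC
  nullMat <- t(vapply(histos, function(h) {
    out <- numeric(maxC + 1L)
    out[seq_along(h)] <- h
    out[1] <- length(genes) - sum(out[-1])  # genes with zero RIDLs
    out
  }, numeric(maxC + 1L)))
  obs <- vapply(counts, function(k) sum(obsCounts == k), numeric(1))
  data.frame(count = counts, observed_genes = obs,
             null_lo = apply(nullMat, 2, stats::quantile, probs = 0.025),
             null_hi = apply(nullMat, 2, stats::quantile, probs = 0.975),
             null_mean = colMeans(nullMat))
}

#' Sample a control gene set matched on a covariate distribution
#'
#' Histogram-bin matching on log-spaced bins (default 20) of the matching
#' variable (typically exonic length): for each bin, as many pool genes as
#' target genes are sampled without replacement; exhausted bins are capped
#' at availability and reported.
#'
#' @param targetValues named numeric; matching variable for target genes.
#' @param poolValues named numeric; matching variable for the candidate
#'   pool (must be disjoint from targets).
#' @param nBins number of log-spaced bins.
#' @param seed RNG seed.
#' @return list with \code{controls} (character ids), \code{diagnostics}
#'   data.frame per bin (n_target, n_pool, n_sampled).
#' @export
sampleMatchedControls <- function(targetValues, poolValues, nBins = 20L,
                                  seed = NULL) {
  if (length(intersect(names(targetValues), names(poolValues))))
    stop("pool must be disjoint from targets")
  if (!is.null(seed)) set.seed(seed)
  all_ <- c(targetValues, poolValues)
  stopifnot(all(all_ > 0))
  breaks <- exp(seq(log(min(all_)), log(max(all_)), length.out = nBins + 1L))
  breaks[1] <- breaks[1] * (1 - 1e-9); breaks[nBins + 1] <-
    breaks[nBins + 1] * (1 + 1e-9)
  tBin <- cut(targetValues, breaks, labels = FALSE)
  pBin <- cut(poolValues, breaks, labels = FALSE)
  controls <- character()
  diag_ <- data.frame(bin = seq_len(nBins), n_target = 0L, n_pool = 0L,
                      n_sampled = 0L)
  for (b in seq_len(nBins)) {
    nt <- sum(tBin == b)
    poolIds <- names(poolValues)[pBin == b]
    ns <- min(nt, length(poolIds))
    if (ns > 0L)
      controls <- c(controls, sample(poolIds, ns))
    diag_$n_target[b] <- nt; diag_$n_pool[b] <- length(poolIds)
    diag_$n_sampled[b] <- ns
  }
  short <- sum(diag_$n_target - diag_$n_sampled)
  if (short >= 0.1 * length(targetValues))
    warning("matched sampling exhausted pool bins covering ", short,
            " of ", length(targetValues), " targets")
  list(controls = controls, diagnostics = diag_)
}

#' Fisher's exact test of a binary trait between gene sets
#'
#' 2x2 table of trait presence in targets versus controls; exact
#' hypergeometric p (two-sided) and both the sample odds ratio and the
#' conditional-MLE odds ratio from \code{fisher.test}. Zero cells give an
#' infinite/zero sample OR; a Haldane-corrected (+0.5) auxiliary estimate
#' is always reported.
#'
#' @param targetFlags,controlFlags logical vectors of trait presence.
#' @return list with table, or_sample, or_cmle, or_haldane, p.
#' @export
fisherEnrichment <- function(targetFlags, controlFlags) {
  tab <- matrix(c(sum(targetFlags), sum(!targetFlags),
                  sum(controlFlags), sum(!controlFlags)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("target", "control"),
                                c("trait", "no_trait")))
  ft <- stats::fisher.test(tab, alternative = "two.sided")
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  orSample <- (a * d) / (b * c_)
  orHaldane <- ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5))
  list(table = tab, or_sample = orSample,
       or_cmle = unname(ft$estimate), or_haldane = orHaldane,
       p = ft$p.value)
}

#' Logistic regression of a functional-association outcome on RIDL load
#'
#' Maximum-likelihood logistic regression of a binary gene trait on RIDL
#' count, exonic length and exonic conservation fraction, with VIFs as a
#' multicollinearity check. Complete separation is detected (fitted
#' probabilities collapsing to 0/1) and handled by a ridge-penalized
#' fallback fit (coefficients only, p-values NA, flagged).
#'
#' @param records data.frame with columns outcome (logical/0-1),
#'   ridl_count, exonic_length, exonic_conservation.
#' @return list with coefficients, p_values, vifs, n, separation, fit.
#' @export
fitFunctionalModel <- function(records) {
  need <- c("outcome", "ridl_count", "exonic_length", "exonic_conservation")
  stopifnot(all(need %in% names(records)))
  df <- records[stats::complete.cases(records[need]), need]
  y <- as.integer(df$outcome)
  if (length(unique(y)) < 2L)
    stop("both outcome classes must be present")
  X <- as.matrix(df[, c("ridl_count", "exonic_length",
                        "exonic_conservation")])
  fit <- suppressWarnings(
    stats::glm(y ~ ridl_count + exonic_length + exonic_conservation,
               data = df, family = stats::binomial()))
  mu <- stats::fitted(fit)
  separated <- !fit$converged || any(mu > 1 - 1e-8) || any(mu < 1e-8)
  if (separated) {
    gf <- glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                         lambda = 1e-3, standardize = TRUE)
    co <- as.numeric(stats::coef(gf))
    names(co) <- c("(Intercept)", colnames(X))
    return(list(coefficients = co,
                p_values = stats::setNames(rep(NA_real_, length(co)),
                                           names(co)),
                vifs = stats::setNames(.vifs(X), colnames(X)),
                n = nrow(df), separation = TRUE, fit = gf))
  }
  sm <- summary(fit)$coefficients
  list(coefficients = sm[, "Estimate"], p_values = sm[, "Pr(>|z|)"],
       vifs = stats::setNames(.vifs(X), colnames(X)),
       n = nrow(df), separation = FALSE, fit = fit)
}

#' Derived-allele-frequency spectrum by region class
#'
#' Bins DAF values per region class (default deciles), reports per-class
#' bin proportions (summing to 1) and the rare-allele fraction
#' (DAF < 0.1), with an optional pairwise two-proportion test of the rare
#' bin against a reference class.
#'
#' @param snps data.frame with columns daf and region_class.
#' @param breaks bin breaks on [0, 1] (default deciles).
#' @param rareCutoff rare-allele threshold (default 0.1).
#' @param testAgainst optional reference class for pairwise rare-bin
#'   proportion tests.
#' @return list with \code{spectrum} (class x bin proportion matrix),
#'   \code{rare_fraction} named vector, \code{n} per class, and
#'   \code{rare_tests} (if requested).
#' @export
dafSpectrum <- function(snps, breaks = seq(0, 1, 0.1), rareCutoff = 0.1,
                        testAgainst = NULL) {
  stopifnot(all(c("daf", "region_class") %in% names(snps)))
  classes <- sort(unique(snps$region_class))
  empty <- vapply(classes, function(cl)
    sum(snps$region_class == cl) == 0L, logical(1))
  if (any(empty)) {
    warning("omitting empty classes: ",
            paste(classes[empty], collapse = ", "))
    classes <- classes[!empty]
  }
  bin <- cut(snps$daf, breaks, include.lowest = TRUE, right = FALSE)
  spec <- t(vapply(classes, function(cl) {
    tab <- table(bin[snps$region_class == cl])
    as.numeric(tab) / sum(tab)
  }, numeric(length(levels(bin)))))
  rownames(spec) <- classes; colnames(spec) <- levels(bin)
  rare <- vapply(classes, function(cl)
    mean(snps$daf[snps$region_class == cl] < rareCutoff), numeric(1))
  n <- vapply(classes, function(cl)
    sum(snps$region_class == cl), numeric(1))
  out <- list(spectrum = spec, rare_fraction = rare, n = n)
  if (!is.null(testAgainst)) {
    stopifnot(testAgainst %in% classes)
    ref <- snps$daf[snps$region_class == testAgainst] < rareCutoff
    out$rare_tests <- do.call(rbind, lapply(
      setdiff(classes, testAgainst), function(cl) {
        x <- snps$daf[snps$region_class == cl] < rareCutoff
        pt <- suppressWarnings(
          stats::prop.test(c(sum(x), sum(ref)),
                           c(length(x), length(ref))))
        data.frame(region_class = cl, reference = testAgainst,
                   rare_fraction = mean(x), reference_rare = mean(ref),
                   p = pt$p.value, stringsAsFactors = FALSE)
      }))
  }
  out
}
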