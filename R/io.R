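#' Read a two-column chromosome size table
#'
#' @param path tab-separated file with columns chromosome name and length (nt).
#' @return named integer vector of chromosome lengths.
#' @export
readChromSizes <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          col.names = c("chrom", "size"))
  if (nrow(dt) == 0L) stop("empty chromosome size table: ", path)
  if (any(is.na(dt$size)) || any(dt$size <= 0))
    stop("chromosome sizes must be positive integers")
  stats::setNames(as.integer(dt$size), dt$chrom)
}

.parseGtfAttr <- function(attr, key) {
  m <- regmatches(attr, regexpr(paste0(key, ' "[^"]*"'), attr))
  out <- rep(NA_character_, length(attr))
  hit <- lengths(regmatches(attr, gregexpr(paste0(key, ' "'), attr))) > 0
  out[hit] <- sub('"$', "", sub(paste0(key, ' "'), "", m))
  out
}

#' Read gene models from a GENCODE-style GTF
#'
#' Parses exon features of a GTF 2.2 file (1-based, closed intervals) into a
#' GRanges of exons carrying \code{gene_id}, \code{transcript_id} and
#' \code{biotype} metadata. Coordinates are kept in the 1-based closed
#' convention of GRanges; BED output converts at the boundary.
#'
#' @param path GTF file.
#' @param biotypeFilter optional biotype (gene_type/transcript_type value);
#'   genes failing the filter are dropped.
#' @return GRanges of exons, sorted, one row per exon record.
#' @export
readGeneModels <- function(path, biotypeFilter = NULL) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0L) {
    return(GRanges(gene_id = character(), transcript_id = character(),
                   biotype = character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 9L)
  if (length(bad))
    stop("malformed GTF line ", bad[1], ": expected 9 tab-separated fields, ",
         "got ", lengths(fields)[bad[1]])
  m <- matrix(unlist(lapply(fields, `[`, 1:9)), ncol = 9, byrow = TRUE)
  feat <- m[, 3]
  keep <- feat == "exon"
  if (!any(keep)) {
    return(GRanges(gene_id = character(), transcript_id = character(),
                   biotype = character()))
  }
  m <- m[keep, , drop = FALSE]
  starts <- suppressWarnings(as.integer(m[, 4]))
  ends <- suppressWarnings(as.integer(m[, 5]))
  if (any(is.na(starts)) || any(is.na(ends)))
    stop("malformed GTF line ", which(keep)[which(is.na(starts) |
         is.na(ends))][1], ": non-numeric coordinates")
  if (any(ends < starts))
    stop("rejected GTF record: exon with end < start at line ",
         which(keep)[which(ends < starts)[1]])
  attr <- m[, 9]
  gid <- .parseGtfAttr(attr, "gene_id")
  tid <- .parseGtfAttr(attr, "transcript_id")
  bt <- .parseGtfAttr(attr, "gene_type")
  bt2 <- .parseGtfAttr(attr, "transcript_type")
  bt[is.na(bt)] <- bt2[is.na(bt)]
  if (any(is.na(gid)) || any(is.na(tid)))
    stop("malformed GTF attributes: gene_id/transcript_id required ",
         "(first offending exon record ",
         which(is.na(gid) | is.na(tid))[1], ")")
  gr <- GRanges(m[, 1], IRanges(starts, ends), strand = m[, 7],
                gene_id = gid, transcript_id = tid, biotype = bt)
  if (!is.null(biotypeFilter))
    gr <- gr[!is.na(gr$biotype) & gr$biotype == biotypeFilter]
  sort(gr, ignore.strand = TRUE)
}

#' Write gene models to GTF
#'
#' Emits gene, transcript and exon features in GTF 2.2 (1-based closed), so
#' that reading the file back recovers the exon coordinates exactly.
#'
#' @param exons GRanges as returned by [readGeneModels()].
#' @param path output file.
#' @param source source field (column 2).
#' @export
writeGtf <- function(exons, path, source = "ridlscan") {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(exons) == 0L) return(invisible(path))
  df <- data.frame(chrom = as.character(seqnames(exons)),
                   start = start(exons), end = end(exons),
                   strand = as.character(strand(exons)),
                   gene_id = exons$gene_id,
                   transcript_id = exons$transcript_id,
                   biotype = if (is.null(exons$biotype)) "lncRNA"
                             else exons$biotype)
  df <- df[order(df$chrom, df$start, df$end), ]
  lines <- character()
  for (g in split(df, df$gene_id)) {
    gl <- sprintf(
      '%s\t%s\tgene\t%d\t%d\t.\t%s\t.\tgene_id "%s"; gene_type "%s";',
      g$chrom[1], source, min(g$start), max(g$end), g$strand[1],
      g$gene_id[1], g$biotype[1])
    tl <- vapply(split(g, g$transcript_id), function(t) {
      paste(c(sprintf(
        paste0('%s\t%s\ttranscript\t%d\t%d\t.\t%s\t.\tgene_id "%s"; ',
               'transcript_id "%s"; gene_type "%s";'),
        t$chrom[1], source, min(t$start), max(t$end), t$strand[1],
        t$gene_id[1], t$transcript_id[1], t$biotype[1]),
        sprintf(
          paste0('%s\t%s\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; ',
                 'transcript_id "%s"; gene_type "%s";'),
          t$chrom, source, t$start, t$end, t$strand, t$gene_id,
          t$transcript_id, t$biotype)), collapse = "\n")
    }, character(1))
    lines <- c(lines, gl, tl)
  }
  writeLines(lines, con)
  invisible(path)
}

#' Default column map for the RepeatMasker-style TE BED dialect
#'
#' Maps logical field names to 1-based column indices of the tab-separated
#' TE table: BED coordinates (0-based half-open), repeat name/class/family
#' and 1-based consensus coordinates.
#' @export
teBedColmap <- function() {
  c(chrom = 1L, start = 2L, end = 3L, repName = 4L, score = 5L, strand = 6L,
    repClass = 7L, repFamily = 8L, consensus_start = 9L,
    consensus_end = 10L, consensus_length = 11L)
}

#' Read TE instances from a RepeatMasker-style BED export
#'
#' BED starts (0-based half-open) are converted to the 1-based closed GRanges
#' convention. Consensus coordinates (1-based, inclusive) are stored verbatim.
#' The parser is lossless: duplicated rows give distinct instances, each
#' tagged with an \code{instance_id} equal to its row number.
#'
#' @param path tab-separated file, no header.
#' @param colmap named integer vector mapping fields to columns; see
#'   [teBedColmap()]. Consensus columns may be absent (set to NA).
#' @return GRanges with metadata columns te_type, te_class, te_family,
#'   consensus_start, consensus_end, consensus_length, instance_id.
#' @export
readTeBed <- function(path, colmap = teBedColmap()) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t")
  if (nrow(dt) == 0L)
    return(GRanges(te_type = character(), te_class = character(),
                   te_family = character(), consensus_start = integer(),
                   consensus_end = integer(), consensus_length = integer(),
                   instance_id = integer()))
  if (is.na(colmap["repName"]) || colmap["repName"] > ncol(dt))
    stop("TE table format error: missing repName column")
  col <- function(key) {
    i <- colmap[key]
    if (is.na(i) || i > ncol(dt)) return(NULL)
    dt[[i]]
  }
  start0 <- as.integer(col("start")); end0 <- as.integer(col("end"))
  if (any(start0 < 0))
    stop("rejected TE record: negative start at row ", which(start0 < 0)[1])
  if (any(end0 <= start0))
    stop("rejected TE record: end <= start at row ", which(end0 <= start0)[1])
  consS <- col("consensus_start"); consE <- col("consensus_end")
  consL <- col("consensus_length")
  gr <- GRanges(as.character(col("chrom")), IRanges(start0 + 1L, end0),
                strand = if (is.null(col("strand"))) "*" else col("strand"))
  mcols(gr) <- DataFrame(
    te_type = as.character(col("repName")),
    te_class = if (is.null(col("repClass"))) NA_character_
               else as.character(col("repClass")),
    te_family = if (is.null(col("repFamily"))) NA_character_
                else as.character(col("repFamily")),
    consensus_start = if (is.null(consS)) NA_integer_ else as.integer(consS),
    consensus_end = if (is.null(consE)) NA_integer_ else as.integer(consE),
    consensus_length = if (is.null(consL)) NA_integer_
                       else as.integer(consL),
    instance_id = seq_len(nrow(dt)))
  bad <- !is.na(gr$consensus_start) &
    (gr$consensus_start < 1L | gr$consensus_start > gr$consensus_end |
     gr$consensus_end > gr$consensus_length)
  if (any(bad))
    stop("rejected TE record: inconsistent consensus coordinates at row ",
         which(bad)[1])
  gr
}

#' Read a BED3/BED6 file into GRanges
#'
#' @param path BED file (0-based half-open); converted to 1-based closed.
#' @return GRanges; name/score kept as metadata when present.
#' @export
readBed <- function(path) {
  dt <- tryCatch(data.table::fread(path, header = FALSE, sep = "\t"),
                 error = function(e) data.table::data.table())
  if (nrow(dt) == 0L) return(GRanges(name = character()))
  st <- if (ncol(dt) >= 6) as.character(dt[[6]]) else "*"
  st[st == "."] <- "*"
  gr <- GRanges(as.character(dt[[1]]),
                IRanges(as.integer(dt[[2]]) + 1L, as.integer(dt[[3]])),
                strand = st)
  mcols(gr)$name <- if (ncol(dt) >= 4) as.character(dt[[4]])
                    else rep(".", nrow(dt))
  if (ncol(dt) >= 5) mcols(gr)$score <- dt[[5]]
  gr
}

#' Write intervals to a BED6 file
#'
#' Output is 0-based half-open, sorted lexicographically by chromosome, then
#' start, then end, so identical inputs give byte-identical files.
#'
#' @param gr GRanges; a \code{name} metadata column is used for column 4.
#' @param path output file.
#' @param extraCols optional character vector of metadata column names to
#'   append after the six BED columns.
#' @export
writeBed <- function(gr, path, extraCols = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(gr) == 0L) return(invisible(path))
  nm <- if (!is.null(mcols(gr)$name)) as.character(mcols(gr)$name)
        else rep(".", length(gr))
  sc <- if (!is.null(mcols(gr)$score)) mcols(gr)$score
        else rep(0L, length(gr))
  st <- as.character(strand(gr)); st[st == "*"] <- "."
  df <- data.frame(chrom = as.character(seqnames(gr)),
                   start = start(gr) - 1L, end = end(gr),
                   name = nm, score = sc, strand = st,
                   stringsAsFactors = FALSE)
  for (ec in extraCols) {
    v <- mcols(gr)[[ec]]
    if (is.list(v) || inherits(v, "List"))
      v <- vapply(as.list(v), paste, character(1), collapse = ",")
    df[[ec]] <- v
  }
  o <- order(df$chrom, df$start, df$end, method = "radix")
  df <- df[o, , drop = FALSE]
  writeLines(do.call(paste, c(df, sep = "\t")), con)
  invisible(path)
}

#' Read a per-fraction expression table
#'
#' @param path TSV with header columns transcript_id, gene_id, cell_line,
#'   fraction (nuclear / cytoplasmic / whole_cell), rpkm.
#' @return data.frame in long format.
#' @export
readExpressionTable <- function(path) {
  dt <- data.table::fread(path, header = TRUE, sep = "\t")
  need <- c("transcript_id", "cell_line", "fraction", "rpkm")
  if (!all(need %in% names(dt)))
    stop("expression table must have columns: ",
         paste(need, collapse = ", "))
  if (any(dt$rpkm < 0)) stop("data error: negative RPKM")
  as.data.frame(dt)
}

#' Read a SNP table with derived allele frequencies
#'
#' @param path TSV with header columns chrom, pos (1-based), daf and
#'   optionally region_class.
#' @return data.frame.
#' @export
readSnpTable <- function(path) {
  dt <- data.table::fread(path, header = TRUE, sep = "\t")
  need <- c("chrom", "pos", "daf")
  if (!all(need %in% names(dt)))
    stop("SNP table must have columns: ", paste(need, collapse = ", "))
  if (any(dt$daf < 0 | dt$daf > 1)) stop("DAF values must lie in [0, 1]")
  as.data.frame(dt)
}

#' Read a one-gene-id-per-line membership list
#' @param path text file.
#' @return character vector of gene ids.
#' @export
readGeneList <- function(path) {
  x <- readLines(path)
  x[nzchar(x)]
}
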