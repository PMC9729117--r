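## Plain-text readers and writers for the pipeline's standard formats.

#' Read a .pairs contact-pair file (4DN dialect)
#'
#' Skips '#' header lines and reads the 4DN column order: readID,
#' chrom1, pos1, chrom2, pos2, strand1, strand2.
#'
#' @param path File path.
#' @return data.frame (readID, chrom1, pos1, chrom2, pos2, strand1,
#'   strand2).
#' @export
readPairs <- function(path) {
  d <- read.table(path, header = FALSE, comment.char = "#",
                  stringsAsFactors = FALSE)
  colnames(d)[1:7] <- c("readID", "chrom1", "pos1", "chrom2", "pos2",
                        "strand1", "strand2")
  d
}

#' Write contact pairs in .pairs format
#'
#' @param pairs data.frame with chrom1, pos1, strand1, chrom2, pos2,
#'   strand2 (readID generated if absent).
#' @param path Output path.
#' @param chromLength Chromosome length for the header chromsize line.
#' @export
writePairs <- function(pairs, path, chromLength = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("## pairs format v1.0", con)
  writeLines("#columns: readID chr1 pos1 chr2 pos2 strand1 strand2",
             con)
  if (!is.null(chromLength))
    writeLines(paste("#chromsize:", pairs$chrom1[1], chromLength),
               con)
  id <- if (is.null(pairs$readID))
    paste0("read", seq_len(nrow(pairs))) else pairs$readID
  write.table(data.frame(id, pairs$chrom1, pairs$pos1, pairs$chrom2,
                         pairs$pos2, pairs$strand1, pairs$strand2),
              con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
}

#' Read/write a contact matrix as sparse COO or dense TSV
#'
#' COO files have columns bin1, bin2, count (0-based bins, upper
#' triangle); dense files are full matrices. Metadata (chrom, bin
#' size) travels in '#' header lines.
#'
#' @param path File path.
#' @param x A \linkS4class{BinnedContactMatrix}.
#' @param format "coo" or "dense".
#' @return \code{readContactMatrix}: a
#'   \linkS4class{BinnedContactMatrix}.
#' @export
writeContactMatrix <- function(x, path, format = c("coo", "dense")) {
  format <- match.arg(format)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# chrom=%s binSize=%d nBins=%d format=%s",
                     x@chrom, as.integer(x@binSize),
                     length(x), format), con)
  if (format == "coo") {
    idx <- which(upper.tri(x@counts, diag = TRUE) & x@counts > 0,
                 arr.ind = TRUE)
    d <- data.frame(bin1 = idx[, 1] - 1L, bin2 = idx[, 2] - 1L,
                    count = x@counts[idx])
    write.table(d, con, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  } else {
    write.table(x@counts, con, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
}

#' @rdname writeContactMatrix
#' @export
readContactMatrix <- function(path) {
  hdr <- readLines(path, n = 1)
  meta <- regmatches(hdr, gregexpr("[a-zA-Z]+=[^ ]+", hdr))[[1]]
  kv <- do.call(rbind, strsplit(meta, "="))
  get <- function(k) kv[kv[, 1] == k, 2]
  n <- as.integer(get("nBins"))
  bs <- as.numeric(get("binSize"))
  chrom <- get("chrom")
  d <- read.table(path, header = FALSE, comment.char = "#")
  if (get("format") == "coo") {
    counts <- matrix(0, n, n)
    counts[cbind(d[, 1] + 1L, d[, 2] + 1L)] <- d[, 3]
    counts[cbind(d[, 2] + 1L, d[, 1] + 1L)] <- d[, 3]
  } else {
    counts <- as.matrix(d)
    dimnames(counts) <- NULL
  }
  BinnedContactMatrix(counts, chrom = chrom, binSize = bs)
}

#' Read/write loops as BEDPE
#'
#' Standard BEDPE columns (chrom1, start1, end1, chrom2, start2, end2,
#' name, score, strand1, strand2) plus a class column; coordinates are
#' 0-based half-open.
#'
#' @param x A \linkS4class{LoopSet}.
#' @param path File path.
#' @param scoreColumn Which score column to write (default the first,
#'   or 0 when none).
#' @return \code{readLoopsBedpe}: a \linkS4class{LoopSet}.
#' @export
writeLoopsBedpe <- function(x, path, scoreColumn = 1L) {
  sc <- if (ncol(x@scores) >= scoreColumn && nrow(x@scores))
    x@scores[[scoreColumn]] else rep(0, length(x))
  d <- data.frame(
    chrom1 = as.character(seqnames(anchorOne(x))),
    start1 = start(anchorOne(x)) - 1L, end1 = end(anchorOne(x)),
    chrom2 = as.character(seqnames(anchorTwo(x))),
    start2 = start(anchorTwo(x)) - 1L, end2 = end(anchorTwo(x)),
    name = paste0("loop", seq_len(length(x))), score = sc,
    strand1 = ".", strand2 = ".", class = loopClass(x))
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
}

#' @rdname writeLoopsBedpe
#' @export
readLoopsBedpe <- function(path) {
  d <- read.table(path, header = FALSE, stringsAsFactors = FALSE)
  a1 <- GRanges(d[, 1], IRanges(start = d[, 2] + 1L, end = d[, 3]))
  a2 <- GRanges(d[, 4], IRanges(start = d[, 5] + 1L, end = d[, 6]))
  cls <- if (ncol(d) >= 11) d[, 11] else rep("other", nrow(d))
  sc <- if (ncol(d) >= 8) data.frame(score = d[, 8]) else
    data.frame(row.names = seq_len(nrow(d)))
  LoopSet(a1, a2, loopClass = cls, scores = sc)
}

#' Read/write SPT trajectories as CSV
#'
#' Columns: trajectory_id, frame, t_s, x_um, y_um.
#'
#' @param x A \linkS4class{TrajectorySet}.
#' @param path File path.
#' @param frameInterval,sigmaLoc Acquisition metadata for reading.
#' @return \code{readTrajectories}: a \linkS4class{TrajectorySet}.
#' @export
writeTrajectories <- function(x, path) {
  write.table(x@tracks, path, sep = ",", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
}

#' @rdname writeTrajectories
#' @export
readTrajectories <- function(path, frameInterval, sigmaLoc = NA) {
  d <- read.table(path, header = TRUE, sep = ",")
  TrajectorySet(d, frameInterval = frameInterval,
                sigmaLoc = sigmaLoc)
}

#' Read a gene table (TSV)
#'
#' Expects header columns name, tss, tes, strand, tpm and optionally
#' deg_status.
#'
#' @param path File path.
#' @return data.frame; deg_status defaults to "no".
#' @export
readGeneTable <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t",
                  stringsAsFactors = FALSE)
  if (is.null(d$deg_status)) d$deg_status <- "no"
  d
}

#' Read a FRAP recovery curve (CSV: t_s, intensity)
#'
#' @param path File path.
#' @param bleachFrame Prebleach frame count recorded as an attribute.
#' @return data.frame (t_s, intensity) with a \code{bleachFrame}
#'   attribute.
#' @export
readFrapCurve <- function(path, bleachFrame = 20L) {
  d <- read.table(path, header = TRUE, sep = ",")
  structure(d, bleachFrame = bleachFrame)
}
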