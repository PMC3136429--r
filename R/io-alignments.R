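#' Read candidate multi-alignments from SAM/BAM or BED-like text
#'
#' Parses an alignment file in which every candidate alignment of each read
#' is reported (e.g. an aligner run in report-all mode with a mismatch cap),
#' groups records by read id, and applies the standard multi-read filters:
#' alignments with more than \code{maxMismatches} mismatches are discarded,
#' and reads with \code{maxHits} or more surviving alignments are dropped
#' entirely (the default reproduces the convention of discarding reads with
#' 100 or more candidate locations).
#'
#' SAM/BAM input is read with \pkg{Rsamtools}; mismatch counts are taken from
#' the \code{NM} tag (absent tags count as 0).  Secondary-alignment flags are
#' ignored for grouping: all mapped records sharing a query name form one
#' candidate set.  The BED-like text dialect has 6 tab-separated columns:
#' chrom, 0-based start, end, read id, mismatches, strand.
#'
#' @param path file path.
#' @param format \code{"auto"} (by extension), \code{"sam"}, \code{"bam"} or
#'   \code{"bed"}.
#' @param maxHits reads with this many or more alignments are dropped
#'   (default 100).
#' @param maxMismatches alignments with more mismatches are discarded
#'   (default 2).
#' @return a \code{\linkS4class{ReadAlignments}}; the filter summary (counts
#'   of kept uni/multi reads and dropped reads) is stored in
#'   \code{S4Vectors::metadata(alignments(x))$filter_summary}.
#' @export
readAlignmentFile <- function(path, format = c("auto", "sam", "bam", "bed"),
                              maxHits = 100L, maxMismatches = 2L) {
    format <- match.arg(format)
    if (format == "auto") {
        ext <- tolower(tools::file_ext(path))
        format <- switch(ext, sam = "sam", bam = "bam", "bed")
    }
    if (!file.exists(path)) stop("no such file: ", path)
    tab <- switch(format,
        sam = , bam = .parseSamBam(path, format),
        bed = .parseBedText(path))
    .buildReadAlignments(tab, maxHits = as.integer(maxHits),
                         maxMismatches = as.integer(maxMismatches))
}

.parseSamBam <- function(path, format) {
    bam <- path
    if (format == "sam") {
        bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                                indexDestination = FALSE)
    }
    p <- Rsamtools::ScanBamParam(
        what = c("qname", "flag", "rname", "pos", "strand", "qwidth"),
        tag = "NM")
    res <- Rsamtools::scanBam(bam, param = p)[[1L]]
    mapped <- !bitwAnd(res$flag, 4L)
    nm <- res$tag$NM
    if (is.null(nm)) nm <- rep(NA_integer_, length(res$qname))
    nm[is.na(nm)] <- 0L
    data.frame(read_id = res$qname[mapped],
               chrom = as.character(res$rname[mapped]),
               start = res$pos[mapped],
               width = res$qwidth[mapped],
               strand = as.character(res$strand[mapped]),
               mismatches = nm[mapped],
               stringsAsFactors = FALSE)
}

.parseBedText <- function(path) {
    tab <- tryCatch(
        read.table(path, sep = "\t", stringsAsFactors = FALSE,
                   col.names = c("chrom", "start", "end", "read_id",
                                 "mismatches", "strand"),
                   colClasses = c("character", "integer", "integer",
                                  "character", "integer", "character")),
        error = function(e) stop("malformed BED-like alignment file '",
                                 path, "': ", conditionMessage(e)))
    if (nrow(tab) == 0L)
        return(data.frame(read_id = character(), chrom = character(),
                          start = integer(), width = integer(),
                          strand = character(), mismatches = integer()))
    bad <- which(tab$start < 0L | tab$end <= tab$start)
    if (length(bad))
        stop("malformed coordinates at record ", bad[1L], " of ", path)
    if (!all(tab$strand %in% c("+", "-")))
        stop("invalid strand field in ", path)
    data.frame(read_id = tab$read_id, chrom = tab$chrom,
               start = tab$start + 1L, width = tab$end - tab$start,
               strand = tab$strand, mismatches = tab$mismatches,
               stringsAsFactors = FALSE)
}

.buildReadAlignments <- function(tab, maxHits, maxMismatches,
                                 weights = NULL, weighted = FALSE) {
    n0_reads <- length(unique(tab$read_id))
    keep_mm <- tab$mismatches <= maxMismatches
    tab <- tab[keep_mm, , drop = FALSE]
    hits <- table(tab$read_id)
    over <- names(hits)[hits >= maxHits]
    dropped_mm <- n0_reads - length(hits)
    tab <- tab[!(tab$read_id %in% over), , drop = FALSE]
    if (nrow(tab)) {
        ord <- order(tab$read_id, tab$chrom, tab$start)
        tab <- tab[ord, , drop = FALSE]
        if (!is.null(weights)) weights <- weights[keep_mm][ord]
    }
    gr <- GenomicRanges::GRanges(
        seqnames = if (nrow(tab)) tab$chrom else character(),
        ranges = IRanges::IRanges(start = tab$start, width = tab$width),
        strand = if (nrow(tab)) tab$strand else character())
    S4Vectors::mcols(gr)$read_id <- tab$read_id
    S4Vectors::mcols(gr)$mismatches <- as.integer(tab$mismatches)
    S4Vectors::mcols(gr)$weight <-
        if (is.null(weights)) rep(NA_real_, nrow(tab)) else weights
    hits2 <- table(tab$read_id)
    S4Vectors::metadata(gr)$filter_summary <- list(
        reads_kept = length(hits2),
        uni_reads = sum(hits2 == 1L),
        multi_reads = sum(hits2 > 1L),
        reads_dropped_max_hits = length(over),
        reads_dropped_mismatch = dropped_mm)
    rl <- if (nrow(tab)) as.integer(tab$width[1L]) else NA_integer_
    new("ReadAlignments", alignments = gr, readLength = rl,
        weighted = weighted)
}

#' Write weighted alignments as tab-delimited text
#'
#' Persists allocated alignments in a BED-like dialect with the allocation
#' weight as an extra column: chrom, 0-based start, end, read id, weight
#' (6 decimals), strand, mismatches.  Per-read weight conservation is
#' verified before writing; \code{\link{readWeightedAlignments}} reads the
#' format back and re-checks conservation at tolerance 1e-5.
#'
#' @param x a weighted \code{ReadAlignments}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeWeightedAlignments <- function(x, path) {
    stopifnot(is(x, "ReadAlignments"))
    if (!isWeighted(x)) stop("alignments are not weighted; run allocation first")
    gr <- alignments(x)
    mc <- S4Vectors::mcols(gr)
    s <- rowsum(mc$weight, mc$read_id)
    if (any(abs(s - 1) > 1e-5))
        stop("per-read weights do not sum to 1")
    tab <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                      start = GenomicRanges::start(gr) - 1L,
                      end = GenomicRanges::end(gr),
                      read_id = mc$read_id,
                      weight = sprintf("%.6f", mc$weight),
                      strand = as.character(GenomicRanges::strand(gr)),
                      mismatches = mc$mismatches)
    ok <- tryCatch({
        write.table(tab, path, sep = "\t", quote = FALSE,
                    row.names = FALSE, col.names = FALSE)
        TRUE
    }, error = function(e) stop("cannot write '", path, "': ",
                                conditionMessage(e)))
    invisible(path)
}

#' Read weighted alignments written by writeWeightedAlignments
#'
#' @param path file path.
#' @return a weighted \code{ReadAlignments}.
#' @export
readWeightedAlignments <- function(path) {
    tab <- read.table(path, sep = "\t", stringsAsFactors = FALSE,
                      col.names = c("chrom", "start", "end", "read_id",
                                    "weight", "strand", "mismatches"))
    df <- data.frame(read_id = tab$read_id, chrom = tab$chrom,
                     start = tab$start + 1L, width = tab$end - tab$start,
                     strand = tab$strand, mismatches = tab$mismatches,
                     stringsAsFactors = FALSE)
    x <- .buildReadAlignments(df, maxHits = .Machine$integer.max,
                              maxMismatches = .Machine$integer.max,
                              weights = as.numeric(tab$weight),
                              weighted = TRUE)
    mc <- S4Vectors::mcols(alignments(x))
    s <- rowsum(mc$weight, mc$read_id)
    if (any(abs(s - 1) > 1e-5))
        stop("weight conservation violated in '", path, "'")
    x
}

#' Export pseudo-reads for uni-read-only tools
#'
#' Converts weighted alignments into an unweighted alignment set usable by
#' software that cannot handle fractional counts: uni-reads pass through
#' unchanged, and each multi-read is emitted at most once, at its
#' maximum-weight location, only when that maximum weight rounds up to 1
#' (i.e. is at least 0.5).  Ties at the maximum are broken deterministically
#' by smallest (chromosome, start) so a read is never emitted twice.
#'
#' @param x a weighted \code{ReadAlignments}.
#' @param path optional output path for a 6-column BED-like file (chrom,
#'   0-based start, end, read id, mismatches, strand).
#' @return \code{GRanges} of the exported alignments (metadata column
#'   \code{read_id}), invisibly when \code{path} is given.
#' @export
exportPseudoReads <- function(x, path = NULL) {
    stopifnot(is(x, "ReadAlignments"))
    if (!isWeighted(x)) stop("alignments are not weighted")
    gr <- alignments(x)
    mc <- S4Vectors::mcols(gr)
    id <- mc$read_id
    w <- mc$weight
    chrom <- as.character(GenomicRanges::seqnames(gr))
    st <- GenomicRanges::start(gr)
    # order so that within a read the best candidate comes first:
    # weight descending, then chrom, then start ascending
    ord <- order(id, -w, chrom, st)
    first <- !duplicated(id[ord])
    best <- ord[first]
    keep <- best[w[best] >= 0.5]
    out <- gr[sort(keep)]
    S4Vectors::mcols(out) <- S4Vectors::mcols(out)[c("read_id", "mismatches")]
    if (!is.null(path)) {
        tab <- data.frame(chrom = as.character(GenomicRanges::seqnames(out)),
                          start = GenomicRanges::start(out) - 1L,
                          end = GenomicRanges::end(out),
                          read_id = S4Vectors::mcols(out)$read_id,
                          mismatches = S4Vectors::mcols(out)$mismatches,
                          strand = as.character(GenomicRanges::strand(out)))
        write.table(tab, path, sep = "\t", quote = FALSE,
                    row.names = FALSE, col.names = FALSE)
        return(invisible(out))
    }
    out
}

#' Read a BED interval file
#'
#' Thin wrapper over \code{rtracklayer::import} returning a \code{GRanges}
#' with a \code{label} metadata column (BED name field).  Coordinates are
#' validated: negative or inverted intervals are an error.
#'
#' @param path BED file path.
#' @return \code{GRanges} with a \code{label} column.
#' @export
readIntervals <- function(path) {
    raw <- tryCatch(read.table(path, sep = "\t", stringsAsFactors = FALSE),
                    error = function(e) stop("cannot parse BED file '", path,
                                             "': ", conditionMessage(e)))
    if (ncol(raw) < 3L) stop("BED file needs at least 3 columns")
    if (any(raw[[2L]] < 0L)) stop("negative coordinate in ", path)
    if (any(raw[[3L]] <= raw[[2L]])) stop("inverted/empty interval in ", path)
    gr <- rtracklayer::import(path, format = "BED")
    lab <- S4Vectors::mcols(gr)$name
    if (is.null(lab)) lab <- rep(NA_character_, length(gr))
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(label = lab)
    gr
}

#' Write a GRanges as BED
#'
#' @param gr \code{GRanges}; a \code{label} (or \code{name}) metadata column
#'   becomes the BED name field.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeIntervals <- function(gr, path) {
    stopifnot(is(gr, "GRanges"))
    out <- gr
    mc <- S4Vectors::mcols(out)
    nm <- if (!is.null(mc$label)) mc$label else mc$name
    if (is.null(nm)) nm <- rep(".", length(out))
    S4Vectors::mcols(out) <- S4Vectors::DataFrame(name = nm)
    rtracklayer::export(out, path, format = "BED")
    invisible(path)
}
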