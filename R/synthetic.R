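#' Simulate a genome with segmental duplications
#'
#' Draws i.i.d. bases for each chromosome, then copies the requested blocks
#' to their target locations with a per-base substitution rate of
#' \code{1 - identity}, emulating segmental duplications (repeats of at least
#' 1 kb with at least 90\% identity to another locus).  Blocks shorter than
#' 1 kb or with identity below 0.9 are allowed but trigger a warning, since
#' they would not qualify as segmental duplications.
#'
#' @param chromLengths named integer vector of chromosome lengths (bp).
#' @param duplications optional data.frame with columns \code{chrom},
#'   \code{start}, \code{width}, \code{target_chrom}, \code{target_start},
#'   \code{identity}; each row copies \code{[start, start+width-1]} of
#'   \code{chrom} over the same-width window at the target.  Overlapping
#'   target placements are an error.
#' @param baseProbs probabilities for A, C, G, T (default uniform).
#' @param seed integer seed; the same seed reproduces the same genome.
#' @return list with \code{genome} (\code{DNAStringSet}) and \code{segdups}
#'   (\code{GRanges} of both copies of every block, metadata columns
#'   \code{label} pairing the copies and \code{identity}).
#' @export
simulateGenome <- function(chromLengths, duplications = NULL,
                           baseProbs = c(A = .25, C = .25, G = .25, T = .25),
                           seed = 1L) {
    stopifnot(!is.null(names(chromLengths)), all(chromLengths > 0))
    set.seed(seed)
    bases <- c("A", "C", "G", "T")
    seqs <- lapply(chromLengths, function(len)
        sample(bases, len, replace = TRUE, prob = baseProbs))
    segdups <- GenomicRanges::GRanges()
    if (!is.null(duplications) && nrow(duplications)) {
        d <- duplications
        need <- c("chrom", "start", "width", "target_chrom",
                  "target_start", "identity")
        stopifnot(all(need %in% names(d)))
        if (any(d$width < 1000L))
            warning("duplication block(s) shorter than 1 kb do not qualify ",
                    "as segmental duplications")
        if (any(d$identity < 0.9))
            warning("duplication identity below 0.9 does not qualify as a ",
                    "segmental duplication")
        tgt <- GenomicRanges::GRanges(d$target_chrom,
            IRanges::IRanges(d$target_start, width = d$width))
        if (length(GenomicRanges::findOverlaps(tgt, drop.self = TRUE)))
            stop("overlapping duplication target placements")
        for (i in seq_len(nrow(d))) {
            if (d$start[i] < 1L ||
                d$start[i] + d$width[i] - 1L > chromLengths[[d$chrom[i]]] ||
                d$target_start[i] < 1L ||
                d$target_start[i] + d$width[i] - 1L >
                    chromLengths[[d$target_chrom[i]]])
                stop("duplication block ", i, " outside the genome")
            src <- seqs[[d$chrom[i]]][d$start[i]:(d$start[i] + d$width[i] - 1L)]
            nsub <- rbinom(1L, d$width[i], 1 - d$identity[i])
            if (nsub > 0L) {
                at <- sample.int(d$width[i], nsub)
                src[at] <- vapply(src[at], function(b)
                    sample(setdiff(bases, b), 1L), character(1))
            }
            seqs[[d$target_chrom[i]]][
                d$target_start[i]:(d$target_start[i] + d$width[i] - 1L)] <- src
        }
        lab <- sprintf("dup%d", seq_len(nrow(d)))
        segdups <- GenomicRanges::GRanges(
            c(d$chrom, d$target_chrom),
            IRanges::IRanges(c(d$start, d$target_start),
                             width = rep(d$width, 2L)))
        S4Vectors::mcols(segdups)$label <- rep(lab, 2L)
        S4Vectors::mcols(segdups)$identity <- rep(d$identity, 2L)
    }
    genome <- Biostrings::DNAStringSet(
        vapply(seqs, paste, character(1), collapse = ""))
    names(genome) <- names(chromLengths)
    list(genome = genome, segdups = segdups)
}

.seqlens <- function(genome) setNames(Biostrings::width(genome),
                                      names(genome))

#' Simulate a ChIP-seq experiment with planted peaks
#'
#' Fragments of length \code{fragLength} are drawn from a mixture of planted
#' peak components and a uniform background: with probability proportional to
#' \code{(rate - 1) * width(peak)} a fragment is centered uniformly inside a
#' peak (so the read density inside a peak is \code{rate} times the flanking
#' background density); otherwise its start is uniform over the genome.  A
#' read is the first \code{readLength} bases of the fragment on a uniformly
#' chosen strand.  The matched input sample has uniform fragment origins
#' throughout.  Exactly \code{depth} ChIP reads and \code{inputDepth} input
#' reads are emitted.
#'
#' @param genome \code{DNAStringSet}.
#' @param peaks \code{GRanges} of planted binding sites with a numeric
#'   \code{rate} metadata column (fold-enrichment over background); may be
#'   empty.
#' @param depth number of ChIP reads.
#' @param readLength tag length k (bp, default 36).
#' @param fragLength fragment length L (bp, default 200; must be >= k).
#' @param errorRate i.i.d. per-base substitution error rate (default 0 so
#'   alignment-ambiguity structure is exact).
#' @param inputDepth number of input reads (default \code{depth}).
#' @param seed integer seed.
#' @return list with \code{chip} and \code{input} (\code{DNAStringSet} of
#'   reads, names = read ids) and \code{truth}: a list holding the planted
#'   \code{peaks}, per-read origin data.frames (\code{chip_origins},
#'   \code{input_origins}: read id, chrom, fragment start, strand,
#'   component), \code{fragLength} and \code{readLength}.
#' @export
simulateChipSeq <- function(genome, peaks, depth, readLength = 36L,
                            fragLength = 200L, errorRate = 0,
                            inputDepth = depth, seed = 1L) {
    stopifnot(fragLength >= readLength)
    lens <- .seqlens(genome)
    if (length(peaks)) {
        bad <- as.character(GenomicRanges::seqnames(peaks)) %in% names(lens)
        if (!all(bad)) stop("peak on unknown chromosome")
        if (any(GenomicRanges::end(peaks) >
                lens[as.character(GenomicRanges::seqnames(peaks))]) ||
            any(GenomicRanges::start(peaks) < 1L))
            stop("planted peak outside the genome")
        if (is.null(S4Vectors::mcols(peaks)$rate))
            stop("peaks need a 'rate' metadata column")
    }
    set.seed(seed)
    chip <- .simulateSample(genome, peaks, depth, readLength, fragLength,
                            errorRate, prefix = "chip")
    inp <- .simulateSample(genome, peaks[0], inputDepth, readLength,
                           fragLength, errorRate, prefix = "input")
    list(chip = chip$reads, input = inp$reads,
         truth = list(peaks = peaks, chip_origins = chip$origins,
                      input_origins = inp$origins,
                      fragLength = as.integer(fragLength),
                      readLength = as.integer(readLength)))
}

.simulateSample <- function(genome, peaks, depth, k, L, errorRate, prefix) {
    lens <- .seqlens(genome)
    valid <- pmax(lens - L + 1L, 0L)      # fragment must fit the chromosome
    npk <- length(peaks)
    rate <- if (npk) S4Vectors::mcols(peaks)$rate else numeric()
    wts <- c(sum(valid), if (npk) (rate - 1) * GenomicRanges::width(peaks))
    comp <- sample.int(npk + 1L, depth, replace = TRUE,
                       prob = wts / sum(wts)) - 1L   # 0 = background
    chrom <- character(depth); fs <- integer(depth)
    bg <- comp == 0L
    if (any(bg)) {
        ch_i <- sample.int(length(lens), sum(bg), replace = TRUE,
                           prob = valid / sum(valid))
        chrom[bg] <- names(lens)[ch_i]
        fs[bg] <- as.integer(floor(runif(sum(bg)) * valid[ch_i])) + 1L
    }
    for (i in seq_len(npk)) {
        sel <- comp == i
        if (!any(sel)) next
        ch <- as.character(GenomicRanges::seqnames(peaks)[i])
        ctr <- GenomicRanges::start(peaks)[i] +
            floor(runif(sum(sel)) * GenomicRanges::width(peaks)[i])
        s <- as.integer(round(ctr - L / 2))
        s <- pmin(pmax(s, 1L), valid[[ch]])
        chrom[sel] <- ch
        fs[sel] <- s
    }
    strand <- sample(c("+", "-"), depth, replace = TRUE)
    ids <- sprintf("%s_%06d", prefix, seq_len(depth))
    seqs <- character(depth)
    for (ch in unique(chrom)) {
        sel <- chrom == ch
        s <- fs[sel]; str <- strand[sel]
        rs <- ifelse(str == "+", s, s + L - k)
        v <- Biostrings::extractAt(genome[[ch]],
            IRanges::IRanges(rs, width = k))
        v <- as.character(v)
        rev <- str == "-"
        if (any(rev))
            v[rev] <- as.character(Biostrings::reverseComplement(
                Biostrings::DNAStringSet(v[rev])))
        seqs[sel] <- v
    }
    if (errorRate > 0) {
        m <- matrix(unlist(strsplit(seqs, "")), nrow = k)
        err <- matrix(runif(length(m)) < errorRate, nrow = k)
        if (any(err)) {
            bases <- c("A", "C", "G", "T")
            m[err] <- vapply(m[err],
                function(b) sample(setdiff(bases, b), 1L), character(1))
            seqs <- apply(m, 2L, paste, collapse = "")
        }
    }
    reads <- Biostrings::DNAStringSet(seqs)
    names(reads) <- ids
    origins <- data.frame(read_id = ids, chrom = chrom, frag_start = fs,
                          strand = strand,
                          component = ifelse(comp == 0L, "background",
                                             sprintf("peak%d", comp)),
                          stringsAsFactors = FALSE)
    list(reads = reads, origins = origins)
}

#' Toy exhaustive multi-mapper
#'
#' Reports every alignment of each read against both strands of the genome
#' with at most \code{maxMismatches} substitutions, then applies the
#' standard filters (reads with \code{maxHits} or more alignments dropped).
#' Intended for desk-scale synthetic genomes, as a stand-in for a report-all
#' short-read aligner; it agrees with a position-by-position brute-force
#' scan.  With \code{maxMismatches = 0} a constant-width dictionary match is
#' used; otherwise each read is scanned individually.
#'
#' @param reads named \code{DNAStringSet} of constant-width tags.
#' @param genome \code{DNAStringSet}.
#' @param maxMismatches maximum substitutions per alignment (default 0).
#' @param maxHits multi-read cap (default 100).
#' @return a \code{\linkS4class{ReadAlignments}}; reads with no alignment
#'   are simply absent.
#' @export
exactMultiMap <- function(reads, genome, maxMismatches = 0L, maxHits = 100L) {
    stopifnot(length(unique(Biostrings::width(reads))) <= 1L)
    if (is.null(names(reads))) names(reads) <- sprintf("r%06d",
                                                       seq_along(reads))
    k <- if (length(reads)) Biostrings::width(reads)[1L] else 0L
    if (k > min(Biostrings::width(genome)))
        stop("read length exceeds the shortest chromosome")
    hits <- if (maxMismatches == 0L)
        .mapExact(reads, genome, k) else
        .mapMismatch(reads, genome, k, maxMismatches)
    .buildReadAlignments(hits, maxHits = as.integer(maxHits),
                         maxMismatches = as.integer(maxMismatches))
}

.mapExact <- function(reads, genome, k) {
    fwd <- Biostrings::PDict(reads)
    rev <- Biostrings::PDict(Biostrings::reverseComplement(reads))
    out <- vector("list", 2L * length(genome))
    j <- 0L
    for (ch in names(genome)) {
        subj <- genome[[ch]]
        for (strand in c("+", "-")) {
            m <- Biostrings::matchPDict(if (strand == "+") fwd else rev, subj)
            cnt <- S4Vectors::elementNROWS(m)
            if (sum(cnt) == 0L) next
            st <- unlist(IRanges::start(m), use.names = FALSE)
            j <- j + 1L
            out[[j]] <- data.frame(
                read_id = rep(names(reads), cnt), chrom = ch,
                start = st, width = k, strand = strand,
                mismatches = 0L, stringsAsFactors = FALSE)
        }
    }
    if (j == 0L)
        return(data.frame(read_id = character(), chrom = character(),
                          start = integer(), width = integer(),
                          strand = character(), mismatches = integer()))
    do.call(rbind, out[seq_len(j)])
}

.mapMismatch <- function(reads, genome, k, mm) {
    res <- list(); j <- 0L
    for (ch in names(genome)) {
        subj <- genome[[ch]]
        for (i in seq_along(reads)) {
            for (strand in c("+", "-")) {
                pat <- if (strand == "+") reads[[i]] else
                    Biostrings::reverseComplement(reads[[i]])
                m <- Biostrings::matchPattern(pat, subj, max.mismatch = mm)
                if (length(m) == 0L) next
                st <- IRanges::start(m)
                nm <- Biostrings::neditStartingAt(pat, subj, starting.at = st,
                                                  with.indels = FALSE)
                j <- j + 1L
                res[[j]] <- data.frame(read_id = names(reads)[i], chrom = ch,
                                       start = st, width = k, strand = strand,
                                       mismatches = as.integer(nm),
                                       stringsAsFactors = FALSE)
            }
        }
    }
    if (j == 0L)
        return(data.frame(read_id = character(), chrom = character(),
                          start = integer(), width = integer(),
                          strand = character(), mismatches = integer()))
    do.call(rbind, res)
}
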