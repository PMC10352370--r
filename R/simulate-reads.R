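## Read-pair simulation: mate-pair style fragments with truncated-normal
## inserts, emitted directly as paired-alignment records so concordance can
## be evaluated without an external aligner.

## Truncated normal insert sizes within insert_mean * (1 +/- insert_tol).
## sd is chosen as insert_mean*insert_tol/2 so the window is about +/- 2 sd.
drawInserts <- function(n, insert_mean, insert_tol) {
    lo <- ceiling(insert_mean * (1 - insert_tol))
    hi <- floor(insert_mean * (1 + insert_tol))
    out <- integer(0)
    while (length(out) < n) {
        x <- as.integer(round(stats::rnorm(n - length(out), insert_mean,
                                           insert_mean * insert_tol / 2)))
        out <- c(out, x[x >= lo & x <= hi])
    }
    out[seq_len(n)]
}

#' Simulate read pairs along sequences
#'
#' Draws pairs uniformly along each sequence at the requested fold coverage
#' (pair counts per sequence are Poisson with mean
#' \code{len * coverage / (2 * read_len)}), with inserts from a truncated
#' normal confined to \code{insert_mean * (1 +/- insert_tol)} and mates in
#' convergent (FR) orientation. Records carry both mate positions so
#' concordance can be evaluated directly. Optionally writes a FASTQ pair
#' (Phred+33, fixed Q30) when \code{fastq_prefix} is given and \code{seqs}
#' holds sequences rather than lengths.
#'
#' @param seqs named \link[Biostrings]{DNAStringSet} or named integer vector
#'   of sequence lengths.
#' @param cfg a \linkS4class{SimConfig} (read_len, insert model, coverage,
#'   seed).
#' @param fastq_prefix optional path prefix; writes
#'   \code{<prefix>_1.fastq} / \code{<prefix>_2.fastq}.
#' @return data.frame of paired records (read_id, seq_id, pos1, strand1,
#'   pos2, strand2, insert), 0-based leftmost mate positions.
#' @export
simulateReadPairs <- function(seqs, cfg, fastq_prefix = NULL) {
    methods::validObject(cfg)
    if (cfg@coverage <= 0) stopf("coverage must be > 0")
    if (cfg@insert_mean <= 2L * cfg@read_len)
        stopf("insert_mean must exceed 2 * read_len")
    lens <- if (is.numeric(seqs)) as.integer(seqs)
            else BiocGenerics::width(seqs)
    names(lens) <- names(seqs)
    set.seed(childSeed(cfg@seed, 4L))
    recs <- list()
    for (ch in names(lens)) {
        n <- stats::rpois(1L, lens[[ch]] * cfg@coverage / (2 * cfg@read_len))
        if (!n) next
        ins <- drawInserts(n, cfg@insert_mean, cfg@insert_tol)
        ok <- ins <= lens[[ch]]
        ins <- ins[ok]
        if (!length(ins)) next
        p1 <- vapply(lens[[ch]] - ins,
                     function(m) if (m == 0L) 0L else sampleInt(m + 1L, 1L) - 1L,
                     0L)
        recs[[ch]] <- data.frame(
            read_id = sprintf("%s_p%06d", ch, seq_along(ins)),
            seq_id = ch, pos1 = p1, strand1 = "+",
            pos2 = p1 + ins - cfg@read_len, strand2 = "-",
            insert = ins, stringsAsFactors = FALSE)
    }
    pairs <- if (length(recs)) do.call(rbind, recs) else emptyPairs()
    rownames(pairs) <- NULL
    if (!is.null(fastq_prefix)) {
        if (is.numeric(seqs))
            stopf("FASTQ output needs sequences, not lengths")
        writePairFastq(pairs, seqs, cfg@read_len, fastq_prefix)
    }
    pairs
}

writePairFastq <- function(pairs, seqs, read_len, prefix) {
    qual <- strrep(rawToChar(as.raw(30L + 33L)), read_len)
    con1 <- file(paste0(prefix, "_1.fastq"), "w")
    con2 <- file(paste0(prefix, "_2.fastq"), "w")
    on.exit({ close(con1); close(con2) })
    schr <- as.character(seqs)
    for (i in seq_len(nrow(pairs))) {
        s <- schr[[pairs$seq_id[i]]]
        r1 <- substring(s, pairs$pos1[i] + 1L, pairs$pos1[i] + read_len)
        r2 <- revcompChr(substring(s, pairs$pos2[i] + 1L,
                                   pairs$pos2[i] + read_len))
        writeLines(c(paste0("@", pairs$read_id[i], "/1"), r1, "+", qual), con1)
        writeLines(c(paste0("@", pairs$read_id[i], "/2"), r2, "+", qual), con2)
    }
    invisible(prefix)
}

#' Simulate read pairs on contigs from the truth placements
#'
#' Draws pairs within each contiguous source part of every contig, in contig
#' coordinates. Because a chimeric contig joins two fragments that are not
#' adjacent in the true sample genome, no emitted pair ever spans a planted
#' misjoin - such fragments are physically impossible - while every true
#' junction inside a contig receives ordinary spanning coverage.
#'
#' @param truth \linkS4class{TruthSet} with placements.
#' @param cfg a \linkS4class{SimConfig}.
#' @return data.frame of paired records in contig coordinates.
#' @export
simulatePairsFromTruth <- function(truth, cfg) {
    methods::validObject(cfg)
    if (cfg@coverage <= 0) stopf("coverage must be > 0")
    set.seed(childSeed(cfg@seed, 5L))
    pl <- truth@placements
    recs <- list()
    for (i in seq_len(nrow(pl))) {
        L <- pl$q_end[i] - pl$q_start[i]
        n <- stats::rpois(1L, L * cfg@coverage / (2 * cfg@read_len))
        if (!n) next
        ins <- drawInserts(n, cfg@insert_mean, cfg@insert_tol)
        ins <- ins[ins <= L]
        if (!length(ins)) next
        rel <- vapply(L - ins,
                      function(m) if (m == 0L) 0L else sampleInt(m + 1L, 1L) - 1L,
                      0L)
        p1 <- pl$q_start[i] + rel
        recs[[length(recs) + 1L]] <- data.frame(
            read_id = sprintf("%s_part%d_p%06d", pl$contig_id[i], pl$part[i],
                              seq_along(ins)),
            seq_id = pl$contig_id[i], pos1 = p1, strand1 = "+",
            pos2 = p1 + ins - cfg@read_len, strand2 = "-",
            insert = ins, stringsAsFactors = FALSE)
    }
    pairs <- if (length(recs)) do.call(rbind, recs) else emptyPairs()
    rownames(pairs) <- NULL
    pairs
}
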