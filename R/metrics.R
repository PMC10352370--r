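## Self-contained assembly and library statistics ("QUAST-lite").

#' N50 of a set of sequence lengths
#'
#' The length L, itself a member of the input, such that sequences of length
#' at least L contain at least half of all bases (sorted-descending
#' cumulative rule, boundary at >= half).
#'
#' @param lengths numeric vector of sequence lengths.
#' @return N50 in bases.
#' @examples
#' n50(c(5, 4, 3, 2, 1))  # cumulative 5, 9 >= 7.5 -> 4
#' @export
n50 <- function(lengths) {
    if (!length(lengths)) stopf("n50 of an empty length set is undefined")
    s <- sort(as.numeric(lengths), decreasing = TRUE)
    s[which(cumsum(s) >= sum(s) / 2)[1]]
}

#' Whole-assembly statistics
#'
#' Sequence counts and sizes, N50, the count and base fraction of sequences
#' longer than 100 kb (strictly greater), and gap (N-run) counts and totals.
#'
#' @param seqs \link[Biostrings]{DNAStringSet}.
#' @return list with n_sequences, total_len, n50, largest, n_over_100kb,
#'   frac_bases_over_100kb, gap_count, gap_total.
#' @export
assemblyStats <- function(seqs) {
    if (!length(seqs)) stopf("empty assembly")
    w <- as.numeric(BiocGenerics::width(seqs))
    gap_count <- 0L
    gap_total <- 0
    for (i in seq_along(seqs)) {
        nr <- Biostrings::matchPattern("N", seqs[[i]])
        if (length(nr)) {
            runs <- IRanges::reduce(methods::as(nr, "IRanges"))
            gap_count <- gap_count + length(runs)
            gap_total <- gap_total + sum(as.numeric(BiocGenerics::width(runs)))
        }
    }
    over <- w > 100000
    list(n_sequences = length(w), total_len = sum(w), n50 = n50(w),
         largest = max(w), n_over_100kb = sum(over),
         frac_bases_over_100kb = sum(w[over]) / sum(w),
         gap_count = gap_count, gap_total = gap_total)
}

#' Library base totals
#'
#' For a fixed-length paired library, total bases = pairs x 2 x read length.
#' (Variable-length, trimmed libraries are not reproducible from counts
#' alone; supply their printed totals to \code{\link{libraryTable}}.)
#'
#' @param read_pairs number of read pairs.
#' @param read_len bases per mate.
#' @return total bases (numeric, exact for counts beyond integer range).
#' @examples
#' libraryStats(574495990, 90)
#' @export
libraryStats <- function(read_pairs, read_len) {
    if (read_pairs < 0 || read_len < 0)
        stopf("counts must be non-negative")
    as.numeric(read_pairs) * 2 * as.numeric(read_len)
}

#' Totals over a library table
#'
#' Each row describes a library by \code{read_pairs} and \code{read_len}
#' (fixed-length libraries, totals computed) or by a supplied
#' \code{total_bases} (variable-length or single-end libraries). Returns the
#' per-row totals and the grand total.
#'
#' @param rows data.frame with columns \code{library}, and either
#'   \code{read_pairs} + \code{read_len} or \code{total_bases}.
#' @return list: \code{rows} (with a filled \code{total_bases} column) and
#'   \code{total} (grand total bases).
#' @export
libraryTable <- function(rows) {
    if (!"total_bases" %in% names(rows)) rows$total_bases <- NA_real_
    for (i in seq_len(nrow(rows))) {
        if (is.na(rows$total_bases[i]))
            rows$total_bases[i] <- libraryStats(rows$read_pairs[i],
                                                rows$read_len[i])
    }
    list(rows = rows, total = sum(rows$total_bases))
}

#' Fraction of the reference covered by alignment blocks
#'
#' Union of the target spans divided by total reference length; overlapping
#' blocks count once.
#'
#' @param blocks alignment blocks (data.frame).
#' @param reference \link[Biostrings]{DNAStringSet} or named numeric vector
#'   of chromosome lengths.
#' @return fraction in [0, 1].
#' @export
genomeFraction <- function(blocks, reference) {
    lens <- if (is.numeric(reference)) reference
            else stats::setNames(as.numeric(BiocGenerics::width(reference)),
                                 names(reference))
    covered <- 0
    for (ch in names(lens)) {
        sub <- blocks[blocks$target_id == ch, , drop = FALSE]
        if (nrow(sub))
            covered <- covered + intervalUnionWidth0(sub$t_start, sub$t_end)
    }
    covered / sum(lens)
}

#' Classify feature coverage by an assembly
#'
#' A feature is \code{complete} when its span lies fully inside the union of
#' the aligned target spans, \code{partial} when it intersects the union
#' without being contained, and \code{missing} otherwise; counts are
#' reported per feature type.
#'
#' @param features data.frame from \code{\link{readGff3}} in reference
#'   coordinates.
#' @param blocks alignment blocks on the same reference.
#' @return list: \code{per_feature} (data.frame with a \code{status}
#'   column) and \code{summary} (data.frame type, complete, partial,
#'   missing).
#' @export
featureCoverage <- function(features, blocks) {
    status <- character(nrow(features))
    for (ch in unique(features$seq_id)) {
        fidx <- which(features$seq_id == ch)
        sub <- blocks[blocks$target_id == ch, , drop = FALSE]
        if (!nrow(sub)) {
            status[fidx] <- "missing"
            next
        }
        u <- intervalUnion0(sub$t_start, sub$t_end)
        uir <- asIRanges0(u$start, u$end)
        fir <- asIRanges0(features$start[fidx], features$end[fidx])
        inside <- IRanges::overlapsAny(fir, uir, type = "within")
        touches <- IRanges::overlapsAny(fir, uir)
        status[fidx] <- ifelse(inside, "complete",
                               ifelse(touches, "partial", "missing"))
    }
    per <- cbind(features, status = status, stringsAsFactors = FALSE)
    types <- unique(features$type)
    summ <- data.frame(
        type = types,
        complete = vapply(types, function(t)
            sum(per$type == t & per$status == "complete"), 0L),
        partial = vapply(types, function(t)
            sum(per$type == t & per$status == "partial"), 0L),
        missing = vapply(types, function(t)
            sum(per$type == t & per$status == "missing"), 0L),
        stringsAsFactors = FALSE, row.names = NULL)
    list(per_feature = per, summary = summ)
}
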