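## Contig filtration, misassembly breakpoint classification, read-pair
## concordance validation, and contig splitting.

#' Filter contig alignments before chromosome construction
#'
#' Excludes contigs shorter than \code{min_contig_len} (a contig of exactly
#' the threshold is kept) and removes every alignment whose target span lies
#' completely within the target span of an alignment of a larger contig.
#' A contig whose alignments are all removed this way is excluded as
#' contained.
#'
#' @param blocks alignment blocks (data.frame, see \code{\link{readPaf}}).
#' @param cfg a \linkS4class{BuilderConfig}.
#' @return list: \code{kept} (blocks data.frame), \code{excluded}
#'   (data.frame contig_id, reason) and \code{removed_blocks} (row indices of
#'   \code{blocks} dropped by containment).
#' @export
filterAlignments <- function(blocks, cfg = builderConfig()) {
    if (!nrow(blocks))
        return(list(kept = blocks,
                    excluded = data.frame(contig_id = character(),
                                          reason = character()),
                    removed_blocks = integer()))
    validatePaf(blocks)
    excluded <- data.frame(contig_id = character(), reason = character(),
                           stringsAsFactors = FALSE)
    short_ids <- unique(blocks$query_id[blocks$query_len < cfg@min_contig_len])
    if (length(short_ids))
        excluded <- rbind(excluded, data.frame(contig_id = short_ids,
                                               reason = "short"))
    keep <- !(blocks$query_id %in% short_ids)
    bl <- blocks[keep, , drop = FALSE]

    ## containment: target span inside the span of a larger contig's block
    drop <- logical(nrow(bl))
    for (tg in unique(bl$target_id)) {
        idx <- which(bl$target_id == tg)
        ir <- asIRanges0(bl$t_start[idx], bl$t_end[idx])
        ov <- IRanges::findOverlaps(ir, ir, type = "within")
        qh <- idx[S4Vectors::queryHits(ov)]
        sh <- idx[S4Vectors::subjectHits(ov)]
        contained <- bl$query_id[qh] != bl$query_id[sh] &
            bl$query_len[qh] < bl$query_len[sh]
        drop[unique(qh[contained])] <- TRUE
    }
    gone <- setdiff(unique(bl$query_id[drop]), unique(bl$query_id[!drop]))
    if (length(gone))
        excluded <- rbind(excluded, data.frame(contig_id = gone,
                                               reason = "contained"))
    kept <- bl[!drop, , drop = FALSE]
    rownames(kept) <- NULL
    list(kept = kept, excluded = excluded,
         removed_blocks = which(keep)[drop])
}

## distance between two 0-based half-open target spans (0 when overlapping)
refGap <- function(s1, e1, s2, e2) {
    max(0L, max(s1, s2) - min(e1, e2))
}

#' Classify a contig's mapping and nominate breakpoints
#'
#' A contig maps in one of three classes: \code{single} (one alignment, or
#' several consecutive alignments close together on one chromosome),
#' \code{multi_same_chrom_far} (multiple segments on one chromosome whose
#' reference gap exceeds \code{far_distance}), or \code{multi_diff_chrom}
#' (alignments on different chromosomes). For every adjacent query-segment
#' pair that is far apart or on different chromosomes, one candidate
#' breakpoint is nominated at the midpoint of the unaligned query interval
#' between the segments (at the shared coordinate when the segments abut).
#'
#' @param blocks alignment blocks of one contig.
#' @param cfg a \linkS4class{BuilderConfig}.
#' @return list: \code{contig_id}, \code{mapping_class}, \code{breakpoints}
#'   (data.frame contig_id, q_pos, left_target, right_target, pair_class).
#' @export
classifyContig <- function(blocks, cfg = builderConfig()) {
    stopifnot(nrow(blocks) >= 1L)
    if (length(unique(blocks$query_id)) != 1L)
        stopf("classifyContig expects blocks of a single contig")
    id <- blocks$query_id[1]
    bl <- blocks[order(blocks$q_start, blocks$q_end), , drop = FALSE]
    bps <- data.frame(contig_id = character(), q_pos = integer(),
                      left_target = character(), right_target = character(),
                      pair_class = character(), stringsAsFactors = FALSE)
    cls <- "single"
    if (nrow(bl) > 1L) {
        for (i in seq_len(nrow(bl) - 1L)) {
            l <- bl[i, ]; r <- bl[i + 1L, ]
            pair_class <- if (l$target_id != r$target_id) "multi_diff_chrom"
            else if (refGap(l$t_start, l$t_end, r$t_start, r$t_end) >
                         cfg@far_distance) "multi_same_chrom_far"
            else NA_character_
            if (!is.na(pair_class)) {
                q_pos <- as.integer(floor((l$q_end + r$q_start) / 2))
                q_pos <- max(1L, min(q_pos, l$query_len - 1L))
                bps <- rbind(bps, data.frame(
                    contig_id = id, q_pos = q_pos,
                    left_target = l$target_id, right_target = r$target_id,
                    pair_class = pair_class, stringsAsFactors = FALSE))
            }
        }
        if (any(bps$pair_class == "multi_diff_chrom")) cls <- "multi_diff_chrom"
        else if (any(bps$pair_class == "multi_same_chrom_far"))
            cls <- "multi_same_chrom_far"
    }
    list(contig_id = id, mapping_class = cls, breakpoints = bps)
}

#' Validate a candidate breakpoint against read-pair concordance
#'
#' A pair is concordant when both mates map to the same contig in convergent
#' (FR) orientation with an insert inside
#' \code{insert_mean * (1 +/- insert_tol)}. The support for a breakpoint is
#' the number of concordant pairs whose insert physically spans it (first
#' mate ends before the breakpoint, second mate starts after it). A junction
#' is kept when support reaches \code{min_support}; with fewer spanning
#' concordant pairs - in particular none at all - the verdict is
#' \code{split}.
#'
#' @param call one row of a breakpoint table (contig_id, q_pos).
#' @param pairs paired records (see \code{\link{readPairedAlignments}}).
#' @param cfg a \linkS4class{BuilderConfig}.
#' @param contig_len contig length, for the coordinate check (optional).
#' @return the call as a one-row data.frame with added
#'   \code{concordant_support}, \code{discordant_or_zero} and \code{verdict}.
#' @export
validateBreakpoint <- function(call, pairs, cfg = builderConfig(),
                               contig_len = NULL) {
    q_pos <- call$q_pos
    if (!is.null(contig_len) && (q_pos <= 0L || q_pos >= contig_len))
        stopf("breakpoint at %d outside contig %s", q_pos, call$contig_id)
    sub <- pairs[pairs$seq_id == call$contig_id, , drop = FALSE]
    lo <- cfg@insert_mean * (1 - cfg@insert_tol)
    hi <- cfg@insert_mean * (1 + cfg@insert_tol)
    support <- 0L
    if (nrow(sub)) {
        read_len <- sub$insert - (sub$pos2 - sub$pos1)
        conc <- sub$strand1 == "+" & sub$strand2 == "-" &
            sub$pos2 >= sub$pos1 & sub$insert >= lo & sub$insert <= hi
        span <- conc & (sub$pos1 + read_len) < q_pos & q_pos < sub$pos2
        support <- sum(span)
    }
    out <- as.data.frame(call, stringsAsFactors = FALSE)
    out$concordant_support <- support
    out$discordant_or_zero <- support == 0L
    out$verdict <- if (support < cfg@min_support) "split" else "keep"
    out
}

#' Split contigs at confirmed breakpoints
#'
#' Every contig carrying at least one \code{split} verdict is replaced by
#' its pieces, named \code{<id>.1}, \code{<id>.2}, ... in coordinate order.
#' Total base count is conserved exactly.
#'
#' @param contigs \link[Biostrings]{DNAStringSet}.
#' @param verdicts data.frame with contig_id, q_pos, verdict.
#' @return \link[Biostrings]{DNAStringSet} of revised contigs.
#' @export
splitContigs <- function(contigs, verdicts) {
    splits <- verdicts[verdicts$verdict == "split", , drop = FALSE]
    if (!nrow(splits)) return(contigs)
    if (!all(splits$contig_id %in% names(contigs)))
        stopf("split verdict for unknown contig")
    out <- list()
    for (id in names(contigs)) {
        cuts <- sort(unique(splits$q_pos[splits$contig_id == id]))
        len <- BiocGenerics::width(contigs)[names(contigs) == id]
        if (!length(cuts)) {
            out[[id]] <- contigs[[id]]
            next
        }
        if (any(cuts <= 0L | cuts >= len))
            stopf("degenerate split of %s at contig boundary", id)
        edges <- c(0L, cuts, len)
        for (k in seq_len(length(edges) - 1L))
            out[[sprintf("%s.%d", id, k)]] <-
                Biostrings::subseq(contigs[[id]], edges[k] + 1L, edges[k + 1L])
    }
    Biostrings::DNAStringSet(out)
}

#' Rewrite alignment blocks after contig splitting
#'
#' Assigns each block of a split contig to the piece containing it and
#' shifts query coordinates into the piece frame; a block crossing a cut is
#' divided at the cut (target coordinates adjusted colinearly by strand).
#'
#' @param blocks alignment blocks.
#' @param verdicts data.frame with contig_id, q_pos, verdict.
#' @param contig_lens named integer vector of original contig lengths.
#' @return revised blocks data.frame.
#' @export
splitBlocks <- function(blocks, verdicts, contig_lens) {
    splits <- verdicts[verdicts$verdict == "split", , drop = FALSE]
    if (!nrow(splits)) return(blocks)
    rows <- list()
    for (i in seq_len(nrow(blocks))) {
        b <- blocks[i, ]
        cuts <- sort(unique(splits$q_pos[splits$contig_id == b$query_id]))
        if (!length(cuts)) {
            rows[[length(rows) + 1L]] <- b
            next
        }
        len <- contig_lens[[b$query_id]]
        edges <- c(0L, cuts, len)
        for (k in seq_len(length(edges) - 1L)) {
            s <- max(b$q_start, edges[k]); e <- min(b$q_end, edges[k + 1L])
            if (s >= e) next
            piece <- b
            piece$query_id <- sprintf("%s.%d", b$query_id, k)
            piece$query_len <- edges[k + 1L] - edges[k]
            piece$q_start <- s - edges[k]
            piece$q_end <- e - edges[k]
            ## colinear target trim
            if (b$strand == "+") {
                piece$t_start <- b$t_start + (s - b$q_start)
                piece$t_end <- b$t_start + (e - b$q_start)
            } else {
                piece$t_start <- b$t_start + (b$q_end - e)
                piece$t_end <- b$t_start + (b$q_end - s)
            }
            frac <- (e - s) / (b$q_end - b$q_start)
            piece$block_len <- e - s
            piece$n_match <- min(piece$block_len,
                                 as.integer(round(b$n_match * frac)))
            rows[[length(rows) + 1L]] <- piece
        }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}
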