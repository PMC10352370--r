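## Contig ordering along reference chromosomes, gap sizing, overlap merging,
## uncovered-region recovery, gap patching and unplaced-contig rescue.

## One placement per contig: the chromosome of its highest-n_match block
## (ties: lower t_start, then contig name), spanned by the chain of its
## blocks on that chromosome.
chainPlacements <- function(blocks, cfg = builderConfig()) {
    if (!nrow(blocks))
        return(data.frame(contig_id = character(), chrom = character(),
                          t_start = integer(), t_end = integer(),
                          strand = character(), stringsAsFactors = FALSE))
    ord <- order(-blocks$n_match, blocks$t_start, blocks$query_id)
    best <- blocks[ord, ][!duplicated(blocks$query_id[ord]), , drop = FALSE]
    rows <- lapply(seq_len(nrow(best)), function(i) {
        id <- best$query_id[i]; ch <- best$target_id[i]
        sub <- blocks[blocks$query_id == id & blocks$target_id == ch, ]
        data.frame(contig_id = id, chrom = ch,
                   t_start = min(sub$t_start), t_end = max(sub$t_end),
                   strand = best$strand[i], stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out[order(out$chrom, out$t_start, out$t_end, out$contig_id), ]
}

#' Flag contigs lying in complex structural-variation regions
#'
#' A region where three or more contig placements mutually overlap cannot be
#' ordered automatically; such contigs are flagged for manual review and
#' excluded from the automatic layout, mirroring a manual curation step.
#' For intervals, mutual pairwise overlap of three placements is equivalent
#' to a common covered position, so the flag is computed from coverage
#' depth.
#'
#' @param blocks alignment blocks (after filtration and splitting).
#' @param cfg a \linkS4class{BuilderConfig}.
#' @return character vector of flagged contig ids (possibly empty).
#' @export
flagComplex <- function(blocks, cfg = builderConfig()) {
    pl <- chainPlacements(blocks, cfg)
    flagged <- character()
    for (ch in unique(pl$chrom)) {
        sub <- pl[pl$chrom == ch, , drop = FALSE]
        if (nrow(sub) < 3L) next
        ir <- asIRanges0(sub$t_start, sub$t_end)
        cov <- IRanges::coverage(ir)
        deep <- IRanges::slice(cov, lower = 3L)
        if (!length(deep)) next
        deep_ir <- methods::as(deep, "IRanges")
        hit <- IRanges::findOverlaps(ir, deep_ir)
        flagged <- c(flagged, sub$contig_id[unique(S4Vectors::queryHits(hit))])
    }
    sort(unique(flagged))
}

#' Merge two overlapping placements
#'
#' The overlap suffix of the left (oriented) sequence is aligned globally to
#' the overlap prefix of the right one; at identity of at least
#' \code{overlap_merge_identity} the sequences are joined cutting at the
#' overlap midpoint (merged length = sum of lengths minus overlap), otherwise
#' they are left abutting with a zero-length gap and a conflict flag.
#'
#' @param left,right oriented \link[Biostrings]{DNAString} (or character)
#'   sequences as they will appear on the chromosome.
#' @param overlap reference overlap length in bases (> 0).
#' @param cfg a \linkS4class{BuilderConfig}.
#' @return list: \code{merged} (logical), \code{seq} (DNAString when merged),
#'   \code{identity}.
#' @export
mergeOverlapping <- function(left, right, overlap, cfg = builderConfig()) {
    left <- Biostrings::DNAString(as.character(left))
    right <- Biostrings::DNAString(as.character(right))
    o <- as.integer(overlap)
    stopifnot(o > 0L)
    if (o >= min(length(left), length(right)))
        stopf("overlap of %d covers a whole sequence: containment filtration should have removed this placement", o)
    sfx <- Biostrings::subseq(left, length(left) - o + 1L, length(left))
    pfx <- Biostrings::subseq(right, 1L, o)
    aln <- Biostrings::pairwiseAlignment(
        sfx, pfx, type = "global",
        substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
            match = 1, mismatch = -1),
        gapOpening = 4, gapExtension = 1)
    identity <- Biostrings::nmatch(aln) / o
    if (identity < cfg@overlap_merge_identity)
        return(list(merged = FALSE, seq = NULL, identity = identity))
    h <- o %/% 2L
    merged <- Biostrings::xscat(
        Biostrings::subseq(left, 1L, length(left) - o + h),
        Biostrings::subseq(right, h + 1L, length(right)))
    list(merged = TRUE, seq = merged, identity = identity)
}

#' Order contigs along chromosomes and size the gaps
#'
#' Contigs are placed in reference order. Between consecutive placements at
#' reference distance \code{d > 0} a gap of \code{round(gap_scale * d)} N
#' bases is recorded; abutting placements get no gap; overlapping placements
#' are merged sequence-level (see \code{\link{mergeOverlapping}}), falling
#' back to a zero gap with a conflict flag when the overlap disagrees.
#' Minus-strand contigs are reverse-complemented at rendering. Two
#' placements with identical spans raise an ambiguity report and only the
#' alphabetically first contig is kept.
#'
#' @param blocks alignment blocks after filtration and splitting.
#' @param contigs \link[Biostrings]{DNAStringSet} of the contigs.
#' @param cfg a \linkS4class{BuilderConfig}.
#' @param exclude contig ids to keep out of the layout (e.g. flagged ones).
#' @return a \linkS4class{ChromosomeLayout}; attributes \code{conflicts} and
#'   \code{ambiguous} carry the respective reports.
#' @export
layoutChromosomes <- function(blocks, contigs, cfg = builderConfig(),
                              exclude = character()) {
    pl <- chainPlacements(blocks, cfg)
    pl <- pl[!(pl$contig_id %in% exclude), , drop = FALSE]
    conflicts <- data.frame(chrom = character(), left = character(),
                            right = character(), identity = numeric(),
                            stringsAsFactors = FALSE)
    ambiguous <- character()
    tb <- data.frame(chrom = character(), order = integer(),
                     component_id = character(), comp_len = integer(),
                     t_start = integer(), t_end = integer(),
                     strand = character(), gap_after = integer(),
                     stringsAsFactors = FALSE)
    comps <- list()
    orient <- function(id, strand) {
        s <- contigs[[id]]
        if (strand == "-") Biostrings::reverseComplement(s) else s
    }
    for (ch in unique(pl$chrom)) {
        sub <- pl[pl$chrom == ch, , drop = FALSE]
        ## ambiguous order: identical spans
        key <- paste(sub$t_start, sub$t_end)
        dup <- duplicated(key)
        if (any(dup)) {
            ambiguous <- c(ambiguous, sub$contig_id[dup])
            sub <- sub[!dup, , drop = FALSE]
        }
        ## current open component
        cur_id <- sub$contig_id[1]
        cur_seq <- orient(cur_id, sub$strand[1])
        cur_strand <- sub$strand[1]
        cur_raw <- TRUE   # TRUE while cur_seq is the unmodified contig
        cur_s <- sub$t_start[1]; cur_e <- sub$t_end[1]
        rows <- list()
        flush <- function(gap) {
            if (cur_raw) {
                comps[[cur_id]] <<- contigs[[cur_id]]
                strand_out <- cur_strand
            } else {
                comps[[cur_id]] <<- cur_seq
                strand_out <- "+"
            }
            rows[[length(rows) + 1L]] <<- data.frame(
                chrom = ch, order = length(rows) + 1L, component_id = cur_id,
                comp_len = length(cur_seq), t_start = cur_s, t_end = cur_e,
                strand = strand_out, gap_after = as.integer(gap),
                stringsAsFactors = FALSE)
        }
        i <- 2L
        while (i <= nrow(sub)) {
            nx_id <- sub$contig_id[i]
            nx_seq <- orient(nx_id, sub$strand[i])
            d <- sub$t_start[i] - cur_e
            if (d >= 0L) {
                flush(round(cfg@gap_scale * d))
                cur_id <- nx_id; cur_seq <- nx_seq
                cur_strand <- sub$strand[i]; cur_raw <- TRUE
                cur_s <- sub$t_start[i]; cur_e <- sub$t_end[i]
            } else {
                o <- -d
                ## an overlap engulfing a whole sequence cannot be merged;
                ## leave the placements abutting and flag the conflict
                m <- if (o >= min(length(cur_seq), length(nx_seq)))
                    list(merged = FALSE, seq = NULL, identity = NA_real_)
                else mergeOverlapping(cur_seq, nx_seq, o, cfg)
                if (m$merged) {
                    cur_id <- paste(cur_id, nx_id, sep = "+")
                    cur_seq <- m$seq
                    cur_raw <- FALSE
                    cur_e <- max(cur_e, sub$t_end[i])
                } else {
                    conflicts <- rbind(conflicts, data.frame(
                        chrom = ch, left = cur_id, right = nx_id,
                        identity = m$identity, stringsAsFactors = FALSE))
                    flush(0L)
                    cur_id <- nx_id; cur_seq <- nx_seq
                    cur_strand <- sub$strand[i]; cur_raw <- TRUE
                    cur_s <- sub$t_start[i]; cur_e <- sub$t_end[i]
                }
            }
            i <- i + 1L
        }
        flush(0L)
        tb <- rbind(tb, do.call(rbind, rows))
    }
    layout <- methods::new("ChromosomeLayout", table = tb,
                           components = Biostrings::DNAStringSet(comps))
    attr(layout, "conflicts") <- conflicts
    attr(layout, "ambiguous") <- ambiguous
    layout
}

#' Report reference regions not covered by any placed contig
#'
#' Maximal uncovered reference intervals are extended by \code{flank_ext}
#' bases on both sides (clamped at chromosome ends); regions whose
#' extensions touch are merged.
#'
#' @param layout a \linkS4class{ChromosomeLayout}.
#' @param reference reference \link[Biostrings]{DNAStringSet}.
#' @param cfg a \linkS4class{BuilderConfig}.
#' @return data.frame chrom, start, end (0-based half-open, BED-ready).
#' @export
findUncoveredRegions <- function(layout, reference, cfg = builderConfig()) {
    tb <- layoutTable(layout)
    out <- list()
    for (ch in names(reference)) {
        len <- BiocGenerics::width(reference)[names(reference) == ch]
        sub <- tb[tb$chrom == ch, , drop = FALSE]
        unc <- intervalComplement0(sub$t_start, sub$t_end, len)
        if (!nrow(unc)) next
        ext_s <- pmax(0L, unc$start - cfg@flank_ext)
        ext_e <- pmin(len, unc$end + cfg@flank_ext)
        mrg <- intervalUnion0(ext_s, ext_e)
        out[[ch]] <- data.frame(chrom = ch, start = mrg$start, end = mrg$end,
                                stringsAsFactors = FALSE)
    }
    if (!length(out))
        return(data.frame(chrom = character(), start = integer(),
                          end = integer(), stringsAsFactors = FALSE))
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}

## Local-alignment anchor of `flank` inside `cand`; success requires
## nmatch >= id * flank length. Returns NULL or subject (candidate) span.
anchorFlank <- function(cand, flank, id) {
    if (length(flank) == 0L) return(NULL)
    aln <- Biostrings::pairwiseAlignment(
        flank, cand, type = "local",
        substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
            match = 1, mismatch = -2),
        gapOpening = 4, gapExtension = 1)
    if (Biostrings::nmatch(aln) < id * length(flank)) return(NULL)
    sp <- Biostrings::subject(aln)
    c(start = BiocGenerics::start(sp) - 1L, end = BiocGenerics::end(sp))
}

#' Patch assembly gaps with candidate sequences
#'
#' A candidate that anchors (identity at least \code{overlap_merge_identity}
#' over \code{flank_ext} bases) to both flanks of a gap fills it completely
#' with its interior sequence; a candidate anchoring to one flank shortens
#' the gap by its interior overhang; candidates are also tried
#' reverse-complemented. The per-gap report records
#' complete/partial/failed.
#'
#' @param layout a \linkS4class{ChromosomeLayout}.
#' @param candidates named \link[Biostrings]{DNAStringSet} (locally
#'   assembled contigs or long-read scaffolds).
#' @param cfg a \linkS4class{BuilderConfig}.
#' @return list: \code{layout} (updated) and \code{report} (data.frame
#'   chrom, left_component, gap_before, gap_after, status, candidate).
#' @export
patchGaps <- function(layout, candidates, cfg = builderConfig()) {
    tb <- layoutTable(layout)
    comps <- as.list(layoutComponents(layout))
    report <- list()
    newtb <- list()
    for (ch in unique(tb$chrom)) {
        sub <- tb[tb$chrom == ch, , drop = FALSE]
        sub <- sub[order(sub$order), , drop = FALSE]
        i <- 1L
        while (i <= nrow(sub)) {
            row <- sub[i, , drop = FALSE]
            g <- row$gap_after
            if (g > 0L && i < nrow(sub)) {
                leftc <- comps[[row$component_id]]
                if (row$strand == "-")
                    leftc <- Biostrings::reverseComplement(leftc)
                nxt <- sub[i + 1L, ]
                rightc <- comps[[nxt$component_id]]
                if (nxt$strand == "-")
                    rightc <- Biostrings::reverseComplement(rightc)
                fl <- Biostrings::subseq(
                    leftc, max(1L, length(leftc) - cfg@flank_ext + 1L),
                    length(leftc))
                fr <- Biostrings::subseq(
                    rightc, 1L, min(cfg@flank_ext, length(rightc)))
                best <- NULL
                for (cid in names(candidates)) {
                    for (rc in c(FALSE, TRUE)) {
                        cand <- candidates[[cid]]
                        if (rc) cand <- Biostrings::reverseComplement(cand)
                        al <- anchorFlank(cand, fl, cfg@overlap_merge_identity)
                        ar <- anchorFlank(cand, fr, cfg@overlap_merge_identity)
                        if (!is.null(al) && !is.null(ar) &&
                            al[["end"]] <= ar[["start"]]) {
                            interior <-
                                if (ar[["start"]] > al[["end"]])
                                    Biostrings::subseq(cand, al[["end"]] + 1L,
                                                       ar[["start"]])
                                else Biostrings::DNAString("")
                            best <- list(status = "complete", cid = cid,
                                         interior = interior)
                            break
                        }
                        if (is.null(best) && !is.null(al) &&
                            al[["end"]] < length(cand)) {
                            ov <- Biostrings::subseq(cand, al[["end"]] + 1L,
                                                     length(cand))
                            keepn <- min(length(ov), g)
                            best <- list(status = "partial", cid = cid,
                                         side = "left",
                                         interior = Biostrings::subseq(ov, 1L, keepn))
                        } else if (is.null(best) && !is.null(ar) &&
                                   ar[["start"]] > 0L) {
                            ov <- Biostrings::subseq(cand, 1L, ar[["start"]])
                            keepn <- min(length(ov), g)
                            best <- list(status = "partial", cid = cid,
                                         side = "right",
                                         interior = Biostrings::subseq(
                                             ov, length(ov) - keepn + 1L,
                                             length(ov)))
                        }
                    }
                    if (!is.null(best) && best$status == "complete") break
                }
                if (is.null(best)) {
                    report[[length(report) + 1L]] <- data.frame(
                        chrom = ch, left_component = row$component_id,
                        gap_before = g, gap_after = g, status = "failed",
                        candidate = NA_character_, stringsAsFactors = FALSE)
                    newtb[[length(newtb) + 1L]] <- row
                } else {
                    ilen <- length(best$interior)
                    patch_id <- paste0("patch_", best$cid, "_", ch, "_", i)
                    if (best$status == "complete") {
                        row$gap_after <- 0L
                        remaining <- 0L
                    } else {
                        row$gap_after <- if (identical(best$side, "left")) 0L
                                         else as.integer(g - ilen)
                        remaining <- as.integer(g - ilen)
                    }
                    newtb[[length(newtb) + 1L]] <- row
                    if (ilen > 0L) {
                        comps[[patch_id]] <- best$interior
                        newtb[[length(newtb) + 1L]] <- data.frame(
                            chrom = ch, order = 0L, component_id = patch_id,
                            comp_len = ilen, t_start = row$t_end,
                            t_end = row$t_end + ilen, strand = "+",
                            gap_after = if (identical(best$side, "right")) 0L
                                        else remaining,
                            stringsAsFactors = FALSE)
                    }
                    report[[length(report) + 1L]] <- data.frame(
                        chrom = ch, left_component = row$component_id,
                        gap_before = g, gap_after = remaining,
                        status = best$status, candidate = best$cid,
                        stringsAsFactors = FALSE)
                }
            } else {
                newtb[[length(newtb) + 1L]] <- row
            }
            i <- i + 1L
        }
    }
    tb2 <- do.call(rbind, newtb)
    ## renumber order within chromosomes
    tb2$order <- stats::ave(seq_len(nrow(tb2)), tb2$chrom,
                            FUN = seq_along)
    rownames(tb2) <- NULL
    layout2 <- methods::new("ChromosomeLayout", table = tb2,
                            components = Biostrings::DNAStringSet(comps))
    rep_df <- if (length(report)) do.call(rbind, report)
              else data.frame(chrom = character(), left_component = character(),
                              gap_before = integer(), gap_after = integer(),
                              status = character(), candidate = character(),
                              stringsAsFactors = FALSE)
    list(layout = layout2, report = rep_df)
}

#' Rescue unplaced contigs that carry annotated features
#'
#' An unplaced contig is retained in the final assembly when it carries at
#' least one gene, exon or CDS feature (annotation given in contig
#' coordinates); feature-free contigs are dropped.
#'
#' @param unplaced character vector of contig ids.
#' @param features data.frame from \code{\link{readGff3}} with contig seqids.
#' @return list: \code{retained}, \code{dropped} (character vectors) and
#'   \code{report} (data.frame contig_id, n_features, retained).
#' @export
rescueUnplaced <- function(unplaced, features) {
    nf <- vapply(unplaced, function(id)
        sum(features$seq_id == id &
                features$type %in% c("gene", "exon", "CDS")), 0L)
    keep <- nf >= 1L
    list(retained = unplaced[keep], dropped = unplaced[!keep],
         report = data.frame(contig_id = unplaced, n_features = nf,
                             retained = keep, stringsAsFactors = FALSE,
                             row.names = NULL))
}
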