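## Synthetic genome simulator with full ground truth.
##
## The generator emulates the statistical structure the builder assumes:
## a multi-chromosome reference; a sample genome derived from it by
## substitutions, deletions (which later surface as uncovered regions) and
## reciprocal interchromosomal translocations; contigs tiling the sample with
## slight overlaps, planted chimeric misjoins and contained duplicates; and
## mate-pair style read pairs with inserts of about 2600 bp +/- 30 percent.
## Every edit is recorded in a TruthSet so downstream results can be checked
## by direct string comparison.

#' Generate a reference genome
#'
#' Uniform-composition random chromosomes named \code{chr1..chrN}.
#' Deterministic in \code{cfg@seed}: the same configuration yields identical
#' sequences.
#'
#' @param cfg a \linkS4class{SimConfig}.
#' @return named \link[Biostrings]{DNAStringSet}.
#' @examples
#' ref <- makeReference(simConfig(n_chromosomes = 2, chrom_length = 10000))
#' @export
makeReference <- function(cfg) {
    methods::validObject(cfg)
    set.seed(childSeed(cfg@seed, 1L))
    seqs <- vapply(seq_len(cfg@n_chromosomes),
                   function(i) randomDna(cfg@chrom_length), "")
    names(seqs) <- paste0("chr", seq_len(cfg@n_chromosomes))
    Biostrings::DNAStringSet(seqs)
}

## Sample non-overlapping spans of length `len` on chromosomes `lens`,
## keeping `end_margin` clear of the chromosome ends and `sep` clear of
## every span in `occupied` (data.frame chrom/start/end).
## Returns data.frame(chrom, start, end).
sampleSpans <- function(n, len, lens, occupied, end_margin = 15000L,
                        sep = 12000L, chroms = NULL, what = "span") {
    out <- data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE)
    tries <- 0L
    while (nrow(out) < n) {
        if ((tries <- tries + 1L) > 1000L * n)
            stopf("could not place %d %ss of %d bases", n, what, len)
        ch <- if (is.null(chroms)) sample(names(lens), 1L) else
            sample(chroms, 1L)
        hi <- lens[[ch]] - len - end_margin
        if (hi <= end_margin) next
        s <- end_margin + sampleInt(hi - end_margin, 1L)
        cand <- data.frame(chrom = ch, start = s, end = s + len)
        all_occ <- rbind(occupied[, c("chrom", "start", "end")],
                         out[, c("chrom", "start", "end")])
        same <- all_occ[all_occ$chrom == ch, , drop = FALSE]
        if (nrow(same) && any(pmax(same$start - sep, cand$start) <
                                  pmin(same$end + sep, cand$end)))
            next
        out <- rbind(out, cand)
    }
    out
}

#' Derive a sample genome from a reference
#'
#' Applies, in order: reciprocal interchromosomal translocations (equal-length
#' fragment swaps between two chromosomes, hence length-neutral),
#' per-base substitutions, and deletions. Translocation and deletion spans
#' are recorded in reference coordinates; substitutions in the pre-deletion
#' coordinate frame of their sample chromosome. Deletions and translocations
#' never overlap one another, so every recorded span is verifiable by direct
#' substring comparison.
#'
#' @param reference named \link[Biostrings]{DNAStringSet}.
#' @param cfg a \linkS4class{SimConfig}.
#' @return list with elements \code{genome} (DNAStringSet) and \code{truth}
#'   (\linkS4class{TruthSet} with translocations, deletions, substitutions).
#' @export
deriveSampleGenome <- function(reference, cfg) {
    methods::validObject(cfg)
    if (!length(reference)) stopf("reference is empty")
    if (cfg@n_translocations > 0L &&
        cfg@translocation_len >= min(BiocGenerics::width(reference)))
        stopf("translocation_len must be smaller than every chromosome")
    if (cfg@n_translocations > 0L && length(reference) < 2L)
        stopf("interchromosomal translocations need >= 2 chromosomes")
    set.seed(childSeed(cfg@seed, 2L))
    truth <- emptyTruthSet()
    lens <- stats::setNames(as.list(BiocGenerics::width(reference)),
                            names(reference))
    seqs <- as.character(reference)

    ## -- reciprocal translocations ------------------------------------------
    ## Variant spans stay >= 15 kb clear of chromosome ends and >= 12 kb
    ## clear of each other, so every inter-variant segment can host a
    ## contig that passes the builder's 10 kb length filter.
    occupied <- data.frame(chrom = character(), start = integer(),
                           end = integer(), stringsAsFactors = FALSE)
    tl <- cfg@translocation_len
    ## swaps are kept well apart (up to 60 kb where chromosomes allow) so
    ## that distinct events are never bridged by co-linear block merging
    sep_tr <- as.integer(max(12000, min(60000,
                                        min(unlist(lens)) %/% 6)))
    for (i in seq_len(cfg@n_translocations)) {
        placed <- NULL
        for (attempt in 1:50) {    # re-draw the chromosome pair on failure
            pair <- sample(names(seqs), 2L)
            placed <- tryCatch({
                sp_a <- sampleSpans(1L, tl, lens, occupied, sep = sep_tr,
                                    chroms = pair[1], what = "translocation")
                sp_b <- sampleSpans(1L, tl, lens, rbind(occupied, sp_a),
                                    sep = sep_tr,
                                    chroms = pair[2], what = "translocation")
                list(a = sp_a, b = sp_b)
            }, error = function(e) NULL)
            if (!is.null(placed)) break
        }
        if (is.null(placed))
            stopf("could not place translocation %d of %d bases", i, tl)
        sp_a <- placed$a; sp_b <- placed$b
        occupied <- rbind(occupied, sp_a, sp_b)
        a <- pair[1]; b <- pair[2]
        frag_a <- substr(seqs[[a]], sp_a$start + 1L, sp_a$end)
        frag_b <- substr(seqs[[b]], sp_b$start + 1L, sp_b$end)
        substr(seqs[[a]], sp_a$start + 1L, sp_a$end) <- frag_b
        substr(seqs[[b]], sp_b$start + 1L, sp_b$end) <- frag_a
        truth@translocations <- rbind(truth@translocations, data.frame(
            chrom_a = a, start_a = sp_a$start, end_a = sp_a$end,
            chrom_b = b, start_b = sp_b$start, end_b = sp_b$end,
            stringsAsFactors = FALSE))
    }

    ## -- substitutions ------------------------------------------------------
    if (cfg@substitution_rate > 0) {
        bases <- c("A", "C", "G", "T")
        for (ch in names(seqs)) {
            n_sub <- stats::rbinom(1L, lens[[ch]], cfg@substitution_rate)
            if (!n_sub) next
            pos <- sort(sampleInt(lens[[ch]], n_sub))   # 1-based here
            chars <- strsplit(seqs[[ch]], "", fixed = TRUE)[[1]]
            ## shift each base by 1..3 in alphabet order: always a different base
            shift <- sampleInt(3L, n_sub, replace = TRUE)
            chars[pos] <- bases[(match(chars[pos], bases) - 1L + shift) %% 4L + 1L]
            seqs[[ch]] <- paste(chars, collapse = "")
            truth@substitutions <- rbind(truth@substitutions, data.frame(
                chrom = ch, pos = pos - 1L, stringsAsFactors = FALSE))
        }
    }

    ## -- deletions ----------------------------------------------------------
    if (cfg@n_deletions > 0L) {
        dels <- sampleSpans(cfg@n_deletions, cfg@deletion_len, lens,
                            occupied, what = "deletion")
        dels <- dels[order(dels$chrom, dels$start), ]
        truth@deletions <- data.frame(chrom = dels$chrom,
                                      start = dels$start, end = dels$end,
                                      stringsAsFactors = FALSE)
        for (ch in unique(dels$chrom)) {
            sub <- dels[dels$chrom == ch, , drop = FALSE]
            keep <- intervalComplement0(sub$start, sub$end, lens[[ch]])
            seqs[[ch]] <- paste(substring(seqs[[ch]], keep$start + 1L,
                                          keep$end), collapse = "")
        }
    }
    list(genome = Biostrings::DNAStringSet(unlist(seqs)), truth = truth)
}

## Cumulative deleted bases on `chrom` before (reference) position of the
## sample position `pos0`: maps sample -> pre-deletion (reference-frame)
## coordinates of that chromosome.
sampleToRefOffset <- function(truth, chrom, pos0) {
    dels <- truth@deletions
    dels <- dels[dels$chrom == chrom, , drop = FALSE]
    if (!nrow(dels)) return(rep(0L, length(pos0)))
    dels <- dels[order(dels$start), , drop = FALSE]
    vapply(pos0, function(p) {
        off <- 0L
        for (i in seq_len(nrow(dels))) {
            if (p + off >= dels$start[i]) off <- off + (dels$end[i] - dels$start[i])
            else break
        }
        off
    }, 0L)
}

## Map a contiguous sample-genome span (no deletion/translocation boundary
## inside) to its reference location. Returns list(chrom, start, end).
mapSpanToRef <- function(truth, chrom, s, e) {
    off <- sampleToRefOffset(truth, chrom, s)
    r1 <- s + off; r2 <- e + off
    tr <- truth@translocations
    if (nrow(tr)) {
        for (i in seq_len(nrow(tr))) {
            if (chrom == tr$chrom_a[i] && r1 >= tr$start_a[i] &&
                r2 <= tr$end_a[i])
                return(list(chrom = tr$chrom_b[i],
                            start = tr$start_b[i] + (r1 - tr$start_a[i]),
                            end = tr$start_b[i] + (r2 - tr$start_a[i])))
            if (chrom == tr$chrom_b[i] && r1 >= tr$start_b[i] &&
                r2 <= tr$end_b[i])
                return(list(chrom = tr$chrom_a[i],
                            start = tr$start_a[i] + (r1 - tr$start_b[i]),
                            end = tr$start_a[i] + (r2 - tr$start_b[i])))
        }
    }
    list(chrom = chrom, start = r1, end = r2)
}

## Sample-coordinate positions on `chrom` where fragmentation must break:
## deletion junctions and translocation edges. These are the loci where a
## real assembly would terminate contigs (divergent junctions).
forcedBoundaries <- function(truth, chrom, len) {
    pts <- integer()
    dels <- truth@deletions[truth@deletions$chrom == chrom, , drop = FALSE]
    if (nrow(dels))
        pts <- c(pts, dels$start - sampleToRefOffsetRef(truth, chrom, dels$start))
    tr <- truth@translocations
    edges_ref <- c(tr$start_a[tr$chrom_a == chrom], tr$end_a[tr$chrom_a == chrom],
                   tr$start_b[tr$chrom_b == chrom], tr$end_b[tr$chrom_b == chrom])
    if (length(edges_ref))
        pts <- c(pts, edges_ref - sampleToRefOffsetRef(truth, chrom, edges_ref))
    sort(unique(pts[pts > 0L & pts < len]))
}

## Deleted bases strictly before reference position `rpos`: maps reference ->
## sample coordinates (valid for positions outside deletions).
sampleToRefOffsetRef <- function(truth, chrom, rpos) {
    dels <- truth@deletions
    dels <- dels[dels$chrom == chrom, , drop = FALSE]
    if (!nrow(dels)) return(rep(0L, length(rpos)))
    vapply(rpos, function(r) {
        d <- dels[dels$start < r, , drop = FALSE]
        as.integer(sum(pmin(d$end, r) - d$start))
    }, 0L)
}
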