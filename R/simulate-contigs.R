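## Fragmentation of the sample genome into contigs with planted defects.

#' Fragment a sample genome into contigs
#'
#' Tiles every sample chromosome with fragments whose lengths follow a
#' truncated normal model, adjacent fragments abutting or overlapping by up
#' to \code{max_overlap} bases. Fragment boundaries are forced at deletion
#' junctions and translocation edges (where a real assembly would break).
#' A deterministic number of chimeric contigs
#' (\code{round(misjoin_rate * n_fragments)}) is planted by concatenating two
#' fragments from different chromosomes with no linker bases, recording the
#' join offset; with probability \code{containment_rate} a redundant
#' sub-fragment fully inside a contig is also emitted; with probability
#' \code{short_contig_frac} a fragment is drawn shorter than 10 kb to
#' exercise the length filter. Each contig is emitted on a random strand.
#'
#' @param sample named \link[Biostrings]{DNAStringSet}, the sample genome.
#' @param cfg a \linkS4class{SimConfig}.
#' @param truth \linkS4class{TruthSet} from \code{\link{deriveSampleGenome}}
#'   (placements and misjoins are appended to it).
#' @return list with elements \code{contigs} (DNAStringSet) and \code{truth}.
#' @export
fragmentIntoContigs <- function(sample, cfg, truth = emptyTruthSet()) {
    methods::validObject(cfg)
    if (!length(sample)) stopf("sample genome is empty")
    if (cfg@contig_len_mean < 2 * cfg@read_len)
        stopf("contig_len_mean must be >= 2 * read_len")
    set.seed(childSeed(cfg@seed, 3L))
    min_len <- max(2L * cfg@read_len, 1000L)
    ## tails shorter than this are absorbed into the previous fragment, so
    ## a chromosome end never produces an accidental sub-10 kb contig
    min_tail <- 10000L

    drawLen <- function() {
        if (cfg@short_contig_frac > 0 && stats::runif(1) < cfg@short_contig_frac)
            return(as.integer(round(stats::runif(1, min_len, 9999))))
        max(min_len,
            as.integer(round(stats::rnorm(1, cfg@contig_len_mean,
                                          cfg@contig_len_sd))))
    }

    ## -- tile each chromosome into fragments --------------------------------
    frags <- data.frame(chrom = character(), start = integer(),
                        end = integer(), stringsAsFactors = FALSE)
    for (ch in names(sample)) {
        len <- BiocGenerics::width(sample)[names(sample) == ch]
        bnds <- forcedBoundaries(truth, ch, len)
        segs <- data.frame(s = c(0L, bnds), e = c(bnds, len))
        for (k in seq_len(nrow(segs))) {
            pos <- segs$s[k]
            repeat {
                l <- drawLen()
                e <- pos + l
                if (e >= segs$e[k] - min_tail) e <- segs$e[k]
                frags <- rbind(frags, data.frame(chrom = ch, start = pos,
                                                 end = e))
                if (e >= segs$e[k]) break
                ov <- sampleInt(cfg@max_overlap + 1L, 1L) - 1L
                pos <- max(pos + 1L, e - ov)
            }
        }
    }
    n_frag <- nrow(frags)

    ## -- choose chimera pairs (different chromosomes) -----------------------
    ## Partners must come from different loci both in the sample and on the
    ## reference (a fragment inside a translocated span maps back to its
    ## source chromosome), so every junction is a detectable breakpoint.
    refChrom <- vapply(seq_len(n_frag), function(i)
        mapSpanToRef(truth, frags$chrom[i], frags$start[i],
                     frags$end[i])$chrom, "")
    n_mis <- min(round(cfg@misjoin_rate * n_frag), n_frag %/% 2L)
    ord <- sampleInt(n_frag, n_frag)
    pairs <- list()
    used <- logical(n_frag)
    i <- 1L
    while (length(pairs) < n_mis && i <= n_frag) {
        a <- ord[i]; i <- i + 1L
        if (used[a]) next
        j <- i
        while (j <= n_frag &&
               (used[ord[j]] || frags$chrom[ord[j]] == frags$chrom[a] ||
                refChrom[ord[j]] == refChrom[a]))
            j <- j + 1L
        if (j > n_frag) break
        b <- ord[j]
        used[a] <- used[b] <- TRUE
        pairs[[length(pairs) + 1L]] <- c(a, b)
    }

    ## -- emit contigs -------------------------------------------------------
    contigs <- character()
    placements <- list()
    misjoins <- list()
    schr <- as.character(sample)
    tigId <- function(n) sprintf("tig%05d", n)
    n_tig <- 0L

    emit <- function(parts) {
        ## parts: data.frame(chrom, start, end) in concatenation order
        n_tig <<- n_tig + 1L
        id <- tigId(n_tig)
        seq <- paste(substring(schr[parts$chrom], parts$start + 1L,
                               parts$end), collapse = "")
        L <- sum(parts$end - parts$start)
        flip <- stats::runif(1) < 0.5
        offs <- cumsum(c(0L, utils::head(parts$end - parts$start, -1)))
        plens <- parts$end - parts$start
        if (flip) {
            seq <- revcompChr(seq)
            q1 <- L - (offs + plens); q2 <- L - offs
            strand <- "-"
        } else {
            q1 <- offs; q2 <- offs + plens
            strand <- "+"
        }
        placements[[length(placements) + 1L]] <<- data.frame(
            contig_id = id, part = seq_len(nrow(parts)),
            chrom = parts$chrom, start = parts$start, end = parts$end,
            strand = strand, q_start = as.integer(q1), q_end = as.integer(q2),
            stringsAsFactors = FALSE)
        if (nrow(parts) > 1L) {
            jq <- if (flip) plens[2L] else plens[1L]
            misjoins[[length(misjoins) + 1L]] <<- data.frame(
                contig_id = id, q_pos = as.integer(jq),
                stringsAsFactors = FALSE)
        }
        contigs[id] <<- seq
        id
    }

    for (p in pairs) emit(frags[p, , drop = FALSE])
    for (f in which(!used)) {
        id <- emit(frags[f, , drop = FALSE])
        if (cfg@containment_rate > 0 &&
            stats::runif(1) < cfg@containment_rate) {
            fl <- frags$end[f] - frags$start[f]
            sub_len <- max(2000L, as.integer(fl * 0.4))
            if (sub_len < fl - 200L) {
                s0 <- frags$start[f] + sampleInt(fl - sub_len - 100L, 1L) + 50L
                emit(data.frame(chrom = frags$chrom[f], start = s0,
                                end = s0 + sub_len))
            }
        }
    }

    truth@placements <- rbind(truth@placements, do.call(rbind, placements))
    if (length(misjoins))
        truth@misjoins <- rbind(truth@misjoins, do.call(rbind, misjoins))
    methods::validObject(truth)
    list(contigs = Biostrings::DNAStringSet(contigs), truth = truth)
}

#' Emit truth alignments of contigs against the reference as PAF blocks
#'
#' Converts each recorded contig placement part from sample-genome
#' coordinates to reference coordinates (accounting for deletions and
#' translocation content sources) and emits one PAF block per part, so tests
#' and demos never require an external aligner. \code{n_match} discounts the
#' recorded substitutions falling inside the block.
#'
#' @param truth \linkS4class{TruthSet} with placements.
#' @param contigs contig \link[Biostrings]{DNAStringSet}.
#' @param reference reference \link[Biostrings]{DNAStringSet}.
#' @return data.frame of alignment blocks (see \code{\link{readPaf}}).
#' @export
truthContigPaf <- function(truth, contigs, reference) {
    pl <- truth@placements
    if (!nrow(pl)) return(emptyPaf())
    clen <- stats::setNames(BiocGenerics::width(contigs), names(contigs))
    rlen <- stats::setNames(BiocGenerics::width(reference), names(reference))
    subs <- truth@substitutions
    rows <- lapply(seq_len(nrow(pl)), function(i) {
        m <- mapSpanToRef(truth, pl$chrom[i], pl$start[i], pl$end[i])
        blen <- pl$end[i] - pl$start[i]
        nsub <- if (nrow(subs)) {
            off <- sampleToRefOffset(truth, pl$chrom[i], pl$start[i])
            sum(subs$chrom == pl$chrom[i] &
                    subs$pos >= pl$start[i] + off &
                    subs$pos < pl$end[i] + off)
        } else 0L
        data.frame(query_id = pl$contig_id[i],
                   query_len = clen[[pl$contig_id[i]]],
                   q_start = pl$q_start[i], q_end = pl$q_end[i],
                   strand = pl$strand[i], target_id = m$chrom,
                   target_len = rlen[[m$chrom]],
                   t_start = as.integer(m$start), t_end = as.integer(m$end),
                   n_match = as.integer(blen - nsub),
                   block_len = as.integer(blen), mapq = 60L,
                   tags = "", stringsAsFactors = FALSE)
    })
    blocks <- do.call(rbind, rows)
    rownames(blocks) <- NULL
    validatePaf(blocks, where = "truth PAF")
}

#' Emit a whole-genome truth alignment of the sample against the reference
#'
#' Segments each sample chromosome at deletion junctions and translocation
#' edges and maps every segment to its reference source, yielding the
#' assembly-vs-assembly alignment used for translocation detection.
#'
#' @param truth \linkS4class{TruthSet}.
#' @param sample sample genome \link[Biostrings]{DNAStringSet}.
#' @param reference reference \link[Biostrings]{DNAStringSet}.
#' @return data.frame of alignment blocks.
#' @export
truthGenomePaf <- function(truth, sample, reference) {
    rlen <- stats::setNames(BiocGenerics::width(reference), names(reference))
    slen <- stats::setNames(BiocGenerics::width(sample), names(sample))
    subs <- truth@substitutions
    rows <- list()
    for (ch in names(sample)) {
        len <- slen[[ch]]
        bnds <- forcedBoundaries(truth, ch, len)
        segs <- data.frame(s = c(0L, bnds), e = c(bnds, len))
        for (k in seq_len(nrow(segs))) {
            m <- mapSpanToRef(truth, ch, segs$s[k], segs$e[k])
            blen <- segs$e[k] - segs$s[k]
            nsub <- if (nrow(subs)) {
                off <- sampleToRefOffset(truth, ch, segs$s[k])
                sum(subs$chrom == ch & subs$pos >= segs$s[k] + off &
                        subs$pos < segs$e[k] + off)
            } else 0L
            rows[[length(rows) + 1L]] <- data.frame(
                query_id = ch, query_len = len,
                q_start = segs$s[k], q_end = segs$e[k], strand = "+",
                target_id = m$chrom, target_len = rlen[[m$chrom]],
                t_start = as.integer(m$start), t_end = as.integer(m$end),
                n_match = as.integer(blen - nsub),
                block_len = as.integer(blen), mapq = 60L, tags = "",
                stringsAsFactors = FALSE)
        }
    }
    blocks <- do.call(rbind, rows)
    rownames(blocks) <- NULL
    validatePaf(blocks, where = "truth genome PAF")
}
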