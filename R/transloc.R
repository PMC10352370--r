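## Interchromosomal translocation detection between two chromosome-level
## assemblies from whole-genome alignment blocks.

#' Majority homology map between two assemblies
#'
#' For each query chromosome, the target chromosome receiving the most
#' aligned bases, with the base fraction it receives. Chromosome naming is
#' irrelevant: homology is defined by the majority of aligned sequence.
#'
#' @param blocks whole-genome alignment blocks (data.frame).
#' @return data.frame: query_chrom, target_chrom, fraction.
#' @export
homologyMap <- function(blocks) {
    if (!nrow(blocks))
        return(data.frame(query_chrom = character(),
                          target_chrom = character(), fraction = numeric(),
                          stringsAsFactors = FALSE))
    ab <- as.numeric(blocks$q_end - blocks$q_start)
    agg <- stats::aggregate(ab, list(query_chrom = blocks$query_id,
                                     target_chrom = blocks$target_id), sum)
    out <- do.call(rbind, lapply(split(agg, agg$query_chrom), function(d) {
        best <- d[which.max(d$x), ]
        data.frame(query_chrom = best$query_chrom,
                   target_chrom = best$target_chrom,
                   fraction = best$x / sum(d$x), stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    out
}

#' Detect interchromosomal translocations
#'
#' Blocks aligning a query chromosome to a chromosome other than its
#' homolog are collected; co-linear blocks within \code{merge_dist} on both
#' genomes are merged into fragments; fragments of merged query length at
#' least \code{min_len} become links. A reciprocal swap produces mirrored
#' evidence from both assemblies' sides; links are canonically ordered and
#' deduplicated so each arc is counted once.
#'
#' @param blocks whole-genome alignment blocks.
#' @param hmap homology map (from \code{\link{homologyMap}}; recomputed when
#'   missing).
#' @param min_len minimal fragment length in bases (default 10000: fragments
#'   of at least 10 kb count).
#' @param merge_dist co-linearity merge distance on both genomes.
#' @param mirror_tol tolerance when recognising the two mirrored reports of
#'   one reciprocal swap (their coordinates can be shifted against each
#'   other by nearby indels).
#' @return data.frame of links: chrom_a, start_a, end_a, chrom_b, start_b,
#'   end_b, length, n_blocks.
#' @export
detectTranslocations <- function(blocks, hmap = NULL, min_len = 10000,
                                 merge_dist = 50000, mirror_tol = 25000) {
    emptyLinks <- data.frame(chrom_a = character(), start_a = integer(),
                             end_a = integer(), chrom_b = character(),
                             start_b = integer(), end_b = integer(),
                             length = integer(), n_blocks = integer(),
                             stringsAsFactors = FALSE)
    if (!nrow(blocks)) return(emptyLinks)
    if (is.null(hmap)) hmap <- homologyMap(blocks)
    hom <- stats::setNames(hmap$target_chrom, hmap$query_chrom)
    off <- blocks[blocks$target_id != hom[blocks$query_id], , drop = FALSE]
    if (!nrow(off)) return(emptyLinks)

    ## merge co-linear blocks within merge_dist on both genomes
    frags <- list()
    for (key in unique(paste(off$query_id, off$target_id, off$strand))) {
        parts <- strsplit(key, " ", fixed = TRUE)[[1]]
        sub <- off[off$query_id == parts[1] & off$target_id == parts[2] &
                       off$strand == parts[3], , drop = FALSE]
        sub <- sub[order(sub$q_start), , drop = FALSE]
        cur <- sub[1, , drop = FALSE]
        n <- 1L
        addFrag <- function(b, n) frags[[length(frags) + 1L]] <<- data.frame(
            chrom_a = b$query_id, start_a = b$q_start, end_a = b$q_end,
            chrom_b = b$target_id, start_b = b$t_start, end_b = b$t_end,
            length = b$q_end - b$q_start, n_blocks = n,
            stringsAsFactors = FALSE)
        for (i in seq_len(nrow(sub))[-1]) {
            b <- sub[i, ]
            ## co-linear continuation: ascending on the target for forward
            ## blocks, descending for reverse ones
            colinear <- if (parts[3] == "+")
                b$t_start >= cur$t_start &&
                    b$t_start - cur$t_end <= merge_dist
            else cur$t_start >= b$t_start &&
                    cur$t_start - b$t_end <= merge_dist
            if (b$q_start - cur$q_end <= merge_dist && colinear) {
                cur$q_end <- max(cur$q_end, b$q_end)
                cur$t_start <- min(cur$t_start, b$t_start)
                cur$t_end <- max(cur$t_end, b$t_end)
                n <- n + 1L
            } else {
                addFrag(cur, n)
                cur <- b; n <- 1L
            }
        }
        addFrag(cur, n)
    }
    links <- do.call(rbind, frags)
    links <- links[links$length >= min_len, , drop = FALSE]
    if (!nrow(links)) return(emptyLinks)

    ## canonical ordering: side a = lexicographically smaller chromosome
    flip <- links$chrom_b < links$chrom_a
    links[flip, c("chrom_a", "start_a", "end_a",
                  "chrom_b", "start_b", "end_b")] <-
        links[flip, c("chrom_b", "start_b", "end_b",
                      "chrom_a", "start_a", "end_a")]

    ## deduplicate reciprocal mirrors: same chromosome pair with spans
    ## overlapping or within mirror_tol on both sides counts once (the two
    ## sides of a swap are seen from either assembly's coordinates, which
    ## can be shifted against each other by nearby indels)
    near <- function(s1, e1, s2, e2) s1 < e2 + mirror_tol &&
        s2 < e1 + mirror_tol
    keep <- rep(TRUE, nrow(links))
    for (i in seq_len(nrow(links))) {
        if (!keep[i]) next
        for (j in seq_len(nrow(links))) {
            if (j <= i || !keep[j]) next
            if (links$chrom_a[i] == links$chrom_a[j] &&
                links$chrom_b[i] == links$chrom_b[j] &&
                near(links$start_a[i], links$end_a[i],
                     links$start_a[j], links$end_a[j]) &&
                near(links$start_b[i], links$end_b[i],
                     links$start_b[j], links$end_b[j]))
                keep[j] <- FALSE
        }
    }
    links <- links[keep, , drop = FALSE]
    links <- links[order(links$chrom_a, links$start_a), , drop = FALSE]
    rownames(links) <- NULL
    links
}
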