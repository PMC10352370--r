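## Miniature translated homology search (six-frame, TBLASTN-like) with
## Karlin-Altschul significance and site merging.

#' Six-frame translation with coordinate maps
#'
#' Translates a nucleotide sequence in all six reading frames (three
#' forward, three on the reverse complement). Stop codons are rendered
#' \code{*}; ambiguous codons become \code{X}. The companion
#' \code{\link{aaToGenomic}} converts any amino-acid span of a frame back to
#' the exact genomic nucleotide span.
#'
#' @param dna a \link[Biostrings]{DNAString} or character sequence.
#' @return list of six elements, each \code{list(frame =, aa =)} with frame
#'   in \code{1, 2, 3, -1, -2, -3}.
#' @examples
#' sixFrameTranslate("ATG")[[1]]$aa  # "M"
#' @export
sixFrameTranslate <- function(dna) {
    dna <- Biostrings::DNAString(as.character(dna))
    rc <- Biostrings::reverseComplement(dna)
    L <- length(dna)
    one <- function(seq, f) {
        start <- f
        n_cod <- (length(seq) - f + 1L) %/% 3L
        if (n_cod < 1L) return("")
        sub <- Biostrings::subseq(seq, start, start + 3L * n_cod - 1L)
        as.character(Biostrings::translate(sub, if.fuzzy.codon = "X",
                                           no.init.codon = TRUE))
    }
    out <- list()
    for (f in 1:3)
        out[[length(out) + 1L]] <- list(frame = f, aa = one(dna, f))
    for (f in 1:3)
        out[[length(out) + 1L]] <- list(frame = -f, aa = one(rc, f))
    out
}

#' Map an amino-acid span of a reading frame to genomic coordinates
#'
#' @param frame frame in \code{1, 2, 3, -1, -2, -3}.
#' @param seq_len nucleotide length of the translated sequence.
#' @param aa_start,aa_end 0-based half-open amino-acid span within the
#'   frame's translation.
#' @return integer vector \code{c(start, end)}: 0-based half-open genomic
#'   nucleotide span on the forward strand.
#' @export
aaToGenomic <- function(frame, seq_len, aa_start, aa_end) {
    g <- abs(frame)
    s <- (g - 1L) + 3L * aa_start
    e <- (g - 1L) + 3L * aa_end
    if (frame > 0) c(start = as.integer(s), end = as.integer(e))
    else c(start = as.integer(seq_len - e), end = as.integer(seq_len - s))
}

## Substitution matrix with stop-codon policy applied; integer matrix with
## residue characters as dimnames.
scoringMatrix <- function(params) {
    if (params@matrix != "BLOSUM62")
        stopf("unknown substitution matrix '%s'", params@matrix)
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    mat <- e$BLOSUM62
    stop_score <- if (params@stop_breaks) -100000L else -4L
    mat["*", ] <- stop_score
    mat[, "*"] <- stop_score
    storage.mode(mat) <- "integer"
    mat
}

encodeAA <- function(x, alphabet) {
    v <- match(strsplit(x, "", fixed = TRUE)[[1]], alphabet)
    if (anyNA(v))
        stopf("unknown residue '%s'",
              strsplit(x, "", fixed = TRUE)[[1]][which(is.na(v))[1]])
    v - 1L
}

#' Local protein alignment (Smith-Waterman, affine gaps)
#'
#' Optimal local alignment of two amino-acid sequences under the configured
#' substitution matrix with affine gap costs (a gap of length k costs
#' \code{gap_open + k * gap_extend}). With \code{stop_breaks} (the default)
#' alignments never extend through a stop codon, reflecting that the
#' targets of the screen are pseudogenised insertions.
#'
#' @param query,subject amino-acid sequences (character or
#'   \link[Biostrings]{AAString}).
#' @param params a \linkS4class{ScoringParams}.
#' @return list: \code{score} (raw score S) and 0-based half-open
#'   \code{q_start}, \code{q_end}, \code{s_start}, \code{s_end} aligned
#'   spans.
#' @export
localAlign <- function(query, subject, params = scoringParams()) {
    query <- as.character(query); subject <- as.character(subject)
    if (!nzchar(query) || !nzchar(subject))
        stopf("empty sequence")
    mat <- scoringMatrix(params)
    alph <- rownames(mat)
    qenc <- encodeAA(query, alph)
    if (params@stop_breaks && grepl("*", subject, fixed = TRUE)) {
        ## a stop hard-breaks the subject: align each stop-free segment
        segs <- strsplit(subject, "*", fixed = TRUE)[[1]]
        offs <- cumsum(c(0L, nchar(segs) + 1L))
        best <- list(score = 0, q_start = 0L, q_end = 0L,
                     s_start = 0L, s_end = 0L)
        for (k in seq_along(segs)) {
            if (!nzchar(segs[k])) next
            r <- .sw_align(qenc, encodeAA(segs[k], alph), mat,
                           params@gap_open, params@gap_extend)
            if (r$score > best$score) {
                r$s_start <- r$s_start + offs[k]
                r$s_end <- r$s_end + offs[k]
                best <- r
            }
        }
        best$score <- as.numeric(best$score)
        return(best)
    }
    res <- .sw_align(qenc, encodeAA(subject, alph), mat,
                     params@gap_open, params@gap_extend)
    res$score <- as.numeric(res$score)
    res
}

#' Karlin-Altschul bit score and E-value
#'
#' \code{E = K * m * n * exp(-lambda * S)} and
#' \code{bit = (lambda * S - ln K) / ln 2}. The search space is the raw
#' product of query length and searched letters (no length correction).
#'
#' @param S raw alignment score.
#' @param m query length (amino acids).
#' @param n searched letters (total translated amino acids).
#' @param params a \linkS4class{ScoringParams} carrying lambda and K.
#' @return list: \code{bit}, \code{evalue}.
#' @examples
#' karlinAltschulEvalue(0, 100, 1000)$evalue  # K*m*n = 4100
#' @export
karlinAltschulEvalue <- function(S, m, n, params = scoringParams()) {
    if (any(S < 0) || m <= 0 || n <= 0)
        stopf("need S >= 0 and positive search space")
    list(bit = (params@lambda * S - log(params@K)) / log(2),
         evalue = params@K * m * n * exp(-params@lambda * S))
}

## Residue encoding (0 = unknown) and rolling word codes for seed matching.
encodeForSeeds <- function(x, alphabet) {
    v <- match(strsplit(x, "", fixed = TRUE)[[1]], alphabet)
    v[is.na(v)] <- 0L
    v
}

rollWordCodes <- function(v, word_size, alphabet) {
    nA <- length(alphabet) + 1L
    n <- length(v) - word_size + 1L
    if (n < 1L) return(numeric(0))
    code <- numeric(n)
    for (k in seq_len(word_size))
        code <- code * nA + v[k:(k + n - 1L)]
    code
}

## Subject positions (0-based) of two-hit seeds: two exact word_size-mer
## matches lying on the same query-subject diagonal within two_hit_dist.
## The two-hit rule keeps the candidate set small on unrelated sequence
## while diverged homologous regions produce many co-diagonal words.
## `senc`/`qenc` are encoded residue vectors from encodeForSeeds().
seedPositions <- function(senc, qenc, word_size, alphabet,
                          two_hit_dist = 64L) {
    qcode <- rollWordCodes(qenc, word_size, alphabet)
    scode <- rollWordCodes(senc, word_size, alphabet)
    uq <- unique(qcode)
    qpos_by_word <- split(seq_along(qcode) - 1L, match(qcode, uq))
    hit <- match(scode, uq)
    sidx <- which(!is.na(hit))
    if (!length(sidx)) return(integer(0))
    qpos <- qpos_by_word[as.character(hit[sidx])]
    spos <- rep.int(sidx - 1L, lengths(qpos))
    diag <- spos - unlist(qpos, use.names = FALSE)
    ord <- order(diag, spos)
    diag <- diag[ord]; spos <- spos[ord]
    hit2 <- which(diff(diag) == 0L & diff(spos) > 0L &
                      diff(spos) <= two_hit_dist)
    if (!length(hit2)) return(data.frame(spos = integer(), diag = integer()))
    out <- unique(data.frame(spos = spos[hit2 + 1L], diag = diag[hit2 + 1L]))
    out[order(out$spos), , drop = FALSE]
}

## Best ungapped segment score along a candidate diagonal (maximum
## subarray of per-residue substitution scores, computed via cumulative
## sums), restricted to about one query length around the seed. Candidates
## whose ungapped diagonal score stays below `min_score` are discarded
## before gapped verification - the usual translated-search staging.
ungappedDiagScore <- function(senc, qenc, spos, diag, mat, xidx) {
    q0 <- spos - diag            # query position aligned with spos
    lo <- max(0L, spos - q0)     # subject start when query starts at 0
    qlo <- lo - diag
    n <- min(length(senc) - lo, length(qenc) - qlo)
    if (n <= 0L) return(0)
    si <- senc[(lo + 1L):(lo + n)]
    qi <- qenc[(qlo + 1L):(qlo + n)]
    si[si == 0L] <- xidx
    qi[qi == 0L] <- xidx
    sc <- mat[cbind(qi, si)]
    cs <- cumsum(as.numeric(sc))
    max(cs - cummin(c(0, cs[-length(cs)])))
}

## Merge seed positions into candidate subject windows [start, end) 0-based,
## splitting any merged window into tiles so a single verification alignment
## never exceeds a few query lengths.
seedWindows <- function(seed_pos, qlen, subj_len, slack = 50L) {
    if (!length(seed_pos)) return(data.frame(start = integer(),
                                             end = integer()))
    s <- pmax(0L, seed_pos - qlen - slack)
    e <- pmin(subj_len, seed_pos + qlen + slack)
    u <- intervalUnion0(as.integer(s), as.integer(e))
    maxw <- 4L * qlen + 2L * slack
    out <- list()
    for (i in seq_len(nrow(u))) {
        if (u$end[i] - u$start[i] <= maxw) {
            out[[length(out) + 1L]] <- u[i, ]
        } else {
            st <- u$start[i]
            while (st < u$end[i]) {
                out[[length(out) + 1L]] <- data.frame(
                    start = st, end = min(u$end[i], st + maxw))
                st <- st + maxw - qlen   # tiles overlap by one query length
            }
        }
    }
    do.call(rbind, out)
}

#' Scan a genome for translated matches to protein queries
#'
#' Six-frame translation of every chromosome; exact \code{word_size}-mer
#' seeds locate candidate windows which are verified by Smith-Waterman local
#' alignment; hits passing the query-coverage and E-value filters (strictly
#' greater than \code{qcov_min}, strictly less than \code{evalue_max}) are
#' reported with genomic coordinates. The search space \code{n} is the total
#' number of translated letters over all frames and chromosomes.
#'
#' @param queries named character vector or \link[Biostrings]{AAStringSet}
#'   of protein queries.
#' @param genome named \link[Biostrings]{DNAStringSet}.
#' @param params a \linkS4class{ScoringParams}.
#' @return data.frame of hits: query_id, q_start, q_end (aa), chrom, start,
#'   end (nt, forward-strand), strand, frame, score, bit, evalue, qcov.
#' @export
scanGenome <- function(queries, genome, params = scoringParams()) {
    queries <- stats::setNames(as.character(queries), names(queries))
    if (is.null(names(queries)) || any(!nzchar(names(queries))))
        stopf("queries must be named")
    mat <- scoringMatrix(params)
    alph <- rownames(mat)
    xidx <- match("X", alph)
    frames <- lapply(names(genome), function(ch) {
        fr <- sixFrameTranslate(genome[[ch]])
        lapply(fr, function(f) {
            f$enc <- encodeForSeeds(f$aa, alph)   # once per frame
            f
        })
    })
    names(frames) <- names(genome)
    n_letters <- sum(vapply(frames, function(fr)
        sum(vapply(fr, function(f) nchar(f$aa), 0)), 0))
    hits <- list()
    for (qid in names(queries)) {
        qseq <- queries[[qid]]
        qlen <- nchar(qseq)
        qenc <- encodeForSeeds(qseq, alph)
        for (ch in names(genome)) {
            chrom_len <- BiocGenerics::width(genome)[names(genome) == ch]
            for (f in frames[[ch]]) {
                if (!nzchar(f$aa)) next
                seeds <- seedPositions(f$enc, qenc, params@word_size, alph)
                if (nrow(seeds)) {
                    ug <- vapply(seq_len(nrow(seeds)), function(k)
                        ungappedDiagScore(f$enc, qenc, seeds$spos[k],
                                          seeds$diag[k], mat, xidx), 0)
                    seeds <- seeds[ug >= params@ungapped_min, , drop = FALSE]
                }
                wins <- seedWindows(seeds$spos, qlen, nchar(f$aa))
                for (w in seq_len(nrow(wins))) {
                    sub <- substring(f$aa, wins$start[w] + 1L, wins$end[w])
                    al <- localAlign(qseq, sub, params)
                    if (al$score <= 0) next
                    ka <- karlinAltschulEvalue(al$score, qlen, n_letters,
                                               params)
                    qcov <- (al$q_end - al$q_start) / qlen
                    if (!(qcov > params@qcov_min &&
                          ka$evalue < params@evalue_max)) next
                    gsp <- aaToGenomic(f$frame, chrom_len,
                                       wins$start[w] + al$s_start,
                                       wins$start[w] + al$s_end)
                    hits[[length(hits) + 1L]] <- data.frame(
                        query_id = qid, q_start = al$q_start,
                        q_end = al$q_end, chrom = ch,
                        start = gsp[["start"]], end = gsp[["end"]],
                        strand = if (f$frame > 0) "+" else "-",
                        frame = f$frame, score = al$score, bit = ka$bit,
                        evalue = ka$evalue, qcov = qcov,
                        stringsAsFactors = FALSE)
                }
            }
        }
    }
    out <- if (length(hits)) do.call(rbind, hits) else
        data.frame(query_id = character(), q_start = integer(),
                   q_end = integer(), chrom = character(), start = integer(),
                   end = integer(), strand = character(), frame = integer(),
                   score = numeric(), bit = numeric(), evalue = numeric(),
                   qcov = numeric(), stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out[order(out$query_id, out$chrom, out$start), , drop = FALSE]
}

#' Merge hits into sites
#'
#' Hits of the same query on the same chromosome and strand that overlap or
#' lie within \code{merge_dist} collapse into one site; each site keeps its
#' best (lowest E-value) hit. Frameshifted insertions, which surface as
#' several same-locus hits in different frames, are unified here.
#'
#' @param hits data.frame from \code{\link{scanGenome}}.
#' @param merge_dist merge distance in nucleotides.
#' @return data.frame of sites: chrom, start, end, query_id, strand,
#'   n_hits, best_frame, best_score, best_evalue, best_qcov.
#' @export
mergeHitsToSites <- function(hits, merge_dist = 1000) {
    empty <- data.frame(chrom = character(), start = integer(),
                        end = integer(), query_id = character(),
                        strand = character(), n_hits = integer(),
                        best_frame = integer(), best_score = numeric(),
                        best_evalue = numeric(), best_qcov = numeric(),
                        stringsAsFactors = FALSE)
    if (!nrow(hits)) return(empty)
    sites <- list()
    for (key in unique(paste(hits$query_id, hits$chrom, hits$strand))) {
        p <- strsplit(key, " ", fixed = TRUE)[[1]]
        sub <- hits[hits$query_id == p[1] & hits$chrom == p[2] &
                        hits$strand == p[3], , drop = FALSE]
        sub <- sub[order(sub$start), , drop = FALSE]
        grp <- cumsum(c(1L, as.integer(
            sub$start[-1] > cummax(sub$end[-nrow(sub)]) + merge_dist)))
        for (g in unique(grp)) {
            gg <- sub[grp == g, , drop = FALSE]
            best <- gg[which.min(gg$evalue), ]
            sites[[length(sites) + 1L]] <- data.frame(
                chrom = p[2], start = min(gg$start), end = max(gg$end),
                query_id = p[1], strand = p[3], n_hits = nrow(gg),
                best_frame = best$frame, best_score = best$score,
                best_evalue = best$evalue, best_qcov = best$qcov,
                stringsAsFactors = FALSE)
        }
    }
    out <- do.call(rbind, sites)
    out <- out[order(out$chrom, out$start), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Per-chromosome distribution of sites with a uniformity statistic
#'
#' Counts sites per chromosome, their density per Mb, a chi-square statistic
#' of the observed counts against a length-proportional expectation, and
#' the coefficient of variation of the density - small values of either
#' indicate locations spread uniformly across the genome.
#'
#' @param sites data.frame from \code{\link{mergeHitsToSites}}.
#' @param chrom_lens named numeric vector of chromosome lengths (bases).
#' @return list: \code{table} (chrom, n_sites, density_per_mb),
#'   \code{chisq_stat}, \code{chisq_p}, \code{cv_density}.
#' @export
summarizeDistribution <- function(sites, chrom_lens) {
    counts <- vapply(names(chrom_lens),
                     function(ch) sum(sites$chrom == ch), 0L)
    dens <- counts / (chrom_lens / 1e6)
    tab <- data.frame(chrom = names(chrom_lens), n_sites = counts,
                      density_per_mb = as.numeric(dens),
                      stringsAsFactors = FALSE, row.names = NULL)
    if (sum(counts) > 0) {
        cs <- suppressWarnings(
            stats::chisq.test(counts, p = chrom_lens / sum(chrom_lens)))
        stat <- unname(cs$statistic); pval <- unname(cs$p.value)
    } else {
        stat <- NA_real_; pval <- NA_real_
    }
    list(table = tab, chisq_stat = stat, chisq_p = pval,
         cv_density = if (mean(dens) > 0) stats::sd(dens) / mean(dens)
                      else NA_real_)
}
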