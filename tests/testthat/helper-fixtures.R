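## Shared fixtures: small synthetic scenarios and independent test oracles.

## A small builder scenario: 2 x 80 kb chromosomes, ~15 kb contigs,
## a couple of misjoins, 2 deletions, no translocations.
smallScenario <- function(seed = 7, n_translocations = 0, n_deletions = 2,
                          misjoin_rate = 0.2, substitution_rate = 0,
                          ...) {
    cfg <- simConfig(n_chromosomes = 2, chrom_length = 120000,
                     substitution_rate = substitution_rate,
                     n_translocations = n_translocations,
                     translocation_len = 12000,
                     n_deletions = n_deletions, deletion_len = 3000,
                     contig_len_mean = 15000, contig_len_sd = 2500,
                     misjoin_rate = misjoin_rate, seed = seed, ...)
    ref <- makeReference(cfg)
    sg <- deriveSampleGenome(ref, cfg)
    fr <- fragmentIntoContigs(sg$genome, cfg, sg$truth)
    list(cfg = cfg, reference = ref, sample = sg$genome, truth = fr$truth,
         contigs = fr$contigs,
         blocks = truthContigPaf(fr$truth, fr$contigs, ref),
         pairs = simulatePairsFromTruth(fr$truth, cfg))
}

## Independent N50 oracle: largest member length L with sum(lengths >= L)
## reaching half the total, by enumeration.
n50Oracle <- function(lengths) {
    tot <- sum(lengths)
    cand <- sort(unique(lengths), decreasing = TRUE)
    for (L in cand)
        if (sum(lengths[lengths >= L]) >= tot / 2) return(L)
    min(lengths)
}

## Per-base bitmap oracle for covered fraction and feature classification.
bitmapCovered <- function(blocks, len, chrom) {
    v <- logical(len)
    sub <- blocks[blocks$target_id == chrom, , drop = FALSE]
    for (i in seq_len(nrow(sub)))
        if (sub$t_end[i] > sub$t_start[i])
            v[(sub$t_start[i] + 1):sub$t_end[i]] <- TRUE
    v
}

## Brute-force affine-gap local alignment score oracle (O(n*m) DP kept
## deliberately plain and independent of the package implementation).
swOracle <- function(q, s, mat, gap_open, gap_extend) {
    qv <- strsplit(q, "")[[1]]; sv <- strsplit(s, "")[[1]]
    n <- length(qv); m <- length(sv)
    NEG <- -1e9; oc <- gap_open + gap_extend
    M <- matrix(0, n + 1, m + 1)
    X <- matrix(NEG, n + 1, m + 1)
    Y <- matrix(NEG, n + 1, m + 1)
    best <- 0
    for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
        X[i, j] <- max(M[i - 1, j] - oc, X[i - 1, j] - gap_extend)
        Y[i, j] <- max(M[i, j - 1] - oc, Y[i, j - 1] - gap_extend)
        sc <- mat[qv[i - 1], sv[j - 1]]
        M[i, j] <- max(0, max(M[i - 1, j - 1], X[i - 1, j - 1],
                              Y[i - 1, j - 1]) + sc)
        best <- max(best, M[i, j])
    }
    best
}

blosum62 <- function() {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    e$BLOSUM62
}

randomProtein <- function(n) {
    aas <- setdiff(rownames(blosum62()), c("B", "J", "Z", "X", "*"))
    paste(sample(aas, n, replace = TRUE), collapse = "")
}

emptyPaf0 <- function() chromStitch:::emptyPaf()

emptyTruthSetForTests <- function() chromStitch:::emptyTruthSet()

randomDnaChr <- function(n) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

emptyPairsDf <- function() {
    data.frame(read_id = character(), seq_id = character(),
               pos1 = integer(), strand1 = character(), pos2 = integer(),
               strand2 = character(), insert = integer(),
               stringsAsFactors = FALSE)
}

## Minimal PAF row constructor for hand-built alignment scenarios.
pafRow <- function(query_id, query_len, q_start, q_end, strand, target_id,
                   target_len, t_start, t_end,
                   n_match = q_end - q_start, block_len = q_end - q_start,
                   mapq = 60L) {
    data.frame(query_id = query_id, query_len = as.integer(query_len),
               q_start = as.integer(q_start), q_end = as.integer(q_end),
               strand = strand, target_id = target_id,
               target_len = as.integer(target_len),
               t_start = as.integer(t_start), t_end = as.integer(t_end),
               n_match = as.integer(n_match),
               block_len = as.integer(block_len), mapq = as.integer(mapq),
               tags = "", stringsAsFactors = FALSE)
}
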