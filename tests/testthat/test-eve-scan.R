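test_that("six-frame translation matches a plain codon-table oracle", {
    expect_equal(sixFrameTranslate("ATG")[[1]]$aa, "M")

    set.seed(37)
    dna <- randomDnaChr(300)
    frames <- sixFrameTranslate(dna)
    gc <- Biostrings::GENETIC_CODE
    oracle <- function(s, f) {
        sub <- substring(s, f, f + 3 * ((nchar(s) - f + 1) %/% 3) - 1)
        cods <- substring(sub, seq(1, nchar(sub), 3), seq(3, nchar(sub), 3))
        paste(unname(gc[cods]), collapse = "")
    }
    rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(dna)))
    for (f in 1:3) {
        expect_identical(frames[[f]]$aa, oracle(dna, f))
        expect_identical(frames[[3 + f]]$aa, oracle(rc, f))
    }
})

test_that("aa spans map back to exact genomic nucleotide spans in all frames", {
    set.seed(41)
    dna <- randomDnaChr(601)
    frames <- sixFrameTranslate(dna)
    for (f in frames) {
        n_aa <- nchar(f$aa)
        for (k in 1:10) {
            a <- sample(0:(n_aa - 5), 1); b <- a + sample(1:4, 1)
            sp <- aaToGenomic(f$frame, nchar(dna), a, b)
            expect_equal(sp[["end"]] - sp[["start"]], 3 * (b - a))
            piece <- substr(dna, sp[["start"]] + 1, sp[["end"]])
            if (f$frame < 0)
                piece <- as.character(Biostrings::reverseComplement(
                    Biostrings::DNAString(piece)))
            expect_identical(
                as.character(Biostrings::translate(
                    Biostrings::DNAString(piece), if.fuzzy.codon = "X",
                    no.init.codon = TRUE)),
                substr(f$aa, a + 1, b))
        }
    }
})

test_that("local alignment equals self-score on identical sequences and a DP oracle on random pairs", {
    params <- scoringParams()
    mat <- blosum62()
    q <- "MKVLHTWQRS"
    al <- localAlign(q, q, params)
    diagsum <- sum(vapply(strsplit(q, "")[[1]], function(a) mat[a, a], 0))
    expect_equal(al$score, diagsum)
    expect_equal(c(al$q_start, al$q_end), c(0L, 10L))

    ## no positive-scoring pair: empty local alignment scores zero
    expect_equal(localAlign("PPPP", "WWWW", params)$score, 0)

    ## 50 random pairs against an independent quadratic DP oracle
    set.seed(43)
    for (i in 1:50) {
        a <- randomProtein(sample(5:40, 1))
        b <- randomProtein(sample(5:40, 1))
        got <- localAlign(a, b, params)$score
        expect_equal(got, swOracle(a, b, mat, params@gap_open,
                                   params@gap_extend))
    }

    ## cross-check against an established aligner on a diverged pair
    set.seed(47)
    a <- randomProtein(60)
    bv <- strsplit(a, "")[[1]]
    idx <- sample(60, 12)
    bv[idx] <- vapply(bv[idx], function(x)
        sample(setdiff(c("A", "R", "N", "D", "C"), x), 1), "")
    b <- paste(bv, collapse = "")
    ref_aln <- Biostrings::pairwiseAlignment(
        Biostrings::AAString(a), Biostrings::AAString(b), type = "local",
        substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1)
    expect_equal(localAlign(a, b, params)$score,
                 as.numeric(Biostrings::score(ref_aln)))

    expect_error(localAlign("MK;V", "MKV", params), "unknown residue")
})

test_that("stop codons break alignments unless readthrough is enabled", {
    left <- randomProtein(30)
    q <- paste0(left, randomProtein(30))
    s <- paste0(left, "*", substr(q, 31, 60))
    hard <- localAlign(q, s, scoringParams())
    soft <- localAlign(q, s, scoringParams(stop_breaks = FALSE))
    ## hard break: best alignment confined to one side of the stop
    expect_lte(hard$q_end - hard$q_start, 30L)
    expect_gt(soft$q_end - soft$q_start, 30L)
})

test_that("E-values follow the closed form and its scaling laws", {
    p <- scoringParams()
    expect_equal(karlinAltschulEvalue(0, 100, 1000, p)$evalue,
                 0.041 * 100 * 1000)
    e1 <- karlinAltschulEvalue(50, 200, 1e6, p)$evalue
    e2 <- karlinAltschulEvalue(50, 200, 2e6, p)$evalue
    expect_equal(e2 / e1, 2)
    ## monotone decreasing in S; exact closed form at spot values
    S <- c(10, 40, 80, 160)
    ev <- vapply(S, function(s)
        karlinAltschulEvalue(s, 137, 3.3e6, p)$evalue, 0)
    expect_true(all(diff(ev) < 0))
    expect_equal(ev, 0.041 * 137 * 3.3e6 * exp(-0.267 * S))
    bits <- vapply(S, function(s)
        karlinAltschulEvalue(s, 137, 3.3e6, p)$bit, 0)
    expect_equal(bits, (0.267 * S - log(0.041)) / log(2))
})

test_that("the scanner finds planted copies with exact coordinates and honours both filters", {
    cfg <- simConfig(n_chromosomes = 1, chrom_length = 150000, seed = 53,
                     n_translocations = 0, n_deletions = 0,
                     substitution_rate = 0)
    ref <- makeReference(cfg)
    prot <- syntheticProtein(120, seed = 53)
    pl <- plantEveCopies(ref, prot, 3, aa_divergence = 0, seed = 53)
    hits <- scanGenome(c(q = prot), pl$genome)
    expect_equal(nrow(hits), 3L)
    expect_true(all(hits$qcov == 1))
    expect_true(all(hits$evalue < 1e-10))
    expect_equal(hits$start, pl$truth$start)
    expect_equal(hits$end, pl$truth$end)
    expect_equal(hits$strand, pl$truth$strand)
    expect_equal(hits$frame, pl$truth$frame)

    ## coordinate fidelity: re-translating each hit span in the recorded
    ## frame reproduces the aligned subject residues (here, the query)
    for (i in seq_len(nrow(hits))) {
        dna <- Biostrings::subseq(pl$genome[[hits$chrom[i]]],
                                  hits$start[i] + 1, hits$end[i])
        if (hits$strand[i] == "-")
            dna <- Biostrings::reverseComplement(dna)
        expect_identical(as.character(
            Biostrings::translate(dna, no.init.codon = TRUE)), prot)
    }

    ## a hit covering only 40% of the query is rejected regardless of E
    long_q <- paste0(prot, syntheticProtein(180, seed = 59))
    hits40 <- scanGenome(c(q = long_q), pl$genome)
    expect_equal(nrow(hits40), 0L)
    ## same alignment passes once the coverage threshold admits it
    hits40b <- scanGenome(c(q = long_q), pl$genome,
                          scoringParams(qcov_min = 0.30))
    expect_equal(nrow(hits40b), 3L)
    expect_true(all(hits40b$evalue < 1e-10))
    expect_true(all(abs(hits40b$qcov - 0.4) < 0.02))

    ## shuffled negative control: no significant hits
    set.seed(61)
    shuf <- paste(sample(strsplit(prot, "")[[1]]), collapse = "")
    expect_equal(nrow(scanGenome(c(neg = shuf), pl$genome)), 0L)

    ## monotonicity: stricter thresholds can only shrink the hit set
    relaxed <- scanGenome(c(q = long_q), pl$genome,
                          scoringParams(qcov_min = 0.2, evalue_max = 10))
    strict <- scanGenome(c(q = long_q), pl$genome,
                         scoringParams(qcov_min = 0.35, evalue_max = 1e-5))
    key <- function(h) paste(h$chrom, h$start, h$end, h$frame)
    expect_true(all(key(strict) %in% key(relaxed)))
})

test_that("hit merging unifies nearby hits and the distribution summary is length-aware", {
    h <- data.frame(query_id = "q", q_start = 0L, q_end = 100L,
                    chrom = "chr1", start = c(1000L, 1800L, 20000L),
                    end = c(1300L, 2100L, 20300L), strand = "+",
                    frame = c(1L, 2L, 1L), score = c(100, 90, 80),
                    bit = 50, evalue = c(1e-20, 1e-10, 1e-5),
                    qcov = 0.9, stringsAsFactors = FALSE)
    sites <- mergeHitsToSites(h, merge_dist = 1000)
    expect_equal(nrow(sites), 2L)
    expect_equal(sites$n_hits, c(2L, 1L))
    expect_equal(sites$best_evalue[1], 1e-20)
    expect_equal(sites$start[1], 1000L)
    expect_equal(sites$end[1], 2100L)
    ## a single hit is its own site; different strands never merge
    h2 <- h[1:2, ]; h2$strand <- c("+", "-")
    expect_equal(nrow(mergeHitsToSites(h2, merge_dist = 1000)), 2L)

    lens <- c(chr1 = 2e6, chr2 = 1e6)
    s <- summarizeDistribution(sites, lens)
    expect_equal(s$table$n_sites, c(2L, 0L))
    expect_equal(s$table$density_per_mb, c(1, 0))
    expect_true(is.finite(s$chisq_stat))
})
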