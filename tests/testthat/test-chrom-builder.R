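test_that("filtration drops short contigs at the 10 kb boundary and contained alignments", {
    blocks <- rbind(
        pafRow("short", 9999, 0, 9999, "+", "chr1", 500000, 0, 9999),
        pafRow("exact", 10000, 0, 10000, "+", "chr1", 500000, 20000, 30000),
        pafRow("big", 450000, 0, 450000, "+", "chr1", 500000, 50000, 500000),
        pafRow("inner", 100000, 0, 100000, "+", "chr1", 500000,
               100000, 200000))
    res <- filterAlignments(blocks, builderConfig())
    expect_setequal(res$excluded$contig_id, c("short", "inner"))
    expect_equal(res$excluded$reason[res$excluded$contig_id == "short"],
                 "short")
    expect_equal(res$excluded$reason[res$excluded$contig_id == "inner"],
                 "contained")
    expect_setequal(unique(res$kept$query_id), c("exact", "big"))

    ## single contig, single alignment passes untouched
    one <- pafRow("solo", 20000, 0, 20000, "+", "chr1", 500000, 0, 20000)
    expect_equal(nrow(filterAlignments(one)$kept), 1L)
})

test_that("containment removal agrees with a brute-force pairwise oracle", {
    set.seed(101)
    for (rep in 1:5) {
        n <- 30
        ql <- sample(10000:80000, n, replace = TRUE)
        st <- sample(0:400000, n, replace = TRUE)
        blocks <- do.call(rbind, lapply(seq_len(n), function(i)
            pafRow(sprintf("t%02d", i), ql[i], 0, ql[i], "+", "chr1",
                   500000, st[i], min(500000, st[i] + ql[i]))))
        res <- filterAlignments(blocks, builderConfig(min_contig_len = 1000))
        drop_oracle <- vapply(seq_len(n), function(i) {
            any(vapply(seq_len(n), function(j) {
                j != i && blocks$query_id[j] != blocks$query_id[i] &&
                    blocks$query_len[i] < blocks$query_len[j] &&
                    blocks$t_start[j] <= blocks$t_start[i] &&
                    blocks$t_end[i] <= blocks$t_end[j]
            }, logical(1)))
        }, logical(1))
        expect_setequal(res$kept$query_id, blocks$query_id[!drop_oracle])
    }
})

test_that("mapping classification nominates breakpoints only for far or cross-chromosome segments", {
    cfg <- builderConfig()
    one <- pafRow("a", 50000, 500, 49500, "+", "chr1", 500000, 0, 49000)
    cl <- classifyContig(one, cfg)
    expect_equal(cl$mapping_class, "single")
    expect_equal(nrow(cl$breakpoints), 0L)

    ## two segments 40 kb apart on one chromosome: not "far", no breakpoint
    near <- rbind(
        pafRow("a", 50000, 0, 25000, "+", "chr1", 500000, 0, 25000),
        pafRow("a", 50000, 25000, 50000, "+", "chr1", 500000, 65000, 90000))
    cl <- classifyContig(near, cfg)
    expect_equal(nrow(cl$breakpoints), 0L)
    expect_equal(cl$mapping_class, "single")

    ## same segments beyond far_distance
    far <- near
    far$t_start[2] <- 150000; far$t_end[2] <- 175000
    cl <- classifyContig(far, cfg)
    expect_equal(cl$mapping_class, "multi_same_chrom_far")
    expect_equal(nrow(cl$breakpoints), 1L)

    ## different chromosomes split at the shared query offset
    diffc <- rbind(
        pafRow("a", 25000, 0, 12000, "+", "chr1", 500000, 0, 12000),
        pafRow("a", 25000, 12000, 25000, "+", "chr3", 500000, 50000, 63000))
    cl <- classifyContig(diffc, cfg)
    expect_equal(cl$mapping_class, "multi_diff_chrom")
    expect_equal(cl$breakpoints$q_pos, 12000L)
})

test_that("breakpoint verdicts follow spanning concordant support", {
    cfg <- builderConfig(min_support = 3)
    call <- data.frame(contig_id = "a", q_pos = 12000L,
                       stringsAsFactors = FALSE)
    ## no pairs at all: split
    v <- validateBreakpoint(call, emptyPairsDf(), cfg, contig_len = 25000L)
    expect_equal(v$verdict, "split")
    expect_true(v$discordant_or_zero)

    ## five spanning concordant pairs: keep
    mk <- function(p1, insert = 2600L, s1 = "+", s2 = "-", id = "a")
        data.frame(read_id = "r", seq_id = id, pos1 = p1, strand1 = s1,
                   pos2 = p1 + insert - 100L, strand2 = s2,
                   insert = insert, stringsAsFactors = FALSE)
    good <- do.call(rbind, lapply(seq(10000, 11000, length.out = 5), mk))
    v <- validateBreakpoint(call, good, cfg, contig_len = 25000L)
    expect_equal(v$verdict, "keep")
    expect_equal(v$concordant_support, 5L)

    ## pairs outside the insert window or non-convergent never count
    bad <- rbind(mk(10500, insert = 5000L),   # outside 2600 +/- 30%
                 mk(10500, s1 = "-", s2 = "-"),
                 mk(100, insert = 2600L))     # does not span q_pos
    v <- validateBreakpoint(call, bad, cfg, contig_len = 25000L)
    expect_equal(v$verdict, "split")

    expect_error(validateBreakpoint(
        data.frame(contig_id = "a", q_pos = 30000L), good, cfg,
        contig_len = 25000L), "outside")
})

test_that("splitting conserves bases and produces single-mapping pieces", {
    contigs <- Biostrings::DNAStringSet(c(a = strrep("ACGTT", 5000)))
    verd <- data.frame(contig_id = "a", q_pos = 12000L, verdict = "split",
                       stringsAsFactors = FALSE)
    out <- splitContigs(contigs, verd)
    expect_equal(names(out), c("a.1", "a.2"))
    expect_equal(BiocGenerics::width(out), c(12000L, 13000L))
    expect_equal(sum(BiocGenerics::width(out)),
                 sum(BiocGenerics::width(contigs)))
    expect_identical(splitContigs(contigs, verd[0, ]), contigs)
    expect_error(splitContigs(contigs, transform(verd, q_pos = 0L)),
                 "degenerate")

    ## after splitting all planted misjoins every piece maps in one class
    sc <- smallScenario(seed = 53, misjoin_rate = 0.3)
    bld <- buildChromosomes(sc$contigs, sc$reference, sc$blocks, sc$pairs,
                            builderConfig())
    kept2 <- splitBlocks(sc$blocks, bld$breakpoints,
                         stats::setNames(BiocGenerics::width(sc$contigs),
                                         names(sc$contigs)))
    for (id in unique(kept2$query_id)) {
        cl <- classifyContig(kept2[kept2$query_id == id, ], builderConfig())
        expect_equal(cl$mapping_class, "single")
    }
})

test_that("overlap merging cuts at the midpoint above the identity threshold", {
    set.seed(7)
    cfg <- builderConfig()
    left <- paste0(randomDnaChr(5000), strrep("ACGT", 75))
    right <- paste0(strrep("ACGT", 75), randomDnaChr(4000))
    m <- mergeOverlapping(left, right, 300, cfg)
    expect_true(m$merged)
    expect_equal(length(m$seq), nchar(left) + nchar(right) - 300L)

    ## ~25% identity overlap refuses to merge
    m2 <- mergeOverlapping(paste0(randomDnaChr(5000), randomDnaChr(300)),
                           paste0(randomDnaChr(300), randomDnaChr(4000)),
                           300, cfg)
    expect_false(m2$merged)
    expect_lt(m2$identity, cfg@overlap_merge_identity)

    expect_error(mergeOverlapping(randomDnaChr(200), randomDnaChr(5000),
                                  300, cfg), "containment")
})

test_that("layout sizes gaps from reference distance and renders single contigs", {
    contigs <- Biostrings::DNAStringSet(c(a = randomDnaChr(10000),
                                          b = randomDnaChr(12000)))
    blocks <- rbind(
        pafRow("a", 10000, 0, 10000, "+", "chr1", 50000, 0, 10000),
        pafRow("b", 12000, 0, 12000, "+", "chr1", 50000, 10500, 22500))
    layout <- layoutChromosomes(blocks, contigs, builderConfig())
    tb <- layoutTable(layout)
    expect_equal(tb$gap_after, c(500L, 0L))
    rendered <- renderLayout(layout)
    expect_equal(substr(as.character(rendered[[1]]), 10001, 10500),
                 strrep("N", 500))

    ## single minus-strand contig chromosome
    b2 <- pafRow("a", 10000, 0, 10000, "-", "chr2", 20000, 100, 10100)
    l2 <- layoutChromosomes(b2, contigs["a"], builderConfig())
    r2 <- renderLayout(l2)
    expect_identical(as.character(r2[["chr2"]]),
                     as.character(Biostrings::reverseComplement(
                         contigs[["a"]])))
})

test_that("uncovered regions extend deletions by exactly the flank and merge when touching", {
    ref <- Biostrings::DNAStringSet(c(chr1 = randomDnaChr(100000)))
    contigs <- Biostrings::DNAStringSet(c(a = randomDnaChr(50000),
                                          b = randomDnaChr(45000)))
    blocks <- rbind(
        pafRow("a", 50000, 0, 50000, "+", "chr1", 100000, 0, 50000),
        pafRow("b", 45000, 0, 45000, "+", "chr1", 100000, 55000, 100000))
    layout <- layoutChromosomes(blocks, contigs, builderConfig())
    unc <- findUncoveredRegions(layout, ref, builderConfig())
    expect_equal(unc$start, 49000L)
    expect_equal(unc$end, 56000L)

    ## full coverage: empty report
    full <- pafRow("a", 100000, 0, 100000, "+", "chr1", 100000, 0, 100000)
    lfull <- layoutChromosomes(full, Biostrings::DNAStringSet(
        c(a = randomDnaChr(100000))), builderConfig())
    expect_equal(nrow(findUncoveredRegions(lfull, ref, builderConfig())), 0L)
})

test_that("gap patching fills completely with a spanning candidate and partially from one flank", {
    set.seed(31)
    cfg <- builderConfig()
    truthL <- randomDnaChr(6000); gapSeq <- randomDnaChr(3000)
    truthR <- randomDnaChr(6000)
    contigs <- Biostrings::DNAStringSet(c(L = truthL, R = truthR))
    blocks <- rbind(
        pafRow("L", 6000, 0, 6000, "+", "chr1", 15000, 0, 6000),
        pafRow("R", 6000, 0, 6000, "+", "chr1", 15000, 9000, 15000))
    layout <- layoutChromosomes(blocks, contigs,
                                builderConfig(min_contig_len = 1000))
    expect_equal(layoutTable(layout)$gap_after[1], 3000L)

    ## spanning candidate: both flanks anchored, complete fill
    cand <- Biostrings::DNAStringSet(c(
        fill = paste0(substr(truthL, 5001, 6000), gapSeq,
                      substr(truthR, 1, 1000))))
    res <- patchGaps(layout, cand, cfg)
    expect_equal(res$report$status, "complete")
    expect_equal(res$report$gap_after, 0L)
    rendered <- renderLayout(res$layout)
    expect_identical(as.character(rendered[["chr1"]]),
                     paste0(truthL, gapSeq, truthR))

    ## left-anchored candidate with 2000 interior bases shortens the gap
    cand2 <- Biostrings::DNAStringSet(c(
        part = paste0(substr(truthL, 5001, 6000), substr(gapSeq, 1, 2000))))
    res2 <- patchGaps(layout, cand2, cfg)
    expect_equal(res2$report$status, "partial")
    expect_equal(res2$report$gap_after, 1000L)

    ## unrelated candidate fails and leaves the layout unchanged
    res3 <- patchGaps(layout, Biostrings::DNAStringSet(
        c(junk = randomDnaChr(4000))), cfg)
    expect_equal(res3$report$status, "failed")
    expect_identical(layoutTable(res3$layout), layoutTable(layout))
})

test_that("unplaced contigs are rescued only when they carry features", {
    feats <- data.frame(
        seq_id = c("u1", "u1", "u3", "u5", "u7"),
        type = c("gene", "exon", "CDS", "gene", "mRNA"),
        start = 0L, end = 100L, strand = "+",
        feature_id = paste0("f", 1:5), stringsAsFactors = FALSE)
    unplaced <- paste0("u", 1:10)
    res <- rescueUnplaced(unplaced, feats)
    expect_setequal(res$retained, c("u1", "u3", "u5"))
    expect_equal(length(res$dropped), 7L)
})

test_that("complex regions (3+ mutual overlaps) are flagged and excluded", {
    clean <- rbind(
        pafRow("a", 20000, 0, 20000, "+", "chr1", 100000, 0, 20000),
        pafRow("b", 20000, 0, 20000, "+", "chr1", 100000, 19800, 39800))
    expect_equal(flagComplex(clean, builderConfig()), character(0))

    three <- rbind(
        pafRow("a", 30000, 0, 30000, "+", "chr1", 100000, 0, 30000),
        pafRow("b", 30000, 0, 30000, "+", "chr1", 100000, 5000, 35000),
        pafRow("c", 30000, 0, 30000, "+", "chr1", 100000, 10000, 40000))
    flagged <- flagComplex(three, builderConfig())
    expect_setequal(flagged, c("a", "b", "c"))
    layout <- layoutChromosomes(three, Biostrings::DNAStringSet(
        c(a = randomDnaChr(30000), b = randomDnaChr(30000),
          c = randomDnaChr(30000))), builderConfig(), exclude = flagged)
    expect_equal(nrow(layoutTable(layout)), 0L)
})

test_that("noise-free construction reproduces the sample genome and is idempotent", {
    sc <- smallScenario(seed = 61, misjoin_rate = 0.25)
    bld <- buildChromosomes(sc$contigs, sc$reference, sc$blocks, sc$pairs,
                            builderConfig())
    ## all planted misjoins split, nothing else
    val <- validateAgainstTruth(sc$truth, breakpoints = bld$breakpoints,
                                uncovered = bld$uncovered)
    expect_equal(val$recall[val$class == "misjoin"], 1)
    expect_equal(val$precision[val$class == "misjoin"], 1)
    expect_true(all(renderedMatchesSample(bld$chromosomes, sc$sample,
                                          sc$truth)))
    ## base conservation through splitting
    expect_equal(sum(BiocGenerics::width(bld$contigs_final)),
                 sum(BiocGenerics::width(sc$contigs)))
    ## the emitted AGP re-renders to exactly the emitted FASTA
    f <- withr::local_tempfile(fileext = ".agp")
    writeAgp(bld$layout, f)
    re <- renderFromAgp(readAgp(f), layoutComponents(bld$layout))
    expect_identical(as.character(re)[names(bld$chromosomes)],
                     as.character(bld$chromosomes))

    ## idempotence: feeding the rendered chromosomes back (as an identity
    ## alignment against the reference frame) yields one placement per
    ## chromosome and nominates no breakpoints
    sc0 <- smallScenario(seed = 67, misjoin_rate = 0, n_deletions = 0)
    bld0 <- buildChromosomes(sc0$contigs, sc0$reference, sc0$blocks,
                             sc0$pairs, builderConfig())
    rendered <- bld0$chromosomes
    idblocks <- do.call(rbind, lapply(names(rendered), function(ch) {
        w <- BiocGenerics::width(rendered)[names(rendered) == ch]
        pafRow(ch, w, 0, w, "+", ch,
               BiocGenerics::width(sc0$reference)[
                   names(sc0$reference) == ch], 0, w)
    }))
    bld1 <- buildChromosomes(rendered, sc0$reference, idblocks,
                             emptyPairsDf(), builderConfig())
    expect_equal(nrow(bld1$breakpoints), 0L)
    tb <- layoutTable(bld1$layout)
    expect_equal(nrow(tb), length(rendered))
})
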