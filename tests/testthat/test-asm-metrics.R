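test_that("N50 follows the cumulative >= half rule and matches the enumeration oracle", {
    expect_equal(n50(10), 10)
    expect_equal(n50(c(5, 4, 3, 2, 1)), 4)   # cumulative 5, 9 >= 7.5
    expect_error(n50(numeric(0)), "empty")

    set.seed(11)
    for (i in 1:100) {
        lens <- sample(1:5000, sample(1:40, 1), replace = TRUE)
        expect_equal(n50(lens), n50Oracle(lens))
        perm <- lens[sample.int(length(lens))]
        expect_equal(n50(perm), n50(lens))   # permutation invariant
    }
})

test_that("assembly statistics count gaps and the strict 100 kb boundary", {
    seqs <- Biostrings::DNAStringSet(c(
        a = paste0(strrep("A", 60000), strrep("N", 500), strrep("C", 39500)),
        b = strrep("G", 100000),            # exactly 100 kb: not "over"
        c = strrep("T", 100001),
        d = paste0(strrep("A", 1000), strrep("N", 20), strrep("A", 980))))
    st <- assemblyStats(seqs)
    expect_equal(st$n_sequences, 4L)
    expect_equal(st$total_len, 302001)
    expect_equal(st$largest, 100001)
    expect_equal(st$n_over_100kb, 1L)
    expect_equal(st$frac_bases_over_100kb, 100001 / 302001)
    expect_equal(st$gap_count, 2L)
    expect_equal(st$gap_total, 520)
    expect_true(st$n50 <= st$largest && st$largest <= st$total_len)
})

test_that("library totals reproduce fixed-length arithmetic", {
    expect_equal(libraryStats(574495990, 90), 103409278200)
    expect_equal(libraryStats(132057641, 150), 39617292300)
    expect_equal(libraryStats(0, 150), 0)
    expect_error(libraryStats(-1, 100), "non-negative")

    rows <- data.frame(
        library = c("pe90", "pe150", "mp150"),
        read_pairs = c(574495990, NA, 132057641),
        read_len = c(90, NA, 150),
        total_bases = c(NA, 126972193554, NA))
    tot <- libraryTable(rows)
    expect_equal(tot$rows$total_bases[1], 103409278200)
    expect_equal(tot$total, 103409278200 + 126972193554 + 39617292300)
})

test_that("genome fraction equals the per-base bitmap oracle and is monotone", {
    ref <- c(chr1 = 5000, chr2 = 3000)
    expect_equal(genomeFraction(emptyPaf0(), ref), 0)

    set.seed(23)
    for (rep in 1:20) {
        n <- sample(1:15, 1)
        ch <- sample(names(ref), n, replace = TRUE)
        st <- vapply(ch, function(c1) sample(0:(ref[[c1]] - 10), 1), 0)
        en <- pmin(ref[ch], st + sample(10:2000, n, replace = TRUE))
        blocks <- do.call(rbind, lapply(seq_len(n), function(i)
            pafRow(paste0("q", i), 5000, 0, en[i] - st[i], "+", ch[i],
                   ref[[ch[i]]], st[i], en[i])))
        want <- (sum(bitmapCovered(blocks, 5000, "chr1")) +
                     sum(bitmapCovered(blocks, 3000, "chr2"))) / sum(ref)
        expect_equal(genomeFraction(blocks, ref), want, tolerance = 1e-12)
        ## monotone non-decreasing as blocks are added
        half <- blocks[seq_len(max(1, n %/% 2)), , drop = FALSE]
        expect_lte(genomeFraction(half, ref), genomeFraction(blocks, ref))
    }

    tiling <- rbind(pafRow("q1", 5000, 0, 5000, "+", "chr1", 5000, 0, 5000),
                    pafRow("q2", 3000, 0, 3000, "+", "chr2", 3000, 0, 3000))
    expect_equal(genomeFraction(tiling, ref), 1)
})

test_that("feature coverage three-way classification matches the bitmap oracle", {
    blocks <- rbind(pafRow("q", 10000, 0, 4000, "+", "chr1", 10000, 0, 4000),
                    pafRow("q", 10000, 0, 2000, "+", "chr1", 10000,
                           6000, 8000))
    feats <- data.frame(seq_id = "chr1", type = "gene",
                        start = c(100L, 3500L, 4500L),
                        end = c(900L, 4500L, 5500L), strand = "+",
                        feature_id = c("inside", "edge", "outside"),
                        stringsAsFactors = FALSE)
    fc <- featureCoverage(feats, blocks)
    expect_equal(fc$per_feature$status, c("complete", "partial", "missing"))
    expect_equal(fc$summary$complete + fc$summary$partial +
                     fc$summary$missing, nrow(feats))

    set.seed(29)
    cov <- bitmapCovered(blocks, 10000, "chr1")
    for (i in 1:100) {
        s <- sample(0:9900, 1); e <- s + sample(1:99, 1)
        f1 <- data.frame(seq_id = "chr1", type = "gene", start = s, end = e,
                         strand = "+", feature_id = "f",
                         stringsAsFactors = FALSE)
        got <- featureCoverage(f1, blocks)$per_feature$status
        span <- cov[(s + 1):e]
        want <- if (all(span)) "complete" else if (any(span)) "partial"
                else "missing"
        expect_equal(got, want)
    }
})

test_that("gap totals of rendered chromosomes equal the AGP N rows exactly", {
    sc <- smallScenario(seed = 71)
    bld <- buildChromosomes(sc$contigs, sc$reference, sc$blocks, sc$pairs,
                            builderConfig())
    st <- assemblyStats(bld$chromosomes)
    f <- withr::local_tempfile(fileext = ".agp")
    writeAgp(bld$layout, f)
    agp <- readAgp(f)
    expect_equal(st$gap_total, sum(agp$gap_length, na.rm = TRUE))
    expect_equal(st$gap_count, sum(agp$component_type == "N"))
})
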