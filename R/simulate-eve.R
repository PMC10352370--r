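## Planting of diverged endogenous viral element (EVE) copies: a protein is
## reverse-translated with uniform-random synonymous codons, mutated to the
## requested amino-acid divergence, and inserted on a random strand at
## recorded loci at least 10 kb apart.

aaAlphabet <- function() {
    sort(unique(Biostrings::GENETIC_CODE[Biostrings::GENETIC_CODE != "*"]))
}

## codons per amino acid, from the standard genetic code
codonTable <- function() {
    gc <- Biostrings::GENETIC_CODE
    split(names(gc), unname(gc))
}

reverseTranslate <- function(aa) {
    tab <- codonTable()
    res <- strsplit(aa, "", fixed = TRUE)[[1]]
    paste(vapply(res, function(a) {
        cods <- tab[[a]]
        if (is.null(cods)) stopf("cannot reverse-translate residue '%s'", a)
        cods[sampleInt(length(cods), 1L)]
    }, ""), collapse = "")
}

divergeProtein <- function(aa, aa_divergence) {
    res <- strsplit(aa, "", fixed = TRUE)[[1]]
    alph <- aaAlphabet()
    hit <- which(stats::runif(length(res)) < aa_divergence)
    for (i in hit)
        res[i] <- sample(setdiff(alph, res[i]), 1L)
    paste(res, collapse = "")
}

#' Plant diverged protein-coding copies into a genome
#'
#' Each site is a reverse-translated copy of \code{protein} (uniform-random
#' synonymous codons) carrying amino-acid-changing mutations at the requested
#' divergence, inserted on a random strand at a recorded locus; sites are at
#' least 10 kb apart. Re-translating a planted locus in the recorded frame
#' recovers the diverged protein exactly (the copies carry no internal
#' stops).
#'
#' @param genome named \link[Biostrings]{DNAStringSet}.
#' @param protein amino-acid sequence (character or
#'   \link[Biostrings]{AAString}), at least 50 residues.
#' @param n_sites number of copies to plant.
#' @param aa_divergence fraction of residues mutated, in [0, 0.5).
#' @param query_id name recorded for the planted query.
#' @param seed RNG seed.
#' @return list with elements \code{genome} (modified DNAStringSet),
#'   \code{truth} (data.frame of planted sites: chrom, start, end, query_id,
#'   strand, frame, in post-insertion coordinates) and \code{proteins}
#'   (character vector of the diverged copies).
#' @export
plantEveCopies <- function(genome, protein, n_sites, aa_divergence = 0.2,
                           query_id = "query", seed = 1) {
    protein <- as.character(protein)
    if (nchar(protein) < 50L)
        stopf("protein must be at least 50 aa")
    if (grepl("\\*", protein))
        stopf("protein must not contain stop codons")
    if (aa_divergence < 0 || aa_divergence >= 0.5)
        stopf("aa_divergence must lie in [0, 0.5)")
    set.seed(childSeed(seed, 6L))
    min_sep <- 10000L
    margin <- 1000L
    ins_len <- 3L * nchar(protein)
    lens <- stats::setNames(as.numeric(BiocGenerics::width(genome)),
                            names(genome))
    capacity <- sum(pmax(0, floor((lens - 2 * margin) / (min_sep + ins_len))))
    if (n_sites > capacity)
        stopf("genome too small to hold %d sites %d bases apart",
              n_sites, min_sep)

    ## choose pre-insertion loci, >= 10 kb apart on the same chromosome
    loci <- data.frame(chrom = character(), pos = numeric())
    tries <- 0L
    while (nrow(loci) < n_sites) {
        if ((tries <- tries + 1L) > 1000L * n_sites)
            stopf("could not place %d EVE sites", n_sites)
        ch <- sample(names(lens), 1L, prob = lens)
        p <- margin + sampleInt(as.integer(lens[[ch]] - 2 * margin), 1L)
        same <- loci$pos[loci$chrom == ch]
        if (length(same) && any(abs(same - p) < min_sep + ins_len)) next
        loci <- rbind(loci, data.frame(chrom = ch, pos = p))
    }
    loci <- loci[order(loci$chrom, loci$pos), ]

    seqs <- as.character(genome)
    copies <- character(n_sites)
    strands <- sample(c("+", "-"), n_sites, replace = TRUE)
    sites <- list()
    for (ch in unique(loci$chrom)) {
        idx <- which(loci$chrom == ch)
        off <- 0L
        for (i in idx) {
            aa <- divergeProtein(protein, aa_divergence)
            copies[i] <- aa
            dna <- reverseTranslate(aa)
            if (strands[i] == "-") dna <- revcompChr(dna)
            p <- as.integer(loci$pos[i] + off)   # post-insertion position
            seqs[[ch]] <- paste0(substring(seqs[[ch]], 1L, p),
                                 dna,
                                 substring(seqs[[ch]], p + 1L))
            sites[[length(sites) + 1L]] <- data.frame(
                chrom = ch, start = p, end = p + ins_len,
                query_id = query_id, strand = strands[i],
                frame = NA_integer_, stringsAsFactors = FALSE)
            off <- off + ins_len
        }
    }
    truth <- do.call(rbind, sites)
    ## frames from final coordinates, matching sixFrameTranslate numbering
    final_lens <- nchar(seqs)
    truth$frame <- ifelse(truth$strand == "+",
                          truth$start %% 3L + 1L,
                          -(((final_lens[truth$chrom] - truth$end) %% 3L) + 1L))
    truth <- truth[order(truth$chrom, truth$start), ]
    rownames(truth) <- NULL
    list(genome = Biostrings::DNAStringSet(seqs), truth = truth,
         proteins = copies)
}

#' Generate a synthetic viral-like protein query
#'
#' Deterministic random protein over the 20 standard amino acids, used as a
#' stand-in for retroviral gag/pol queries in simulations and examples
#' (real protein accessions are inputs the user supplies).
#'
#' @param n_aa protein length.
#' @param seed RNG seed.
#' @return character protein sequence.
#' @export
syntheticProtein <- function(n_aa = 500, seed = 99) {
    set.seed(childSeed(seed, 7L))
    paste(sample(aaAlphabet(), n_aa, replace = TRUE), collapse = "")
}
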