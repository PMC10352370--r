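## End-to-end demonstration pipeline on synthetic data, and truth-based
## validation of its outputs.

matchCount <- function(pred_key, truth_key) {
    sum(truth_key %in% pred_key)
}

#' Validate pipeline outputs against a synthetic truth set
#'
#' Computes recall and precision per defect class by direct comparison with
#' the ground truth: split verdicts vs planted misjoins (matched by contig
#' and breakpoint offset within \code{tol}), translocation links vs planted
#' reciprocal swaps (matched by canonical chromosome pair and overlapping
#' spans on both sides), reported uncovered regions vs planted deletions
#' extended by \code{flank_ext}, and recovered sites vs planted EVE loci
#' (matched by chromosome and span overlap).
#'
#' @param truth a \linkS4class{TruthSet}.
#' @param breakpoints validated breakpoint table (with \code{verdict}).
#' @param links translocation links data.frame.
#' @param uncovered uncovered-region data.frame.
#' @param sites EVE site data.frame.
#' @param eve_truth planted-site data.frame (from
#'   \code{\link{plantEveCopies}}).
#' @param flank_ext extension used when the uncovered regions were reported.
#' @param tol breakpoint offset tolerance in bases.
#' @return data.frame: class, n_truth, n_pred, tp, recall, precision.
#' @export
validateAgainstTruth <- function(truth, breakpoints = NULL, links = NULL,
                                 uncovered = NULL, sites = NULL,
                                 eve_truth = NULL, flank_ext = 1000,
                                 tol = 100) {
    rows <- list()
    addRow <- function(class, n_truth, n_pred, tp) {
        rows[[length(rows) + 1L]] <<- data.frame(
            class = class, n_truth = n_truth, n_pred = n_pred, tp = tp,
            recall = if (n_truth) tp / n_truth else NA_real_,
            precision = if (n_pred) tp / n_pred else NA_real_,
            stringsAsFactors = FALSE)
    }
    if (!is.null(breakpoints)) {
        mj <- truthMisjoins(truth)
        splits <- breakpoints[breakpoints$verdict == "split", , drop = FALSE]
        tp <- 0L
        for (i in seq_len(nrow(mj)))
            if (any(splits$contig_id == mj$contig_id[i] &
                        abs(splits$q_pos - mj$q_pos[i]) <= tol))
                tp <- tp + 1L
        pred_tp <- 0L
        for (i in seq_len(nrow(splits)))
            if (any(mj$contig_id == splits$contig_id[i] &
                        abs(mj$q_pos - splits$q_pos[i]) <= tol))
                pred_tp <- pred_tp + 1L
        addRow("misjoin", nrow(mj), nrow(splits), tp)
    }
    if (!is.null(links)) {
        tr <- truthTranslocations(truth)
        ## canonicalise the truth swap to match link ordering
        tp <- 0L
        for (i in seq_len(nrow(tr))) {
            a <- tr[i, ]
            if (a$chrom_b < a$chrom_a)
                a <- data.frame(chrom_a = a$chrom_b, start_a = a$start_b,
                                end_a = a$end_b, chrom_b = a$chrom_a,
                                start_b = a$start_a, end_b = a$end_a)
            hit <- links$chrom_a == a$chrom_a & links$chrom_b == a$chrom_b &
                links$start_a < a$end_a & a$start_a < links$end_a &
                links$start_b < a$end_b & a$start_b < links$end_b
            if (any(hit)) tp <- tp + 1L
        }
        addRow("translocation", nrow(tr), nrow(links), tp)
    }
    if (!is.null(uncovered)) {
        dl <- truthDeletions(truth)
        tp <- 0L
        for (i in seq_len(nrow(dl)))
            if (any(uncovered$chrom == dl$chrom[i] &
                        uncovered$start < dl$end[i] + flank_ext &
                        dl$start[i] - flank_ext < uncovered$end))
                tp <- tp + 1L
        addRow("uncovered_region", nrow(dl), nrow(uncovered), tp)
    }
    if (!is.null(sites) && !is.null(eve_truth)) {
        tp <- 0L
        for (i in seq_len(nrow(eve_truth)))
            if (any(sites$chrom == eve_truth$chrom[i] &
                        sites$start < eve_truth$end[i] &
                        eve_truth$start[i] < sites$end))
                tp <- tp + 1L
        addRow("eve_site", nrow(eve_truth), nrow(sites), tp)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Revert recorded reciprocal translocations in a sample genome
#'
#' Swaps the translocated fragments back to their reference arrangement (in
#' sample coordinates, accounting for deletions), producing the genome a
#' reference-guided layout is expected to reconstruct.
#'
#' @param sample sample genome \link[Biostrings]{DNAStringSet}.
#' @param truth a \linkS4class{TruthSet}.
#' @return \link[Biostrings]{DNAStringSet}.
#' @export
revertTranslocations <- function(sample, truth) {
    tr <- truthTranslocations(truth)
    if (!nrow(tr)) return(sample)
    seqs <- as.character(sample)
    for (i in seq_len(nrow(tr))) {
        len <- tr$end_a[i] - tr$start_a[i]
        sa <- tr$start_a[i] - sampleToRefOffsetRef(truth, tr$chrom_a[i],
                                                   tr$start_a[i])
        sb <- tr$start_b[i] - sampleToRefOffsetRef(truth, tr$chrom_b[i],
                                                   tr$start_b[i])
        a <- tr$chrom_a[i]; b <- tr$chrom_b[i]
        frag_a <- substr(seqs[[a]], sa + 1L, sa + len)
        frag_b <- substr(seqs[[b]], sb + 1L, sb + len)
        substr(seqs[[a]], sa + 1L, sa + len) <- frag_b
        substr(seqs[[b]], sb + 1L, sb + len) <- frag_a
    }
    Biostrings::DNAStringSet(seqs)
}

#' Do rendered chromosomes reproduce the sample genome outside gaps?
#'
#' Removes the N gap runs from each rendered chromosome and compares the
#' result with the corresponding sample chromosome: under a noise-free
#' layout the two must be identical, since gaps arise only where deleted
#' reference sequence separates consecutive contigs. When a truth set with
#' translocations is supplied, the comparison target is the sample with the
#' reciprocal swaps reverted, since a reference-guided layout re-arranges
#' translocated content into reference order.
#'
#' @param chromosomes rendered \link[Biostrings]{DNAStringSet}.
#' @param sample sample genome \link[Biostrings]{DNAStringSet}.
#' @param truth optional \linkS4class{TruthSet} for the translocation
#'   reversal.
#' @return named logical vector, one element per sample chromosome.
#' @export
renderedMatchesSample <- function(chromosomes, sample, truth = NULL) {
    if (!is.null(truth)) sample <- revertTranslocations(sample, truth)
    vapply(names(sample), function(ch) {
        if (!ch %in% names(chromosomes)) return(FALSE)
        got <- gsub("N", "", as.character(chromosomes[[ch]]), fixed = TRUE)
        identical(got, as.character(sample[[ch]]))
    }, logical(1))
}

#' Run the whole pipeline on synthetic data
#'
#' Simulates a reference/sample genome pair with planted defects, fragments
#' it into contigs, simulates read pairs, builds chromosomes, computes
#' assembly metrics, detects translocations, plants and screens for EVE
#' sites, validates everything against the truth, and writes the output
#' bundle (FASTA, AGP, BED, TSV) to \code{out_dir}.
#'
#' @param out_dir output directory (created if missing).
#' @param sim a \linkS4class{SimConfig}.
#' @param builder a \linkS4class{BuilderConfig}.
#' @param scoring a \linkS4class{ScoringParams}.
#' @param n_eve_sites planted EVE copies (default 24).
#' @param aa_divergence amino-acid divergence of the planted copies.
#' @param seed overrides \code{sim@seed} when given.
#' @return (invisibly) list with all intermediate objects, the validation
#'   table (\code{$validation}) and the summary data.frame (\code{$summary}).
#' @export
runDemo <- function(out_dir = tempfile("chromstitch_demo"),
                    sim = simConfig(), builder = builderConfig(),
                    scoring = scoringParams(), n_eve_sites = 24,
                    aa_divergence = 0.2, seed = NULL) {
    if (!is.null(seed)) sim@seed <- as.integer(seed)
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    p <- function(f) file.path(out_dir, f)

    reference <- makeReference(sim)
    sg <- deriveSampleGenome(reference, sim)
    fr <- fragmentIntoContigs(sg$genome, sim, sg$truth)
    truth <- fr$truth
    pairs <- simulatePairsFromTruth(truth, sim)
    blocks <- truthContigPaf(truth, fr$contigs, reference)

    build <- buildChromosomes(fr$contigs, reference, blocks, pairs, builder)
    stats <- assemblyStats(build$chromosomes)

    gblocks <- truthGenomePaf(truth, sg$genome, reference)
    links <- detectTranslocations(gblocks)

    protein <- syntheticProtein(seed = sim@seed)
    planted <- plantEveCopies(sg$genome, protein, n_eve_sites,
                              aa_divergence, query_id = "gag_like",
                              seed = sim@seed)
    hits <- scanGenome(c(gag_like = protein), planted$genome, scoring)
    sites <- mergeHitsToSites(hits)

    validation <- validateAgainstTruth(
        truth, breakpoints = build$breakpoints, links = links,
        uncovered = build$uncovered, sites = sites,
        eve_truth = planted$truth, flank_ext = builder@flank_ext)
    rendered_ok <- renderedMatchesSample(build$chromosomes, sg$genome, truth)

    writeFasta(reference, p("reference.fasta"))
    writeFasta(sg$genome, p("sample.fasta"))
    writeFasta(fr$contigs, p("contigs.fasta"))
    writeFasta(build$chromosomes, p("chromosomes.fasta"))
    writeAgp(build$layout, p("chromosomes.agp"))
    writePaf(blocks, p("contigs_vs_reference.paf"))
    writePairedAlignments(pairs, p("pairs.tsv"))
    writeBed(build$uncovered, p("uncovered.bed"))
    writeLinks(links, p("translocations.tsv"))
    utils::write.table(build$breakpoints, p("breakpoints.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(sites, p("eve_sites.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(validation, p("validation.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)

    summary <- data.frame(
        metric = c("n_contigs", "n_chromosomes", "assembly_n50",
                   "assembly_total_len", "gap_total", "n_breakpoint_splits",
                   "n_translocation_links", "n_eve_sites",
                   "rendered_chrom_ok"),
        value = c(length(fr$contigs), stats$n_sequences, stats$n50,
                  stats$total_len, stats$gap_total,
                  sum(build$breakpoints$verdict == "split"),
                  nrow(links), nrow(sites), sum(rendered_ok)),
        stringsAsFactors = FALSE)
    utils::write.table(summary, p("summary.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)

    invisible(list(reference = reference, sample = sg$genome, truth = truth,
                   contigs = fr$contigs, pairs = pairs, blocks = blocks,
                   build = build, stats = stats, links = links,
                   eve = planted, hits = hits, sites = sites,
                   validation = validation, rendered_ok = rendered_ok,
                   summary = summary, out_dir = out_dir))
}
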