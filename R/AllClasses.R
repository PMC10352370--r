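#' @import methods
#' @importFrom stats rnorm runif rbinom setNames chisq.test sd
#' @importFrom utils read.delim write.table head tail
#' @useDynLib chromStitch, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

## ---------------------------------------------------------------------------
## Configuration classes
## ---------------------------------------------------------------------------

#' Simulation configuration
#'
#' Parameters of the synthetic genome generator: a multi-chromosome reference,
#' a derived sample genome carrying substitutions, deletions and reciprocal
#' interchromosomal translocations, contigs with planted chimeric misjoins and
#' contained duplicates, and mate-pair style read pairs.
#'
#' All coordinates produced under a given configuration are deterministic in
#' \code{seed}: the same configuration yields byte-identical outputs.
#'
#' @slot n_chromosomes number of reference chromosomes.
#' @slot chrom_length bases per chromosome.
#' @slot substitution_rate per-base substitution probability in the sample.
#' @slot n_translocations number of reciprocal interchromosomal swaps.
#' @slot translocation_len length (bases) of each swapped fragment.
#' @slot n_deletions number of deleted regions (become uncovered regions).
#' @slot deletion_len length (bases) of each deletion.
#' @slot contig_len_mean,contig_len_sd normal contig-length model (bases).
#' @slot misjoin_rate expected chimeric joins per tiling fragment.
#' @slot containment_rate probability a redundant contained contig is emitted.
#' @slot short_contig_frac fraction of fragments drawn shorter than 10 kb.
#' @slot max_overlap maximal overlap (bases) between adjacent tiling fragments.
#' @slot read_len bases per mate.
#' @slot insert_mean mean insert size (bases); the mate-pair library modelled
#'   here has inserts of about 2600 bp.
#' @slot insert_tol fractional insert tolerance; inserts are truncated to
#'   \code{insert_mean * (1 +/- insert_tol)}.
#' @slot coverage fold sequence coverage of the read pairs.
#' @slot seed integer RNG seed.
#' @export
setClass("SimConfig", representation(
    n_chromosomes = "integer",
    chrom_length = "integer",
    substitution_rate = "numeric",
    n_translocations = "integer",
    translocation_len = "integer",
    n_deletions = "integer",
    deletion_len = "integer",
    contig_len_mean = "numeric",
    contig_len_sd = "numeric",
    misjoin_rate = "numeric",
    containment_rate = "numeric",
    short_contig_frac = "numeric",
    max_overlap = "integer",
    read_len = "integer",
    insert_mean = "integer",
    insert_tol = "numeric",
    coverage = "numeric",
    seed = "integer"
))

setValidity("SimConfig", function(object) {
    msg <- character()
    lens <- c(chrom_length = object@chrom_length,
              translocation_len = object@translocation_len,
              deletion_len = object@deletion_len,
              read_len = object@read_len,
              insert_mean = object@insert_mean)
    if (any(lens <= 0L))
        msg <- c(msg, paste0("lengths must be > 0: ",
                             paste(names(lens)[lens <= 0L], collapse = ", ")))
    if (object@contig_len_mean <= 0)
        msg <- c(msg, "contig_len_mean must be > 0")
    rates <- c(substitution_rate = object@substitution_rate,
               misjoin_rate = object@misjoin_rate,
               containment_rate = object@containment_rate,
               short_contig_frac = object@short_contig_frac,
               insert_tol = object@insert_tol)
    if (any(rates < 0 | rates > 1))
        msg <- c(msg, paste0("rates must lie in [0,1]: ",
                             paste(names(rates)[rates < 0 | rates > 1],
                                   collapse = ", ")))
    if (any(c(object@n_chromosomes, object@n_translocations,
              object@n_deletions) < 0L))
        msg <- c(msg, "counts must be >= 0")
    if (object@n_chromosomes < 1L)
        msg <- c(msg, "need at least one chromosome")
    if (length(msg)) msg else TRUE
})

#' Construct a simulation configuration
#'
#' Defaults describe the study conditions exercised throughout the package:
#' three 500 kb chromosomes, a sample genome with three 15 kb reciprocal
#' interchromosomal translocations and four 5 kb deletions, ~60 kb contigs
#' with chimeric misjoins, and a ~2600 bp +/- 30 percent mate-pair library at
#' 10-fold coverage.
#'
#' @param n_chromosomes,chrom_length reference shape.
#' @param substitution_rate per-base substitution probability.
#' @param n_translocations,translocation_len reciprocal swap count and size.
#' @param n_deletions,deletion_len deletion count and size.
#' @param contig_len_mean,contig_len_sd contig length model.
#' @param misjoin_rate expected chimeric joins per tiling fragment.
#' @param containment_rate probability of emitting a contained duplicate.
#' @param short_contig_frac fraction of fragments drawn below 10 kb.
#' @param max_overlap maximal overlap between adjacent fragments.
#' @param read_len,insert_mean,insert_tol,coverage read-pair library model.
#' @param seed integer RNG seed.
#' @return A validated \linkS4class{SimConfig}.
#' @examples
#' cfg <- simConfig(n_chromosomes = 2, chrom_length = 50000, seed = 1)
#' @export
simConfig <- function(n_chromosomes = 3, chrom_length = 500000,
                      substitution_rate = 0.001,
                      n_translocations = 3, translocation_len = 15000,
                      n_deletions = 4, deletion_len = 5000,
                      contig_len_mean = 60000, contig_len_sd = 12000,
                      misjoin_rate = 0.2, containment_rate = 0,
                      short_contig_frac = 0, max_overlap = 300,
                      read_len = 100, insert_mean = 2600, insert_tol = 0.30,
                      coverage = 10, seed = 1) {
    new("SimConfig",
        n_chromosomes = as.integer(n_chromosomes),
        chrom_length = as.integer(chrom_length),
        substitution_rate = as.numeric(substitution_rate),
        n_translocations = as.integer(n_translocations),
        translocation_len = as.integer(translocation_len),
        n_deletions = as.integer(n_deletions),
        deletion_len = as.integer(deletion_len),
        contig_len_mean = as.numeric(contig_len_mean),
        contig_len_sd = as.numeric(contig_len_sd),
        misjoin_rate = as.numeric(misjoin_rate),
        containment_rate = as.numeric(containment_rate),
        short_contig_frac = as.numeric(short_contig_frac),
        max_overlap = as.integer(max_overlap),
        read_len = as.integer(read_len),
        insert_mean = as.integer(insert_mean),
        insert_tol = as.numeric(insert_tol),
        coverage = as.numeric(coverage),
        seed = as.integer(seed))
}

setMethod("show", "SimConfig", function(object) {
    cat("SimConfig:", object@n_chromosomes, "chromosomes x",
        object@chrom_length, "bp\n")
    cat("  sample edits: sub rate", object@substitution_rate, ";",
        object@n_translocations, "translocations of",
        object@translocation_len, "bp;",
        object@n_deletions, "deletions of", object@deletion_len, "bp\n")
    cat("  contigs: mean", object@contig_len_mean, "+/-",
        object@contig_len_sd, "bp; misjoin_rate", object@misjoin_rate,
        "; containment_rate", object@containment_rate, "\n")
    cat("  reads: 2 x", object@read_len, "bp, insert", object@insert_mean,
        "+/-", object@insert_tol * 100, "%, coverage", object@coverage,
        "x; seed", object@seed, "\n")
})

#' Chromosome-builder configuration
#'
#' Thresholds for contig filtration, breakpoint classification, read-pair
#' concordance validation, overlap merging and gap sizing.
#'
#' @slot min_contig_len contigs below this length are excluded (default
#'   10000; a contig of exactly 10 kb is kept).
#' @slot far_distance reference gap (bases) beyond which two same-chromosome
#'   segments of one contig count as "far apart" (default 100000).
#' @slot insert_mean,insert_tol expected insert window for concordance.
#' @slot min_support concordant pairs required to keep a junction.
#' @slot flank_ext extension (bases) applied to uncovered regions and used as
#'   the anchoring length when patching gaps (default 1000).
#' @slot overlap_merge_identity minimum identity for merging overlaps.
#' @slot gap_scale multiplier on the reference distance when sizing gaps.
#' @export
setClass("BuilderConfig", representation(
    min_contig_len = "integer",
    far_distance = "integer",
    insert_mean = "integer",
    insert_tol = "numeric",
    min_support = "integer",
    flank_ext = "integer",
    overlap_merge_identity = "numeric",
    gap_scale = "numeric"
))

setValidity("BuilderConfig", function(object) {
    msg <- character()
    if (any(c(object@min_contig_len, object@far_distance, object@insert_mean,
              object@min_support, object@flank_ext) <= 0L))
        msg <- c(msg, "all lengths/counts must be positive")
    if (object@insert_tol <= 0 || object@insert_tol >= 1)
        msg <- c(msg, "insert_tol must lie in (0,1)")
    if (object@overlap_merge_identity <= 0 || object@overlap_merge_identity > 1)
        msg <- c(msg, "overlap_merge_identity must lie in (0,1]")
    if (object@gap_scale <= 0)
        msg <- c(msg, "gap_scale must be positive")
    if (length(msg)) msg else TRUE
})

#' Construct a builder configuration
#'
#' @param min_contig_len minimum contig length kept (bases).
#' @param far_distance same-chromosome "far apart" threshold (bases).
#' @param insert_mean,insert_tol concordant-insert window.
#' @param min_support concordant pairs required at a junction.
#' @param flank_ext uncovered-region extension / patch anchor length.
#' @param overlap_merge_identity identity needed to merge an overlap.
#' @param gap_scale gap length = \code{round(gap_scale * reference distance)}.
#' @return A validated \linkS4class{BuilderConfig}.
#' @export
builderConfig <- function(min_contig_len = 10000, far_distance = 100000,
                          insert_mean = 2600, insert_tol = 0.30,
                          min_support = 3, flank_ext = 1000,
                          overlap_merge_identity = 0.95, gap_scale = 1.0) {
    new("BuilderConfig",
        min_contig_len = as.integer(min_contig_len),
        far_distance = as.integer(far_distance),
        insert_mean = as.integer(insert_mean),
        insert_tol = as.numeric(insert_tol),
        min_support = as.integer(min_support),
        flank_ext = as.integer(flank_ext),
        overlap_merge_identity = as.numeric(overlap_merge_identity),
        gap_scale = as.numeric(gap_scale))
}

setMethod("show", "BuilderConfig", function(object) {
    cat("BuilderConfig: min_contig_len", object@min_contig_len,
        "; far_distance", object@far_distance, "\n")
    cat("  concordance: insert", object@insert_mean, "+/-",
        object@insert_tol * 100, "%, min_support", object@min_support, "\n")
    cat("  flank_ext", object@flank_ext, "; merge identity >=",
        object@overlap_merge_identity, "; gap_scale", object@gap_scale, "\n")
})

#' Scoring parameters of the translated homology search
#'
#' Substitution matrix, affine gap costs, Karlin-Altschul statistics and
#' significance thresholds for the six-frame protein-vs-genome search.
#' Defaults mirror the common gapped BLOSUM62 (open 11 / extend 1)
#' parameterisation with lambda = 0.267 and K = 0.041.
#'
#' @slot matrix substitution matrix name (\code{"BLOSUM62"}).
#' @slot gap_open,gap_extend affine gap costs (positive).
#' @slot lambda,K Karlin-Altschul parameters.
#' @slot qcov_min minimum query coverage (strictly greater-than filter).
#' @slot evalue_max maximum E-value (strictly less-than filter).
#' @slot word_size exact-seed length in amino acids.
#' @slot ungapped_min minimum ungapped diagonal segment score a two-hit
#'   seed region must reach before gapped verification (the usual staging
#'   of translated searches; raise to speed up, lower to catch weaker,
#'   heavily gapped matches).
#' @slot stop_breaks if TRUE (default) alignments never extend through a stop
#'   codon; if FALSE, '*' is scored as a -4 mismatch (readthrough tolerance).
#' @export
setClass("ScoringParams", representation(
    matrix = "character",
    gap_open = "integer",
    gap_extend = "integer",
    lambda = "numeric",
    K = "numeric",
    qcov_min = "numeric",
    evalue_max = "numeric",
    word_size = "integer",
    ungapped_min = "numeric",
    stop_breaks = "logical"
))

setValidity("ScoringParams", function(object) {
    msg <- character()
    if (object@lambda <= 0 || object@K <= 0)
        msg <- c(msg, "lambda and K must be > 0")
    if (object@gap_open <= 0L || object@gap_extend <= 0L)
        msg <- c(msg, "gap costs must be > 0")
    if (object@qcov_min < 0 || object@qcov_min > 1)
        msg <- c(msg, "qcov_min must lie in [0,1]")
    if (object@evalue_max <= 0)
        msg <- c(msg, "evalue_max must be > 0")
    if (object@word_size < 1L)
        msg <- c(msg, "word_size must be >= 1")
    if (length(msg)) msg else TRUE
})

#' Construct scoring parameters
#'
#' @param matrix substitution matrix name (only \code{"BLOSUM62"} ships).
#' @param gap_open,gap_extend affine gap costs.
#' @param lambda,K Karlin-Altschul parameters for the chosen scoring system.
#' @param qcov_min query-coverage threshold (hits need qcov > qcov_min).
#' @param evalue_max E-value threshold (hits need E < evalue_max).
#' @param word_size exact seed length (amino acids).
#' @param ungapped_min ungapped pre-score a seed region must reach.
#' @param stop_breaks whether stop codons hard-break alignments.
#' @return A validated \linkS4class{ScoringParams}.
#' @export
scoringParams <- function(matrix = "BLOSUM62", gap_open = 11, gap_extend = 1,
                          lambda = 0.267, K = 0.041, qcov_min = 0.50,
                          evalue_max = 0.05, word_size = 3,
                          ungapped_min = 40, stop_breaks = TRUE) {
    new("ScoringParams", matrix = matrix, gap_open = as.integer(gap_open),
        gap_extend = as.integer(gap_extend), lambda = as.numeric(lambda),
        K = as.numeric(K), qcov_min = as.numeric(qcov_min),
        evalue_max = as.numeric(evalue_max), word_size = as.integer(word_size),
        ungapped_min = as.numeric(ungapped_min),
        stop_breaks = as.logical(stop_breaks))
}

setMethod("show", "ScoringParams", function(object) {
    cat("ScoringParams:", object@matrix, "gap", object@gap_open, "/",
        object@gap_extend, "; lambda", object@lambda, "K", object@K, "\n")
    cat("  filters: qcov >", object@qcov_min, ", E <", object@evalue_max,
        "; word_size", object@word_size, "; stop_breaks",
        object@stop_breaks, "\n")
})

## ---------------------------------------------------------------------------
## TruthSet
## ---------------------------------------------------------------------------

#' Ground truth of a synthetic scenario
#'
#' Records every planted feature of a simulated genome so downstream results
#' can be verified by direct comparison: contig placements (sample-genome
#' coordinates plus the matching contig-frame span), chimeric misjoin
#' breakpoints, reciprocal translocations and deletions (reference
#' coordinates), per-base substitutions, and planted endogenous viral element
#' (EVE) sites.
#'
#' All spans are 0-based half-open.
#'
#' @slot placements data.frame: contig_id, part, chrom, start, end, strand,
#'   q_start, q_end (contig-frame span of the part).
#' @slot misjoins data.frame: contig_id, q_pos (0-based offset of the join).
#' @slot translocations data.frame: chrom_a, start_a, end_a, chrom_b,
#'   start_b, end_b (reference coordinates of a reciprocal swap).
#' @slot deletions data.frame: chrom, start, end (reference coordinates).
#' @slot substitutions data.frame: chrom, pos (reference coordinates).
#' @slot eve_sites data.frame: chrom, start, end, query_id, strand, frame.
#' @export
setClass("TruthSet", representation(
    placements = "data.frame",
    misjoins = "data.frame",
    translocations = "data.frame",
    deletions = "data.frame",
    substitutions = "data.frame",
    eve_sites = "data.frame"
))

emptyTruthSet <- function() {
    new("TruthSet",
        placements = data.frame(contig_id = character(), part = integer(),
                                chrom = character(), start = integer(),
                                end = integer(), strand = character(),
                                q_start = integer(), q_end = integer(),
                                stringsAsFactors = FALSE),
        misjoins = data.frame(contig_id = character(), q_pos = integer(),
                              stringsAsFactors = FALSE),
        translocations = data.frame(chrom_a = character(),
                                    start_a = integer(), end_a = integer(),
                                    chrom_b = character(),
                                    start_b = integer(), end_b = integer(),
                                    stringsAsFactors = FALSE),
        deletions = data.frame(chrom = character(), start = integer(),
                               end = integer(), stringsAsFactors = FALSE),
        substitutions = data.frame(chrom = character(), pos = integer(),
                                   stringsAsFactors = FALSE),
        eve_sites = data.frame(chrom = character(), start = integer(),
                               end = integer(), query_id = character(),
                               strand = character(), frame = integer(),
                               stringsAsFactors = FALSE))
}

setValidity("TruthSet", function(object) {
    msg <- character()
    pl <- object@placements
    need <- c("contig_id", "part", "chrom", "start", "end", "strand",
              "q_start", "q_end")
    if (!all(need %in% names(pl)))
        msg <- c(msg, "placements lack required columns")
    else if (nrow(pl) && any(pl$start >= pl$end))
        msg <- c(msg, "placement spans must be non-empty half-open intervals")
    mj <- object@misjoins
    if (nrow(mj) && nrow(pl)) {
        clen <- tapply(pl$q_end, pl$contig_id, max)
        bad <- mj$q_pos <= 0L | mj$q_pos >= clen[mj$contig_id]
        if (any(bad, na.rm = TRUE) || anyNA(bad))
            msg <- c(msg, "misjoin offsets must lie strictly inside contigs")
    }
    if (length(msg)) msg else TRUE
})

setMethod("show", "TruthSet", function(object) {
    cat("TruthSet:", length(unique(object@placements$contig_id)),
        "contigs in", nrow(object@placements), "placement parts;",
        nrow(object@misjoins), "misjoins;",
        nrow(object@translocations), "translocations;",
        nrow(object@deletions), "deletions;",
        nrow(object@eve_sites), "EVE sites\n")
})

#' @describeIn TruthSet-accessors contig placement table
#' @export
truthPlacements <- function(x) x@placements

#' Accessors for TruthSet slots
#'
#' @param x a \linkS4class{TruthSet}.
#' @return The corresponding data.frame.
#' @name TruthSet-accessors
NULL

#' @describeIn TruthSet-accessors misjoin breakpoints
#' @export
truthMisjoins <- function(x) x@misjoins

#' @describeIn TruthSet-accessors reciprocal translocations
#' @export
truthTranslocations <- function(x) x@translocations

#' @describeIn TruthSet-accessors deleted reference regions
#' @export
truthDeletions <- function(x) x@deletions

#' @describeIn TruthSet-accessors planted EVE sites
#' @export
truthEveSites <- function(x) x@eve_sites

## ---------------------------------------------------------------------------
## ChromosomeLayout
## ---------------------------------------------------------------------------

#' Ordered, oriented contig layout of assembled chromosomes
#'
#' The result of placing contigs along reference chromosomes: a placement
#' table (one row per component, carrying the reference span it was placed
#' from, its orientation, and the gap that follows it) plus the component
#' sequences themselves (original contigs, split pieces, or merged runs).
#' Serialised as AGP v2.1 plus FASTA; \code{renderLayout} reproduces the
#' chromosome sequences exactly.
#'
#' @slot table data.frame: chrom, order, component_id, comp_len, t_start,
#'   t_end, strand, gap_after (0-based half-open reference spans; gap_after
#'   is the N-gap length following the component, 0 for the last one).
#' @slot components \link[Biostrings]{DNAStringSet} of component sequences.
#' @export
setClass("ChromosomeLayout", representation(
    table = "data.frame",
    components = "ANY"
))

setValidity("ChromosomeLayout", function(object) {
    msg <- character()
    tb <- object@table
    need <- c("chrom", "order", "component_id", "comp_len", "t_start",
              "t_end", "strand", "gap_after")
    if (!all(need %in% names(tb)))
        return("layout table lacks required columns")
    if (nrow(tb)) {
        if (any(tb$gap_after < 0)) msg <- c(msg, "gaps must be >= 0")
        if (!all(tb$component_id %in% names(object@components)))
            msg <- c(msg, "every component needs a sequence")
        else {
            lens <- BiocGenerics::width(object@components)[
                match(tb$component_id, names(object@components))]
            if (any(lens != tb$comp_len))
                msg <- c(msg, "comp_len must match component sequence length")
        }
        for (ch in unique(tb$chrom)) {
            sub <- tb[tb$chrom == ch, ]
            if (is.unsorted(sub$t_start))
                msg <- c(msg, paste0("placements on ", ch,
                                     " not sorted by t_start"))
        }
    }
    if (length(msg)) msg else TRUE
})

setMethod("show", "ChromosomeLayout", function(object) {
    tb <- object@table
    cat("ChromosomeLayout:", length(unique(tb$chrom)), "chromosomes,",
        nrow(tb), "placed components,",
        sum(tb$gap_after > 0), "gaps totalling", sum(tb$gap_after), "bp\n")
})

#' @describeIn ChromosomeLayout placement table accessor
#' @param x a \linkS4class{ChromosomeLayout}.
#' @export
layoutTable <- function(x) x@table

#' @describeIn ChromosomeLayout component sequences accessor
#' @export
layoutComponents <- function(x) x@components
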