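## Internal helpers: interval algebra on 0-based half-open spans, seeded RNG.

#' @importFrom IRanges IRanges reduce setdiff findOverlaps coverage
#' @importFrom S4Vectors queryHits subjectHits
NULL

## Convert 0-based half-open (start, end) to IRanges (1-based closed) and back.
asIRanges0 <- function(start, end) {
    IRanges::IRanges(start = start + 1L, end = end)
}

fromIRanges0 <- function(ir) {
    data.frame(start = BiocGenerics::start(ir) - 1L,
               end = BiocGenerics::end(ir))
}

## Union of 0-based half-open intervals; merges touching intervals.
intervalUnion0 <- function(start, end) {
    if (!length(start))
        return(data.frame(start = integer(), end = integer()))
    fromIRanges0(IRanges::reduce(asIRanges0(start, end)))
}

## Complement of intervals within [0, len).
intervalComplement0 <- function(start, end, len) {
    universe <- IRanges::IRanges(1L, len)
    if (!length(start))
        return(data.frame(start = 0L, end = as.integer(len)))
    gaps <- IRanges::setdiff(universe, asIRanges0(start, end))
    fromIRanges0(gaps)
}

## Total number of bases covered by the union of intervals.
intervalUnionWidth0 <- function(start, end) {
    u <- intervalUnion0(start, end)
    sum(as.numeric(u$end - u$start))
}

## Draw integers without replacement; sample() without its size-1 surprise.
sampleInt <- function(n, size, replace = FALSE) {
    sample.int(n, size = size, replace = replace)
}

## Deterministic child seed for stage `k` of a run seeded with `seed`.
## Keeps derived seeds within 32-bit integer range.
childSeed <- function(seed, k) {
    as.integer((as.numeric(seed) * 1103515245 + k * 12345) %% 2147483647)
}

randomDna <- function(n) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## Reverse-complement of a plain character string.
revcompChr <- function(x) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
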