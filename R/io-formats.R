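## Readers and writers for the standard formats the pipeline touches.
## Internal convention: every coordinate is 0-based half-open; the 1-based
## inclusive formats (AGP, GFF3) are converted at this boundary only.

#' Read a FASTA file
#'
#' Thin wrapper over \code{\link[Biostrings]{readDNAStringSet}} that enforces
#' unique sequence ids, normalises case to upper, and truncates ids at the
#' first whitespace (the common convention of alignment tools).
#'
#' @param path FASTA file.
#' @return A \link[Biostrings]{DNAStringSet}.
#' @export
readFasta <- function(path) {
    seqs <- Biostrings::readDNAStringSet(path)
    names(seqs) <- sub("\\s.*$", "", names(seqs))
    if (anyDuplicated(names(seqs)))
        stopf("duplicate sequence id in %s: %s", path,
              names(seqs)[duplicated(names(seqs))][1])
    toupper(seqs)
}

#' Write sequences as 60-column wrapped FASTA
#'
#' @param seqs named \link[Biostrings]{DNAStringSet} (or coercible).
#' @param path output file.
#' @return Invisibly, \code{path}.
#' @export
writeFasta <- function(seqs, path) {
    if (!methods::is(seqs, "XStringSet"))
        seqs <- Biostrings::DNAStringSet(seqs)
    if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
        stopf("sequences must carry unique names")
    Biostrings::writeXStringSet(seqs, path, width = 60L)
    invisible(path)
}

## ---------------------------------------------------------------------------
## PAF
## ---------------------------------------------------------------------------

pafColumns <- c("query_id", "query_len", "q_start", "q_end", "strand",
                "target_id", "target_len", "t_start", "t_end", "n_match",
                "block_len", "mapq")

emptyPaf <- function() {
    df <- data.frame(query_id = character(), query_len = integer(),
                     q_start = integer(), q_end = integer(),
                     strand = character(), target_id = character(),
                     target_len = integer(), t_start = integer(),
                     t_end = integer(), n_match = integer(),
                     block_len = integer(), mapq = integer(),
                     tags = character(), stringsAsFactors = FALSE)
    df
}

validatePaf <- function(blocks, where = "PAF") {
    miss <- setdiff(pafColumns, names(blocks))
    if (length(miss))
        stopf("%s: missing columns: %s", where, paste(miss, collapse = ", "))
    bad <- which(!(blocks$q_start >= 0 & blocks$q_start < blocks$q_end &
                       blocks$q_end <= blocks$query_len))
    if (length(bad))
        stopf("%s: invalid query span at line %d", where, bad[1])
    bad <- which(!(blocks$t_start >= 0 & blocks$t_start < blocks$t_end &
                       blocks$t_end <= blocks$target_len))
    if (length(bad))
        stopf("%s: invalid target span at line %d", where, bad[1])
    bad <- which(blocks$n_match > blocks$block_len)
    if (length(bad))
        stopf("%s: n_match > block_len at line %d", where, bad[1])
    bad <- which(!(blocks$strand %in% c("+", "-")))
    if (length(bad))
        stopf("%s: bad strand at line %d", where, bad[1])
    bad <- which(blocks$mapq < 0 | blocks$mapq > 255)
    if (length(bad))
        stopf("%s: mapq out of range at line %d", where, bad[1])
    invisible(blocks)
}

#' Read alignment blocks from a PAF file
#'
#' Parses the 12 mandatory tab-separated columns of the pairwise alignment
#' format emitted by minimap2-family aligners; any additional columns are
#' preserved verbatim in a single \code{tags} string. All alignment-block
#' invariants (half-open spans within sequence bounds, \code{n_match <=
#' block_len}) are enforced with the offending line number reported.
#'
#' @param path PAF file.
#' @return A data.frame of alignment blocks with 0-based half-open spans.
#' @export
readPaf <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    if (!length(lines)) return(emptyPaf())
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 12L))
        stopf("PAF %s: fewer than 12 columns at line %d", path,
              which(nf < 12L)[1])
    getc <- function(i) vapply(fields, `[[`, "", i)
    blocks <- data.frame(
        query_id = getc(1), query_len = as.integer(getc(2)),
        q_start = as.integer(getc(3)), q_end = as.integer(getc(4)),
        strand = getc(5), target_id = getc(6),
        target_len = as.integer(getc(7)), t_start = as.integer(getc(8)),
        t_end = as.integer(getc(9)), n_match = as.integer(getc(10)),
        block_len = as.integer(getc(11)), mapq = as.integer(getc(12)),
        tags = vapply(fields, function(f)
            if (length(f) > 12L) paste(f[-seq_len(12L)], collapse = "\t")
            else "", ""),
        stringsAsFactors = FALSE)
    validatePaf(blocks, where = paste0("PAF ", path))
}

#' Write alignment blocks as PAF
#'
#' @param blocks data.frame as returned by \code{\link{readPaf}}.
#' @param path output file.
#' @return Invisibly, \code{path}.
#' @export
writePaf <- function(blocks, path) {
    validatePaf(blocks)
    core <- blocks[, pafColumns]
    lines <- do.call(paste, c(unname(as.list(core)), sep = "\t"))
    tags <- if ("tags" %in% names(blocks)) blocks$tags else character(nrow(blocks))
    has <- nzchar(tags)
    lines[has] <- paste(lines[has], tags[has], sep = "\t")
    writeLines(lines, path)
    invisible(path)
}

## ---------------------------------------------------------------------------
## Paired alignment records (TSV / minimal SAM)
## ---------------------------------------------------------------------------

pairColumns <- c("read_id", "seq_id", "pos1", "strand1", "pos2", "strand2",
                 "insert")

emptyPairs <- function() {
    data.frame(read_id = character(), seq_id = character(),
               pos1 = integer(), strand1 = character(), pos2 = integer(),
               strand2 = character(), insert = integer(),
               stringsAsFactors = FALSE)
}

#' Read paired-alignment records from TSV
#'
#' The paired-alignment TSV carries one fragment per row: read id, the
#' sequence both mates map to, the 0-based leftmost positions and strands of
#' the two mates, and the observed insert (outer distance). This is the
#' aligner-free carrier of read-pair evidence used for breakpoint validation.
#'
#' @param path headered TSV file.
#' @return data.frame of paired records.
#' @export
readPairedAlignments <- function(path) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    miss <- setdiff(pairColumns, names(df))
    if (length(miss))
        stopf("paired TSV %s: missing columns: %s", path,
              paste(miss, collapse = ", "))
    df
}

#' Write paired-alignment records as TSV
#'
#' @param pairs data.frame of paired records.
#' @param path output file.
#' @return Invisibly, \code{path}.
#' @export
writePairedAlignments <- function(pairs, path) {
    utils::write.table(pairs[, pairColumns], path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read paired records from a minimal SAM file
#'
#' A deliberately minimal SAM parser for read pairs: only QNAME, FLAG, RNAME,
#' POS, MAPQ and TLEN are interpreted. Mates are joined on QNAME; only pairs
#' with both mates mapped to the same sequence are returned. Strands come
#' from FLAG bit 0x10 of each mate, the insert from the positive TLEN.
#'
#' @param path SAM file (header lines ignored).
#' @return data.frame of paired records as in
#'   \code{\link{readPairedAlignments}}.
#' @export
readSamPairs <- function(path) {
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "@") & nzchar(lines)]
    if (!length(lines)) return(emptyPairs())
    fields <- strsplit(lines, "\t", fixed = TRUE)
    if (any(lengths(fields) < 11L))
        stopf("SAM %s: fewer than 11 columns", path)
    qname <- vapply(fields, `[[`, "", 1)
    flag <- as.integer(vapply(fields, `[[`, "", 2))
    rname <- vapply(fields, `[[`, "", 3)
    pos <- as.integer(vapply(fields, `[[`, "", 4)) - 1L  # SAM is 1-based
    tlen <- as.integer(vapply(fields, `[[`, "", 9))
    mapped <- bitwAnd(flag, 4L) == 0L & rname != "*"
    first <- bitwAnd(flag, 64L) != 0L
    rev <- bitwAnd(flag, 16L) != 0L
    df <- data.frame(qname, flag, rname, pos, tlen, first, rev, mapped,
                     stringsAsFactors = FALSE)
    out <- emptyPairs()
    for (q in unique(df$qname)) {
        sub <- df[df$qname == q & df$mapped, ]
        if (nrow(sub) != 2L || length(unique(sub$rname)) != 1L) next
        m1 <- sub[which.min(sub$pos), ]
        m2 <- sub[which.max(sub$pos), ]
        out <- rbind(out, data.frame(
            read_id = q, seq_id = m1$rname,
            pos1 = m1$pos, strand1 = if (m1$rev) "-" else "+",
            pos2 = m2$pos, strand2 = if (m2$rev) "-" else "+",
            insert = abs(m1$tlen), stringsAsFactors = FALSE))
    }
    rownames(out) <- NULL
    out
}

## ---------------------------------------------------------------------------
## GFF3
## ---------------------------------------------------------------------------

#' Read gene/exon/CDS features from GFF3
#'
#' Imports a GFF3 file via \code{\link[rtracklayer]{import}} and returns the
#' gene, exon and CDS features with spans converted to the package-internal
#' 0-based half-open convention. Other feature types are skipped (their count
#' is reported in a message).
#'
#' @param path GFF3 file.
#' @return data.frame: seq_id, type, start, end, strand, feature_id.
#' @export
readGff3 <- function(path) {
    gr <- rtracklayer::import(path, format = "gff3")
    type <- as.character(gr$type)
    keep <- type %in% c("gene", "exon", "CDS")
    nskip <- sum(!keep)
    if (nskip)
        message("readGff3: skipped ", nskip, " non gene/exon/CDS features")
    gr <- gr[keep]
    id <- if (!is.null(gr$ID)) as.character(gr$ID) else NA_character_
    id[is.na(id)] <- paste0("feature", seq_len(sum(is.na(id))))
    data.frame(seq_id = as.character(GenomeInfoDb::seqnames(gr)),
               type = as.character(gr$type),
               start = BiocGenerics::start(gr) - 1L,   # to 0-based half-open
               end = BiocGenerics::end(gr),
               strand = as.character(BiocGenerics::strand(gr)),
               feature_id = id, stringsAsFactors = FALSE)
}

## ---------------------------------------------------------------------------
## BED / links
## ---------------------------------------------------------------------------

#' Write and read BED intervals
#'
#' BED is natively 0-based half-open, matching the internal convention, so no
#' conversion happens.
#'
#' @param regions data.frame with columns chrom, start, end (extra columns
#'   appended verbatim).
#' @param path output file.
#' @return Invisibly, \code{path} (\code{readBed} returns the data.frame).
#' @export
writeBed <- function(regions, path) {
    utils::write.table(regions, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' @rdname writeBed
#' @export
readBed <- function(path) {
    if (file.size(path) == 0)
        return(data.frame(chrom = character(), start = integer(),
                          end = integer(), stringsAsFactors = FALSE))
    df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    names(df)[1:3] <- c("chrom", "start", "end")
    df
}

#' Write translocation links for circular plotting
#'
#' Emits the link table consumed by circos-style plotters: one row per arc
#' with the two chromosome spans and the fragment length.
#'
#' @param links data.frame with columns chrom_a, start_a, end_a, chrom_b,
#'   start_b, end_b, length.
#' @param path output TSV.
#' @return Invisibly, \code{path}.
#' @export
writeLinks <- function(links, path) {
    cols <- c("chrom_a", "start_a", "end_a", "chrom_b", "start_b", "end_b",
              "length")
    utils::write.table(links[, cols], path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
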