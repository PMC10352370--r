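## AGP v2.1 serialisation of chromosome layouts, and rendering back to FASTA.
## AGP is 1-based inclusive; conversion from the internal 0-based half-open
## layout happens here only.

#' Serialise chromosome layouts as AGP v2.1
#'
#' One W row per placed component (full component span, recorded
#' orientation) and one N row per inter-component gap of known length
#' (\code{gap_type} \code{scaffold}, linkage yes, evidence
#' \code{paired-ends}). Unknown-length U gaps are never emitted: the builder
#' always computes a gap length from the reference distance.
#'
#' @param layout a \linkS4class{ChromosomeLayout}.
#' @param path output AGP file.
#' @return Invisibly, \code{path}.
#' @export
writeAgp <- function(layout, path) {
    stopifnot(methods::is(layout, "ChromosomeLayout"))
    methods::validObject(layout)
    tb <- layoutTable(layout)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("##agp-version\t2.1", con)
    for (ch in unique(tb$chrom)) {
        sub <- tb[tb$chrom == ch, , drop = FALSE]
        sub <- sub[order(sub$order), , drop = FALSE]
        pos <- 0L   # bases of the object written so far
        part <- 0L
        for (i in seq_len(nrow(sub))) {
            part <- part + 1L
            clen <- sub$comp_len[i]
            writeLines(paste(ch, pos + 1L, pos + clen, part, "W",
                             sub$component_id[i], 1L, clen, sub$strand[i],
                             sep = "\t"), con)
            pos <- pos + clen
            g <- sub$gap_after[i]
            if (g > 0L) {
                part <- part + 1L
                writeLines(paste(ch, pos + 1L, pos + g, part, "N", g,
                                 "scaffold", "yes", "paired-ends",
                                 sep = "\t"), con)
                pos <- pos + g
            }
        }
    }
    invisible(path)
}

#' Read an AGP v2.1 file
#'
#' @param path AGP file.
#' @return data.frame with 1-based inclusive object coordinates as printed:
#'   object, object_beg, object_end, part_number, component_type, and the
#'   component or gap fields.
#' @export
readAgp <- function(path) {
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
    if (!length(lines))
        return(data.frame())
    fields <- strsplit(lines, "\t", fixed = TRUE)
    if (any(lengths(fields) < 9L))
        stopf("AGP %s: fewer than 9 columns at line %d", path,
              which(lengths(fields) < 9L)[1])
    getc <- function(i) vapply(fields, `[[`, "", i)
    df <- data.frame(object = getc(1),
                     object_beg = as.integer(getc(2)),
                     object_end = as.integer(getc(3)),
                     part_number = as.integer(getc(4)),
                     component_type = getc(5),
                     col6 = getc(6), col7 = getc(7), col8 = getc(8),
                     col9 = getc(9), stringsAsFactors = FALSE)
    isw <- df$component_type == "W"
    df$component_id <- ifelse(isw, df$col6, NA_character_)
    df$component_beg <- ifelse(isw, suppressWarnings(as.integer(df$col7)), NA)
    df$component_end <- ifelse(isw, suppressWarnings(as.integer(df$col8)), NA)
    df$orientation <- ifelse(isw, df$col9, NA_character_)
    df$gap_length <- ifelse(!isw, suppressWarnings(as.integer(df$col6)), NA)
    bad <- which(df$object_beg > df$object_end)
    if (length(bad)) stopf("AGP %s: inverted object span at row %d", path, bad[1])
    ## tiling invariant: parts must abut with no overlap and no holes
    for (ob in unique(df$object)) {
        sub <- df[df$object == ob, ]
        sub <- sub[order(sub$part_number), ]
        expect <- c(1L, utils::head(sub$object_end, -1) + 1L)
        if (any(sub$object_beg != expect))
            stopf("AGP %s: object %s parts do not tile", path, ob)
    }
    df
}

#' Render chromosome sequences from a layout
#'
#' Concatenates the oriented component sequences with runs of \code{N} of
#' the recorded gap lengths, reproducing exactly the FASTA that accompanies
#' the AGP.
#'
#' @param layout a \linkS4class{ChromosomeLayout}.
#' @return \link[Biostrings]{DNAStringSet}, one sequence per chromosome.
#' @export
renderLayout <- function(layout) {
    stopifnot(methods::is(layout, "ChromosomeLayout"))
    tb <- layoutTable(layout)
    comps <- layoutComponents(layout)
    out <- character()
    for (ch in unique(tb$chrom)) {
        sub <- tb[tb$chrom == ch, , drop = FALSE]
        sub <- sub[order(sub$order), , drop = FALSE]
        pieces <- character(0)
        for (i in seq_len(nrow(sub))) {
            s <- comps[[sub$component_id[i]]]
            if (sub$strand[i] == "-") s <- Biostrings::reverseComplement(s)
            pieces <- c(pieces, as.character(s))
            if (sub$gap_after[i] > 0L)
                pieces <- c(pieces, strrep("N", sub$gap_after[i]))
        }
        out[ch] <- paste(pieces, collapse = "")
    }
    Biostrings::DNAStringSet(out)
}

#' Render chromosome sequences from an AGP table and component sequences
#'
#' Independent render path used to check that every emitted AGP re-renders
#' to exactly the emitted FASTA.
#'
#' @param agp data.frame as returned by \code{\link{readAgp}}.
#' @param components named \link[Biostrings]{DNAStringSet}.
#' @return \link[Biostrings]{DNAStringSet}.
#' @export
renderFromAgp <- function(agp, components) {
    out <- character()
    for (ob in unique(agp$object)) {
        sub <- agp[agp$object == ob, , drop = FALSE]
        sub <- sub[order(sub$part_number), , drop = FALSE]
        pieces <- character(0)
        for (i in seq_len(nrow(sub))) {
            if (sub$component_type[i] == "W") {
                cid <- sub$component_id[i]
                if (!cid %in% names(components))
                    stopf("AGP component %s has no sequence", cid)
                s <- Biostrings::subseq(components[[cid]],
                                        sub$component_beg[i],
                                        sub$component_end[i])
                if (identical(sub$orientation[i], "-"))
                    s <- Biostrings::reverseComplement(s)
                pieces <- c(pieces, as.character(s))
            } else {
                pieces <- c(pieces, strrep("N", sub$gap_length[i]))
            }
        }
        out[ob] <- paste(pieces, collapse = "")
    }
    Biostrings::DNAStringSet(out)
}
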