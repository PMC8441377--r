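#' Spliced-read filter parameters
#'
#' @param minJunction junction size that must be exceeded (strictly) for a
#'   read to count as spliced; default 2 bp, i.e. junctions of 3 bp and up
#'   qualify.
#' @param minAlignedRatio alignment-ratio threshold (strict `>`), default
#'   0.95.
#' @param minIdentity per-base identity floor within aligned segments
#'   (`>=`), default 0.95.
#' @param minFlank minimum length of each segment flanking a junction,
#'   default 20 bp.
#' @param ratioBasis what the ratio filter measures: `"aligned"` (fraction
#'   of read bases placed in segments; the junction gap itself never counts
#'   against a read) or `"identity"` (fraction of read bases matching).
#' @return A [FilterParams-class].
#' @export
filterParams <- function(minJunction = 2L, minAlignedRatio = 0.95,
                         minIdentity = 0.95, minFlank = 20L,
                         ratioBasis = c("aligned", "identity")) {
    new("FilterParams", minJunction = as.integer(minJunction),
        minAlignedRatio = as.numeric(minAlignedRatio),
        minIdentity = as.numeric(minIdentity),
        minFlank = as.integer(minFlank),
        ratioBasis = match.arg(ratioBasis))
}

.refAsCharacter <- function(reference) {
    if (is(reference, "AmpliconReference"))
        as.character(reference@sequence)
    else if (is(reference, "DNAString"))
        as.character(reference)
    else as.character(reference)
}

.readsAsCharacter <- function(reads) {
    if (is(reads, "XStringSet")) {
        ids <- names(reads)
        reads <- as.character(reads)
    } else {
        ids <- names(reads)
        reads <- as.character(reads)
    }
    if (is.null(ids)) ids <- paste0("read", seq_along(reads))
    ids <- sub("\\s.*$", "", ids)
    list(ids = ids, seq = unname(reads))
}

#' Align a batch of reads to the amplicon with one free deletion junction
#'
#' Each read is aligned on both strands under the split model: the best of
#' (i) a single ungapped local alignment and (ii) all chains of two
#' collinear ungapped segments separated by one reference gap of any size
#' (the junction, free of charge). Scoring is match +1 / mismatch -1;
#' score ties are broken towards the smaller junction (a contiguous
#' alignment beats an equal-scoring split), then the leftmost junction
#' start, then the + strand. Within-segment indels are not modelled;
#' a handful of bases inserted at a deletion junction is absorbed into the
#' flanking segments as mismatches.
#'
#' @param reads a [Biostrings::DNAStringSet], named character vector, or
#'   FASTQ/FASTA path (see [readReads()]).
#' @param reference an [AmpliconReference-class] (or plain sequence).
#' @param tryMinus also try the reverse-complement orientation
#'   (default `TRUE`).
#' @return data.frame with one row per read: `read_id`, `strand`, `score`,
#'   `nseg`, segment coordinates (0-based half-open; `r*` on the read in
#'   aligned orientation, `f*` on the reference), `junction_size`,
#'   `del_start`/`del_end` (the junction interval, `NA` for contiguous
#'   alignments), `aligned_bases`, `matches`, `mismatches`,
#'   `aligned_ratio`, `identity`.
#' @seealso [alignRead()] for a single read as a rich object,
#'   [classifyReads()] for the spliced/wild-type/unmapped calls.
#' @export
alignReads <- function(reads, reference, tryMinus = TRUE) {
    if (is.character(reads) && length(reads) == 1L && file.exists(reads))
        reads <- readReads(reads)
    rr <- .readsAsCharacter(reads)
    if (!length(rr$seq)) stop("no reads to align")
    if (any(!nzchar(rr$seq))) stop("empty read sequence")
    refc <- .refAsCharacter(reference)
    if (!nzchar(refc)) stop("empty reference")
    m <- cpp_align_batch(rr$seq, refc, tryMinus)
    df <- as.data.frame(m)
    df$read_id <- rr$ids
    df$strand <- ifelse(df$strand == 1L, "-", "+")
    df$mismatches <- df$aligned_bases - df$matches
    df$aligned_ratio <- df$aligned_bases / df$read_length
    df$identity <- ifelse(df$aligned_bases > 0,
                          df$matches / df$aligned_bases, 0)
    df$del_start <- ifelse(df$nseg == 2L, df$f1_end, NA_integer_)
    df$del_end <- ifelse(df$nseg == 2L, df$f2_start, NA_integer_)
    df[, c("read_id", "strand", "score", "nseg",
           "r1_start", "r1_end", "f1_start", "f1_end", "m1",
           "r2_start", "r2_end", "f2_start", "f2_end", "m2",
           "junction_size", "del_start", "del_end",
           "aligned_bases", "matches", "mismatches",
           "aligned_ratio", "identity", "read_length")]
}

#' Align one read and return a SplitAlignment
#'
#' @param read character string or [Biostrings::DNAString].
#' @param reference an [AmpliconReference-class] (or plain sequence).
#' @param readId identifier used in the result.
#' @param tryMinus also try the reverse-complement orientation.
#' @return A [SplitAlignment-class].
#' @export
alignRead <- function(read, reference, readId = "read", tryMinus = TRUE) {
    read <- as.character(read)
    if (!nzchar(read)) stop("empty read")
    df <- alignReads(setNames(read, readId), reference, tryMinus)
    segs <- data.frame(
        read_start = df$r1_start, read_end = df$r1_end,
        ref_start = df$f1_start, ref_end = df$f1_end, matches = df$m1
    )
    if (df$nseg == 2L)
        segs <- rbind(segs, data.frame(
            read_start = df$r2_start, read_end = df$r2_end,
            ref_start = df$f2_start, ref_end = df$f2_end, matches = df$m2))
    new("SplitAlignment", readId = readId, strand = df$strand,
        score = as.numeric(df$score), segments = segs,
        junctionSize = as.integer(df$junction_size),
        insertedBases = 0L,
        alignedRatio = df$aligned_ratio, identity = df$identity,
        readLength = as.integer(df$read_length))
}

setMethod("show", "SplitAlignment", function(object) {
    cat("SplitAlignment '", object@readId, "' (", object@strand,
        "): score ", object@score, ", ", nrow(object@segments),
        " segment(s)", sep = "")
    if (object@junctionSize > 0L)
        cat(", junction ", object@junctionSize, " bp [",
            object@segments$ref_end[1L], ",",
            object@segments$ref_start[2L], ")", sep = "")
    cat(sprintf(", aligned %.3f, identity %.3f\n",
                object@alignedRatio, object@identity))
})

#' Classify aligned reads as spliced, wild-type mapped, or unmapped
#'
#' Applies the spliced-read extraction filters: a read is `spliced` when
#' its junction is strictly larger than `minJunction` bp, its alignment
#' ratio is strictly above `minAlignedRatio`, its identity reaches
#' `minIdentity`, and both segments span at least `minFlank` bp. A read
#' failing the junction criterion but passing ratio and identity is
#' `wt_mapped`; everything else is `unmapped`.
#'
#' @param aln data.frame from [alignReads()] (or a [SplitAlignment-class]).
#' @param params a [FilterParams-class], see [filterParams()].
#' @return For a data.frame input, the same data.frame with a `class`
#'   column (factor levels `wt_mapped`, `spliced`, `unmapped`); for a
#'   single [SplitAlignment-class], the class label as a character scalar.
#' @export
classifyReads <- function(aln, params = filterParams()) {
    if (is(aln, "SplitAlignment")) {
        flanks <- aln@segments$read_end - aln@segments$read_start
        df <- data.frame(
            junction_size = aln@junctionSize,
            aligned_ratio = aln@alignedRatio,
            identity = aln@identity,
            matches = sum(aln@segments$matches),
            read_length = aln@readLength,
            nseg = nrow(aln@segments),
            flank1 = flanks[1L],
            flank2 = if (length(flanks) > 1L) flanks[2L] else NA_integer_)
        return(as.character(classifyReads(df, params)$class))
    }
    stopifnot(is.data.frame(aln))
    if (!"flank1" %in% names(aln)) {
        aln$flank1 <- aln$r1_end - aln$r1_start
        aln$flank2 <- ifelse(aln$nseg == 2L, aln$r2_end - aln$r2_start,
                             NA_integer_)
    }
    ratio <- if (params@ratioBasis == "identity")
        aln$matches / aln$read_length else aln$aligned_ratio
    mappedOk <- ratio > params@minAlignedRatio &
        aln$identity >= params@minIdentity
    flankOk <- aln$nseg == 2L & aln$flank1 >= params@minFlank &
        !is.na(aln$flank2) & aln$flank2 >= params@minFlank
    spliced <- aln$junction_size > params@minJunction & mappedOk & flankOk
    cls <- ifelse(spliced, "spliced",
                  ifelse(mappedOk, "wt_mapped", "unmapped"))
    aln$class <- factor(cls, levels = c("wt_mapped", "spliced", "unmapped"))
    aln
}

#' Read amplicon reads from FASTQ or FASTA
#'
#' Format is chosen from the file extension (`.fastq`, `.fq`, optionally
#' `.gz`-compressed, are read as FASTQ; anything else as FASTA).
#'
#' @param file path to the reads file.
#' @return A [Biostrings::DNAStringSet] named by read id.
#' @export
readReads <- function(file) {
    if (!file.exists(file)) stop("reads file not found: ", file)
    fmt <- if (grepl("\\.(fastq|fq)(\\.gz)?$", file, ignore.case = TRUE))
        "fastq" else "fasta"
    Biostrings::readDNAStringSet(file, format = fmt)
}

#' Write per-read alignment classifications as TSV
#'
#' @param aln classified data.frame from [classifyReads()].
#' @param file output path.
#' @return The path, invisibly.
#' @export
writeAlignments <- function(aln, file) {
    cols <- c("read_id", "class", "del_start", "del_end", "junction_size",
              "aligned_ratio", "identity", "strand", "score",
              "f1_start", "f1_end", "f2_start", "f2_end",
              "aligned_bases", "matches", "read_length")
    cols <- intersect(cols, names(aln))
    out <- aln[, cols]
    num <- vapply(out, is.numeric, logical(1))
    out[num] <- lapply(out[num], function(x) round(x, 6))
    write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(file)
}

#' Write classified alignments as a minimal SAM file
#'
#' Encodes each mapped read as a single SAM record with the deletion
#' junction expressed as a CIGAR `D` operation (soft-clipping any
#' unaligned read ends), for inspection in genome browsers. Unmapped reads
#' are emitted with flag 4.
#'
#' @param aln classified data.frame from [classifyReads()].
#' @param reads the reads that were aligned (DNAStringSet or named
#'   character vector) in their original orientation.
#' @param reference the [AmpliconReference-class] used.
#' @param file output path.
#' @return The path, invisibly.
#' @export
writeSam <- function(aln, reads, reference, file) {
    rr <- .readsAsCharacter(reads)
    seqs <- setNames(rr$seq, rr$ids)
    con <- file(file, "w")
    on.exit(close(con))
    writeLines(c("@HD\tVN:1.6\tSO:unknown",
                 paste0("@SQ\tSN:", reference@name, "\tLN:",
                        length(reference@sequence))), con)
    for (i in seq_len(nrow(aln))) {
        id <- aln$read_id[i]
        seq <- seqs[[id]]
        if (aln$class[i] == "unmapped") {
            writeLines(paste(id, 4L, "*", 0L, 0L, "*", "*", 0L, 0L,
                             seq, "*", sep = "\t"), con)
            next
        }
        if (aln$strand[i] == "-")
            seq <- as.character(Biostrings::reverseComplement(
                Biostrings::DNAString(seq)))
        n <- nchar(seq)
        lead <- aln$r1_start[i]
        cig <- if (lead > 0L) paste0(lead, "S") else ""
        cig <- paste0(cig, aln$r1_end[i] - aln$r1_start[i], "M")
        tailLen <- n - aln$r1_end[i]
        if (aln$nseg[i] == 2L) {
            if (aln$junction_size[i] > 0L)
                cig <- paste0(cig, aln$junction_size[i], "D")
            cig <- paste0(cig, aln$r2_end[i] - aln$r2_start[i], "M")
            tailLen <- n - aln$r2_end[i]
        }
        if (tailLen > 0L) cig <- paste0(cig, tailLen, "S")
        flag <- if (aln$strand[i] == "-") 16L else 0L
        writeLines(paste(id, flag, reference@name,
                         aln$f1_start[i] + 1L, 60L, cig, "*", 0L, 0L,
                         seq, "*", sep = "\t"), con)
    }
    invisible(file)
}
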