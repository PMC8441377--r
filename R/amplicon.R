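#' Construct an amplicon reference
#'
#' @param name record name used in output and FASTA headers.
#' @param sequence amplicon sequence as a character string or
#'   [Biostrings::DNAString] (uppercased; `ACGTN` alphabet).
#' @param pcrFwdStart,pcrRevEnd 0-based half-open footprint of the outer PCR
#'   product; defaults to the whole amplicon. The difference is the
#'   wild-type band size returned by [wtProductSize()].
#' @param snpPositions optional integer vector of 0-based annotated variant
#'   positions.
#' @param genomeOffset optional genome coordinate of amplicon position 0,
#'   kept as annotation only.
#'
#' @return An [AmpliconReference-class] object.
#' @examples
#' ref <- AmpliconReference("amp", strrep("ACGT", 30))
#' wtProductSize(ref)
#' @export
AmpliconReference <- function(name, sequence, pcrFwdStart = 0L,
                              pcrRevEnd = NULL, snpPositions = integer(),
                              genomeOffset = NA_integer_) {
    if (is.character(sequence))
        sequence <- Biostrings::DNAString(toupper(sequence))
    if (is.null(pcrRevEnd))
        pcrRevEnd <- length(sequence)
    new("AmpliconReference",
        name = as.character(name),
        sequence = sequence,
        pcrFwdStart = as.integer(pcrFwdStart),
        pcrRevEnd = as.integer(pcrRevEnd),
        snpPositions = as.integer(snpPositions),
        genomeOffset = as.integer(genomeOffset))
}

#' Read a single-record amplicon FASTA
#'
#' @param file path to a FASTA file holding exactly one record.
#' @param ... further arguments passed to [AmpliconReference()]
#'   (`pcrFwdStart`, `pcrRevEnd`, `snpPositions`, `genomeOffset`).
#' @return An [AmpliconReference-class].
#' @export
readAmpliconFasta <- function(file, ...) {
    seqs <- Biostrings::readDNAStringSet(file)
    if (length(seqs) != 1L)
        stop("amplicon FASTA must contain exactly one record, found ",
             length(seqs))
    nm <- sub("\\s.*$", "", names(seqs)[1L])
    AmpliconReference(nm, seqs[[1L]], ...)
}

#' @rdname AmpliconReference
#' @export
setMethod("ampliconSeq", "AmpliconReference", function(x) x@sequence)

#' @rdname AmpliconReference
#' @export
setMethod("wtProductSize", "AmpliconReference",
    function(x) x@pcrRevEnd - x@pcrFwdStart)

setMethod("show", "AmpliconReference", function(object) {
    cat("AmpliconReference '", object@name, "': ",
        length(object@sequence), " bp, WT product ",
        wtProductSize(object), " bp", sep = "")
    if (length(object@snpPositions))
        cat(", ", length(object@snpPositions), " annotated SNP position(s)",
            sep = "")
    cat("\n")
})

#' Locate the Cas9 cut site of a protospacer on the amplicon
#'
#' Finds the unique occurrence of a protospacer (on either or a given
#' strand), checks for an adjacent NGG PAM, and returns the blunt SpCas9
#' cut position 3 bp 5' of the PAM on the protospacer strand, as a 0-based
#' inter-base coordinate on the amplicon.
#'
#' @param protospacer protospacer sequence (17-23 nt, no PAM).
#' @param pamStrand `"+"`, `"-"`, or `NA` to search both strands.
#' @param reference an [AmpliconReference-class] or
#'   [Biostrings::DNAString].
#'
#' @return Integer cut site (0-based, inter-base).
#' @examples
#' ref <- AmpliconReference("amp",
#'     paste0(strrep("T", 10), "ACGACGTAGCTAGCTAGGAC", "TGG",
#'            strrep("A", 10)))
#' cutSiteFromProtospacer("ACGACGTAGCTAGCTAGGAC", "+", ref)
#' @export
cutSiteFromProtospacer <- function(protospacer, pamStrand = NA, reference) {
    seq <- if (is(reference, "AmpliconReference")) reference@sequence
           else Biostrings::DNAString(reference)
    proto <- Biostrings::DNAString(toupper(as.character(protospacer)))
    chars <- strsplit(as.character(seq), "")[[1L]]
    len <- length(chars)
    strands <- if (is.na(pamStrand)) c("+", "-") else as.character(pamStrand)

    hits <- list()   # list of c(cut = ..., pam_ok = 0/1)
    if ("+" %in% strands) {
        m <- Biostrings::matchPattern(proto, seq)
        for (s1 in Biostrings::start(m)) {        # 1-based start
            e0 <- s1 - 1L + length(proto)          # 0-based half-open end
            ok <- e0 + 3L <= len &&
                chars[e0 + 2L] == "G" && chars[e0 + 3L] == "G"
            hits[[length(hits) + 1L]] <- c(cut = e0 - 3L, ok = as.integer(ok))
        }
    }
    if ("-" %in% strands) {
        m <- Biostrings::matchPattern(Biostrings::reverseComplement(proto),
                                      seq)
        for (s1 in Biostrings::start(m)) {
            s0 <- s1 - 1L                          # 0-based start
            ok <- s0 - 3L >= 0L &&
                chars[s0 - 2L] == "C" && chars[s0 - 1L] == "C"
            hits[[length(hits) + 1L]] <- c(cut = s0 + 3L, ok = as.integer(ok))
        }
    }
    if (length(hits) == 0L)
        stop("guide not found: protospacer has no match in the reference")
    if (length(hits) > 1L)
        stop("ambiguous guide placement: protospacer matches ",
             length(hits), " positions")
    hit <- hits[[1L]]
    if (!hit[["ok"]])
        stop("no PAM adjacent: protospacer match lacks an NGG PAM")
    as.integer(hit[["cut"]])
}

#' Construct a guide
#'
#' @param id guide identifier (e.g. `"US-3"`).
#' @param side `"upstream"` or `"downstream"`.
#' @param protospacer optional protospacer sequence.
#' @param pamStrand `"+"`, `"-"` or `NA`.
#' @param cutSite 0-based inter-base cut position; if missing it is derived
#'   from the protospacer against `reference`. An explicit `cutSite` takes
#'   precedence over the protospacer.
#' @param reference [AmpliconReference-class]; required only when the cut
#'   site must be derived.
#' @return A [Guide-class].
#' @export
Guide <- function(id, side, protospacer = NA_character_, pamStrand = NA,
                  cutSite = NA, reference = NULL) {
    if (is.na(cutSite)) {
        if (is.na(protospacer))
            stop("guide '", id, "': either cutSite or protospacer required")
        if (is.null(reference))
            stop("guide '", id, "': reference required to derive cut site")
        cutSite <- cutSiteFromProtospacer(protospacer, pamStrand, reference)
    }
    new("Guide", id = as.character(id), side = as.character(side),
        protospacer = ifelse(is.na(protospacer), NA_character_,
                             toupper(as.character(protospacer))),
        pamStrand = as.character(pamStrand), cutSite = as.integer(cutSite))
}

#' @rdname Guide
#' @param x a [Guide-class].
#' @export
setMethod("cutSite", "Guide", function(x) x@cutSite)

setMethod("show", "Guide", function(object) {
    cat("Guide ", object@id, " (", object@side, "), cut site ",
        object@cutSite, "\n", sep = "")
})

#' Construct a guide pair
#'
#' @param usGuide,dsGuide upstream and downstream [Guide-class] objects.
#' @return A [GuidePair-class].
#' @export
GuidePair <- function(usGuide, dsGuide) {
    new("GuidePair", usGuide = usGuide, dsGuide = dsGuide)
}

#' @rdname GuidePair
#' @export
setMethod("pairId", "GuidePair",
    function(x) paste(x@usGuide@id, x@dsGuide@id, sep = "/"))

#' @rdname GuidePair
#' @export
setMethod("expectedDeletionSize", "GuidePair",
    function(x) x@dsGuide@cutSite - x@usGuide@cutSite)

setMethod("show", "GuidePair", function(object) {
    cat("GuidePair ", pairId(object), ": cuts ", object@usGuide@cutSite,
        " / ", object@dsGuide@cutSite, ", expected deletion ",
        expectedDeletionSize(object), " bp\n", sep = "")
})

#' Enumerate all upstream x downstream guide pairs
#'
#' @param guides list of [Guide-class] objects (mixed sides).
#' @return List of [GuidePair-class] objects, named by [pairId()], one per
#'   upstream/downstream combination.
#' @export
guidePairs <- function(guides) {
    sides <- vapply(guides, function(g) g@side, character(1))
    us <- guides[sides == "upstream"]
    ds <- guides[sides == "downstream"]
    if (!length(us) || !length(ds))
        stop("need at least one upstream and one downstream guide")
    pairs <- list()
    for (u in us) for (d in ds) {
        p <- GuidePair(u, d)
        pairs[[pairId(p)]] <- p
    }
    pairs
}

#' Predicted PCR product size after deletion
#'
#' Deterministic size arithmetic connecting a deletion to its expected gel
#' band: the wild-type product shrinks by exactly the deleted interval.
#'
#' @param wtProduct wild-type product size in bp, or an
#'   [AmpliconReference-class] (its [wtProductSize()] is used).
#' @param deletionSize deletion size(s) in bp, `0 <= deletionSize < wtProduct`.
#' @return Predicted product size(s) in bp.
#' @examples
#' predictedProductSize(2370, c(595, 1739))   # 1775, 631
#' @export
predictedProductSize <- function(wtProduct, deletionSize) {
    if (is(wtProduct, "AmpliconReference"))
        wtProduct <- wtProductSize(wtProduct)
    deletionSize <- as.integer(deletionSize)
    if (any(deletionSize < 0L))
        stop("deletion size must be >= 0")
    if (any(deletionSize >= wtProduct))
        stop("deletion exceeds amplicon: size >= wild-type product")
    as.integer(wtProduct) - deletionSize
}

#' Read a guide configuration table
#'
#' Tab-separated file with header columns `id`, `side`, and either
#' `protospacer` (+ optional `strand`) or `cut_site` (0-based inter-base
#' coordinate). When both are present, `cut_site` wins and the protospacer
#' is kept as annotation.
#'
#' @param file path to the TSV.
#' @param reference [AmpliconReference-class], needed when any guide is
#'   specified by protospacer only.
#' @return List of [Guide-class] objects, named by id.
#' @export
readGuideTable <- function(file, reference = NULL) {
    if (!file.exists(file))
        stop("guide file not found: ", file)
    tab <- read.delim(file, stringsAsFactors = FALSE)
    need <- c("id", "side")
    if (!all(need %in% names(tab)))
        stop("guide table must have columns 'id' and 'side'")
    if (!"protospacer" %in% names(tab)) tab$protospacer <- NA_character_
    if (!"strand" %in% names(tab)) tab$strand <- NA_character_
    if (!"cut_site" %in% names(tab)) tab$cut_site <- NA_integer_
    tab$protospacer[!is.na(tab$protospacer) & tab$protospacer == ""] <-
        NA_character_
    guides <- vector("list", nrow(tab))
    for (i in seq_len(nrow(tab))) {
        guides[[i]] <- Guide(
            id = tab$id[i], side = tab$side[i],
            protospacer = tab$protospacer[i],
            pamStrand = if (is.na(tab$strand[i]) || tab$strand[i] == "")
                NA_character_ else tab$strand[i],
            cutSite = if (is.na(tab$cut_site[i])) NA else tab$cut_site[i],
            reference = reference)
    }
    names(guides) <- tab$id
    guides
}

#' Design summary of a dual-guide deletion experiment
#'
#' One row per guide pair: cut sites, expected deletion size and expected
#' PCR band size given the wild-type product.
#'
#' @param reference [AmpliconReference-class].
#' @param pairs list of [GuidePair-class] objects (see [guidePairs()]).
#' @return data.frame with columns `pair_id`, `us_id`, `ds_id`, `us_cut`,
#'   `ds_cut`, `expected_deletion_bp`, `expected_band_bp`.
#' @export
designSummary <- function(reference, pairs) {
    wt <- wtProductSize(reference)
    df <- data.frame(
        pair_id = vapply(pairs, pairId, character(1)),
        us_id = vapply(pairs, function(p) p@usGuide@id, character(1)),
        ds_id = vapply(pairs, function(p) p@dsGuide@id, character(1)),
        us_cut = vapply(pairs, function(p) p@usGuide@cutSite, integer(1)),
        ds_cut = vapply(pairs, function(p) p@dsGuide@cutSite, integer(1)),
        expected_deletion_bp = vapply(pairs, expectedDeletionSize,
                                      integer(1)),
        row.names = NULL, stringsAsFactors = FALSE)
    df$expected_band_bp <- predictedProductSize(wt, df$expected_deletion_bp)
    df
}
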