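#' @useDynLib ampliconDel, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
#' @importClassesFrom Biostrings DNAString XStringSet
#' @importFrom stats rnorm runif sd qnorm pt setNames aggregate t.test
#' @importFrom utils read.delim write.table packageVersion
NULL

## All amplicon coordinates in this package are 0-based, half-open
## (cut sites are inter-base positions). This matches the convention of
## the upstream alignment tooling the pipeline emulates; conversion to
## 1-based R string indices happens only at the point of substring
## extraction.

#' Wild-type amplicon reference
#'
#' Container for the wild-type PCR amplicon against which all reads are
#' aligned: the sequence, the outer PCR primer footprint (which defines the
#' wild-type product size), and optional annotation of the proxy-SNP
#' positions targeted for deletion.
#'
#' @slot name single-record name (FASTA header).
#' @slot sequence a [Biostrings::DNAString] with the amplicon sequence.
#' @slot pcrFwdStart,pcrRevEnd 0-based half-open footprint of the outer PCR
#'   product on the amplicon; `pcrRevEnd - pcrFwdStart` is the wild-type
#'   band size.
#' @slot snpPositions integer vector of 0-based positions (annotation only).
#' @slot genomeOffset optional genome coordinate of amplicon position 0
#'   (`NA` if unused); computation is always amplicon-local.
#'
#' @seealso [AmpliconReference()] for the user-facing constructor,
#'   [readAmpliconFasta()].
#' @exportClass AmpliconReference
setClass("AmpliconReference",
    slots = c(
        name         = "character",
        sequence     = "DNAString",
        pcrFwdStart  = "integer",
        pcrRevEnd    = "integer",
        snpPositions = "integer",
        genomeOffset = "integer"
    )
)

setValidity("AmpliconReference", function(object) {
    len <- length(object@sequence)
    msg <- character()
    if (len < 1L)
        msg <- c(msg, "amplicon sequence must have length >= 1")
    if (length(object@name) != 1L || is.na(object@name) || !nzchar(object@name))
        msg <- c(msg, "'name' must be a single non-empty string")
    if (object@pcrFwdStart < 0L || object@pcrRevEnd > len)
        msg <- c(msg, "PCR primer footprint outside [0, length)")
    if (object@pcrRevEnd - object@pcrFwdStart <= 0L)
        msg <- c(msg, "wild-type product size must be positive")
    if (length(object@snpPositions) &&
        (any(object@snpPositions < 0L) || any(object@snpPositions >= len)))
        msg <- c(msg, "snpPositions outside [0, length)")
    if (length(msg)) msg else TRUE
})

#' Single guide RNA with its Cas9 cut site
#'
#' One sgRNA of a dual-guide design. Guides are `upstream` or `downstream`
#' of the target region; each carries a blunt Cas9 cut site expressed as a
#' 0-based inter-base coordinate on the amplicon. The cut site is either
#' given directly or derived from the protospacer via
#' [cutSiteFromProtospacer()] (3 bp 5' of an NGG PAM).
#'
#' @slot id guide identifier, e.g. `"US-3"`.
#' @slot side `"upstream"` or `"downstream"`.
#' @slot protospacer protospacer sequence (17-23 nt) or `NA`.
#' @slot pamStrand `"+"`, `"-"`, or `NA` when configured by coordinate.
#' @slot cutSite 0-based inter-base cut position on the amplicon.
#'
#' @exportClass Guide
setClass("Guide",
    slots = c(
        id          = "character",
        side        = "character",
        protospacer = "character",
        pamStrand   = "character",
        cutSite     = "integer"
    )
)

setValidity("Guide", function(object) {
    msg <- character()
    if (!object@side %in% c("upstream", "downstream"))
        msg <- c(msg, "side must be 'upstream' or 'downstream'")
    if (length(object@cutSite) != 1L || is.na(object@cutSite) ||
        object@cutSite < 0L)
        msg <- c(msg, "cutSite must be a single non-negative integer")
    if (!is.na(object@protospacer)) {
        n <- nchar(object@protospacer)
        if (n < 17L || n > 23L)
            msg <- c(msg, "protospacer length must be 17-23 nt")
    }
    if (!is.na(object@pamStrand) && !object@pamStrand %in% c("+", "-"))
        msg <- c(msg, "pamStrand must be '+', '-' or NA")
    if (length(msg)) msg else TRUE
})

#' Upstream/downstream guide pair
#'
#' The unit whose deletion efficiency is estimated: one upstream and one
#' downstream guide whose paired Cas9 cuts excise the intervening interval
#' `[usCut, dsCut)`.
#'
#' @slot usGuide,dsGuide [Guide-class] objects with `side` `"upstream"` and
#'   `"downstream"`; the upstream cut must precede the downstream cut.
#'
#' @exportClass GuidePair
setClass("GuidePair",
    slots = c(usGuide = "Guide", dsGuide = "Guide")
)

setValidity("GuidePair", function(object) {
    msg <- character()
    if (object@usGuide@side != "upstream")
        msg <- c(msg, "usGuide must have side 'upstream'")
    if (object@dsGuide@side != "downstream")
        msg <- c(msg, "dsGuide must have side 'downstream'")
    if (!(object@usGuide@cutSite < object@dsGuide@cutSite))
        msg <- c(msg, "upstream cut site must be strictly left of downstream")
    if (length(msg)) msg else TRUE
})

#' Spliced-read filter parameters
#'
#' Thresholds used by [classifyReads()] to extract deletion-junction
#' ("spliced") reads: a junction must be strictly larger than `minJunction`
#' bases, the fraction of read bases placed in aligned segments must be
#' strictly above `minAlignedRatio`, per-base identity within segments must
#' reach `minIdentity`, and each segment flanking a junction must span at
#' least `minFlank` bases.
#'
#' @slot minJunction junction size threshold in bp (strict `>`; default 2).
#' @slot minAlignedRatio aligned-fraction threshold (strict `>`; default 0.95).
#' @slot minIdentity identity floor within aligned segments (`>=`; default 0.95).
#' @slot minFlank minimum per-segment length around a junction (default 20).
#' @slot ratioBasis `"aligned"` (fraction of read bases placed in segments)
#'   or `"identity"` (fraction of read bases matching), selecting what the
#'   alignment-ratio filter measures.
#'
#' @exportClass FilterParams
setClass("FilterParams",
    slots = c(
        minJunction     = "integer",
        minAlignedRatio = "numeric",
        minIdentity     = "numeric",
        minFlank        = "integer",
        ratioBasis      = "character"
    )
)

setValidity("FilterParams", function(object) {
    msg <- character()
    if (object@minJunction < 0L)
        msg <- c(msg, "minJunction must be >= 0")
    if (object@minAlignedRatio < 0 || object@minAlignedRatio > 1)
        msg <- c(msg, "minAlignedRatio must be in [0, 1]")
    if (object@minIdentity < 0 || object@minIdentity > 1)
        msg <- c(msg, "minIdentity must be in [0, 1]")
    if (object@minFlank < 1L)
        msg <- c(msg, "minFlank must be >= 1")
    if (!object@ratioBasis %in% c("aligned", "identity"))
        msg <- c(msg, "ratioBasis must be 'aligned' or 'identity'")
    if (length(msg)) msg else TRUE
})

#' Ground-truth simulation configuration
#'
#' Parameters of the synthetic amplicon library: the mixture of wild-type
#' reads, per-pair deletion reads and unmappable ("garbage") reads, the
#' breakpoint jitter around the nominal cut sites, the junction-insertion
#' and substitution error processes, and the read geometry (single-end reads
#' anchored a fixed distance upstream of each pair's upstream cut site,
#' emulating pooled sequencing primers placed ~50 bp upstream of every cut
#' site).
#'
#' @slot reference an [AmpliconReference-class].
#' @slot pairs list of [GuidePair-class] objects.
#' @slot pairFractions named numeric, fraction of reads per pair id.
#' @slot wtFraction fraction of wild-type reads. Any remainder
#'   `1 - wtFraction - sum(pairFractions)` is emitted as random garbage reads.
#' @slot jitterSd per-breakpoint Gaussian jitter sd in bp (rounded to integer).
#' @slot insertJunctionProb probability a deletion read carries 1-5 random
#'   inserted bases at the junction.
#' @slot substErrorRate per-base substitution error probability.
#' @slot readLength read length in bp.
#' @slot readAnchorOffset read start, in bp upstream of the upstream cut site.
#' @slot nReads number of reads to simulate.
#' @slot seed integer seed; simulation is deterministic given the seed.
#'
#' @exportClass TruthConfig
setClass("TruthConfig",
    slots = c(
        reference          = "AmpliconReference",
        pairs              = "list",
        pairFractions      = "numeric",
        wtFraction         = "numeric",
        jitterSd           = "numeric",
        insertJunctionProb = "numeric",
        substErrorRate     = "numeric",
        readLength         = "integer",
        readAnchorOffset   = "integer",
        nReads             = "integer",
        seed               = "integer"
    )
)

setValidity("TruthConfig", function(object) {
    msg <- character()
    fr <- object@pairFractions
    if (length(object@pairs) != length(fr))
        msg <- c(msg, "one fraction per guide pair required")
    if (any(fr < 0) || object@wtFraction < 0)
        msg <- c(msg, "fractions must be >= 0")
    if (object@wtFraction + sum(fr) > 1 + 1e-9)
        msg <- c(msg, "wtFraction + sum(pairFractions) must be <= 1")
    if (is.null(names(fr)) || any(!nzchar(names(fr))))
        msg <- c(msg, "pairFractions must be named by pair id")
    if (object@jitterSd < 0)
        msg <- c(msg, "jitterSd must be >= 0")
    if (object@insertJunctionProb < 0 || object@insertJunctionProb > 1)
        msg <- c(msg, "insertJunctionProb must be in [0, 1]")
    if (object@substErrorRate < 0 || object@substErrorRate > 1)
        msg <- c(msg, "substErrorRate must be in [0, 1]")
    if (object@readLength < 1L)
        msg <- c(msg, "readLength must be >= 1")
    if (object@readAnchorOffset < 0L)
        msg <- c(msg, "readAnchorOffset must be >= 0")
    if (object@nReads < 1L)
        msg <- c(msg, "nReads must be >= 1")
    if (length(msg)) msg else TRUE
})

#' Split alignment of one read
#'
#' Best alignment of a read to the amplicon under the split model: either a
#' single ungapped local segment, or two collinear ungapped segments
#' separated by one free reference gap (the deletion junction). Segment
#' coordinates are 0-based half-open; read coordinates refer to the aligned
#' orientation of the read.
#'
#' @slot readId read identifier.
#' @slot strand `"+"` or `"-"` (reverse-complement alignment).
#' @slot score alignment score (match +1, mismatch -1; junction free).
#' @slot segments data.frame with one row per segment
#'   (`read_start`, `read_end`, `ref_start`, `ref_end`, `matches`).
#' @slot junctionSize reference gap between the segments (0 if one segment).
#' @slot insertedBases read bases between segments (always 0 under the
#'   ungapped-segment model; junction insertions are absorbed into flanking
#'   segments as mismatches).
#' @slot alignedRatio fraction of read bases placed in segments.
#' @slot identity matches / aligned bases.
#' @slot readLength length of the read.
#'
#' @exportClass SplitAlignment
setClass("SplitAlignment",
    slots = c(
        readId        = "character",
        strand        = "character",
        score         = "numeric",
        segments      = "data.frame",
        junctionSize  = "integer",
        insertedBases = "integer",
        alignedRatio  = "numeric",
        identity      = "numeric",
        readLength    = "integer"
    )
)

setValidity("SplitAlignment", function(object) {
    msg <- character()
    ns <- nrow(object@segments)
    if (!ns %in% c(1L, 2L))
        msg <- c(msg, "a split alignment has one or two segments")
    if (object@junctionSize < 0L)
        msg <- c(msg, "junctionSize must be >= 0")
    if ((ns == 2L) != (object@junctionSize > 0L || object@insertedBases > 0L))
        msg <- c(msg, "two segments iff junction or inserted bases present")
    if (object@alignedRatio < 0 || object@alignedRatio > 1)
        msg <- c(msg, "alignedRatio must be in [0, 1]")
    if (length(msg)) msg else TRUE
})

#' Per-library deletion quantification
#'
#' Read-class counts and per-pair editing efficiencies for one sequencing
#' library. Efficiency of a pair is the number of spliced reads assigned to
#' it divided by the total mapped reads (wild-type + spliced) of the
#' library. Ambiguous and unassigned spliced reads are counted in
#' `splicedReads` but enter no pair's numerator.
#'
#' @slot libraryId library identifier.
#' @slot totalReads,mappedReads,wtReads,splicedReads,unassignedSpliced,ambiguousSpliced
#'   read-class counts; `mappedReads = wtReads + splicedReads` and
#'   `splicedReads = sum(perPair$count) + unassignedSpliced + ambiguousSpliced`.
#' @slot perPair data.frame with columns `pair_id`, `count`, `efficiency`,
#'   `ci_lo`, `ci_hi` (95% Wilson score interval).
#'
#' @exportClass LibraryQuant
setClass("LibraryQuant",
    slots = c(
        libraryId         = "character",
        totalReads        = "integer",
        mappedReads       = "integer",
        wtReads           = "integer",
        splicedReads      = "integer",
        unassignedSpliced = "integer",
        ambiguousSpliced  = "integer",
        perPair           = "data.frame"
    )
)

setValidity("LibraryQuant", function(object) {
    msg <- character()
    if (object@mappedReads != object@wtReads + object@splicedReads)
        msg <- c(msg, "mappedReads must equal wtReads + splicedReads")
    if (object@mappedReads > object@totalReads)
        msg <- c(msg, "mappedReads cannot exceed totalReads")
    if (sum(object@perPair$count) + object@unassignedSpliced +
        object@ambiguousSpliced != object@splicedReads)
        msg <- c(msg, "spliced counts must partition splicedReads")
    if (nrow(object@perPair) &&
        (any(object@perPair$efficiency < 0) ||
         any(object@perPair$efficiency > 1)))
        msg <- c(msg, "efficiencies must lie in [0, 1]")
    if (length(msg)) msg else TRUE
})
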