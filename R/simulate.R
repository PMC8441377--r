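## Evaluate expr under a fixed seed without disturbing the caller's RNG.
.withSeed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(),
                        inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    force(expr)
}

#' Ground-truth simulation configuration
#'
#' See [TruthConfig-class] for the meaning of each field. Defaults mirror
#' the targeted assay: 150-bp single-end MiSeq-style reads anchored 50 bp
#' upstream of the upstream cut site, 5-bp breakpoint jitter, an occasional
#' short junction insertion, and a low substitution error rate.
#'
#' @param reference an [AmpliconReference-class].
#' @param pairs list of [GuidePair-class] objects (named or not; pair ids
#'   are taken from [pairId()]).
#' @param pairFractions numeric vector of per-pair read fractions, either
#'   named by pair id or in the order of `pairs`.
#' @param wtFraction fraction of wild-type reads; the remainder
#'   `1 - wtFraction - sum(pairFractions)` becomes random garbage reads.
#' @param jitterSd,insertJunctionProb,substErrorRate,readLength,readAnchorOffset,nReads,seed
#'   see [TruthConfig-class].
#' @return A validated [TruthConfig-class].
#' @export
truthConfig <- function(reference, pairs, pairFractions, wtFraction,
                        jitterSd = 5, insertJunctionProb = 0.1,
                        substErrorRate = 0.003, readLength = 150L,
                        readAnchorOffset = 50L, nReads = 1000L,
                        seed = 1L) {
    ids <- vapply(pairs, pairId, character(1))
    names(pairs) <- ids
    if (is.null(names(pairFractions))) {
        if (length(pairFractions) != length(pairs))
            stop("pairFractions must match pairs")
        names(pairFractions) <- ids
    }
    if (!setequal(names(pairFractions), ids))
        stop("pairFractions names must match pair ids")
    pairFractions <- pairFractions[ids]
    new("TruthConfig", reference = reference, pairs = pairs,
        pairFractions = pairFractions, wtFraction = as.numeric(wtFraction),
        jitterSd = as.numeric(jitterSd),
        insertJunctionProb = as.numeric(insertJunctionProb),
        substErrorRate = as.numeric(substErrorRate),
        readLength = as.integer(readLength),
        readAnchorOffset = as.integer(readAnchorOffset),
        nReads = as.integer(nReads), seed = as.integer(seed))
}

setMethod("show", "TruthConfig", function(object) {
    cat("TruthConfig: ", object@nReads, " reads of ", object@readLength,
        " bp on '", object@reference@name, "' (seed ", object@seed, ")\n",
        sep = "")
    cat("  wt ", object@wtFraction, "; pairs: ",
        paste(sprintf("%s=%.3g", names(object@pairFractions),
                      object@pairFractions), collapse = ", "),
        "; jitter sd ", object@jitterSd, " bp, subst ",
        object@substErrorRate, "\n", sep = "")
})

.randomDna <- function(n) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.addSubstErrors <- function(seq, rate) {
    if (rate <= 0) return(seq)
    n <- nchar(seq)
    hit <- which(runif(n) < rate)
    if (!length(hit)) return(seq)
    ch <- strsplit(seq, "")[[1L]]
    for (p in hit) {
        alt <- setdiff(c("A", "C", "G", "T"), ch[p])
        ch[p] <- alt[sample.int(3L, 1L)]
    }
    paste(ch, collapse = "")
}

#' Simulate an amplicon library with known ground truth
#'
#' Draws read classes from the configured mixture, excises the jittered
#' inter-cut-site interval for deletion reads (optionally inserting 1-5
#' random bases at the junction), windows every non-garbage read to
#' `readLength` bases starting `readAnchorOffset` bp upstream of the
#' relevant upstream cut site (clamped to the amplicon), and applies
#' per-base substitution errors. Wild-type reads are anchored at the
#' upstream cut site of a randomly chosen pair, mimicking the pooled
#' sequencing-primer design. Deterministic given `config@seed`.
#'
#' @param config a [TruthConfig-class] from [truthConfig()].
#' @return A list with elements `reads` (a named [Biostrings::DNAStringSet])
#'   and `truth` (data.frame with columns `read_id`, `class`
#'   (`wt`/`deletion`/`garbage`), `pair_id`, `true_start`, `true_end`,
#'   `true_size`; breakpoints 0-based half-open).
#' @seealso [writeLibrary()] to write FASTQ plus truth TSV,
#'   [truthEfficiencies()].
#' @export
simulateLibrary <- function(config) {
    validObject(config)
    .withSeed(config@seed, {
        ref <- as.character(config@reference@sequence)
        len <- nchar(ref)
        ids <- names(config@pairFractions)
        classes <- c(ids, ".wt", ".garbage")
        probs <- c(config@pairFractions, config@wtFraction,
                   max(0, 1 - config@wtFraction -
                           sum(config@pairFractions)))
        draw <- sample(classes, config@nReads, replace = TRUE,
                       prob = probs)
        usCuts <- vapply(config@pairs, function(p) p@usGuide@cutSite,
                         integer(1))
        dsCuts <- vapply(config@pairs, function(p) p@dsGuide@cutSite,
                         integer(1))

        readIds <- sprintf("sim%d:r%06d", config@seed,
                           seq_len(config@nReads))
        seqs <- character(config@nReads)
        cls <- character(config@nReads)
        pid <- rep(NA_character_, config@nReads)
        tstart <- rep(NA_integer_, config@nReads)
        tend <- rep(NA_integer_, config@nReads)

        for (i in seq_len(config@nReads)) {
            d <- draw[i]
            if (d == ".garbage") {
                cls[i] <- "garbage"
                seqs[i] <- .randomDna(config@readLength)
                next
            }
            if (d == ".wt") {
                cls[i] <- "wt"
                us <- usCuts[[sample.int(length(usCuts), 1L)]]
                anchor <- max(0L, us - config@readAnchorOffset)
                seqs[i] <- substr(ref, anchor + 1L,
                                  min(len, anchor + config@readLength))
            } else {
                cls[i] <- "deletion"
                pid[i] <- d
                us <- usCuts[[d]]
                ds <- dsCuts[[d]]
                start <- us + as.integer(round(rnorm(1, 0,
                                                     config@jitterSd)))
                end <- ds + as.integer(round(rnorm(1, 0, config@jitterSd)))
                start <- max(0L, min(start, len - 3L))
                end <- max(start + 3L, min(end, len))
                ins <- if (runif(1) < config@insertJunctionProb)
                    .randomDna(sample.int(5L, 1L)) else ""
                delseq <- paste0(substr(ref, 1L, start), ins,
                                 substr(ref, end + 1L, len))
                anchor <- max(0L, us - config@readAnchorOffset)
                seqs[i] <- substr(delseq, anchor + 1L,
                                  min(nchar(delseq),
                                      anchor + config@readLength))
                tstart[i] <- start
                tend[i] <- end
            }
            seqs[i] <- .addSubstErrors(seqs[i], config@substErrorRate)
        }

        reads <- Biostrings::DNAStringSet(seqs)
        names(reads) <- readIds
        truth <- data.frame(
            read_id = readIds, class = cls, pair_id = pid,
            true_start = tstart, true_end = tend,
            true_size = tend - tstart, stringsAsFactors = FALSE)
        list(reads = reads, truth = truth)
    })
}

#' Ground-truth per-pair deletion fractions
#'
#' Per-pair deletion-read count divided by the total number of non-garbage
#' (mappable) reads; the ideal value recovered by [quantifyLibrary()].
#'
#' @param truth truth data.frame from [simulateLibrary()].
#' @param pairIds optional pair ids fixing the order (and zero-filling
#'   pairs without reads).
#' @return Named numeric vector of fractions.
#' @export
truthEfficiencies <- function(truth, pairIds = NULL) {
    mapped <- truth[truth$class %in% c("wt", "deletion"), , drop = FALSE]
    if (!nrow(mapped)) stop("no mapped-class reads in truth")
    if (is.null(pairIds))
        pairIds <- sort(unique(mapped$pair_id[!is.na(mapped$pair_id)]))
    counts <- vapply(pairIds, function(p)
        sum(mapped$pair_id == p, na.rm = TRUE), integer(1))
    counts / nrow(mapped)
}

#' Write a simulated library as FASTQ plus truth TSV
#'
#' FASTQ records carry constant Q30 qualities; the simulation seed is
#' embedded in every read id. Gzip output is selected by a `.gz` extension.
#'
#' @param sim result of [simulateLibrary()].
#' @param fastq output FASTQ path.
#' @param truthFile optional output path for the truth table.
#' @return The FASTQ path, invisibly.
#' @export
writeLibrary <- function(sim, fastq, truthFile = NULL) {
    quals <- Biostrings::BStringSet(
        vapply(nchar(as.character(sim$reads)),
               function(w) strrep("?", w), character(1)))
    Biostrings::writeXStringSet(sim$reads, fastq, format = "fastq",
                                compress = grepl("\\.gz$", fastq),
                                qualities = quals)
    if (!is.null(truthFile))
        write.table(sim$truth, truthFile, sep = "\t", quote = FALSE,
                    row.names = FALSE)
    invisible(fastq)
}
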