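#' Assign deletion breakpoints to sgRNA pairs
#'
#' A pair is a candidate for a call when both breakpoints fall within
#' `window` bp of the pair's respective cut sites (two-sided mode). With a
#' single candidate the call is assigned to it; with several, to the pair
#' minimising the summed breakpoint-to-cut-site distance (an exact tie is
#' `ambiguous`); with none the call is `unassigned`. One-sided mode
#' (`bothEnds = FALSE`) requires only one breakpoint within the window.
#'
#' @param starts,ends integer vectors of deletion breakpoints (0-based
#'   half-open junction interval on the amplicon).
#' @param pairs list of [GuidePair-class] objects.
#' @param window assignment window in bp (default 60, `<=` comparison).
#' @param bothEnds require both breakpoints within the window
#'   (default `TRUE`).
#' @return data.frame with columns `assigned_pair` (pair id, `"ambiguous"`
#'   or `"unassigned"`), `distance_us`, `distance_ds` (`NA` unless
#'   assigned).
#' @export
assignCalls <- function(starts, ends, pairs, window = 60L,
                        bothEnds = TRUE) {
    stopifnot(length(starts) == length(ends), length(pairs) >= 1L,
              window >= 0L)
    ids <- vapply(pairs, pairId, character(1))
    usCuts <- vapply(pairs, function(p) p@usGuide@cutSite, integer(1))
    dsCuts <- vapply(pairs, function(p) p@dsGuide@cutSite, integer(1))
    n <- length(starts)
    assigned <- character(n)
    dUs <- rep(NA_integer_, n)
    dDs <- rep(NA_integer_, n)
    for (i in seq_len(n)) {
        du <- abs(starts[i] - usCuts)
        dd <- abs(ends[i] - dsCuts)
        cand <- if (bothEnds) du <= window & dd <= window
                else du <= window | dd <= window
        k <- which(cand)
        if (length(k) == 0L) {
            assigned[i] <- "unassigned"
        } else if (length(k) == 1L) {
            assigned[i] <- ids[k]
            dUs[i] <- du[k]
            dDs[i] <- dd[k]
        } else {
            tot <- du[k] + dd[k]
            bestv <- min(tot)
            b <- k[tot == bestv]
            if (length(b) > 1L) {
                assigned[i] <- "ambiguous"
            } else {
                assigned[i] <- ids[b]
                dUs[i] <- du[b]
                dDs[i] <- dd[b]
            }
        }
    }
    data.frame(assigned_pair = assigned, distance_us = dUs,
               distance_ds = dDs, stringsAsFactors = FALSE)
}

.wilson <- function(x, n, conf = 0.95) {
    if (n == 0L) return(c(NA_real_, NA_real_))
    z <- qnorm(1 - (1 - conf) / 2)
    p <- x / n
    den <- 1 + z^2 / n
    centre <- (p + z^2 / (2 * n)) / den
    half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
    c(max(0, centre - half), min(1, centre + half))
}

#' Quantify per-pair deletion efficiencies for one library
#'
#' Counts read classes, assigns spliced reads to guide pairs by cut-site
#' proximity ([assignCalls()]) and computes each pair's editing efficiency
#' as its assigned spliced-read count divided by total mapped reads
#' (wild-type + spliced; unmapped reads are excluded from the
#' denominator). Ambiguous and unassigned spliced reads stay in the
#' spliced total but enter no pair's numerator.
#'
#' @param aln classified data.frame from [classifyReads()].
#' @param pairs list of [GuidePair-class] objects.
#' @param window assignment window in bp (default 60).
#' @param libraryId identifier recorded in the result.
#' @param bothEnds passed to [assignCalls()].
#' @return A [LibraryQuant-class].
#' @export
quantifyLibrary <- function(aln, pairs, window = 60L, libraryId = "lib",
                            bothEnds = TRUE) {
    stopifnot(is.data.frame(aln), "class" %in% names(aln))
    total <- nrow(aln)
    wt <- sum(aln$class == "wt_mapped")
    spl <- aln[aln$class == "spliced", , drop = FALSE]
    mapped <- wt + nrow(spl)
    if (mapped == 0L)
        stop("empty library: no mapped reads")
    ids <- vapply(pairs, pairId, character(1))
    counts <- setNames(integer(length(ids)), ids)
    ambiguous <- 0L
    unassigned <- 0L
    spectrumCalls <- NULL
    if (nrow(spl)) {
        asg <- assignCalls(spl$del_start, spl$del_end, pairs,
                           window = window, bothEnds = bothEnds)
        tab <- table(asg$assigned_pair)
        ambiguous <- if ("ambiguous" %in% names(tab))
            as.integer(tab[["ambiguous"]]) else 0L
        unassigned <- if ("unassigned" %in% names(tab))
            as.integer(tab[["unassigned"]]) else 0L
        hit <- intersect(names(tab), ids)
        counts[hit] <- as.integer(tab[hit])
        spectrumCalls <- cbind(
            spl[, c("read_id", "del_start", "del_end", "junction_size")],
            asg)
    }
    ci <- t(vapply(counts, .wilson, numeric(2), n = mapped))
    perPair <- data.frame(
        pair_id = ids, count = as.integer(counts),
        efficiency = as.numeric(counts) / mapped,
        ci_lo = ci[, 1L], ci_hi = ci[, 2L],
        row.names = NULL, stringsAsFactors = FALSE)
    q <- new("LibraryQuant", libraryId = as.character(libraryId),
             totalReads = as.integer(total), mappedReads = as.integer(mapped),
             wtReads = as.integer(wt), splicedReads = nrow(spl),
             unassignedSpliced = unassigned, ambiguousSpliced = ambiguous,
             perPair = perPair)
    attr(q, "calls") <- spectrumCalls
    q
}

#' @rdname efficiencies
#' @export
setMethod("efficiencies", "LibraryQuant", function(x)
    setNames(x@perPair$efficiency, x@perPair$pair_id))

setMethod("show", "LibraryQuant", function(object) {
    cat("LibraryQuant '", object@libraryId, "': ", object@totalReads,
        " reads, ", object@mappedReads, " mapped (", object@wtReads,
        " wt + ", object@splicedReads, " spliced; ",
        object@unassignedSpliced, " unassigned, ",
        object@ambiguousSpliced, " ambiguous)\n", sep = "")
    pp <- object@perPair
    for (i in seq_len(nrow(pp)))
        cat(sprintf("  %-12s %6d reads  efficiency %.3f [%.3f, %.3f]\n",
                    pp$pair_id[i], pp$count[i], pp$efficiency[i],
                    pp$ci_lo[i], pp$ci_hi[i]))
})

#' Deletion calls of a quantified library
#'
#' @param quant a [LibraryQuant-class] from [quantifyLibrary()].
#' @return data.frame of spliced-read calls (`read_id`, `del_start`,
#'   `del_end`, `junction_size`, `assigned_pair`, `distance_us`,
#'   `distance_ds`), or `NULL` when the library has no spliced reads.
#' @export
deletionCalls <- function(quant) attr(quant, "calls")

#' Aggregate per-pair efficiencies across replicate libraries
#'
#' Arithmetic mean and sample standard deviation of each pair's efficiency
#' across libraries. A pair missing from some libraries is treated as
#' efficiency 0 there (with a warning); a single library yields sd 0 with
#' a warning.
#'
#' @param quants list of [LibraryQuant-class] objects.
#' @return data.frame with columns `pair_id`, `mean`, `sd`, `n`.
#' @export
aggregateReplicates <- function(quants) {
    stopifnot(length(quants) >= 1L)
    ids <- unique(unlist(lapply(quants, function(q) q@perPair$pair_id)))
    mat <- matrix(0, nrow = length(quants), ncol = length(ids),
                  dimnames = list(NULL, ids))
    missing <- FALSE
    for (i in seq_along(quants)) {
        e <- efficiencies(quants[[i]])
        if (!all(ids %in% names(e))) missing <- TRUE
        hit <- intersect(ids, names(e))
        mat[i, hit] <- e[hit]
    }
    if (missing)
        warning("some pairs absent from some libraries; treated as 0")
    if (length(quants) == 1L) {
        warning("single library: sd undefined, reported as 0")
        sds <- rep(0, length(ids))
    } else {
        sds <- apply(mat, 2L, sd)
    }
    data.frame(pair_id = ids, mean = colMeans(mat), sd = sds,
               n = length(quants), row.names = NULL,
               stringsAsFactors = FALSE)
}

#' Deletion spectrum and per-pair breakpoint dispersion
#'
#' Unique breakpoint pairs with their read counts (sorted by count,
#' descending) plus, per assigned pair, the standard deviation of the
#' start and end breakpoints — the horizontal "cut-site variability" of a
#' deletion-spectrum plot.
#'
#' @param calls data.frame of deletion calls (see [deletionCalls()]); the
#'   columns `del_start`, `del_end` are required, `assigned_pair` is used
#'   for the dispersion summary when present.
#' @return list with elements `spectrum` (data.frame `start`, `end`,
#'   `size`, `count`) and `dispersion` (data.frame `pair_id`, `n`,
#'   `sd_start`, `sd_end`, `mean_size`).
#' @export
deletionSpectrum <- function(calls) {
    stopifnot(is.data.frame(calls), nrow(calls) >= 1L)
    key <- paste(calls$del_start, calls$del_end)
    tab <- as.data.frame(table(key), stringsAsFactors = FALSE)
    parts <- strsplit(tab$key, " ")
    spectrum <- data.frame(
        start = as.integer(vapply(parts, `[`, character(1), 1L)),
        end = as.integer(vapply(parts, `[`, character(1), 2L)),
        count = as.integer(tab$Freq))
    spectrum$size <- spectrum$end - spectrum$start
    spectrum <- spectrum[order(-spectrum$count, spectrum$start,
                               spectrum$end),
                         c("start", "end", "size", "count")]
    rownames(spectrum) <- NULL

    dispersion <- NULL
    if ("assigned_pair" %in% names(calls)) {
        real <- calls[!calls$assigned_pair %in%
                          c("ambiguous", "unassigned"), , drop = FALSE]
        if (nrow(real)) {
            sp <- split(real, real$assigned_pair)
            dispersion <- data.frame(
                pair_id = names(sp),
                n = vapply(sp, nrow, integer(1)),
                sd_start = vapply(sp, function(d)
                    if (nrow(d) > 1L) sd(d$del_start) else 0, numeric(1)),
                sd_end = vapply(sp, function(d)
                    if (nrow(d) > 1L) sd(d$del_end) else 0, numeric(1)),
                mean_size = vapply(sp, function(d)
                    mean(d$del_end - d$del_start), numeric(1)),
                row.names = NULL, stringsAsFactors = FALSE)
        }
    }
    list(spectrum = spectrum, dispersion = dispersion)
}

#' Write per-pair quantification rows for one or more libraries
#'
#' @param quants a [LibraryQuant-class] or list thereof.
#' @param file output TSV path.
#' @return The path, invisibly.
#' @export
writeQuant <- function(quants, file) {
    if (is(quants, "LibraryQuant")) quants <- list(quants)
    rows <- do.call(rbind, lapply(quants, function(q) {
        cbind(data.frame(library_id = q@libraryId,
                         total_reads = q@totalReads,
                         mapped_reads = q@mappedReads,
                         wt_reads = q@wtReads,
                         spliced_reads = q@splicedReads,
                         unassigned_spliced = q@unassignedSpliced,
                         ambiguous_spliced = q@ambiguousSpliced),
              q@perPair)
    }))
    num <- vapply(rows, is.numeric, logical(1))
    rows[num] <- lapply(rows[num], function(x) round(x, 6))
    write.table(rows, file, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(file)
}
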