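.md5Named <- function(paths) {
    setNames(as.list(unname(tools::md5sum(paths))), basename(paths))
}

.configError <- function(...) {
    stop(errorCondition(paste0(...),
                        class = c("ampliconDelConfigError", "error")))
}

.dataError <- function(...) {
    stop(errorCondition(paste0(...),
                        class = c("ampliconDelDataError", "error")))
}

#' Read a pipeline run configuration
#'
#' YAML configuration with keys `reference` (FASTA path), `guides` (TSV
#' path), `outdir`, `seed`, `window`, an optional `filter` block
#' (`min_junction`, `min_aligned_ratio`, `min_identity`, `min_flank`),
#' and a `libraries` list whose entries carry an `id` plus either a
#' `fastq` path or a `simulate` block (`n_reads`, `wt_fraction`,
#' `pair_fractions` map, `jitter_sd`, `insert_junction_prob`,
#' `subst_error_rate`, `read_length`, `read_anchor_offset`). Relative
#' paths are resolved against the configuration file's directory.
#'
#' @param file YAML path.
#' @return A named list (the parsed configuration with resolved paths).
#' @export
readRunConfig <- function(file) {
    if (!file.exists(file)) .configError("config file not found: ", file)
    cfg <- yaml::read_yaml(file)
    base <- dirname(normalizePath(file))
    resolve <- function(p)
        if (!is.null(p) && !grepl("^(/|[A-Za-z]:)", p))
            file.path(base, p) else p
    cfg$reference <- resolve(cfg$reference)
    cfg$guides <- resolve(cfg$guides)
    if (!is.null(cfg$libraries))
        cfg$libraries <- lapply(cfg$libraries, function(lib) {
            lib$fastq <- resolve(lib$fastq)
            lib
        })
    cfg
}

.cfgFilter <- function(cfg) {
    f <- cfg$filter
    filterParams(
        minJunction = if (is.null(f$min_junction)) 2L else f$min_junction,
        minAlignedRatio = if (is.null(f$min_aligned_ratio)) 0.95
                          else f$min_aligned_ratio,
        minIdentity = if (is.null(f$min_identity)) 0.95
                      else f$min_identity,
        minFlank = if (is.null(f$min_flank)) 20L else f$min_flank)
}

#' Run the full deletion-quantification pipeline
#'
#' Executes simulate (or FASTQ import), split alignment, read
#' classification, per-pair quantification, replicate aggregation and
#' deletion-spectrum summarisation, writing one TSV per stage plus a JSON
#' manifest with package version, parameters, seeds and input/output MD5
#' checksums. Deterministic for a fixed configuration and seed: a rerun
#' produces byte-identical outputs.
#'
#' @param config path to a YAML configuration (see [readRunConfig()]) or
#'   an equivalent named list.
#' @param outdir optional output directory overriding the configuration.
#' @return Invisibly, the manifest as a list (also written as
#'   `manifest.json`).
#' @export
runPipeline <- function(config, outdir = NULL) {
    if (is.character(config)) config <- readRunConfig(config)
    if (is.null(config$reference))
        .configError("config lacks 'reference'")
    if (is.null(config$guides)) .configError("config lacks 'guides'")
    if (is.null(outdir)) outdir <- config$outdir
    if (is.null(outdir)) .configError("config lacks 'outdir'")
    if (!file.exists(config$reference))
        .configError("reference file not found: ", config$reference)
    if (!file.exists(config$guides))
        .configError("guide file not found: ", config$guides)
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

    seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
    window <- if (is.null(config$window)) 60L
              else as.integer(config$window)
    params <- .cfgFilter(config)

    reference <- readAmpliconFasta(config$reference)
    guides <- readGuideTable(config$guides, reference)
    pairs <- guidePairs(guides)

    design <- designSummary(reference, pairs)
    designFile <- file.path(outdir, "design_summary.tsv")
    write.table(design, designFile, sep = "\t", quote = FALSE,
                row.names = FALSE)

    inputs <- c(config$reference, config$guides)
    quants <- list()
    allCalls <- list()
    alnFiles <- character()
    for (k in seq_along(config$libraries)) {
        lib <- config$libraries[[k]]
        libId <- if (is.null(lib$id)) paste0("lib", k) else lib$id
        if (!is.null(lib$fastq)) {
            if (!file.exists(lib$fastq))
                .configError("fastq file not found: ", lib$fastq)
            inputs <- c(inputs, lib$fastq)
            reads <- readReads(lib$fastq)
        } else if (!is.null(lib$simulate)) {
            s <- lib$simulate
            fr <- unlist(s$pair_fractions)
            tc <- truthConfig(
                reference, pairs[names(fr)], fr,
                wtFraction = s$wt_fraction,
                jitterSd = if (is.null(s$jitter_sd)) 5 else s$jitter_sd,
                insertJunctionProb = if (is.null(s$insert_junction_prob))
                    0.1 else s$insert_junction_prob,
                substErrorRate = if (is.null(s$subst_error_rate)) 0.003
                                 else s$subst_error_rate,
                readLength = if (is.null(s$read_length)) 150L
                             else s$read_length,
                readAnchorOffset = if (is.null(s$read_anchor_offset)) 50L
                                   else s$read_anchor_offset,
                nReads = s$n_reads, seed = seed + 1000L * k)
            sim <- simulateLibrary(tc)
            writeLibrary(sim, file.path(outdir,
                                        paste0(libId, ".fastq")),
                         file.path(outdir, paste0(libId, "_truth.tsv")))
            reads <- sim$reads
        } else {
            .configError("library '", libId,
                         "' needs either 'fastq' or 'simulate'")
        }
        aln <- tryCatch(
            classifyReads(alignReads(reads, reference), params),
            error = function(e) .dataError("alignment failed for '",
                                           libId, "': ",
                                           conditionMessage(e)))
        alnFile <- file.path(outdir, paste0(libId, "_alignments.tsv"))
        writeAlignments(aln, alnFile)
        alnFiles <- c(alnFiles, alnFile)
        q <- tryCatch(
            quantifyLibrary(aln, pairs, window = window,
                            libraryId = libId),
            error = function(e) .dataError("quantification failed for '",
                                           libId, "': ",
                                           conditionMessage(e)))
        quants[[libId]] <- q
        calls <- deletionCalls(q)
        if (!is.null(calls)) {
            calls$library_id <- libId
            allCalls[[libId]] <- calls
        }
    }
    if (!length(quants)) .configError("no libraries configured")

    quantFile <- file.path(outdir, "library_quant.tsv")
    writeQuant(quants, quantFile)
    aggFile <- file.path(outdir, "aggregate.tsv")
    agg <- suppressWarnings(aggregateReplicates(quants))
    write.table(agg, aggFile, sep = "\t", quote = FALSE,
                row.names = FALSE)

    spectrumFile <- file.path(outdir, "spectrum.tsv")
    plotFile <- file.path(outdir, "plot_segments.tsv")
    if (length(allCalls)) {
        calls <- do.call(rbind, allCalls)
        spec <- deletionSpectrum(calls)
        write.table(spec$spectrum, spectrumFile, sep = "\t",
                    quote = FALSE, row.names = FALSE)
        if (!is.null(spec$dispersion))
            write.table(spec$dispersion,
                        file.path(outdir, "dispersion.tsv"),
                        sep = "\t", quote = FALSE, row.names = FALSE)
        ## long-format, plot-ready: one row per library x deletion segment
        calls$count <- 1L
        plotLong <- aggregate(
            count ~ library_id + assigned_pair + del_start + del_end,
            data = calls, FUN = sum)
        plotLong <- plotLong[order(plotLong$library_id,
                                   plotLong$assigned_pair,
                                   -plotLong$count), ]
        write.table(plotLong, plotFile, sep = "\t", quote = FALSE,
                    row.names = FALSE)
    }

    outputs <- c(designFile, alnFiles, quantFile, aggFile,
                 Filter(file.exists, c(spectrumFile, plotFile)))
    manifest <- list(
        package = "ampliconDel",
        version = as.character(packageVersion("ampliconDel")),
        seed = seed,
        parameters = list(
            window = window,
            min_junction = params@minJunction,
            min_aligned_ratio = params@minAlignedRatio,
            min_identity = params@minIdentity,
            min_flank = params@minFlank),
        inputs = .md5Named(unique(inputs)),
        outputs = .md5Named(outputs))
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    invisible(manifest)
}
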