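#' Comparative-CT (delta-delta-Ct) fold changes
#'
#' Implements the Livak comparative-CT method with an assumed amplification
#' efficiency of 2: per sample, `dCt = Cq(target) - Cq(housekeeping)`
#' (technical replicate rows are averaged to one Cq per sample and gene
#' first); `ddCt = dCt - mean dCt of the calibrator samples`; fold change
#' `= 2^(-ddCt)`. Two normalisation schemes are supported:
#' `"global_calibrator"` uses one calibrator cell (group + condition) for
#' every sample; `"condition_matched"` uses the calibrator group matched to
#' each sample's own condition.
#'
#' @param qpcr data.frame with columns `sample_id`, `group`, `condition`,
#'   `gene`, `cq` (a `replicate` column, if present, is carried through
#'   unchanged; multiple rows per sample/gene are treated as technical
#'   replicates).
#' @param calibrator length-2 character vector `c(group, condition)`; under
#'   `"condition_matched"` only the group component is used.
#' @param scheme `"global_calibrator"` or `"condition_matched"`.
#' @param targetGene,housekeepingGene values of `gene` identifying the
#'   target and the housekeeping (normaliser) gene.
#' @return data.frame with one row per sample: `sample_id`, `group`,
#'   `condition`, `dct`, `ddct`, `fold_change`.
#' @examples
#' tab <- data.frame(
#'     sample_id = rep(c("c1", "t1"), each = 2),
#'     group = rep(c("empty_vector", "crispr_pool"), each = 2),
#'     condition = "differentiated_39.5",
#'     gene = rep(c("target", "housekeeping"), 2),
#'     cq = c(24, 18, 28, 18))
#' ddctFoldChange(tab, calibrator = c("empty_vector",
#'                                    "differentiated_39.5"))
#' @export
ddctFoldChange <- function(qpcr,
                           calibrator,
                           scheme = c("global_calibrator",
                                      "condition_matched"),
                           targetGene = "target",
                           housekeepingGene = "housekeeping") {
    scheme <- match.arg(scheme)
    need <- c("sample_id", "group", "condition", "gene", "cq")
    if (!all(need %in% names(qpcr)))
        stop("qpcr table must have columns ",
             paste(need, collapse = ", "))
    if (any(qpcr$cq <= 0 | qpcr$cq >= 45))
        stop("Cq values must lie in (0, 45)")

    ## average technical replicates to one Cq per sample and gene
    agg <- aggregate(cq ~ sample_id + group + condition + gene,
                     data = qpcr, FUN = mean)
    tg <- agg[agg$gene == targetGene, ]
    hk <- agg[agg$gene == housekeepingGene, ]
    samples <- unique(agg[, c("sample_id", "group", "condition")])
    m <- merge(samples, tg[, c("sample_id", "cq")], by = "sample_id",
               all.x = TRUE)
    names(m)[names(m) == "cq"] <- "cq_target"
    m <- merge(m, hk[, c("sample_id", "cq")], by = "sample_id",
               all.x = TRUE)
    names(m)[names(m) == "cq"] <- "cq_housekeeping"
    if (any(is.na(m$cq_housekeeping)))
        stop("missing housekeeping Cq for sample(s): ",
             paste(m$sample_id[is.na(m$cq_housekeeping)], collapse = ", "))
    if (any(is.na(m$cq_target)))
        stop("missing target Cq for sample(s): ",
             paste(m$sample_id[is.na(m$cq_target)], collapse = ", "))
    m$dct <- m$cq_target - m$cq_housekeeping

    calGroup <- calibrator[1L]
    if (scheme == "global_calibrator") {
        if (length(calibrator) < 2L)
            stop("global calibrator needs c(group, condition)")
        calRows <- m$group == calGroup & m$condition == calibrator[2L]
        if (!any(calRows)) stop("empty calibrator cell")
        m$ddct <- m$dct - mean(m$dct[calRows])
    } else {
        m$ddct <- NA_real_
        for (cond in unique(m$condition)) {
            calRows <- m$group == calGroup & m$condition == cond
            if (!any(calRows))
                stop("empty calibrator cell for condition ", cond)
            sel <- m$condition == cond
            m$ddct[sel] <- m$dct[sel] - mean(m$dct[calRows])
        }
    }
    m$fold_change <- 2^(-m$ddct)
    m[order(m$group, m$condition, m$sample_id),
      c("sample_id", "group", "condition", "dct", "ddct", "fold_change")]
}

.cellValues <- function(intensity, measure, cell, normalizer = NULL) {
    sel <- intensity$measure == measure & intensity$group == cell[1L] &
        intensity$condition == cell[2L]
    d <- intensity[sel, , drop = FALSE]
    if (!nrow(d)) stop("no rows for measure '", measure, "' in cell (",
                       cell[1L], ", ", cell[2L], ")")
    v <- d$value
    if (!is.null(normalizer)) {
        nsel <- intensity$measure == normalizer &
            intensity$group == cell[1L] & intensity$condition == cell[2L]
        nd <- intensity[nsel, , drop = FALSE]
        nv <- nd$value[match(d$replicate, nd$replicate)]
        if (any(is.na(nv)))
            stop("missing normalizer '", normalizer, "' for replicate(s)")
        if (any(nv <= 0)) stop("normalizer values must be > 0")
        v <- v / nv
    }
    setNames(v, d$replicate)
}

#' Percent change of an intensity measure between two experimental cells
#'
#' Per-replicate intensities (optionally divided by a matched normaliser
#' measure, e.g. a tubulin loading control for immunoblot bands) are
#' averaged per cell, and the change is reported on the percent scale with
#' a decrease positive:
#' `100 * (mean_control - mean_treated) / mean_control`.
#'
#' @param intensity data.frame with columns `group`, `condition`,
#'   `replicate`, `measure`, `value` (values >= 0).
#' @param measure the measure to compare (e.g. `"alp_stain"`, `"band_U"`).
#' @param treated,control length-2 character vectors `c(group, condition)`.
#' @param normalizer optional measure used as per-replicate denominator.
#' @return list with `percent_change` (positive = decrease),
#'   `mean_treated`, `mean_control`, and the per-replicate normalised
#'   `values_treated` / `values_control`.
#' @examples
#' tab <- data.frame(group = rep(c("empty_vector", "crispr_pool"), 3),
#'                   condition = "differentiated_39.5",
#'                   replicate = rep(1:3, each = 2),
#'                   measure = "alp_stain",
#'                   value = c(100, 39, 102, 40, 98, 38))
#' percentChange(tab, "alp_stain",
#'               treated = c("crispr_pool", "differentiated_39.5"),
#'               control = c("empty_vector", "differentiated_39.5"))
#' @export
percentChange <- function(intensity, measure, treated, control,
                          normalizer = NULL) {
    stopifnot(all(c("group", "condition", "replicate", "measure",
                    "value") %in% names(intensity)))
    if (any(intensity$value < 0)) stop("intensity values must be >= 0")
    vt <- .cellValues(intensity, measure, treated, normalizer)
    vc <- .cellValues(intensity, measure, control, normalizer)
    mc <- mean(vc)
    if (mc == 0) stop("undefined percent change: control mean is 0")
    list(percent_change = 100 * (mc - mean(vt)) / mc,
         mean_treated = mean(vt), mean_control = mc,
         values_treated = vt, values_control = vc)
}

#' Transduction efficiency from paired cell counts
#'
#' Per replicate, the ratio of marker-positive (e.g. mCherry fluorescent)
#' to bright-field cell counts; the estimate is the mean of per-replicate
#' ratios, not the pooled-count ratio.
#'
#' @param intensity data.frame as in [percentChange()], holding the two
#'   count measures for matching replicates.
#' @param positiveMeasure,totalMeasure `measure` values of the
#'   marker-positive and total (bright-field) counts.
#' @param group,condition optional filters restricting the rows used.
#' @return list with `efficiency` (mean of ratios) and per-replicate
#'   `ratios`.
#' @export
transductionEfficiency <- function(intensity,
                                   positiveMeasure = "cells_mcherry",
                                   totalMeasure = "cells_brightfield",
                                   group = NULL, condition = NULL) {
    d <- intensity
    if (!is.null(group)) d <- d[d$group %in% group, , drop = FALSE]
    if (!is.null(condition))
        d <- d[d$condition %in% condition, , drop = FALSE]
    pos <- d[d$measure == positiveMeasure, , drop = FALSE]
    tot <- d[d$measure == totalMeasure, , drop = FALSE]
    if (!nrow(pos) || !nrow(tot))
        stop("both count measures must be present")
    key <- function(x) paste(x$group, x$condition, x$replicate)
    tv <- tot$value[match(key(pos), key(tot))]
    if (any(is.na(tv)))
        stop("unmatched bright-field count for some replicate(s)")
    if (any(tv == 0)) stop("bright-field count of 0")
    ratios <- setNames(pos$value / tv, key(pos))
    if (any(ratios > 1))
        warning("marker-positive count exceeds total for some replicate(s)")
    list(efficiency = mean(ratios), ratios = ratios)
}

#' Welch two-sample t test
#'
#' Two-sided two-sample t test; Welch (unequal variances) by default, with
#' the pooled-variance variant behind a flag.
#'
#' @param x,y numeric vectors, each of length >= 2.
#' @param pooled use the pooled-variance (classical) test instead of Welch.
#' @return list with elements `t`, `df`, `p`.
#' @export
twoSampleT <- function(x, y, pooled = FALSE) {
    if (length(x) < 2L || length(y) < 2L)
        stop("each group needs at least 2 observations")
    if (sd(x) == 0 && sd(y) == 0) {
        df <- length(x) + length(y) - 2
        if (mean(x) == mean(y))
            return(list(t = 0, df = df, p = 1))
        return(list(t = sign(mean(x) - mean(y)) * Inf, df = df, p = 0))
    }
    ht <- t.test(x, y, var.equal = pooled)
    list(t = unname(ht$statistic), df = unname(ht$parameter),
         p = ht$p.value)
}
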