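test_that("fold changes follow the comparative-CT arithmetic", {
    qp <- qpcrFixture()
    cal <- c("empty_vector", "permissive_33.5")
    fc <- ddctFoldChange(qp, calibrator = cal)
    # calibrator-cell samples: dCt equals the calibrator mean -> fold 1
    ev33 <- fc$group == "empty_vector" & fc$condition == "permissive_33.5"
    expect_equal(fc$fold_change[ev33], rep(1, 3), tolerance = 1e-12)
    # ddCt of -4 (dct 6 vs calibrator 10) -> 2^4 = 16
    ev39 <- fc$group == "empty_vector" &
        fc$condition == "differentiated_39.5"
    expect_equal(unique(fc$ddct[ev39]), -4)
    expect_equal(fc$fold_change[ev39], rep(16, 3))
    # ddCt of +1 halves expression
    qp2 <- qpcrFixture(dct = c(ev_perm = 10, cp_perm = 11,
                               ev_diff = 10, cp_diff = 10))
    fc2 <- ddctFoldChange(qp2, calibrator = cal)
    cp33 <- fc2$group == "crispr_pool" &
        fc2$condition == "permissive_33.5"
    expect_equal(fc2$fold_change[cp33], rep(0.5, 3))
})

test_that("calibrator closure holds under both schemes", {
    qp <- qpcrFixture()
    cal <- c("empty_vector", "permissive_33.5")
    fcG <- ddctFoldChange(qp, cal, scheme = "global_calibrator")
    evG <- fcG$group == "empty_vector" &
        fcG$condition == "permissive_33.5"
    expect_equal(mean(fcG$fold_change[evG]), 1, tolerance = 1e-12)
    fcC <- ddctFoldChange(qp, cal, scheme = "condition_matched")
    for (cond in unique(fcC$condition)) {
        sel <- fcC$group == "empty_vector" & fcC$condition == cond
        expect_equal(mean(fcC$fold_change[sel]), 1, tolerance = 1e-12)
    }
})

test_that("condition-matched normalisation equals global divided by the condition control", {
    # noisy fixture exercising the identity beyond trivial cases
    set.seed(41)
    qp <- qpcrFixture(dct = c(ev_perm = 10.3, cp_perm = 9.1,
                              ev_diff = 6.4, cp_diff = 8.2))
    qp$cq <- qp$cq + round(rnorm(nrow(qp), 0, 0.2), 3)
    cal <- c("empty_vector", "permissive_33.5")
    fcG <- ddctFoldChange(qp, cal, scheme = "global_calibrator")
    fcC <- ddctFoldChange(qp, cal, scheme = "condition_matched")
    for (i in seq_len(nrow(fcG))) {
        cond <- fcG$condition[i]
        ctrl <- fcG$group == "empty_vector" & fcG$condition == cond
        # geometric-mean control fold change of the sample's condition
        gm <- 2^mean(log2(fcG$fold_change[ctrl]))
        j <- fcC$sample_id == fcG$sample_id[i]
        expect_equal(fcC$fold_change[j], fcG$fold_change[i] / gm,
                     tolerance = 1e-9)
    }
})

test_that("qPCR input problems are reported per sample", {
    qp <- qpcrFixture()
    qp <- qp[!(qp$sample_id == qp$sample_id[1] &
                   qp$gene == "housekeeping"), ]
    expect_error(
        ddctFoldChange(qp, c("empty_vector", "permissive_33.5")),
        "missing housekeeping")
    expect_error(
        ddctFoldChange(qpcrFixture(), c("nonexistent", "permissive_33.5")),
        "empty calibrator")
})

test_that("percent change reports decreases on the percent scale", {
    tab <- data.frame(
        group = rep(c("empty_vector", "crispr_pool"), each = 3),
        condition = "differentiated_39.5",
        replicate = rep(1:3, 2), measure = "alp_stain",
        value = c(100, 100, 100, 39, 39, 39))
    pc <- percentChange(tab, "alp_stain",
                        treated = c("crispr_pool", "differentiated_39.5"),
                        control = c("empty_vector",
                                    "differentiated_39.5"))
    expect_equal(pc$percent_change, 61)
    # treated == control -> 0%
    tab0 <- tab
    tab0$value <- 50
    pc0 <- percentChange(tab0, "alp_stain",
                         treated = c("crispr_pool", "differentiated_39.5"),
                         control = c("empty_vector",
                                     "differentiated_39.5"))
    expect_equal(pc0$percent_change, 0)
})

test_that("normaliser-corrected band quantification matches hand computation", {
    tab <- rbind(
        data.frame(group = "crispr_pool", condition = "differentiated_39.5",
                   replicate = 1, measure = c("band_U", "tubulin"),
                   value = c(10, 2)),
        data.frame(group = "empty_vector",
                   condition = "differentiated_39.5",
                   replicate = 1, measure = c("band_U", "tubulin"),
                   value = c(20, 1)))
    tab <- rbind(tab, transform(tab, replicate = 2))
    pc <- percentChange(tab, "band_U",
                        treated = c("crispr_pool", "differentiated_39.5"),
                        control = c("empty_vector", "differentiated_39.5"),
                        normalizer = "tubulin")
    # 10/2 = 5 vs 20/1 = 20 -> 75% decrease
    expect_equal(pc$percent_change, 75)
})

test_that("percent change is scale invariant", {
    set.seed(42)
    tab <- data.frame(
        group = rep(c("empty_vector", "crispr_pool"), each = 4),
        condition = "differentiated_39.5",
        replicate = rep(1:4, 2), measure = "alp_stain",
        value = runif(8, 10, 100))
    args <- list(measure = "alp_stain",
                 treated = c("crispr_pool", "differentiated_39.5"),
                 control = c("empty_vector", "differentiated_39.5"))
    base <- do.call(percentChange, c(list(tab), args))$percent_change
    for (cc in c(0.001, 3, 1e6)) {
        scaled <- tab
        scaled$value <- scaled$value * cc
        expect_equal(do.call(percentChange,
                             c(list(scaled), args))$percent_change,
                     base, tolerance = 1e-12)
    }
    # zero control mean is undefined
    tab$value[tab$group == "empty_vector"] <- 0
    expect_error(do.call(percentChange, c(list(tab), args)), "undefined")
})

test_that("transduction efficiency is the mean of per-replicate ratios", {
    tab <- rbind(
        data.frame(group = "crispr_pool", condition = "permissive_33.5",
                   replicate = 1:3, measure = "cells_brightfield",
                   value = c(200, 100, 400)),
        data.frame(group = "crispr_pool", condition = "permissive_33.5",
                   replicate = 1:3, measure = "cells_mcherry",
                   value = c(174, 87, 348)))
    te <- transductionEfficiency(tab)
    expect_equal(te$efficiency, 0.87)
    # mean of ratios, not the pooled-count ratio
    tab2 <- tab
    tab2$value[tab2$measure == "cells_mcherry"] <- c(100, 90, 400)
    te2 <- transductionEfficiency(tab2)
    pooled <- sum(c(100, 90, 400)) / sum(c(200, 100, 400))
    expect_equal(te2$efficiency, mean(c(100 / 200, 90 / 100, 400 / 400)))
    expect_false(isTRUE(all.equal(te2$efficiency, pooled)))
    # marker count above total is allowed but flagged
    tab3 <- tab
    tab3$value[tab3$measure == "cells_mcherry"] <- c(210, 87, 348)
    expect_warning(transductionEfficiency(tab3), "exceeds")
    tab4 <- tab
    tab4$value[tab4$measure == "cells_brightfield"][1] <- 0
    expect_error(transductionEfficiency(tab4), "count of 0")
})

test_that("the Welch t test matches its closed form", {
    x <- c(27.5, 21.0, 19.0, 23.6, 17.0, 17.9, 16.9, 20.1, 21.9, 22.6,
           23.1, 19.6)
    y <- c(27.1, 22.0, 20.8, 23.4, 23.4, 23.5, 25.8, 22.0, 24.8, 20.2,
           21.9, 22.1)
    res <- twoSampleT(x, y)
    # closed-form Welch statistic and Welch-Satterthwaite df
    se2x <- var(x) / length(x)
    se2y <- var(y) / length(y)
    tstat <- (mean(x) - mean(y)) / sqrt(se2x + se2y)
    df <- (se2x + se2y)^2 /
        (se2x^2 / (length(x) - 1) + se2y^2 / (length(y) - 1))
    p <- 2 * pt(-abs(tstat), df)
    expect_equal(res$t, tstat, tolerance = 1e-6)
    expect_equal(res$df, df, tolerance = 1e-6)
    expect_equal(res$p, p, tolerance = 1e-6)
    # identical vectors: no evidence of difference
    same <- twoSampleT(c(1, 1, 1), c(1, 1, 1))
    expect_equal(same$t, 0)
    expect_equal(same$p, 1)
    # clear separation with tiny jitter
    sep <- twoSampleT(c(0, 0, 0) + c(0, 1e-6, -1e-6),
                      c(1, 1, 1) + c(1e-6, 0, -1e-6))
    expect_lt(sep$p, 0.01)
    expect_error(twoSampleT(1, c(1, 2)), "at least 2")
})

test_that("the bundled synthetic qPCR table reproduces the expected induction", {
    qp <- read.delim(system.file("extdata", "demo_qpcr.tsv",
                                 package = "ampliconDel"))
    cal <- c("empty_vector", "permissive_33.5")
    fcG <- ddctFoldChange(qp, cal, scheme = "global_calibrator")
    ev39 <- fcG$group == "empty_vector" &
        fcG$condition == "differentiated_39.5"
    # strong differentiation-induced increase in the control samples
    expect_gt(mean(fcG$fold_change[ev39]), 12)
    # condition-matched view: edited cells several-fold below control
    fcC <- ddctFoldChange(qp, cal, scheme = "condition_matched")
    cp39 <- fcC$group == "crispr_pool" &
        fcC$condition == "differentiated_39.5"
    expect_lt(mean(fcC$fold_change[cp39]), 1 / 3)
    expect_gt(mean(fcC$fold_change[cp39]), 1 / 7)
    # per-group Welch t test on dct values separates the 39.5 groups
    tt <- twoSampleT(fcC$dct[cp39],
                     fcC$dct[fcC$group == "empty_vector" &
                                 fcC$condition == "differentiated_39.5"])
    expect_lt(tt$p, 0.04)
})
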