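# classified alignment table builder for direct quantification tests
mkAln <- function(nSpliced, nWt, delStart = 120L, delEnd = 240L,
                  nUnmapped = 0L) {
    n <- nSpliced + nWt + nUnmapped
    data.frame(
        read_id = sprintf("r%04d", seq_len(n)),
        class = factor(c(rep("spliced", nSpliced), rep("wt_mapped", nWt),
                         rep("unmapped", nUnmapped)),
                       levels = c("wt_mapped", "spliced", "unmapped")),
        del_start = c(rep(delStart, nSpliced), rep(NA_integer_,
                                                   nWt + nUnmapped)),
        del_end = c(rep(delEnd, nSpliced), rep(NA_integer_,
                                               nWt + nUnmapped)),
        junction_size = c(rep(delEnd - delStart, nSpliced),
                          rep(0L, nWt + nUnmapped)))
}

test_that("breakpoints assign to pairs by the cut-site window", {
    ref <- demoReference()
    pairs <- demoPairs(ref)
    # exactly at the US-1/DS-1 cut sites
    a <- assignCalls(120L, 240L, pairs)
    expect_identical(a$assigned_pair, "US-1/DS-1")
    expect_identical(a$distance_us, 0L)
    expect_identical(a$distance_ds, 0L)
    # 61 bp off the only pair's upstream cut site -> unassigned
    one <- pairs["US-1/DS-1"]
    expect_identical(assignCalls(120L + 61L, 240L, one)$assigned_pair,
                     "unassigned")
    expect_identical(assignCalls(120L + 60L, 240L, one)$assigned_pair,
                     "US-1/DS-1")
    # shared US guide, end exactly between DS-1 (240) and DS-2 (300)
    two <- pairs[c("US-1/DS-1", "US-1/DS-2")]
    expect_identical(assignCalls(120L, 270L, two)$assigned_pair,
                     "ambiguous")
    expect_identical(assignCalls(120L, 269L, two)$assigned_pair,
                     "US-1/DS-1")
    # brute-force check over all nine pairs of the 3x3 design
    for (start in c(118L, 155L)) for (end in c(243L, 297L, 361L)) {
        du <- abs(start - vapply(pairs, function(p) p@usGuide@cutSite,
                                 integer(1)))
        dd <- abs(end - vapply(pairs, function(p) p@dsGuide@cutSite,
                               integer(1)))
        cand <- which(du <= 60L & dd <= 60L)
        want <- if (!length(cand)) "unassigned"
                else names(pairs)[cand[which.min((du + dd)[cand])]]
        expect_identical(assignCalls(start, end, pairs)$assigned_pair,
                         want)
    }
})

test_that("library quantification divides assigned reads by mapped reads", {
    pairs <- demoPairs()
    q <- quantifyLibrary(mkAln(60L, 40L), pairs, libraryId = "L1")
    eff <- efficiencies(q)
    expect_equal(unname(eff[["US-1/DS-1"]]), 0.6)
    expect_true(all(eff[setdiff(names(eff), "US-1/DS-1")] == 0))
    expect_identical(q@mappedReads, 100L)
    # no spliced reads: every efficiency 0
    q0 <- quantifyLibrary(mkAln(0L, 50L), pairs)
    expect_true(all(efficiencies(q0) == 0))
    expect_identical(q0@splicedReads, 0L)
    # only unmapped reads: empty library error
    expect_error(quantifyLibrary(mkAln(0L, 0L, nUnmapped = 10L), pairs),
                 "empty library")
})

test_that("simulated libraries recover configured fractions within binomial error", {
    ref <- demoReference()
    pairs <- recoveryPairs(ref)
    fr <- c(0.3, 0.2, 0.1)
    tc <- truthConfig(ref, pairs, pairFractions = fr, wtFraction = 0.4,
                      jitterSd = 5, nReads = 10000L, seed = 1234L)
    sim <- simulateLibrary(tc)
    aln <- classifyReads(alignReads(sim$reads, ref))
    q <- quantifyLibrary(aln, pairs, libraryId = "sim")
    eff <- efficiencies(q)
    truth <- truthEfficiencies(sim$truth, names(eff))
    for (p in names(eff)) {
        sigma <- sqrt(fr[[match(p, names(pairs))]] *
                          (1 - fr[[match(p, names(pairs))]]) / 10000)
        expect_lt(abs(eff[[p]] - truth[[p]]), 4 * sigma)
    }
})

test_that("count conservation holds at every stage", {
    ref <- demoReference()
    pairs <- recoveryPairs(ref)
    tc <- truthConfig(ref, pairs, pairFractions = c(0.25, 0.2, 0.15),
                      wtFraction = 0.3, nReads = 3000L, seed = 55L)
    sim <- simulateLibrary(tc)
    aln <- classifyReads(alignReads(sim$reads, ref))
    q <- quantifyLibrary(aln, pairs)
    expect_identical(q@totalReads, 3000L)
    expect_identical(q@totalReads,
                     q@mappedReads + sum(aln$class == "unmapped"))
    expect_identical(q@mappedReads, q@wtReads + q@splicedReads)
    expect_identical(q@splicedReads,
                     sum(q@perPair$count) + q@unassignedSpliced +
                         q@ambiguousSpliced)
    eff <- efficiencies(q)
    expect_true(all(eff >= 0 & eff <= 1))
    expect_lte(sum(eff), q@splicedReads / q@mappedReads)
})

test_that("a wild-type-only library yields zero efficiency everywhere", {
    ref <- demoReference()
    pairs <- recoveryPairs(ref)
    tc <- truthConfig(ref, pairs, pairFractions = c(0, 0, 0),
                      wtFraction = 1, nReads = 500L, seed = 66L)
    sim <- simulateLibrary(tc)
    q <- quantifyLibrary(classifyReads(alignReads(sim$reads, ref)), pairs)
    expect_true(all(efficiencies(q) == 0))
})

test_that("widening the assignment window never loses assigned reads", {
    ref <- demoReference()
    pairs <- recoveryPairs(ref)
    tc <- truthConfig(ref, pairs, pairFractions = c(0.3, 0.3, 0.3),
                      wtFraction = 0.1, jitterSd = 25,
                      nReads = 2000L, seed = 77L)
    sim <- simulateLibrary(tc)
    aln <- classifyReads(alignReads(sim$reads, ref))
    q60 <- quantifyLibrary(aln, pairs, window = 60L)
    q120 <- quantifyLibrary(aln, pairs, window = 120L)
    # widening admits new candidates, so reads may move between pairs via
    # the nearest-pair rule, but the assigned total can only grow and the
    # unassigned pool can only shrink
    expect_gte(sum(q120@perPair$count), sum(q60@perPair$count))
    expect_lte(q120@unassignedSpliced, q60@unassignedSpliced)
    expect_gt(q60@unassignedSpliced, 0L)   # jitter 25 leaves strays at 60
    # with a single candidate pair the per-pair count is monotone
    one <- pairs["US-1/DS-1"]
    calls <- deletionCalls(quantifyLibrary(aln, one, window = 60L))
    n60 <- sum(calls$assigned_pair == "US-1/DS-1")
    calls120 <- deletionCalls(quantifyLibrary(aln, one, window = 120L))
    expect_gte(sum(calls120$assigned_pair == "US-1/DS-1"), n60)
})

test_that("replicate aggregation averages per-pair efficiencies", {
    mkq <- function(id, eff, mapped = 1000L) {
        count <- as.integer(round(eff * mapped))
        new("LibraryQuant", libraryId = id, totalReads = mapped,
            mappedReads = mapped, wtReads = mapped - count,
            splicedReads = count, unassignedSpliced = 0L,
            ambiguousSpliced = 0L,
            perPair = data.frame(pair_id = "P1", count = count,
                                 efficiency = eff, ci_lo = NA_real_,
                                 ci_hi = NA_real_))
    }
    agg <- aggregateReplicates(list(mkq("a", 0.50), mkq("b", 0.60),
                                    mkq("c", 0.679)))
    expect_equal(agg$mean, 0.593)
    expect_equal(agg$sd, sd(c(0.50, 0.60, 0.679)))
    expect_identical(agg$n, 3L)
    expect_warning(one <- aggregateReplicates(list(mkq("a", 0.5))),
                   "single library")
    expect_equal(one$sd, 0)
    # a pair absent from one library counts as 0 there, with a warning
    qa <- mkq("a", 0.4)
    qb <- mkq("b", 0.2)
    qb@perPair$pair_id <- "P2"
    expect_warning(agg2 <- aggregateReplicates(list(qa, qb)), "absent")
    expect_equal(agg2$mean[agg2$pair_id == "P1"], 0.2)
    expect_equal(agg2$mean[agg2$pair_id == "P2"], 0.1)
})

test_that("deletion spectrum summarises breakpoints and dispersion", {
    calls <- data.frame(read_id = sprintf("r%d", 1:10),
                        del_start = rep(120L, 10), del_end = rep(240L, 10),
                        assigned_pair = rep("US-1/DS-1", 10))
    sp <- deletionSpectrum(calls)
    expect_identical(nrow(sp$spectrum), 1L)
    expect_identical(sp$spectrum$count, 10L)
    expect_identical(sp$spectrum$size, 120L)
    expect_equal(sp$dispersion$sd_start, 0)
    expect_equal(sp$dispersion$sd_end, 0)
})

test_that("breakpoint dispersion recovers the configured jitter", {
    ref <- demoReference()
    pair <- recoveryPairs(ref)["US-2/DS-2"]
    tc <- truthConfig(ref, pair, pairFractions = 1, wtFraction = 0,
                      jitterSd = 5, insertJunctionProb = 0,
                      substErrorRate = 0, nReads = 2000L, seed = 88L)
    sim <- simulateLibrary(tc)
    aln <- classifyReads(alignReads(sim$reads, ref))
    q <- quantifyLibrary(aln, pair)
    sp <- deletionSpectrum(deletionCalls(q))
    d <- sp$dispersion[sp$dispersion$pair_id == "US-2/DS-2", ]
    expect_gt(d$sd_start, 3.5)
    expect_lt(d$sd_start, 6.5)
    expect_gt(d$sd_end, 3.5)
    expect_lt(d$sd_end, 6.5)
    # spectrum sizes bracket the configured deletion within 4 sd per end
    expect_gte(min(sp$spectrum$size), 160 - 8 * 5)
    expect_lte(max(sp$spectrum$size), 160 + 8 * 5)
})
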