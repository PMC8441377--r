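# Shared fixtures built in code: the bundled synthetic demo design plus
# small ad hoc references.

demoReference <- function() {
    readAmpliconFasta(system.file("extdata", "demo_reference.fa",
                                  package = "ampliconDel"))
}

demoGuides <- function(reference = demoReference()) {
    readGuideTable(system.file("extdata", "demo_guides.tsv",
                               package = "ampliconDel"), reference)
}

demoPairs <- function(reference = demoReference()) {
    guidePairs(demoGuides(reference))
}

# the three well-separated pairs used for recovery experiments
recoveryPairs <- function(reference = demoReference()) {
    demoPairs(reference)[c("US-1/DS-1", "US-2/DS-2", "US-3/DS-3")]
}

randomSeq <- function(n, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# guide pair defined directly by cut-site coordinates
coordPair <- function(usCut, dsCut, id = "P") {
    GuidePair(Guide(paste0(id, "-US"), "upstream", cutSite = usCut),
              Guide(paste0(id, "-DS"), "downstream", cutSite = dsCut))
}

# noiseless qPCR fixture: dct values per (group, condition) cell,
# three samples per cell, identical within a cell
qpcrFixture <- function(dct = c(ev_perm = 10, cp_perm = 10,
                                ev_diff = 6, cp_diff = 8),
                        hk = 18) {
    cells <- data.frame(
        group = c("empty_vector", "crispr_pool",
                  "empty_vector", "crispr_pool"),
        condition = c("permissive_33.5", "permissive_33.5",
                      "differentiated_39.5", "differentiated_39.5"),
        dct = unname(dct), stringsAsFactors = FALSE)
    rows <- lapply(seq_len(nrow(cells)), function(i) {
        do.call(rbind, lapply(1:3, function(r) {
            data.frame(
                sample_id = sprintf("%s_%s_r%d", cells$group[i],
                                    cells$condition[i], r),
                group = cells$group[i], condition = cells$condition[i],
                replicate = r, gene = c("target", "housekeeping"),
                cq = c(hk + cells$dct[i], hk),
                stringsAsFactors = FALSE)
        }))
    })
    do.call(rbind, rows)
}
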