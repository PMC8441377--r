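# Independent alignment oracle: exhaustive enumeration over all diagonal
# pairs (equivalently, all read offsets x deletion (start, length)
# placements) of the best one- or two-segment ungapped local alignment with
# one free reference gap. Shares no code with the package's DP.
oracleScore <- function(read, ref) {
    NEG <- -1e9
    r <- utf8ToInt(toupper(read))
    f <- utf8ToInt(toupper(ref))
    nN <- utf8ToInt("N")
    n <- length(r)
    m <- length(f)
    ds <- seq(-(n - 1L), m - 1L)           # diagonal d = refpos - readpos
    E <- matrix(NEG, length(ds), n)        # best run ending at read pos c
    S <- matrix(NEG, length(ds), n)        # best run starting at read pos c
    best1 <- NEG
    for (k in seq_along(ds)) {
        d <- ds[k]
        i0 <- max(1L, 1L - d)
        i1 <- min(n, m - d)
        if (i0 > i1) next
        idx <- i0:i1
        v <- ifelse(r[idx] == f[idx + d] & r[idx] != nN, 1, -1)
        C <- cumsum(v)
        pre <- c(0, C[-length(C)])
        bestEnd <- C - cummin(pre)
        best1 <- max(best1, max(bestEnd))
        bestStart <- rev(cummax(rev(C))) - pre
        E[k, idx] <- bestEnd
        S[k, idx] <- bestStart
    }
    best2 <- NEG
    if (n >= 2L) {
        for (cpos in 1:(n - 1L)) {
            e <- E[, cpos]
            s <- S[, cpos + 1L]
            cm <- cummax(e)                 # over d1 <= current - 1
            best2 <- max(best2, max(cm[-length(cm)] + s[-1L]))
        }
    }
    max(best1, best2)
}

# Random instance with one planted deletion; returns the read, the
# reference and the true (start, length) of the planted excision.
plantDeletionInstance <- function(seed, nErrors = NULL) {
    set.seed(seed)
    m <- sample(150:300, 1)
    refc <- sample(c("A", "C", "G", "T"), m, replace = TRUE)
    ref <- paste(refc, collapse = "")
    L <- sample(3:min(150L, m - 80L), 1)
    s0 <- sample(30:(m - L - 30L), 1)      # 0-based deletion start
    del <- paste0(substr(ref, 1, s0), substr(ref, s0 + L + 1, m))
    dn <- nchar(del)
    rl <- sample(60:min(120L, dn), 1)
    # window containing the junction (junction at deleted-seq offset s0)
    lo <- max(1L, s0 - rl + 25L)
    hi <- max(lo, min(dn - rl + 1L, s0 - 24L))
    o <- sample(lo:hi, 1)
    read <- substr(del, o, o + rl - 1)
    if (is.null(nErrors)) nErrors <- sample(0:2, 1)
    if (nErrors > 0) {
        ch <- strsplit(read, "")[[1]]
        pos <- sample(seq_along(ch), nErrors)
        for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"),
                                               ch[p]), 1)
        read <- paste(ch, collapse = "")
    }
    list(read = read, ref = ref, del_start = s0, del_len = L)
}
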