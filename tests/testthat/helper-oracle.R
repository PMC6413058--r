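# Independent quadratic-DP local alignment oracle with greedy declumping,
# written separately from the package's scan path: full score matrix in R,
# best cell by max score (ties: smallest subject end, then smallest query
# end), traceback preferring diagonal over up over left, subject interval
# masked between passes.

oracleSw <- function(query, subject, match = 5L, mismatch = -4L, gap = 8L,
                     k = 1L) {
    q <- strsplit(toupper(query), "")[[1L]]
    s <- strsplit(toupper(subject), "")[[1L]]
    m <- length(q); n <- length(s)
    masked <- rep(FALSE, n)
    hits <- list()
    for (pass in seq_len(k)) {
        H <- matrix(0L, m + 1L, n + 1L)
        for (j in seq_len(n)) {
            if (masked[j]) next
            for (i in seq_len(m)) {
                sc <- if (q[i] %in% c("A", "C", "G", "T") && q[i] == s[j])
                    match else mismatch
                v <- max(0L, H[i, j] + sc, H[i, j + 1L] - gap,
                         H[i + 1L, j] - gap)
                H[i + 1L, j + 1L] <- v
            }
        }
        best <- max(H)
        if (best < 1L) break
        # smallest subject end, then smallest query end
        cand <- which(H == best, arr.ind = TRUE)
        cand <- cand[order(cand[, 2L], cand[, 1L]), , drop = FALSE]
        bi <- cand[1L, 1L] - 1L; bj <- cand[1L, 2L] - 1L
        i <- bi; j <- bj
        while (i > 0L && j > 0L && H[i + 1L, j + 1L] > 0L) {
            h <- H[i + 1L, j + 1L]
            sc <- if (q[i] %in% c("A", "C", "G", "T") && q[i] == s[j])
                match else mismatch
            if (H[i, j] + sc == h) { i <- i - 1L; j <- j - 1L }
            else if (H[i, j + 1L] - gap == h) i <- i - 1L
            else if (H[i + 1L, j] - gap == h) j <- j - 1L
            else break
        }
        hits[[pass]] <- c(score = best, s_start = j + 1L, s_end = bj,
                          q_start = i + 1L, q_end = bi)
        masked[(j + 1L):bj] <- TRUE
    }
    if (!length(hits))
        return(data.frame(score = integer(0), s_start = integer(0),
                          s_end = integer(0), q_start = integer(0),
                          q_end = integer(0)))
    as.data.frame(do.call(rbind, hits))
}

randomDna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = "")

revCompChr <- function(x) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1L]]), collapse = "")
}
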