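`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (regexes, difference arrays, IRanges) so they can
# arbitrate.

# exact one-sided hypergeometric tail by direct enumeration of the 2x2
# conditional distribution: P(X >= sK) with margins (m stops, n readthroughs,
# nK draws)
enumTailOracle <- function(sK, nK, sLi, nLi) {
  m <- sK + sLi
  n <- (nK - sK) + (nLi - sLi)
  ks <- max(0, nK - n):min(m, nK)
  probs <- choose(m, ks) * choose(n, nK - ks) / choose(m + n, nK)
  sum(probs[ks >= sK])
}

# brute-force interval-stabbing coverage: O(n * L)
coverageOracle <- function(stops, ends, L) {
  cov <- integer(L)
  for (i in seq_along(stops))
    for (p in stops[i]:(ends[i] - 1L)) cov[p + 1L] <- cov[p + 1L] + 1L
  cov
}

# union-find style merge of called positions (gap <= mergeGap joins)
mergeOracle <- function(txid, pos, mergeGap = 1L) {
  o <- order(txid, pos)
  txid <- txid[o]; pos <- pos[o]
  sites <- list()
  cs <- ce <- NULL; ct <- NULL
  for (i in seq_along(pos)) {
    if (is.null(cs) || txid[i] != ct || pos[i] - ce > mergeGap) {
      if (!is.null(cs))
        sites[[length(sites) + 1L]] <- data.frame(transcript_id = ct,
                                                  start = cs, end = ce + 1L)
      cs <- pos[i]; ct <- txid[i]
    }
    ce <- pos[i]
  }
  if (!is.null(cs))
    sites[[length(sites) + 1L]] <- data.frame(transcript_id = ct,
                                              start = cs, end = ce + 1L)
  do.call(rbind, sites)
}

# sweep-line interval union (0-based half-open; bookended spans merge)
sweepUnionOracle <- function(d) {
  res <- lapply(split(d, d$transcript_id), function(x) {
    x <- x[order(x$start), , drop = FALSE]
    out <- list(); cs <- x$start[1]; ce <- x$end[1]
    for (i in seq_len(nrow(x))[-1]) {
      if (x$start[i] <= ce) ce <- max(ce, x$end[i])
      else { out[[length(out) + 1L]] <- c(cs, ce); cs <- x$start[i]; ce <- x$end[i] }
    }
    out[[length(out) + 1L]] <- c(cs, ce)
    data.frame(transcript_id = x$transcript_id[1],
               start = vapply(out, `[`, 1, 1), end = vapply(out, `[`, 1, 2))
  })
  out <- do.call(rbind, res)
  out <- out[order(out$transcript_id, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# ---- brute-force quadruplex-class recognizer -------------------------------
# recursive segmentation over tract/loop splits; no regular expressions

isRun <- function(s, ch = "G", minLen = 1L)
  nchar(s) >= minLen && all(strsplit(s, "")[[1]] == ch)

isLoop <- function(s, lo, hi) nchar(s) >= lo && nchar(s) <= hi

# bulged tract: exactly two G-runs totalling >= 3 Gs, separated by 1-7 non-G
isBulgedTract <- function(s) {
  ch <- strsplit(s, "")[[1]]
  if (length(ch) < 4L || ch[1] != "G" || ch[length(ch)] != "G") return(FALSE)
  runs <- rle(ch == "G")
  if (length(runs$lengths) != 3L || !runs$values[1] || runs$values[2]) return(FALSE)
  gap <- strsplit(s, "")[[1]][(runs$lengths[1] + 1):(runs$lengths[1] + runs$lengths[2])]
  if (any(gap == "G") || runs$lengths[2] < 1L || runs$lengths[2] > 7L) return(FALSE)
  runs$lengths[1] + runs$lengths[3] >= 3L
}

# can `s` be split as t1 l1 t2 l2 ... tn with the given validators?
segMatch <- function(s, tractChecks, loopLo = 1L, loopHi = 7L,
                     loopLens = NULL) {
  n <- length(tractChecks)
  rec <- function(str, k) {
    if (k == n) return(tractChecks[[k]](str))
    L <- nchar(str)
    for (tlen in seq_len(L - 1L)) {
      if (!tractChecks[[k]](substr(str, 1L, tlen))) next
      lo <- if (is.null(loopLens)) loopLo else loopLens[[k]][1]
      hi <- if (is.null(loopLens)) loopHi else loopLens[[k]][2]
      for (llen in lo:hi) {
        if (tlen + llen >= L) break
        if (rec(substr(str, tlen + llen + 1L, L), k + 1L)) return(TRUE)
      }
    }
    FALSE
  }
  rec(s, 1L)
}

# does any motif of `cls` end exactly at 1-based position `anchor1`?
oracleMatchesAt <- function(seq, anchor1, cls, window = 50L) {
  lo <- max(1L, anchor1 - window + 1L)
  g3 <- function(s) isRun(s, "G", 3L)
  g2 <- function(s) isRun(s, "G", 2L)
  for (st in lo:anchor1) {
    s <- substr(seq, st, anchor1)
    ok <- switch(cls,
      canonical = segMatch(s, list(g3, g3, g3, g3)),
      long_loop = any(vapply(1:3, function(i) {
        ll <- list(c(1, 7), c(1, 7), c(1, 7)); ll[[i]] <- c(8, 12)
        segMatch(s, list(g3, g3, g3, g3), loopLens = ll)
      }, TRUE)),
      bulge = any(vapply(1:4, function(i) {
        tc <- list(g3, g3, g3, g3); tc[[i]] <- isBulgedTract
        segMatch(s, tc)
      }, TRUE)),
      two_quartet = segMatch(s, list(g2, g2, g2, g2)),
      g_triplex = segMatch(s, list(g3, g3, g3)))
    if (ok) return(TRUE)
  }
  FALSE
}

oracleClassify <- function(seq, anchor1, window = 50L) {
  for (cls in c("canonical", "long_loop", "bulge", "two_quartet", "g_triplex"))
    if (oracleMatchesAt(seq, anchor1, cls, window)) return(cls)
  "others"
}

# small shared simulation fixture (memoised per test file sourcing)
smallSimConfig <- function(seed = 101L, depth = 4000L, ...) {
  simConfig(seed = seed, nTranscripts = 8L, lengthRange = c(500L, 900L),
            motifPlan = c(canonical = 3L, two_quartet = 2L), depth = depth,
            ...)
}

nullSimConfig <- function(seed, depth = 4000L, ...) {
  simConfig(seed = seed, nTranscripts = 8L, lengthRange = c(500L, 900L),
            motifPlan = c(canonical = 0L), depth = depth, ...)
}

randomSeq <- function(n, probs = c(A = 0.2, C = 0.2, G = 0.4, T = 0.2))
  paste(sample(names(probs), n, replace = TRUE, prob = probs), collapse = "")
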