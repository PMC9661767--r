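siteDistance <- function(s1, e1, s2, e2) {
  # distance between nearest span boundaries of [s1,e1) and [s2,e2);
  # 0 when the spans overlap or are bookended
  pmax(0L, pmax(s2 - e1, s1 - e2))
}

#' Intersect two RTS site lists
#'
#' Two sites on the same transcript are considered overlapping when the
#' distance between their spans is strictly below `overlapDist` (overlapping
#' spans have distance 0). Agreed pairs are formed greedily nearest-first and
#' each site is used at most once, so the agreed-pair count is symmetric in
#' A and B.
#'
#' @param A,B Site tables (`transcript_id`, `start`, `end`).
#' @param cfg A [benchmarkConfig()].
#' @return List: `agreed` (data frame of paired indices `idxA`, `idxB` and
#'   `distance`), `onlyA`, `onlyB` (row indices of unmatched sites).
#' @examples
#' A <- data.frame(transcript_id = "t", start = 90L, end = 100L)
#' B <- data.frame(transcript_id = "t", start = 104L, end = 110L)
#' intersectSites(A, B)$agreed    # distance 4 < 5: agreed
#' @export
intersectSites <- function(A, B, cfg = benchmarkConfig()) {
  pairs <- list()
  if (nrow(A) && nrow(B)) {
    for (txid in intersect(unique(A$transcript_id), unique(B$transcript_id))) {
      ia <- which(A$transcript_id == txid)
      ib <- which(B$transcript_id == txid)
      d <- outer(seq_along(ia), seq_along(ib), function(i, j)
        siteDistance(A$start[ia[i]], A$end[ia[i]],
                     B$start[ib[j]], B$end[ib[j]]))
      cand <- which(d < cfg$overlapDist, arr.ind = TRUE)
      if (!nrow(cand)) next
      ord <- order(d[cand], cand[, 1], cand[, 2])
      usedA <- logical(length(ia)); usedB <- logical(length(ib))
      for (k in ord) {
        i <- cand[k, 1]; j <- cand[k, 2]
        if (usedA[i] || usedB[j]) next
        usedA[i] <- TRUE; usedB[j] <- TRUE
        pairs[[length(pairs) + 1L]] <-
          data.frame(idxA = ia[i], idxB = ib[j], distance = d[i, j])
      }
    }
  }
  agreed <- if (length(pairs)) do.call(rbind, pairs)
  else data.frame(idxA = integer(), idxB = integer(), distance = integer())
  list(agreed = agreed,
       onlyA = setdiff(seq_len(nrow(A)), agreed$idxA),
       onlyB = setdiff(seq_len(nrow(B)), agreed$idxB))
}

#' Consensus of site lists across replicates or libraries
#'
#' A site of the first (basis) list is kept when every other list contains an
#' agreeing site under [intersectSites()]; the first list anchors the
#' comparison, mirroring consensus building against a reference library.
#'
#' @param siteLists Non-empty list of site tables; the first is the basis.
#' @param cfg A [benchmarkConfig()].
#' @return The subset of the basis list present in all lists.
#' @export
consensusSites <- function(siteLists, cfg = benchmarkConfig()) {
  stopIfNot(length(siteLists) >= 1L, "at least one site list required")
  basis <- siteLists[[1]]
  keep <- seq_len(nrow(basis))
  for (other in siteLists[-1]) {
    if (!length(keep)) break
    ov <- intersectSites(basis[keep, , drop = FALSE], other, cfg)
    keep <- keep[sort(ov$agreed$idxA)]
  }
  out <- basis[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Union of site lists by interval merge
#'
#' Concatenates the lists and merges overlapping or bookended spans on the
#' same transcript (all sites are plus-strand in transcript coordinates),
#' the interval-merge semantics of standard BED tooling.
#'
#' @param siteLists List of site tables.
#' @param cfg A [benchmarkConfig()] (unused; kept for interface symmetry).
#' @return Merged site table `transcript_id`, `start`, `end`.
#' @export
unionSites <- function(siteLists, cfg = benchmarkConfig()) {
  all <- do.call(rbind, lapply(siteLists, function(s)
    s[, c("transcript_id", "start", "end")]))
  if (is.null(all) || nrow(all) == 0L)
    return(data.frame(transcript_id = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  res <- lapply(split(all, all$transcript_id), function(d) {
    r <- IRanges::reduce(IRanges::IRanges(start = d$start + 1L, end = d$end))
    data.frame(transcript_id = d$transcript_id[1],
               start = IRanges::start(r) - 1L, end = IRanges::end(r),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out <- out[order(out$transcript_id, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Coverage regression between matched sites of two libraries
#'
#' Ordinary least squares of `log10(covB)` on `log10(covA)` over agreed site
#' pairs; read coverages span orders of magnitude, so the log scale is the
#' interpretable one. A slope near 1 with small intercept indicates
#' equivalent coverage; intercept `-log10(2)` corresponds to a uniform
#' two-fold coverage loss.
#'
#' @param covA,covB Positive coverages of matched sites (equal length >= 3).
#' @return List `slope`, `intercept`, `r` (Pearson correlation in log
#'   space), `n`.
#' @export
coverageRegression <- function(covA, covB) {
  stopIfNot(length(covA) == length(covB), "pair vectors must align")
  stopIfNot(length(covA) >= 3L, "need at least 3 pairs")
  stopIfNot(all(covA > 0) && all(covB > 0), "coverages must be positive")
  x <- log10(covA); y <- log10(covB)
  if (sd(x) == 0) stop("degenerate regression: zero variance in covA")
  fit <- lm(y ~ x)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r = if (sd(y) == 0) 0 else cor(x, y), n = length(x))
}

#' Nucleotide distributions of read 5' ends and stalled positions
#'
#' Three views of 5'-nucleotide composition used to quantify protocol bias:
#' (i) `reads5p` — transcript base at the 5' end (stop position) of all
#' deduplicated template-strand reads; (ii) `rtsReads5p` — the same over
#' RTS-supporting K+ reads only (reads whose stop lies on a called
#' position); (iii) `positions` — called positions split into G versus
#' non-G, with the A/C/T shares within non-G.
#'
#' @param reads Deduplicated read table.
#' @param tx A [Transcriptome-class] or named character sequences.
#' @param calledPositions Optional [callStalledPositions()] output (rows with
#'   `called == TRUE` are used) enabling views (ii) and (iii).
#' @return List of named frequency vectors: `reads5p` (A/C/G/T, sums to 1),
#'   and when positions are supplied `rtsReads5p`, `positionsG` (G vs non_G)
#'   and `positionsNonG` (A/C/T shares).
#' @export
ntDistributions <- function(reads, tx, calledPositions = NULL) {
  seqs <- txSequences(tx)
  baseAt <- function(txid, pos)
    substr(unlist(seqs[txid]), pos + 1L, pos + 1L)
  freqs <- function(b, levels) {
    tb <- table(factor(b, levels = levels))
    n <- sum(tb)
    setNames(if (n > 0) as.numeric(tb) / n else rep(0, length(levels)),
             levels)
  }
  b5 <- baseAt(reads$transcript_id, reads$stop_pos)
  out <- list(reads5p = freqs(b5, c("A", "C", "G", "T")))
  if (!is.null(calledPositions)) {
    cp <- calledPositions
    if ("called" %in% names(cp)) cp <- cp[cp$called, , drop = FALSE]
    key <- paste(cp$transcript_id, cp$pos)
    sup <- reads[paste(reads$transcript_id, reads$stop_pos) %in% key, ,
                 drop = FALSE]
    out$rtsReads5p <- freqs(baseAt(sup$transcript_id, sup$stop_pos),
                            c("A", "C", "G", "T"))
    pb <- baseAt(cp$transcript_id, cp$pos)
    out$positionsG <- freqs(ifelse(pb == "G", "G", "non_G"), c("G", "non_G"))
    out$positionsNonG <- freqs(pb[pb != "G"], c("A", "C", "T"))
  }
  out
}

#' Alexander-Govern comparison of group means
#'
#' The Alexander-Govern test compares the means of independent groups
#' without assuming equal variances: each group mean is standardised by its
#' own standard error, the t-like statistics are transformed to approximate
#' normal scores by the Hill normalising expansion, and the summed squared
#' scores follow a chi-squared distribution with k-1 degrees of freedom
#' under the null. Used here to compare per-replicate 5'-A fractions between
#' protocols or libraries.
#'
#' @param ... Two or more numeric vectors (>= 2 values each), or a single
#'   list of them.
#' @return List `statistic`, `p.value`, `df`.
#' @examples
#' alexanderGovern(c(0.65, 0.66), c(0.35, 0.36))
#' @export
alexanderGovern <- function(...) {
  groups <- list(...)
  if (length(groups) == 1L && is.list(groups[[1]])) groups <- groups[[1]]
  stopIfNot(length(groups) >= 2L, "need at least two groups")
  n <- vapply(groups, length, 1L)
  stopIfNot(all(n >= 2L), "each group needs at least 2 values")
  m <- vapply(groups, mean, 1)
  se <- vapply(groups, function(g) sd(g) / sqrt(length(g)), 1)
  if (any(se == 0)) stop("zero within-group variance")
  w <- (1 / se^2) / sum(1 / se^2)
  grand <- sum(w * m)
  t <- (m - grand) / se
  nu <- n - 1
  a <- nu - 0.5
  b <- 48 * a^2
  cc <- sqrt(a * log(1 + t^2 / nu))
  z <- cc + (cc^3 + 3 * cc) / b -
    (4 * cc^7 + 33 * cc^5 + 240 * cc^3 + 855 * cc) /
    (10 * b^2 + 8 * b * cc^4 + 1000 * b)
  A <- sum(z^2)
  list(statistic = A, p.value = pchisq(A, df = length(groups) - 1,
                                       lower.tail = FALSE),
       df = length(groups) - 1)
}

#' Quantify transcript and gene abundances in TPM
#'
#' `TPM_t = (c_t / l_t) / sum_j(c_j / l_j) * 1e6`; transcript TPMs of a gene
#' sum to the gene abundance. All-zero counts yield all-zero TPM.
#'
#' @param counts Named (or positionally matched) read counts per transcript.
#' @param lengths Positive transcript lengths (nt).
#' @param tx2gene Optional named character map transcript -> gene.
#' @return List: `transcript` (named numeric TPM), `gene` (named numeric,
#'   present when `tx2gene` given).
#' @examples
#' tpmQuantify(c(a = 10, b = 10), c(a = 1000, b = 2000))$transcript
#' @export
tpmQuantify <- function(counts, lengths, tx2gene = NULL) {
  stopIfNot(all(lengths > 0), "lengths must be positive")
  stopIfNot(length(counts) == length(lengths), "counts/lengths must align")
  rate <- counts / lengths
  tot <- sum(rate)
  tpm <- if (tot == 0) rate * 0 else rate / tot * 1e6
  if (!is.null(names(counts))) names(tpm) <- names(counts)
  out <- list(transcript = tpm)
  if (!is.null(tx2gene)) {
    g <- tx2gene[names(tpm)]
    out$gene <- tapply(tpm, g, sum)
    out$gene <- setNames(as.numeric(out$gene), names(out$gene))
  }
  out
}

#' Minimum RNA input recommended for a target abundance
#'
#' Looks up parent-gene abundances in the input guideline table
#' ([guidelineTable()]): genes below 4 TPM are not recommended targets;
#' 4-8 TPM requires at least 100 ng post-enrichment RNA, 8-16 TPM at least
#' 30 ng, and >= 16 TPM at least 10 ng.
#'
#' @param geneTpm Non-negative numeric vector of gene abundances (TPM).
#' @return Data frame `tpm`, `min_input_ng` (numeric, `NA` when not
#'   recommended), `recommendation` (character).
#' @examples
#' recommendInput(c(2, 5, 10, 20))
#' @export
recommendInput <- function(geneTpm) {
  stopIfNot(all(geneTpm >= 0), "TPM must be non-negative")
  gt <- guidelineTable()
  idx <- findInterval(geneTpm, gt$tpm_lo)
  data.frame(tpm = geneTpm, min_input_ng = gt$min_input_ng[idx],
             recommendation = gt$recommendation[idx],
             stringsAsFactors = FALSE)
}

#' Join RTS-site coverage with parent-gene abundance
#'
#' Per-site pairs of local read coverage and parent-gene TPM, the
#' relationship underlying the input/depth guidelines: sites on low-TPM
#' genes sit at low coverage and fall below the ~16x detection limit first
#' as input is reduced.
#'
#' @param sites Site table with `mean_cov`.
#' @param geneTpm Named numeric gene abundances.
#' @param tx2gene Named character transcript -> gene map.
#' @return Data frame `transcript_id`, `start`, `end`, `mean_cov`, `gene`,
#'   `gene_tpm`, `mapped`; unmapped sites are flagged and excluded from the
#'   `summary` attribute (median coverage and TPM of mapped sites).
#' @export
coverageVsTpm <- function(sites, geneTpm, tx2gene) {
  g <- tx2gene[sites$transcript_id]
  tpm <- geneTpm[g]
  out <- data.frame(transcript_id = sites$transcript_id,
                    start = sites$start, end = sites$end,
                    mean_cov = sites$mean_cov,
                    gene = unname(g), gene_tpm = unname(tpm),
                    mapped = !is.na(g) & !is.na(tpm),
                    stringsAsFactors = FALSE)
  mapped <- out[out$mapped, , drop = FALSE]
  attr(out, "summary") <- c(median_cov = stats::median(mapped$mean_cov),
                            median_tpm = stats::median(mapped$gene_tpm))
  out
}
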