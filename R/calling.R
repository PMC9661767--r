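#' StopProfile: per-position RT-stop counts and coverage for K+ and Li+
#'
#' For every transcript position i (0-based), the number of deduplicated
#' template-strand reads whose 5' base lies at i (`stops`) and the number of
#' reads whose span `[stop_pos, end_pos)` contains i (`cov`), separately for
#' the K+ and Li+ conditions. Stops never exceed coverage.
#'
#' @slot transcripts Character vector of transcript ids.
#' @slot lengths Named integer transcript lengths.
#' @slot stopsK,stopsLi,covK,covLi Named lists of integer vectors, one per
#'   transcript, each of the transcript length.
#' @export
setClass("StopProfile",
  representation(transcripts = "character", lengths = "integer",
                 stopsK = "list", stopsLi = "list",
                 covK = "list", covLi = "list"))

setValidity("StopProfile", function(object) {
  msgs <- character()
  for (id in object@transcripts) {
    L <- object@lengths[[id]]
    for (sl in c("stopsK", "stopsLi", "covK", "covLi"))
      if (length(slot(object, sl)[[id]]) != L)
        msgs <- c(msgs, paste0(sl, " length mismatch for ", id))
    if (any(object@stopsK[[id]] > object@covK[[id]]) ||
        any(object@stopsLi[[id]] > object@covLi[[id]]))
      msgs <- c(msgs, paste0("stops exceed coverage on ", id))
  }
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "StopProfile", function(object) {
  cat(sprintf("StopProfile: %d transcripts, %d positions, %d K+ / %d Li+ stops\n",
              length(object@transcripts), sum(object@lengths),
              sum(vapply(object@stopsK, sum, 0)),
              sum(vapply(object@stopsLi, sum, 0))))
})

#' @describeIn StopProfile Per-transcript arrays for one condition.
#' @param x A `StopProfile`.
#' @param transcript Transcript id.
#' @param condition `"K"` or `"Li"`.
#' @export
profileArrays <- function(x, transcript, condition = c("K", "Li")) {
  condition <- match.arg(condition)
  if (condition == "K")
    list(stops = x@stopsK[[transcript]], cov = x@covK[[transcript]])
  else
    list(stops = x@stopsLi[[transcript]], cov = x@covLi[[transcript]])
}

# stop counts and interval-stabbing coverage for one condition on one
# transcript; coverage by difference array, O(n + L)
conditionArrays <- function(reads, L) {
  stops <- tabulate(reads$stop_pos + 1L, nbins = L)
  d <- integer(L + 1L)
  if (nrow(reads)) {
    inc <- tabulate(reads$stop_pos + 1L, nbins = L + 1L)
    dec <- tabulate(reads$end_pos + 1L, nbins = L + 1L)
    d <- inc - dec
  }
  cov <- cumsum(d[seq_len(L)])
  list(stops = as.integer(stops), cov = as.integer(cov))
}

#' Build K+/Li+ stop profiles from deduplicated reads
#'
#' Template-strand reads only: the 5'-most base of each read (in RNA
#' direction) is the position where reverse transcription stopped.
#'
#' @param readsK,readsLi Deduplicated usable read tables for the K+ and Li+
#'   libraries of one replicate.
#' @param tx A [Transcriptome-class] (or named lengths vector) defining
#'   transcripts; reads on unknown transcripts are an error.
#' @return A [StopProfile-class].
#' @export
buildStopProfile <- function(readsK, readsLi, tx) {
  lens <- txLengths(tx)
  for (r in list(readsK, readsLi)) {
    bad <- setdiff(unique(r$transcript_id), names(lens))
    stopIfNot(length(bad) == 0L,
              paste0("reads on unknown transcript(s): ",
                     paste(bad, collapse = ", ")))
    stopIfNot(all(r$strand == "+"), "template-strand reads required")
    stopIfNot(all(r$stop_pos < r$end_pos), "stop_pos must precede end_pos")
  }
  ids <- names(lens)
  byK <- split(readsK, factor(readsK$transcript_id, levels = ids))
  byLi <- split(readsLi, factor(readsLi$transcript_id, levels = ids))
  sK <- cK <- sLi <- cLi <- setNames(vector("list", length(ids)), ids)
  for (id in ids) {
    aK <- conditionArrays(byK[[id]], lens[[id]])
    aLi <- conditionArrays(byLi[[id]], lens[[id]])
    sK[[id]] <- aK$stops; cK[[id]] <- aK$cov
    sLi[[id]] <- aLi$stops; cLi[[id]] <- aLi$cov
  }
  new("StopProfile", transcripts = ids, lengths = lens,
      stopsK = sK, stopsLi = sLi, covK = cK, covLi = cLi)
}

#' One-sided exact test for excess K+ stalling at a position
#'
#' Exact conditional test on the 2x2 table of stops versus read-throughs,
#' `[sK, nK - sK; sLi, nLi - sLi]`, against the one-sided alternative that
#' the K+ stop rate exceeds the Li+ stop rate. The p-value is the
#' hypergeometric upper tail with all margins fixed (identical to the
#' one-sided Fisher exact test). Vectorised over positions.
#'
#' @param sK,nK Stops and coverage in K+ (`sK <= nK`).
#' @param sLi,nLi Stops and coverage in Li+.
#' @return p-value(s) in (0, 1].
#' @examples
#' testPosition(10, 100, 0, 100)
#' @export
testPosition <- function(sK, nK, sLi, nLi) {
  stopIfNot(all(nK > 0) && all(nLi > 0),
            "position not testable: zero coverage in a condition")
  stopIfNot(all(sK <= nK) && all(sLi <= nLi), "stops must not exceed coverage")
  phyper(sK - 1, sK + sLi, (nK - sK) + (nLi - sLi), nK, lower.tail = FALSE)
}

#' Call RT-stalled positions from a stop profile
#'
#' Tests every position with K+ coverage at least `minCov` (and non-zero Li+
#' coverage; zero-coverage positions are not testable and are flagged),
#' adjusts p-values by Benjamini-Hochberg across all tested positions of the
#' run, and calls a position stalled when the adjusted p-value is at most
#' `alpha` and the empirical K+ stop rate exceeds the Li+ rate.
#'
#' @param profile A [StopProfile-class].
#' @param cfg A [callerConfig()].
#' @return Data frame of tested positions: `transcript_id`, `pos` (0-based),
#'   `sK`, `nK`, `sLi`, `nLi`, `p`, `padj`, `called`; attribute `untestable`
#'   counts positions that passed the coverage gate but had zero Li+
#'   coverage.
#' @export
callStalledPositions <- function(profile, cfg = callerConfig()) {
  stopifnot(is(profile, "StopProfile"))
  rows <- lapply(profile@transcripts, function(id) {
    cK <- profile@covK[[id]]
    gate <- which(cK >= cfg$minCov)
    if (!length(gate)) return(NULL)
    data.frame(transcript_id = id, pos = gate - 1L,
               sK = profile@stopsK[[id]][gate], nK = cK[gate],
               sLi = profile@stopsLi[[id]][gate],
               nLi = profile@covLi[[id]][gate], stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab) || nrow(tab) == 0L) {
    out <- data.frame(transcript_id = character(), pos = integer(),
                      sK = integer(), nK = integer(), sLi = integer(),
                      nLi = integer(), p = numeric(), padj = numeric(),
                      called = logical(), stringsAsFactors = FALSE)
    attr(out, "untestable") <- 0L
    return(out)
  }
  testable <- tab$nLi > 0L
  untestable <- sum(!testable)
  tab <- tab[testable, , drop = FALSE]
  testFun <- if (is.function(cfg$test)) cfg$test
  else if (identical(cfg$test, "fisher")) testPosition
  else stop("unknown caller test: ", cfg$test)
  tab$p <- if (nrow(tab)) testFun(tab$sK, tab$nK, tab$sLi, tab$nLi) else numeric()
  tab$padj <- p.adjust(tab$p, method = "BH")
  tab$called <- tab$padj <= cfg$alpha & (tab$sK / tab$nK) > (tab$sLi / tab$nLi)
  rownames(tab) <- NULL
  attr(tab, "untestable") <- untestable
  tab
}

#' Merge adjacent stalled positions into RTS sites
#'
#' Called positions on one transcript whose coordinate difference is at most
#' `mergeGap` join one RTS site spanning them; each singleton stalled
#' position is one 1-nt RTS site.
#'
#' @param positions Output of [callStalledPositions()] (or any frame with
#'   `transcript_id`, `pos`, and optionally `sK`, `nK`, `padj`); only rows
#'   with `called == TRUE` are used if a `called` column is present.
#' @param cfg A [callerConfig()].
#' @return Site table: `transcript_id`, `start`, `end` (0-based half-open),
#'   `n_positions`, `support_K` (RTS-supporting reads, summed stops),
#'   `mean_cov` (mean K+ coverage over the span), `score`
#'   (max -log10 adjusted p over the site).
#' @examples
#' pos <- data.frame(transcript_id = "t", pos = c(100L, 101L, 105L))
#' mergePositions(pos)
#' @export
mergePositions <- function(positions, cfg = callerConfig()) {
  p <- positions
  if ("called" %in% names(p)) p <- p[p$called, , drop = FALSE]
  if (nrow(p) == 0L)
    return(data.frame(transcript_id = character(), start = integer(),
                      end = integer(), n_positions = integer(),
                      support_K = integer(), mean_cov = numeric(),
                      score = numeric(), stringsAsFactors = FALSE))
  p <- p[order(p$transcript_id, p$pos), , drop = FALSE]
  newSite <- c(TRUE, diff(p$pos) > cfg$mergeGap |
                 p$transcript_id[-1] != p$transcript_id[-nrow(p)])
  grp <- cumsum(newSite)
  res <- lapply(split(p, grp), function(d) {
    data.frame(transcript_id = d$transcript_id[1],
               start = min(d$pos), end = max(d$pos) + 1L,
               n_positions = nrow(d),
               support_K = if ("sK" %in% names(d)) sum(d$sK) else NA_integer_,
               mean_cov = if ("nK" %in% names(d)) mean(d$nK) else NA_real_,
               score = if ("padj" %in% names(d))
                 max(-log10(pmax(d$padj, 1e-300))) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out <- out[order(out$transcript_id, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Call RTS sites for one replicate pair of libraries
#'
#' Convenience wrapper: dedup both conditions, build the stop profile, call
#' stalled positions and merge them into sites.
#'
#' @param readsK,readsLi Raw aligned-read tables (K+ and Li+).
#' @param tx A [Transcriptome-class].
#' @param cfg A [callerConfig()].
#' @return List: `sites`, `positions`, `profile`.
#' @export
callSites <- function(readsK, readsLi, tx, cfg = callerConfig()) {
  dK <- dedup(readsK)$reads
  dLi <- dedup(readsLi)$reads
  profile <- buildStopProfile(dK, dLi, tx)
  positions <- callStalledPositions(profile, cfg)
  list(sites = mergePositions(positions, cfg), positions = positions,
       profile = profile)
}

#' Write RTS sites as BED6
#'
#' Score column is the site `-log10` adjusted p-value; name is the class if
#' present, else `RTS`.
#'
#' @param sites Site table ([mergePositions()] / [classifySites()] output).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeSitesBed <- function(sites, path) {
  nm <- if ("class" %in% names(sites)) sites$class else rep("RTS", nrow(sites))
  bed <- data.frame(sites$transcript_id, sites$start, sites$end, nm,
                    round(sites$score, 3), "+")
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
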