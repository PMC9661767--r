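#' Structural taxonomy of putative quadruplex sequences
#'
#' Builds the ordered class taxonomy used to assign an rG4 structural class
#' to the sequence immediately upstream of an RTS site. Classes are tried in
#' priority order and the first match wins:
#'
#' * `canonical` — four G-tracts of >= `gRunMin` Gs, loops of
#'   `loopMin`–`loopMax` nt.
#' * `long_loop` — as canonical but exactly one loop of
#'   `longLoopMin`–`longLoopMax` nt.
#' * `bulge` — four tracts totalling >= `gRunMin` Gs each, exactly one tract
#'   interrupted by a `bulgeMin`–`bulgeMax` nt non-G bulge.
#' * `two_quartet` — four G-tracts of >= `twoQuartetRun` Gs, loops 1–7.
#' * `g_triplex` — three G-tracts of >= `gRunMin` Gs, loops 1–7.
#' * `others` — none of the above; treated as a false-positive detection
#'   since the sequence fails the minimum requirements for a quadruplex or
#'   triplex.
#'
#' The reporting group map (canonical -> "canonical"; long_loop, bulge ->
#' "non-canonical"; two_quartet, g_triplex -> "variant"; others -> "Others")
#' is a configurable convention, not a fixed fact of the taxonomy.
#'
#' @param gRunMin Minimum G-run length for three-quartet classes (default 3).
#' @param twoQuartetRun G-run length for the two-quartet class (default 2).
#' @param loopMin,loopMax Ordinary loop length bounds in nt (default 1, 7).
#' @param longLoopMin,longLoopMax Long-loop bounds (default 8, 12).
#' @param bulgeMin,bulgeMax Bulge size bounds in nt (default 1, 7).
#' @param window Upstream search window W in nt (default 50).
#' @param anchorOffsets Offsets of the motif 3'-end G relative to the site
#'   start, tried in order (default `c(0, 1)`, the position-0/+1 convention).
#' @param grouping Named character map class -> reporting group.
#' @return A list of class `"ClassTaxonomy"` with the parameters, the
#'   compiled regular expressions (`patterns`, in priority order) and the
#'   grouping map.
#' @examples
#' tax <- classTaxonomy()
#' names(tax$patterns)
#' @export
classTaxonomy <- function(gRunMin = 3L, twoQuartetRun = 2L,
                          loopMin = 1L, loopMax = 7L,
                          longLoopMin = 8L, longLoopMax = 12L,
                          bulgeMin = 1L, bulgeMax = 7L,
                          window = 50L, anchorOffsets = c(0L, 1L),
                          grouping = c(canonical = "canonical",
                                       long_loop = "non-canonical",
                                       bulge = "non-canonical",
                                       two_quartet = "variant",
                                       g_triplex = "variant",
                                       others = "Others")) {
  g <- gRunMin
  loop <- sprintf("[ACGT]{%d,%d}", loopMin, loopMax)
  longLoop <- sprintf("[ACGT]{%d,%d}", longLoopMin, longLoopMax)
  tract <- sprintf("G{%d,}", g)
  # bulged tract: two G-runs totalling >= gRunMin separated by a non-G bulge
  bulged <- sprintf("(?:G{2,}[ACT]{%d,%d}G+|G+[ACT]{%d,%d}G{2,})",
                    bulgeMin, bulgeMax, bulgeMin, bulgeMax)
  canonical <- sprintf("%s(?:%s%s){3}", tract, loop, tract)
  # exactly one of the three loops is long
  longLoopPat <- paste(vapply(1:3, function(i) {
    loops <- rep(loop, 3); loops[i] <- longLoop
    sprintf("%s%s%s%s%s%s%s", tract, loops[1], tract, loops[2], tract,
            loops[3], tract)
  }, ""), collapse = "|")
  bulgePat <- paste(vapply(1:4, function(i) {
    tr <- rep(tract, 4); tr[i] <- bulged
    sprintf("%s%s%s%s%s%s%s", tr[1], loop, tr[2], loop, tr[3], loop, tr[4])
  }, ""), collapse = "|")
  twoQ <- sprintf("G{%d,}(?:%sG{%d,}){3}", twoQuartetRun, loop, twoQuartetRun)
  triplex <- sprintf("%s(?:%s%s){2}", tract, loop, tract)
  structure(list(
    gRunMin = g, twoQuartetRun = twoQuartetRun, loopMin = loopMin,
    loopMax = loopMax, longLoopMin = longLoopMin, longLoopMax = longLoopMax,
    bulgeMin = bulgeMin, bulgeMax = bulgeMax, window = as.integer(window),
    anchorOffsets = as.integer(anchorOffsets), grouping = grouping,
    patterns = c(canonical = canonical, long_loop = longLoopPat,
                 bulge = bulgePat, two_quartet = twoQ, g_triplex = triplex)),
    class = "ClassTaxonomy")
}

# longest match of `pattern` ending exactly at the end of `window` sequence;
# returns match length or 0. Anchoring at $ makes the regex engine consider
# every feasible start.
matchLenAtEnd <- function(window, pattern) {
  m <- regexpr(paste0("(?:", pattern, ")$"), window, perl = TRUE)
  if (m[1] == -1L) 0L else attr(m, "match.length")
}

#' Classify one RTS site from its upstream sequence
#'
#' For each anchor offset (position 0, then +1) the window of `window` nt
#' ending at the putative 3'-end G of the motif is searched for the
#' highest-priority class whose pattern ends exactly at the anchor. The first
#' success is returned; if no pattern matches at any offset the class is
#' `"others"`.
#'
#' @param siteStart 0-based coordinate of the first stalled position of the
#'   site on the transcript.
#' @param sequence Transcript sequence (character).
#' @param taxonomy A [classTaxonomy()] object.
#' @return A list (`MotifCall`): `class`, `group`, `motifStart`, `motifEnd`
#'   (0-based half-open), `motifSeq`, `anchorOffset`, and `flank3` — the
#'   nucleotide at position +1 of the motif, or `NA` at the transcript end.
#' @examples
#' tx <- paste0(strrep("A", 30), "GGGAGGGAGGGAGGG", "T")
#' classifySite(45, tx, classTaxonomy())$class   # canonical
#' @export
classifySite <- function(siteStart, sequence, taxonomy = classTaxonomy()) {
  L <- nchar(sequence)
  noCall <- list(class = "others", group = unname(taxonomy$grouping["others"]),
                 motifStart = NA_integer_, motifEnd = NA_integer_,
                 motifSeq = NA_character_, anchorOffset = NA_integer_,
                 flank3 = NA_character_)
  for (off in taxonomy$anchorOffsets) {
    g1 <- siteStart - off + 1L            # 1-based anchor (motif 3'-most G)
    if (g1 < 1L || g1 > L) next
    if (substr(sequence, g1, g1) != "G") next
    win <- substr(sequence, max(1L, g1 - taxonomy$window + 1L), g1)
    if (nchar(win) == 0L) next
    for (cls in names(taxonomy$patterns)) {
      len <- matchLenAtEnd(win, taxonomy$patterns[[cls]])
      if (len > 0L) {
        flank <- if (g1 < L) substr(sequence, g1 + 1L, g1 + 1L) else NA_character_
        return(list(class = cls, group = unname(taxonomy$grouping[cls]),
                    motifStart = g1 - len, motifEnd = g1,
                    motifSeq = substr(sequence, g1 - len + 1L, g1),
                    anchorOffset = as.integer(off), flank3 = flank))
      }
    }
  }
  noCall
}

#' Classify a table of RTS sites against a transcriptome
#'
#' @param sites Site table as returned by [mergePositions()] (columns
#'   `transcript_id`, `start`, `end`).
#' @param tx A [Transcriptome-class] or named character vector of sequences.
#' @param taxonomy A [classTaxonomy()].
#' @return `sites` with columns `class`, `group`, `motif_start`, `motif_end`,
#'   `motif_seq`, `flank3` appended.
#' @export
classifySites <- function(sites, tx, taxonomy = classTaxonomy()) {
  seqs <- txSequences(tx)
  calls <- lapply(seq_len(nrow(sites)), function(i) {
    s <- seqs[[sites$transcript_id[i]]]
    stopIfNot(!is.null(s) && !is.na(s),
              paste0("unknown transcript: ", sites$transcript_id[i]))
    classifySite(sites$start[i], s, taxonomy)
  })
  sites$class <- vapply(calls, `[[`, "", "class")
  sites$group <- vapply(calls, `[[`, "", "group")
  sites$motif_start <- vapply(calls, function(x) as.integer(x$motifStart), 1L)
  sites$motif_end <- vapply(calls, function(x) as.integer(x$motifEnd), 1L)
  sites$motif_seq <- vapply(calls, function(x) as.character(x$motifSeq), "")
  sites$flank3 <- vapply(calls, function(x) as.character(x$flank3), "")
  sites
}

#' Distribution of the 3'-flanking nucleotide of classified motifs
#'
#' Counts the nucleotide at motif position +1 over a set of motif calls.
#' An rG4 motif always ends in G (position 0) but its 3' flank can be any
#' base; bias in RT-stall detection shows up as bias in this distribution.
#'
#' @param calls Data frame with a `flank3` column ([classifySites()] output).
#' @return Named integer counts over A/C/G/T (bases with no calls are 0);
#'   calls with undefined flank (transcript end) are excluded.
#' @export
flankDistribution <- function(calls) {
  f <- calls$flank3
  f <- f[!is.na(f) & f %in% c("A", "C", "G", "T")]
  counts <- table(factor(f, levels = c("A", "C", "G", "T")))
  setNames(as.integer(counts), names(counts))
}

#' Scan transcript sequences for all class matches
#'
#' Finds, for every G that terminates a G-run, the highest-priority class
#' whose pattern ends at that G. Used to validate planted motifs and to build
#' motif inventories; on simulator output every planted motif is recovered
#' with its planted class.
#'
#' @param tx A [Transcriptome-class] or named character vector.
#' @param taxonomy A [classTaxonomy()].
#' @return Data frame `transcript_id`, `start`, `end` (0-based half-open
#'   motif span), `class`, `group`.
#' @export
scanTranscriptome <- function(tx, taxonomy = classTaxonomy()) {
  seqs <- txSequences(tx)
  res <- lapply(names(seqs), function(id) {
    s <- seqs[[id]]
    ch <- strsplit(s, "")[[1]]
    isG <- ch == "G"
    # run-terminal Gs: G followed by non-G or end
    ends1 <- which(isG & c(!isG[-1], TRUE))
    hits <- lapply(ends1, function(g1) {
      win <- substr(s, max(1L, g1 - taxonomy$window + 1L), g1)
      for (cls in names(taxonomy$patterns)) {
        len <- matchLenAtEnd(win, taxonomy$patterns[[cls]])
        if (len > 0L)
          return(data.frame(transcript_id = id, start = g1 - len, end = g1,
                            class = cls,
                            group = unname(taxonomy$grouping[cls]),
                            stringsAsFactors = FALSE))
      }
      NULL
    })
    do.call(rbind, hits)
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(transcript_id = character(), start = integer(),
                      end = integer(), class = character(),
                      group = character(), stringsAsFactors = FALSE)
  out
}
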