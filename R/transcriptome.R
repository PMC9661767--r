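#' Transcriptome: synthetic polyA transcripts with planted rG4 motifs
#'
#' Holds the simulated transcript set the read simulator draws from: the
#' sequences (plus strand, transcript coordinates), their true abundances in
#' TPM, a transcript-to-gene map, and the planted quadruplex motifs that
#' constitute the simulation ground truth. Background sequence is constrained
#' to contain no G-G dinucleotide, so no putative quadruplex of any class can
#' arise outside the planted motifs.
#'
#' @slot sequences Named [Biostrings::DNAStringSet] of transcript sequences
#'   (DNA alphabet; the RNA is represented by its cDNA-sense sequence).
#' @slot tpm Named numeric, true abundance per transcript, summing to 1e6.
#' @slot geneId Named character, parent gene of each transcript.
#' @slot planted Data frame of planted motifs: `transcript_id`, `start`,
#'   `end` (0-based half-open), `class`, `sequence`.
#' @export
setClass("Transcriptome",
  representation(sequences = "DNAStringSet", tpm = "numeric",
                 geneId = "character", planted = "data.frame"))

setValidity("Transcriptome", function(object) {
  msgs <- character()
  n <- length(object@sequences)
  if (length(object@tpm) != n || length(object@geneId) != n)
    msgs <- c(msgs, "tpm and geneId must parallel sequences")
  p <- object@planted
  if (nrow(p)) {
    len <- setNames(Biostrings::width(object@sequences),
                    names(object@sequences))
    if (any(!p$transcript_id %in% names(len)))
      msgs <- c(msgs, "planted motif on unknown transcript")
    else if (any(p$start < 0L) || any(p$end > len[p$transcript_id]))
      msgs <- c(msgs, "planted motif outside its transcript")
    bad <- vapply(split(p, p$transcript_id), function(d) {
      d <- d[order(d$start), ]
      nrow(d) > 1L && any(d$start[-1] < d$end[-nrow(d)])
    }, TRUE)
    if (any(bad)) msgs <- c(msgs, "planted motifs overlap on a transcript")
  }
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "Transcriptome", function(object) {
  cat(sprintf("Transcriptome: %d transcripts (%d-%d nt), %d planted motifs\n",
              length(object@sequences),
              if (length(object@sequences)) min(Biostrings::width(object@sequences)) else 0L,
              if (length(object@sequences)) max(Biostrings::width(object@sequences)) else 0L,
              nrow(object@planted)))
  if (nrow(object@planted))
    print(table(object@planted$class))
})

#' @describeIn Transcriptome Transcript sequences as a named character
#'   vector (also accepts a plain named character vector and returns it as a
#'   list-like vector).
#' @param x A `Transcriptome` or named character vector.
#' @export
txSequences <- function(x) {
  if (is(x, "Transcriptome")) as.list(as.character(x@sequences))
  else as.list(x)
}

#' @describeIn Transcriptome Transcript lengths (named integer).
#' @export
txLengths <- function(x) {
  if (is(x, "Transcriptome"))
    setNames(Biostrings::width(x@sequences), names(x@sequences))
  else setNames(nchar(x), names(x))
}

#' @describeIn Transcriptome True abundances (TPM, named numeric).
#' @export
txTPM <- function(x) x@tpm

#' @describeIn Transcriptome Planted ground-truth motif table.
#' @export
plantedMotifs <- function(x) x@planted

#' @describeIn Transcriptome Transcript-to-gene map (named character).
#' @export
txGeneId <- function(x) x@geneId

# random motif sequence of a given structural class; loops/bulges use A/C/T
# so the planted motif is the only source of G-G dinucleotides around it
motifSequence <- function(class, tax = classTaxonomy()) {
  loopChars <- c("A", "C", "T")
  rloop <- function(lo, hi) paste(sample(loopChars, sample(lo:hi, 1L),
                                         replace = TRUE), collapse = "")
  tract <- strrep("G", tax$gRunMin)
  switch(class,
    canonical = paste0(tract, rloop(tax$loopMin, tax$loopMax), tract,
                       rloop(tax$loopMin, tax$loopMax), tract,
                       rloop(tax$loopMin, tax$loopMax), tract),
    long_loop = {
      loops <- c(rloop(tax$loopMin, tax$loopMax),
                 rloop(tax$loopMin, tax$loopMax),
                 rloop(tax$loopMin, tax$loopMax))
      loops[sample(3L, 1L)] <- rloop(tax$longLoopMin, tax$longLoopMax)
      paste0(tract, loops[1], tract, loops[2], tract, loops[3], tract)
    },
    bulge = {
      bulgedTract <- paste0("GG", rloop(tax$bulgeMin, tax$bulgeMax), "G")
      tr <- rep(tract, 4L); tr[sample(4L, 1L)] <- bulgedTract
      paste0(tr[1], rloop(tax$loopMin, tax$loopMax), tr[2],
             rloop(tax$loopMin, tax$loopMax), tr[3],
             rloop(tax$loopMin, tax$loopMax), tr[4])
    },
    two_quartet = {
      t2 <- strrep("G", tax$twoQuartetRun)
      paste0(t2, rloop(tax$loopMin, tax$loopMax), t2,
             rloop(tax$loopMin, tax$loopMax), t2,
             rloop(tax$loopMin, tax$loopMax), t2)
    },
    g_triplex = paste0(tract, rloop(tax$loopMin, tax$loopMax), tract,
                       rloop(tax$loopMin, tax$loopMax), tract),
    stop("unknown motif class: ", class))
}

# background sequence with no G-G dinucleotide: sample from A/C/T, then
# convert isolated, non-adjacent positions to G
backgroundSequence <- function(len, gDensity = 0.15) {
  ch <- sample(c("A", "C", "T"), len, replace = TRUE)
  nG <- round(len * gDensity)
  if (nG > 0L) {
    cand <- sample(seq_len(len))
    keep <- integer(0)
    taken <- logical(len + 2L)
    for (p in cand) {
      if (!taken[p] && !taken[p + 1L] && !(p > 1L && taken[p - 1L])) {
        keep <- c(keep, p); taken[p] <- TRUE
        if (length(keep) >= nG) break
      }
    }
    ch[keep] <- "G"
  }
  paste(ch, collapse = "")
}

#' Generate a ground-truthed synthetic transcriptome
#'
#' Builds a polyA-transcriptome with log-normal true abundances and plants
#' quadruplex motifs of the requested classes at well-separated positions.
#' Background sequence carries no G-run of length >= 2, so the planted motifs
#' are the only quadruplex-compatible sequences; motif flanks are forced to
#' non-G. Reproducible under the config seed.
#'
#' @param cfg A [simConfig()].
#' @return A [Transcriptome-class].
#' @examples
#' tx <- generateTranscriptome(simConfig(seed = 1, nTranscripts = 5,
#'   motifPlan = c(canonical = 3)))
#' plantedMotifs(tx)
#' @export
generateTranscriptome <- function(cfg) {
  tax <- cfg$taxonomy %||% classTaxonomy()
  withSeed(childSeed(cfg$seed, "transcriptome"), {
    n <- cfg$nTranscripts
    lens <- sample(cfg$lengthRange[1]:cfg$lengthRange[2], n, replace = TRUE)
    ids <- sprintf("tx%03d", seq_len(n))
    tpm <- rlnorm(n, cfg$abundanceMeanlog, cfg$abundanceSdlog)
    tpm <- tpm / sum(tpm) * 1e6
    seqs <- vapply(lens, backgroundSequence, "")
    plan <- cfg$motifPlan
    plan <- plan[plan > 0]
    planted <- data.frame(transcript_id = character(), start = integer(),
                          end = integer(), class = character(),
                          sequence = character(), stringsAsFactors = FALSE)
    if (length(plan)) {
      classes <- rep(names(plan), plan)
      classes <- sample(classes)                 # spread classes over transcripts
      # round-robin assignment over transcripts long enough
      margin <- cfg$motifMargin
      txIdx <- rep_len(seq_len(n), length(classes))
      occupied <- lapply(seq_len(n), function(i) matrix(integer(), ncol = 2))
      for (k in seq_along(classes)) {
        mseq <- motifSequence(classes[k], tax)
        mlen <- nchar(mseq)
        placed <- FALSE
        for (ti in c(txIdx[k], setdiff(sample(seq_len(n)), txIdx[k]))) {
          L <- lens[ti]
          lo <- margin; hi <- L - margin - mlen
          if (hi <= lo) next
          for (try in seq_len(50L)) {
            st <- sample(lo:hi, 1L)              # 0-based motif start
            occ <- occupied[[ti]]
            clash <- nrow(occ) && any(st < occ[, 2] + cfg$motifSpacing &
                                      st + mlen + cfg$motifSpacing > occ[, 1])
            if (!clash) {
              ch <- strsplit(seqs[ti], "")[[1]]
              ch[(st + 1L):(st + mlen)] <- strsplit(mseq, "")[[1]]
              # non-G flanks so tracts do not extend beyond the motif
              if (st >= 1L && ch[st] == "G") ch[st] <- "A"
              if (st + mlen < L && ch[st + mlen + 1L] == "G")
                ch[st + mlen + 1L] <- sample(c("A", "C", "T"), 1L)
              seqs[ti] <- paste(ch, collapse = "")
              occupied[[ti]] <- rbind(occ, c(st, st + mlen))
              planted <- rbind(planted, data.frame(
                transcript_id = ids[ti], start = st, end = st + mlen,
                class = classes[k], sequence = mseq, stringsAsFactors = FALSE))
              placed <- TRUE
            }
            if (placed) break
          }
          if (placed) break
        }
        if (!placed)
          stop("motif plan infeasible: could not place a '", classes[k],
               "' motif; increase transcript lengths or count")
      }
    }
    planted <- planted[order(planted$transcript_id, planted$start), ]
    rownames(planted) <- NULL
    new("Transcriptome",
        sequences = Biostrings::DNAStringSet(setNames(seqs, ids)),
        tpm = setNames(tpm, ids),
        geneId = setNames(sprintf("gene%03d", seq_len(n)), ids),
        planted = planted)
  })
}

#' Write transcript sequences as FASTA
#'
#' @param tx A [Transcriptome-class].
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
writeTranscriptFasta <- function(tx, path) {
  Biostrings::writeXStringSet(tx@sequences, path)
  invisible(path)
}

#' Write planted ground-truth motifs as BED6
#'
#' Spans are 0-based half-open on transcript coordinates, strand `+`, score
#' 0, name = planted class.
#'
#' @param tx A [Transcriptome-class].
#' @param path Output BED path.
#' @return `path`, invisibly.
#' @export
writeTruthBed <- function(tx, path) {
  p <- tx@planted
  if (nrow(p) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  bed <- data.frame(p$transcript_id, p$start, p$end, p$class, 0L, "+")
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED6 file of transcript-coordinate features
#'
#' @param path BED path (0-based half-open, tab-separated, no header).
#' @return Data frame `transcript_id`, `start`, `end`, `name`, `score`,
#'   `strand`.
#' @export
readBed <- function(path) {
  if (file.size(path) == 0)
    return(data.frame(transcript_id = character(), start = integer(),
                      end = integer(), name = character(), score = numeric(),
                      strand = character(), stringsAsFactors = FALSE))
  b <- read.table(path, sep = "\t", stringsAsFactors = FALSE)
  names(b)[1:6] <- c("transcript_id", "start", "end", "name", "score", "strand")
  b
}
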