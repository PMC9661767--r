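randomUMIs <- function(n, umiLen) {
  if (n == 0L) return(character())
  m <- matrix(sample(c("A", "C", "G", "T"), n * umiLen, replace = TRUE),
              nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

emptyReadTable <- function() {
  data.frame(read_id = character(), transcript_id = character(),
             strand = character(), stop_pos = integer(), end_pos = integer(),
             umi = character(), condition = character(),
             replicate = integer(), input_ng = numeric(), fate = character(),
             molecule_id = character(), is_duplicate_of = character(),
             stringsAsFactors = FALSE)
}

# per-library stall probabilities: variant classes get a logit-scale
# per-replicate jitter, reflecting their higher stochasticity
replicateTheta <- function(cfg, replicate) {
  th <- cfg$thetaStop
  variant <- intersect(names(th), c("two_quartet", "g_triplex"))
  if (length(variant) && cfg$thetaJitterSd > 0) {
    withSeed(childSeed(cfg$seed, paste0("jitter_", replicate)), {
      j <- rnorm(length(variant), 0, cfg$thetaJitterSd)
      th[variant] <- stats::plogis(stats::qlogis(pmin(pmax(th[variant],
                                                           1e-6), 1 - 1e-6)) + j)
    })
  }
  th
}

#' Simulate one rG4-seq sequencing library
#'
#' Draws RNA fragments proportional to true abundance times transcript
#' length, applies condition-dependent reverse-transcription stalling, PCR
#' duplication and a 5'-nucleotide ligation bias, and returns one aligned
#' read record per sequenced read pair.
#'
#' Mechanics per molecule: a fragment `[fs, fe)` is drawn (length
#' ~ Normal(`fragMean`, `fragSd`)); reverse transcription proceeds from the
#' fragment 3' end toward 5'. In K+, each planted motif fully contained in
#' the fragment stalls the polymerase with its class-specific probability at
#' motif position 0 (the 3'-most G) or +1 per `p0p1`; in Li+, motifs behave
#' as background. In both conditions a background stop occurs at any position
#' with probability `epsilonBg`. The realised stop is the 3'-most stalling
#' event; absent any event the whole fragment is read through and the stop is
#' the fragment start. The molecule is then accepted with a probability
#' depending on the transcript base at the stop — the protocol's target
#' 5'-nucleotide frequencies importance-corrected by the transcriptome base
#' composition, so the realised read 5'-base distribution approximates
#' `abiasWeights` (the protocol's ligation bias). It is tagged with a random UMI, assigned a
#' fate (usable / adapter_only / unalignable / multimapped) and amplified
#' into `1 + Poisson(dupScale * pcrCycles / inputNg)` read copies. Molecules
#' are emitted until `depth` read pairs are reached.
#'
#' @param tx A [Transcriptome-class].
#' @param cfg A [simConfig()].
#' @param condition `"K"` or `"Li"`.
#' @param replicate Replicate index (integer).
#' @return Aligned-read data frame with columns `read_id`, `transcript_id`,
#'   `strand`, `stop_pos`, `end_pos` (0-based half-open template-strand
#'   span; `stop_pos` is the read 5' base, the RT stop), `umi`, `condition`,
#'   `replicate`, `input_ng`, `fate`, `molecule_id`, `is_duplicate_of`
#'   (parent molecule for PCR copies beyond the first, else `NA`).
#' @examples
#' cfg <- simConfig(seed = 1, nTranscripts = 5, depth = 500,
#'                  motifPlan = c(canonical = 3))
#' tx <- generateTranscriptome(cfg)
#' reads <- simulateLibrary(tx, cfg, "K", 1)
#' head(reads)
#' @export
simulateLibrary <- function(tx, cfg, condition, replicate = 1L) {
  stopIfNot(condition %in% c("K", "Li"),
            "condition must be 'K' or 'Li'")
  if (cfg$depth == 0L) return(emptyReadTable())
  lens <- txLengths(tx)
  ids <- names(lens)
  seqChar <- as.character(tx@sequences)
  tpm <- txTPM(tx)
  prob <- tpm * lens
  motifs <- plantedMotifs(tx)
  theta <- replicateTheta(cfg, replicate)
  lambda <- cfg$dupScale * cfg$pcrCycles / cfg$inputNg
  # acceptance weights targeting the protocol's 5'-base distribution:
  # importance-correct by the transcriptome base composition so the realised
  # read 5'-nucleotide frequencies approximate abiasWeights
  comp <- colSums(Biostrings::letterFrequency(tx@sequences,
                                              c("A", "C", "G", "T")))
  comp <- comp / sum(comp)
  accW <- cfg$abiasWeights[c("A", "C", "G", "T")] / pmax(comp, 1e-9)
  accW <- accW / max(accW)
  fateLevels <- c("usable", names(cfg$fateRates))
  fateProbs <- c(1 - sum(cfg$fateRates), cfg$fateRates)

  withSeed(childSeed(cfg$seed, paste0("lib_", condition, "_", replicate,
                                      "_", cfg$protocol, "_", cfg$inputNg)), {
    molecules <- list()
    total <- 0L; made <- 0L
    while (total < cfg$depth) {
      nb <- max(200L, ceiling((cfg$depth - total) / (1 + lambda) * 1.3))
      ti <- sample(length(ids), nb, replace = TRUE, prob = prob)
      L <- lens[ti]
      flen <- pmin(pmax(round(rnorm(nb, cfg$fragMean, cfg$fragSd)), 30L), L)
      fs <- floor(runif(nb) * (L - flen + 1))
      fe <- fs + flen
      # background stop: geometric scan from the 3' end
      stopPos <- fs
      if (cfg$epsilonBg > 0) {
        d <- rgeom(nb, cfg$epsilonBg)
        bg <- fe - 1L - d
        stopPos <- pmax(stopPos, ifelse(bg >= fs, bg, fs))
      }
      if (condition == "K" && nrow(motifs)) {
        for (k in seq_len(nrow(motifs))) {
          m <- motifs[k, ]
          el <- which(ids[ti] == m$transcript_id & fs <= m$start & fe > m$end)
          if (!length(el)) next
          fire <- el[runif(length(el)) < theta[[m$class]]]
          if (!length(fire)) next
          off <- sample(c(0L, 1L), length(fire), replace = TRUE,
                        prob = cfg$p0p1)
          stallAt <- (m$end - 1L) + off
          stopPos[fire] <- pmax(stopPos[fire], stallAt)
        }
      }
      # 5'-nucleotide ligation bias: accept on the transcript base at the stop
      base5 <- substr(seqChar[ti], stopPos + 1L, stopPos + 1L)
      keep <- runif(nb) < accW[base5]
      keep[is.na(keep)] <- FALSE
      if (!any(keep)) next
      idx <- which(keep)
      copies <- 1L + rpois(length(idx), lambda)
      mol <- data.frame(
        molecule_id = sprintf("mol_%s_%d_%07d", condition, replicate,
                              made + seq_along(idx)),
        transcript_id = ids[ti[idx]], stop_pos = as.integer(stopPos[idx]),
        end_pos = as.integer(fe[idx]),
        umi = randomUMIs(length(idx), cfg$umiLen),
        fate = sample(fateLevels, length(idx), replace = TRUE,
                      prob = fateProbs),
        copies = copies, stringsAsFactors = FALSE)
      made <- made + length(idx)
      molecules[[length(molecules) + 1L]] <- mol
      total <- total + sum(copies)
    }
    mol <- do.call(rbind, molecules)
    ridx <- rep(seq_len(nrow(mol)), mol$copies)
    copyNo <- sequence(mol$copies)
    reads <- data.frame(
      read_id = sprintf("%s/%d", mol$molecule_id[ridx], copyNo),
      transcript_id = mol$transcript_id[ridx], strand = "+",
      stop_pos = mol$stop_pos[ridx], end_pos = mol$end_pos[ridx],
      umi = mol$umi[ridx], condition = condition,
      replicate = as.integer(replicate), input_ng = cfg$inputNg,
      fate = mol$fate[ridx], molecule_id = mol$molecule_id[ridx],
      is_duplicate_of = ifelse(copyNo > 1L, mol$molecule_id[ridx],
                               NA_character_),
      stringsAsFactors = FALSE)
    utils::head(reads, cfg$depth)
  })
}

#' Write a simulated library as paired FASTQ
#'
#' Mate 1 begins with the UMI followed by the template-strand insert from the
#' RT stop; mate 2 is the reverse complement of the insert 3' end. Phred+33
#' with a fixed quality. Files are gzip-compressed when the path ends in
#' `.gz`.
#'
#' @param reads Aligned-read table from [simulateLibrary()].
#' @param tx The [Transcriptome-class] the reads were simulated from.
#' @param prefix Output path prefix; writes `<prefix>_R1.fastq.gz` and
#'   `<prefix>_R2.fastq.gz`.
#' @param cfg The [simConfig()] used (for `readLen`/`umiLen`).
#' @return Character vector of the two paths, invisibly.
#' @export
writeLibraryFastq <- function(reads, tx, prefix, cfg) {
  seqs <- as.character(tx@sequences)[reads$transcript_id]
  insLen <- cfg$readLen - cfg$umiLen
  ins1 <- substr(seqs, reads$stop_pos + 1L,
                 pmin(reads$stop_pos + insLen, reads$end_pos))
  r1 <- paste0(reads$umi, ins1)
  start2 <- pmax(reads$stop_pos + 1L, reads$end_pos - cfg$readLen + 1L)
  ins2 <- substr(seqs, start2, reads$end_pos)
  r2 <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(ins2)))
  paths <- paste0(prefix, c("_R1.fastq.gz", "_R2.fastq.gz"))
  for (i in 1:2) {
    sq <- if (i == 1) r1 else r2
    con <- gzfile(paths[i], "wb")
    writeLines(paste0("@", reads$read_id, "\n", sq, "\n+\n",
                      strrep("I", nchar(sq))), con, sep = "\n")
    close(con)
  }
  invisible(paths)
}

#' Extract UMIs from a FASTQ mate-1 file
#'
#' Removes the first `umiLen` bases of each mate-1 read, records them as the
#' read UMI and returns the trimmed inserts. Reads not longer than the UMI
#' are discarded with fate `"too_short"`.
#'
#' @param fastq1 Path to the mate-1 FASTQ (optionally gzipped).
#' @param umiLen UMI length; 0 is the identity transformation.
#' @return Data frame `read_id`, `umi`, `insert`, `fate` (`"usable"` or
#'   `"too_short"`; short reads have empty umi/insert).
#' @export
extractUMI <- function(fastq1, umiLen) {
  con <- gzfile(fastq1, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  stopIfNot(length(lines) %% 4L == 0L,
            paste0("malformed FASTQ (", length(lines), " lines): ", fastq1))
  ids <- sub("^@", "", sub("\\s.*", "", lines[seq(1, length(lines), 4)]))
  sq <- lines[seq(2, length(lines), 4)]
  stopIfNot(all(grepl("^[ACGTN]*$", sq)), paste0("corrupt FASTQ records in ", fastq1))
  ok <- nchar(sq) > umiLen
  data.frame(read_id = ids,
             umi = ifelse(ok, substr(sq, 1L, umiLen), ""),
             insert = ifelse(ok, substr(sq, umiLen + 1L, nchar(sq)), ""),
             fate = ifelse(ok, "usable", "too_short"),
             stringsAsFactors = FALSE)
}

#' Emit simulation ground truth
#'
#' Writes the planted-motif BED and the per-molecule lineage table that
#' downstream sensitivity/FDR scoring joins against.
#'
#' @param tx A [Transcriptome-class].
#' @param reads Aligned-read table.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the two paths, invisibly.
#' @export
emitTruth <- function(tx, reads, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  bed <- file.path(dir, "truth_motifs.bed")
  writeTruthBed(tx, bed)
  lineage <- file.path(dir, "truth_molecules.tsv")
  checkReadTable(reads)
  write.table(reads[, READ_COLUMNS], lineage, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(motifs = bed, molecules = lineage))
}

#' Read/write the aligned-read table
#'
#' Tab-separated with a header row, one row per sequenced read pair, columns
#' as produced by [simulateLibrary()].
#'
#' @param reads Aligned-read data frame.
#' @param path File path.
#' @return `readReadTable` returns the data frame; `writeReadTable` returns
#'   `path` invisibly.
#' @export
writeReadTable <- function(reads, path) {
  checkReadTable(reads)
  write.table(reads[, READ_COLUMNS], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname writeReadTable
#' @export
readReadTable <- function(path) {
  r <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                  colClasses = c(is_duplicate_of = "character",
                                 umi = "character"))
  checkReadTable(r)
  r
}
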