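dedupKey <- function(reads) {
  paste(reads$transcript_id, reads$strand, reads$stop_pos, reads$umi,
        sep = "\r")
}

#' Collapse PCR duplicates by UMI
#'
#' Deduplicates usable aligned reads on the exact 4-tuple (transcript,
#' strand, stop position, UMI): reads agreeing on all four fields form one
#' duplicate group and a single representative survives — the first in
#' `read_id` order (ties broken lexicographically). Reads with distinct stop
#' positions are never collapsed even when their UMIs collide. The operation
#' is idempotent.
#'
#' @param reads Aligned-read table; only rows with `fate == "usable"` are
#'   considered (others are dropped with the non-aligned reads).
#' @param mode Duplicate-grouping mode; only `"exact"` is implemented.
#' @return List: `reads` (the surviving unique molecules, one per key),
#'   `duplicates` (number of removed reads).
#' @examples
#' cfg <- simConfig(seed = 2, nTranscripts = 4, depth = 400,
#'                  motifPlan = c(canonical = 2))
#' tx <- generateTranscriptome(cfg)
#' d <- dedup(simulateLibrary(tx, cfg, "K", 1))
#' d$duplicates
#' @export
dedup <- function(reads, mode = "exact") {
  checkReadTable(reads)
  stopIfNot(identical(mode, "exact"),
            "only exact-match duplicate grouping is implemented")
  if (any(is.na(reads$umi) | reads$umi == ""))
    stop("reads with missing UMI cannot be deduplicated")
  usable <- reads[reads$fate == "usable", , drop = FALSE]
  usable <- usable[order(usable$read_id), , drop = FALSE]
  keep <- !duplicated(dedupKey(usable))
  out <- usable[keep, , drop = FALSE]
  rownames(out) <- NULL
  list(reads = out, duplicates = nrow(usable) - nrow(out))
}

#' Randomly subsample a read table
#'
#' Uniform subset without replacement of exactly `targetDepth` read pairs.
#' Subsampling is omitted when the target depth exceeds the number of reads
#' available (no up-sampling). Deterministic under `seed`.
#'
#' @param reads Aligned-read table.
#' @param targetDepth Non-negative target read-pair count.
#' @param seed Seed (NULL = current RNG stream).
#' @return The subsampled table (input order preserved).
#' @export
subsampleReads <- function(reads, targetDepth, seed = NULL) {
  stopIfNot(targetDepth >= 0, "targetDepth must be >= 0")
  n <- nrow(reads)
  if (targetDepth >= n) return(reads)
  idx <- withSeed(seed, sample(n, targetDepth))
  out <- reads[sort(idx), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Stage-wise yield accounting
#'
#' Tracks read counts through the pre-processing stages: `raw` (all read
#' pairs), `trimmed` (adapter-only pairs removed), `uniquely_aligned`
#' (unalignable and multimapped pairs removed) and `deduplicated` (one read
#' per UMI duplicate group). Counts are non-increasing and each stage reports
#' its fraction of raw.
#'
#' @param reads Aligned-read table with fate flags.
#' @return Data frame `stage`, `reads`, `fraction_of_raw`.
#' @examples
#' cfg <- simConfig(seed = 3, nTranscripts = 4, depth = 400,
#'                  motifPlan = c(canonical = 2))
#' tx <- generateTranscriptome(cfg)
#' yieldReport(simulateLibrary(tx, cfg, "K", 1))
#' @export
yieldReport <- function(reads) {
  checkReadTable(reads)
  raw <- nrow(reads)
  trimmed <- sum(reads$fate != "adapter_only")
  aligned <- sum(reads$fate == "usable")
  dd <- if (aligned > 0L) nrow(dedup(reads)$reads) else 0L
  counts <- c(raw = raw, trimmed = trimmed, uniquely_aligned = aligned,
              deduplicated = dd)
  stopIfNot(all(diff(counts) <= 0), "stage counts must be non-increasing")
  data.frame(stage = names(counts), reads = as.integer(counts),
             fraction_of_raw = if (raw > 0) counts / raw else rep(0, 4),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Sequencing-saturation curve
#'
#' Subsamples the raw library to a grid of depths and reports the number of
#' unique molecules (deduplicated reads) recovered at each depth, the
#' standard read-depth saturation analysis. Subsamples are nested (drawn from
#' one seeded permutation), so the curve is non-decreasing by construction
#' and depths on the grid exceeding the library size reuse the full library.
#'
#' @param reads Aligned-read table (raw, before dedup).
#' @param grid Fractions of the available depth to evaluate (default
#'   10\%..100\% by 10\%).
#' @param seed Seed for the permutation.
#' @return Data frame `fraction`, `depth`, `unique_molecules`.
#' @export
saturationCurve <- function(reads, grid = seq(0.1, 1, by = 0.1),
                            seed = NULL) {
  checkReadTable(reads)
  n <- nrow(reads)
  perm <- withSeed(seed, sample(n))
  res <- lapply(grid, function(f) {
    k <- min(n, round(f * n))
    sub <- reads[perm[seq_len(k)], , drop = FALSE]
    u <- if (any(sub$fate == "usable")) nrow(dedup(sub)$reads) else 0L
    data.frame(fraction = f, depth = k, unique_molecules = u)
  })
  do.call(rbind, res)
}
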