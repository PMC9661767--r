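test_that("transcriptome generation satisfies the motif plan deterministically", {
  cfg <- simConfig(seed = 5, nTranscripts = 10,
                   motifPlan = c(canonical = 5L))
  tx <- generateTranscriptome(cfg)
  p <- plantedMotifs(tx)
  expect_equal(nrow(p), 5L)
  expect_true(all(p$class == "canonical"))
  # identical output under the same config
  tx2 <- generateTranscriptome(cfg)
  expect_identical(as.character(tx@sequences), as.character(tx2@sequences))
  expect_identical(plantedMotifs(tx2), p)
  expect_equal(sum(txTPM(tx)), 1e6)
})

test_that("background sequence yields no quadruplex call at any position", {
  cfg <- nullSimConfig(seed = 6)
  tx <- generateTranscriptome(cfg)
  # exhaustive oracle scan of every position of one transcript
  s <- txSequences(tx)[[1]]
  expect_false(grepl("GG", s, fixed = TRUE))
  anchors <- which(strsplit(s, "")[[1]] == "G")
  for (a in anchors[seq(1, length(anchors), length.out = min(25, length(anchors)))])
    expect_equal(oracleClassify(s, a), "others")
  # package scan agrees: nothing above 'others'
  expect_equal(nrow(scanTranscriptome(tx)), 0L)
})

test_that("degenerate stall probabilities pin every stop to the motif 3' G", {
  cfg <- smallSimConfig(seed = 7, epsilonBg = 0,
                        thetaStop = c(canonical = 1, two_quartet = 1),
                        thetaJitterSd = 0, p0p1 = c(1, 0),
                        fateRates = c(adapter_only = 0, unalignable = 0,
                                      multimapped = 0))
  tx <- generateTranscriptome(cfg)
  reads <- simulateLibrary(tx, cfg, "K", 1)
  m <- plantedMotifs(tx)
  anchors <- split(m$end - 1L, m$transcript_id)
  starts <- split(m$start, m$transcript_id)
  # if a fragment fully contains a motif, the stop must be a motif 3' G
  violations <- 0L
  for (i in seq_len(nrow(reads))) {
    r <- reads[i, ]
    a <- anchors[[r$transcript_id]]
    st <- starts[[r$transcript_id]]
    contained <- length(a) && any(st >= r$stop_pos & (a + 1L) < r$end_pos)
    if (contained && !(r$stop_pos %in% a)) violations <- violations + 1L
  }
  expect_equal(violations, 0L)
  # duplicates share umi and stop position with their parent
  dups <- reads[!is.na(reads$is_duplicate_of), ]
  if (nrow(dups)) {
    parents <- reads[match(paste0(dups$is_duplicate_of, "/1"), reads$read_id), ]
    expect_equal(dups$umi, parents$umi)
    expect_equal(dups$stop_pos, parents$stop_pos)
  }
})

test_that("stops stay within transcript bounds and libraries are seeded", {
  cfg <- smallSimConfig(seed = 8)
  tx <- generateTranscriptome(cfg)
  reads <- simulateLibrary(tx, cfg, "K", 1)
  lens <- txLengths(tx)
  expect_true(all(reads$stop_pos >= 0))
  expect_true(all(reads$end_pos <= lens[reads$transcript_id]))
  expect_true(all(reads$stop_pos < reads$end_pos))
  expect_equal(nrow(reads), cfg$depth)
  expect_identical(simulateLibrary(tx, cfg, "K", 1), reads)
  expect_false(identical(simulateLibrary(tx, cfg, "K", 2)$umi, reads$umi))
  expect_error(simulateLibrary(tx, cfg, "Na", 1), "condition")
  expect_equal(nrow(simulateLibrary(tx, simConfig(seed = 8, depth = 0), "K", 1)), 0L)
})

test_that("protocol 1.0 libraries start with ~65% A at the read 5' end", {
  cfg <- simConfig(seed = 9, nTranscripts = 10, depth = 50000,
                   motifPlan = c(canonical = 2L), protocol = "1.0")
  tx <- generateTranscriptome(cfg)
  reads <- simulateLibrary(tx, cfg, "K", 1)
  dd <- dedup(reads)$reads
  f <- ntDistributions(dd, tx)$reads5p
  expect_gt(f[["A"]], 0.62)
  expect_lt(f[["A"]], 0.68)
  cfg2 <- simConfig(seed = 9, nTranscripts = 10, depth = 50000,
                    motifPlan = c(canonical = 2L), protocol = "2.0")
  f2 <- ntDistributions(dedup(simulateLibrary(tx, cfg2, "K", 1))$reads,
                        tx)$reads5p
  expect_gt(f2[["A"]], 0.32)
  expect_lt(f2[["A"]], 0.38)
})

test_that("Li+ stops at planted motifs are indistinguishable from background", {
  cfg <- smallSimConfig(seed = 10, depth = 20000)
  tx <- generateTranscriptome(cfg)
  dd <- dedup(simulateLibrary(tx, cfg, "Li", 1))$reads
  prof <- buildStopProfile(dd, dd, tx)
  m <- plantedMotifs(tx)
  sA <- cA <- sO <- cO <- 0
  for (id in names(txLengths(tx))) {
    stops <- profileArrays(prof, id, "K")$stops
    cov <- profileArrays(prof, id, "K")$cov
    seqc <- strsplit(txSequences(tx)[[id]], "")[[1]]
    anchors <- m$end[m$transcript_id == id] - 1L
    gpos <- which(seqc == "G") - 1L
    other <- setdiff(gpos, c(anchors, anchors + 1L))
    sA <- sA + sum(stops[anchors + 1L]); cA <- cA + sum(cov[anchors + 1L])
    sO <- sO + sum(stops[other + 1L]); cO <- cO + sum(cov[other + 1L])
  }
  tab <- matrix(c(sA, cA - sA, sO, cO - sO), nrow = 2, byrow = TRUE)
  p <- suppressWarnings(stats::chisq.test(tab)$p.value)
  expect_gt(p, 0.01)
})

test_that("library complexity scales with RNA input at fixed depth", {
  cfg <- function(ng) smallSimConfig(seed = 11, depth = 8000, inputNg = ng)
  tx <- generateTranscriptome(cfg(100))
  uniq <- dupfrac <- c()
  for (ng in c(10, 100, 500)) {
    r <- simulateLibrary(tx, cfg(ng), "K", 1)
    d <- dedup(r)
    uniq[as.character(ng)] <- nrow(d$reads)
    dupfrac[as.character(ng)] <- d$duplicates / sum(r$fate == "usable")
  }
  expect_true(uniq[["10"]] < uniq[["100"]] && uniq[["100"]] < uniq[["500"]])
  expect_true(dupfrac[["10"]] > dupfrac[["100"]] &&
                dupfrac[["100"]] > dupfrac[["500"]])
})

test_that("FASTQ round-trip reproduces read id, UMI and insert", {
  cfg <- smallSimConfig(seed = 12, depth = 1500)
  tx <- generateTranscriptome(cfg)
  reads <- simulateLibrary(tx, cfg, "K", 1)
  dir <- withr::local_tempdir()
  paths <- writeLibraryFastq(reads, tx, file.path(dir, "lib"), cfg)
  got <- extractUMI(file.path(dir, "lib_R1.fastq.gz"), cfg$umiLen)
  expect_equal(got$read_id, reads$read_id)
  expect_equal(got$umi, reads$umi)
  seqs <- txSequences(tx)
  ins <- substr(unlist(seqs[reads$transcript_id]), reads$stop_pos + 1L,
                pmin(reads$stop_pos + cfg$readLen - cfg$umiLen,
                     reads$end_pos))
  expect_equal(got$insert, unname(ins))
})

test_that("truth artifacts round-trip and cover all reads", {
  cfg <- smallSimConfig(seed = 13, depth = 800)
  tx <- generateTranscriptome(cfg)
  reads <- simulateLibrary(tx, cfg, "K", 1)
  dir <- withr::local_tempdir()
  paths <- emitTruth(tx, reads, dir)
  bed <- readBed(paths[["motifs"]])
  p <- plantedMotifs(tx)
  expect_equal(bed$start, p$start)
  expect_equal(bed$end, p$end)
  expect_equal(bed$name, p$class)
  back <- readReadTable(paths[["molecules"]])
  expect_equal(back$read_id, reads$read_id)
  expect_equal(back$umi, reads$umi)
  # empty truth: no motifs -> empty BED
  tx0 <- generateTranscriptome(nullSimConfig(seed = 13))
  p0 <- emitTruth(tx0, reads, withr::local_tempdir())
  expect_equal(nrow(readBed(p0[["motifs"]])), 0L)
})
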