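simpleReads <- function(stops, ends, transcript = "t1", cond = "K") {
  n <- length(stops)
  if (n == 0L)
    return(quadstop:::emptyReadTable())
  data.frame(read_id = sprintf("%s%04d", cond, seq_len(n)),
             transcript_id = transcript, strand = "+",
             stop_pos = as.integer(stops), end_pos = as.integer(ends),
             umi = sprintf("U%04d", seq_len(n)), condition = cond,
             replicate = 1L, input_ng = 100, fate = "usable",
             molecule_id = sprintf("m%04d", seq_len(n)),
             is_duplicate_of = NA_character_, stringsAsFactors = FALSE)
}
oneTx <- function(L = 120L) setNames(strrep("A", L), "t1")

test_that("stop profile counts stops and coverage correctly", {
  r <- simpleReads(5, 100)
  prof <- buildStopProfile(r, simpleReads(integer(0), integer(0)), oneTx())
  a <- profileArrays(prof, "t1", "K")
  expect_equal(a$stops[6], 1L)                 # 0-based position 5
  expect_equal(sum(a$stops), 1L)
  expect_equal(a$cov, c(rep(0L, 5), rep(1L, 95), rep(0L, 20)))
  expect_error(buildStopProfile(simpleReads(5, 100, transcript = "zz"),
                                r, oneTx()), "unknown transcript")
})

test_that("coverage matches the brute-force interval-stabbing oracle", {
  set.seed(31)
  L <- 200L
  stops <- sample(0:(L - 10), 100, replace = TRUE)
  ends <- pmin(L, stops + sample(5:80, 100, replace = TRUE))
  r <- simpleReads(stops, ends)
  prof <- buildStopProfile(r, simpleReads(integer(0), integer(0)),
                           oneTx(L))
  a <- profileArrays(prof, "t1", "K")
  expect_equal(a$cov, coverageOracle(stops, ends, L))
  expect_equal(sum(a$stops), 100L)             # stop-count conservation
})

test_that("the per-position exact test matches enumeration and fisher.test", {
  # equal rates cannot be called
  expect_gt(testPosition(5, 100, 5, 100), 0.05)
  # wrong direction is ~1
  expect_gt(testPosition(0, 100, 10, 100), 0.99)
  # exact tail by independent enumeration
  expect_equal(testPosition(10, 100, 0, 100),
               enumTailOracle(10, 100, 0, 100), tolerance = 1e-12)
  set.seed(32)
  for (i in 1:20) {
    nK <- sample(10:200, 1); nLi <- sample(10:200, 1)
    sK <- sample(0:nK, 1); sLi <- sample(0:nLi, 1)
    ft <- stats::fisher.test(matrix(c(sK, nK - sK, sLi, nLi - sLi), 2,
                                    byrow = TRUE),
                             alternative = "greater")$p.value
    expect_equal(testPosition(sK, nK, sLi, nLi), ft, tolerance = 1e-9)
    expect_equal(testPosition(sK, nK, sLi, nLi),
                 enumTailOracle(sK, nK, sLi, nLi), tolerance = 1e-9)
  }
  expect_error(testPosition(5, 100, 1, 0), "zero coverage")
})

test_that("coverage gating suppresses calls below the detection limit", {
  r <- simpleReads(rep(10, 15), rep(60, 15))          # cov 15 < 16
  rl <- simpleReads(rep(30, 15), rep(60, 15), cond = "Li")
  prof <- buildStopProfile(r, rl, oneTx())
  calls <- callStalledPositions(prof, callerConfig(minCov = 16))
  expect_equal(sum(calls$called), 0L)
  expect_equal(nrow(calls), 0L)                       # nothing tested
})

test_that("a strong stall at good coverage is called at its anchor", {
  # theta 0.9 motif at coverage 100 versus background epsilon
  stopsK <- c(rep(50L, 90), sample(0:40, 10, replace = TRUE))
  rK <- simpleReads(stopsK, rep(110L, 100))
  rLi <- simpleReads(sample(0:40, 100, replace = TRUE), rep(110L, 100),
                     cond = "Li")
  prof <- buildStopProfile(rK, rLi, oneTx())
  calls <- callStalledPositions(prof, callerConfig())
  expect_true(any(calls$called & calls$pos == 50L))
})

test_that("null profiles are controlled at the FDR level", {
  set.seed(33)
  called <- tested <- 0
  for (i in 1:10) {
    stopsK <- sample(0:99, 400, replace = TRUE)
    stopsLi <- sample(0:99, 400, replace = TRUE)
    rK <- simpleReads(stopsK, pmin(120L, stopsK + 20L))
    rLi <- simpleReads(stopsLi, pmin(120L, stopsLi + 20L), cond = "Li")
    calls <- callStalledPositions(buildStopProfile(rK, rLi, oneTx()),
                                  callerConfig())
    called <- called + sum(calls$called)
    tested <- tested + nrow(calls)
  }
  expect_gt(tested, 100)
  expect_lte(called / tested, 1.5 * 0.05)
})

test_that("position merging matches the spec examples and a union-find oracle", {
  cfg <- callerConfig()
  s <- mergePositions(data.frame(transcript_id = "t", pos = c(100L, 101L)), cfg)
  expect_equal(nrow(s), 1L)
  expect_equal(c(s$start, s$end), c(100L, 102L))
  s2 <- mergePositions(data.frame(transcript_id = "t", pos = c(100L, 105L)), cfg)
  expect_equal(nrow(s2), 2L)
  expect_true(all(s2$end - s2$start == 1L))           # singletons are 1-nt sites
  set.seed(34)
  pos <- data.frame(transcript_id = sample(c("a", "b", "c"), 1000, TRUE),
                    pos = sample(0:2000, 1000, TRUE))
  pos <- pos[!duplicated(pos), ]
  got <- mergePositions(pos, cfg)[, c("transcript_id", "start", "end")]
  want <- mergeOracle(pos$transcript_id, pos$pos, cfg$mergeGap)
  rownames(want) <- NULL
  expect_equal(got, want)
})

test_that("calls are invariant under read order permutation", {
  cfg <- smallSimConfig(seed = 35)
  tx <- generateTranscriptome(cfg)
  rK <- simulateLibrary(tx, cfg, "K", 1)
  rLi <- simulateLibrary(tx, cfg, "Li", 1)
  res1 <- callSites(rK, rLi, tx)
  set.seed(36)
  res2 <- callSites(rK[sample(nrow(rK)), ], rLi[sample(nrow(rLi)), ], tx)
  expect_equal(res2$sites, res1$sites)
  expect_equal(res2$positions$called, res1$positions$called)
})

test_that("condition swap removes motif calls", {
  cfg <- smallSimConfig(seed = 37)
  tx <- generateTranscriptome(cfg)
  rK <- simulateLibrary(tx, cfg, "K", 1)
  rLi <- simulateLibrary(tx, cfg, "Li", 1)
  fwd <- callSites(rK, rLi, tx)
  swp <- callSites(rLi, rK, tx)
  expect_gt(sum(fwd$positions$called), 0)
  frac <- if (nrow(swp$positions)) mean(swp$positions$called) else 0
  expect_lte(frac, 1.5 * 0.05)
})
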