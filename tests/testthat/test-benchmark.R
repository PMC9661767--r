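site <- function(tx, s, e, cov = 50) {
  data.frame(transcript_id = tx, start = as.integer(s), end = as.integer(e),
             mean_cov = cov, stringsAsFactors = FALSE)
}

test_that("site intersection uses strict sub-5-nt boundary distance", {
  cfg <- benchmarkConfig()
  A <- site("t", 90, 100)
  expect_equal(nrow(intersectSites(A, site("t", 104, 110), cfg)$agreed), 1L)
  expect_equal(intersectSites(A, site("t", 104, 110), cfg)$agreed$distance, 4)
  # distance exactly 5 is not an overlap
  expect_equal(nrow(intersectSites(A, site("t", 105, 110), cfg)$agreed), 0L)
  # span overlap is distance 0
  expect_equal(intersectSites(A, site("t", 95, 98), cfg)$agreed$distance, 0)
  # different transcripts never overlap
  expect_equal(nrow(intersectSites(A, site("u", 90, 100), cfg)$agreed), 0L)
})

test_that("intersection is symmetric and self-intersection is total", {
  set.seed(51)
  mk <- function() {
    st <- sort(sample(0:5000, 40))
    site(sample(c("a", "b"), 40, TRUE), st, st + sample(1:3, 40, TRUE))
  }
  A <- mk(); B <- mk()
  nab <- nrow(intersectSites(A, B)$agreed)
  nba <- nrow(intersectSites(B, A)$agreed)
  expect_equal(nab, nba)
  self <- intersectSites(A, A)
  expect_equal(nrow(self$agreed), nrow(A))     # Jaccard 1
  expect_length(self$onlyA, 0)
})

test_that("consensus and union behave on identical and disjoint lists", {
  A <- site("t", c(10, 100, 300), c(12, 103, 301))
  expect_equal(consensusSites(list(A, A))[, 1:3], A[, 1:3])
  expect_equal(unionSites(list(A, A)), A[, 1:3])
  B <- site("t", c(1000, 2000), c(1002, 2003))
  expect_equal(nrow(consensusSites(list(A, B))), 0L)
  expect_equal(nrow(unionSites(list(A, B))), nrow(A) + nrow(B))
})

test_that("interval union equals the sweep-line oracle on random spans", {
  set.seed(52)
  for (i in 1:10) {
    d <- site(sample(c("x", "y"), 60, TRUE),
              s <- sample(0:400, 60, TRUE), s + sample(1:30, 60, TRUE))
    got <- unionSites(list(d[1:30, ], d[31:60, ]))
    want <- sweepUnionOracle(d)
    expect_equal(got, want)
  }
})

test_that("coverage regression recovers identity and closed-form offsets", {
  set.seed(53)
  covA <- 10^runif(50, 1, 3)
  r <- coverageRegression(covA, covA)
  expect_equal(r$slope, 1, tolerance = 1e-9)
  expect_equal(r$intercept, 0, tolerance = 1e-9)
  r2 <- coverageRegression(covA, covA / 2)
  expect_equal(r2$slope, 1, tolerance = 1e-9)
  expect_equal(r2$intercept, -log10(2), tolerance = 1e-9)
  # normal-equations oracle on noisy pairs
  covB <- covA^0.8 * 10^rnorm(50, 0, 0.05)
  fit <- coverageRegression(covA, covB)
  x <- log10(covA); y <- log10(covB)
  slopeNE <- (sum(x * y) - length(x) * mean(x) * mean(y)) /
    (sum(x^2) - length(x) * mean(x)^2)
  expect_equal(fit$slope, slopeNE, tolerance = 1e-9)
  expect_equal(fit$intercept, mean(y) - slopeNE * mean(x), tolerance = 1e-9)
  expect_error(coverageRegression(c(10, 10, 10), c(1, 2, 3)), "degenerate")
  expect_error(coverageRegression(1:2, 1:2), "at least 3")
})

test_that("nucleotide distributions match a brute-force recount", {
  tx <- setNames(c("GAGAGAGAGA", "CCCCCCCCCC"), c("t1", "t2"))
  reads <- data.frame(transcript_id = c(rep("t1", 6), rep("t2", 4)),
                      stop_pos = c(0, 2, 4, 1, 3, 5, 0, 1, 2, 3))
  f <- ntDistributions(reads, tx)$reads5p
  expect_equal(sum(f), 1)
  expect_equal(f[["G"]], 0.3)   # stops at even t1 positions
  expect_equal(f[["A"]], 0.3)
  expect_equal(f[["C"]], 0.4)
  # all stops on G
  fr <- ntDistributions(data.frame(transcript_id = "t1", stop_pos = c(0, 2)),
                        tx)$reads5p
  expect_equal(fr[["G"]], 1)
  # called-position views
  cp <- data.frame(transcript_id = c("t1", "t1", "t2"), pos = c(0L, 1L, 0L),
                   called = TRUE)
  v <- ntDistributions(reads, tx, cp)
  expect_equal(v$positionsG, c(G = 1 / 3, non_G = 2 / 3))
  expect_equal(v$positionsNonG, c(A = 0.5, C = 0.5, T = 0))
  # RTS-supporting reads: stops on called positions only
  expect_equal(sum(v$rtsReads5p), 1)
  expect_equal(v$rtsReads5p[["G"]], 1 / 3)    # read at t1 pos 0 of 3 support reads
})

test_that("Alexander-Govern matches the reference implementation", {
  # identical groups: no effect
  expect_gt(alexanderGovern(c(0.5, 0.6, 0.7), c(0.5, 0.6, 0.7))$p.value, 0.97)
  # frozen reference values (scipy.stats.alexandergovern)
  ag <- alexanderGovern(c(0.65, 0.66), c(0.35, 0.36))
  expect_equal(ag$statistic, 12.985661208852415, tolerance = 1e-10)
  expect_equal(ag$p.value, 0.00031388547482250604, tolerance = 1e-8)
  ag2 <- alexanderGovern(c(0.61, 0.63, 0.66), c(0.33, 0.35, 0.40))
  expect_equal(ag2$statistic, 11.279304412645715, tolerance = 1e-10)
  expect_equal(ag2$p.value, 0.0007837591738556823, tolerance = 1e-8)
  expect_lt(ag$p.value, 0.05)
  expect_error(alexanderGovern(c(0.5, 0.5), c(0.3, 0.4)), "zero within-group")
  expect_error(alexanderGovern(c(0.5, 0.6)), "two groups")
})

test_that("TPM quantification is normalised and length-corrected", {
  t1 <- tpmQuantify(c(a = 10, b = 10), c(a = 1000, b = 2000))$transcript
  expect_equal(unname(t1), c(2e6 / 3, 1e6 / 3), tolerance = 1e-9)
  expect_equal(sum(t1), 1e6)
  expect_equal(unname(tpmQuantify(5, 100)$transcript), 1e6)
  expect_equal(sum(tpmQuantify(c(0, 0), c(10, 10))$transcript), 0)
  g <- tpmQuantify(c(a = 10, b = 10, c = 5), c(a = 1000, b = 2000, c = 500),
                   tx2gene = c(a = "g1", b = "g1", c = "g2"))
  expect_equal(sum(g$gene), 1e6)
  expect_equal(unname(g$gene["g1"]),
               unname(g$transcript["a"] + g$transcript["b"]))
  expect_error(tpmQuantify(1, 0), "positive")
})

test_that("input guideline lookups follow the abundance bands", {
  r <- recommendInput(c(2, 5, 10, 20))
  expect_equal(r$min_input_ng, c(NA, 100, 30, 10))
  expect_equal(r$recommendation[1], "not recommended")
  # half-open boundaries
  expect_equal(recommendInput(c(4, 8, 16))$min_input_ng, c(100, 30, 10))
  expect_equal(recommendInput(3.999)$recommendation, "not recommended")
  expect_error(recommendInput(-1), "non-negative")
})

test_that("coverage-vs-TPM join matches brute-force lookup", {
  sites <- site(c("a", "a", "b", "zz"), c(10, 50, 10, 10),
                c(12, 52, 12, 12), cov = c(20, 40, 60, 5))
  tx2gene <- c(a = "g1", b = "g2")
  geneTpm <- c(g1 = 8, g2 = 32)
  j <- coverageVsTpm(sites, geneTpm, tx2gene)
  expect_equal(nrow(j), 4L)
  expect_equal(sum(j$mapped), 3L)
  expect_equal(j$gene_tpm[1:3], c(8, 8, 32))
  expect_false(j$mapped[4])
  for (i in 1:3)
    expect_equal(j$gene_tpm[i], unname(geneTpm[tx2gene[sites$transcript_id[i]]]))
})
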