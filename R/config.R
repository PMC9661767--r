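#' Simulation configuration
#'
#' Parameters of the synthetic rG4-seq library generator. Defaults encode the
#' study conditions the simulator emulates: ~250-nt RNA fragments (sd 50) from
#' heat fragmentation targeting ~300 nt; condition-dependent RT stalling at
#' planted motif 3' ends in K+ only, split 0.6/0.4 between position 0 (the
#' 3'-most G) and position +1; per-class stall probabilities 0.9 (canonical),
#' 0.7 (non-canonical), 0.4 (variant classes, which show higher
#' stochasticity, with a per-replicate jitter); a background per-position
#' stop probability of 1e-3 in both conditions; 10-nt UMIs; PCR duplication
#' with mean copies scaled by cycles over input; and a protocol-dependent
#' 5'-nucleotide acceptance bias (protocol "1.0": ~65% A starts; protocol
#' "2.0": ~35% A).
#'
#' @param seed Integer master seed; every downstream draw derives from it.
#' @param nTranscripts Number of transcripts.
#' @param lengthRange Transcript length range in nt, `c(min, max)`.
#' @param abundanceMeanlog,abundanceSdlog Log-normal parameters of true TPM.
#' @param motifPlan Named integer vector of planted motif counts per class.
#' @param motifMargin Minimum distance of a motif from transcript ends (nt).
#' @param motifSpacing Minimum gap between motifs on one transcript (nt).
#' @param fragMean,fragSd Fragment length mean/sd in nt.
#' @param thetaStop Named per-class K+ stall probabilities at the motif.
#' @param thetaJitterSd SD of per-replicate logit jitter applied to variant
#'   classes (`two_quartet`, `g_triplex`).
#' @param p0p1 Length-2 probability split of the stall between position 0 and
#'   position +1.
#' @param epsilonBg Background per-position stop probability (both
#'   conditions).
#' @param protocol `"2.0"` or `"1.0"`; selects `abiasWeights` defaults.
#' @param abiasWeights Named acceptance weights over A/C/G/T for the
#'   transcript base at the read 5' end; must sum to 1. `NULL` = protocol
#'   default.
#' @param umiLen UMI length in nt.
#' @param dupScale PCR duplication scale: mean extra copies per molecule is
#'   `dupScale * pcrCycles / inputNg`.
#' @param pcrCycles PCR cycle count.
#' @param inputNg RNA input in ng.
#' @param depth Read pairs per library.
#' @param readLen Read length in nt.
#' @param fateRates Named rates of non-usable read fates injected at the
#'   molecule level (`adapter_only`, `unalignable`, `multimapped`).
#' @param taxonomy Motif taxonomy used when generating planted motifs.
#' @return A list of class `"SimConfig"`.
#' @examples
#' cfg <- simConfig(seed = 1)
#' cfg$thetaStop
#' @export
simConfig <- function(seed = 1L,
                      nTranscripts = 30L,
                      lengthRange = c(600L, 1500L),
                      abundanceMeanlog = 1, abundanceSdlog = 1,
                      motifPlan = c(canonical = 8L, long_loop = 4L,
                                    bulge = 4L, two_quartet = 4L,
                                    g_triplex = 4L),
                      motifMargin = 80L, motifSpacing = 120L,
                      fragMean = 250, fragSd = 50,
                      thetaStop = c(canonical = 0.9, long_loop = 0.7,
                                    bulge = 0.7, two_quartet = 0.4,
                                    g_triplex = 0.4),
                      thetaJitterSd = 0.3,
                      p0p1 = c(0.6, 0.4),
                      epsilonBg = 1e-3,
                      protocol = c("2.0", "1.0"),
                      abiasWeights = NULL,
                      umiLen = 10L,
                      dupScale = 12,
                      pcrCycles = 11L,
                      inputNg = 100,
                      depth = 20000L,
                      readLen = 150L,
                      fateRates = c(adapter_only = 0.05, unalignable = 0.10,
                                    multimapped = 0.05),
                      taxonomy = classTaxonomy()) {
  protocol <- match.arg(protocol)
  if (is.null(abiasWeights)) {
    abiasWeights <- if (protocol == "1.0")
      c(A = 0.65, C = 0.35 / 3, G = 0.35 / 3, T = 0.35 / 3)
    else
      c(A = 0.35, C = 0.65 / 3, G = 0.65 / 3, T = 0.65 / 3)
  }
  stopIfNot(abs(sum(abiasWeights) - 1) < 1e-6, "abiasWeights must sum to 1")
  stopIfNot(all(thetaStop >= 0 & thetaStop <= 1), "thetaStop must be in [0,1]")
  stopIfNot(abs(sum(p0p1) - 1) < 1e-6 && all(p0p1 >= 0),
            "p0p1 must be a probability split")
  stopIfNot(epsilonBg >= 0 && epsilonBg <= 1, "epsilonBg must be in [0,1]")
  stopIfNot(depth >= 0, "depth must be non-negative")
  stopIfNot(nTranscripts > 0, "nTranscripts must be positive")
  stopIfNot(sum(fateRates) < 1, "fateRates must sum to < 1")
  structure(list(
    seed = as.integer(seed), nTranscripts = as.integer(nTranscripts),
    lengthRange = as.integer(lengthRange),
    abundanceMeanlog = abundanceMeanlog, abundanceSdlog = abundanceSdlog,
    motifPlan = motifPlan, motifMargin = as.integer(motifMargin),
    motifSpacing = as.integer(motifSpacing),
    fragMean = fragMean, fragSd = fragSd, thetaStop = thetaStop,
    thetaJitterSd = thetaJitterSd, p0p1 = p0p1, epsilonBg = epsilonBg,
    protocol = protocol, abiasWeights = abiasWeights,
    umiLen = as.integer(umiLen), dupScale = dupScale,
    pcrCycles = as.integer(pcrCycles), inputNg = inputNg,
    depth = as.integer(depth), readLen = as.integer(readLen),
    fateRates = fateRates, taxonomy = taxonomy), class = "SimConfig")
}

#' RTS-caller configuration
#'
#' @param minCov Minimum K+ read coverage at a position for it to be tested
#'   (default 16, the typical detection limit of stall-based rG4 calling).
#' @param alpha FDR level for Benjamini-Hochberg control (default 0.05).
#' @param mergeGap Maximum coordinate gap (nt) between stalled positions
#'   merged into one RTS site (default 1).
#' @param test Name of the per-position two-sample test; `"fisher"` (the
#'   one-sided exact conditional test on the 2x2 stop/read-through table) is
#'   the only built-in; alternatively a function
#'   `f(sK, nK, sLi, nLi) -> p-value` may be supplied.
#' @return A list of class `"CallerConfig"`.
#' @export
callerConfig <- function(minCov = 16L, alpha = 0.05, mergeGap = 1L,
                         test = "fisher") {
  stopIfNot(minCov >= 1, "minCov must be >= 1")
  stopIfNot(alpha > 0 && alpha < 1, "alpha must be in (0,1)")
  structure(list(minCov = as.integer(minCov), alpha = alpha,
                 mergeGap = as.integer(mergeGap), test = test),
            class = "CallerConfig")
}

#' Benchmark configuration
#'
#' @param overlapDist Two RTS sites closer than this many nt are considered
#'   overlapping (strict `<`, default 5).
#' @param saturationGrid Fractions of total depth for saturation subsampling
#'   (default 10\%..100\% in steps of 10\%).
#' @return A list of class `"BenchmarkConfig"`.
#' @export
benchmarkConfig <- function(overlapDist = 5L,
                            saturationGrid = seq(0.1, 1, by = 0.1)) {
  stopIfNot(overlapDist >= 1, "overlapDist must be >= 1")
  structure(list(overlapDist = as.integer(overlapDist),
                 saturationGrid = saturationGrid), class = "BenchmarkConfig")
}

#' Guideline: minimum RNA input by target-gene abundance
#'
#' The recommendation table linking post-enrichment parent-gene abundance to
#' the minimum post-enrichment RNA input: below 4 TPM profiling is not
#' recommended; 4-8 TPM requires at least 100 ng; 8-16 TPM at least 30 ng;
#' >= 16 TPM at least 10 ng. Interval bounds are half-open `[lo, hi)`.
#'
#' @return Data frame `tpm_lo`, `tpm_hi`, `min_input_ng` (NA = not
#'   recommended), `recommendation`.
#' @examples
#' guidelineTable()
#' @export
guidelineTable <- function() {
  data.frame(
    tpm_lo = c(0, 4, 8, 16), tpm_hi = c(4, 8, 16, Inf),
    min_input_ng = c(NA, 100, 30, 10),
    recommendation = c("not recommended", "100 ng", "30 ng", "10 ng"),
    stringsAsFactors = FALSE)
}

#' Read and write a full pipeline run configuration
#'
#' A run configuration is a single YAML document holding the seed, output
#' paths and the per-module parameter blocks (`sim`, `caller`, `benchmark`);
#' a pipeline run is reproducible from the configuration alone.
#'
#' @param path YAML file path.
#' @param config For `writeRunConfig`, a list as returned by `runConfig()`.
#' @return `readRunConfig` returns the config list with parameter blocks
#'   instantiated; `runConfig` builds one from arguments.
#' @param seed Master seed.
#' @param outDir Output directory for pipeline artifacts.
#' @param sim,caller,benchmark Module parameter lists (or NULL for defaults).
#' @param replicates Number of replicates per condition.
#' @param writeFastq Whether the pipeline writes FASTQ files.
#' @export
runConfig <- function(seed = 1L, outDir = "quadstop_run", sim = NULL,
                      caller = NULL, benchmark = NULL, replicates = 2L,
                      writeFastq = TRUE) {
  list(seed = as.integer(seed), outDir = outDir,
       replicates = as.integer(replicates), writeFastq = isTRUE(writeFastq),
       sim = sim %||% simConfig(seed = seed),
       caller = caller %||% callerConfig(),
       benchmark = benchmark %||% benchmarkConfig())
}

#' @rdname runConfig
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  seed <- y$seed %||% 1L
  simArgs <- y$sim %||% list()
  if (is.null(simArgs$seed)) simArgs$seed <- seed
  if (!is.null(simArgs$motifPlan)) simArgs$motifPlan <- unlist(simArgs$motifPlan)
  if (!is.null(simArgs$thetaStop)) simArgs$thetaStop <- unlist(simArgs$thetaStop)
  if (!is.null(simArgs$abiasWeights))
    simArgs$abiasWeights <- unlist(simArgs$abiasWeights)
  if (!is.null(simArgs$fateRates)) simArgs$fateRates <- unlist(simArgs$fateRates)
  if (!is.null(simArgs$p0p1)) simArgs$p0p1 <- unlist(simArgs$p0p1)
  if (!is.null(simArgs$lengthRange))
    simArgs$lengthRange <- unlist(simArgs$lengthRange)
  runConfig(seed = seed, outDir = y$outDir %||% "quadstop_run",
            sim = do.call(simConfig, simArgs),
            caller = do.call(callerConfig, y$caller %||% list()),
            benchmark = do.call(benchmarkConfig, y$benchmark %||% list()),
            replicates = y$replicates %||% 2L,
            writeFastq = y$writeFastq %||% TRUE)
}

#' @rdname runConfig
#' @export
writeRunConfig <- function(config, path) {
  asMap <- function(x) if (!is.null(names(x)) && length(x) > 1) as.list(x) else x
  sim <- lapply(config$sim[setdiff(names(config$sim), "taxonomy")], asMap)
  sim$lengthRange <- unname(unlist(sim$lengthRange))
  sim$p0p1 <- unname(unlist(sim$p0p1))
  ser <- list(seed = config$seed, outDir = config$outDir,
              replicates = config$replicates, writeFastq = config$writeFastq,
              sim = sim, caller = unclass(config$caller),
              benchmark = unclass(config$benchmark))
  yaml::write_yaml(ser, path, precision = 15)
  invisible(path)
}
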