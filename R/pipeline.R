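#' Run the full simulate -> preprocess -> call -> classify -> benchmark
#' pipeline
#'
#' Executes one reproducible end-to-end run from a configuration: generates
#' the ground-truthed transcriptome, simulates K+/Li+ libraries for each
#' replicate, writes FASTQ and aligned-read tables, performs yield
#' accounting and saturation analysis, calls and merges RTS sites per
#' replicate, classifies them, builds the replicate consensus and union,
#' quantifies TPM and emits a summary of site counts per class. All
#' randomness derives from the configuration seed, so two runs from the same
#' configuration produce byte-identical outputs.
#'
#' @param config A [runConfig()] (or path to a YAML run configuration).
#' @return Invisibly, a list with the main in-memory results (`tx`,
#'   `libraries`, `calls`, `consensus`, `union`, `summary`, `yield`,
#'   `saturation`, `files`).
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- readRunConfig(config)
  cfg <- config$sim
  out <- config$outDir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  logPath <- file.path(out, "run.log")
  logLines <- c(sprintf("quadstop %s", as.character(utils::packageVersion("quadstop"))),
                sprintf("R %s.%s", R.version$major, R.version$minor),
                sprintf("seed: %d", config$seed),
                sprintf("protocol: %s  inputNg: %g  depth: %d  replicates: %d",
                        cfg$protocol, cfg$inputNg, cfg$depth,
                        config$replicates),
                sprintf("caller: minCov=%d alpha=%g mergeGap=%d",
                        config$caller$minCov, config$caller$alpha,
                        config$caller$mergeGap))

  tx <- generateTranscriptome(cfg)
  writeTranscriptFasta(tx, file.path(out, "transcripts.fa"))
  writeTruthBed(tx, file.path(out, "truth_motifs.bed"))

  libraries <- list(); yieldTabs <- list(); satTabs <- list()
  for (rep in seq_len(config$replicates)) {
    for (cond in c("K", "Li")) {
      reads <- simulateLibrary(tx, cfg, cond, rep)
      tag <- sprintf("%s_rep%d", cond, rep)
      writeReadTable(reads, file.path(out, paste0("reads_", tag, ".tsv")))
      if (config$writeFastq)
        writeLibraryFastq(reads, tx, file.path(out, paste0("lib_", tag)), cfg)
      yr <- yieldReport(reads)
      yr$library <- tag
      yieldTabs[[tag]] <- yr
      if (cond == "K") {
        sat <- saturationCurve(reads, config$benchmark$saturationGrid,
                               seed = childSeed(config$seed,
                                                paste0("sat_", tag)))
        sat$library <- tag
        satTabs[[tag]] <- sat
      }
      libraries[[tag]] <- reads
    }
  }
  yield <- do.call(rbind, yieldTabs); rownames(yield) <- NULL
  saturation <- do.call(rbind, satTabs); rownames(saturation) <- NULL
  write.table(yield, file.path(out, "yield_report.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(saturation, file.path(out, "saturation.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  calls <- list()
  for (rep in seq_len(config$replicates)) {
    res <- callSites(libraries[[sprintf("K_rep%d", rep)]],
                     libraries[[sprintf("Li_rep%d", rep)]], tx, config$caller)
    res$sites <- classifySites(res$sites, tx, cfg$taxonomy)
    writeSitesBed(res$sites, file.path(out, sprintf("rts_sites_rep%d.bed", rep)))
    calls[[rep]] <- res
    logLines <- c(logLines, sprintf("replicate %d: %d positions called, %d sites",
                                    rep, sum(res$positions$called),
                                    nrow(res$sites)))
  }
  siteLists <- lapply(calls, `[[`, "sites")
  consensus <- consensusSites(siteLists, config$benchmark)
  union <- unionSites(siteLists, config$benchmark)
  writeSitesBed(consensus, file.path(out, "rts_sites_consensus.bed"))
  write.table(union, file.path(out, "rts_sites_union.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  # abundance from the rep-1 K+ library, all aligned (usable) reads
  k1 <- libraries[["K_rep1"]]
  cnt <- table(factor(k1$transcript_id[k1$fate == "usable"],
                      levels = names(txLengths(tx))))
  tpm <- tpmQuantify(setNames(as.numeric(cnt), names(cnt)), txLengths(tx),
                     tx2gene = txGeneId(tx))
  abTab <- data.frame(transcript_id = names(tpm$transcript),
                      tpm = round(unname(tpm$transcript), 4),
                      gene = unname(txGeneId(tx)))
  write.table(abTab, file.path(out, "abundance_tpm.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  groups <- c("canonical", "non-canonical", "variant", "Others")
  summary <- do.call(rbind, lapply(seq_along(siteLists), function(i) {
    tb <- table(factor(siteLists[[i]]$group, levels = groups))
    data.frame(library = sprintf("rep%d", i), group = groups,
               sites = as.integer(tb), stringsAsFactors = FALSE)
  }))
  write.table(summary, file.path(out, "summary_site_classes.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(logLines, logPath)

  invisible(list(tx = tx, libraries = libraries, calls = calls,
                 consensus = consensus, union = union, summary = summary,
                 yield = yield, saturation = saturation,
                 files = list.files(out)))
}
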