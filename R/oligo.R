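#' Oligo: a synthetic DNA oligonucleotide with deoxyuridine marks
#'
#' An S4 container for a single-stranded DNA oligo as used in dU-adapter
#' library chemistry: the base sequence (5'->3'), the 1-based positions that
#' carry deoxyuridine (dU) instead of thymidine, and the end chemistry that
#' governs ligation competence -- a 5' phosphate (required on the downstream
#' ligation partner) and an optional 3' C3-spacer block (which prevents the
#' oligo from serving as the upstream partner and thereby suppresses
#' self-oligomerisation).
#'
#' @slot name Single character identifier.
#' @slot sequence DNA string over A/C/G/T/N, written 5'->3'. dU positions are
#'   T in the base sequence; their deoxyuridine identity is carried in
#'   `duPositions`.
#' @slot duPositions Integer vector of 1-based dU positions from the 5' end.
#' @slot has5pPhosphate Logical; 5'-phosphorylated end.
#' @slot has3pBlock Logical; 3' C3 spacer present.
#'
#' @examples
#' ad <- duAdapter()
#' oligoLength(ad)
#' duPositions(ad)
#' @export
setClass("Oligo",
  representation(name = "character", sequence = "character",
                 duPositions = "integer", has5pPhosphate = "logical",
                 has3pBlock = "logical"))

setValidity("Oligo", function(object) {
  msgs <- character()
  if (length(object@sequence) != 1L) msgs <- c(msgs, "sequence must be a single string")
  s <- object@sequence
  if (length(s) == 1L && nchar(s) > 0L &&
      grepl("[^ACGTN]", s)) msgs <- c(msgs, "sequence must be over A/C/G/T/N")
  n <- nchar(s)
  dp <- object@duPositions
  if (length(dp) && (any(dp < 1L) || any(dp > n)))
    msgs <- c(msgs, "duPositions must lie in [1, length]")
  if (anyDuplicated(dp)) msgs <- c(msgs, "duplicate duPositions")
  if (length(msgs)) msgs else TRUE
})

#' Construct an Oligo
#'
#' @param sequence DNA string 5'->3' (A/C/G/T/N). Lowercase `u` characters are
#'   interpreted as deoxyuridine: they are recorded in `duPositions` and
#'   stored as `T` in the base sequence.
#' @param name Identifier.
#' @param duPositions 1-based dU positions (merged with any `u` in `sequence`).
#' @param has5pPhosphate Logical, 5' phosphate present.
#' @param has3pBlock Logical, 3' C3-spacer block present.
#' @return An [Oligo-class] object.
#' @examples
#' Oligo("ACGuACG", name = "x")  # dU at position 4
#' @export
Oligo <- function(sequence, name = "oligo", duPositions = integer(),
                  has5pPhosphate = FALSE, has3pBlock = FALSE) {
  sequence <- as.character(sequence)
  fromU <- which(strsplit(sequence, "")[[1]] == "u")
  seqUp <- toupper(chartr("u", "T", sequence))
  dp <- sort(unique(c(as.integer(duPositions), as.integer(fromU))))
  new("Oligo", name = as.character(name), sequence = seqUp,
      duPositions = dp, has5pPhosphate = isTRUE(has5pPhosphate),
      has3pBlock = isTRUE(has3pBlock))
}

#' @describeIn Oligo Length of the oligo in nucleotides.
#' @param x,object An `Oligo`.
#' @export
oligoLength <- function(x) nchar(x@sequence)

#' @describeIn Oligo 1-based dU positions.
#' @export
duPositions <- function(x) x@duPositions

#' @describeIn Oligo Base sequence with dU shown as lowercase `u`.
#' @export
oligoSequence <- function(x) {
  ch <- strsplit(x@sequence, "")[[1]]
  ch[x@duPositions] <- "u"
  paste(ch, collapse = "")
}

setMethod("show", "Oligo", function(object) {
  cat(sprintf("Oligo '%s': %d nt, %d dU (%s)%s%s\n", object@name,
              oligoLength(object), length(object@duPositions),
              paste(object@duPositions, collapse = ","),
              if (object@has5pPhosphate) ", 5'P" else "",
              if (object@has3pBlock) ", 3'C3-block" else ""))
  cat(" ", oligoSequence(object), "\n")
})

#' Cleave an oligo at its deoxyuridine positions
#'
#' Models USER II treatment: excision of uracil and backbone scission at each
#' dU. Scission is placed immediately 5' of the dU, so the dU position opens
#' each downstream fragment and fragment lengths are conserved: an oligo with
#' k dU positions yields k+1 fragments whose lengths sum to the input length.
#' A 44-nt adapter with dU at position 24 yields 23-nt and 21-nt fragments;
#' the 106-nt ligated product (dU at position 86) yields 85 nt and 21 nt.
#'
#' @param oligo An [Oligo-class] with at least one dU position.
#' @return List of fragment `Oligo`s in 5'->3' order. The 5'-phosphate flag is
#'   retained on the first fragment only; cleavage leaves downstream fragments
#'   5'-phosphorylated; the 3' block is retained on the last fragment.
#' @examples
#' frags <- cleaveAtDU(duAdapter())
#' vapply(frags, oligoLength, 1L)  # 23 21
#' @export
cleaveAtDU <- function(oligo) {
  stopifnot(is(oligo, "Oligo"))
  dp <- oligo@duPositions
  if (length(dp) == 0L)
    stop("non-cleavable substrate: oligo '", oligo@name, "' has no dU positions")
  n <- oligoLength(oligo)
  cuts <- sort(dp)                       # fragment i+1 starts at cuts[i]
  starts <- c(1L, cuts)
  ends <- c(cuts - 1L, n)
  frags <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    sq <- substr(oligo@sequence, starts[i], ends[i])
    localDU <- dp[dp >= starts[i] & dp <= ends[i]] - starts[i] + 1L
    frags[[i]] <- new("Oligo",
      name = sprintf("%s_frag%d", oligo@name, i), sequence = sq,
      duPositions = as.integer(localDU),
      has5pPhosphate = if (i == 1L) oligo@has5pPhosphate else TRUE,
      has3pBlock = if (i == length(starts)) oligo@has3pBlock else FALSE)
  }
  frags
}

#' Ligate two oligos
#'
#' Single-stranded ligation of `upstream` (providing the 3'-OH) to
#' `downstream` (which must carry a 5' phosphate). An upstream oligo with a
#' 3' C3-spacer block is ligation-incompetent. dU positions of the downstream
#' partner are shifted by the upstream length.
#'
#' @param upstream,downstream [Oligo-class] objects.
#' @return The ligated `Oligo`, length additive.
#' @examples
#' lig <- ligate(cdnaMimic(), duAdapter())
#' oligoLength(lig)   # 106
#' duPositions(lig)   # 86
#' @export
ligate <- function(upstream, downstream) {
  stopifnot(is(upstream, "Oligo"), is(downstream, "Oligo"))
  if (upstream@has3pBlock)
    stop("ligation-incompetent: upstream oligo '", upstream@name,
         "' carries a 3' C3-spacer block")
  if (!downstream@has5pPhosphate)
    stop("ligation-incompetent: downstream oligo '", downstream@name,
         "' lacks a 5' phosphate")
  off <- oligoLength(upstream)
  new("Oligo",
      name = sprintf("%s+%s", upstream@name, downstream@name),
      sequence = paste0(upstream@sequence, downstream@sequence),
      duPositions = as.integer(sort(c(upstream@duPositions,
                                      downstream@duPositions + off))),
      has5pPhosphate = upstream@has5pPhosphate,
      has3pBlock = downstream@has3pBlock)
}

# -- worked-example oligos ---------------------------------------------------

#' Worked-example oligos for the dU-adapter chemistry
#'
#' `duAdapter()` is a synthetic 44-nt single-stranded 5' adapter carrying a
#' deoxyuridine at position 24, a 5' phosphate and a 3' C3-spacer block;
#' USER II cleavage yields 23-nt and 21-nt fragments. `cdnaMimic()` is a
#' synthetic 62-nt cDNA mimic (40 randomised nt plus a 22-nt 3'-adapter
#' region). Ligating the mimic to the adapter gives the 106-nt product with
#' dU at global position 86, whose cleavage yields 85-nt and 21-nt fragments.
#' Both sequences are synthetic stand-ins generated under a fixed seed; only
#' their lengths, dU placement and end chemistry are meaningful.
#'
#' @param seed Seed for the synthetic base sequence.
#' @return An [Oligo-class].
#' @examples
#' vapply(cleaveAtDU(ligate(cdnaMimic(), duAdapter())), oligoLength, 1L)
#' @export
duAdapter <- function(seed = 4401L) {
  sq <- withSeed(seed, paste(sample(c("A", "C", "G", "T"), 44, replace = TRUE),
                             collapse = ""))
  sq <- paste0(substr(sq, 1, 23), "T", substr(sq, 25, 44))
  Oligo(sq, name = "dU_adapter_44nt", duPositions = 24L,
        has5pPhosphate = TRUE, has3pBlock = TRUE)
}

#' @rdname duAdapter
#' @export
cdnaMimic <- function(seed = 6201L) {
  sq <- withSeed(seed, paste(sample(c("A", "C", "G", "T"), 62, replace = TRUE),
                             collapse = ""))
  Oligo(sq, name = "N40p22_mimic_62nt", has5pPhosphate = FALSE,
        has3pBlock = FALSE)
}

# -- gel quantification ------------------------------------------------------

#' Gel-band quantification metrics for the dU-adapter workflow
#'
#' Computes the five densitometry-derived efficiency metrics from
#' background-corrected band intensities. Band roles: A uncleaved adapter;
#' B cleaved adapter; C template (cDNA mimic) band; D ligated product without
#' USER II; E ligated product after USER II; F/G 106-nt mimic without/with
#' column purification; H/I cleaved adapters before/after column purification.
#'
#' \deqn{cleavage = B/(A+B) \times 100}
#' \deqn{ligation = D/(C+D) \times 100}
#' \deqn{reduction = (1 - E/D) \times 100}
#' \deqn{recovery = G/F \times 100}
#' \deqn{removal  = (1 - I/H) \times 100}
#'
#' Values outside \[0, 100\] can arise from noisy densitometry (e.g. E > D);
#' they are clipped into range and flagged in the `clipped` attribute, since
#' the formulas assume ideal quantification.
#'
#' @param bands Named numeric vector or list with any of `A`..`I`, all >= 0.
#'   Only metrics whose bands are present are computed.
#' @return Named numeric vector of percentages (subset of `cleavage_rate`,
#'   `ligation_efficiency`, `reduction_rate`, `recovery_rate`,
#'   `removal_rate`) with attribute `clipped` naming any clipped metrics.
#' @examples
#' gelMetrics(c(A = 1, B = 3))        # cleavage 75%
#' gelMetrics(c(F = 100, G = 91))     # recovery 91%
#' @export
gelMetrics <- function(bands) {
  b <- as.list(bands)
  vals <- unlist(b[names(b) %in% LETTERS[1:9]])
  stopIfNot(all(vals >= 0), "band intensities must be non-negative")
  out <- c(); clipped <- character()
  metric <- function(name, num, den, eq) {
    if (den == 0) stop("undefined metric '", name, "' (", eq,
                       "): zero denominator")
    v <- num / den * 100
    if (v < 0 || v > 100) { clipped <<- c(clipped, name); v <- min(max(v, 0), 100) }
    out[[name]] <<- v
  }
  has <- function(...) all(c(...) %in% names(b))
  if (has("A", "B")) metric("cleavage_rate", b$B, b$A + b$B, "B/(A+B)")
  if (has("C", "D")) metric("ligation_efficiency", b$D, b$C + b$D, "D/(C+D)")
  if (has("D", "E")) metric("reduction_rate", b$D - b$E, b$D, "1-E/D")
  if (has("F", "G")) metric("recovery_rate", b$G, b$F, "G/F")
  if (has("H", "I")) metric("removal_rate", b$H - b$I, b$H, "1-I/H")
  res <- unlist(out)
  attr(res, "clipped") <- clipped
  res
}

# -- oligo FASTA I/O ---------------------------------------------------------

#' Read and write oligos as FASTA with lowercase-u deoxyuridine
#'
#' Oligos are exchanged as FASTA where deoxyuridine is encoded as lowercase
#' `u` in an extended alphabet; end chemistry is carried in the description
#' line as `5P` and/or `3C3` tokens. This extended alphabet is outside what
#' standard DNA FASTA readers accept, so parsing is done directly.
#'
#' @param oligos List of [Oligo-class] objects.
#' @param path File path.
#' @return `writeOligoFasta` returns `path` invisibly; `readOligoFasta`
#'   returns a list of `Oligo`s.
#' @examples
#' tf <- tempfile(fileext = ".fa")
#' writeOligoFasta(list(duAdapter()), tf)
#' readOligoFasta(tf)[[1]]
#' @export
writeOligoFasta <- function(oligos, path) {
  lines <- unlist(lapply(oligos, function(o) {
    tags <- c(if (o@has5pPhosphate) "5P", if (o@has3pBlock) "3C3")
    c(paste0(">", o@name, if (length(tags)) paste0(" ", paste(tags, collapse = " "))),
      oligoSequence(o))
  }))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeOligoFasta
#' @export
readOligoFasta <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^>", lines)
  stopIfNot(length(hdr) > 0L, "no FASTA records found")
  ends <- c(hdr[-1] - 1L, length(lines))
  lapply(seq_along(hdr), function(i) {
    h <- sub("^>", "", lines[hdr[i]])
    toks <- strsplit(h, "\\s+")[[1]]
    sq <- paste(lines[(hdr[i] + 1L):ends[i]], collapse = "")
    Oligo(sq, name = toks[1],
          has5pPhosphate = "5P" %in% toks[-1], has3pBlock = "3C3" %in% toks[-1])
  })
}
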