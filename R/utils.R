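#' @import methods
#' @importFrom stats rnorm rpois rlnorm rgeom runif lm coef cor phyper
#'   p.adjust pchisq sd setNames
#' @importFrom utils write.table read.table head
#' @importClassesFrom Biostrings DNAStringSet
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG state
#'
#' Runs `expr` with the random number generator seeded to `seed`, then
#' restores the caller's RNG state, so seeded helpers do not perturb the
#' global random stream.
#'
#' @param seed Integer seed, or `NULL` to use the current stream.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# derive a reproducible child seed below 2^31 from a base seed and a tag
childSeed <- function(seed, tag) {
  stopifnot(is.numeric(seed))
  h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  as.integer((as.numeric(seed) * 2654435.0 + h) %% 2147483629)
}

stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

# required columns of the aligned-read table shared across modules
READ_COLUMNS <- c("read_id", "transcript_id", "strand", "stop_pos", "end_pos",
                  "umi", "condition", "replicate", "input_ng", "fate",
                  "molecule_id", "is_duplicate_of")

checkReadTable <- function(reads) {
  miss <- setdiff(READ_COLUMNS, names(reads))
  stopIfNot(length(miss) == 0L,
            paste0("read table missing columns: ", paste(miss, collapse = ", ")))
  invisible(reads)
}
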