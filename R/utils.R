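DNA_BASES <- c("A", "C", "G", "T")

#' Derive a reproducible sub-stream seed from a master seed
#'
#' Each pipeline stage draws its random numbers from its own stream so that a
#' stage can be re-run in isolation and still produce the numbers it would
#' have produced inside a full run.
#'
#' @param seed master integer seed.
#' @param stage character label of the stage (e.g. `"graph"`, `"counts"`).
#' @return An integer seed in `[0, 2^31)`.
#' @export
substream_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)) * 1103L)
  as.integer((abs(seed) * 2654435761 + h) %% .Machine$integer.max)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

random_dna <- function(n, length, prob = rep(0.25, 4)) {
  vapply(seq_len(n), function(i) {
    paste(sample(DNA_BASES, length, replace = TRUE, prob = prob),
          collapse = "")
  }, character(1))
}

#' Reverse complement of DNA strings
#' @param x character vector of DNA sequences (A/C/G/T).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

seq_to_int <- function(s) {
  match(strsplit(s, "", fixed = TRUE)[[1]], DNA_BASES)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, stringsAsFactors = FALSE, ...)
}
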