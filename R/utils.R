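#' @useDynLib bchrom, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median pt rbinom rnbinom runif setNames
#' @importFrom utils read.delim write.table
NULL

DNA_ALPHABET <- c("A", "C", "G", "T", "N")

#' Reverse complement of DNA strings
#'
#' Vectorised over its input; accepts A/C/G/T/N only.
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTN", "TGCAN", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(s) paste(rev(s), collapse = ""), character(1))
}

assert_dna <- function(x, what = "sequence", allow_n = TRUE) {
  pat <- if (allow_n) "^[ACGTN]+$" else "^[ACGT]+$"
  bad <- !grepl(pat, x)
  if (any(bad))
    stop(sprintf("%s %s contains characters outside {A,C,G,T%s}",
                 what, which(bad)[1], if (allow_n) ",N" else ""), call. = FALSE)
  invisible(TRUE)
}

#' Derive a stage-specific sub-seed
#'
#' Deterministic 32-bit sub-seed from a master seed and a stage label, so
#' that independent stages of one run draw from decoupled random streams.
#'
#' @param seed master integer seed.
#' @param salt stage label (any string).
#' @return an integer seed below 2^31.
#' @export
derive_seed <- function(seed, salt) {
  h <- sum(utf8ToInt(salt) * seq_along(utf8ToInt(salt)))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483647L)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}

# Point substitutions at per-base probability p; substitute to a different base.
mutate_dna <- function(seq, p) {
  if (p <= 0) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(chars)) < p & chars != "N")
  if (length(hit)) {
    alt <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                G = c("A", "C", "T"), T = c("A", "C", "G"))
    chars[hit] <- vapply(chars[hit], function(b) sample(alt[[b]], 1), character(1))
  }
  paste(chars, collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
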