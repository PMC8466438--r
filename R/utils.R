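# shared internal helpers

DNA_ALPHABET_OK <- c("A", "C", "G", "T", "N", "-")

#' Normalize a DNA string
#'
#' Uppercases, maps U to T, and validates against the `A/C/G/T/N/-` alphabet.
#' Idempotent.
#'
#' @param x character vector of DNA strings.
#' @param what label used in error messages (e.g. the record id).
#' @return normalized character vector.
#' @keywords internal
normalize_seq <- function(x, what = "sequence") {
  x <- chartr("u", "T", toupper(x))
  x <- chartr("U", "T", x)
  bad <- vapply(strsplit(x, ""), function(ch) {
    b <- setdiff(unique(ch), DNA_ALPHABET_OK)
    if (length(b)) paste(b, collapse = ",") else ""
  }, character(1))
  if (any(nzchar(bad))) {
    i <- which(nzchar(bad))[1]
    stop("illegal character(s) [", bad[i], "] in ", what,
         if (length(what) > 1) paste0(" '", what[i], "'") else "",
         call. = FALSE)
  }
  x
}

#' Reverse complement of a DNA string
#' @param x character vector of DNA strings (A/C/G/T/N/- alphabet).
#' @return reverse complement, same length vector.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    chartr("ACGTN-", "TGCAN-", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

# run code with a temporary RNG state; NULL seed leaves the stream alone
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) stats::runif(1)
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

# character matrix (rows = sequences) from a vector of equal-length strings
seq_char_matrix <- function(seqs, ids = NULL) {
  m <- do.call(rbind, strsplit(seqs, ""))
  rownames(m) <- ids
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a
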