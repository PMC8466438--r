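#' Labeled DNA sequence records
#'
#' The basic substrate of the barcoding side of the package: a data frame
#' with columns `id`, `species`, `seq` and `source`, one row per sequence.
#' Sequences are normalized (uppercase, U mapped to T) and validated against
#' the `A/C/G/T/N/-` alphabet; ids must be non-empty and unique.
#'
#' @param id character vector of unique record identifiers.
#' @param species species labels (may be rank-free, e.g. `"Neoplerochila_sp."`).
#' @param seq DNA strings.
#' @param source free-text provenance, recycled.
#' @return a `barcode_records` data frame.
#' @export
barcode_records <- function(id, species, seq, source = "") {
  id <- as.character(id)
  if (any(!nzchar(id))) stop("empty record id", call. = FALSE)
  if (anyDuplicated(id)) {
    stop("duplicate record id(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "), call. = FALSE)
  }
  if (length(seq) != length(id)) stop("id and seq lengths differ", call. = FALSE)
  if (any(!nzchar(seq))) {
    stop("empty sequence for record(s): ",
         paste(id[!nzchar(seq)], collapse = ", "), call. = FALSE)
  }
  for (i in seq_along(seq)) seq[i] <- normalize_seq(seq[i], what = id[i])
  out <- data.frame(id = id, species = as.character(species), seq = seq,
                    source = rep_len(as.character(source), length(id)),
                    stringsAsFactors = FALSE)
  class(out) <- c("barcode_records", "data.frame")
  out
}

#' Promote records to an alignment
#'
#' All sequences must have identical length; offending ids are listed
#' otherwise.
#'
#' @param records a `barcode_records` data frame.
#' @return a `dna_alignment` (records plus the alignment contract).
#' @export
as_alignment <- function(records) {
  stopifnot(nrow(records) >= 1)
  len <- nchar(records$seq)
  if (length(unique(len)) > 1) {
    tab <- split(records$id, len)
    stop("alignment length mismatch: ",
         paste(vapply(names(tab), function(l) {
           paste0(l, " bp: ", paste(tab[[l]], collapse = ", "))
         }, character(1)), collapse = "; "), call. = FALSE)
  }
  class(records) <- unique(c("dna_alignment", class(records)))
  records
}

#' Alignment length (columns, bp)
#' @param aln a `dna_alignment`.
#' @return integer number of columns.
#' @export
aln_length <- function(aln) nchar(aln$seq[1])

#' @export
print.barcode_records <- function(x, ...) {
  cat(if (inherits(x, "dna_alignment")) "DNA alignment: " else "DNA records: ",
      nrow(x), " sequence(s)", sep = "")
  if (inherits(x, "dna_alignment")) cat(", ", aln_length(x), " columns", sep = "")
  cat("; ", length(unique(x$species)), " species label(s)\n", sep = "")
  invisible(x)
}
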