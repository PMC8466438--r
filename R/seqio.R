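#' Read a FASTA file into barcode records
#'
#' Headers are split on whitespace: the first token is the record id.  The
#' species label defaults to the remainder of the header line (so both
#' `>MZ673417 Neoplerochila_sp.` and `>id Genus species` work); a tab-separated
#' id-to-species mapping file overrides header-derived labels.
#'
#' @param path FASTA file.
#' @param species_map optional path to a two-column (id TAB species) file, or a
#'   named character vector mapping id to species.
#' @param default_species label for records without a header species or mapping
#'   entry.
#' @return a `barcode_records` data frame.
#' @export
read_fasta <- function(path, species_map = NULL, default_species = NA_character_) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) {
    out <- data.frame(id = character(), species = character(),
                      seq = character(), source = character(),
                      stringsAsFactors = FALSE)
    class(out) <- c("barcode_records", "data.frame")
    return(out)
  }
  headers <- names(set)
  if (any(!nzchar(trimws(headers)))) {
    stop("empty FASTA header at record ",
         which(!nzchar(trimws(headers)))[1], call. = FALSE)
  }
  toks <- strsplit(trimws(headers), "[ \t]+")
  id <- vapply(toks, `[`, character(1), 1)
  species <- vapply(toks, function(t) {
    if (length(t) > 1) paste(t[-1], collapse = " ") else NA_character_
  }, character(1))
  if (!is.null(species_map)) {
    map <- if (is.character(species_map) && length(species_map) == 1 &&
               file.exists(species_map)) read_species_map(species_map) else species_map
    hit <- id %in% names(map)
    species[hit] <- unname(map[id[hit]])
  }
  species[is.na(species)] <- default_species
  barcode_records(id = id, species = species,
                  seq = as.character(set), source = path)
}

#' Read a tab-separated id-to-species mapping file
#' @param path two-column TSV (id, species), no header.
#' @return named character vector (names are ids).
#' @export
read_species_map <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character", quote = "",
                           comment.char = "")
  if (ncol(tab) < 2) stop("species map needs two tab-separated columns", call. = FALSE)
  stats::setNames(tab[[2]], tab[[1]])
}

#' Write barcode records as FASTA (id and species on the header line)
#' @param records a `barcode_records` data frame.
#' @param path output file.
#' @param width line-wrap width for sequences.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    hdr <- records$id[i]
    if (!is.na(records$species[i]) && nzchar(records$species[i])) {
      hdr <- paste(hdr, gsub(" ", "_", records$species[i]))
    }
    writeLines(paste0(">", hdr), con)
    s <- records$seq[i]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Read an aligned FASTA file
#'
#' As [read_fasta()] but enforcing the alignment contract: all sequences must
#' have identical length, and the offending ids are listed otherwise.
#'
#' @inheritParams read_fasta
#' @return a `dna_alignment`.
#' @export
read_alignment <- function(path, species_map = NULL) {
  recs <- read_fasta(path, species_map = species_map)
  if (nrow(recs) == 0) stop("empty alignment file: ", path, call. = FALSE)
  as_alignment(recs)
}

# ---- annotated circular mitogenomes -------------------------------------

FEATURE_TYPES <- c("PCG", "tRNA", "rRNA", "control")

#' Construct an annotated circular mitogenome
#'
#' Coordinates are 1-based inclusive on the published (J) strand
#' representation, the GenBank convention.  A feature wrapping the circular
#' origin is stored with `end < start`.  Features are sorted by start and each
#' canonical gene name may appear at most once.
#'
#' @param seq the circular genome sequence (single DNA string).
#' @param features data frame with columns `name`, `ftype` (one of PCG, tRNA,
#'   rRNA, control), `start`, `end`, `strand` ("J" majority / "N" minority).
#' @return a `mito_annotation` list with elements `seq`, `features`,
#'   `genome_length`.
#' @export
mito_annotation <- function(seq, features) {
  seq <- normalize_seq(seq, "genome")
  stopifnot(is.data.frame(features),
            all(c("name", "ftype", "start", "end", "strand") %in% names(features)))
  if (!all(features$ftype %in% FEATURE_TYPES)) {
    stop("unknown feature type(s): ",
         paste(setdiff(features$ftype, FEATURE_TYPES), collapse = ", "),
         call. = FALSE)
  }
  if (!all(features$strand %in% c("J", "N"))) stop("strand must be J or N", call. = FALSE)
  if (anyDuplicated(features$name)) {
    stop("duplicated gene name(s): ",
         paste(unique(features$name[duplicated(features$name)]), collapse = ", "),
         call. = FALSE)
  }
  L <- nchar(seq)
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  if (any(features$start < 1 | features$start > L | features$end < 1 | features$end > L)) {
    stop("feature coordinates outside 1..", L, call. = FALSE)
  }
  features <- features[order(features$start), , drop = FALSE]
  rownames(features) <- NULL
  structure(list(seq = seq, features = features, genome_length = L),
            class = "mito_annotation")
}

#' @export
print.mito_annotation <- function(x, ...) {
  cat("Circular mitogenome: ", x$genome_length, " bp, ",
      nrow(x$features), " features (",
      paste(names(table(x$features$ftype)), table(x$features$ftype),
            sep = ":", collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Length of a feature on a circular genome (wrap-aware)
#' @param ann a `mito_annotation`.
#' @param name feature name.
#' @return length in bp.
#' @export
feature_length <- function(ann, name) {
  f <- ann$features[ann$features$name == name, ]
  if (nrow(f) != 1) stop("unknown feature: ", name, call. = FALSE)
  if (f$end >= f$start) f$end - f$start + 1 else ann$genome_length - f$start + 1 + f$end
}

#' Extract the strand-native sequence of a feature
#'
#' Features wrapping the origin are materialized by concatenating the tail and
#' head of the genome; minority (N) strand features are reverse complemented
#' so the result reads in gene orientation.
#'
#' @param ann a `mito_annotation`.
#' @param name feature name.
#' @param native if `FALSE`, return the J-strand slice without reverse
#'   complementing.
#' @return DNA string.
#' @export
feature_sequence <- function(ann, name, native = TRUE) {
  f <- ann$features[ann$features$name == name, ]
  if (nrow(f) != 1) stop("unknown feature: ", name, call. = FALSE)
  s <- if (f$end >= f$start) {
    substr(ann$seq, f$start, f$end)
  } else {
    paste0(substr(ann$seq, f$start, ann$genome_length), substr(ann$seq, 1, f$end))
  }
  if (native && f$strand == "N") revcomp(s) else s
}

# ---- GenBank flatfile ----------------------------------------------------

# map a GenBank feature key to the internal feature type
.gb_key_to_ftype <- function(key) {
  switch(key, CDS = "PCG", tRNA = "tRNA", rRNA = "rRNA",
         misc_feature = "control", D_loop = "control", `D-loop` = "control",
         NA_character_)
}

# parse "a..b", "complement(a..b)", "join(a..L,1..b)" (origin wrap) and
# complement(join(...)); returns list(start, end, strand)
.parse_gb_location <- function(loc, what = "feature") {
  strand <- "J"
  loc <- gsub("[<>]", "", gsub("[[:space:]]", "", loc))
  if (grepl("^complement\\(", loc)) {
    strand <- "N"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc)) {
    inner <- sub("^join\\((.*)\\)$", "\\1", loc)
    parts <- strsplit(inner, ",")[[1]]
    rng <- lapply(parts, function(p) as.integer(strsplit(p, "\\.\\.")[[1]]))
    return(list(start = rng[[1]][1], end = rng[[length(rng)]][2], strand = strand))
  }
  m <- regmatches(loc, regexec("^([0-9]+)\\.\\.([0-9]+)$", loc))[[1]]
  if (length(m) != 3) {
    if (grepl("^[0-9]+$", loc)) {
      return(list(start = as.integer(loc), end = as.integer(loc), strand = strand))
    }
    stop("unparseable location '", loc, "' for ", what, call. = FALSE)
  }
  list(start = as.integer(m[2]), end = as.integer(m[3]), strand = strand)
}

#' Read a GenBank flatfile into a mitogenome annotation
#'
#' Supports the subset of the flatfile grammar used by mitogenome deposits:
#' `CDS`, `tRNA`, `rRNA`, `misc_feature` and `D-loop` features with plain,
#' `complement(...)` and origin-wrapping `join(...)` locations; gene names are
#' taken from `/gene=`, then `/product=`, then `/note=` qualifiers.  Plain
#' `gene` features (duplicating CDS/tRNA/rRNA spans) are ignored.
#'
#' @param path GenBank flatfile.
#' @return a `mito_annotation`.
#' @export
read_genbank <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  ori <- grep("^ORIGIN", lines)
  if (length(ori) != 1) stop("missing (or multiple) ORIGIN section in ", path, call. = FALSE)
  endrec <- grep("^//", lines)
  endrec <- if (length(endrec)) endrec[endrec > ori][1] else length(lines) + 1
  seq <- toupper(gsub("[^A-Za-z]", "", paste(lines[(ori + 1):(endrec - 1)], collapse = "")))
  if (!nzchar(seq)) stop("empty ORIGIN sequence in ", path, call. = FALSE)

  fstart <- grep("^FEATURES", lines)
  feats <- list()
  if (length(fstart) == 1) {
    block <- lines[(fstart + 1):(ori - 1)]
    # feature lines start at column 6; qualifiers at column 22
    is_key <- grepl("^ {1,10}[A-Za-z'_-]+ +\\S", block) & !grepl("^ {12,}", block)
    idx <- which(is_key)
    for (j in seq_along(idx)) {
      first <- block[idx[j]]
      key <- sub("^ +([A-Za-z'_-]+) +.*$", "\\1", first)
      body_end <- if (j < length(idx)) idx[j + 1] - 1 else length(block)
      body <- block[idx[j]:body_end]
      ftype <- .gb_key_to_ftype(key)
      if (key == "source" || is.na(ftype)) next
      # location may continue over lines until the first qualifier
      qual_at <- grep("^ +/", body)
      loc_lines <- body[seq_len(if (length(qual_at)) qual_at[1] - 1 else length(body))]
      loc <- paste(gsub("[[:space:]]", "", sub("^ +[A-Za-z'_-]+ +", "", loc_lines[1])),
                   paste(gsub("[[:space:]]", "", loc_lines[-1]), collapse = ""), sep = "")
      qual <- function(q) {
        ln <- grep(paste0("^ +/", q, "="), body, value = TRUE)
        if (!length(ln)) return(NA_character_)
        gsub('"', "", sub(paste0("^ +/", q, "="), "", ln[1]))
      }
      name <- qual("gene")
      if (is.na(name)) name <- qual("product")
      if (is.na(name)) name <- qual("note")
      if (is.na(name)) name <- paste0(key, "_", idx[j])
      p <- .parse_gb_location(loc, what = name)
      if (ftype == "control" && grepl("AT-rich|control region|D-loop", name, ignore.case = TRUE)) {
        name <- "AT-rich"
      }
      feats[[length(feats) + 1]] <- data.frame(
        name = name, ftype = ftype, start = p$start, end = p$end,
        strand = p$strand, stringsAsFactors = FALSE)
    }
  }
  if (!length(feats)) stop("no usable features in ", path, call. = FALSE)
  mito_annotation(seq, do.call(rbind, feats))
}

#' Write a mitogenome annotation as a GenBank flatfile
#'
#' Emits the dialect [read_genbank()] consumes (LOCUS, FEATURES with
#' CDS/tRNA/rRNA/misc_feature entries, ORIGIN with 60 bases per line).
#'
#' @param ann a `mito_annotation`.
#' @param path output file.
#' @param accession accession string for the LOCUS/ACCESSION lines.
#' @param organism organism name for the source feature.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(ann, path, accession = "SYNTH0001",
                          organism = "synthetic organism") {
  L <- ann$genome_length
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("LOCUS       %s             %d bp    DNA     circular INV %s",
                     accession, L, format(Sys.Date(), "%d-%b-%Y")), con)
  writeLines(c(sprintf("DEFINITION  %s mitochondrion, complete genome.", organism),
               sprintf("ACCESSION   %s", accession),
               "FEATURES             Location/Qualifiers",
               sprintf("     source          1..%d", L),
               sprintf('                     /organism="%s"', organism)), con)
  key_of <- c(PCG = "CDS", tRNA = "tRNA", rRNA = "rRNA", control = "misc_feature")
  for (i in seq_len(nrow(ann$features))) {
    f <- ann$features[i, ]
    loc <- if (f$end >= f$start) {
      sprintf("%d..%d", f$start, f$end)
    } else {
      sprintf("join(%d..%d,1..%d)", f$start, L, f$end)
    }
    if (f$strand == "N") loc <- sprintf("complement(%s)", loc)
    writeLines(sprintf("     %-15s %s", key_of[[f$ftype]], loc), con)
    if (f$ftype == "control") {
      writeLines(sprintf('                     /note="%s"', f$name), con)
    } else {
      writeLines(sprintf('                     /gene="%s"', f$name), con)
    }
  }
  writeLines("ORIGIN", con)
  pos <- seq(1, L, by = 60)
  for (p in pos) {
    chunk <- substr(ann$seq, p, min(p + 59, L))
    tens <- seq(1, nchar(chunk), by = 10)
    writeLines(sprintf("%9d %s", p,
                       paste(tolower(substring(chunk, tens, pmin(tens + 9, nchar(chunk)))),
                             collapse = " ")), con)
  }
  writeLines("//", con)
  invisible(path)
}
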