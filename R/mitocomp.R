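# Comparative mitogenome descriptive statistics: composition and strand
# skews, start/stop codon classification under the invertebrate
# mitochondrial code, relative synonymous codon usage, gene overlap /
# intergenic spacing on the circular genome, Nei-Gojobori Ka/Ks, and tandem
# repeats in the AT-rich control region.

#' Genetic code table
#'
#' Codon-to-amino-acid map for an NCBI translation table (default 5, the
#' invertebrate mitochondrial code).  Stops are `"*"`.
#'
#' @param table NCBI translation table id as a string.
#' @return named character vector, names are DNA codons.
#' @export
mito_code <- function(table = "5") {
  Biostrings::getGeneticCode(as.character(table))
}

.split_codons <- function(cds) {
  n <- nchar(cds) %/% 3
  substring(cds, 3 * seq_len(n) - 2, 3 * seq_len(n))
}

#' Nucleotide composition and strand skews
#'
#' AT skew = (A - T)/(A + T); GC skew = (G - C)/(G + C).  A skew whose
#' denominator is zero is reported as `NA` (undefined), never as 0.
#'
#' @param seq DNA string.
#' @param label region label carried into the report row.
#' @return one-row data frame: label, length, counts of A/C/G/T/other,
#'   at_percent, gc_percent, other_percent, at_skew, gc_skew.
#' @export
composition_and_skew <- function(seq, label = "sequence") {
  if (!nzchar(seq)) stop("empty sequence for ", label, call. = FALSE)
  ch <- strsplit(toupper(seq), "")[[1]]
  n <- length(ch)
  a <- sum(ch == "A"); c_ <- sum(ch == "C"); g <- sum(ch == "G"); t <- sum(ch == "T")
  oth <- n - a - c_ - g - t
  data.frame(
    label = label, length = n, A = a, C = c_, G = g, T = t, other = oth,
    at_percent = 100 * (a + t) / n,
    gc_percent = 100 * (g + c_) / n,
    other_percent = 100 * oth / n,
    at_skew = if (a + t > 0) (a - t) / (a + t) else NA_real_,
    gc_skew = if (g + c_ > 0) (g - c_) / (g + c_) else NA_real_,
    stringsAsFactors = FALSE)
}

#' Per-feature and aggregate composition reports for a mitogenome
#'
#' One row per annotated feature plus aggregate rows: whole genome (J
#' strand), all PCGs, all tRNAs, all rRNAs and the AT-rich region.  Feature
#' rows use the strand-native sequence by default (minority-strand features
#' are reverse complemented), so A/T skews read in gene orientation; set
#' `native = FALSE` for published-strand (J) slices throughout.
#'
#' @param ann a `mito_annotation`.
#' @param native compute minority-strand features on their reverse
#'   complement (`TRUE`, default) or on the J strand.
#' @return data frame of composition rows (see [composition_and_skew()]).
#' @export
per_feature_composition <- function(ann, native = TRUE) {
  feats <- ann$features
  seqs <- vapply(feats$name, function(nm) feature_sequence(ann, nm, native = native),
                 character(1))
  rows <- lapply(seq_len(nrow(feats)), function(i) {
    composition_and_skew(seqs[i], label = feats$name[i])
  })
  agg <- function(sel, label) {
    if (!any(sel)) return(NULL)
    composition_and_skew(paste(seqs[sel], collapse = ""), label = label)
  }
  out <- rbind(composition_and_skew(ann$seq, "whole_genome"),
               agg(feats$ftype == "PCG", "all_PCG"),
               agg(feats$ftype == "tRNA", "all_tRNA"),
               agg(feats$ftype == "rRNA", "all_rRNA"),
               agg(feats$ftype == "control", "AT_rich_region"),
               do.call(rbind, rows))
  rownames(out) <- NULL
  out
}

#' Classify start and stop codons of a protein-coding gene
#'
#' The start is the first 3-mer, classed canonical (`ATN`) or alternative
#' (e.g. `GTG`).  A CDS whose length is a multiple of 3 must end in a
#' complete stop of the genetic code; length mod 3 = 2 implies the incomplete
#' stop `TA`, and mod 3 = 1 implies `T` (both completed to TAA by
#' polyadenylation).  A terminal residue inconsistent with that convention is
#' flagged as an anomaly, not silently accepted.  Internal stops are counted
#' over complete codons strictly between the start and the terminator.
#'
#' @param cds gene-native CDS string (length >= 4).
#' @param code genetic code from [mito_code()].
#' @param gene optional gene label carried into the result.
#' @return list: gene, start_codon, start_class, stop, stop_class
#'   (`"complete"`, `"TA"`, `"T"`), anomaly (character, `NA` if none),
#'   internal_stops, codon_count (complete codons including start).
#' @export
classify_start_stop <- function(cds, code = mito_code(), gene = NA_character_) {
  cds <- normalize_seq(cds, gene %||% "CDS")
  n <- nchar(cds)
  if (n < 4) stop("CDS too short (", n, " bp)", call. = FALSE)
  start <- substr(cds, 1, 3)
  start_class <- if (substr(start, 1, 2) == "AT") "ATN" else "alternative"
  stops <- names(code)[code == "*"]
  mod <- n %% 3
  anomaly <- NA_character_
  codons <- .split_codons(cds)
  if (mod == 0) {
    stop_codon <- codons[length(codons)]
    stop_class <- "complete"
    if (!stop_codon %in% stops) {
      anomaly <- paste0("final codon ", stop_codon, " is not a stop")
    }
    internal <- codons[-c(1, length(codons))]
  } else {
    stop_codon <- substr(cds, n - mod + 1, n)
    stop_class <- if (mod == 2) "TA" else "T"
    expected <- if (mod == 2) "TA" else "T"
    if (stop_codon != expected) {
      anomaly <- paste0("trailing '", stop_codon,
                        "' inconsistent with incomplete-stop convention")
    }
    internal <- codons[-1]
  }
  internal_stops <- sum(internal %in% stops)
  list(gene = gene, start_codon = start, start_class = start_class,
       stop = stop_codon, stop_class = stop_class, anomaly = anomaly,
       internal_stops = internal_stops, codon_count = length(codons))
}

#' Relative synonymous codon usage
#'
#' RSCU(c) = count(c) / mean count over c's synonymous family, with families
#' taken from the genetic code and stop codons excluded.  Codons of a family
#' never observed get `NA` (undefined), and the RSCU values of each observed
#' family sum to the family's degeneracy.
#'
#' @param cds_set character vector of CDS strings (complete codons are
#'   counted; a trailing incomplete codon is ignored; stop codons are
#'   excluded from families).
#' @param code genetic code from [mito_code()].
#' @return data frame: codon, aa, count, family_size, rscu.
#' @export
rscu <- function(cds_set, code = mito_code()) {
  codons <- unlist(lapply(cds_set, .split_codons))
  codons <- codons[codons %in% names(code)]
  if (!length(codons)) stop("no complete codons in input", call. = FALSE)
  sense <- names(code)[code != "*"]
  counts <- table(factor(codons, levels = sense))
  out <- data.frame(codon = sense, aa = unname(code[sense]),
                    count = as.integer(counts), stringsAsFactors = FALSE)
  out$family_size <- ave(rep(1L, nrow(out)), out$aa, FUN = sum)
  fam_mean <- ave(out$count, out$aa, FUN = mean)
  out$rscu <- ifelse(fam_mean > 0, out$count / fam_mean, NA_real_)
  out[order(out$aa, out$codon), ]
}

#' Gene overlaps and intergenic spacers on a circular genome
#'
#' For consecutive features (sorted by start, with the circular closure pair
#' last-to-first across the origin): overlap = max(0, prev_end - next_start
#' + 1) and spacer = max(0, next_start - prev_end - 1), in 1-based inclusive
#' terms.  A feature nested inside its predecessor still yields a
#' well-defined overlap (the inner length) with a warning.
#'
#' @param ann a `mito_annotation` with at least 2 features.
#' @return list: `pairs` (data frame: feature_a, feature_b, overlap, spacer,
#'   relation) and `totals` (n_overlaps, overlap_bp, n_spacers, spacer_bp,
#'   mean_spacer).
#' @export
spacing_and_overlaps <- function(ann) {
  feats <- ann$features
  if (nrow(feats) < 2) stop("need at least 2 features", call. = FALSE)
  L <- ann$genome_length
  # linearize: a wrap feature (end < start) extends past L
  end_lin <- ifelse(feats$end >= feats$start, feats$end, feats$end + L)
  n <- nrow(feats)
  nxt <- c(2:n, 1)
  rows <- lapply(seq_len(n), function(i) {
    j <- nxt[i]
    s_next <- if (j == 1) feats$start[j] + L else feats$start[j]
    raw <- end_lin[i] - s_next + 1
    inner_len <- end_lin[j] - feats$start[j] + 1
    if (raw > inner_len) {
      warning("feature ", feats$name[j], " nested inside ", feats$name[i])
      raw <- inner_len
    }
    overlap <- max(0L, as.integer(raw))
    spacer <- max(0L, as.integer(s_next - end_lin[i] - 1))
    data.frame(feature_a = feats$name[i], feature_b = feats$name[j],
               overlap = overlap, spacer = spacer,
               relation = if (overlap > 0) "overlapping" else
                 if (spacer > 0) "spaced" else "abutting",
               stringsAsFactors = FALSE)
  })
  pairs <- do.call(rbind, rows)
  totals <- list(
    n_overlaps = sum(pairs$overlap > 0),
    overlap_bp = sum(pairs$overlap),
    n_spacers = sum(pairs$spacer > 0),
    spacer_bp = sum(pairs$spacer),
    mean_spacer = if (any(pairs$spacer > 0))
      mean(pairs$spacer[pairs$spacer > 0]) else NA_real_)
  list(pairs = pairs, totals = totals)
}

# per-position synonymous fraction of a codon: for each of the three
# positions, the share of the three possible substitutions that preserve the
# amino acid; substitutions creating a stop count as nonsynonymous
.codon_syn_sites <- function(codon, code) {
  aa <- code[[codon]]
  bases <- c("A", "C", "G", "T")
  s <- 0
  for (pos in 1:3) {
    for (b in setdiff(bases, substr(codon, pos, pos))) {
      alt <- codon
      substr(alt, pos, pos) <- b
      if (code[[alt]] != "*" && code[[alt]] == aa) s <- s + 1 / 3
    }
  }
  s
}

# pathway-averaged synonymous/nonsynonymous difference counts for one codon
# pair; pathways passing through stop codons are excluded (all pathways are
# used when every one hits a stop)
.codon_pair_diffs <- function(c1, c2, code) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  nd <- length(pos)
  if (nd == 0) return(c(sd = 0, nd = 0))
  perms <- if (nd == 1) list(pos) else {
    p <- combinat_perms(pos)
    p
  }
  walk <- function(order) {
    cur <- c1
    sd <- 0; ndn <- 0; hit_stop <- FALSE
    for (p in order) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (code[[nxt]] == "*") hit_stop <- TRUE
      if (code[[cur]] == code[[nxt]]) sd <- sd + 1 else ndn <- ndn + 1
      cur <- nxt
    }
    c(sd, ndn, hit_stop)
  }
  res <- t(vapply(perms, walk, numeric(3)))
  ok <- res[, 3] == 0
  if (!any(ok)) ok <- rep(TRUE, nrow(res))
  c(sd = mean(res[ok, 1]), nd = mean(res[ok, 2]))
}

# all permutations of a short vector (n <= 3 here)
combinat_perms <- function(x) {
  if (length(x) == 1) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in combinat_perms(x[-i])) out[[length(out) + 1]] <- c(x[i], rest)
  }
  out
}

#' Nei-Gojobori (1986) Ka/Ks with Jukes-Cantor correction
#'
#' Synonymous site fractions are averaged over both sequences; observed
#' differences are classified by equal-weight pathway averaging for
#' multi-hit codons (pathways through stop codons excluded); proportions are
#' corrected as \eqn{d = -\frac{3}{4}\ln(1 - \frac{4p}{3})}.  Codons holding
#' a gap or N in either sequence, and codons that are stops in either
#' sequence, are dropped pairwise.
#'
#' @param cds_a,cds_b equal-length in-frame CDS strings (length multiple of
#'   3, no internal stops).
#' @param code genetic code from [mito_code()].
#' @param gene optional label.
#' @return list: gene, ka, ks, ratio (NA when Ks = 0), S_sites, N_sites,
#'   Sd, Nd, ps, pn, saturated_s, saturated_n (when saturated the
#'   uncorrected proportion is returned in ks/ka with the flag set).
#' @export
nei_gojobori_kaks <- function(cds_a, cds_b, code = mito_code(), gene = NA_character_) {
  if (nchar(cds_a) != nchar(cds_b)) stop("CDS lengths differ", call. = FALSE)
  if (nchar(cds_a) %% 3 != 0) stop("CDS length not a multiple of 3", call. = FALSE)
  ca <- .split_codons(cds_a)
  cb <- .split_codons(cds_b)
  valid <- ca %in% names(code) & cb %in% names(code) &
    code[ca] != "*" & code[cb] != "*"
  ca <- ca[valid]; cb <- cb[valid]
  if (!length(ca)) stop("no comparable codons", call. = FALSE)
  syn_tab <- vapply(unique(c(ca, cb)), .codon_syn_sites, numeric(1), code = code)
  S <- (sum(syn_tab[ca]) + sum(syn_tab[cb])) / 2
  N <- 3 * length(ca) - S
  diffs <- vapply(seq_along(ca), function(i) {
    .codon_pair_diffs(ca[i], cb[i], code)
  }, numeric(2))
  Sd <- sum(diffs["sd", ]); Nd <- sum(diffs["nd", ])
  ps <- if (S > 0) Sd / S else 0
  pn <- if (N > 0) Nd / N else 0
  jc <- function(p) if (p < 0.75) -0.75 * log(1 - 4 * p / 3) else NA_real_
  ks <- jc(ps); ka <- jc(pn)
  saturated_s <- is.na(ks); saturated_n <- is.na(ka)
  if (saturated_s) ks <- ps
  if (saturated_n) ka <- pn
  list(gene = gene, ka = ka, ks = ks,
       ratio = if (!saturated_s && !saturated_n && ks > 0) ka / ks else NA_real_,
       S_sites = S, N_sites = N, Sd = Sd, Nd = Nd, ps = ps, pn = pn,
       saturated_s = saturated_s, saturated_n = saturated_n)
}

#' Jukes-Cantor correction of a difference proportion
#' @param p proportion of differing sites (< 0.75).
#' @return corrected distance; `NA` when saturated.
#' @export
jukes_cantor <- function(p) {
  ifelse(p < 0.75, -0.75 * log(1 - 4 * p / 3), NA_real_)
}

#' Find tandem repeats by exhaustive motif scan
#'
#' Deterministic detector for tandem arrays in (control-region) sequences:
#' for every motif length and array period, adjacent copies (separated by at
#' most `max_spacer` bp) are accepted when their pairwise identity reaches
#' `min_identity`; overlapping reports are reduced to maximal arrays.
#' Arrays are ranked by identity, then coverage, then smaller motif.
#'
#' @param region DNA string (length >= 2 * `min_motif`).
#' @param min_motif,max_motif motif length range scanned, bp.
#' @param min_copies minimum copies for a reported array.
#' @param min_identity minimum pairwise identity between adjacent copies.
#' @param max_spacer maximum gap between adjacent copies, bp.
#' @return data frame (possibly empty): motif, motif_len, copies, spacer,
#'   start, span, coverage, identity.
#' @export
find_tandem_repeats <- function(region, min_motif = 20, max_motif = 300,
                                min_copies = 2, min_identity = 0.9,
                                max_spacer = 10) {
  region <- normalize_seq(region, "region")
  n <- nchar(region)
  if (n < 2 * min_motif) stop("region shorter than two minimum motifs", call. = FALSE)
  ch <- strsplit(region, "")[[1]]
  max_motif <- min(max_motif, n %/% 2)
  cand <- list()
  for (o in (min_motif):(max_motif + max_spacer)) {
    if (o + 1 > n) break
    i <- seq_len(n - o)
    mm <- as.integer(ch[i] != ch[i + o])
    cs <- cumsum(mm)
    csum <- function(a, b) cs[b] - if (a > 1) cs[a - 1] else 0  # mismatches in a..b
    for (m in seq(max(min_motif, o - max_spacer), min(max_motif, o))) {
      g <- o - m
      starts <- seq_len(max(0, n - o - m + 1))
      if (!length(starts)) next
      ident <- 1 - (cs[starts + m - 1] - c(0, cs)[starts]) / m
      hits <- starts[ident >= min_identity]
      if (!length(hits)) next
      # one anchor per contiguous run of hits: the best-identity start
      # (ties towards the left)
      run <- cumsum(c(1L, diff(hits) != 1L))
      hits <- vapply(split(seq_along(hits), run), function(ii) {
        hid <- ident[match(hits[ii], starts)]
        hits[ii][which.max(hid)]
      }, integer(1))
      for (s in hits) {
        # chain further copies at the same period
        copies <- 2
        idents <- 1 - csum(s, s + m - 1) / m
        repeat {
          w <- s + (copies - 1) * o       # start of last confirmed copy
          if (w + o + m - 1 > n) break    # next copy would not fit
          id2 <- 1 - csum(w, w + m - 1) / m
          if (id2 < min_identity) break
          idents <- c(idents, id2)
          copies <- copies + 1
        }
        span <- copies * m + (copies - 1) * g
        cand[[length(cand) + 1]] <- data.frame(
          motif = substr(region, s, s + m - 1), motif_len = m,
          copies = copies, spacer = g, start = s, span = span,
          coverage = span / n, identity = mean(idents),
          stringsAsFactors = FALSE)
      }
    }
  }
  empty <- data.frame(motif = character(), motif_len = integer(),
                      copies = integer(), spacer = integer(), start = integer(),
                      span = integer(), coverage = numeric(), identity = numeric(),
                      stringsAsFactors = FALSE)
  if (!length(cand)) return(empty)
  cand <- do.call(rbind, cand)
  cand <- cand[cand$copies >= min_copies, , drop = FALSE]
  if (!nrow(cand)) return(empty)
  ord <- order(-cand$identity, -cand$coverage, cand$motif_len,
               -cand$copies, cand$spacer, cand$start)
  cand <- cand[ord, , drop = FALSE]
  kept <- empty
  for (i in seq_len(nrow(cand))) {
    a1 <- cand$start[i]; b1 <- cand$start[i] + cand$span[i] - 1
    overlaps <- FALSE
    if (nrow(kept)) {
      a2 <- kept$start; b2 <- kept$start + kept$span - 1
      overlaps <- any(pmax(a1, a2) <= pmin(b1, b2))
    }
    if (!overlaps) kept <- rbind(kept, cand[i, ])
  }
  rownames(kept) <- NULL
  kept
}
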