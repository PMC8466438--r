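# Seeded generator for annotated circular mitogenomes with the canonical
# 37-gene arthropod arrangement and planted, fully recorded ground truth:
# start/stop codons (including alternative GTG and incomplete T/TA stops),
# gene overlaps and intergenic spacers, AT-rich-region base content and a
# tandem repeat array at its 3' end, and AT-biased codon usage.

# canonical arthropod gene order; gap_after is the distance to the next
# feature (negative = overlap), the last entry closing the circle
.default_gene_table <- function() {
  g <- function(name, ftype, strand, length, start = NA, stop = NA, gap = 0L) {
    data.frame(name = name, ftype = ftype, strand = strand, length = length,
               start_codon = start, stop_codon = stop, gap_after = gap,
               stringsAsFactors = FALSE)
  }
  rbind(
    g("tRNA-Ile", "tRNA", "J", 66, gap = 1L),
    g("tRNA-Gln", "tRNA", "N", 66, gap = -14L),
    g("tRNA-Met", "tRNA", "J", 66),
    g("ND2",      "PCG",  "J", 978, "ATT", "TAA", gap = 1L),
    g("tRNA-Trp", "tRNA", "J", 66, gap = -8L),
    g("tRNA-Cys", "tRNA", "N", 66),
    g("tRNA-Tyr", "tRNA", "N", 66, gap = 9L),
    g("COI",      "PCG",  "J", 1536, "ATG", "TAA", gap = 1L),
    g("tRNA-Leu2", "tRNA", "J", 66, gap = 2L),
    g("COII",     "PCG",  "J", 680, "ATT", "TA", gap = 1L),
    g("tRNA-Lys", "tRNA", "J", 74, gap = -1L),
    g("tRNA-Asp", "tRNA", "J", 66),
    g("ATP8",     "PCG",  "J", 156, "ATT", "TAA"),
    g("ATP6",     "PCG",  "J", 675, "ATG", "TAA"),
    g("COIII",    "PCG",  "J", 786, "ATG", "TAA"),
    g("tRNA-Gly", "tRNA", "J", 66, gap = 1L),
    g("ND3",      "PCG",  "J", 351, "GTG", "TAA"),
    g("tRNA-Ala", "tRNA", "J", 63, gap = -2L),
    g("tRNA-Arg", "tRNA", "J", 66),
    g("tRNA-Asn", "tRNA", "J", 66, gap = 1L),
    g("tRNA-Ser1", "tRNA", "J", 66),
    g("tRNA-Glu", "tRNA", "J", 66),
    g("tRNA-Phe", "tRNA", "N", 66),
    g("ND5",      "PCG",  "N", 1717, "ATG", "T"),
    g("tRNA-His", "tRNA", "N", 66),
    g("ND4",      "PCG",  "N", 1328, "ATG", "TA"),
    g("ND4L",     "PCG",  "N", 288, "ATA", "TAA", gap = -19L),
    g("tRNA-Thr", "tRNA", "J", 76, gap = 12L),
    g("tRNA-Pro", "tRNA", "N", 66),
    g("ND6",      "PCG",  "J", 492, "ATT", "TAA"),
    g("CYTB",     "PCG",  "J", 1135, "ATG", "T"),
    g("tRNA-Ser2", "tRNA", "J", 66, gap = 1L),
    g("ND1",      "PCG",  "N", 939, "ATG", "TAG"),
    g("tRNA-Leu1", "tRNA", "N", 66),
    g("16S-rRNA", "rRNA", "N", 1228),
    g("tRNA-Val", "tRNA", "N", 66, gap = 2L),
    g("12S-rRNA", "rRNA", "N", 771),
    g("AT-rich",  "control", "J", 780))
}

#' Configuration for the mitogenome generator
#'
#' The default gene table carries the canonical 37-feature arthropod
#' arrangement (23 genes on the majority J strand, 14 on the minority N
#' strand) with planted start codons (including an alternative GTG on ND3),
#' stop codons (complete TAA/TAG and incomplete TA on COII/ND4, T on
#' ND5/CYTB), five gene overlaps (longest 19 bp at ND4L/tRNA-Thr) and eleven
#' intergenic spacers totalling 32 bp.
#'
#' @param gene_table feature layout (see `barcodemito:::.default_gene_table`):
#'   columns name, ftype, strand, length, start_codon, stop_codon, gap_after
#'   (bp to the next feature; negative = overlap; the last entry closes the
#'   circle back to the first feature).
#' @param base_composition background base probabilities (tRNA/rRNA filler
#'   and the codon-bias weights derive from it).
#' @param at_rich_at A+T target fraction of the AT-rich region.
#' @param repeat_motif_len,repeat_copies,repeat_spacer tandem repeat planted
#'   at the 3' end of the AT-rich region (`repeat_copies = 0` plants none).
#' @param seed RNG seed.
#' @return a `mito_sim_config` list.
#' @export
mito_sim_config <- function(gene_table = .default_gene_table(),
                            base_composition = c(A = 0.35, C = 0.12,
                                                 G = 0.12, T = 0.41),
                            at_rich_at = 0.78,
                            repeat_motif_len = 170, repeat_copies = 2,
                            repeat_spacer = 4, seed = 1) {
  stopifnot(abs(sum(base_composition) - 1) < 1e-8,
            repeat_copies == 0 || repeat_motif_len >= 1)
  at_len <- gene_table$length[gene_table$ftype == "control"]
  if (repeat_copies > 0 && length(at_len) == 1) {
    need <- repeat_copies * repeat_motif_len +
      (repeat_copies - 1) * repeat_spacer + 12
    if (need > at_len) stop("repeat array does not fit the AT-rich region",
                            call. = FALSE)
  }
  # overlaps must not cut into a protein-coding gene laid out later
  for (i in which(gene_table$gap_after < 0)) {
    j <- if (i == nrow(gene_table)) 1 else i + 1
    if (gene_table$ftype[j] == "PCG") {
      stop("overlap into PCG ", gene_table$name[j],
           " would corrupt its coding sequence", call. = FALSE)
    }
    if (-gene_table$gap_after[i] >= gene_table$length[j]) {
      stop("overlap longer than feature ", gene_table$name[j], call. = FALSE)
    }
  }
  structure(list(gene_table = gene_table, base_composition = base_composition,
                 at_rich_at = at_rich_at, repeat_motif_len = repeat_motif_len,
                 repeat_copies = repeat_copies, repeat_spacer = repeat_spacer,
                 seed = seed),
            class = "mito_sim_config")
}

# sense codons of a code, with sampling weights from the base composition
.codon_weights <- function(code, base_composition) {
  sense <- names(code)[code != "*"]
  w <- vapply(sense, function(cod) {
    prod(base_composition[strsplit(cod, "")[[1]]])
  }, numeric(1))
  w / sum(w)
}

.build_cds <- function(start, stop, length, code, codon_w) {
  stop_len <- nchar(stop)
  n_internal <- (length - 3 - stop_len) / 3
  if (n_internal != round(n_internal) || n_internal < 1) {
    stop("PCG length ", length, " inconsistent with start '", start,
         "' and stop '", stop, "'", call. = FALSE)
  }
  internal <- sample(names(codon_w), n_internal, replace = TRUE, prob = codon_w)
  paste0(start, paste(internal, collapse = ""), stop)
}

#' Simulate an annotated mitogenome with known ground truth
#'
#' Features are laid out in the configured order honouring the planted
#' overlaps and spacers; protein-coding genes are filled with codons drawn
#' from AT-biased weights (never a stop internally) with the planted
#' start/stop codons; tRNA/rRNA filler is random under the base composition;
#' the AT-rich region carries the planted tandem repeat array, with the
#' array flanks/spacer forced to break the repeat period so the planted
#' motif length is the unique maximal exact repeat.
#'
#' @param cfg a [mito_sim_config()].
#' @return list with `annotation` (a `mito_annotation`) and `truth`: the
#'   feature table with coordinates, planted start/stop codons, overlap and
#'   spacer lists, strand gene counts, repeat geometry and AT targets.
#' @export
simulate_mitogenome <- function(cfg) {
  stopifnot(inherits(cfg, "mito_sim_config"))
  with_seed(cfg$seed, {
    gt <- cfg$gene_table
    n <- nrow(gt)
    starts <- integer(n); ends <- integer(n)
    pos <- 1L
    for (i in seq_len(n)) {
      starts[i] <- pos
      ends[i] <- pos + gt$length[i] - 1L
      pos <- ends[i] + 1L + gt$gap_after[i]
    }
    L <- ends[n] + gt$gap_after[n]
    bases <- c("A", "C", "G", "T")
    chars <- rep(NA_character_, L)
    code <- mito_code()
    codon_w <- .codon_weights(code, cfg$base_composition)
    repeat_truth <- NULL
    for (i in seq_len(n)) {
      idx <- starts[i]:ends[i]
      if (gt$ftype[i] == "PCG") {
        if (any(!is.na(chars[idx]))) {
          stop("layout writes into PCG ", gt$name[i], call. = FALSE)
        }
        cds <- .build_cds(gt$start_codon[i], gt$stop_codon[i], gt$length[i],
                          code, codon_w)
        slice <- if (gt$strand[i] == "J") cds else revcomp(cds)
        chars[idx] <- strsplit(slice, "")[[1]]
      } else if (gt$ftype[i] == "control") {
        at <- cfg$at_rich_at
        # count-exact fill: the A+T target is planted to rounding, not
        # merely in expectation
        exact_fill <- function(n, at) {
          n_at <- round(n * at)
          sample(c(sample(c("A", "T"), n_at, replace = TRUE),
                   sample(c("G", "C"), n - n_at, replace = TRUE)))
        }
        fill <- exact_fill(length(idx), at)
        if (cfg$repeat_copies >= 2) {
          m <- cfg$repeat_motif_len; g <- cfg$repeat_spacer
          k <- cfg$repeat_copies
          o <- m + g
          span <- k * m + (k - 1) * g
          s1 <- length(idx) - 10 - span + 1  # array at the 3' end
          motif <- exact_fill(m, at)
          # copies carry the motif; everything else is count-exact filler,
          # so the region total also hits the target to rounding
          fill <- character(length(idx))
          copy_pos <- unlist(lapply(seq_len(k), function(cp) {
            (s1 + (cp - 1) * o):(s1 + (cp - 1) * o + m - 1)
          }))
          fill[-copy_pos] <- exact_fill(length(idx) - length(copy_pos), at)
          for (cp in seq_len(k)) {
            fill[(s1 + (cp - 1) * o):(s1 + (cp - 1) * o + m - 1)] <- motif
          }
          # break the array period at the flank and spacers so the planted
          # motif length is the unique maximal exact repeat: for the
          # position just left of the array and every spacer position q,
          # force fill[q + o] != fill[q]
          guard <- c(if (s1 > 1) s1 - 1,
                     unlist(lapply(seq_len(k - 1), function(cp) {
                       sp <- s1 + (cp - 1) * o + m
                       if (g > 0) sp:(sp + g - 1) else integer()
                     })))
          for (q in guard) {
            if (q >= 1 && q + o <= length(idx) && fill[q] == fill[q + o]) {
              # swap within the A/T (or G/C) group so counts stay exact
              fill[q + o] <- chartr("ATGC", "TACG", fill[q + o])
            }
          }
          repeat_truth <- list(motif = paste(motif, collapse = ""),
                               motif_len = m, copies = k, spacer = g,
                               start_in_region = s1, span = span,
                               coverage = span / length(idx))
        }
        chars[idx] <- fill  # control region owns its span entirely
      } else {
        free <- idx[is.na(chars[idx])]
        chars[free] <- sample(bases, length(free), replace = TRUE,
                              prob = cfg$base_composition[bases])
      }
    }
    # spacers between features are unwritten: background filler
    gapidx <- which(is.na(chars))
    chars[gapidx] <- sample(bases, length(gapidx), replace = TRUE,
                            prob = cfg$base_composition[bases])
    feats <- data.frame(name = gt$name, ftype = gt$ftype, start = starts,
                        end = ends, strand = gt$strand, stringsAsFactors = FALSE)
    ann <- mito_annotation(paste(chars, collapse = ""), feats)
    gene_rows <- gt$ftype != "control"
    nxt <- c(2:n, 1)
    truth <- list(
      genome_length = L,
      features = cbind(gt, start = starts, end = ends),
      starts = stats::setNames(gt$start_codon[gt$ftype == "PCG"],
                               gt$name[gt$ftype == "PCG"]),
      stops = stats::setNames(gt$stop_codon[gt$ftype == "PCG"],
                              gt$name[gt$ftype == "PCG"]),
      overlaps = data.frame(feature_a = gt$name[gt$gap_after < 0],
                            feature_b = gt$name[nxt[gt$gap_after < 0]],
                            overlap = -gt$gap_after[gt$gap_after < 0],
                            stringsAsFactors = FALSE),
      spacers = data.frame(feature_a = gt$name[gt$gap_after > 0],
                           feature_b = gt$name[nxt[gt$gap_after > 0]],
                           spacer = gt$gap_after[gt$gap_after > 0],
                           stringsAsFactors = FALSE),
      strand_counts = c(J = sum(gt$strand == "J" & gene_rows),
                        N = sum(gt$strand == "N" & gene_rows)),
      at_rich_at_target = cfg$at_rich_at,
      repeat_array = repeat_truth,
      config = cfg)
    list(annotation = ann, truth = truth)
  })
}

#' Derive a related mitogenome under a planted selection regime
#'
#' Copies a simulated genome and applies, per protein-coding gene, a chosen
#' number of synonymous and nonsynonymous codon changes (never touching the
#' start codon or terminator, never creating a stop).  With
#' `n_nonsyn << n_syn` the pair shows the purifying-selection signature
#' (Ka/Ks < 1) for every gene.
#'
#' @param sim result of [simulate_mitogenome()].
#' @param n_syn synonymous changes per gene.
#' @param n_nonsyn nonsynonymous changes per gene.
#' @param seed RNG seed.
#' @return list with `annotation` and `truth` (per-gene applied changes).
#' @export
derive_mitogenome <- function(sim, n_syn = 8, n_nonsyn = 1, seed = 1) {
  ann <- sim$annotation
  code <- mito_code()
  sense <- names(code)[code != "*"]
  with_seed(seed, {
    chars <- strsplit(ann$seq, "")[[1]]
    changes <- list()
    for (nm in ann$features$name[ann$features$ftype == "PCG"]) {
      f <- ann$features[ann$features$name == nm, ]
      cds <- feature_sequence(ann, nm)
      codons <- .split_codons(cds)
      stop_len <- nchar(cds) %% 3
      editable <- 2:(length(codons) - if (stop_len == 0) 1 else 0)
      pick_change <- function(synonymous) {
        for (ci in sample(editable)) {
          cod <- codons[ci]
          alts <- sense[sense != cod &
                          vapply(sense, function(a) {
                            sum(strsplit(a, "")[[1]] != strsplit(cod, "")[[1]]) == 1
                          }, logical(1))]
          alts <- if (synonymous) alts[code[alts] == code[cod]] else
            alts[code[alts] != code[cod]]
          if (length(alts)) {
            return(c(ci, sample(alts, 1)))
          }
        }
        NULL
      }
      applied <- data.frame(codon_index = integer(), from = character(),
                            to = character(), synonymous = logical(),
                            stringsAsFactors = FALSE)
      for (kind in c(rep(TRUE, n_syn), rep(FALSE, n_nonsyn))) {
        ch <- pick_change(kind)
        if (is.null(ch)) next
        ci <- as.integer(ch[1])
        applied <- rbind(applied, data.frame(
          codon_index = ci, from = codons[ci], to = ch[2], synonymous = kind,
          stringsAsFactors = FALSE))
        codons[ci] <- ch[2]
      }
      new_cds <- paste0(paste(codons, collapse = ""),
                        if (stop_len) substr(cds, nchar(cds) - stop_len + 1,
                                             nchar(cds)) else "")
      slice <- if (f$strand == "J") new_cds else revcomp(new_cds)
      chars[f$start:f$end] <- strsplit(slice, "")[[1]]
      changes[[nm]] <- applied
    }
    list(annotation = mito_annotation(paste(chars, collapse = ""),
                                      ann$features),
         truth = list(changes = changes, base = sim$truth))
  })
}
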