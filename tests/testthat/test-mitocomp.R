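code5 <- mito_code()

test_that("composition and skews match hand counts and symmetries", {
  r <- composition_and_skew("AATGC")
  expect_equal(r$at_percent, 60)
  expect_equal(r$at_skew, 1 / 3, tolerance = 1e-12)
  expect_equal(r$gc_skew, 0)

  r2 <- composition_and_skew("ATAT")
  expect_equal(r2$at_skew, 0)
  expect_true(is.na(r2$gc_skew))     # undefined, not zero

  # reverse complement negates both skews
  set.seed(2)
  s <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  f <- composition_and_skew(s); b <- composition_and_skew(revcomp(s))
  expect_equal(b$at_skew, -f$at_skew, tolerance = 1e-12)
  expect_equal(b$gc_skew, -f$gc_skew, tolerance = 1e-12)

  # self-concatenation leaves fractions unchanged
  d <- composition_and_skew(paste0(s, s))
  expect_equal(d$at_percent, f$at_percent, tolerance = 1e-12)
  expect_equal(d$at_skew, f$at_skew, tolerance = 1e-12)

  expect_error(composition_and_skew(""), "empty")
})

test_that("per-feature composition covers features, aggregates and strand handling", {
  feats <- data.frame(name = c("g1", "g2"), ftype = c("PCG", "tRNA"),
                      start = c(1, 11), end = c(9, 16),
                      strand = c("J", "N"), stringsAsFactors = FALSE)
  ann <- mito_annotation(strrep("A", 20), feats)
  pc <- per_feature_composition(ann)
  expect_true(all(c("whole_genome", "all_PCG", "all_tRNA", "g1", "g2") %in% pc$label))
  expect_true(all(pc$at_percent == 100))
  # all-A genome: J features skew +1, N features are all-T natively -> -1
  expect_equal(pc$at_skew[pc$label == "g1"], 1)
  expect_equal(pc$at_skew[pc$label == "g2"], -1)
  expect_equal(per_feature_composition(ann, native = FALSE)$at_skew[
    pc$label == "g2"], 1)
})

test_that("start/stop classification handles complete, incomplete and anomalies", {
  r <- classify_start_stop("ATGAAATAA", code5)
  expect_equal(r$start_codon, "ATG"); expect_equal(r$start_class, "ATN")
  expect_equal(r$stop, "TAA"); expect_equal(r$stop_class, "complete")
  expect_equal(r$internal_stops, 0)
  expect_equal(r$codon_count, 3)

  r2 <- classify_start_stop("GTGAAATAG", code5)
  expect_equal(r2$start_class, "alternative")
  expect_equal(r2$stop, "TAG")

  r3 <- classify_start_stop("ATGAAAT", code5)
  expect_equal(r3$stop_class, "T")
  expect_equal(r3$codon_count, 2)
  expect_true(is.na(r3$anomaly))

  r4 <- classify_start_stop("ATGAAATA", code5)
  expect_equal(r4$stop_class, "TA")

  # trailing residue inconsistent with the convention is flagged
  r5 <- classify_start_stop("ATGAAAC", code5)
  expect_false(is.na(r5$anomaly))
  # internal stop counted
  r6 <- classify_start_stop("ATGTAAAAATAA", code5)
  expect_equal(r6$internal_stops, 1)
})

test_that("RSCU definition arithmetic and family-sum invariant hold", {
  # uniform 2-fold family -> both 1.0
  r <- rscu(c("TTTTTCTTTTTC"), code5)
  expect_equal(r$rscu[r$codon %in% c("TTT", "TTC")], c(1, 1))

  # 3:1 usage -> 1.5 / 0.5
  r2 <- rscu(c("TTTTTTTTTTTC"), code5)
  expect_equal(r2$rscu[r2$codon == "TTT"], 1.5)
  expect_equal(r2$rscu[r2$codon == "TTC"], 0.5)

  # family sums equal degeneracy on random usage tables
  set.seed(19)
  sense <- names(code5)[code5 != "*"]
  for (i in 1:10) {
    cds <- paste(sample(sense, 400, TRUE, prob = stats::runif(length(sense))),
                 collapse = "")
    r3 <- rscu(cds, code5)
    sums <- tapply(r3$rscu, r3$aa, sum)
    degen <- tapply(r3$family_size, r3$aa, unique)
    observed <- !is.na(sums)
    expect_equal(sums[observed], degen[observed], tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
})

test_that("spacing and overlaps follow 1-based inclusive interval arithmetic", {
  mkann <- function(coords, L = 60) {
    feats <- data.frame(name = paste0("f", seq_len(nrow(coords))),
                        ftype = "tRNA", start = coords[, 1], end = coords[, 2],
                        strand = "J", stringsAsFactors = FALSE)
    mito_annotation(strrep("ACGT", L / 4), feats)
  }
  sp <- spacing_and_overlaps(mkann(rbind(c(1, 10), c(8, 20))))
  row <- sp$pairs[sp$pairs$feature_a == "f1" & sp$pairs$feature_b == "f2", ]
  expect_equal(row$overlap, 3)

  sp2 <- spacing_and_overlaps(mkann(rbind(c(1, 10), c(11, 20))))
  row2 <- sp2$pairs[1, ]
  expect_equal(row2$overlap, 0); expect_equal(row2$spacer, 0)
  expect_equal(row2$relation, "abutting")

  sp3 <- spacing_and_overlaps(mkann(rbind(c(1, 10), c(13, 20))))
  expect_equal(sp3$pairs$spacer[1], 2)

  # circular closure: last feature to first across the origin
  sp4 <- spacing_and_overlaps(mkann(rbind(c(5, 10), c(40, 55))))
  closure <- sp4$pairs[sp4$pairs$feature_a == "f2", ]
  expect_equal(closure$spacer, 60 - 55 + 5 - 1)
})

test_that("spacing totals are invariant under rotation of the circular origin", {
  sim <- simulate_mitogenome(mito_sim_config(seed = 41))
  ann <- sim$annotation
  base <- spacing_and_overlaps(ann)$totals
  # rotate the origin by 1000 bp
  L <- ann$genome_length; shift <- 1000
  rot <- function(x) ((x - 1 - shift) %% L) + 1
  feats <- ann$features
  feats$start <- rot(feats$start); feats$end <- rot(feats$end)
  seq_rot <- paste0(substr(ann$seq, shift + 1, L), substr(ann$seq, 1, shift))
  rot_tot <- spacing_and_overlaps(mito_annotation(seq_rot, feats))$totals
  expect_equal(rot_tot, base)
})

test_that("NG86 agrees with the closed-form JC step and trivial cases", {
  r <- nei_gojobori_kaks("ATGAAATTT", "ATGAAATTT", code5)
  expect_equal(r$ka, 0); expect_equal(r$ks, 0); expect_true(is.na(r$ratio))
  expect_equal(jukes_cantor(0.1), 0.10732563, tolerance = 1e-7)
  expect_true(is.na(jukes_cantor(0.8)))
  expect_equal(r$S_sites + r$N_sites, 9)
})

test_that("NG86 site and difference counts match the pathway oracle", {
  sense <- names(code5)[code5 != "*"]
  set.seed(3)
  # sites: every sense codon against the independent per-codon oracle
  for (cod in sense) {
    expect_equal(barcodemito:::.codon_syn_sites(cod, code5),
                 oracle_ng_sites(cod, code5), tolerance = 1e-12, label = cod)
  }
  # differences: a random sample of codon pairs here (the acceptance suite
  # runs the full enumeration)
  pairs <- cbind(sample(sense, 300, TRUE), sample(sense, 300, TRUE))
  for (i in seq_len(nrow(pairs))) {
    got <- barcodemito:::.codon_pair_diffs(pairs[i, 1], pairs[i, 2], code5)
    want <- oracle_ng_pair(pairs[i, 1], pairs[i, 2], code5)
    expect_equal(unname(got), unname(want), tolerance = 1e-12,
                 label = paste(pairs[i, ], collapse = "-"))
  }
})

test_that("planted synonymous-only changes give Ka = 0, Ks > 0", {
  set.seed(8)
  sense <- names(code5)[code5 != "*"]
  fourfold <- sense[substr(sense, 1, 2) %in% c("GC", "GG", "CC", "CG", "AC", "GT", "TC", "CT")]
  cds <- paste(c("ATG", sample(fourfold, 300, TRUE), "TAA"), collapse = "")
  codons <- barcodemito:::.split_codons(cds)
  idx <- sample(2:301, 25)
  for (i in idx) {
    # swap the third position within the 4-fold family: always synonymous
    third <- substr(codons[i], 3, 3)
    substr(codons[i], 3, 3) <- sample(setdiff(c("A", "C", "G", "T"), third), 1)
  }
  cds2 <- paste(codons, collapse = "")
  r <- nei_gojobori_kaks(cds, cds2, code5)
  expect_equal(r$ka, 0)
  expect_gt(r$ks, 0)
  expect_equal(r$ratio, 0)
  expect_equal(r$S_sites + r$N_sites, 3 * 301)
})

test_that("tandem repeat scan: negative control, planted short and long arrays", {
  set.seed(4)
  reg <- paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = "")
  expect_equal(nrow(find_tandem_repeats(reg)), 0)

  planted <- paste0("GGCCCC", strrep("ACGT", 3), "CCCCGG")
  hit <- find_tandem_repeats(planted, min_motif = 4, max_motif = 8)
  expect_equal(hit$motif_len[1], 4)
  expect_equal(hit$copies[1], 3)
  expect_equal(hit$spacer[1], 0)

  # 170-bp motif x2 separated by 4 bp inside a 780-bp region
  sim <- simulate_mitogenome(mito_sim_config(seed = 11))
  tr <- find_tandem_repeats(feature_sequence(sim$annotation, "AT-rich"))
  expect_equal(tr$motif_len[1], 170)
  expect_equal(tr$copies[1], 2)
  expect_equal(tr$spacer[1], 4)
  expect_equal(tr$coverage[1], sim$truth$repeat_array$coverage, tolerance = 1e-9)
  expect_equal(tr$coverage[1], 0.44, tolerance = 0.01)
})
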