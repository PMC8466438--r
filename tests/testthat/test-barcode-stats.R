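test_that("dataset filtering applies rank, length and group-size rules in order", {
  recs <- barcode_records(
    id = paste0("r", 1:9),
    species = c("A_alpha", "A_alpha", "A_alpha", "B_beta", "B_beta",
                "Genus sp.", "C_gamma", "C_gamma", "C_gamma"),
    seq = c(rep(strrep("ACGTG", 104), 5),            # 520 bp: A x3, B x2
            strrep("ACGTG", 104),                    # rank-free record
            rep(strrep("ACGTG", 96), 3)))            # 480 bp: C x3
  out <- filter_barcode_dataset(recs, min_len = 500, min_per_species = 3)
  expect_equal(out$records$species, rep("A_alpha", 3))
  expect_equal(unname(out$report), c(1L, 3L, 2L))
  expect_equal(names(out$report), c("rank", "length", "group_size"))
})

test_that("neutral thresholds keep every record and order is preserved", {
  recs <- barcode_records(paste0("r", 1:4),
                          c("A sp.", "B_b", "C_c", "D_d"),
                          c("ACGT", "A-GT", "ACGT", "ACGT"))
  out <- filter_barcode_dataset(recs, min_len = 0, min_per_species = 1,
                                require_species_level = FALSE)
  expect_equal(out$records$id, recs$id)
  expect_equal(sum(out$report), 0L)
})

test_that("haplotype collapsing uses complete deletion of gap/N columns", {
  aln <- make_aln(rep(strrep("ACGT", 10), 14))
  tab <- collapse_haplotypes(aln)
  expect_equal(tab$k, 1)
  expect_equal(tab$n, 14)

  # difference at one site -> 2 haplotypes
  tab2 <- collapse_haplotypes(make_aln(c("ACGTACGT", "ACGTACGA")))
  expect_equal(tab2$k, 2)

  # gap column excluded: the only difference vanishes
  tab3 <- collapse_haplotypes(make_aln(c("ACGTACG-", "ACGTACGA")))
  expect_equal(tab3$k, 1)
  expect_equal(tab3$L_compared, 7)

  # groups 3/2/1 -> k = 3 with counts in first-occurrence order
  seqs <- c(rep("AAAA", 3), rep("AAAT", 2), "AATT")
  tab4 <- collapse_haplotypes(make_aln(seqs))
  expect_equal(tab4$k, 3)
  expect_equal(tab4$haplotypes$count, c(3L, 2L, 1L))

  expect_error(collapse_haplotypes(make_aln(c("A-", "-A"))), "no comparable sites")
})

test_that("haplotype diversity matches the frozen worked example and edge cases", {
  hd <- haplotype_diversity(c(3, 2, 1))
  expect_equal(unname(hd["H"]), 11 / 15, tolerance = 1e-12)
  expect_equal(unname(hd["H_sd"]), sqrt(117 / 4860), tolerance = 1e-12)

  expect_equal(unname(haplotype_diversity(c(1, 1))["H"]), 1)
  expect_true(all(is.na(haplotype_diversity(c(1)))))   # n < 2: undefined
  # monomorphic with n >= 2 is exactly (0, 0); the report layer prints n.a.
  expect_equal(unname(haplotype_diversity(c(14))["H"]), 0)
  expect_equal(unname(haplotype_diversity(c(14))["H_sd"]), 0)
  expect_equal(unname(haplotype_diversity(c(4, 0))["H"]), 0)
})

test_that("H equals brute-force pair discordance for all multisets n <= 8", {
  for (n in 2:8) {
    for (counts in partitions_of(n)) {
      expect_equal(unname(haplotype_diversity(counts)["H"]),
                   brute_force_H(counts), tolerance = 1e-12,
                   label = paste("counts", paste(counts, collapse = ",")))
    }
  }
})

test_that("Nei variance agrees with a multinomial bootstrap oracle", {
  set.seed(11)
  counts <- c(3, 2, 1); n <- sum(counts)
  p <- counts / n
  boot <- replicate(2e4, {
    cnt <- as.vector(stats::rmultinom(1, n, p))
    unname(haplotype_diversity(cnt[cnt > 0])["H"])
  })
  expect_equal(unname(haplotype_diversity(counts)["H_sd"]), sd(boot),
               tolerance = 0.03)
})

test_that("nucleotide diversity matches hand-enumerated pairwise differences", {
  expect_equal(unname(nucleotide_diversity(make_aln(rep("ACGTACGTAC", 4)),
                                           n_boot = 0)["pi"]), 0)
  # 2 sequences, 10 comparable sites, 2 differences
  expect_equal(unname(nucleotide_diversity(make_aln(c("ACGTACGTAC", "ACGTACGTGT")),
                                           n_boot = 0)["pi"]), 0.2)
  # 4 sequences: enumerate all 6 pairs by hand
  seqs <- c("AAAAAAAAAA", "AAAAAAAAAT", "AAAAAAAATT", "AAAAAAATTT")
  # pairwise differences: 1,2,3,1,2,1 -> mean 10/6 per 10 sites
  expect_equal(unname(nucleotide_diversity(make_aln(seqs), n_boot = 0)["pi"]),
               (10 / 6) / 10, tolerance = 1e-12)
  # pi is invariant under reordering
  expect_equal(unname(nucleotide_diversity(make_aln(rev(seqs)), n_boot = 0)["pi"]),
               (10 / 6) / 10, tolerance = 1e-12)
  # bootstrap SD is seeded and reproducible
  a <- nucleotide_diversity(make_aln(seqs), n_boot = 50, seed = 3)
  b <- nucleotide_diversity(make_aln(seqs), n_boot = 50, seed = 3)
  expect_identical(a, b)
})

test_that("segregating sites counts polymorphic compared columns", {
  expect_equal(segregating_sites(make_aln(rep("ACGT", 14))), 0)
  expect_equal(segregating_sites(make_aln(c("AAAA", "AAAA", "GAAA"))), 1)
  # gap/N columns never count
  expect_equal(segregating_sites(make_aln(c("GAA-", "AAAN", "AAAA"))), 1)
})

test_that("p-distance follows pairwise deletion and flags undefined pairs", {
  expect_equal(p_distance("ACGT", "ACGT"), 0)
  a <- paste(rep("A", 501), collapse = "")
  b <- paste(c(rep("C", 15), rep("A", 486)), collapse = "")
  expect_equal(p_distance(a, b), 15 / 501, tolerance = 1e-12)
  expect_true(is.na(p_distance("ACGT", "NNNN")))
})

test_that("K2P matches the closed form and its boundary behaviour", {
  expect_equal(k2p_from_pq(0.10, 0.05), -0.5 * log(0.75 * sqrt(0.90)),
               tolerance = 1e-12)
  expect_equal(k2p_from_pq(0.10, 0.05), 0.17018, tolerance = 1e-5)
  expect_true(is.na(k2p_from_pq(0.5, 0)))      # saturation
  expect_true(is.na(k2p_from_pq(0.2, 0.5)))
  expect_equal(k2p_distance("ACGT", "ACGT"), 0)
  # transitions vs transversions classified correctly: A->G is P, A->C is Q
  d <- k2p_distance("AAAAAAAAAA", "GAAAAAAAAC")
  expect_equal(d, k2p_from_pq(0.1, 0.1), tolerance = 1e-12)
})

test_that("K2P >= p wherever defined and converges to p as p -> 0", {
  set.seed(23)
  for (i in 1:50) {
    a <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
    nmut <- sample(0:60, 1)
    bb <- strsplit(a, "")[[1]]
    sites <- sample(300, nmut)
    bb[sites] <- vapply(bb[sites], function(x) {
      sample(setdiff(c("A", "C", "G", "T"), x), 1)
    }, character(1))
    b <- paste(bb, collapse = "")
    k <- k2p_distance(a, b); p <- p_distance(a, b)
    if (!is.na(k)) expect_gte(k + 1e-12, p)
  }
  # one difference in 1000 sites: ratio within 1% of 1
  a <- strrep("ACGT", 250)
  b <- paste0("G", substr(a, 2, 1000))
  expect_equal(k2p_distance(a, b) / p_distance(a, b), 1, tolerance = 0.01)
})

test_that("K2P matrix agrees with an independent implementation (ape)", {
  sim <- simulate_barcodes(barcode_sim_config(n_species = 3, n_per_species = 4,
                                              seed = 3))
  D <- distance_matrix(sim$records, "K2P")
  bin <- ape::as.DNAbin(strsplit(setNames(sim$records$seq, sim$records$id), ""))
  Da <- as.matrix(ape::dist.dna(bin, model = "K80"))
  expect_equal(D[rownames(Da), colnames(Da)], Da, tolerance = 1e-9,
               ignore_attr = TRUE)
  Dp <- distance_matrix(sim$records, "p")
  Dap <- as.matrix(ape::dist.dna(bin, model = "raw"))
  expect_equal(Dp[rownames(Dap), colnames(Dap)], Dap, tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("divergence summary separates species and flags planted outliers", {
  # two species, clean gap (intra divergence 1%, inter ~100%)
  seqs_a <- c(strrep("A", 100), paste0(strrep("A", 99), "T"))
  seqs_b <- c(strrep("G", 100), paste0(strrep("G", 99), "T"))
  aln <- as_alignment(barcode_records(paste0("x", 1:4),
                                      rep(c("SpA", "SpB"), each = 2),
                                      c(seqs_a, seqs_b)))
  dv <- divergence_summary(aln, model = "p")
  expect_true(all(dv$inter$barcode_gap))
  expect_false(any(dv$intra$flagged))

  # a 9%-divergent conspecific outlier trips the 3% screen
  base <- strrep("ACGT", 50)   # 200 bp
  out <- strsplit(base, "")[[1]]
  out[seq(1, 36, by = 2)] <- "T"   # ~9% of sites changed
  aln2 <- as_alignment(barcode_records(paste0("y", 1:3), "SpC",
                                       c(base, base, paste(out, collapse = ""))))
  dv2 <- divergence_summary(aln2, model = "p")
  expect_true(dv2$intra$flagged[1])
  expect_gt(dv2$intra$max[1], 0.03)
})

test_that("per-species diversity summary recovers the monomorphic pattern", {
  cfg <- barcode_sim_config(n_species = 2, n_per_species = c(14, 6),
                            intra_lambda = c(0, 2), seed = 9)
  sim <- simulate_barcodes(cfg)
  ds <- diversity_summary(sim$records, n_boot = 50, seed = 1)
  mono <- ds[ds$n == 14, ]
  expect_equal(mono$k, 1)
  expect_equal(mono$S, 0)
  expect_equal(mono$H, 0)
  expect_equal(mono$pi, 0)
})
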