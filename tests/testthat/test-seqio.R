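test_that("FASTA round-trip preserves records field by field", {
  set.seed(101)
  n <- 25
  recs <- barcode_records(
    id = sprintf("ACC%04d", seq_len(n)),
    species = sample(c("Genus_alpha", "Genus_beta", "Genus_sp."), n, TRUE),
    seq = vapply(seq_len(n), function(i) {
      paste(sample(c("A", "C", "G", "T"), sample(80:200, 1), TRUE), collapse = "")
    }, character(1)))
  f <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(recs, f, width = 60)
  back <- read_fasta(f)
  expect_equal(back$id, recs$id)
  expect_equal(back$species, recs$species)
  expect_equal(back$seq, recs$seq)
})

test_that("FASTA reader handles empty files, wrapping and normalization", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(), f)
  expect_equal(nrow(read_fasta(f)), 0)

  # one record over three wrapped lines of 60/60/30
  writeLines(c(">rec1 Some_species",
               strrep("ACGT", 15), strrep("TGCA", 15), strrep("AACC", 7), "AC"), f)
  r <- read_fasta(f)
  expect_equal(nchar(r$seq), 150)
  expect_equal(r$species, "Some_species")

  # normalization is idempotent: lowercase and U map into the alphabet
  writeLines(c(">r1 sp_x", "acguacgu"), f)
  expect_equal(read_fasta(f)$seq, "ACGTACGT")

  # illegal characters are a named error
  writeLines(c(">bad1 sp_x", "ACGTXX"), f)
  expect_error(read_fasta(f), "bad1")
})

test_that("species mapping file overrides header labels", {
  f <- withr::local_tempfile(fileext = ".fasta")
  m <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(">a hdr_species", "ACGT", ">b", "TTTT"), f)
  writeLines(c("a\tMapped species", "b\tOther species"), m)
  r <- read_fasta(f, species_map = m)
  expect_equal(r$species, c("Mapped species", "Other species"))
})

test_that("alignment contract rejects unequal lengths naming offenders", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">id500 spA", strrep("A", 500), ">id501 spA", strrep("A", 501)), f)
  expect_error(read_alignment(f), "id500")
  expect_error(read_alignment(f), "id501")

  writeLines(c(">one spA", strrep("ACG", 167)), f)
  one <- read_alignment(f)
  expect_s3_class(one, "dna_alignment")
  expect_equal(aln_length(one), 501)
})

test_that("a 3 x 501 aligned FASTA yields L = 501", {
  f <- withr::local_tempfile(fileext = ".fasta")
  set.seed(7)
  writeLines(unlist(lapply(1:3, function(i) {
    c(paste0(">t", i, " spA"),
      paste(sample(c("A", "C", "G", "T"), 501, TRUE), collapse = ""))
  })), f)
  expect_equal(aln_length(read_alignment(f)), 501)
})

test_that("GenBank locations parse strand and wrap arithmetic", {
  gb <- withr::local_tempfile(fileext = ".gb")
  writeLines(c(
    "LOCUS       TEST             220 bp    DNA     circular INV 01-JAN-2026",
    "FEATURES             Location/Qualifiers",
    "     source          1..220",
    "     CDS             1..9",
    '                     /gene="ND2"',
    "     CDS             complement(100..200)",
    '                     /gene="ND1"',
    "ORIGIN",
    paste0("        1 ", paste(rep("acgtacgtac", 6), collapse = " ")),
    paste0("       61 ", paste(rep("acgtacgtac", 6), collapse = " ")),
    paste0("      121 ", paste(rep("acgtacgtac", 6), collapse = " ")),
    paste0("      181 ", paste(rep("acgtacgtac", 4), collapse = " ")),
    "//"), gb)
  ann <- read_genbank(gb)
  expect_equal(ann$genome_length, 220)
  f1 <- ann$features[ann$features$name == "ND2", ]
  expect_equal(f1$strand, "J")
  expect_equal(f1$ftype, "PCG")
  f2 <- ann$features[ann$features$name == "ND1", ]
  expect_equal(f2$strand, "N")
  expect_equal(feature_length(ann, "ND1"), 101)
})

test_that("missing ORIGIN and unparseable locations fail loudly", {
  gb <- withr::local_tempfile(fileext = ".gb")
  writeLines(c("LOCUS       X 10 bp", "FEATURES",
               "     CDS             1..9", '                     /gene="g"'), gb)
  expect_error(read_genbank(gb), "ORIGIN")
  writeLines(c("LOCUS       X 10 bp", "FEATURES",
               "     CDS             1..x..9", '                     /gene="gX"',
               "ORIGIN", "        1 acgtacgtac", "//"), gb)
  expect_error(read_genbank(gb), "gX")
})

test_that("synthetic 37-feature flatfile round-trips against generator truth", {
  sim <- simulate_mitogenome(mito_sim_config(seed = 31))
  gb <- withr::local_tempfile(fileext = ".gb")
  write_genbank(sim$annotation, gb)
  ann <- read_genbank(gb)
  expect_identical(ann$seq, sim$annotation$seq)
  expect_identical(ann$features, sim$annotation$features)
  expect_equal(unname(table(ann$features$ftype)[c("PCG", "tRNA", "rRNA", "control")]),
               c(13L, 22L, 2L, 1L), ignore_attr = TRUE)
})

test_that("circular wrap features materialize tail + head and strand-native extraction", {
  feats <- data.frame(name = c("geneA", "geneB"),
                      ftype = c("PCG", "tRNA"),
                      start = c(18, 5), end = c(4, 10),
                      strand = c("J", "N"), stringsAsFactors = FALSE)
  ann <- mito_annotation(paste(rep(c("A", "C", "G", "T"), 5), collapse = ""), feats)
  # geneA wraps the origin: positions 18..20 then 1..4
  expect_equal(feature_length(ann, "geneA"), 7)
  expect_equal(feature_sequence(ann, "geneA"),
               paste0(substr(ann$seq, 18, 20), substr(ann$seq, 1, 4)))
  # N-strand extraction reverse complements
  expect_equal(feature_sequence(ann, "geneB"), revcomp(substr(ann$seq, 5, 10)))
  expect_equal(feature_sequence(ann, "geneB", native = FALSE), substr(ann$seq, 5, 10))
})

test_that("wrap-aware extraction length is consistent over random intervals", {
  set.seed(5)
  L <- 200
  ann0 <- paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = "")
  for (i in 1:200) {
    s <- sample(L, 1); e <- sample(L, 1)
    feats <- data.frame(name = "g", ftype = "PCG", start = s, end = e,
                        strand = "J", stringsAsFactors = FALSE)
    ann <- mito_annotation(ann0, feats)
    expect_equal(nchar(feature_sequence(ann, "g")), feature_length(ann, "g"))
    expect_equal(feature_length(ann, "g"),
                 if (e >= s) e - s + 1 else L - s + 1 + e)
  }
})
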