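# End-to-end report bundles: the per-species diversity table, pairwise
# distance and divergence tables, haplotype networks, NJ tree with bootstrap
# supports and monophyly verdicts (barcode side); composition/skew, codon
# classification, RSCU, spacing, tandem-repeat and Ka/Ks tables (mitogenome
# side).  Every run writes a machine-readable JSON manifest of its inputs,
# thresholds and seed, and is byte-reproducible from the manifest.

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

.fmt <- function(x, digits = 4) {
  ifelse(is.na(x), "n.a.", formatC(x, digits = digits, format = "f"))
}

.log_stage <- function(quiet, ...) if (!quiet) message("[barcodemito] ", ...)

#' Run the barcode analysis report
#'
#' Full chain: read, filter, collapse, diversity, distances, divergence
#' screen, per-species median-joining networks, NJ tree with bootstrap and
#' per-species monophyly.  Writes TSV tables, GML networks, a Newick tree
#' and a JSON manifest into `outdir`.  Monomorphic species print `"n.a."`
#' for H and pi, the convention of standard diversity tables.
#'
#' @param fasta path to an aligned FASTA file (or a `dna_alignment`).
#' @param outdir output directory (created if needed).
#' @param species_map optional id-to-species mapping file or named vector.
#' @param model distance model for divergence and trees, `"K2P"` or `"p"`.
#' @param min_len,min_per_species,require_species_level filtering thresholds
#'   (see [filter_barcode_dataset()]).
#' @param threshold conspecificity threshold (proportion).
#' @param reps bootstrap replicates.
#' @param seed RNG seed (bootstrap and pi SD).
#' @param outgroup_species species label to use as outgroup for rooting; its
#'   first record becomes the outgroup tip.  `NULL` skips tree/monophyly.
#' @param networks build a per-species median-joining network for each
#'   species with at least 2 haplotypes.
#' @param quiet suppress progress messages.
#' @return (invisibly) list of produced artifact paths plus the in-memory
#'   tables.
#' @export
run_barcode_report <- function(fasta, outdir, species_map = NULL,
                               model = c("K2P", "p"), min_len = 500,
                               min_per_species = 3,
                               require_species_level = TRUE,
                               threshold = 0.03, reps = 1000, seed = 1,
                               outgroup_species = NULL, networks = TRUE,
                               quiet = FALSE) {
  model <- match.arg(model)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  .log_stage(quiet, "reading input")
  recs <- if (is.character(fasta)) read_fasta(fasta, species_map = species_map)
          else fasta
  .log_stage(quiet, "filtering ", nrow(recs), " records")
  keep_og <- NULL
  ingroup <- recs
  if (!is.null(outgroup_species)) {
    hit <- which(recs$species == outgroup_species)
    if (!length(hit)) stop("no record found for outgroup species ",
                           outgroup_species, call. = FALSE)
    keep_og <- recs[hit[1], , drop = FALSE]
    ingroup <- recs[recs$species != outgroup_species, , drop = FALSE]
    class(ingroup) <- class(recs)
  }
  flt <- filter_barcode_dataset(ingroup,
                                min_len = min_len,
                                min_per_species = min_per_species,
                                require_species_level = require_species_level)
  kept <- flt$records
  if (nrow(kept) == 0) stop("filtering removed every record", call. = FALSE)
  aln <- as_alignment(kept)
  .log_stage(quiet, "diversity statistics for ",
             length(unique(aln$species)), " species")
  div <- diversity_summary(aln, seed = seed)
  div_out <- data.frame(species = div$species, n = div$n, k = div$k, S = div$S,
                        H = .fmt(ifelse(div$k == 1, NA, div$H)),
                        H_sd = .fmt(ifelse(div$k == 1, NA, div$H_sd)),
                        pi = .fmt(ifelse(div$k == 1, NA, div$pi), 6),
                        pi_sd = .fmt(ifelse(div$k == 1, NA, div$pi_sd), 6))
  paths <- list(summary = .write_tsv(div_out, file.path(outdir, "diversity_summary.tsv")))

  .log_stage(quiet, "pairwise distances (", model, ")")
  D <- distance_matrix(aln, model = model)
  lt <- which(upper.tri(D), arr.ind = TRUE)
  dist_long <- data.frame(id_1 = rownames(D)[lt[, 1]], id_2 = rownames(D)[lt[, 2]],
                          species_1 = aln$species[lt[, 1]],
                          species_2 = aln$species[lt[, 2]],
                          model = model, distance = D[lt],
                          percent = round(100 * D[lt], 4))
  paths$distances <- .write_tsv(dist_long, file.path(outdir, "pairwise_distances.tsv"))

  dv <- divergence_summary(aln, model = model, threshold = threshold)
  intra_out <- dv$intra
  intra_out$max_percent <- round(100 * intra_out$max, 4)
  intra_out$mean_percent <- round(100 * intra_out$mean, 4)
  paths$divergence_intra <- .write_tsv(intra_out, file.path(outdir, "divergence_intra.tsv"))
  if (!is.null(dv$inter)) {
    inter_out <- dv$inter
    inter_out$min_percent <- round(100 * inter_out$min, 4)
    inter_out$max_percent <- round(100 * inter_out$max, 4)
    paths$divergence_inter <- .write_tsv(inter_out, file.path(outdir, "divergence_inter.tsv"))
  }

  if (networks) {
    .log_stage(quiet, "median-joining networks")
    species_of <- stats::setNames(aln$species, aln$id)
    for (s in unique(aln$species)) {
      sub <- aln[aln$species == s, , drop = FALSE]
      class(sub) <- class(aln)
      tab <- collapse_haplotypes(sub)
      net <- annotate_network_species(median_joining(tab), tab, species_of)
      f <- file.path(outdir, paste0("network_", gsub("[^A-Za-z0-9]", "_", s), ".gml"))
      export_network(net, f, "GML")
      paths[[paste0("network_", s)]] <- f
    }
  }

  tree_path <- NULL; mono <- NULL
  if (!is.null(outgroup_species)) {
    .log_stage(quiet, "NJ tree + bootstrap (", reps, " replicates)")
    full <- rbind(kept, keep_og)
    class(full) <- class(kept)
    full_aln <- as_alignment(full)
    boot <- bootstrap_support(full_aln, reps = reps, seed = seed, model = model)
    tree_path <- file.path(outdir, "nj_tree.nwk")
    ape::write.tree(boot$tree, tree_path)
    paths$tree <- tree_path
    mono <- monophyly_report(boot, stats::setNames(full_aln$species, full_aln$id),
                             outgroup = keep_og$id)
    paths$monophyly <- .write_tsv(mono, file.path(outdir, "monophyly.tsv"))
  }

  manifest <- list(tool = "barcodemito", report = "barcode",
                   input = if (is.character(fasta)) fasta else "in-memory records",
                   thresholds = list(min_len = min_len,
                                     min_per_species = min_per_species,
                                     require_species_level = require_species_level,
                                     conspecificity_threshold = threshold),
                   model = model, bootstrap_reps = reps, seed = seed,
                   filter_report = as.list(flt$report),
                   n_records_in = nrow(recs), n_records_kept = nrow(kept),
                   outgroup_species = outgroup_species,
                   version = as.character(utils::packageVersion("barcodemito")))
  manifest_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  paths$manifest <- manifest_path
  invisible(list(paths = paths, diversity = div, divergence = dv,
                 monophyly = mono, filter_report = flt$report))
}

#' Run the comparative mitogenome report
#'
#' Per genome: composition/skew table, start/stop codon classification,
#' RSCU table, spacing/overlap report and AT-rich tandem repeats.  With two
#' or more genomes: a per-gene Ka/Ks table averaged over genome pairs and a
#' cross-genome start-codon tally.  Orthologous CDSs of unequal length are
#' codon-truncated to the common length for Ka/Ks (pre-aligned inputs are
#' compared as-is).
#'
#' @param gb_paths character vector of GenBank flatfiles (or a list of
#'   `mito_annotation` objects, named by genome).
#' @param outdir output directory.
#' @param seed recorded in the manifest (the report itself is
#'   deterministic).
#' @param quiet suppress progress messages.
#' @return (invisibly) list of artifact paths and in-memory tables.
#' @export
run_mitogenome_report <- function(gb_paths, outdir, seed = 1, quiet = FALSE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  anns <- if (is.list(gb_paths) && inherits(gb_paths[[1]], "mito_annotation")) {
    if (is.null(names(gb_paths))) names(gb_paths) <- paste0("genome_", seq_along(gb_paths))
    gb_paths
  } else {
    stats::setNames(lapply(gb_paths, read_genbank),
                    sub("\\.(gb|gbk|genbank)$", "", basename(gb_paths)))
  }
  code <- mito_code()
  paths <- list(); bundle <- list()
  for (g in names(anns)) {
    ann <- anns[[g]]
    .log_stage(quiet, "genome ", g, ": ", ann$genome_length, " bp")
    comp <- per_feature_composition(ann)
    paths[[paste0(g, "_composition")]] <-
      .write_tsv(comp, file.path(outdir, paste0(g, "_composition.tsv")))
    pcg <- ann$features$name[ann$features$ftype == "PCG"]
    cls <- do.call(rbind, lapply(pcg, function(nm) {
      r <- classify_start_stop(feature_sequence(ann, nm), code, gene = nm)
      data.frame(gene = nm, start_codon = r$start_codon,
                 start_class = r$start_class, stop = r$stop,
                 stop_class = r$stop_class,
                 anomaly = r$anomaly %||% NA_character_,
                 internal_stops = r$internal_stops,
                 codon_count = r$codon_count, stringsAsFactors = FALSE)
    }))
    paths[[paste0(g, "_codons")]] <-
      .write_tsv(cls, file.path(outdir, paste0(g, "_codon_classification.tsv")))
    ru <- rscu(vapply(pcg, function(nm) feature_sequence(ann, nm), character(1)),
               code)
    paths[[paste0(g, "_rscu")]] <-
      .write_tsv(ru, file.path(outdir, paste0(g, "_rscu.tsv")))
    sp <- spacing_and_overlaps(ann)
    paths[[paste0(g, "_spacing")]] <-
      .write_tsv(sp$pairs, file.path(outdir, paste0(g, "_spacing.tsv")))
    reps <- NULL
    ctrl <- ann$features$name[ann$features$ftype == "control"]
    if (length(ctrl) == 1) {
      reps <- find_tandem_repeats(feature_sequence(ann, ctrl))
      paths[[paste0(g, "_repeats")]] <-
        .write_tsv(reps, file.path(outdir, paste0(g, "_tandem_repeats.tsv")))
    }
    bundle[[g]] <- list(genome_length = ann$genome_length,
                        composition = comp, codon_classification = cls,
                        rscu = ru, spacing_totals = sp$totals,
                        tandem_repeats = reps)
  }
  # cross-genome tables
  kaks_tab <- NULL
  start_tally <- NULL
  if (length(anns) >= 2) {
    .log_stage(quiet, "cross-genome Ka/Ks over ", length(anns), " genomes")
    genes <- Reduce(intersect, lapply(anns, function(a) {
      a$features$name[a$features$ftype == "PCG"]
    }))
    kaks_tab <- do.call(rbind, lapply(genes, function(nm) {
      vals <- list()
      cmb <- utils::combn(names(anns), 2)
      for (cc in seq_len(ncol(cmb))) {
        c1 <- feature_sequence(anns[[cmb[1, cc]]], nm)
        c2 <- feature_sequence(anns[[cmb[2, cc]]], nm)
        len <- min(nchar(c1), nchar(c2)) %/% 3 * 3
        r <- nei_gojobori_kaks(substr(c1, 1, len), substr(c2, 1, len), code,
                               gene = nm)
        vals[[cc]] <- c(ka = r$ka, ks = r$ks,
                        ratio = if (is.na(r$ratio)) NA else r$ratio)
      }
      m <- do.call(rbind, vals)
      data.frame(gene = nm, n_pairs = nrow(m),
                 mean_ka = mean(m[, "ka"], na.rm = TRUE),
                 mean_ks = mean(m[, "ks"], na.rm = TRUE),
                 mean_kaks = mean(m[, "ratio"], na.rm = TRUE),
                 stringsAsFactors = FALSE)
    }))
    paths$kaks <- .write_tsv(kaks_tab, file.path(outdir, "kaks_per_gene.tsv"))
    start_tally <- do.call(rbind, lapply(names(anns), function(g) {
      cls <- bundle[[g]]$codon_classification
      data.frame(genome = g, gene = cls$gene, start_codon = cls$start_codon,
                 stringsAsFactors = FALSE)
    }))
    paths$start_codons <- .write_tsv(start_tally,
                                     file.path(outdir, "start_codon_tally.tsv"))
  } else {
    .log_stage(quiet, "Ka/Ks table skipped: needs at least 2 genomes")
  }
  manifest <- list(tool = "barcodemito", report = "mitogenome",
                   inputs = if (is.list(gb_paths) &&
                                inherits(gb_paths[[1]], "mito_annotation"))
                     names(anns) else unname(gb_paths),
                   n_genomes = length(anns), seed = seed,
                   kaks = if (length(anns) >= 2) "computed" else
                     "skipped: needs at least 2 genomes",
                   version = as.character(utils::packageVersion("barcodemito")))
  manifest_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  paths$manifest <- manifest_path
  jsonlite::write_json(bundle, file.path(outdir, "bundle.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  paths$bundle <- file.path(outdir, "bundle.json")
  invisible(list(paths = paths, bundle = bundle, kaks = kaks_tab,
                 start_codons = start_tally))
}
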