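# Seeded generator for multi-species barcode datasets with a planted
# intra/inter-specific divergence gap and transition/transversion bias.
#
# Model: a root sequence drawn from the base composition; species ancestors
# placed on a star phylogeny at exactly `inter_div` substituted sites from
# the root; individuals mutated from their ancestor with a Poisson number of
# substitutions.  Substitutions choose a transition with probability
# kappa/(kappa + 2), otherwise one of the two transversions.  No indels, so
# the sequences are trivially aligned.

#' Configuration for the barcode dataset generator
#'
#' @param n_species number of species.
#' @param n_per_species individuals per species (scalar or vector).
#' @param L alignment length in bp.
#' @param inter_div substitutions between the root and each species ancestor.
#' @param intra_lambda expected substitutions per individual from its
#'   ancestor (Poisson mean; 0 gives monomorphic species); scalar or one
#'   value per species.
#' @param kappa transition/transversion weight; a transition is chosen with
#'   probability kappa/(kappa + 2).
#' @param base_composition named probabilities for A, C, G, T.
#' @param species_names optional species labels.
#' @param outgroup_div if non-`NULL`, one extra "outgroup" record is placed
#'   at this many substitutions from the root.
#' @param seed RNG seed; the generator is a pure function of (config, seed).
#' @return a `barcode_sim_config` list.
#' @export
barcode_sim_config <- function(n_species = 3, n_per_species = 10, L = 501,
                               inter_div = 40, intra_lambda = 2, kappa = 4,
                               base_composition = c(A = 0.35, C = 0.12,
                                                    G = 0.12, T = 0.41),
                               species_names = NULL, outgroup_div = NULL,
                               seed = 1) {
  stopifnot(n_species >= 1, L >= 1, inter_div >= 0, intra_lambda >= 0,
            kappa > 0, abs(sum(base_composition) - 1) < 1e-8)
  n_per_species <- rep_len(n_per_species, n_species)
  intra_lambda <- rep_len(intra_lambda, n_species)
  if (is.null(species_names)) {
    species_names <- sprintf("Species_%02d", seq_len(n_species))
  }
  structure(list(n_species = n_species, n_per_species = n_per_species, L = L,
                 inter_div = inter_div, intra_lambda = intra_lambda,
                 kappa = kappa, base_composition = base_composition,
                 species_names = species_names, outgroup_div = outgroup_div,
                 seed = seed),
            class = "barcode_sim_config")
}

.TS_PARTNER <- c(A = "G", G = "A", C = "T", T = "C")

# mutate `k` distinct positions of a sequence under the kappa kernel
.mutate_sites <- function(chars, k, kappa) {
  if (k == 0) return(list(chars = chars, sites = integer(), to = character()))
  sites <- sort(sample.int(length(chars), min(k, length(chars))))
  to <- vapply(sites, function(s) {
    base <- chars[s]
    if (stats::runif(1) < kappa / (kappa + 2)) {
      .TS_PARTNER[[base]]
    } else {
      sample(setdiff(c("A", "C", "G", "T"), c(base, .TS_PARTNER[[base]])), 1)
    }
  }, character(1))
  chars[sites] <- to
  list(chars = chars, sites = sites, to = to)
}

#' Simulate a barcode dataset with known ground truth
#'
#' @param cfg a [barcode_sim_config()].
#' @return list with `records` (a `barcode_records` data frame whose
#'   sequences are aligned by construction) and `truth`: root and ancestor
#'   sequences, per-individual mutation lists, the haplotype partition per
#'   species, the per-species segregating-site counts, and the config.
#' @export
simulate_barcodes <- function(cfg) {
  stopifnot(inherits(cfg, "barcode_sim_config"))
  with_seed(cfg$seed, {
    bases <- c("A", "C", "G", "T")
    root <- sample(bases, cfg$L, replace = TRUE,
                   prob = cfg$base_composition[bases])
    ids <- character(); species <- character(); seqs <- character()
    ancestors <- list(); mutations <- list()
    for (s in seq_len(cfg$n_species)) {
      anc <- .mutate_sites(root, cfg$inter_div, cfg$kappa)
      ancestors[[cfg$species_names[s]]] <- paste(anc$chars, collapse = "")
      for (i in seq_len(cfg$n_per_species[s])) {
        nmut <- stats::rpois(1, cfg$intra_lambda[s])
        ind <- .mutate_sites(anc$chars, nmut, cfg$kappa)
        id <- sprintf("%s_%02d", gsub("[^A-Za-z0-9]", "", cfg$species_names[s]), i)
        ids <- c(ids, id); species <- c(species, cfg$species_names[s])
        seqs <- c(seqs, paste(ind$chars, collapse = ""))
        mutations[[id]] <- data.frame(site = ind$sites, to = ind$to,
                                      stringsAsFactors = FALSE)
      }
    }
    if (!is.null(cfg$outgroup_div)) {
      og <- .mutate_sites(root, cfg$outgroup_div, cfg$kappa)
      ids <- c(ids, "OUTGROUP_01"); species <- c(species, "Outgroup")
      seqs <- c(seqs, paste(og$chars, collapse = ""))
    }
    records <- as_alignment(barcode_records(ids, species, seqs,
                                            source = "simulate_barcodes"))
    # ground truth computed directly from the emitted sequences
    partition <- lapply(split(seq_along(ids), species), function(idx) {
      unname(split(ids[idx], match(seqs[idx], unique(seqs[idx]))))
    })
    seg <- vapply(split(seqs, species), function(ss) {
      m <- seq_char_matrix(ss)
      sum(apply(m, 2, function(col) length(unique(col))) >= 2)
    }, integer(1))
    list(records = records,
         truth = list(root = paste(root, collapse = ""), ancestors = ancestors,
                      mutations = mutations, haplotype_partition = partition,
                      segregating_sites = seg, config = cfg))
  })
}
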