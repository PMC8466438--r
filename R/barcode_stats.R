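# Barcode dataset filtering and diversity / divergence statistics.
#
# Conventions: haplotype collapsing, segregating sites and nucleotide
# diversity use complete deletion (columns holding a gap or N in any sequence
# are dropped); pairwise distances use pairwise deletion.  Distances are
# proportions internally; percentages only appear at report boundaries.

#' Filter a barcode dataset by identification rank, length and group size
#'
#' Rules are applied in order: (1) drop records whose species label is not at
#' species level (matches `rank_pattern`, e.g. "sp.", "cf."), (2) drop records
#' whose ungapped length is below `min_len`, (3) drop whole species with fewer
#' than `min_per_species` surviving records.  Input order is preserved.
#'
#' @param records a `barcode_records` data frame.
#' @param min_len minimum ungapped length in bp.
#' @param min_per_species minimum records per species after the other rules.
#' @param require_species_level reject rank-free labels when `TRUE`.
#' @param rank_pattern regex identifying rank-free labels.
#' @return list with `records` (the survivors) and `report` (named counts of
#'   records removed per rule: `rank`, `length`, `group_size`).
#' @export
filter_barcode_dataset <- function(records, min_len = 500, min_per_species = 3,
                                   require_species_level = TRUE,
                                   rank_pattern = "(^|[ _])(sp|cf|aff)\\.?([ _]|$)") {
  report <- c(rank = 0L, length = 0L, group_size = 0L)
  keep <- rep(TRUE, nrow(records))
  if (require_species_level) {
    bad <- grepl(rank_pattern, records$species) | is.na(records$species)
    report["rank"] <- sum(bad & keep)
    keep <- keep & !bad
  }
  ungapped <- nchar(gsub("-", "", records$seq))
  bad <- ungapped < min_len
  report["length"] <- sum(bad & keep)
  keep <- keep & !bad
  counts <- table(records$species[keep])
  small <- names(counts)[counts < min_per_species]
  bad <- records$species %in% small
  report["group_size"] <- sum(bad & keep)
  keep <- keep & !bad
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(records)
  list(records = out, report = report)
}

# indices of columns free of gaps and Ns in every sequence
.complete_columns <- function(aln) {
  m <- seq_char_matrix(aln$seq, aln$id)
  ok <- colSums(m == "-" | m == "N") == 0
  list(matrix = m, sites = which(ok))
}

#' Collapse aligned sequences into haplotypes
#'
#' Sequences identical at all compared columns share a haplotype.  Columns
#' containing any gap or N in any sequence are excluded from comparison
#' (complete deletion).
#'
#' @param aln a `dna_alignment`.
#' @return a `haplotype_table`: list with `haplotypes` (data frame: name,
#'   seq over compared sites, count), `members` (list of id vectors), `n`,
#'   `k`, `sites` (compared column indices) and `L_compared`.
#' @export
collapse_haplotypes <- function(aln) {
  stopifnot(nrow(aln) >= 1)
  cc <- .complete_columns(aln)
  if (length(cc$sites) == 0) stop("no comparable sites (every column holds a gap or N)",
                                  call. = FALSE)
  key <- apply(cc$matrix[, cc$sites, drop = FALSE], 1, paste, collapse = "")
  first <- !duplicated(key)
  uniq <- key[first]
  grp <- match(key, uniq)
  members <- split(aln$id, grp)
  names(members) <- paste0("H", seq_along(uniq))
  structure(list(
    haplotypes = data.frame(name = names(members), seq = uniq,
                            count = as.integer(lengths(members)),
                            stringsAsFactors = FALSE),
    members = members,
    n = nrow(aln), k = length(uniq),
    sites = cc$sites, L_compared = length(cc$sites)),
    class = "haplotype_table")
}

#' @export
print.haplotype_table <- function(x, ...) {
  cat("Haplotype table: n = ", x$n, ", k = ", x$k,
      ", compared sites = ", x$L_compared, "\n", sep = "")
  invisible(x)
}

#' Haplotype diversity with Nei's sampling variance
#'
#' \eqn{H = n(1 - \sum p_i^2)/(n - 1)}; the standard deviation is the square
#' root of Nei's (1987) variance estimator.  Undefined (`NA`) for `n < 2`;
#' a monomorphic sample gives exactly (0, 0).
#'
#' @param tab a `haplotype_table`, or an integer vector of haplotype counts.
#' @return named numeric `c(H =, H_sd =)`; both `NA` when undefined.
#' @export
haplotype_diversity <- function(tab) {
  counts <- if (inherits(tab, "haplotype_table")) tab$haplotypes$count else as.integer(tab)
  n <- sum(counts)
  if (n < 2) return(c(H = NA_real_, H_sd = NA_real_))
  p <- counts / n
  s2 <- sum(p^2); s3 <- sum(p^3)
  H <- n * (1 - s2) / (n - 1)
  V <- 2 / (n * (n - 1)) * (2 * (n - 2) * (s3 - s2^2) + s2 - s2^2)
  c(H = H, H_sd = sqrt(max(V, 0)))
}

# mean pairwise differences per compared site (complete deletion), plus the
# per-pair machinery shared with the bootstrap
.pi_point <- function(m, sites) {
  n <- nrow(m)
  sub <- m[, sites, drop = FALSE]
  npairs <- choose(n, 2)
  # per column: number of discordant pairs = C(n,2) - sum_b C(n_b,2);
  # complete deletion guarantees only A/C/G/T states remain
  cnt <- vapply(c("A", "C", "G", "T"),
                function(b) colSums(sub == b), numeric(ncol(sub)))
  if (is.null(dim(cnt))) cnt <- matrix(cnt, nrow = 1)
  disc <- npairs - rowSums(choose(cnt, 2))
  sum(disc) / npairs / length(sites)
}

#' Nucleotide diversity with a bootstrap standard deviation
#'
#' \eqn{\pi} is the mean proportion of differing sites over all sequence
#' pairs, computed on gap/N-free columns (complete deletion).  The standard
#' deviation comes from a seeded nonparametric bootstrap over sequences.
#'
#' @param aln a `dna_alignment` with at least 2 sequences.
#' @param n_boot bootstrap replicates for the SD (0 skips it).
#' @param seed RNG seed for the bootstrap.
#' @return named numeric `c(pi =, pi_sd =)`.
#' @export
nucleotide_diversity <- function(aln, n_boot = 1000, seed = NULL) {
  stopifnot(nrow(aln) >= 2)
  cc <- .complete_columns(aln)
  if (length(cc$sites) == 0) stop("no comparable sites (every column holds a gap or N)",
                                  call. = FALSE)
  pi_hat <- .pi_point(cc$matrix, cc$sites)
  pi_sd <- NA_real_
  if (n_boot > 0) {
    n <- nrow(cc$matrix)
    reps <- with_seed(seed, vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      .pi_point(cc$matrix[idx, , drop = FALSE], cc$sites)
    }, numeric(1)))
    pi_sd <- stats::sd(reps)
  }
  c(pi = pi_hat, pi_sd = pi_sd)
}

#' Number of segregating (polymorphic) sites
#'
#' Counts compared columns (complete deletion) with two or more distinct
#' states among A/C/G/T.
#'
#' @param aln a `dna_alignment`.
#' @return integer count.
#' @export
segregating_sites <- function(aln) {
  cc <- .complete_columns(aln)
  if (length(cc$sites) == 0) return(0L)
  sub <- cc$matrix[, cc$sites, drop = FALSE]
  sum(apply(sub, 2, function(col) length(unique(col))) >= 2)
}

# comparable positions for a pair (both in A/C/G/T)
.pair_sites <- function(a, b) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  if (length(ca) != length(cb)) stop("sequences differ in length", call. = FALSE)
  ok <- ca %in% c("A", "C", "G", "T") & cb %in% c("A", "C", "G", "T")
  list(a = ca[ok], b = cb[ok])
}

#' Uncorrected p-distance between two aligned sequences
#'
#' Proportion of differing sites among pairwise-comparable sites (both
#' nucleotides in A/C/G/T).  `NA` when no site is comparable.
#'
#' @param a,b equal-length DNA strings.
#' @return proportion in `[0, 1]`, or `NA`.
#' @export
p_distance <- function(a, b) {
  s <- .pair_sites(a, b)
  if (length(s$a) == 0) return(NA_real_)
  mean(s$a != s$b)
}

#' Kimura 2-parameter distance from transition/transversion proportions
#'
#' \eqn{d = -\frac{1}{2}\ln[(1 - 2P - Q)\sqrt{1 - 2Q}]} with P the transition
#' and Q the transversion proportion.  `NA` (saturation) when either log
#' argument is non-positive.
#'
#' @param P transition proportion.
#' @param Q transversion proportion.
#' @return K2P distance, or `NA` on saturation.
#' @export
k2p_from_pq <- function(P, Q) {
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) return(NA_real_)
  -0.5 * log(w1 * sqrt(w2))
}

#' Kimura 2-parameter distance between two aligned sequences
#'
#' Pairwise deletion of gap/N sites; transitions are A<->G and C<->T.
#'
#' @inheritParams p_distance
#' @return K2P distance, or `NA` when no site is comparable or the correction
#'   is saturated.
#' @export
k2p_distance <- function(a, b) {
  s <- .pair_sites(a, b)
  if (length(s$a) == 0) return(NA_real_)
  diff <- s$a != s$b
  purine <- function(x) x %in% c("A", "G")
  ts <- diff & (purine(s$a) == purine(s$b))
  k2p_from_pq(mean(ts), mean(diff & !ts))
}

#' Pairwise distance matrix over an alignment
#'
#' @param aln a `dna_alignment`.
#' @param model `"K2P"` or `"p"`.
#' @return symmetric matrix with record ids as dimnames and the model stored
#'   in `attr(, "model")`; undefined pairs are `NA`.
#' @export
distance_matrix <- function(aln, model = c("K2P", "p")) {
  model <- match.arg(model)
  d <- .distance_matrix_chars(seq_char_matrix(aln$seq, aln$id), model)
  attr(d, "model") <- model
  d
}

# vectorized pairwise distances over a character matrix (rows = sequences)
.distance_matrix_chars <- function(m, model) {
  n <- nrow(m)
  ok <- matrix(m %in% c("A", "C", "G", "T"), nrow = n)
  pur <- m == "A" | m == "G"
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        comp <- ok[i, ] & ok[j, ]
        nc <- sum(comp)
        if (nc == 0) { d[i, j] <- d[j, i] <- NA_real_; next }
        diffv <- m[i, comp] != m[j, comp]
        d[i, j] <- d[j, i] <- if (model == "p") mean(diffv) else {
          ts <- diffv & (pur[i, comp] == pur[j, comp])
          k2p_from_pq(sum(ts) / nc, sum(diffv & !ts) / nc)
        }
      }
    }
  }
  d
}

#' Intra- and interspecific divergence summary with a conspecificity screen
#'
#' Per species: maximum and mean intraspecific distance, flagged when the
#' maximum exceeds `threshold` (potential misidentification / cryptic
#' diversity) and marked as warning when it falls inside `warn_band`.  Per
#' species pair: minimum/maximum/mean interspecific distance, plus a
#' barcode-gap verdict (`TRUE` when every interspecific distance of the pair
#' exceeds both species' intraspecific maxima).
#'
#' @param aln a `dna_alignment`.
#' @param labels species label per record (defaults to `aln$species`).
#' @param model `"K2P"` or `"p"`.
#' @param threshold conspecificity threshold on the intraspecific maximum
#'   (proportion; default 0.03).
#' @param warn_band two-element proportion band reported as a warning zone.
#' @return list with data frames `intra` and `inter`, and `n_undefined`
#'   (count of undefined pairwise distances excluded).
#' @export
divergence_summary <- function(aln, labels = aln$species, model = c("K2P", "p"),
                               threshold = 0.03, warn_band = c(0.02, 0.03)) {
  model <- match.arg(model)
  d <- distance_matrix(aln, model = model)
  sp <- unique(labels)
  n_undef <- sum(is.na(d[upper.tri(d)]))
  intra <- do.call(rbind, lapply(sp, function(s) {
    idx <- which(labels == s)
    if (length(idx) < 2) {
      return(data.frame(species = s, n = length(idx), max = NA_real_,
                        mean = NA_real_, flagged = NA, warn = NA))
    }
    v <- d[idx, idx][upper.tri(diag(length(idx)))]
    v <- v[!is.na(v)]
    mx <- if (length(v)) max(v) else NA_real_
    data.frame(species = s, n = length(idx), max = mx, mean = mean(v),
               flagged = isTRUE(mx > threshold),
               warn = isTRUE(mx > warn_band[1] && mx <= warn_band[2]))
  }))
  inter <- NULL
  if (length(sp) >= 2) {
    pairs <- utils::combn(sp, 2)
    inter <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(c2) {
      s1 <- pairs[1, c2]; s2 <- pairs[2, c2]
      v <- as.vector(d[labels == s1, labels == s2, drop = FALSE])
      v <- v[!is.na(v)]
      gap <- NA
      if (length(v)) {
        mx1 <- intra$max[intra$species == s1]
        mx2 <- intra$max[intra$species == s2]
        gap <- min(v) > max(0, mx1, mx2, na.rm = TRUE)
      }
      data.frame(species_1 = s1, species_2 = s2,
                 min = if (length(v)) min(v) else NA_real_,
                 max = if (length(v)) max(v) else NA_real_,
                 mean = if (length(v)) mean(v) else NA_real_,
                 barcode_gap = gap)
    }))
  }
  list(intra = intra, inter = inter, n_undefined = n_undef, model = model,
       threshold = threshold, warn_band = warn_band)
}

#' Per-species diversity summary table
#'
#' One row per species with n, k, S, H (± SD) and pi (± SD); the layout of a
#' standard barcoding diversity table.
#'
#' @param aln a `dna_alignment` carrying species labels.
#' @param n_boot bootstrap replicates for the pi SD.
#' @param seed RNG seed for the bootstrap.
#' @return data frame with columns species, n, k, S, H, H_sd, pi, pi_sd.
#' @export
diversity_summary <- function(aln, n_boot = 1000, seed = NULL) {
  sp <- unique(aln$species)
  do.call(rbind, lapply(sp, function(s) {
    sub <- aln[aln$species == s, , drop = FALSE]
    class(sub) <- class(aln)
    tab <- collapse_haplotypes(sub)
    if (nrow(sub) >= 2) {
      hd <- haplotype_diversity(tab)
      pd <- nucleotide_diversity(sub, n_boot = n_boot, seed = seed)
      S <- segregating_sites(sub)
    } else {
      hd <- c(H = NA_real_, H_sd = NA_real_)
      pd <- c(pi = NA_real_, pi_sd = NA_real_)
      S <- 0L
    }
    data.frame(species = s, n = nrow(sub), k = tab$k, S = S,
               H = unname(hd["H"]), H_sd = unname(hd["H_sd"]),
               pi = unname(pd["pi"]), pi_sd = unname(pd["pi_sd"]))
  }))
}
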