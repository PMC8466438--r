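# Distance-based clustering: Saitou-Nei neighbor joining with deterministic
# tie-breaking, column-resampling bootstrap, per-species monophyly verdicts.

.newick_quote <- function(x) {
  ifelse(grepl("[^A-Za-z0-9_.|-]", x), paste0("'", gsub("'", "''", x), "'"), x)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration with the Q-criterion.  Deterministic:
#' ties in Q are broken on the lexicographically smallest ordered pair of
#' joined labels.  Negative branch-length estimates are clamped to zero with
#' a warning.  The result is an unrooted `ape::phylo`.
#'
#' @param D symmetric distance matrix with labels as dimnames (>= 3 taxa,
#'   finite entries; `NA` entries are an error naming the pairs).
#' @return an unrooted `phylo` tree.
#' @export
nj_tree <- function(D) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (n < 3) stop("need at least 3 taxa", call. = FALSE)
  labs <- rownames(D) %||% paste0("t", seq_len(n))
  if (any(!is.finite(D))) {
    bad <- which(!is.finite(D) & upper.tri(D), arr.ind = TRUE)
    stop("undefined distances for pair(s): ",
         paste(labs[bad[, 1]], labs[bad[, 2]], sep = "~", collapse = ", "),
         call. = FALSE)
  }
  clamped <- FALSE
  # each active node is a Newick fragment
  frag <- .newick_quote(labs)
  keylab <- labs  # lexicographic key per active node (smallest member label)
  d <- D
  bl <- function(x) {
    if (x < 0) clamped <<- TRUE
    sprintf("%.12g", max(x, 0))
  }
  while (length(frag) > 3) {
    m <- length(frag)
    r <- rowSums(d)
    q <- (m - 2) * d - outer(r, r, "+")
    diag(q) <- Inf
    qmin <- min(q)
    cand <- which(q - qmin <= 1e-12 & upper.tri(q), arr.ind = TRUE)
    # deterministic tie-break on ordered label pairs
    key <- apply(cand, 1, function(ij) {
      p <- sort(c(keylab[ij[1]], keylab[ij[2]]))
      paste(p, collapse = "\r")
    })
    pick <- cand[order(key)[1], ]
    i <- min(pick); j <- max(pick)
    vi <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    vj <- d[i, j] - vi
    newfrag <- paste0("(", frag[i], ":", bl(vi), ",", frag[j], ":", bl(vj), ")")
    newd <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], newd[keep]),
               c(newd[keep], 0))
    frag <- c(frag[keep], newfrag)
    keylab <- c(keylab[keep], min(keylab[c(i, j)]))
  }
  # final 3-star
  v1 <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  v2 <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  v3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  nwk <- paste0("(", frag[1], ":", bl(v1), ",", frag[2], ":", bl(v2),
                ",", frag[3], ":", bl(v3), ");")
  if (clamped) warning("negative NJ branch length(s) clamped to zero")
  ape::read.tree(text = nwk)
}

#' Column-resampling bootstrap for the NJ tree
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree per
#' replicate, and reports for each internal edge of the original tree the
#' percentage of replicates containing the same bipartition (as node
#' labels).  Seeded and reproducible.
#'
#' @param aln a `dna_alignment`.
#' @param reps bootstrap replicates (>= 1).
#' @param seed RNG seed.
#' @param model distance model, `"K2P"` or `"p"`.
#' @return list: `tree` (original NJ `phylo`, `node.label` holding supports
#'   in `[0, 100]`, root label empty), `boot_trees` (list of replicate
#'   `phylo`), `reps`, `seed`, `model`.
#' @export
bootstrap_support <- function(aln, reps = 1000, seed = NULL,
                              model = c("K2P", "p")) {
  model <- match.arg(model)
  if (reps < 1) stop("reps must be >= 1", call. = FALSE)
  L <- aln_length(aln)
  chars <- seq_char_matrix(aln$seq, aln$id)
  dist_of <- function(mat) {
    D <- .distance_matrix_chars(mat, model)
    if (any(is.na(D))) {
      # saturated / incomparable replicate pairs: fall back to the largest
      # defined distance so the replicate stays usable
      D[is.na(D)] <- max(D, na.rm = TRUE) * 1.5
    }
    D
  }
  tree <- nj_tree(dist_of(chars))
  boot_trees <- with_seed(seed, lapply(seq_len(reps), function(b) {
    # clamping warnings are routine inside replicates
    suppressWarnings(
      nj_tree(dist_of(chars[, sample.int(L, L, replace = TRUE), drop = FALSE])))
  }))
  counts <- ape::prop.clades(tree, boot_trees, rooted = FALSE)
  counts[is.na(counts)] <- 0
  tree$node.label <- as.character(round(100 * counts / reps, 1))
  list(tree = tree, boot_trees = boot_trees, reps = reps, seed = seed,
       model = model)
}

#' Monophyly verdict for a tip set
#'
#' After rooting on the declared outgroup, `TRUE` iff the tip subset is
#' exactly the tip set of some clade.
#'
#' @param tree a `phylo`.
#' @param tips character vector of tip labels (not containing the outgroup).
#' @param outgroup tip label used to root the tree.
#' @return logical verdict.
#' @export
is_monophyletic <- function(tree, tips, outgroup) {
  all_tips <- tree$tip.label
  unknown <- setdiff(c(tips, outgroup), all_tips)
  if (length(unknown)) stop("unknown tip(s): ", paste(unknown, collapse = ", "),
                            call. = FALSE)
  if (outgroup %in% tips) stop("outgroup must not be in the tip subset", call. = FALSE)
  if (length(tips) == 1) return(TRUE)
  rooted <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  clades <- ape::prop.part(rooted)
  target <- sort(match(tips, rooted$tip.label))
  any(vapply(clades, function(cl) identical(sort(cl), target), logical(1)))
}

#' Per-species monophyly report with bootstrap support
#'
#' For each species, the verdict on the original tree plus the percentage of
#' bootstrap replicates in which the species' tips are monophyletic (after
#' rooting on the outgroup).
#'
#' @param boot result of [bootstrap_support()].
#' @param species named character vector mapping tip label to species (the
#'   outgroup tip may be omitted or carry its own label).
#' @param outgroup tip label of the outgroup.
#' @return data frame: species, n_tips, monophyletic, support.
#' @export
monophyly_report <- function(boot, species, outgroup) {
  sp <- setdiff(unique(species[names(species) != outgroup]), NA)
  do.call(rbind, lapply(sp, function(s) {
    tips <- names(species)[species == s & names(species) != outgroup]
    verdict <- is_monophyletic(boot$tree, tips, outgroup)
    supp <- if (length(tips) == 1) 100 else {
      100 * mean(vapply(boot$boot_trees, function(t) {
        is_monophyletic(t, tips, outgroup)
      }, logical(1)))
    }
    data.frame(species = s, n_tips = length(tips), monophyletic = verdict,
               support = supp, stringsAsFactors = FALSE)
  }))
}
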