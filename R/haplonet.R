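# Median-joining haplotype networks.
#
# The construction follows the classic scheme: minimum-spanning network
# (epsilon-relaxed) over the current node set, quasi-medians of linked
# triples as candidate Steiner points, iterative addition until no candidate
# shortens the network, then pruning of inferred nodes that are not needed.
# Ties are broken lexicographically on the haplotype sequence so the result
# is deterministic.

.hamming <- function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])

# pairwise Hamming distances over equal-length sequences
.hamming_matrix <- function(seqs) {
  n <- length(seqs)
  m <- seq_char_matrix(seqs)
  d <- matrix(0L, n, n)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) d[i, j] <- d[j, i] <- sum(m[i, ] != m[j, ])
    }
  }
  d
}

# minimum-spanning network: an edge (i, j) belongs to the network iff
# d_ij <= delta_ij + epsilon, where delta_ij is the connection cost (the
# single-linkage merge level of i and j).  With epsilon = 0 this is exactly
# the union of all minimum spanning trees.
.msn_edges <- function(d, epsilon = 0) {
  n <- nrow(d)
  if (n == 1) return(data.frame(from = integer(), to = integer(), weight = integer()))
  if (n == 2) return(data.frame(from = 1L, to = 2L, weight = d[1, 2]))
  hc <- stats::hclust(stats::as.dist(d), method = "single")
  delta <- as.matrix(stats::cophenetic(hc))
  keep <- which(upper.tri(d) & d <= delta + epsilon + 1e-9, arr.ind = TRUE)
  data.frame(from = keep[, 1], to = keep[, 2], weight = d[keep])
}

# total length of the MSN over a sequence set
.msn_length <- function(seqs, epsilon = 0) {
  e <- .msn_edges(.hamming_matrix(seqs), epsilon)
  sum(e$weight)
}

# quasi-medians of a triple: column-wise majority state; columns where all
# three states differ branch into all three choices
.quasi_medians <- function(a, b, c, max_branch = 81) {
  m <- rbind(strsplit(a, "")[[1]], strsplit(b, "")[[1]], strsplit(c, "")[[1]])
  cols <- lapply(seq_len(ncol(m)), function(j) {
    tb <- table(m[, j])
    if (max(tb) >= 2) names(tb)[which.max(tb)] else sort(unique(m[, j]))
  })
  n_branch <- prod(lengths(cols))
  if (n_branch > max_branch) {
    # keep only the first max_branch lexicographic combinations
    cols <- lapply(cols, `[`, 1)
  }
  grid <- expand.grid(cols, stringsAsFactors = FALSE)
  sort(unique(apply(grid, 1, paste, collapse = "")))
}

#' Median-joining haplotype network
#'
#' Builds a haplotype network from a [collapse_haplotypes()] table: the
#' minimum-spanning network over observed haplotypes, augmented with inferred
#' median vectors (quasi-medians of linked triples) added while they shorten
#' the network, then pruned of unnecessary inferred nodes.  With the default
#' `epsilon = 0` the network contains all links of the minimum-spanning
#' network.  Deterministic: candidates are processed in lexicographic order.
#'
#' @param tab a `haplotype_table`.
#' @param epsilon relaxation parameter (>= 0) admitting longer alternative
#'   links, as in the original algorithm.
#' @param max_rounds cap on median-addition rounds; exceeding it is an error
#'   rather than a silent truncation.
#' @return an `mj_network`: list with `nodes` (data frame: name, seq, count,
#'   inferred, species), `edges` (data frame: from, to, weight with node
#'   names), and `epsilon`.
#' @export
median_joining <- function(tab, epsilon = 0, max_rounds = 20) {
  stopifnot(inherits(tab, "haplotype_table"), epsilon >= 0)
  obs <- tab$haplotypes$seq
  seqs <- obs
  for (round in seq_len(max_rounds + 1)) {
    if (round > max_rounds) stop("median-joining did not converge in ",
                                 max_rounds, " rounds", call. = FALSE)
    d <- .hamming_matrix(seqs)
    e <- .msn_edges(d, epsilon)
    cur_len <- sum(e$weight)
    # linked triples: u-v and v-w are MSN edges
    adj <- lapply(seq_along(seqs), function(i) {
      sort(unique(c(e$to[e$from == i], e$from[e$to == i])))
    })
    cand <- character()
    for (v in seq_along(seqs)) {
      nb <- adj[[v]]
      if (length(nb) >= 2) {
        for (p in utils::combn(nb, 2, simplify = FALSE)) {
          cand <- c(cand, .quasi_medians(seqs[p[1]], seqs[v], seqs[p[2]]))
        }
      }
    }
    cand <- setdiff(sort(unique(cand)), seqs)
    if (!length(cand)) break
    gain <- vapply(cand, function(s) cur_len - .msn_length(c(seqs, s), epsilon),
                   numeric(1))
    best <- which(gain > 0)
    if (!length(best)) break
    # largest reduction first, lexicographic sequence breaks ties
    best <- best[order(-gain[best], cand[best])][1]
    seqs <- c(seqs, cand[best])
  }
  # prune inferred nodes that do not shorten the network, then any inferred
  # node of degree <= 1
  repeat {
    d <- .hamming_matrix(seqs)
    e <- .msn_edges(d, epsilon)
    cur_len <- sum(e$weight)
    inferred <- setdiff(seq_along(seqs), seq_along(obs))
    drop <- NA
    for (i in inferred[order(seqs[inferred])]) {
      deg <- sum(e$from == i) + sum(e$to == i)
      if (deg <= 1 || .msn_length(seqs[-i], epsilon) <= cur_len) { drop <- i; break }
    }
    if (is.na(drop)) break
    seqs <- seqs[-drop]
  }
  d <- .hamming_matrix(seqs)
  e <- .msn_edges(d, epsilon)
  n_obs <- length(obs)
  names <- c(tab$haplotypes$name,
             if (length(seqs) > n_obs) paste0("mv", seq_len(length(seqs) - n_obs)))
  counts <- c(tab$haplotypes$count, rep(0L, length(seqs) - n_obs))
  species <- rep(NA_character_, length(seqs))
  nodes <- data.frame(name = names, seq = seqs, count = counts,
                      inferred = seq_along(seqs) > n_obs,
                      species = species, stringsAsFactors = FALSE)
  edges <- data.frame(from = names[e$from], to = names[e$to],
                      weight = as.integer(e$weight), stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges, epsilon = epsilon),
            class = "mj_network")
}

#' Annotate network nodes with species composition
#'
#' @param net an `mj_network`.
#' @param tab the `haplotype_table` the network was built from.
#' @param species_of named character vector mapping record id to species.
#' @return the network with `nodes$species` filled as
#'   `"species:count"` comma-joined strings for observed haplotypes.
#' @export
annotate_network_species <- function(net, tab, species_of) {
  for (i in which(!net$nodes$inferred)) {
    ids <- tab$members[[net$nodes$name[i]]]
    tb <- sort(table(species_of[ids]), decreasing = TRUE)
    net$nodes$species[i] <- paste(names(tb), tb, sep = ":", collapse = ",")
  }
  net
}

#' @export
print.mj_network <- function(x, ...) {
  cat("Median-joining network: ", sum(!x$nodes$inferred), " observed + ",
      sum(x$nodes$inferred), " median node(s), ", nrow(x$edges),
      " edge(s), total length ", sum(x$edges$weight),
      " (epsilon = ", x$epsilon, ")\n", sep = "")
  invisible(x)
}

.as_igraph <- function(net) {
  g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                     vertices = net$nodes)
  g
}

#' Export a haplotype network to GML or DOT
#'
#' Node attributes (count, inferred flag, species composition, sequence) and
#' the edge weight are serialized.  GML files can be re-imported with
#' [import_network()].
#'
#' @param net an `mj_network`.
#' @param path output file.
#' @param format `"GML"` or `"DOT"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path, format = c("GML", "DOT")) {
  format <- match.arg(format)
  g <- .as_igraph(net)
  # igraph GML writer needs plain attribute types; logical -> numeric
  igraph::V(g)$inferred <- as.numeric(igraph::V(g)$inferred)
  igraph::V(g)$species <- ifelse(is.na(igraph::V(g)$species), "",
                                 igraph::V(g)$species)
  igraph::write_graph(g, path, format = tolower(format))
  invisible(path)
}

#' Re-import a GML haplotype network
#' @param path a GML file written by [export_network()].
#' @return an `mj_network`.
#' @export
import_network <- function(path) {
  g <- igraph::read_graph(path, format = "gml")
  nodes <- data.frame(name = igraph::V(g)$name,
                      seq = igraph::V(g)$seq,
                      count = as.integer(igraph::V(g)$count),
                      inferred = as.logical(igraph::V(g)$inferred),
                      species = ifelse(nzchar(igraph::V(g)$species),
                                       igraph::V(g)$species, NA_character_),
                      stringsAsFactors = FALSE)
  el <- igraph::as_edgelist(g)
  edges <- data.frame(from = el[, 1], to = el[, 2],
                      weight = as.integer(igraph::E(g)$weight),
                      stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges,
                 epsilon = NA_real_), class = "mj_network")
}

#' Total edge length of the minimum spanning tree over observed haplotypes
#'
#' Reference quantity for the network-length invariant (a median-joining
#' network is never longer than the observed-haplotype MST).
#'
#' @param tab a `haplotype_table`.
#' @return total MST length (sum of Hamming edge weights).
#' @export
mst_length <- function(tab) {
  d <- .hamming_matrix(tab$haplotypes$seq)
  n <- nrow(d)
  if (n <= 1) return(0)
  # Prim's algorithm
  in_tree <- c(TRUE, rep(FALSE, n - 1))
  total <- 0
  while (!all(in_tree)) {
    sub <- d[in_tree, !in_tree, drop = FALSE]
    total <- total + min(sub)
    j <- which(!in_tree)[which(sub == min(sub), arr.ind = TRUE)[1, 2]]
    in_tree[j] <- TRUE
  }
  total
}
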