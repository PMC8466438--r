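# in-code fixtures and independent oracles shared across the suite

make_aln <- function(seqs, species = "Species x", ids = NULL) {
  ids <- ids %||% paste0("s", seq_along(seqs))
  as_alignment(barcode_records(ids, rep_len(species, length(seqs)), seqs))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# all partitions of n into positive parts (haplotype count multisets)
partitions_of <- function(n, max_part = n) {
  if (n == 0) return(list(integer()))
  out <- list()
  for (k in seq_len(min(n, max_part))) {
    for (rest in partitions_of(n - k, k)) out[[length(out) + 1]] <- c(k, rest)
  }
  out
}

# brute-force haplotype diversity: probability that two distinct sampled
# individuals carry different haplotypes, with the n/(n-1) correction folded
# in by enumerating unordered pairs
brute_force_H <- function(counts) {
  n <- sum(counts)
  pairs <- utils::combn(rep(seq_along(counts), counts), 2)
  mean(pairs[1, ] != pairs[2, ])
}

# independent Nei-Gojobori oracle: exhaustive pathway enumeration written as
# a depth-first recursion (the package uses permutation lists), same
# stop-pathway exclusion semantics
oracle_ng_pair <- function(c1, c2, code) {
  paths <- list()
  recurse <- function(cur, sd, nd, hit_stop) {
    pos <- which(strsplit(cur, "")[[1]] != strsplit(c2, "")[[1]])
    if (!length(pos)) {
      paths[[length(paths) + 1]] <<- c(sd, nd, hit_stop)
      return(invisible())
    }
    for (p in pos) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      syn <- code[[cur]] == code[[nxt]]
      recurse(nxt, sd + syn, nd + !syn, hit_stop || code[[nxt]] == "*")
    }
  }
  recurse(c1, 0, 0, FALSE)
  m <- do.call(rbind, paths)
  ok <- m[, 3] == 0
  if (!any(ok)) ok <- rep(TRUE, nrow(m))
  c(sd = mean(m[ok, 1]), nd = mean(m[ok, 2]))
}

# independent synonymous-site count for one codon
oracle_ng_sites <- function(codon, code) {
  s <- 0
  for (pos in 1:3) {
    for (b in setdiff(c("A", "C", "G", "T"), substr(codon, pos, pos))) {
      alt <- codon
      substr(alt, pos, pos) <- b
      if (code[[alt]] != "*" && code[[alt]] == code[[codon]]) s <- s + 1
    }
  }
  s / 3
}

# random additive distance matrix from a random tree; returns list(D, tree)
random_additive_matrix <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n, br = function(k) stats::runif(k, 0.1, 2))
  list(D = ape::cophenetic.phylo(tr), tree = tr)
}

# total MJ network length helper
net_length <- function(net) sum(net$edges$weight)
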