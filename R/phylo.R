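#' SNV distance between two call vectors
#'
#' Counts positions where both calls are non-ambiguous and differ.  Symmetric;
#' because ambiguous positions are skipped pairwise, the triangle inequality
#' is not guaranteed.
#'
#' @param calls_a,calls_b equal-length character vectors over `{A,C,G,T,N}`.
#' @return integer SNV count.
#' @export
hamming_distance <- function(calls_a, calls_b) {
  if (length(calls_a) != length(calls_b)) {
    stop("call vectors differ in length (", length(calls_a), " vs ",
         length(calls_b), ")")
  }
  sum(calls_a != calls_b & calls_a != "N" & calls_b != "N")
}

#' Pairwise SNV distance matrix
#'
#' @param genotypes a [genotype_matrix()].
#' @return symmetric integer matrix of pairwise [hamming_distance()] values.
#' @export
hamming_matrix <- function(genotypes) {
  calls <- genotypes$calls
  n <- nrow(calls)
  d <- matrix(0L, n, n, dimnames = list(rownames(calls), rownames(calls)))
  if (n < 2L) return(d)
  ok <- calls != "N"
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d[i, j] <- d[j, i] <-
        sum(calls[i, ] != calls[j, ] & ok[i, ] & ok[j, ])
    }
  }
  d
}

#' Read a phylogeny with bootstrap support
#'
#' Reads Newick or NEXUS, midpoint-roots unrooted trees, and extracts
#' bootstrap support from internal node labels.  Labels on a 0-100 scale are
#' rescaled to 0-1.
#'
#' @param path tree file.
#' @param format `"newick"` or `"nexus"`.
#' @return an `ape::phylo` tree (rooted), with numeric `node.label`
#'   bootstrap values in `[0, 1]` (`NA` where absent).
#' @export
read_phylogeny <- function(path, format = c("newick", "nexus")) {
  format <- match.arg(format)
  tree <- if (format == "newick") ape::read.tree(path) else
    ape::read.nexus(path)
  if (inherits(tree, "multiPhylo")) tree <- tree[[1]]
  normalize_tree(tree)
}

# Midpoint-root if needed and coerce node labels to bootstrap in [0,1].
normalize_tree <- function(tree) {
  if (!ape::is.rooted(tree)) tree <- phangorn::midpoint(tree)
  if (is.null(tree$node.label)) {
    tree$node.label <- rep(NA_real_, tree$Nnode)
  } else {
    bs <- suppressWarnings(as.numeric(tree$node.label))
    if (any(bs > 1, na.rm = TRUE)) bs <- bs / 100
    tree$node.label <- bs
  }
  tree
}

#' Scale tree branch lengths into core-genome SNV units
#'
#' Compares patristic distances against pairwise SNV ([hamming_distance()])
#' distances over all leaf pairs.  When the Pearson correlation exceeds
#' `min_r`, branch lengths are multiplied by the least-squares
#' through-the-origin slope mapping patristic distance to SNV distance and
#' the tree is marked as SNV-scaled; otherwise the raw lengths are kept and
#' downstream clade criteria expressed in SNV units will refuse to run
#' without an explicit override.
#'
#' @param tree an `ape::phylo` tree (Newick string and file paths are also
#'   accepted); unrooted trees are midpoint-rooted.
#' @param genotypes a [genotype_matrix()] covering every leaf.
#' @param min_r minimum Pearson correlation for scaling (default 0.75,
#'   strict inequality).
#' @return An object of class `scaled_phylogeny`: list with elements `tree`
#'   (branch lengths rescaled when applicable), `bootstrap` (per internal
#'   node, `[0,1]`), `scale_unit` (`"SNVs"` or `"raw"`), `slope`, `r`.
#' @export
scale_tree <- function(tree, genotypes, min_r = 0.75) {
  if (is.character(tree)) {
    tree <- if (file.exists(tree)) ape::read.tree(tree) else
      ape::read.tree(text = tree)
  }
  tree <- normalize_tree(tree)
  tips <- tree$tip.label
  if (length(tips) < 3L) stop("cannot correlate distances with < 3 leaves")
  miss <- setdiff(tips, genotypes$genome_ids)
  if (length(miss) > 0L) {
    stop("leaves missing from genotype matrix: ", paste(miss, collapse = ", "))
  }
  pat <- ape::cophenetic.phylo(tree)[tips, tips]
  sub <- genotype_matrix(
    genotypes$calls[match(tips, genotypes$genome_ids), , drop = FALSE],
    genotypes$positions)
  ham <- hamming_matrix(sub)
  ut <- upper.tri(pat)
  p <- pat[ut]
  h <- ham[ut]
  r <- if (stats::sd(p) == 0 || stats::sd(h) == 0) 0 else stats::cor(p, h)
  slope <- sum(p * h) / sum(p * p)
  scaled <- r > min_r
  if (scaled) tree$edge.length <- tree$edge.length * slope
  structure(list(tree = tree, bootstrap = tree$node.label,
                 scale_unit = if (scaled) "SNVs" else "raw",
                 slope = if (scaled) slope else NA_real_, r = r),
            class = "scaled_phylogeny")
}

#' @export
print.scaled_phylogeny <- function(x, ...) {
  cat("scaled_phylogeny: ", length(x$tree$tip.label), " leaves; unit = ",
      x$scale_unit, sprintf(" (r = %.3f)", x$r), "\n", sep = "")
  invisible(x)
}

#' Dereplicate near-identical reference genomes
#'
#' Density-based clustering (DBSCAN) on the pairwise SNV distance matrix.
#' Points with at least `min_cluster` genomes (including themselves) within
#' `epsilon` SNVs seed clusters, which grow through density-connected
#' neighbours.  One representative is kept per cluster — the genome with the
#' highest median coverage, ties broken lexicographically by id — and all
#' noise singletons are retained.
#'
#' @param genotypes a [genotype_matrix()].
#' @param epsilon neighbourhood radius in SNVs (default 500).
#' @param min_cluster minimum genomes per cluster (default 2).
#' @param coverage optional named numeric vector of median coverages used to
#'   pick representatives; missing/absent values are treated as equal.
#' @return character vector of retained genome ids (sorted).
#' @export
dereplicate_genomes <- function(genotypes, epsilon = 500, min_cluster = 2,
                                coverage = NULL) {
  ids <- genotypes$genome_ids
  n <- length(ids)
  if (n <= 1L) return(ids)
  d <- hamming_matrix(genotypes)
  cov <- rep(0, n)
  names(cov) <- ids
  if (!is.null(coverage)) {
    hit <- intersect(names(coverage), ids)
    cov[hit] <- coverage[hit]
  }
  neighbours <- lapply(seq_len(n), function(i) which(d[i, ] <= epsilon))
  core <- vapply(neighbours, length, 0L) >= min_cluster
  cluster <- rep(0L, n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (cluster[i] != 0L || !core[i]) next
    cl <- cl + 1L
    queue <- i
    cluster[i] <- cl
    while (length(queue) > 0L) {
      p <- queue[1L]
      queue <- queue[-1L]
      if (!core[p]) next
      for (q in neighbours[[p]]) {
        if (cluster[q] == 0L) {
          cluster[q] <- cl
          queue <- c(queue, q)
        }
      }
    }
  }
  reps <- character(0)
  for (k in seq_len(max(cluster, 0L))) {
    members <- ids[cluster == k]
    ord <- order(-cov[members], members)
    reps <- c(reps, members[ord][1L])
  }
  sort(c(reps, ids[cluster == 0L]))
}
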