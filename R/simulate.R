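#' Simulate a clonal frame: genomes evolved along a random tree
#'
#' Draws a random rooted topology, assigns exponential branch lengths in
#' expected SNVs (separate means for internal and terminal branches; deep
#' population structure with long internal branches is what makes clades
#' identifiable), places `Poisson(branch length)` mutations on each branch at
#' globally distinct core-genome sites, and propagates genotypes from the
#' root to the leaves.  Branch lengths of the returned tree are set to the
#' realized mutation counts, so patristic distances equal Hamming distances
#' exactly and the tree is already in SNV units.  Bootstrap support is 1 on
#' every internal node (the topology is known without error).
#'
#' @param n_genomes number of leaves (default 30).
#' @param core_length core-genome length in bp (default 1e5).
#' @param mean_branch_internal expected SNVs on internal branches
#'   (default 1000).
#' @param mean_branch_terminal expected SNVs on terminal branches
#'   (default 300).
#' @param seed integer seed; identical seeds give identical frames.
#' @param max_density maximum total mutations as a fraction of
#'   `core_length` before erroring (default 0.5); distinct-site sampling
#'   needs head room.
#' @return An object of class `clonal_frame`: list with `tree` (ape phylo,
#'   SNV branch lengths, bootstrap node labels), `positions` (sorted mutated
#'   sites), `ref_alleles`, `genotypes` (leaf x site call matrix),
#'   `mutations` (edge, position, from, to), `core_length`, `seed`.
#' @export
simulate_genomes <- function(n_genomes = 30, core_length = 1e5,
                             mean_branch_internal = 1000,
                             mean_branch_terminal = 300, seed = NULL,
                             max_density = 0.5) {
  stopifnot(n_genomes >= 3, core_length > 0,
            mean_branch_internal > 0, mean_branch_terminal > 0)
  if (!is.null(seed)) set.seed(seed)
  tree <- ape::rtree(n_genomes, rooted = TRUE, br = NULL)
  tree$tip.label <- sprintf("g%02d", seq_len(n_genomes))
  ntip <- n_genomes
  internal_child <- tree$edge[, 2L] > ntip
  expected <- ifelse(internal_child,
                     stats::rexp(nrow(tree$edge), 1 / mean_branch_internal),
                     stats::rexp(nrow(tree$edge), 1 / mean_branch_terminal))
  n_mut <- stats::rpois(nrow(tree$edge), expected)
  total <- sum(n_mut)
  if (total > max_density * core_length) {
    stop("mutation density too high for distinct-site sampling (",
         total, " mutations on a ", core_length,
         " bp core); increase core_length")
  }
  tree$edge.length <- as.numeric(n_mut)
  tree$node.label <- rep(1, tree$Nnode)
  sites <- sort(sample.int(core_length, total))
  edge_of <- rep(seq_len(nrow(tree$edge)), n_mut)
  edge_of <- sample(edge_of)  # shuffle site -> branch assignment
  ref <- sample(NUCLEOTIDES, total, replace = TRUE)
  to <- vapply(ref, function(b) sample(setdiff(NUCLEOTIDES, b), 1L), "")
  mutations <- data.frame(edge = edge_of, position = sites, from = ref,
                          to = to, stringsAsFactors = FALSE)
  # propagate genotypes root -> leaves over node genotype vectors
  nnode_total <- ntip + tree$Nnode
  geno <- matrix(NA_character_, nnode_total, total)
  root <- ntip + 1L
  geno[root, ] <- ref
  ord <- order(node_depths_topo(tree))  # parents before children
  edges_by_child <- match(seq_len(nnode_total), tree$edge[, 2L])
  for (nd in ord) {
    if (nd == root) next
    e <- edges_by_child[nd]
    parent <- tree$edge[e, 1L]
    g <- geno[parent, ]
    hit <- which(mutations$edge == e)
    if (length(hit) > 0L) g[match(mutations$position[hit], sites)] <-
        mutations$to[hit]
    geno[nd, ] <- g
  }
  leaves <- geno[seq_len(ntip), , drop = FALSE]
  rownames(leaves) <- tree$tip.label
  structure(list(tree = tree, positions = sites, ref_alleles = ref,
                 genotypes = leaves, mutations = mutations,
                 core_length = core_length, seed = seed,
                 params = list(n_genomes = n_genomes,
                               mean_branch_internal = mean_branch_internal,
                               mean_branch_terminal = mean_branch_terminal)),
            class = "clonal_frame")
}

# Topological depth (edges from root) per node; root first in order.
node_depths_topo <- function(tree) {
  ntip <- length(tree$tip.label)
  n <- ntip + tree$Nnode
  depth <- rep(NA_integer_, n)
  depth[ntip + 1L] <- 0L
  # edges in ape trees are not guaranteed preorder; iterate until stable
  repeat {
    done <- TRUE
    for (e in seq_len(nrow(tree$edge))) {
      p <- tree$edge[e, 1L]
      c <- tree$edge[e, 2L]
      if (!is.na(depth[p]) && is.na(depth[c])) {
        depth[c] <- depth[p] + 1L
        done <- FALSE
      }
    }
    if (done) break
  }
  depth
}

#' @export
print.clonal_frame <- function(x, ...) {
  cat("clonal_frame: ", nrow(x$genotypes), " genomes, ",
      length(x$positions), " mutated sites on a ", x$core_length,
      " bp core\n", sep = "")
  invisible(x)
}

#' Genotype matrix of a clonal frame
#'
#' @param frame a `clonal_frame`.
#' @return a [genotype_matrix()] over the frame's mutated sites.
#' @export
frame_genotypes <- function(frame) {
  genotype_matrix(frame$genotypes, frame$positions)
}

#' Export frame genotypes as FASTA
#'
#' Writes the concatenated variable-site alignment (one record per genome);
#' synthetic data, for interoperability with external tree builders.
#'
#' @param frame a `clonal_frame`.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_frame_fasta <- function(frame, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (g in rownames(frame$genotypes)) {
    writeLines(c(paste0(">", g),
                 paste(frame$genotypes[g, ], collapse = "")), con)
  }
  invisible(path)
}

#' True divergence of a genome from a clade's defining branch
#'
#' `DV_b = 1 - shared / total` branch length of the branch `b` subtending
#' the clade, computed on the full (pre-hold-out) tree: 0 when the genome
#' attaches at or below the clade's MRCA (full sharing), 1 when it diverges
#' at or above the top of the branch (no sharing), and the unshared fraction
#' of the branch when it diverges part-way down.
#'
#' @param frame a `clonal_frame`.
#' @param members genome ids whose MRCA defines the clade.
#' @param genome the (held-out) genome id being classified.
#' @param branch_length total length of the defining branch in SNV units;
#'   defaults to the full-tree edge above the members' MRCA, but after
#'   pruning a database the defining branch is typically a concatenation of
#'   full-tree edges whose summed length the caller supplies.
#' @return `DV_b` in `[0, 1]`.
#' @export
true_divergence <- function(frame, members, genome,
                            branch_length = NULL) {
  tree <- frame$tree
  if (!genome %in% tree$tip.label) {
    stop("genome '", genome, "' is not a leaf of the frame")
  }
  if (!all(members %in% tree$tip.label)) stop("unknown clade member id(s)")
  if (genome %in% members) return(0)
  ntip <- length(tree$tip.label)
  v <- if (length(members) == 1L) match(members, tree$tip.label) else
    ape::getMRCA(tree, members)
  depths <- ape::node.depth.edgelength(tree)
  if (is.null(branch_length)) {
    e <- which(tree$edge[, 2L] == v)
    if (length(e) == 0L) stop("clade MRCA is the root: no defining branch")
    branch_length <- tree$edge.length[e]
  }
  if (branch_length <= 0) stop("defining branch has non-positive length")
  a <- ape::getMRCA(tree, unique(c(members, genome)))
  if (is.null(a)) stop("genome '", genome, "' unrelated to the clade")
  unshared <- depths[v] - depths[a]
  min(max(unshared / branch_length, 0), 1)
}

#' Lognormal mixture frequencies
#'
#' Helper matching the benchmark design: strain abundances drawn lognormal
#' and normalized to sum to 1.
#'
#' @param n number of strains (default 5).
#' @param meanlog,sdlog lognormal parameters (defaults 1 and 1).
#' @return numeric vector of `n` frequencies summing to 1.
#' @export
lognormal_mixture <- function(n = 5, meanlog = 1, sdlog = 1) {
  f <- stats::rlnorm(n, meanlog, sdlog)
  f / sum(f)
}

#' Simulate per-position allele counts for a metagenomic sample
#'
#' Reads are simulated as per-position allele counts (no FASTQ, no aligner):
#' for each mixture genome, per-position read counts are negative binomial
#' with mean `frequency x total_depth` and shape `dispersion`; each read
#' carries the genome's allele, substituted uniformly at random with
#' probability `error_rate`; counts are split across strands
#' `Binomial(1/2)`.
#'
#' @param frame a `clonal_frame`.
#' @param mixture named numeric vector mapping genome ids to relative
#'   frequencies (need not sum to 1; each genome's expected depth is
#'   `frequency * total_depth`).
#' @param total_depth total focal-species depth.
#' @param dispersion negative-binomial shape for depth noise (default 5;
#'   `Inf` gives Poisson depths).
#' @param error_rate per-read substitution probability (default 0: the
#'   benchmark reads are error-free).
#' @param sample_id identifier for the resulting sample (default
#'   `"sample1"`).
#' @param seed integer seed.
#' @return a single-sample [allele_counts] object over the frame's mutated
#'   sites.
#' @export
simulate_sample_counts <- function(frame, mixture, total_depth,
                                   dispersion = 5, error_rate = 0,
                                   sample_id = "sample1", seed = NULL) {
  stopifnot(all(mixture >= 0), total_depth > 0)
  if (is.null(names(mixture)) ||
      !all(names(mixture) %in% rownames(frame$genotypes))) {
    stop("mixture must be named by frame genome ids")
  }
  if (!is.null(seed)) set.seed(seed)
  np <- length(frame$positions)
  tot <- matrix(0, np, 4, dimnames = list(NULL, NUCLEOTIDES))
  for (g in names(mixture)) {
    mu <- mixture[[g]] * total_depth
    if (mu == 0) next
    reads <- if (is.finite(dispersion)) {
      stats::rnbinom(np, mu = mu, size = dispersion)
    } else {
      stats::rpois(np, mu)
    }
    errs <- if (error_rate > 0) stats::rbinom(np, reads, error_rate) else
      integer(np)
    own <- reads - errs
    ai <- match(frame$genotypes[g, ], NUCLEOTIDES)
    tot[cbind(seq_len(np), ai)] <- tot[cbind(seq_len(np), ai)] + own
    if (any(errs > 0)) {
      # split errors over the three non-genotype alleles
      e1 <- stats::rbinom(np, errs, 1 / 3)
      e2 <- stats::rbinom(np, errs - e1, 1 / 2)
      e3 <- errs - e1 - e2
      alt <- matrix(0L, np, 3)
      for (k in 1:3) {
        # k-th alternative allele index for each position
        alt[, k] <- vapply(seq_len(np), function(i) {
          setdiff(1:4, ai[i])[k]
        }, 0L)
      }
      tot[cbind(seq_len(np), alt[, 1])] <-
        tot[cbind(seq_len(np), alt[, 1])] + e1
      tot[cbind(seq_len(np), alt[, 2])] <-
        tot[cbind(seq_len(np), alt[, 2])] + e2
      tot[cbind(seq_len(np), alt[, 3])] <-
        tot[cbind(seq_len(np), alt[, 3])] + e3
    }
  }
  fwd <- matrix(stats::rbinom(np * 4L, as.integer(tot), 0.5), np, 4)
  counts <- array(0, c(1L, np, 4L, 2L))
  counts[1L, , , 1L] <- fwd
  counts[1L, , , 2L] <- tot - fwd
  allele_counts(sample_id, frame$positions, counts)
}

#' Simulate reference-genome allele counts for the full pipeline
#'
#' Emulates the aligner + pileup stage for each reference genome: clean
#' clonal sequencing of one genome at a stated depth, producing the count
#' tensor the filtering cascade consumes.
#'
#' @param frame a `clonal_frame`.
#' @param depth per-genome sequencing depth (default 50).
#' @param dispersion,error_rate see [simulate_sample_counts()].
#' @param seed integer seed.
#' @return an [allele_counts] object with one row per frame genome.
#' @export
simulate_reference_counts <- function(frame, depth = 50, dispersion = 20,
                                      error_rate = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ids <- rownames(frame$genotypes)
  np <- length(frame$positions)
  counts <- array(0, c(length(ids), np, 4L, 2L))
  for (i in seq_along(ids)) {
    one <- simulate_sample_counts(frame, stats::setNames(1, ids[i]), depth,
                                  dispersion = dispersion,
                                  error_rate = error_rate,
                                  sample_id = ids[i])
    counts[i, , , ] <- one$counts[1L, , , ]
  }
  allele_counts(ids, frame$positions, counts)
}
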