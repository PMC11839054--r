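# Shared fixture builders.  Everything is generated in code; no binary data.

# Build an allele_counts object from a depth matrix (samples x positions)
# where every read carries the stated genotype allele, split evenly across
# strands (odd depths put the extra read on the forward strand).
acm_from_depths <- function(depths, genotypes, positions = NULL,
                            call_quality = NULL, indel_fraction = NULL) {
  ns <- nrow(depths)
  np <- ncol(depths)
  if (is.null(positions)) positions <- seq_len(np)
  counts <- array(0, c(ns, np, 4, 2))
  nuc <- c("A", "C", "G", "T")
  for (s in seq_len(ns)) {
    for (p in seq_len(np)) {
      k <- match(genotypes[s, p], nuc)
      d <- depths[s, p]
      counts[s, p, k, 1] <- ceiling(d / 2)
      counts[s, p, k, 2] <- floor(d / 2)
    }
  }
  allele_counts(rownames(depths) %||% paste0("s", seq_len(ns)),
                positions, counts, call_quality, indel_fraction)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Single-sample allele_counts with explicit per-position (x, y) counts for
# one clade allele vs one background allele.
acm_xy <- function(positions, x, y, allele = "A", other = "C",
                   sample_id = "s1") {
  np <- length(positions)
  counts <- array(0, c(1, np, 4, 2))
  ai <- match(allele, c("A", "C", "G", "T"))
  oi <- match(other, c("A", "C", "G", "T"))
  for (p in seq_len(np)) {
    counts[1, p, ai, 1] <- ceiling(x[p] / 2)
    counts[1, p, ai, 2] <- floor(x[p] / 2)
    rest <- y[p] - x[p]
    counts[1, p, oi, 1] <- ceiling(rest / 2)
    counts[1, p, oi, 2] <- floor(rest / 2)
  }
  allele_counts(sample_id, positions, counts)
}

# A small hand-specified genotype matrix: 6 genomes x 20 positions with a
# 3-genome clade {gA, gB, gC} carrying private alleles at known positions.
toy_genotypes <- function() {
  nuc <- c("A", "C", "G", "T")
  set.seed(99)
  base <- matrix(sample(nuc, 20, replace = TRUE), nrow = 1)
  calls <- base[rep(1, 6), ]
  rownames(calls) <- c("gA", "gB", "gC", "gD", "gE", "gF")
  # clade-private alleles at positions 2, 7, 11 (shared by gA..gC only)
  for (p in c(2, 7, 11)) {
    alt <- setdiff(nuc, calls[1, p])[1]
    calls[1:3, p] <- alt
  }
  # a non-clade-specific variant: gD shares the clade allele at position 15
  alt15 <- setdiff(nuc, calls[1, 15])[1]
  calls[c(1:3, 4), 15] <- alt15
  # an ambiguous clade position: gA is N at position 18 where gB,gC carry alt
  alt18 <- setdiff(nuc, calls[1, 18])[1]
  calls[2:3, 18] <- alt18
  calls[1, 18] <- "N"
  genotype_matrix(calls, seq_len(20) * 10)
}

# Independent brute-force barcode oracle: literal position-by-position
# re-statement of the barcode rules, used to check the vectorized finder.
oracle_barcode <- function(members, genotypes, outgroups = character(0),
                           max_inclade_ambig = 0.10,
                           max_outgroup_nonambig = 0.10) {
  ids <- genotypes$genome_ids
  calls <- genotypes$calls
  others <- setdiff(ids, c(members, outgroups))
  out <- data.frame(position = integer(0), allele = character(0))
  for (j in seq_along(genotypes$positions)) {
    inc <- calls[match(members, ids), j]
    nonN <- inc[inc != "N"]
    if (length(unique(nonN)) != 1L) next
    allele <- nonN[1]
    if (mean(inc == "N") >= max_inclade_ambig) next
    if (any(calls[match(others, ids), j] == allele)) next
    if (length(outgroups) > 0) {
      og <- calls[match(outgroups, ids), j]
      if (mean(og != "N") > max_outgroup_nonambig) next
    }
    out <- rbind(out, data.frame(position = genotypes$positions[j],
                                 allele = allele))
  }
  out
}

# Small cached frame shared by heavier tests (built once per test run).
small_frame <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_genomes(n_genomes = 15, core_length = 3e4,
                                 mean_branch_internal = 600,
                                 mean_branch_terminal = 150, seed = 77)
    }
    cache
  }
})

# Fake clade_fit carrying engineered pi draws, for detection-rule tests.
fake_fit <- function(pi_draws, lambda = 5, lambda_all = 10,
                     status = "ok") {
  draws <- cbind(pi = pi_draws, lambda = lambda, alpha = 1)
  structure(list(clade_id = "fake", method = "gibbs", status = status,
                 n_positions = length(pi_draws), n_supporting = 99,
                 draws = draws, pi_grid = NULL, pi_weight = NULL,
                 map = c(pi = stats::median(pi_draws), lambda = lambda,
                         alpha = 1),
                 hpd_pi = hpd_interval(pi_draws),
                 lambda_all = lambda_all, alpha_all = 1,
                 prior = list(a = 1, b = 1, fallback = FALSE), seed = 1,
                 rhat_pi = 1, warnings = character(0)),
            class = "clade_fit")
}
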