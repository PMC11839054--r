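test_that("clonal frames are reproducible and internally consistent", {
  f1 <- simulate_genomes(8, 1e4, mean_branch_internal = 400,
                         mean_branch_terminal = 100, seed = 5)
  f2 <- simulate_genomes(8, 1e4, mean_branch_internal = 400,
                         mean_branch_terminal = 100, seed = 5)
  expect_identical(f1$genotypes, f2$genotypes)
  expect_identical(f1$tree$edge.length, f2$tree$edge.length)
  # genotype distance to any other genome equals the mutation count on the
  # connecting path (no back-mutation by construction)
  geno <- frame_genotypes(f1)
  d <- hamming_matrix(geno)
  pat <- ape::cophenetic.phylo(f1$tree)[geno$genome_ids, geno$genome_ids]
  expect_equal(unname(d), unname(pat))
  # vanishing mutation rate: all genomes identical
  f0 <- simulate_genomes(5, 1e3, mean_branch_internal = 1e-9,
                         mean_branch_terminal = 1e-9, seed = 1)
  expect_equal(length(f0$positions), 0)
  # too-dense mutation load errors with advice
  expect_error(simulate_genomes(10, 200, mean_branch_internal = 500,
                                mean_branch_terminal = 500, seed = 2),
               "core_length")
})

test_that("true divergence follows the branch-sharing arithmetic", {
  # handmade tree: clade {a,b} subtended by a 400-SNV branch from n2; x
  # diverges part-way down that path in the pruned database tree
  txt <- "(((a:50,b:50)n3:300,x:120)n2:100,(c:60,d:60)n4:500)r;"
  tree <- ape::read.tree(text = txt)
  tree$node.label <- rep(1, tree$Nnode)
  frame <- structure(list(tree = tree), class = "clonal_frame")
  # genome inside the clade: full sharing
  expect_equal(true_divergence(frame, c("a", "b"), "a"), 0)
  # after dropping x the defining branch of {a,b} is 300 + 100 = 400;
  # x attaches at n3's parent, i.e. 100/400 of the branch is shared
  expect_equal(true_divergence(frame, c("a", "b"), "x",
                               branch_length = 400), 0.75)
  # c diverges at the top of (or above) the branch: no sharing
  expect_equal(true_divergence(frame, c("a", "b"), "c",
                               branch_length = 400), 1)
  # diverging 3/4 of the way down a 1200-SNV concatenated branch (300
  # unshared SNVs remain below the attachment) leaves DV = 0.25
  expect_equal(true_divergence(frame, c("a", "b"), "x",
                               branch_length = 1200), 0.25,
               tolerance = 1e-12)
  expect_error(true_divergence(frame, c("a", "b"), "nope"), "leaf")
})

test_that("sample count simulation matches its stated expectations", {
  frame <- small_frame()
  g <- rownames(frame$genotypes)[1]
  # Poisson depths, no errors: every read carries the genotype allele
  cnt <- simulate_sample_counts(frame, stats::setNames(1, g), 20,
                                dispersion = Inf, seed = 9)
  tot <- apply(cnt$counts[1, , , ], c(1, 2), sum)
  ai <- match(frame$genotypes[g, ], c("A", "C", "G", "T"))
  own <- tot[cbind(seq_len(nrow(tot)), ai)]
  expect_equal(rowSums(tot), own)
  expect_equal(mean(rowSums(tot)), 20, tolerance = 0.1)
  # 50/50 two-genome mixture at 100X: private alleles average ~50X
  g2 <- rownames(frame$genotypes)[8]
  mix <- stats::setNames(c(0.5, 0.5), c(g, g2))
  cnt2 <- simulate_sample_counts(frame, mix, 100, seed = 10)
  diff_pos <- which(frame$genotypes[g, ] != frame$genotypes[g2, ])
  tot2 <- apply(cnt2$counts[1, diff_pos, , ], c(1, 2), sum)
  ai1 <- match(frame$genotypes[g, diff_pos], c("A", "C", "G", "T"))
  private_depth <- tot2[cbind(seq_along(diff_pos), ai1)]
  expect_equal(mean(private_depth), 50, tolerance = 0.2)
  # determinism
  cnt3 <- simulate_sample_counts(frame, mix, 100, seed = 10)
  expect_identical(cnt2$counts, cnt3$counts)
  # substitution errors land on non-genotype alleles at the stated rate
  cnt4 <- simulate_sample_counts(frame, stats::setNames(1, g), 50,
                                 dispersion = Inf, error_rate = 0.02,
                                 seed = 11)
  tot4 <- apply(cnt4$counts[1, , , ], c(1, 2), sum)
  own4 <- tot4[cbind(seq_len(nrow(tot4)), ai)]
  err_frac <- 1 - sum(own4) / sum(tot4)
  expect_equal(err_frac, 0.02, tolerance = 0.25)
})

test_that("lognormal mixtures normalize to 1", {
  set.seed(3)
  f <- lognormal_mixture(5)
  expect_length(f, 5)
  expect_equal(sum(f), 1)
  expect_true(all(f > 0))
})

test_that("excess distance equals the weighted-distance arithmetic", {
  nuc <- c("A", "C", "G", "T")
  set.seed(12)
  base <- sample(nuc, 60, replace = TRUE)
  flip <- function(v, idx) {
    v[idx] <- vapply(v[idx], function(b) setdiff(nuc, b)[1], "")
    v
  }
  calls <- rbind(truth = base,
                 near = flip(base, 1:10),     # 10 SNVs from truth
                 far = flip(base, 11:30),     # 20 SNVs from truth
                 other = flip(base, 31:55))   # 25 SNVs from truth
  geno <- genotype_matrix(calls, seq_len(60))
  dbg <- c("near", "far", "other")
  # single output = closest reference: zero excess
  expect_equal(excess_distance(c(near = 1), "truth", dbg, geno), 0)
  # R = (0.5, 0.5), distances (10, 20), closest 10 -> excess 5
  expect_equal(excess_distance(c(near = 0.5, far = 0.5), "truth", dbg,
                               geno), 5)
  # weights renormalize; brute-force recomputation on a random output set
  set.seed(13)
  w <- stats::runif(3)
  outs <- stats::setNames(w, dbg)
  deltas <- c(10, 20, 25)
  expect_equal(excess_distance(outs, "truth", dbg, geno),
               sum((w / sum(w)) * (deltas - 10)))
  expect_true(is.na(excess_distance(stats::setNames(numeric(0),
                                                    character(0)),
                                    "truth", dbg, geno)))
})

test_that("profile metrics reproduce hand confusion counts", {
  truth <- c(c1 = 0.5, c2 = 0.3, c3 = 0.005, c4 = 0)
  exact <- profile_metrics(truth, truth)
  expect_equal(unname(exact[c("precision", "recall", "f1", "l2")]),
               c(1, 1, 1, 0))
  # empty estimate: no false claims -> precision 1, recall 0
  none <- profile_metrics(truth, stats::setNames(numeric(0), character(0)))
  expect_equal(unname(none["precision"]), 1)
  expect_equal(unname(none["recall"]), 0)
  expect_equal(unname(none["f1"]), 0)
  # hand-built 4-clade case: est calls c1 (TP), misses c2 (FN), adds c4
  # (FP); c3 below the 1% floor on both sides
  est <- c(c1 = 0.4, c2 = 0.004, c3 = 0.002, c4 = 0.2)
  m <- profile_metrics(truth, est)
  expect_equal(unname(m["precision"]), 1 / 2)   # TP 1, FP 1
  expect_equal(unname(m["recall"]), 1 / 2)      # TP 1, FN 1
  expect_equal(unname(m["f1"]), 0.5)
  expect_equal(unname(m["l2"]),
               sqrt(sum((c(0.5, 0.3, 0.005, 0) -
                           c(0.4, 0.004, 0.002, 0.2))^2)))
})
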