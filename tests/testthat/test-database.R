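# Hand-built scaled phylogeny with known branch lengths and bootstraps.
toy_phylo <- function(bootstraps = c(NA, 0.9, 0.9, 0.9)) {
  txt <- paste0("(((a:100,b:100)n3:1000,(c:100,d:100,e:100,f:100)n4:999)",
                "n2:500,(g:100,h:100)nX:500)n1;")
  tree <- ape::read.tree(text = txt)
  tree$node.label <- bootstraps[seq_len(tree$Nnode)]
  structure(list(tree = tree, bootstrap = tree$node.label,
                 scale_unit = "SNVs", slope = 1, r = 1),
            class = "scaled_phylogeny")
}

test_that("candidate-clade criteria follow the stated inequalities", {
  # n1 root; n2 = {a..f} branch 500; n3 = {a,b} 2 members; n4 = {c..f}
  # 4 members, branch 999
  sp <- toy_phylo(c(NA, 0.9, 0.9, 0.9, 0.9))
  cand <- enumerate_candidate_clades(sp)
  got <- cand[, c("clade_id", "n_members", "branch_length", "accepted")]
  n3 <- cand[cand$n_members == 2, ]
  expect_false(n3$accepted)                      # < 4 genomes
  n4 <- cand[cand$n_members == 4 & cand$branch_length == 999, ]
  expect_false(n4$accepted)                      # branch 999 < 1000
  # exactly 1000 SNVs passes (>=), exactly 0.75 bootstrap fails (>)
  sp2 <- toy_phylo(c(NA, 0.9, 0.9, 0.9, 0.9))
  sp2$tree$edge.length[sp2$tree$edge[, 2] ==
                         ape::getMRCA(sp2$tree, c("c", "d", "e", "f"))] <-
    1000
  cand2 <- enumerate_candidate_clades(sp2)
  expect_true(cand2$accepted[cand2$n_members == 4])
  sp3 <- sp2
  sp3$bootstrap[] <- 0.75
  sp3$tree$node.label[] <- 0.75
  cand3 <- enumerate_candidate_clades(sp3)
  expect_false(any(cand3$accepted))              # bootstrap not > 0.75
  # the two root-adjacent branches are never candidates
  root_kids <- sp$tree$edge[sp$tree$edge[, 1] ==
                              length(sp$tree$tip.label) + 1L, 2]
  expect_false(any(cand$node %in% root_kids))
})

test_that("clade-specific alleles match the brute-force oracle", {
  geno <- toy_genotypes()
  members <- c("gA", "gB", "gC")
  bc <- find_clade_specific_alleles(members, geno)
  oracle <- oracle_barcode(members, geno)
  expect_equal(bc$position, oracle$position)
  expect_equal(bc$allele, oracle$allele)
  # engineered structure: private alleles at positions 2, 7, 11 are in;
  # position 15 (shared with gD) is out; position 18 (1/3 in-clade N) out
  expect_setequal(bc$position, c(20, 70, 110))

  # an allele carried by one non-member genome is excluded
  geno2 <- geno
  geno2$calls["gF", 2] <- geno$calls["gA", 2]
  expect_false(20 %in% find_clade_specific_alleles(members, geno2)$position)

  # outgroup mask: positions callable in > 10% of outgroups are discarded
  bc_og <- find_clade_specific_alleles(members, geno,
                                       outgroups = c("gE", "gF"))
  expect_length(bc_og$position, 0)      # outgroups callable everywhere
  geno3 <- geno
  geno3$calls[c("gE", "gF"), 2] <- "N"
  bc_og3 <- find_clade_specific_alleles(members, geno3,
                                        outgroups = c("gE", "gF"))
  expect_setequal(bc_og3$position, 20)
  expect_equal(bc_og3, oracle_barcode(members, geno3,
                                      outgroups = c("gE", "gF")),
               ignore_attr = TRUE)
})

test_that("random frames satisfy the barcode correctness oracle", {
  for (seed in c(101, 202)) {
    frame <- simulate_genomes(12, 2e4, mean_branch_internal = 500,
                              mean_branch_terminal = 100, seed = seed)
    geno <- frame_genotypes(frame)
    sp <- scale_tree(frame$tree, geno)
    db <- tryCatch(
      build_database(sp, geno, min_branch = 200, min_genomes = 3),
      error = function(e) NULL)
    if (is.null(db)) next
    for (id in db$clades$clade_id) {
      bc <- db$barcodes[[id]]
      expect_equal(bc, oracle_barcode(db$members[[id]], geno,
                                      max_inclade_ambig = 0.10),
                   ignore_attr = TRUE)
      idx <- match(bc$position, geno$positions)
      inc <- geno$calls[match(db$members[[id]], geno$genome_ids), idx,
                        drop = FALSE]
      outc <- geno$calls[!geno$genome_ids %in% db$members[[id]], idx,
                         drop = FALSE]
      al <- matrix(bc$allele, nrow(inc), length(idx), byrow = TRUE)
      expect_true(all(inc == al | inc == "N"))
      alo <- matrix(bc$allele, nrow(outc), length(idx), byrow = TRUE)
      expect_true(all(outc != alo))
    }
    # nested clades carry disjoint (position, allele) barcodes
    ids <- db$clades$clade_id
    for (i in seq_along(ids)) {
      for (j in seq_along(ids)) {
        if (i == j) next
        if (all(db$members[[i]] %in% db$members[[j]])) {
          shared <- merge(db$barcodes[[i]], db$barcodes[[j]])
          expect_equal(nrow(shared), 0)
        }
      }
    }
  }
})

test_that("build_database enforces the minimum barcode size", {
  sp <- toy_phylo(c(NA, 0.9, 0.9, 0.9, 0.9))
  sp$tree$edge.length[sp$tree$edge[, 2] ==
                        ape::getMRCA(sp$tree, c("c", "d", "e", "f"))] <- 1000
  nuc <- c("A", "C", "G", "T")
  set.seed(7)
  base <- sample(nuc, 40, replace = TRUE)
  calls <- matrix(rep(base, each = 8), 8, 40,
                  dimnames = list(letters[1:8], NULL))
  # give clade {c,d,e,f} exactly 9 private alleles
  for (p in 1:9) {
    calls[3:6, p] <- setdiff(nuc, base[p])[1]
  }
  geno <- genotype_matrix(calls, seq_len(40))
  expect_error(build_database(sp, geno), "empty database")
  db9 <- build_database(sp, geno, min_cssnvs = 9)
  expect_equal(db9$clades$n_cssnvs, 9L)
  # a 10th private allele admits the clade at the default threshold
  calls[3:6, 10] <- setdiff(nuc, base[10])[1]
  db10 <- build_database(sp, genotype_matrix(calls, seq_len(40)))
  expect_equal(db10$clades$n_cssnvs, 10L)
})

test_that("database archives round-trip", {
  frame <- small_frame()
  geno <- frame_genotypes(frame)
  db <- build_database(scale_tree(frame$tree, geno), geno,
                       min_branch = 300, min_genomes = 3)
  dir <- withr::local_tempdir()
  save_database(db, dir)
  db2 <- load_database(dir)
  expect_equal(db2$clades[, c("clade_id", "n_members", "branch_length",
                              "bootstrap", "n_cssnvs", "level")],
               db$clades[, c("clade_id", "n_members", "branch_length",
                             "bootstrap", "n_cssnvs", "level")])
  expect_equal(db2$members, db$members)
  expect_equal(db2$barcodes, db$barcodes, ignore_attr = TRUE)
  expect_equal(db2$informative_positions, db$informative_positions)
  # deterministic build: serializing again is byte-identical
  dir2 <- withr::local_tempdir()
  save_database(db2, dir2)
  for (f in list.files(dir)) {
    expect_identical(readLines(file.path(dir2, f)),
                     readLines(file.path(dir, f)), label = f)
  }
})

test_that("removing a genome matches exhaustive barcode recomputation", {
  frame <- small_frame()
  geno <- frame_genotypes(frame)
  sp <- scale_tree(frame$tree, geno)
  db <- build_database(sp, geno, min_branch = 300, min_genomes = 3)
  victim <- setdiff(geno$genome_ids, unlist(db$members))[1]
  if (is.na(victim)) victim <- geno$genome_ids[1]
  keep <- setdiff(geno$genome_ids, victim)
  geno2 <- genotype_matrix(geno$calls[keep, , drop = FALSE],
                           geno$positions)
  pruned <- ape::drop.tip(frame$tree, victim)
  pruned$node.label <- rep(1, pruned$Nnode)
  db2 <- build_database(scale_tree(pruned, geno2), geno2,
                        min_branch = 300, min_genomes = 3)
  for (id in db2$clades$clade_id) {
    expect_equal(db2$barcodes[[id]],
                 oracle_barcode(db2$members[[id]], geno2),
                 ignore_attr = TRUE)
  }
})
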