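#' Enumerate candidate clades on a scaled phylogeny
#'
#' Every internal node defines a candidate clade (the leaves it subtends).
#' A candidate is accepted when it has at least `min_genomes` members, its
#' subtending branch is at least `min_branch` SNVs long, and its bootstrap
#' support strictly exceeds `min_bootstrap`.  Nested acceptance is allowed
#' and is what produces the hierarchical levels of the database.  The two
#' branches originating at the root are excluded (their split is an artefact
#' of rooting).
#'
#' @param phylo a `scaled_phylogeny` from [scale_tree()].
#' @param min_genomes minimum clade size (default 4).
#' @param min_branch minimum subtending-branch length in SNVs (default 1000,
#'   `>=` accepts).
#' @param min_bootstrap minimum bootstrap (default 0.75, strict `>` accepts;
#'   `NA` support never accepts).
#' @param allow_unscaled evaluate `min_branch` against raw branch lengths
#'   when the tree could not be SNV-scaled (default `FALSE`: error).
#' @return data.frame with one row per internal node considered: `clade_id`,
#'   `node`, `n_members`, `branch_length`, `bootstrap`, `accepted`, plus a
#'   list-column `members` of genome ids.
#' @export
enumerate_candidate_clades <- function(phylo, min_genomes = 4,
                                       min_branch = 1000,
                                       min_bootstrap = 0.75,
                                       allow_unscaled = FALSE) {
  stopifnot(inherits(phylo, "scaled_phylogeny"))
  if (phylo$scale_unit != "SNVs" && !allow_unscaled) {
    stop("tree branch lengths are not in SNV units (scaling correlation r = ",
         sprintf("%.3f", phylo$r), " did not exceed the threshold); ",
         "clade branch-length criteria are undefined — rerun with ",
         "allow_unscaled = TRUE to use raw units")
  }
  tree <- phylo$tree
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  internal <- sort(setdiff((ntip + 1L):(ntip + tree$Nnode), root))
  root_children <- tree$edge[tree$edge[, 1L] == root, 2L]
  rows <- list()
  for (nd in internal) {
    if (nd %in% root_children) next
    edge_i <- which(tree$edge[, 2L] == nd)
    blen <- tree$edge.length[edge_i]
    members <- tree$tip.label[tip_descendants(tree, nd)]
    bs <- phylo$bootstrap[nd - ntip]
    accepted <- length(members) >= min_genomes &&
      blen >= min_branch && !is.na(bs) && bs > min_bootstrap
    rows[[length(rows) + 1L]] <- list(
      clade_id = paste0("clade_", nd), node = nd,
      n_members = length(members), branch_length = blen,
      bootstrap = bs, accepted = accepted, members = members)
  }
  out <- data.frame(
    clade_id = vapply(rows, `[[`, "", "clade_id"),
    node = vapply(rows, `[[`, 0L, "node"),
    n_members = vapply(rows, `[[`, 0L, "n_members"),
    branch_length = vapply(rows, `[[`, 0, "branch_length"),
    bootstrap = vapply(rows, `[[`, 0, "bootstrap"),
    accepted = vapply(rows, `[[`, TRUE, "accepted"),
    stringsAsFactors = FALSE)
  out$members <- lapply(rows, `[[`, "members")
  out
}

# Tip indices descending from a node (the node itself if it is a tip).
tip_descendants <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(node)
  out <- integer(0)
  stack <- node
  children <- split(tree$edge[, 2L], tree$edge[, 1L])
  while (length(stack) > 0L) {
    nd <- stack[length(stack)]
    stack <- stack[-length(stack)]
    kids <- children[[as.character(nd)]]
    tips <- kids[kids <= ntip]
    out <- c(out, tips)
    stack <- c(stack, kids[kids > ntip])
  }
  sort(out)
}

#' Find the clade-specific SNV barcode of one clade
#'
#' A (position, allele) pair belongs to the barcode when: every in-clade
#' genome with a non-ambiguous call carries the allele; fewer than
#' `max_inclade_ambig` of in-clade members are ambiguous there; no genome
#' outside the clade carries the allele; and (when outgroup genomes are
#' supplied) at most `max_outgroup_nonambig` of outgroups have a
#' non-ambiguous call at the position.
#'
#' @param members genome ids forming the clade.
#' @param genotypes a [genotype_matrix()] containing members, all other
#'   reference genomes, and any outgroups.
#' @param outgroups genome ids of user-defined outgroup genomes assumed to
#'   competitively recruit reads (default none); they are excluded from the
#'   "any other genome" comparison and used only for the position mask.
#' @param max_inclade_ambig maximum in-clade ambiguous fraction
#'   (default 0.10; a fraction `>=` this removes the position).
#' @param max_outgroup_nonambig maximum fraction of outgroups with a
#'   non-ambiguous call (default 0.10, strict `>` removes the position).
#' @return data.frame with columns `position`, `allele`.
#' @export
find_clade_specific_alleles <- function(members, genotypes,
                                        outgroups = character(0),
                                        max_inclade_ambig = 0.10,
                                        max_outgroup_nonambig = 0.10) {
  ids <- genotypes$genome_ids
  if (!all(members %in% ids)) stop("clade members missing from genotypes")
  calls <- genotypes$calls
  inc <- calls[match(members, ids), , drop = FALSE]
  others <- setdiff(ids, c(members, outgroups))
  outc <- calls[match(others, ids), , drop = FALSE]
  np <- ncol(calls)

  n_frac <- colMeans(inc == "N")
  # unanimous non-N allele within the clade
  allele <- rep(NA_character_, np)
  n_alleles <- integer(np)
  for (b in c("A", "C", "G", "T")) {
    hit <- colSums(inc == b) > 0L
    allele[hit & is.na(allele)] <- b
    n_alleles <- n_alleles + hit
  }
  unanimous <- n_alleles == 1L & !is.na(allele)
  keep <- unanimous & n_frac < max_inclade_ambig
  if (nrow(outc) > 0L) {
    idx <- which(keep)
    if (length(idx) > 0L) {
      carried <- colSums(outc[, idx, drop = FALSE] ==
                           matrix(allele[idx], nrow(outc), length(idx),
                                  byrow = TRUE)) > 0L
      keep[idx[carried]] <- FALSE
    }
  }
  if (length(outgroups) > 0L) {
    og <- calls[match(outgroups, ids), , drop = FALSE]
    og_nonN <- colMeans(og != "N")
    keep <- keep & og_nonN <= max_outgroup_nonambig
  }
  data.frame(position = genotypes$positions[keep],
             allele = allele[keep], stringsAsFactors = FALSE)
}

#' Build a hierarchical clade reference database
#'
#' Enumerates candidate clades on the scaled phylogeny, derives the
#' clade-specific SNV barcode of each accepted candidate, removes clades
#' whose barcode is smaller than `min_cssnvs`, and assigns hierarchical
#' levels by nesting depth (level 1 = outermost accepted clades).
#'
#' @param phylo a `scaled_phylogeny` from [scale_tree()].
#' @param genotypes a [genotype_matrix()] covering all leaves.
#' @param outgroups optional outgroup genome ids (see
#'   [find_clade_specific_alleles()]).
#' @param min_genomes,min_branch,min_bootstrap candidate-clade criteria, see
#'   [enumerate_candidate_clades()].
#' @param min_cssnvs minimum barcode size (default 10).
#' @param max_inclade_ambig,max_outgroup_nonambig barcode criteria, see
#'   [find_clade_specific_alleles()].
#' @param allow_unscaled see [enumerate_candidate_clades()].
#' @return An object of class `reference_db`: list with `phylo`, `clades`
#'   (data.frame: clade_id, node, n_members, branch_length, bootstrap,
#'   n_cssnvs, level), `members` (named list of genome-id vectors),
#'   `barcodes` (named list of position/allele data.frames),
#'   `informative_positions`, and `params`.
#' @export
build_database <- function(phylo, genotypes, outgroups = character(0),
                           min_genomes = 4, min_branch = 1000,
                           min_bootstrap = 0.75, min_cssnvs = 10,
                           max_inclade_ambig = 0.10,
                           max_outgroup_nonambig = 0.10,
                           allow_unscaled = FALSE) {
  cand <- enumerate_candidate_clades(phylo, min_genomes = min_genomes,
                                     min_branch = min_branch,
                                     min_bootstrap = min_bootstrap,
                                     allow_unscaled = allow_unscaled)
  acc <- cand[cand$accepted, , drop = FALSE]
  barcodes <- list()
  keep <- logical(nrow(acc))
  for (i in seq_len(nrow(acc))) {
    bc <- find_clade_specific_alleles(
      acc$members[[i]], genotypes, outgroups = outgroups,
      max_inclade_ambig = max_inclade_ambig,
      max_outgroup_nonambig = max_outgroup_nonambig)
    if (nrow(bc) >= min_cssnvs) {
      keep[i] <- TRUE
      barcodes[[acc$clade_id[i]]] <- bc
    }
  }
  acc <- acc[keep, , drop = FALSE]
  if (nrow(acc) == 0L) {
    stop("empty database: no candidate clade passed the acceptance and ",
         "minimum-barcode criteria")
  }
  members <- acc$members
  names(members) <- acc$clade_id
  # nesting depth among the final clade set
  level <- vapply(seq_along(members), function(i) {
    1L + sum(vapply(seq_along(members), function(j) {
      j != i && length(members[[j]]) > length(members[[i]]) &&
        all(members[[i]] %in% members[[j]])
    }, TRUE))
  }, 0L)
  clades <- data.frame(
    clade_id = acc$clade_id, node = acc$node, n_members = acc$n_members,
    branch_length = acc$branch_length, bootstrap = acc$bootstrap,
    n_cssnvs = vapply(acc$clade_id, function(id) nrow(barcodes[[id]]), 0L),
    level = level, stringsAsFactors = FALSE)
  rownames(clades) <- NULL
  structure(list(
    phylo = phylo, clades = clades, members = members, barcodes = barcodes,
    informative_positions =
      sort(unique(unlist(lapply(barcodes, `[[`, "position")))),
    params = list(min_genomes = min_genomes, min_branch = min_branch,
                  min_bootstrap = min_bootstrap, min_cssnvs = min_cssnvs,
                  max_inclade_ambig = max_inclade_ambig,
                  max_outgroup_nonambig = max_outgroup_nonambig,
                  scale_unit = phylo$scale_unit,
                  n_outgroups = length(outgroups))),
    class = "reference_db")
}

#' @export
print.reference_db <- function(x, ...) {
  cat("reference_db: ", nrow(x$clades), " clade(s) over ",
      length(x$phylo$tree$tip.label), " genomes; ",
      length(x$informative_positions), " informative positions\n", sep = "")
  invisible(x)
}

#' Serialize a reference database to a plain-text archive directory
#'
#' Writes `clades.tsv`, `members.tsv`, `barcodes.tsv`, `tree.nwk` (branch
#' lengths in the database's scale unit, node labels carrying bootstrap) and
#' `params.txt`.  Deterministic: identical databases produce byte-identical
#' archives.
#'
#' @param db a `reference_db`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_database <- function(db, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fmt <- function(x) {
    if (is.numeric(x) && !is.integer(x)) sprintf("%.17g", x) else
      as.character(x)
  }
  write_tsv <- function(d, path) {
    d[] <- lapply(d, fmt)
    utils::write.table(d, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  write_tsv(db$clades, file.path(dir, "clades.tsv"))
  mem <- data.frame(
    clade_id = rep(names(db$members), lengths(db$members)),
    genome_id = unlist(db$members, use.names = FALSE))
  write_tsv(mem, file.path(dir, "members.tsv"))
  bc <- do.call(rbind, lapply(names(db$barcodes), function(id) {
    cbind(clade_id = id, db$barcodes[[id]])
  }))
  write_tsv(bc, file.path(dir, "barcodes.tsv"))
  tree <- db$phylo$tree
  tree$node.label <- ifelse(is.na(db$phylo$bootstrap), "",
                            sprintf("%.17g", db$phylo$bootstrap))
  ape::write.tree(tree, file.path(dir, "tree.nwk"), digits = 17)
  par <- c(db$params,
           list(scale_slope = db$phylo$slope, scale_r = db$phylo$r))
  writeLines(paste0(names(par), "=", vapply(par, fmt, "")),
             file.path(dir, "params.txt"))
  invisible(dir)
}

#' Load a reference database archive
#'
#' @param dir directory written by [save_database()].
#' @return a `reference_db`.
#' @export
load_database <- function(dir) {
  need <- c("clades.tsv", "members.tsv", "barcodes.tsv", "tree.nwk",
            "params.txt")
  miss <- need[!file.exists(file.path(dir, need))]
  if (length(miss) > 0L) {
    stop("not a database archive (missing ", paste(miss, collapse = ", "),
         "): ", dir)
  }
  clades <- utils::read.table(file.path(dir, "clades.tsv"), header = TRUE,
                              sep = "\t", stringsAsFactors = FALSE)
  mem <- utils::read.table(file.path(dir, "members.tsv"), header = TRUE,
                           sep = "\t", stringsAsFactors = FALSE)
  bc <- utils::read.table(file.path(dir, "barcodes.tsv"), header = TRUE,
                          sep = "\t", stringsAsFactors = FALSE,
                          colClasses = c("character", "integer", "character"))
  tree <- normalize_tree(ape::read.tree(file.path(dir, "tree.nwk")))
  par_lines <- readLines(file.path(dir, "params.txt"))
  kv <- strsplit(par_lines, "=", fixed = TRUE)
  params <- lapply(kv, function(x) {
    v <- paste(x[-1], collapse = "=")
    num <- suppressWarnings(as.numeric(v))
    if (is.na(num)) v else num
  })
  names(params) <- vapply(kv, `[[`, "", 1L)
  members <- split(mem$genome_id, mem$clade_id)[clades$clade_id]
  barcodes <- lapply(split(bc[, c("position", "allele")], bc$clade_id),
                     function(d) {
                       rownames(d) <- NULL
                       d
                     })[clades$clade_id]
  # node numbers are recomputed: tip/node numbering is an artefact of the
  # Newick serialization order
  clades$node <- vapply(clades$clade_id, function(id) {
    m <- members[[id]]
    if (length(m) == 1L) match(m, tree$tip.label) else
      ape::getMRCA(tree, m)
  }, 0L)
  phylo <- structure(list(tree = tree, bootstrap = tree$node.label,
                          scale_unit = params$scale_unit,
                          slope = params$scale_slope, r = params$scale_r),
                     class = "scaled_phylogeny")
  params$scale_slope <- NULL
  params$scale_r <- NULL
  structure(list(phylo = phylo, clades = clades, members = members,
                 barcodes = barcodes,
                 informative_positions = sort(unique(bc$position)),
                 params = params),
            class = "reference_db")
}
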