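#' Hold-out (novel diversity) experiment
#'
#' For every well-supported branch of the frame's tree (bootstrap > 0.75,
#' excluding the two branches originating at the root), all genomes
#' descended from the branch are held out, the reference database is rebuilt
#' from the remaining genomes, and one held-out genome is simulated at each
#' coverage and classified.  Each record pairs a clade's estimated `pi` with
#' the genome's true divergence `DV_b` from that clade's defining branch,
#' computed on the full tree.
#'
#' @param frame a `clonal_frame`.
#' @param db_params named list overriding [build_database()] defaults.
#' @param coverage_grid coverages to simulate (default 10).
#' @param method `"mle"` or `"gibbs"` (see [classify_sample()]).
#' @param dispersion,error_rate see [simulate_sample_counts()].
#' @param seed integer seed driving genome choice and count noise.
#' @param steps,burnin_frac Gibbs parameters when `method = "gibbs"`.
#' @return data.frame with one row per (hold-out, coverage, clade):
#'   `holdout_node`, `heldout_genome`, `n_heldout`, `coverage`, `clade`,
#'   `dv_true`, `pi_map`, `detected`, `relative_abundance`, `status`.
#' @export
holdout_experiment <- function(frame, db_params = list(),
                               coverage_grid = 10, method = "mle",
                               dispersion = 5, error_rate = 0, seed = 1,
                               steps = 10000, burnin_frac = 0.10) {
  tree <- frame$tree
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  root_children <- tree$edge[tree$edge[, 1L] == root, 2L]
  geno_all <- frame_genotypes(frame)
  # candidate held-out branches: daughters of well-supported internal nodes
  supported <- which(!is.na(tree$node.label) & tree$node.label > 0.75) + ntip
  targets <- unique(tree$edge[tree$edge[, 1L] %in% supported, 2L])
  targets <- setdiff(targets, root_children)
  rows <- list()
  set.seed(seed)
  run_seeds <- sample.int(1e6, length(targets))
  for (ti in seq_along(targets)) {
    nd <- targets[ti]
    heldout <- tree$tip.label[tip_descendants(tree, nd)]
    retained <- setdiff(tree$tip.label, heldout)
    if (length(retained) < 5L) next
    pruned <- ape::drop.tip(tree, heldout)
    pruned$node.label <- rep(1, pruned$Nnode)  # simulated topology is exact
    geno_ret <- genotype_matrix(
      geno_all$calls[match(retained, geno_all$genome_ids), , drop = FALSE],
      geno_all$positions)
    phylo <- scale_tree(pruned, geno_ret)
    db <- tryCatch(
      do.call(build_database, c(list(phylo = phylo, genotypes = geno_ret),
                                db_params)),
      error = function(e) NULL)
    if (is.null(db)) next
    set.seed(run_seeds[ti])
    g <- if (length(heldout) == 1L) heldout else sample(heldout, 1L)
    truth <- vapply(db$clades$clade_id, function(id) {
      i <- match(id, db$clades$clade_id)
      true_divergence(frame, db$members[[id]], g,
                      branch_length = db$clades$branch_length[i])
    }, 0)
    for (cov in coverage_grid) {
      cnt <- simulate_sample_counts(
        frame, stats::setNames(1, g), cov, dispersion = dispersion,
        error_rate = error_rate, sample_id = g,
        seed = (run_seeds[ti] + round(100 * cov)) %% .Machine$integer.max)
      prof <- classify_sample(cnt, db, method = method, steps = steps,
                              burnin_frac = burnin_frac,
                              seed = run_seeds[ti])
      rows[[length(rows) + 1L]] <- data.frame(
        holdout_node = nd, heldout_genome = g, n_heldout = length(heldout),
        coverage = cov, clade = prof$clade, dv_true = unname(truth),
        pi_map = prof$pi_map, detected = prof$detected,
        relative_abundance = prof$relative_abundance,
        status = prof$status, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "params") <- list(coverage_grid = coverage_grid,
                              method = method, dispersion = dispersion,
                              error_rate = error_rate, seed = seed)
  out
}

#' Synthetic multi-strain metagenome experiment
#'
#' Each replicate mixes `n_strains` random database genomes at lognormal
#' frequencies, simulates counts over a grid of focal coverages, classifies
#' the sample, and scores detections against the true clade frequencies
#' (the summed frequencies of each clade's member genomes) with
#' [profile_metrics()].
#'
#' @param frame a `clonal_frame`.
#' @param db a `reference_db` built from the frame (perfect database).
#' @param n_replicates number of mixtures (default 15).
#' @param coverages focal-species coverages
#'   (default `c(0.1, 0.5, 1, 2, 5, 10, 20)`).
#' @param n_strains genomes per mixture (default 5).
#' @param meanlog,sdlog lognormal abundance parameters (defaults 1, 1).
#' @param method,dispersion,error_rate,steps,burnin_frac see
#'   [holdout_experiment()].
#' @param seed integer seed.
#' @return data.frame with one row per (replicate, coverage):
#'   `replicate`, `coverage`, `precision`, `recall`, `f1`, `l2`,
#'   `n_true`, `n_detected`.
#' @export
mixture_experiment <- function(frame, db, n_replicates = 15,
                               coverages = c(0.1, 0.5, 1, 2, 5, 10, 20),
                               n_strains = 5, meanlog = 1, sdlog = 1,
                               method = "mle", dispersion = 5,
                               error_rate = 0, seed = 1, steps = 10000,
                               burnin_frac = 0.10) {
  tips <- frame$tree$tip.label
  set.seed(seed)
  rep_seeds <- sample.int(1e6, n_replicates)
  rows <- list()
  for (r in seq_len(n_replicates)) {
    set.seed(rep_seeds[r])
    genomes <- sample(tips, n_strains)
    freqs <- stats::setNames(lognormal_mixture(n_strains, meanlog, sdlog),
                             genomes)
    truth <- vapply(db$clades$clade_id, function(id) {
      sum(freqs[names(freqs) %in% db$members[[id]]])
    }, 0)
    for (cov in coverages) {
      cnt <- simulate_sample_counts(
        frame, freqs, cov, dispersion = dispersion,
        error_rate = error_rate,
        seed = (rep_seeds[r] + round(1000 * cov)) %% .Machine$integer.max)
      prof <- classify_sample(cnt, db, method = method, steps = steps,
                              burnin_frac = burnin_frac, seed = rep_seeds[r])
      est <- stats::setNames(ifelse(prof$detected,
                                    prof$relative_abundance, 0),
                             prof$clade)
      m <- profile_metrics(truth, est)
      rows[[length(rows) + 1L]] <- data.frame(
        replicate = r, coverage = cov, precision = m["precision"],
        recall = m["recall"], f1 = m["f1"], l2 = m["l2"],
        n_true = sum(truth > 0.01), n_detected = sum(prof$detected),
        row.names = NULL)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "params") <- list(n_replicates = n_replicates,
                              coverages = coverages, n_strains = n_strains,
                              meanlog = meanlog, sdlog = sdlog,
                              method = method, dispersion = dispersion,
                              error_rate = error_rate, seed = seed)
  out
}

#' Presence/abundance metrics for one profile
#'
#' Presence means frequency strictly above `presence_threshold` (default
#' 1%).  Precision is 1 by convention when nothing is called (no false
#' claims); recall is 1 when nothing is truly present; F1 is the harmonic
#' mean (0 when precision + recall = 0).  L2 is the Euclidean distance
#' between the frequency vectors over the union of clades.
#'
#' @param truth named numeric vector of true clade frequencies.
#' @param estimate named numeric vector of estimated clade frequencies.
#' @param presence_threshold presence cutoff (default 0.01, strict `>`).
#' @return named vector `c(precision, recall, f1, l2)`.
#' @export
profile_metrics <- function(truth, estimate, presence_threshold = 0.01) {
  clades <- union(names(truth), names(estimate))
  t_f <- stats::setNames(rep(0, length(clades)), clades)
  e_f <- t_f
  t_f[names(truth)] <- truth
  e_f[names(estimate)] <- estimate
  t_p <- t_f > presence_threshold
  e_p <- e_f > presence_threshold
  tp <- sum(t_p & e_p)
  fp <- sum(!t_p & e_p)
  fn <- sum(t_p & !e_p)
  precision <- if (tp + fp == 0) 1 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 1 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  c(precision = precision, recall = recall, f1 = f1,
    l2 = sqrt(sum((t_f - e_f)^2)))
}

#' Abundance-weighted excess SNV distance of reported genomes
#'
#' `sum_i R_i * (Delta_i - Delta_t)` where `Delta_i` is the SNV distance
#' from reported genome i to the truth genome and `Delta_t` the distance
#' from the truly closest database genome.  Weights are renormalized to sum
#' to 1 when they do not already.
#'
#' @param outputs named numeric vector: reported genome ids mapped to their
#'   relative abundances `R_i`.
#' @param truth_genome id of the true (held-out) genome.
#' @param db_genomes ids of all database genomes (`Delta_t` is minimized
#'   over these).
#' @param genotypes a [genotype_matrix()] containing all genomes involved.
#' @return excess distance in SNVs, or `NA` (a distinct no-call outcome)
#'   when `outputs` is empty.
#' @export
excess_distance <- function(outputs, truth_genome, db_genomes, genotypes) {
  if (length(outputs) == 0L) return(NA_real_)
  ids <- genotypes$genome_ids
  need <- unique(c(names(outputs), truth_genome, db_genomes))
  if (!all(need %in% ids)) stop("genome(s) missing from genotypes")
  calls <- genotypes$calls
  truth_calls <- calls[match(truth_genome, ids), ]
  dist_to_truth <- function(g) {
    hamming_distance(calls[match(g, ids), ], truth_calls)
  }
  delta_i <- vapply(names(outputs), dist_to_truth, 0)
  delta_t <- min(vapply(db_genomes, dist_to_truth, 0))
  w <- outputs / sum(outputs)
  sum(w * (delta_i - delta_t))
}

#' Zero-inflation parameter recovery experiment
#'
#' Simulates zero-inflated negative-binomial counts over a grid of true
#' `(pi, lambda)` cells and estimates `pi` with the marker-absence
#' heuristic, the unconstrained maximum-likelihood fit (no dispersion
#' prior), and the two-step prior-informed estimators (penalized MLE and,
#' optionally, Gibbs).
#'
#' @param pi_grid true zero-inflation values
#'   (default `c(0, 0.2, 0.4, 0.6, 0.8)`).
#' @param lambda_grid true expected depths (default `c(2, 10, 50)`).
#' @param alpha true dispersion shape (default 5).
#' @param n_positions positions per simulated clade (default 300).
#' @param replicates replicates per cell (default 3).
#' @param seed integer seed; the table is bit-reproducible given the seed.
#' @param methods estimators to run; subset of
#'   `c("heuristic", "mle_unconstrained", "mle", "gibbs")`.
#' @param steps,burnin_frac Gibbs parameters.
#' @return data.frame with one row per (cell, replicate, method):
#'   `pi_true`, `lambda_true`, `replicate`, `method`, `pi_hat`.
#' @export
zinb_recovery_experiment <- function(pi_grid = c(0, 0.2, 0.4, 0.6, 0.8),
                                     lambda_grid = c(2, 10, 50), alpha = 5,
                                     n_positions = 300, replicates = 3,
                                     seed = 1,
                                     methods = c("heuristic",
                                                 "mle_unconstrained",
                                                 "mle"),
                                     steps = 2000, burnin_frac = 0.10) {
  stopifnot(length(pi_grid) > 0, length(lambda_grid) > 0)
  set.seed(seed)
  rows <- list()
  for (pi_true in pi_grid) {
    for (lambda in lambda_grid) {
      for (r in seq_len(replicates)) {
        z <- stats::runif(n_positions) > pi_true
        lam_i <- stats::rgamma(n_positions, shape = alpha,
                               rate = alpha / lambda)
        x <- stats::rpois(n_positions, lam_i * z)
        y <- stats::rnbinom(n_positions, mu = lambda, size = alpha)
        ic <- list(clade_id = "sim", x = x, y = y)
        step1 <- fit_all_alleles(y)
        for (m in methods) {
          pi_hat <- switch(
            m,
            heuristic = mean(x == 0),
            mle_unconstrained = {
              f <- fit_zinb_mle(ic, prior = NULL, grid_points = 21)
              if (f$status == "ok") unname(f$map["pi"]) else NA_real_
            },
            mle = {
              f <- fit_zinb_mle(ic, prior = step1$prior, grid_points = 21,
                                lambda_all = step1$lambda_all)
              if (f$status == "ok") unname(f$map["pi"]) else NA_real_
            },
            gibbs = {
              f <- fit_zinb_gibbs(ic, step1$prior, steps = steps,
                                  burnin_frac = burnin_frac,
                                  seed = sample.int(1e6, 1),
                                  lambda_all = step1$lambda_all)
              if (f$status == "ok") unname(f$map["pi"]) else NA_real_
            },
            stop("unknown method: ", m))
          rows[[length(rows) + 1L]] <- data.frame(
            pi_true = pi_true, lambda_true = lambda, replicate = r,
            method = m, pi_hat = pi_hat, stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "params") <- list(alpha = alpha, n_positions = n_positions,
                              replicates = replicates, seed = seed)
  out
}
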