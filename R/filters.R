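#' Filtered genotype calls for reference genomes
#'
#' @param calls character matrix `genomes x positions` over `{A,C,G,T,N}`
#'   with genome ids as row names.
#' @param positions integer vector of 1-based coordinates, one per column.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(calls, positions) {
  positions <- as.integer(positions)
  stopifnot(is.matrix(calls), ncol(calls) == length(positions),
            !is.null(rownames(calls)))
  if (!all(calls %in% c("A", "C", "G", "T", "N"))) {
    stop("calls must be in {A,C,G,T,N}")
  }
  if (length(positions) > 1L && any(diff(positions) <= 0L)) {
    stop("positions must be strictly increasing")
  }
  structure(list(genome_ids = rownames(calls), positions = positions,
                 calls = calls),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix: ", length(x$genome_ids), " genome(s) x ",
      length(x$positions), " position(s); ",
      sprintf("%.2f%%", 100 * mean(x$calls == "N")), " ambiguous\n", sep = "")
  invisible(x)
}

#' Genome-level filters
#'
#' Stage one drops genomes whose median coverage across all positions is
#' below `min_median_cov`.  If `retained_positions` is supplied (stage two,
#' after position filtering) genomes with more than `max_ambig_frac`
#' ambiguous calls among those positions are additionally dropped.
#'
#' @param m an [allele_counts] object holding the reference genomes.
#' @param calls call matrix from [call_bases()], aligned to `m`.
#' @param min_median_cov minimum median depth (default 8).
#' @param max_ambig_frac maximum N fraction among retained positions
#'   (default 0.10, strict inequality fires the drop).
#' @param retained_positions coordinates surviving [filter_positions()];
#'   `NULL` skips the ambiguity stage.
#' @return character vector of retained genome ids.
#' @export
filter_genomes <- function(m, calls, min_median_cov = 8,
                           max_ambig_frac = 0.10,
                           retained_positions = NULL) {
  stopifnot(all(dim(calls) == c(length(m$sample_ids), length(m$positions))))
  depth <- total_depth(m)
  keep <- apply(depth, 1, stats::median) >= min_median_cov
  if (!is.null(retained_positions)) {
    pi <- match(retained_positions, m$positions)
    if (anyNA(pi)) stop("retained_positions not a subset of m$positions")
    if (length(pi) == 0L) {
      keep[] <- FALSE
    } else {
      nfrac <- rowMeans(calls[, pi, drop = FALSE] == "N")
      keep <- keep & nfrac <= max_ambig_frac
    }
  }
  m$sample_ids[keep]
}

#' Position-level filters
#'
#' Drops positions where more than `max_n_frac` of genomes carry an
#' ambiguous call, where the median cross-genome coverage is below
#' `min_median_cov`, or where the median cross-genome coverage exceeds
#' `copy_number_mult` times the genome-wide median of per-position median
#' coverages (a copy-number proxy).
#'
#' @param m an [allele_counts] object.
#' @param calls call matrix aligned to `m`.
#' @param max_n_frac maximum tolerated N fraction across genomes
#'   (default 0.10, strict inequality fires the drop).
#' @param min_median_cov minimum median cross-genome depth (default 5).
#' @param copy_number_mult copy-number multiple of the overall median
#'   (default 2, strict inequality fires the drop).
#' @param genomes optional subset of genome ids to evaluate over (e.g. the
#'   coverage-retained set).
#' @return sorted integer vector of retained coordinates.
#' @export
filter_positions <- function(m, calls, max_n_frac = 0.10,
                             min_median_cov = 5, copy_number_mult = 2,
                             genomes = m$sample_ids) {
  si <- match(genomes, m$sample_ids)
  if (anyNA(si)) stop("unknown genome id(s)")
  depth <- total_depth(m)[si, , drop = FALSE]
  nfrac <- colMeans(calls[si, , drop = FALSE] == "N")
  med <- apply(depth, 2, stats::median)
  overall <- stats::median(med)
  keep <- nfrac <= max_n_frac &
    med >= min_median_cov &
    med <= copy_number_mult * overall
  sort(m$positions[keep])
}

#' Build a filtered genotype matrix from reference-genome counts
#'
#' Runs the full filtering cascade: base calling, genome coverage filter,
#' position filters over the coverage-retained genomes, then the
#' post-filtering genome ambiguity filter.
#'
#' @param m an [allele_counts] object holding reference genomes.
#' @param maf_min,strand_min,fq_max,indel_max see [call_bases()].
#' @param genome_min_cov,genome_max_ambig see [filter_genomes()].
#' @param pos_max_n,pos_min_cov,pos_copy_mult see [filter_positions()].
#' @param variable_only keep only positions with at least two distinct
#'   non-N calls among retained genomes (default `TRUE`; these are the
#'   positions a phylogeny and barcodes can be built from).
#' @return a [genotype_matrix()].
#' @export
build_genotypes <- function(m, maf_min = 0.85, strand_min = 3, fq_max = -30,
                            indel_max = 1 / 3,
                            genome_min_cov = 8, genome_max_ambig = 0.10,
                            pos_max_n = 0.10, pos_min_cov = 5,
                            pos_copy_mult = 2, variable_only = TRUE) {
  calls <- call_bases(m, maf_min = maf_min, strand_min = strand_min,
                      fq_max = fq_max, indel_max = indel_max)
  g1 <- filter_genomes(m, calls, min_median_cov = genome_min_cov)
  if (length(g1) == 0L) stop("all genomes failed the coverage filter")
  pos <- filter_positions(m, calls, max_n_frac = pos_max_n,
                          min_median_cov = pos_min_cov,
                          copy_number_mult = pos_copy_mult, genomes = g1)
  if (length(pos) == 0L) stop("all positions removed by filtering")
  g2 <- filter_genomes(m, calls, min_median_cov = genome_min_cov,
                       max_ambig_frac = genome_max_ambig,
                       retained_positions = pos)
  if (length(g2) == 0L) stop("all genomes failed the ambiguity filter")
  si <- match(g2, m$sample_ids)
  pi <- match(pos, m$positions)
  sub <- calls[si, pi, drop = FALSE]
  if (variable_only) {
    nvar <- apply(sub, 2, function(col) {
      length(unique(col[col != "N"]))
    })
    keepv <- nvar >= 2L
    sub <- sub[, keepv, drop = FALSE]
    pos <- pos[keepv]
  }
  genotype_matrix(sub, pos)
}
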