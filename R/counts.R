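NUCLEOTIDES <- c("A", "C", "G", "T")
STRANDS <- c("fwd", "rev")

# call_quality value guaranteed never to trip the "above fq_max" ambiguity
# rule when counts come from a source without a consensus-quality score.
QUALITY_SENTINEL <- -Inf

#' Per-position stranded allele counts
#'
#' The universal input container: read counts per sample, genome position,
#' nucleotide and strand, with optional per-cell call-quality scores (on the
#' consensus-quality scale produced by pileup callers, where more negative
#' means more confident) and the fraction of reads supporting an indel within
#' 3 bp of the position.
#'
#' @param sample_ids character vector of sample (or genome) identifiers.
#' @param positions strictly increasing integer vector of 1-based coordinates
#'   on the single reference assembly.
#' @param counts integer array of dimension
#'   `c(length(sample_ids), length(positions), 4, 2)`; nucleotide order
#'   A, C, G, T; strand order fwd, rev.
#' @param call_quality numeric matrix `samples x positions`; defaults to a
#'   sentinel (`-Inf`) that never triggers the quality ambiguity rule.
#' @param indel_fraction numeric matrix `samples x positions` in `[0, 1]`;
#'   defaults to 0.
#'
#' @return An object of class `allele_counts`.
#' @export
allele_counts <- function(sample_ids, positions, counts,
                          call_quality = NULL, indel_fraction = NULL) {
  sample_ids <- as.character(sample_ids)
  positions <- as.integer(positions)
  ns <- length(sample_ids)
  np <- length(positions)
  if (is.null(call_quality)) {
    call_quality <- matrix(QUALITY_SENTINEL, ns, np)
  }
  if (is.null(indel_fraction)) {
    indel_fraction <- matrix(0, ns, np)
  }
  dimnames(counts) <- list(sample_ids, NULL, NUCLEOTIDES, STRANDS)
  obj <- structure(
    list(sample_ids = sample_ids, positions = positions, counts = counts,
         call_quality = call_quality, indel_fraction = indel_fraction),
    class = "allele_counts")
  validate_allele_counts(obj)
  obj
}

validate_allele_counts <- function(m) {
  stopifnot(inherits(m, "allele_counts"))
  ns <- length(m$sample_ids)
  np <- length(m$positions)
  d <- dim(m$counts)
  if (length(d) != 4L || !all(d == c(ns, np, 4L, 2L))) {
    stop("counts tensor dimensions inconsistent with sample/position sets: ",
         "expected (", ns, ", ", np, ", 4, 2), got (",
         paste(d, collapse = ", "), ")")
  }
  if (anyDuplicated(m$sample_ids)) stop("duplicated sample ids")
  if (np > 1L && any(diff(m$positions) <= 0L)) {
    stop("positions must be strictly increasing")
  }
  if (any(m$counts < 0)) stop("negative read counts")
  if (any(m$indel_fraction < 0 | m$indel_fraction > 1)) {
    stop("indel_fraction outside [0, 1]")
  }
  if (!all(dim(m$call_quality) == c(ns, np)) ||
      !all(dim(m$indel_fraction) == c(ns, np))) {
    stop("call_quality / indel_fraction dimensions inconsistent")
  }
  invisible(m)
}

#' @export
print.allele_counts <- function(x, ...) {
  cat("allele_counts: ", length(x$sample_ids), " sample(s) x ",
      length(x$positions), " position(s)\n", sep = "")
  invisible(x)
}

#' Total read depth per sample and position
#'
#' Depth sums both strands and all four nucleotides.
#'
#' @param m an [allele_counts] object.
#' @return numeric matrix `samples x positions`.
#' @export
total_depth <- function(m) {
  d <- dim(m$counts)
  mat <- matrix(m$counts, nrow = d[1] * d[2])
  matrix(rowSums(mat), d[1], d[2], dimnames = list(m$sample_ids, NULL))
}

#' Subset an allele-count matrix
#'
#' @param m an [allele_counts] object.
#' @param samples sample ids to keep (default all).
#' @param positions genome coordinates to keep (default all); must be a subset
#'   of `m$positions`.
#' @return an [allele_counts] object.
#' @export
subset_counts <- function(m, samples = m$sample_ids, positions = m$positions) {
  si <- match(samples, m$sample_ids)
  pi <- match(positions, m$positions)
  if (anyNA(si)) stop("unknown sample id(s): ",
                      paste(samples[is.na(si)], collapse = ", "))
  if (anyNA(pi)) stop("unknown position(s)")
  allele_counts(m$sample_ids[si], m$positions[pi],
                m$counts[si, pi, , , drop = FALSE],
                m$call_quality[si, pi, drop = FALSE],
                m$indel_fraction[si, pi, drop = FALSE])
}

native_header <- c("sample", "position",
                   paste(rep(NUCLEOTIDES, each = 2), STRANDS, sep = "_"),
                   "call_quality", "indel_fraction")

#' Write allele counts in the native TSV format
#'
#' One row per (sample, position), eight stranded nucleotide-count columns,
#' plus call_quality and indel_fraction.  Round-trips losslessly through
#' [read_counts()].  A path ending in `.gz` writes the compressed twin of the
#' same format.
#'
#' @param m an [allele_counts] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(m, path) {
  validate_allele_counts(m)
  ns <- length(m$sample_ids)
  np <- length(m$positions)
  # column-major over (sample, position): sample varies fastest
  # row order strand-fastest: A_fwd, A_rev, C_fwd, ... matching the header
  cnt <- matrix(aperm(m$counts, c(4, 3, 1, 2)), nrow = 8)  # 8 x (ns*np)
  rows <- data.frame(
    sample = rep(m$sample_ids, times = np),
    position = rep(m$positions, each = ns),
    t(cnt),
    call_quality = as.vector(m$call_quality),
    indel_fraction = as.vector(m$indel_fraction),
    check.names = FALSE)
  # native nucleotide-major column order A_fwd, A_rev, C_fwd, ...
  names(rows)[3:10] <- paste(rep(NUCLEOTIDES, each = 2), STRANDS, sep = "_")
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(paste(native_header, collapse = "\t"), con)
  utils::write.table(rows, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read allele counts
#'
#' @param path input file.
#' @param format `"native"` for the package's TSV format (see
#'   [write_counts()]); `"pileup"` for SAMtools mpileup text (see
#'   [read_pileup()]).
#' @param ... passed to [read_pileup()] when `format = "pileup"`.
#' @return an [allele_counts] object.
#' @export
read_counts <- function(path, format = c("native", "pileup"), ...) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file does not exist: ", path)
  if (format == "pileup") return(read_pileup(path, ...))
  tab <- tryCatch(
    utils::read.table(path, header = TRUE, sep = "\t",
                      colClasses = c("character", rep("numeric", 11)),
                      check.names = FALSE),
    error = function(e) stop("malformed counts file '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (nrow(tab) == 0L) stop("empty counts file: ", path)
  if (!identical(names(tab), native_header)) {
    stop("counts file header does not match the native dialect")
  }
  samples <- unique(tab$sample)
  positions <- sort(unique(as.integer(tab$position)))
  np <- length(positions)
  ns <- length(samples)
  if (nrow(tab) != np * ns) {
    stop("structural error: inconsistent position sets across samples ",
         "(", nrow(tab), " rows for ", ns, " samples x ", np, " positions)")
  }
  si <- match(tab$sample, samples)
  pi <- match(as.integer(tab$position), positions)
  if (anyDuplicated(cbind(si, pi))) {
    stop("structural error: duplicated (sample, position) rows")
  }
  counts <- array(0, c(ns, np, 4, 2))
  cq <- matrix(QUALITY_SENTINEL, ns, np)
  indf <- matrix(0, ns, np)
  for (k in seq_along(NUCLEOTIDES)) {
    for (s in 1:2) {
      col <- paste(NUCLEOTIDES[k], STRANDS[s], sep = "_")
      counts[cbind(si, pi, k, s)] <- tab[[col]]
    }
  }
  cq[cbind(si, pi)] <- tab$call_quality
  indf[cbind(si, pi)] <- tab$indel_fraction
  allele_counts(samples, positions, counts, cq, indf)
}

#' Parse SAMtools mpileup text output
#'
#' Parses the classic 6-column-per-sample mpileup text format (chrom, pos,
#' ref, depth, read bases, base qualities).  Read-base strings are decoded:
#' `.`/`,` count as the reference base on the forward/reverse strand,
#' `ACGT`/`acgt` as the stated base per strand; read starts (`^q`), read ends
#' (`$`) and deletion placeholders (`*`) are skipped; indel records
#' (`+n<seq>` / `-n<seq>`) are removed from the base string and counted
#' towards the indel fraction of every position within 3 bp.  The consensus
#' quality (FQ) score is not present in plain pileup text, so `call_quality`
#' is left at the never-firing sentinel.
#'
#' @param path pileup text file.
#' @param sample_ids identifiers for the sample columns; defaults to
#'   `sample1..sampleN`.
#' @return an [allele_counts] object.
#' @export
read_pileup <- function(path, sample_ids = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty pileup file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  n_samp <- (nf[1] - 3L) %/% 3L
  if (n_samp < 1L || any(nf != 3L + 3L * n_samp)) {
    bad <- which(nf != nf[1])[1]
    stop("malformed pileup line ", if (is.na(bad)) 1 else bad,
         ": expected ", 3L + 3L * max(1L, n_samp), " fields")
  }
  if (is.null(sample_ids)) sample_ids <- paste0("sample", seq_len(n_samp))
  positions <- as.integer(vapply(fields, `[[`, "", 2L))
  if (anyNA(positions)) {
    stop("malformed pileup line ", which(is.na(positions))[1],
         ": non-numeric position")
  }
  ord <- order(positions)
  fields <- fields[ord]
  positions <- positions[ord]
  np <- length(positions)
  counts <- array(0, c(n_samp, np, 4, 2))
  indel_events <- matrix(0, n_samp, np)
  depth_for_indel <- matrix(0, n_samp, np)
  for (i in seq_len(np)) {
    ref <- toupper(fields[[i]][3L])
    for (s in seq_len(n_samp)) {
      bases <- fields[[i]][3L + 3L * (s - 1L) + 2L]
      parsed <- parse_pileup_bases(bases, ref, line = i)
      counts[s, i, , ] <- parsed$counts
      indel_events[s, i] <- parsed$indels
      depth_for_indel[s, i] <- parsed$reads
    }
  }
  # indel support within +/- 3 bp: an event at p counts against every
  # retained position within the window
  indf <- matrix(0, n_samp, np)
  for (i in seq_len(np)) {
    win <- which(abs(positions - positions[i]) <= 3L)
    ev <- rowSums(indel_events[, win, drop = FALSE])
    dp <- pmax(depth_for_indel[, i], 1)
    indf[, i] <- pmin(ev / dp, 1)
  }
  allele_counts(sample_ids, positions, counts, indel_fraction = indf)
}

# Decode one mpileup read-base string into stranded ACGT counts.
parse_pileup_bases <- function(bases, ref, line = NA) {
  counts <- matrix(0, 4, 2, dimnames = list(NUCLEOTIDES, STRANDS))
  chars <- strsplit(bases, "")[[1]]
  i <- 1L
  n <- length(chars)
  indels <- 0L
  reads <- 0L
  while (i <= n) {
    ch <- chars[i]
    if (ch == "^") {
      i <- i + 2L  # mapping-quality character follows
    } else if (ch == "$" || ch == "*" || ch == ">" || ch == "<") {
      reads <- reads + as.integer(ch == "*")
      i <- i + 1L
    } else if (ch == "+" || ch == "-") {
      j <- i + 1L
      while (j <= n && grepl("[0-9]", chars[j])) j <- j + 1L
      len <- suppressWarnings(
        as.integer(paste(chars[(i + 1L):(j - 1L)], collapse = "")))
      if (is.na(len)) stop("malformed pileup line ", line,
                           ": indel without length")
      indels <- indels + 1L
      i <- j + len
    } else if (ch == "." || ch == ",") {
      b <- ref
      strand <- if (ch == ".") 1L else 2L
      if (b %in% NUCLEOTIDES) counts[b, strand] <- counts[b, strand] + 1
      reads <- reads + 1L
      i <- i + 1L
    } else if (toupper(ch) %in% NUCLEOTIDES) {
      strand <- if (ch %in% NUCLEOTIDES) 1L else 2L
      b <- toupper(ch)
      counts[b, strand] <- counts[b, strand] + 1
      reads <- reads + 1L
      i <- i + 1L
    } else if (ch %in% c("n", "N")) {
      reads <- reads + 1L
      i <- i + 1L
    } else {
      stop("malformed pileup line ", line, ": unexpected character '",
           ch, "' in read bases")
    }
  }
  list(counts = counts, indels = indels, reads = max(reads, 1L))
}

#' Validate counts against a reference assembly FASTA
#'
#' Checks that all positions fall within the length of the (single-contig)
#' reference sequence.
#'
#' @param m an [allele_counts] object.
#' @param fasta path to the reference assembly FASTA.
#' @return the reference length, invisibly.
#' @export
validate_reference <- function(m, fasta) {
  seqs <- ape::read.FASTA(fasta)
  if (length(seqs) != 1L) {
    stop("reference assembly must be a single contig; got ", length(seqs))
  }
  len <- length(seqs[[1]])
  if (max(m$positions) > len || min(m$positions) < 1L) {
    stop("positions exceed reference '", names(seqs)[1], "' of length ", len)
  }
  invisible(len)
}

#' Call consensus bases with ambiguity filters
#'
#' The call at each (sample, position) is the major allele unless any
#' ambiguity rule fires, in which case it is `N`.  Rules are evaluated
#' independently and OR-combined: consensus quality above `fq_max`
#' (quality scale: more negative = more confident), major-allele depth on
#' either strand below `strand_min`, major allele frequency below `maf_min`,
#' or indel-supporting read fraction strictly above `indel_max`.  Positions
#' with zero coverage are `N`.
#'
#' @param m an [allele_counts] object.
#' @param maf_min minimum major-allele frequency (default 0.85).
#' @param strand_min minimum major-allele depth per strand (default 3).
#' @param fq_max consensus-quality ceiling (default -30).
#' @param indel_max maximum tolerated indel-read fraction (default 1/3,
#'   strict inequality).
#' @return character matrix `samples x positions` over `{A,C,G,T,N}`.
#' @export
call_bases <- function(m, maf_min = 0.85, strand_min = 3, fq_max = -30,
                       indel_max = 1 / 3) {
  validate_allele_counts(m)
  ns <- length(m$sample_ids)
  np <- length(m$positions)
  ncell <- ns * np
  fwd <- matrix(m$counts[, , , 1L], nrow = ncell)  # ncell x 4
  rev <- matrix(m$counts[, , , 2L], nrow = ncell)
  tot <- fwd + rev
  depth <- rowSums(tot)
  maj <- max.col(tot, ties.method = "first")
  idx <- cbind(seq_len(ncell), maj)
  maj_count <- tot[idx]
  maf <- ifelse(depth > 0, maj_count / depth, 0)
  ambiguous <- depth == 0 |
    as.vector(m$call_quality) > fq_max |
    fwd[idx] < strand_min | rev[idx] < strand_min |
    maf < maf_min |
    as.vector(m$indel_fraction) > indel_max
  calls <- NUCLEOTIDES[maj]
  calls[ambiguous] <- "N"
  matrix(calls, ns, np, dimnames = list(m$sample_ids, NULL))
}
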