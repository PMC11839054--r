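test_that("informative counts are extracted exactly", {
  # database with one clade whose barcode is 5 known (position, allele)
  # pairs; engineered counts give hand-computed (x, y)
  frame <- small_frame()
  geno <- frame_genotypes(frame)
  db <- build_database(scale_tree(frame$tree, geno), geno,
                       min_branch = 300, min_genomes = 3)
  id <- db$clades$clade_id[1]
  bc <- db$barcodes[[id]][1:5, ]
  x <- c(3, 0, 7, 2, 5)
  y <- c(10, 4, 7, 9, 5)
  counts <- array(0, c(1, 5, 4, 2))
  for (p in 1:5) {
    ai <- match(bc$allele[p], c("A", "C", "G", "T"))
    oi <- setdiff(1:4, ai)[1]
    counts[1, p, ai, ] <- c(ceiling(x[p] / 2), floor(x[p] / 2))
    counts[1, p, oi, ] <- c(y[p] - x[p], 0)
  }
  ord <- order(bc$position)
  m <- allele_counts("s1", bc$position[ord],
                     counts[, ord, , , drop = FALSE])
  ic <- extract_informative_counts(m, db, id)
  full <- db$barcodes[[id]]
  sel <- match(bc$position, full$position)
  expect_equal(ic$x[sel], x)
  expect_equal(ic$y[sel], y)
  # barcode positions absent from the sample matrix count as x = y = 0
  expect_true(all(ic$x[-sel] == 0) && all(ic$y[-sel] == 0))
  expect_equal(ic$n_missing, nrow(full) - 5L)
})

test_that("pure and empty samples give the expected count limits", {
  frame <- small_frame()
  geno <- frame_genotypes(frame)
  db <- build_database(scale_tree(frame$tree, geno), geno,
                       min_branch = 300, min_genomes = 3)
  id <- db$clades$clade_id[1]
  g <- db$members[[id]][1]
  cnt <- simulate_sample_counts(frame, stats::setNames(1, g), 10,
                                dispersion = Inf, seed = 3)
  ic <- extract_informative_counts(cnt, db, id)
  # an in-clade genome carries every barcode allele: x == y position-wise
  expect_equal(ic$x, ic$y)
  expect_equal(mean(ic$y), 10, tolerance = 0.15)
  zero <- allele_counts("s0", frame$positions,
                        array(0, c(1, length(frame$positions), 4, 2)))
  ic0 <- extract_informative_counts(zero, db, id)
  expect_true(all(ic0$x == 0) && all(ic0$y == 0))
})

test_that("the dispersion prior follows the printed moment formula", {
  y <- c(5, 10, 15, 10, 10)   # mean 10, sample variance 12.5 by hand
  fit <- fit_all_alleles(y)
  expect_equal(fit$prior$a, 10 / (12.5 - 10))   # = 4
  expect_equal(fit$prior$b, 1)
  expect_false(fit$prior$fallback)
  # classical method-of-moments switch
  expect_equal(fit_all_alleles(y, classical_shape = TRUE)$prior$a,
               100 / 2.5)
  # under-dispersed depths fall back to the wide prior
  expect_true(fit_all_alleles(c(10, 10, 10, 11, 9))$prior$fallback)
  expect_error(fit_all_alleles(rep(0, 10)), "no coverage")
  expect_error(fit_all_alleles(5), "at least 2")
})

test_that("negative-binomial depth fit recovers simulated parameters", {
  set.seed(2024)
  y <- stats::rnbinom(500, mu = 20, size = 2)
  fit <- fit_all_alleles(y)
  expect_equal(fit$lambda_all, 20, tolerance = 0.10)
  expect_equal(fit$alpha_all, 2, tolerance = 0.50)
})

test_that("hpd_interval matches brute force on awkward shapes", {
  expect_equal(unname(hpd_interval(rep(3.2, 200))), c(3.2, 3.2))
  set.seed(5)
  u <- stats::runif(20000)
  h <- hpd_interval(u)
  expect_equal(unname(h[2] - h[1]), 0.95, tolerance = 0.02)
  # bimodal fixture against exhaustive window search
  bim <- c(stats::rnorm(300, 0, 0.05), stats::rnorm(100, 1, 0.05))
  s <- sort(bim)
  k <- ceiling(0.95 * length(s))
  widths <- s[k:length(s)] - s[1:(length(s) - k + 1)]
  i <- which.min(widths)
  expect_equal(unname(hpd_interval(bim)), c(s[i], s[i + k - 1]))
  expect_error(hpd_interval(stats::runif(99)), "100")
})

test_that("detection rule truth table at the default thresholds", {
  # 60% of pi mass below 0.35, HPD lower 0.05, abundance 0.3 -> detected
  draws_pass <- c(seq(0.0, 0.34, length.out = 600),
                  seq(0.5, 0.9, length.out = 400))
  expect_true(decide_detection(fake_fit(draws_pass), abundance = 0.3))
  # HPD lower bound at 0.15 vetoes regardless of mass
  draws_high_low <- seq(0.15, 0.30, length.out = 1000)
  f2 <- fake_fit(draws_high_low)
  expect_gte(pi_mass_below(f2, 0.35), 0.5)
  expect_false(decide_detection(f2, abundance = 0.3))
  # abundance below 1% vetoes
  expect_false(decide_detection(fake_fit(draws_pass), abundance = 0.005))
  # insufficient mass below the divergence threshold vetoes
  draws_mass <- c(seq(0, 0.05, length.out = 400),
                  seq(0.4, 0.9, length.out = 600))
  expect_false(decide_detection(fake_fit(draws_mass), abundance = 0.3))
  # non-ok fits are never detected
  expect_false(decide_detection(fake_fit(draws_pass, status = "no_call"),
                                abundance = 0.3))
})

test_that("relative abundance is the MAP depth ratio", {
  f <- fake_fit(stats::runif(200), lambda = 5, lambda_all = 10)
  expect_equal(relative_abundance(f), 0.5)
  f0 <- fake_fit(stats::runif(200), lambda = 0, lambda_all = 10)
  expect_equal(relative_abundance(f0), 0)
  fna <- fake_fit(stats::runif(200), lambda = 5, lambda_all = 0)
  expect_true(is.na(relative_abundance(fna)))
})

test_that("profile normalization caps level sums at 1", {
  prof <- data.frame(
    clade = c("c1", "c2", "c3", "c4"),
    level = c(1, 1, 2, 2),
    detected = c(TRUE, TRUE, TRUE, FALSE),
    relative_abundance = c(0.8, 0.4, 0.7, 0.1),
    stringsAsFactors = FALSE)
  class(prof) <- c("sample_profile", "data.frame")
  out <- normalize_profile(prof)
  # level 1 summed to 1.2 -> scaled to sum exactly 1
  expect_equal(sum(out$relative_abundance[out$level == 1 & out$detected]),
               1)
  expect_equal(out$relative_abundance[1] / out$relative_abundance[2],
               2, tolerance = 1e-12)
  # level 2 sums to 0.7 -> untouched, unclassified 0.3
  expect_equal(out$relative_abundance[3], 0.7)
  lv <- attr(out, "levels")
  expect_equal(lv$unclassified[lv$level == 2], 0.3)
  empty <- prof[0, ]
  class(empty) <- c("sample_profile", "data.frame")
  expect_equal(nrow(normalize_profile(empty)), 0)
})
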