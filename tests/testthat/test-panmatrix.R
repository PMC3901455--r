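test_that("pan-matrix construction records copy numbers and spectra", {
  cat_ <- build_families(list(g1 = c(p1 = "F1", p2 = "F2", p3 = "F2"),
                              g2 = c(q1 = "F1")))
  pm <- build_panmatrix(cat_)
  expect_equal(unname(unclass(pm)), rbind(c(1L, 2L), c(1L, 0L)))
  sp <- spectrum_summary(pm)
  expect_equal(unname(sp$y), c(1L, 1L))
  expect_equal(sp$pangenome, 2L)

  # single genome: every family is both core and ORFan
  pm1 <- as_panmat(matrix(1L, 1, 5))
  sp1 <- spectrum_summary(pm1)
  expect_equal(sp1$orfans, 5L)
  expect_equal(sp1$core, 5L)

  # spectrum of an explicit presence matrix
  sp2 <- spectrum_summary(pm_from_rows(c(1, 1, 0), c(1, 0, 1)))
  expect_equal(unname(sp2$y), c(2L, 1L))
  expect_equal(sp2$core, 1L)
  expect_equal(sp2$orfans, 2L)
  expect_equal(sp2$pangenome, 3L)
})

test_that("pan_matrix.txt round-trips exactly", {
  pm <- as_panmat(matrix(rpois(12, 1.5), 3, 4,
                         dimnames = list(paste0("g", 1:3), NULL)))
  tf <- tempfile(fileext = ".txt")
  write_panmatrix(pm, tf)
  expect_equal(read_panmatrix(tf), pm)
})

test_that("Manhattan distances count presence/absence differences", {
  pm <- pm_from_rows(a = c(1, 1, 0), b = c(1, 0, 1), c = c(1, 1, 0))
  d <- manhattan_distances(pm)
  expect_equal(d["a", "b"], 2)
  expect_equal(d["a", "c"], 0)          # identical genomes
  expect_equal(diag(d), c(a = 0, b = 0, c = 0))
  # copy numbers are ignored
  pm2 <- pm_from_rows(a = c(5, 2, 0), b = c(1, 0, 3), c = c(1, 1, 0))
  expect_equal(manhattan_distances(pm2), d)
  # complementary rows are at distance M
  pmc <- pm_from_rows(c(1, 1, 0, 0), c(0, 0, 1, 1))
  expect_equal(manhattan_distances(pmc)[1, 2], 4)
})

test_that("Manhattan distance satisfies the triangle inequality", {
  set.seed(11)
  for (rep in 1:10) {
    pm <- as_panmat(matrix(rbinom(8 * 30, 1, 0.5), 8, 30))
    d <- manhattan_distances(pm)
    G <- nrow(d)
    for (a in 1:G) for (b in 1:G) for (c in 1:G)
      expect_lte(d[a, b], d[a, c] + d[c, b])
  }
})

test_that("genome Jaccard and fluidity behave on the canonical cases", {
  # identical genomes
  same <- genome_jaccard_and_fluidity(pm_from_rows(c(1, 1), c(1, 1)))
  expect_equal(same$mean_jaccard, 0)
  expect_equal(same$fluidity, 0)
  # disjoint genomes
  disj <- genome_jaccard_and_fluidity(pm_from_rows(c(1, 1, 0, 0), c(0, 0, 1, 1)))
  expect_equal(disj$mean_jaccard, 1)
  expect_equal(disj$fluidity, 1)
  # two equal-sized genomes sharing 90% of families
  n <- 1000L; shared <- 900L
  a <- c(rep(1, shared), rep(1, n - shared), rep(0, n - shared))
  b <- c(rep(1, shared), rep(0, n - shared), rep(1, n - shared))
  r <- genome_jaccard_and_fluidity(pm_from_rows(a, b))
  expect_equal(r$mean_jaccard, 1 - 0.9 / 1.1, tolerance = 1e-12)
  expect_equal(r$fluidity, 0.1, tolerance = 1e-12)
  # invariance to copy numbers
  r2 <- genome_jaccard_and_fluidity(pm_from_rows(3 * a, 7 * b))
  expect_equal(r2$mean_jaccard, r$mean_jaccard)
})

test_that("PCA scores separate duplicated genome groups and are deterministic", {
  rows <- rbind(matrix(rep(c(1, 1, 1, 0, 0, 0), 3), 3, byrow = TRUE),
                matrix(rep(c(0, 0, 0, 1, 1, 1), 3), 3, byrow = TRUE))
  pc <- pca_scores(as_panmat(rows), 2)
  expect_gt(pc$variance_fraction[1], 0.999)
  expect_gt(abs(diff(range(pc$scores[, 1]))), 0)
  expect_equal(sign(pc$scores[1, 1]), -sign(pc$scores[4, 1]))

  # identical rows: zero variance, zero scores
  pcz <- pca_scores(pm_from_rows(c(1, 0, 1), c(1, 0, 1)), 1)
  expect_equal(unname(pcz$scores[, 1]), c(0, 0))

  set.seed(3)
  pm <- as_panmat(matrix(rbinom(10 * 50, 1, 0.4), 10, 50))
  p1 <- pca_scores(pm, 4)
  p2 <- pca_scores(pm, 4)
  expect_identical(p1, p2)
  expect_true(all(diff(p1$variance_fraction) <= 1e-12))
  expect_lte(sum(p1$variance_fraction), 1 + 1e-12)
  expect_error(pca_scores(pm, 50), "n_components")
})

test_that("pangenome trees are valid Newick with half-distance branches", {
  d <- matrix(c(0, 4, 4, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  nwk <- pangenome_tree(d)
  expect_match(nwk, ";$")
  tr <- ape::read.tree(text = nwk)
  expect_setequal(tr$tip.label, c("A", "B"))
  expect_equal(unname(tr$edge.length), c(2, 2))

  # identical pair merges first
  pm <- pm_from_rows(a = c(1, 1, 0), b = c(1, 1, 0), c = c(0, 0, 1))
  tr3 <- ape::read.tree(text = pangenome_tree(manhattan_distances(pm)))
  coph <- ape::cophenetic.phylo(tr3)
  expect_equal(coph["a", "b"], 0)                 # identical pair merges first
  expect_equal(coph["a", "c"], coph["b", "c"])

  expect_error(pangenome_tree(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("cutoff sweep reproduces the baseline and tracks planted breakpoints", {
  set.seed(5)
  # two genomes; one ORFan-defining hit planted at iEvalue 1e-5
  h1 <- rbind(
    data.frame(query = "p1", accession = "PF00001.1", ievalue = 1e-30,
               score = 1, ali_from = 1L, ali_to = 40L,
               env_from = 1L, env_to = 40L),
    data.frame(query = "p2", accession = "PF00002.1", ievalue = 1e-5,
               score = 1, ali_from = 1L, ali_to = 40L,
               env_from = 1L, env_to = 40L))
  h2 <- data.frame(query = "q1", accession = "PF00001.1", ievalue = 1e-25,
                   score = 1, ali_from = 1L, ali_to = 40L,
                   env_from = 1L, env_to = 40L)
  hits <- list(g1 = h1, g2 = h2)
  sw <- cutoff_sweep(hits, c(NA, 1e0, 1e-6, 1e-40))
  # no cutoff and a loose cutoff match the unfiltered baseline
  base <- spectrum_summary(build_panmatrix(build_families(
    lapply(hits, genome_domain_sequences))))
  expect_equal(sw$core[1], base$core)
  expect_equal(sw$orfans[1], base$orfans)
  expect_equal(sw[2, c("core", "orfans")], sw[1, c("core", "orfans")],
               ignore_attr = TRUE)
  # sweeping past 1e-5 removes exactly the planted ORFan
  expect_equal(sw$orfans[1] - sw$orfans[3], 1L)
  # cutoff below everything empties the catalog
  expect_equal(unlist(sw[4, c("core", "orfans", "pangenome")]),
               c(core = 0L, orfans = 0L, pangenome = 0L))
})
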