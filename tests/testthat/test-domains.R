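test_that("domtblout parsing maps the documented columns", {
  path <- write_domtbl_fixture(c(
    "# comment line",
    domtbl_line("PF00005.22", "prot1", 3.1e-40, 12, 210),
    domtbl_line("PF07690.11", "prot1", 2e-12, 215, 240),
    domtbl_line("PF00528.17", "prot2", 5e-8, 1, 60)))
  h <- parse_domtblout(path)
  expect_equal(nrow(h), 3L)
  expect_equal(h$accession[1L], "PF00005.22")
  expect_equal(h$ievalue[1L], 3.1e-40)
  expect_equal(h$ali_from[1L], 12L)
  expect_equal(h$ali_to[1L], 210L)
  expect_equal(sum(h$query == "prot1"), 2L)

  # comment-only file -> empty
  expect_equal(nrow(parse_domtblout(write_domtbl_fixture(c("# a", "# b")))), 0L)
  # short line -> error with line number
  bad <- write_domtbl_fixture(c("# x", "PF1 PF1.1 10 q - 250"))
  expect_error(parse_domtblout(bad), "line 2")
  # unparsable E-value
  l <- domtbl_line("PF1.1", "q", 1e-5, 1, 10)
  l <- sub("1e-05", "oops", l, fixed = TRUE)
  expect_error(parse_domtblout(write_domtbl_fixture(l)), "unparsable")
})

test_that("E-value filtering honours the cutoff and preserves order", {
  h <- data.frame(query = "p", accession = c("A.1", "B.2"),
                  ievalue = c(1e-50, 1e-9), score = 1,
                  ali_from = c(1L, 50L), ali_to = c(10L, 60L),
                  env_from = c(1L, 50L), env_to = c(10L, 60L))
  expect_identical(filter_hits(h, NULL), h)
  expect_equal(filter_hits(h, 1e-10)$accession, "A.1")
  expect_equal(nrow(filter_hits(h, 1e-60)), 0L)
  expect_error(filter_hits(h, -1), "non-negative")
})

hitdf <- function(acc, iev, from, to) {
  data.frame(query = "p1", accession = acc, ievalue = iev, score = 1,
             ali_from = from, ali_to = to, env_from = from, env_to = to,
             stringsAsFactors = FALSE)
}

test_that("recursive overlap elimination follows the worst-first rule", {
  # A(1-100, 1e-50), B(90-200, 1e-10), C(150-300, 1e-20): B is removed
  # first (largest E among overlapping hits), after which A and C are clear
  h <- rbind(hitdf("A.1", 1e-50, 1, 100), hitdf("B.1", 1e-10, 90, 200),
             hitdf("C.1", 1e-20, 150, 300))
  r <- resolve_overlaps(h)
  expect_equal(r$accession, c("A.1", "C.1"))
  expect_equal(r, oracle_resolve(h))

  # nested hit with worse E-value is eliminated
  h2 <- rbind(hitdf("A.1", 1e-30, 1, 100), hitdf("B.1", 1e-5, 50, 80))
  expect_equal(resolve_overlaps(h2)$accession, "A.1")

  # non-overlapping scrambled hits come back sorted, untouched
  h3 <- rbind(hitdf("B.1", 1e-5, 50, 80), hitdf("A.1", 1e-30, 1, 40))
  expect_equal(resolve_overlaps(h3)$accession, c("A.1", "B.1"))

  # hits from two proteins are rejected
  h4 <- rbind(hitdf("A.1", 1e-5, 1, 10), hitdf("A.1", 1e-5, 1, 10))
  h4$query <- c("p1", "p2")
  expect_error(resolve_overlaps(h4), "single query")
})

test_that("overlap elimination matches the literal recursive oracle", {
  set.seed(7)
  for (i in 1:300) {
    h <- random_hitset(sample(2:6, 1L))
    got <- resolve_overlaps(h)
    want <- oracle_resolve(h)
    expect_equal(got, want, info = paste("case", i))
    # invariant: output subset of input, pairwise non-overlapping
    expect_true(all(paste(got$accession, got$ali_from, got$ali_to) %in%
                      paste(h$accession, h$ali_from, h$ali_to)))
    if (nrow(got) > 1L)
      expect_true(all(got$ali_from[-1L] > got$ali_to[-nrow(got)]))
  }
})

test_that("domain sequences are ordered accession keys", {
  h <- rbind(hitdf("PF03466.15", 1e-20, 70, 150),
             hitdf("PF00126.22", 1e-30, 5, 60))
  expect_equal(domain_sequence(resolve_overlaps(h)), "PF00126,PF03466")
  expect_equal(domain_sequence(resolve_overlaps(h), keep_versions = TRUE),
               "PF00126.22,PF03466.15")
  expect_equal(domain_sequence(hitdf("PF07690.11", 1e-9, 1, 50)), "PF07690")
  # repeats allowed when non-overlapping
  rep2 <- rbind(hitdf("PF00005.22", 1e-9, 1, 50),
                hitdf("PF00005.22", 1e-9, 60, 110))
  expect_equal(domain_sequence(rep2), "PF00005,PF00005")
  # overlapping input is a contract violation
  ov <- rbind(hitdf("A.1", 1e-9, 1, 50), hitdf("B.1", 1e-9, 40, 80))
  expect_error(domain_sequence(ov), "overlap")
  # empty -> protein discarded
  empty <- hitdf("A.1", 1e-9, 1, 10)[0L, , drop = FALSE]
  expect_true(is.na(domain_sequence(empty)))
})

test_that("version stripping is idempotent and never reorders accessions", {
  accs <- c("PF00005.22", "PF00005", "PF03466.15")
  expect_equal(strip_versions(accs), c("PF00005", "PF00005", "PF03466"))
  expect_equal(strip_versions(strip_versions(accs)), strip_versions(accs))
})

test_that("family grouping is by identical key with first-seen Cluster ids", {
  per_genome <- list(
    gA = c(p1 = "PF07690", p2 = "PF00005", p3 = "PF00005,PF00005"),
    gB = c(q1 = "PF07690", q2 = "PF00005,PF00005"))
  cat_ <- build_families(per_genome)
  expect_equal(cat_$families$family_id,
               paste("Cluster", 1:3))
  expect_equal(cat_$families$key,
               c("PF07690", "PF00005", "PF00005,PF00005"))
  # copy numbers per genome
  pm <- build_panmatrix(cat_)
  expect_equal(unname(unclass(pm)["gA", ]), c(1L, 1L, 1L))
  expect_equal(unname(unclass(pm)["gB", ]), c(1L, 0L, 1L))
  # total copy numbers equal number of proteins with non-empty architecture
  expect_equal(sum(pm), nrow(cat_$members))
  # empty input -> empty catalog
  expect_equal(nrow(build_families(list())$families), 0L)
})

test_that("length histogram counts families, not member proteins", {
  cat_ <- build_families(list(g1 = c(p1 = "A", p2 = "B", p3 = "A,B"),
                              g2 = c(q1 = "A", q2 = "A,B")))
  h <- length_histogram(cat_)
  expect_equal(unname(h), c(2L, 1L))
  expect_equal(sum(h), nrow(cat_$families))
  expect_equal(length(length_histogram(build_families(list()))), 0L)
})
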