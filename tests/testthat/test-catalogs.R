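test_that("load_catalog reads a valid TSV back and enforces its invariants", {
  path <- write_tsv_fixture(
    data.frame(feature_id = c("g1", "g2", "g3"), species = "human",
               gene_symbol = c("A", "B", "C")),
    withr::local_tempfile(fileext = ".tsv"))
  cat_ <- load_catalog(path, "chip")
  expect_s3_class(cat_, "feature_catalog")
  expect_equal(catalog_size(cat_), 3L)
  expect_equal(cat_$features$feature_id, c("g1", "g2", "g3"))
  expect_equal(cat_$species, "human")

  # header-only file is a valid empty catalog
  empty <- write_tsv_fixture(
    data.frame(feature_id = character(), species = character()),
    withr::local_tempfile(fileext = ".tsv"))
  expect_equal(catalog_size(load_catalog(empty)), 0L)

  dup <- write_tsv_fixture(
    data.frame(feature_id = c("g1", "g2", "g1"), species = "mouse"),
    withr::local_tempfile(fileext = ".tsv"))
  expect_error(load_catalog(dup), "duplicate feature_id 'g1' at line 4")

  badsp <- write_tsv_fixture(
    data.frame(feature_id = c("g1", "g2"), species = c("human", "rat")),
    withr::local_tempfile(fileext = ".tsv"))
  expect_error(load_catalog(badsp), "unrecognized species label 'rat' at line 3")

  expect_error(load_catalog("no/such/file.tsv"), "not found")
})

test_that("map_to_unique_ccds deduplicates, drops unmapped features, and matches a brute-force pair scan", {
  map <- ccds_map(c("p1", "p2", "p3"), c("C1", "C1", "C2"), universe_size = 10)
  expect_equal(map_to_unique_ccds(c("p1", "p2", "p3"), map), c("C1", "C2"))
  expect_message(
    out <- map_to_unique_ccds("p9", map),
    "1 feature\\(s\\) had no CCDS association")
  expect_length(out, 0L)

  # random many-to-many fixture: 50 probes, 30 CCDS IDs
  set.seed(42)
  probes <- sprintf("p%02d", 1:50)
  assoc_f <- sample(probes, 120, replace = TRUE)
  assoc_c <- sample(sprintf("C%02d", 1:30), 120, replace = TRUE)
  keep <- !duplicated(paste(assoc_f, assoc_c))
  big <- ccds_map(assoc_f[keep], assoc_c[keep], universe_size = 60)
  query <- sample(probes, 20)
  # oracle: exhaustive scan over every association pair
  oracle <- sort(unique(unlist(
    lapply(seq_along(assoc_f[keep]), function(i) {
      if (assoc_f[keep][i] %in% query) assoc_c[keep][i] else character(0)
    }))))
  expect_equal(suppressMessages(map_to_unique_ccds(query, big)), oracle)
})

test_that("map_to_unique_ccds is monotone and distributes over union", {
  set.seed(7)
  map <- suppressWarnings(
    ccds_map(sample(sprintf("p%d", 1:40), 80, replace = TRUE),
             sample(sprintf("C%d", 1:25), 80, replace = TRUE),
             universe_size = 50))
  for (i in 1:10) {
    s1 <- sample(sprintf("p%d", 1:40), sample(1:15, 1))
    s2 <- sample(sprintf("p%d", 1:40), sample(1:15, 1))
    m1 <- suppressMessages(map_to_unique_ccds(s1, map))
    m2 <- suppressMessages(map_to_unique_ccds(s2, map))
    m12 <- suppressMessages(map_to_unique_ccds(union(s1, s2), map))
    expect_true(all(m1 %in% m12))                  # monotone
    expect_equal(m12, sort(union(m1, m2)))         # union homomorphism
  }
})

test_that("catalog_coverage reproduces the chip-coverage arithmetic and is scale-free", {
  expect_equal(catalog_coverage(16579, 25504), 65.0)
  expect_equal(catalog_coverage(13518, 22131), 61.1)
  expect_equal(catalog_coverage(0, 100), 0.0)
  expect_equal(catalog_coverage(2 * 16579, 2 * 25504),
               catalog_coverage(16579, 25504))
  expect_error(catalog_coverage(101, 100), "inconsistent catalog")
})

test_that("load_ortholog_map validates, collapses duplicates, and matches set semantics", {
  path <- write_tsv_fixture(
    data.frame(human_id = c("h1", "h2", "h3"), mouse_id = c("m1", "m2", "m3")),
    withr::local_tempfile(fileext = ".tsv"))
  omap <- load_ortholog_map(path)
  expect_equal(nrow(omap$pairs), 3L)

  dup <- write_tsv_fixture(
    data.frame(human_id = c("h1", "h1"), mouse_id = c("m1", "m1")),
    withr::local_tempfile(fileext = ".tsv"))
  expect_warning(omap2 <- load_ortholog_map(dup), "collapsed 1 duplicated")
  expect_equal(nrow(omap2$pairs), 1L)

  # 100 random pairs containing 10 duplicates -> 90 kept, equal to tuple set
  set.seed(11)
  h <- sprintf("h%03d", 1:90)
  m <- sprintf("m%03d", sample(1:90))
  idx <- c(seq_len(90), sample(90, 10))
  big <- write_tsv_fixture(data.frame(human_id = h[idx], mouse_id = m[idx]),
                           withr::local_tempfile(fileext = ".tsv"))
  expect_warning(omap3 <- load_ortholog_map(big), "10 duplicated")
  oracle <- unique(data.frame(human_id = h[idx], mouse_id = m[idx]))
  expect_equal(nrow(omap3$pairs), 90L)
  expect_setequal(paste(omap3$pairs$human_id, omap3$pairs$mouse_id),
                  paste(oracle$human_id, oracle$mouse_id))

  bad <- write_tsv_fixture(
    data.frame(human_id = c("h1", ""), mouse_id = c("m1", "m2")),
    withr::local_tempfile(fileext = ".tsv"))
  expect_error(load_ortholog_map(bad), "malformed ortholog row at line 3")
})

test_that("load_ccds_map reads both the plain and the NCBI CCDS.current dialect", {
  plain <- write_tsv_fixture(
    data.frame(feature_id = c("g1", "g2"), ccds_id = c("CCDS1", "CCDS2")),
    withr::local_tempfile(fileext = ".tsv"))
  m1 <- load_ccds_map(plain, universe_size = 5)
  expect_equal(sort(m1$associations$ccds_id), c("CCDS1", "CCDS2"))

  ncbi <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("#chromosome\tgene\tgene_id\tccds_id\tccds_status",
               "1\tA1BG\tg1\tCCDS1\tPublic",
               "1\tA2M\tg2\tCCDS2\tPublic"), ncbi)
  m2 <- load_ccds_map(ncbi, universe_size = 5)
  expect_equal(m2$associations$feature_id, c("g1", "g2"))
  expect_equal(m2$associations$ccds_id, c("CCDS1", "CCDS2"))

  expect_error(ccds_map("g1", "CCDS1", universe_size = 0), "positive")
  expect_error(ccds_map(c("g1", "g2"), c("C1", "C2"), universe_size = 1),
               "smaller than")
})
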