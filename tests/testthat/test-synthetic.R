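test_that("generate_truth honors degenerate rates and is seed-reproducible", {
  gen0 <- generate_truth(50, frac_orthologs = 0, seed = 3)
  expect_equal(nrow(gen0$orthologs$pairs), 0L)

  gen1 <- generate_truth(50, cross_rates = c(pure_and_mix = 0, mix_only = 0,
                                             pure_only = 0), seed = 3)
  expect_true(all(gen1$truth$cross_class == "none"))
  expect_true(all(is.na(gen1$truth$cross_prob)))

  gen2a <- generate_truth(100, seed = 9)
  gen2b <- generate_truth(100, seed = 9)
  expect_identical(gen2a$truth, gen2b$truth)
  expect_identical(gen2a$orthologs$pairs, gen2b$orthologs$pairs)

  expect_error(generate_truth(10, frac_expressed = 1.2), "probability")
  expect_error(generate_truth(10, cross_rates = c(pure_and_mix = 0.8,
                                                  mix_only = 0.3)),
               "sum to at most 1")
})

test_that("planted crosser count follows the binomial law", {
  # n = 10,000 genes per species at a 5% plant rate: the per-species planted
  # count must fall within 3 binomial standard deviations of 500
  gen <- generate_truth(10000,
                        cross_rates = c(pure_and_mix = 0.05, mix_only = 0,
                                        pure_only = 0),
                        seed = 123)
  sd3 <- 3 * sqrt(10000 * 0.05 * 0.95)
  for (sp in c("human", "mouse")) {
    n_planted <- sum(gen$truth$cross_class[gen$truth$species == sp] != "none")
    expect_lt(abs(n_planted - 500), sd3)
  }
})

test_that("every gene with a planted cross class carries a cross-detection probability in (0,1]", {
  gen <- generate_truth(500, cross_rates = c(pure_and_mix = 0.1,
                                             mix_only = 0.1,
                                             pure_only = 0.1), seed = 5)
  eligible <- gen$truth$cross_class != "none"
  expect_true(any(eligible))
  expect_true(all(gen$truth$cross_prob[eligible] > 0 &
                    gen$truth$cross_prob[eligible] <= 1))
  expect_true(all(is.finite(gen$truth$cross_abundance[eligible])))
  expect_true(all(is.na(gen$truth$cross_prob[!eligible])))
})

test_that("microarray p-values encode the latent signal coin exactly", {
  design <- std_design(seed = 2)
  # silent gene: never expressed, never crossing -> p >= 0.05 everywhere
  truth <- make_truth(c("HSG1", "HSG2"), "human",
                      expressed_same = c(FALSE, TRUE))
  tab <- simulate_microarray(truth, design, "human",
                             detect_prob_same = function(f) as.numeric(f == 1))
  expect_true(all(tab$values["HSG1", ] >= 0.05))
  # certain detection at the pure point -> all three replicates < 0.05
  pure_cols <- sprintf("h100_m0_r%d", 1:3)
  expect_true(all(tab$values["HSG2", pure_cols] < 0.05))
  # and nowhere else for a detect-only-at-1 probability curve
  expect_true(all(tab$values["HSG2", setdiff(colnames(tab$values),
                                             pure_cols)] >= 0.05))
})

test_that("simulated 2-of-3 detection matches the analytic binomial value", {
  # per-replicate signal probability 0.9 -> present rate 3*0.9^2*0.1 + 0.9^3
  n <- 1000
  truth <- make_truth(sprintf("HSG%04d", 1:n), "human")
  design <- std_design(seed = 8)
  tab <- simulate_microarray(truth, design, "human",
                             detect_prob_same = function(f) 0.9 * (f > 0))
  det <- call_detection(tab, detection_config())
  p_pass <- 3 * 0.9^2 * 0.1 + 0.9^3  # 0.972
  observed <- length(detected_at(det, 1)) / n
  expect_lt(abs(observed - p_pass), 3 * sqrt(p_pass * (1 - p_pass) / n))
})

test_that("RNA-Seq counts are zero without a source and match NB moments with one", {
  design <- std_design(seed = 4)
  silent <- make_truth(c("MMG1", "MMG2"), "mouse",
                       expressed_same = FALSE)
  tab0 <- simulate_rnaseq(silent, design, "mouse")
  expect_true(all(tab0$values == 0))
  det0 <- call_detection(tab0, detection_config())
  expect_true(all(vapply(det0, length, 0L) == 0L))

  # 500 equal-abundance features, library sized for mean 20, dispersion 1:
  # the grand mean over 200 replicate draws sits within 3 SD of 20
  n <- 500
  truth <- make_truth(sprintf("HSG%04d", 1:n), "human")
  wide <- titration_design(replicates = 200, seed = 6)
  tab <- simulate_rnaseq(truth, wide, "human", library_size = 20 * n,
                         dispersion = 1, cross_alignment_rate = 0)
  pure_cols <- grep("^h100_m0_", colnames(tab$values))
  draws <- tab$values[, pure_cols]
  var_one <- 20 + 20^2 / 1
  expect_lt(abs(mean(draws) - 20), 3 * sqrt(var_one / length(draws)))
  # per-feature means: at 3 SD nearly all features must conform
  feature_means <- rowMeans(draws)
  within <- abs(feature_means - 20) < 3 * sqrt(var_one / 200)
  expect_gte(mean(within), 0.98)
})

test_that("experiments round-trip through disk byte-for-byte and by seed", {
  design <- std_design(seed = 21)
  gen <- generate_truth(40, seed = 21)
  tab <- simulate_microarray(gen$truth, design, "human")
  cnt <- simulate_rnaseq(gen$truth, design, "mouse")
  dir1 <- withr::local_tempdir()
  manifest <- write_experiment(
    list(microarray_human = tab, rnaseq_mouse = cnt),
    list(human_catalog = gen$human_catalog),
    gen$orthologs, dir1, truth = gen$truth)
  expect_true(file.exists(manifest))

  back <- read_detection_table(file.path(dir1, "microarray_human.tsv"),
                               "microarray", "human", seed = 21)
  expect_equal(back$values, tab$values, tolerance = 1e-12)
  expect_equal(back$design$mixture_levels, design$mixture_levels)
  cback <- read_detection_table(file.path(dir1, "rnaseq_mouse.tsv"),
                                "rnaseq", "mouse", seed = 21)
  expect_equal(cback$values, cnt$values)  # integer storage vs double draws

  # same seed regenerates identical tables; a different seed does not
  tab_again <- simulate_microarray(gen$truth, design, "human")
  expect_identical(tab_again$values, tab$values)
  design2 <- std_design(seed = 22)
  tab_other <- simulate_microarray(gen$truth, design2, "human")
  expect_false(identical(tab_other$values, tab$values))

  # manifest records the seed and generator parameters
  mf <- yaml::read_yaml(manifest)
  expect_equal(mf$design$seed, 21)
  expect_equal(mf$truth_params$n_genes_per_species, 40)
})

test_that("synthetic CCDS maps are many-to-many and reproducible", {
  cat_ <- feature_catalog("chip", "human", sprintf("HSG%04d", 1:400))
  m1 <- generate_ccds_map(cat_, seed = 3)
  m2 <- generate_ccds_map(cat_, seed = 3)
  expect_identical(m1$associations, m2$associations)
  expect_lte(length(unique(m1$associations$feature_id)), 400L)
  expect_gte(m1$universe_size, length(unique(m1$associations$ccds_id)))
  # some feature maps to >1 CCDS and some CCDS to >1 feature
  expect_true(any(duplicated(m1$associations$feature_id)))
  expect_true(any(duplicated(m1$associations$ccds_id)))
})
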