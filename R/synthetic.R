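# Synthetic titration experiments: planted ground truth, microarray
# detection p-values, RNA-Seq counts, and on-disk round-trip.
#
# The generative model is built so the published detection rule coincides
# exactly with a latent Bernoulli event: a "signal" coin with the feature's
# detection probability at that mixture emits a p-value uniform on (0, 0.05),
# a "no signal" coin uniform on [0.05, 1]. The downstream p < 0.05 rule then
# recovers the coin with probability one, which keeps analytic oracles
# (2-of-3 binomial formulas) exact.

#' Titration experiment design
#'
#' The mixture series of pseudo-xenograft samples: human RNA fractions in
#' 25% steps by default, each assayed in triplicate.
#'
#' @param mixture_levels ordered human RNA fractions; must be distinct, lie
#'   in \[0, 1\] and include both pure samples (0 and 1).
#' @param replicates number of independent replicates per mixture.
#' @param seed master seed; all simulation draws derive per-stage streams
#'   from it.
#' @return an object of class `titration_design`.
#' @export
titration_design <- function(mixture_levels = c(0, 0.25, 0.5, 0.75, 1),
                             replicates = 3L, seed = 1L) {
  if (anyDuplicated(mixture_levels) || any(mixture_levels < 0) ||
      any(mixture_levels > 1) || !all(c(0, 1) %in% mixture_levels)) {
    stop("mixture_levels must be distinct fractions in [0, 1] including 0 and 1")
  }
  if (replicates < 1L) stop("replicates must be >= 1")
  structure(
    list(mixture_levels = sort(mixture_levels),
         replicates = as.integer(replicates),
         seed = as.integer(seed)),
    class = "titration_design"
  )
}

#' @export
print.titration_design <- function(x, ...) {
  cat(sprintf("Titration design: human fractions {%s} x %d replicates (seed %d)\n",
              paste(x$mixture_levels, collapse = ", "), x$replicates, x$seed))
  invisible(x)
}

design_labels <- function(design) {
  unlist(lapply(design$mixture_levels,
                function(h) vapply(seq_len(design$replicates),
                                   function(r) sample_label(h, r), "")))
}

#' Generate planted ground truth for a two-species titration experiment
#'
#' Draws, per species, a catalog of genes with expression status and
#' relative abundance, links a fraction of genes into human-mouse ortholog
#' pairs, and plants cross-detectable genes in one of three classes:
#'
#' * `pure_and_mix` — cross-detectable in mixtures and in the 100%
#'   cross-species sample (the typical ortholog-driven crosser);
#' * `mix_only` — cross-detectable only in mixtures, never in the pure
#'   cross-species sample;
#' * `pure_only` — cross-detectable only in the pure cross-species sample.
#'
#' The last two classes exist so that the titration crosser definition and
#' the pure-sample definition provably disagree in both directions: neither
#' resulting list need contain the other, which mirrors what real
#' pseudo-xenograft data shows.
#'
#' @param n_genes_per_species genes per species (>= 1).
#' @param frac_expressed probability a gene is expressed in its own species'
#'   RNA source.
#' @param frac_orthologs fraction of genes (per species) linked into 1:1
#'   ortholog pairs, sampled uniformly.
#' @param cross_rates named probabilities for classes `pure_and_mix`,
#'   `mix_only`, `pure_only` (each gene draws its class independently; the
#'   remainder is class `none`). Must sum to at most 1.
#' @param cross_detect_prob per-replicate cross-detection probability, in
#'   (0, 1\], assigned to every planted crosser.
#' @param abundance_meanlog,abundance_sdlog log-normal parameters of
#'   relative abundance (arbitrary units).
#' @param seed integer seed (stream derived internally).
#' @return a list with elements `human_catalog`, `mouse_catalog`
#'   ([feature_catalog()]s), `orthologs` ([ortholog_map()]) and `truth`, a
#'   data.frame of class `synthetic_truth` with one row per gene per species
#'   and columns `gene_id`, `species`, `expressed_same`,
#'   `relative_abundance`, `ortholog_partner`, `cross_class`, `cross_prob`,
#'   `cross_abundance`.
#' @export
generate_truth <- function(n_genes_per_species,
                           frac_expressed = 0.6,
                           frac_orthologs = 0.7,
                           cross_rates = c(pure_and_mix = 0.04,
                                           mix_only = 0.01,
                                           pure_only = 0.01),
                           cross_detect_prob = 0.95,
                           abundance_meanlog = 3,
                           abundance_sdlog = 1.5,
                           seed = 1L) {
  if (n_genes_per_species < 1L) stop("n_genes_per_species must be >= 1")
  check_probability(frac_expressed, "frac_expressed")
  check_probability(frac_orthologs, "frac_orthologs")
  classes <- c("pure_and_mix", "mix_only", "pure_only")
  rates <- setNames(rep(0, 3), classes)
  rates[names(cross_rates)] <- cross_rates
  check_probability(rates, "cross_rates")
  if (sum(rates) > 1) stop("cross_rates must sum to at most 1")
  if (cross_detect_prob <= 0 || cross_detect_prob > 1) {
    stop("cross_detect_prob must lie in (0, 1]")
  }

  set.seed(derive_seed(seed, 1L))
  n <- as.integer(n_genes_per_species)
  gene_ids <- list(human = sprintf("HSG%06d", seq_len(n)),
                   mouse = sprintf("MMG%06d", seq_len(n)))

  # 1:1 ortholog pairs over uniformly sampled genes of each species
  n_pairs <- round(frac_orthologs * n)
  h_part <- sample(gene_ids$human, n_pairs)
  m_part <- sample(gene_ids$mouse, n_pairs)

  per_species <- lapply(c(human = "human", mouse = "mouse"), function(sp) {
    ids <- gene_ids[[sp]]
    partner <- rep(NA_character_, n)
    if (sp == "human") {
      partner[match(h_part, ids)] <- m_part
    } else {
      partner[match(m_part, ids)] <- h_part
    }
    cls <- sample(c(classes, "none"), n, replace = TRUE,
                  prob = c(rates, 1 - sum(rates)))
    data.frame(
      gene_id = ids,
      species = sp,
      expressed_same = runif(n) < frac_expressed,
      relative_abundance = rlnorm(n, abundance_meanlog, abundance_sdlog),
      ortholog_partner = partner,
      cross_class = cls,
      stringsAsFactors = FALSE
    )
  })
  truth <- rbind(per_species$human, per_species$mouse)
  rownames(truth) <- NULL

  eligible <- truth$cross_class != "none"
  truth$cross_prob <- ifelse(eligible, cross_detect_prob, NA_real_)
  # Cross-detection is ortholog-mediated where a partner exists: the
  # cross-species RNA that lights this feature is the partner's transcript,
  # so the cross abundance is the partner's. Planted crossers without a
  # partner (homology outside the ortholog table) draw an independent
  # abundance from the same law.
  partner_abund <- truth$relative_abundance[match(truth$ortholog_partner,
                                                  truth$gene_id)]
  orphan <- eligible & is.na(partner_abund)
  partner_abund[orphan] <- rlnorm(sum(orphan), abundance_meanlog,
                                  abundance_sdlog)
  truth$cross_abundance <- ifelse(eligible, partner_abund, NA_real_)
  class(truth) <- c("synthetic_truth", "data.frame")
  attr(truth, "params") <- list(
    n_genes_per_species = n, frac_expressed = frac_expressed,
    frac_orthologs = frac_orthologs, cross_rates = as.list(rates),
    cross_detect_prob = cross_detect_prob,
    abundance_meanlog = abundance_meanlog,
    abundance_sdlog = abundance_sdlog, seed = as.integer(seed)
  )

  list(
    human_catalog = feature_catalog("human_platform", "human", gene_ids$human),
    mouse_catalog = feature_catalog("mouse_platform", "mouse", gene_ids$mouse),
    orthologs = ortholog_map(h_part, m_part, keying = "gene"),
    truth = truth
  )
}

truth_for_species <- function(truth, species) {
  stopifnot(inherits(truth, "synthetic_truth"))
  truth[truth$species == species, , drop = FALSE]
}

# Per-replicate cross-detection probability of one feature at cross-species
# fraction f_cross, given its planted class. pure_and_mix scales over the
# whole series; mix_only is extinguished at the pure cross point; pure_only
# fires only there.
cross_signal_prob <- function(cross_class, cross_prob, f_cross, scale_fun) {
  p <- numeric(length(cross_class))
  if (f_cross <= 0) return(p)
  s <- scale_fun(f_cross)
  if (f_cross < 1) {
    on <- cross_class %in% c("pure_and_mix", "mix_only")
    p[on] <- cross_prob[on] * s
  } else {
    on <- cross_class %in% c("pure_and_mix", "pure_only")
    p[on] <- cross_prob[on] * ifelse(cross_class[on] == "pure_only", 1, s)
  }
  p
}

#' Construct a detection-evidence table
#'
#' Container for per-replicate detection evidence on one platform: a
#' feature-by-sample matrix of detection p-values (microarray) or
#' non-negative integer read counts (RNA-Seq), with column labels
#' `h{percent}_m{percent}_r{replicate}`.
#'
#' @param platform `"microarray"` or `"rnaseq"`.
#' @param platform_species species of the platform, `"human"` or `"mouse"`.
#' @param values numeric matrix, rows = features (rownames required),
#'   columns = every (mixture, replicate) cell of `design` in design order.
#' @param design the [titration_design()].
#' @return an object of class `detection_table`.
#' @export
detection_table <- function(platform, platform_species, values, design) {
  platform <- match.arg(platform, c("microarray", "rnaseq"))
  check_species(platform_species)
  stopifnot(inherits(design, "titration_design"), is.matrix(values))
  labels <- design_labels(design)
  if (is.null(rownames(values))) stop("values must have feature rownames")
  if (!identical(sort(colnames(values)), sort(labels))) {
    stop("values columns must cover the complete design (every mixture x replicate)")
  }
  values <- values[, labels, drop = FALSE]
  if (platform == "microarray") {
    if (any(values < 0) || any(values > 1)) stop("p-values must lie in [0, 1]")
  } else {
    if (any(values < 0) || any(values != floor(values))) {
      stop("counts must be non-negative integers")
    }
  }
  structure(
    list(platform = platform, platform_species = platform_species,
         values = values, design = design),
    class = "detection_table"
  )
}

#' @export
print.detection_table <- function(x, ...) {
  cat(sprintf("Detection table: %s (%s platform), %d features x %d samples\n",
              x$platform, x$platform_species, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Simulate microarray detection p-values over a titration series
#'
#' For each feature, mixture and replicate an independent coin decides
#' signal/no-signal; signal draws a p-value uniform on (0, 0.05), no-signal
#' uniform on \[0.05, 1\]. The same-species signal probability is
#' `detect_prob_same(f)` at same-species RNA fraction `f` for expressed
#' features; the cross-species probability is the feature's planted
#' `cross_prob` scaled by `cross_prob_scale(f_cross)` for eligible classes
#' (see [generate_truth()]). The two sources combine independently.
#'
#' @param truth a `synthetic_truth` (see [generate_truth()]).
#' @param design a [titration_design()].
#' @param platform_species the chip's species.
#' @param detect_prob_same function mapping same-species fraction to a
#'   per-replicate detection probability in \[0, 1\]. The default saturating
#'   curve `f^0.2` reflects that abundant transcripts stay detectable well
#'   below 100% input, and reaches 1 at pure same-species input so that an
#'   expressed feature is always a member of the pure-sample set A (making
#'   "zero cross rates imply zero crossers" structural rather than
#'   statistical).
#' @param cross_prob_scale function mapping cross-species fraction to a
#'   multiplier in \[0, 1\]; default linear in the fraction.
#' @param seed optional override of the stream derived from `design$seed`.
#' @return a [detection_table()] of p-values.
#' @export
simulate_microarray <- function(truth, design, platform_species,
                                detect_prob_same = function(f) f^0.2,
                                cross_prob_scale = function(f) f,
                                seed = NULL) {
  check_species(platform_species)
  tr <- truth_for_species(truth, platform_species)
  fr_same <- same_species_fraction(design$mixture_levels, platform_species)
  check_probability(vapply(fr_same, detect_prob_same, 0), "detect_prob_same values")
  fr_cross <- (1 - fr_same)[fr_same < 1]
  if (length(fr_cross)) {
    check_probability(vapply(fr_cross, cross_prob_scale, 0),
                      "cross_prob_scale values")
  }
  stage <- if (platform_species == "human") 2L else 3L
  set.seed(if (is.null(seed)) derive_seed(design$seed, stage)
           else derive_seed(seed, stage))

  n <- nrow(tr)
  cols <- lapply(design$mixture_levels, function(h) {
    f_same <- same_species_fraction(h, platform_species)
    p_same <- ifelse(tr$expressed_same, detect_prob_same(f_same), 0)
    p_cross <- cross_signal_prob(tr$cross_class, tr$cross_prob,
                                 1 - f_same, cross_prob_scale)
    p_signal <- 1 - (1 - p_same) * (1 - p_cross)
    reps <- lapply(seq_len(design$replicates), function(r) {
      signal <- runif(n) < p_signal
      ifelse(signal, runif(n, 0, 0.05), runif(n, 0.05, 1))
    })
    do.call(cbind, reps)
  })
  values <- do.call(cbind, cols)
  rownames(values) <- tr$gene_id
  colnames(values) <- design_labels(design)
  detection_table("microarray", platform_species, values, design)
}

#' Simulate RNA-Seq read counts over a titration series
#'
#' Counts are negative binomial with variance = mean + mean^2 / dispersion.
#' The same-species mean is `library_size` times the feature's abundance
#' (normalized over expressed same-species features) times the same-species
#' RNA fraction. Cross-eligible features add a cross term:
#' `library_size` x normalized partner abundance x cross-species fraction x
#' `cross_alignment_rate`, active in mixtures and/or the pure cross sample
#' according to the planted class. A mean of zero yields a count of zero.
#'
#' @param truth a `synthetic_truth`.
#' @param design a [titration_design()].
#' @param reference_species species of the reference the reads align to.
#' @param library_size expected total same-species reads per sample at 100%
#'   same-species input.
#' @param dispersion NB dispersion (the `size` parameter); smaller means
#'   more overdispersed.
#' @param cross_alignment_rate probability-scale attenuation of the
#'   cross-species mean (the fraction of a transcript's reads that align to
#'   the other species' reference).
#' @param seed optional override of the stream derived from `design$seed`.
#' @return a [detection_table()] of counts.
#' @export
simulate_rnaseq <- function(truth, design, reference_species,
                            library_size = 1e6, dispersion = 2,
                            cross_alignment_rate = 0.1, seed = NULL) {
  check_species(reference_species)
  if (library_size < 1) stop("library_size must be >= 1")
  if (dispersion <= 0) stop("dispersion must be positive")
  check_probability(cross_alignment_rate, "cross_alignment_rate")
  tr <- truth_for_species(truth, reference_species)
  other <- truth_for_species(truth, other_species(reference_species))

  same_total <- sum(tr$relative_abundance[tr$expressed_same])
  abund_same <- ifelse(tr$expressed_same & same_total > 0,
                       tr$relative_abundance / max(same_total, .Machine$double.eps),
                       0)
  cross_total <- sum(other$relative_abundance[other$expressed_same])
  if (cross_total <= 0) cross_total <- sum(tr$cross_abundance, na.rm = TRUE)
  abund_cross <- ifelse(is.na(tr$cross_abundance), 0,
                        tr$cross_abundance / max(cross_total, .Machine$double.eps))

  stage <- if (reference_species == "human") 4L else 5L
  set.seed(if (is.null(seed)) derive_seed(design$seed, stage)
           else derive_seed(seed, stage))

  n <- nrow(tr)
  cols <- lapply(design$mixture_levels, function(h) {
    f_same <- same_species_fraction(h, reference_species)
    f_cross <- 1 - f_same
    cross_on <- cross_signal_prob(tr$cross_class,
                                  rep(1, n), f_cross, function(f) 1) > 0
    mu <- library_size * abund_same * f_same +
      library_size * abund_cross * f_cross * cross_alignment_rate * cross_on
    reps <- lapply(seq_len(design$replicates), function(r) {
      rnbinom(n, size = dispersion, mu = mu)
    })
    do.call(cbind, reps)
  })
  values <- do.call(cbind, cols)
  rownames(values) <- tr$gene_id
  colnames(values) <- design_labels(design)
  detection_table("rnaseq", reference_species, values, design)
}

#' Generate a synthetic feature-to-CCDS association map
#'
#' Builds a plausibly messy (synthetic) CCDS map for a catalog: most features
#' map to one CCDS ID, some to two, a few share a CCDS ID with another
#' feature (many-to-many), and a fraction map to nothing.
#'
#' @param catalog a [feature_catalog()].
#' @param frac_mapped fraction of features with at least one association.
#' @param universe_margin the CCDS universe is this multiple of the distinct
#'   CCDS IDs generated (rounded up), emulating a platform that covers only
#'   part of the annotation.
#' @param seed integer seed.
#' @return a [ccds_map()].
#' @export
generate_ccds_map <- function(catalog, frac_mapped = 0.85,
                              universe_margin = 1.3, seed = 1L) {
  stopifnot(inherits(catalog, "feature_catalog"))
  check_probability(frac_mapped, "frac_mapped")
  if (universe_margin < 1) stop("universe_margin must be >= 1")
  set.seed(derive_seed(seed, 6L))
  ids <- catalog$features$feature_id
  mapped <- ids[runif(length(ids)) < frac_mapped]
  if (!length(mapped)) stop("no features mapped; raise frac_mapped")
  prefix <- toupper(substr(catalog$species, 1, 1))
  primary <- sprintf("CCDS%s%06d", prefix, seq_along(mapped))
  feature_id <- mapped
  ccds_id <- primary
  # ~10% of mapped features carry a second CCDS ID; ~5% additionally share
  # their neighbour's primary CCDS ID (many-to-many)
  second <- runif(length(mapped)) < 0.10
  if (any(second)) {
    feature_id <- c(feature_id, mapped[second])
    ccds_id <- c(ccds_id, sprintf("CCDS%s%06dB", prefix, which(second)))
  }
  shared <- which(runif(length(mapped)) < 0.05)
  shared <- shared[shared > 1L]
  if (length(shared)) {
    feature_id <- c(feature_id, mapped[shared])
    ccds_id <- c(ccds_id, primary[shared - 1L])
  }
  universe <- ceiling(length(unique(ccds_id)) * universe_margin)
  ccds_map(feature_id, ccds_id, universe)
}

#' Write a synthetic experiment to disk
#'
#' Emits one TSV per detection table (rows = features, columns = samples),
#' one TSV per catalog, the ortholog pair table, and a YAML manifest that
#' records the design, seed and generator parameters so the experiment can
#' be reproduced exactly.
#'
#' @param tables named list of [detection_table()]s.
#' @param catalogs named list of [feature_catalog()]s.
#' @param orthologs an [ortholog_map()], or `NULL`.
#' @param out_dir output directory (created if needed).
#' @param truth optional `synthetic_truth`; its generator parameters are
#'   recorded in the manifest and the truth table itself written as TSV.
#' @return invisibly, the manifest path.
#' @export
write_experiment <- function(tables, catalogs, orthologs, out_dir,
                             truth = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop(sprintf("cannot create directory %s", out_dir))
  table_files <- list()
  for (nm in names(tables)) {
    tab <- tables[[nm]]
    stopifnot(inherits(tab, "detection_table"))
    f <- file.path(out_dir, paste0(nm, ".tsv"))
    df <- data.frame(feature_id = rownames(tab$values), tab$values,
                     check.names = FALSE, stringsAsFactors = FALSE)
    write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
    table_files[[nm]] <- list(file = basename(f), platform = tab$platform,
                              platform_species = tab$platform_species)
  }
  for (nm in names(catalogs)) {
    cat_ <- catalogs[[nm]]
    df <- data.frame(feature_id = cat_$features$feature_id,
                     species = cat_$species,
                     gene_symbol = cat_$features$gene_symbol,
                     stringsAsFactors = FALSE)
    write.table(df, file.path(out_dir, paste0(nm, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(orthologs)) {
    write.table(orthologs$pairs, file.path(out_dir, "orthologs.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(truth)) {
    write.table(as.data.frame(truth), file.path(out_dir, "truth.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  design <- tables[[1]]$design
  manifest <- list(
    format_version = 1L,
    design = list(mixture_levels = design$mixture_levels,
                  replicates = design$replicates, seed = design$seed),
    # cross-detection scaling across mixture steps is linear in the
    # cross-species fraction by default; a modeling choice, recorded here
    cross_scaling = "linear_in_cross_fraction",
    truth_params = if (!is.null(truth)) attr(truth, "params") else NULL,
    tables = table_files,
    catalogs = as.list(names(catalogs))
  )
  manifest_path <- file.path(out_dir, "manifest.yaml")
  yaml::write_yaml(manifest, manifest_path)
  invisible(manifest_path)
}

#' Read a detection table written by [write_experiment()]
#'
#' Reconstructs the [titration_design()] from the column labels
#' (`h{percent}_m{percent}_r{rep}`).
#'
#' @param path TSV file with a `feature_id` column and sample columns.
#' @param platform `"microarray"` or `"rnaseq"`.
#' @param platform_species the platform's species.
#' @param seed seed to record on the reconstructed design.
#' @return a [detection_table()].
#' @export
read_detection_table <- function(path, platform, platform_species, seed = 1L) {
  if (!file.exists(path)) stop(sprintf("table file not found: %s", path))
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"feature_id" %in% names(df)) stop("missing feature_id column")
  labels <- setdiff(names(df), "feature_id")
  parsed <- regmatches(labels, regexec("^h(\\d+)_m(\\d+)_r(\\d+)$", labels))
  if (any(lengths(parsed) != 4L)) stop("sample columns must be h*_m*_r* labels")
  h <- vapply(parsed, function(m) as.numeric(m[2]) / 100, 0)
  r <- vapply(parsed, function(m) as.integer(m[4]), 0L)
  design <- titration_design(sort(unique(h)), max(r), seed = seed)
  values <- as.matrix(df[, labels, drop = FALSE])
  rownames(values) <- df$feature_id
  detection_table(platform, platform_species, values, design)
}
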