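# Venn region counts, cross-technology summaries, and the end-to-end
# pipeline driver over a synthetic titration experiment.

#' Exact exclusive Venn region counts for 2-5 labeled sets
#'
#' Computes the size of every non-empty region of the Venn diagram via
#' membership signatures: each element of the union is assigned to exactly
#' one region (the subset of sets containing it), so region counts always
#' sum to the union size (asserted).
#'
#' @param sets named list of 2 to 5 character vectors.
#' @return an object of class `venn_regions`: `set_labels` (input names)
#'   and `region_counts`, a named integer vector over all `2^n - 1`
#'   label subsets, names like `"A"`, `"A&C"`, in subset order.
#' @export
venn_regions <- function(sets) {
  if (!is.list(sets) || length(sets) < 2L || length(sets) > 5L) {
    stop("venn_regions needs a list of 2 to 5 sets")
  }
  if (is.null(names(sets)) || any(names(sets) == "") ||
      anyDuplicated(names(sets))) {
    stop("sets must have unique non-empty names")
  }
  labels <- names(sets)
  n <- length(sets)
  universe <- unique(unlist(lapply(sets, as.character), use.names = FALSE))
  sig <- integer(length(universe))
  for (i in seq_len(n)) {
    sig <- sig + bitwShiftL(as.integer(universe %in% sets[[i]]), i - 1L)
  }
  masks <- seq_len(2^n - 1L)
  region_names <- vapply(masks, function(m) {
    paste(labels[bitwAnd(m, bitwShiftL(1L, seq_len(n) - 1L)) != 0L],
          collapse = "&")
  }, "")
  counts <- vapply(masks, function(m) sum(sig == m), 0L)
  names(counts) <- region_names
  stopifnot(sum(counts) == length(universe))
  structure(list(set_labels = labels, region_counts = counts),
            class = "venn_regions")
}

#' @export
print.venn_regions <- function(x, ...) {
  cat(sprintf("Venn regions over {%s} (union = %d):\n",
              paste(x$set_labels, collapse = ", "),
              sum(x$region_counts)))
  nz <- x$region_counts[x$region_counts > 0]
  for (nm in names(nz)) cat(sprintf("  %s: %d\n", nm, nz[[nm]]))
  invisible(x)
}

#' Cross-technology detection summary for one sample
#'
#' Splits the union of features detected by RNA-Seq and by microarray into
#' the three exclusive regions and their total; the total is additive by
#' construction (asserted).
#'
#' @param rnaseq_detected,microarray_detected character vectors of detected
#'   IDs in a shared identifier space (typically CCDS).
#' @return a list with `unique_rnaseq`, `shared`, `unique_microarray`,
#'   `union_total`.
#' @export
two_technology_summary <- function(rnaseq_detected, microarray_detected) {
  r <- unique(as.character(rnaseq_detected))
  m <- unique(as.character(microarray_detected))
  shared <- length(intersect(r, m))
  out <- list(unique_rnaseq = length(r) - shared,
              shared = shared,
              unique_microarray = length(m) - shared,
              union_total = length(union(r, m)))
  stopifnot(out$union_total ==
              out$unique_rnaseq + out$shared + out$unique_microarray)
  out
}

#' Run the full synthetic titration pipeline
#'
#' Generates a two-species titration experiment with planted crossers, then
#' runs every analysis stage for both platforms (microarray and RNA-Seq) and
#' both platform species: detection calling, titration- and
#' pure-sample-definition crossers, CCDS normalization of crosser lists,
#' ortholog summaries, per-technology five-sample Venn region counts at CCDS
#' level, and the pure-sample cross-technology summaries. Fixing `seed`
#' fixes the entire bundle.
#'
#' @param n_genes_per_species genes per species.
#' @param frac_expressed,frac_orthologs,cross_rates,cross_detect_prob
#'   passed to [generate_truth()].
#' @param library_size,dispersion,cross_alignment_rate passed to
#'   [simulate_rnaseq()].
#' @param detect_prob_same,cross_prob_scale passed to
#'   [simulate_microarray()].
#' @param config a [detection_config()].
#' @param rate_denominator `"detected"` (features detected in >= 1 sample of
#'   the titration; default) or `"catalog"` for [crosser_rate()].
#' @param seed master seed for the whole run.
#' @param out_dir if non-NULL, the experiment tables, a JSON summary and a
#'   YAML manifest are written here.
#' @return a list of class `pipeline_bundle` with elements `truth`
#'   (generator output), `detected`, `crossers`, `comparisons`, `rates`,
#'   `ccds` (maps plus CCDS-level crossers), `orthology`, `venn`,
#'   `technology` and `params`. Analysis elements are keyed
#'   `<platform>_<species>` (e.g. `microarray_human`).
#' @export
run_pipeline <- function(n_genes_per_species = 10000,
                         frac_expressed = 0.6,
                         frac_orthologs = 0.7,
                         cross_rates = c(pure_and_mix = 0.04,
                                         mix_only = 0.01,
                                         pure_only = 0.01),
                         cross_detect_prob = 0.95,
                         library_size = 1e6,
                         dispersion = 2,
                         cross_alignment_rate = 0.1,
                         detect_prob_same = function(f) f^0.2,
                         cross_prob_scale = function(f) f,
                         config = detection_config(),
                         rate_denominator = c("detected", "catalog"),
                         seed = 1L,
                         out_dir = NULL) {
  rate_denominator <- match.arg(rate_denominator)
  design <- titration_design(seed = seed)
  gen <- generate_truth(n_genes_per_species, frac_expressed, frac_orthologs,
                        cross_rates, cross_detect_prob, seed = seed)
  catalogs <- list(human = gen$human_catalog, mouse = gen$mouse_catalog)
  ccds_maps <- list(
    human = generate_ccds_map(gen$human_catalog, seed = derive_seed(seed, 11L)),
    mouse = generate_ccds_map(gen$mouse_catalog, seed = derive_seed(seed, 12L))
  )

  tables <- list()
  detected <- list()
  crossers <- list()
  comparisons <- list()
  rates <- list()
  ccds_crossers <- list()
  ccds_detected <- list()   # per run key, per level: CCDS-level detected sets
  for (platform in c("microarray", "rnaseq")) {
    for (sp in c("human", "mouse")) {
      key <- paste(platform, sp, sep = "_")
      tab <- if (platform == "microarray") {
        simulate_microarray(gen$truth, design, sp,
                            detect_prob_same = detect_prob_same,
                            cross_prob_scale = cross_prob_scale)
      } else {
        simulate_rnaseq(gen$truth, design, sp, library_size = library_size,
                        dispersion = dispersion,
                        cross_alignment_rate = cross_alignment_rate)
      }
      tables[[key]] <- tab
      det <- call_detection(tab, config)
      detected[[key]] <- det
      tsets <- titration_sets(det)
      tit <- titration_crossers(tsets)
      pure <- pure_sample_crossers(tsets)
      crossers[[key]] <- list(titration = tit, pure_sample = pure)
      comparisons[[key]] <- compare_definitions(tit, pure)
      denom <- if (rate_denominator == "detected") {
        length(detected_anywhere(det))
      } else {
        catalog_size(catalogs[[sp]])
      }
      rates[[key]] <- if (denom > 0) {
        crosser_rate(tit, denom, rate_denominator)
      } else {
        list(percent = NA_real_, n_crossers = length(tit$crossers),
             denominator = 0L, convention = rate_denominator)
      }
      ccds_crossers[[key]] <- list(
        titration = suppressMessages(
          map_to_unique_ccds(tit$crossers, ccds_maps[[sp]])),
        pure_sample = suppressMessages(
          map_to_unique_ccds(pure$crossers, ccds_maps[[sp]]))
      )
      ccds_detected[[key]] <- lapply(det, function(s) {
        suppressMessages(map_to_unique_ccds(s, ccds_maps[[sp]]))
      })
    }
  }

  # Gene-keyed ortholog content per technology: human-platform crossers are
  # human gene IDs, mouse-platform crossers mouse gene IDs.
  orthology <- list()
  for (platform in c("microarray", "rnaseq")) {
    hkey <- paste(platform, "human", sep = "_")
    mkey <- paste(platform, "mouse", sep = "_")
    orthology[[platform]] <- list(
      crossers = ortholog_fraction(crossers[[hkey]]$titration,
                                   crossers[[mkey]]$titration,
                                   gen$orthologs),
      breakdown = ortholog_detection_breakdown(
        detected_anywhere(detected[[hkey]]),
        detected_anywhere(detected[[mkey]]),
        gen$orthologs)
    )
  }

  # Five-sample Venn at CCDS level per technology and species (samples
  # labeled by human percentage), plus pure-sample technology comparison.
  venn <- list()
  technology <- list()
  for (sp in c("human", "mouse")) {
    for (platform in c("microarray", "rnaseq")) {
      key <- paste(platform, sp, sep = "_")
      venn[[key]] <- venn_regions(ccds_detected[[key]])
    }
    pure_level <- if (sp == "human") level_key(1) else level_key(0)
    technology[[sp]] <- two_technology_summary(
      ccds_detected[[paste0("rnaseq_", sp)]][[pure_level]],
      ccds_detected[[paste0("microarray_", sp)]][[pure_level]]
    )
  }

  params <- list(
    n_genes_per_species = n_genes_per_species,
    frac_expressed = frac_expressed, frac_orthologs = frac_orthologs,
    cross_rates = as.list(cross_rates),
    cross_detect_prob = cross_detect_prob, library_size = library_size,
    dispersion = dispersion, cross_alignment_rate = cross_alignment_rate,
    alpha = config$alpha, min_reads = config$min_reads,
    min_replicates = config$min_replicates,
    n_replicates = config$n_replicates,
    rate_denominator = rate_denominator, seed = as.integer(seed),
    schema_version = 1L
  )

  bundle <- structure(
    list(truth = gen, design = design, detected = detected,
         crossers = crossers, comparisons = comparisons, rates = rates,
         ccds = list(maps = ccds_maps, crossers = ccds_crossers,
                     detected = ccds_detected),
         orthology = orthology, venn = venn, technology = technology,
         params = params),
    class = "pipeline_bundle"
  )
  if (!is.null(out_dir)) write_bundle(bundle, tables, out_dir)
  bundle
}

#' @export
print.pipeline_bundle <- function(x, ...) {
  cat(sprintf("Titration pipeline bundle (seed %d, %d genes/species)\n",
              x$params$seed, x$params$n_genes_per_species))
  for (key in names(x$crossers)) {
    cat(sprintf("  %s: %d titration / %d pure-sample crossers (rate %s%%, %s)\n",
                key, length(x$crossers[[key]]$titration$crossers),
                length(x$crossers[[key]]$pure_sample$crossers),
                format(x$rates[[key]]$percent),
                x$rates[[key]]$convention))
  }
  invisible(x)
}

# Serialize a bundle: experiment TSVs + crosser TSVs + JSON summary. Every
# percentage is written with its numerator, denominator and convention so
# the denominator is never ambiguous downstream.
write_bundle <- function(bundle, tables, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_experiment(tables,
                   list(human_catalog = bundle$truth$human_catalog,
                        mouse_catalog = bundle$truth$mouse_catalog),
                   bundle$truth$orthologs, out_dir,
                   truth = bundle$truth$truth)
  for (key in names(bundle$crossers)) {
    for (def in c("titration", "pure_sample")) {
      ids <- bundle$crossers[[key]][[def]]$crossers
      write.table(data.frame(feature_id = ids),
                  file.path(out_dir, sprintf("crossers_%s_%s.tsv", key, def)),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  summary <- list(
    schema_version = 1L,
    params = bundle$params,
    crosser_rates = lapply(bundle$rates, function(r) {
      list(percent = r$percent, numerator = r$n_crossers,
           denominator = r$denominator, convention = r$convention)
    }),
    definition_overlap = lapply(bundle$comparisons, function(cmp) {
      cmp[c("n_both", "n_titration_only", "n_pure_only",
            "pct_titration_in_pure", "undefined")]
    }),
    orthology = lapply(bundle$orthology, function(o) {
      list(combined_fraction = o$crossers$combined_fraction,
           numerator = o$crossers$n_hits_total,
           denominator = o$crossers$n_crossers_human +
             o$crossers$n_crossers_mouse,
           fraction_human = o$crossers$fraction_human,
           fraction_mouse = o$crossers$fraction_mouse,
           breakdown = o$breakdown[c("human_only", "mouse_only", "both",
                                     "n_pairs_considered")])
    }),
    technology = bundle$technology,
    venn = lapply(bundle$venn, function(v) as.list(v$region_counts))
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(out_dir)
}
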