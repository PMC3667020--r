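# Replicate-aware present/absent calls and detection rates.

#' Detection thresholds
#'
#' The present/absent rule: a microarray feature is present at a mixture
#' level when its detection p-value is strictly below `alpha` in at least
#' `min_replicates` of `n_replicates` replicates; an RNA-Seq feature when its
#' read count is at least `min_reads` in at least `min_replicates`
#' replicates.
#'
#' @param alpha detection p-value cutoff (strict `<`), default 0.05.
#' @param min_reads minimal uniquely-aligned read count (inclusive `>=`),
#'   default 5.
#' @param min_replicates replicates that must pass, default 2.
#' @param n_replicates replicates expected per mixture level, default 3.
#' @return an object of class `detection_config`.
#' @export
detection_config <- function(alpha = 0.05, min_reads = 5L,
                             min_replicates = 2L, n_replicates = 3L) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (min_reads < 0) stop("min_reads must be non-negative")
  if (min_replicates < 1L || min_replicates > n_replicates) {
    stop("need 1 <= min_replicates <= n_replicates")
  }
  structure(
    list(alpha = alpha, min_reads = as.integer(min_reads),
         min_replicates = as.integer(min_replicates),
         n_replicates = as.integer(n_replicates)),
    class = "detection_config"
  )
}

#' Call detected features at every mixture level
#'
#' Applies the replicate rule of [detection_config()] to a
#' [detection_table()], producing the per-sample detected-feature sets from
#' which crosser sets are drawn.
#'
#' @param table a [detection_table()].
#' @param config a [detection_config()]; its `n_replicates` must match the
#'   table's design.
#' @return an object of class `detected_sets`: a list keyed by level label
#'   (`h{p}_m{p}`), each element a character vector of detected feature IDs,
#'   with attributes `platform`, `platform_species`, `design` and
#'   `human_fraction` (named numeric vector keyed like the list).
#' @export
call_detection <- function(table, config = detection_config()) {
  stopifnot(inherits(table, "detection_table"))
  stopifnot(inherits(config, "detection_config"))
  design <- table$design
  if (design$replicates != config$n_replicates) {
    stop(sprintf("design has %d replicates but config expects %d",
                 design$replicates, config$n_replicates))
  }
  pass <- if (table$platform == "microarray") {
    table$values < config$alpha
  } else {
    table$values >= config$min_reads
  }
  sets <- lapply(design$mixture_levels, function(h) {
    cols <- vapply(seq_len(design$replicates),
                   function(r) sample_label(h, r), "")
    n_pass <- rowSums(pass[, cols, drop = FALSE])
    rownames(table$values)[n_pass >= config$min_replicates]
  })
  keys <- vapply(design$mixture_levels, level_key, "")
  names(sets) <- keys
  structure(sets,
            platform = table$platform,
            platform_species = table$platform_species,
            design = design,
            human_fraction = setNames(design$mixture_levels, keys),
            class = "detected_sets")
}

#' @export
print.detected_sets <- function(x, ...) {
  cat(sprintf("Detected sets (%s, %s platform):\n",
              attr(x, "platform"), attr(x, "platform_species")))
  for (k in names(x)) cat(sprintf("  %s: %d features\n", k, length(x[[k]])))
  invisible(x)
}

# Detected set at a given same-species fraction.
detected_at <- function(detected, same_fraction) {
  stopifnot(inherits(detected, "detected_sets"))
  hf <- attr(detected, "human_fraction")
  sp <- attr(detected, "platform_species")
  target <- if (sp == "human") same_fraction else 1 - same_fraction
  key <- names(hf)[abs(hf - target) < 1e-9]
  if (length(key) != 1L) {
    stop(sprintf("design has no mixture with same-species fraction %g",
                 same_fraction))
  }
  detected[[key]]
}

#' Detection rate as a percentage of the catalog
#'
#' @param detected character vector (set) of detected feature IDs.
#' @param catalog_size number of features in the platform's catalog.
#' @return `100 * |detected| / catalog_size`, half-up to one decimal.
#' @export
detection_rate <- function(detected, catalog_size) {
  n <- length(unique(detected))
  if (catalog_size <= 0) stop("catalog_size must be positive")
  if (n > catalog_size) stop("detected set larger than catalog")
  percent_one_decimal(n, catalog_size)
}

#' Detection-rate curve across the titration series
#'
#' @param detected a `detected_sets` object from [call_detection()].
#' @param catalog_size features on the platform.
#' @return data.frame with columns `level`, `human_fraction`,
#'   `same_fraction`, `n_detected`, `rate_percent`.
#' @export
detection_rate_curve <- function(detected, catalog_size) {
  stopifnot(inherits(detected, "detected_sets"))
  hf <- attr(detected, "human_fraction")
  sp <- attr(detected, "platform_species")
  data.frame(
    level = names(detected),
    human_fraction = unname(hf),
    same_fraction = unname(vapply(hf, same_species_fraction, 0, species = sp)),
    n_detected = unname(vapply(detected, length, 0L)),
    rate_percent = unname(vapply(detected, detection_rate, 0,
                                 catalog_size = catalog_size)),
    stringsAsFactors = FALSE
  )
}
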