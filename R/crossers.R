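# Crosser identification: the titration set-algebra definition
# ((B u C u D) - A) and the simpler pure-sample definition, plus the
# comparison between the two lists.

#' Assemble the titration sets A-D for one platform
#'
#' From per-level detected sets, extracts the four sets of the titration
#' crosser definition: `A` = features detected in the pure same-species
#' sample, `B`/`C`/`D` = features detected at 25%/50%/75% cross-species RNA.
#' The pure cross-species sample (100% of the other species) is not part of
#' the definition but is carried along for the pure-sample definition.
#'
#' @param detected a `detected_sets` object from [call_detection()] over the
#'   standard five-point design (0, 25, 50, 75, 100% human).
#' @return an object of class `titration_sets` with elements `A`, `B`, `C`,
#'   `D`, `pure_cross`, `platform`, `platform_species`.
#' @export
titration_sets <- function(detected) {
  stopifnot(inherits(detected, "detected_sets"))
  structure(
    list(A = detected_at(detected, 1),
         B = detected_at(detected, 0.75),
         C = detected_at(detected, 0.5),
         D = detected_at(detected, 0.25),
         pure_cross = detected_at(detected, 0),
         platform = attr(detected, "platform"),
         platform_species = attr(detected, "platform_species")),
    class = "titration_sets"
  )
}

new_crosser_result <- function(crossers, definition, platform,
                               platform_species) {
  structure(
    list(crossers = sort(unique(as.character(crossers))),
         definition = definition, platform = platform,
         platform_species = platform_species),
    class = "crosser_result"
  )
}

#' @export
print.crosser_result <- function(x, ...) {
  cat(sprintf("%d crossers (%s definition, %s %s platform)\n",
              length(x$crossers), x$definition, x$platform_species,
              x$platform))
  invisible(x)
}

#' Titration-definition crossers: (B u C u D) - A
#'
#' A feature cross-hybridizes (microarray) or cross-aligns (RNA-Seq) by the
#' titration definition when it is detected in at least one mixed sample but
#' not in the pure same-species sample. The result is structurally disjoint
#' from `A` (asserted after every call).
#'
#' @param sets a [titration_sets()].
#' @return a `crosser_result` with `definition = "titration"`.
#' @export
titration_crossers <- function(sets) {
  stopifnot(inherits(sets, "titration_sets"))
  out <- setdiff(union(union(sets$B, sets$C), sets$D), sets$A)
  stopifnot(length(intersect(out, sets$A)) == 0L)
  new_crosser_result(out, "titration", sets$platform, sets$platform_species)
}

#' Pure-sample-definition crossers
#'
#' The simpler, broader definition: every feature detected when 100%
#' cross-species RNA is assayed on this platform is called a crosser.
#'
#' @param x either a [titration_sets()] / `detected_sets` object (the pure
#'   cross-species level is extracted), or a character vector of feature IDs
#'   detected at the 100% cross-species design point, in which case
#'   `platform` and `platform_species` must be given.
#' @param platform,platform_species metadata when `x` is a bare set.
#' @return a `crosser_result` with `definition = "pure_sample"`.
#' @export
pure_sample_crossers <- function(x, platform = NULL, platform_species = NULL) {
  if (inherits(x, "titration_sets")) {
    return(new_crosser_result(x$pure_cross, "pure_sample", x$platform,
                              x$platform_species))
  }
  if (inherits(x, "detected_sets")) {
    return(new_crosser_result(detected_at(x, 0), "pure_sample",
                              attr(x, "platform"),
                              attr(x, "platform_species")))
  }
  if (is.null(platform) || is.null(platform_species)) {
    stop("platform and platform_species are required for a bare feature set")
  }
  new_crosser_result(x, "pure_sample", platform, platform_species)
}

#' Compare the titration and pure-sample crosser lists
#'
#' Counts the overlap structure of the two definitions' lists and the
#' percentage of the titration list also present in the pure-sample list.
#' Because mixtures can detect features that the pure cross-species sample
#' does not (and vice versa), neither list need contain the other.
#'
#' @param titration a `crosser_result` with the titration definition.
#' @param pure a `crosser_result` with the pure-sample definition, from the
#'   same platform and species.
#' @return a list with `n_both`, `n_titration_only`, `n_pure_only`,
#'   `pct_titration_in_pure` (one decimal; `NA` with `undefined = TRUE` when
#'   the titration list is empty), `platform`, `platform_species`.
#' @export
compare_definitions <- function(titration, pure) {
  stopifnot(inherits(titration, "crosser_result"),
            inherits(pure, "crosser_result"))
  if (titration$definition != "titration" || pure$definition != "pure_sample") {
    stop("arguments must be a titration result and a pure-sample result")
  }
  if (titration$platform != pure$platform ||
      titration$platform_species != pure$platform_species) {
    stop("crosser results come from different platforms")
  }
  both <- intersect(titration$crossers, pure$crossers)
  res <- list(
    n_both = length(both),
    n_titration_only = length(setdiff(titration$crossers, pure$crossers)),
    n_pure_only = length(setdiff(pure$crossers, titration$crossers)),
    pct_titration_in_pure = if (length(titration$crossers) == 0L) NA_real_
      else percent_one_decimal(length(both), length(titration$crossers)),
    undefined = length(titration$crossers) == 0L,
    platform = titration$platform,
    platform_species = titration$platform_species
  )
  stopifnot(res$n_both + res$n_titration_only == length(titration$crossers))
  res
}

#' Crosser rate
#'
#' Percentage of features that cross, relative to an explicit denominator.
#' The convention (number of features detected in at least one titration
#' sample, or the full catalog size) is recorded in the output because
#' published crosser percentages rarely state their denominator.
#'
#' @param crossers a `crosser_result` (or bare set of feature IDs).
#' @param denominator positive count of features in the reference universe.
#' @param convention label recorded with the result: `"detected"` (features
#'   detected anywhere in the titration, the default reading of "percentage
#'   of detected genes") or `"catalog"` (all features on the platform).
#' @return a list with `percent` (one decimal), `n_crossers`, `denominator`,
#'   `convention`.
#' @export
crosser_rate <- function(crossers, denominator,
                         convention = c("detected", "catalog")) {
  convention <- match.arg(convention)
  ids <- if (inherits(crossers, "crosser_result")) crossers$crossers
         else unique(as.character(crossers))
  if (denominator <= 0) stop("denominator must be positive")
  list(percent = percent_one_decimal(length(ids), denominator),
       n_crossers = length(ids),
       denominator = as.integer(denominator),
       convention = convention)
}

#' Union of detected features across all titration samples
#'
#' The default denominator for [crosser_rate()]: every feature detected in
#' at least one sample of the series.
#'
#' @param detected a `detected_sets` object.
#' @return character vector of feature IDs.
#' @export
detected_anywhere <- function(detected) {
  stopifnot(inherits(detected, "detected_sets"))
  sort(unique(unlist(detected, use.names = FALSE)))
}
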