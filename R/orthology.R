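# Ortholog content of crosser lists and the species-of-detection breakdown
# of detected ortholog pairs.

#' Ortholog content of the human and mouse crosser lists
#'
#' A human crosser is an ortholog hit when its identifier appears as
#' `human_id` in any pair of the map; mouse analogously. One-to-many
#' pairings count a crosser once (genes are counted, not pairs).
#'
#' @param crossers_human,crossers_mouse character vectors (or
#'   `crosser_result` objects) of crossing feature IDs, in the same
#'   identifier space as the map (gene- or CCDS-keyed).
#' @param map an [ortholog_map()].
#' @return an object of class `ortholog_summary`: counts
#'   `n_crossers_human`, `n_crossers_mouse`, `n_hits_human`, `n_hits_mouse`,
#'   `n_hits_total`; percentages `combined_fraction`, `fraction_human`,
#'   `fraction_mouse` (one decimal, `NA` + `undefined = TRUE` when the
#'   corresponding crosser list is empty); hit ID vectors `hits_human`,
#'   `hits_mouse`; and the map's `keying`.
#' @export
ortholog_fraction <- function(crossers_human, crossers_mouse, map) {
  stopifnot(inherits(map, "ortholog_map"))
  as_ids <- function(x) {
    if (inherits(x, "crosser_result")) x$crossers
    else unique(as.character(x))
  }
  ch <- as_ids(crossers_human)
  cm <- as_ids(crossers_mouse)
  hits_h <- ch[ch %in% map$pairs$human_id]
  hits_m <- cm[cm %in% map$pairs$mouse_id]
  n_comb <- length(ch) + length(cm)
  if (n_comb >= 100 && nrow(map$pairs) >= 100 &&
      length(hits_h) + length(hits_m) == 0L) {
    warning(sprintf(
      paste0("no ortholog hits among %d crossers despite %d pairs; ",
             "crosser IDs and map keying ('%s') may use different ",
             "identifier spaces"),
      n_comb, nrow(map$pairs), map$keying))
  }
  pct <- function(num, den) if (den == 0L) NA_real_
         else percent_one_decimal(num, den)
  structure(
    list(n_crossers_human = length(ch), n_crossers_mouse = length(cm),
         n_hits_human = length(hits_h), n_hits_mouse = length(hits_m),
         n_hits_total = length(hits_h) + length(hits_m),
         combined_fraction = pct(length(hits_h) + length(hits_m), n_comb),
         fraction_human = pct(length(hits_h), length(ch)),
         fraction_mouse = pct(length(hits_m), length(cm)),
         undefined = n_comb == 0L,
         hits_human = sort(hits_h), hits_mouse = sort(hits_m),
         keying = map$keying),
    class = "ortholog_summary"
  )
}

#' @export
print.ortholog_summary <- function(x, ...) {
  cat(sprintf("Ortholog content (%s-keyed): %d/%d hits combined (%s%%)\n",
              x$keying, x$n_hits_total,
              x$n_crossers_human + x$n_crossers_mouse,
              format(x$combined_fraction)))
  cat(sprintf("  human: %d/%d (%s%%); mouse: %d/%d (%s%%)\n",
              x$n_hits_human, x$n_crossers_human, format(x$fraction_human),
              x$n_hits_mouse, x$n_crossers_mouse, format(x$fraction_mouse)))
  invisible(x)
}

#' Species-of-detection breakdown of ortholog pairs
#'
#' Over the ortholog pairs with at least one detected side, the percentage
#' detected only via the human member, only via the mouse member, or via
#' both. The base population (pairs with >= 1 detected side) is recorded in
#' the output.
#'
#' @param detected_human,detected_mouse character vectors of detected
#'   feature IDs per species, same identifier space as the map.
#' @param map an [ortholog_map()].
#' @return a list with `n_pairs_considered`, counts `n_human_only`,
#'   `n_mouse_only`, `n_both`, and one-decimal percentages `human_only`,
#'   `mouse_only`, `both` (all `NA` with `undefined = TRUE` when no pair has
#'   a detected side). Percentages sum to 100 within rounding.
#' @export
ortholog_detection_breakdown <- function(detected_human, detected_mouse, map) {
  stopifnot(inherits(map, "ortholog_map"))
  detected_human <- unique(as.character(detected_human))
  detected_mouse <- unique(as.character(detected_mouse))
  h_det <- map$pairs$human_id %in% detected_human
  m_det <- map$pairs$mouse_id %in% detected_mouse
  any_det <- h_det | m_det
  n <- sum(any_det)
  if (n == 0L) {
    return(list(n_pairs_considered = 0L, n_human_only = 0L,
                n_mouse_only = 0L, n_both = 0L,
                human_only = NA_real_, mouse_only = NA_real_,
                both = NA_real_, undefined = TRUE))
  }
  n_both <- sum(h_det & m_det)
  n_h <- sum(h_det & !m_det)
  n_m <- sum(m_det & !h_det)
  list(n_pairs_considered = n, n_human_only = n_h, n_mouse_only = n_m,
       n_both = n_both,
       human_only = percent_one_decimal(n_h, n),
       mouse_only = percent_one_decimal(n_m, n),
       both = percent_one_decimal(n_both, n),
       undefined = FALSE)
}
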