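# Feature catalogs, CCDS association maps and ortholog pair tables:
# constructors, TSV readers, and catalog normalization to unique CCDS IDs.

#' Feature catalog
#'
#' A per-platform inventory of features (microarray probes or RNA-Seq gene
#' models) for one species. Feature identifiers must be unique within a
#' catalog; `species` is `"human"` or `"mouse"`.
#'
#' @param platform_id label for the platform (e.g. `"human_chip"`).
#' @param species `"human"` or `"mouse"`.
#' @param feature_id character vector of unique feature identifiers.
#' @param gene_symbol optional character vector of gene symbols, recycled
#'   `NA` if omitted.
#' @return an object of class `feature_catalog`: a list with elements
#'   `platform_id`, `species` and `features` (a data.frame with columns
#'   `feature_id`, `gene_symbol`).
#' @export
feature_catalog <- function(platform_id, species, feature_id,
                            gene_symbol = NULL) {
  check_species(species)
  feature_id <- as.character(feature_id)
  dup <- duplicated(feature_id)
  if (any(dup)) {
    stop(sprintf("duplicate feature_id in catalog: %s",
                 paste(unique(feature_id[dup]), collapse = ", ")))
  }
  if (is.null(gene_symbol)) gene_symbol <- rep(NA_character_, length(feature_id))
  structure(
    list(platform_id = platform_id, species = species,
         features = data.frame(feature_id = feature_id,
                               gene_symbol = as.character(gene_symbol),
                               stringsAsFactors = FALSE)),
    class = "feature_catalog"
  )
}

#' @export
print.feature_catalog <- function(x, ...) {
  cat(sprintf("Feature catalog '%s' (%s): %d features\n",
              x$platform_id, x$species, nrow(x$features)))
  invisible(x)
}

#' Number of features in a catalog
#' @param catalog a [feature_catalog()].
#' @return integer count.
#' @export
catalog_size <- function(catalog) {
  stopifnot(inherits(catalog, "feature_catalog"))
  nrow(catalog$features)
}

#' Read a feature catalog from a tab-delimited file
#'
#' Expects a header with at least `feature_id` and `species` columns and an
#' optional `gene_symbol` column. All rows must carry the same recognized
#' species label. Errors report the offending line number (header = line 1).
#'
#' @param path path to a TSV file.
#' @param platform_id platform label; defaults to the file name without
#'   extension.
#' @return a [feature_catalog()].
#' @export
load_catalog <- function(path, platform_id = NULL) {
  if (!file.exists(path)) stop(sprintf("catalog file not found: %s", path))
  if (is.null(platform_id)) platform_id <- sub("\\.[^.]*$", "", basename(path))
  df <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("feature_id", "species")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sprintf("catalog %s lacks required column(s): %s",
                 path, paste(miss, collapse = ", ")))
  }
  if (nrow(df) == 0L) {
    return(feature_catalog(platform_id, "human", character(0)))
  }
  bad <- which(!df$species %in% c("human", "mouse"))
  if (length(bad)) {
    stop(sprintf("unrecognized species label '%s' at line %d of %s",
                 df$species[bad[1]], bad[1] + 1L, path))
  }
  if (length(unique(df$species)) > 1L) {
    stop(sprintf("catalog %s mixes species labels; one catalog per platform-species",
                 path))
  }
  dup <- which(duplicated(df$feature_id))
  if (length(dup)) {
    stop(sprintf("duplicate feature_id '%s' at line %d of %s",
                 df$feature_id[dup[1]], dup[1] + 1L, path))
  }
  feature_catalog(platform_id, df$species[1], df$feature_id,
                  if ("gene_symbol" %in% names(df)) df$gene_symbol else NULL)
}

#' CCDS association map
#'
#' Many-to-many associations between platform features and Consensus Coding
#' Sequence (CCDS) identifiers, plus the size of the species' CCDS universe
#' (which is an explicit input, never fetched, because CCDS releases drift).
#'
#' @param feature_id,ccds_id character vectors of equal length giving the
#'   association pairs. Duplicated pairs are collapsed with a warning.
#' @param universe_size positive count of CCDS IDs for the species; must be
#'   at least the number of distinct `ccds_id` values supplied.
#' @return an object of class `ccds_map` with elements `associations`
#'   (data.frame `feature_id`, `ccds_id`) and `universe_size`.
#' @export
ccds_map <- function(feature_id, ccds_id, universe_size) {
  feature_id <- as.character(feature_id)
  ccds_id <- as.character(ccds_id)
  stopifnot(length(feature_id) == length(ccds_id))
  if (!is.numeric(universe_size) || length(universe_size) != 1L ||
      universe_size < 1) {
    stop("universe_size must be a positive integer")
  }
  key <- paste(feature_id, ccds_id, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    warning(sprintf("collapsed %d duplicated feature/CCDS association(s)",
                    sum(dup)))
    feature_id <- feature_id[!dup]
    ccds_id <- ccds_id[!dup]
  }
  n_distinct <- length(unique(ccds_id))
  if (universe_size < n_distinct) {
    stop(sprintf("universe_size (%d) smaller than the %d distinct CCDS IDs mapped",
                 universe_size, n_distinct))
  }
  structure(
    list(associations = data.frame(feature_id = feature_id, ccds_id = ccds_id,
                                   stringsAsFactors = FALSE),
         universe_size = as.integer(universe_size)),
    class = "ccds_map"
  )
}

#' Read feature-to-CCDS associations from a tab-delimited file
#'
#' Accepts two dialects: a plain TSV with `feature_id` and `ccds_id` columns,
#' or the NCBI `CCDS.current.txt` layout (tab-delimited, header line prefixed
#' with `#`), from which the `gene_id` column is taken as the feature key and
#' the `ccds_id` column as the CCDS identifier.
#'
#' @param path path to the TSV file.
#' @param universe_size CCDS universe size for the species (see [ccds_map()]).
#' @return a [ccds_map()].
#' @export
load_ccds_map <- function(path, universe_size) {
  if (!file.exists(path)) stop(sprintf("CCDS map file not found: %s", path))
  first <- readLines(path, n = 1L)
  if (startsWith(first, "#")) {
    header <- strsplit(sub("^#", "", first), "\t", fixed = TRUE)[[1]]
    df <- read.delim(path, skip = 1L, header = FALSE,
                     col.names = header, stringsAsFactors = FALSE,
                     colClasses = "character")
    if (!all(c("gene_id", "ccds_id") %in% names(df))) {
      stop(sprintf("%s: NCBI-dialect header lacks gene_id/ccds_id", path))
    }
    ccds_map(df$gene_id, df$ccds_id, universe_size)
  } else {
    df <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
    if (!all(c("feature_id", "ccds_id") %in% names(df))) {
      stop(sprintf("%s lacks feature_id/ccds_id columns", path))
    }
    ccds_map(df$feature_id, df$ccds_id, universe_size)
  }
}

#' Collapse a feature set to its unique CCDS identifiers
#'
#' Returns the distinct CCDS IDs associated with any of the supplied
#' features. Features without an association contribute nothing; the number
#' dropped is reported via [message()]. A CCDS ID downstream counts as
#' detected when at least one mapped feature is detected, so this collapse is
#' the CCDS-level detection rule.
#'
#' @param feature_ids character vector (treated as a set) of feature IDs.
#' @param map a [ccds_map()].
#' @return sorted character vector of unique CCDS IDs.
#' @export
map_to_unique_ccds <- function(feature_ids, map) {
  stopifnot(inherits(map, "ccds_map"))
  feature_ids <- unique(as.character(feature_ids))
  hit <- map$associations$feature_id %in% feature_ids
  mapped <- unique(map$associations$feature_id[hit])
  n_drop <- length(feature_ids) - length(mapped)
  if (n_drop > 0L) {
    message(sprintf("map_to_unique_ccds: %d feature(s) had no CCDS association",
                    n_drop))
  }
  sort(unique(map$associations$ccds_id[hit]))
}

#' CCDS coverage of a platform catalog
#'
#' Percentage of a species' CCDS universe represented on a platform,
#' rounded half-up to one decimal.
#'
#' @param unique_ccds_count number of distinct CCDS IDs the platform covers.
#' @param universe_size total CCDS IDs for the species.
#' @return percentage with one decimal.
#' @examples
#' catalog_coverage(16579, 25504)  # 65.0 (human chip)
#' catalog_coverage(13518, 22131)  # 61.1 (mouse chip)
#' @export
catalog_coverage <- function(unique_ccds_count, universe_size) {
  if (unique_ccds_count < 0 || universe_size <= 0 ||
      unique_ccds_count > universe_size) {
    stop("inconsistent catalog: need 0 <= unique_ccds_count <= universe_size")
  }
  percent_one_decimal(unique_ccds_count, universe_size)
}

#' Ortholog pair map
#'
#' Human-mouse ortholog pairs. Pairs are unique; one-to-many pairings are
#' stored as multiple pairs. Identifier space (gene-keyed or CCDS-keyed) is
#' the caller's choice and recorded so downstream summaries can report it.
#'
#' @param human_id,mouse_id character vectors of equal length.
#' @param keying `"gene"` or `"ccds"`, recorded only.
#' @return an object of class `ortholog_map` with a `pairs` data.frame.
#' @export
ortholog_map <- function(human_id, mouse_id, keying = "gene") {
  human_id <- as.character(human_id)
  mouse_id <- as.character(mouse_id)
  stopifnot(length(human_id) == length(mouse_id))
  keying <- match.arg(keying, c("gene", "ccds"))
  key <- paste(human_id, mouse_id, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    warning(sprintf("collapsed %d duplicated ortholog pair(s)", sum(dup)))
    human_id <- human_id[!dup]
    mouse_id <- mouse_id[!dup]
  }
  structure(
    list(pairs = data.frame(human_id = human_id, mouse_id = mouse_id,
                            stringsAsFactors = FALSE),
         keying = keying),
    class = "ortholog_map"
  )
}

#' @export
print.ortholog_map <- function(x, ...) {
  cat(sprintf("Ortholog map (%s-keyed): %d pairs\n", x$keying, nrow(x$pairs)))
  invisible(x)
}

#' Read an ortholog pair table from a tab-delimited file
#'
#' @param path TSV with columns `human_id` and `mouse_id`.
#' @param keying identifier space of the pairs, `"gene"` or `"ccds"`.
#' @return an [ortholog_map()].
#' @export
load_ortholog_map <- function(path, keying = "gene") {
  if (!file.exists(path)) stop(sprintf("ortholog file not found: %s", path))
  df <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  if (!all(c("human_id", "mouse_id") %in% names(df))) {
    stop(sprintf("%s lacks human_id/mouse_id columns", path))
  }
  if (anyNA(df$human_id) || anyNA(df$mouse_id) ||
      any(df$human_id == "") || any(df$mouse_id == "")) {
    bad <- which(is.na(df$human_id) | is.na(df$mouse_id) |
                   df$human_id == "" | df$mouse_id == "")[1]
    stop(sprintf("malformed ortholog row at line %d of %s", bad + 1L, path))
  }
  ortholog_map(df$human_id, df$mouse_id, keying = keying)
}
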