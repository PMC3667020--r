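# Shared helpers: percentage formatting, seed streams, sample labels.

#' Round half-up
#'
#' Rounds to `digits` decimals with ties going away from zero for positive
#' input, the convention used for every percentage this package reports.
#' Base [round()] rounds half to even, which disagrees on printed one-decimal
#' percentages often enough to matter.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @keywords internal
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  # small offset absorbs binary representation error in x * scale + 0.5
  floor(x * scale + 0.5 + 1e-9) / scale
}

#' Percentage rounded half-up to one decimal
#'
#' @param numerator,denominator non-negative counts; `denominator` must be
#'   positive.
#' @return `100 * numerator / denominator` rounded half-up to one decimal.
#' @examples
#' percent_one_decimal(16579, 25504)  # 65.0
#' @export
percent_one_decimal <- function(numerator, denominator) {
  stopifnot(is.numeric(numerator), is.numeric(denominator))
  if (any(denominator <= 0)) stop("denominator must be positive")
  if (any(numerator < 0)) stop("numerator must be non-negative")
  round_half_up(100 * numerator / denominator, 1)
}

# One master seed drives independent streams for truth generation and each
# simulated platform: stream k uses a deterministic arithmetic derivation of
# (seed, k) kept below 2^31 so set.seed() accepts it on all platforms.
derive_seed <- function(seed, stage) {
  seed <- as.numeric(seed)
  stage <- as.numeric(stage)
  as.integer((abs(seed) * 7919 + stage * 104729 + 12345) %% 2147483647)
}

# Column labels of the titration design: h{percent human}_m{percent mouse},
# with _r{replicate} appended for individual replicate columns.
level_key <- function(human_fraction) {
  sprintf("h%d_m%d", round(100 * human_fraction), round(100 * (1 - human_fraction)))
}

sample_label <- function(human_fraction, replicate) {
  sprintf("%s_r%d", level_key(human_fraction), replicate)
}

# Fraction of the platform's own species in each mixture of a design.
same_species_fraction <- function(human_fraction, species) {
  if (species == "human") human_fraction else 1 - human_fraction
}

check_species <- function(species) {
  if (!is.character(species) || length(species) != 1L ||
      !species %in% c("human", "mouse")) {
    stop("species must be \"human\" or \"mouse\"")
  }
  species
}

other_species <- function(species) {
  if (species == "human") "mouse" else "human"
}

check_probability <- function(x, name) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0) || any(x > 1)) {
    stop(sprintf("%s must be a probability in [0, 1]", name))
  }
  x
}
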