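#' Amino-acid frequency profiles
#'
#' A frequency profile is the 20-state compositional vector that underlies
#' every model flavour in hetcheck: the single stationary distribution of a
#' homogeneous model, the class profiles of a finite mixture, and the per-site
#' profiles of a PMSF model.  `frequency_profile()` validates, regularizes
#' and normalizes a numeric vector into one.
#'
#' Zero entries make the substitution process non-ergodic (a state that can
#' never be reached has undefined likelihood contributions), so they are
#' floored at `floor_eps` and the vector renormalized.  Set
#' `regularize = FALSE` to forbid zeros instead.
#'
#' @param freqs numeric vector of 20 non-negative values.
#' @param regularize floor zero entries at `floor_eps` and renormalize
#'   (default) rather than rejecting them.
#' @param floor_eps the floor applied to zero entries.
#' @return a numeric vector of length 20 summing to 1, named by amino acid.
#' @examples
#' frequency_profile(rep(1, 20))
#' @export
frequency_profile <- function(freqs, regularize = TRUE, floor_eps = 1e-10) {
  freqs <- as.numeric(freqs)
  if (length(freqs) != 20L) {
    stop("a frequency profile needs exactly 20 entries, got ", length(freqs))
  }
  if (anyNA(freqs) || any(freqs < 0)) {
    stop("frequency profile entries must be non-negative and non-missing")
  }
  s <- sum(freqs)
  if (s <= 0) stop("frequency profile sums to zero")
  freqs <- freqs / s
  if (!regularize) {
    if (any(freqs == 0)) {
      stop("frequency profile has zero entries; ",
           "the resulting chain is not ergodic")
    }
  } else if (any(freqs < floor_eps)) {
    freqs <- pmax(freqs, floor_eps)
    freqs <- freqs / sum(freqs)
  }
  names(freqs) <- AA_STATES
  freqs
}

is_valid_profile <- function(p, tol = 1e-9) {
  is.numeric(p) && length(p) == 20L && !anyNA(p) &&
    all(p >= 0) && abs(sum(p) - 1) <= tol
}

#' Uniform amino-acid profile
#' @return frequency profile with all entries 1/20.
#' @export
uniform_profile <- function() frequency_profile(rep(1 / 20, 20))

# profiles as rows of an n x 20 matrix; shared validation
as_profile_matrix <- function(profiles) {
  if (is.numeric(profiles) && is.null(dim(profiles))) {
    profiles <- matrix(profiles, nrow = 1)
  }
  if (is.list(profiles)) profiles <- do.call(rbind, profiles)
  if (ncol(profiles) != 20L) stop("profiles must have 20 columns")
  t(apply(profiles, 1, frequency_profile))
}
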