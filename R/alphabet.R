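#' The amino-acid state space
#'
#' All machinery in hetcheck works on the 20 canonical amino acids in a fixed
#' alphabetical one-letter order (the order used by Phylobayes-style site
#' profile files).  Gap characters and ambiguity codes are both treated as
#' "unobserved": they contribute no state information to likelihoods or to the
#' diversity statistic.
#'
#' @format `aa_states()` returns a character vector of length 20.
#' @examples
#' aa_states()
#' @export
aa_states <- function() AA_STATES

AA_STATES <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

AA_GAP_CHARS <- c("-", "?")
AA_AMBIG_CHARS <- c("X", "B", "Z", "J", "*", ".")

#' Classify alignment characters
#'
#' Maps each character to its canonical state index (1-20), or to `0` for
#' gaps (`-`, `?`) and ambiguity codes (`X`, `B`, `Z`, `J`, `*`, `.`), which
#' are equivalent "unobserved" classes everywhere in the package.  Lower-case
#' input is accepted.  Any other character is an error.
#'
#' @param x character vector of single characters.
#' @return integer vector of the same length; 0 means unobserved.
#' @examples
#' aa_encode(c("A", "-", "X", "w"))
#' @export
aa_encode <- function(x) {
  x <- toupper(as.character(x))
  idx <- match(x, AA_STATES)
  unobserved <- x %in% c(AA_GAP_CHARS, AA_AMBIG_CHARS)
  idx[unobserved] <- 0L
  bad <- is.na(idx)
  if (any(bad)) {
    stop("unrecognised alignment character(s): ",
         paste(unique(x[bad]), collapse = " "))
  }
  idx
}

# inverse of aa_encode; 0 -> "-"
aa_decode <- function(i) {
  out <- rep("-", length(i))
  obs <- i > 0L
  out[obs] <- AA_STATES[i[obs]]
  out
}
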