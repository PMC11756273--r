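#' Exchangeability matrices
#'
#' A symmetric 20x20 matrix of relative substitution rates with zero
#' diagonal.  Two presets are provided: `"Poisson"` (all off-diagonal rates
#' equal, the exchangeability part of F81-style models) and `"LG"` (the
#' empirical Le-Gascuel matrix, taken from phangorn's shipped copy and
#' reordered to this package's alphabetical state order).  A custom symmetric
#' matrix can be supplied for GTR-style models.
#'
#' @param name `"Poisson"`, `"LG"`, or `"GTR-custom"`.
#' @param s for `"GTR-custom"`: a symmetric 20x20 non-negative matrix.
#' @return an object of class `exchangeability` (matrix with a `name`
#'   attribute).
#' @examples
#' e <- exchangeability("Poisson")
#' attr(e, "name")
#' @export
exchangeability <- function(name = c("Poisson", "LG", "GTR-custom"), s = NULL) {
  name <- match.arg(name)
  if (name == "Poisson") {
    s <- matrix(1, 20, 20)
    diag(s) <- 0
  } else if (name == "LG") {
    s <- lg_model()$s
  } else {
    if (is.null(s)) stop("GTR-custom needs an explicit matrix `s`")
    s <- as.matrix(s)
  }
  if (!all(dim(s) == c(20L, 20L))) stop("exchangeability matrix must be 20x20")
  if (any(s < 0)) stop("exchangeabilities must be non-negative")
  if (!isTRUE(all.equal(s, t(s), tolerance = 0))) {
    # require exact symmetry; symmetrize explicit input upstream if needed
    if (max(abs(s - t(s))) > 0) stop("exchangeability matrix must be symmetric")
  }
  diag(s) <- 0
  dimnames(s) <- list(AA_STATES, AA_STATES)
  structure(s, name = name, class = c("exchangeability", "matrix"))
}

# LG exchangeabilities + frequencies from phangorn, reordered from the PAML
# amino-acid order (ARNDCQEGHILKMFPSTWYV) to alphabetical
lg_model <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    lg <- utils::getFromNamespace(".LG", "phangorn")
    paml <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
              "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
    s <- matrix(0, 20, 20, dimnames = list(paml, paml))
    s[lower.tri(s)] <- lg$Q
    s <- s + t(s)
    s <- s[AA_STATES, AA_STATES]
    bf <- lg$bf
    names(bf) <- paml
    cache <<- list(s = s, freqs = frequency_profile(bf[AA_STATES]))
    cache
  }
})

#' LG equilibrium frequencies
#' @return the published LG amino-acid frequency profile.
#' @export
lg_frequencies <- function() lg_model()$freqs

is_poisson_exchangeability <- function(exch) {
  identical(attr(exch, "name"), "Poisson")
}

#' Build a reversible rate matrix
#'
#' Standard general-time-reversible construction: `Q[i, j] = s[i, j] * pi[j]`
#' for `i != j`, diagonal set so rows sum to zero, then the whole matrix
#' scaled so that the expected substitution rate at stationarity,
#' `-sum(pi * diag(Q))`, is 1 (branch lengths are then expected
#' substitutions per site).
#'
#' @param exch an [exchangeability()] matrix.
#' @param profile a [frequency_profile()]; zero entries are rejected because
#'   they make the chain non-ergodic (regularize the profile first).
#' @return a list of class `rate_matrix` with elements `Q` (20x20) and `pi`
#'   (the stationary profile).
#' @export
build_rate_matrix <- function(exch, profile) {
  profile <- frequency_profile(profile, regularize = FALSE)
  Q <- sweep(unclass(exch)[, , drop = TRUE], 2, profile, `*`)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  scale <- -sum(profile * diag(Q))
  if (scale <= 0) stop("degenerate rate matrix (zero overall rate)")
  Q <- Q / scale
  structure(list(Q = Q, pi = profile), class = "rate_matrix")
}

#' Transition probability matrix
#'
#' `P(t) = exp(Q t)` computed through the symmetrized eigendecomposition
#' available for reversible chains: with `D = diag(sqrt(pi))`, `D Q D^-1` is
#' symmetric, so its eigendecomposition is stable and `P(t)` follows by
#' scaling back.
#'
#' @param rate a `rate_matrix` from [build_rate_matrix()].
#' @param t branch length, non-negative.
#' @return a 20x20 row-stochastic matrix.
#' @export
transition_matrix <- function(rate, t) {
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t < 0) {
    stop("branch length must be a single non-negative number")
  }
  if (t == 0) {
    P <- diag(20)
    dimnames(P) <- list(AA_STATES, AA_STATES)
    return(P)
  }
  ed <- rate_eigen(rate)
  P <- ed$right %*% (exp(ed$values * t) * ed$left)
  P[P < 0] <- 0
  P <- P / rowSums(P)
  dimnames(P) <- list(AA_STATES, AA_STATES)
  P
}

# symmetrized eigendecomposition, cached on the rate_matrix if present
rate_eigen <- function(rate) {
  if (!is.null(rate$eigen)) return(rate$eigen)
  d <- sqrt(rate$pi)
  S <- rate$Q * (d %o% (1 / d))
  S <- (S + t(S)) / 2
  es <- eigen(S, symmetric = TRUE)
  list(
    values = es$values,
    right = (1 / d) * es$vectors,      # D^-1 U
    left = t(es$vectors * d)           # U' D
  )
}

# attach the cached eigendecomposition (used by the simulator/likelihood)
with_eigen <- function(rate) {
  rate$eigen <- rate_eigen(rate)
  rate
}

#' Discrete gamma rate categories
#'
#' The usual mean-of-equiprobable-quantile-bins discretization of a
#' mean-one gamma distribution (shape and rate both `alpha`): the rate axis
#' is cut at the `i/K` quantiles and each category rate is the exact
#' conditional mean within its bin, computed from the incomplete-gamma
#' identity.  Category weights are uniform `1/K` and the weighted mean rate
#' is exactly 1.
#'
#' @param alpha gamma shape, > 0.  Small values mean strong rate variation.
#' @param K number of categories, >= 1.
#' @return a list of class `gamma_rates`: `alpha`, `n_categories`,
#'   `category_rates`, `category_weights`.
#' @examples
#' discrete_gamma_rates(0.5, 4)$category_rates
#' @export
discrete_gamma_rates <- function(alpha, K = 4L) {
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) || alpha <= 0) {
    stop("gamma shape `alpha` must be a single positive number")
  }
  K <- as.integer(K)
  if (is.na(K) || K < 1L) stop("number of categories must be >= 1")
  if (K == 1L) {
    rates <- 1
  } else {
    cuts <- stats::qgamma(seq_len(K - 1) / K, shape = alpha, rate = alpha)
    # mean of X over (cuts[i-1], cuts[i]] equals the difference of the
    # shape+1 CDF at the cut points, times K (bin mass is 1/K)
    upper <- c(stats::pgamma(cuts, shape = alpha + 1, rate = alpha), 1)
    lower <- c(0, stats::pgamma(cuts, shape = alpha + 1, rate = alpha))
    rates <- K * (upper - lower)
    rates <- rates / sum(rates / K)   # exact mean 1 despite rounding
  }
  structure(
    list(alpha = alpha, n_categories = K, category_rates = rates,
         category_weights = rep(1 / K, K)),
    class = "gamma_rates"
  )
}

## ---- model flavours ------------------------------------------------------

new_model <- function(flavour, exch, gamma, fields) {
  stopifnot(inherits(gamma, "gamma_rates"))
  structure(
    c(list(flavour = flavour, exchangeabilities = exch, gamma = gamma),
      fields),
    class = c(paste0(flavour, "_model"), "aa_model")
  )
}

#' Site-homogeneous substitution model
#'
#' One stationary profile shared by every site (e.g. LG+G4, Poisson+F+G4).
#'
#' @param exch an [exchangeability()] matrix.
#' @param profile a single [frequency_profile()].
#' @param gamma a [discrete_gamma_rates()] object.
#' @return an `aa_model` of flavour `"homogeneous"`.
#' @export
homogeneous_model <- function(exch, profile, gamma = discrete_gamma_rates(1, 4)) {
  new_model("homogeneous", exch, gamma,
            list(profile = frequency_profile(profile)))
}

#' Finite profile-mixture model
#'
#' A fixed number of frequency-profile classes shared across sites
#' (the CXX family): each site belongs to one class, with prior class
#' weights; exchangeabilities and gamma rates are shared.
#'
#' @param exch an [exchangeability()] matrix.
#' @param class_profiles list or matrix (rows) of frequency profiles.
#' @param class_weights non-negative weights summing to 1; default uniform.
#' @param gamma a [discrete_gamma_rates()] object.
#' @return an `aa_model` of flavour `"mixture"`.
#' @export
mixture_model <- function(exch, class_profiles, class_weights = NULL,
                          gamma = discrete_gamma_rates(1, 4)) {
  profs <- as_profile_matrix(class_profiles)
  k <- nrow(profs)
  if (k < 1L) stop("a mixture needs at least one class")
  if (is.null(class_weights)) class_weights <- rep(1 / k, k)
  if (length(class_weights) != k || any(class_weights < 0)) {
    stop("class weights must be non-negative, one per class")
  }
  if (abs(sum(class_weights) - 1) > 1e-9) {
    stop("class weights must sum to 1")
  }
  new_model("mixture", exch, gamma,
            list(class_profiles = profs, class_weights = class_weights))
}

#' Site-specific profile (PMSF-style) model
#'
#' One frequency profile per alignment site; the alignment length is fixed
#' by the number of profiles.  This is the form a posterior-mean
#' site-frequency (PMSF) model takes once exported from a mixture.
#'
#' @param exch an [exchangeability()] matrix.
#' @param site_profiles list or matrix (rows = sites) of frequency profiles.
#' @param gamma a [discrete_gamma_rates()] object.
#' @return an `aa_model` of flavour `"site_profile"`.
#' @export
site_profile_model <- function(exch, site_profiles,
                               gamma = discrete_gamma_rates(1, 4)) {
  profs <- as_profile_matrix(site_profiles)
  if (nrow(profs) < 1L) stop("need at least one site profile")
  new_model("site_profile", exch, gamma, list(site_profiles = profs))
}

#' @export
print.aa_model <- function(x, ...) {
  n <- switch(x$flavour,
    homogeneous = "1 shared profile",
    mixture = paste0(nrow(x$class_profiles), " profile classes"),
    site_profile = paste0(nrow(x$site_profiles), " site profiles")
  )
  cat(sprintf(
    "<aa_model> %s | %s exchangeabilities | %s | gamma(alpha=%g, K=%d)\n",
    x$flavour, attr(x$exchangeabilities, "name"), n,
    x$gamma$alpha, x$gamma$n_categories))
  invisible(x)
}

# number of sites a model pins down, or NA if free
model_fixed_length <- function(model) {
  if (model$flavour == "site_profile") nrow(model$site_profiles) else NA_integer_
}

#' Parse a model specification string
#'
#' Understands the compact strings used in configs and on the command line:
#' \describe{
#'   \item{`"LG+G4"`}{homogeneous LG with its published frequencies.}
#'   \item{`"Poisson+G4"`}{homogeneous Poisson with a uniform profile (or a
#'     supplied one).}
#'   \item{`"Poisson+C<N>+G4"` / `"LG+C<N>+G4"`}{finite mixture with N
#'     classes; the class profiles must be supplied via `profiles` (no
#'     empirical C-series tables ship with the package).}
#'   \item{`"PMSF:<file>+G4"`}{site-specific profiles read from an
#'     IQ-TREE-style site-frequency file.}
#' }
#' The trailing `G<K>` sets the number of gamma categories; the shape is not
#' encoded in the string and comes from `alpha`.
#'
#' @param spec the specification string.
#' @param alpha gamma shape to use (the string only fixes K).
#' @param profiles optional profile matrix: the homogeneous profile
#'   (1 row) or the mixture class profiles (N rows).
#' @param class_weights optional mixture weights.
#' @return an `aa_model`.
#' @examples
#' parse_model_spec("Poisson+G4", alpha = 0.8)
#' @export
parse_model_spec <- function(spec, alpha = 1, profiles = NULL,
                             class_weights = NULL) {
  spec <- trimws(spec)
  m <- regmatches(spec, regexec("^PMSF:(.+)\\+G([0-9]+)$", spec))[[1]]
  if (length(m) == 3L) {
    gamma <- discrete_gamma_rates(alpha, as.integer(m[3]))
    profs <- read_site_profiles(m[2], dialect = "iqtree_fs")[[1]]
    return(site_profile_model(exchangeability("Poisson"), profs, gamma))
  }
  m <- regmatches(spec,
                  regexec("^(Poisson|LG)(\\+C([0-9]+))?\\+G([0-9]+)$", spec))[[1]]
  if (length(m) == 0L) stop("unrecognised model spec: '", spec, "'")
  exch <- exchangeability(m[2])
  gamma <- discrete_gamma_rates(alpha, as.integer(m[5]))
  if (nzchar(m[3])) {
    n_class <- as.integer(m[4])
    if (is.null(profiles)) {
      stop("model '", spec, "' is a ", n_class, "-class mixture: supply the ",
           "class profiles (no empirical C-series tables ship with hetcheck)")
    }
    profs <- as_profile_matrix(profiles)
    if (nrow(profs) != n_class) {
      stop("spec asks for ", n_class, " classes but ", nrow(profs),
           " profiles were supplied")
    }
    return(mixture_model(exch, profs, class_weights, gamma))
  }
  profile <- if (!is.null(profiles)) {
    as_profile_matrix(profiles)[1, ]
  } else if (m[2] == "LG") {
    lg_frequencies()
  } else {
    uniform_profile()
  }
  homogeneous_model(exch, profile, gamma)
}
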