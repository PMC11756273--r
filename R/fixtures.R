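#' Generate a fixture tree
#'
#' Random trees for simulation studies and tests.  Styles: `"balanced"`
#' (fully balanced binary shape; needs a power-of-two taxon count),
#' `"pectinate"` (caterpillar), `"star"` (one internal node), and
#' `"coalescent"` (random coalescent genealogy via [ape::rcoal()], whose
#' own coalescent branch lengths are kept).  For the shape styles, branch
#' lengths are drawn i.i.d. from the requested distribution.  Deterministic
#' per seed.
#'
#' @param n_taxa number of leaves, >= 3.
#' @param style tree shape, see above.
#' @param branch_lengths `"uniform"` or `"exponential"` (ignored for
#'   `"coalescent"`).
#' @param bl_min,bl_max range of the uniform length distribution.
#' @param bl_rate rate of the exponential length distribution.
#' @param seed integer seed.
#' @return an [ape::phylo] tree with branch lengths.
#' @examples
#' generate_tree(8, "balanced", seed = 1)
#' @export
generate_tree <- function(n_taxa,
                          style = c("coalescent", "balanced", "pectinate", "star"),
                          branch_lengths = c("uniform", "exponential"),
                          bl_min = 0.05, bl_max = 0.5, bl_rate = 5,
                          seed = 1) {
  style <- match.arg(style)
  branch_lengths <- match.arg(branch_lengths)
  if (n_taxa < 3L) stop("need at least 3 taxa")
  set.seed(seed)
  if (style == "coalescent") {
    return(ape::rcoal(n_taxa))
  }
  if (style == "balanced" && log2(n_taxa) %% 1 != 0) {
    stop("balanced trees need a power-of-two taxon count")
  }
  tr <- ape::stree(n_taxa, type = switch(style,
    balanced = "balanced", pectinate = "left", star = "star"))
  n_edge <- nrow(tr$edge)
  tr$edge.length <- switch(branch_lengths,
    uniform = stats::runif(n_edge, bl_min, bl_max),
    exponential = stats::rexp(n_edge, bl_rate))
  tr$tip.label <- sprintf("t%d", seq_len(n_taxa))
  tr
}

#' Generate site profiles
#'
#' Random per-site frequency profiles emulating CAT-style across-site
#' compositional heterogeneity.  `"dirichlet"` draws each site's profile
#' from a symmetric Dirichlet: small concentrations (e.g. 0.1) give sparse
#' profiles where a handful of amino acids carry nearly all the mass -- the
#' regime in which homogeneous models misjudge per-site diversity.
#' `"k_class"` first draws `k` class profiles from the Dirichlet, then
#' assigns each site to a class uniformly (assignments in the
#' `"assignment"` attribute, class profiles in `"classes"`), emulating a
#' finite CXX-style mixture.  `"uniform"` gives every site the flat
#' profile.
#'
#' @param n_sites number of profiles.
#' @param generator `"uniform"`, `"dirichlet"` or `"k_class"`.
#' @param concentration symmetric Dirichlet concentration, > 0.
#' @param k number of classes for `"k_class"`.
#' @param seed integer seed.
#' @return an n_sites x 20 matrix of profiles (rows sum to 1).
#' @export
generate_site_profiles <- function(n_sites,
                                   generator = c("dirichlet", "uniform", "k_class"),
                                   concentration = 0.5, k = 4, seed = 1) {
  generator <- match.arg(generator)
  if (n_sites < 1L) stop("n_sites must be >= 1")
  if (generator == "uniform") {
    return(as_profile_matrix(matrix(1 / 20, n_sites, 20)))
  }
  if (!is.numeric(concentration) || concentration <= 0) {
    stop("Dirichlet concentration must be > 0")
  }
  set.seed(seed)
  rdirichlet <- function(n) {
    g <- matrix(stats::rgamma(n * 20, shape = concentration), n, 20)
    g / rowSums(g)
  }
  if (generator == "dirichlet") {
    return(as_profile_matrix(rdirichlet(n_sites)))
  }
  classes <- as_profile_matrix(rdirichlet(k))
  assignment <- sample.int(k, n_sites, replace = TRUE)
  out <- as_profile_matrix(classes[assignment, , drop = FALSE])
  attr(out, "classes") <- classes
  attr(out, "assignment") <- assignment
  out
}

#' Bonferroni-corrected significance level
#'
#' The per-test significance level when a hypothesis is tested `n_tests`
#' times at family-wise level `family_alpha`:
#' `family_alpha / n_tests`.  E.g. eight repeated topology tests at 0.05
#' give 0.00625.
#'
#' @param family_alpha family-wise error rate, in (0, 1).
#' @param n_tests number of tests, >= 1.
#' @return the corrected per-test alpha.
#' @examples
#' bonferroni_alpha(0.05, 8)
#' @export
bonferroni_alpha <- function(family_alpha, n_tests) {
  if (!is.numeric(family_alpha) || length(family_alpha) != 1L ||
      is.na(family_alpha) || family_alpha <= 0 || family_alpha >= 1) {
    stop("family_alpha must be a single number in (0, 1)")
  }
  n_tests <- as.integer(n_tests)
  if (is.na(n_tests) || n_tests < 1L) stop("n_tests must be >= 1")
  family_alpha / n_tests
}

#' Bundled fixture topologies
#'
#' Eight synthetic ecdysozoan hypothesis topologies (Newick, synthetic
#' branch lengths) covering the usual competing resolutions of
#' Panarthropoda (Lobopodia, Tactopoda, Protoarthropoda) and of the
#' position of Tardigrada and Nematoida (Cryptovermes, Cycloneuralia,
#' Tardigrada + Scalidophora).  They reproduce the *shape* of
#' profile-estimated-under-topology-X experiments at desk scale; they are
#' constructed fixtures, not published trees.
#'
#' @return named character vector of .nwk file paths.
#' @export
fixture_topologies <- function() {
  dir <- system.file("extdata", "topologies_synthetic", package = "hetcheck")
  files <- list.files(dir, pattern = "\\.nwk$", full.names = TRUE)
  stats::setNames(files, sub("\\.nwk$", "", basename(files)))
}

#' Read a flat key-value config file
#'
#' One `key = value` pair per line; blank lines and `#` comments ignored.
#'
#' @param path config file.
#' @return named list of character values.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([^=]+)=(.*)$", lines))
  bad <- lengths(kv) != 3L
  if (any(bad)) stop("config line not of the form key = value: ", lines[bad][1])
  stats::setNames(
    lapply(kv, function(x) trimws(x[3])),
    vapply(kv, function(x) trimws(x[2]), character(1))
  )
}

#' One calibration / discrimination trial of the adequacy test
#'
#' The desk-scale simulation study behind the package's self-checks.  A
#' trial generates a random coalescent tree, draws per-site Dirichlet
#' profiles, simulates one "observed" alignment under the resulting
#' site-profile model (Poisson exchangeabilities, discrete gamma), and
#' adequacy-tests that alignment under either the generating model itself
#' (`test_under = "true"`: the self-consistency setting, where |Z| should
#' stay within +/-2) or the site-homogeneous model whose single profile is
#' the mean of the site profiles (`test_under = "mean"`: the discrimination
#' setting, where averaging away the across-site heterogeneity makes
#' simulated columns far too diverse and pushes Z well above 2).  All
#' randomness derives from `seed`.
#'
#' @param seed integer seed for the trial.
#' @param n_taxa,n_sites fixture size (default 100 taxa x 2000 sites).
#' @param concentration Dirichlet concentration of the site profiles
#'   (0.5 for the calibration setting; 0.1 gives the sparse profiles used
#'   for discrimination).
#' @param test_under `"true"` or `"mean"`, see above.
#' @param n_reps bootstrap replicates.
#' @param alpha gamma shape (4 categories).
#' @return an `adequacy_result`.
#' @export
adequacy_trial <- function(seed, n_taxa = 100, n_sites = 2000,
                           concentration = 0.5,
                           test_under = c("true", "mean"),
                           n_reps = 100, alpha = 1) {
  test_under <- match.arg(test_under)
  tree <- generate_tree(n_taxa, "coalescent", seed = seed)
  profs <- generate_site_profiles(n_sites, "dirichlet",
                                  concentration = concentration,
                                  seed = seed + 1000L)
  gamma <- discrete_gamma_rates(alpha, 4)
  true_model <- site_profile_model(exchangeability("Poisson"), profs, gamma)
  obs <- simulate_alignment(tree, true_model, seed = seed)
  model <- switch(test_under,
    true = true_model,
    mean = homogeneous_model(exchangeability("Poisson"), colMeans(profs), gamma)
  )
  adequacy_test(obs, model, tree, n_reps = n_reps, seed = seed + 50L,
                model_spec = paste0("trial:", test_under))
}
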