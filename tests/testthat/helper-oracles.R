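# Test helpers: tiny fixtures and independent oracles.
# The oracles deliberately avoid the package's own code paths: likelihoods by
# exhaustive enumeration over internal-node states, gamma category rates by
# numerical quadrature, transition probabilities by dense matrix exponential
# series.

rand_profile <- function(seed, concentration = 1) {
  set.seed(seed)
  frequency_profile(rgamma(20, concentration) + 1e-6)
}

# brute-force site likelihood: sum over all internal-node state assignments,
# averaged over gamma categories (1/K) and mixture classes (weights)
enum_site_likelihood <- function(tree, model, column) {
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  nint <- tree$Nnode
  root <- tree$edge[nrow(tree$edge), 1]
  states <- hetcheck::aa_encode(column[tree$tip.label])
  K <- model$gamma$n_categories
  rates <- model$gamma$category_rates

  comp <- switch(model$flavour,
    homogeneous = list(profiles = matrix(model$profile, 1, 20, byrow = TRUE),
                       weights = 1),
    mixture = list(profiles = model$class_profiles,
                   weights = model$class_weights),
    site_profile = list(profiles = model$site_profiles[1, , drop = FALSE],
                        weights = 1)
  )
  total <- 0
  for (k in seq_along(comp$weights)) {
    prof <- comp$profiles[k, ]
    rm <- hetcheck::build_rate_matrix(model$exchangeabilities, prof)
    for (c_i in seq_len(K)) {
      Ps <- lapply(seq_len(nrow(tree$edge)), function(e) {
        series_expm(rm$Q * rates[c_i] * tree$edge.length[e])
      })
      lik <- 0
      grid <- as.matrix(expand.grid(rep(list(1:20), nint)))
      for (g in seq_len(nrow(grid))) {
        st <- c(states, grid[g, ])  # node states: tips 1..ntip, then internals
        p <- unname(prof[st[root]])
        for (e in seq_len(nrow(tree$edge))) {
          child <- tree$edge[e, 2]
          if (child <= ntip && states[child] == 0L) next  # gap tip: sums to 1
          p <- p * Ps[[e]][st[tree$edge[e, 1]], st[child]]
          if (p == 0) break
        }
        lik <- lik + p
      }
      total <- total + comp$weights[k] * lik / K
    }
  }
  unname(total)
}

# dense Taylor-series matrix exponential with scaling and squaring
series_expm <- function(M) {
  n <- nrow(M)
  s <- max(0L, ceiling(log2(max(1, norm(M, "1")))))
  A <- M / 2^s
  E <- diag(n)
  term <- diag(n)
  for (k in 1:30) {
    term <- term %*% A / k
    E <- E + term
  }
  for (i in seq_len(s)) E <- E %*% E
  E
}

# quadrature oracle for the mean of a mean-one gamma within quantile bins
quadrature_gamma_rates <- function(alpha, K) {
  cuts <- c(0, stats::qgamma(seq_len(K - 1) / K, alpha, alpha), Inf)
  vapply(seq_len(K), function(i) {
    upper <- if (is.finite(cuts[i + 1])) cuts[i + 1] else
      stats::qgamma(1 - 1e-12, alpha, alpha)
    v <- stats::integrate(function(x) x * stats::dgamma(x, alpha, alpha),
                          cuts[i], upper, rel.tol = 1e-10)$value
    v * K
  }, numeric(1))
}

# handy tiny fixtures
tree5 <- function() hetcheck::parse_newick(
  "((A:0.12,B:0.31):0.09,C:0.27,(D:0.18,E:0.05):0.22);")

poisson_uniform_model <- function(K = 1, alpha = 1) {
  hetcheck::homogeneous_model(hetcheck::exchangeability("Poisson"),
                              hetcheck::uniform_profile(),
                              hetcheck::discrete_gamma_rates(alpha, K))
}

# gene family on a fixed rooted tree with per-leaf terminal lengths
family_from_lengths <- function(term_lengths, internal_length = 0.1,
                                seqs = NULL, taxon_of = NULL,
                                id = "fam1") {
  n <- length(term_lengths)
  labs <- names(term_lengths) %||% sprintf("s%d", seq_len(n))
  # pectinate rooted tree: ((..(s1,s2),s3),...,sn)
  nwk <- paste0("(", labs[1], ":", term_lengths[1], ",",
                labs[2], ":", term_lengths[2], ")")
  for (i in seq(3, n)) {
    nwk <- paste0("(", nwk, ":", internal_length, ",",
                  labs[i], ":", term_lengths[i], ")")
  }
  tr <- hetcheck::parse_newick(paste0(nwk, ";"))
  if (is.null(seqs)) {
    seqs <- stats::setNames(rep(strrep("ACDEFGHIKL", 10), n), labs)
  }
  hetcheck::gene_family(id, hetcheck::aa_alignment(seqs), tr, taxon_of)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# terminal branch length per leaf, recomputed from the edge table
terminal_branch_lengths_pub <- function(tr) {
  idx <- match(seq_along(tr$tip.label), tr$edge[, 2])
  stats::setNames(tr$edge.length[idx], tr$tip.label)
}
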