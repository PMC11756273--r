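#' Phylogenetic likelihoods and PMSF profiles
#'
#' Felsenstein-pruning site likelihoods under the three model flavours, with
#' per-node rescaling accumulated in log space to avoid underflow, and the
#' posterior mean site frequency (PMSF) computation that turns a fitted
#' finite mixture into a site-specific profile model on a fixed tree.
#'
#' @name likelihood
NULL

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# tip partial likelihoods: 20 x n_sites per tip; unobserved -> all ones
tip_partials <- function(states_row) {
  n <- length(states_row)
  L <- matrix(0, 20, n)
  obs <- states_row > 0L
  L[cbind(states_row[obs], which(obs))] <- 1
  L[, !obs] <- 1
  L
}

# pruning pass, one shared profile, one rate scalar -> per-site log-lik
prune_shared <- function(tree, exch, profile, rate, tipmat) {
  rm <- with_eigen(build_rate_matrix(exch, profile))
  ntip <- length(tree$tip.label)
  total <- ntip + tree$Nnode
  n_sites <- ncol(tipmat)
  L <- vector("list", total)
  logscale <- vector("list", total)
  for (i in seq_len(ntip)) {
    L[[i]] <- tip_partials(tipmat[i, ])
    logscale[[i]] <- numeric(n_sites)
  }
  tr <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(tr$edge))) {
    parent <- tr$edge[e, 1]
    child <- tr$edge[e, 2]
    P <- transition_matrix(rm, tr$edge.length[e] * rate)
    contrib <- P %*% L[[child]]
    sc <- apply(contrib, 2, max)
    sc[sc == 0] <- 1  # impossible site: keep zeros, log(0) surfaces at root
    contrib <- sweep(contrib, 2, sc, `/`)
    ls <- logscale[[child]] + log(sc)
    if (is.null(L[[parent]])) {
      L[[parent]] <- contrib
      logscale[[parent]] <- ls
    } else {
      L[[parent]] <- L[[parent]] * contrib
      logscale[[parent]] <- logscale[[parent]] + ls
    }
  }
  root <- tr$edge[nrow(tr$edge), 1]
  log(colSums(profile * L[[root]])) + logscale[[root]]
}

# pruning with per-site profiles under Poisson exchangeabilities: the F81
# closed form makes the per-site kernel a scalar mix with the site profile
prune_site_f81 <- function(tree, prof, rate, tipmat) {
  beta <- 1 / (1 - rowSums(prof^2))
  pt <- t(prof)                       # 20 x n_sites
  ntip <- length(tree$tip.label)
  total <- ntip + tree$Nnode
  n_sites <- ncol(tipmat)
  L <- vector("list", total)
  logscale <- vector("list", total)
  for (i in seq_len(ntip)) {
    L[[i]] <- tip_partials(tipmat[i, ])
    logscale[[i]] <- numeric(n_sites)
  }
  tr <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(tr$edge))) {
    parent <- tr$edge[e, 1]
    child <- tr$edge[e, 2]
    A <- exp(-beta * rate * tr$edge.length[e])
    M <- colSums(L[[child]] * pt)
    # sum_j P_ij L_j = A L_i + (1 - A) (pi . L), the same for every i
    contrib <- sweep(L[[child]], 2, A, `*`) +
      matrix((1 - A) * M, 20, n_sites, byrow = TRUE)
    sc <- apply(contrib, 2, max)
    sc[sc == 0] <- 1
    contrib <- sweep(contrib, 2, sc, `/`)
    ls <- logscale[[child]] + log(sc)
    if (is.null(L[[parent]])) {
      L[[parent]] <- contrib
      logscale[[parent]] <- ls
    } else {
      L[[parent]] <- L[[parent]] * contrib
      logscale[[parent]] <- logscale[[parent]] + ls
    }
  }
  root <- tr$edge[nrow(tr$edge), 1]
  log(colSums(L[[root]] * pt)) + logscale[[root]]
}

# per-site log-likelihood for every (class, gamma category) combination:
# returns list(ll = array n_sites x n_class x K, weights, class_profiles)
component_logliks <- function(tree, model, aln) {
  check_branch_lengths(tree)
  if (!setequal(rownames(aln), tree$tip.label)) {
    stop("alignment taxa and tree leaves differ")
  }
  tipmat <- encode_alignment(aln)[tree$tip.label, , drop = FALSE]
  n_sites <- ncol(tipmat)
  fixed <- model_fixed_length(model)
  if (!is.na(fixed) && fixed != n_sites) {
    stop("site-profile model has ", fixed, " profiles but the alignment has ",
         n_sites, " sites")
  }
  K <- model$gamma$n_categories
  rates <- model$gamma$category_rates
  exch <- model$exchangeabilities

  if (model$flavour == "site_profile") {
    prof <- model$site_profiles
    ll <- array(NA_real_, c(n_sites, 1L, K))
    for (c_i in seq_len(K)) {
      if (is_poisson_exchangeability(exch)) {
        ll[, 1, c_i] <- prune_site_f81(tree, prof, rates[c_i], tipmat)
      } else {
        ll[, 1, c_i] <- vapply(seq_len(n_sites), function(s) {
          prune_shared(tree, exch, prof[s, ], rates[c_i],
                       tipmat[, s, drop = FALSE])
        }, numeric(1))
      }
    }
    return(list(ll = ll, weights = 1, class_profiles = NULL))
  }

  profs <- if (model$flavour == "homogeneous") {
    matrix(model$profile, 1, 20, byrow = TRUE)
  } else {
    model$class_profiles
  }
  w <- if (model$flavour == "homogeneous") 1 else model$class_weights
  ll <- array(NA_real_, c(n_sites, nrow(profs), K))
  for (k in seq_len(nrow(profs))) {
    for (c_i in seq_len(K)) {
      ll[, k, c_i] <- prune_shared(tree, exch, profs[k, ], rates[c_i], tipmat)
    }
  }
  list(ll = ll, weights = w, class_profiles = profs)
}

#' Site log-likelihood
#'
#' Log-likelihood of a single alignment column under a model on a tree,
#' averaged over the gamma categories (weight 1/K) and, for a mixture, over
#' the profile classes with their weights.  Gap and ambiguity characters
#' contribute a flat partial likelihood of 1 over all states, so an all-gap
#' column has log-likelihood 0.
#'
#' @param tree an [ape::phylo] tree with branch lengths.
#' @param model an `aa_model`.
#' @param column a named character vector (one residue per tree leaf) or a
#'   one-column [aa_alignment()].
#' @return the site log-likelihood (natural log).
#' @export
site_log_likelihood <- function(tree, model, column) {
  if (!inherits(column, "aa_alignment")) {
    if (is.null(names(column))) stop("column must be named by taxon")
    column <- aa_alignment(matrix(column, ncol = 1,
                                  dimnames = list(names(column), NULL)))
  }
  if (ncol(column) != 1L) stop("expected a single alignment column")
  if (nrow(column) != length(tree$tip.label)) {
    stop("column has ", nrow(column), " states for ",
         length(tree$tip.label), " leaves")
  }
  total_log_likelihood(tree, model, column)
}

#' Total log-likelihood of an alignment
#'
#' Sum of [site_log_likelihood()] over the columns (site independence).
#'
#' @inheritParams site_log_likelihood
#' @param aln an [aa_alignment()] whose taxa are the tree's leaves.
#' @return the total log-likelihood.
#' @export
total_log_likelihood <- function(tree, model, aln) {
  comp <- component_logliks(tree, model, aln)
  K <- dim(comp$ll)[3]
  logw <- log(comp$weights) - log(K)
  per_site <- apply(comp$ll, 1, function(m) logsumexp(m + logw))
  sum(per_site)
}

#' Posterior mean site frequency (PMSF) profiles
#'
#' The PMSF step: given a finite profile mixture and a fixed tree, each
#' alignment site gets the posterior distribution over mixture classes
#' (gamma categories marginalised inside each class),
#' `p_k(i) proportional to w_k * mean_c L(site i | class k, category c)`,
#' and its PMSF profile is the posterior-weighted average of the class
#' profiles, `sum_k p_k(i) pi_k`.  The result is a site-specific profile
#' model reusing the mixture's exchangeabilities and gamma rates -- a fast
#' stand-in for the mixture in downstream tree search and simulation.
#'
#' @param tree an [ape::phylo] tree with branch lengths.
#' @param mixture an `aa_model` of flavour `"mixture"`.
#' @param aln the alignment the profiles are computed from.
#' @return an `aa_model` of flavour `"site_profile"` with one profile per
#'   alignment column and a `class_posteriors` attribute (sites x classes).
#' @export
compute_pmsf_profiles <- function(tree, mixture, aln) {
  if (!identical(mixture$flavour, "mixture")) {
    stop("`mixture` must be a mixture-flavour aa_model")
  }
  comp <- component_logliks(tree, mixture, aln)
  K <- dim(comp$ll)[3]
  n_sites <- dim(comp$ll)[1]
  n_class <- dim(comp$ll)[2]
  post <- matrix(NA_real_, n_sites, n_class)
  for (s in seq_len(n_sites)) {
    lk <- apply(comp$ll[s, , , drop = FALSE], 2, function(x) {
      logsumexp(x - log(K))
    })
    lp <- log(comp$weights) + lk
    if (all(!is.finite(lp))) {
      stop("site ", s, " has zero likelihood under every class; ",
           "regularize the class profiles")
    }
    post[s, ] <- exp(lp - logsumexp(lp))
  }
  profiles <- post %*% comp$class_profiles
  out <- site_profile_model(mixture$exchangeabilities, profiles,
                            mixture$gamma)
  attr(out, "class_posteriors") <- post
  out
}
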