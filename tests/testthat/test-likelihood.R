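test_that("degenerate columns have closed-form likelihoods", {
  tr <- parse_newick("((A:1,B:1):1,C:2);")
  m <- poisson_uniform_model(K = 4)
  expect_equal(site_log_likelihood(tr, m, c(A = "-", B = "?", C = "X")), 0)

  # two leaves, total path t, Poisson/uniform, same residue
  tr2 <- parse_newick("(A:0.1,B:0.2);")
  t <- 0.3
  m1 <- poisson_uniform_model(K = 1)
  expect_equal(site_log_likelihood(tr2, m1, c(A = "W", B = "W")),
               log(1 / 20 * (1 / 20 + 19 / 20 * exp(-20 * t / 19))),
               tolerance = 1e-12)
  expect_equal(site_log_likelihood(tr2, m1, c(A = "W", B = "C")),
               log(1 / 20 * (1 / 20 - 1 / 20 * exp(-20 * t / 19))),
               tolerance = 1e-12)
  expect_error(site_log_likelihood(tr, m, c(A = "A", B = "C")), "3 leaves")
})

test_that("pruning equals exhaustive enumeration on small trees", {
  trees <- list(
    parse_newick("((A:0.21,B:0.09):0.14,C:0.33);"),
    parse_newick("((A:0.2,B:0.4):0.1,(C:0.3,D:0.05):0.2);"),
    tree5()  # unrooted 5-leaf with a basal trifurcation
  )
  models <- list(
    homogeneous_model(exchangeability("Poisson"), rand_profile(1),
                      discrete_gamma_rates(0.6, 2)),
    homogeneous_model(exchangeability("LG"), rand_profile(2),
                      discrete_gamma_rates(1.3, 2)),
    mixture_model(exchangeability("Poisson"),
                  list(rand_profile(3, 0.5), rand_profile(4, 0.5)),
                  class_weights = c(0.7, 0.3),
                  gamma = discrete_gamma_rates(0.9, 2))
  )
  set.seed(17)
  for (tr in trees) {
    leaves <- tr$tip.label
    for (m in models) {
      for (rep in 1:2) {
        col <- stats::setNames(sample(c(aa_states(), "-"), length(leaves),
                                      replace = TRUE), leaves)
        got <- site_log_likelihood(tr, m, col)
        want <- log(enum_site_likelihood(tr, m, col))
        expect_equal(got, want, tolerance = 1e-9)
      }
    }
  }
})

test_that("site-profile pruning agrees with per-site homogeneous pruning", {
  tr <- parse_newick("((A:0.2,B:0.4):0.1,(C:0.3,D:0.05):0.2);")
  profs <- generate_site_profiles(6, "dirichlet", concentration = 0.4, seed = 21)
  g <- discrete_gamma_rates(0.8, 4)
  spm <- site_profile_model(exchangeability("Poisson"), profs, g)
  aln <- simulate_alignment(tr, spm, seed = 5)
  got <- total_log_likelihood(tr, spm, aln)
  want <- sum(vapply(1:6, function(i) {
    hm <- homogeneous_model(exchangeability("Poisson"), profs[i, ], g)
    site_log_likelihood(tr, hm, unclass(aln)[, i])
  }, numeric(1)))
  expect_equal(got, want, tolerance = 1e-9)
})

test_that("total log-likelihood is additive and invariant to taxon order and root", {
  tr <- tree5()
  m <- homogeneous_model(exchangeability("LG"), rand_profile(5),
                         discrete_gamma_rates(1, 4))
  col <- c(A = "A", B = "C", C = "-", D = "A", E = "W")
  one <- site_log_likelihood(tr, m, col)
  aln10 <- aa_alignment(vapply(col, strrep, character(1), 10))
  expect_equal(total_log_likelihood(tr, m, aln10), 10 * one, tolerance = 1e-8)

  # taxon reordering
  aln <- simulate_alignment(tr, m, n_sites = 30, seed = 3)
  perm <- unclass(aln)[sample(rownames(aln)), , drop = FALSE]
  expect_equal(total_log_likelihood(tr, m, aa_alignment(perm)),
               total_log_likelihood(tr, m, aln), tolerance = 1e-10)

  # pulley principle: rerooting does not change a reversible likelihood
  rerooted <- ape::root(tr, outgroup = "C", resolve.root = TRUE)
  expect_equal(total_log_likelihood(rerooted, m, aln),
               total_log_likelihood(tr, m, aln), tolerance = 1e-8)
})

test_that("the generating tree is preferred over rearrangements", {
  wins <- 0L
  for (s in 1:5) {
    true_tr <- generate_tree(6, "coalescent", seed = s + 200)
    m <- homogeneous_model(exchangeability("Poisson"), rand_profile(s),
                           discrete_gamma_rates(1, 4))
    aln <- simulate_alignment(true_tr, m, n_sites = 300, seed = s)
    rivals <- list(
      ape::rtree(6, tip.label = sample(true_tr$tip.label)),
      ape::rtree(6, tip.label = sample(true_tr$tip.label))
    )
    lls <- vapply(c(list(true_tr), rivals), function(tr) {
      tr$edge.length <- pmax(tr$edge.length, 1e-3)
      total_log_likelihood(tr, m, aln)
    }, numeric(1))
    if (which.max(lls) == 1L) wins <- wins + 1L
  }
  expect_gte(wins, 3L)
})

test_that("PMSF degenerates correctly for trivial mixtures", {
  tr <- parse_newick("((A:0.2,B:0.4):0.1,(C:0.3,D:0.05):0.2);")
  g <- discrete_gamma_rates(1, 4)
  p <- rand_profile(6)
  aln <- simulate_alignment(tr, homogeneous_model(exchangeability("Poisson"),
                                                  p, g), n_sites = 8, seed = 2)
  # single class: every site profile is that class, exactly
  m1 <- mixture_model(exchangeability("Poisson"), matrix(p, 1, 20,
                                                         byrow = TRUE),
                      gamma = g)
  pm1 <- compute_pmsf_profiles(tr, m1, aln)
  expect_equal(pm1$site_profiles,
               matrix(p, 8, 20, byrow = TRUE, dimnames = list(NULL, aa_states())))
  # two identical classes: same, independent of the weights
  m2 <- mixture_model(exchangeability("Poisson"), rbind(p, p),
                      class_weights = c(0.9, 0.1), gamma = g)
  pm2 <- compute_pmsf_profiles(tr, m2, aln)
  expect_lt(max(abs(pm2$site_profiles - pm1$site_profiles)), 1e-12)
})

test_that("PMSF posteriors find the class that explains a column", {
  set.seed(30)
  tr <- generate_tree(50, "coalescent", seed = 44)
  ala <- frequency_profile(c(0.9, rep(0.1 / 19, 19)))      # alanine-rich
  gly <- frequency_profile(c(rep(0.1 / 19, 5), 0.9, rep(0.1 / 19, 14)))
  g <- discrete_gamma_rates(1, 4)
  mix <- mixture_model(exchangeability("Poisson"), rbind(ala, gly), gamma = g)
  aln <- aa_alignment(matrix(c(rep("A", 50), rep("G", 50)), 50, 2,
                             dimnames = list(tr$tip.label, NULL)))
  pm <- compute_pmsf_profiles(tr, mix, aln)
  post <- attr(pm, "class_posteriors")
  expect_gt(post[1, 1], 0.99)   # all-alanine column -> alanine class
  expect_gt(post[2, 2], 0.99)
  expect_lt(sum(abs(pm$site_profiles[1, ] - ala)), 1e-2 + 0.02)
  # posterior check against the enumeration oracle on a small tree
  tr4 <- parse_newick("((A:0.2,B:0.4):0.1,(C:0.3,D:0.05):0.2);")
  col <- c(A = "A", B = "A", C = "A", D = "A")
  aln4 <- aa_alignment(matrix(col, 4, 1, dimnames = list(names(col), NULL)))
  pm4 <- compute_pmsf_profiles(tr4, mix, aln4)
  lik_ala <- enum_site_likelihood(
    tr4, homogeneous_model(exchangeability("Poisson"), ala, g), col)
  lik_gly <- enum_site_likelihood(
    tr4, homogeneous_model(exchangeability("Poisson"), gly, g), col)
  want <- 0.5 * lik_ala / (0.5 * lik_ala + 0.5 * lik_gly)
  expect_equal(attr(pm4, "class_posteriors")[1, 1], want, tolerance = 1e-9)
})

test_that("PMSF profiles are convex combinations of the class profiles", {
  tr <- generate_tree(10, "coalescent", seed = 3)
  classes <- generate_site_profiles(4, "dirichlet", concentration = 0.3,
                                    seed = 7)
  mix <- mixture_model(exchangeability("Poisson"), classes,
                       gamma = discrete_gamma_rates(1, 2))
  spm_true <- site_profile_model(exchangeability("Poisson"),
                                 generate_site_profiles(25, seed = 9))
  aln <- simulate_alignment(tr, spm_true, seed = 4)
  pm <- compute_pmsf_profiles(tr, mix, aln)
  post <- attr(pm, "class_posteriors")
  expect_true(all(post >= -1e-12))
  expect_lt(max(abs(rowSums(post) - 1)), 1e-9)
  recon <- post %*% mix$class_profiles
  expect_lt(max(abs(recon - pm$site_profiles)), 1e-9)
})

test_that("PMSF fits heterogeneous data at least as well as the mean profile", {
  wins <- 0L
  for (s in 1:3) {
    tr <- generate_tree(16, "coalescent", seed = s + 400)
    profs <- generate_site_profiles(120, "k_class", concentration = 0.15,
                                    k = 4, seed = s)
    g <- discrete_gamma_rates(1, 4)
    truth <- site_profile_model(exchangeability("Poisson"), profs, g)
    aln <- simulate_alignment(tr, truth, seed = s + 40)
    mix <- mixture_model(exchangeability("Poisson"), attr(profs, "classes"),
                         gamma = g)
    pmsf <- compute_pmsf_profiles(tr, mix, aln)
    homog <- homogeneous_model(exchangeability("Poisson"), colMeans(profs), g)
    if (total_log_likelihood(tr, pmsf, aln) >=
        total_log_likelihood(tr, homog, aln)) wins <- wins + 1L
  }
  expect_gte(wins, 2L)
})
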