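test_that("leaf_partials maps residues, gaps and unknowns", {
  expect_equal(unname(leaf_partials("A")), c(1, 0, 0, 0, 0))
  expect_equal(unname(leaf_partials("-")), c(0, 0, 0, 0, 1))
  expect_equal(unname(leaf_partials("N")), c(1, 1, 1, 1, 0))
  expect_equal(unname(leaf_partials("y")), c(1, 1, 1, 1, 0))
  expect_error(leaf_partials("Z"), "unmapped")
})

test_that("pruning matches exhaustive enumeration on small trees", {
  # zero-length cherry: root partial is the indicator of the shared residue
  cherry <- read_newick("(A:0,B:0);")
  m <- default_indel_model()
  pl <- prune_column(cherry, c(A = "A", B = "A"), m)
  expect_equal(unname(pl$partials * exp(pl$log_scale)), c(1, 0, 0, 0, 0))

  set.seed(11)
  for (rep in 1:25) {
    ntip <- sample(2:4, 1)
    tr <- random_small_tree(ntip)
    mm <- random_indel_model()
    col <- stats::setNames(sample(c("A", "C", "G", "T", "-", "N"), ntip,
                                  replace = TRUE), tr$tip.label)
    if (all(col == "-")) col[1] <- "A"
    expect_equal(pkg_column_loglik(tr, col, mm),
                 enum_column_loglik(tr, col, mm), tolerance = 1e-12)
  }

  # all-gap column on a 4-leaf tree: root retains positive mass on gap AND
  # residues (recurrent insertions are permitted)
  tr4 <- read_newick("((A:0.4,B:0.3):0.2,(C:0.5,D:0.2):0.1);")
  pl <- prune_column(tr4, c(A = "-", B = "-", C = "-", D = "-"), m)
  expect_true(pl$partials[5] > 0)
  expect_true(all(pl$partials[1:4] > 0))
  expect_equal(column_loglik(pl, m),
               enum_column_loglik(tr4, c(A = "-", B = "-", C = "-", D = "-"),
                                  m),
               tolerance = 1e-12)
})

test_that("column_loglik applies the ancestral-length prior", {
  # one-leaf tree at t = 0 observing 'A' gives log(p * pi_A)
  one <- list(edge = matrix(c(2L, 1L), 1, 2), tip.label = "A",
              edge.length = 0, Nnode = 1L)
  class(one) <- "phylo"
  m <- default_indel_model()
  pl <- prune_column(one, c(A = "A"), m)
  expect_equal(column_loglik(pl, m), log(m$p * m$f84$pi[1]))

  # lambda = mu = 0 on a gapless column equals log(p) + F84 log-likelihood
  tr <- read_newick("((A:0.12,B:0.3):0.1,C:0.25);")
  f84 <- f84_params(0.513467, 0.486533, c(0.254698, 0.260464, 0.263575,
                                          0.221263))
  m0 <- indel_model(0, 0, f84, 0.998058)
  for (col in list(c(A = "A", B = "A", C = "A"),
                   c(A = "A", B = "C", C = "T"),
                   c(A = "G", B = "G", C = "N"))) {
    expect_equal(pkg_column_loglik(tr, col, m0),
                 log(m0$p) + pkg_column_loglik(tr, col, f84),
                 tolerance = 1e-12)
  }
})

test_that("column likelihoods over the full pattern space sum to one", {
  m <- default_indel_model()
  tr2 <- read_newick("(A:0.3,B:0.7);")
  pats2 <- expand.grid(A = c("A", "C", "G", "T", "-"),
                       B = c("A", "C", "G", "T", "-"),
                       stringsAsFactors = FALSE)
  tot <- sum(vapply(seq_len(nrow(pats2)), function(i) {
    exp(pkg_column_loglik(tr2, unlist(pats2[i, ]), m))
  }, 0))
  expect_equal(tot, 1, tolerance = 1e-10)

  tr3 <- read_newick("((A:0.2,B:0.4):0.15,C:0.3);")
  pats3 <- expand.grid(A = c("A", "C", "G", "T", "-"),
                       B = c("A", "C", "G", "T", "-"),
                       C = c("A", "C", "G", "T", "-"),
                       stringsAsFactors = FALSE)
  tot3 <- sum(vapply(seq_len(nrow(pats3)), function(i) {
    exp(pkg_column_loglik(tr3, unlist(pats3[i, ]), m))
  }, 0))
  expect_equal(tot3, 1, tolerance = 1e-10)
})

test_that("dataset_loglik modes differ by the termination and observability terms", {
  tr <- read_newick("(A:0.3,B:0.7);")
  m <- default_indel_model()
  aset <- toy_aset(c(A = "ACG-T", B = "AC-TT"), tr)
  ll_site <- dataset_loglik(aset, m, "site_test")
  cols <- list(c(A = "A", B = "A"), c(A = "C", B = "C"), c(A = "G", B = "-"),
               c(A = "-", B = "T"), c(A = "T", B = "T"))
  expect_equal(ll_site,
               sum(vapply(cols, function(cc) pkg_column_loglik(tr, cc, m), 0)),
               tolerance = 1e-12)

  # fit mode adds log(1 - p) once and subtracts n log(1 - P_invisible)
  p_inv <- exp(pkg_column_loglik(tr, c(A = "-", B = "-"), m))
  expect_equal(dataset_loglik(aset, m, "fit"),
               ll_site + log(1 - m$p) - 5 * log(1 - p_inv),
               tolerance = 1e-12)

  # lambda = mu = 0: the invisible pattern is exactly the ancestral-gap
  # prior mass, so the correction reduces to -n log p
  m0 <- indel_model(0, 0, m$f84, m$p)
  aset0 <- toy_aset(c(A = "ACGT", B = "ACTT"), tr)
  expect_equal(dataset_loglik(aset0, m0, "fit"),
               dataset_loglik(aset0, m0, "site_test") + log(1 - m0$p) -
                 4 * log(m0$p),
               tolerance = 1e-12)
  expect_equal(exp(pkg_column_loglik(tr, c(A = "-", B = "-"), m0)), 1 - m0$p,
               tolerance = 1e-14)

  expect_error(dataset_loglik(alignment_set(list(), list()), m), "empty")
})

test_that("likelihood is invariant to leaf order and to rerooting without indels", {
  f84 <- random_f84()
  # two rootings of the same unrooted metric tree
  t1 <- read_newick("((A:0.1,B:0.2):0.05,C:0.25);")
  t2 <- read_newick("(A:0.1,(B:0.2,C:0.3):0.0);")
  for (col in list(c(A = "A", B = "C", C = "G"),
                   c(A = "T", B = "T", C = "C"))) {
    expect_equal(pkg_column_loglik(t1, col, f84),
                 pkg_column_loglik(t2, col, f84), tolerance = 1e-10)
  }

  # leaf-order permutation of the alignment matrix
  tr <- benchmark_tree()
  m <- default_indel_model()
  sim <- simulate_family(tr, m, 40, seed = 3)
  aset1 <- alignment_set(list(sim$alignment), list(tr))
  perm <- sample(nrow(sim$alignment$seqs))
  mat <- sim$alignment$seqs[perm, ]
  aln2 <- suppressMessages(new_alignment(mat, "permuted"))
  aset2 <- alignment_set(list(aln2), list(tr))
  expect_equal(dataset_loglik(aset1, m, "fit"), dataset_loglik(aset2, m, "fit"),
               tolerance = 1e-10)
})

test_that("adding gaps to a gapless column cannot raise the likelihood when indel rates are tiny", {
  tr <- benchmark_tree()
  m <- indel_model(1e-6, 1e-6, f84_params(0.5, 0.5, rep(0.25, 4)), 0.998)
  base <- stats::setNames(rep("A", 10), tr$tip.label)
  ll0 <- pkg_column_loglik(tr, base, m)
  for (i in c(1, 4, 9)) {
    col <- base
    col[i] <- "-"
    expect_lt(pkg_column_loglik(tr, col, m), ll0)
  }
})
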