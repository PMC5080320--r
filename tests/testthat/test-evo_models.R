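paper_pi <- c(0.254698, 0.260464, 0.263575, 0.221263)

test_that("F84 rate matrix: JC limit, stationarity, detailed balance", {
  # alpha = 0 with uniform pi collapses to equal off-diagonals
  Q <- build_f84_rate_matrix(f84_params(0, 1, rep(0.25, 4)))
  off <- Q[row(Q) != col(Q)]
  expect_true(all(abs(off - off[1]) < 1e-12))

  # piQ = 0 at the reported parameter block
  p <- f84_params(0.513467, 0.486533, paper_pi)
  Q <- build_f84_rate_matrix(p)
  expect_lt(max(abs(paper_pi %*% Q)), 1e-12)

  # detailed balance over random parameter draws
  set.seed(1)
  for (i in 1:100) {
    m <- random_f84()
    Q <- build_f84_rate_matrix(m)
    bal <- outer(m$pi, rep(1, 4)) * Q
    expect_lt(max(abs(bal - t(bal))), 1e-12)
  }

  expect_error(build_f84_rate_matrix(f84_params(1, 1, c(0.5, 0.5, 0, 0))),
               "positive")
})

test_that("HKY+G matrix: decoupling, stationarity, indel asymmetry", {
  # the printed frequencies sum to 0.9999; renormalize onto the simplex
  pi5 <- c(0.2522, 0.2578, 0.2609, 0.2191, 0.0099)
  pi5 <- pi5 / sum(pi5)
  # sigma = 0 decouples the gap state
  Q0 <- build_hkyg_rate_matrix(hkyg_params(2, 0, pi5))
  expect_true(all(Q0[5, ] == 0) && all(Q0[1:4, 5] == 0))

  Q <- build_hkyg_rate_matrix(hkyg_params(2, 0.3, pi5))
  # pi5 is the left null vector
  expect_lt(max(abs(pi5 %*% Q)), 1e-12)
  # insertion/deletion rate asymmetry equals pi_A / pi_gap (~25.5, the
  # two-orders-of-magnitude imbalance for the full residue set)
  expect_equal(Q[5, 1] / Q[1, 5], pi5[1] / pi5[5], tolerance = 1e-12)
  expect_equal(pi5[1] / pi5[5], 25.47, tolerance = 0.01)

  expect_error(build_hkyg_rate_matrix(
    hkyg_params(2, 0.3, c(0.25, 0.25, 0.25, 0.25, 0))), "pi_gap")
})

test_that("F84e-relaxed matrix: embedding, lumping, stationary gap mass", {
  f84 <- f84_params(0.513467, 0.486533, paper_pi)
  # lambda = mu = 0 embeds F84 with a silent gap state
  Q0 <- build_f84e_rate_matrix(indel_model(0, 0, f84, 0.998))
  expect_equal(Q0[1:4, 1:4], build_f84_rate_matrix(f84))
  expect_true(all(Q0[5, ] == 0) && all(Q0[1:4, 5] == 0))

  m <- indel_model(0.008509, 0.061660, f84, 0.998058)
  Q <- build_f84e_rate_matrix(m)
  # lumped residue/gap chain has exact rates mu and lambda
  expect_equal(unname(Q[1:4, 5]), rep(m$mu, 4))
  expect_equal(sum(Q[5, 1:4]), m$lambda)
  # stationary gap frequency mu / (lambda + mu) ~ 0.8787
  ev <- eigen(t(Q))
  v <- abs(Re(ev$vectors[, which.min(abs(ev$values))]))
  v <- v / sum(v)
  expect_equal(v[5], m$mu / (m$lambda + m$mu), tolerance = 1e-9)
  expect_equal(v[5], 0.8787, tolerance = 1e-4)
})

test_that("conditional_matrix: identity, series oracle, semigroup, xi identity", {
  m <- default_indel_model()
  Q <- build_f84e_rate_matrix(m)
  expect_equal(conditional_matrix(Q, 0), diag(5), ignore_attr = TRUE)
  expect_error(conditional_matrix(Q, -1), ">= 0")

  # truncated series oracle
  series_expm <- function(Q, t, kmax = 50) {
    A <- diag(nrow(Q))
    term <- diag(nrow(Q))
    for (k in 1:kmax) {
      term <- term %*% (Q * t) / k
      A <- A + term
    }
    A
  }
  set.seed(2)
  for (i in 1:20) {
    mm <- random_indel_model()
    Qi <- build_f84e_rate_matrix(mm)
    t <- stats::runif(1, 0, 3)
    P <- conditional_matrix(Qi, t)
    expect_lt(max(abs(P - series_expm(Qi, t))), 1e-9)
    expect_lt(max(abs(rowSums(P) - 1)), 1e-10)
    expect_true(all(P >= 0 & P <= 1))
    # Chapman-Kolmogorov
    t2 <- stats::runif(1, 0, 3)
    expect_lt(max(abs(conditional_matrix(Qi, t) %*% conditional_matrix(Qi, t2) -
                        conditional_matrix(Qi, t + t2))), 1e-9)
    # paper identity P(-|-,t) = 1 - xi_t, and the residue marginal of the
    # gap row equals xi_t (the lumped two-state chain)
    expect_equal(P[5, 5], 1 - xi(mm$lambda, mm$mu, t), tolerance = 1e-12)
    expect_equal(sum(P[5, 1:4]), xi(mm$lambda, mm$mu, t), tolerance = 1e-12)
  }
})

test_that("xi: limits and degenerate cases", {
  expect_equal(xi(0.3, 0.5, 0), 0)
  expect_equal(xi(0, 0.5, c(1, 10)), c(0, 0))
  expect_equal(xi(0, 0, 5), 0)
  expect_equal(xi(0.3, 0.5, 1e4), 0.3 / 0.8, tolerance = 1e-12)
  # cross-check the t -> Inf limit against the matrix exponential
  m <- indel_model(0.3, 0.5, f84_params(1, 1, rep(0.25, 4)), 0.99)
  P <- conditional_matrix(build_f84e_rate_matrix(m), 1e4)
  expect_equal(sum(P[5, 1:4]), 0.3 / 0.8, tolerance = 1e-9)
})

test_that("apply_indel_scaling: edge cases and multiplicativity", {
  m <- default_indel_model()
  z <- apply_indel_scaling(m, scale_context(0, 2))
  expect_equal(c(z$lambda, z$mu), c(0, 0))
  d <- apply_indel_scaling(m, scale_context(2, 1))
  expect_equal(c(d$lambda, d$mu), 2 * c(m$lambda, m$mu))
  expect_equal(d$f84, m$f84)
  expect_equal(d$p, m$p)

  # DI ratio from the reported totals I = 4506, D = 26577
  di <- 26577 / 4506
  expect_equal(di, 5.8981, tolerance = 1e-4)
  s <- apply_indel_scaling(m, scale_context(0.5, di))
  expect_equal(s$lambda, 0.5 * di * m$lambda)
  expect_equal(s$mu, 0.5 * m$mu)

  # scaling by rho1 then rho2 equals scaling by rho1 * rho2
  a <- apply_indel_scaling(apply_indel_scaling(m, scale_context(2, di)),
                           scale_context(3, di))
  b <- apply_indel_scaling(m, scale_context(6, di^2))
  expect_equal(a$mu, b$mu)
  expect_equal(a$lambda, b$lambda)
})
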