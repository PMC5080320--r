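# Rate-matrix construction for the three model families.
#
# F84: reversible nucleotide substitution with a transition-specific
# component alpha and a general component beta, both weighted by the target
# base frequency (transitions additionally by the frequency of the target's
# purine/pyrimidine group).
#
# F84e-relaxed: F84 embedded in the 5-state alphabet {A,C,G,T,-} with
# residue->gap rate mu (deletion) and gap->residue_j rate lambda*pi_j
# (insertion).  Lumping the four residues into one state gives the exact
# two-state chain with rates mu and lambda, which is the module's analytic
# oracle: P(res | gap, t) = xi(t) = lambda/(lambda+mu) * (1 - exp(-(lambda+mu) t)).
#
# HKY+G: HKY85 on the residues (frequencies renormalized) with gap as a
# fifth character, residue->gap rate sigma*pi_gap and gap->residue_j rate
# sigma*pi_j.  Stationary in pi5 and reversible.

PURINES <- c(1L, 3L)      # A, G
PYRIMIDINES <- c(2L, 4L)  # C, T

check_simplex <- function(p, tol = 1e-9) {
  if (any(!is.finite(p)) || any(p < 0)) stop("frequencies must be finite and >= 0")
  if (abs(sum(p) - 1) > tol) stop("frequencies must sum to 1 (got ", sum(p), ")")
  invisible(p)
}

#' F84 substitution model parameters
#' @param alpha transition-specific rate component (>= 0).
#' @param beta general rate component (>= 0).
#' @param pi residue frequencies over A,C,G,T (simplex).
#' @return object of class `f84_params`.
#' @export
f84_params <- function(alpha, beta, pi) {
  stopifnot(is.finite(alpha), alpha >= 0, is.finite(beta), beta >= 0,
            length(pi) == 4)
  check_simplex(pi)
  structure(list(alpha = alpha, beta = beta, pi = unname(pi)),
            class = c("f84_params", "ip_model"))
}

#' Gap-extended F84 indel model (F84e-relaxed)
#' @param lambda per-site insertion rate (>= 0).
#' @param mu per-site deletion rate (>= 0).
#' @param f84 an [f84_params()] object for the residue block.
#' @param p geometric ancestral-length parameter, 0 < p < 1.
#' @return object of class `indel_model`.
#' @export
indel_model <- function(lambda, mu, f84, p) {
  stopifnot(is.finite(lambda), lambda >= 0, is.finite(mu), mu >= 0,
            inherits(f84, "f84_params"), p > 0, p < 1)
  structure(list(lambda = lambda, mu = mu, f84 = f84, p = p),
            class = c("indel_model", "ip_model"))
}

#' HKY + gap-as-fifth-character model parameters
#' @param kappa transition/transversion ratio (>= 0).
#' @param sigma indel rate multiplier (>= 0).
#' @param pi5 frequencies over A,C,G,T,- (simplex, gap frequency last).
#' @return object of class `hkyg_params`.
#' @export
hkyg_params <- function(kappa, sigma, pi5) {
  stopifnot(is.finite(kappa), kappa >= 0, is.finite(sigma), sigma >= 0,
            length(pi5) == 5)
  check_simplex(pi5)
  structure(list(kappa = kappa, sigma = sigma, pi5 = unname(pi5)),
            class = c("hkyg_params", "ip_model"))
}

#' Indel-rate scaling context
#'
#' Carries the per-column scale factor rho_indel and the deletion/insertion
#' total-length ratio used to weight the insertion scaling.
#'
#' @param rho_indel scale factor (>= 0).
#' @param di_ratio total deletion length / total insertion length (> 0).
#' @return object of class `scale_context`.
#' @export
scale_context <- function(rho_indel, di_ratio = 1) {
  stopifnot(is.finite(rho_indel), rho_indel >= 0,
            is.finite(di_ratio), di_ratio > 0)
  structure(list(rho_indel = rho_indel, di_ratio = di_ratio),
            class = "scale_context")
}

assert_rate_matrix <- function(Q, tol = 1e-10) {
  off <- Q - diag(diag(Q))
  if (any(off < -tol)) stop("negative off-diagonal rate")
  if (any(abs(rowSums(Q)) > tol)) stop("rate matrix rows do not sum to 0")
  Q
}

#' Build the 4x4 F84 rate matrix
#'
#' For `i != j`: `rate(i->j) = beta*pi_j + alpha*pi_j/pi_group(j)` when i and
#' j are both purines or both pyrimidines, else `beta*pi_j`; diagonals close
#' the rows.  `pi` is the stationary distribution and the chain is
#' reversible.
#'
#' @param params an [f84_params()] object.
#' @return 4x4 rate matrix over A,C,G,T.
#' @export
build_f84_rate_matrix <- function(params) {
  stopifnot(inherits(params, "f84_params"))
  pi <- params$pi
  if (any(pi == 0)) stop("F84 requires strictly positive frequencies (group normalization undefined)")
  pR <- sum(pi[PURINES])
  pY <- sum(pi[PYRIMIDINES])
  grp <- ifelse(seq_len(4) %in% PURINES, pR, pY)
  Q <- matrix(0, 4, 4, dimnames = list(ALPHA5[1:4], ALPHA5[1:4]))
  for (i in 1:4) for (j in 1:4) {
    if (i == j) next
    r <- params$beta * pi[j]
    same_group <- (i %in% PURINES) == (j %in% PURINES)
    if (same_group) r <- r + params$alpha * pi[j] / grp[j]
    Q[i, j] <- r
  }
  diag(Q) <- -rowSums(Q)
  assert_rate_matrix(Q)
}

#' Build the 5-state F84e-relaxed rate matrix
#'
#' Residue block from [build_f84_rate_matrix()]; every residue turns into a
#' gap at rate `mu`; a gap turns into residue j at rate `lambda * pi_j`.
#'
#' @param model an [indel_model()] object.
#' @return 5x5 rate matrix over A,C,G,T,-.
#' @export
build_f84e_rate_matrix <- function(model) {
  stopifnot(inherits(model, "indel_model"))
  Q <- matrix(0, 5, 5, dimnames = list(ALPHA5, ALPHA5))
  Q[1:4, 1:4] <- build_f84_rate_matrix(model$f84)
  Q[1:4, 5] <- model$mu
  Q[5, 1:4] <- model$lambda * model$f84$pi
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  assert_rate_matrix(Q)
}

#' Build the 5-state HKY + gap rate matrix
#'
#' Residue block follows HKY85 with `kappa` and the residue entries of `pi5`
#' renormalized; `rate(residue -> gap) = sigma * pi_gap`;
#' `rate(gap -> residue j) = sigma * pi5_j`.  Stationary in `pi5`.
#'
#' @param params an [hkyg_params()] object.
#' @return 5x5 rate matrix over A,C,G,T,-.
#' @export
build_hkyg_rate_matrix <- function(params) {
  stopifnot(inherits(params, "hkyg_params"))
  pi5 <- params$pi5
  if (pi5[5] == 0 && params$sigma > 0) {
    stop("pi_gap = 0 with sigma > 0: gap rates undefined")
  }
  pit <- pi5[1:4] / sum(pi5[1:4])
  Q <- matrix(0, 5, 5, dimnames = list(ALPHA5, ALPHA5))
  for (i in 1:4) for (j in 1:4) {
    if (i == j) next
    same_group <- (i %in% PURINES) == (j %in% PURINES)
    Q[i, j] <- if (same_group) params$kappa * pit[j] else pit[j]
  }
  Q[1:4, 5] <- params$sigma * pi5[5]
  Q[5, 1:4] <- params$sigma * pi5[1:4]
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  assert_rate_matrix(Q)
}

#' Finite-time conditional probability matrix
#'
#' `P = exp(Q t)` by Pade approximation with scaling and squaring
#' (`Matrix::expm`).  Row `i`, column `q` holds `P(q | i, t)`.
#'
#' @param Q a rate matrix (square, zero row sums).
#' @param t branch length, `t >= 0`.
#' @return stochastic matrix of the same dimension as `Q`.
#' @export
conditional_matrix <- function(Q, t) {
  if (!is.finite(t) || t < 0) stop("branch length t must be finite and >= 0")
  P <- as.matrix(Matrix::expm(Q * t))
  # Pade round-off can leave entries a hair outside [0,1]
  P[P < 0 & P > -1e-12] <- 0
  P[P > 1 & P < 1 + 1e-12] <- 1
  dimnames(P) <- dimnames(Q)
  P
}

#' Gap-to-residue transition probability of the lumped two-state chain
#'
#' `xi(t) = lambda/(lambda+mu) * (1 - exp(-(lambda+mu) t))`, so that
#' `P(- | -, t) = 1 - xi(t)`.  Returns 0 when `lambda = 0` (and in the
#' degenerate `lambda = mu = 0` case).
#'
#' @param lambda insertion rate (>= 0).
#' @param mu deletion rate (>= 0).
#' @param t branch length(s), `t >= 0` (vectorized).
#' @return probability vector of `length(t)`.
#' @export
xi <- function(lambda, mu, t) {
  stopifnot(lambda >= 0, mu >= 0, all(t >= 0))
  if (lambda + mu == 0) return(rep(0, length(t)))
  lambda / (lambda + mu) * (1 - exp(-(lambda + mu) * t))
}

#' Scale the indel rates of a model
#'
#' Deletion rate is multiplied by `rho_indel`; insertion rate by
#' `rho_indel * di_ratio`.  The deletion/insertion weighting compensates for
#' the per-residue event counting: rates estimated at the dataset level are
#' dominated by deletions, so the insertion scaling is multiplied by the
#' ratio of total deletion to insertion length.  Substitution parameters and
#' `p` are untouched.
#'
#' @param model an [indel_model()].
#' @param ctx a [scale_context()].
#' @return a new `indel_model`.
#' @export
apply_indel_scaling <- function(model, ctx) {
  stopifnot(inherits(model, "indel_model"), inherits(ctx, "scale_context"))
  indel_model(lambda = ctx$rho_indel * ctx$di_ratio * model$lambda,
              mu = ctx$rho_indel * model$mu,
              f84 = model$f84, p = model$p)
}

# ---- generic engine accessors -------------------------------------------

model_nstates <- function(model) UseMethod("model_nstates")
model_nstates.f84_params <- function(model) 4L
model_nstates.indel_model <- function(model) 5L
model_nstates.hkyg_params <- function(model) 5L

model_rate_matrix <- function(model) UseMethod("model_rate_matrix")
model_rate_matrix.f84_params <- function(model) build_f84_rate_matrix(model)
model_rate_matrix.indel_model <- function(model) build_f84e_rate_matrix(model)
model_rate_matrix.hkyg_params <- function(model) build_hkyg_rate_matrix(model)

# Root prior: for the indel model the geometric length prior contributes
# weight p*pi_a to an ancestral residue and (1-p) to "no ancestral residue"
# (the gap state); F84 and HKY+G use their stationary frequencies.
model_root_prior <- function(model) UseMethod("model_root_prior")
model_root_prior.f84_params <- function(model) model$pi
model_root_prior.indel_model <- function(model) {
  c(model$p * model$f84$pi, 1 - model$p)
}
model_root_prior.hkyg_params <- function(model) model$pi5

model_leaf_partials <- function(model) {
  if (model_nstates(model) == 5L) LEAF_PARTIALS5 else LEAF_PARTIALS4
}

# TRUE for models that carry the geometric ancestral-length prior and hence
# the per-alignment termination and observability terms in fit mode.
has_length_prior <- function(model) inherits(model, "indel_model")
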