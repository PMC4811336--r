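# CaMKII holoenzyme ring automaton ---------------------------------------
#
# The kinase is a ring of 6 subunits. Intersubunit autophosphorylation is
# directional: a subunit can be phosphorylated when it binds Ca4CaM and its
# (say, counter-clockwise) neighbour is already phosphorylated (rate k7*g),
# or when both it and that neighbour are CaM-bound but unphosphorylated
# (initiation, rate k6*g^2), g being the CaM-bound probability of one
# subunit. Dephosphorylation removes one phospho-group at a time through
# PP1 (Michaelis-Menten, shared over all phospho-subunits). Because every
# rate is rotation-invariant, the 64 phosphorylation patterns lump exactly
# into the 14 binary necklaces of length 6; the lumped generator is
#   k6*g^2 * A6  +  k7*g * A7  +  mu * A12
# with integer matrices computed here once by direct enumeration.

.camkii_env <- new.env(parent = emptyenv())

.necklace_class <- function(pat) {
  # pat: integer vector of 6 bits; returns canonical (minimal) rotation key
  rots <- vapply(0:5, function(r) {
    idx <- ((seq_len(6) - 1 + r) %% 6) + 1
    sum(pat[idx] * 2^(0:5))
  }, numeric(1))
  min(rots)
}

#' Lumped transition matrices of the CaMKII ring automaton
#'
#' Enumerates all 2^6 phosphorylation patterns of the 6-subunit ring,
#' groups them into the 14 rotation classes, and returns the integer flux
#' matrices of the lumped master equation (columns = source class, with
#' outflow on the diagonal), together with the phospho-subunit count of
#' each class. Class 1 is the fully unphosphorylated ring.
#'
#' @return list with `A6`, `A7`, `A12` (14 x 14 matrices) and `nphos`
#'   (integer vector of length 14).
#' @export
camkii_transition_matrices <- function() {
  if (!is.null(.camkii_env$mats)) return(.camkii_env$mats)
  pats <- lapply(0:63, function(k) as.integer(intToBits(k)[1:6]))
  keys <- vapply(pats, .necklace_class, numeric(1))
  ukeys <- sort(unique(keys))            # 14 canonical keys
  stopifnot(length(ukeys) == 14L)
  class_of <- match(keys, ukeys)
  # order classes by phosphorylation count then key, unphosphorylated first
  nph_key <- vapply(ukeys, function(k) sum(as.integer(intToBits(k)[1:6])), numeric(1))
  ord <- order(nph_key, ukeys)
  relabel <- match(seq_along(ukeys), ord)  # old class id -> new id
  class_of <- relabel[class_of]
  nphos <- nph_key[ord]

  A6 <- A7 <- A12 <- matrix(0, 14, 14)
  reps <- vapply(split(seq_along(keys), class_of), `[`, numeric(1), 1)
  for (c0 in 1:14) {
    p <- pats[[reps[[c0]]]]
    for (j in 1:6) {
      pred <- ((j - 2) %% 6) + 1
      if (p[j] == 0L) {
        q <- p; q[j] <- 1L
        c1 <- relabel[match(.necklace_class(q), ukeys)]
        if (p[pred] == 1L) {
          A7[c1, c0] <- A7[c1, c0] + 1; A7[c0, c0] <- A7[c0, c0] - 1
        } else {
          A6[c1, c0] <- A6[c1, c0] + 1; A6[c0, c0] <- A6[c0, c0] - 1
        }
      } else {
        q <- p; q[j] <- 0L
        c1 <- relabel[match(.necklace_class(q), ukeys)]
        A12[c1, c0] <- A12[c1, c0] + 1; A12[c0, c0] <- A12[c0, c0] - 1
      }
    }
  }
  .camkii_env$mats <- list(A6 = A6, A7 = A7, A12 = A12, nphos = nphos)
  .camkii_env$mats
}

# Ca4CaM concentration (equilibrium 4-site activation) and the CaM-bound
# probability of a CaMKII subunit.
.cam_active <- function(Ca, ps) {
  if (ps$CaM_T <= 0) return(0)
  ps$CaM_T * Ca^4 / (Ca^4 + ps$K_CaM^4)
}

.cam_gamma <- function(Ca, ps) {
  ca4 <- .cam_active(Ca, ps)
  if (ca4 <= 0) return(0)
  ca4 / (ps$K5_CaMKII + ca4)
}

#' Time derivatives of the CaMKII/PP1/inhibitor-1 subsystem
#'
#' Computes the right-hand side of the bistable CaMKII switch at a given
#' cytosolic calcium concentration: the 13 phosphorylated ring classes
#' (the unphosphorylated class follows by conservation), free PP1 and free
#' phosphorylated inhibitor-1. PKA activation by calcium uses a Hill
#' function with exponent `n_PKA` (default 3).
#'
#' @param state named list or vector with `B` (numeric, length 13), `I1P`
#'   and `PP1`.
#' @param Ca cytosolic calcium (uM).
#' @param ps parameter set.
#' @return list with `dB` (length 13), `dI1P`, `dPP1`, and the phospho-
#'   subunit concentration `CaMKII_act`.
#' @export
camkii_subsystem_rhs <- function(state, Ca, ps) {
  m <- camkii_transition_matrices()
  B <- as.numeric(state$B)
  stopifnot(length(B) == 13L)
  I1P <- state$I1P; PP1 <- state$PP1
  B0 <- ps$CaMKII_T - sum(B)
  Bfull <- c(B0, B)
  Sp <- sum(m$nphos * Bfull)
  g <- .cam_gamma(Ca, ps)
  mu <- ps$k12_PP1 * PP1 / (ps$K_M_PP1 + Sp)
  gen <- ps$k6_CaMKII * g^2 * m$A6 + ps$k7_CaMKII * g * m$A7 + mu * m$A12
  dB <- as.numeric(gen %*% Bfull)[-1]
  cplx <- ps$PP1_T - PP1
  I1free <- ps$I1_T - I1P - cplx
  vPKA <- ps$k_PKA0 + ps$k_PKA * Ca^ps$n_PKA / (Ca^ps$n_PKA + ps$K_PKA^ps$n_PKA)
  vCaN <- ps$k_CaN0 + ps$k_CaN * Ca^ps$n_CaN / (Ca^ps$n_CaN + ps$K_CaN^ps$n_CaN)
  dPP1 <- -ps$k3_I1PP1 * I1P * PP1 + ps$k4_I1PP1 * cplx
  dI1P <- dPP1 + vPKA * I1free - vCaN * I1P
  list(dB = dB, dI1P = dI1P, dPP1 = dPP1, CaMKII_act = Sp)
}

#' Locate the stable states of the CaMKII switch at clamped calcium
#'
#' Integrates the isolated CaMKII/PP1/I1 subsystem at fixed calcium from a
#' fully dephosphorylated and a fully phosphorylated start until
#' stationarity, and reports the resulting fixed points. The subsystem is
#' bistable at the given calcium when the two ends differ.
#'
#' @param ps parameter set.
#' @param Ca clamped cytosolic calcium (uM).
#' @param t_end integration horizon (s).
#' @return list with `down`, `up` (phospho-subunit concentrations),
#'   `bistable` flag and the two full states.
#' @export
find_bistable_states <- function(ps, Ca = ps$Ca_b, t_end = 20000) {
  m <- camkii_transition_matrices()
  rest <- .camkii_rest_i1(ps, Ca)
  rhs <- function(t, y, parms) {
    st <- list(B = y[1:13], I1P = y[14], PP1 = y[15])
    d <- camkii_subsystem_rhs(st, Ca, ps)
    list(c(d$dB, d$dI1P, d$dPP1))
  }
  run <- function(y0) {
    out <- deSolve::lsoda(y0, c(0, t_end / 10, t_end), rhs, NULL,
                          rtol = 1e-9, atol = 1e-12)
    if (attr(out, "istate")[1] < 0)
      stop("CaMKII fixed-point integration failed to converge")
    y <- out[nrow(out), -1]
    st <- list(B = y[1:13], I1P = y[14], PP1 = y[15])
    d <- camkii_subsystem_rhs(st, Ca, ps)
    resid <- max(abs(c(d$dB, d$dI1P, d$dPP1)))
    list(state = y, act = d$CaMKII_act, resid = resid)
  }
  y_dn <- c(rep(0, 13), rest$I1P, rest$PP1)
  up13 <- numeric(13); up13[13] <- ps$CaMKII_T   # fully phosphorylated ring
  y_up <- c(up13, rest$I1P, rest$PP1)
  dn <- run(y_dn); up <- run(y_up)
  max_act <- 6 * ps$CaMKII_T
  bist <- abs(up$act - dn$act) > 0.05 * max_act
  list(down = dn$act, up = up$act, bistable = bist,
       down_state = dn$state, up_state = up$state)
}

# resting I1P / PP1 at clamped calcium (algebraic fixed point)
.camkii_rest_i1 <- function(ps, Ca) {
  vPKA <- ps$k_PKA0 + ps$k_PKA * Ca^ps$n_PKA / (Ca^ps$n_PKA + ps$K_PKA^ps$n_PKA)
  vCaN <- ps$k_CaN0 + ps$k_CaN * Ca^ps$n_CaN / (Ca^ps$n_CaN + ps$K_CaN^ps$n_CaN)
  # solve for I1P with complex in equilibrium: cplx = k3*I1P*PP1/k4,
  # PP1 = PP1_T/(1 + k3*I1P/k4), I1P = (vPKA/vCaN) * I1free
  f <- function(I1P) {
    PP1 <- ps$PP1_T / (1 + ps$k3_I1PP1 * I1P / ps$k4_I1PP1)
    cplx <- ps$PP1_T - PP1
    I1free <- max(ps$I1_T - I1P - cplx, 0)
    vPKA * I1free - vCaN * I1P
  }
  I1P <- tryCatch(stats::uniroot(f, c(0, ps$I1_T), tol = 1e-12)$root,
                  error = function(e) 0)
  PP1 <- ps$PP1_T / (1 + ps$k3_I1PP1 * I1P / ps$k4_I1PP1)
  list(I1P = I1P, PP1 = PP1)
}

#' Postsynaptic weight readout
#'
#' Linear map from the concentration of phosphorylated CaMKII subunits to
#' the postsynaptic weight, `W_post = 1 + gain * act / act_max`, so the
#' weight spans 1 (down state) to 1 + gain (fully phosphorylated; 4.5 with
#' the default gain of 3.5, i.e. 450 percent of baseline).
#'
#' @param camkii_act phosphorylated subunit concentration (uM).
#' @param ps parameter set.
#' @return dimensionless postsynaptic weight.
#' @export
w_post <- function(camkii_act, ps) {
  act_max <- 6 * ps$CaMKII_T
  if (any(camkii_act < 0) || any(camkii_act > act_max * (1 + 1e-9)))
    stop("camkii_act must lie in [0, CaMKII_act_max]")
  1 + ps$w_post_gain * camkii_act / act_max
}
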