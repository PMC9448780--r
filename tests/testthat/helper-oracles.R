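## Independent oracles used by the tests. These deliberately avoid the
## package's Newton/integrator code paths:
##  - a 1-D root scan of the symmetric reduction g(c) for diagonal equilibria,
##  - a nullcline-composition scan over a fine (C_I, C_P) grid for the general
##    two-species equilibrium problem,
##  - a random-schedule generator for property tests.

oracle_hill <- function(c, n) c^n / (1 + c^n)

## symmetric reduction: both species identical, g(c) = 0 at equilibria
oracle_g <- function(c, S, F, n = 2, kf = 1, kr = 0.1)
  (kf * S + F * oracle_hill(c, n)) * (1 - c) - kr * c

oracle_diagonal_roots <- function(S, F, n = 2, kf = 1, kr = 0.1,
                                  grid_n = 4001) {
  grid <- seq(0, 1, length.out = grid_n)
  v <- oracle_g(grid, S, F, n, kf, kr)
  idx <- which(v[-1] * v[-length(v)] <= 0 & v[-length(v)] != 0)
  roots <- vapply(idx, function(i)
    uniroot(oracle_g, c(grid[i], grid[i + 1]), S = S, F = F, n = n,
            kf = kf, kr = kr, tol = 1e-13)$root, 0)
  if (v[1] == 0) roots <- c(0, roots)
  sort(unique(round(roots, 12)))
}

## smallest S at which the low diagonal branch has vanished (fold), by
## bisection on the diagonal root count
oracle_fold_S <- function(F = 1, n = 2, lo = 0, hi = 0.01) {
  count <- function(S) length(oracle_diagonal_roots(S, F, n))
  for (i in 1:50) {
    mid <- (lo + hi) / 2
    if (count(mid) >= 3) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

## general-drive equilibria via nullcline composition: the C_I nullcline gives
## C_I explicitly as a function of C_P (and vice versa), so equilibria are the
## sign changes of h(C_P) = psi(phi(C_P)) - C_P scanned over a fine grid
## seeded from a 41 x 41 flow grid.
oracle_fixed_points <- function(S, F, uI = 0, uP = 0, p = list(
                                  k1f = 1, k2f = 1, k3f = 1,
                                  k1r = 0.1, k2r = 0.1, k3r = 0.1, n = 2)) {
  phi <- function(cp) { # C_I on its nullcline, given C_P
    a <- (1 - uI) * (p$k1f * S + F * oracle_hill(cp, p$n))
    a / (a + p$k1r)
  }
  psi <- function(ci) {
    a <- (1 - uP) * (p$k2f * S + F * oracle_hill(ci, p$n))
    a / (a + p$k2r)
  }
  h <- function(cp) psi(phi(cp)) - cp
  coarse <- seq(0, 1, length.out = 41)
  grid <- sort(unique(c(coarse, seq(0, 1, length.out = 2001))))
  v <- h(grid)
  idx <- which(v[-1] * v[-length(v)] <= 0 & v[-length(v)] != 0)
  cps <- vapply(idx, function(i)
    uniroot(h, c(grid[i], grid[i + 1]), tol = 1e-13)$root, 0)
  if (v[1] == 0) cps <- c(0, cps)
  cps <- sort(unique(round(cps, 10)))
  t(vapply(cps, function(cp) {
    ci <- phi(cp)
    prod3 <- p$k3f * (ci + cp)
    ca <- if (prod3 == 0 && p$k3r == 0) 0 else prod3 / (prod3 + p$k3r)
    c(C_I = ci, C_P = cp, C_a = ca)
  }, c(C_I = 0, C_P = 0, C_a = 0)))
}

## random piecewise schedule for property tests
random_schedule <- function() {
  k <- sample(1:3, 1)
  durs <- runif(k, 2, 20)
  edges <- c(0, cumsum(durs))
  segs <- data.frame(t_start = edges[-(k + 1)], t_end = edges[-1],
                     stiffness_kpa = runif(k, 0, 25),
                     u_I = runif(k, 0, 1), u_P = runif(k, 0, 1))
  fb <- if (runif(1) < 0.5) feedback_ramp(tau_F = runif(1, 5, 25))
        else feedback_explicit(c(0, edges[k + 1]), runif(2))
  pfl_schedule(segs, feedback = fb)
}

random_params <- function() {
  pfl_params(k1f = runif(1, 0.2, 2), k2f = runif(1, 0.2, 2),
             k3f = runif(1, 0.2, 2), k1r = runif(1, 0.05, 0.5),
             k2r = runif(1, 0.05, 0.5), k3r = runif(1, 0.05, 0.5),
             n = sample(c(1, 2, 3, 4), 1))
}
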