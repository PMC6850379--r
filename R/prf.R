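# Poisson-random-field machinery shared by the simulator and the DFE fitter.
#
# Selection is parameterised by the population-scaled coefficient S = 4*Ne*s
# (negative for deleterious mutations). Internally we work with T = -S >= 0.

# Stationary-density ratio (1 - exp(-S*(1-x))) / (1 - exp(-S)) for S = -T,
# computed stably for any T >= 0; the neutral limit (T -> 0) is 1 - x.
# Vectorised over x.
sel_ratio <- function(x, T) {
  if (T < 1e-9) return(1 - x)
  exp(-T * x) * (-expm1(-T * (1 - x))) / (-expm1(-T))
}

# Relative fixation probability S / (1 - exp(-S)) for S = -T, i.e. the
# deleterious substitution rate relative to neutral. Vectorised over T.
fixation_rate <- function(T) {
  out <- T / expm1(T)       # stable: -> 0 for large T, Inf/Inf avoided below
  out[T < 1e-9] <- 1
  out[!is.finite(out)] <- 0
  out
}

# Quadrature rule over allele frequency x in (0,1) for binomial sampling of
# the PRF density. The integrand is a polynomial of degree <= n in x times
# the smooth selection kernel, so Gauss-Legendre with n_nodes >= ~n is
# near-exact. Returns the (n-1) x K matrix M with
#   M[i, k] = w_k * dbinom(i, n, x_k) / (x_k * (1 - x_k))
# so that H(-T, i, n) = M %*% sel_ratio(x, T).
# Cache of Gauss-Legendre rules on [-1, 1]; mapped affinely where needed.
.gl_cache <- new.env(parent = emptyenv())
gl_nodes <- function(n) {
  key <- as.character(n)
  if (is.null(.gl_cache[[key]]))
    .gl_cache[[key]] <- pracma::gaussLegendre(n, -1, 1)
  .gl_cache[[key]]
}

prf_sampling_matrix <- function(n_alleles, n_nodes = 96) {
  gl0 <- gl_nodes(n_nodes)
  gl <- list(x = (gl0$x + 1) / 2, w = gl0$w / 2)
  x <- gl$x
  i <- seq_len(n_alleles - 1)
  M <- outer(i, x, function(ii, xx) dbinom(ii, n_alleles, xx) / (xx * (1 - xx)))
  M <- sweep(M, 2, gl$w, `*`)
  list(M = M, x = x)
}

#' Expected sampled allele-frequency distribution under selection
#'
#' Computes `H(S, i, n)`, the expected density of segregating sites at derived
#' count `i` in a sample of `n` haploid sequences, per unit mutational input,
#' for a mutation with population-scaled selection coefficient `S` under the
#' Poisson random field model: the stationary frequency density
#' `f(x; S) = [1/(x(1-x))] (1 - e^{-S(1-x)})/(1 - e^{-S})` integrated against
#' binomial sampling `C(n,i) x^i (1-x)^{n-i}`. The neutral limit is `1/i`.
#'
#' @param S population-scaled selection coefficient (<= 0 here; 0 = neutral).
#' @param n_alleles sample size n (number of ingroup haplotypes).
#' @param n_nodes number of Gauss-Legendre nodes for the frequency integral.
#' @return numeric vector of length `n_alleles - 1`, entry i = `H(S, i, n)`.
#' @examples
#' prf_h(0, 10)          # 1/i
#' prf_h(-50, 10)        # rare-variant excess relative shape, low absolute mass
#' @export
prf_h <- function(S, n_alleles, n_nodes = 96) {
  stopifnot(length(S) == 1, is.finite(S), S <= 0, n_alleles >= 2)
  sm <- prf_sampling_matrix(n_alleles, n_nodes)
  drop(sm$M %*% sel_ratio(sm$x, -S))
}

# Discretised gamma distribution over T = -S on a log grid between extreme
# quantiles; weights renormalised to sum to one. mean_T and shape > 0.
gamma_mixture <- function(shape, mean_T, n_nodes = 160, q_eps = 1e-10) {
  scale <- mean_T / shape
  lo <- stats::qgamma(q_eps, shape, scale = scale)
  hi <- stats::qgamma(1 - q_eps, shape, scale = scale)
  lo <- max(lo, 1e-300)
  gl <- gl_nodes(n_nodes)
  mid <- (log(hi) + log(lo)) / 2
  half <- (log(hi) - log(lo)) / 2
  T <- exp(mid + half * gl$x)
  w <- gl$w * half * stats::dgamma(T, shape, scale = scale) * T
  list(T = T, w = w / sum(w))
}

#' Mean relative fixation rate of deleterious mutations under a gamma DFE
#'
#' `E[S / (1 - e^{-S})]` over a gamma distribution of deleterious effects:
#' the expected nonsynonymous-to-synonymous substitution-rate ratio for
#' mutations drawn from the DFE (the nonadaptive dN/dS, `omega_na`).
#' `mean_S = 0` is the neutral point mass and returns 1.
#'
#' @param shape gamma shape parameter (> 0).
#' @param mean_S mean population-scaled selection coefficient (<= 0).
#' @param n_nodes quadrature nodes for the mixing integral.
#' @return scalar in (0, 1].
#' @export
dfe_omega_na <- function(shape, mean_S, n_nodes = 160) {
  stopifnot(shape > 0, mean_S <= 0)
  if (mean_S == 0) return(1)
  gm <- gamma_mixture(shape, -mean_S, n_nodes)
  sum(gm$w * fixation_rate(gm$T))
}

# Mean H(-T, i, n) over a gamma DFE: vector over i. Reuses a precomputed
# sampling matrix when fitting (sm argument) to avoid recomputation.
dfe_hbar <- function(shape, mean_S, n_alleles, sm = NULL, n_nodes = 160,
                     x_nodes = 96) {
  if (is.null(sm)) sm <- prf_sampling_matrix(n_alleles, x_nodes)
  if (mean_S == 0) return(drop(sm$M %*% (1 - sm$x)))
  gm <- gamma_mixture(shape, -mean_S, n_nodes)
  G <- vapply(gm$T, function(T) sel_ratio(sm$x, T), numeric(length(sm$x)))
  drop((sm$M %*% G) %*% gm$w)
}

# Fold a length n-1 unfolded expectation/count vector into floor(n/2) minor-
# allele bins: bin i combines i and n-i (i = n/2 stands alone for even n).
fold_sfs <- function(v, n_alleles) {
  n <- n_alleles
  nb <- floor(n / 2)
  out <- numeric(nb)
  for (i in seq_len(nb)) {
    out[i] <- if (i == n - i) v[i] else v[i] + v[n - i]
  }
  names(out) <- seq_len(nb)
  out
}

#' Expected site frequency spectrum under a gamma DFE
#'
#' Expected Poisson mean per frequency class: `theta * L * r_i * Hbar_i`,
#' where `Hbar_i` averages [prf_h()] over the gamma DFE (synonymous/neutral
#' sites use `mean_S = 0`, giving the Watterson `1/i` expectation), and `r`
#' is a vector of per-class nuisance factors absorbing demography and
#' ascertainment (`r[1]` conventionally 1).
#'
#' @param shape,mean_S gamma DFE parameters; `mean_S = 0` for neutral sites.
#' @param theta population-scaled mutation rate per site.
#' @param L number of sites.
#' @param n_alleles sample size.
#' @param r nuisance factors, length `n_alleles - 1` (unfolded) or
#'   `floor(n_alleles/2)` (folded); default all 1.
#' @param folded combine derived classes i and n-i into minor-allele bins?
#' @return expected counts per frequency class.
#' @examples
#' expected_sfs(1, 0, theta = 0.01, L = 6000, n_alleles = 20)  # 60/i
#' @export
expected_sfs <- function(shape, mean_S, theta, L, n_alleles, r = NULL,
                         folded = FALSE) {
  stopifnot(theta > 0, L > 0, n_alleles >= 2, shape > 0, mean_S <= 0)
  h <- dfe_hbar(shape, mean_S, n_alleles)
  e <- theta * L * h
  if (folded) e <- fold_sfs(e, n_alleles)
  if (is.null(r)) r <- rep(1, length(e))
  stopifnot(length(r) == length(e))
  unname(e * r)
}
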