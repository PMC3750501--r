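#' Transcriptional sensor construct (built-in case study)
#'
#' Five-state mass-action model of a synthetic sensor: a constitutively and
#' auto-activated gene expresses a protein that dimerizes; the dimer is the
#' transcriptional activator of its own promoter, and an external inhibitor
#' input traps the dimer in an inactive complex. States:
#'
#' * `x1` mRNA, `x2` protein monomer, `x3` dimer, `x4` inhibited dimer,
#'   `x5` activator-bound promoter (all nM).
#'
#' The right-hand side is
#' \deqn{\dot x_1 = k_1(x_5^0 - x_5) + k_2 x_5 - k_3 x_1}
#' \deqn{\dot x_2 = k_4 x_1 - 2 k_5 x_2^2 + 2 k_6 x_3 - k_{11} x_2}
#' \deqn{\dot x_3 = k_5 x_2^2 - k_6 x_3 - k_7 x_3 y(t) + k_8 x_4
#'       - k_9 (x_5^0 - x_5) x_3 + k_{10} x_5 - k_{11} x_3}
#' \deqn{\dot x_4 = k_7 x_3 y(t) - k_8 x_4 - k_{11} x_4}
#' \deqn{\dot x_5 = k_9 (x_5^0 - x_5) x_3 - k_{10} x_5 - k_{11} x_5}
#'
#' with `y(t)` the inhibitor input and `x5_total` (\eqn{x_5^0}) the total
#' promoter concentration. The promoter count is conserved structurally:
#' `x5` stays in `[0, x5_total]` because every binding flux carries a
#' `(x5_total - x5)` factor. Nominal rates:
#'
#' | rate | value | meaning |
#' |------|-------|---------|
#' | k1  | 0.02 /sec       | basal transcription |
#' | k2  | 0.4 /sec        | active-promoter transcription |
#' | k3  | 0.3 /sec        | mRNA degradation |
#' | k4  | 3 /(nM sec)     | translation |
#' | k5  | 0.1 /(nM sec)   | dimerization |
#' | k6  | 0.001 /sec      | dimer dissociation |
#' | k7  | 0.011 /(nM sec) | inhibitor binding |
#' | k8  | 0.2 /sec        | inhibitor unbinding |
#' | k9  | 0.21 /(nM sec)  | dimer-promoter binding |
#' | k10 | 0.2 /sec        | dimer-promoter unbinding |
#' | k11 | 0.2 /sec        | protein/dilution degradation |
#'
#' The flux decomposition uses 14 elementary reactions (basal and active
#' transcription, mRNA decay, translation, dimerization/dissociation,
#' inhibitor binding/unbinding, promoter binding/unbinding, and first-order
#' degradation of monomer, dimer, inhibited dimer and bound promoter), whose
#' stoichiometric combination reproduces the right-hand side above exactly.
#'
#' @param x5_total total promoter concentration \eqn{x_5^0} in nM. The model
#'   presumes several gene copies (default 10 nM) so the deterministic
#'   rate-equation description is sensible.
#' @return A [reaction_network()] with nominal parameters attached.
#' @export
sensor_network <- function(x5_total = 10) {
  stopifnot(x5_total > 0)
  params <- c(k1 = 0.02, k2 = 0.4, k3 = 0.3, k4 = 3, k5 = 0.1,
              k6 = 0.001, k7 = 0.011, k8 = 0.2, k9 = 0.21,
              k10 = 0.2, k11 = 0.2)
  species <- c("x1", "x2", "x3", "x4", "x5")

  # columns: 1 basal txn, 2 active txn, 3 mRNA decay, 4 translation,
  # 5 dimerization, 6 dissociation, 7 inhibitor binding, 8 unbinding,
  # 9 promoter binding, 10 promoter unbinding, 11-14 degradation of x2..x5
  N <- matrix(0L, 5, 14, dimnames = list(species, NULL))
  N[1, 1] <- 1L; N[1, 2] <- 1L; N[1, 3] <- -1L
  N[2, 4] <- 1L; N[2, 5] <- -2L; N[2, 6] <- 2L; N[2, 11] <- -1L
  N[3, 5] <- 1L; N[3, 6] <- -1L; N[3, 7] <- -1L; N[3, 8] <- 1L
  N[3, 9] <- -1L; N[3, 10] <- 1L; N[3, 12] <- -1L
  N[4, 7] <- 1L; N[4, 8] <- -1L; N[4, 13] <- -1L
  N[5, 9] <- 1L; N[5, 10] <- -1L; N[5, 14] <- -1L

  flux <- function(x, k, u, t) {
    free <- x5_total - x[5]
    c(k[1] * free,           # basal transcription
      k[2] * x[5],           # active transcription
      k[3] * x[1],           # mRNA decay
      k[4] * x[1],           # translation
      k[5] * x[2]^2,         # dimerization
      k[6] * x[3],           # dimer dissociation
      k[7] * x[3] * u,       # inhibitor binding
      k[8] * x[4],           # inhibitor unbinding
      k[9] * free * x[3],    # promoter binding
      k[10] * x[5],          # promoter unbinding
      k[11] * x[2], k[11] * x[3], k[11] * x[4], k[11] * x[5])
  }

  flux_jac_x <- function(x, k, u, t) {
    J <- matrix(0, 14, 5)
    J[1, 5] <- -k[1]
    J[2, 5] <- k[2]
    J[3, 1] <- k[3]
    J[4, 1] <- k[4]
    J[5, 2] <- 2 * k[5] * x[2]
    J[6, 3] <- k[6]
    J[7, 3] <- k[7] * u
    J[8, 4] <- k[8]
    J[9, 3] <- k[9] * (x5_total - x[5]); J[9, 5] <- -k[9] * x[3]
    J[10, 5] <- k[10]
    J[11, 2] <- k[11]; J[12, 3] <- k[11]; J[13, 4] <- k[11]; J[14, 5] <- k[11]
    J
  }

  flux_jac_k <- function(x, k, u, t) {
    J <- matrix(0, 14, 11)
    J[1, 1] <- x5_total - x[5]
    J[2, 2] <- x[5]
    J[3, 3] <- x[1]
    J[4, 4] <- x[1]
    J[5, 5] <- x[2]^2
    J[6, 6] <- x[3]
    J[7, 7] <- x[3] * u
    J[8, 8] <- x[4]
    J[9, 9] <- (x5_total - x[5]) * x[3]
    J[10, 10] <- x[5]
    J[11, 11] <- x[2]; J[12, 11] <- x[3]; J[13, 11] <- x[4]; J[14, 11] <- x[5]
    J
  }

  net <- reaction_network(
    species = species, stoich = N, flux = flux,
    flux_jac_x = flux_jac_x, flux_jac_k = flux_jac_k,
    param_names = names(params), params = params,
    conserved_bounds = list(x5 = c(0, x5_total)))
  net$x5_total <- x5_total
  net
}

#' Generic mass-action network from monomial rate laws
#'
#' Builds a [reaction_network()] from reactions whose rates are monomials
#' `k_j * prod_i x_i^(e_ij) * u^(e_u)`: the standard mass-action form, with
#' an optional dependence on the scalar external input. Stoichiometry and
#' both flux Jacobians are assembled analytically from the exponents.
#'
#' @param species character vector of species names.
#' @param params named numeric vector of nonnegative rate constants, one per
#'   reaction (shared constants may repeat a name).
#' @param reactions list of reactions; each is a list with elements
#'   `rate` (a name in `params`), `reactants` (named integer vector: rate-law
#'   exponents, also consumed stoichiometry), `products` (named integer
#'   vector), and optionally `input_exponent` (default 0).
#' @return A [reaction_network()].
#' @examples
#' # A -> 0 with rate k * A
#' decay <- mass_action_network(
#'   species = "A", params = c(k = 1),
#'   reactions = list(list(rate = "k", reactants = c(A = 1), products = NULL)))
#' @export
mass_action_network <- function(species, params, reactions) {
  n <- length(species)
  pnames <- names(params)
  q <- length(reactions)
  cc <- check_collector()
  for (j in seq_len(q)) {
    rx <- reactions[[j]]
    cc$add(rx$rate %in% pnames,
           sprintf("reaction %d: unknown rate constant '%s'", j, rx$rate))
    bad <- setdiff(c(names(rx$reactants), names(rx$products)), species)
    cc$add(length(bad) == 0,
           sprintf("reaction %d: unknown species %s", j,
                   paste(bad, collapse = ", ")))
  }
  cc$fail_if_any("invalid mass-action model")

  E <- matrix(0, q, n, dimnames = list(NULL, species))   # rate-law exponents
  N <- matrix(0L, n, q, dimnames = list(species, NULL))
  eu <- numeric(q)
  kidx <- integer(q)
  for (j in seq_len(q)) {
    rx <- reactions[[j]]
    kidx[j] <- match(rx$rate, pnames)
    eu[j] <- rx$input_exponent %||% 0
    for (s in names(rx$reactants)) {
      E[j, s] <- rx$reactants[[s]]
      N[s, j] <- N[s, j] - as.integer(rx$reactants[[s]])
    }
    for (s in names(rx$products))
      N[s, j] <- N[s, j] + as.integer(rx$products[[s]])
  }

  monomial <- function(x, u) {
    # prod_i x_i^E[j,i] * u^eu[j] for all j; 0^0 treated as 1
    xm <- matrix(rep(pmax(x, 0), each = q), q, n)
    apply(xm^E, 1, prod) * ifelse(eu == 0, 1, pmax(u, 0)^eu)
  }
  flux <- function(x, k, u, t) k[kidx] * monomial(x, u)
  flux_jac_x <- function(x, k, u, t) {
    J <- matrix(0, q, n)
    for (i in seq_len(n)) {
      e <- E[, i]
      pos <- e > 0
      if (!any(pos)) next
      # d/dx_i of x_i^e = e * x_i^(e-1); rebuild the rest of the monomial
      # explicitly so the derivative is exact at x_i = 0
      xi <- pmax(x[i], 0)
      for (j in which(pos)) {
        xo <- pmax(x, 0); xo[i] <- 1
        base <- prod(xo^E[j, ]) * ifelse(eu[j] == 0, 1, pmax(u, 0)^eu[j])
        J[j, i] <- k[kidx[j]] * e[j] * xi^(e[j] - 1) * base
      }
    }
    J
  }
  flux_jac_k <- function(x, k, u, t) {
    m <- monomial(x, u)
    J <- matrix(0, q, length(pnames))
    J[cbind(seq_len(q), kidx)] <- m
    J
  }
  reaction_network(species, N, flux, flux_jac_x, flux_jac_k,
                   param_names = pnames, params = params)
}
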