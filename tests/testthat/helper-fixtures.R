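# Small deterministic fixtures and independent oracles used across tests.

# two trials, six patients, valid by construction
tiny_ipd_df <- function() {
  data.frame(
    trial_id = rep(c("A", "B"), each = 3),
    patient_id = rep(c("p1", "p2", "p3"), 2),
    z = c(0, 1, 1, 0, 0, 1),
    x = c(0, 1, 0, 1, 1, 0),
    time = c(1, 2, 3, 1.5, 2.5, 0.5),
    event = c(1, 0, 1, 1, 0, 1),
    stringsAsFactors = FALSE
  )
}

# seeded simulated dataset at configurable size
sim_ipd <- function(seed, J = 4, N = 50, kind = "binary", V1 = 0.4, V2 = 10,
                    beta4 = 0, ...) {
  set.seed(seed)
  scn <- scenario_config(J = J, N = N, covariate_kind = kind, V1 = V1, V2 = V2,
                         beta4 = beta4, ...)
  generate_dataset(scn)
}

# Independent stratified Cox partial log-likelihood (Breslow; simulated times
# are continuous so ties have measure zero and Breslow equals Efron).
oracle_plik <- function(beta, X, time, event, strata) {
  tot <- 0
  for (idx in split(seq_along(time), strata)) {
    eta <- as.numeric(X[idx, , drop = FALSE] %*% beta)
    o <- order(time[idx], decreasing = TRUE)
    eta <- eta[o]
    ev <- event[idx][o]
    cs <- cumsum(exp(eta))
    tot <- tot + sum(eta[ev == 1] - log(cs[ev == 1]))
  }
  tot
}

# brute-force maximiser of the stratified partial likelihood
oracle_fit_fixed <- function(table, spec) {
  des <- build_design(table, spec)
  p <- ncol(des$X)
  op <- optim(rep(0, p),
              function(b) -oracle_plik(b, des$X, des$time, des$event, des$strata),
              method = "BFGS", control = list(reltol = 1e-14, maxit = 500))
  setNames(op$par, colnames(des$X))
}

# Independent maximiser of the integrated stratified partial likelihood:
# same estimand as fit_random but with adaptive integrate() instead of
# Gauss-Hermite and optim() instead of nlminb().
oracle_fit_random <- function(table, spec, start) {
  des <- build_design(table, spec)
  p <- ncol(des$X)
  idxs <- split(seq_along(des$time), des$strata)
  nll <- function(par) {
    g <- par[seq_len(p)]
    tau <- exp(par[p + 1])
    tot <- 0
    for (idx in idxs) {
      X <- des$X[idx, , drop = FALSE]
      z <- X[, "treat"]
      eta0 <- as.numeric(X %*% g)
      pl <- function(b) {
        oracle_plik(matrix(1), matrix(eta0 + b * z), des$time[idx],
                    des$event[idx], rep(1, length(idx)))
      }
      shift <- pl(0)   # keeps exp() in range; added back after the log
      f <- function(b) vapply(b, function(bb)
        exp(pl(bb) - shift + dnorm(bb, 0, tau, log = TRUE)), 0)
      tot <- tot + log(integrate(f, -6, 6, rel.tol = 1e-10)$value) + shift
    }
    -tot
  }
  op <- optim(start, nll, method = "BFGS", control = list(reltol = 1e-13, maxit = 500))
  list(coef = setNames(op$par[seq_len(p)], colnames(des$X)),
       tau = exp(op$par[p + 1]), loglik = -op$value)
}
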