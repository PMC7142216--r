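# Independent oracles: brute-force / closed-form implementations kept
# deliberately separate from the package's code paths.

# Cox partial log-likelihood for a single covariate, distinct event times
# (no ties, so Breslow == Efron).
oracle_cox_loglik <- function(beta, x, time, event) {
  ll <- 0
  for (i in which(event == 1)) {
    at_risk <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[at_risk])))
  }
  ll
}

# Analytic score U(beta) and information I(beta) for the same model.
oracle_cox_score_info <- function(beta, x, time, event) {
  U <- 0
  I <- 0
  for (i in which(event == 1)) {
    r <- which(time >= time[i])
    w <- exp(beta * x[r])
    s0 <- sum(w)
    s1 <- sum(w * x[r])
    s2 <- sum(w * x[r]^2)
    U <- U + x[i] - s1 / s0
    I <- I + s2 / s0 - (s1 / s0)^2
  }
  c(U = U, I = I)
}

# Same log-likelihood, O(n log n): risk-set sums via cumsum after sorting
# by descending time (distinct times assumed).
oracle_cox_loglik_fast <- function(beta, x, time, event) {
  ord <- order(time, decreasing = TRUE)
  xs <- x[ord]
  ev <- event[ord]
  cums <- cumsum(exp(beta * xs))
  sum(beta * xs[ev == 1] - log(cums[ev == 1]))
}

# Maximum-partial-likelihood estimate by grid search at fixed resolution.
# The partial log-likelihood is concave in beta, so a coarse pass followed
# by a fine pass around the coarse maximum visits the same 1e-4 grid point
# an exhaustive scan would pick.
oracle_cox_beta_grid <- function(x, time, event, lo = -5, hi = 5,
                                 resolution = 1e-4) {
  coarse_by <- max(resolution, 5e-3)
  coarse <- seq(lo, hi, by = coarse_by)
  ll <- vapply(coarse, oracle_cox_loglik_fast, numeric(1),
               x = x, time = time, event = event)
  b0 <- coarse[which.max(ll)]
  fine <- seq(max(lo, b0 - 2 * coarse_by), min(hi, b0 + 2 * coarse_by),
              by = resolution)
  llf <- vapply(fine, oracle_cox_loglik_fast, numeric(1),
                x = x, time = time, event = event)
  fine[which.max(llf)]
}

# The three overall-test p-values evaluated from the oracle quantities.
oracle_cox_pvalues <- function(beta_hat, x, time, event) {
  ll0 <- oracle_cox_loglik(0, x, time, event)
  ll1 <- oracle_cox_loglik(beta_hat, x, time, event)
  si0 <- oracle_cox_score_info(0, x, time, event)
  si1 <- oracle_cox_score_info(beta_hat, x, time, event)
  c(lrt = pchisq(2 * (ll1 - ll0), 1, lower.tail = FALSE),
    wald = pchisq(beta_hat^2 * si1[["I"]], 1, lower.tail = FALSE),
    score = pchisq(si0[["U"]]^2 / si0[["I"]], 1, lower.tail = FALSE))
}

# Harrell's C by explicit pair loops.
oracle_cindex <- function(risk, time, event) {
  num <- 0
  den <- 0
  n <- length(risk)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (time[i] < time[j] && event[i] == 1) {
        den <- den + 1
        if (risk[i] > risk[j]) num <- num + 1
        else if (risk[i] == risk[j]) num <- num + 0.5
      }
    }
  }
  num / den
}

# Product-limit estimator by hand.
oracle_km <- function(time, event) {
  ut <- sort(unique(time))
  surv <- numeric(length(ut))
  s <- 1
  for (k in seq_along(ut)) {
    at_risk <- sum(time >= ut[k])
    d <- sum(time == ut[k] & event == 1)
    s <- s * (1 - d / at_risk)
    surv[k] <- s
  }
  data.frame(time = ut, survival = surv)
}

# Two-group log-rank statistic by hand (O - E over V).
oracle_logrank_p <- function(group, time, event) {
  g <- as.integer(as.factor(group)) - 1L  # 0/1
  ut <- sort(unique(time[event == 1]))
  O_minus_E <- 0
  V <- 0
  for (t in ut) {
    at_risk <- time >= t
    n_tot <- sum(at_risk)
    n1 <- sum(at_risk & g == 1)
    d_tot <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g == 1)
    O_minus_E <- O_minus_E + d1 - d_tot * n1 / n_tot
    if (n_tot > 1) {
      V <- V + d_tot * (n1 / n_tot) * (1 - n1 / n_tot) *
        (n_tot - d_tot) / (n_tot - 1)
    }
  }
  pchisq(O_minus_E^2 / V, df = 1, lower.tail = FALSE)
}

# Upper-tail hypergeometric probability by exhaustive enumeration of all
# size-n draws from a universe of N genes of which the first M are marked.
oracle_hyper_enum <- function(N, M, n, i) {
  if (n == 0) return(as.numeric(i <= 0))
  draws <- utils::combn(N, n)
  overlap <- colSums(draws <= M)
  mean(overlap >= i)
}

# Small synthetic survival dataset with distinct times for Cox oracles.
make_tiny_cox_data <- function(n, seed) {
  set.seed(seed)
  x <- round(rnorm(n), 2)
  time <- sample(seq(10, 10 * n, by = 10))  # distinct by construction
  event <- rbinom(n, 1, 0.8)
  if (sum(event) == 0) event[1] <- 1L
  list(x = x, time = time, event = event)
}

# Standard small dataset shared by pipeline-level tests: five two-layer
# drivers acting through mixed layer pairs.
driver_pairs <- list(c("GE", "SCNA"), c("GE", "DM"), c("SCNA", "ME"),
                     c("DM", "ME"), c("GE", "ME"))

make_driver_dataset <- function(n_genes = 120, n_samples = 250, seed = 42,
                                effect_size = 1.0, n_drivers = 5) {
  generate_dataset(sim_config(
    n_genes, n_samples, n_drivers = n_drivers,
    driver_layers = driver_pairs[seq_len(n_drivers)],
    effect_size = effect_size, censor_rate = 0.3, seed = seed))
}
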