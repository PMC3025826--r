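## Independent oracles used to check the package's statistics. Each is a
## deliberately naive implementation (enumeration, closed form, or textbook
## Newton iterations) sharing no code with the package.

## Newton-Raphson maximizer of the Cox partial likelihood (Breslow ties).
oracle_cox_beta <- function(time, event, x, tol = 1e-10, maxit = 50) {
  x <- as.matrix(x)
  p <- ncol(x)
  beta <- rep(0, p)
  for (it in seq_len(maxit)) {
    U <- rep(0, p)
    I <- matrix(0, p, p)
    for (i in which(event == 1)) {
      risk <- which(time >= time[i])
      w <- exp(drop(x[risk, , drop = FALSE] %*% beta))
      W <- sum(w)
      xbar <- colSums(x[risk, , drop = FALSE] * w) / W
      U <- U + x[i, ] - xbar
      xx <- crossprod(x[risk, , drop = FALSE] * sqrt(w)) / W
      I <- I + xx - tcrossprod(xbar)
    }
    step <- solve(I, U)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  list(beta = beta, var = solve(I))
}

## Manual Kaplan-Meier product-limit table (events before censorings).
oracle_km <- function(time, event) {
  ts <- sort(unique(time[event == 1]))
  surv <- numeric(length(ts))
  s <- 1
  for (k in seq_along(ts)) {
    n_risk <- sum(time >= ts[k])
    d <- sum(time == ts[k] & event == 1)
    s <- s * (1 - d / n_risk)
    surv[k] <- s
  }
  data.frame(time = ts, surv = surv)
}

## Two-group log-rank statistic from observed-minus-expected sums.
oracle_logrank2 <- function(time, event, group) {
  g <- as.integer(as.factor(group))
  ts <- sort(unique(time[event == 1]))
  O_E <- 0; V <- 0
  for (tk in ts) {
    at_risk <- time >= tk
    n <- sum(at_risk)
    n1 <- sum(at_risk & g == 1)
    d <- sum(time == tk & event == 1)
    d1 <- sum(time == tk & event == 1 & g == 1)
    O_E <- O_E + d1 - d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  stat <- O_E^2 / V
  list(statistic = stat, p = pchisq(stat, 1, lower.tail = FALSE))
}

## Exhaustive pair enumeration of Harrell's C.
oracle_cindex <- function(scores, time, event) {
  conc <- 0; comp <- 0
  n <- length(time)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (event[i] == 1 && time[i] < time[j]) {
      comp <- comp + 1
      if (scores[i] > scores[j]) conc <- conc + 1
      else if (scores[i] == scores[j]) conc <- conc + 0.5
    }
  }
  conc / comp
}

## Exhaustive pair counting AUC.
oracle_auc <- function(pred, labels) {
  pos <- pred[labels == 1]; neg <- pred[labels == 0]
  s <- 0
  for (a in pos) for (b in neg) {
    s <- s + (a > b) + 0.5 * (a == b)
  }
  s / (length(pos) * length(neg))
}

## Small survival cohort with continuous (tie-free) times.
toy_survival <- function(n = 60, seed = 42, beta = 0.8) {
  set.seed(seed)
  x <- rnorm(n)
  t_ev <- rexp(n, rate = 0.2 * exp(beta * x))
  t_c <- rexp(n, rate = 0.1)
  data.frame(x = x, time = pmin(t_ev, t_c),
             event = as.integer(t_ev <= t_c))
}

## Minimal clinical cohort data.frame builder.
toy_cohort <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(
    sample_id = sprintf("P%03d", seq_len(n)),
    er = sample(c("pos", "neg"), n, TRUE, prob = c(0.7, 0.3)),
    size = sample(c("lt2cm", "ge2cm"), n, TRUE),
    grade = sample(1:3, n, TRUE),
    her2 = sample(c("pos", "neg"), n, TRUE, prob = c(0.2, 0.8)),
    source = sample(c("SrcA", "SrcB"), n, TRUE),
    platform = sample(c("PlatA", "PlatB"), n, TRUE),
    stringsAsFactors = FALSE)
}

## Simulated cohort + latent-score features shared by resampling tests.
make_sim <- function(n_samples = 300, n_modules = 10, coefs = c(MOD01 = 0.8),
                     seed = 1, module_correlation = 0.7, n_genes = 200,
                     genes_per_module = 5, ...) {
  cfg <- simulation_config(n_samples = n_samples, n_genes = n_genes,
                           n_modules = n_modules,
                           genes_per_module = genes_per_module,
                           module_correlation = module_correlation,
                           true_coefficients = coefs, seed = seed, ...)
  sim <- generate_expression_cohort(cfg)
  sim$config <- cfg
  sim$latent <- truth_module_scores(sim$truth)
  sim
}
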