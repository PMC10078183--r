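# Shared fixture builders; everything is generated in code at test time.

tiny_landscape <- function(n_rows = 10, n_cols = 10, seed = 1,
                           n_numeric = 2, n_categorical = 1,
                           correlation_length = 3000) {
  generate_landscape(landscape_config(
    n_rows, n_cols, cell_size = 1000, n_numeric = n_numeric,
    n_categorical = n_categorical, n_levels = 3,
    correlation_length = correlation_length, seed = seed))
}

## a biased observed dataset with truth attached (oracle use only)
biased_dataset <- function(seed = 1, n_rows = 30, n_cols = 30,
                           theta = 0.4, family_truth = "negbin") {
  land <- tiny_landscape(n_rows, n_cols, seed = seed, n_numeric = 3)
  beta <- c(0.5, 0.8, -0.4, 0.3, 0.3, -0.3)
  gamma <- c(1.2, -0.9, 0.6, 0, 0.4, 0)
  th <- if (family_truth == "poisson") 1e8 else theta
  tr <- truth_config(beta, th, gamma, seed = seed)
  N <- simulate_true_abundance(land, tr)
  s <- simulate_sampling(land, N, tr)
  list(land = land, truth = tr, N = N, Y = s$Y, excess = s$excess, pi = s$pi,
       X = landscape_design(land))
}

random_records <- function(n, extent = 10000, seed = 1) {
  set.seed(seed)
  data.frame(record_id = seq_len(n),
             x = runif(n, 0, extent), y = runif(n, 0, extent))
}

## brute-force mixture log-likelihood in plain (non-log) arithmetic: the
## independent oracle for zi_loglik
bf_zi_loglik <- function(params, Xc, Xz, y, family) {
  pc <- ncol(Xc); pz <- ncol(Xz)
  beta <- params[seq_len(pc)]; gamma <- params[pc + seq_len(pz)]
  total <- 0
  for (i in seq_along(y)) {
    mu <- exp(sum(Xc[i, ] * beta))
    pi <- 1 / (1 + exp(-sum(Xz[i, ] * gamma)))
    f <- if (family == "poisson") dpois(y[i], mu)
         else dnbinom(y[i], size = exp(params[pc + pz + 1]), mu = mu)
    total <- total + log(pi * (y[i] == 0) + (1 - pi) * f)
  }
  total
}

## brute-force mean nearest-neighbour distance
bf_mnnd <- function(rec) {
  d <- as.matrix(dist(cbind(rec$x, rec$y)))
  diag(d) <- Inf
  mean(apply(d, 1, min))
}
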