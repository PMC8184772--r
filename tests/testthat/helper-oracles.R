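# Independent oracles used to freeze/verify expected values. These stay
# deliberately naive and share no code with the package internals.

# exact Wilcoxon signed-rank two-sided p by brute-force enumeration of all
# 2^n sign assignments
oracle_wilcoxon_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  W_all <- drop(signs %*% r)
  p_lo <- mean(W_all <= W_obs)
  p_hi <- mean(W_all >= W_obs)
  min(1, 2 * min(p_lo, p_hi))
}

# Heap's algorithm: all permutations of 1..n (independent of the package's
# own permutation generator)
oracle_perms <- function(n) {
  out <- list()
  a <- seq_len(n)
  rec <- function(k) {
    if (k == 1) {
      out[[length(out) + 1]] <<- a
      return(invisible(NULL))
    }
    for (i in seq_len(k)) {
      rec(k - 1)
      if (k %% 2 == 0) {
        tmp <- a[i]; a[i] <<- a[k]; a[k] <<- tmp
      } else {
        tmp <- a[1]; a[1] <<- a[k]; a[k] <<- tmp
      }
    }
  }
  rec(n)
  do.call(rbind, out)
}

# exhaustive-permutation two-sided Spearman p
oracle_spearman_p <- function(x, y) {
  rho_obs <- stats::cor(x, y, method = "spearman")
  perms <- oracle_perms(length(y))
  rhos <- apply(perms, 1, function(ix)
    stats::cor(x, y[ix], method = "spearman"))
  mean(abs(rhos) >= abs(rho_obs) - 1e-12)
}

# hand-executable two-stage BKY reference (step-up written independently)
oracle_bky <- function(p, q) {
  m <- length(p)
  stepup <- function(p, lvl) {
    o <- order(p); k <- 0
    for (i in seq_len(m)) if (p[o[i]] <= lvl * i / m) k <- i
    flags <- logical(m)
    if (k > 0) flags[o[seq_len(k)]] <- TRUE
    flags
  }
  q1 <- q / (1 + q)
  s1 <- stepup(p, q1)
  r1 <- sum(s1)
  if (r1 == 0 || r1 == m) return(s1)
  stepup(p, q1 * m / (m - r1))
}

# small, fast simulation shared by several suites
small_sim <- function(seed = 11, n_donors = 4, cells = 800, ...) {
  cfg <- sim_config(n_donors = n_donors, cells_per_sample = cells,
                    seed = seed, ...)
  simulate_experiment(cfg)
}

gate_all <- function(sim, hierarchy = build_default_hierarchy()) {
  lapply(sim$tables, apply_gating, hierarchy = hierarchy)
}
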