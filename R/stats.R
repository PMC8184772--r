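#' Exact Wilcoxon signed-rank test
#'
#' Paired nonparametric test on signed ranks of within-pair differences.
#' Zero differences are dropped; tied magnitudes receive midranks. For
#' `n <= exact_limit` non-zero differences the two-sided p-value is exact
#' over all `2^n` equally likely sign assignments (computed by
#' generating-function convolution over the doubled rank weights, which
#' enumerates the same distribution); above that, a normal approximation
#' with tie correction and continuity correction is used.
#'
#' @param differences numeric vector of paired differences.
#' @param exact_limit largest n for which the exact null distribution is
#'   computed (default 25).
#' @return A `paired_test`: list with `statistic` (W, sum of positive-sign
#'   ranks), `p_two_sided`, `n_effective`, `method`.
#' @examples
#' wilcoxon_signed_rank_exact(c(1, 2, 3))$p_two_sided  # 0.25
#' @export
wilcoxon_signed_rank_exact <- function(differences, exact_limit = 25) {
  d <- differences[!is.na(differences)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    stop("all differences are zero: signed-rank test undefined",
         call. = FALSE)
  }
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= exact_limit) {
    # doubled ranks are integers even with midranks
    w2 <- as.integer(round(2 * r))
    total <- sum(w2)
    # distribution of 2W over 0..total via polynomial product of (1 + z^w)
    dist <- numeric(total + 1L)
    dist[1L] <- 1
    for (w in w2) {
      shifted <- c(rep(0, w), dist[seq_len(total + 1L - w)])
      dist <- dist + shifted
    }
    dist <- dist / 2^n
    w2obs <- as.integer(round(2 * W))
    p_lo <- sum(dist[seq_len(w2obs + 1L)])
    p_hi <- sum(dist[(w2obs + 1L):(total + 1L)])
    p <- min(1, 2 * min(p_lo, p_hi))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(ties^3 - ties) / 48
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal-approx"
  }
  structure(list(statistic = W, p_two_sided = p, n_effective = n,
                 method = method),
            class = "paired_test")
}

#' @export
print.paired_test <- function(x, ...) {
  cat("Wilcoxon signed-rank (", x$method, "): W = ", x$statistic,
      ", n = ", x$n_effective, ", p = ", format(x$p_two_sided, digits = 4),
      "\n", sep = "")
  invisible(x)
}

bh_step_up <- function(p, level) {
  m <- length(p)
  o <- order(p)
  thresh <- level * seq_len(m) / m
  ok <- which(p[o] <= thresh)
  r <- if (length(ok)) max(ok) else 0L
  flags <- logical(m)
  if (r > 0) flags[o[seq_len(r)]] <- TRUE
  flags
}

#' Two-stage Benjamini-Krieger-Yekutieli FDR procedure
#'
#' Adaptive linear step-up FDR control: stage 1 runs Benjamini-Hochberg at
#' the shrunk level `q' = q / (1 + q)`; its rejection count `r1` gives the
#' null-count estimate `m0 = m - r1`, and stage 2 reruns the step-up at the
#' inflated level `q' * m / m0`. If stage 1 rejects nothing (or everything)
#' the procedure stops there.
#'
#' @param p_values numeric vector in \[0, 1\].
#' @param q target FDR level (default 0.01).
#' @return An `fdr_result`: list with `discoveries` (logical flags in input
#'   order), `q_level`, `p_values`, `m0` (estimated true nulls), `stage2_level`.
#' @export
bky_two_stage_fdr <- function(p_values, q = 0.01) {
  p <- as.numeric(p_values)
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  if (!(q > 0 && q < 1)) stop("q must be in (0, 1)", call. = FALSE)
  m <- length(p)
  q1 <- q / (1 + q)
  stage1 <- bh_step_up(p, q1)
  r1 <- sum(stage1)
  if (r1 == 0L || r1 == m) {
    return(structure(list(discoveries = stage1, q_level = q, p_values = p,
                          m0 = m - r1, stage2_level = q1),
                     class = "fdr_result"))
  }
  m0 <- m - r1
  level2 <- q1 * m / m0
  flags <- bh_step_up(p, level2)
  structure(list(discoveries = flags, q_level = q, p_values = p, m0 = m0,
                 stage2_level = level2),
            class = "fdr_result")
}

#' @export
print.fdr_result <- function(x, ...) {
  cat("BKY two-stage FDR at q = ", x$q_level, ": ", sum(x$discoveries),
      " / ", length(x$p_values), " discoveries (m0 = ", x$m0, ")\n",
      sep = "")
  invisible(x)
}

# all permutations of 1..n (n <= 8), deterministic order
permutations_of <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  row <- 0L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    for (i in seq_len(nrow(sub))) {
      row <- row + 1L
      out[row, ] <- c(k, rest[sub[i, ]])
    }
  }
  out
}

# exhaustive permutation null of Spearman rho for rank vectors rx, ry
spearman_perm_null <- function(rx, ry) {
  n <- length(rx)
  perms <- permutations_of(n)
  rxc <- rx - mean(rx)
  ryc <- ry - mean(ry)
  M <- matrix(ryc[t(perms)], nrow = n)   # one permuted ry per column
  colSums(M * rxc) / sqrt(sum(rxc^2) * sum(ryc^2))
}

#' Spearman rank correlation with small-sample p-value
#'
#' Rho is the Pearson correlation of midranks. The two-sided p-value is the
#' exact permutation tail probability (all `n!` orderings) for
#' `n <= exact_limit`, and the t-distribution approximation
#' `t = rho * sqrt((n-2) / (1-rho^2))` above it.
#'
#' @param x,y equal-length numeric vectors, length >= 4.
#' @param exact_limit largest n for full permutation enumeration
#'   (default 8).
#' @return List with `rho`, `p_two_sided`, `n`, `method`; `rho` is `NA`
#'   (undefined) when either vector is constant.
#' @export
spearman_rho_p <- function(x, y, exact_limit = 8) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 4) stop("need at least 4 observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(rho = NA_real_, p_two_sided = NA_real_, n = n,
                method = "undefined-constant"))
  }
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= exact_limit) {
    rho_perm <- spearman_perm_null(rx, ry)
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
    method <- "exact-permutation"
  } else {
    if (abs(rho) >= 1) {
      p <- 0
    } else {
      tt <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * stats::pt(-abs(tt), n - 2)
    }
    method <- "t-approx"
  }
  list(rho = rho, p_two_sided = p, n = n, method = method)
}

#' Relative quantification by the 2^-ddCt method
#'
#' qRT-PCR fold change of a target gene, normalized to a reference gene and
#' expressed relative to the control condition: `dCt = Ct_target - Ct_ref`
#' per condition, `ddCt = dCt_treated - dCt_control`, fold change
#' `2^-ddCt`.
#'
#' @param ct_target_control,ct_ref_control,ct_target_treated,ct_ref_treated
#'   cycle-threshold values (positive reals).
#' @return Fold change (treated relative to control).
#' @examples
#' ddct_fold_change(20, 15, 21, 15)  # 0.5
#' @export
ddct_fold_change <- function(ct_target_control, ct_ref_control,
                             ct_target_treated, ct_ref_treated) {
  cts <- c(ct_target_control, ct_ref_control,
           ct_target_treated, ct_ref_treated)
  if (length(cts) != 4 || any(is.na(cts)) || any(cts <= 0)) {
    stop("all four Ct values must be present and positive", call. = FALSE)
  }
  dct_control <- ct_target_control - ct_ref_control
  dct_treated <- ct_target_treated - ct_ref_treated
  2^(-(dct_treated - dct_control))
}

#' Univariate paired screen of a feature matrix
#'
#' For every feature, tests the paired per-donor microgravity-minus-1G
#' difference with the exact Wilcoxon signed-rank test, then flags
#' discoveries with the BKY two-stage FDR procedure at level `q`.
#'
#' @param fm a `feature_matrix` with both gravity conditions per donor.
#' @param q FDR level (default 0.01).
#' @return data.frame: feature, subset, marker, statistic, p, discovery.
#' @export
univariate_screen <- function(fm, q = 0.01) {
  rm_ <- attr(fm, "row_meta")
  cm <- attr(fm, "col_meta")
  donors <- sort(unique(rm_$donor))
  i_ug <- match(paste(donors, "uG", sep = "|"), rownames(fm))
  i_1g <- match(paste(donors, "1G", sep = "|"), rownames(fm))
  if (any(is.na(i_ug)) || any(is.na(i_1g))) {
    stop("every donor needs both gravity conditions", call. = FALSE)
  }
  X <- unclass(fm)
  res <- data.frame(feature = colnames(fm), subset = cm$subset,
                    marker = cm$marker, statistic = NA_real_, p = NA_real_,
                    stringsAsFactors = FALSE)
  for (j in seq_len(ncol(X))) {
    diffs <- X[i_ug, j] - X[i_1g, j]
    diffs <- diffs[!is.na(diffs)]
    if (length(diffs) == 0 || all(diffs == 0)) next
    t <- wilcoxon_signed_rank_exact(diffs)
    res$statistic[j] <- t$statistic
    res$p[j] <- t$p_two_sided
  }
  ok <- !is.na(res$p)
  res$discovery <- FALSE
  if (any(ok)) {
    res$discovery[ok] <- bky_two_stage_fdr(res$p[ok], q)$discoveries
  }
  res
}
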