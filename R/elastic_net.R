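#' Elastic-net objective value
#'
#' Evaluates the penalized residual sum of squares
#' `|Y - intercept - X beta|^2 + lambda1 * |beta|_1 + lambda2 * |beta|_2^2`.
#' The ridge term uses the squared L2 norm, the form under which exact
#' coordinate-wise soft-threshold minimization applies; `ridge = "literal"`
#' evaluates the unsquared norm `lambda2 * |beta|_2` for reporting purposes
#' only (it is never the optimization target).
#'
#' @param X numeric matrix (n x p).
#' @param Y numeric response vector (length n).
#' @param beta coefficient vector (length p).
#' @param lambda1,lambda2 nonnegative penalties.
#' @param intercept scalar offset (default 0).
#' @param ridge `"squared"` (default) or `"literal"`.
#' @return Scalar objective value.
#' @export
en_objective <- function(X, Y, beta, lambda1, lambda2, intercept = 0,
                         ridge = c("squared", "literal")) {
  ridge <- match.arg(ridge)
  if (!is.matrix(X) || nrow(X) != length(Y) || ncol(X) != length(beta)) {
    stop("X, Y, beta have incompatible shapes", call. = FALSE)
  }
  stopifnot(lambda1 >= 0, lambda2 >= 0)
  r <- Y - intercept - drop(X %*% beta)
  pen2 <- if (ridge == "squared") sum(beta^2) else sqrt(sum(beta^2))
  sum(r^2) + lambda1 * sum(abs(beta)) + lambda2 * pen2
}

#' Fit an elastic net by cyclic coordinate descent
#'
#' Minimizes `|Yc - Xs beta|^2 + lambda1 |beta|_1 + lambda2 |beta|_2^2`
#' where `Xs` has internally standardized columns (mean 0, unit variance)
#' and `Yc` is centered. Each coordinate update is the exact minimizer
#' `beta_j = S(x_j' r + ||x_j||^2 beta_j, lambda1/2) / (||x_j||^2 +
#' lambda2)`, so the objective is non-increasing across sweeps. Iteration
#' stops when the largest coefficient change in a sweep falls below `tol`.
#' KKT subgradient residuals are checked at exit; a non-converged fit is
#' flagged, never silent.
#'
#' @param X numeric matrix (n x p), n >= 2.
#' @param Y numeric response.
#' @param lambda1,lambda2 nonnegative penalties (on the standardized scale).
#' @param tol convergence tolerance on max coefficient change
#'   (default 1e-8).
#' @param max_sweeps sweep cap (default 1e5).
#' @param warm_start optional initial beta (standardized scale).
#' @return An `en_fit`: `beta` (standardized scale), `beta_raw` (original
#'   scale), `intercept` (original scale), `lambda1`, `lambda2`,
#'   `objective` (on the standardized training data), `n_nonzero`,
#'   `converged`, `sweeps`, `kkt_max`, plus the centering/scaling record.
#' @export
fit_en <- function(X, Y, lambda1, lambda2, tol = 1e-8, max_sweeps = 1e5,
                   warm_start = NULL) {
  if (!all(is.finite(X)) || !all(is.finite(Y))) {
    stop("X and Y must be finite", call. = FALSE)
  }
  n <- nrow(X); p <- ncol(X)
  stopifnot(n >= 2, length(Y) == n, lambda1 >= 0, lambda2 >= 0)
  center <- colMeans(X)
  scale_ <- apply(X, 2, stats::sd)
  scale_[scale_ == 0] <- 1   # constant columns stay zero after centering
  Xs <- sweep(sweep(X, 2, center), 2, scale_, "/")
  ybar <- mean(Y)
  Yc <- Y - ybar
  xtx <- colSums(Xs^2)

  beta0 <- if (is.null(warm_start)) numeric(p) else warm_start
  stopifnot(length(beta0) == p)
  cd <- .cd_fit(Xs, Yc, xtx, lambda1, lambda2, tol, max_sweeps, beta0)
  beta <- cd$beta
  r <- cd$residual
  converged <- cd$converged
  sweeps <- cd$sweeps
  # KKT: grad_j = -2 x_j'r + 2 lambda2 beta_j; subgradient of lambda1|b|
  grad <- -2 * drop(crossprod(Xs, r)) + 2 * lambda2 * beta
  kkt <- ifelse(beta != 0, abs(grad + lambda1 * sign(beta)),
                pmax(abs(grad) - lambda1, 0))
  if (!converged) {
    warning("coordinate descent did not converge in ", max_sweeps,
            " sweeps (max KKT residual ", format(max(kkt), digits = 3),
            ")")
  }
  beta_raw <- beta / scale_
  structure(list(
    beta = beta, beta_raw = beta_raw,
    intercept = ybar - sum(beta_raw * center),
    lambda1 = lambda1, lambda2 = lambda2,
    objective = en_objective(Xs, Yc, beta, lambda1, lambda2),
    n_nonzero = sum(beta != 0),
    converged = converged, sweeps = sweeps, kkt_max = max(kkt),
    center = center, scale = scale_, y_mean = ybar,
    features = colnames(X)
  ), class = "en_fit")
}

#' @export
print.en_fit <- function(x, ...) {
  cat("<en_fit> lambda1 = ", format(x$lambda1, digits = 4),
      ", lambda2 = ", format(x$lambda2, digits = 4), ", ",
      x$n_nonzero, " nonzero of ", length(x$beta),
      " coefficients, objective = ", format(x$objective, digits = 6),
      "\n", sep = "")
  invisible(x)
}

#' @export
predict.en_fit <- function(object, newdata, ...) {
  object$intercept + drop(as.matrix(newdata) %*% object$beta_raw)
}

#' Smallest lambda1 with an all-zero solution
#'
#' On standardized columns and centered response, beta = 0 is optimal iff
#' `lambda1 >= 2 * max |Xs' (Y - mean(Y))|`.
#'
#' @param X,Y as in [fit_en()].
#' @return Scalar lambda1 bound.
#' @export
lambda1_max <- function(X, Y) {
  center <- colMeans(X)
  scale_ <- apply(X, 2, stats::sd)
  scale_[scale_ == 0] <- 1
  Xs <- sweep(sweep(X, 2, center), 2, scale_, "/")
  2 * max(abs(crossprod(Xs, Y - mean(Y))))
}

#' Cross-validated penalty path with leave-one-donor-out folds
#'
#' Encodes the two penalties as an overall level and a mixing fraction
#' (`lambda1 = mixing * lambda`, `lambda2 = (1 - mixing) * lambda`) and
#' evaluates a log-spaced lambda grid by leave-one-donor-out
#' cross-validation: both of a donor's rows (1G and microgravity) are held
#' out together, features are standardized inside each training fold only,
#' and the fold error is the misclassification rate of the sign of the
#' held-out scores after centering within the donor pair (a zero centered
#' score counts 1/2). Two penalties bracketing the optimal region are
#' reported, as the two dotted lines of the classical CV error-curve plot:
#' `lambda_min`, the smallest penalty attaining the minimal mean CV error
#' (the dense, discovery-oriented end), and `lambda_1se`, the largest
#' penalty whose error is within one standard error of that minimum (the
#' parsimonious end); warm-started full-data fits at both are included.
#'
#' @param X feature matrix (rows = donor x gravity units).
#' @param Y numeric response in `{-1, +1}` (1G = -1, microgravity = +1).
#' @param donors character vector of donor ids per row.
#' @param lambda_grid decreasing lambda grid; computed from the data when
#'   `NULL` (log-spaced, `n_lambda` points spanning `decades` decades below
#'   the all-zero bound).
#' @param mixing L1 fraction in (0, 1]; default 0.5.
#' @param n_lambda,decades grid shape when `lambda_grid` is `NULL`.
#' @param seed retained in the fold record for provenance (the fold scheme
#'   itself is deterministic).
#' @param tol,max_sweeps passed to [fit_en()].
#' @return A `cv_result`: `lambda_grid`, `cv_mean`, `cv_sd`, `cv_se`,
#'   `lambda_min`, `lambda_1se`, `fold_errors` (fold x lambda),
#'   `oof_scores` (row x lambda out-of-fold scores), `fit_min`, `fit_1se`,
#'   `degenerate` flag (flat error curve), `folds`, `mixing`, `seed`.
#' @export
cv_lambda_path <- function(X, Y, donors, lambda_grid = NULL, mixing = 0.5,
                           n_lambda = 50, decades = 4, seed = NULL,
                           tol = 1e-8, max_sweeps = 1e5) {
  X <- as.matrix(X)
  stopifnot(length(Y) == nrow(X), length(donors) == nrow(X))
  if (!all(Y %in% c(-1, 1))) {
    stop("Y must be coded -1 (1G) / +1 (microgravity)", call. = FALSE)
  }
  uds <- sort(unique(donors))
  if (length(uds) < 3) stop("need at least 3 donors", call. = FALSE)
  for (d in uds) {
    if (!setequal(Y[donors == d], c(-1, 1))) {
      stop("donor ", d, " lacks one of the two gravity conditions",
           call. = FALSE)
    }
  }
  if (mixing <= 0 || mixing > 1) {
    stop("mixing must be in (0, 1]", call. = FALSE)
  }
  if (is.null(lambda_grid)) {
    lmax <- lambda1_max(X, Y) / mixing
    if (lmax <= 0) lmax <- 1
    lambda_grid <- exp(seq(log(lmax), log(lmax) - decades * log(10),
                           length.out = n_lambda))
  }
  nl <- length(lambda_grid)
  oof <- matrix(NA_real_, nrow(X), nl)
  fold_err <- matrix(NA_real_, length(uds), nl,
                     dimnames = list(uds, NULL))
  for (fi in seq_along(uds)) {
    hold <- donors == uds[fi]
    oof[hold, ] <- en_path_scores(X, Y, hold, lambda_grid, mixing, tol,
                                  max_sweeps)
    fold_err[fi, ] <- en_pair_error(oof[hold, , drop = FALSE], Y[hold])
  }
  cv_mean <- colMeans(fold_err)
  cv_sd <- apply(fold_err, 2, stats::sd)
  cv_se <- cv_sd / sqrt(length(uds))
  # the two selected penalties bracket the optimal region: lambda_min is
  # the smallest penalty attaining the minimal CV error (dense,
  # discovery-oriented end), lambda_1se the largest penalty within one
  # standard error of it (parsimonious end)
  i_min <- max(which(cv_mean == min(cv_mean)))
  within <- which(cv_mean <= cv_mean[i_min] + cv_se[i_min])
  i_1se <- min(within)                          # grid is decreasing
  degenerate <- diff(range(cv_mean)) == 0
  if (degenerate) {
    warning("flat cross-validation error curve; lambda selection is ",
            "degenerate")
  }
  # full-data fits, warm-started down the path like the fold fits
  fits <- vector("list", max(i_min, i_1se))
  warm <- NULL
  for (li in seq_len(max(i_min, i_1se))) {
    fits[[li]] <- fit_en(X, Y, mixing * lambda_grid[li],
                         (1 - mixing) * lambda_grid[li],
                         tol = tol, max_sweeps = max_sweeps,
                         warm_start = warm)
    warm <- fits[[li]]$beta
  }
  fit_at <- function(i) fits[[i]]
  structure(list(
    lambda_grid = lambda_grid, cv_mean = cv_mean, cv_sd = cv_sd,
    cv_se = cv_se,
    lambda_min = lambda_grid[i_min], lambda_1se = lambda_grid[i_1se],
    i_min = i_min, i_1se = i_1se,
    fold_errors = fold_err, oof_scores = oof,
    fit_min = fit_at(i_min), fit_1se = fit_at(i_1se),
    degenerate = degenerate, folds = donors, Y = Y, X = X,
    mixing = mixing, tol = tol, max_sweeps = max_sweeps, seed = seed
  ), class = "cv_result")
}

# fit the penalty path on the rows with hold == FALSE (warm-started) and
# return the held-out rows' scores, one column per lambda
en_path_scores <- function(X, Y, hold, lambda_grid, mixing, tol,
                           max_sweeps) {
  out <- matrix(NA_real_, sum(hold), length(lambda_grid))
  warm <- NULL
  for (li in seq_along(lambda_grid)) {
    fit <- fit_en(X[!hold, , drop = FALSE], Y[!hold],
                  mixing * lambda_grid[li],
                  (1 - mixing) * lambda_grid[li],
                  tol = tol, max_sweeps = max_sweeps, warm_start = warm)
    warm <- fit$beta
    out[, li] <- predict(fit, X[hold, , drop = FALSE])
  }
  out
}

# misclassification of the sign of scores centered within the held-out
# donor pair; a zero centered score counts 1/2
en_pair_error <- function(scores, y) {
  sc <- sweep(scores, 2, colMeans(scores))
  colMeans(ifelse(sc == 0, 0.5, (sign(sc) != y) * 1))
}

#' @export
print.cv_result <- function(x, ...) {
  cat("<cv_result> ", length(x$lambda_grid), "-point lambda path, ",
      length(unique(x$folds)), " leave-one-donor-out folds\n",
      "  lambda_min = ", format(x$lambda_min, digits = 4),
      " (cv error ", format(x$cv_mean[x$i_min], digits = 3), "), ",
      "lambda_1se = ", format(x$lambda_1se, digits = 4),
      " (cv error ", format(x$cv_mean[x$i_1se], digits = 3), ")\n",
      sep = "")
  invisible(x)
}

#' Paired model significance from out-of-fold scores
#'
#' For each donor, the difference between the out-of-fold model scores of
#' the microgravity and 1G rows is tested with the exact Wilcoxon
#' signed-rank test: under the null of no gravity signal the paired score
#' differences are symmetric about zero.
#'
#' With `which = "nested"` (the default) each donor's score is taken at a
#' penalty selected by an *inner* leave-one-donor-out cross-validation on
#' the remaining donors only (the 1-SE rule applied to the inner error
#' curve). This pre-validated selection keeps the paired test calibrated:
#' picking the penalty from the same folds that produced the scores would
#' favor, under the null, whichever penalty happened to classify the pairs
#' well, inflating the rejection rate several-fold. Inner training sets
#' (all donors minus a pair) are shared across outer folds, so the extra
#' cost is about one additional path per donor pair. `"1se"` and `"min"`
#' use the globally selected penalties and are provided for descriptive
#' use.
#'
#' @param cv a `cv_result`.
#' @param which `"nested"` (default), `"1se"` or `"min"`.
#' @return A `model_significance`: `scores` data.frame (donor, score_1g,
#'   score_ug, diff, lambda used), `test` (a `paired_test`), `which`.
#' @export
model_significance <- function(cv, which = c("nested", "1se", "min")) {
  which <- match.arg(which)
  donors <- sort(unique(cv$folds))
  li_by_donor <- if (which == "nested") {
    nested_lambda_indices(cv)
  } else {
    rep(if (which == "1se") cv$i_1se else cv$i_min, length(donors))
  }
  s_ug <- s_1g <- numeric(length(donors))
  for (i in seq_along(donors)) {
    sel <- cv$folds == donors[i]
    s_ug[i] <- cv$oof_scores[sel & cv$Y == 1, li_by_donor[i]]
    s_1g[i] <- cv$oof_scores[sel & cv$Y == -1, li_by_donor[i]]
  }
  diffs <- s_ug - s_1g
  test <- wilcoxon_signed_rank_exact(diffs)
  structure(list(
    scores = data.frame(donor = donors, score_1g = s_1g, score_ug = s_ug,
                        diff = diffs,
                        lambda = cv$lambda_grid[li_by_donor],
                        stringsAsFactors = FALSE),
    test = test, which = which
  ), class = "model_significance")
}

# per-donor penalty index from inner leave-one-donor-out CV on the other
# donors; fits on "all minus a donor pair" are computed once per pair
nested_lambda_indices <- function(cv) {
  donors <- sort(unique(cv$folds))
  nd <- length(donors)
  nl <- length(cv$lambda_grid)
  # pair_scores[[a]][[b]]: scores of donor b's rows from the fit without
  # donors a and b (symmetric in construction, both directions filled)
  pair_scores <- lapply(seq_len(nd), function(i) vector("list", nd))
  for (a in seq_len(nd - 1)) for (b in (a + 1):nd) {
    hold_a <- cv$folds == donors[a]
    hold_b <- cv$folds == donors[b]
    sc <- en_path_scores(cv$X, cv$Y, hold_a | hold_b, cv$lambda_grid,
                         cv$mixing, cv$tol, cv$max_sweeps)
    held <- which(hold_a | hold_b)
    pair_scores[[a]][[b]] <- sc[held %in% which(hold_b), , drop = FALSE]
    pair_scores[[b]][[a]] <- sc[held %in% which(hold_a), , drop = FALSE]
  }
  vapply(seq_len(nd), function(d) {
    inner <- setdiff(seq_len(nd), d)
    err <- t(vapply(inner, function(e) {
      en_pair_error(pair_scores[[d]][[e]],
                    cv$Y[cv$folds == donors[e]])
    }, numeric(nl)))
    m <- colMeans(err)
    se <- apply(err, 2, stats::sd) / sqrt(length(inner))
    i_min <- max(which(m == min(m)))
    min(which(m <= m[i_min] + se[i_min]))
  }, 0L)
}

#' @export
print.model_significance <- function(x, ...) {
  cat("<model_significance> lambda_", x$which, " model: ", sep = "")
  print(x$test)
  invisible(x)
}

#' Ranked elastic-net component report
#'
#' Tabulates the nonzero model coefficients together with the univariate
#' screen and (optionally) correlation-network community of each feature.
#' The sign of a coefficient is its direction in microgravity relative to
#' 1G under the `{-1, +1}` response coding. Rows are sorted by discovery
#' flag, then raw p, then decreasing `|beta|`.
#'
#' @param fit an `en_fit`.
#' @param univariate data.frame from [univariate_screen()] over the same
#'   features (optional).
#' @param communities named integer vector of community labels (optional).
#' @return data.frame: feature, subset, marker, beta, direction, abs_beta,
#'   p, discovery, community.
#' @export
component_report <- function(fit, univariate = NULL, communities = NULL) {
  feats <- fit$features
  if (is.null(feats)) feats <- paste0("V", seq_along(fit$beta))
  sel <- fit$beta != 0
  parts <- strsplit(feats[sel], "|", fixed = TRUE)
  rep_ <- data.frame(
    feature = feats[sel],
    subset = vapply(parts, `[`, "", 1),
    marker = vapply(parts, function(p) if (length(p) >= 2) p[2] else "", ""),
    beta = fit$beta_raw[sel],
    direction = ifelse(fit$beta[sel] > 0, "increased-in-uG",
                       "decreased-in-uG"),
    abs_beta = abs(fit$beta[sel]),
    stringsAsFactors = FALSE)
  if (!is.null(univariate)) {
    if (!all(rep_$feature %in% univariate$feature)) {
      stop("univariate screen does not cover the model features",
           call. = FALSE)
    }
    m <- match(rep_$feature, univariate$feature)
    rep_$p <- univariate$p[m]
    rep_$discovery <- univariate$discovery[m]
  } else {
    rep_$p <- rep(NA_real_, nrow(rep_))
    rep_$discovery <- rep(NA, nrow(rep_))
  }
  rep_$community <- if (!is.null(communities)) {
    as.integer(communities[rep_$feature])
  } else rep(NA_integer_, nrow(rep_))
  ord <- order(!rep_$discovery, rep_$p, -rep_$abs_beta, rep_$feature,
               na.last = TRUE)
  rep_ <- rep_[ord, , drop = FALSE]
  rownames(rep_) <- NULL
  rep_
}
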