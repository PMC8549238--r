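#' Sample correlation matrix of standardized intakes
#'
#' @param standardized data.frame from [standardize_intakes()] (`subject_id`
#'   plus z-score columns).
#' @return Symmetric correlation matrix with unit diagonal, dimnames set to
#'   the food-group labels.
#' @export
sample_correlation <- function(standardized) {
  cols <- setdiff(names(standardized), "subject_id")
  x <- as.matrix(standardized[cols])
  if (nrow(x) < 2) stop("need at least 2 subjects")
  if (any(apply(x, 2, sd) == 0)) stop("constant column(s) present")
  S <- cor(x)
  dimnames(S) <- list(cols, cols)
  S
}

#' Graphical lasso: L1-penalised sparse precision estimation
#'
#' Maximizes `log det(Omega) - trace(S Omega) - lambda * sum_{i != j}
#' |omega_ij|` by block coordinate descent over rows (each row update solves a
#' lasso subproblem by coordinate descent). The penalty applies to
#' off-diagonal elements only unless `penalize_diagonal = TRUE`. At
#' `lambda = 0` the solution is the inverse of `S` (which must then be
#' non-singular); for `lambda >= max |S_ij|` off-diagonal the solution is
#' exactly diagonal.
#'
#' @param S symmetric correlation (or covariance) matrix.
#' @param lambda penalty, >= 0.
#' @param penalize_diagonal include diagonal elements in the penalty.
#' @param maxit maximum number of full sweeps (default 500).
#' @param tol convergence: maximum elementwise change in the working
#'   covariance per sweep (default 1e-6).
#' @param zero_mask optional logical/0-1 matrix; off-diagonal precision
#'   entries where it is FALSE/0 are constrained to exactly zero. With
#'   `lambda = 0` this gives the maximum-likelihood estimate restricted to a
#'   given edge support (used to undo lasso shrinkage after selection).
#' @return Object of class `precision_fit`: `omega`, `w` (estimated
#'   covariance), `lambda`, `iterations`, `converged`, `max_change`.
#' @export
graphical_lasso <- function(S, lambda, penalize_diagonal = FALSE,
                            maxit = 500, tol = 1e-6, zero_mask = NULL) {
  S <- as.matrix(S)
  if (!isSymmetric(S, tol = 1e-8)) stop("S must be symmetric")
  if (lambda < 0) stop("lambda must be >= 0")
  if (lambda == 0 && is.null(zero_mask)) {
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < .Machine$double.eps * nrow(S) * max(ev)) {
      stop("S is singular at lambda = 0; use a positive penalty")
    }
  }
  if (!is.null(zero_mask)) {
    zero_mask <- matrix(as.integer(zero_mask != 0), nrow(S), ncol(S))
  }
  fit <- glasso_cd(S, lambda, penalize_diagonal, as.integer(maxit), tol,
                   zero_mask)
  if (!fit$converged) {
    stop("graphical lasso did not converge after ", maxit,
         " sweeps (max change ", format(fit$max_change), ") at lambda = ",
         lambda)
  }
  omega <- fit$omega
  dimnames(omega) <- dimnames(S)
  structure(
    list(omega = omega, w = fit$w, lambda = lambda,
         iterations = fit$iterations, converged = fit$converged,
         max_change = fit$max_change),
    class = "precision_fit")
}

#' @export
print.precision_fit <- function(x, ...) {
  nz <- sum(abs(x$omega[upper.tri(x$omega)]) > 1e-10)
  cat("Graphical lasso fit: p =", ncol(x$omega), " lambda =", x$lambda,
      "\n  nonzero off-diagonal pairs:", nz,
      "\n  sweeps:", x$iterations, " converged:", x$converged, "\n")
  invisible(x)
}

ggm_loglik <- function(omega, S, n) {
  n / 2 * (determinant(omega, logarithm = TRUE)$modulus[1] -
             sum(S * omega))
}

#' Select the graphical-lasso penalty by extended BIC
#'
#' Fits the graphical lasso down a descending penalty grid and picks the
#' penalty minimizing `EBIC = -2 loglik + k log n + 4 k gamma log p`, where
#' `k` counts nonzero upper-triangle off-diagonal precision elements
#' (numerical zero 1e-10). The log-likelihood is evaluated at the
#' maximum-likelihood estimate *restricted to the selected support* (the
#' penalized estimate's zero pattern refitted with `lambda = 0`), so lasso
#' shrinkage does not bias the criterion toward denser graphs. Ties go to
#' the larger (sparser) penalty. The default grid has 30 log-spaced points
#' from `max |S_ij|` down two decades.
#'
#' @param standardized data.frame from [standardize_intakes()].
#' @param lambda_grid descending penalty grid; NULL for the default.
#' @param gamma EBIC weight in `[0, 1]` (default 0.5).
#' @param n_lambda grid size when the default grid is used.
#' @return list of class `penalty_selection`: `lambda` (chosen), `fit` (the
#'   penalized `precision_fit` at the chosen penalty), `refit` (the
#'   support-restricted MLE, whose partial correlations are unshrunk),
#'   `table` (per-penalty EBIC diagnostics).
#' @export
select_penalty <- function(standardized, lambda_grid = NULL, gamma = 0.5,
                           n_lambda = 30) {
  if (gamma < 0 || gamma > 1) stop("gamma must be in [0, 1]")
  S <- sample_correlation(standardized)
  n <- nrow(standardized)
  p <- ncol(S)
  if (is.null(lambda_grid)) {
    lmax <- max(abs(S[upper.tri(S)]))
    lambda_grid <- exp(seq(log(lmax), log(lmax / 100), length.out = n_lambda))
  }
  if (!length(lambda_grid)) stop("lambda_grid must be nonempty")
  if (is.unsorted(rev(lambda_grid), strictly = FALSE)) {
    stop("lambda_grid must be descending")
  }
  rows <- vector("list", length(lambda_grid))
  fits <- vector("list", length(lambda_grid))
  refits <- vector("list", length(lambda_grid))
  refit_cache <- list()
  errs <- character(0)
  for (i in seq_along(lambda_grid)) {
    lam <- lambda_grid[i]
    fit <- tryCatch(graphical_lasso(S, lam), error = function(e) e)
    if (inherits(fit, "error")) {
      errs <- c(errs, sprintf("lambda=%.4g: %s", lam, conditionMessage(fit)))
      next
    }
    support <- abs(fit$omega) > 1e-10
    key <- paste0("s:", paste(which(support[upper.tri(support)]),
                              collapse = ","))
    if (is.null(refit_cache[[key]])) {
      refit_cache[[key]] <- tryCatch(
        graphical_lasso(S, 0, zero_mask = support),
        error = function(e) e)
    }
    refit <- refit_cache[[key]]
    if (inherits(refit, "error")) {
      errs <- c(errs, sprintf("lambda=%.4g (refit): %s", lam,
                              conditionMessage(refit)))
      next
    }
    k <- sum(support[upper.tri(support)])
    ebic <- -2 * ggm_loglik(refit$omega, S, n) + k * log(n) +
      4 * k * gamma * log(p)
    rows[[i]] <- data.frame(lambda = lam, k = k, ebic = ebic)
    fits[[i]] <- fit
    refits[[i]] <- refit
  }
  ok <- !vapply(rows, is.null, logical(1))
  if (!any(ok)) {
    stop("all penalties failed:\n", paste(errs, collapse = "\n"))
  }
  tab <- do.call(rbind, rows[ok])
  fits <- fits[ok]
  refits <- refits[ok]
  # grid is descending, which.min takes the first (largest lambda) on ties
  best <- which.min(tab$ebic)
  structure(
    list(lambda = tab$lambda[best], fit = fits[[best]],
         refit = refits[[best]], table = tab, gamma = gamma, n = n),
    class = "penalty_selection")
}

#' Convert a precision matrix to a partial-correlation network
#'
#' Partial correlations are `rho_ij = -omega_ij / sqrt(omega_ii * omega_jj)`
#' with unit diagonal. An edge exists wherever `|omega_ij| > 1e-10`; edges
#' with `|rho| >= strong_threshold` are flagged strong. Positive partial
#' correlations mean positive conditional association (drawn as solid edges in
#' the field's network figures; negative as dashed).
#'
#' @param omega precision matrix, a `precision_fit`, or a
#'   `planted_precision`.
#' @param nodes node labels; defaults to `colnames(omega)` or `V1`...
#' @param strong_threshold magnitude flagged as a strong conditional
#'   association (default 0.20).
#' @return Object of class `pcor_network`: `nodes`, `rho` (matrix), `edges`
#'   (data.frame: from, to, i, j, partial_correlation, sign, strong).
#' @export
precision_to_partial <- function(omega, nodes = NULL, strong_threshold = 0.20) {
  if (inherits(omega, "precision_fit")) omega <- omega$omega
  if (inherits(omega, "planted_precision")) omega <- omega$omega
  omega <- as.matrix(omega)
  if (any(diag(omega) <= 0)) stop("precision diagonal must be positive")
  p <- ncol(omega)
  if (is.null(nodes)) {
    nodes <- colnames(omega)
    if (is.null(nodes)) nodes <- sprintf("V%d", seq_len(p))
  }
  d <- sqrt(diag(omega))
  rho <- -omega / outer(d, d)
  diag(rho) <- 1
  dimnames(rho) <- list(nodes, nodes)
  idx <- which(upper.tri(omega) & abs(omega) > 1e-10, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  pc <- rho[idx]
  edges <- data.frame(
    from = nodes[idx[, 1]], to = nodes[idx[, 2]],
    i = idx[, 1], j = idx[, 2],
    partial_correlation = pc,
    sign = ifelse(pc >= 0, "positive", "negative"),
    strong = abs(pc) >= strong_threshold,
    stringsAsFactors = FALSE)
  structure(list(nodes = nodes, rho = rho, edges = edges,
                 strong_threshold = strong_threshold),
            class = "pcor_network")
}

#' @export
print.pcor_network <- function(x, ...) {
  cat("Partial-correlation network:", length(x$nodes), "food groups,",
      nrow(x$edges), "edges (", sum(x$edges$strong), "strong at |rho| >=",
      x$strong_threshold, ")\n")
  invisible(x)
}

#' Write a partial-correlation edge list to CSV
#'
#' @param network a `pcor_network`.
#' @param file output path.
#' @export
write_edge_list <- function(network, file) {
  write.csv(network$edges[c("from", "to", "partial_correlation",
                            "sign", "strong")],
            file, row.names = FALSE)
}
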