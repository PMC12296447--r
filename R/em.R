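#' Assign cells to parameter-sharing pools
#'
#' Model parameters (abundance `pi`, reassignment `theta`) are estimated per
#' pool of cells: every cell alone (`individual`), all cells together
#' (`pseudobulk`), or per user-provided label (`celltype`).
#'
#' @param barcodes character vector of cell barcodes (the cells in the
#'   model).
#' @param mode one of `"individual"`, `"pseudobulk"`, `"celltype"`.
#' @param labels named character vector (or 2-column data.frame barcode,
#'   label) mapping each barcode to its cell-type label; required for
#'   `celltype` mode.
#' @return a `te_pools` object: list with `mode`, `pools` (pool ids) and
#'   `cell_to_pool` (named character vector).
#' @export
assign_pools <- function(barcodes, mode = c("pseudobulk", "individual", "celltype"),
                         labels = NULL) {
  mode <- match.arg(mode)
  barcodes <- unique(barcodes)
  cell_to_pool <- switch(mode,
    individual = setNames(barcodes, barcodes),
    pseudobulk = setNames(rep("pool1", length(barcodes)), barcodes),
    celltype = {
      if (is.null(labels)) stop("celltype mode requires a cell label mapping")
      if (is.data.frame(labels)) {
        labels <- setNames(as.character(labels[[2L]]), as.character(labels[[1L]]))
      }
      missing <- setdiff(barcodes, names(labels))
      if (length(missing)) {
        stop("celltype labels missing for barcodes: ",
             paste(utils::head(missing, 10L), collapse = ", "),
             if (length(missing) > 10L) sprintf(" (and %d more)", length(missing) - 10L))
      }
      setNames(as.character(labels[barcodes]), barcodes)
    }
  )
  pools <- unique(unname(cell_to_pool))
  structure(list(mode = mode, pools = pools, cell_to_pool = cell_to_pool),
            class = "te_pools")
}

#' @exportS3Method base::print
print.te_pools <- function(x, ...) {
  cat("te_pools: mode=", x$mode, ", ", length(x$pools), " pool(s), ",
      length(x$cell_to_pool), " cell(s)\n", sep = "")
  invisible(x)
}

# map matrix rows to pool indices; errors on barcodes absent from the pools
row_pool_index <- function(wm, pools) {
  p <- pools$cell_to_pool[wm$fragments$cb]
  if (anyNA(p)) {
    stop("fragments from barcodes without a pool assignment: ",
         paste(utils::head(unique(wm$fragments$cb[is.na(p)]), 5L), collapse = ", "))
  }
  match(unname(p), pools$pools)
}

new_model_params <- function(pi, theta, pools, features) {
  structure(list(pi = pi, theta = theta, pools = pools, features = features),
            class = "te_model_params")
}

uniform_params <- function(pools, feature_cols) {
  D <- length(pools)
  Kp1 <- length(feature_cols)
  m <- matrix(1 / Kp1, nrow = D, ncol = Kp1,
              dimnames = list(pools, feature_cols))
  new_model_params(m, m, pools, feature_cols)
}

#' Marginal probability of one fragment under the mixture
#'
#' `Pr(f_i, b_i | pi_P, theta_P, q_i) = sum_j pi_Pj * theta_Pj^y_i * q_ij`
#' over the fragment's candidate features, where `P` is the pool of the
#' fragment's cell and `y_i` indicates an ambiguously aligned fragment
#' (unique fragments bypass `theta`).
#'
#' @param params a `te_model_params`.
#' @param pool pool id.
#' @param q named numeric vector of nonzero alignment weights (names are
#'   feature columns, including possibly the no-feature column).
#' @param y 0/1 ambiguity indicator.
#' @return scalar probability.
#' @export
fragment_probability <- function(params, pool, q, y) {
  if (length(q) == 0L || all(q == 0)) stop("fragment has an all-zero weight row")
  j <- names(q)
  pi_ <- params$pi[pool, j]
  th <- if (y == 1) params$theta[pool, j] else rep(1, length(j))
  sum(pi_ * th * q)
}

#' E-step: posterior membership weights
#'
#' For each fragment the posterior over its candidate features is
#' proportional to `pi_Pj * theta_Pj^y_i * q_ij`, normalized to sum to one;
#' the sparsity pattern of the weight matrix is preserved (a fragment has
#' zero posterior mass on features it does not align to). Rows whose every
#' term vanishes under the current parameters are renormalized over `q`
#' alone with a warning.
#'
#' @param params a `te_model_params`.
#' @param wm a `te_weight_matrix`.
#' @param pools a `te_pools`.
#' @return sparse `dgCMatrix` of posteriors, same shape as `wm$weights`.
#' @export
e_step <- function(params, wm, pools) {
  p_idx <- row_pool_index(wm, pools)
  s <- Matrix::summary(wm$weights)
  y <- wm$fragments$y[s$i]
  pr <- params$pi[cbind(p_idx[s$i], s$j)] *
    ifelse(y == 1L, params$theta[cbind(p_idx[s$i], s$j)], 1) * s$x
  tot <- numeric(nrow(wm$weights))
  agg <- rowsum(pr, s$i)
  tot[as.integer(rownames(agg))] <- agg[, 1L]
  tot_model <- tot
  dead <- tot == 0
  if (any(dead)) {
    warning(sum(dead), " fragment(s) had zero probability under current ",
            "parameters; renormalizing over alignment weights alone")
    qtot <- numeric(nrow(wm$weights))
    aggq <- rowsum(s$x, s$i)
    qtot[as.integer(rownames(aggq))] <- aggq[, 1L]
    pr[dead[s$i]] <- s$x[dead[s$i]]
    tot[dead] <- qtot[dead]
  }
  out <- Matrix::sparseMatrix(i = s$i, j = s$j, x = pr / tot[s$i],
                              dims = dim(wm$weights),
                              dimnames = dimnames(wm$weights))
  # observed-data log-likelihood at the supplied parameters (sum over
  # fragments of the log marginal); free by-product of the E-step
  attr(out, "obs_lnL") <- sum(log(tot_model))
  out
}

#' M-step: maximum a posteriori parameter update
#'
#' Per pool `P` with `N_P` fragments and symmetric Dirichlet pseudocounts
#' `a_pi`, `a_theta` on all `K + 1` components:
#' `pi_Pj = (sum_i x_Pij + a_pi) / (N_P + (K+1) a_pi)` and
#' `theta_Pj = (sum_i y_i x_Pij + a_theta) / (sum_i y_i + (K+1) a_theta)`.
#' The default prior `a_theta = 200000` deliberately pins `theta` near
#' uniform so that reassignment is driven by the abundances `pi`. Pools with
#' no fragments get uniform parameters and are flagged.
#'
#' @param posterior sparse posterior matrix from [e_step()].
#' @param wm a `te_weight_matrix`.
#' @param pools a `te_pools`.
#' @param pi_prior,theta_prior Dirichlet pseudocounts (defaults 0 and
#'   200000).
#' @return a `te_model_params` (attribute `empty_pools` lists pools with no
#'   fragments).
#' @export
m_step <- function(posterior, wm, pools, pi_prior = 0, theta_prior = 200000) {
  p_idx <- row_pool_index(wm, pools)
  D <- length(pools$pools)
  Kp1 <- ncol(posterior)
  N <- nrow(posterior)
  ind <- Matrix::sparseMatrix(i = seq_len(N), j = p_idx, x = 1,
                              dims = c(N, D))
  colsum <- as.matrix(Matrix::t(Matrix::crossprod(posterior, ind)))  # D x (K+1)
  n_pool <- as.vector(Matrix::colSums(ind))
  y <- wm$fragments$y
  colsum_y <- as.matrix(Matrix::t(Matrix::crossprod(
    Matrix::Diagonal(N, y) %*% posterior, ind)))
  y_pool_full <- vapply(split(y, factor(p_idx, levels = seq_len(D))),
                        sum, numeric(1))

  pi_den <- n_pool + Kp1 * pi_prior
  pi_new <- (colsum + pi_prior) / ifelse(pi_den > 0, pi_den, 1)
  th_den <- y_pool_full + Kp1 * theta_prior
  th_new <- (colsum_y + theta_prior) / ifelse(th_den > 0, th_den, 1)
  empty <- n_pool == 0
  pi_new[empty, ] <- 1 / Kp1
  th_new[th_den == 0, ] <- 1 / Kp1
  dimnames(pi_new) <- dimnames(th_new) <-
    list(pools$pools, colnames(wm$weights))
  out <- new_model_params(pi_new, th_new, pools$pools, colnames(wm$weights))
  attr(out, "empty_pools") <- pools$pools[empty]
  out
}

#' Complete-data log-likelihood
#'
#' `sum_P sum_i sum_j x_Pij * log(pi_Pj * theta_Pj^y_i * q_ij)` over entries
#' with positive posterior mass; a zero model term under positive posterior
#' yields `-Inf` with attribute `degenerate = TRUE`.
#'
#' @param params a `te_model_params`.
#' @param posterior sparse posterior matrix.
#' @param wm a `te_weight_matrix`.
#' @param pools a `te_pools`.
#' @return scalar log-likelihood.
#' @export
complete_data_log_likelihood <- function(params, posterior, wm, pools) {
  p_idx <- row_pool_index(wm, pools)
  sx <- Matrix::summary(posterior)
  sq <- Matrix::summary(wm$weights)
  q <- Matrix::sparseMatrix(i = sq$i, j = sq$j, x = sq$x, dims = dim(posterior))
  keep <- sx$x > 0
  i <- sx$i[keep]; j <- sx$j[keep]; x <- sx$x[keep]
  y <- wm$fragments$y[i]
  pi_ <- params$pi[cbind(p_idx[i], j)]
  th <- ifelse(y == 1L, params$theta[cbind(p_idx[i], j)], 1)
  qv <- q[cbind(i, j)]
  if (any(pi_ <= 0 | th <= 0 | qv <= 0)) {
    out <- -Inf
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  # sum of logs, not log of product: pi can be subnormal and the product
  # would underflow to an exact zero
  sum(x * (log(pi_) + y * log(th) + log(qv)))
}

#' Fit the pooled mixture model by EM
#'
#' Alternates [e_step()] and [m_step()] from uniform initialization until the
#' largest absolute change over all `pi` and `theta` entries falls below
#' `tol`, or `max_iter` iterations. Fragments whose only candidate is the
#' no-feature column carry no TE information; they are dropped from the fit
#' (and tallied) if present.
#'
#' @param wm a deduplicated `te_weight_matrix`.
#' @param pools a `te_pools`.
#' @param pi_prior,theta_prior Dirichlet pseudocounts (defaults 0, 200000).
#' @param max_iter maximum EM iterations (default 500).
#' @param tol convergence threshold on the parameter sup-norm change
#'   (default 1e-7).
#' @return a `te_fitted_model`: list with `params`, `posterior` (final
#'   E-step under the final parameters), `lnL` (complete-data log-likelihood
#'   at the final parameters and posterior, used for BIC/AIC), `lnL_trace`
#'   (observed-data log-likelihood per iteration -- the quantity the EM
#'   theorem guarantees non-decreasing; the complete-data value is not
#'   monotone in general), `iterations`, `converged`, `k` (2 x observed
#'   feature columns per pool, summed), `n` (fragments fitted), `BIC`,
#'   `AIC`, `pools`.
#' @export
fit_em <- function(wm, pools, pi_prior = 0, theta_prior = 200000,
                   max_iter = 500, tol = 1e-7) {
  if (nrow(wm$fragments) == 0L) stop("cannot fit model on an empty matrix")
  n_locus <- Matrix::rowSums(wm$weights[, -1L, drop = FALSE] != 0)
  dropped <- sum(n_locus == 0L)
  if (dropped > 0L) wm <- subset_weight_matrix(wm, which(n_locus > 0L))

  params <- uniform_params(pools$pools, colnames(wm$weights))
  trace <- numeric(0)
  converged <- FALSE
  it <- 0L
  posterior <- NULL
  repeat {
    it <- it + 1L
    posterior <- e_step(params, wm, pools)
    trace <- c(trace, attr(posterior, "obs_lnL"))
    new_params <- m_step(posterior, wm, pools, pi_prior, theta_prior)
    delta <- max(abs(new_params$pi - params$pi), abs(new_params$theta - params$theta))
    params <- new_params
    if (delta < tol) { converged <- TRUE; break }
    if (it >= max_iter) break
  }
  # final posterior consistent with the returned parameters; its obs_lnL
  # closes the trace
  posterior <- e_step(params, wm, pools)
  trace <- c(trace, attr(posterior, "obs_lnL"))
  lnL <- complete_data_log_likelihood(params, posterior, wm, pools)

  p_idx <- row_pool_index(wm, pools)
  D <- length(pools$pools)
  observed <- vapply(seq_len(D), function(d) {
    rows <- which(p_idx == d)
    if (!length(rows)) return(0L)
    sum(Matrix::colSums(wm$weights[rows, , drop = FALSE] != 0) > 0L)
  }, integer(1L))
  k <- sum(2L * observed)
  n <- nrow(wm$fragments)
  fit <- structure(list(
    params = params, posterior = posterior, lnL = as.numeric(lnL),
    lnL_trace = trace, iterations = it, converged = converged,
    k = k, n = n,
    BIC = k * log(n) - 2 * as.numeric(lnL),
    AIC = 2 * k - 2 * as.numeric(lnL),
    pools = pools, observed_features = observed,
    dropped_no_feature_only = dropped
  ), class = "te_fitted_model")
  fit
}

#' @exportS3Method base::print
print.te_fitted_model <- function(x, ...) {
  cat("te_fitted_model: ", x$n, " fragments, ", length(x$pools$pools),
      " pool(s); lnL=", format(x$lnL, digits = 8),
      ", iterations=", x$iterations,
      if (x$converged) " (converged)" else " (max_iter reached)",
      "\n  k=", x$k, " n=", x$n,
      " BIC=", format(x$BIC, digits = 8), " AIC=", format(x$AIC, digits = 8),
      "\n", sep = "")
  invisible(x)
}

#' Model-selection criteria
#'
#' `BIC = k ln(n) - 2 lnL`; `AIC = 2k - 2 lnL`, with `k` the number of
#' estimated parameters (two per observed feature column per pool, summed
#' over pools) and `n` the number of fragments after UMI deduplication.
#' These allow comparing pooling modes or cell-type assignments on one
#' dataset.
#'
#' @param fitted a `te_fitted_model`, or a list with `k`, `n`, `lnL`.
#' @return named numeric vector `c(BIC=, AIC=)`.
#' @export
model_selection <- function(fitted) {
  if (is.null(fitted$n) || fitted$n == 0) stop("n must be positive")
  c(BIC = fitted$k * log(fitted$n) - 2 * fitted$lnL,
    AIC = 2 * fitted$k - 2 * fitted$lnL)
}

#' Per-pool fit report
#'
#' @param fitted a `te_fitted_model`.
#' @return data.frame, one row per pool plus model-level columns.
#' @export
fit_report <- function(fitted) {
  data.frame(
    pool = fitted$pools$pools,
    cells = as.integer(table(factor(unname(fitted$pools$cell_to_pool),
                                    levels = fitted$pools$pools))),
    observed_features = fitted$observed_features,
    iterations = fitted$iterations,
    converged = fitted$converged,
    lnL = fitted$lnL, k = fitted$k, n = fitted$n,
    BIC = fitted$BIC, AIC = fitted$AIC,
    stringsAsFactors = FALSE
  )
}
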