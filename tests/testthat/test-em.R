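pools_of <- function(wm, mode = "pseudobulk", labels = NULL) {
  assign_pools(unique(wm$fragments$cb), mode, labels)
}

test_that("pool assignment covers the three modes and validates labels", {
  bcs <- c("c1", "c2", "c3")
  pb <- assign_pools(bcs, "pseudobulk")
  expect_length(pb$pools, 1L)
  expect_equal(unname(pb$cell_to_pool), rep("pool1", 3))

  ind <- assign_pools(bcs, "individual")
  expect_length(ind$pools, 3L)
  expect_equal(unname(ind$cell_to_pool), bcs)

  ct <- assign_pools(bcs, "celltype", labels = c(c1 = "T", c2 = "T", c3 = "B"))
  expect_length(ct$pools, 2L)
  expect_equal(sum(ct$cell_to_pool == "T"), 2L)

  expect_error(assign_pools(bcs, "celltype"), "label")
  expect_error(assign_pools(bcs, "celltype", labels = c(c1 = "T")),
               "c2.*c3|c2, c3")
})

test_that("fragment_probability matches hand computations", {
  feats <- c("A", "B")
  params <- scTElocus:::new_model_params(
    pi = rbind(pool1 = c(0, 0.6, 0.4)),
    theta = rbind(pool1 = c(0, 0.7, 0.3)),
    "pool1", c(NO_FEATURE_LABEL, feats))
  colnames(params$pi) <- colnames(params$theta) <- c(NO_FEATURE_LABEL, feats)

  # unique read bypasses theta: pi_A alone
  expect_equal(fragment_probability(params, "pool1", c(A = 1), y = 0), 0.6)
  # ambiguous, equal pi/theta/q
  params2 <- scTElocus:::new_model_params(
    pi = rbind(pool1 = c(0, 0.5, 0.5)), theta = rbind(pool1 = c(0, 0.5, 0.5)),
    "pool1", c(NO_FEATURE_LABEL, feats))
  colnames(params2$pi) <- colnames(params2$theta) <- c(NO_FEATURE_LABEL, feats)
  expect_equal(fragment_probability(params2, "pool1", c(A = 1, B = 1), y = 1), 0.5)
  # 0.6*0.7*1 + 0.4*0.3*0.5 = 0.48
  expect_equal(fragment_probability(params, "pool1", c(A = 1, B = 0.5), y = 1),
               0.48)
  expect_error(fragment_probability(params, "pool1", numeric(0), 0), "zero")
})

test_that("e_step equals brute-force normalization", {
  feats <- c("A", "B")
  wm <- make_wm(list(
    list(q = c(A = 1)),                       # unique
    list(q = c(A = 1, B = 1)),                # ambiguous, equal weights
    list(q = c(A = 1, B = 0.5))               # ambiguous, unequal
  ), feats)
  pools <- pools_of(wm)
  mk <- function(pi, th) {
    p <- scTElocus:::new_model_params(rbind(pool1 = pi), rbind(pool1 = th),
                                      "pool1", c(NO_FEATURE_LABEL, feats))
    colnames(p$pi) <- colnames(p$theta) <- c(NO_FEATURE_LABEL, feats)
    p
  }
  post <- e_step(mk(c(0, 0.75, 0.25), c(1/3, 1/3, 1/3)), wm, pools)
  expect_equal(as.numeric(post[1, "A"]), 1.0)
  expect_equal(as.numeric(post[2, c("A", "B")]), c(0.75, 0.25))

  post2 <- e_step(mk(c(0, 0.5, 0.5), c(0, 0.5, 0.5)), wm, pools)
  expect_equal(as.numeric(post2[3, c("A", "B")]), c(2/3, 1/3))

  # random parameters vs per-row oracle
  set.seed(17)
  for (rep in 1:30) {
    pi <- c(0, runif(2)); pi <- pi / sum(pi)
    th <- runif(3); th <- th / sum(th)
    p <- mk(pi, th)
    post <- e_step(p, wm, pools)
    for (i in 1:3) {
      qrow <- wm$weights[i, ]
      qrow <- qrow[qrow > 0]
      pv <- setNames(as.numeric(p$pi[1, names(qrow)]), names(qrow))
      tv <- setNames(as.numeric(p$theta[1, names(qrow)]), names(qrow))
      expected <- oracle_estep(pv, tv, qrow, wm$fragments$y[i])
      expect_equal(as.numeric(post[i, names(qrow)]), unname(expected),
                   tolerance = 1e-12)
    }
  }
})

test_that("m_step reproduces closed-form updates and prior limits", {
  feats <- c("A", "B")
  # 4 fragments certain on A
  wm <- make_wm(rep(list(list(q = c(A = 1))), 4), feats)
  pools <- pools_of(wm)
  post <- e_step(scTElocus:::uniform_params("pool1", colnames(wm$weights)),
                 wm, pools)
  par <- m_step(post, wm, pools, pi_prior = 0, theta_prior = 0)
  expect_equal(unname(par$pi[1, "A"]), 1.0)

  # posteriors {A:1}, {A:.5,B:.5} -> pi (0.75, 0.25)
  wm2 <- make_wm(list(list(q = c(A = 1)), list(q = c(A = 1, B = 1))), feats)
  post2 <- Matrix::sparseMatrix(
    i = c(1, 2, 2), j = c(2, 2, 3), x = c(1, 0.5, 0.5), dims = c(2, 3),
    dimnames = dimnames(wm2$weights))
  par2 <- m_step(post2, wm2, pools_of(wm2), pi_prior = 0, theta_prior = 0)
  expect_equal(unname(par2$pi[1, c("A", "B")]), c(0.75, 0.25))
  # theta from the single ambiguous fragment
  expect_equal(unname(par2$theta[1, c("A", "B")]), c(0.5, 0.5))

  # huge theta prior forces uniformity regardless of data
  par3 <- m_step(post2, wm2, pools_of(wm2), pi_prior = 0, theta_prior = 1e12)
  expect_equal(unname(par3$theta[1, ]), rep(1/3, 3), tolerance = 1e-9)

  # parameters normalize within 1e-9
  expect_equal(unname(rowSums(par2$pi)), 1, tolerance = 1e-9)
  expect_equal(unname(rowSums(par2$theta)), 1, tolerance = 1e-9)
})

test_that("complete-data log-likelihood matches direct accumulation", {
  feats <- c("A", "B")
  wm <- make_wm(list(list(q = c(A = 1))), feats)
  pools <- pools_of(wm)
  mk <- function(piA) {
    p <- scTElocus:::new_model_params(
      rbind(pool1 = c(0, piA, 1 - piA)),
      rbind(pool1 = rep(1/3, 3)), "pool1", colnames(wm$weights))
    colnames(p$pi) <- colnames(p$theta) <- colnames(wm$weights)
    p
  }
  post <- Matrix::sparseMatrix(i = 1, j = 2, x = 1, dims = c(1, 3),
                               dimnames = dimnames(wm$weights))
  expect_equal(complete_data_log_likelihood(mk(1), post, wm, pools), 0)
  expect_equal(complete_data_log_likelihood(mk(0.5), post, wm, pools),
               log(0.5))

  # toy two-fragment instance vs oracle accumulation
  wm2 <- make_wm(list(list(q = c(A = 1, B = 0.5)), list(q = c(B = 1))), feats)
  pools2 <- pools_of(wm2)
  p <- scTElocus:::uniform_params("pool1", colnames(wm2$weights))
  post2 <- e_step(p, wm2, pools2)
  got <- complete_data_log_likelihood(p, post2, wm2, pools2)
  expect_equal(got, oracle_lnl(p$pi, p$theta, as.matrix(post2), wm2,
                               rep("pool1", 2)))

  # x > 0 on a zero-probability component flags -Inf
  pz <- scTElocus:::new_model_params(
    rbind(pool1 = c(0, 0, 1)), rbind(pool1 = rep(1/3, 3)),
    "pool1", colnames(wm$weights))
  colnames(pz$pi) <- colnames(pz$theta) <- colnames(wm$weights)
  expect_equal(complete_data_log_likelihood(pz, post, wm, pools), -Inf,
               ignore_attr = TRUE)
})

test_that("fit_em recovers empirical proportions and respects symmetry", {
  feats <- c("A", "B")
  # all unique: converges fast, pi = empirical proportions when pi_prior=0
  wm <- make_wm(c(rep(list(list(q = c(A = 1))), 3),
                  rep(list(list(q = c(B = 1))), 1)), feats)
  fit <- fit_em(wm, pools_of(wm), pi_prior = 0, theta_prior = 0)
  expect_true(fit$converged)
  expect_lte(fit$iterations, 2L)
  expect_equal(unname(fit$params$pi[1, c("A", "B")]), c(0.75, 0.25))

  # symmetric instance: identical columns keep identical parameters
  wms <- make_wm(rep(list(list(q = c(A = 1, B = 1))), 6), feats)
  fits <- fit_em(wms, pools_of(wms))
  expect_equal(unname(fits$params$pi[1, "A"]), unname(fits$params$pi[1, "B"]))

  expect_error(fit_em(make_wm(list(), feats), assign_pools("c", "pseudobulk")),
               "empty")
})

test_that("lnL trace is non-decreasing and posterior rows sum to one", {
  set.seed(202)
  for (rep in 1:25) {
    wm <- rand_wm(sample(5:50, 1), sample(2:10, 1))
    mode <- sample(c("pseudobulk", "individual"), 1)
    fit <- fit_em(wm, pools_of(wm, mode), max_iter = 200)
    expect_true(all(diff(fit$lnL_trace) >= -1e-9))
    rs <- Matrix::rowSums(fit$posterior)
    expect_equal(unname(rs), rep(1, nrow(wm$weights)), tolerance = 1e-12)
    # sparsity pattern preserved
    expect_true(all((fit$posterior != 0) * 1 <= (wm$weights != 0) * 1))
  }
})

test_that("pooling equivalences hold exactly", {
  set.seed(33)
  # one-cell dataset: pseudobulk == individual
  wm <- rand_wm(30, 5, n_cells = 1)
  f_pb <- fit_em(wm, pools_of(wm, "pseudobulk"))
  f_in <- fit_em(wm, pools_of(wm, "individual"))
  expect_equal(unname(f_pb$params$pi), unname(f_in$params$pi), tolerance = 1e-12)
  expect_equal(unname(f_pb$params$theta), unname(f_in$params$theta),
               tolerance = 1e-12)
  expect_equal(f_pb$posterior, f_in$posterior, tolerance = 1e-12)

  # celltype with one shared label == pseudobulk
  wm2 <- rand_wm(40, 6, n_cells = 4)
  bcs <- unique(wm2$fragments$cb)
  f_pb2 <- fit_em(wm2, assign_pools(bcs, "pseudobulk"))
  f_ct <- fit_em(wm2, assign_pools(bcs, "celltype",
                                   labels = setNames(rep("all", 4), bcs)))
  expect_equal(unname(f_pb2$params$pi), unname(f_ct$params$pi), tolerance = 1e-12)
  expect_equal(unname(f_pb2$params$theta), unname(f_ct$params$theta),
               tolerance = 1e-12)
  expect_equal(f_pb2$posterior, f_ct$posterior, tolerance = 1e-12)
  expect_equal(f_pb2$lnL, f_ct$lnL, tolerance = 1e-12)
})

test_that("pools are independent in celltype mode", {
  set.seed(44)
  wm <- rand_wm(60, 5, n_cells = 6)
  bcs <- sort(unique(wm$fragments$cb))
  labels <- setNames(rep(c("T", "B"), length.out = length(bcs)), bcs)
  pools <- assign_pools(bcs, "celltype", labels)
  fit <- fit_em(wm, pools)

  # permute pool-T fragments; pool B parameters unchanged
  rows_t <- which(labels[wm$fragments$cb] == "T")
  perm <- seq_len(nrow(wm$fragments))
  perm[rows_t] <- rev(rows_t)
  fit2 <- fit_em(scTElocus:::subset_weight_matrix(wm, perm), pools)
  expect_equal(fit$params$pi["B", ], fit2$params$pi["B", ], tolerance = 1e-12)
  expect_equal(fit$params$theta["B", ], fit2$params$theta["B", ],
               tolerance = 1e-12)
})

test_that("EM fixed point maximizes the observed-data objective (grid oracle)", {
  feats <- c("A", "B")
  set.seed(91)
  for (rep in 1:5) {
    wm <- make_wm(list(
      list(q = setNames(c(1, round(runif(1, 0.3, 1), 2)), feats)),
      list(q = c(A = 1)),
      list(q = setNames(c(round(runif(1, 0.3, 1), 2), 1), feats))
    ), feats)
    pools <- pools_of(wm)
    fit <- fit_em(wm, pools, pi_prior = 0, theta_prior = 0, tol = 1e-12,
                  max_iter = 2000)
    th <- fit$params$theta
    obj <- function(piA) {
      p <- scTElocus:::new_model_params(
        rbind(pool1 = c(0, piA, 1 - piA)), th, "pool1", colnames(wm$weights))
      colnames(p$pi) <- colnames(wm$weights)
      sum(log(vapply(1:3, function(i) {
        qrow <- wm$weights[i, ]; qrow <- qrow[qrow > 0]
        fragment_probability(p, "pool1", qrow, wm$fragments$y[i])
      }, numeric(1))))
    }
    grid <- seq(1e-3, 1 - 1e-3, by = 1e-3)
    vals <- vapply(grid, obj, numeric(1))
    pi_hat <- unname(fit$params$pi[1, "A"])
    expect_lt(abs(grid[which.max(vals)] - pi_hat), 2e-3)
  }
})

test_that("model selection matches the closed formulas", {
  ms <- model_selection(list(k = 2, n = 100, lnL = -50))
  expect_equal(unname(ms["BIC"]), 2 * log(100) + 100)
  expect_equal(unname(ms["AIC"]), 104)
  ms0 <- model_selection(list(k = 0, n = 10, lnL = -7))
  expect_equal(unname(ms0["BIC"]), 14)
  expect_equal(unname(ms0["AIC"]), 14)
  expect_error(model_selection(list(k = 1, n = 0, lnL = -1)), "positive")

  # same k, higher lnL -> strictly lower criteria
  a <- model_selection(list(k = 4, n = 50, lnL = -20))
  b <- model_selection(list(k = 4, n = 50, lnL = -10))
  expect_true(all(b < a))
})

test_that("k counts two parameters per observed feature per pool; n is fragments", {
  feats <- c("A", "B", "C")
  wm <- make_wm(list(
    list(q = c(A = 1), cb = "c1"),
    list(q = c(A = 1, B = 0.5), cb = "c1"),
    list(q = c(C = 1), cb = "c2")
  ), feats)
  bcs <- c("c1", "c2")
  fit_pb <- fit_em(wm, assign_pools(bcs, "pseudobulk"))
  expect_equal(fit_pb$n, 3L)
  expect_equal(fit_pb$k, 2L * 3L)   # A, B, C observed in the single pool

  fit_in <- fit_em(wm, assign_pools(bcs, "individual"))
  # pool c1 observes {A, B}, pool c2 observes {C}
  expect_equal(fit_in$k, 2L * (2L + 1L))
  expect_equal(fit_in$n, 3L)
})
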