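test_that("build_grm: closed form, identical samples, brute-force oracle", {
  ## one marker, dosages (0, 2): p = 0.5, W = (-1, 1), denom 2 p q = 0.5
  expect_equal(build_grm(matrix(c(0, 2), 2, 1)),
               matrix(c(2, -2, -2, 2), 2, 2))
  withr::with_seed(21, {
    X <- rbind(s1 = rbinom(50, 2, 0.4), s2 = rbinom(50, 2, 0.4))
    X <- rbind(X, s3 = X["s1", ])  # s3 duplicates s1
    G <- build_grm(X)
    expect_equal(G["s1", "s3"], G["s1", "s1"])
    expect_equal(G["s3", "s3"], G["s1", "s1"])
    ## brute-force double loop
    n <- 60; m <- 200
    Y <- matrix(rbinom(n * m, 2, runif(m, 0.1, 0.5)[rep(1:m, each = n)]), n, m)
    Y[sample(length(Y), 30)] <- NA
    G2 <- build_grm(Y)
    Yi <- apply(Y, 2, function(c) { c[is.na(c)] <- mean(c, na.rm = TRUE); c })
    p <- colMeans(Yi) / 2
    keep <- p > 0 & p < 1
    W <- sweep(Yi[, keep], 2, 2 * p[keep])
    denom <- 2 * sum(p[keep] * (1 - p[keep]))
    Gbf <- matrix(0, n, n)
    for (i in 1:n) for (j in 1:n) Gbf[i, j] <- sum(W[i, ] * W[j, ]) / denom
    expect_equal(unname(G2), Gbf, tolerance = 1e-8)
    expect_lt(max(abs(G2 - t(G2))), 1e-10)
  })
  ## standardized mean diagonal stays near 1 on the fixture
  d <- fx_small()
  expect_lt(abs(mean(diag(build_grm(d$geno))) - 1), 0.2)
})

test_that("reml_h2: noiseless limit, pure noise, scaling invariance", {
  withr::with_seed(31, {
    cfg <- sim_config(n_samples = 120, n_markers = 800, seed = 8)
    g <- simulate_genotypes(cfg)
    G <- build_grm(g)
    eg <- eigen(G, symmetric = TRUE)
    ## y drawn exactly with covariance G (sigma_e2 = 0)
    y0 <- drop(eg$vectors %*% (sqrt(pmax(eg$values, 0)) * rnorm(120)))
    expect_gt(reml_h2(y0, G)$h2, 0.95)
    ## y independent of G
    h2_noise <- replicate(5, reml_h2(rnorm(120), G)$h2)
    expect_lt(mean(h2_noise), 0.15)
    ## scaling y by c scales variances by c^2, h2 unchanged
    yn <- y0 + rnorm(120, sd = sd(y0))
    v1 <- reml_h2(yn, G); v2 <- reml_h2(3 * yn, G)
    expect_equal(v2$h2, v1$h2, tolerance = 1e-8)
    expect_equal(v2$sigma_g2, 9 * v1$sigma_g2, tolerance = 1e-6)
    expect_equal(v2$sigma_e2, 9 * v1$sigma_e2, tolerance = 1e-6)
  })
  expect_error(reml_h2(rep(1, 10), diag(10)), "zero variance")
})

test_that("gblup_fit_predict: no-information and interpolation limits", {
  withr::with_seed(41, {
    n <- 40
    y <- rnorm(n)
    ## G = I: unrelated samples, every prediction is the GLS mean
    pred <- gblup_fit_predict(y[1:30], diag(n), 1:30, 31:40)
    expect_equal(unname(pred), rep(mean(pred), 10), tolerance = 1e-6)
    expect_lt(abs(pred[1] - mean(y[1:30])), 0.5)
    ## test sample genotypically identical to a training sample, lambda -> 0
    X <- matrix(rbinom(39 * 300, 2, 0.4), 39, 300)
    X <- rbind(X, X[1, ])  # sample 40 duplicates sample 1
    G <- build_grm(X)
    vc0 <- structure(list(sigma_g2 = 1, sigma_e2 = 1e-9, h2 = 1,
                          loglik = NA, delta = 1e-9), class = "varcomp")
    yg <- rnorm(39)
    pred2 <- gblup_fit_predict(yg, G, 1:39, 40, vc = vc0)
    expect_equal(unname(pred2), yg[1], tolerance = 1e-3)
  })
})

test_that("GBLUP equals ridge-regression BLUP with the mapped penalty", {
  withr::with_seed(51, {
    d <- fx_small()
    ids <- sample(d$geno$markers$id, 300)
    Xd <- d$geno$dosages[, sort(match(ids, d$geno$markers$id))]
    Xd <- apply(Xd, 2, function(c) { c[is.na(c)] <- mean(c, na.rm = TRUE); c })
    y <- d$pheno$y
    tr <- 1:110; te <- 111:150
    p <- colMeans(Xd) / 2
    keep <- p > 0 & p < 1
    W <- sweep(Xd[, keep], 2, 2 * p[keep])
    cden <- 2 * sum(p[keep] * (1 - p[keep]))
    G <- build_grm(Xd)
    vc <- reml_h2(y[tr], G[tr, tr])
    pred_g <- gblup_fit_predict(y[tr], G, tr, te, vc = vc)
    ## independent ridge-on-markers computation with lambda_r = cden * lambda_g
    lam_g <- vc$sigma_e2 / vc$sigma_g2
    Vtt <- G[tr, tr] + diag(lam_g, length(tr))
    mu <- sum(solve(Vtt, y[tr])) / sum(solve(Vtt, rep(1, length(tr))))
    beta <- solve(crossprod(W[tr, ]) + diag(cden * lam_g, ncol(W)),
                  crossprod(W[tr, ], y[tr] - mu))
    pred_r <- mu + drop(W[te, ] %*% beta)
    expect_equal(unname(pred_g), unname(pred_r), tolerance = 1e-6)
  })
})

test_that("pca_covariates: cluster separation, orthogonality, degeneracy", {
  withr::with_seed(61, {
    n <- 60; m <- 400
    p1 <- runif(m, 0.3, 0.6)
    p2 <- pmin(0.9, pmax(0.1, p1 + sample(c(-0.25, 0.25), m, TRUE)))
    A <- sapply(p1, function(p) rbinom(n / 2, 2, p))
    B <- sapply(p2, function(p) rbinom(n / 2, 2, p))
    sc <- pca_covariates(rbind(A, B), k = 3)
    grp <- rep(1:2, each = n / 2)
    ## silhouette of PC1 for the two constructed clusters
    s <- vapply(seq_len(n), function(i) {
      a <- mean(abs(sc[i, 1] - sc[grp == grp[i], 1]))
      b <- mean(abs(sc[i, 1] - sc[grp != grp[i], 1]))
      (b - a) / max(a, b)
    }, numeric(1))
    expect_gt(mean(s), 0.8)
    xx <- crossprod(sc)
    expect_lt(max(abs(xx[upper.tri(xx)])), 1e-6 * max(diag(xx)))
  })
  expect_error(pca_covariates(matrix(1, 10, 5), k = 2), "rank|polymorphic")
})
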