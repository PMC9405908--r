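test_that("graph Fourier transform round-trips and preserves energy", {
  a <- random_graph(8, seed = 1)
  sp <- graph_spectra(a)
  x <- matrix(rnorm(8 * 3), 8, 3)
  xh <- graph_fourier(x, sp$eigenvectors)
  expect_equal(inverse_graph_fourier(xh, sp$eigenvectors), x, tolerance = 1e-10)
  # Parseval
  expect_equal(sum(xh^2), sum(x^2), tolerance = 1e-10)
  # an eigenvector transforms to a standard basis vector
  u3 <- sp$eigenvectors[, 3, drop = FALSE]
  e3 <- graph_fourier(u3, sp$eigenvectors)
  expect_equal(as.numeric(e3), replace(rep(0, 8), 3, 1), tolerance = 1e-10)
})

test_that("spectral filtering reduces to known operators", {
  a <- random_graph(7, seed = 2)
  sp <- graph_spectra(a)
  x <- matrix(rnorm(7 * 2), 7, 2)
  expect_equal(spectral_filter_apply(sp, function(l) 1, x), x,
               tolerance = 1e-10)
  expect_equal(spectral_filter_apply(sp, function(l) l, x),
               sp$normalized_laplacian %*% x, tolerance = 1e-10)
  # degree-3 polynomial equals the dense matrix-polynomial oracle
  theta <- c(0.3, -1.2, 0.5, 2)
  l <- sp$normalized_laplacian
  oracle <- theta[1] * x + theta[2] * l %*% x +
    theta[3] * l %*% l %*% x + theta[4] * l %*% l %*% l %*% x
  g <- function(lam) theta[1] + theta[2] * lam + theta[3] * lam^2 + theta[4] * lam^3
  expect_equal(spectral_filter_apply(sp, g, x), oracle, tolerance = 1e-8)
})

test_that("chebyshev recursion matches the eigen-domain evaluation", {
  cheb_scalar <- function(k, x) {
    if (k == 0) return(1)
    if (k == 1) return(x)
    tm2 <- 1; tm1 <- x
    for (i in 2:k) { t <- 2 * x * tm1 - tm2; tm2 <- tm1; tm1 <- t }
    tm1
  }
  expect_equal(cheb_scalar(2, 0.5), -0.5) # 2*0.5*0.5 - 1
  set.seed(3)
  for (rep in 1:20) {
    n <- sample(4:10, 1)
    a <- random_graph(n)
    sp <- graph_spectra(a)
    x <- matrix(rnorm(n * 2), n, 2)
    theta <- rnorm(sample(1:5, 1))
    lmax <- max(sp$eigenvalues)
    direct <- chebyshev_filter(sp$normalized_laplacian, theta, lmax, x)
    g <- function(l) {
      sum(sapply(seq_along(theta), function(k) {
        theta[k] * cheb_scalar(k - 1, 2 * l / lmax - 1)
      }))
    }
    via_eigen <- spectral_filter_apply(sp, g, x)
    expect_lt(max(abs(direct - via_eigen)), 1e-8)
  }
  # K = 0 is a pure gain
  a <- random_graph(5, seed = 4)
  x <- matrix(rnorm(10), 5, 2)
  expect_equal(chebyshev_filter(graph_spectra(a), 0.7, 2, x), 0.7 * x)
})

test_that("the renormalized layer matches hand-derived propagation", {
  # K2: A~ = ones(2,2), D~ = 2I -> P = [[.5,.5],[.5,.5]]
  expect_equal(propagation_matrix(complete_graph(2)),
               matrix(0.5, 2, 2), tolerance = 1e-12)
  # edgeless graph: P = I, layer reduces to f(X Theta)
  x <- matrix(rnorm(8), 4, 2)
  theta <- matrix(rnorm(6), 2, 3)
  out <- gcn_layer_forward(matrix(0, 4, 4), x, theta)
  expect_equal(out, pmax(x %*% theta, 0), tolerance = 1e-12)
  # propagation matrix is symmetric with spectrum in [-1, 1]
  set.seed(5)
  for (rep in 1:10) {
    p <- propagation_matrix(random_graph(sample(4:12, 1)))
    expect_equal(p, t(p), tolerance = 1e-12)
    ev <- eigen(p, symmetric = TRUE, only.values = TRUE)$values
    expect_true(all(ev >= -1 - 1e-10 & ev <= 1 + 1e-10))
  }
})

test_that("the layer is permutation-equivariant", {
  set.seed(6)
  for (rep in 1:10) {
    n <- sample(4:10, 1)
    a <- random_graph(n)
    x <- matrix(rnorm(n * 3), n, 3)
    theta <- matrix(rnorm(12), 3, 4)
    perm <- sample(n)
    direct <- gcn_layer_forward(a, x, theta)
    permuted <- gcn_layer_forward(a[perm, perm], x[perm, , drop = FALSE], theta)
    expect_equal(permuted, direct[perm, , drop = FALSE], tolerance = 1e-10)
  }
})

test_that("model forward obeys shape, softmax and mode contracts", {
  set.seed(7)
  samples <- lapply(1:6, function(i) {
    n <- sample(5:8, 1)
    list(p = propagation_matrix(random_graph(n)), x = matrix(rnorm(n * 4), n, 4))
  })
  y <- rep(0:2, 2)
  cfg <- gcn_config(hidden = 10, epochs = 3, batch_size = 3, seed = 1)
  m <- fit_gcn(samples, y, config = cfg)
  pr <- predict(m, samples, type = "prob")
  expect_equal(dim(pr), c(6, 3))
  expect_equal(unname(rowSums(pr)), rep(1, 6), tolerance = 1e-10)
  # eval mode determinism
  expect_identical(predict(m, samples, type = "logits"),
                   predict(m, samples, type = "logits"))
  # dropout 0 + batch norm frozen at the batch statistics: train-mode and
  # eval-mode forwards agree (momentum 1 copies batch stats into the running
  # stats, which eval then reuses on the same batch)
  cfg0 <- gcn_config(hidden = 10, dropout = 0, epochs = 1, bn_momentum = 1,
                     seed = 1)
  ns <- asNamespace("conndecode")
  params <- ns$init_gcn_params(4, 10, 3, 3)
  bn <- ns$init_bn_state(10, 3)
  fw_tr <- ns$gcn_forward(samples, params, bn, cfg0, mode = "train")
  fw_ev <- ns$gcn_forward(samples, params, fw_tr$bn_state, cfg0, mode = "eval")
  expect_equal(fw_ev$logits, fw_tr$logits, tolerance = 1e-10)
})

test_that("training is deterministic, snapshots the best epoch, and overfits", {
  set.seed(8)
  # two well-separated classes of small graphs
  cfg <- tiny_sim(n_subjects = 10, n_classes = 2, effect = 0.9, T = 120,
                  parcels = 16, blocks = 4, seed = 20)
  runs <- simulate_dataset(cfg)
  rep_ <- build_run_representations(runs, embedding = "none")
  scaler <- fit_feature_scaler(rep_$features)
  feats <- lapply(rep_$features, scale_features, scaler = scaler)
  samples <- prepare_gcn_inputs(rep_$graphs, feats)
  gcfg <- gcn_config(epochs = 100, batch_size = 8, seed = 5)
  m1 <- fit_gcn(samples, rep_$labels, config = gcfg)
  m2 <- fit_gcn(samples, rep_$labels, config = gcfg)
  expect_identical(m1$history, m2$history)
  # returned snapshot has the minimum validation loss seen
  expect_equal(m1$best_val_loss, min(m1$history$val_loss), tolerance = 1e-12)
  expect_lte(m1$best_val_loss, m1$history$val_loss[nrow(m1$history)])
  # overfit sanity: training accuracy reaches 100%
  pred <- predict(m1, samples)
  expect_equal(mean(pred == rep_$labels), 1)
})

test_that("a fitted model round-trips through the JSON checkpoint", {
  set.seed(9)
  samples <- lapply(1:4, function(i) {
    list(p = propagation_matrix(random_graph(5)), x = matrix(rnorm(15), 5, 3))
  })
  y <- c(0, 1, 0, 1)
  m <- fit_gcn(samples, y, config = gcn_config(hidden = 6, epochs = 2, seed = 2))
  f <- withr::local_tempfile(fileext = ".json")
  save_gcn(m, f)
  m2 <- load_gcn(f)
  expect_equal(predict(m2, samples, type = "logits"),
               predict(m, samples, type = "logits"), tolerance = 1e-10)
})
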