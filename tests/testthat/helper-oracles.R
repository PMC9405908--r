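# Independent, deliberately naive reference implementations used as oracles.
# They share no code with the package: loops and first-principles formulas
# only, plus a different leading-digit extraction route (string based).

naive_features <- function(x, c3_lag = 1L) {
  n <- length(x)
  asc <- 0
  for (i in 1:(n - 1)) asc <- asc + abs(x[i + 1] - x[i])

  # Benford: leading digit via scientific-notation string
  digits <- c()
  for (v in x) {
    if (v != 0) {
      digits <- c(digits, as.integer(substr(formatC(abs(v), format = "e"), 1, 1)))
    }
  }
  benford <- 0
  if (length(digits) > 0) {
    freq <- numeric(9)
    for (d in digits) freq[d] <- freq[d] + 1
    freq <- freq / length(digits)
    ben_p <- sapply(1:9, function(d) log10(1 + 1 / d))
    if (max(freq) > min(freq)) {
      mx <- mean(freq); my <- mean(ben_p)
      benford <- sum((freq - mx) * (ben_p - my)) /
        sqrt(sum((freq - mx)^2) * sum((ben_p - my)^2))
    }
  }

  c3v <- 0
  if (n > 2 * c3_lag) {
    acc <- 0
    for (i in 1:(n - 2 * c3_lag)) acc <- acc + x[i + 2 * c3_lag] * x[i + c3_lag] * x[i]
    c3v <- acc / (n - 2 * c3_lag)
  }

  mu <- sum(x) / n
  vv <- sum((x - mu)^2) / n
  sdev <- sqrt(vv)
  cid <- 0
  if (sdev > 0) {
    z <- (x - mu) / sdev
    acc <- 0
    for (i in 1:(n - 1)) acc <- acc + (z[i + 1] - z[i])^2
    cid <- sqrt(acc)
  }

  strike <- 0
  cur <- 0
  for (v in x) {
    if (v > mu) {
      cur <- cur + 1
      if (cur > strike) strike <- cur
    } else {
      cur <- 0
    }
  }

  skew <- if (vv == 0) 0 else (sum((x - mu)^3) / n) / sdev^3

  xs <- sort(x)
  h <- (n - 1) * 0.25
  lo <- floor(h)
  q25 <- xs[lo + 1] + (h - lo) * (xs[min(lo + 2, n)] - xs[lo + 1])

  c(absolute_sum_of_changes = asc, benford_correlation = benford, c3 = c3v,
    cid_ce = cid, longest_strike_above_mean = strike, variance = vv,
    standard_deviation = sdev, skewness = skew, quantile_25 = q25)
}

# Brute-force metric suite from per-class counts; MCC via the covariance
# (one-hot Pearson correlation) route, a different formula from the package's
# confusion-matrix expression.
naive_metrics <- function(y_true, y_pred, k) {
  n <- length(y_true)
  acc <- sum(y_true == y_pred) / n
  precision <- recall <- f1 <- support <- numeric(k)
  for (cl in 0:(k - 1)) {
    tp <- sum(y_true == cl & y_pred == cl)
    fp <- sum(y_true != cl & y_pred == cl)
    fn <- sum(y_true == cl & y_pred != cl)
    precision[cl + 1] <- if (tp + fp > 0) tp / (tp + fp) else 0
    recall[cl + 1] <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1[cl + 1] <- if (precision[cl + 1] + recall[cl + 1] > 0) {
      2 * precision[cl + 1] * recall[cl + 1] / (precision[cl + 1] + recall[cl + 1])
    } else 0
    support[cl + 1] <- sum(y_true == cl)
  }
  present <- support > 0
  xt <- matrix(0, n, k)
  xp <- matrix(0, n, k)
  for (i in 1:n) {
    xt[i, y_true[i] + 1] <- 1
    xp[i, y_pred[i] + 1] <- 1
  }
  cov_tp <- cov_tt <- cov_pp <- 0
  for (cl in 1:k) {
    cov_tp <- cov_tp + sum((xt[, cl] - mean(xt[, cl])) * (xp[, cl] - mean(xp[, cl])))
    cov_tt <- cov_tt + sum((xt[, cl] - mean(xt[, cl]))^2)
    cov_pp <- cov_pp + sum((xp[, cl] - mean(xp[, cl]))^2)
  }
  mcc <- if (cov_tt == 0 || cov_pp == 0) 0 else cov_tp / sqrt(cov_tt * cov_pp)
  list(accuracy = acc,
       balanced_accuracy = mean(recall[present]),
       f1_macro = mean(f1),
       f1_micro = acc,
       f1_weighted = sum(support / n * f1),
       mcc = mcc,
       precision_macro = mean(precision),
       recall_macro = mean(recall[present]))
}

# Adjusted Rand index from the pair-counting definition.
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  expected <- sum_a * sum_b / n2
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# Two-block stochastic block model adjacency (unit weights).
sample_sbm2 <- function(n, p_in, p_out, seed) {
  set.seed(seed)
  half <- n / 2
  blocks <- rep(1:2, each = half)
  a <- matrix(0, n, n)
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      p <- if (blocks[i] == blocks[j]) p_in else p_out
      if (runif(1) < p) a[i, j] <- a[j, i] <- 1
    }
  }
  list(adjacency = a, blocks = blocks)
}

# Random symmetric weighted graph with guaranteed positive degrees
# (a random spanning path plus random extra edges).
random_graph <- function(n, extra = n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  a <- matrix(0, n, n)
  perm <- sample(n)
  for (i in 1:(n - 1)) {
    w <- runif(1, 0.2, 1)
    a[perm[i], perm[i + 1]] <- a[perm[i + 1], perm[i]] <- w
  }
  for (e in seq_len(extra)) {
    ij <- sample(n, 2)
    w <- runif(1, 0.2, 1)
    a[ij[1], ij[2]] <- a[ij[2], ij[1]] <- w
  }
  a
}

# Small deterministic graphs
path_graph <- function(n) {
  a <- matrix(0, n, n)
  for (i in 1:(n - 1)) a[i, i + 1] <- a[i + 1, i] <- 1
  a
}

cycle_graph <- function(n) {
  a <- path_graph(n)
  a[1, n] <- a[n, 1] <- 1
  a
}

complete_graph <- function(n) {
  a <- matrix(1, n, n) - diag(n)
  a
}

two_cliques <- function(size = 5) {
  n <- 2 * size
  a <- matrix(0, n, n)
  a[1:size, 1:size] <- 1
  a[(size + 1):n, (size + 1):n] <- 1
  diag(a) <- 0
  # single bridge so walks can mix between cliques
  a[size, size + 1] <- a[size + 1, size] <- 1
  a
}

mean_cosine <- function(emb, idx_a, idx_b) {
  nrm <- sqrt(rowSums(emb^2))
  e <- emb / pmax(nrm, 1e-12)
  s <- e[idx_a, , drop = FALSE] %*% t(e[idx_b, , drop = FALSE])
  if (identical(idx_a, idx_b)) mean(s[upper.tri(s)]) else mean(s)
}

# small fast simulation config used across tests
tiny_sim <- function(n_subjects = 6, n_classes = 3, effect = 0.8, seed = 7,
                     group_effect = 0, T = 100, parcels = 20, blocks = 4) {
  sim_config(n_subjects = n_subjects, n_parcels = parcels,
             n_classes = n_classes, n_timepoints = T, effect_size = effect,
             group_effect = group_effect, n_blocks = blocks, seed = seed)
}
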