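graph_adjacency <- function(graph) {
  if (inherits(graph, "brain_graph")) graph$adjacency else unclass(as.matrix(graph))
}

# sorted 0-based neighbor lists + matching weights, for the C++ walkers
adjacency_lists <- function(a) {
  n <- nrow(a)
  nbr <- vector("list", n)
  wgt <- vector("list", n)
  for (v in seq_len(n)) {
    idx <- which(a[v, ] > 0)
    nbr[[v]] <- as.integer(idx - 1L)
    wgt[[v]] <- as.numeric(a[v, idx])
  }
  list(neighbors = nbr, weights = wgt)
}

#' Second-order (biased) random walks
#'
#' Generates Node2Vec-style walks: from current node `v` with previous node
#' `t`, the unnormalized probability of moving to candidate `x` is the edge
#' weight `w(v, x)` times `1/p` if `x = t`, times `1` if `x` is adjacent to
#' `t`, and times `1/q` otherwise. `p = q = 1` collapses to a first-order
#' weighted random walk. Isolated nodes emit length-1 walks.
#'
#' @param graph a [brain_graph()] or adjacency matrix with positive weights.
#' @param walks_per_node walks started at each node.
#' @param walk_length maximum walk length (number of visited nodes).
#' @param p return parameter (> 0).
#' @param q in-out parameter (> 0).
#' @param seed RNG seed (walks are deterministic given the seed).
#' @return integer matrix, one walk per row, 1-based node indices, `NA`
#'   padding past the end of short walks.
#' @export
second_order_walks <- function(graph, walks_per_node = 10L, walk_length = 80L,
                               p = 1, q = 1, seed = 1L) {
  a <- graph_adjacency(graph)
  if (any(a < 0)) stop("walk transition weights require non-negative adjacency")
  if (sum(a) == 0) stop("graph has no edges")
  al <- adjacency_lists(a)
  w <- cpp_random_walks(al$neighbors, al$weights,
                        as.integer(walks_per_node), as.integer(walk_length),
                        p, q, as.integer(seed))
  w[w < 0] <- NA_integer_
  w + 1L
}

#' Second-order transition distribution (analytic)
#'
#' The normalized transition distribution used by [second_order_walks()] when
#' standing at `current` having arrived from `previous`. Exposed for
#' verification: empirical step frequencies of the walker converge to this.
#'
#' @inheritParams second_order_walks
#' @param previous,current 1-based node indices.
#' @return named numeric vector of probabilities over the neighbors of
#'   `current`.
#' @export
second_order_transition <- function(graph, previous, current, p = 1, q = 1) {
  if (p <= 0 || q <= 0) stop("p and q must be positive")
  a <- graph_adjacency(graph)
  cand <- which(a[current, ] > 0)
  bias <- vapply(cand, function(x) {
    if (x == previous) 1 / p
    else if (a[previous, x] > 0) 1
    else 1 / q
  }, numeric(1))
  pr <- a[current, cand] * bias
  pr <- pr / sum(pr)
  names(pr) <- cand
  pr
}

#' Skip-gram embedding with negative sampling
#'
#' Trains skip-gram node vectors by stochastic gradient descent over
#' (center, context) pairs extracted from a walk corpus, with noise samples
#' drawn from the corpus unigram distribution raised to 3/4 and a linearly
#' decaying learning rate. Returns the center vectors.
#'
#' @param corpus walk matrix from [second_order_walks()] (1-based, NA
#'   padding).
#' @param n_nodes total number of nodes.
#' @param dim embedding dimension.
#' @param window context window half-width.
#' @param negative_samples noise samples per positive pair.
#' @param epochs passes over the corpus.
#' @param learning_rate initial SGD step size.
#' @param seed RNG seed (training is deterministic given the seed).
#' @param skip if > 0, restrict contexts to exact offset `skip` (used by the
#'   Walklets scales); 0 means every offset within `window`.
#' @return N x dim matrix; nodes that never occur in a pair get a zero row
#'   with a warning.
#' @export
skipgram_embed <- function(corpus, n_nodes, dim = 32L, window = 5L,
                           negative_samples = 5L, epochs = 5L,
                           learning_rate = 0.025, seed = 1L, skip = 0L) {
  w <- as.matrix(corpus)
  if (length(w) == 0 || all(is.na(w))) stop("empty walk corpus")
  w[is.na(w)] <- 0L
  res <- cpp_sgns(w - 1L, as.integer(n_nodes), as.integer(dim),
                  as.integer(window), as.integer(negative_samples),
                  as.integer(epochs), learning_rate, as.integer(seed),
                  as.integer(skip))
  if (!all(res$seen)) {
    warning(sprintf("node(s) absent from the walk-pair corpus (zero vector): %s",
                    paste(which(!res$seen), collapse = ", ")))
  }
  res$embedding
}

#' Node2Vec embedding
#'
#' Composition of [second_order_walks()] (biased second-order walks that
#' interpolate between breadth-first and depth-first neighborhood sampling
#' via `p` and `q`) and [skipgram_embed()].
#'
#' @inheritParams second_order_walks
#' @inheritParams skipgram_embed
#' @return N x dim embedding matrix.
#' @export
node2vec_embed <- function(graph, dim = 32L, walks_per_node = 10L,
                           walk_length = 80L, window = 5L,
                           negative_samples = 5L, epochs = 5L,
                           learning_rate = 0.025, p = 1, q = 1, seed = 1L) {
  walks <- second_order_walks(graph, walks_per_node, walk_length, p, q, seed)
  skipgram_embed(walks, nrow(graph_adjacency(graph)), dim, window,
                 negative_samples, epochs, learning_rate, seed = seed + 1L)
}

#' Walklets embedding
#'
#' For each scale `k = 1..n_scales`, extracts pairs `(w_i, w_{i+k})` from
#' first-order random walks and trains an independent skip-gram embedding of
#' dimension `dim / n_scales`; the scale blocks are concatenated in order, so
#' successive blocks capture successively coarser neighborhood structure.
#'
#' @inheritParams node2vec_embed
#' @param n_scales number of skip scales K; `dim` must be divisible by K.
#' @return N x dim embedding matrix (K blocks of dim/K columns).
#' @export
walklets_embed <- function(graph, dim = 32L, n_scales = 4L,
                           walks_per_node = 10L, walk_length = 80L,
                           negative_samples = 5L, epochs = 5L,
                           learning_rate = 0.025, seed = 1L) {
  if (dim %% n_scales != 0) {
    stop(sprintf("dim (%d) must be divisible by n_scales (%d)", dim, n_scales))
  }
  sub_dim <- dim %/% n_scales
  walks <- second_order_walks(graph, walks_per_node, walk_length,
                              p = 1, q = 1, seed = seed)
  n <- nrow(graph_adjacency(graph))
  blocks <- lapply(seq_len(n_scales), function(k) {
    skipgram_embed(walks, n, sub_dim, window = k,
                   negative_samples = negative_samples, epochs = epochs,
                   learning_rate = learning_rate, seed = seed + k, skip = k)
  })
  do.call(cbind, blocks)
}

# deterministic sign convention: largest-magnitude entry of each column > 0
fix_svd_signs <- function(u) {
  for (j in seq_len(ncol(u))) {
    i <- which.max(abs(u[, j]))
    if (u[i, j] < 0) u[, j] <- -u[, j]
  }
  u
}

#' NetMF embedding
#'
#' Factorizes the (dense) matrix that DeepWalk implicitly factorizes:
#' `M = vol(G)/(b T) * (sum_{r=1..T} (D^-1 A)^r) * D^-1`, truncated at
#' `M' = log(max(M, 1))` elementwise, followed by a rank-`dim` SVD; the
#' embedding is `U_d sqrt(S_d)`. Deterministic given the graph (SVD column
#' signs fixed by forcing each column's largest-magnitude entry positive).
#'
#' @inheritParams node2vec_embed
#' @param window_T window size T (number of transition powers summed).
#' @param negative_b negative-sampling parameter b (>= 1).
#' @return N x dim embedding matrix.
#' @export
netmf_embed <- function(graph, dim = 32L, window_T = 5L, negative_b = 1) {
  a <- graph_adjacency(graph)
  m <- netmf_log_matrix(a, window_T, negative_b)
  if (dim > nrow(m)) stop("embedding dim exceeds the number of nodes")
  sv <- svd(m, nu = dim, nv = 0)
  u <- fix_svd_signs(sv$u[, seq_len(dim), drop = FALSE])
  u %*% diag(sqrt(sv$d[seq_len(dim)]), dim)
}

#' The dense log-truncated NetMF matrix M'
#'
#' @inheritParams netmf_embed
#' @return N x N matrix `log(max(M, 1))`.
#' @export
netmf_log_matrix <- function(graph, window_T = 5L, negative_b = 1) {
  a <- graph_adjacency(graph)
  if (window_T < 1L) stop("window_T must be >= 1")
  if (negative_b < 1) stop("negative_b must be >= 1")
  d <- rowSums(a)
  if (any(d == 0)) {
    stop(sprintf("isolated node(s) (zero degree): %s — D^-1 undefined",
                 paste(which(d == 0), collapse = ", ")))
  }
  p <- a / d # D^-1 A, row-stochastic
  s <- p
  pk <- p
  if (window_T > 1L) {
    for (r in 2:window_T) {
      pk <- pk %*% p
      s <- s + pk
    }
  }
  m <- (sum(d) / (negative_b * window_T)) * sweep(s, 2, d, "/")
  log(pmax(m, 1))
}

#' RandNE embedding
#'
#' Iterative Gaussian random projection: with `R` an N x dim matrix of
#' `Normal(0, 1/dim)` entries and `S = D^-1 A` the row-stochastic transition
#' matrix, computes `U_0 = R`, `U_k = S U_{k-1}`, and returns the weighted
#' sum `sum_k alpha_k U_k`. Higher orders inject smoothed (longer-range)
#' proximity; the construction is linear in `alpha`.
#'
#' @inheritParams node2vec_embed
#' @param weights_alpha order weights `alpha_0..alpha_K` (length = max order
#'   + 1).
#' @param projection optional N x dim Gaussian projection matrix; supplying
#'   the same matrix for several graphs puts their embeddings in one common
#'   coordinate system (defaults to a fresh `Normal(0, 1/dim)` draw under
#'   `seed`).
#' @return N x dim embedding matrix.
#' @export
randne_embed <- function(graph, dim = 32L, weights_alpha = c(1, 1e2, 1e4),
                         seed = 1L, projection = NULL) {
  a <- graph_adjacency(graph)
  d <- rowSums(a)
  if (any(d == 0)) {
    stop(sprintf("isolated node(s) (zero degree): %s — row normalization undefined",
                 paste(which(d == 0), collapse = ", ")))
  }
  n <- nrow(a)
  if (is.null(projection)) {
    set.seed(seed)
    projection <- matrix(stats::rnorm(n * dim, 0, 1 / sqrt(dim)), n, dim)
  }
  if (nrow(projection) != n || ncol(projection) != dim) {
    stop("projection must be an N x dim matrix")
  }
  u <- projection
  out <- weights_alpha[1] * u
  if (length(weights_alpha) > 1) {
    s <- a / d
    for (k in 2:length(weights_alpha)) {
      u <- s %*% u
      out <- out + weights_alpha[k] * u
    }
  }
  out
}

#' Compute a node embedding by name
#'
#' Dispatcher over the four implemented algorithms with their defaults.
#'
#' @param graph a [brain_graph()] or adjacency matrix.
#' @param algorithm one of `"node2vec"`, `"walklets"`, `"netmf"`, `"randne"`.
#' @param dim embedding dimension.
#' @param seed RNG seed (ignored by the deterministic NetMF).
#' @param ... further arguments passed to the algorithm.
#' @return N x dim embedding matrix.
#' @export
node_embedding <- function(graph,
                           algorithm = c("netmf", "randne", "node2vec", "walklets"),
                           dim = 32L, seed = 1L, ...) {
  algorithm <- match.arg(algorithm)
  switch(algorithm,
    netmf = netmf_embed(graph, dim = dim, ...),
    randne = randne_embed(graph, dim = dim, seed = seed, ...),
    node2vec = node2vec_embed(graph, dim = dim, seed = seed, ...),
    walklets = walklets_embed(graph, dim = dim, seed = seed, ...)
  )
}
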