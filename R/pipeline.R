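# Thresholding can isolate nodes; the embedding algorithms reject zero-degree
# nodes (D^-1 undefined), so the pipeline embeds the non-isolated subgraph
# and assigns isolated nodes an all-zero embedding row.
embed_with_isolated <- function(graph, algorithm, dim, seed, ...) {
  a <- graph_adjacency(graph)
  deg <- rowSums(a)
  extra <- list(...)
  if (algorithm == "randne" && is.null(extra$projection)) {
    # draw the shared projection at full size so subsetting isolated nodes
    # cannot desynchronize the coordinate system across runs
    set.seed(seed)
    extra$projection <- matrix(stats::rnorm(nrow(a) * dim, 0, 1 / sqrt(dim)),
                               nrow(a), dim)
  }
  if (all(deg > 0)) {
    return(do.call(node_embedding,
                   c(list(a, algorithm = algorithm, dim = dim, seed = seed),
                     extra)))
  }
  keep <- which(deg > 0)
  if (length(keep) < 2) stop("graph has fewer than two connected nodes")
  if (!is.null(extra$projection)) {
    extra$projection <- extra$projection[keep, , drop = FALSE]
  }
  sub <- do.call(node_embedding,
                 c(list(a[keep, keep, drop = FALSE], algorithm = algorithm,
                        dim = dim, seed = seed), extra))
  out <- matrix(0, nrow(a), dim)
  out[keep, ] <- sub
  out
}

#' Build graphs and node features for every run
#'
#' Per run: Pearson correlation of the parcel series, Fisher z transform,
#' thresholding into a weighted [brain_graph()], the nine statistical node
#' features, and (optionally) a topology embedding of that run's graph,
#' concatenated into the node feature matrix.
#'
#' @param runs list of runs from [simulate_dataset()] / [read_runs()].
#' @param embedding embedding algorithm name, or `"none"` for statistical
#'   features only.
#' @param embedding_dim embedding dimension.
#' @param threshold_method,threshold_level passed to [threshold_graph()].
#' @param seed base seed for the (stochastic) embeddings; run i uses
#'   `seed + i`.
#' @return list with `graphs` (list of [brain_graph()]), `features` (list of
#'   N x d matrices, unstandardized) and `labels` (integer class labels).
#' @export
build_run_representations <- function(runs,
                                      embedding = c("none", "netmf", "randne",
                                                    "node2vec", "walklets"),
                                      embedding_dim = 32L,
                                      threshold_method = "proportional",
                                      threshold_level = 0.10,
                                      seed = 1L) {
  embedding <- match.arg(embedding)
  graphs <- vector("list", length(runs))
  features <- vector("list", length(runs))
  for (i in seq_along(runs)) {
    g <- functional_graph(runs[[i]]$series, method = threshold_method,
                          level = threshold_level)
    sf <- node_stat_features(runs[[i]]$series)
    # one embedding seed for the whole study: RandNE then shares a single
    # projection matrix across runs, making embedding coordinates comparable
    # between graphs (walk-based methods still differ run to run through the
    # graphs themselves)
    emb <- if (embedding == "none") NULL else {
      embed_with_isolated(g, algorithm = embedding, dim = embedding_dim,
                          seed = seed)
    }
    graphs[[i]] <- g
    features[[i]] <- assemble_feature_matrix(sf, emb)
  }
  list(graphs = graphs, features = features,
       labels = run_labels(runs, "class"))
}

#' Decode task state with the full GCN pipeline under stratified CV
#'
#' Runs the complete evaluation protocol: build graph + feature
#' representations, make a stratified k-fold split plan (held-out fifth split
#' 60:40 into validation and test), standardize node features with
#' training-fold statistics, train the GCN per fold, and score the test
#' split. Headline metrics are the mean over folds; confusion matrices are
#' summed.
#'
#' @param runs list of labeled runs.
#' @param embedding,embedding_dim,threshold_method,threshold_level passed to
#'   [build_run_representations()].
#' @param k number of CV folds.
#' @param val_fraction validation share of the held-out fold.
#' @param config a [gcn_config()]; its seed is offset per fold.
#' @param seed seed of the split plan and representation building.
#' @return object of class `decode_result`: per-fold `metric_report`s, mean
#'   metrics, the pooled confusion matrix, the split plan and the fold
#'   models.
#' @export
decode_runs <- function(runs, embedding = "netmf", embedding_dim = 32L,
                        threshold_method = "proportional",
                        threshold_level = 0.10, k = 5L, val_fraction = 0.6,
                        config = gcn_config(), seed = 1L) {
  rep <- build_run_representations(runs, embedding, embedding_dim,
                                   threshold_method, threshold_level, seed)
  n_classes <- length(unique(rep$labels))
  plan <- stratified_cv_split(rep$labels, k = k, val_fraction = val_fraction,
                              seed = seed)
  fold_metrics <- vector("list", k)
  models <- vector("list", k)
  confusion <- NULL
  for (f in seq_len(k)) {
    fold <- plan[[f]]
    scaler <- fit_feature_scaler(rep$features[fold$train])
    feats <- lapply(rep$features, scale_features, scaler = scaler)
    samples <- prepare_gcn_inputs(rep$graphs, feats)
    cfg <- config
    cfg$seed <- config$seed + f
    model <- fit_gcn(samples[fold$train], rep$labels[fold$train],
                     samples[fold$validation], rep$labels[fold$validation],
                     cfg)
    pred <- predict(model, samples[fold$test])
    m <- compute_metrics(rep$labels[fold$test], pred, n_classes)
    fold_metrics[[f]] <- m
    models[[f]] <- model
    confusion <- if (is.null(confusion)) m$confusion else confusion + m$confusion
  }
  scalar_names <- c("accuracy", "balanced_accuracy", "f1_macro", "f1_micro",
                    "f1_weighted", "mcc", "precision_macro", "recall_macro")
  mean_metrics <- vapply(scalar_names, function(nm) {
    mean(vapply(fold_metrics, function(m) m[[nm]], numeric(1)))
  }, numeric(1))
  structure(list(
    fold_metrics = fold_metrics, mean_metrics = as.list(mean_metrics),
    confusion = confusion, split_plan = plan, models = models,
    embedding = embedding, n_classes = n_classes
  ), class = "decode_result")
}

#' @export
print.decode_result <- function(x, ...) {
  cat(sprintf("decode_result: %d-fold CV, embedding = %s, %d classes\n",
              length(x$fold_metrics), x$embedding, x$n_classes))
  m <- x$mean_metrics
  cat(sprintf("  mean accuracy %.4f | F1 macro %.4f | MCC %.4f\n",
              m$accuracy, m$f1_macro, m$mcc))
  invisible(x)
}

#' One full GCN train/test cycle returning the test MCC
#'
#' A single stratified train/validation/test split (one CV fold), GCN
#' training and test-set MCC — the unit of work repeated by
#' [repeated_run_comparison()] when the full pipeline (rather than the cheap
#' centroid classifier) is the classifier under study.
#'
#' @param runs list of labeled runs.
#' @param seed per-run seed (controls split, embedding and training).
#' @param embedding,embedding_dim,threshold_level,config as in
#'   [decode_runs()].
#' @return scalar test MCC.
#' @export
gcn_pipeline_mcc <- function(runs, seed = 1L, embedding = "netmf",
                             embedding_dim = 32L, threshold_level = 0.10,
                             config = gcn_config()) {
  rep <- build_run_representations(runs, embedding, embedding_dim,
                                   threshold_level = threshold_level,
                                   seed = seed)
  n_classes <- length(unique(rep$labels))
  plan <- stratified_cv_split(rep$labels, k = 5L, seed = seed)
  fold <- plan[[1L]]
  scaler <- fit_feature_scaler(rep$features[fold$train])
  feats <- lapply(rep$features, scale_features, scaler = scaler)
  samples <- prepare_gcn_inputs(rep$graphs, feats)
  cfg <- config
  cfg$seed <- seed
  model <- fit_gcn(samples[fold$train], rep$labels[fold$train],
                   samples[fold$validation], rep$labels[fold$validation], cfg)
  pred <- predict(model, samples[fold$test])
  compute_metrics(rep$labels[fold$test], pred, n_classes)$mcc
}

#' Split a simulated dataset by its binary group label
#'
#' @param runs list of labeled runs.
#' @return list with elements `group0` and `group1`.
#' @export
split_by_group <- function(runs) {
  g <- run_labels(runs, "group")
  list(group0 = runs[g == 0], group1 = runs[g == 1])
}
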