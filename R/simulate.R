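#' Simulation configuration for synthetic parcel time series
#'
#' Defines a multi-subject, multi-class study in which each class (task
#' state) is identified by a block-community covariance structure planted in
#' the innovation covariance of a stationary Gaussian AR(1) process. Parcels
#' are partitioned once into `n_blocks` communities of unequal sizes
#' (proportional to 1..K); every block has elevated within-block correlation,
#' and class `c` additionally strengthens the within-block correlation and
#' the innovation amplitude of its designated block — emulating task-evoked
#' regional co-activation, so task state is decodable from graph topology and
#' node amplitude. (Unequal block sizes matter: with equal blocks the class
#' distributions would be node permutations of one another and no
#' permutation-invariant graph readout could separate them.) A binary group
#' attribute (emulating, e.g., a gender split) scales all within-block
#' correlations by `(1 + group_effect)` for group-1 subjects.
#'
#' @param n_subjects number of subjects; each subject contributes one run per
#'   class. Subjects are split into two equal-sized groups (group 0 and 1).
#' @param n_parcels number of parcels (graph nodes). Default 360, the size of
#'   a whole-cortex multimodal parcellation.
#' @param n_classes number of task classes. Default 7.
#' @param n_timepoints run length T. Default 176 (a typical task-run length).
#' @param effect_size non-negative increment of within-block over baseline
#'   correlation; 0 makes all classes share one covariance.
#' @param group_effect non-negative scaling of the within-block increment for
#'   group-1 subjects: their within-block correlation becomes
#'   `rho_between + effect_size * (1 + group_effect)`.
#' @param ar_coefficient lag-1 autoregressive coefficient, in (-1, 1).
#' @param n_blocks number of community blocks (must be >= n_classes so every
#'   class has its own designated block).
#' @param rho_between baseline correlation between any two parcels.
#' @param subject_sd standard deviation of the per-subject jitter added to
#'   the within-block correlation (subject-level heterogeneity).
#' @param seed master seed; per-run substreams are derived deterministically
#'   from it, so identical configs give bit-identical datasets.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_subjects,
                       n_parcels = 360L,
                       n_classes = 7L,
                       n_timepoints = 176L,
                       effect_size = 0.4,
                       group_effect = 0,
                       ar_coefficient = 0.3,
                       n_blocks = n_classes,
                       rho_between = 0.05,
                       subject_sd = 0.02,
                       seed = 1L) {
  cfg <- list(
    n_subjects = as.integer(n_subjects),
    n_parcels = as.integer(n_parcels),
    n_classes = as.integer(n_classes),
    n_timepoints = as.integer(n_timepoints),
    effect_size = effect_size,
    group_effect = group_effect,
    ar_coefficient = ar_coefficient,
    n_blocks = as.integer(n_blocks),
    rho_between = rho_between,
    subject_sd = subject_sd,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_classes < 2L) stop("n_classes must be >= 2")
  if (cfg$n_parcels < 2L) stop("n_parcels must be >= 2")
  if (cfg$n_subjects < 1L) stop("n_subjects must be >= 1")
  if (cfg$n_timepoints < 3L) stop("n_timepoints must be >= 3 (Pearson r undefined below)")
  if (cfg$effect_size < 0) stop("effect_size must be >= 0")
  if (cfg$group_effect < 0) stop("group_effect must be >= 0")
  if (abs(cfg$ar_coefficient) >= 1) stop("ar_coefficient must lie in (-1, 1)")
  if (cfg$n_blocks < 2L || cfg$n_blocks > cfg$n_parcels) {
    stop("n_blocks must lie in [2, n_parcels]")
  }
  if (cfg$n_blocks < cfg$n_classes) {
    stop(sprintf(paste0(
      "n_blocks (%d) < n_classes (%d): every class needs its own designated ",
      "block; increase n_blocks"), cfg$n_blocks, cfg$n_classes))
  }
  if (min(block_sizes(cfg)) < 2L) {
    stop("smallest block would have < 2 parcels; increase n_parcels or decrease n_blocks")
  }
  invisible(cfg)
}

# Unequal block sizes proportional to 1..K (largest-remainder rounding).
block_sizes <- function(cfg) {
  k <- cfg$n_blocks
  quota <- cfg$n_parcels * seq_len(k) / sum(seq_len(k))
  sizes <- floor(quota)
  short <- cfg$n_parcels - sum(sizes)
  if (short > 0) {
    extra <- order(quota - sizes, decreasing = TRUE)[seq_len(short)]
    sizes[extra] <- sizes[extra] + 1L
  }
  sizes
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "sim_config: %d subjects x %d classes (%d parcels, T=%d)\n",
    x$n_subjects, x$n_classes, x$n_parcels, x$n_timepoints
  ))
  cat(sprintf(
    "  effect_size=%.3g group_effect=%.3g ar=%.2f blocks=%d seed=%d\n",
    x$effect_size, x$group_effect, x$ar_coefficient, x$n_blocks, x$seed
  ))
  invisible(x)
}

# Fixed block membership of each parcel (1-based block ids, contiguous
# blocks of unequal sizes).
block_partition <- function(cfg) {
  rep(seq_len(cfg$n_blocks), times = block_sizes(cfg))
}

# Innovation covariance for one run of class `cls` (1-based): baseline
# correlation rho_between everywhere; within-block correlation raised to
# rho_between + effect_size/2 in every block (community structure shared by
# all classes) and to rho_between + effect_size (+ the subject jitter) in the
# class's designated block, whose innovation standard deviation is also
# raised by effect_size — task-evoked regional co-activation. `group`
# scales all within-block correlation increments by (1 + group_effect).
# effect_size = 0 collapses everything to one shared covariance.
class_covariance <- function(cfg, cls, group = 0, jitter = 0) {
  n <- cfg$n_parcels
  blocks <- block_partition(cfg)
  gscale <- 1 + cfg$group_effect * group
  rho_in <- cfg$rho_between + (0.5 * cfg$effect_size + jitter) * gscale
  rho_cls <- cfg$rho_between + (cfg$effect_size + jitter) * gscale
  # clamp only the jitter: a config whose deterministic correlations are
  # already invalid must fail the positive-definiteness check downstream
  det_in <- cfg$rho_between + 0.5 * cfg$effect_size * gscale
  det_cls <- cfg$rho_between + cfg$effect_size * gscale
  if (det_in <= 0.95) rho_in <- min(max(rho_in, cfg$rho_between), 0.95)
  if (det_cls <= 0.95) rho_cls <- min(max(rho_cls, cfg$rho_between), 0.95)
  sigma <- matrix(cfg$rho_between, n, n)
  same <- outer(blocks, blocks, "==")
  sigma[same] <- rho_in
  in_cls <- blocks == cls
  sigma[outer(in_cls, in_cls, "&") & same] <- rho_cls
  diag(sigma) <- 1
  sdev <- ifelse(in_cls, 1 + cfg$effect_size, 1)
  sigma * outer(sdev, sdev)
}

run_seed <- function(master, index) {
  as.integer((as.double(master) + 7919 * as.double(index)) %% 2147483647)
}

# Draws one stationary AR(1) run: x_t = phi x_{t-1} + e_t, e_t ~ N(0, Sigma),
# x_1 ~ N(0, Sigma / (1 - phi^2)) so the process starts in its stationary law.
draw_ar1_run <- function(n_timepoints, chol_sigma, phi) {
  n <- ncol(chol_sigma)
  innov <- matrix(stats::rnorm(n_timepoints * n), n_timepoints, n) %*% chol_sigma
  x <- matrix(0, n_timepoints, n)
  x[1, ] <- innov[1, ] / sqrt(1 - phi^2)
  for (t in 2:n_timepoints) x[t, ] <- phi * x[t - 1, ] + innov[t, ]
  x
}

#' Simulate a labeled multi-subject, multi-class dataset
#'
#' Generates `n_subjects * n_classes` runs. Each run is a stationary Gaussian
#' AR(1) process whose innovation covariance carries the class-specific
#' block-community structure (see [sim_config()]). The stationary covariance
#' is proportional to the innovation covariance, so the planted correlation
#' matrix is exactly the block-structured one.
#'
#' @param cfg a [sim_config()].
#' @return a list of runs; each run is a list with elements `series`
#'   (T x N matrix, columns named by parcel), `class_label` (integer in
#'   `[0, n_classes)`), `subject_id` (character), and `group_label` (0 or 1).
#' @export
simulate_dataset <- function(cfg) {
  validate_sim_config(cfg)
  groups <- as.integer(seq_len(cfg$n_subjects) > cfg$n_subjects / 2)
  runs <- vector("list", cfg$n_subjects * cfg$n_classes)
  k <- 0L
  for (s in seq_len(cfg$n_subjects)) {
    # subject-level heterogeneity: one jitter per subject, shared by its runs
    set.seed(run_seed(cfg$seed, 1000000L + s))
    jitter <- stats::rnorm(1, 0, cfg$subject_sd)
    for (cls in seq_len(cfg$n_classes)) {
      k <- k + 1L
      sigma <- class_covariance(cfg, cls, groups[s], jitter)
      ch <- tryCatch(chol(sigma), error = function(e) {
        stop(sprintf(paste0(
          "planted covariance for class %d is not positive-definite; ",
          "reduce effect_size or group_effect"), cls - 1L))
      })
      set.seed(run_seed(cfg$seed, k))
      runs[[k]] <- list(
        series = {
          x <- draw_ar1_run(cfg$n_timepoints, ch, cfg$ar_coefficient)
          colnames(x) <- paste0("parcel_", seq_len(cfg$n_parcels))
          x
        },
        class_label = cls - 1L,
        subject_id = sprintf("subj_%03d", s),
        group_label = groups[s]
      )
    }
  }
  runs
}

#' Simulate voxel-level runs within parcels
#'
#' Expands each parcel time series into `voxels_per_parcel` voxel series by
#' adding independent Gaussian voxel noise, for testing voxel-to-parcel
#' averaging. Parcel averaging of the returned voxel series recovers the
#' parcel series up to the averaged noise.
#'
#' @param cfg a [sim_config()].
#' @param voxels_per_parcel number of voxels per parcel (>= 1).
#' @param voxel_noise_sd standard deviation of the independent voxel noise.
#' @return a list of runs; each has `voxel_series` (T x (N*V) matrix),
#'   `parcel_assignment` (integer vector of length N*V mapping each voxel to
#'   its parcel), `parcel_series` (the noiseless T x N truth), and the labels
#'   of [simulate_dataset()].
#' @export
simulate_voxel_runs <- function(cfg, voxels_per_parcel, voxel_noise_sd = 0) {
  if (voxels_per_parcel < 1L) stop("voxels_per_parcel must be >= 1")
  runs <- simulate_dataset(cfg)
  lapply(seq_along(runs), function(i) {
    r <- runs[[i]]
    tt <- nrow(r$series)
    n <- ncol(r$series)
    assignment <- rep(seq_len(n), each = voxels_per_parcel)
    set.seed(run_seed(cfg$seed, 2000000L + i))
    vox <- r$series[, assignment, drop = FALSE] +
      matrix(stats::rnorm(tt * n * voxels_per_parcel, 0, voxel_noise_sd),
             tt, n * voxels_per_parcel)
    colnames(vox) <- paste0("voxel_", seq_len(n * voxels_per_parcel))
    list(
      voxel_series = vox,
      parcel_assignment = assignment,
      parcel_series = r$series,
      class_label = r$class_label,
      subject_id = r$subject_id,
      group_label = r$group_label
    )
  })
}

#' Extract the label vector of a simulated dataset
#'
#' @param runs a list of runs from [simulate_dataset()].
#' @param what one of "class", "group", "subject".
#' @return vector of labels, one per run.
#' @export
run_labels <- function(runs, what = c("class", "group", "subject")) {
  what <- match.arg(what)
  switch(what,
    class = vapply(runs, function(r) r$class_label, integer(1)),
    group = vapply(runs, function(r) r$group_label, integer(1)),
    subject = vapply(runs, function(r) r$subject_id, character(1))
  )
}

#' Write simulated runs to disk
#'
#' One CSV per run (T rows x N columns, header = parcel IDs) plus a manifest
#' TSV with columns run_file, subject_id, class_label, group_label.
#'
#' @param runs a list of runs from [simulate_dataset()].
#' @param dir output directory (created if missing).
#' @return invisibly, the manifest data frame.
#' @export
write_runs <- function(runs, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- sprintf("run_%04d.csv", seq_along(runs))
  for (i in seq_along(runs)) {
    utils::write.csv(runs[[i]]$series, file.path(dir, files[i]), row.names = FALSE)
  }
  manifest <- data.frame(
    run_file = files,
    subject_id = run_labels(runs, "subject"),
    class_label = run_labels(runs, "class"),
    group_label = run_labels(runs, "group"),
    stringsAsFactors = FALSE
  )
  utils::write.table(manifest, file.path(dir, "manifest.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(manifest)
}

#' Read runs written by [write_runs()]
#'
#' @param dir directory holding the run CSVs and `manifest.tsv`.
#' @return a list of runs in the [simulate_dataset()] format.
#' @export
read_runs <- function(dir) {
  manifest <- utils::read.delim(file.path(dir, "manifest.tsv"),
                                stringsAsFactors = FALSE)
  lapply(seq_len(nrow(manifest)), function(i) {
    list(
      series = as.matrix(utils::read.csv(file.path(dir, manifest$run_file[i]))),
      class_label = as.integer(manifest$class_label[i]),
      subject_id = as.character(manifest$subject_id[i]),
      group_label = as.integer(manifest$group_label[i])
    )
  })
}
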