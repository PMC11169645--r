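#' Specification of a synthetic ROI time-series cohort
#'
#' Describes a two-group cohort of zero-mean multivariate-normal ROI time
#' series whose covariance switches between `n_states` regimes over time.
#' Both groups share a block (community) correlation structure; the patient
#' group's correlation is additionally perturbed by `effect_size` on
#' `effect_edges` — in all states (a static difference) or in a subset
#' (`affected_states`, a dynamic difference). The model consumes only
#' second-order temporal structure, so Gaussian regimes are the minimal
#' sufficient emulation of windowed BOLD covariance dynamics; no hemodynamic
#' convolution, motion or site effects are simulated.
#'
#' Defaults state the desk-scale world the method is validated in: 100
#' subjects per group, 20 ROIs in four communities of five, 240 timepoints
#' (12 windows of 20), two covariance states, and a correlation delta of 0.4
#' planted on 10 between-community edges in the second state only.
#'
#' @param n_subjects_per_group Subjects per group (default 100).
#' @param n_rois Number of ROIs `N` (default 20).
#' @param n_timepoints Series length (default 240).
#' @param window_length Window size `L` the cohort is meant to be analysed at
#'   (default 20); state boundaries align to multiples of it.
#' @param n_states Number of covariance regimes (default 2).
#' @param community_partition Integer vector mapping each ROI to a community;
#'   default: consecutive blocks of 5.
#' @param within_block_corr,between_block_corr Baseline correlations inside /
#'   across communities (defaults 0.3 / 0.05).
#' @param effect_edges Two-column matrix (or list of pairs) of ROI pairs
#'   whose correlation differs between groups; default: 10 fixed edges
#'   between the first two communities.
#' @param effect_size Correlation delta added on `effect_edges` for patients
#'   (default 0.4). Must keep all correlations in (-1, 1).
#' @param affected_states States in which the effect is present (default:
#'   the last state only, i.e. a purely dynamic difference).
#' @param noise_sd Marginal signal standard deviation (default 1).
#' @param align_to_windows If `FALSE`, state boundaries are shifted by half a
#'   window to deliberately misalign regimes and windows.
#' @param schedule `"blocks"` (deterministic contiguous equal blocks,
#'   default) or `"markov"` (per-subject Markov switching, stay probability
#'   0.95).
#' @param seed Integer seed; generation is fully deterministic given it.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_subjects_per_group = 100L, n_rois = 20L,
                        n_timepoints = 240L, window_length = 20L,
                        n_states = 2L, community_partition = NULL,
                        within_block_corr = 0.3, between_block_corr = 0.05,
                        effect_edges = NULL, effect_size = 0.4,
                        affected_states = NULL, noise_sd = 1,
                        align_to_windows = TRUE,
                        schedule = c("blocks", "markov"), seed = 1L) {
  schedule <- match.arg(schedule)
  stopifnot(n_subjects_per_group >= 1, n_rois >= 2, n_timepoints >= 1,
            window_length >= 1, n_states >= 1, noise_sd > 0,
            within_block_corr >= 0, within_block_corr < 1,
            between_block_corr >= 0, between_block_corr < 1)
  if (is.null(community_partition)) {
    community_partition <- rep(seq_len(ceiling(n_rois / 5)),
                               each = 5)[seq_len(n_rois)]
  }
  stopifnot(length(community_partition) == n_rois)
  if (is.null(effect_edges)) {
    blk1 <- which(community_partition == community_partition[1])
    blk2 <- which(community_partition != community_partition[1])
    pairs <- expand.grid(i = blk1, j = blk2[seq_len(min(5, length(blk2)))])
    effect_edges <- as.matrix(pairs[seq_len(min(10L, nrow(pairs))), ])
  }
  if (is.list(effect_edges)) {
    effect_edges <- do.call(rbind, lapply(effect_edges, as.integer))
  }
  effect_edges <- matrix(as.integer(effect_edges), ncol = 2L)
  stopifnot(all(effect_edges >= 1), all(effect_edges <= n_rois),
            all(effect_edges[, 1] != effect_edges[, 2]))
  if (is.null(affected_states)) affected_states <- n_states
  stopifnot(all(affected_states %in% seq_len(n_states)))
  spec <- structure(
    list(n_subjects_per_group = as.integer(n_subjects_per_group),
         n_rois = as.integer(n_rois),
         n_timepoints = as.integer(n_timepoints),
         window_length = as.integer(window_length),
         n_states = as.integer(n_states),
         community_partition = as.integer(community_partition),
         within_block_corr = within_block_corr,
         between_block_corr = between_block_corr,
         effect_edges = effect_edges, effect_size = effect_size,
         affected_states = as.integer(affected_states),
         noise_sd = noise_sd, align_to_windows = isTRUE(align_to_windows),
         schedule = schedule, seed = as.integer(seed)),
    class = "cohort_spec"
  )
  # validate: every implied correlation matrix must be (repairable to) PD
  for (g in 0:1) for (st in seq_len(n_states)) state_correlation(spec, g, st)
  spec
}

#' Target correlation matrix for one group and state
#'
#' @param spec A [cohort_spec()].
#' @param group 0 (control) or 1 (patient).
#' @param state State index.
#' @param quiet Suppress the eigenvalue-repair message.
#' @return `N x N` correlation matrix (positive definite).
#' @export
state_correlation <- function(spec, group, state, quiet = TRUE) {
  n <- spec$n_rois
  cp <- spec$community_partition
  r <- matrix(spec$between_block_corr, n, n)
  same <- outer(cp, cp, "==")
  r[same] <- spec$within_block_corr
  diag(r) <- 1
  if (group == 1L && state %in% spec$affected_states) {
    for (k in seq_len(nrow(spec$effect_edges))) {
      i <- spec$effect_edges[k, 1]; j <- spec$effect_edges[k, 2]
      val <- r[i, j] + spec$effect_size
      if (abs(val) >= 1) stop("effect_size pushes a correlation outside (-1, 1)")
      r[i, j] <- r[j, i] <- val
    }
  }
  ev <- eigen(r, symmetric = TRUE)
  if (min(ev$values) < 1e-8) {
    # repair: clip eigenvalues, renormalise to unit diagonal
    vals <- pmax(ev$values, 1e-6)
    r <- ev$vectors %*% (vals * t(ev$vectors))
    d <- sqrt(diag(r))
    r <- r / outer(d, d)
    if (!quiet) message("state_correlation: eigenvalue-clipped to restore PD")
    if (min(eigen(r, symmetric = TRUE, only.values = TRUE)$values) < 1e-10) {
      stop("correlation matrix not positive definite after repair")
    }
  }
  r
}

state_schedule_blocks <- function(spec) {
  # contiguous equal blocks; boundaries snapped to window multiples
  t_tot <- spec$n_timepoints
  per <- t_tot / spec$n_states
  bounds <- round(seq_len(spec$n_states - 1L) * per /
                    spec$window_length) * spec$window_length
  if (!spec$align_to_windows) bounds <- bounds + spec$window_length %/% 2L
  bounds <- pmin(pmax(bounds, 1L), t_tot - 1L)
  states <- rep(spec$n_states, t_tot)
  prev <- 0L
  for (s in seq_along(bounds)) {
    states[(prev + 1L):bounds[s]] <- s
    prev <- bounds[s]
  }
  if (length(bounds) == 0L) states[] <- 1L
  states
}

#' Per-timepoint state labels for a subject
#'
#' For the default `"blocks"` schedule this is the same deterministic
#' contiguous sequence for every subject; under `"markov"` each subject gets
#' its own switching path (stay probability 0.95), drawn inside
#' [generate_cohort()]'s seeded stream.
#'
#' @param spec A [cohort_spec()].
#' @return Integer vector of length `n_timepoints` (blocks schedule).
#' @export
state_schedule <- function(spec) {
  if (spec$schedule != "blocks") {
    stop("per-subject schedules are drawn inside generate_cohort()")
  }
  state_schedule_blocks(spec)
}

#' Generate a labeled synthetic cohort
#'
#' Draws every subject's series as zero-mean multivariate normal per
#' timepoint with the state-dependent covariance
#' `noise_sd^2 * state_correlation(...)`. Controls come first (label 0), then
#' patients (label 1). Bit-identical across runs with the same spec.
#'
#' @param spec A [cohort_spec()].
#' @return A `roi_cohort` with a manifest recording subject ids and labels.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_rois
  chol_cache <- list()
  get_chol <- function(group, state) {
    key <- paste(group, state)
    if (is.null(chol_cache[[key]])) {
      sig <- spec$noise_sd^2 * state_correlation(spec, group, state)
      chol_cache[[key]] <<- chol(sig)
    }
    chol_cache[[key]]
  }
  subjects <- vector("list", 2L * spec$n_subjects_per_group)
  labels <- integer(length(subjects))
  i <- 0L
  for (group in 0:1) {
    for (s in seq_len(spec$n_subjects_per_group)) {
      i <- i + 1L
      states <- if (spec$schedule == "markov") {
        markov_states(spec$n_timepoints, spec$n_states, stay = 0.95)
      } else {
        state_schedule_blocks(spec)
      }
      x <- matrix(0, n, spec$n_timepoints)
      for (st in unique(states)) {
        cols <- which(states == st)
        z <- matrix(stats::rnorm(length(cols) * n), length(cols), n)
        x[, cols] <- t(z %*% get_chol(group, st))
      }
      id <- sprintf("sub-%s%03d", c("c", "p")[group + 1L], s)
      subjects[[i]] <- roi_time_series(x, id, group)
      labels[i] <- group
    }
  }
  manifest <- tibble::tibble(
    subject_id = vapply(subjects, `[[`, character(1), "subject_id"),
    label = labels
  )
  new_roi_cohort(subjects, manifest)
}

markov_states <- function(t_tot, n_states, stay = 0.95) {
  s <- integer(t_tot)
  s[1] <- 1L
  for (t in 2:t_tot) {
    s[t] <- if (stats::runif(1) < stay) s[t - 1L] else {
      sample(setdiff(seq_len(n_states), s[t - 1L]), 1L)
    }
  }
  s
}

#' Ground-truth group-difference masks
#'
#' One binary `N x N` matrix per state: 1 exactly on the (symmetrised)
#' planted effect edges in affected states, 0 elsewhere, zero diagonal.
#'
#' @param spec A [cohort_spec()].
#' @return List of `n_states` 0/1 matrices.
#' @export
ground_truth_diff_mask <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  lapply(seq_len(spec$n_states), function(st) {
    m <- matrix(0L, spec$n_rois, spec$n_rois)
    if (st %in% spec$affected_states && nrow(spec$effect_edges) > 0) {
      for (k in seq_len(nrow(spec$effect_edges))) {
        i <- spec$effect_edges[k, 1]; j <- spec$effect_edges[k, 2]
        m[i, j] <- m[j, i] <- 1L
      }
    }
    m
  })
}
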