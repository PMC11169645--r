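#' Edge-wise Welch t-test between two groups of connectivity values
#'
#' Vectorised unequal-variance (Welch) two-sample t-test applied
#' column-wise: each column of `x1`/`x2` holds one edge's values across the
#' subjects of a group. Degenerate columns (both group variances zero) give
#' `p = 1` when the group means agree and `p = 0` otherwise.
#'
#' @param x1,x2 Numeric matrices, subjects x edges (>= 2 rows each).
#' @return List of vectors `t`, `df`, `p`.
#' @export
welch_edge_test <- function(x1, x2) {
  n1 <- nrow(x1); n2 <- nrow(x2)
  if (n1 < 2L || n2 < 2L) stop("each group needs at least 2 subjects")
  m1 <- colMeans(x1); m2 <- colMeans(x2)
  v1 <- colSums(sweep(x1, 2L, m1)^2) / (n1 - 1L)
  v2 <- colSums(sweep(x2, 2L, m2)^2) / (n2 - 1L)
  se2 <- v1 / n1 + v2 / n2
  tt <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1L) + (v2 / n2)^2 / (n2 - 1L))
  p <- 2 * stats::pt(-abs(tt), df)
  zero <- se2 == 0
  if (any(zero)) {
    tt[zero] <- 0
    df[zero] <- n1 + n2 - 2L
    p[zero] <- ifelse(m1[zero] == m2[zero], 1, 0)
  }
  list(t = tt, df = df, p = p)
}

#' Group-difference maps of (learned) dynamic FC networks
#'
#' For every window and every ROI pair, collects one connectivity value per
#' subject, runs an edge-wise Welch t-test between patients and controls,
#' and binarises the p-value map with the convention that `p > alpha` maps
#' to 1 and `p <= alpha` to 0 (significant edges are the zeros). A static
#' comparator map computed from full-series Pearson FC is always included.
#'
#' The per-window connectivity can come from a trained model's forward
#' diagnostics — `"connectivity"` (the second-order matrices, default) or
#' `"adjacency"` (the learned graph, symmetrised) — or, with
#' `source = "pearson"`, directly from windowed Pearson correlation of the
#' raw series (no model required).
#'
#' @param cohort A labeled `roi_cohort` with at least 2 subjects per group.
#' @param fit An `astnet_fit`; required unless `source = "pearson"`.
#' @param source Which per-window FC enters the test (see above).
#' @param window_length Window size for `source = "pearson"` without a fit.
#' @param alpha Significance threshold (default 0.05).
#' @param adjust `"none"` (the published convention: raw p at 0.05) or
#'   `"fdr"` (Benjamini-Hochberg, clearly an extension).
#' @return An `fc_diff` object: `maps` (per-window lists with `p_values`,
#'   `binarized`, `segment_index`), `static` (same for full-series Pearson
#'   FC), `alpha`, `source`.
#' @export
group_difference_maps <- function(cohort, fit = NULL,
                                  source = c("connectivity", "adjacency",
                                             "pearson"),
                                  window_length = NULL, alpha = 0.05,
                                  adjust = c("none", "fdr")) {
  source <- match.arg(source)
  adjust <- match.arg(adjust)
  labels <- cohort_labels(cohort)
  if (sum(labels == 1L) < 2L || sum(labels == 0L) < 2L) {
    stop("each group needs at least 2 subjects")
  }
  n <- nrow(cohort$subjects[[1]]$data)
  uidx <- upper_index(n)

  if (source == "pearson") {
    window_length <- window_length %||% fit$model$config$window_length %||%
      stop("`window_length` required when source = 'pearson' and no fit given")
    t_len <- min(vapply(cohort$subjects, function(s) ncol(s$data),
                        integer(1))) %/% window_length
    vals <- lapply(seq_len(t_len), function(t) {
      do.call(rbind, lapply(cohort$subjects, function(s) {
        cols <- ((t - 1L) * window_length + 1L):(t * window_length)
        pearson_fc(s$data[, cols, drop = FALSE])[uidx]
      }))
    })
  } else {
    if (is.null(fit)) stop("`fit` is required unless source = 'pearson'")
    model <- fit$model
    prep <- prepare_cohort_data(cohort, model$config, model$spec)
    t_len <- model$n_windows
    n_sub <- length(cohort$subjects)
    vals <- lapply(seq_len(t_len), function(t) matrix(0, n_sub, length(uidx)))
    for (bi in split(seq_len(n_sub), ceiling(seq_len(n_sub) / 32))) {
      fw <- nn_forward(model$params, model$config, model$spec, prep, bi,
                       training = FALSE, bn_state = model$bn_state,
                       keep_diagnostics = TRUE)
      for (j in seq_along(bi)) {
        for (t in seq_len(t_len)) {
          k <- (j - 1L) * t_len + t
          m <- if (source == "connectivity") {
            fw$diagnostics$connectivity[[k]]
          } else {
            a <- fw$diagnostics$adjacency[[k]]
            (a + t(a)) / 2
          }
          vals[[t]][bi[j], ] <- m[uidx]
        }
      }
    }
  }

  edge_map <- function(mat) {
    res <- welch_edge_test(mat[labels == 1L, , drop = FALSE],
                           mat[labels == 0L, , drop = FALSE])
    p <- res$p
    if (adjust == "fdr") p <- stats::p.adjust(p, method = "BH")
    pm <- matrix_from_upper(p, n, diag = 1)
    list(p_values = pm, binarized = 1L * (pm > alpha))
  }
  maps <- lapply(seq_along(vals), function(t) {
    c(edge_map(vals[[t]]), list(segment_index = t))
  })
  static_vals <- do.call(rbind, lapply(cohort$subjects, function(s) {
    pearson_fc(s$data)[uidx]
  }))
  structure(
    list(maps = maps, static = edge_map(static_vals), alpha = alpha,
         source = source, n_rois = n, n_windows = length(maps)),
    class = "fc_diff"
  )
}

#' @export
print.fc_diff <- function(x, ...) {
  sig <- vapply(x$maps, function(m) {
    mean(m$binarized[upper_index(x$n_rois)] == 0L)
  }, numeric(1))
  cat(sprintf(
    "<fc_diff> %s: %d windows, %.1f%% of edges significant on average (alpha %.2f)\n",
    x$source, x$n_windows, 100 * mean(sig), x$alpha))
  invisible(x)
}

#' Fraction of edges flagged significant per window
#'
#' @param x An `fc_diff`.
#' @return Numeric vector (one entry per window) of the fraction of
#'   off-diagonal edges with `p <= alpha`.
#' @export
significant_fraction <- function(x) {
  stopifnot(inherits(x, "fc_diff"))
  vapply(x$maps, function(m) {
    mean(m$binarized[upper_index(x$n_rois)] == 0L)
  }, numeric(1))
}

#' Window-size sweep
#'
#' Re-partitions, re-trains and re-evaluates a variant at each window
#' length. Lengths longer than the shortest series are recorded as skipped
#' rather than failing the sweep.
#'
#' @param cohort Training cohort.
#' @param test_cohort Held-out cohort for evaluation.
#' @param window_lengths Grid of window sizes (default `c(10, 15, 20, 25,
#'   30)`).
#' @param config Base [astnet_config()]; `window_length` is overridden per
#'   run.
#' @param variant Variant name (default `"ASTNet"`).
#' @param epochs Optional epoch cap passed to [astnet_train()].
#' @param csv_path Optional path to also write the table as CSV.
#' @return Tibble (class `astnet_sweep`) with one row per window length:
#'   `window_length`, `n_windows`, `skipped`, and the [confusion_metrics()]
#'   columns for non-skipped rows.
#' @export
window_sweep <- function(cohort, test_cohort,
                         window_lengths = c(10L, 15L, 20L, 25L, 30L),
                         config = astnet_config(), variant = "ASTNet",
                         epochs = NULL, csv_path = NULL) {
  min_len <- min(vapply(c(cohort$subjects, test_cohort$subjects),
                        function(s) ncol(s$data), integer(1)))
  rows <- lapply(as.integer(window_lengths), function(L) {
    if (min_len < L) {
      return(tibble::tibble(window_length = L, n_windows = NA_integer_,
                            skipped = TRUE))
    }
    L <- as.integer(L)
    cfg <- config
    cfg$window_length <- L
    t_len <- min_len %/% L
    model <- build_variant(variant, cfg, n_windows = t_len,
                           n_timepoints = min_len)
    fit <- astnet_train(model, cohort, epochs = epochs)
    met <- evaluate(fit, test_cohort)
    dplyr::bind_cols(
      tibble::tibble(window_length = L, n_windows = t_len, skipped = FALSE),
      met)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("astnet_sweep", class(out))
  if (!is.null(csv_path)) readr::write_csv(out, csv_path)
  out
}
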