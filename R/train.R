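#' Train a model on a cohort
#'
#' Minimises the joint loss (cross-entropy + graph-learning regulariser) with
#' minibatch Adam. All randomness (shuffling, dropout masks) is seeded from
#' `config$seed`, so two runs with the same inputs produce identical
#' histories. Training stops early when the epoch training loss has not
#' improved by more than `tol` for `config$patience` consecutive epochs.
#'
#' @param model An `astnet_model` from [build_variant()], or an existing
#'   `astnet_fit` to resume from (optimiser state is kept).
#' @param cohort A `roi_cohort`; all subjects must share the ROI count and
#'   (for dynamic variants) yield the model's number of windows.
#' @param epochs,lr,batch_size Override the corresponding config values.
#' @param tol Minimum loss improvement that resets the patience counter.
#' @param monitor Which epoch quantity drives early stopping and
#'   best-checkpoint restoration: `"cross_entropy"` (default) or
#'   `"total_loss"`. The graph-learning regulariser decreases secularly
#'   toward its trivial minimum (the uniform graph), so a total-loss plateau
#'   may never occur; monitoring the classification term stops training — and
#'   snapshots the returned parameters — at the most discriminative epoch.
#' @param history_path Optional path; when given, the per-epoch history is
#'   also written there as CSV.
#' @param verbose Print a line every 10 epochs.
#' @return An `astnet_fit`: the trained model, the per-epoch `history`
#'   tibble (columns `epoch`, `total_loss`, `cross_entropy`, `graph_loss`),
#'   and the optimiser state (for resuming).
#' @export
astnet_train <- function(model, cohort, epochs = NULL, lr = NULL,
                         batch_size = NULL, tol = 1e-4,
                         monitor = c("cross_entropy", "total_loss"),
                         history_path = NULL, verbose = FALSE) {
  monitor <- match.arg(monitor)
  resumed <- inherits(model, "astnet_fit")
  fit0 <- if (resumed) model else NULL
  if (resumed) model <- fit0$model
  stopifnot(inherits(model, "astnet_model"), inherits(cohort, "roi_cohort"))
  n_sub <- length(cohort$subjects)
  if (n_sub == 0L) stop("empty cohort")
  labels <- cohort_labels(cohort)
  if (length(unique(labels)) < 2L) {
    stop("cohort contains a single class; cannot train a classifier")
  }
  config <- model$config
  epochs <- epochs %||% config$epochs
  lr <- lr %||% config$lr
  batch_size <- batch_size %||% config$batch_size
  prep <- prepare_cohort_data(cohort, config, model$spec)
  if (prep$n_windows != model$n_windows) {
    stop(sprintf("model built for T=%d windows but cohort yields T=%d",
                 model$n_windows, prep$n_windows))
  }
  params <- model$params
  bn_state <- model$bn_state
  opt <- if (resumed) fit0$optimizer else adam_init(params)
  set.seed(if (resumed) config$seed + 1000L * nrow(fit0$history) else config$seed)
  history <- vector("list", epochs)
  best <- Inf
  best_snap <- NULL
  best_epoch <- 0L
  wait <- 0L
  n_done <- 0L
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n_sub)
    batches <- split(ord, ceiling(seq_along(ord) / batch_size))
    tot <- ce <- gl <- 0
    for (bi in batches) {
      fw <- nn_forward(params, config, model$spec, prep, bi,
                       training = TRUE, bn_state = bn_state,
                       keep_cache = TRUE)
      bn_state <- fw$bn_state
      grads <- nn_backward(params, config, model$spec, prep, fw)
      upd <- adam_step(params, grads, opt, lr = lr)
      params <- upd$params
      opt <- upd$state
      w <- length(bi) / n_sub
      tot <- tot + fw$total * w
      ce <- ce + fw$ce * w
      gl <- gl + fw$graph_loss * w
    }
    n_done <- ep
    history[[ep]] <- tibble::tibble(epoch = ep, total_loss = tot,
                                    cross_entropy = ce, graph_loss = gl)
    if (verbose && ep %% 10L == 0L) {
      message(sprintf("epoch %3d  total %.4f  ce %.4f  graph %.4f",
                      ep, tot, ce, gl))
    }
    mon_val <- if (monitor == "cross_entropy") ce else tot
    if (mon_val < best - tol) {
      best <- mon_val
      best_snap <- list(params = params, bn_state = bn_state)
      best_epoch <- ep
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$patience) break
    }
  }
  history <- dplyr::bind_rows(history[seq_len(n_done)])
  if (resumed) {
    history$epoch <- history$epoch + nrow(fit0$history)
    history <- dplyr::bind_rows(fit0$history, history)
  }
  if (!is.null(history_path)) readr::write_csv(history, history_path)
  # restore the best-monitored snapshot (standard keep-best practice)
  if (!is.null(best_snap)) {
    model$params <- best_snap$params
    model$bn_state <- best_snap$bn_state
  } else {
    model$params <- params
    model$bn_state <- bn_state
  }
  structure(list(model = model, history = history, optimizer = opt,
                 best_epoch = best_epoch, monitor = monitor),
            class = "astnet_fit")
}

#' @export
print.astnet_fit <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  cat(sprintf(
    "<astnet_fit> %s: %d epochs, final loss %.4f (ce %.4f + graph %.4f)\n",
    x$model$variant, nrow(x$history), last$total_loss, last$cross_entropy,
    last$graph_loss))
  invisible(x)
}

#' Predict class probabilities for a cohort
#'
#' Deterministic evaluation-mode forward pass; the predicted class is the
#' argmax over the two logits.
#'
#' @param object An `astnet_fit`.
#' @param cohort A `roi_cohort`.
#' @param ... Unused.
#' @return Tibble with `subject_id`, `label`, `prob_patient`, `pred`.
#' @export
predict.astnet_fit <- function(object, cohort, ...) {
  model <- object$model
  prep <- prepare_cohort_data(cohort, model$config, model$spec)
  if (prep$n_windows != model$n_windows) {
    stop(sprintf("model built for T=%d windows but cohort yields T=%d",
                 model$n_windows, prep$n_windows))
  }
  n_sub <- length(cohort$subjects)
  probs <- matrix(0, n_sub, 2L)
  for (bi in split(seq_len(n_sub), ceiling(seq_len(n_sub) / 64))) {
    fw <- nn_forward(model$params, model$config, model$spec, prep, bi,
                     training = FALSE, bn_state = model$bn_state)
    probs[bi, ] <- fw$probs
  }
  tibble::tibble(
    subject_id = vapply(cohort$subjects, `[[`, character(1), "subject_id"),
    label = cohort_labels(cohort),
    prob_patient = probs[, 2L],
    pred = as.integer(probs[, 2L] > probs[, 1L])
  )
}

#' Classification metrics from confusion counts
#'
#' ACC, SEN (sensitivity: true-positive rate over patients) and SPE
#' (specificity: true-negative rate over controls), in percent. A
#' zero-denominator ratio is reported as `NaN` with a warning, never
#' silently as 0.
#'
#' @param tp,tn,fp,fn Non-negative integer confusion counts (patients,
#'   label 1, are the positive class).
#' @return One-row tibble `tp`, `tn`, `fp`, `fn`, `acc`, `sen`, `spe`.
#' @export
confusion_metrics <- function(tp, tn, fp, fn) {
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0)
  safe_pct <- function(num, den, what) {
    if (den == 0) {
      warning(sprintf("%s undefined (zero denominator); reporting NaN", what))
      NaN
    } else 100 * num / den
  }
  tibble::tibble(
    tp = as.integer(tp), tn = as.integer(tn),
    fp = as.integer(fp), fn = as.integer(fn),
    acc = safe_pct(tp + tn, tp + tn + fp + fn, "accuracy"),
    sen = safe_pct(tp, tp + fn, "sensitivity"),
    spe = safe_pct(tn, tn + fp, "specificity")
  )
}

#' Evaluate a fitted model on a labeled cohort
#'
#' @param fit An `astnet_fit`.
#' @param cohort A labeled `roi_cohort` (patients = label 1 = positives).
#' @return One-row tibble from [confusion_metrics()].
#' @export
evaluate <- function(fit, cohort) {
  pred <- stats::predict(fit, cohort)
  if (anyNA(pred$label)) stop("cohort contains unlabeled subjects")
  confusion_metrics(
    tp = sum(pred$pred == 1L & pred$label == 1L),
    tn = sum(pred$pred == 0L & pred$label == 0L),
    fp = sum(pred$pred == 1L & pred$label == 0L),
    fn = sum(pred$pred == 0L & pred$label == 1L)
  )
}

#' Stratified train/test split of a cohort
#'
#' @param cohort A `roi_cohort`.
#' @param test_frac Fraction of each class held out (default 0.3).
#' @param seed Seed for the split.
#' @return List with `train` and `test` cohorts.
#' @export
cohort_split <- function(cohort, test_frac = 0.3, seed = 1L) {
  labels <- cohort_labels(cohort)
  set.seed(seed)
  test_idx <- unlist(lapply(unique(labels), function(l) {
    i <- which(labels == l)
    sample(i, round(length(i) * test_frac))
  }))
  list(train = cohort_subset(cohort, setdiff(seq_along(labels), test_idx)),
       test = cohort_subset(cohort, sort(test_idx)))
}

#' Save / load a fitted model
#'
#' The fit is serialised with [saveRDS()]; a JSON sidecar (`<path>.json`)
#' records the variant, configuration and seed for provenance.
#'
#' @param fit An `astnet_fit`.
#' @param path Destination `.rds` path.
#' @return `path`, invisibly.
#' @export
astnet_save <- function(fit, path) {
  stopifnot(inherits(fit, "astnet_fit"))
  saveRDS(fit, path)
  side <- fit$model$config
  side$variant <- fit$model$variant
  side$n_windows <- fit$model$n_windows
  writeLines(to_json(side), paste0(path, ".json"))
  invisible(path)
}

#' @rdname astnet_save
#' @export
astnet_load <- function(path) {
  fit <- readRDS(path)
  stopifnot(inherits(fit, "astnet_fit"))
  fit
}

# minimal JSON writer for the flat config sidecar (avoids a jsonlite import)
to_json <- function(x) {
  enc <- function(v) {
    if (is.character(v)) {
      sprintf('"%s"', v)
    } else if (is.logical(v)) {
      tolower(as.character(v))
    } else {
      format(v, digits = 15)
    }
  }
  items <- vapply(names(x), function(nm) {
    v <- x[[nm]]
    if (is.matrix(v)) v <- as.vector(v)
    body <- if (length(v) == 1L) enc(v) else {
      paste0("[", paste(enc(v), collapse = ","), "]")
    }
    sprintf('"%s": %s', nm, body)
  }, character(1))
  paste0("{", paste(items, collapse = ", "), "}")
}
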