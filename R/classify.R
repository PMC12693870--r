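#' Build a labeled feature set from simulated streams
#'
#' Simulates `n_streams` single-class streams per nominal diameter, runs the
#' derivative pipeline on each, and pools the extracted (dV, dt) features
#' labeled with the stream's class. Expected event counts are equal across
#' classes (same concentration and flow).
#'
#' @param diameters_um Numeric vector of nominal diameters, one class each.
#' @param n_streams Streams per class.
#' @param base_config A [sim_config()] supplying all other parameters.
#' @param master_seed Integer; stream seeds derive from it.
#' @param cfg Optional [detector_config()]; default is matched to the
#'   simulation kinematics per stream.
#' @return data.frame of class `labeled_features` with `dV_V`, `dt_s`,
#'   `label` (factor), `stream`, `seed`.
#' @export
build_labeled_features <- function(diameters_um, n_streams,
                                   base_config = sim_config(),
                                   master_seed = 1, cfg = NULL) {
  seeds <- derive_seeds(master_seed, length(diameters_um) * n_streams)
  rows <- list()
  k <- 0L
  for (d in diameters_um) {
    scfg0 <- base_config
    scfg0$D_um <- d
    scfg0 <- validate_sim_config(scfg0)
    dcfg <- if (is.null(cfg)) detector_config_for(scfg0) else cfg
    for (s in seq_len(n_streams)) {
      k <- k + 1L
      scfg <- scfg0; scfg$seed <- seeds[k]
      stream <- synthesize_stream(scfg, keep_components = FALSE)
      ev <- run_pipeline(stream$trace, dcfg)
      if (nrow(ev))
        rows[[length(rows) + 1L]] <- data.frame(
          dV_V = ev$dV_V, dt_s = ev$dt_s,
          label = paste0(format(d, trim = TRUE), "um"),
          stream = k, seed = seeds[k])
    }
  }
  out <- do.call(rbind, rows)
  out$label <- factor(out$label)
  class(out) <- c("labeled_features", "data.frame")
  out
}

#' Train a decision tree on (dV, dt) features
#'
#' CART-style greedy Gini-impurity splitting (via rpart) on the two features,
#' with a seeded stratified hold-out split for the training report.
#' Deterministic for fixed data and seed.
#'
#' @param data A `labeled_features` data.frame (columns `dV_V`, `dt_s`,
#'   `label`).
#' @param max_depth Maximum tree depth (default 3).
#' @param min_leaf Minimum observations per leaf (default 5).
#' @param holdout Fraction held out per class for the report (default 0.3);
#'   0 trains on everything and skips the report.
#' @param seed Seed for the stratified split.
#' @return Object of class `pulse_tree`: list with the fitted `rpart` model,
#'   `classes`, `settings`, and `report` (held-out confusion matrix and
#'   per-class precision/recall; NULL when `holdout = 0`).
#' @export
train_tree <- function(data, max_depth = 3, min_leaf = 5, holdout = 0.3,
                       seed = 1) {
  stopifnot(all(c("dV_V", "dt_s", "label") %in% names(data)))
  data <- data[is.finite(data$dV_V) & is.finite(data$dt_s), , drop = FALSE]
  data$label <- factor(data$label)
  if (nlevels(data$label) < 2L) {
    warning("single-class data: degenerate single-leaf model")
    return(structure(list(model = NULL, classes = levels(data$label),
                          settings = list(max_depth = max_depth,
                                          min_leaf = min_leaf,
                                          holdout = holdout, seed = seed),
                          report = NULL),
                     class = "pulse_tree"))
  }
  idx_test <- integer(0)
  if (holdout > 0 && nlevels(data$label) >= 2L) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(seed)
    idx_test <- unlist(lapply(split(seq_len(nrow(data)), data$label),
                              function(ix) sample(ix, round(holdout * length(ix)))))
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }
  train <- if (length(idx_test)) data[-idx_test, , drop = FALSE] else data
  fit <- rpart::rpart(label ~ dV_V + dt_s, data = train, method = "class",
                      parms = list(split = "gini"),
                      control = rpart::rpart.control(
                        maxdepth = max_depth, minbucket = min_leaf,
                        minsplit = max(2L * min_leaf, 2L),
                        cp = 0, xval = 0,
                        maxcompete = 0, maxsurrogate = 0))
  report <- NULL
  if (length(idx_test)) {
    test <- data[idx_test, , drop = FALSE]
    pred <- predict(fit, test, type = "class")
    report <- confusion_report(test$label, pred)
  }
  structure(list(model = fit, classes = levels(data$label),
                 settings = list(max_depth = max_depth, min_leaf = min_leaf,
                                 holdout = holdout, seed = seed),
                 report = report),
            class = "pulse_tree")
}

# confusion matrix plus per-class precision/recall
confusion_report <- function(truth, pred) {
  truth <- factor(truth)
  pred <- factor(pred, levels = levels(truth))
  cm <- table(truth = truth, predicted = pred)
  prec <- diag(cm) / pmax(colSums(cm), 1)
  rec <- diag(cm) / pmax(rowSums(cm), 1)
  list(confusion = cm,
       per_class = data.frame(class = rownames(cm),
                              precision = as.numeric(prec),
                              recall = as.numeric(rec)),
       accuracy = sum(diag(cm)) / sum(cm))
}

#' @export
print.pulse_tree <- function(x, ...) {
  cat(sprintf("<pulse_tree> %d classes, max_depth=%d, min_leaf=%d\n",
              length(x$classes), x$settings$max_depth, x$settings$min_leaf))
  if (!is.null(x$report)) {
    cat(sprintf("held-out accuracy: %.4f\n", x$report$accuracy))
    print(x$report$per_class, row.names = FALSE)
  }
  invisible(x)
}

#' Predict particle classes for extracted features
#'
#' Deterministic leaf lookup; cost is O(depth) per event. Rows with
#' non-finite features are rejected (label `NA`, posterior `NA`) rather than
#' assigned a class. At a split threshold, values strictly below the
#' threshold go left; a value exactly equal to the threshold follows the
#' right branch.
#'
#' @param object A `pulse_tree`.
#' @param features data.frame with columns `dV_V`, `dt_s`.
#' @param ... Unused.
#' @return data.frame with `label` (character) and `posterior` (leaf
#'   posterior of the winning class).
#' @export
predict.pulse_tree <- function(object, features, ...) {
  stopifnot(all(c("dV_V", "dt_s") %in% names(features)))
  n <- nrow(features)
  out <- data.frame(label = rep(NA_character_, n),
                    posterior = rep(NA_real_, n))
  ok <- is.finite(features$dV_V) & is.finite(features$dt_s)
  if (is.null(object$model)) {       # degenerate single-leaf model
    out$label[ok] <- object$classes[1L]
    out$posterior[ok] <- 1
    return(out)
  }
  if (any(ok)) {
    pr <- predict(object$model, features[ok, , drop = FALSE], type = "prob")
    win <- max.col(pr, ties.method = "first")
    out$label[ok] <- colnames(pr)[win]
    out$posterior[ok] <- pr[cbind(seq_len(nrow(pr)), win)]
  }
  out
}

#' Serialize a trained tree to portable JSON
#'
#' Walks the rpart frame into a plain nested structure (split variable,
#' threshold, direction, leaf class posteriors) so a model can be stored,
#' inspected, or applied outside R.
#'
#' @param tree A `pulse_tree`.
#' @param path Optional file to write; when `NULL` the JSON string is
#'   returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
tree_to_json <- function(tree, path = NULL) {
  fit <- tree$model
  fr <- fit$frame
  node_ids <- as.integer(rownames(fr))
  splits <- fit$splits
  ylev <- attr(fit, "ylevels")
  ncls <- length(ylev)
  # posterior columns of frame$yval2: ncls counts then ncls proportions
  build <- function(id) {
    r <- which(node_ids == id)
    if (fr$var[r] == "<leaf>") {
      post <- fr$yval2[r, (1 + ncls + 1):(1 + 2 * ncls)]
      return(list(leaf = TRUE,
                  class = ylev[fr$yval2[r, 1]],
                  posterior = as.list(stats::setNames(as.numeric(post), ylev))))
    }
    # with maxcompete = maxsurrogate = 0 the splits rows are exactly the
    # primary splits of the non-leaf frame rows, in frame (pre)order
    nonleaf <- which(fr$var != "<leaf>")
    sp <- splits[match(r, nonleaf), , drop = TRUE]
    left_lt <- sp[["ncat"]] < 0  # ncat = -1: x < threshold goes left
    list(leaf = FALSE,
         var = as.character(fr$var[r]),
         threshold = as.numeric(sp[["index"]]),
         left_if_less = isTRUE(left_lt),
         left = build(2L * id), right = build(2L * id + 1L))
  }
  obj <- list(classes = ylev,
              settings = tree$settings[c("max_depth", "min_leaf")],
              root = build(1L))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}

#' Load a JSON tree and predict with it
#'
#' @param path JSON file written by [tree_to_json()] (or a JSON string).
#' @return Object of class `pulse_tree_json` usable with
#'   [predict.pulse_tree_json()].
#' @export
tree_from_json <- function(path) {
  txt <- if (file.exists(path)) paste(readLines(path), collapse = "\n") else path
  obj <- jsonlite::fromJSON(txt, simplifyVector = FALSE)
  class(obj) <- "pulse_tree_json"
  obj
}

#' @rdname tree_from_json
#' @param object A `pulse_tree_json`.
#' @param features data.frame with `dV_V`, `dt_s`.
#' @param ... Unused.
#' @export
predict.pulse_tree_json <- function(object, features, ...) {
  walk <- function(node, x) {
    while (!isTRUE(node$leaf)) {
      v <- x[[node$var]]
      go_left <- if (node$left_if_less) v < node$threshold else v >= node$threshold
      node <- if (go_left) node$left else node$right
    }
    node
  }
  n <- nrow(features)
  out <- data.frame(label = rep(NA_character_, n),
                    posterior = rep(NA_real_, n))
  for (i in seq_len(n)) {
    x <- list(dV_V = features$dV_V[i], dt_s = features$dt_s[i])
    if (!is.finite(x$dV_V) || !is.finite(x$dt_s)) next
    leaf <- walk(object$root, x)
    out$label[i] <- leaf$class
    out$posterior[i] <- as.numeric(leaf$posterior[[leaf$class]])
  }
  out
}

#' End-to-end two-class classification experiment
#'
#' Simulates labeled training streams for each nominal diameter, trains the
#' decision tree on derivative-extracted (dV, dt) features, simulates fresh
#' evaluation streams, and scores per-class precision and recall of the
#' predictions against the evaluation streams' class labels.
#'
#' @param diameters_um Nominal diameters, one class each (default 4 and 7 um).
#' @param n_train Training streams per class (default 15, i.e. 30 total for
#'   two classes).
#' @param n_eval Fresh evaluation streams per class (default 5).
#' @param base_config A [sim_config()] for everything except diameter.
#' @param master_seed Integer; training/evaluation stream seeds and the
#'   hold-out split derive from it.
#' @param ... Passed to [train_tree()].
#' @return List with `tree`, `per_class` (precision/recall on the fresh
#'   evaluation events), `accuracy`, `min_pr` (the minimum over per-class
#'   precision and recall), `n_eval_events`.
#' @export
classification_experiment <- function(diameters_um = c(4, 7), n_train = 15,
                                      n_eval = 5, base_config = sim_config(),
                                      master_seed = 1, ...) {
  seeds <- derive_seeds(master_seed, 3)
  train_feats <- build_labeled_features(diameters_um, n_train,
                                        base_config, seeds[1])
  tree <- train_tree(train_feats, seed = seeds[2], ...)
  eval_feats <- build_labeled_features(diameters_um, n_eval,
                                       base_config, seeds[3])
  pred <- predict(tree, eval_feats)
  rep <- confusion_report(eval_feats$label,
                          factor(pred$label, levels = levels(eval_feats$label)))
  list(tree = tree, per_class = rep$per_class, accuracy = rep$accuracy,
       min_pr = min(rep$per_class$precision, rep$per_class$recall),
       n_eval_events = nrow(eval_feats))
}

#' Chunked detection and classification of a streaming trace
#'
#' Processes the trace in chunks of `chunk_s` seconds, each extended by
#' `overlap_s` on both sides so events straddling a chunk boundary are seen
#' whole; an event is kept by the chunk that owns its centre. With a fixed
#' threshold the output equals whole-trace processing except possibly in the
#' final partial chunk. The threshold is resolved once (on the first chunk
#' when `theta` is NULL) and then frozen, as a streaming consumer would.
#'
#' @param trace A [signal_trace()].
#' @param model A trained `pulse_tree` (or NULL to skip classification).
#' @param cfg A [detector_config()].
#' @param chunk_s Chunk duration (s); must cover several transit times.
#' @param overlap_s Overlap on each side (s).
#' @param theta Optional fixed threshold (V/s).
#' @return Detected-event data.frame with `label` and `posterior` columns
#'   appended (NA when `model` is NULL), plus attribute `chunk_times_s`
#'   (per-chunk processing seconds).
#' @export
stream_classify <- function(trace, model = NULL, cfg = detector_config(),
                            chunk_s = 1, overlap_s = 0.01, theta = NULL) {
  stopifnot(inherits(trace, "signal_trace"))
  fs <- trace$fs
  n <- length(trace$samples)
  chunk_n <- as.integer(round(chunk_s * fs))
  if (chunk_n < 3L) stop("chunk shorter than 3 samples")
  ov_n <- as.integer(round(overlap_s * fs))
  starts <- seq.int(1L, n, by = chunk_n)
  out <- list()
  times <- numeric(0)
  for (cs in starts) {
    ce <- min(n, cs + chunk_n - 1L)
    lo <- max(1L, cs - ov_n)
    hi <- min(n, ce + ov_n)
    if (hi - lo + 1L < 3L) next
    tic <- proc.time()[["elapsed"]]
    sub <- signal_trace(trace$samples[lo:hi], fs,
                        trace$t_start + (lo - 1L) / fs)
    if (is.null(theta)) {
      d <- compute_derivative(sub)
      theta <- auto_threshold(d, cfg$auto_k)
      if (!is.null(cfg$threshold_V_s)) theta <- cfg$threshold_V_s
    }
    ev <- run_pipeline(sub, cfg, theta = theta)
    times <- c(times, proc.time()[["elapsed"]] - tic)
    if (!nrow(ev)) next
    centre <- event_centers(ev)
    core_lo <- trace$t_start + (cs - 1L) / fs
    core_hi <- trace$t_start + ce / fs
    keep <- centre >= core_lo & centre < core_hi
    ev <- ev[keep, , drop = FALSE]
    if (nrow(ev)) {
      # shift landmark indices back to whole-trace coordinates
      for (col in c("left_idx", "pos_idx", "neg_idx", "right_idx"))
        ev[[col]] <- ev[[col]] + lo - 1L
      out[[length(out) + 1L]] <- ev
    }
  }
  ev <- if (length(out)) do.call(rbind, out) else empty_events()
  if (nrow(ev)) {
    ev <- ev[order(ev$t_pos_s), , drop = FALSE]
    ev$event_id <- seq_len(nrow(ev))
    rownames(ev) <- NULL
  }
  if (!is.null(model) && nrow(ev)) {
    pred <- predict(model, ev)
    ev$label <- pred$label
    ev$posterior <- pred$posterior
  } else {
    ev$label <- rep(NA_character_, nrow(ev))
    ev$posterior <- rep(NA_real_, nrow(ev))
  }
  attr(ev, "chunk_times_s") <- times
  attr(ev, "theta") <- if (is.null(theta)) NA_real_ else as.numeric(theta)
  ev
}
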