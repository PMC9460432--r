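# Training of the recurrent classifiers (and baseline wrappers).
#
# Each fused feature row is a 20-value vector [ecd, 19 EEG features]; for
# the recurrent models it is fed as a length-20 sequence of scalar inputs
# (one feature per timestep). The recurrent layer's per-position states
# are mean-pooled (both directions concatenated for the bidirectional
# variants), passed through dropout and a 3-unit dense softmax layer, and
# trained with cross-entropy under Adam. Backpropagation through time is
# hand-implemented and validated against finite differences in the tests.

#' Training configuration
#'
#' Defaults are the published configuration: 128 hidden units, at most 30
#' epochs with at least 600 optimizer steps, learning rate 0.005, dropout
#' 0.2, 3 output classes.
#'
#' @param hidden_units recurrent state size.
#' @param max_epochs maximum passes over the training rows.
#' @param min_steps minimum number of optimizer (minibatch) steps; epochs
#'   continue past `max_epochs` until this floor is reached.
#' @param learning_rate Adam step size.
#' @param dropout drop probability on the pooled representation.
#' @param n_classes number of output classes.
#' @param batch_size minibatch size.
#' @param seed seed for initialization, shuffling and dropout.
#' @export
train_config <- function(hidden_units = 128, max_epochs = 30, min_steps = 600,
                         learning_rate = 0.005, dropout = 0.2, n_classes = 3,
                         batch_size = 32, seed = 1) {
  stopifnot(dropout >= 0, dropout < 1, n_classes == round(n_classes))
  structure(list(hidden_units = hidden_units, max_epochs = max_epochs,
                 min_steps = min_steps, learning_rate = learning_rate,
                 dropout = dropout, n_classes = n_classes,
                 batch_size = batch_size, seed = seed),
            class = "train_config")
}

RECURRENT_MODELS <- c("bigru", "gru", "lstm", "bilstm")
BASELINE_MODELS <- c("svm", "knn", "rf")

zero_like <- function(p) {
  if (is.list(p)) lapply(p, zero_like)
  else if (is.numeric(p)) p * 0
  else p
}

map_params <- function(f, ...) {
  args <- list(...)
  p <- args[[1L]]
  if (is.list(p)) {
    out <- p
    for (nm in names(p)) {
      if (is.list(p[[nm]]) || is.numeric(p[[nm]]))
        out[[nm]] <- do.call(map_params, c(list(f), lapply(args, `[[`, nm)))
    }
    out
  } else if (is.numeric(p)) {
    do.call(f, args)
  } else p
}

new_recurrent_net <- function(type, hidden, n_classes) {
  bidir <- type %in% c("bigru", "bilstm")
  make <- if (type %in% c("gru", "bigru")) gru_cell else lstm_cell
  cells <- list(f = make(1L, hidden))
  if (bidir) cells$b <- make(1L, hidden)
  pooled_dim <- hidden * (1L + bidir)
  list(cells = cells, W_out = glorot(pooled_dim, n_classes),
       b_out = numeric(n_classes), type = type, hidden = hidden,
       bidirectional = bidir, n_classes = n_classes)
}

# ---- forward with caches ---------------------------------------------------

run_direction_fwd <- function(cell, X, reverse = FALSE) {
  B <- nrow(X); Tn <- ncol(X); hs <- cell$hidden_size
  order_t <- if (reverse) rev(seq_len(Tn)) else seq_len(Tn)
  h <- matrix(0, B, hs)
  cache <- vector("list", Tn)
  if (inherits(cell, "lstm_cell")) {
    cc <- matrix(0, B, hs)
    for (k in seq_along(order_t)) {
      t <- order_t[k]
      st <- lstm_step(cell, h, cc, matrix(X[, t], ncol = 1), detail = TRUE)
      cache[[k]] <- c(st, list(h_prev = h, c_prev = cc, x = X[, t]))
      h <- st$h; cc <- st$c
    }
  } else {
    for (k in seq_along(order_t)) {
      t <- order_t[k]
      st <- gru_step(cell, h, matrix(X[, t], ncol = 1), detail = TRUE)
      cache[[k]] <- c(st, list(h_prev = h, x = X[, t]))
      h <- st$h
    }
  }
  list(cache = cache, order_t = order_t, mean_h = Reduce(
    `+`, lapply(cache, `[[`, "h")) / Tn)
}

# ---- backward through one direction ---------------------------------------

run_direction_bwd <- function(cell, fwd, d_mean_h) {
  Tn <- length(fwd$cache)
  B <- nrow(d_mean_h)
  hs <- cell$hidden_size
  d_step <- d_mean_h / Tn                       # mean pooling spreads evenly
  grads <- zero_like(cell)
  dh_carry <- matrix(0, B, hs)
  lstm <- inherits(cell, "lstm_cell")
  if (lstm) dc_carry <- matrix(0, B, hs)
  for (k in rev(seq_len(Tn))) {
    cc <- fwd$cache[[k]]
    dh <- d_step + dh_carry
    A <- cbind(cc$h_prev, cc$x)
    if (lstm) {
      tc <- tanh(cc$c)
      do_ <- dh * tc
      dc <- dc_carry + dh * cc$o * (1 - tc^2)
      df <- dc * cc$c_prev
      di <- dc * cc$g
      dg <- dc * cc$i
      dc_carry <- dc * cc$f
      da_f <- df * cc$f * (1 - cc$f)
      da_i <- di * cc$i * (1 - cc$i)
      da_o <- do_ * cc$o * (1 - cc$o)
      da_g <- dg * (1 - cc$g^2)
      grads$W_f <- grads$W_f + crossprod(A, da_f)
      grads$W_i <- grads$W_i + crossprod(A, da_i)
      grads$W_o <- grads$W_o + crossprod(A, da_o)
      grads$W_g <- grads$W_g + crossprod(A, da_g)
      grads$b_f <- grads$b_f + colSums(da_f)
      grads$b_i <- grads$b_i + colSums(da_i)
      grads$b_o <- grads$b_o + colSums(da_o)
      grads$b_g <- grads$b_g + colSums(da_g)
      dA <- da_f %*% t(cell$W_f) + da_i %*% t(cell$W_i) +
            da_o %*% t(cell$W_o) + da_g %*% t(cell$W_g)
      dh_carry <- dA[, seq_len(hs), drop = FALSE]
    } else {
      dz <- dh * (cc$hc - cc$h_prev)
      dhc <- dh * cc$z
      dh_prev <- dh * (1 - cc$z)
      da_h <- dhc * (1 - cc$hc^2)
      A2 <- cbind(cc$h_prev * cc$r, cc$x)
      grads$W_h <- grads$W_h + crossprod(A2, da_h)
      grads$b_h <- grads$b_h + colSums(da_h)
      dA2 <- da_h %*% t(cell$W_h)
      dHr <- dA2[, seq_len(hs), drop = FALSE]
      dh_prev <- dh_prev + dHr * cc$r
      dr <- dHr * cc$h_prev
      da_r <- dr * cc$r * (1 - cc$r)
      da_z <- dz * cc$z * (1 - cc$z)
      grads$W_r <- grads$W_r + crossprod(A, da_r)
      grads$b_r <- grads$b_r + colSums(da_r)
      grads$W_z <- grads$W_z + crossprod(A, da_z)
      grads$b_z <- grads$b_z + colSums(da_z)
      dA <- da_r %*% t(cell$W_r) + da_z %*% t(cell$W_z)
      dh_prev <- dh_prev + dA[, seq_len(hs), drop = FALSE]
      dh_carry <- dh_prev
    }
  }
  grads
}

# Forward (+ optional backward) pass of the full network on a minibatch.
# y: integer labels 1..K; drop_mask: NULL or B x pooled_dim multiplier.
net_pass <- function(net, X, y = NULL, drop_mask = NULL, grads = FALSE) {
  fwd_f <- run_direction_fwd(net$cells$f, X, reverse = FALSE)
  pooled <- fwd_f$mean_h
  if (net$bidirectional) {
    fwd_b <- run_direction_fwd(net$cells$b, X, reverse = TRUE)
    pooled <- cbind(pooled, fwd_b$mean_h)
  }
  dropped <- if (is.null(drop_mask)) pooled else pooled * drop_mask
  logits <- sweep(dropped %*% net$W_out, 2, net$b_out, "+")
  m <- apply(logits, 1, max)
  expl <- exp(logits - m)
  probs <- expl / rowSums(expl)
  out <- list(probs = probs)
  if (!is.null(y)) {
    B <- nrow(X)
    out$loss <- -mean(log(pmax(probs[cbind(seq_len(B), y)], 1e-300)))
    if (grads) {
      Y <- matrix(0, B, net$n_classes)
      Y[cbind(seq_len(B), y)] <- 1
      dlogits <- (probs - Y) / B
      g <- list(W_out = crossprod(dropped, dlogits),
                b_out = colSums(dlogits), cells = list())
      dpooled <- dlogits %*% t(net$W_out)
      if (!is.null(drop_mask)) dpooled <- dpooled * drop_mask
      hs <- net$hidden
      g$cells$f <- run_direction_bwd(net$cells$f, fwd_f,
                                     dpooled[, seq_len(hs), drop = FALSE])
      if (net$bidirectional)
        g$cells$b <- run_direction_bwd(net$cells$b, fwd_b,
                                       dpooled[, hs + seq_len(hs), drop = FALSE])
      out$grads <- g
    }
  }
  out
}

adam_update <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8) {
  state$t <- state$t + 1
  state$m <- map_params(function(m, g) beta1 * m + (1 - beta1) * g,
                        state$m, grads)
  state$v <- map_params(function(v, g) beta2 * v + (1 - beta2) * g^2,
                        state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  params <- map_params(function(p, m, v)
    p - lr * (m / bc1) / (sqrt(v / bc2) + eps),
    params, state$m, state$v)
  list(params = params, state = state)
}

train_recurrent <- function(X, y, type, config) {
  set.seed(config$seed)
  net <- new_recurrent_net(type, config$hidden_units, config$n_classes)
  trainable <- list(cells = net$cells, W_out = net$W_out, b_out = net$b_out)
  astate <- list(m = zero_like(trainable), v = zero_like(trainable), t = 0)
  n <- nrow(X)
  bs <- min(config$batch_size, n)
  steps_per_epoch <- ceiling(n / bs)
  pooled_dim <- config$hidden_units * (1L + (type %in% c("bigru", "bilstm")))
  steps <- 0; epoch <- 0
  history <- numeric(0)
  while (epoch < config$max_epochs || steps < config$min_steps) {
    epoch <- epoch + 1
    perm <- sample.int(n)
    epoch_loss <- 0
    for (b in seq_len(steps_per_epoch)) {
      idx <- perm[((b - 1) * bs + 1):min(b * bs, n)]
      Xb <- X[idx, , drop = FALSE]
      yb <- y[idx]
      mask <- NULL
      if (config$dropout > 0) {
        keep <- 1 - config$dropout
        mask <- matrix(stats::rbinom(length(idx) * pooled_dim, 1, keep) / keep,
                       nrow = length(idx))
      }
      pass <- net_pass(net, Xb, yb, drop_mask = mask, grads = TRUE)
      upd <- adam_update(trainable, pass$grads, astate,
                         lr = config$learning_rate)
      trainable <- upd$params
      astate <- upd$state
      net$cells <- trainable$cells
      net$W_out <- trainable$W_out
      net$b_out <- trainable$b_out
      steps <- steps + 1
      epoch_loss <- epoch_loss + pass$loss
    }
    history <- c(history, epoch_loss / steps_per_epoch)
    if (epoch > 10 * config$max_epochs) break   # safety
  }
  net$history <- history
  net
}

#' Train a fatigue classifier on fused feature rows
#'
#' Recurrent models (`"bigru"`, `"gru"`, `"lstm"`, `"bilstm"`) feed each
#' row's feature vector as a sequence of scalar inputs and are trained
#' with Adam on softmax cross-entropy. Baselines wrap standard
#' implementations: `"svm"` (radial-basis e1071::svm), `"knn"`
#' (class::knn, k = 5), `"rf"` (randomForest, 500 trees, with feature
#' importances).
#'
#' @param rows feature table (already standardized with training-split
#'   statistics) containing the feature columns and a `label` column with
#'   values in 1..n_classes.
#' @param model model name.
#' @param config a [train_config()].
#' @param feature_cols feature columns fed to the model, in sequence
#'   order; default the fused 20 (`ecd` + 19 EEG features).
#' @return object of class `fatigue_classifier`.
#' @export
train_classifier <- function(rows, model = "bigru", config = train_config(),
                             feature_cols = c("ecd", EEG_FEATURE_NAMES)) {
  model <- match.arg(model, c(RECURRENT_MODELS, BASELINE_MODELS))
  labs <- rows$label
  if (any(!labs %in% seq_len(config$n_classes)))
    stop("labels must lie in 1..", config$n_classes)
  X <- as.matrix(rows[, feature_cols, drop = FALSE])
  fit <- if (model %in% RECURRENT_MODELS) {
    train_recurrent(X, as.integer(labs), model, config)
  } else {
    set.seed(config$seed)
    yf <- factor(labs, levels = seq_len(config$n_classes))
    switch(model,
      svm = e1071::svm(X, yf, kernel = "radial"),
      knn = list(train_x = X, train_y = yf, k = 5L),
      rf  = randomForest::randomForest(X, yf, ntree = 500, importance = TRUE))
  }
  structure(list(model = model, fit = fit, config = config,
                 feature_cols = feature_cols),
            class = "fatigue_classifier")
}

#' Predict fatigue labels for feature rows
#'
#' @param object a `fatigue_classifier`.
#' @param rows feature table standardized with the training statistics.
#' @param ... unused.
#' @return integer labels, one per row.
#' @export
predict.fatigue_classifier <- function(object, rows, ...) {
  missing <- setdiff(object$feature_cols, names(rows))
  if (length(missing))
    stop("rows lack feature column(s): ", paste(missing, collapse = ", "))
  X <- as.matrix(rows[, object$feature_cols, drop = FALSE])
  if (object$model %in% RECURRENT_MODELS) {
    probs <- net_pass(object$fit, X)$probs
    max.col(probs, ties.method = "first")
  } else if (object$model == "svm") {
    as.integer(as.character(stats::predict(object$fit, X)))
  } else if (object$model == "knn") {
    set.seed(object$config$seed)   # deterministic distant-tie resolution
    as.integer(as.character(class::knn(object$fit$train_x, X,
                                       object$fit$train_y, k = object$fit$k)))
  } else {
    as.integer(as.character(stats::predict(object$fit, X)))
  }
}

#' Subject-wise cross-validation plan
#'
#' Partitions subjects into folds (21 subjects and 7 folds give the
#' published 18:3 train:test split per fold); every subject is held out
#' exactly once.
#'
#' @param subjects vector of subject identifiers.
#' @param n_folds number of folds (default 7).
#' @param seed shuffle seed.
#' @return object of class `cv_plan`: list of per-fold held-out subjects.
#' @export
make_cv_plan <- function(subjects, n_folds = 7, seed = 1) {
  subjects <- unique(subjects)
  if (length(subjects) < n_folds)
    stop("need at least as many subjects as folds")
  set.seed(seed)
  shuffled <- sample(subjects)
  folds <- split(shuffled, rep(seq_len(n_folds), length.out = length(shuffled)))
  structure(list(folds = unname(folds), n_folds = n_folds), class = "cv_plan")
}

#' Subject-wise cross-validation with per-row and voted accuracy
#'
#' For each fold, feature standardization is refit on the training
#' subjects only, a classifier is trained, held-out rows are predicted,
#' and the three channel predictions of each sample are corrected by
#' majority vote ([majority_vote()]).
#'
#' @param rows fused feature table with `subject`, `sample_id`, `channel`,
#'   feature columns and `label` (unstandardized; scaling is fit per fold).
#' @param model model name (see [train_classifier()]).
#' @param config a [train_config()].
#' @param plan a [make_cv_plan()]; default builds a 7-fold plan from the
#'   subjects present.
#' @param feature_cols columns fed to the classifier.
#' @param folds optional subset of fold indices to run (default all).
#' @return list with `fold_metrics` (data frame: fold, n_rows, row
#'   accuracy, voted per-sample accuracy), `mean_row_accuracy`,
#'   `mean_sample_accuracy`, and `predictions` (per-row table in the
#'   published layout: sample_id, channel, pred_label, vote_label,
#'   real_label).
#' @export
cross_validate <- function(rows, model = "bigru", config = train_config(),
                           plan = NULL,
                           feature_cols = c("ecd", EEG_FEATURE_NAMES),
                           folds = NULL) {
  if (is.null(plan)) plan <- make_cv_plan(unique(rows$subject), seed = config$seed)
  if (is.null(folds)) folds <- seq_len(plan$n_folds)
  all_subj <- unique(rows$subject)
  metrics <- data.frame()
  pred_tables <- list()
  for (fi in folds) {
    test_subj <- plan$folds[[fi]]
    train_subj <- setdiff(all_subj, test_subj)
    if (length(intersect(train_subj, test_subj)))
      stop("cv plan error: subject in both train and test")
    tr <- rows[rows$subject %in% train_subj, , drop = FALSE]
    te <- rows[rows$subject %in% test_subj, , drop = FALSE]
    scaling <- fit_feature_scaling(tr)
    tr_s <- standardize_features(tr, scaling)
    te_s <- standardize_features(te, scaling)
    clf <- train_classifier(tr_s, model = model, config = config,
                            feature_cols = feature_cols)
    pred <- predict(clf, te_s)
    ptab <- vote_predictions(te$sample_id, te$channel, pred, te$label)
    sample_acc <- corrected_accuracy(ptab)
    metrics <- rbind(metrics, data.frame(
      fold = fi, n_rows = nrow(te),
      row_accuracy = 100 * mean(pred == te$label),
      sample_accuracy = sample_acc))
    pred_tables[[length(pred_tables) + 1L]] <- ptab
  }
  list(fold_metrics = metrics,
       mean_row_accuracy = mean(metrics$row_accuracy),
       mean_sample_accuracy = mean(metrics$sample_accuracy),
       predictions = do.call(rbind, pred_tables))
}
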