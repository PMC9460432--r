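make_sep_rows <- function(n_per = 100, gap = 2, seed = 1) {
  set.seed(seed)
  rows <- do.call(rbind, lapply(1:3, function(cls) {
    m <- matrix(rnorm(n_per * 20, mean = cls * gap), n_per, 20)
    df <- as.data.frame(m)
    names(df) <- c("ecd", EEG_FEATURE_NAMES)
    df$label <- cls
    df
  }))
  rows
}

test_that("gru_step matches an independent elementwise evaluation", {
  set.seed(101)
  for (i in 1:30) {
    hs <- sample(2:6, 1)
    cell <- gru_cell(1L, hs)
    cell$b_r <- rnorm(hs); cell$b_z <- rnorm(hs); cell$b_h <- rnorm(hs)
    h_prev <- rnorm(hs)
    x <- rnorm(1)
    expect_equal(gru_step(cell, h_prev, x), gru_step_oracle(cell, h_prev, x),
                 tolerance = 1e-10)
  }
})

test_that("the update gate interpolates between carry and candidate", {
  set.seed(102)
  cell <- gru_cell(1L, 4L)
  h_prev <- rnorm(4); x <- 0.3
  carry <- cell; carry$W_z <- carry$W_z * 0; carry$b_z <- rep(-50, 4)
  expect_equal(gru_step(carry, h_prev, x), h_prev, tolerance = 1e-10)
  replace <- cell; replace$W_z <- replace$W_z * 0; replace$b_z <- rep(50, 4)
  st <- gru_step(replace, h_prev, x, detail = TRUE)
  expect_equal(drop(st$h), drop(st$hc), tolerance = 1e-10)
})

test_that("gate activations stay in their ranges and states stay bounded", {
  set.seed(103)
  cell <- gru_cell(1L, 8L)
  h <- rnorm(8)
  for (t in 1:20) {
    st <- gru_step(cell, h, rnorm(1), detail = TRUE)
    expect_true(all(st$r > 0 & st$r < 1))
    expect_true(all(st$z > 0 & st$z < 1))
    expect_true(all(abs(st$hc) < 1))
    expect_true(all(abs(st$h) <= pmax(abs(h), 1) + 1e-12))
    h <- drop(st$h)
  }
})

test_that("bidirectional encoding concatenates forward and backward states", {
  set.seed(104)
  f <- gru_cell(1L, 5L); b <- gru_cell(1L, 5L)
  H <- encode_bigru(f, b, rnorm(7))
  expect_equal(dim(H), c(7L, 10L))
  # a length-1 sequence feeds the same input to both halves
  H1 <- encode_bigru(f, f, 0.4)
  expect_equal(H1[1, 1:5], H1[1, 6:10])
  # tied cells on a palindrome: forward state at t = backward at T+1-t
  pal <- c(0.3, -1.2, 0.5, -1.2, 0.3)
  Hp <- encode_bigru(f, f, pal)
  for (t in 1:5) expect_equal(Hp[t, 1:5], Hp[6 - t, 6:10], tolerance = 1e-12)
  expect_error(encode_bigru(f, b, numeric(0)), "empty")
  expect_equal(ncol(encode_bigru(gru_cell(1, 128), gru_cell(1, 128),
                                 rnorm(3))), 256)
})

test_that("backpropagation matches central finite differences", {
  fd_check <- function(type) {
    set.seed(105)
    net <- fatigueEEG:::new_recurrent_net(type, 4L, 3L)
    X <- matrix(rnorm(15), 3, 5)
    y <- 1:3
    trainable <- list(cells = net$cells, W_out = net$W_out, b_out = net$b_out)
    pass <- fatigueEEG:::net_pass(net, X, y, grads = TRUE)
    paths <- list(c("W_out"), c("b_out"),
                  c("cells", "f", if (grepl("lstm", type)) "W_f" else "W_r"),
                  c("cells", "f", if (grepl("lstm", type)) "b_g" else "b_h"))
    if (grepl("^bi", type))
      paths <- c(paths, list(c("cells", "b",
                               if (grepl("lstm", type)) "W_o" else "W_z")))
    eps <- 1e-6
    for (p in paths) {
      param <- trainable[[p]]
      grad <- pass$grads[[p]]
      for (k in sample(seq_along(param), min(4, length(param)))) {
        loss_at <- function(delta) {
          tp <- trainable
          tp[[p]][k] <- param[k] + delta
          nt <- net
          nt$cells <- tp$cells; nt$W_out <- tp$W_out; nt$b_out <- tp$b_out
          fatigueEEG:::net_pass(nt, X, y)$loss
        }
        num <- (loss_at(eps) - loss_at(-eps)) / (2 * eps)
        expect_equal(grad[k], num, tolerance = 1e-4)
      }
    }
  }
  for (type in c("gru", "bigru", "lstm", "bilstm")) fd_check(type)
})

test_that("every classifier separates well-separated classes", {
  rows <- make_sep_rows()
  cfg <- train_config(hidden_units = 16, max_epochs = 6, min_steps = 80,
                      batch_size = 64, seed = 3)
  for (m in c("bigru", "svm", "knn", "rf")) {
    clf <- train_classifier(rows, m, cfg)
    expect_gte(mean(predict(clf, rows) == rows$label), 0.95)
  }
})

test_that("training is deterministic under a fixed seed", {
  rows <- make_sep_rows(n_per = 40)
  cfg <- train_config(hidden_units = 8, max_epochs = 2, min_steps = 10,
                      batch_size = 32, seed = 11)
  a <- train_classifier(rows, "bigru", cfg)
  b <- train_classifier(rows, "bigru", cfg)
  expect_identical(a$fit$W_out, b$fit$W_out)
  expect_identical(predict(a, rows), predict(b, rows))
})

test_that("single-class training data yields a constant predictor", {
  rows <- make_sep_rows(n_per = 30)
  rows$label <- 2L
  cfg <- train_config(hidden_units = 8, max_epochs = 3, min_steps = 30,
                      batch_size = 32, seed = 12)
  for (m in c("bigru", "knn")) {
    clf <- train_classifier(rows, m, cfg)
    expect_true(all(predict(clf, rows) == 2L))
  }
})

test_that("labels outside 1..3 and missing feature columns are rejected", {
  rows <- make_sep_rows(n_per = 10)
  bad <- rows; bad$label[1] <- 7
  expect_error(train_classifier(bad, "rf"), "labels")
  clf <- train_classifier(rows, "rf", train_config(seed = 1))
  expect_error(predict(clf, rows[, 1:5]), "feature column")
})

test_that("the cross-validation plan partitions subjects 18:3-style", {
  subjects <- sprintf("S%02d", 1:21)
  plan <- make_cv_plan(subjects, n_folds = 7, seed = 2)
  expect_length(plan$folds, 7)
  expect_true(all(lengths(plan$folds) == 3))
  expect_setequal(unlist(plan$folds), subjects)
  expect_equal(anyDuplicated(unlist(plan$folds)), 0)
  expect_error(make_cv_plan(c("a", "b"), n_folds = 7), "at least")
})

test_that("cross-validation refits scaling per fold and reports both accuracies", {
  rows <- mini_rows()
  cfg <- train_config(seed = 5)
  plan <- make_cv_plan(unique(rows$subject), n_folds = 3, seed = 5)
  cv <- cross_validate(rows, "rf", cfg, plan = plan)
  expect_equal(nrow(cv$fold_metrics), 3)
  expect_true(all(cv$fold_metrics$sample_accuracy >= 0 &
                  cv$fold_metrics$sample_accuracy <= 100))
  expect_setequal(unique(cv$predictions$real_label), 1:3)
  # every subject's samples predicted exactly once across folds
  expect_equal(nrow(cv$predictions), nrow(rows))
  # chance level is 33.3%: informative features must beat it clearly
  expect_gt(cv$mean_row_accuracy, 45)
})

test_that("fused closure+EEG features do not underperform EEG-only features", {
  # directional analogue of the fusion benefit, averaged over seeds
  diffs <- vapply(1:10, function(s) {
    rows <- build_cohort_rows(
      generate_cohort(synth_config(n_subjects = 3, section_s = 36,
                                   seed = 400 + s)),
      pipeline_config(section_s = 36, seed = s))
    cfg <- train_config(seed = s)
    plan <- make_cv_plan(unique(rows$subject), n_folds = 3, seed = s)
    fused <- cross_validate(rows, "rf", cfg, plan = plan, folds = 1)
    eeg <- cross_validate(rows, "rf", cfg, plan = plan, folds = 1,
                          feature_cols = EEG_FEATURE_NAMES)
    fused$mean_row_accuracy - eeg$mean_row_accuracy
  }, numeric(1))
  expect_gte(mean(diffs), 0)
})
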