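test_that("branch topology is 1 / k / 2k for early / signal-late / sensor-late", {
  cfg <- toy_config()
  sigs <- c("ch1", "ch2", "ch3", "ch4")
  for (k in 1:4) {
    sel <- sigs[seq_len(k)]
    expect_equal(n_branches(build_model(fusion_spec("early", sel, cfg), 41)), 1L)
    expect_equal(n_branches(build_model(fusion_spec("signal_late", sel, cfg), 41)),
                 k)
    expect_equal(n_branches(build_model(fusion_spec("sensor_late", sel, cfg), 41)),
                 2L * k)
  }
})

test_that("parameter count matches the closed-form topology count", {
  cfg <- toy_config() # filter_len 10, n_filters 4, pool 2, snippet_len 41
  L <- 41L; fl <- 10L; nf <- 4L; pool <- 2L
  nP <- (L - fl + 1L) %/% pool # pooled positions per branch
  closed_form <- function(n_br, c_in) {
    n_br * ((c_in * fl + 1L) * nf) + n_br * nP * nf + 1L
  }
  expect_equal(n_parameters(build_model(fusion_spec("early", c("a", "b", "c"),
                                                    cfg), L)),
               closed_form(1L, 3L))
  expect_equal(n_parameters(build_model(fusion_spec("signal_late",
                                                    c("a", "b", "c"), cfg), L)),
               closed_form(3L, 1L))
  expect_equal(n_parameters(build_model(fusion_spec("sensor_late",
                                                    c("a", "b"), cfg), L)),
               closed_form(4L, 1L))
})

test_that("hybrid cannot be built directly and empty signal sets are refused", {
  cfg <- toy_config()
  expect_error(build_model(fusion_spec("hybrid", c("a"), cfg), 41),
               "train_hybrid")
  expect_error(fusion_spec("early", character(0), cfg), "non-empty")
  expect_error(fusion_spec("early", c("a", "a"), cfg), "duplicates")
})

test_that("analytic gradients agree with finite differences", {
  cfg <- toy_config(dropout = 0, seed = 99L)
  set <- toy_snippet_set(n = 12, n_channels = 2, L = 41, seed = 40)
  for (st in c("early", "signal_late")) {
    m <- build_model(fusion_spec(st, c("ch1", "ch2"), cfg), 41)
    X <- set$data
    y <- set$labels
    w <- rep(1, length(y))
    lg <- respfusion:::model_loss_grads(m, X, y, w)
    params <- respfusion:::model_params(m)
    eps <- 1e-6
    for (nm in c("Wc1", "bc1", "wd", "bd")) {
      th <- params[[nm]]
      for (j in sample(seq_along(th), min(4, length(th)))) {
        pp <- params; pp[[nm]][j] <- th[j] + eps
        mp <- respfusion:::model_set_params(m, pp)
        lp <- respfusion:::model_loss_grads(mp, X, y, w)$loss
        pm <- params; pm[[nm]][j] <- th[j] - eps
        mm <- respfusion:::model_set_params(m, pm)
        lm <- respfusion:::model_loss_grads(mm, X, y, w)$loss
        expect_equal(lg$grads[[nm]][j], (lp - lm) / (2 * eps),
                     tolerance = 1e-4)
      }
    }
  }
})

test_that("training is deterministic and learns a separable toy problem", {
  cfg <- toy_config(epochs = 20L)
  train <- toy_snippet_set(n = 200, seed = 41)
  m1 <- train_fusion(build_model(fusion_spec("signal_late", c("ch1", "ch2"),
                                             cfg), 41), train, cfg)
  m2 <- train_fusion(build_model(fusion_spec("signal_late", c("ch1", "ch2"),
                                             cfg), 41), train, cfg)
  expect_equal(respfusion:::model_params(m1), respfusion:::model_params(m2),
               tolerance = 1e-7)
  p1 <- predict(m1, train)
  p2 <- predict(m2, train)
  expect_identical(p1$Y, p2$Y)
  # loss broadly decreasing on a separable problem
  expect_lt(m1$history[length(m1$history)], m1$history[1])
  # converged toy model classifies its own training set well
  perf <- performance(confusion(p1$Y, train$labels))
  expect_gt(perf$P, 90)
})

test_that("training refuses unlabeled, empty or single-class sets", {
  cfg <- toy_config()
  m <- build_model(fusion_spec("early", c("ch1", "ch2"), cfg), 41)
  set <- toy_snippet_set(n = 20, seed = 42)
  unlab <- set; unlab$labels <- NULL
  expect_error(train_fusion(m, unlab, cfg), "unlabeled")
  onecls <- set; onecls$labels <- rep(1L, 20)
  expect_error(train_fusion(m, onecls, cfg), "single class")
})

test_that("predictions are probabilities, deterministic, and channel-checked", {
  cfg <- toy_config(epochs = 2L)
  train <- toy_snippet_set(n = 60, seed = 43)
  m <- train_fusion(build_model(fusion_spec("early", c("ch1", "ch2"), cfg), 41),
                    train, cfg)
  p <- predict(m, train)
  expect_true(all(p$scores >= 0 & p$scores <= 1))
  expect_equal(p$Y, as.integer(p$scores >= 0.5))
  # a duplicated snippet gets an identical score
  dup <- train
  dup$data[2, , ] <- dup$data[1, , ]
  pd <- predict(m, dup)
  expect_identical(pd$scores[1], pd$scores[2])
  # channel-order mismatch is an error
  other <- train
  other$channels <- c("chA", "chB")
  expect_error(predict(m, other), "channel-order mismatch")
})

test_that("majority vote implements the 2-of-3 rule exhaustively", {
  tt <- expand.grid(a = 0:1, b = 0:1, c = 0:1)
  got <- majority_vote(tt$a, tt$b, tt$c)
  expect_equal(got, as.integer(tt$a + tt$b + tt$c >= 2))
  expect_equal(majority_vote(c(1, 0), c(1, 1), c(0, 0)), c(1L, 0L))
  v <- c(1L, 0L, 1L)
  expect_equal(majority_vote(v, v, v), v)
  expect_error(majority_vote(c(1, 0), c(1), c(0, 0)), "length")
  expect_error(majority_vote(c(2, 0), c(1, 0), c(0, 0)), "binary")
})

test_that("hybrid ensemble equals the elementwise majority of its members", {
  cfg <- toy_config(epochs = 3L)
  train <- toy_snippet_set(n = 120, seed = 44)
  hyb <- train_hybrid(train, cfg, signals = c("ch1", "ch2"))
  expect_named(hyb$members, c("early", "signal_late", "sensor_late"))
  p <- predict(hyb, train)
  member_Y <- lapply(hyb$members, function(m) predict(m, train)$Y)
  expect_equal(p$Y, majority_vote(member_Y$early, member_Y$signal_late,
                                  member_Y$sensor_late))
  # elementwise median of three binary votes is the same rule
  med <- apply(do.call(cbind, member_Y), 1, median)
  expect_equal(p$Y, as.integer(med))
  # reproducible run-to-run
  hyb2 <- train_hybrid(train, cfg, signals = c("ch1", "ch2"))
  expect_identical(predict(hyb2, train)$Y, p$Y)
})

test_that("every fusion strategy learns event detection well above chance", {
  # small simulated study under default signal conditions; the hybrid
  # vote is formed from the three trained members on each fold
  study <- simulate_study(3, scenarios = "city", duration_s = 90,
                          master_seed = 9)
  cfg <- pipeline_config(epochs = 5)
  recs <- lapply(study, function(e) preprocess_recording(e$recording, cfg))
  P <- list()
  for (held in c("s01", "s02")) {
    fold <- split_loso(recs, held, cfg)
    preds <- lapply(c(early = "early", signal_late = "signal_late",
                      sensor_late = "sensor_late"), function(st) {
      m <- train_fusion(build_model(fusion_spec(st, config = cfg),
                                    cfg$snippet_len), fold$train, cfg)
      predict(m, fold$test)$Y
    })
    preds$hybrid <- majority_vote(preds$early, preds$signal_late,
                                  preds$sensor_late)
    for (st in names(preds)) {
      P[[st]] <- c(P[[st]], performance(confusion(preds[[st]],
                                                  fold$test$labels))$P)
    }
  }
  for (st in names(P)) expect_gte(mean(P[[st]]), 70)
})

test_that("model checkpoints round-trip through the text format", {
  cfg <- toy_config(epochs = 2L)
  train <- toy_snippet_set(n = 60, seed = 45)
  m <- train_fusion(build_model(fusion_spec("sensor_late", c("ch1", "ch2"),
                                            cfg), 41), train, cfg)
  dir <- withr::local_tempdir()
  save_model(m, file.path(dir, "ckpt"))
  m2 <- load_model(file.path(dir, "ckpt"))
  expect_equal(predict(m2, train)$scores, predict(m, train)$scores,
               tolerance = 1e-12)
  expect_equal(m2$strategy, "sensor_late")
  expect_equal(n_branches(m2), 4L)
})
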