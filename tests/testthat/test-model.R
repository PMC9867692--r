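test_that("model_config validates and records the recipe", {
  cfg <- model_config()
  expect_equal(cfg$fc_dim, 64)
  expect_equal(cfg$learning_rate, 0.001)
  expect_equal(cfg$l2, 0.01)
  expect_equal(cfg$batch_size, 64)
  expect_equal(cfg$patience, 4)
  expect_equal(cfg$dropout_rate, 0.2)
  expect_error(model_config(scheme = "individual"), "outcome")
  expect_error(model_config(dropout_rate = 1))
  expect_error(model_config(phase = "nope"))
})

test_that("a multitask model has nine heads; individual has one", {
  m9 <- tiny_model("postop")
  expect_equal(periopnet:::n_heads(m9$config), 9)
  expect_equal(sum(grepl("^head_W_", names(m9$params))), 9)
  m1 <- tiny_model("postop", scheme = "individual", outcome = 3)
  expect_equal(periopnet:::n_heads(m1$config), 1)
  expect_equal(sum(grepl("^head_W_", names(m1$params))), 1)
})

test_that("initialization is seed-deterministic", {
  a <- tiny_model("postop", seed = 3L)
  b <- tiny_model("postop", seed = 3L)
  d <- tiny_model("postop", seed = 4L)
  expect_identical(a$params, b$params)
  expect_false(identical(a$params, d$params))
})

test_that("forward logits have the right shape in every phase", {
  fx <- tiny_fixture()
  for (phase in c("preop", "intraop", "postop")) {
    m <- tiny_model(phase)
    batch <- periopnet:::make_batch(fx$tensors, 1:5,
                                    periopnet:::needs_intraop(m),
                                    periopnet:::needs_preop(m))
    fw <- periopnet:::nn_forward(m, batch)
    expect_equal(dim(fw$logits), c(5, 9))
    expect_true(all(is.finite(fw$logits)))
  }
})

test_that("make_batch sorts by non-increasing length and keeps alignment", {
  fx <- tiny_fixture()
  idx <- c(2, 11, 30, 4)
  batch <- periopnet:::make_batch(fx$tensors, idx)
  expect_true(all(diff(batch$lens) <= 0))
  # labels and statics follow the reordering
  for (b in seq_along(batch$idx)) {
    i <- batch$idx[b]
    expect_equal(unname(batch$labels[b, ]), unname(fx$tensors$labels[i, ]))
    expect_equal(batch$lens[b], fx$tensors$intraop[[i]]$length)
    expect_equal(unname(batch$statics[b, ]),
                 unname(fx$tensors$intraop[[i]]$statics))
  }
  # padded tail of each series row is exactly zero
  Tmax <- dim(batch$X)[3]
  for (b in seq_along(batch$idx)) {
    L <- batch$lens[b]
    if (L < Tmax) expect_true(all(batch$X[b, , (L + 1):Tmax] == 0))
  }
})

test_that("attention weights are a distribution over valid steps only", {
  fx <- tiny_fixture()
  m <- tiny_model("intraop")
  batch <- periopnet:::make_batch(fx$tensors, 1:6, TRUE, FALSE)
  fw <- periopnet:::nn_forward(m, batch)
  alpha <- fw$cache$intraop$alpha   # B x Tmax x K
  Tmax <- dim(alpha)[2]
  for (k in c(1, 9)) {
    for (b in 1:6) {
      L <- batch$lens[b]
      expect_equal(sum(alpha[b, , k]), 1, tolerance = 1e-10)
      if (L < Tmax) expect_true(all(alpha[b, (L + 1):Tmax, k] == 0))
      expect_true(all(alpha[b, seq_len(L), k] > 0))
    }
  }
})

test_that("attention matches a direct R computation of the closed form", {
  fx <- tiny_fixture()
  m <- tiny_model("intraop")
  batch <- periopnet:::make_batch(fx$tensors, 3:4, TRUE, FALSE)
  fw <- periopnet:::nn_forward(m, batch)
  io <- fw$cache$intraop
  h <- m$config$rnn_hidden
  k <- 2; b <- 1
  L <- batch$lens[b]
  # reference: s_t = v' tanh(W m_t + b), softmax, context = sum alpha m_t
  W <- m$params[[paste0("att_W_", k)]]
  bb <- m$params[[paste0("att_b_", k)]]
  v <- m$params[[paste0("att_v_", k)]]
  s <- vapply(seq_len(L), function(t) {
    mt <- c(io$fwd$H[b, , t], io$Hb[b, , t])
    sum(v * tanh(drop(mt %*% W) + bb))
  }, numeric(1))
  alpha_ref <- exp(s - max(s)) / sum(exp(s - max(s)))
  expect_equal(unname(io$alpha[b, seq_len(L), k]), alpha_ref,
               tolerance = 1e-10)
  ctx_ref <- colSums(alpha_ref * t(vapply(seq_len(L), function(t) {
    c(io$fwd$H[b, , t], io$Hb[b, , t])
  }, numeric(2 * h))))
  expect_equal(unname(fw$cache$contexts[[k]][b, seq_len(2 * h)]),
               unname(ctx_ref), tolerance = 1e-10)
})

test_that("the GRU recurrence matches a plain R reference", {
  set.seed(5)
  B <- 3; D <- 4; H <- 2; T <- 6
  X <- array(rnorm(B * D * T), dim = c(B, D, T))
  lens <- c(6L, 4L, 2L)
  for (b in 1:B) if (lens[b] < T) X[b, , (lens[b] + 1):T] <- 0
  Wx <- matrix(rnorm(D * 3 * H), D); Wh <- matrix(rnorm(H * 3 * H), H)
  bb <- rnorm(3 * H); bh <- rnorm(H)
  out <- periopnet:::cpp_gru_forward(X, lens, Wx, Wh, matrix(bb, 1),
                                     matrix(bh, 1))
  sig <- function(x) 1 / (1 + exp(-x))
  for (b in 1:B) {
    hp <- rep(0, H)
    for (t in seq_len(lens[b])) {
      pre <- drop(X[b, , t] %*% Wx) + bb
      hpre <- drop(hp %*% Wh)
      r <- sig(pre[1:H] + hpre[1:H])
      z <- sig(pre[H + 1:H] + hpre[H + 1:H])
      u <- hpre[2 * H + 1:H] + bh
      nn <- tanh(pre[2 * H + 1:H] + r * u)
      hp <- (1 - z) * nn + z * hp
      expect_equal(unname(out$H[b, , t]), unname(hp), tolerance = 1e-12)
    }
    if (lens[b] < T) expect_true(all(out$H[b, , (lens[b] + 1):T] == 0))
  }
  expect_error(
    periopnet:::cpp_gru_forward(X, c(2L, 4L, 6L), Wx, Wh, matrix(bb, 1),
                                matrix(bh, 1)),
    "sorted")
})

test_that("analytic gradients match finite differences in every phase", {
  fx <- tiny_fixture()
  eps <- 1e-5
  for (phase in c("preop", "intraop", "postop")) {
    m <- tiny_model(phase)
    batch <- periopnet:::make_batch(fx$tensors, 1:6,
                                    periopnet:::needs_intraop(m),
                                    periopnet:::needs_preop(m))
    w <- rep(1.5, 9)
    fw <- periopnet:::nn_forward(m, batch)
    bce <- periopnet:::weighted_bce(fw$logits, batch$labels, w)
    bw <- periopnet:::nn_backward(m, batch, fw$cache, bce$dlogits,
                                  input_grads = TRUE)
    loss_at <- function(params) {
      m2 <- m; m2$params <- params
      f <- periopnet:::nn_forward(m2, batch)
      periopnet:::weighted_bce(f$logits, batch$labels, w)$loss
    }
    set.seed(99)
    for (nm in names(m$params)) {
      g <- bw$grads[[nm]]
      ii <- sample(length(m$params[[nm]]), min(2, length(m$params[[nm]])))
      for (i in ii) {
        p1 <- m$params; p1[[nm]][i] <- p1[[nm]][i] + eps
        p2 <- m$params; p2[[nm]][i] <- p2[[nm]][i] - eps
        num <- (loss_at(p1) - loss_at(p2)) / (2 * eps)
        expect_lt(abs(num - g[i]) / max(1e-6, abs(num) + abs(g[i])), 1e-4)
      }
    }
    # input gradients (used by integrated gradients)
    loss_of <- function(b) {
      f <- periopnet:::nn_forward(m, b)
      periopnet:::weighted_bce(f$logits, b$labels, w)$loss
    }
    if (periopnet:::needs_intraop(m)) {
      b1 <- batch; b1$X[2, 7, 3] <- b1$X[2, 7, 3] + eps
      b2 <- batch; b2$X[2, 7, 3] <- b2$X[2, 7, 3] - eps
      num <- (loss_of(b1) - loss_of(b2)) / (2 * eps)
      expect_lt(abs(num - bw$dX[2, 7, 3]) /
                  max(1e-6, abs(num) + abs(bw$dX[2, 7, 3])), 1e-4)
    }
    if (periopnet:::needs_preop(m)) {
      b1 <- batch; b1$numeric[3, 10] <- b1$numeric[3, 10] + eps
      b2 <- batch; b2$numeric[3, 10] <- b2$numeric[3, 10] - eps
      num <- (loss_of(b1) - loss_of(b2)) / (2 * eps)
      expect_lt(abs(num - bw$dnumeric[3, 10]) /
                  max(1e-6, abs(num) + abs(bw$dnumeric[3, 10])), 1e-4)
    }
  }
})

test_that("padding does not change a sequence's prediction", {
  fx <- tiny_fixture()
  m <- tiny_model("postop")
  lens <- vapply(fx$tensors$intraop, function(t) t$length, numeric(1))
  short <- which.min(lens); long <- which.max(lens)
  alone <- periopnet:::make_batch(fx$tensors, short)
  together <- periopnet:::make_batch(fx$tensors, c(short, long))
  fa <- periopnet:::nn_forward(m, alone)
  ft <- periopnet:::nn_forward(m, together)
  pos <- which(together$idx == short)
  expect_equal(unname(fa$logits[1, ]), unname(ft$logits[pos, ]),
               tolerance = 1e-10)
})

test_that("predictions are deterministic and batch-composition invariant", {
  fx <- tiny_fixture()
  m <- tiny_model("postop", dropout_rate = 0.2)
  p1 <- predict_risk_matrix(m, fx$tensors)
  p2 <- predict_risk_matrix(m, fx$tensors)
  expect_identical(p1, p2)           # dropout must be inactive at inference
  # scoring a subset reproduces the same rows
  sub <- list(preop = list(
    numeric = fx$tensors$preop$numeric[5:10, ],
    onehot = fx$tensors$preop$onehot[5:10, ],
    cyclic = fx$tensors$preop$cyclic[5:10, ],
    index = fx$tensors$preop$index[5:10, ],
    index_cardinalities = fx$tensors$preop$index_cardinalities),
    intraop = fx$tensors$intraop[5:10],
    labels = fx$tensors$labels[5:10, ],
    encounter_id = fx$tensors$encounter_id[5:10])
  p3 <- predict_risk_matrix(m, sub)
  expect_equal(unname(p3), unname(p1[5:10, ]), tolerance = 1e-12)
  expect_true(all(p1 > 0 & p1 < 1))
})

test_that("predict_risk returns tidy rows", {
  fx <- tiny_fixture()
  m <- tiny_model("preop")
  pr <- predict_risk(m, fx$tensors)
  expect_identical(names(pr), c("encounter_id", "phase", "scheme",
                                "outcome", "probability"))
  expect_equal(nrow(pr), 80 * 9)
  expect_true(all(pr$phase == "preop"))
  expect_true(all(sort(unique(pr$outcome)) == sort(outcome_names())))
})

test_that("dropout masks are inverted-scaled and only active on request", {
  set.seed(1)
  mk <- periopnet:::new_dropout_mask(2000, 10, 0.2)
  expect_true(all(mk %in% c(0, 1 / 0.8)))
  expect_equal(mean(mk == 0), 0.2, tolerance = 0.03)
  fx <- tiny_fixture()
  m <- tiny_model("preop", dropout_rate = 0.5)
  batch <- periopnet:::make_batch(fx$tensors, 1:4, FALSE, TRUE)
  set.seed(2)
  f1 <- periopnet:::nn_forward(m, batch, dropout_active = TRUE)
  set.seed(3)
  f2 <- periopnet:::nn_forward(m, batch, dropout_active = TRUE)
  expect_false(identical(f1$logits, f2$logits))
  f3 <- periopnet:::nn_forward(m, batch, dropout_active = FALSE)
  f4 <- periopnet:::nn_forward(m, batch, dropout_active = FALSE)
  expect_identical(f3$logits, f4$logits)
})
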