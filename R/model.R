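# Multi-task deep architecture: a preoperative sub-model (per-feature
# embeddings for high-cardinality nominals plus a fully connected numeric
# path, fused by a final fully connected layer), an intraoperative
# sub-model (bidirectional GRU over the T x 24 series with a separate
# additive attention mechanism per outcome, statics concatenated to each
# context vector), and one outcome-specific sigmoid head per task.
# Forward and backward passes are hand-derived; the GRU recurrence runs
# in compiled code.

#' Model configuration
#'
#' Defaults follow the reference training recipe: embedding size 64,
#' fully connected layers of size 64, hidden dimension 64, Adam with
#' learning rate 0.001, L2 regularization 0.01, batch size 64, ReLU
#' activations, and early-stopping patience 4 on a 10% development
#' holdout. Dropout (rate 0.2) sits after each fully connected layer and
#' on the attention context vectors, which is what makes Monte Carlo
#' dropout available at inference.
#'
#' @param phase which inputs the model sees: `"preop"` (static features
#'   only), `"intraop"` (time series only) or `"postop"` (both).
#' @param scheme `"multitask"` (nine heads on a shared trunk) or
#'   `"individual"` (one head; set `outcome`).
#' @param outcome outcome index in 1..9 for the individual scheme.
#' @param embed_dim,fc_dim,rnn_hidden,attention_dim layer widths.
#' @param learning_rate,l2,batch_size Adam step size, weight decay and
#'   minibatch size.
#' @param patience early-stopping patience in epochs.
#' @param dropout_rate dropout fraction in \[0, 1); `NULL` builds a
#'   dropout-free model (then Monte Carlo dropout is unavailable).
#' @param n_tasks number of outcomes (9).
#' @param max_epochs training epoch cap.
#' @param seed integer seed governing initialization, the holdout split,
#'   shuffling and dropout.
#' @return An object of class `model_config`.
#' @export
model_config <- function(phase = c("postop", "preop", "intraop"),
                         scheme = c("multitask", "individual"),
                         outcome = NULL,
                         embed_dim = 64, fc_dim = 64, rnn_hidden = 64,
                         attention_dim = 64,
                         learning_rate = 0.001, l2 = 0.01, batch_size = 64,
                         patience = 4, dropout_rate = 0.2, n_tasks = 9,
                         max_epochs = 50, seed = 1L) {
  phase <- match.arg(phase)
  scheme <- match.arg(scheme)
  stopifnot(embed_dim > 0, fc_dim > 0, rnn_hidden > 0, attention_dim > 0,
            batch_size > 0, patience >= 1, max_epochs >= 1, n_tasks >= 1)
  if (!is.null(dropout_rate)) {
    stopifnot(dropout_rate >= 0, dropout_rate < 1)
  }
  if (scheme == "individual") {
    if (is.null(outcome)) stop("individual scheme requires an outcome index")
    stopifnot(outcome >= 1, outcome <= n_tasks)
  }
  structure(list(phase = phase, scheme = scheme, outcome = outcome,
                 embed_dim = embed_dim, fc_dim = fc_dim,
                 rnn_hidden = rnn_hidden, attention_dim = attention_dim,
                 learning_rate = learning_rate, l2 = l2,
                 batch_size = batch_size, patience = patience,
                 dropout_rate = dropout_rate, n_tasks = n_tasks,
                 max_epochs = max_epochs, seed = as.integer(seed)),
            class = "model_config")
}

#' Input layout for model construction
#'
#' @param tensors output of [prepare_tensors()].
#' @return A list describing input widths and embedding cardinalities.
#' @export
model_layout <- function(tensors) {
  p <- tensors$preop
  list(n_numeric = ncol(p$numeric) + ncol(p$onehot) + ncol(p$cyclic),
       index_cardinalities = p$index_cardinalities,
       intraop_width = 24L, n_statics = 3L)
}

init_mat <- function(nr, nc, scale = sqrt(2 / nr)) {
  matrix(rnorm(nr * nc, 0, scale), nr, nc)
}

n_heads <- function(config) {
  if (config$scheme == "multitask") config$n_tasks else 1L
}

head_input_dim <- function(config) {
  switch(config$phase,
         preop = config$fc_dim,
         intraop = 2 * config$rnn_hidden + 3,
         postop = config$fc_dim + 2 * config$rnn_hidden + 3)
}

#' Build the preoperative sub-model parameters
#'
#' Six embedding lookup tables (one per high-cardinality nominal, each
#' with a row for the "missing" index), a fully connected layer over the
#' concatenated embeddings, a fully connected layer over the numeric
#' block (capped/normalized values, masks, one-hots and cyclic calendar
#' features in one block), and a fusing fully connected layer producing
#' the 64-dimensional preoperative representation.
#'
#' @param config a [model_config()].
#' @param layout a [model_layout()].
#' @return Named list of parameter matrices.
#' @export
build_preop_submodel <- function(config, layout) {
  cards <- layout$index_cardinalities
  if (length(cards) != 6) {
    stop("layout must declare 6 embedded nominal features")
  }
  e <- config$embed_dim; f <- config$fc_dim
  params <- list()
  for (j in seq_along(cards)) {
    params[[paste0("emb_", j)]] <- init_mat(cards[j], e, scale = 0.05)
  }
  params$nom_W <- init_mat(length(cards) * e, f)
  params$nom_b <- rep(0, f)
  params$num_W <- init_mat(layout$n_numeric, f)
  params$num_b <- rep(0, f)
  params$fuse_W <- init_mat(2 * f, f)
  params$fuse_b <- rep(0, f)
  params
}

#' Build the intraoperative sub-model parameters
#'
#' A bidirectional GRU over the 24-wide series (12 channels plus their
#' presence masks) whose forward and backward hidden states are
#' concatenated, and a separate additive attention mechanism per task:
#' score v_k' tanh(W_k h_t + b_k), softmax over valid timesteps, context
#' c_k = sum_t alpha_kt h_t, with the three normalized statics appended
#' to each context.
#'
#' @inheritParams build_preop_submodel
#' @return Named list of parameter matrices.
#' @export
build_intraop_submodel <- function(config, layout = NULL) {
  h <- config$rnn_hidden
  d <- if (is.null(layout)) 24L else layout$intraop_width
  a <- config$attention_dim
  params <- list()
  for (dir in c("f", "b")) {
    params[[paste0("gru_", dir, "_Wx")]] <- init_mat(d, 3 * h,
                                                     scale = sqrt(1 / d))
    params[[paste0("gru_", dir, "_Wh")]] <- init_mat(h, 3 * h,
                                                     scale = sqrt(1 / h))
    params[[paste0("gru_", dir, "_b")]] <- rep(0, 3 * h)
    params[[paste0("gru_", dir, "_bh")]] <- rep(0, h)
  }
  for (k in seq_len(n_heads(config))) {
    params[[paste0("att_W_", k)]] <- init_mat(2 * h, a, scale = sqrt(1 / h))
    params[[paste0("att_b_", k)]] <- rep(0, a)
    params[[paste0("att_v_", k)]] <- rnorm(a, 0, sqrt(1 / a))
  }
  params
}

#' Build a complete risk model
#'
#' Assembles the sub-models the phase requires plus one outcome-specific
#' fully connected head (size 1) per task, with sigmoid outputs
#' interpreted as complication probabilities.
#'
#' @inheritParams build_preop_submodel
#' @param layout a [model_layout()]; may omit preop fields for
#'   intraop-only models.
#' @return An object of class `periop_model`.
#' @export
build_model <- function(config, layout) {
  stopifnot(inherits(config, "model_config"))
  set.seed(derive_seed(config$seed, "init"))
  params <- list()
  if (config$phase != "intraop") {
    params <- c(params, build_preop_submodel(config, layout))
  }
  if (config$phase != "preop") {
    params <- c(params, build_intraop_submodel(config, layout))
  }
  hd <- head_input_dim(config)
  for (k in seq_len(n_heads(config))) {
    params[[paste0("head_W_", k)]] <- init_mat(hd, 1, scale = sqrt(1 / hd))
    params[[paste0("head_b_", k)]] <- 0
  }
  structure(list(config = config, layout = layout, params = params,
                 trained = FALSE, log = NULL),
            class = "periop_model")
}

# ---- batching -------------------------------------------------------------

# Assemble a length-sorted minibatch from prepared tensors. Rows are
# sorted by non-increasing series length (required by the GRU kernels);
# `unsort` restores the caller's order.
make_batch <- function(tensors, idx, need_intraop = TRUE,
                       need_preop = TRUE) {
  if (need_intraop) {
    lens <- vapply(tensors$intraop[idx], function(t) t$length, numeric(1))
    ord <- order(lens, decreasing = TRUE)
    idx <- idx[ord]
    lens <- as.integer(lens[ord])
  } else {
    lens <- NULL
  }
  B <- length(idx)
  batch <- list(idx = idx, B = B)
  if (need_preop) {
    p <- tensors$preop
    batch$numeric <- cbind(p$numeric[idx, , drop = FALSE],
                           p$onehot[idx, , drop = FALSE],
                           p$cyclic[idx, , drop = FALSE])
    batch$index <- p$index[idx, , drop = FALSE]
  }
  if (need_intraop) {
    Tmax <- max(lens)
    X <- array(0, dim = c(B, 24L, Tmax))
    statics <- matrix(0, B, 3)
    for (b in seq_len(B)) {
      tb <- tensors$intraop[[idx[b]]]
      X[b, , seq_len(tb$length)] <- t(tb$series)
      statics[b, ] <- tb$statics
    }
    batch$X <- X
    batch$lens <- lens
    batch$statics <- statics
  }
  if (!is.null(tensors$labels)) {
    batch$labels <- tensors$labels[idx, , drop = FALSE]
  }
  batch
}

relu <- function(x) x * (x > 0)

new_dropout_mask <- function(dim1, dim2, rate) {
  matrix((runif(dim1 * dim2) >= rate) / (1 - rate), dim1, dim2)
}

# ---- forward --------------------------------------------------------------

# Forward pass over a batch. dropout_active enables stochastic dropout
# (training and Monte Carlo inference); otherwise the pass is
# deterministic. Returns logits (B x K) and the cache needed by
# nn_backward.
nn_forward <- function(model, batch, dropout_active = FALSE) {
  cfg <- model$config
  P <- model$params
  K <- n_heads(cfg)
  rate <- if (dropout_active && !is.null(cfg$dropout_rate) &&
              cfg$dropout_rate > 0) cfg$dropout_rate else 0
  cache <- list(rate = rate)
  B <- batch$B

  prep <- NULL
  if (cfg$phase != "intraop") {
    if (is.null(batch$embed_override)) {
      E <- do.call(cbind, lapply(1:6, function(j) {
        idx <- batch$index[, j] + 1L
        if (any(idx > nrow(P[[paste0("emb_", j)]]))) {
          stop("nominal index exceeds declared embedding cardinality")
        }
        P[[paste0("emb_", j)]][idx, , drop = FALSE]
      }))
    } else {
      E <- batch$embed_override
    }
    nom_pre <- E %*% P$nom_W + rep(P$nom_b, each = B)
    nom_h <- relu(nom_pre)
    m1 <- if (rate > 0) new_dropout_mask(B, ncol(nom_h), rate) else NULL
    nom_d <- if (is.null(m1)) nom_h else nom_h * m1
    num_pre <- batch$numeric %*% P$num_W + rep(P$num_b, each = B)
    num_h <- relu(num_pre)
    m2 <- if (rate > 0) new_dropout_mask(B, ncol(num_h), rate) else NULL
    num_d <- if (is.null(m2)) num_h else num_h * m2
    fuse_in <- cbind(num_d, nom_d)
    fuse_pre <- fuse_in %*% P$fuse_W + rep(P$fuse_b, each = B)
    fuse_h <- relu(fuse_pre)
    m3 <- if (rate > 0) new_dropout_mask(B, ncol(fuse_h), rate) else NULL
    prep <- if (is.null(m3)) fuse_h else fuse_h * m3
    cache$preop <- list(E = E, nom_h = nom_h, m1 = m1, nom_d = nom_d,
                        num_h = num_h, m2 = m2, num_d = num_d,
                        fuse_in = fuse_in, fuse_h = fuse_h, m3 = m3,
                        prep = prep)
  }

  contexts <- NULL
  if (cfg$phase != "preop") {
    if (is.null(batch$X)) stop("model phase requires intraoperative tensors")
    if (min(batch$lens) < 1) stop("zero-length sequence rejected")
    Tmax <- dim(batch$X)[3]
    fwd <- cpp_gru_forward(batch$X, batch$lens, P$gru_f_Wx, P$gru_f_Wh,
                           matrix(P$gru_f_b, 1), matrix(P$gru_f_bh, 1))
    Xr <- cpp_reverse_sequences(batch$X, batch$lens)
    bwd <- cpp_gru_forward(Xr, batch$lens, P$gru_b_Wx, P$gru_b_Wh,
                           matrix(P$gru_b_b, 1), matrix(P$gru_b_bh, 1))
    Hb <- cpp_reverse_sequences(bwd$H, batch$lens)
    Wall <- do.call(cbind, P[paste0("att_W_", seq_len(K))])
    ball <- unlist(P[paste0("att_b_", seq_len(K))], use.names = FALSE)
    Vall <- do.call(cbind, P[paste0("att_v_", seq_len(K))])
    af <- cpp_attention_forward(fwd$H, Hb, batch$lens, Wall,
                                matrix(ball, 1), Vall)
    contexts <- vector("list", K)
    masks <- vector("list", K)
    for (k in seq_len(K)) {
      C <- af$contexts[, , k, drop = TRUE]
      if (B == 1) C <- matrix(C, 1)
      mk <- if (rate > 0) new_dropout_mask(B, ncol(C), rate) else NULL
      Cd <- if (is.null(mk)) C else C * mk
      contexts[[k]] <- cbind(Cd, batch$statics)
      masks[k] <- list(mk)
    }
    cache$intraop <- list(fwd = fwd, bwd = bwd, Xr = Xr, Hb = Hb,
                          alpha = af$alpha, masks = masks, Tmax = Tmax)
  }

  logits <- matrix(0, B, K)
  head_in <- vector("list", K)
  for (k in seq_len(K)) {
    inp <- switch(cfg$phase,
                  preop = prep,
                  intraop = contexts[[k]],
                  postop = cbind(prep, contexts[[k]]))
    head_in[[k]] <- inp
    logits[, k] <- inp %*% P[[paste0("head_W_", k)]] +
      P[[paste0("head_b_", k)]]
  }
  cache$head_in <- head_in
  cache$contexts <- contexts
  list(logits = logits, cache = cache)
}

zero_like <- function(params) {
  lapply(params, function(p) {
    if (is.matrix(p)) matrix(0, nrow(p), ncol(p)) else rep(0, length(p))
  })
}

# ---- backward -------------------------------------------------------------

# Backward pass. Returns parameter gradients and, when input_grads is
# TRUE, gradients with respect to every model input (numeric block,
# looked-up embedding vectors, intraoperative series, statics) for
# integrated-gradients attribution.
nn_backward <- function(model, batch, cache, dlogits,
                        param_grads = TRUE, input_grads = FALSE) {
  cfg <- model$config
  P <- model$params
  K <- n_heads(cfg)
  B <- batch$B
  G <- if (param_grads) zero_like(P) else list()
  dprep <- NULL
  dcontexts <- vector("list", K)
  f <- cfg$fc_dim

  for (k in seq_len(K)) {
    dk <- dlogits[, k]
    Wk <- P[[paste0("head_W_", k)]]
    dinp <- dk %*% t(Wk)   # B x dim
    if (param_grads) {
      G[[paste0("head_W_", k)]] <- crossprod(cache$head_in[[k]], dk)
      G[[paste0("head_b_", k)]] <- sum(dk)
    }
    if (cfg$phase == "preop") {
      dprep <- if (is.null(dprep)) dinp else dprep + dinp
    } else if (cfg$phase == "intraop") {
      dcontexts[[k]] <- dinp
    } else {
      dp <- dinp[, seq_len(f), drop = FALSE]
      dprep <- if (is.null(dprep)) dp else dprep + dp
      dcontexts[[k]] <- dinp[, -seq_len(f), drop = FALSE]
    }
  }

  out <- list(grads = G)

  if (cfg$phase != "preop") {
    io <- cache$intraop
    h <- cfg$rnn_hidden
    Tmax <- io$Tmax
    a <- cfg$attention_dim
    dstatics <- matrix(0, B, 3)
    dctx <- array(0, dim = c(B, 2 * h, K))
    for (k in seq_len(K)) {
      dck_full <- dcontexts[[k]]
      dstatics <- dstatics + dck_full[, 2 * h + 1:3, drop = FALSE]
      dCd <- dck_full[, seq_len(2 * h), drop = FALSE]
      mk <- io$masks[[k]]
      dctx[, , k] <- if (is.null(mk)) dCd else dCd * mk
    }
    Wall <- do.call(cbind, P[paste0("att_W_", seq_len(K))])
    ball <- unlist(P[paste0("att_b_", seq_len(K))], use.names = FALSE)
    Vall <- do.call(cbind, P[paste0("att_v_", seq_len(K))])
    ab <- cpp_attention_backward(io$fwd$H, io$Hb, batch$lens, Wall,
                                 matrix(ball, 1), Vall, io$alpha, dctx,
                                 param_grads)
    if (param_grads) {
      for (k in seq_len(K)) {
        cols <- (k - 1) * a + seq_len(a)
        G[[paste0("att_W_", k)]] <- ab$dWall[, cols, drop = FALSE]
        G[[paste0("att_b_", k)]] <- as.numeric(ab$dball)[cols]
        G[[paste0("att_v_", k)]] <- ab$dVall[, k]
      }
    }
    dHf <- ab$dHf
    dHb <- ab$dHb
    gf <- cpp_gru_backward(batch$X, batch$lens, P$gru_f_Wx, P$gru_f_Wh,
                           io$fwd$H, io$fwd$r, io$fwd$z, io$fwd$n,
                           io$fwd$u, dHf, param_grads)
    dHb_r <- cpp_reverse_sequences(dHb, batch$lens)
    gb <- cpp_gru_backward(io$Xr, batch$lens, P$gru_b_Wx, P$gru_b_Wh,
                           io$bwd$H, io$bwd$r, io$bwd$z, io$bwd$n,
                           io$bwd$u, dHb_r, param_grads)
    dX <- gf$dX + cpp_reverse_sequences(gb$dX, batch$lens)
    if (param_grads) {
      G$gru_f_Wx <- gf$dWx; G$gru_f_Wh <- gf$dWh
      G$gru_f_b <- as.numeric(gf$db); G$gru_f_bh <- as.numeric(gf$dbh)
      G$gru_b_Wx <- gb$dWx; G$gru_b_Wh <- gb$dWh
      G$gru_b_b <- as.numeric(gb$db); G$gru_b_bh <- as.numeric(gb$dbh)
    }
    if (input_grads) {
      out$dX <- dX
      out$dstatics <- dstatics
    }
  }

  if (cfg$phase != "intraop") {
    pc <- cache$preop
    if (!is.null(pc$m3)) dprep <- dprep * pc$m3
    dfuse_pre <- dprep * (pc$fuse_h > 0)
    dfuse_in <- dfuse_pre %*% t(P$fuse_W)
    dnum_d <- dfuse_in[, seq_len(f), drop = FALSE]
    dnom_d <- dfuse_in[, f + seq_len(f), drop = FALSE]
    if (!is.null(pc$m2)) dnum_d <- dnum_d * pc$m2
    if (!is.null(pc$m1)) dnom_d <- dnom_d * pc$m1
    dnum_pre <- dnum_d * (pc$num_h > 0)
    dnom_pre <- dnom_d * (pc$nom_h > 0)
    dE <- dnom_pre %*% t(P$nom_W)
    if (param_grads) {
      G$fuse_W <- crossprod(pc$fuse_in, dfuse_pre)
      G$fuse_b <- colSums(dfuse_pre)
      G$num_W <- crossprod(batch$numeric, dnum_pre)
      G$num_b <- colSums(dnum_pre)
      G$nom_W <- crossprod(pc$E, dnom_pre)
      G$nom_b <- colSums(dnom_pre)
      e <- cfg$embed_dim
      for (j in 1:6) {
        gj <- G[[paste0("emb_", j)]]
        dEj <- dE[, (j - 1) * e + seq_len(e), drop = FALSE]
        idx <- batch$index[, j] + 1L
        agg <- rowsum(dEj, group = idx, reorder = TRUE)
        gj[as.integer(rownames(agg)), ] <-
          gj[as.integer(rownames(agg)), , drop = FALSE] + agg
        G[[paste0("emb_", j)]] <- gj
      }
    }
    if (input_grads) {
      out$dnumeric <- dnum_pre %*% t(P$num_W)
      out$dembed <- dE
    }
  }
  out$grads <- G
  out
}
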