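#' Restoration network configuration
#'
#' Describes the hybrid dual-path architecture: a four-stage convolutional
#' U-shaped path for local features, a patch-embedding self-attention path
#' for global features, bottleneck fusion by elementwise multiplication and
#' concatenation, and a decoding path that emits one (single-phase, SPIR) or
#' two (dual-phase, DPIR) image channels through a sigmoid so the output
#' retains the input's spatial dimensions and the label range `[0, 1]`.
#'
#' @param input_size input side length; must be divisible by `patch_size`
#'   and by `2^4` (four pooling stages), with `patch_size <= input_size/2`.
#' @param patch_size P: side length of the square patches fed to the
#'   attention path.
#' @param embed_dim K: token embedding dimension.
#' @param n_attention_layers number of self-attention + feed-forward blocks.
#' @param n_heads attention heads (must divide `embed_dim`).
#' @param cnn_base_channels channels of the first convolutional stage;
#'   doubled at each of the four stages.
#' @param output_channels 1 (SPIR) or 2 (DPIR).
#' @param variant `"trans_cnn"` (full dual-path model) or `"cnn_baseline"`
#'   (identical U-shaped path with the attention path and fusion removed —
#'   the conventional-CNN comparison arm).
#' @return a list of class `model_config`.
#' @export
model_config <- function(input_size = 256,
                         patch_size = if (input_size >= 128) 16L else 8L,
                         embed_dim = if (input_size >= 128) 256L else 32L,
                         n_attention_layers = if (input_size >= 128) 4L else 1L,
                         n_heads = if (input_size >= 128) 8L else 2L,
                         cnn_base_channels = if (input_size >= 128) 32L else 4L,
                         output_channels = 1L,
                         variant = c("trans_cnn", "cnn_baseline")) {
  variant <- match.arg(variant)
  input_size <- as.integer(input_size)
  patch_size <- as.integer(patch_size)
  if (input_size %% patch_size != 0) {
    stop("`input_size` must be divisible by `patch_size`", call. = FALSE)
  }
  if (input_size %% 16L != 0) {
    stop("`input_size` must be divisible by 2^4 (four pooling stages)",
         call. = FALSE)
  }
  if ((input_size / patch_size) < (input_size / 16L)) {
    stop("`patch_size` must not exceed 16 (token grid coarser than the ",
         "bottleneck cannot be aligned)", call. = FALSE)
  }
  if (embed_dim %% n_heads != 0) {
    stop("`embed_dim` must be divisible by `n_heads`", call. = FALSE)
  }
  if (!output_channels %in% c(1L, 2L)) {
    stop("`output_channels` must be 1 (SPIR) or 2 (DPIR)", call. = FALSE)
  }
  structure(
    list(
      input_size = input_size, patch_size = patch_size,
      embed_dim = as.integer(embed_dim),
      n_attention_layers = as.integer(n_attention_layers),
      n_heads = as.integer(n_heads),
      cnn_base_channels = as.integer(cnn_base_channels),
      n_cnn_stages = 4L,
      output_channels = as.integer(output_channels),
      variant = variant
    ),
    class = "model_config"
  )
}

enc_channels <- function(cfg) cfg$cnn_base_channels * 2^(0:3)

#' Build a restoration model
#'
#' Allocates and deterministically initializes all trainable parameters of
#' the configured network (He initialization for convolutions, scaled
#' Gaussian for projections, unit-gain layer norms, one learned positional
#' embedding per patch).
#'
#' @param config a [model_config()].
#' @param seed integer seed for the initialization draw.
#' @return an object of class `restoration_model` with fields `config`,
#'   `params` (named list of arrays) and `seed`.
#' @export
build_model <- function(config, seed = 1) {
  stopifnot(inherits(config, "model_config"))
  cfg <- config
  C0 <- cfg$cnn_base_channels
  ch <- enc_channels(cfg)
  p <- list()
  conv_init <- function(cin, cout) {
    array(rnorm(9 * cin * cout, sd = sqrt(2 / (9 * cin))), c(3, 3, cin, cout))
  }
  lin_init <- function(fin, fout, gain = 1) {
    matrix(rnorm(fin * fout, sd = gain * sqrt(1 / fin)), fin, fout)
  }
  params <- with_seed(seed, {
    cin <- 1L
    for (s in 1:4) {
      p[[sprintf("enc%d_conv1_w", s)]] <- conv_init(cin, ch[s])
      p[[sprintf("enc%d_conv1_b", s)]] <- numeric(ch[s])
      p[[sprintf("enc%d_conv2_w", s)]] <- conv_init(ch[s], ch[s])
      p[[sprintf("enc%d_conv2_b", s)]] <- numeric(ch[s])
      cin <- ch[s]
    }
    p$bott_w <- conv_init(ch[4], ch[4])
    p$bott_b <- numeric(ch[4])
    if (cfg$variant == "trans_cnn") {
      K <- cfg$embed_dim
      Tn <- (cfg$input_size / cfg$patch_size)^2
      p$proj_w <- lin_init(cfg$patch_size^2, K)
      p$proj_b <- numeric(K)
      p$pos_emb <- matrix(rnorm(Tn * K, sd = 0.02), Tn, K)
      for (l in seq_len(cfg$n_attention_layers)) {
        nm <- function(x) sprintf("attn%d_%s", l, x)
        p[[nm("ln1_g")]] <- rep(1, K); p[[nm("ln1_b")]] <- numeric(K)
        p[[nm("wq")]] <- lin_init(K, K); p[[nm("bq")]] <- numeric(K)
        p[[nm("wk")]] <- lin_init(K, K); p[[nm("bk")]] <- numeric(K)
        p[[nm("wv")]] <- lin_init(K, K); p[[nm("bv")]] <- numeric(K)
        p[[nm("wo")]] <- lin_init(K, K); p[[nm("bo")]] <- numeric(K)
        p[[nm("ln2_g")]] <- rep(1, K); p[[nm("ln2_b")]] <- numeric(K)
        p[[nm("ff1_w")]] <- lin_init(K, 4 * K, gain = sqrt(2))
        p[[nm("ff1_b")]] <- numeric(4 * K)
        p[[nm("ff2_w")]] <- lin_init(4 * K, K)
        p[[nm("ff2_b")]] <- numeric(K)
      }
      p$lnf_g <- rep(1, K); p$lnf_b <- numeric(K)
      p$tmap_w <- lin_init(K, ch[4], gain = sqrt(2))
      p$tmap_b <- numeric(ch[4])
      p$fuse_w <- lin_init(3 * ch[4], ch[4], gain = sqrt(2))
      p$fuse_b <- numeric(ch[4])
    }
    dch_in <- c(2 * ch[1], 2 * ch[2], 2 * ch[3], 2 * ch[4])
    dch_out <- c(ch[1], ch[1], ch[2], ch[3])
    for (s in 4:1) {
      p[[sprintf("dec%d_conv1_w", s)]] <- conv_init(dch_in[s], dch_out[s])
      p[[sprintf("dec%d_conv1_b", s)]] <- numeric(dch_out[s])
      p[[sprintf("dec%d_conv2_w", s)]] <- conv_init(dch_out[s], dch_out[s])
      p[[sprintf("dec%d_conv2_b", s)]] <- numeric(dch_out[s])
    }
    p$head_w <- lin_init(ch[1], cfg$output_channels)
    # start the sigmoid output near the sparse-glyph gray level instead of
    # 0.5: removes the large uniform offset gradient at the first steps,
    # which otherwise can push entire ReLU stages permanently dead
    p$head_b <- rep(-1.5, cfg$output_channels)
    p
  })
  structure(
    list(config = cfg, params = params, seed = as.integer(seed)),
    class = "restoration_model"
  )
}

#' @export
print.restoration_model <- function(x, ...) {
  cat(sprintf(
    "<restoration_model> %s, input %d, %d output channel(s), %s parameters\n",
    x$config$variant, x$config$input_size, x$config$output_channels,
    format(count_parameters(x), big.mark = ",")
  ))
  invisible(x)
}

#' Number of trainable parameters
#'
#' @param model a [build_model()] result.
#' @return exact integer count of trainable scalars.
#' @export
count_parameters <- function(model) {
  sum(vapply(model$params, length, numeric(1)))
}

# ---- forward -------------------------------------------------------------

# extract non-overlapping P x P patches of x (H, W, N, 1) into a
# (N*T, P^2) matrix, tokens column-major over the token grid within sample
patchify <- function(x, P) {
  d <- dim(x)
  H <- d[1]; W <- d[2]; N <- d[3]
  Ht <- H / P; Wt <- W / P
  Tn <- Ht * Wt
  out <- matrix(0, N * Tn, P^2)
  for (pj in seq_len(P)) {
    for (pi in seq_len(P)) {
      col <- (pj - 1) * P + pi
      v <- x[pi + P * (0:(Ht - 1)), pj + P * (0:(Wt - 1)), , 1]
      out[, col] <- as.vector(v)
    }
  }
  out
}

patchify_bwd <- function(dtok, P, d) {
  H <- d[1]; W <- d[2]; N <- d[3]
  Ht <- H / P; Wt <- W / P
  dx <- array(0, d)
  for (pj in seq_len(P)) {
    for (pi in seq_len(P)) {
      col <- (pj - 1) * P + pi
      dx[pi + P * (0:(Ht - 1)), pj + P * (0:(Wt - 1)), , 1] <-
        array(dtok[, col], c(Ht, Wt, N))
    }
  }
  dx
}

# multi-head self-attention over tokens; E is (N*T, K).  All samples are
# processed together per head: scores are computed as one (N*T x N*T)
# product and masked to the block diagonal, which is faster in practice at
# small token counts than looping over samples.
mhsa_fwd <- function(E, p, nm, n_heads, Tn) {
  K <- ncol(E)
  hd <- K / n_heads
  N <- nrow(E) / Tn
  ln <- layernorm_fwd(E, p[[nm("ln1_g")]], p[[nm("ln1_b")]])
  Q <- linear_fwd(ln$y, p[[nm("wq")]], p[[nm("bq")]])
  Km <- linear_fwd(ln$y, p[[nm("wk")]], p[[nm("bk")]])
  V <- linear_fwd(ln$y, p[[nm("wv")]], p[[nm("bv")]])
  ctx <- matrix(0, nrow(E), K)
  A <- vector("list", n_heads)
  for (h in seq_len(n_heads)) {
    cols <- (h - 1) * hd + seq_len(hd)
    hf <- attn_head_fwd(Q[, cols, drop = FALSE], Km[, cols, drop = FALSE],
                        V[, cols, drop = FALSE], Tn)
    A[[h]] <- hf$A
    ctx[, cols] <- hf$ctx
  }
  O <- linear_fwd(ctx, p[[nm("wo")]], p[[nm("bo")]])
  list(y = E + O, ln = ln, Q = Q, K = Km, V = V, ctx = ctx, A = A)
}

mhsa_bwd <- function(dY, cache, E, p, nm, n_heads, Tn, grads) {
  K <- ncol(E)
  hd <- K / n_heads
  lo <- linear_bwd(cache$ctx, p[[nm("wo")]], dY)
  grads[[nm("wo")]] <- grads[[nm("wo")]] + lo$dw
  grads[[nm("bo")]] <- grads[[nm("bo")]] + lo$db
  dctx <- lo$dx
  dQ <- matrix(0, nrow(E), K); dK <- matrix(0, nrow(E), K)
  dV <- matrix(0, nrow(E), K)
  for (h in seq_len(n_heads)) {
    cols <- (h - 1) * hd + seq_len(hd)
    hb <- attn_head_bwd(dctx[, cols, drop = FALSE], cache$A[[h]],
                        cache$Q[, cols, drop = FALSE],
                        cache$K[, cols, drop = FALSE],
                        cache$V[, cols, drop = FALSE], Tn)
    dQ[, cols] <- hb$dQ; dK[, cols] <- hb$dK; dV[, cols] <- hb$dV
  }
  dln <- matrix(0, nrow(E), K)
  for (w in list(list("wq", "bq", dQ), list("wk", "bk", dK),
                 list("wv", "bv", dV))) {
    lb <- linear_bwd(cache$ln$y, p[[nm(w[[1]])]], w[[3]])
    grads[[nm(w[[1]])]] <- grads[[nm(w[[1]])]] + lb$dw
    grads[[nm(w[[2]])]] <- grads[[nm(w[[2]])]] + lb$db
    dln <- dln + lb$dx
  }
  lnb <- layernorm_bwd(dln, cache$ln, p[[nm("ln1_g")]])
  grads[[nm("ln1_g")]] <- grads[[nm("ln1_g")]] + lnb$dg
  grads[[nm("ln1_b")]] <- grads[[nm("ln1_b")]] + lnb$db
  list(dE = dY + lnb$dx, grads = grads)
}

ffn_fwd <- function(E, p, nm) {
  ln <- layernorm_fwd(E, p[[nm("ln2_g")]], p[[nm("ln2_b")]])
  H1 <- linear_fwd(ln$y, p[[nm("ff1_w")]], p[[nm("ff1_b")]])
  G <- gelu_fwd(H1)
  H2 <- linear_fwd(G, p[[nm("ff2_w")]], p[[nm("ff2_b")]])
  list(y = E + H2, ln = ln, H1 = H1, G = G)
}

ffn_bwd <- function(dY, cache, p, nm, grads) {
  l2 <- linear_bwd(cache$G, p[[nm("ff2_w")]], dY)
  grads[[nm("ff2_w")]] <- grads[[nm("ff2_w")]] + l2$dw
  grads[[nm("ff2_b")]] <- grads[[nm("ff2_b")]] + l2$db
  dG <- gelu_bwd(l2$dx, cache$H1)
  l1 <- linear_bwd(cache$ln$y, p[[nm("ff1_w")]], dG)
  grads[[nm("ff1_w")]] <- grads[[nm("ff1_w")]] + l1$dw
  grads[[nm("ff1_b")]] <- grads[[nm("ff1_b")]] + l1$db
  lnb <- layernorm_bwd(l1$dx, cache$ln, p[[nm("ln2_g")]])
  grads[[nm("ln2_g")]] <- grads[[nm("ln2_g")]] + lnb$dg
  grads[[nm("ln2_b")]] <- grads[[nm("ln2_b")]] + lnb$db
  list(dE = dY + lnb$dx, grads = grads)
}

# attention-path token stack (after embedding); exposed internally so the
# patch-permutation equivariance property can be exercised directly
transformer_tokens_fwd <- function(E, p, cfg) {
  Tn <- (cfg$input_size / cfg$patch_size)^2
  caches <- vector("list", cfg$n_attention_layers)
  for (l in seq_len(cfg$n_attention_layers)) {
    nm <- function(x) sprintf("attn%d_%s", l, x)
    at <- mhsa_fwd(E, p, nm, cfg$n_heads, Tn)
    ff <- ffn_fwd(at$y, p, nm)
    caches[[l]] <- list(attn = at, ffn = ff, E_in = E)
    E <- ff$y
  }
  lnf <- layernorm_fwd(E, p$lnf_g, p$lnf_b)
  list(y = lnf$y, lnf = lnf, caches = caches, E_out = E)
}

#' Forward pass of the restoration network
#'
#' @param model a [build_model()] result.
#' @param x speckle batch: array `(H, W, N)` matching the configured input
#'   size (internally carried as `(H, W, N, C)` channel-last tensors).
#' @param train if `TRUE`, also return the activation cache consumed by the
#'   backward pass.
#' @return array `(H, W, N, output_channels)` of restored images in
#'   `[0, 1]`, or a list `(y, cache)` when `train = TRUE`.
#' @export
forward <- function(model, x, train = FALSE) {
  stopifnot(inherits(model, "restoration_model"))
  cfg <- model$config
  p <- model$params
  if (length(dim(x)) == 3) {
    dim(x) <- c(dim(x), 1L)
  }
  d <- dim(x)
  if (d[1] != cfg$input_size || d[2] != cfg$input_size || d[4] != 1L) {
    stop(sprintf("input batch is %dx%d with %d channel(s), expected %dx%dx1",
                 d[1], d[2], d[4], cfg$input_size, cfg$input_size),
         call. = FALSE)
  }
  ch <- enc_channels(cfg)
  cache <- list(x = x)
  # convolutional encoder
  h <- x
  for (s in 1:4) {
    a1 <- conv3x3_fwd(h, p[[sprintf("enc%d_conv1_w", s)]],
                      p[[sprintf("enc%d_conv1_b", s)]], relu = TRUE)
    a2 <- conv3x3_fwd(a1, p[[sprintf("enc%d_conv2_w", s)]],
                      p[[sprintf("enc%d_conv2_b", s)]], relu = TRUE)
    mp <- maxpool2_fwd(a2)
    cache[[sprintf("enc%d", s)]] <- list(h_in = h, a1 = a1, a2 = a2,
                                         idx = mp$idx)
    h <- mp$y
  }
  f_cnn <- conv3x3_fwd(h, p$bott_w, p$bott_b, relu = TRUE)
  cache$bott_in <- h
  cache$f_cnn <- f_cnn

  if (cfg$variant == "trans_cnn") {
    P <- cfg$patch_size
    tok <- patchify(x, P)
    Tn <- (cfg$input_size / P)^2
    N <- d[3]
    E0 <- linear_fwd(tok, p$proj_w, p$proj_b) +
      p$pos_emb[rep(seq_len(Tn), N), , drop = FALSE]
    tr <- transformer_tokens_fwd(E0, p, cfg)
    Ht <- cfg$input_size / P
    # tokens back onto the spatial grid: (Ht, Wt, N, K)
    tmap <- array(tr$y, c(Ht, Ht, N, cfg$embed_dim))
    pre_t <- conv1x1_fwd(tmap, p$tmap_w, p$tmap_b)
    f_t_full <- relu_fwd(pre_t)
    pf <- as.integer(16 / P) # align token grid to the bottleneck grid
    f_tr <- if (pf > 1) avgpool_fwd(f_t_full, pf) else f_t_full
    prod_ft <- f_cnn * f_tr
    fused_in <- concat_channels(f_cnn, f_tr, prod_ft)
    fused_pre <- conv1x1_fwd(fused_in, p$fuse_w, p$fuse_b)
    dec_in <- relu_fwd(fused_pre)
    cache$trans <- list(tok = tok, E0 = E0, tr = tr, tmap = tmap,
                        pre_t = pre_t, f_t_full = f_t_full, f_tr = f_tr,
                        fused_in = fused_in, dec_in = dec_in, pf = pf)
  } else {
    dec_in <- f_cnn
  }

  # decoder with skip connections from the convolutional path
  dcur <- dec_in
  for (s in 4:1) {
    up <- upsample2_fwd(dcur)
    skip <- cache[[sprintf("enc%d", s)]]$a2
    cat_ <- concat_channels(up, skip)
    h1 <- conv3x3_fwd(cat_, p[[sprintf("dec%d_conv1_w", s)]],
                      p[[sprintf("dec%d_conv1_b", s)]], relu = TRUE)
    h2 <- conv3x3_fwd(h1, p[[sprintf("dec%d_conv2_w", s)]],
                      p[[sprintf("dec%d_conv2_b", s)]], relu = TRUE)
    cache[[sprintf("dec%d", s)]] <- list(d_in = dcur, cat = cat_, h1 = h1,
                                         h2 = h2)
    dcur <- h2
  }
  logits <- conv1x1_fwd(dcur, p$head_w, p$head_b)
  y <- sigmoid_fwd(logits)
  cache$dec_out <- dcur
  cache$y <- y
  if (train) list(y = y, cache = cache) else y
}

# ---- backward ------------------------------------------------------------

# gradient of all parameters given dL/dy; returns a named list aligned with
# model$params
backward <- function(model, cache, dy) {
  cfg <- model$config
  p <- model$params
  grads <- lapply(p, function(v) array(0, dim = dim(v) %||% length(v)))
  dlogits <- sigmoid_bwd(dy, cache$y)
  hb <- conv1x1_bwd(cache$dec_out, p$head_w, dlogits)
  grads$head_w <- grads$head_w + hb$dw
  grads$head_b <- grads$head_b + hb$db
  dcur <- hb$dx
  ch <- enc_channels(cfg)
  dskip <- vector("list", 4)
  for (s in 1:4) {
    dc <- cache[[sprintf("dec%d", s)]]
    b2 <- conv3x3_bwd(dc$h1, p[[sprintf("dec%d_conv2_w", s)]], dcur, dc$h2)
    grads[[sprintf("dec%d_conv2_w", s)]] <-
      grads[[sprintf("dec%d_conv2_w", s)]] + b2$dw
    grads[[sprintf("dec%d_conv2_b", s)]] <-
      grads[[sprintf("dec%d_conv2_b", s)]] + b2$db
    b1 <- conv3x3_bwd(dc$cat, p[[sprintf("dec%d_conv1_w", s)]], b2$dx, dc$h1)
    grads[[sprintf("dec%d_conv1_w", s)]] <-
      grads[[sprintf("dec%d_conv1_w", s)]] + b1$dw
    grads[[sprintf("dec%d_conv1_b", s)]] <-
      grads[[sprintf("dec%d_conv1_b", s)]] + b1$db
    parts <- split_channels(b1$dx, c(dim(dc$d_in)[4], ch[s]))
    dskip[[s]] <- parts[[2]]
    dcur <- upsample2_bwd(parts[[1]], dim(dc$d_in))
  }
  ddec_in <- dcur

  df_cnn <- NULL
  if (cfg$variant == "trans_cnn") {
    tc <- cache$trans
    dfused_pre <- relu_bwd(ddec_in, tc$dec_in)
    fb <- conv1x1_bwd(tc$fused_in, p$fuse_w, dfused_pre)
    grads$fuse_w <- grads$fuse_w + fb$dw
    grads$fuse_b <- grads$fuse_b + fb$db
    parts <- split_channels(fb$dx, rep(ch[4], 3))
    df_cnn <- parts[[1]] + parts[[3]] * tc$f_tr
    df_tr <- parts[[2]] + parts[[3]] * cache$f_cnn
    df_full <- if (tc$pf > 1) {
      avgpool_bwd(df_tr, tc$pf, dim(tc$f_t_full))
    } else {
      df_tr
    }
    dpre_t <- relu_bwd(df_full, tc$f_t_full)
    tb <- conv1x1_bwd(tc$tmap, p$tmap_w, dpre_t)
    grads$tmap_w <- grads$tmap_w + tb$dw
    grads$tmap_b <- grads$tmap_b + tb$db
    dt <- dim(tc$tmap)
    Tn <- dt[1] * dt[2]; N <- dt[3]
    dY <- matrix(tb$dx, Tn * N, cfg$embed_dim)
    # final layer norm
    lnb <- layernorm_bwd(dY, tc$tr$lnf, p$lnf_g)
    grads$lnf_g <- grads$lnf_g + lnb$dg
    grads$lnf_b <- grads$lnf_b + lnb$db
    dE <- lnb$dx
    for (l in rev(seq_len(cfg$n_attention_layers))) {
      nm <- function(x) sprintf("attn%d_%s", l, x)
      lc <- tc$tr$caches[[l]]
      fb2 <- ffn_bwd(dE, lc$ffn, p, nm, grads)
      grads <- fb2$grads
      ab <- mhsa_bwd(fb2$dE, lc$attn, lc$E_in, p, nm, cfg$n_heads, Tn, grads)
      grads <- ab$grads
      dE <- ab$dE
    }
    grads$pos_emb <- grads$pos_emb +
      rowsum(dE, rep(seq_len(Tn), N), reorder = TRUE)
    pb <- linear_bwd(tc$tok, p$proj_w, dE)
    grads$proj_w <- grads$proj_w + pb$dw
    grads$proj_b <- grads$proj_b + pb$db
    # patch path also feeds from the input; input gradient is discarded
  } else {
    df_cnn <- ddec_in
  }

  bb <- conv3x3_bwd(cache$bott_in, p$bott_w, df_cnn, cache$f_cnn)
  grads$bott_w <- grads$bott_w + bb$dw
  grads$bott_b <- grads$bott_b + bb$db
  dh <- bb$dx
  for (s in 4:1) {
    ec <- cache[[sprintf("enc%d", s)]]
    da2 <- maxpool2_bwd(dh, ec$idx, dim(ec$a2)) + dskip[[s]]
    b2 <- conv3x3_bwd(ec$a1, p[[sprintf("enc%d_conv2_w", s)]], da2, ec$a2)
    grads[[sprintf("enc%d_conv2_w", s)]] <-
      grads[[sprintf("enc%d_conv2_w", s)]] + b2$dw
    grads[[sprintf("enc%d_conv2_b", s)]] <-
      grads[[sprintf("enc%d_conv2_b", s)]] + b2$db
    b1 <- conv3x3_bwd(ec$h_in, p[[sprintf("enc%d_conv1_w", s)]], b2$dx, ec$a1)
    grads[[sprintf("enc%d_conv1_w", s)]] <-
      grads[[sprintf("enc%d_conv1_w", s)]] + b1$dw
    grads[[sprintf("enc%d_conv1_b", s)]] <-
      grads[[sprintf("enc%d_conv1_b", s)]] + b1$db
    dh <- b1$dx
  }
  grads
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Save / load a model checkpoint
#'
#' Single-file archive holding the config (as JSON for inspection), the
#' parameter arrays and the training history, loadable by name.
#'
#' @param model a `restoration_model`.
#' @param path file path.
#' @return `save_model` returns `path` invisibly; `load_model` the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "restoration_model"))
  obj <- list(
    config_json = as.character(jsonlite::toJSON(unclass(model$config),
                                                auto_unbox = TRUE)),
    config = model$config, params = model$params, seed = model$seed,
    history = model$history
  )
  saveRDS(obj, path, version = 3)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  m <- structure(
    list(config = obj$config, params = obj$params, seed = obj$seed),
    class = "restoration_model"
  )
  m$history <- obj$history
  m
}
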