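# The multi-task growth-prediction network: a shared 3D convolutional encoder
# (stride-2 downsampling, LeakyReLU 0.2), a sinusoidal time embedding fused at
# the bottleneck by broadcast-concatenation, and three task decoders (warp /
# texture / segmentation) with task-specific extra convolutions on the skip
# connections. The warp decoder emits a displacement field whose final head is
# zero-initialized, so an untrained network starts at the identity transform;
# the texture decoder emits a tanh residual scaled to [-2, 2]; the
# segmentation decoder predicts the follow-up mask through a sigmoid head.
# Transposed convolutions (kernel 2, stride 2) do the upsampling.

#' Network configuration
#'
#' @param voi_size Cubic input edge length; must be divisible by 4 (two
#'   stride-2 stages).
#' @param base_channels Channels at full resolution (doubling per level);
#'   must be even and >= 4. Default 16; the small preset uses 8.
#' @param d_fm Temporal embedding length; defaults to the bottleneck channel
#'   count (4 * base_channels).
#' @param leaky_slope LeakyReLU negative slope.
#' @param mask_input If TRUE (default) the baseline mask is concatenated to
#'   the image as a second input channel.
#' @param deep_supervision Emit the auxiliary direct texture prediction from
#'   the half-resolution decoder stage.
#' @param ncc_window Window edge for the local NCC losses.
#' @return A \code{network_config} list.
#' @export
network_config <- function(voi_size = 48L, base_channels = 16L, d_fm = NULL,
                           leaky_slope = 0.2, mask_input = TRUE,
                           deep_supervision = TRUE, ncc_window = 9L) {
  voi_size <- as.integer(voi_size)
  base_channels <- as.integer(base_channels)
  if (voi_size %% 4L != 0L)
    stop("voi_size must be divisible by 4 (two stride-2 stages)")
  if (base_channels < 4L || base_channels %% 2L != 0L)
    stop("base_channels must be an even integer >= 4")
  d_fm <- as.integer(d_fm %||% (4L * base_channels))
  if (d_fm %% 2L != 0L) stop("d_fm must be even")
  structure(list(voi_size = voi_size, base_channels = base_channels,
                 d_fm = d_fm, leaky_slope = leaky_slope,
                 mask_input = isTRUE(mask_input),
                 deep_supervision = isTRUE(deep_supervision),
                 ncc_window = as.integer(ncc_window)),
            class = "network_config")
}

.he_mat <- function(fan_in, n_out) {
  matrix(rnorm(fan_in * n_out, sd = sqrt(2 / fan_in)), fan_in, n_out)
}

.tasks <- c("warp", "tex", "seg")

#' Initialize network parameters
#'
#' He-initialized convolution weights; the displacement head is
#' zero-initialized so training starts from the identity warp.
#'
#' @param cfg A \code{\link{network_config}}.
#' @param seed RNG seed for the initialization.
#' @return A \code{growth_net} list with \code{params} (named list of weight
#'   matrices / bias vectors) and \code{cfg}.
#' @export
init_network <- function(cfg, seed = 1L) {
  c0 <- cfg$base_channels
  cin <- if (cfg$mask_input) 2L else 1L
  params <- with_seed(seed, {
    p <- list()
    conv <- function(ci, co) list(w = .he_mat(ci * 27L, co), b = numeric(co))
    dcnv <- function(ci, co) list(w = .he_mat(co * 8L, ci), b = numeric(co))
    p$enc1 <- conv(cin, c0)
    p$down1 <- conv(c0, 2L * c0)
    p$enc2 <- conv(2L * c0, 2L * c0)
    p$down2 <- conv(2L * c0, 4L * c0)
    p$bott <- conv(4L * c0, 4L * c0)
    p$fuse <- conv(4L * c0 + cfg$d_fm, 4L * c0)
    outs <- c(warp = 3L, tex = 1L, seg = 1L)
    for (t in .tasks) {
      p[[paste0("skip2_", t)]] <- conv(2L * c0, c0)
      p[[paste0("skip1_", t)]] <- conv(c0, c0 %/% 2L)
      p[[paste0("up2_", t)]] <- dcnv(4L * c0, 2L * c0)
      p[[paste0("dec2_", t)]] <- conv(3L * c0, c0)
      p[[paste0("up1_", t)]] <- dcnv(c0, c0 %/% 2L)
      p[[paste0("head_", t)]] <- conv(c0, outs[[t]])
    }
    p$head_warp$w[] <- 0  # identity transform at initialization
    p$head_warp$b[] <- 0
    p$ds <- dcnv(c0, 1L)
    p
  })
  structure(list(params = params, cfg = cfg), class = "growth_net")
}

# parameter names belonging to each trainable group
.param_groups <- function(params) {
  nm <- names(params)
  enc <- c("enc1", "down1", "enc2", "down2", "bott", "fuse")
  grp <- list(encoder = enc,
              warp = nm[grepl("_warp$", nm)],
              tex = c(nm[grepl("_tex$", nm)], "ds"),
              seg = nm[grepl("_seg$", nm)])
  grp
}

#' Count trainable parameters
#'
#' @param cfg A \code{\link{network_config}}.
#' @return Integer number of scalar parameters.
#' @export
count_parameters <- function(cfg) {
  net <- init_network(cfg, seed = 1L)
  sum(vapply(net$params, function(l) length(l$w) + length(l$b), numeric(1)))
}

# wrap parameter arrays as tape leaves (one set per optimization step)
.param_nodes <- function(tape, params) {
  lapply(params, function(l) list(w = ag_leaf(tape, l$w),
                                  b = ag_leaf(tape, l$b)))
}

# shared encoder + task-specific skip features. The encoder is
# time-independent, so one encoding serves both the main and zero-interval
# passes of a training step. xcf, scf: channel-first (1, D, H, W) leaves.
.encode_nodes <- function(tape, cfg, P, xcf, scf, tasks = .tasks,
                          detach_encoder = FALSE) {
  sl <- cfg$leaky_slope
  xin <- if (cfg$mask_input) ag_concat(tape, xcf, scf) else xcf
  cv <- function(inp, l, stride = 1L, input_grad = TRUE) {
    ag_conv(tape, inp, P[[l]]$w, P[[l]]$b, k = 3L, stride = stride, pad = 1L,
            input_grad = input_grad)
  }
  e1 <- ag_lrelu(tape, cv(xin, "enc1", input_grad = FALSE), sl)
  h1 <- ag_lrelu(tape, cv(e1, "down1", 2L), sl)
  e2 <- ag_lrelu(tape, cv(h1, "enc2"), sl)
  q1 <- ag_lrelu(tape, cv(e2, "down2", 2L), sl)
  bt <- ag_lrelu(tape, cv(q1, "bott"), sl)
  if (detach_encoder) {
    e1 <- ag_detach(tape, e1)
    e2 <- ag_detach(tape, e2)
    bt <- ag_detach(tape, bt)
  }
  enc <- list(e1 = e1, e2 = e2, bt = bt, xcf = xcf, scf = scf)
  for (t in tasks) {
    enc[[paste0("sk2_", t)]] <- ag_lrelu(tape, cv(e2, paste0("skip2_", t)), sl)
    enc[[paste0("sk1_", t)]] <- ag_lrelu(tape, cv(e1, paste0("skip1_", t)), sl)
  }
  enc
}

# decoders for one time conditioning, reusing an encoding
.decode_nodes <- function(tape, cfg, P, enc, t_itv, tasks = .tasks,
                          deep_supervision = cfg$deep_supervision) {
  sl <- cfg$leaky_slope
  cv <- function(inp, l) {
    ag_conv(tape, inp, P[[l]]$w, P[[l]]$b, k = 3L, stride = 1L, pad = 1L)
  }
  qd <- dim(enc$bt$value)[2:4]
  emb <- tem_encode(t_itv, cfg$d_fm)
  embmap <- ag_node(tape, array(rep(emb, prod(qd)), c(cfg$d_fm, qd)))
  bt2 <- ag_lrelu(tape, cv(ag_concat(tape, enc$bt, embmap), "fuse"), sl)
  xcf <- enc$xcf
  scf <- enc$scf
  dec <- function(t) {
    u2 <- ag_deconv(tape, bt2, P[[paste0("up2_", t)]]$w,
                    P[[paste0("up2_", t)]]$b)
    d2 <- ag_lrelu(tape, cv(ag_concat(tape, u2, enc[[paste0("sk2_", t)]]),
                            paste0("dec2_", t)), sl)
    u1 <- ag_deconv(tape, d2, P[[paste0("up1_", t)]]$w,
                    P[[paste0("up1_", t)]]$b)
    head <- cv(ag_concat(tape, u1, enc[[paste0("sk1_", t)]]),
               paste0("head_", t))
    list(head = head, d2 = d2)
  }
  out <- list(params = P)
  if ("warp" %in% tasks) {
    wd <- dec("warp")
    out$u <- wd$head                              # (3, D, H, W), voxel units
    out$x_warp <- ag_warp(tape, xcf, out$u)
    out$s_warp <- ag_warp(tape, scf, out$u)
  }
  if ("tex" %in% tasks) {
    td <- dec("tex")
    out$x_res <- ag_scale(tape, ag_tanh(tape, td$head), 2)  # in [-2, 2]
    if (!is.null(out$x_warp)) {
      out$y_hat <- ag_add(tape, out$x_warp,
                          ag_mul(tape, out$x_res, out$s_warp))
    }
    if (deep_supervision && !is.null(out$x_warp)) {
      xt <- ag_tanh(tape, ag_deconv(tape, td$d2, P$ds$w, P$ds$b))
      one <- ag_node(tape, array(1, dim(out$s_warp$value)))
      out$x_texture <- xt
      out$y_ds <- ag_add(tape,
                         ag_mul(tape, out$x_warp,
                                ag_sub(tape, one, out$s_warp)),
                         ag_mul(tape, xt, out$s_warp))
    }
  }
  if ("seg" %in% tasks) {
    sg <- dec("seg")
    out$seg <- ag_sigmoid(tape, sg$head)
  }
  out
}

#' Run the network on one baseline VOI
#'
#' Executes a full forward pass and returns the prediction bundle as plain
#' arrays: the displacement field \code{u} (voxel units, spatial-last layout),
#' the warped image and mask, the texture residual, the fused prediction
#' \code{y_hat = x_warp + x_res * s_warp}, the segmentation-decoder mask, and
#' (with deep supervision) the auxiliary direct prediction.
#'
#' @param net A \code{growth_net}.
#' @param x Baseline volume, values in [-1, 1], shape \code{voi_size^3}.
#' @param s Baseline mask in [0, 1], same shape.
#' @param t_itv Follow-up interval in months (0--20).
#' @param clamp Clamp \code{y_hat} to [-1, 1] (export convention).
#' @return A \code{prediction_bundle} list.
#' @export
predict_bundle <- function(net, x, s, t_itv, clamp = TRUE) {
  d <- dim(x)
  if (!identical(as.integer(d), rep(net$cfg$voi_size, 3L)))
    stop("input shape must be ", net$cfg$voi_size, "^3")
  if (!identical(dim(s), d)) stop("mask shape must match the volume")
  if (t_itv < 0 || t_itv > 20) stop("t_itv must be in [0, 20] months")
  tape <- ag_tape()
  P <- .param_nodes(tape, net$params)
  xcf <- ag_leaf(tape, array(x, c(1L, d)))
  scf <- ag_leaf(tape, array(s, c(1L, d)))
  enc <- .encode_nodes(tape, net$cfg, P, xcf, scf)
  nd <- .decode_nodes(tape, net$cfg, P, enc, t_itv)
  y <- array(nd$y_hat$value, d)
  if (clamp) y <- pmin(pmax(y, -1), 1)
  out <- list(u = aperm(array(nd$u$value, c(3L, d)), c(2, 3, 4, 1)),
              x_warp = array(nd$x_warp$value, d),
              s_warp = array(nd$s_warp$value, d),
              x_res = array(nd$x_res$value, d),
              y_hat = y,
              seg_mask = array(nd$seg$value, d))
  if (!is.null(nd$y_ds)) {
    out$x_texture <- array(nd$x_texture$value, d)
    out$y_ds <- array(nd$y_ds$value, d)
  }
  structure(out, class = "prediction_bundle")
}

#' Residual fusion of warp and texture branches
#'
#' \code{y = x_warp + x_res * s_warp}: the texture residual is added inside
#' the (soft) warped nodule mask, leaving the background untouched.
#'
#' @param x_warp,x_res,s_warp Arrays of equal shape; \code{s_warp} in [0, 1].
#' @param clamp Clamp the result to [-1, 1] (export convention).
#' @return Fused prediction array.
#' @export
fuse_residual <- function(x_warp, x_res, s_warp, clamp = FALSE) {
  y <- x_warp + x_res * s_warp
  if (clamp) y <- pmin(pmax(y, -1), 1)
  y
}

#' Direct fusion used by deep supervision
#'
#' \code{y = x_warp * (1 - s_warp) + x_texture * s_warp}: a mask-gated blend
#' of the warped background and a directly predicted nodule appearance. It
#' agrees with \code{\link{fuse_residual}} wherever
#' \code{x_texture = x_warp + x_res} on the mask support.
#'
#' @param x_warp,x_texture,s_warp Arrays of equal shape; \code{s_warp} in
#'   [0, 1].
#' @param clamp Clamp the result to [-1, 1].
#' @return Fused prediction array.
#' @export
fuse_direct <- function(x_warp, x_texture, s_warp, clamp = FALSE) {
  y <- x_warp * (1 - s_warp) + x_texture * s_warp
  if (clamp) y <- pmin(pmax(y, -1), 1)
  y
}
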