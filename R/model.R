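#' Model configuration
#'
#' Bundles the architectural hyperparameters of the segmentation network:
#' a four-stage residual encoder whose stages end in channel and spatial
#' attention, three structurally identical decoder branches (nuclear
#' probability, horizontal-vertical distance regression, classification),
#' and one attention-enhanced residual refinement head per branch.
#'
#' @param residual_units_per_stage integer vector of length 4; residual
#'   units in encoder stages 1-4 (default `c(3, 4, 6, 3)`, the ResNet-50
#'   layout with the initial max-pool removed and a stride-1 stem).
#' @param attention_reduction channel-attention bottleneck reduction ratio.
#' @param num_classes number of nucleus types K (background excluded).
#' @param padding_mode `"same"` (output size equals input size) or
#'   `"valid"` (interior computation; the output is center-cropped to
#'   `output_size`, by default `input - 190`, reproducing the 270 to 80
#'   geometry).
#' @param arrm_pool_stages pooling stages in the refinement head (2-4; use 2
#'   when the cropped output, e.g. 164, is not divisible by 16).
#' @param base_width stem width; encoder stage l uses bottleneck width
#'   `base_width * 2^(l-1)` with 4x expansion. 64 gives the full-size model;
#'   small values give desk-scale models.
#' @param growth dense-unit growth rate in the decoder blocks.
#' @param arrm_width channel width inside the refinement head.
#' @param output_size optional center-crop (pixels) applied to the branch
#'   outputs before refinement.
#' @param use_attention enable the encoder attention blocks.
#' @param use_arrm enable the residual refinement heads (when disabled the
#'   refined outputs equal the coarse outputs).
#' @param seed integer seed controlling weight initialization.
#' @return a `model_config` list.
#' @export
model_config <- function(residual_units_per_stage = c(3L, 4L, 6L, 3L),
                         attention_reduction = 16L,
                         num_classes = 4L,
                         padding_mode = c("same", "valid"),
                         arrm_pool_stages = 4L,
                         base_width = 64L,
                         growth = 32L,
                         arrm_width = 32L,
                         output_size = NULL,
                         use_attention = TRUE,
                         use_arrm = TRUE,
                         seed = 1L) {
  padding_mode <- match.arg(padding_mode)
  stopifnot(
    length(residual_units_per_stage) == 4L,
    all(residual_units_per_stage >= 1L),
    arrm_pool_stages %in% 2:4,
    base_width >= 1L, growth >= 1L, num_classes >= 1L,
    attention_reduction >= 1L
  )
  structure(
    list(
      residual_units_per_stage = as.integer(residual_units_per_stage),
      attention_reduction = as.integer(attention_reduction),
      num_classes = as.integer(num_classes),
      padding_mode = padding_mode,
      arrm_pool_stages = as.integer(arrm_pool_stages),
      base_width = as.integer(base_width),
      growth = as.integer(growth),
      arrm_width = as.integer(arrm_width),
      output_size = if (is.null(output_size)) NULL else as.integer(output_size),
      use_attention = isTRUE(use_attention),
      use_arrm = isTRUE(use_arrm),
      seed = as.integer(seed)
    ),
    class = "model_config"
  )
}

enc_channels <- function(config) 4L * config$base_width * c(1L, 2L, 4L, 8L)

# ---- layout helpers ------------------------------------------------------

# User-facing maps are H x W (x C); internally (C, H, W, N).
to_chw <- function(x) {
  if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L)
  y <- aperm(x, c(3L, 1L, 2L))
  dim(y) <- c(dim(y), 1L)
  y
}

from_chw <- function(x, drop_channel = FALSE) {
  d <- dim(x)
  stopifnot(d[4] == 1L)
  dim(x) <- d[1:3]
  y <- aperm(x, c(2L, 3L, 1L))
  if (drop_channel && dim(y)[3] == 1L) dim(y) <- dim(y)[1:2]
  y
}

# Stack a list of H x W x C images into (C, H, W, N) in [0, 1].
images_to_batch <- function(images) {
  if (!is.list(images)) images <- list(images)
  xs <- lapply(images, function(im) to_chw(im / 255))
  d <- dim(xs[[1]])
  out <- array(0, c(d[1:3], length(xs)))
  for (i in seq_along(xs)) out[, , , i] <- xs[[i]]
  out
}

# ---- encoder -------------------------------------------------------------

#' Build the attention-enhanced residual encoder
#'
#' Four residual stages (unit counts from the configuration) each ending in
#' a channel-then-spatial attention block. The stem is a stride-1 7x7
#' convolution and there is no initial max-pooling, so stage 1 keeps full
#' resolution; stages 2-4 downsample by 2 each. The forward pass returns
#' the four per-stage feature maps for the decoder skips.
#'
#' @param config a [model_config()].
#' @return an encoder module with a `$forward(x)` returning `list(e1..e4)`.
#' @export
build_encoder <- function(config) {
  m <- new_module("encoder")
  bw <- config$base_width
  ch <- enc_channels(config)
  seed <- config$seed
  m$children$stem <- mod_cbr(3L, bw, 7L, 1L, seed, "enc/stem")
  cins <- c(bw, ch[1:3])
  for (l in 1:4) {
    m$children[[paste0("stage", l)]] <- mod_csar_stage(
      cins[l], bw * 2L^(l - 1L), ch[l],
      config$residual_units_per_stage[l],
      stride = if (l == 1L) 1L else 2L,
      reduction = config$attention_reduction,
      use_attention = config$use_attention,
      seed = seed, path = paste0("enc/stage", l)
    )
  }
  m$forward <- function(x, override_gates = NULL) {
    x <- m$children$stem$forward(x)
    e1 <- m$children$stage1$forward(x, override_gates)
    e2 <- m$children$stage2$forward(e1, override_gates)
    e3 <- m$children$stage3$forward(e2, override_gates)
    e4 <- m$children$stage4$forward(e3, override_gates)
    list(e1, e2, e3, e4)
  }
  m
}

#' Apply a channel- and spatial-attention block to a feature map
#'
#' Gates the input feature map with a sigmoid channel gate (shared
#' two-layer bottleneck over global average and max pooling) followed by a
#' sigmoid spatial gate (7x7 convolution over channel mean/max maps):
#' `out = x * channel_gate * spatial_gate`. Shape is preserved.
#'
#' @param features H x W x C feature array.
#' @param reduction channel-attention reduction ratio.
#' @param seed weight initialization seed.
#' @param override_gates if given, both gates are forced to this constant
#'   (e.g. 1 turns the block into the identity), a hook used for testing.
#' @param module optionally reuse a previously returned attention module.
#' @return the gated H x W x C array with the module attached as
#'   attribute `"module"`.
#' @export
attention_block <- function(features, reduction = 16L, seed = 1L,
                            override_gates = NULL, module = NULL) {
  x <- to_chw(features)
  C <- dim(x)[1]
  if (is.null(module)) module <- mod_attention(C, reduction, seed, "att")
  y <- ag_no_grad(ag_value(module$forward(as_ag(x), override_gates)))
  structure(from_chw(y), module = module)
}

# ---- decoder branch ------------------------------------------------------

#' Build one decoder branch
#'
#' Three nearest-neighbour x2 upsampling stages restore the encoder's /8
#' resolution; dense blocks of 8 and 4 dense units follow the first and
#' second upsampling. Encoder skip features are merged by elementwise
#' addition through 1x1 projections. The head emits `out_channels` maps.
#'
#' @param config a [model_config()].
#' @param out_channels output channels (2 for the probability and distance
#'   branches, K + 1 for classification).
#' @param name branch name used to seed the weights.
#' @return a decoder module; `$forward(enc_feats)` takes the encoder's
#'   four feature maps.
#' @export
build_decoder_branch <- function(config, out_channels, name = "dec") {
  m <- new_module(name)
  ch <- enc_channels(config)
  g <- config$growth
  seed <- config$seed
  p <- function(x) paste0(name, "/", x)
  m$children$up3_proj <- mod_conv(ch[4], ch[3], 1L, bias = FALSE, seed = seed, path = p("up3_proj"))
  m$children$skip3 <- mod_conv(ch[3], ch[3], 1L, bias = FALSE, seed = seed, path = p("skip3"))
  m$children$dense3 <- mod_dense_block(ch[3], 8L, g, seed, p("dense3"))
  m$children$red3 <- mod_conv(m$children$dense3$cout, ch[2], 1L, bias = FALSE, seed = seed, path = p("red3"))
  m$children$skip2 <- mod_conv(ch[2], ch[2], 1L, bias = FALSE, seed = seed, path = p("skip2"))
  m$children$dense2 <- mod_dense_block(ch[2], 4L, g, seed, p("dense2"))
  m$children$red2 <- mod_conv(m$children$dense2$cout, ch[1], 1L, bias = FALSE, seed = seed, path = p("red2"))
  m$children$skip1 <- mod_conv(ch[1], ch[1], 1L, bias = FALSE, seed = seed, path = p("skip1"))
  m$children$fuse1 <- mod_cbr(ch[1], ch[1], 3L, 1L, seed, p("fuse1"))
  m$children$head <- mod_conv(ch[1], out_channels, 1L, bias = TRUE, seed = seed, path = p("head"))
  m$forward <- function(enc) {
    check_skip <- function(u, e) {
      du <- dims4(ag_value(u))
      de <- dims4(ag_value(e))
      if (!identical(du[2:3], de[2:3])) {
        stop(
          "decoder/skip spatial mismatch: ", du[2], "x", du[3], " vs ",
          de[2], "x", de[3], " (input size incompatible with the architecture)"
        )
      }
    }
    u <- m$children$up3_proj$forward(op_upsample2(enc[[4]]))
    check_skip(u, enc[[3]])
    u <- op_add(u, m$children$skip3$forward(enc[[3]]))
    u <- m$children$red3$forward(m$children$dense3$forward(u))
    u <- op_upsample2(u)
    check_skip(u, enc[[2]])
    u <- op_add(u, m$children$skip2$forward(enc[[2]]))
    u <- m$children$red2$forward(m$children$dense2$forward(u))
    u <- op_upsample2(u)
    check_skip(u, enc[[1]])
    u <- op_add(u, m$children$skip1$forward(enc[[1]]))
    m$children$head$forward(m$children$fuse1$forward(u))
  }
  m
}

# ---- refinement head -----------------------------------------------------

#' Build an attention-enhanced residual refinement head
#'
#' A compact encoder-decoder operating on a branch's coarse prediction map:
#' an entry convolution, `arrm_pool_stages` encoder stages of
#' (3x3 conv - BN - ReLU - channel attention) followed by 2x2 max-pooling, a
#' channel-attention convolution bridge, matching upsample-convolution
#' decoder stages, and an exit convolution back to `channels`. The module
#' returns a residual correction with the input's spatial size; the refined
#' prediction is `coarse + residual`.
#'
#' @param config a [model_config()].
#' @param channels number of prediction channels refined by this head.
#' @param name head name used to seed the weights.
#' @return a refinement module.
#' @export
build_arrm <- function(config, channels, name = "arrm") {
  m <- new_module(name)
  aw <- config$arrm_width
  np <- config$arrm_pool_stages
  red <- config$attention_reduction
  seed <- config$seed
  p <- function(x) paste0(name, "/", x)
  m$children$entry <- mod_conv(channels, aw, 3L, bias = TRUE, seed = seed, path = p("entry"))
  for (i in seq_len(np)) {
    m$children[[paste0("enc", i)]] <- mod_cac(aw, aw, red, seed, p(paste0("enc", i)))
  }
  m$children$bridge <- mod_cac(aw, aw, red, seed, p("bridge"))
  for (i in seq_len(np)) {
    m$children[[paste0("dec", i)]] <- mod_cbr(aw, aw, 3L, 1L, seed, p(paste0("dec", i)))
  }
  m$children$exit <- mod_conv(aw, channels, 3L, bias = TRUE, seed = seed, path = p("exit"))
  m$n_pool <- np
  m$forward <- function(x) {
    d <- dims4(ag_value(x))
    if (d[2] %% 2L^m$n_pool != 0L || d[3] %% 2L^m$n_pool != 0L) {
      stop(
        "refinement head input ", d[2], "x", d[3],
        " is not divisible by 2^", m$n_pool
      )
    }
    u <- m$children$entry$forward(x)
    for (i in seq_len(m$n_pool)) {
      u <- op_maxpool2(m$children[[paste0("enc", i)]]$forward(u))
    }
    u <- m$children$bridge$forward(u)
    for (i in seq_len(m$n_pool)) {
      u <- m$children[[paste0("dec", i)]]$forward(op_upsample2(u))
    }
    m$children$exit$forward(u)
  }
  m
}

# ---- full model ----------------------------------------------------------

#' Assemble the full segmentation and classification network
#'
#' One shared attention-enhanced encoder, three decoder branches (nuclear
#' probability: 2 channels; horizontal-vertical distance regression: 2
#' channels; classification: K + 1 channels) and, when enabled, one
#' residual refinement head per branch.
#'
#' @param config a [model_config()].
#' @return a model module; use [model_forward()] to run it.
#' @export
aernet_model <- function(config) {
  m <- new_module("aernet")
  m$config <- config
  m$children$encoder <- build_encoder(config)
  m$children$np <- build_decoder_branch(config, 2L, "np")
  m$children$hv <- build_decoder_branch(config, 2L, "hv")
  m$children$tp <- build_decoder_branch(config, config$num_classes + 1L, "tp")
  if (config$use_arrm) {
    m$children$arrm_np <- build_arrm(config, 2L, "arrm_np")
    m$children$arrm_hv <- build_arrm(config, 2L, "arrm_hv")
    m$children$arrm_tp <- build_arrm(config, config$num_classes + 1L, "arrm_tp")
  }
  m
}

#' Run the network on a batch of image patches
#'
#' @param model a model from [aernet_model()].
#' @param images an H x W x 3 array with values in `[0, 255]`, or a list of
#'   such arrays (all the same size).
#' @param training logical; training mode uses batch statistics in the
#'   batch-norm layers and records gradients.
#' @param as_arrays return plain arrays (eval) instead of autodiff nodes.
#' @return a list with elements `prob_coarse`, `prob_refined`, `hv_coarse`,
#'   `hv_refined`, `class_coarse`, `class_refined`, each `(C, H', W', N)`
#'   (probability and classification maps are logits), plus `crop_offset`.
#' @export
model_forward <- function(model, images, training = FALSE, as_arrays = !training) {
  config <- model$config
  x <- if (is.list(images) || length(dim(images)) == 3L) {
    images_to_batch(images)
  } else {
    images
  }
  d <- dims4(x)
  H <- d[2]; W <- d[3]
  crop_offset <- c(0L, 0L)
  out_size <- config$output_size
  if (config$padding_mode == "valid") {
    # interior computation: crop the frame to a /8-compatible size, compute
    # with same padding, then center-crop to the published output geometry
    Hc <- (H %/% 8L) * 8L
    Wc <- (W %/% 8L) * 8L
    if (is.null(out_size)) out_size <- min(H, W) - 190L
    if (out_size < 8L) stop("input too small for valid-mode computation")
    oh <- (H - Hc) %/% 2L
    ow <- (W - Wc) %/% 2L
    crop_offset <- c(oh + (Hc - out_size) %/% 2L, ow + (Wc - out_size) %/% 2L)
    x <- x[, oh + seq_len(Hc), ow + seq_len(Wc), , drop = FALSE]
  } else if (H %% 8L != 0L || W %% 8L != 0L) {
    stop("same-padding mode requires input sizes divisible by 8, got ", H, "x", W)
  } else if (!is.null(out_size)) {
    crop_offset <- c((H - out_size) %/% 2L, (W - out_size) %/% 2L)
  }
  run <- function() {
    ag_set_training(training)
    on.exit(ag_set_training(FALSE))
    enc <- model$children$encoder$forward(as_ag(x))
    coarse <- list(
      prob = model$children$np$forward(enc),
      hv = model$children$hv$forward(enc),
      class = model$children$tp$forward(enc)
    )
    if (!is.null(out_size)) {
      coarse <- lapply(coarse, op_crop, out_h = out_size, out_w = out_size)
    }
    refined <- if (config$use_arrm) {
      list(
        prob = op_add(coarse$prob, model$children$arrm_np$forward(coarse$prob)),
        hv = op_add(coarse$hv, model$children$arrm_hv$forward(coarse$hv)),
        class = op_add(coarse$class, model$children$arrm_tp$forward(coarse$class))
      )
    } else {
      coarse
    }
    list(
      prob_coarse = coarse$prob, prob_refined = refined$prob,
      hv_coarse = coarse$hv, hv_refined = refined$hv,
      class_coarse = coarse$class, class_refined = refined$class
    )
  }
  out <- if (training) run() else ag_no_grad(run())
  if (as_arrays) out <- lapply(out, ag_value)
  out$crop_offset <- crop_offset
  out
}

#' Read / write a model configuration as YAML
#'
#' @param config a [model_config()].
#' @param path a `.yaml`/`.yml` file.
#' @return `read_model_config` returns a validated [model_config()].
#' @export
write_model_config <- function(config, path) {
  stopifnot(inherits(config, "model_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_model_config
#' @export
read_model_config <- function(path) {
  v <- yaml::read_yaml(path)
  do.call(model_config, v)
}

# ---- checkpoints ---------------------------------------------------------

collect_bn_states <- function(m, out = list(), prefix = m$kind) {
  if (identical(m$kind, "bn")) {
    out[[prefix]] <- list(
      running_mean = m$state$running_mean,
      running_var = m$state$running_var
    )
  }
  for (nm in names(m$children)) {
    out <- collect_bn_states(m$children[[nm]], out, paste(prefix, nm, sep = "."))
  }
  out
}

restore_bn_states <- function(m, states, prefix = m$kind) {
  if (identical(m$kind, "bn") && !is.null(states[[prefix]])) {
    m$state$running_mean <- states[[prefix]]$running_mean
    m$state$running_var <- states[[prefix]]$running_var
  }
  for (nm in names(m$children)) {
    restore_bn_states(m$children[[nm]], states, paste(prefix, nm, sep = "."))
  }
  invisible(NULL)
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single file holding the configuration (as JSON) and
#' all parameter and batch-norm running statistics; `load_checkpoint`
#' rebuilds the model and restores the exact state, so an eval-mode forward
#' pass after a round-trip is bit-identical.
#'
#' @param model a model from [aernet_model()].
#' @param path file path.
#' @export
save_checkpoint <- function(model, path) {
  params <- collect_params(model)
  saveRDS(list(
    config_json = jsonlite::toJSON(unclass(model$config), auto_unbox = TRUE, null = "null"),
    params = lapply(params, function(p) p$value),
    bn = collect_bn_states(model)
  ), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  cfg <- jsonlite::fromJSON(ck$config_json)
  config <- model_config(
    residual_units_per_stage = cfg$residual_units_per_stage,
    attention_reduction = cfg$attention_reduction,
    num_classes = cfg$num_classes,
    padding_mode = cfg$padding_mode,
    arrm_pool_stages = cfg$arrm_pool_stages,
    base_width = cfg$base_width,
    growth = cfg$growth,
    arrm_width = cfg$arrm_width,
    output_size = cfg$output_size,
    use_attention = cfg$use_attention,
    use_arrm = cfg$use_arrm,
    seed = cfg$seed
  )
  model <- aernet_model(config)
  params <- collect_params(model)
  stopifnot(setequal(names(params), names(ck$params)))
  for (nm in names(params)) params[[nm]]$value <- ck$params[[nm]]
  restore_bn_states(model, ck$bn)
  model
}
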