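# Desk-scale training and inference: joint augmentation, Adam with the
# two-stage halved-rate schedule, and patch inference through the
# watershed post-processing.

#' Jointly augment an image patch and its targets
#'
#' Random horizontal/vertical flips are applied to the image, the instance
#' map, the class map and the distance map together (the flipped distance
#' channel changes sign, which equals recomputing the encoding on the
#' flipped instance map); Gaussian or median blur is applied to the image
#' only.
#'
#' @param image H x W x 3 array (0-255).
#' @param instances,classes H x W integer label maps.
#' @param hv optional H x W x 2 distance map (recomputed from `instances`
#'   when missing).
#' @param seed optional integer seed for the draws.
#' @return list with the augmented `image`, `instances`, `classes`, `hv`
#'   and the `draws` that were applied.
#' @export
augment <- function(image, instances, classes, hv = NULL, seed = NULL) {
  if (is.null(hv)) hv <- compute_hv_map(instances)
  run <- function() {
    do_h <- stats::runif(1) < 0.5
    do_v <- stats::runif(1) < 0.5
    blur <- sample(c("none", "gaussian", "median"), 1L, prob = c(0.5, 0.25, 0.25))
    sigma <- stats::runif(1, 0.5, 1.5)
    W <- ncol(instances)
    H <- nrow(instances)
    if (do_h) {
      image <- image[, W:1, , drop = FALSE]
      instances <- instances[, W:1, drop = FALSE]
      classes <- classes[, W:1, drop = FALSE]
      hv <- hv[, W:1, , drop = FALSE]
      hv[, , 1] <- -hv[, , 1]
    }
    if (do_v) {
      image <- image[H:1, , , drop = FALSE]
      instances <- instances[H:1, , drop = FALSE]
      classes <- classes[H:1, , drop = FALSE]
      hv <- hv[H:1, , , drop = FALSE]
      hv[, , 2] <- -hv[, , 2]
    }
    if (blur == "gaussian") {
      image <- round(pmin(pmax(EBImage::gblur(image / 255, sigma = sigma), 0), 1) * 255)
    } else if (blur == "median") {
      image <- round(EBImage::medianFilter(image / 255, size = 1L) * 255)
    }
    list(
      image = image, instances = instances, classes = classes, hv = hv,
      draws = list(hflip = do_h, vflip = do_v, blur = blur, sigma = sigma)
    )
  }
  if (is.null(seed)) run() else with_seed_local(seed, run())
}

#' Generate a synthetic training set
#'
#' @param n number of scenes.
#' @param template a [scene_spec()] whose seed is offset per scene.
#' @param seed base seed.
#' @return list of samples, each with `image`, `instances`, `classes`, `hv`.
#' @export
make_synthetic_dataset <- function(n, template = scene_spec(), seed = 1L) {
  lapply(seq_len(n), function(i) {
    sp <- template
    sp$seed <- as.integer((seed + 7919 * i) %% .Machine$integer.max)
    sc <- generate_scene(sp)
    sc$hv <- compute_hv_map(sc$instances)
    sc
  })
}

# Stack samples into training arrays (channel-first).
batch_targets <- function(samples, num_classes) {
  N <- length(samples)
  H <- nrow(samples[[1]]$instances)
  W <- ncol(samples[[1]]$instances)
  imgs <- array(0, c(3L, H, W, N))
  hv <- array(0, c(2L, H, W, N))
  prob <- array(0, c(2L, H, W, N))
  cls <- array(0, c(num_classes + 1L, H, W, N))
  fg <- array(FALSE, c(H, W, N))
  for (i in seq_len(N)) {
    s <- samples[[i]]
    imgs[, , , i] <- to_chw(s$image / 255)
    hv[, , , i] <- to_chw(s$hv)
    f <- s$instances > 0L
    fg[, , i] <- f
    prob[1, , , i] <- 1 - f
    prob[2, , , i] <- f
    for (k in 0:num_classes) cls[k + 1L, , , i] <- s$classes == k
  }
  list(
    images = imgs,
    hv = hv, prob_onehot = prob, class_onehot = cls,
    fg_mask = fg, fg_arr = array(as.numeric(fg), c(1L, H, W, N))
  )
}

# Center-crop the spatial dims of the stacked targets to `size`.
crop_targets <- function(tg, size) {
  d <- dim(tg$hv)
  if (d[2] == size && d[3] == size) return(tg)
  ih <- (d[2] - size) %/% 2L + seq_len(size)
  iw <- (d[3] - size) %/% 2L + seq_len(size)
  tg$hv <- tg$hv[, ih, iw, , drop = FALSE]
  tg$prob_onehot <- tg$prob_onehot[, ih, iw, , drop = FALSE]
  tg$class_onehot <- tg$class_onehot[, ih, iw, , drop = FALSE]
  tg$fg_mask <- tg$fg_mask[ih, iw, , drop = FALSE]
  tg$fg_arr <- tg$fg_arr[, ih, iw, , drop = FALSE]
  tg
}

adam_new <- function(params, lr = 1e-4, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st <- new.env(parent = emptyenv())
  st$params <- params
  st$m <- lapply(params, function(p) p$value * 0)
  st$v <- lapply(params, function(p) p$value * 0)
  st$t <- 0L
  st$lr <- lr
  st$beta1 <- beta1
  st$beta2 <- beta2
  st$eps <- eps
  st
}

adam_step <- function(st, lr = st$lr) {
  st$t <- st$t + 1L
  bc1 <- 1 - st$beta1^st$t
  bc2 <- 1 - st$beta2^st$t
  for (i in seq_along(st$params)) {
    p <- st$params[[i]]
    g <- p$grad
    if (is.null(g)) next
    st$m[[i]] <- st$beta1 * st$m[[i]] + (1 - st$beta1) * g
    st$v[[i]] <- st$beta2 * st$v[[i]] + (1 - st$beta2) * g^2
    p$value <- p$value - lr * (st$m[[i]] / bc1) / (sqrt(st$v[[i]] / bc2) + st$eps)
    p$grad <- NULL
  }
  invisible(NULL)
}

#' Learning rate at a given epoch of the two-stage schedule
#'
#' Each stage runs `epochs_per_stage` epochs at `lr`, halving point at
#' `drop_after` epochs after which the rate drops to `lr_after`; the
#' schedule re-warms at the start of every stage.
#'
#' @param epoch 1-based global epoch.
#' @param epochs_per_stage epochs per stage.
#' @param lr,lr_after rates before and after the in-stage drop.
#' @param drop_after epochs before the drop (default half a stage).
#' @return the learning rate in effect.
#' @export
lr_at_epoch <- function(epoch, epochs_per_stage = 50L, lr = 1e-4,
                        lr_after = lr / 10, drop_after = epochs_per_stage %/% 2L) {
  in_stage <- ((epoch - 1L) %% epochs_per_stage) + 1L
  if (in_stage <= drop_after) lr else lr_after
}

#' Train the network
#'
#' Adam optimization of the composite objective on pre-cut patches, using
#' the two-stage schedule: every stage runs the same settings (the encoder
#' is never frozen), with the learning rate dropping from `lr` to
#' `lr / 10` halfway through each stage.
#'
#' @param model a model from [aernet_model()], or a [model_config()].
#' @param data list of samples, each a list with `image`, `instances`,
#'   `classes` and optionally `hv` (see [make_synthetic_dataset()]).
#' @param stages,epochs_per_stage schedule shape (defaults 2 x 50; reduce
#'   for desk-scale runs).
#' @param batch_size mini-batch size.
#' @param lr initial learning rate.
#' @param drop_after epochs per stage before the rate drops to `lr / 10`;
#'   set to `epochs_per_stage` for a constant rate.
#' @param weights a [loss_weights()].
#' @param use_augment apply [augment()] to every sample each epoch.
#' @param seed seed for data order and augmentation.
#' @param log_file optional path; per-step loss terms are appended as
#'   JSON lines.
#' @param checkpoint optional path; the final model is saved there.
#' @param verbose print per-epoch totals.
#' @return list with `model`, `history` (data.frame of per-epoch mean loss
#'   terms and learning rate) and `checkpoint` (path or NULL).
#' @export
train_model <- function(model, data, stages = 2L, epochs_per_stage = 50L,
                        batch_size = 4L, lr = 1e-4,
                        drop_after = epochs_per_stage %/% 2L,
                        weights = loss_weights(),
                        use_augment = TRUE, seed = 1L, log_file = NULL,
                        checkpoint = NULL, verbose = FALSE) {
  if (inherits(model, "model_config")) model <- aernet_model(model)
  config <- model$config
  for (s in data) check_scene_pair(s$instances, s$classes)
  params <- collect_params(model)
  opt <- adam_new(params, lr = lr)
  n <- length(data)
  history <- list()
  total_epochs <- stages * epochs_per_stage
  with_seed_local(seed, {
    for (epoch in seq_len(total_epochs)) {
      rate <- lr_at_epoch(epoch, epochs_per_stage, lr, drop_after = drop_after)
      ord <- sample.int(n)
      logs <- list()
      for (b in seq(1L, n, by = batch_size)) {
        idx <- ord[b:min(b + batch_size - 1L, n)]
        samples <- lapply(data[idx], function(s) {
          if (!use_augment) {
            if (is.null(s$hv)) s$hv <- compute_hv_map(s$instances)
            return(s)
          }
          augment(s$image, s$instances, s$classes, s$hv)
        })
        tg <- batch_targets(samples, config$num_classes)
        step_log <- ag_record({
          out <- model_forward(model, tg$images, training = TRUE)
          out_size <- dim(ag_value(out$hv_coarse))[2]
          obj <- batch_objective(out, crop_targets(tg, out_size), weights)
          ag_backward(obj$loss)
          obj$log
        })
        adam_step(opt, rate)
        logs[[length(logs) + 1L]] <- step_log
        if (!is.null(log_file)) {
          cat(jsonlite::toJSON(as.list(c(epoch = epoch, lr = rate, step_log)),
            auto_unbox = TRUE, digits = 8
          ), "\n", file = log_file, append = TRUE, sep = "")
        }
      }
      ep <- colMeans(do.call(rbind, logs))
      rec <- c(epoch = epoch, lr = rate, ep)
      history[[epoch]] <- rec
      if (verbose) {
        message(sprintf("epoch %d/%d lr %.2g loss %.4f", epoch, total_epochs, rate, ep[["total"]]))
      }
    }
  })
  if (!is.null(checkpoint)) save_checkpoint(model, checkpoint)
  list(
    model = model,
    history = as.data.frame(do.call(rbind, history)),
    checkpoint = checkpoint
  )
}

#' Predict probability, distance and class maps for one patch
#'
#' Eval-mode forward pass of the refined branch outputs, with softmax
#' applied to the probability and classification logits.
#'
#' @param model a trained model.
#' @param image H x W x 3 array (0-255).
#' @return list with `q` (H' x W' foreground probability), `hv`
#'   (H' x W' x 2) and `class_probs` (H' x W' x (K+1)).
#' @export
predict_maps <- function(model, image) {
  out <- model_forward(model, image, training = FALSE)
  soft <- function(z) ag_no_grad(ag_value(op_softmax_ch(as_ag(z))))
  p <- soft(out$prob_refined)
  cl <- soft(out$class_refined)
  list(
    q = from_chw(p[2, , , , drop = FALSE], drop_channel = TRUE),
    hv = from_chw(out$hv_refined),
    class_probs = from_chw(cl)
  )
}

#' Run inference and post-processing on image patches
#'
#' For each image: forward pass, softmax, marker-controlled watershed and
#' per-instance majority-vote typing.
#'
#' @param model a trained model (or checkpoint path).
#' @param images list of H x W x 3 arrays, or a directory of PNG images.
#' @param cfg a [postproc_config()].
#' @param out_dir optional directory; instance maps (16-bit PNG), class
#'   maps (16-bit PNG) and per-instance JSON tables are written per image.
#' @return list per image with `instances`, `class_map`, `types`, `maps`.
#' @export
infer <- function(model, images, cfg = postproc_config(), out_dir = NULL) {
  if (is.character(model)) model <- load_checkpoint(model)
  names_out <- NULL
  if (is.character(images) && length(images) == 1L && dir.exists(images)) {
    files <- sort(list.files(images, "\\.png$", full.names = TRUE))
    names_out <- tools::file_path_sans_ext(basename(files))
    images <- lapply(files, read_image_patch)
  } else if (!is.list(images)) {
    images <- list(images)
  }
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- vector("list", length(images))
  for (i in seq_along(images)) {
    res <- tryCatch(
      {
        maps <- predict_maps(model, images[[i]])
        inst <- watershed_instances(maps$q, maps$hv, cfg)
        ty <- assign_types(inst, maps$class_probs)
        list(instances = inst, class_map = ty$class_map, types = ty$types, maps = maps)
      },
      error = function(e) {
        warning("inference failed for image ", i, ": ", conditionMessage(e))
        NULL
      }
    )
    out[[i]] <- res
    if (!is.null(out_dir) && !is.null(res)) {
      stem <- if (is.null(names_out)) sprintf("patch_%03d", i) else names_out[i]
      write_label_map(res$instances, file.path(out_dir, paste0(stem, "_inst.png")))
      write_label_map(res$class_map, file.path(out_dir, paste0(stem, "_class.png")))
      jsonlite::write_json(res$types, file.path(out_dir, paste0(stem, "_types.json")),
        dataframe = "rows"
      )
    }
  }
  out
}
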