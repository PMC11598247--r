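# Shared desk-scale fixtures. All models here are width-reduced; the
# architecture (stage structure, attention, refinement heads) is unchanged.

tiny_config <- function(...) {
  args <- list(...)
  defaults <- list(
    residual_units_per_stage = c(1L, 1L, 1L, 1L),
    base_width = 2L, growth = 2L, arrm_width = 4L,
    attention_reduction = 2L, num_classes = 3L,
    arrm_pool_stages = 2L, seed = 5L
  )
  defaults[names(args)] <- args
  do.call(model_config, defaults)
}

tiny_scene_spec <- function(seed = 3L, n = 4L, ...) {
  scene_spec(64, 64,
    n_nuclei = n, radius_range = c(5, 9),
    class_probabilities = c(0.5, 0.3, 0.2), seed = seed, ...
  )
}

# Training-mode objective value of a model on fixed samples.
objective_value <- function(model, data, w = loss_weights()) {
  tg <- aernet:::batch_targets(data, model$config$num_classes)
  aernet:::ag_record({
    out <- model_forward(model, tg$images, training = TRUE)
    o <- aernet:::batch_objective(out, tg, w)
    aernet:::ag_reset()
    o$log[["total"]]
  })
}

# A two-instance map with a straight vertical contact line.
touching_pair_map <- function(H = 64L, W = 64L) {
  m <- matrix(0L, H, W)
  yy <- matrix(seq_len(H), H, W)
  xx <- matrix(seq_len(W), H, W, byrow = TRUE)
  in1 <- ((xx - 24)^2 / 100 + (yy - 32)^2 / 144) <= 1
  in2 <- ((xx - 41)^2 / 100 + (yy - 32)^2 / 144) <= 1
  m[in1] <- 1L
  m[in2 & !in1] <- 2L
  m
}

# Random instance map: k rectangular instances dropped on a grid (later
# rectangles overwrite earlier ones, so shapes vary).
random_rect_map <- function(H, W, k, seed) {
  withr::with_seed(seed, {
    m <- matrix(0L, H, W)
    for (id in seq_len(k)) {
      h <- sample(3:9, 1)
      w <- sample(3:9, 1)
      r <- sample(seq_len(H - h), 1)
      cc <- sample(seq_len(W - w), 1)
      m[r:(r + h), cc:(cc + w)] <- id
    }
    canonicalize_instances(m)
  })
}
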