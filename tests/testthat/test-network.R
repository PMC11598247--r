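# Architecture contracts are exercised on width-reduced models; the stage
# structure, attention blocks and refinement heads match the full network.

test_that("the encoder keeps full resolution in stage 1 and halves thereafter", {
  cfg <- tiny_config()
  enc <- build_encoder(cfg)
  x <- array(rnorm(3 * 64 * 64), c(3, 64, 64, 1))
  feats <- aernet:::ag_no_grad(lapply(enc$forward(aernet:::as_ag(x)), aernet:::ag_value))
  sizes <- vapply(feats, function(f) dim(f)[2], numeric(1))
  expect_equal(sizes, c(64, 32, 16, 8))
  ch <- vapply(feats, function(f) dim(f)[1], numeric(1))
  expect_equal(ch, 4 * cfg$base_width * c(1, 2, 4, 8))
})

test_that("deeper stage configurations strictly increase the parameter count", {
  p1 <- count_params(build_encoder(tiny_config()))
  p2 <- count_params(build_encoder(tiny_config(residual_units_per_stage = c(2, 2, 2, 2))))
  expect_lt(p1, p2)
})

test_that("attention gates damp multiplicatively and can be forced to identity", {
  withr::with_seed(9, x <- array(rnorm(8 * 12 * 12), c(12, 12, 8)))
  out_id <- attention_block(x, reduction = 2, seed = 1, override_gates = 1)
  expect_equal(unclass(out_id), x, ignore_attr = "module")
  out <- attention_block(x, reduction = 2, seed = 1)
  expect_identical(dim(out), dim(x))
  expect_true(all(abs(out) <= abs(x) + 1e-12)) # gates in (0,1)
  expect_false(isTRUE(all.equal(unclass(out), x))) # non-vacuous
  # reusing the returned module is deterministic
  out2 <- attention_block(x, module = attr(out, "module"))
  expect_equal(unclass(out2), unclass(out), ignore_attr = "module")
})

test_that("decoder branches restore the input resolution and requested channels", {
  cfg <- tiny_config()
  enc <- build_encoder(cfg)
  x <- array(rnorm(3 * 64 * 64), c(3, 64, 64, 1))
  feats <- aernet:::ag_no_grad(enc$forward(aernet:::as_ag(x)))
  for (oc in c(2L, cfg$num_classes + 1L)) {
    dec <- build_decoder_branch(cfg, oc, name = paste0("dec", oc))
    y <- aernet:::ag_no_grad(aernet:::ag_value(dec$forward(feats)))
    expect_equal(dim(y), c(oc, 64, 64, 1))
  }
})

test_that("zeroed skip projections make the decoder ignore early encoder stages", {
  cfg <- tiny_config()
  dec <- build_decoder_branch(cfg, 2L, name = "probe")
  for (nm in c("skip1", "skip2", "skip3")) {
    dec$children[[nm]]$params$w$value[] <- 0
  }
  ch <- 4L * cfg$base_width * c(1L, 2L, 4L, 8L)
  sz <- c(16L, 8L, 4L, 2L)
  mk <- function(seed) {
    withr::with_seed(seed, lapply(1:4, function(l) {
      aernet:::as_ag(array(rnorm(ch[l] * sz[l]^2), c(ch[l], sz[l], sz[l], 1)))
    }))
  }
  f1 <- mk(1)
  f2 <- mk(2)
  f2[[4]] <- f1[[4]] # same deepest features, different e1..e3
  y1 <- aernet:::ag_no_grad(aernet:::ag_value(dec$forward(f1)))
  y2 <- aernet:::ag_no_grad(aernet:::ag_value(dec$forward(f2)))
  expect_equal(y1, y2)
})

test_that("the refinement head is a shape-preserving encoder-decoder", {
  cfg4 <- tiny_config(arrm_pool_stages = 4L)
  arrm <- build_arrm(cfg4, 2L)
  x <- aernet:::as_ag(array(rnorm(2 * 80 * 80), c(2, 80, 80, 1)))
  y <- aernet:::ag_no_grad(aernet:::ag_value(arrm$forward(x)))
  expect_equal(dim(y), c(2, 80, 80, 1)) # 80 -> bottleneck 5 -> 80
  cfg2 <- tiny_config(arrm_pool_stages = 2L)
  arrm2 <- build_arrm(cfg2, 2L)
  x2 <- aernet:::as_ag(array(rnorm(2 * 164 * 164), c(2, 164, 164, 1)))
  y2 <- aernet:::ag_no_grad(aernet:::ag_value(arrm2$forward(x2)))
  expect_equal(dim(y2), c(2, 164, 164, 1)) # 164 -> bottleneck 41 -> 164
  # 164 is not divisible by 16: the 4-stage head must refuse it
  expect_error(
    aernet:::ag_no_grad(arrm$forward(x2)),
    "not divisible"
  )
  # zero input preserves spatial shape
  z <- aernet:::ag_no_grad(aernet:::ag_value(arrm$forward(
    aernet:::as_ag(array(0, c(2, 80, 80, 1)))
  )))
  expect_equal(dim(z), c(2, 80, 80, 1))
})

test_that("forward reproduces the published input/output geometries", {
  withr::with_seed(1, img270 <- array(runif(270 * 270 * 3) * 255, c(270, 270, 3)))
  out <- model_forward(
    aernet_model(tiny_config(padding_mode = "valid", arrm_pool_stages = 4L)),
    img270
  )
  expect_equal(dim(out$prob_refined), c(2, 80, 80, 1))
  withr::with_seed(2, img256 <- array(runif(256 * 256 * 3) * 255, c(256, 256, 3)))
  out2 <- model_forward(aernet_model(tiny_config(num_classes = 4L)), img256)
  expect_equal(dim(out2$class_refined), c(5, 256, 256, 1))
  out3 <- model_forward(
    aernet_model(tiny_config(output_size = 164L, arrm_pool_stages = 2L)),
    img256
  )
  expect_equal(dim(out3$hv_refined), c(2, 164, 164, 1))
  expect_error(
    model_forward(aernet_model(tiny_config()), array(0, c(100, 100, 3))),
    "divisible by 8"
  )
})

test_that("shape contracts hold for batches and eval mode is deterministic", {
  model <- aernet_model(tiny_config())
  batch <- withr::with_seed(3, lapply(1:4, function(i) {
    array(runif(64 * 64 * 3) * 255, c(64, 64, 3))
  }))
  o4 <- model_forward(model, batch)
  expect_equal(dim(o4$prob_coarse), c(2, 64, 64, 4))
  o1 <- model_forward(model, batch[[1]])
  expect_equal(dim(o1$prob_coarse), c(2, 64, 64, 1))
  expect_identical(o4$hv_refined, model_forward(model, batch)$hv_refined)
  # batch consistency: sample 1 of the batch equals the single forward
  expect_equal(o4$prob_coarse[, , , 1], o1$prob_coarse[, , , 1], tolerance = 1e-12)
})

test_that("disabling refinement heads is strictly additive machinery", {
  cfg <- tiny_config()
  cfg_off <- tiny_config(use_arrm = FALSE)
  m_on <- aernet_model(cfg)
  m_off <- aernet_model(cfg_off)
  expect_lt(count_params(m_off), count_params(m_on))
  img <- withr::with_seed(4, array(runif(64 * 64 * 3) * 255, c(64, 64, 3)))
  o_on <- model_forward(m_on, img)
  o_off <- model_forward(m_off, img)
  expect_identical(o_on$prob_coarse, o_off$prob_coarse)
  expect_identical(o_off$prob_refined, o_off$prob_coarse)
  expect_false(identical(o_on$prob_refined, o_on$prob_coarse))
})

test_that("attention changes the output at identical shared weights", {
  img <- withr::with_seed(5, array(runif(64 * 64 * 3) * 255, c(64, 64, 3)))
  o_att <- model_forward(aernet_model(tiny_config()), img)
  o_no <- model_forward(aernet_model(tiny_config(use_attention = FALSE)), img)
  expect_false(isTRUE(all.equal(o_att$prob_coarse, o_no$prob_coarse)))
})

test_that("autodiff gradients match finite differences through the full model", {
  cfg <- tiny_config()
  model <- aernet_model(cfg)
  data <- make_synthetic_dataset(1, tiny_scene_spec(), seed = 9)
  w <- loss_weights()
  tg <- aernet:::batch_targets(data, cfg$num_classes)
  lossfun <- function() {
    out <- model_forward(model, tg$images, training = TRUE)
    aernet:::batch_objective(out, tg, w)
  }
  obj <- aernet:::ag_record({
    o <- lossfun()
    aernet:::ag_backward(o$loss)
    o
  })
  params <- aernet:::collect_params(model)
  grads <- lapply(params, function(p) p$grad)
  picks <- c(
    grep("np.dense3.d1.bn1.gamma", names(params))[1],
    grep("arrm_hv.enc1.cbr.conv.w", names(params))[1],
    grep("tp.head.w", names(params))[1]
  )
  eps <- 1e-5
  for (pi in picks) {
    p <- params[[pi]]
    j <- 1L
    old <- p$value[j]
    p$value[j] <- old + eps
    f1 <- aernet:::ag_record({
      v <- lossfun()$log[["total"]]
      aernet:::ag_reset()
      v
    })
    p$value[j] <- old - eps
    f2 <- aernet:::ag_record({
      v <- lossfun()$log[["total"]]
      aernet:::ag_reset()
      v
    })
    p$value[j] <- old
    fd <- (f1 - f2) / (2 * eps)
    expect_equal(grads[[pi]][j], fd, tolerance = 1e-3)
  }
})
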