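# Network building blocks. A module is an environment holding parameter
# nodes, child modules, mutable state (batch-norm running moments) and a
# $forward closure. Weight initialization is He-normal, seeded per module
# path so that adding or removing sibling modules (e.g. disabling the
# refinement heads) never shifts the initialization of the others.

new_module <- function(kind) {
  m <- new.env(parent = emptyenv())
  m$kind <- kind
  m$params <- list()
  m$children <- list()
  class(m) <- "ag_module"
  m
}

# Deterministic 31-bit seed from a base seed and a module path string.
derive_seed <- function(seed, path) {
  h <- as.double(seed %% 2147483647L)
  for (ch in utf8ToInt(path)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

with_seed_local <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

he_init <- function(n_out_rows, n_cols, fan_in, seed) {
  with_seed_local(seed, matrix(stats::rnorm(n_out_rows * n_cols, sd = sqrt(2 / fan_in)),
    n_out_rows, n_cols
  ))
}

collect_params <- function(m, out = list(), prefix = m$kind) {
  for (nm in names(m$params)) out[[paste(prefix, nm, sep = ".")]] <- m$params[[nm]]
  for (nm in names(m$children)) {
    out <- collect_params(m$children[[nm]], out, paste(prefix, nm, sep = "."))
  }
  out
}

#' Number of trainable parameters in a module or model
#'
#' @param m a module (e.g. from [aernet_model()] or [build_encoder()]).
#' @return total parameter count.
#' @export
count_params <- function(m) {
  sum(vapply(collect_params(m), function(p) length(p$value), numeric(1)))
}

# ---- primitive modules ---------------------------------------------------

mod_conv <- function(cin, cout, k, stride = 1L, bias = TRUE, seed, path) {
  m <- new_module("conv")
  fan_in <- cin * k * k
  m$params$w <- ag_param(he_init(fan_in, cout, fan_in, derive_seed(seed, path)))
  if (bias) m$params$b <- ag_param(numeric(cout))
  m$k <- as.integer(k)
  m$stride <- as.integer(stride)
  m$forward <- function(x) {
    op_conv2d(x, m$params$w, m$params$b, k = m$k, stride = m$stride)
  }
  m
}

mod_bn <- function(c) {
  m <- new_module("bn")
  m$params$gamma <- ag_param(rep(1, c))
  m$params$beta <- ag_param(numeric(c))
  m$state <- new.env(parent = emptyenv())
  m$state$running_mean <- numeric(c)
  m$state$running_var <- rep(1, c)
  m$forward <- function(x, relu = FALSE) {
    op_bn(x, m$params$gamma, m$params$beta, m$state, relu = relu)
  }
  m
}

# conv -> BN -> ReLU
mod_cbr <- function(cin, cout, k, stride = 1L, seed, path) {
  m <- new_module("cbr")
  m$children$conv <- mod_conv(cin, cout, k, stride, bias = FALSE, seed, paste0(path, "/conv"))
  m$children$bn <- mod_bn(cout)
  m$forward <- function(x) {
    m$children$bn$forward(m$children$conv$forward(x), relu = TRUE)
  }
  m
}

# Squeeze-and-excite style channel attention: shared two-layer bottleneck on
# global average and max pooled descriptors, sigmoid gate per channel.
mod_channel_att <- function(c, reduction, seed, path) {
  m <- new_module("channel_att")
  hidden <- max(1L, c %/% reduction)
  m$params$w1 <- ag_param(he_init(hidden, c, c, derive_seed(seed, paste0(path, "/w1"))))
  m$params$b1 <- ag_param(numeric(hidden))
  m$params$w2 <- ag_param(he_init(c, hidden, hidden, derive_seed(seed, paste0(path, "/w2"))))
  m$params$b2 <- ag_param(numeric(c))
  m$gate <- function(x) {
    mlp <- function(v) {
      op_linear(op_relu(op_linear(v, m$params$w1, m$params$b1)), m$params$w2, m$params$b2)
    }
    op_sigmoid(op_add(mlp(op_gap(x)), mlp(op_gmp(x))))
  }
  m$forward <- function(x, override_gates = NULL) {
    if (!is.null(override_gates)) {
      d <- dims4(ag_value(x))
      return(op_mul_channel_gate(x, as_ag(matrix(override_gates, d[1], d[4]))))
    }
    op_mul_channel_gate(x, m$gate(x))
  }
  m
}

# Spatial attention: 7x7 convolution over channel-pooled mean/max maps.
mod_spatial_att <- function(seed, path, k = 7L) {
  m <- new_module("spatial_att")
  m$children$conv <- mod_conv(2L, 1L, k, bias = TRUE, seed = seed, path = paste0(path, "/conv"))
  m$gate <- function(x) {
    xv <- ag_value(x)
    d <- dims4(xv)
    C <- d[1]
    xm <- matrix(xv, C)
    mean_map <- colMeans(xm)
    max_map <- do.call(pmax, asplit(xm, 1))
    pooled_v <- array(rbind(mean_map, max_map), c(2L, d[2], d[3], d[4]))
    pooled <- ag_node(pooled_v, backward = function(node) {
      g <- node$grad
      dim(g) <- c(2L, d[2] * d[3] * d[4])
      dmean <- g[1, ] / C
      amax <- max.col(t(xm), ties.method = "first")
      dx <- matrix(rep(dmean, each = C), C)
      dx[cbind(amax, seq_along(amax))] <- dx[cbind(amax, seq_along(amax))] + g[2, ]
      dim(dx) <- d
      ag_accum(x, dx)
    })
    op_sigmoid(m$children$conv$forward(pooled))
  }
  m$forward <- function(x, override_gates = NULL) {
    if (!is.null(override_gates)) {
      d <- dims4(ag_value(x))
      g <- array(override_gates, c(1L, d[2], d[3], d[4]))
      return(op_mul_spatial_gate(x, as_ag(g)))
    }
    op_mul_spatial_gate(x, m$gate(x))
  }
  m
}

# Channel then spatial attention (CBAM ordering).
mod_attention <- function(c, reduction, seed, path) {
  m <- new_module("attention")
  m$children$ca <- mod_channel_att(c, reduction, seed, paste0(path, "/ca"))
  m$children$sa <- mod_spatial_att(seed, paste0(path, "/sa"))
  m$forward <- function(x, override_gates = NULL) {
    m$children$sa$forward(m$children$ca$forward(x, override_gates), override_gates)
  }
  m
}

# Bottleneck residual unit (1x1 -> 3x3 -> 1x1 with 4x expansion).
mod_bottleneck <- function(cin, width, cout, stride, seed, path) {
  m <- new_module("bottleneck")
  m$children$c1 <- mod_cbr(cin, width, 1L, 1L, seed, paste0(path, "/c1"))
  m$children$c2 <- mod_cbr(width, width, 3L, stride, seed, paste0(path, "/c2"))
  m$children$c3 <- mod_conv(width, cout, 1L, 1L, bias = FALSE, seed, paste0(path, "/c3"))
  m$children$bn3 <- mod_bn(cout)
  if (cin != cout || stride != 1L) {
    m$children$proj <- mod_conv(cin, cout, 1L, stride, bias = FALSE, seed, paste0(path, "/proj"))
    m$children$bnp <- mod_bn(cout)
  }
  m$forward <- function(x) {
    y <- m$children$bn3$forward(
      m$children$c3$forward(m$children$c2$forward(m$children$c1$forward(x)))
    )
    sc <- if (!is.null(m$children$proj)) {
      m$children$bnp$forward(m$children$proj$forward(x))
    } else {
      x
    }
    op_relu(op_add(y, sc))
  }
  m
}

# One encoder stage: n residual units then channel+spatial attention.
mod_csar_stage <- function(cin, width, cout, n_units, stride, reduction,
                           use_attention, seed, path) {
  m <- new_module("csar")
  for (i in seq_len(n_units)) {
    m$children[[paste0("u", i)]] <- mod_bottleneck(
      if (i == 1L) cin else cout, width, cout,
      if (i == 1L) stride else 1L, seed, paste0(path, "/u", i)
    )
  }
  if (use_attention) {
    m$children$att <- mod_attention(cout, reduction, seed, paste0(path, "/att"))
  }
  m$n_units <- n_units
  m$forward <- function(x, override_gates = NULL) {
    for (i in seq_len(m$n_units)) x <- m$children[[paste0("u", i)]]$forward(x)
    if (!is.null(m$children$att)) x <- m$children$att$forward(x, override_gates)
    x
  }
  m
}

# Dense unit: BN-ReLU-1x1(4g) -> BN-ReLU-3x3(g), concatenated onto the input.
mod_dense_unit <- function(cin, growth, seed, path) {
  m <- new_module("dense_unit")
  m$children$bn1 <- mod_bn(cin)
  m$children$c1 <- mod_conv(cin, 4L * growth, 1L, bias = FALSE, seed = seed, path = paste0(path, "/c1"))
  m$children$bn2 <- mod_bn(4L * growth)
  m$children$c2 <- mod_conv(4L * growth, growth, 3L, bias = FALSE, seed = seed, path = paste0(path, "/c2"))
  m$forward <- function(x) {
    y <- m$children$c1$forward(m$children$bn1$forward(x, relu = TRUE))
    y <- m$children$c2$forward(m$children$bn2$forward(y, relu = TRUE))
    op_concat_ch(list(x, y))
  }
  m
}

mod_dense_block <- function(cin, n_units, growth, seed, path) {
  m <- new_module("dense_block")
  c <- cin
  for (i in seq_len(n_units)) {
    m$children[[paste0("d", i)]] <- mod_dense_unit(c, growth, seed, paste0(path, "/d", i))
    c <- c + growth
  }
  m$cout <- c
  m$n_units <- n_units
  m$forward <- function(x) {
    for (i in seq_len(m$n_units)) x <- m$children[[paste0("d", i)]]$forward(x)
    x
  }
  m
}

# Channel-attention convolution unit of the refinement head:
# 3x3 conv -> BN -> ReLU -> channel attention.
mod_cac <- function(cin, cout, reduction, seed, path) {
  m <- new_module("cac")
  m$children$cbr <- mod_cbr(cin, cout, 3L, 1L, seed, paste0(path, "/cbr"))
  m$children$ca <- mod_channel_att(cout, reduction, seed, paste0(path, "/ca"))
  m$forward <- function(x) m$children$ca$forward(m$children$cbr$forward(x))
  m
}
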