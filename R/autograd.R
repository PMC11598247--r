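# Minimal tape-based reverse-mode autodiff over numeric arrays.
#
# Activations use a channel-first layout, dim = (C, H, W, N), so per-channel
# broadcasts are plain vector recycling (C is the fastest-varying dimension)
# and convolutions lower to one BLAS gemm via im2col (src/kernels.cpp).

.ag <- new.env(parent = emptyenv())
.ag$recording <- FALSE
.ag$training <- FALSE
.ag$tape <- list()
.ag$ntape <- 0L

ag_reset <- function() {
  .ag$tape <- vector("list", 256L)
  .ag$ntape <- 0L
  invisible(NULL)
}

# Evaluate `expr` while recording a tape; returns its result.
ag_record <- function(expr) {
  old_rec <- .ag$recording
  .ag$recording <- TRUE
  ag_reset()
  on.exit({
    .ag$recording <- old_rec
  })
  expr
}

ag_no_grad <- function(expr) {
  old <- .ag$recording
  .ag$recording <- FALSE
  on.exit(.ag$recording <- old)
  expr
}

ag_set_training <- function(on) {
  .ag$training <- isTRUE(on)
  invisible(NULL)
}

# A node holds a value, an accumulated gradient, and a backward closure that
# pushes gradient into its parents. Parameters are nodes with is_param = TRUE;
# they live off-tape but receive gradients through parent links.
ag_node <- function(value, backward = NULL, record = .ag$recording) {
  n <- new.env(parent = emptyenv())
  n$value <- value
  n$grad <- NULL
  n$backward <- if (record) backward else NULL
  n$is_param <- FALSE
  class(n) <- "ag_node"
  if (record && !is.null(backward)) {
    i <- .ag$ntape + 1L
    if (i > length(.ag$tape)) .ag$tape <- c(.ag$tape, vector("list", length(.ag$tape)))
    .ag$tape[[i]] <- n
    .ag$ntape <- i
  }
  n
}

ag_param <- function(value) {
  n <- ag_node(value, record = FALSE)
  n$is_param <- TRUE
  n
}

is_ag <- function(x) inherits(x, "ag_node")

as_ag <- function(x) if (is_ag(x)) x else ag_node(x, record = FALSE)

ag_value <- function(x) if (is_ag(x)) x$value else x

ag_accum <- function(node, g) {
  if (is.null(node$backward) && !node$is_param) return(invisible(NULL))
  if (is.null(node$grad)) node$grad <- g else node$grad <- node$grad + g
  invisible(NULL)
}

# Reverse sweep over the tape. `loss` must be a scalar node from the current
# recording. Gradients accumulate in $grad of every reachable node.
ag_backward <- function(loss) {
  stopifnot(is_ag(loss), length(loss$value) == 1L)
  loss$grad <- 1
  if (!is.null(loss$backward)) loss$backward(loss)
  n <- .ag$ntape
  if (n >= 1L) {
    for (i in seq.int(n, 1L)) {
      nd <- .ag$tape[[i]]
      if (identical(nd, loss)) next
      if (!is.null(nd$grad) && !is.null(nd$backward)) nd$backward(nd)
      .ag$tape[i] <- list(NULL) # release activations as we go
    }
  }
  ag_reset()
  invisible(NULL)
}
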