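# Reverse-mode tape, parameter store and Adam.
#
# The engine is deliberately small: values flowing through the network are
# plain R arrays of dim (H, W, C, N); a "node" is list(v = value, id = tape
# position).  Ops compute eagerly and, when a tape is supplied, append a
# backward closure.  Parameters live in an environment keyed by dotted layer
# names; their gradients are accumulated into tape$pgrads during backward().

new_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 512L)
  tp$n <- 0L
  tp$pgrads <- new.env(parent = emptyenv())
  tp$igrads <- new.env(parent = emptyenv())
  tp
}

# Input node whose gradient is captured in tape$igrads under `key`
# (used by gradient-checking tests and loss-to-input diagnostics).
op_input_tracked <- function(tape, v, key) {
  tp_node(tape, v, parents = integer(0), backward = function(g) {
    old <- tape$igrads[[key]]
    tape$igrads[[key]] <- if (is.null(old)) g else old + g
    list()
  })
}

tp_node <- function(tape, val, parents = integer(0), backward = NULL) {
  if (is.null(tape)) return(list(v = val, id = NA_integer_))
  tape$n <- tape$n + 1L
  if (tape$n > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  tape$nodes[[tape$n]] <- list(parents = parents, backward = backward)
  list(v = val, id = tape$n)
}

acc_pgrad <- function(tape, name, g) {
  old <- tape$pgrads[[name]]
  tape$pgrads[[name]] <- if (is.null(old)) g else old + g
}

# Reverse sweep from the node with id `root`; the seed gradient defaults to 1
# (scalar loss).  Parameter gradients end up in tape$pgrads.
tape_backward <- function(tape, root, seed = 1) {
  grads <- vector("list", tape$n)
  grads[[root]] <- seed
  for (id in seq(root, 1L)) {
    g <- grads[[id]]
    if (is.null(g)) next
    node <- tape$nodes[[id]]
    if (is.null(node$backward)) next
    pg <- node$backward(g)
    ps <- node$parents
    for (j in seq_along(ps)) {
      p <- ps[[j]]
      if (is.na(p) || p <= 0L) next
      gj <- pg[[j]]
      if (is.null(gj)) next
      grads[[p]] <- if (is.null(grads[[p]])) gj else grads[[p]] + gj
    }
    grads[id] <- list(NULL)  # free activation gradients as we go
  }
  invisible(NULL)
}

# --- parameter store -------------------------------------------------------

new_store <- function() {
  st <- new.env(parent = emptyenv())
  st$params <- new.env(parent = emptyenv())
  st$state <- new.env(parent = emptyenv())   # batch-norm running statistics
  st$order <- character(0)
  st
}

add_param <- function(store, name, value) {
  store$params[[name]] <- value
  store$order <- c(store$order, name)
  invisible(name)
}

#' @keywords internal
store_param_names <- function(store) store$order

# He-normal initialisation for a convolution / fully connected weight.
init_he <- function(dims, fan_in) {
  array(stats::rnorm(prod(dims), sd = sqrt(2 / fan_in)), dim = dims)
}

# Run `expr` under a fixed RNG seed without disturbing the caller's stream.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# --- Adam ------------------------------------------------------------------

new_adam <- function(lr = 1e-5, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt <- new.env(parent = emptyenv())
  opt$lr <- lr; opt$beta1 <- beta1; opt$beta2 <- beta2; opt$eps <- eps
  opt$m <- new.env(parent = emptyenv())
  opt$v <- new.env(parent = emptyenv())
  opt$t <- 0L
  opt
}

adam_step <- function(opt, store, pgrads) {
  opt$t <- opt$t + 1L
  b1 <- opt$beta1; b2 <- opt$beta2
  corr1 <- 1 - b1^opt$t
  corr2 <- 1 - b2^opt$t
  for (name in ls(pgrads)) {
    g <- pgrads[[name]]
    m <- opt$m[[name]]
    v <- opt$v[[name]]
    if (is.null(m)) { m <- g * 0; v <- g * 0 }
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g * g
    opt$m[[name]] <- m
    opt$v[[name]] <- v
    step <- opt$lr * (m / corr1) / (sqrt(v / corr2) + opt$eps)
    store$params[[name]] <- store$params[[name]] - step
  }
  invisible(NULL)
}

# --- small shared validators ----------------------------------------------

# Coerce a user-supplied image/feature map to the internal (H, W, C, N) form.
as_feature_map <- function(x, name = "x") {
  if (is.matrix(x)) {
    dim(x) <- c(dim(x), 1L, 1L)
  } else if (is.array(x) && length(dim(x)) == 3L) {
    dim(x) <- c(dim(x), 1L)
  }
  if (!is.array(x) || length(dim(x)) != 4L) {
    stop(sprintf("`%s` must be an (H, W, C) or (H, W, C, N) array", name))
  }
  if (!all(is.finite(x))) {
    stop(sprintf("`%s` contains non-finite values", name))
  }
  x
}

check_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.finite(x) || x < min || x != round(x)) {
    stop(sprintf("`%s` must be an integer >= %d", name, min))
  }
  as.integer(x)
}
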