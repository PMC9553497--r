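# Kernel Selecting Module: three parallel convolutions (3x3, 5x5, 7x7) fused
# by per-channel softmax attention so the effective receptive field adapts
# per channel.  U' , U'', U''' are summed to U-bar; global average pooling
# and a shared bottleneck FC (batch norm + ReLU, selective-kernel
# convention) feed three branch-specific FC maps whose logits are softmaxed
# across branches; the output V is the per-channel convex combination of the
# three branch maps, so it always lies between their elementwise min and max.

ksm_bottleneck_width <- function(C, reduction, min_width) {
  max(as.integer(ceiling(C / reduction)), as.integer(min_width))
}

mk_ksm <- function(store, prefix, C, reduction = 8L, min_width = 32L) {
  for (k in c(3L, 5L, 7L)) {
    mk_conv(store, sprintf("%s.k%d", prefix, k), k, C, C, bias = TRUE)
  }
  d <- ksm_bottleneck_width(C, reduction, min_width)
  mk_fc(store, paste0(prefix, ".fc1"), C, d, bias = FALSE)
  mk_bn1d(store, paste0(prefix, ".bn1"), d)
  for (br in c("a", "b", "c")) {
    mk_fc(store, paste0(prefix, ".fc2", br), d, C)
  }
}

fwd_ksm_branches <- function(tape, x, store, prefix) {
  lapply(c(3L, 5L, 7L), function(k) {
    op_conv(tape, x, store, sprintf("%s.k%d", prefix, k))
  })
}

fwd_ksm_logits <- function(tape, ubar, store, prefix, training) {
  z <- op_gap(tape, ubar)
  z <- op_fc(tape, z, store, paste0(prefix, ".fc1"))
  z <- op_relu(tape, op_bn1d(tape, z, store, paste0(prefix, ".bn1"),
                             training))
  lapply(c("a", "b", "c"), function(br) {
    op_fc(tape, z, store, paste0(prefix, ".fc2", br))
  })
}

fwd_ksm <- function(tape, x, store, prefix, training) {
  us <- fwd_ksm_branches(tape, x, store, prefix)
  ubar <- op_add3(tape, us[[1]], us[[2]], us[[3]])
  lg <- fwd_ksm_logits(tape, ubar, store, prefix, training)
  op_ksm_fuse(tape, us[[1]], us[[2]], us[[3]], lg[[1]], lg[[2]], lg[[3]])
}

# --- exported surfaces -----------------------------------------------------

#' KSM branch convolutions
#'
#' The three parallel same-padding convolutions of the kernel-selecting
#' module, with kernel sizes 3, 5 and 7, each mapping C channels to C
#' channels.
#'
#' @param U An (H, W, C) or (H, W, C, N) numeric array.
#' @param params Optional overrides; names are \code{ksm.k3.W},
#'   \code{ksm.k3.b}, \code{ksm.k5.W}, \code{ksm.k5.b}, \code{ksm.k7.W},
#'   \code{ksm.k7.b}.
#' @param seed Seed for the random initialisation.
#' @return A list of three arrays, each with the shape of \code{U}.
#' @export
ksm_branches <- function(U, params = NULL, seed = 1L) {
  U <- as_feature_map(U, "U")
  C <- dim(U)[3]
  store <- standalone_store(function(s) mk_ksm(s, "ksm", C), seed, params)
  lapply(fwd_ksm_branches(NULL, op_input(NULL, U), store, "ksm"), `[[`, "v")
}

#' KSM attention vectors
#'
#' Computes the per-channel soft attention of the kernel-selecting module
#' from the summed branch map U-bar = U' + U'' + U''': global average
#' pooling, a shared bottleneck FC of width \code{max(ceiling(C /
#' reduction), min_width)} followed by batch norm and ReLU, three
#' branch-specific FC maps giving raw logits, and a softmax across the three
#' branches for every channel, so \code{alpha + beta + gamma = 1}
#' channelwise.
#'
#' @param U_bar An (H, W, C) or (H, W, C, N) array (the summed branches).
#' @param reduction Bottleneck reduction ratio (default 8).
#' @param min_width Minimum bottleneck width (default 32).
#' @param params Optional overrides; names are \code{ksm.fc1.W},
#'   \code{ksm.bn1.gamma/.beta}, \code{ksm.fc2a.W}, \code{ksm.fc2a.b} (and
#'   \code{b}, \code{c} variants).
#' @param seed Seed for the random initialisation.
#' @return A list with (C, N) matrices \code{alpha}, \code{beta},
#'   \code{gamma} (post-softmax, strictly in (0, 1)) and \code{alpha_raw},
#'   \code{beta_raw}, \code{gamma_raw} (logits).
#' @export
ksm_attention <- function(U_bar, reduction = 8L, min_width = 32L,
                          params = NULL, seed = 1L) {
  U_bar <- as_feature_map(U_bar, "U_bar")
  C <- dim(U_bar)[3]
  store <- standalone_store(function(s) {
    mk_ksm(s, "ksm", C, reduction, min_width)
  }, seed, params)
  lg <- fwd_ksm_logits(NULL, op_input(NULL, U_bar), store, "ksm",
                       training = FALSE)
  att <- ksm_softmax3(lg[[1]]$v, lg[[2]]$v, lg[[3]]$v)
  c(att, list(alpha_raw = lg[[1]]$v, beta_raw = lg[[2]]$v,
              gamma_raw = lg[[3]]$v))
}

#' Fuse KSM branches with given attention
#'
#' Applies V_c = alpha_c U'_c + beta_c U''_c + gamma_c U'''_c per channel,
#' broadcasting the attention over spatial positions.
#'
#' @param branches List of three equally shaped (H, W, C, N) arrays.
#' @param attention List with elements \code{alpha}, \code{beta},
#'   \code{gamma}: length-C vectors or (C, N) matrices.
#' @return An array shaped like the branches.
#' @export
ksm_fuse <- function(branches, attention) {
  stopifnot(length(branches) == 3)
  branches <- lapply(branches, as_feature_map, name = "branches")
  d <- dim(branches[[1]])
  HW <- d[1] * d[2]
  att <- lapply(attention[c("alpha", "beta", "gamma")], function(a) {
    if (is.null(dim(a))) a <- matrix(a, d[3], d[4])
    a
  })
  y <- branches[[1]] * bc_cn(att[[1]], HW) +
    branches[[2]] * bc_cn(att[[2]], HW) +
    branches[[3]] * bc_cn(att[[3]], HW)
  dim(y) <- d
  y
}

#' Kernel-selecting module forward pass
#'
#' The full module: branch convolutions, summed attention pathway, and the
#' softmax-weighted fusion.  The result carries the attention triplet as
#' attribute \code{"attention"}.
#'
#' @inheritParams ksm_branches
#' @inheritParams ksm_attention
#' @return An array shaped like \code{U} with attribute \code{"attention"}.
#' @export
ksm_forward <- function(U, reduction = 8L, min_width = 32L, params = NULL,
                        seed = 1L) {
  U <- as_feature_map(U, "U")
  C <- dim(U)[3]
  store <- standalone_store(function(s) {
    mk_ksm(s, "ksm", C, reduction, min_width)
  }, seed, params)
  us <- fwd_ksm_branches(NULL, op_input(NULL, U), store, "ksm")
  ubar <- op_add3(NULL, us[[1]], us[[2]], us[[3]])
  lg <- fwd_ksm_logits(NULL, ubar, store, "ksm", training = FALSE)
  att <- ksm_softmax3(lg[[1]]$v, lg[[2]]$v, lg[[3]]$v)
  V <- ksm_fuse(lapply(us, `[[`, "v"), att)
  attr(V, "attention") <- att
  V
}
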