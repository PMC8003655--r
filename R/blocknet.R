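#' Network architecture configuration
#'
#' Describes the block-named 3D encoder-decoder segmentation network.  The
#' network has `depth` down blocks and `depth` up blocks.  Every block holds
#' `convs_per_block` 3x3x3 convolutions (shape-preserving, ReLU) and one
#' dropout layer; where input and output channel counts agree the block's
#' inner convolutions are wrapped by a residual element-wise sum, which is
#' also the delimiter between blocks.  The down path halves resolution
#' between blocks (strided entry convolution, doubling channels); the up
#' path doubles resolution (kernel-2 stride-2 transposed convolution) and
#' merges the mirrored down-block output through the skip connection.  The
#' final up block ends in a pointwise sigmoid head producing a one-channel
#' voxelwise tumor-probability map.
#'
#' @param depth number of down blocks (= up blocks), >= 2.
#' @param base_channels channels of the first down block, >= 2; doubled at
#'   each deeper level.
#' @param in_channels input channels (default 4: T1, T2, FLAIR, GdT1).
#' @param convs_per_block convolutions per block (default 3).
#' @param dropout_rate dropout probability in [0, 1), default 0.2.
#' @param skip_mode `"concatenate"` (default) or `"sum"`.
#' @param target_shape input spatial shape; every dimension must be
#'   divisible by `2^(depth - 1)`.
#' @param init_seed seed for parameter initialization.
#' @return An object of class `net_config`.
#' @export
net_config <- function(depth = 5L, base_channels = 16L, in_channels = 4L,
                       convs_per_block = 3L, dropout_rate = 0.2,
                       skip_mode = c("concatenate", "sum"),
                       target_shape = c(176L, 192L, 160L), init_seed = 42L) {
  skip_mode <- match.arg(skip_mode)
  depth <- as.integer(depth)
  target_shape <- as.integer(target_shape)
  if (depth < 2L) stop("depth must be >= 2")
  if (base_channels < 2L) stop("base_channels must be >= 2")
  if (dropout_rate < 0 || dropout_rate >= 1) stop("dropout_rate must be in [0, 1)")
  div <- 2L^(depth - 1L)
  for (a in 1:3)
    if (target_shape[a] %% div != 0L)
      stop(sprintf("target_shape dimension %d (%d) is not divisible by 2^(depth-1) = %d",
                   a, target_shape[a], div))
  structure(list(depth = depth, base_channels = as.integer(base_channels),
                 in_channels = as.integer(in_channels),
                 convs_per_block = as.integer(convs_per_block),
                 dropout_rate = dropout_rate, skip_mode = skip_mode,
                 target_shape = target_shape, init_seed = as.integer(init_seed)),
            class = "net_config")
}

.ordinal <- function(i) {
  suff <- if (i %% 100 %in% 11:13) "th"
          else switch(as.character(i %% 10), "1" = "st", "2" = "nd", "3" = "rd", "th")
  paste0(i, suff)
}

#' Block names for a given depth
#'
#' Down blocks are numbered from the shallowest to the deepest ("1st down"
#' ... ), up blocks from the deepest to the shallowest ("1st up" is the
#' deepest up block).
#'
#' @param depth network depth.
#' @return Character vector of 2*depth block names.
#' @export
block_names <- function(depth) {
  c(paste(vapply(1:depth, .ordinal, ""), "down"),
    paste(vapply(1:depth, .ordinal, ""), "up"))
}

.he_init <- function(dims, fan_in) array(rnorm(prod(dims), 0, sqrt(2 / fan_in)), dims)

# channel width of level i
.chan <- function(cfg, i) cfg$base_channels * 2L^(i - 1L)

#' Build the segmentation network and its block registry
#'
#' Initializes all parameters (He-style, seeded by `config$init_seed`) and
#' constructs the registry mapping every learnable parameter to exactly one
#' named block.  Downsampling entry convolutions belong to the down block
#' they feed; transposed up-convolutions and the final head belong to their
#' up block.
#'
#' @param config a [net_config()].
#' @return An object of class `blocknet`: list with `params` (named list of
#'   arrays), `config`, and `registry` (block name -> parameter names).
#' @export
build_network <- function(config) {
  stopifnot(inherits(config, "net_config"))
  d <- config$depth; ncv <- config$convs_per_block
  params <- list()
  add_conv3 <- function(name, cin, cout) {
    params[[paste0(name, ".w")]] <<- .he_init(c(3, 3, 3, cin, cout), 27 * cin)
    params[[paste0(name, ".b")]] <<- numeric(cout)
  }
  with_seed(config$init_seed, {
    for (i in 1:d) {
      cin <- if (i == 1L) config$in_channels else .chan(config, i - 1L)
      add_conv3(sprintf("down%d.conv0", i), cin, .chan(config, i))
      if (ncv > 1L) for (j in 1:(ncv - 1L))
        add_conv3(sprintf("down%d.conv%d", i, j), .chan(config, i), .chan(config, i))
    }
    for (j in 1:d) {
      lev <- d - j + 1L  # resolution level of this up block
      if (j > 1L) {
        cin_up <- .chan(config, lev + 1L)
        params[[sprintf("up%d.upconv.w", j)]] <-
          .he_init(c(2, 2, 2, cin_up, .chan(config, lev)), cin_up)
        params[[sprintf("up%d.upconv.b", j)]] <- numeric(.chan(config, lev))
        cin_entry <- if (config$skip_mode == "concatenate")
          2L * .chan(config, lev) else .chan(config, lev)
      } else cin_entry <- .chan(config, lev)
      add_conv3(sprintf("up%d.conv0", j), cin_entry, .chan(config, lev))
      if (ncv > 1L) for (m in 1:(ncv - 1L))
        add_conv3(sprintf("up%d.conv%d", j, m), .chan(config, lev), .chan(config, lev))
    }
    params[[sprintf("up%d.head.w", d)]] <-
      array(rnorm(config$base_channels, 0, sqrt(1 / config$base_channels)),
            c(config$base_channels, 1L))
    # negative head bias starts predictions near background, matching the
    # small tumor fraction
    params[[sprintf("up%d.head.b", d)]] <- -2
  })
  nm <- names(params)
  registry <- c(
    stats::setNames(lapply(1:d, function(i) nm[startsWith(nm, sprintf("down%d.", i))]),
                    paste(vapply(1:d, .ordinal, ""), "down")),
    stats::setNames(lapply(1:d, function(j) nm[startsWith(nm, sprintf("up%d.", j))]),
                    paste(vapply(1:d, .ordinal, ""), "up")))
  structure(list(params = params, config = config, registry = registry),
            class = "blocknet")
}

#' @export
print.blocknet <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<blocknet> depth %d, base %d ch, %d convs/block, skip %s\n",
              cfg$depth, cfg$base_channels, cfg$convs_per_block, cfg$skip_mode))
  print(block_param_counts(x))
  invisible(x)
}

#' Per-block learnable-parameter counts
#'
#' @param model a [build_network()] model.
#' @return data.frame with block name and parameter count.
#' @export
block_param_counts <- function(model) {
  n <- vapply(model$registry,
              function(ps) sum(vapply(model$params[ps], length, 0L)), 0L)
  data.frame(block = names(model$registry), n_params = as.integer(n),
             row.names = NULL)
}

# Forward pass; optionally records an op tape for backprop.
# Returns list(prob (3D array), buf, tape, out_id).
.net_apply <- function(model, x, training = FALSE, build_tape = FALSE) {
  cfg <- model$config; p <- model$params
  d <- cfg$depth; ncv <- cfg$convs_per_block
  rate <- if (training) cfg$dropout_rate else 0
  if (!identical(dim(x)[1:3], cfg$target_shape))
    stop("input spatial shape [", paste(dim(x)[1:3], collapse = ", "),
         "] does not match target_shape [",
         paste(cfg$target_shape, collapse = ", "), "]")
  buf <- vector("list", 64L); tape <- list(); nid <- 0L
  emit <- function(op, ins, val, w = NULL, stride = 1L, act = "none", extra = NULL) {
    nid <<- nid + 1L
    if (nid > length(buf)) length(buf) <<- 2L * nid
    buf[[nid]] <<- val
    if (build_tape)
      tape[[length(tape) + 1L]] <<- list(op = op, ins = ins, out = nid, w = w,
                                         stride = stride, act = act, extra = extra)
    nid
  }
  conv3 <- function(in_id, name, stride) {
    emit("conv3", in_id,
         .conv3_fw(buf[[in_id]], p[[paste0(name, ".w")]], p[[paste0(name, ".b")]],
                   as.integer(stride), TRUE),
         w = name, stride = as.integer(stride), act = "relu")
  }
  block <- function(in_id, prefix, entry_stride) {
    a0 <- conv3(in_id, paste0(prefix, ".conv0"), entry_stride)
    cur <- a0
    if (ncv > 1L) {
      for (j in 1:(ncv - 1L)) cur <- conv3(cur, sprintf("%s.conv%d", prefix, j), 1L)
      cur <- emit("add", c(a0, cur), buf[[a0]] + buf[[cur]])
    }
    if (rate > 0) {
      keep <- array((runif(length(buf[[cur]])) >= rate) / (1 - rate),
                    dim(buf[[cur]]))
      cur <- emit("dropout", cur, buf[[cur]] * keep, extra = keep)
    }
    cur
  }
  x_id <- emit("input", integer(0), x)
  enc <- integer(d)
  a <- x_id
  for (i in 1:d) {
    a <- block(a, sprintf("down%d", i), if (i == 1L) 1L else 2L)
    enc[i] <- a
  }
  for (j in 1:d) {
    prefix <- sprintf("up%d", j)
    if (j > 1L) {
      u <- emit("convt2", a,
                .convt2_fw(buf[[a]], p[[paste0(prefix, ".upconv.w")]],
                           p[[paste0(prefix, ".upconv.b")]]),
                w = paste0(prefix, ".upconv"))
      s <- enc[d - j + 1L]
      if (cfg$skip_mode == "concatenate") {
        du <- dim(buf[[u]]); ds <- dim(buf[[s]])
        cc <- array(0, c(du[1:3], du[4] + ds[4]))
        cc[, , , seq_len(du[4])] <- buf[[u]]
        cc[, , , du[4] + seq_len(ds[4])] <- buf[[s]]
        a <- emit("concat", c(u, s), cc, extra = c(du[4], ds[4]))
      } else {
        a <- emit("add", c(u, s), buf[[u]] + buf[[s]])
      }
    }
    a <- block(a, prefix, 1L)
  }
  head_name <- sprintf("up%d.head", d)
  out <- emit("conv1", a,
              .conv1_fw(buf[[a]], p[[paste0(head_name, ".w")]],
                        p[[paste0(head_name, ".b")]], TRUE),
              w = head_name, act = "sigmoid")
  list(prob = array(buf[[out]], cfg$target_shape), buf = buf, tape = tape,
       out_id = out)
}

# Backprop through a recorded tape.  trainable: named logical over param
# names (NULL = all).  Returns named list of gradients for trainable params.
.net_backward <- function(model, fwd, dprob, trainable = NULL) {
  p <- model$params
  g <- vector("list", length(fwd$tape) + 1L)
  grads <- list()
  acc <- function(id, v) g[[id]] <<- if (is.null(g[[id]])) v else g[[id]] + v
  gacc <- function(nm, v) grads[[nm]] <<- if (is.null(grads[[nm]])) v else grads[[nm]] + v
  want <- function(name) is.null(trainable) ||
    isTRUE(trainable[[paste0(name, ".w")]])
  dim(dprob) <- dim(fwd$buf[[fwd$out_id]])
  g[[fwd$out_id]] <- dprob
  for (t in rev(fwd$tape)) {
    gy <- g[[t$out]]
    if (is.null(gy)) next
    if (t$op == "conv3") {
      w <- want(t$w)
      need_dx <- t$ins > 1L  # buffer 1 is the network input
      r <- .conv3_bw(fwd$buf[[t$ins]], p[[paste0(t$w, ".w")]], gy,
                     fwd$buf[[t$out]], t$stride, TRUE, w, need_dx)
      if (need_dx) acc(t$ins, r$dx)
      if (w) { gacc(paste0(t$w, ".w"), r$dw); gacc(paste0(t$w, ".b"), r$db) }
    } else if (t$op == "convt2") {
      w <- want(t$w)
      r <- .convt2_bw(fwd$buf[[t$ins]], p[[paste0(t$w, ".w")]], gy, w)
      acc(t$ins, r$dx)
      if (w) { gacc(paste0(t$w, ".w"), r$dw); gacc(paste0(t$w, ".b"), r$db) }
    } else if (t$op == "conv1") {
      w <- want(t$w)
      r <- .conv1_bw(fwd$buf[[t$ins]], p[[paste0(t$w, ".w")]], gy,
                     fwd$buf[[t$out]], TRUE, w)
      acc(t$ins, r$dx)
      if (w) { gacc(paste0(t$w, ".w"), r$dw); gacc(paste0(t$w, ".b"), r$db) }
    } else if (t$op == "add") {
      acc(t$ins[1], gy); acc(t$ins[2], gy)
    } else if (t$op == "concat") {
      c1 <- t$extra[1]; c2 <- t$extra[2]
      acc(t$ins[1], gy[, , , seq_len(c1), drop = FALSE])
      acc(t$ins[2], gy[, , , c1 + seq_len(c2), drop = FALSE])
    } else if (t$op == "dropout") {
      acc(t$ins, gy * t$extra)
    }
  }
  grads
}

#' Run the network on one or more input volumes
#'
#' In inference mode (the default) dropout is disabled and the output is
#' deterministic.  Batches are processed case by case (the architecture has
#' no cross-case statistics, so this is exact).
#'
#' @param model a [build_network()] model.
#' @param x a 4D array `(X, Y, Z, in_channels)`, a [volume4ch()], or a list
#'   of either.
#' @param training logical; enables dropout (uses the current RNG stream).
#' @return A 3D voxelwise probability array in (0, 1), or a list of them
#'   for list input.
#' @export
net_forward <- function(model, x, training = FALSE) {
  stopifnot(inherits(model, "blocknet"))
  if (is.list(x) && !inherits(x, "volume4ch"))
    return(lapply(x, function(xi) net_forward(model, xi, training)))
  if (inherits(x, "volume4ch")) x <- x$data
  .net_apply(model, x, training = training)$prob
}

#' Threshold a probability map into a binary VOI mask
#'
#' Voxels with probability greater than or equal to the threshold are
#' labeled tumor (ties count as tumor).
#'
#' @param prob 3D probability array.
#' @param threshold real in (0, 1); default 0.5.
#' @param spacing,id metadata for the resulting [voi_mask()].
#' @return A [voi_mask()].
#' @export
binarize <- function(prob, threshold = 0.5, spacing = c(1, 1, 1), id = "pred") {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  voi_mask((prob >= threshold) * 1, spacing = spacing, id = id)
}
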