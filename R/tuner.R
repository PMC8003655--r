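#' Selective-layer freezing strategy
#'
#' The five named strategies select which blocks stay learnable during
#' fine-tuning: `fine_all` (every block), `down_only` (the encoder path),
#' `up_only` (the decoder path), `down1_up1` (one block per path) and
#' `down2_up2` (two blocks per path, the recommended protocol).
#'
#' The up-path ordinals admit two readings, both implemented.  Under the
#' `"literal"` reading the "1st up" block is the deepest up block, so
#' `down2_up2` selects the two shallowest down blocks plus the two deepest
#' up blocks.  Under the default `"shallow"` reading the up blocks selected
#' are the two shallowest ones (the mirror images of the selected down
#' blocks, including the output head), which matches the rationale that
#' facility differences live in low-level features.
#'
#' @param name one of `"fine_all"`, `"down_only"`, `"up_only"`,
#'   `"down1_up1"`, `"down2_up2"`.
#' @param depth network depth the strategy will be applied to.
#' @param up_reading `"shallow"` (default) or `"literal"`.
#' @return An object of class `freeze_strategy` with the derived
#'   `learnable_blocks`.
#' @export
freeze_strategy <- function(name, depth,
                            up_reading = c("shallow", "literal")) {
  up_reading <- match.arg(up_reading)
  depth <- as.integer(depth)
  downs <- paste(vapply(1:depth, .ordinal, ""), "down")
  ups <- paste(vapply(1:depth, .ordinal, ""), "up")  # index 1 = deepest
  pick_ups <- function(k) {
    if (k > depth) stop("strategy needs depth >= ", k)
    if (up_reading == "literal") ups[seq_len(k)] else ups[depth - seq_len(k) + 1L]
  }
  blocks <- switch(name,
    fine_all  = c(downs, ups),
    down_only = downs,
    up_only   = ups,
    down1_up1 = c(downs[1], pick_ups(1L)),
    down2_up2 = {
      if (depth < 2L) stop("down2_up2 needs depth >= 2")
      c(downs[1:2], pick_ups(2L))
    },
    stop("unknown strategy '", name, "'; expected one of fine_all, ",
         "down_only, up_only, down1_up1, down2_up2"))
  structure(list(name = name, depth = depth, up_reading = up_reading,
                 learnable_blocks = blocks),
            class = "freeze_strategy")
}

#' Mark parameters trainable or frozen according to a strategy
#'
#' @param model a [build_network()] model.
#' @param strategy a [freeze_strategy()] (or a strategy name, resolved at
#'   the model's depth with the default up-block reading).
#' @return The model with a named logical `$trainable` over all parameters;
#'   `attr(, "counts")` holds the (trainable, frozen) element counts.
#' @export
apply_freeze <- function(model, strategy) {
  stopifnot(inherits(model, "blocknet"))
  if (is.character(strategy))
    strategy <- freeze_strategy(strategy, model$config$depth)
  missing <- setdiff(strategy$learnable_blocks, names(model$registry))
  if (length(missing))
    stop("strategy references unknown blocks: ", paste(missing, collapse = ", "))
  learn_params <- unlist(model$registry[strategy$learnable_blocks],
                         use.names = FALSE)
  trainable <- stats::setNames(names(model$params) %in% learn_params,
                               names(model$params))
  model$trainable <- trainable
  model$strategy <- strategy
  nel <- vapply(model$params, length, 0L)
  attr(model, "counts") <- c(trainable = sum(nel[trainable]),
                             frozen = sum(nel[!trainable]))
  model
}

#' Training specification
#'
#' Defaults follow the fine-tuning protocol: AdaGrad with learning rate
#' 0.005 for 20 epochs.  Base training conventionally uses RMSprop with
#' learning rate 0.0005 (see [train_base()]).
#'
#' @param optimizer `"adagrad"` or `"rmsprop"`.
#' @param learning_rate positive step size.
#' @param epochs positive integer.
#' @param batch_size cases per update; default 1 (whole 3D volumes).
#' @param loss only `"soft_dice"` is provided.
#' @param seed integer driving data order and dropout.
#' @return An object of class `train_spec`.
#' @export
train_spec <- function(optimizer = "adagrad", learning_rate = 0.005,
                       epochs = 20L, batch_size = 1L, loss = "soft_dice",
                       seed = 0L) {
  if (learning_rate <= 0) stop("learning_rate must be positive")
  epochs <- as.integer(epochs)
  if (epochs < 1L) stop("epochs must be >= 1")
  if (!optimizer %in% c("adagrad", "rmsprop"))
    stop("unknown optimizer '", optimizer, "'")
  structure(list(optimizer = optimizer, learning_rate = learning_rate,
                 epochs = epochs, batch_size = as.integer(batch_size),
                 loss = loss, seed = as.integer(seed)),
            class = "train_spec")
}

#' Soft Dice loss
#'
#' `1 - (2 * sum(p*t) + eps) / (sum(p) + sum(t) + eps)` with `eps = 1`,
#' aligning the training objective with the Dice evaluation metric and
#' keeping the empty-mask case finite.
#'
#' @param prob voxelwise probability array.
#' @param truth binary array (or [voi_mask()]) of the same shape.
#' @param eps smoothing constant, part of the contract (default 1).
#' @return Scalar loss in [0, 1].
#' @export
soft_dice_loss <- function(prob, truth, eps = 1) {
  if (inherits(truth, "voi_mask")) truth <- truth$data
  if (!identical(dim(prob)[1:3], dim(truth)[1:3]))
    stop("probability map and truth shapes differ")
  s_pt <- sum(prob * truth); s_p <- sum(prob); s_t <- sum(truth)
  1 - (2 * s_pt + eps) / (s_p + s_t + eps)
}

# gradient of soft dice loss wrt prob
.soft_dice_grad <- function(prob, truth, eps = 1) {
  s_pt <- sum(prob * truth); s_p <- sum(prob); s_t <- sum(truth)
  den <- s_p + s_t + eps
  ((2 * s_pt + eps) - 2 * truth * den) / den^2
}

# one optimizer state + update step over a named grads list.
# AdaGrad follows the Keras convention of a 0.1 initial accumulator, which
# tempers the first steps (a zero-initialized accumulator makes the first
# update exactly +/- lr for every parameter, which can saturate the sigmoid
# head and collapse predictions to empty).
.opt_new <- function(spec) new.env(parent = emptyenv())
.opt_step <- function(model, grads, spec, state) {
  eps <- 1e-7
  for (nm in names(grads)) {
    gr <- grads[[nm]]
    if (spec$optimizer == "adagrad") {
      st <- if (exists(nm, state)) get(nm, state) else 0.1
      st <- st + gr^2
    } else {  # rmsprop
      st <- if (exists(nm, state)) get(nm, state) else 0
      st <- 0.9 * st + 0.1 * gr^2
    }
    assign(nm, st, state)
    model$params[[nm]] <- model$params[[nm]] - spec$learning_rate * gr / (sqrt(st) + eps)
  }
  model
}

# cases: list of list(x = 4D array, y = 3D binary array)
.train_loop <- function(model, cases, spec, trainable = NULL,
                        val_cases = NULL, log_file = NULL, track_best = FALSE) {
  state <- .opt_new(spec)
  history <- list()
  best <- NULL; best_dice <- -Inf
  log_line <- function(rec) {
    history[[length(history) + 1L]] <<- rec
    if (!is.null(log_file))
      cat(jsonlite::toJSON(rec, auto_unbox = TRUE), "\n",
          file = log_file, append = TRUE)
  }
  with_seed(derive_seed(spec$seed, "train"), {
    for (ep in seq_len(spec$epochs)) {
      ord <- sample.int(length(cases))
      ep_loss <- 0
      for (ci in ord) {
        cs <- cases[[ci]]
        fwd <- .net_apply(model, cs$x, training = TRUE, build_tape = TRUE)
        loss <- soft_dice_loss(fwd$prob, cs$y)
        dprob <- .soft_dice_grad(fwd$prob, cs$y)
        grads <- .net_backward(model, fwd, dprob, trainable)
        model <- .opt_step(model, grads, spec, state)
        ep_loss <- ep_loss + loss
      }
      rec <- list(epoch = ep, split = "train",
                  loss = ep_loss / length(cases))
      if (!is.null(val_cases) && length(val_cases)) {
        vd <- vapply(val_cases, function(vc) {
          pr <- .net_apply(model, vc$x, training = FALSE)$prob
          pred <- (pr >= 0.5) * 1
          if (sum(pred) + sum(vc$y) == 0) return(NA_real_)
          2 * sum(pred * vc$y) / (sum(pred) + sum(vc$y))
        }, 0)
        rec$val_dice <- mean(vd, na.rm = TRUE)
        if (track_best && rec$val_dice >= best_dice) {
          best_dice <- rec$val_dice
          best <- model$params
        }
      }
      log_line(rec)
    }
  })
  if (track_best && !is.null(best)) model$params <- best
  hist_df <- do.call(rbind, lapply(history, function(r)
    data.frame(epoch = r$epoch, loss = r$loss,
               val_dice = if (is.null(r$val_dice)) NA_real_ else r$val_dice)))
  list(model = model, history = hist_df)
}

#' Train a network from scratch on a source dataset
#'
#' All parameters are learnable.  Per-epoch training loss and validation
#' Dice are logged; the returned model carries the parameters of the
#' best-validation-Dice epoch.  Base training defaults to RMSprop with
#' learning rate 0.0005.
#'
#' @param model a [build_network()] model.
#' @param train_cases,val_cases nonempty lists of preprocessed cases
#'   (`list(x = 4D array, y = binary 3D array)`, see [preprocess_case()]).
#' @param spec a [train_spec()]; default RMSprop, lr 0.0005, 20 epochs.
#' @param log_file optional path for line-oriented JSON epoch logs.
#' @return list with `model` (best checkpoint) and `history` (data.frame of
#'   epoch, loss, val_dice).
#' @export
train_base <- function(model, train_cases, val_cases,
                       spec = train_spec(optimizer = "rmsprop",
                                         learning_rate = 5e-4),
                       log_file = NULL) {
  stopifnot(inherits(model, "blocknet"))
  if (!length(train_cases) || !length(val_cases))
    stop("train and validation datasets must be nonempty")
  .train_loop(model, train_cases, spec, trainable = NULL,
              val_cases = val_cases, log_file = log_file, track_best = TRUE)
}

#' Fine-tune a trained model on a small facility dataset
#'
#' Applies the freezing strategy and continues training on at most
#' `max_cases` cases from the target facility; all supplied cases are used
#' for training (the epoch count is fixed, no validation split).  Frozen
#' parameters are guaranteed bit-identical to the base model.
#'
#' @param base_model a trained [build_network()] model.
#' @param facility_cases 1 to `max_cases` preprocessed cases.  Supplying
#'   more is an error: subsample explicitly, e.g. with [sample_cases()].
#' @param strategy a [freeze_strategy()] or strategy name.
#' @param spec a [train_spec()]; default AdaGrad, lr 0.005, 20 epochs.
#' @param max_cases cap on fine-tuning cases (default 20).
#' @param log_file optional path for JSON epoch logs.
#' @return list with `model` and `history`.
#' @export
fine_tune <- function(base_model, facility_cases, strategy,
                      spec = train_spec(), max_cases = 20L, log_file = NULL) {
  stopifnot(inherits(base_model, "blocknet"))
  n <- length(facility_cases)
  if (n < 1L) stop("at least one fine-tuning case is required")
  if (n > max_cases)
    stop("got ", n, " fine-tuning cases but max_cases = ", max_cases,
         "; subsample explicitly (see sample_cases())")
  model <- apply_freeze(base_model, strategy)
  res <- .train_loop(model, facility_cases, spec,
                     trainable = model$trainable, log_file = log_file)
  res
}

#' Seeded subsampling of a case list
#'
#' @param cases list of cases.
#' @param n number to keep (all if `n >= length(cases)`).
#' @param seed integer.
#' @return Subsampled list.
#' @export
sample_cases <- function(cases, n, seed) {
  if (n >= length(cases)) return(cases)
  idx <- with_seed(derive_seed(seed, "sample"), sample.int(length(cases), n))
  cases[idx]
}

#' Save / load a model checkpoint
#'
#' Writes `<prefix>.rds` (parameters and configuration) and a JSON manifest
#' `<prefix>.manifest.json` describing every block: its parameter names,
#' shapes and counts.
#'
#' @param model a [build_network()] model.
#' @param prefix path prefix for the two files.
#' @return `save_checkpoint`: invisibly, the two paths.
#' @export
save_checkpoint <- function(model, prefix) {
  stopifnot(inherits(model, "blocknet"))
  rds <- paste0(prefix, ".rds")
  manifest <- paste0(prefix, ".manifest.json")
  saveRDS(list(params = model$params, config = unclass(model$config)), rds)
  blocks <- lapply(model$registry, function(ps) {
    list(params = ps,
         shapes = lapply(model$params[ps], function(a)
           if (is.null(dim(a))) length(a) else dim(a)),
         n_params = sum(vapply(model$params[ps], length, 0L)))
  })
  jsonlite::write_json(blocks, manifest, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(rds, manifest))
}

#' @rdname save_checkpoint
#' @return `load_checkpoint`: the restored `blocknet` model.
#' @export
load_checkpoint <- function(prefix) {
  obj <- readRDS(paste0(prefix, ".rds"))
  cfg <- do.call(net_config, obj$config[setdiff(names(obj$config), NULL)])
  model <- build_network(cfg)
  stopifnot(identical(sort(names(model$params)), sort(names(obj$params))))
  model$params <- obj$params
  model
}
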