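test_that("freeze strategies resolve to the documented block sets", {
  d <- 5L
  expect_setequal(freeze_strategy("fine_all", d)$learnable_blocks, block_names(d))
  expect_setequal(freeze_strategy("down_only", d)$learnable_blocks,
                  paste(c("1st", "2nd", "3rd", "4th", "5th"), "down"))
  expect_setequal(freeze_strategy("up_only", d)$learnable_blocks,
                  paste(c("1st", "2nd", "3rd", "4th", "5th"), "up"))
  # literal reading: "1st up" is the deepest up block
  expect_setequal(freeze_strategy("down2_up2", d, "literal")$learnable_blocks,
                  c("1st down", "2nd down", "1st up", "2nd up"))
  # shallow reading: the mirror blocks of the selected down blocks
  expect_setequal(freeze_strategy("down2_up2", d, "shallow")$learnable_blocks,
                  c("1st down", "2nd down", "4th up", "5th up"))
  expect_setequal(freeze_strategy("down1_up1", d, "literal")$learnable_blocks,
                  c("1st down", "1st up"))
  expect_error(freeze_strategy("everything", d), "unknown strategy")
})

test_that("apply_freeze flags exactly the strategy's parameters", {
  net <- build_network(tiny_net_config(depth = 3, shape = c(16, 16, 16)))
  total <- sum(vapply(net$params, length, 0L))

  m <- apply_freeze(net, "fine_all")
  expect_equal(attr(m, "counts")[["frozen"]], 0)

  m <- apply_freeze(net, freeze_strategy("down1_up1", 3, "literal"))
  expect_setequal(names(which(m$trainable)),
                  c(net$registry[["1st down"]], net$registry[["1st up"]]))
  expect_equal(sum(attr(m, "counts")), total)

  for (st in c("down_only", "up_only", "down2_up2"))
    expect_equal(sum(attr(apply_freeze(net, st), "counts")), total)
})

test_that("soft Dice loss matches direct summation", {
  ones <- array(1, c(2, 2, 2))
  expect_equal(soft_dice_loss(ones, ones), 0)
  zeros <- array(0, c(2, 2, 2))
  expect_equal(soft_dice_loss(zeros, ones), 1 - 1 / 9)  # eps keeps it finite
  withr::with_seed(5, {
    p <- array(runif(8), c(2, 2, 2))
    t <- array(sample(0:1, 8, TRUE), c(2, 2, 2))
  })
  direct <- 1 - (2 * sum(p * t) + 1) / (sum(p) + sum(t) + 1)
  expect_equal(soft_dice_loss(p, t), direct)
  expect_true(soft_dice_loss(p, t) >= 0 && soft_dice_loss(p, t) <= 1)
  expect_error(soft_dice_loss(p, array(1, c(3, 3, 3))), "shapes")
})

test_that("train_spec and fine_tune validate their preconditions", {
  expect_error(train_spec(epochs = 0), "epochs")
  expect_error(train_spec(learning_rate = 0), "learning_rate")
  expect_error(train_spec(optimizer = "adam"), "optimizer")
  net <- build_network(tiny_net_config())
  cases <- lapply(1:3, tiny_case)
  expect_error(fine_tune(net, cases, "down2_up2", max_cases = 2L), "max_cases")
  expect_error(fine_tune(net, list(), "down2_up2"), "at least one")
  expect_error(train_base(net, list(), cases), "nonempty")
})

test_that("base training is reproducible and updates every block", {
  net <- build_network(tiny_net_config())
  cases <- lapply(1:2, tiny_case)
  spec <- train_spec("rmsprop", 1e-3, epochs = 1L, seed = 7L)
  f1 <- train_base(net, cases, cases[1], spec)
  f2 <- train_base(net, cases, cases[1], spec)
  expect_identical(f1$model$params, f2$model$params)
  for (blk in names(net$registry)) {
    changed <- any(vapply(net$registry[[blk]], function(nm)
      !identical(f1$model$params[[nm]], net$params[[nm]]), TRUE))
    expect_true(changed, label = paste("block", blk, "updated"))
  }
  expect_equal(nrow(f1$history), 1)
})

test_that("training loss decreases over sustained optimization", {
  net <- build_network(net_config(depth = 2, base_channels = 3,
                                  convs_per_block = 2, dropout_rate = 0,
                                  target_shape = c(8, 8, 8), init_seed = 2))
  ph <- make_base_phantom(c(8L, 8L, 8L), list(center = c(4.5, 4.5, 4.5),
                                              radii = c(2, 2, 2), rim_width = 1,
                                              edema_width = 1), seed = 1)
  cs <- list(x = zscore_normalize(ph$volume)$data, y = merge_voi(ph$labels)$data)
  fit <- fine_tune(net, list(cs), "fine_all",
                   train_spec("adagrad", 0.01, epochs = 50L, seed = 1L))
  expect_lt(fit$history$loss[50], fit$history$loss[1])
})

test_that("a tiny network can overfit a single case to high Dice", {
  net <- build_network(net_config(depth = 2, base_channels = 4,
                                  convs_per_block = 2, dropout_rate = 0,
                                  target_shape = c(8, 8, 8), init_seed = 3))
  ph <- make_base_phantom(c(8L, 8L, 8L), list(center = c(4.5, 4.5, 4.5),
                                              radii = c(2, 2, 2), rim_width = 1,
                                              edema_width = 1), seed = 2)
  cs <- list(x = zscore_normalize(ph$volume)$data, y = merge_voi(ph$labels)$data)
  fit <- fine_tune(net, list(cs), "fine_all",
                   train_spec("adagrad", 0.01, epochs = 200L, seed = 4L))
  pred <- (net_forward(fit$model, cs$x) >= 0.5) * 1
  expect_gt(2 * sum(pred * cs$y) / (sum(pred) + sum(cs$y)), 0.9)
})

test_that("fine-tuning keeps frozen parameters bit-identical", {
  base <- build_network(tiny_net_config(depth = 3, shape = c(16, 16, 16)))
  cases <- lapply(1:2, tiny_case)
  for (reading in c("shallow", "literal")) {
    st <- freeze_strategy("down2_up2", 3, reading)
    ft <- fine_tune(base, cases, st,
                    train_spec("adagrad", 0.005, epochs = 2L, seed = 5L))
    frozen_blocks <- setdiff(names(base$registry), st$learnable_blocks)
    for (blk in frozen_blocks)
      for (nm in base$registry[[blk]])
        expect_identical(ft$model$params[[nm]], base$params[[nm]],
                         label = paste(reading, nm, "frozen"))
    for (blk in st$learnable_blocks) {
      changed <- any(vapply(base$registry[[blk]], function(nm)
        !identical(ft$model$params[[nm]], base$params[[nm]]), TRUE))
      expect_true(changed, label = paste(reading, blk, "learnable"))
    }
  }
})

test_that("down2_up2 updates strictly fewer parameters than fine_all", {
  base <- build_network(tiny_net_config(depth = 3, shape = c(16, 16, 16)))
  cases <- lapply(1:2, tiny_case)
  spec <- train_spec("adagrad", 0.005, epochs = 1L, seed = 6L)
  fa <- fine_tune(base, cases, "fine_all", spec)
  d2 <- fine_tune(base, cases, "down2_up2", spec)
  n_changed <- function(m) sum(vapply(names(base$params), function(nm)
    sum(m$model$params[[nm]] != base$params[[nm]]), 0))
  expect_lt(n_changed(d2), n_changed(fa))
})

test_that("checkpoints round-trip with a block manifest", {
  net <- build_network(tiny_net_config())
  prefix <- file.path(tempdir(), "ckpt_test")
  save_checkpoint(net, prefix)
  back <- load_checkpoint(prefix)
  expect_identical(back$params, net$params)
  expect_identical(back$registry, net$registry)
  manifest <- jsonlite::read_json(paste0(prefix, ".manifest.json"))
  expect_equal(length(manifest), 2 * net$config$depth)
  expect_equal(sum(vapply(manifest, function(b) b$n_params, 0)),
               sum(vapply(net$params, length, 0L)))
})
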