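# Shared tiny fixtures, generated in code.

tiny_shape <- c(16L, 16L, 16L)

tiny_net_config <- function(depth = 2L, base = 4L, shape = tiny_shape, ...) {
  net_config(depth = depth, base_channels = base, convs_per_block = 2L,
             dropout_rate = 0.1, target_shape = shape, ...)
}

tiny_phantom <- function(seed = 1, shape = c(24L, 24L, 24L), radii = c(5, 5, 5)) {
  make_base_phantom(shape,
                    list(center = (shape + 1) / 2, radii = radii,
                         rim_width = 2, edema_width = 2),
                    seed = seed)
}

# a preprocessed training case from a phantom
tiny_case <- function(seed = 1, shape = tiny_shape) {
  ph <- make_base_phantom(shape,
                          list(center = (shape + 1) / 2, radii = c(3.5, 3.5, 3.5),
                               rim_width = 1.5, edema_width = 1.5),
                          seed = seed)
  preprocess_case(ph$volume, ph$labels, shape)
}

random_mask <- function(shape, p = 0.3, seed = 1) {
  withr::with_seed(seed, voi_mask(array(as.numeric(runif(prod(shape)) < p), shape)))
}

# brute-force voxel-counting Dice, independent of dice()
dice_oracle <- function(a, b) {
  av <- a$data != 0; bv <- b$data != 0
  inter <- 0; na <- 0; nb <- 0
  for (i in seq_along(av)) {
    if (av[i]) na <- na + 1
    if (bv[i]) nb <- nb + 1
    if (av[i] && bv[i]) inter <- inter + 1
  }
  2 * inter / (na + nb)
}
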