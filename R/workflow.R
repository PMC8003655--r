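#' Deterministic experiment splits
#'
#' Source cases are split 60/20/20 into train/validation/test; each target
#' facility is split into two balanced halves (pre-training and independent
#' test, counts differing by at most 1), and the pre-training half is split
#' 75/25 into train/validation.  Fractional counts are resolved by
#' largest-remainder assignment with ties broken in role order
#' (train, validation, test); case order is a seeded shuffle.
#'
#' @param source_ids character vector of source-domain case ids.
#' @param target_ids_by_facility named list: facility id -> character
#'   vector of case ids (each facility needs >= 2 cases).
#' @param seed integer.
#' @return An object of class `split_plan`: data.frame with `case_id`,
#'   `facility_id` (`"source"` for source cases) and `role` in
#'   {source_train, source_val, source_test, target_pretrain_train,
#'   target_pretrain_val, target_test}; counts table in `attr(, "counts")`.
#' @export
make_splits <- function(source_ids, target_ids_by_facility, seed) {
  lr_counts <- function(n, ratios) {
    raw <- n * ratios
    base <- floor(raw)
    rem <- n - sum(base)
    if (rem > 0) {
      extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
      base[extra] <- base[extra] + 1
    }
    as.integer(base)
  }
  assign_roles <- function(ids, roles, counts, seed) {
    ids <- with_seed(seed, sample(sort(ids)))
    data.frame(case_id = ids, role = rep(roles, counts),
               stringsAsFactors = FALSE)
  }
  out <- assign_roles(source_ids,
                      c("source_train", "source_val", "source_test"),
                      lr_counts(length(source_ids), c(0.6, 0.2, 0.2)),
                      derive_seed(seed, "source"))
  out$facility_id <- "source"
  for (fac in names(target_ids_by_facility)) {
    ids <- target_ids_by_facility[[fac]]
    if (length(ids) < 2L)
      stop("facility '", fac, "' has fewer than 2 cases")
    n <- length(ids)
    n_pre <- ceiling(n / 2)
    ids <- with_seed(derive_seed(seed, "target", fac), sample(sort(ids)))
    pre <- ids[seq_len(n_pre)]
    tst <- ids[-seq_len(n_pre)]
    cts <- lr_counts(n_pre, c(0.75, 0.25))
    fac_df <- rbind(
      data.frame(case_id = pre,
                 role = rep(c("target_pretrain_train", "target_pretrain_val"), cts),
                 stringsAsFactors = FALSE),
      data.frame(case_id = tst, role = "target_test", stringsAsFactors = FALSE))
    fac_df$facility_id <- fac
    out <- rbind(out, fac_df)
  }
  counts <- table(out$facility_id, out$role)
  structure(out[, c("case_id", "facility_id", "role")],
            counts = counts, class = c("split_plan", "data.frame"))
}

#' Experiment configuration
#'
#' Bundles everything [run_experiment()] needs.  The defaults describe the
#' built-in two-facility smoke configuration: a tiny 16^3 depth-2 network
#' and a handful of cases per facility, small enough to run in seconds.
#'
#' @param source_spec [facility_spec()] of the source domain (the public
#'   dataset analog).
#' @param target_specs named list of [facility_spec()]s for the target
#'   facilities (the clinical-cohort analog).
#' @param n_source,n_target_per_facility case counts to generate.
#' @param shape volume shape; must match `net$target_shape`.
#' @param sampler a [tumor_sampler()].
#' @param net a [net_config()].
#' @param base_spec,finetune_spec [train_spec()]s for base training and
#'   fine-tuning (seeds are re-derived from the experiment seed).
#' @param strategy fine-tuning strategy name.
#' @param up_reading up-block ordinal reading, see [freeze_strategy()].
#' @param max_cases fine-tuning cap (default 20).
#' @param n_finetune_cases cases actually drawn per facility (<= max_cases).
#' @param threshold binarization threshold for predictions.
#' @param seed master experiment seed; all randomness (generation, splits,
#'   initialization, data order, dropout, sampling) derives from it through
#'   named substreams.
#' @return list of class `experiment_config`.
#' @export
experiment_config <- function(
    source_spec = facility_spec("A"),
    target_specs = list(B = facility_spec("B", gamma = 1.8, noise_sigma = 0.08,
                                          bias_field_amplitude = 0.2,
                                          slice_thickness_factor = 2L,
                                          rng_seed_offset = 101L)),
    n_source = 8L, n_target_per_facility = 8L,
    shape = c(16L, 16L, 16L),
    sampler = tumor_sampler(radius_range = c(3, 5), rim_width = 1.5,
                            edema_width = 1.5, center_jitter = 1),
    net = net_config(depth = 2L, base_channels = 4L, convs_per_block = 2L,
                     dropout_rate = 0.1, target_shape = c(16L, 16L, 16L)),
    base_spec = train_spec(optimizer = "rmsprop", learning_rate = 1e-3,
                           epochs = 2L),
    finetune_spec = train_spec(epochs = 2L),
    strategy = "down2_up2", up_reading = "shallow",
    max_cases = 20L, n_finetune_cases = 3L, threshold = 0.5, seed = 0L) {
  if (!identical(as.integer(shape), net$target_shape))
    stop("shape must equal net$target_shape")
  structure(list(source_spec = source_spec, target_specs = target_specs,
                 n_source = n_source,
                 n_target_per_facility = n_target_per_facility,
                 shape = as.integer(shape), sampler = sampler, net = net,
                 base_spec = base_spec, finetune_spec = finetune_spec,
                 strategy = strategy, up_reading = up_reading,
                 max_cases = max_cases, n_finetune_cases = n_finetune_cases,
                 threshold = threshold, seed = as.integer(seed)),
            class = "experiment_config")
}

# preprocess a generated phantom case for the model
.prep <- function(case, target_shape) {
  pc <- preprocess_case(case$volume, case$labels, target_shape)
  pc$facility_id <- case$facility_id
  pc$metadata_label <- case$metadata_label
  pc$tumor_volume_ml <- case$tumor_volume_ml
  pc
}

.eval_model <- function(model, cases, model_type, threshold) {
  do.call(rbind, lapply(cases, function(cs) {
    pr <- net_forward(model, cs$x)
    pred <- (pr >= threshold) * 1
    d <- if (sum(pred) + sum(cs$y) == 0) NA_real_ else
      2 * sum(pred * cs$y) / (sum(pred) + sum(cs$y))
    eval_record(cs$id, cs$facility_id, model_type, d, cs$tumor_volume_ml,
                cs$metadata_label)
  }))
}

#' Run the full degradation-and-recovery experiment
#'
#' Generates synthetic datasets for the source domain and every target
#' facility, preprocesses them, builds the three model types — (1) a source
#' model trained on source data, (2) a target model trained on the pooled
#' target pre-training halves, (3) one fine-tuned model per facility,
#' adapted from the source model with at most `max_cases` cases — and
#' evaluates all three on each facility's held-out target test cases (the
#' same cases for every model type, so the comparison is paired; each
#' fine-tuned model is evaluated on its own facility).  Facilities whose
#' fine-tuning pool is empty are skipped with a warning.
#'
#' @param config an [experiment_config()].
#' @param out_dir optional run directory; if given, evaluation records
#'   (CSV), the report (JSON), model checkpoints and training logs are
#'   written there.
#' @return list with `records` (evaluation records, one row per case x
#'   model type), `aggregates` (by model type, and by facility x model
#'   type), `stats` ([compare_models()] output or NULL if degenerate),
#'   `pearson` (Dice vs tumor volume per model type), `split`, `history`,
#'   `models`.
#' @export
run_experiment <- function(config = experiment_config(), out_dir = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  seed <- config$seed
  ts <- config$net$target_shape

  src_cases <- generate_facility_dataset(
    config$source_spec, config$n_source, config$shape, config$sampler,
    seed = derive_seed(seed, "gen", "source"))
  tgt_cases <- lapply(config$target_specs, function(sp)
    generate_facility_dataset(sp, config$n_target_per_facility, config$shape,
                              config$sampler,
                              seed = derive_seed(seed, "gen", sp$facility_id)))

  src_prep <- lapply(src_cases, .prep, target_shape = ts)
  tgt_prep <- lapply(tgt_cases, function(cl) lapply(cl, .prep, target_shape = ts))

  ids <- function(cl) vapply(cl, `[[`, "", "id")
  split <- make_splits(ids(src_prep), lapply(tgt_prep, ids),
                       derive_seed(seed, "split"))
  pick <- function(cl, role, fac = NULL) {
    sel <- split$role == role
    if (!is.null(fac)) sel <- sel & split$facility_id == fac
    keep <- split$case_id[sel]
    cl[ids(cl) %in% keep]
  }

  net <- config$net
  net$init_seed <- derive_seed(seed, "init")
  histories <- list()

  base_spec <- config$base_spec
  base_spec$seed <- derive_seed(seed, "train", "source")
  src_fit <- train_base(build_network(net), pick(src_prep, "source_train"),
                        pick(src_prep, "source_val"), base_spec)
  histories$source <- src_fit$history

  pool_prep <- unlist(tgt_prep, recursive = FALSE)
  tgt_spec <- config$base_spec
  tgt_spec$seed <- derive_seed(seed, "train", "target")
  tgt_fit <- train_base(build_network(net),
                        pick(pool_prep, "target_pretrain_train"),
                        pick(pool_prep, "target_pretrain_val"), tgt_spec)
  histories$target <- tgt_fit$history

  strategy <- freeze_strategy(config$strategy, net$depth, config$up_reading)
  ft_models <- list()
  ft_pools <- list()
  test_sets <- list()
  records <- data.frame()
  for (fac in names(config$target_specs)) {
    fac_prep <- tgt_prep[[fac]]
    pool <- pick(fac_prep, "target_pretrain_train", fac)
    test <- pick(fac_prep, "target_test", fac)
    if (!length(pool)) {
      warning("facility '", fac, "' has an empty fine-tuning pool; skipped")
      next
    }
    ft_spec <- config$finetune_spec
    ft_spec$seed <- derive_seed(seed, "finetune", fac)
    ft_cases <- sample_cases(pool, config$n_finetune_cases,
                             derive_seed(seed, "ftsample", fac))
    ft_pools[[fac]] <- ft_cases
    test_sets[[fac]] <- test
    ft_fit <- fine_tune(src_fit$model, ft_cases, strategy, ft_spec,
                        max_cases = config$max_cases)
    ft_models[[fac]] <- ft_fit$model
    histories[[paste0("finetune_", fac)]] <- ft_fit$history
    records <- rbind(records,
                     .eval_model(src_fit$model, test, "source", config$threshold),
                     .eval_model(tgt_fit$model, test, "target", config$threshold),
                     .eval_model(ft_fit$model, test, "finetuned", config$threshold))
  }

  aggregates <- list(
    by_model = aggregate_records(records, "model_type"),
    by_facility = aggregate_records(records, c("model_type", "facility_id")))
  stats <- tryCatch(compare_models(records), error = function(e) NULL)
  pearson <- lapply(split(records, records$model_type), function(r)
    tryCatch(pearson_r(r$tumor_volume_ml, r$dice), error = function(e) NA_real_))

  report <- list(records = records, aggregates = aggregates, stats = stats,
                 pearson = pearson, split = split, history = histories,
                 models = list(source = src_fit$model, target = tgt_fit$model,
                               finetuned = ft_models),
                 ft_cases = ft_pools, test_cases = test_sets,
                 config = config)
  if (!is.null(out_dir)) .write_report(report, out_dir)
  invisible(report)
}

.write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$records, file.path(out_dir, "eval_records.csv"),
                   row.names = FALSE)
  js <- list(
    aggregates = report$aggregates,
    welch = report$stats$welch,
    games_howell = report$stats$games_howell,
    pearson = report$pearson,
    split_counts = as.data.frame(attr(report$split, "counts")))
  jsonlite::write_json(js, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, dataframe = "rows")
  save_checkpoint(report$models$source, file.path(out_dir, "model_source"))
  save_checkpoint(report$models$target, file.path(out_dir, "model_target"))
  for (fac in names(report$models$finetuned))
    save_checkpoint(report$models$finetuned[[fac]],
                    file.path(out_dir, paste0("model_finetuned_", fac)))
  invisible(out_dir)
}

#' One trial of the desk-scale degradation-and-recovery study
#'
#' Runs the core transfer experiment for a single seed: a source model is
#' trained on facility A (no acquisition shift), a target model on facility
#' B (gamma 1.8, noise SD 0.08, bias amplitude 0.2, slice factor 2), and
#' the source model is fine-tuned on a small sample of B cases with the
#' requested strategies.  All models are evaluated on the same held-out B
#' test cases.  Problem sizes default to the study conditions: 32^3
#' volumes, a depth-3 network with 8 base channels and 2 convolutions per
#' block, 40 A training cases, a 20-case B pool (from which 10 fine-tuning
#' cases are drawn) and 20 B test cases.
#'
#' @param seed integer; drives every random component of the trial.
#' @param strategies character vector of fine-tuning strategies to run.
#' @param n_src_train,n_src_val,n_tgt_pool,n_tgt_val,n_tgt_test case counts.
#' @param n_finetune fine-tuning cases drawn from the B pool.
#' @param shape volume and network input shape.
#' @param net a [net_config()].
#' @param base_epochs,target_epochs training epochs for the A and B models
#'   (chosen so both get a comparable number of optimization steps).
#' @param base_lr base-training learning rate (RMSprop).
#' @param ft_spec fine-tuning [train_spec()] (AdaGrad, lr 0.005, 20 epochs).
#' @param target_spec_b [facility_spec()] of the shifted facility.
#' @return list with `mean_dice` (named: source, target, and one entry per
#'   strategy), `per_case` (data.frame of per-case Dice by model), and
#'   `history` of the base fits.
#' @export
degradation_recovery_trial <- function(
    seed,
    strategies = c("down2_up2", "fine_all"),
    n_src_train = 40L, n_src_val = 6L,
    n_tgt_pool = 20L, n_tgt_val = 4L, n_tgt_test = 20L,
    n_finetune = 10L,
    shape = c(32L, 32L, 32L),
    net = net_config(depth = 3L, base_channels = 8L, convs_per_block = 2L,
                     dropout_rate = 0.2, target_shape = shape),
    base_epochs = 3L, target_epochs = 12L, base_lr = 1e-3,
    ft_spec = train_spec(optimizer = "adagrad", learning_rate = 0.005,
                         epochs = 20L),
    target_spec_b = facility_spec("B", gamma = 1.8, noise_sigma = 0.08,
                                  bias_field_amplitude = 0.2,
                                  slice_thickness_factor = 2L,
                                  rng_seed_offset = 101L)) {
  spec_a <- facility_spec("A")
  smp <- tumor_sampler()
  gen <- function(spec, n, tag) {
    cl <- generate_facility_dataset(spec, n, shape, smp,
                                    seed = derive_seed(seed, "gen", tag))
    lapply(cl, .prep, target_shape = shape)
  }
  a_tr <- gen(spec_a, n_src_train, "src_train")
  a_va <- gen(spec_a, n_src_val, "src_val")
  b_pool <- gen(target_spec_b, n_tgt_pool, "tgt_pool")
  b_va <- gen(target_spec_b, n_tgt_val, "tgt_val")
  b_te <- gen(target_spec_b, n_tgt_test, "tgt_test")

  net$init_seed <- derive_seed(seed, "init")
  fit_a <- train_base(build_network(net), a_tr, a_va,
                      train_spec("rmsprop", base_lr, epochs = base_epochs,
                                 seed = derive_seed(seed, "train", "A")))
  net_b <- net
  net_b$init_seed <- derive_seed(seed, "init", "B")
  fit_b <- train_base(build_network(net_b), b_pool, b_va,
                      train_spec("rmsprop", base_lr, epochs = target_epochs,
                                 seed = derive_seed(seed, "train", "B")))

  ft_cases <- sample_cases(b_pool, n_finetune, derive_seed(seed, "ftsample"))
  per_case <- data.frame()
  eval_dice <- function(model, label) {
    d <- vapply(seq_along(b_te), function(i) {
      cs <- b_te[[i]]
      pred <- (net_forward(model, cs$x) >= 0.5) * 1
      2 * sum(pred * cs$y) / (sum(pred) + sum(cs$y))
    }, 0)
    per_case <<- rbind(per_case,
                       data.frame(case = seq_along(b_te), model = label, dice = d))
    mean(d)
  }
  means <- c(source = eval_dice(fit_a$model, "source"),
             target = eval_dice(fit_b$model, "target"))
  for (st in strategies) {
    sp <- ft_spec
    sp$seed <- derive_seed(seed, "ft", st)
    ft <- fine_tune(fit_a$model, ft_cases, freeze_strategy(st, net$depth),
                    spec = sp)
    means[st] <- eval_dice(ft$model, st)
  }
  list(mean_dice = means, per_case = per_case,
       history = list(source = fit_a$history, target = fit_b$history))
}
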