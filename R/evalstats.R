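#' Dice coefficient between two binary masks
#'
#' `2 |A n B| / (|A| + |B|)`: twice the overlapping voxel count divided by
#' the total voxel count of both masks.  Symmetric, 1 for an exact match.
#' Two empty masks are rejected (0/0 is undefined; silently returning 1
#' would inflate averages on tumor-free cases).
#'
#' @param a,b [voi_mask()] objects or binary 3D arrays of equal shape.
#' @return Dice score in [0, 1].
#' @export
dice <- function(a, b) {
  if (inherits(a, "voi_mask")) a <- a$data
  if (inherits(b, "voi_mask")) b <- b$data
  if (!identical(dim(a), dim(b))) stop("mask shapes differ")
  na <- sum(a != 0); nb <- sum(b != 0)
  if (na + nb == 0)
    stop("Dice is undefined for two empty masks; handle tumor-free cases explicitly")
  2 * sum(a != 0 & b != 0) / (na + nb)
}

#' Tumor volume of a mask in milliliters
#'
#' @param mask a [voi_mask()] (spacing metadata in mm).
#' @return Nonzero voxel count times voxel volume (mm^3) / 1000.
#' @export
tumor_volume_ml <- function(mask) {
  stopifnot(inherits(mask, "voi_mask"))
  sum(mask$data != 0) * prod(mask$spacing) / 1000
}

.check_groups <- function(groups) {
  if (length(groups) < 2L) stop("at least two groups are required")
  for (i in seq_along(groups)) {
    g <- groups[[i]]
    if (length(g) < 2L)
      stop("group ", i, " has fewer than 2 values")
    if (stats::var(g) == 0)
      stop("group ", i, " has zero variance")
  }
}

#' Welch's heteroscedastic one-way ANOVA
#'
#' Robust to unequal variances and sample sizes.  Computed through
#' `stats::oneway.test(var.equal = FALSE)`; with two groups the F statistic
#' equals the square of the Welch t statistic.
#'
#' @param groups list of >= 2 numeric vectors, each with >= 2 values and
#'   nonzero variance.
#' @return list with `F`, `df1`, `df2`, `p`.
#' @export
welch_anova <- function(groups) {
  .check_groups(groups)
  y <- unlist(groups, use.names = FALSE)
  f <- factor(rep(seq_along(groups), lengths(groups)))
  res <- stats::oneway.test(y ~ f, var.equal = FALSE)
  list(F = unname(res$statistic), df1 = unname(res$parameter[1]),
       df2 = unname(res$parameter[2]), p = unname(res$p.value))
}

#' Games-Howell post-hoc pairwise comparison
#'
#' For each pair of groups, a studentized-range statistic on the Welch
#' standard error with Welch-Satterthwaite degrees of freedom; the adjusted
#' p-value comes from the studentized range distribution with `k` groups,
#' so multiplicity is controlled without assuming equal variances or sizes.
#'
#' @param groups named list of >= 2 numeric vectors (unnamed groups get
#'   `g1`, `g2`, ...).
#' @return data.frame with one row per pair: `group1`, `group2`, `diff`
#'   (mean difference, group2 - group1), `se`, `t`, `df`, `p_adj`.
#' @export
games_howell <- function(groups) {
  .check_groups(groups)
  k <- length(groups)
  nms <- names(groups)
  if (is.null(nms)) nms <- paste0("g", seq_len(k))
  m <- vapply(groups, mean, 0)
  v <- vapply(groups, stats::var, 0)
  n <- lengths(groups)
  pairs <- utils::combn(k, 2)
  out <- data.frame()
  for (c in seq_len(ncol(pairs))) {
    i <- pairs[1, c]; j <- pairs[2, c]
    se2 <- v[i] / n[i] + v[j] / n[j]
    se <- sqrt(se2)
    tstat <- abs(m[j] - m[i]) / se
    df <- se2^2 / ((v[i] / n[i])^2 / (n[i] - 1) + (v[j] / n[j])^2 / (n[j] - 1))
    p <- stats::ptukey(tstat * sqrt(2), nmeans = k, df = df, lower.tail = FALSE)
    out <- rbind(out, data.frame(group1 = nms[i], group2 = nms[j],
                                 diff = m[j] - m[i], se = se, t = tstat,
                                 df = df, p_adj = p))
  }
  out
}

#' Pearson product-moment correlation
#'
#' @param x,y numeric vectors of equal length >= 3 with nonzero variance.
#' @return Correlation coefficient in [-1, 1].
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("x and y must both have nonzero variance")
  stats::cor(x, y, method = "pearson")
}

#' Z-score histogram profile of a normalized volume against its VOI
#'
#' Summarizes, per channel, the distribution of Z-scored voxel values over
#' the in-brain support, plus the VOI-restricted histogram of one chosen
#' channel.  On easy cases the VOI sits at the right edge of the chosen
#' channel's histogram and occupies a visible fraction of it; hard cases
#' sit centrally.  Values beyond the outermost bin edges are clamped into
#' the edge bins so counts always sum to the support size.
#'
#' @param vol a Z-score normalized [volume4ch()].
#' @param voi a [voi_mask()] of matching shape.
#' @param channel channel index for the VOI-restricted histogram
#'   (default 2, T2).
#' @param breaks bin edges over Z (default 60 uniform bins on [-3, 3]).
#' @return An object of class `histogram_profile`: list with `breaks`,
#'   `counts` (support-wide, bins x 4 matrix), `voi_counts` (chosen
#'   channel), `channel`, `voi_fraction`, `voi_median_z` (NA for an empty
#'   VOI).
#' @export
histogram_profile <- function(vol, voi, channel = 2L,
                              breaks = seq(-3, 3, length.out = 61)) {
  stopifnot(inherits(vol, "volume4ch"), inherits(voi, "voi_mask"))
  if (!identical(dim(vol$data)[1:3], dim(voi$data)))
    stop("volume and VOI shapes differ")
  supp <- .support_mask(vol)
  clamp <- function(z) pmin(pmax(z, breaks[1]), breaks[length(breaks)])
  counts <- sapply(1:4, function(c) {
    z <- clamp(vol$data[, , , c][supp])
    hist(z, breaks = breaks, plot = FALSE)$counts
  })
  invoi <- voi$data != 0 & supp
  zv <- clamp(vol$data[, , , channel][invoi])
  voi_counts <- hist(zv, breaks = breaks, plot = FALSE)$counts
  structure(list(breaks = breaks, counts = counts, voi_counts = voi_counts,
                 channel = channel,
                 voi_fraction = sum(invoi) / sum(supp),
                 voi_median_z = if (sum(invoi)) median(vol$data[, , , channel][invoi]) else NA_real_),
            class = "histogram_profile")
}

#' Build one evaluation record
#'
#' @param case_id,facility_id,model_type,metadata_label strings;
#'   `model_type` one of `"source"`, `"target"`, `"finetuned"`.
#' @param dice Dice score in [0, 1].
#' @param tumor_volume_ml nonnegative tumor volume.
#' @return One-row data.frame.
#' @export
eval_record <- function(case_id, facility_id, model_type, dice,
                        tumor_volume_ml, metadata_label = "unspecified") {
  stopifnot(model_type %in% c("source", "target", "finetuned"),
            is.na(dice) || (dice >= 0 && dice <= 1), tumor_volume_ml >= 0)
  data.frame(case_id = case_id, facility_id = facility_id,
             model_type = model_type, dice = dice,
             tumor_volume_ml = tumor_volume_ml,
             metadata_label = metadata_label, stringsAsFactors = FALSE)
}

#' Aggregate evaluation records into mean +/- SD tables
#'
#' @param records data.frame of evaluation records (see [eval_record()]).
#' @param by grouping column: `"facility_id"`, `"model_type"` or
#'   `"metadata_label"` (optionally a character vector of several).
#' @return data.frame with group columns, `mean_dice`, `sd_dice` (sample
#'   SD; 0 for singleton groups), `n`, in stable (sorted) group order.
#' @export
aggregate_records <- function(records, by = "model_type") {
  stopifnot(nrow(records) > 0, all(by %in% names(records)))
  key <- interaction(records[by], drop = TRUE, lex.order = TRUE)
  idx <- split(seq_len(nrow(records)), key)
  rows <- lapply(idx, function(ii) {
    d <- records$dice[ii]
    cbind(records[ii[1], by, drop = FALSE],
          data.frame(mean_dice = mean(d),
                     sd_dice = if (length(d) > 1) sd(d) else 0,
                     n = length(d)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare model types with Welch ANOVA and Games-Howell
#'
#' Runs the omnibus Welch ANOVA across model types and the Games-Howell
#' pairwise post-hoc test.  `level = "case"` (default) compares per-case
#' Dice pooled across facilities; `level = "facility"` first averages per
#' facility and compares facility means.
#'
#' @param records data.frame of evaluation records.
#' @param level `"case"` or `"facility"`.
#' @return list with `welch` (see [welch_anova()]), `games_howell` (see
#'   [games_howell()]) and `groups` (the compared vectors).
#' @export
compare_models <- function(records, level = c("case", "facility")) {
  level <- match.arg(level)
  if (level == "facility") {
    agg <- aggregate_records(records, by = c("model_type", "facility_id"))
    groups <- split(agg$mean_dice, agg$model_type)
  } else {
    groups <- split(records$dice, records$model_type)
  }
  groups <- groups[order(names(groups))]
  list(welch = welch_anova(groups), games_howell = games_howell(groups),
       groups = groups)
}
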