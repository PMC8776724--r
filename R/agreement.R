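#' Dice overlap between two segmentations
#'
#' Dice = 2|A intersect B| / (|A| + |B|). Inputs must share grid shape and
#' affine; comparing masks from different spaces is a hard error, not a 0.
#'
#' @param a,b `liver_mask` or `segment_labels` objects.
#' @param code optional segment code/name: when given, the comparison is
#'   restricted to that label (e.g. `code = "4a"`).
#' @return a `dice_result`: dice, intersection_voxels, size_a, size_b.
#' @export
dice <- function(a, b, code = NULL) {
  ga <- a$grid; gb <- b$grid
  if (!identical(dim(ga), dim(gb)))
    cn_stop("grids have different shapes", "couinaud_shape_mismatch")
  if (max(abs(a$affine - b$affine)) > 1e-6)
    cn_stop("grids have different affines", "couinaud_affine_mismatch")
  if (!is.null(code)) {
    cd <- normalize_codes(code)
    if (length(cd) != 1) cn_stop("dice takes a single segment code",
                                 "couinaud_bad_input")
    ga <- ga == cd; gb <- gb == cd
  } else {
    ga <- ga != 0L; gb <- gb != 0L
  }
  sa <- sum(ga); sb <- sum(gb)
  if (sa + sb == 0) cn_stop("both selections are empty: Dice undefined",
                            "couinaud_empty_dice")
  inter <- sum(ga & gb)
  structure(list(dice = 2 * inter / (sa + sb),
                 intersection_voxels = inter, size_a = sa, size_b = sb),
            class = "dice_result")
}

#' @export
print.dice_result <- function(x, ...) {
  cat(sprintf("Dice %.4f  (|A| = %d, |B| = %d, |A∩B| = %d)\n",
              x$dice, x$size_a, x$size_b, x$intersection_voxels))
  invisible(x)
}

#' Bland-Altman agreement with 95% limits of agreement
#'
#' Differences are a - b (absolute mode) or 100 (a - b) / ((a + b)/2)
#' (percent mode, the standard Bland-Altman form for proportional
#' measurements). Bias is the mean difference, the SD uses the n - 1
#' denominator, and the 95% limits of agreement are bias +/- 1.96 SD (the
#' conventional multiplier, no small-sample t correction).
#'
#' @param a,b paired measurement vectors; alternatively `a` may be a data
#'   frame with columns `value_a` and `value_b` (and `b` omitted).
#' @param mode "absolute" or "percent".
#' @return a `bland_altman` object: n, bias, sd_diff, loa_low, loa_high,
#'   mode, plus the per-pair means and differences for plotting.
#' @examples
#' ba <- bland_altman(c(102, 100, 99), c(98, 100, 101), mode = "percent")
#' ba$bias       # 0.667
#' ba$loa_high   # 6.655
#' @export
bland_altman <- function(a, b = NULL, mode = c("absolute", "percent")) {
  mode <- match.arg(mode)
  if (is.data.frame(a)) {
    if (!all(c("value_a", "value_b") %in% names(a)))
      cn_stop("data frame input needs columns value_a and value_b",
              "couinaud_bad_pairs")
    b <- a$value_b; a <- a$value_a
  }
  if (length(a) != length(b))
    cn_stop("paired vectors have different lengths", "couinaud_bad_pairs")
  keep <- is.finite(a) & is.finite(b)
  a <- a[keep]; b <- b[keep]
  n <- length(a)
  if (n < 3) cn_stop(sprintf("need at least 3 pairs, got %d", n),
                     "couinaud_too_few_pairs")
  m <- (a + b) / 2
  if (mode == "percent") {
    if (any(m <= 0)) cn_stop("percent mode requires positive pair means",
                             "couinaud_nonpositive_mean")
    d <- 100 * (a - b) / m
  } else {
    d <- a - b
  }
  bias <- mean(d)
  sdd <- stats::sd(d)
  structure(list(n = n, bias = bias, sd_diff = sdd,
                 loa_low = bias - 1.96 * sdd, loa_high = bias + 1.96 * sdd,
                 mode = mode, means = m, differences = d),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  unit <- if (x$mode == "percent") "%" else ""
  cat(sprintf("Bland-Altman (%s mode), n = %d\n", x$mode, x$n))
  cat(sprintf("  bias %.4f%s, SD %.4f%s\n", x$bias, unit, x$sd_diff, unit))
  cat(sprintf("  95%% LOA [%.4f, %.4f]%s\n", x$loa_low, x$loa_high, unit))
  invisible(x)
}

#' Bland-Altman plot: pair means against differences, with bias (dashed) and
#' 95% LOA (dotted) lines; percent mode adds the +/-10% guide lines (green
#' dotted).
#' @param x a `bland_altman` object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.bland_altman <- function(x, ...) {
  ylab <- if (x$mode == "percent") "difference (% of pair mean)" else "difference"
  ylim <- range(c(x$differences, x$loa_low, x$loa_high,
                  if (x$mode == "percent") c(-10, 10)))
  graphics::plot(x$means, x$differences, xlab = "pair mean", ylab = ylab,
                 ylim = ylim, pch = 19, ...)
  graphics::abline(h = x$bias, lty = 2)
  graphics::abline(h = c(x$loa_low, x$loa_high), lty = 3)
  if (x$mode == "percent")
    graphics::abline(h = c(-10, 10), lty = 3, col = "darkgreen")
  invisible(x)
}

#' Recovery simulation for the Bland-Altman estimator
#'
#' Simulates `reps` paired datasets under the multiplicative Gaussian
#' difference model of [simulate_pairs()] (second reading low by
#' `bias_pct + noise` percent), runs [bland_altman()] in percent mode on
#' each, and summarizes recovered bias and LOA against the analytic Normal
#' values (bias, bias +/- 1.96 sd).
#'
#' @param bias_pct true mean percent difference between readings.
#' @param sd_pct true SD of the percent difference; must be >= 0.
#' @param n pairs per dataset (>= 3).
#' @param seed integer seed.
#' @param reps number of simulated datasets.
#' @return list with `truth` (analytic bias/LOA), `reps` (data frame of
#'   recovered bias, loa_low, loa_high per rep) and `mean_bias`,
#'   `mean_loa_low`, `mean_loa_high`.
#' @export
simulate_recovery <- function(bias_pct, sd_pct, n, seed = 1, reps = 1) {
  if (!is.numeric(sd_pct) || sd_pct < 0) cn_stop("sd_pct must be >= 0",
                                                 "couinaud_bad_input")
  if (n < 3) cn_stop("n must be at least 3", "couinaud_too_few_pairs")
  rows <- lapply(seq_len(reps), function(r) {
    pairs <- simulate_pairs(NULL, bias_pct, sd_pct, n, seed = seed + r - 1)
    ba <- bland_altman(pairs, mode = "percent")
    data.frame(rep = r, bias = ba$bias, loa_low = ba$loa_low,
               loa_high = ba$loa_high)
  })
  df <- do.call(rbind, rows)
  list(truth = list(bias = bias_pct,
                    loa_low = bias_pct - 1.96 * sd_pct,
                    loa_high = bias_pct + 1.96 * sd_pct),
       reps = df,
       mean_bias = mean(df$bias),
       mean_loa_low = mean(df$loa_low),
       mean_loa_high = mean(df$loa_high))
}
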