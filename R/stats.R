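#' Deviation ratio between measured and predicted pressure
#'
#' Prediction-error metric DRO = |P_rigid - P_LM| / P_rigid x 100 (%), where
#' `P_rigid` is the measured pressure on the rigid leg model and `P_LM` the
#' corresponding simulated value.
#'
#' @param P_rigid measured pressure (mmHg), > 0; vectorised.
#' @param P_LM predicted pressure (mmHg), >= 0.
#' @return deviation ratio (%).
#' @examples
#' dro(19.17, 18.02)  # 6.0 %
#' dro(19.92, 23.62)  # 18.6 %
#' @export
dro <- function(P_rigid, P_LM) {
  if (any(P_rigid <= 0)) stop("P_rigid must be > 0")
  abs(P_rigid - P_LM) / P_rigid * 100
}

#' Shapiro-Wilk normality test
#'
#' Normality screen appropriate for the small per-group sample sizes of
#' pressure studies (3 <= n <= 50). Thin wrapper over
#' [stats::shapiro.test()] that enforces the sample-size window and rejects
#' zero-variance input.
#'
#' @param x numeric sample.
#' @return list with `W` and `p`.
#' @export
shapiro_wilk <- function(x) {
  n <- length(x)
  if (n < 3 || n > 50) stop("Shapiro-Wilk used here for 3 <= n <= 50, got n = ", n)
  if (stats::sd(x) == 0) stop("constant sample: zero variance")
  st <- stats::shapiro.test(x)
  list(W = unname(st$statistic), p = st$p.value)
}

#' Pearson correlation with two-sided test
#'
#' @param x,y numeric samples of equal length >= 3, non-constant.
#' @return list with `r` and `p` (two-sided).
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant input")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Paired t tests with Bonferroni correction
#'
#' Runs a two-sided paired t test per comparison and adjusts the p-values by
#' the number of comparisons actually run (p_adj = min(1, m p_raw)).
#'
#' @param groups named list of comparisons, each a list/data frame with
#'   equal-length numeric vectors `x` and `y` (paired samples, n >= 3).
#' @param alpha significance level on the adjusted p, default 0.05.
#' @return data frame with one row per comparison: `comparison`, `n`, `t`,
#'   `df`, `p_raw`, `p_adj`, `significant`.
#' @examples
#' g <- list(AB = list(x = c(18, 20, 22, 19), y = c(19, 21, 21, 20)))
#' paired_t_bonferroni(g)
#' @export
paired_t_bonferroni <- function(groups, alpha = 0.05) {
  stopifnot(is.list(groups), length(groups) >= 1)
  m <- length(groups)
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("cmp", seq_len(m))
  rows <- lapply(names(groups), function(nm) {
    g <- groups[[nm]]
    if (length(g$x) != length(g$y))
      stop("comparison '", nm, "': unequal pair lengths")
    if (length(g$x) < 3) stop("comparison '", nm, "': need n >= 3 pairs")
    d <- g$x - g$y
    if (stats::sd(d) == 0) {
      # identical pairs: t = 0 by convention, certainly not significant
      tt <- list(statistic = c(t = 0), parameter = c(df = length(d) - 1),
                 p.value = 1)
    } else {
      tt <- stats::t.test(g$x, g$y, paired = TRUE)
    }
    data.frame(comparison = nm, n = length(g$x),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p_raw = tt$p.value, p_adj = min(1, tt$p.value * m))
  })
  out <- do.call(rbind, rows)
  out$significant <- out$p_adj < alpha
  out
}

#' Pairwise stiffness-group comparison of pressure sets
#'
#' Convenience wrapper building all pairwise paired comparisons between the
#' columns of a pressure matrix (one column per tissue-stiffness group, one
#' row per garment/position case) and running [paired_t_bonferroni()].
#'
#' @param pressure_matrix numeric matrix or data frame, >= 2 columns.
#' @param alpha significance level.
#' @return the [paired_t_bonferroni()] table.
#' @export
stiffness_group_tests <- function(pressure_matrix, alpha = 0.05) {
  pm <- as.matrix(pressure_matrix)
  if (ncol(pm) < 2) stop("need at least two stiffness groups")
  if (is.null(colnames(pm))) colnames(pm) <- paste0("G", seq_len(ncol(pm)))
  cmb <- utils::combn(ncol(pm), 2)
  groups <- lapply(seq_len(ncol(cmb)), function(j)
    list(x = pm[, cmb[1, j]], y = pm[, cmb[2, j]]))
  names(groups) <- apply(cmb, 2, function(ij)
    paste(colnames(pm)[ij], collapse = " vs "))
  paired_t_bonferroni(groups, alpha = alpha)
}

#' Stiffness-group measurement experiment on matched true pressures
#'
#' Emulates comparing garment pressures measured on legs of different tissue
#' stiffness when the delivered pressure is stiffness-independent (the Hertz
#' pressure-diversity identity): every group reads the same true pressures
#' through an independent +/-3 mmHg meter, and the groups are compared by
#' pairwise paired t tests with Bonferroni correction. Under this matched
#' null, significant differences arise only at the test's error rate.
#'
#' @param P_true true delivered pressures (mmHg), one per garment/position
#'   case; replicated `repeats` times to form the per-group sample.
#' @param levels group names, default `c("LS1", "LS2", "LS3")`.
#' @param repeats measurement repeats per case, default 4.
#' @param seed integer seed (one independent meter per group).
#' @param alpha significance level.
#' @return list with `table` (the [paired_t_bonferroni()] table), `n` per
#'   group and `any_significant`.
#' @export
stiffness_noise_experiment <- function(P_true, levels = c("LS1", "LS2", "LS3"),
                                       repeats = 4, seed = 1, alpha = 0.05) {
  stopifnot(length(P_true) >= 1, repeats >= 1, length(levels) >= 2)
  truths <- rep(P_true, repeats)
  mat <- vapply(seq_along(levels), function(g)
    simulate_picopress(truths, seed = derive_seed(seed, "group", levels[g])),
    numeric(length(truths)))
  colnames(mat) <- levels
  tab <- stiffness_group_tests(mat, alpha = alpha)
  list(table = tab, n = length(truths), any_significant = any(tab$significant))
}
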