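#' Area under the ROC curve with bootstrap confidence interval
#'
#' The AUC is the Mann-Whitney statistic normalized by
#' `n_cases * n_controls` (midranks, so ties count one half), i.e. the
#' probability that a random case outscores a random control. The 95%
#' confidence interval comes from a seeded stratified bootstrap (cases and
#' controls resampled separately). The ROC itself is the exact step
#' function over all unique score thresholds.
#'
#' @param scores numeric score vector.
#' @param labels binary labels (1 = case, 0 = control); both classes must
#'   be present.
#' @param ci compute the bootstrap interval.
#' @param n_boot bootstrap resamples (default 2,000).
#' @param seed seed for the bootstrap.
#' @return An object of class `auc_est`: `auc`, `ci_low`, `ci_high`,
#'   `n_case`, `n_control` and `roc` (data frame of `fpr`, `tpr`).
#' @export
auc <- function(scores, labels, ci = TRUE, n_boot = 2000, seed = 1) {
  if (inherits(labels, "phenotype_set")) labels <- labels$label
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  point <- function(s, l) {
    r <- rank(s)
    (sum(r[l == 1]) - sum(l == 1) * (sum(l == 1) + 1) / 2) /
      (sum(l == 1) * sum(l == 0))
  }
  a <- point(scores, labels)
  lo <- hi <- NA_real_
  if (ci) {
    set.seed(seed)
    ic <- which(labels == 1); ik <- which(labels == 0)
    boot <- vapply(seq_len(n_boot), function(b) {
      idx <- c(sample(ic, n1, replace = TRUE),
               sample(ik, n0, replace = TRUE))
      point(scores[idx], labels[idx])
    }, numeric(1))
    q <- quantile(boot, c(0.025, 0.975), names = FALSE)
    lo <- q[1]; hi <- q[2]
  }
  th <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(th, function(t) mean(scores[labels == 1] >= t), numeric(1))
  fpr <- vapply(th, function(t) mean(scores[labels == 0] >= t), numeric(1))
  structure(list(auc = a, ci_low = lo, ci_high = hi,
                 n_case = n1, n_control = n0,
                 roc = data.frame(fpr = c(0, fpr, 1), tpr = c(0, tpr, 1))),
            class = "auc_est")
}

#' @export
print.auc_est <- function(x, ...) {
  cat(sprintf("AUC = %.4f", x$auc))
  if (!is.na(x$ci_low))
    cat(sprintf(" (95%% CI %.4f-%.4f)", x$ci_low, x$ci_high))
  cat(sprintf(" [%d cases, %d controls]\n", x$n_case, x$n_control))
  invisible(x)
}

#' Pearson correlation between two score vectors
#'
#' @param scores_a,scores_b aligned per-individual scores (n >= 3).
#' @return named vector `c(r =, r2 =)`, both `NA_real_` when either vector
#'   is constant (undefined).
#' @export
score_correlation <- function(scores_a, scores_b) {
  stopifnot(length(scores_a) == length(scores_b), length(scores_a) >= 3)
  if (sd(scores_a) == 0 || sd(scores_b) == 0)
    return(c(r = NA_real_, r2 = NA_real_))
  r <- cor(scores_a, scores_b)
  c(r = r, r2 = r^2)
}

#' Case/control score distribution summary
#'
#' Group means and shared-bin densities suitable for a case-vs-control
#' score distribution plot. The sign of the case-minus-control shift is
#' reported, not assumed.
#'
#' @param scores numeric score vector.
#' @param labels binary labels (both classes present) or a `phenotype_set`.
#' @param n_bins number of shared histogram bins.
#' @return An object of class `group_summary`: `mean_case`, `mean_control`,
#'   `shift` (case minus control), and `density` (data frame of bin `mid`,
#'   `case`, `control` densities).
#' @export
group_summary <- function(scores, labels, n_bins = 30) {
  if (inherits(labels, "phenotype_set")) labels <- labels$label
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  if (!any(labels == 1) || !any(labels == 0))
    stop("both classes must be present")
  brk <- seq(min(scores), max(scores), length.out = n_bins + 1)
  if (brk[1] == brk[length(brk)]) brk <- brk[1] + c(-0.5, 0.5)
  dens <- function(x) {
    h <- graphics::hist(x, breaks = brk, plot = FALSE)
    h$density
  }
  mids <- (brk[-1] + brk[-length(brk)]) / 2
  structure(list(mean_case = mean(scores[labels == 1]),
                 mean_control = mean(scores[labels == 0]),
                 shift = mean(scores[labels == 1]) -
                   mean(scores[labels == 0]),
                 density = data.frame(mid = mids,
                                      case = dens(scores[labels == 1]),
                                      control = dens(scores[labels == 0]))),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf(
    "Score distributions: case mean %.4f, control mean %.4f (shift %+.4f)\n",
    x$mean_case, x$mean_control, x$shift))
  invisible(x)
}

#' Density plot of case and control score distributions
#' @param x a `group_summary`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.group_summary <- function(x, ...) {
  graphics::matplot(x$density$mid, cbind(x$density$case, x$density$control),
                    type = "l", lty = 1, col = c("firebrick", "seagreen"),
                    xlab = "polygenic risk score", ylab = "density", ...)
  graphics::abline(v = c(x$mean_case, x$mean_control), lty = 2,
                   col = c("firebrick", "seagreen"))
  graphics::legend("topright", c("cases", "controls"), lty = 1,
                   col = c("firebrick", "seagreen"), bty = "n")
  invisible(x)
}
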