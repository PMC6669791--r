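#' Per-case, per-organ cohort evaluation
#'
#' Computes Dice, directed RMS surface distance (prediction to ground
#' truth), symmetrised mean surface distance and Hausdorff distance for
#' every matched case and organ. A case is excluded per organ — never
#' wholly — when either mask is empty (for instance when a model fails to
#' produce a structure); exclusions are always listed explicitly with a
#' reason. Summary statistics report the median per organ (robust: a
#' single failing segmentation can deteriorate a mean substantially) with
#' the mean alongside for comparability.
#'
#' @param predictions,ground_truth named lists of [structure_set]s keyed
#'   by case id; ids must match.
#' @return A `metrics_report`: data frame with columns case, organ, dice,
#'   rms_surface_mm, mean_surface_mm, hausdorff_mm, excluded, reason;
#'   the per-organ summary is available via [summary.metrics_report()].
#' @export
evaluate_cohort <- function(predictions, ground_truth) {
  ids <- names(predictions)
  if (is.null(ids) || !setequal(ids, names(ground_truth)))
    stop("case ids of predictions and ground truth do not match",
         call. = FALSE)
  rows <- list()
  for (id in ids) {
    ps <- predictions[[id]]; gs <- ground_truth[[id]]
    for (organ in names(gs$masks)) {
      pm <- ps$masks[[organ]]
      gm <- gs$masks[[organ]]
      if (is.null(pm)) {
        rows[[length(rows) + 1]] <- data.frame(
          case = id, organ = organ, dice = NA_real_,
          rms_surface_mm = NA_real_, mean_surface_mm = NA_real_,
          hausdorff_mm = NA_real_, excluded = TRUE,
          reason = "missing prediction")
        next
      }
      empty_p <- sum(pm) == 0
      empty_g <- sum(gm) == 0
      if (empty_p || empty_g) {
        rows[[length(rows) + 1]] <- data.frame(
          case = id, organ = organ, dice = NA_real_,
          rms_surface_mm = NA_real_, mean_surface_mm = NA_real_,
          hausdorff_mm = NA_real_, excluded = TRUE,
          reason = if (empty_p) "empty prediction" else "empty ground truth")
        next
      }
      sp_p <- surface_points(pm, spacing = ps$spacing, origin = ps$origin)
      sp_g <- surface_points(gm, spacing = gs$spacing, origin = gs$origin)
      rows[[length(rows) + 1]] <- data.frame(
        case = id, organ = organ,
        dice = dice_coefficient(pm, gm),
        rms_surface_mm = rms_surface_distance(sp_p, sp_g),
        mean_surface_mm = symmetric_mean_surface_distance(sp_p, sp_g),
        hausdorff_mm = hausdorff_distance(sp_p, sp_g),
        excluded = FALSE, reason = "")
    }
  }
  rep_df <- do.call(rbind, rows)
  class(rep_df) <- c("metrics_report", class(rep_df))
  rep_df
}

#' @export
summary.metrics_report <- function(object, ...) {
  ok <- object[!object$excluded, , drop = FALSE]
  out <- do.call(rbind, lapply(split(ok, ok$organ), function(d) data.frame(
    organ = d$organ[1], n = nrow(d),
    median_dice = median(d$dice), mean_dice = mean(d$dice),
    median_rms_mm = median(d$rms_surface_mm),
    median_hausdorff_mm = median(d$hausdorff_mm),
    excluded = sum(object$excluded[object$organ == d$organ[1]]))))
  rownames(out) <- NULL
  out
}

#' Paired two-tailed t test between two matched score lists
#'
#' Classical paired t on the differences with `n - 1` degrees of freedom.
#' When all differences are zero the statistic is undefined and a flagged
#' degenerate result is returned instead of a number.
#'
#' @param a,b numeric vectors of equal length >= 2 (matched per case).
#' @return List with `t`, `p` (two-tailed), `df`, `mean_diff` and
#'   `degenerate`.
#' @export
paired_t_test <- function(a, b) {
  if (length(a) != length(b) || length(a) < 2)
    stop("need two equal-length vectors of length >= 2", call. = FALSE)
  d <- a - b
  if (all(d == 0) || sd(d) == 0)
    return(list(t = NA_real_, p = NA_real_, df = length(d) - 1L,
                mean_diff = mean(d), degenerate = TRUE))
  ht <- t.test(a, b, paired = TRUE, alternative = "two.sided")
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter), mean_diff = mean(d), degenerate = FALSE)
}

#' Bonferroni-adjusted significance level
#'
#' `alpha / m` for `m` comparisons; with the conventional 5% level and
#' three model pairs this gives 0.05 / 3 = 0.0167.
#'
#' @param alpha nominal significance level in (0, 1).
#' @param m number of comparisons (>= 1).
#' @return The adjusted level.
#' @examples
#' bonferroni_alpha(0.05, 3)
#' @export
bonferroni_alpha <- function(alpha, m) {
  if (m < 1) stop("`m` must be >= 1", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0, 1)",
                                     call. = FALSE)
  alpha / m
}

#' Compare two evaluation reports with paired t tests
#'
#' For every organ present in both reports, runs paired two-tailed t tests
#' on Dice and on RMS surface distance over the cases scored in both, and
#' reports raw p-values alongside the Bonferroni-adjusted significance
#' level.
#'
#' @param report_a,report_b `metrics_report` data frames from
#'   [evaluate_cohort()].
#' @param alpha nominal level; @param m number of comparisons for the
#'   Bonferroni adjustment (defaults to the number of organs).
#' @return Data frame with one row per organ and metric.
#' @export
compare_models <- function(report_a, report_b, alpha = 0.05, m = NULL) {
  organs <- intersect(unique(report_a$organ), unique(report_b$organ))
  if (is.null(m)) m <- length(organs)
  athr <- bonferroni_alpha(alpha, m)
  rows <- list()
  for (organ in organs) {
    for (metric in c("dice", "rms_surface_mm")) {
      da <- report_a[report_a$organ == organ & !report_a$excluded, ]
      db <- report_b[report_b$organ == organ & !report_b$excluded, ]
      common <- intersect(da$case, db$case)
      va <- da[[metric]][match(common, da$case)]
      vb <- db[[metric]][match(common, db$case)]
      tt <- paired_t_test(va, vb)
      rows[[length(rows) + 1]] <- data.frame(
        organ = organ, metric = metric, n = length(common),
        t = tt$t, p = tt$p, alpha_adjusted = athr,
        significant = !tt$degenerate && !is.na(tt$p) && tt$p < athr)
    }
  }
  do.call(rbind, rows)
}
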