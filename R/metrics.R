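# Agreement statistics for validating automated against manual TMTV:
# voxel-overlap metrics per case, and cohort-level correlation / agreement
# analyses over per-case TMTV values.

mask_values <- function(x) if (inherits(x, "binary_mask")) x$values else x

check_pair <- function(a, b) {
  av <- mask_values(a); bv <- mask_values(b)
  if (!identical(dim(av), dim(bv))) stop("masks are not on the same grid")
  list(a = as.logical(av), b = as.logical(bv))
}

#' Dice similarity coefficient
#'
#' 2|A n B| / (|A| + |B|). Two empty masks agree perfectly on the absence
#' of disease and score 1; empty vs non-empty scores 0.
#'
#' @param a,b [binary_mask()]s or logical arrays on one grid.
#' @return Dice in \[0, 1\].
#' @export
dice <- function(a, b) {
  p <- check_pair(a, b)
  sa <- sum(p$a); sb <- sum(p$b)
  if (sa + sb == 0) return(1)
  2 * sum(p$a & p$b) / (sa + sb)
}

#' Jaccard coefficient
#'
#' |A n B| / |A u B|; equals dice / (2 - dice). Empty vs empty is 1.
#'
#' @inheritParams dice
#' @return Jaccard in \[0, 1\].
#' @export
jaccard <- function(a, b) {
  p <- check_pair(a, b)
  u <- sum(p$a | p$b)
  if (u == 0) return(1)
  sum(p$a & p$b) / u
}

#' Voxel-level confusion metrics
#'
#' Sensitivity, specificity, positive and negative predictive value of a
#' predicted mask against truth, counted over all voxels. A ratio with a
#' zero denominator (e.g. PPV for an empty prediction) is reported as `NA`,
#' not 0.
#'
#' @param pred,truth [binary_mask()]s or logical arrays on one grid.
#' @return List with `dice`, `jaccard`, `se`, `sp`, `ppv`, `npv` and the
#'   raw counts `tp`, `tn`, `fp`, `fn`.
#' @export
confusion_metrics <- function(pred, truth) {
  p <- check_pair(pred, truth)
  tp <- sum(p$a & p$b); fp <- sum(p$a & !p$b)
  fn <- sum(!p$a & p$b); tn <- sum(!p$a & !p$b)
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  list(dice = dice(pred, truth), jaccard = jaccard(pred, truth),
       se = ratio(tp, tp + fn), sp = ratio(tn, tn + fp),
       ppv = ratio(tp, tp + fp), npv = ratio(tn, tn + fn),
       tp = tp, tn = tn, fp = fp, fn = fn)
}

#' Bland-Altman agreement
#'
#' Differences d = x - y; bias = mean(d), limits of agreement
#' bias +/- 1.96 * sd(d) with the sample (n-1) standard deviation.
#'
#' @param x,y Paired measurements (e.g. manual and predicted TMTV, mL).
#' @return List with `bias`, `loa_low`, `loa_high`, `sd_diff`, `n`.
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  if (length(x) < 2) stop("need at least 2 pairs")
  d <- x - y
  bias <- mean(d)
  s <- sd(d)
  list(bias = bias, loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
       sd_diff = s, n = length(d))
}

#' Spearman rank correlation
#'
#' Pearson correlation of ranks (average ranks on ties) with a two-sided
#' p-value. Constant input has no defined rank correlation and returns
#' `NA` for both.
#'
#' @param x,y Paired numeric vectors, length >= 3.
#' @return List with `r` and `p`.
#' @export
spearman <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  if (length(x) < 3) stop("need at least 3 pairs")
  if (sd(x) == 0 || sd(y) == 0) return(list(r = NA_real_, p = NA_real_))
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Paired Student's t-test p-value
#'
#' Two-sided paired t-test on per-case measurements. Identical vectors
#' (zero differences throughout) have t = 0 and p = 1.
#'
#' @param x,y Paired numeric vectors, length >= 2.
#' @return Two-sided p-value.
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  d <- x - y
  if (sd(d) == 0) return(if (mean(d) == 0) 1 else 0)  # t = 0 or +/-Inf
  t.test(x, y, paired = TRUE)$p.value
}

dist_stats <- function(v) {
  c(max = max(v), min = min(v), mean = mean(v), median = median(v), sd = sd(v))
}

#' Cohort-level agreement report
#'
#' Aggregates per-case agreement between manual and predicted TMTV into
#' the validation tables: per methodology (and optionally per lymphoma
#' subtype) the dice distribution, the TMTV distribution of both arms
#' (max/min/mean/median/sd), Spearman correlation, Bland-Altman bias and
#' limits of agreement, and the paired t-test p-value. Cases missing a
#' methodology are excluded from that methodology's rows.
#'
#' @param cases A data.frame with one row per case and methodology:
#'   columns `case`, `method`, `tmtv_manual`, `tmtv_pred`, `dice`, and
#'   optionally `subtype`.
#' @param alpha Significance level separating "NS" from significant.
#' @return An object of class `agreement_report`: list with `per_method`
#'   (data.frame), `per_subtype` (data.frame or NULL) and `cases`.
#' @export
cohort_report <- function(cases, alpha = 0.05) {
  needed <- c("case", "method", "tmtv_manual", "tmtv_pred", "dice")
  if (!all(needed %in% names(cases)))
    stop("`cases` must have columns ", paste(needed, collapse = ", "))
  cases <- cases[stats::complete.cases(cases[needed]), , drop = FALSE]

  summarize <- function(df) {
    man <- dist_stats(df$tmtv_manual); prd <- dist_stats(df$tmtv_pred)
    sp <- if (nrow(df) >= 3) spearman(df$tmtv_manual, df$tmtv_pred)
          else list(r = NA_real_, p = NA_real_)
    ba <- if (nrow(df) >= 2) bland_altman(df$tmtv_manual, df$tmtv_pred)
          else list(bias = NA_real_, loa_low = NA_real_, loa_high = NA_real_)
    tp <- if (nrow(df) >= 2) paired_t(df$tmtv_manual, df$tmtv_pred) else NA_real_
    data.frame(
      n = nrow(df),
      dice_median = median(df$dice), dice_mean = mean(df$dice),
      dice_sd = if (nrow(df) > 1) sd(df$dice) else NA_real_,
      tmtv_manual_median = man[["median"]], tmtv_manual_mean = man[["mean"]],
      tmtv_manual_sd = man[["sd"]],
      tmtv_pred_median = prd[["median"]], tmtv_pred_mean = prd[["mean"]],
      tmtv_pred_sd = prd[["sd"]],
      spearman_r = sp$r, spearman_p = sp$p,
      ba_bias = ba$bias, ba_loa_low = ba$loa_low, ba_loa_high = ba$loa_high,
      t_p = tp, significant = !is.na(tp) & tp < alpha)
  }

  per_method <- do.call(rbind, lapply(split(cases, cases$method), summarize))
  per_method <- cbind(method = rownames(per_method), per_method)
  rownames(per_method) <- NULL

  per_subtype <- NULL
  if ("subtype" %in% names(cases)) {
    key <- interaction(cases$subtype, cases$method, drop = TRUE, sep = " / ")
    per_subtype <- do.call(rbind, lapply(split(cases, key), summarize))
    per_subtype <- cbind(group = rownames(per_subtype), per_subtype)
    rownames(per_subtype) <- NULL
  }

  structure(list(per_method = per_method, per_subtype = per_subtype,
                 cases = cases, alpha = alpha),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat("<agreement_report>", length(unique(x$cases$case)), "case(s),",
      nrow(x$per_method), "methodology row(s)\n")
  cols <- c("method", "n", "dice_median", "spearman_r", "ba_bias", "t_p")
  print(x$per_method[, cols], digits = 3)
  invisible(x)
}

#' Write an agreement report as CSV and JSON
#'
#' @param report An `agreement_report`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_agreement_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$per_method, file.path(dir, "per_method.csv"),
                   row.names = FALSE)
  if (!is.null(report$per_subtype))
    utils::write.csv(report$per_subtype, file.path(dir, "per_subtype.csv"),
                     row.names = FALSE)
  jsonlite::write_json(report[c("per_method", "per_subtype")],
                       file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}
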