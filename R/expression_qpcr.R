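# qPCR expression analysis: 16S-normalized relative expression, paired
# HS_C/Blank fold ratios, normality-routed paired testing, BH-FDR.

#' 16S-normalized relative expression from a Ct pair
#'
#' expression = efficiency^(Ct_reference - Ct_target), the delta-Ct form with
#' the 16S rRNA gene as internal reference. Default efficiency 2 (perfect
#' doubling per cycle); per-gene efficiencies may be supplied.
#'
#' @param ct_target target-gene Ct (cycles, in (0, 45))
#' @param ct_reference 16S reference Ct (cycles)
#' @param efficiency amplification factor per cycle, in (1, 2.2]
#' @return relative expression (dimensionless, > 0)
#' @export
relative_expression <- function(ct_target, ct_reference, efficiency = 2) {
  if (any(ct_target <= 0) || any(ct_target >= 45) ||
      any(ct_reference <= 0) || any(ct_reference >= 45)) {
    stop("Ct values must lie in (0, 45) cycles", call. = FALSE)
  }
  if (any(efficiency <= 1) || any(efficiency > 2.2)) {
    stop("efficiency must lie in (1, 2.2]", call. = FALSE)
  }
  efficiency^(ct_reference - ct_target)
}

#' Treatment/control fold ratio across matched pairs
#'
#' Per matched pair, the ratio of treatment to control expression; summarized
#' across pairs with the geometric mean (ratios are multiplicative), with the
#' arithmetic mean available behind `summary`. Pairs missing either partner
#' are dropped with a message.
#'
#' @param expression numeric expression values
#' @param group "Blank" or "HS_C" (or any two labels; `treatment` and
#'   `control` name which is which)
#' @param pair_id pair identifiers matching treatment to control
#' @param treatment,control group labels
#' @param summary "geometric" or "arithmetic"
#' @return list with `ratios` (named per pair), `summary_ratio`, `n_pairs`,
#'   `dropped_pairs`
#' @export
treatment_ratio <- function(expression, group, pair_id,
                            treatment = "HS_C", control = "Blank",
                            summary = c("geometric", "arithmetic")) {
  summary <- match.arg(summary)
  stopifnot(length(expression) == length(group),
            length(expression) == length(pair_id))
  ids <- unique(pair_id)
  ratios <- c()
  dropped <- character(0)
  for (id in ids) {
    tr <- expression[pair_id == id & group == treatment]
    ct <- expression[pair_id == id & group == control]
    if (length(tr) != 1L || length(ct) != 1L || ct == 0) {
      dropped <- c(dropped, as.character(id))
      next
    }
    ratios[as.character(id)] <- tr / ct
  }
  if (length(dropped)) {
    message("treatment_ratio: dropped ", length(dropped),
            " pair(s) missing a partner: ", paste(dropped, collapse = ", "))
  }
  sr <- if (length(ratios) == 0) NA_real_
        else if (summary == "geometric") exp(mean(log(ratios)))
        else mean(ratios)
  list(ratios = ratios, summary_ratio = sr, n_pairs = length(ratios),
       dropped_pairs = dropped)
}

#' Ratio of two fold-ratios
#'
#' Compares the enhancement of one gene against another, e.g. the nosZII
#' fold-ratio relative to the nosZI fold-ratio.
#'
#' @param ratio_a,ratio_b summary fold ratios (> 0)
#' @return ratio_a / ratio_b
#' @export
ratio_of_ratios <- function(ratio_a, ratio_b) {
  if (any(ratio_a <= 0) || any(ratio_b <= 0)) {
    stop("fold ratios must be > 0", call. = FALSE)
  }
  ratio_a / ratio_b
}

#' Normality-routed paired test
#'
#' Shapiro-Wilk on the paired differences at `alpha` routes to a paired
#' t-test (normal) or a Wilcoxon matched-pairs signed-rank test (otherwise);
#' the path taken is reported. All-zero differences are degenerate and
#' flagged.
#'
#' @param values_a,values_b equal-length paired vectors, n >= 3
#' @param alpha Shapiro-Wilk routing threshold
#' @return list with `test` ("paired t-test", "wilcoxon signed-rank" or
#'   "degenerate"), `statistic`, `p_value`, `shapiro_p`, `flags`
#' @export
paired_test <- function(values_a, values_b, alpha = 0.05) {
  stopifnot(length(values_a) == length(values_b))
  if (length(values_a) < 3) stop("need n >= 3 pairs", call. = FALSE)
  d <- values_a - values_b
  if (all(d == 0)) {
    return(list(test = "degenerate", statistic = NA_real_,
                p_value = NA_real_, shapiro_p = NA_real_,
                flags = "all_differences_zero"))
  }
  sw <- if (stats::sd(d) == 0) list(p.value = 0)
        else stats::shapiro.test(d)
  if (sw$p.value >= alpha) {
    tt <- stats::t.test(values_a, values_b, paired = TRUE)
    list(test = "paired t-test", statistic = unname(tt$statistic),
         p_value = tt$p.value, shapiro_p = sw$p.value, flags = character(0))
  } else {
    wt <- suppressWarnings(stats::wilcox.test(values_a, values_b,
                                              paired = TRUE))
    list(test = "wilcoxon signed-rank", statistic = unname(wt$statistic),
         p_value = wt$p.value, shapiro_p = sw$p.value, flags = character(0))
  }
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment across a test family (delegates to
#' [stats::p.adjust()]).
#'
#' @param pvalues p-values in `[0, 1]`
#' @return q-values, same order as input
#' @export
bh_fdr <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Full expression analysis of a Ct table
#'
#' For each target gene: per-record relative expression, the paired
#' HS_C/Blank fold ratio, a normality-routed paired test on log expression,
#' then BH-FDR across the gene family.
#'
#' @param ct_table data.frame with columns `target_gene`, `ct_target`,
#'   `ct_reference`, `group`, `pair_id`, optionally `efficiency`
#' @param treatment,control group labels
#' @return data.frame, one row per gene: `gene`, `fold_ratio`, `test`,
#'   `statistic`, `p_value`, `q_value`, `n_pairs`
#' @export
qpcr_gene_table <- function(ct_table, treatment = "HS_C", control = "Blank") {
  need <- c("target_gene", "ct_target", "ct_reference", "group", "pair_id")
  if (!all(need %in% names(ct_table))) {
    stop("ct_table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  eff <- if ("efficiency" %in% names(ct_table)) ct_table$efficiency else 2
  ct_table$expression <- relative_expression(ct_table$ct_target,
                                             ct_table$ct_reference, eff)
  genes <- unique(ct_table$target_gene)
  rows <- lapply(genes, function(g) {
    sub <- ct_table[ct_table$target_gene == g, ]
    tr <- treatment_ratio(sub$expression, sub$group, sub$pair_id,
                          treatment, control)
    ids <- names(tr$ratios)
    a <- vapply(ids, function(id)
      log(sub$expression[sub$pair_id == id & sub$group == treatment][1]),
      numeric(1))
    b <- vapply(ids, function(id)
      log(sub$expression[sub$pair_id == id & sub$group == control][1]),
      numeric(1))
    tst <- if (length(ids) >= 3) paired_test(a, b)
           else list(test = "insufficient pairs", statistic = NA_real_,
                     p_value = NA_real_)
    data.frame(gene = g, fold_ratio = tr$summary_ratio, test = tst$test,
               statistic = tst$statistic, p_value = tst$p_value,
               n_pairs = tr$n_pairs)
  })
  out <- do.call(rbind, rows)
  out$q_value <- bh_fdr(out$p_value)
  out
}
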