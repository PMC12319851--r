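#' Group comparison of normalised cluster sizes
#'
#' One-way ANOVA per cluster of per-subject normalised cluster sizes across
#' groups (e.g. HC vs RRMS vs ProgMS). No multiple-testing correction is
#' applied across clusters by default; `p_adjust = "bonferroni"` is
#' available.
#'
#' @param sizes numeric matrix or data frame, subjects x clusters, of
#'   normalised cluster sizes.
#' @param groups factor or character vector of group labels per subject
#'   (>= 2 groups, each with >= 2 subjects).
#' @param p_adjust `"none"` (default) or any method of [stats::p.adjust()].
#' @return Data frame with one row per cluster: `cluster`, `F`, `df1`,
#'   `df2`, `p` (and `p_adj` if requested).
#' @export
anova_cluster_sizes <- function(sizes, groups, p_adjust = "none") {
  sizes <- as.matrix(sizes)
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need at least two groups")
  if (any(table(groups) < 2L)) stop("each group needs at least two subjects")
  if (nrow(sizes) != length(groups))
    stop("rows of 'sizes' must match length of 'groups'")
  out <- do.call(rbind, lapply(seq_len(ncol(sizes)), function(k) {
    fit <- stats::aov(sizes[, k] ~ groups)
    tab <- summary(fit)[[1L]]
    data.frame(cluster = k, F = tab[1L, "F value"],
               df1 = as.integer(tab[1L, "Df"]),
               df2 = as.integer(tab[2L, "Df"]),
               p = tab[1L, "Pr(>F)"])
  }))
  if (!identical(p_adjust, "none"))
    out$p_adj <- stats::p.adjust(out$p, method = p_adjust)
  out
}

#' Tukey HSD post-hoc pairwise comparisons
#'
#' All pairwise group differences with simultaneous 95% confidence
#' intervals and family-wise adjusted p-values; intended for clusters whose
#' ANOVA is significant at `alpha`.
#'
#' @param values numeric vector (e.g. normalised sizes of one cluster).
#' @param groups group labels, same length.
#' @param conf_level confidence level (default 0.95).
#' @return Data frame with `comparison`, `difference`, `lower`, `upper`,
#'   `p_adj`.
#' @export
tukey_posthoc <- function(values, groups, conf_level = 0.95) {
  groups <- factor(groups)
  fit <- stats::aov(values ~ groups)
  tk <- stats::TukeyHSD(fit, conf.level = conf_level)$groups
  data.frame(comparison = rownames(tk),
             difference = tk[, "diff"],
             lower = tk[, "lwr"], upper = tk[, "upr"],
             p_adj = tk[, "p adj"], row.names = NULL)
}

#' Welch two-sample t-test on severity scores
#'
#' Unpaired two-sided Welch test (Satterthwaite degrees of freedom) for
#' comparing severity scores between two phenotypes with unequal variances
#' and sample sizes.
#'
#' @param x,y numeric vectors of severity scores (>= 2 each).
#' @return List with `t`, `df`, `p`, `mean_x`, `mean_y`.
#' @export
welch_severity <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L)
    stop("need at least two scores per group")
  ht <- stats::t.test(x, y, var.equal = FALSE, alternative = "two.sided")
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, mean_x = mean(x), mean_y = mean(y))
}

#' Spearman correlation of severity with clinical scores
#'
#' Rank correlation (average ranks for ties, two-sided p from the
#' t approximation) of per-subject severity scores against a clinical
#' score, overall or within a phenotype. Subjects missing either value are
#' dropped and the analysed `n` is reported.
#'
#' @param severity named numeric vector of severity scores (names =
#'   subject ids) or plain numeric aligned with `clinical`.
#' @param clinical data frame with columns `subject_id` and the score
#'   column, or a plain numeric vector.
#' @param score column of `clinical` to correlate (default `"SDMT"`).
#' @param group_filter optional: restrict to subjects whose `group` column
#'   in `clinical` equals this value.
#' @return List with `r`, `p`, `n`.
#' @export
spearman_clinical <- function(severity, clinical, score = "SDMT",
                              group_filter = NULL) {
  if (is.data.frame(clinical)) {
    if (!is.null(group_filter))
      clinical <- clinical[clinical$group %in% group_filter, , drop = FALSE]
    if (is.null(names(severity)))
      stop("severity must be named by subject_id when clinical is a table")
    idx <- match(clinical$subject_id, names(severity))
    sv <- severity[idx]
    cl <- clinical[[score]]
  } else {
    sv <- severity
    cl <- clinical
  }
  ok <- is.finite(sv) & is.finite(cl)
  n <- sum(ok)
  if (n < 3L) stop("fewer than three complete pairs")
  ht <- suppressWarnings(stats::cor.test(sv[ok], cl[ok], method = "spearman",
                                         exact = FALSE))
  list(r = unname(ht$estimate), p = ht$p.value, n = n)
}

#' Read a clinical-scores table
#'
#' CSV with columns `subject_id, group, EDSS, SDMT`; blanks are missing.
#' EDSS values outside \[0, 10\] are rejected.
#'
#' @param path CSV file.
#' @return Data frame.
#' @export
read_clinical_scores <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "EDSS", "SDMT")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("clinical table missing column(s): ",
                         paste(miss, collapse = ", "))
  bad <- which(is.finite(tab$EDSS) & (tab$EDSS < 0 | tab$EDSS > 10))
  if (length(bad)) stop("EDSS out of [0,10] for subject(s): ",
                        paste(tab$subject_id[bad], collapse = ", "))
  tab
}
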