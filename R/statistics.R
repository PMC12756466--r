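#' One group of measurements
#'
#' @param group_label Group name, e.g. `"CTRL"`, `"GDNF"`, `"GWEN"`.
#' @param values Non-empty numeric vector of finite measurements (counts,
#'   proportions or distances).
#' @return An object of class `group_sample`.
#' @export
group_sample <- function(group_label, values) {
  values <- as.numeric(values)
  if (length(values) == 0 || any(!is.finite(values)))
    stop("group_sample: values must be non-empty and finite")
  structure(list(group_label = as.character(group_label), values = values),
            class = "group_sample")
}

# internal: pooled long format from a list of group_sample
samples_long <- function(samples) {
  stopifnot(length(samples) >= 2L)
  data.frame(
    value = unlist(lapply(samples, `[[`, "values")),
    group = factor(rep(vapply(samples, `[[`, "", "group_label"),
                       vapply(samples, function(s) length(s$values), 0L))))
}

comparison_result <- function(test_name, groups, statistic, p_raw,
                              p_adjusted = p_raw) {
  data.frame(test_name = test_name,
             groups = paste(groups, collapse = " vs "),
             statistic = statistic, p_raw = p_raw, p_adjusted = p_adjusted,
             significant = p_adjusted < 0.05,
             stars = significance_stars(p_adjusted),
             stringsAsFactors = FALSE)
}

#' Significance stars at the conventional thresholds
#'
#' `*` for p < 0.05, `**` < 0.01, `***` < 0.001, `****` < 0.0001.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector.
#' @export
significance_stars <- function(p) {
  vapply(p, function(x) {
    if (x < 1e-4) "****" else if (x < 1e-3) "***"
    else if (x < 0.01) "**" else if (x < 0.05) "*" else ""
  }, "")
}

#' Omnibus group comparison
#'
#' Kruskal-Wallis (mid-rank ties correction, as in [stats::kruskal.test])
#' or one-way ANOVA over two or more groups.
#'
#' @param samples List of [group_sample], each with >= 2 values.
#' @param method `"kruskal"` or `"anova"`.
#' @return A one-row `comparison_result` data.frame with columns
#'   `test_name`, `groups`, `statistic`, `p_raw`, `p_adjusted`,
#'   `significant`, `stars`.
#' @export
omnibus_compare <- function(samples, method = c("kruskal", "anova")) {
  method <- match.arg(method)
  if (length(samples) < 2L)
    stop("validation error: need at least 2 groups")
  small <- vapply(samples, function(s) length(s$values) < 2L, TRUE)
  if (any(small))
    stop(sprintf("validation error: group(s) with < 2 values: %s",
                 paste(vapply(samples[small], `[[`, "", "group_label"),
                       collapse = ", ")))
  d <- samples_long(samples)
  if (method == "kruskal") {
    kt <- stats::kruskal.test(value ~ group, data = d)
    comparison_result("kruskal-wallis", levels(d$group),
                      unname(kt$statistic), kt$p.value)
  } else {
    fit <- stats::aov(value ~ group, data = d)
    an <- summary(fit)[[1L]]
    comparison_result("one-way-anova", levels(d$group),
                      an[["F value"]][1L], an[["Pr(>F)"]][1L])
  }
}

# Dunn's post hoc z test on the pooled mid-ranks with tie correction:
# z_ij = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T/(12(N-1))) (1/n_i + 1/n_j)),
# T = sum over tie groups of (t^3 - t); two-sided normal p.
dunn_pair <- function(values, groups, g1, g2) {
  r <- rank(values)
  N <- length(values)
  tie <- table(values)
  Tcorr <- sum(tie^3 - tie)
  v <- N * (N + 1) / 12 - Tcorr / (12 * (N - 1))
  n1 <- sum(groups == g1); n2 <- sum(groups == g2)
  z <- (mean(r[groups == g1]) - mean(r[groups == g2])) /
    sqrt(v * (1 / n1 + 1 / n2))
  list(statistic = z, p = 2 * stats::pnorm(-abs(z)))
}

mannwhitney_pair <- function(x, y) {
  # exact enumeration for small untied samples, normal approximation with
  # continuity and tie correction otherwise (wilcox.test implements both)
  exact <- length(x) <= 8L && length(y) <= 8L && !anyDuplicated(c(x, y))
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact, correct = TRUE))
  list(statistic = unname(wt$statistic), p = wt$p.value)
}

#' Pairwise post hoc comparisons
#'
#' One result per unordered group pair. `"dunn"` uses pooled-rank z tests
#' (the usual follow-up to Kruskal-Wallis), `"tukey"` uses Tukey's honest
#' significant differences after one-way ANOVA, `"mannwhitney"` uses
#' rank-sum tests (exact enumeration for untied samples of size <= 8, the
#' tie-corrected normal approximation otherwise).
#'
#' Holm adjustment (`adjust = "holm"`, the default) is applied across the
#' pairwise family for dunn and mannwhitney; Tukey p-values are already
#' family-adjusted by construction and are passed through unchanged.
#'
#' @param samples List of [group_sample] (>= 2 groups).
#' @param method `"dunn"`, `"tukey"` or `"mannwhitney"`.
#' @param adjust `"holm"` or `"none"`.
#' @return A `comparison_result` data.frame, one row per pair.
#' @export
posthoc_pairwise <- function(samples, method = c("dunn", "tukey", "mannwhitney"),
                             adjust = c("holm", "none")) {
  method <- match.arg(method)
  adjust <- match.arg(adjust)
  if (length(samples) < 2L) stop("validation error: need at least 2 groups")
  labels <- vapply(samples, `[[`, "", "group_label")
  pairs <- utils::combn(seq_along(samples), 2L)
  d <- samples_long(samples)
  if (method == "tukey") {
    fit <- stats::aov(value ~ group, data = d)
    tk <- stats::TukeyHSD(fit)$group
    out <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
      i <- pairs[1L, k]; j <- pairs[2L, k]
      key <- paste0(labels[j], "-", labels[i])
      if (!key %in% rownames(tk)) key <- paste0(labels[i], "-", labels[j])
      comparison_result("tukey-hsd", labels[c(i, j)],
                        tk[key, "diff"], tk[key, "p adj"])
    }))
    return(out)
  }
  res <- lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1L, k]; j <- pairs[2L, k]
    if (method == "dunn")
      dunn_pair(d$value, as.character(d$group), labels[i], labels[j])
    else
      mannwhitney_pair(samples[[i]]$values, samples[[j]]$values)
  })
  p_raw <- vapply(res, `[[`, 0, "p")
  p_adj <- if (adjust == "holm") holm_adjust(p_raw) else p_raw
  do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
    comparison_result(method, labels[pairs[, k]],
                      res[[k]]$statistic, p_raw[k], p_adj[k])
  }))
}

#' Holm step-down adjustment of p-values
#'
#' Sorted ascending, `p_(i)adj = max_{j <= i} min(1, (m - j + 1) p_(j))`,
#' returned in the original order; output never falls below the input and
#' is capped at 1.
#'
#' @param p_raw Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in the original order.
#' @export
holm_adjust <- function(p_raw) {
  if (any(!is.finite(p_raw)) || any(p_raw < 0 | p_raw > 1))
    stop("validation error: p-values must lie in [0, 1]")
  stats::p.adjust(p_raw, method = "holm")
}
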