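#' Statistical comparison configuration
#'
#' @param policy `"auto"` (Shapiro-gated: Welch t when both groups look
#'   Gaussian, Mann-Whitney otherwise), `"nonparametric"` (always
#'   Mann-Whitney) or `"parametric"` (always Welch t).
#' @param correction Pairwise multiple-comparison correction: `"holm"`
#'   (Holm on the pairwise tests), `"dunn_kw"` (Dunn's rank contrasts after
#'   Kruskal-Wallis, Holm-adjusted) or `"none"`.
#' @param alpha Significance level.
#' @param permutations Number of permutations for curve-level tests
#'   (>= 1000).
#' @param seed Seed for permutation tests.
#' @return A list of class `stats_config`.
#' @export
stats_config <- function(policy = c("auto", "nonparametric", "parametric"),
                         correction = c("holm", "dunn_kw", "none"),
                         alpha = 0.05, permutations = 5000, seed = 1) {
  policy <- match.arg(policy)
  correction <- match.arg(correction)
  stopifnot(alpha > 0, alpha < 1, permutations >= 1000)
  structure(list(policy = policy, correction = correction, alpha = alpha,
                 permutations = permutations, seed = seed),
            class = "stats_config")
}

group_mean_sem <- function(x) {
  x <- x[is.finite(x)]
  c(n = length(x), mean = mean(x), sem = sd(x) / sqrt(length(x)))
}

#' Compare one scalar feature between two groups
#'
#' Under the `auto` policy the test is Welch's t when a Shapiro-Wilk test
#' rejects normality in neither group, and the Mann-Whitney (Wilcoxon
#' rank-sum) test otherwise, exact where sample sizes and ties permit.
#' Degenerate input (all values identical in both groups) yields p = 1 with
#' the test flagged `"degenerate"`.
#'
#' @param values_by_group Named list of numeric vectors, one per group.
#' @param pair Character vector of the two group names to contrast.
#' @param config A [stats_config()].
#' @param feature Feature name recorded in the output.
#' @return One-row data.frame with the comparison fields (`n`, mean, SEM
#'   per group, `test_name`, `statistic`, `p_value`, `p_adjusted` — equal
#'   to `p_value` here, adjusted by callers that own a family —
#'   `significant`).
#' @export
compare_scalar_feature <- function(values_by_group, pair,
                                   config = stats_config(),
                                   feature = "feature") {
  a <- values_by_group[[pair[1]]]
  b <- values_by_group[[pair[2]]]
  a <- a[is.finite(a)]
  b <- b[is.finite(b)]
  if (length(a) < 3L || length(b) < 3L) {
    stop("need at least 3 finite values per group")
  }
  degenerate <- length(unique(c(a, b))) == 1L
  if (degenerate) {
    test_name <- "degenerate"
    stat <- 0
    p <- 1
  } else {
    use_t <- switch(config$policy,
      parametric = TRUE,
      nonparametric = FALSE,
      auto = {
        normal_a <- length(unique(a)) > 1 && shapiro.test(a)$p.value > 0.05
        normal_b <- length(unique(b)) > 1 && shapiro.test(b)$p.value > 0.05
        normal_a && normal_b
      })
    if (use_t) {
      tt <- t.test(a, b)
      test_name <- "welch_t"
      stat <- unname(tt$statistic)
      p <- tt$p.value
    } else {
      wt <- suppressWarnings(wilcox.test(a, b))
      test_name <- "mann_whitney"
      stat <- unname(wt$statistic)
      p <- wt$p.value
    }
  }
  ma <- group_mean_sem(a)
  mb <- group_mean_sem(b)
  data.frame(feature = feature, group_a = pair[1], group_b = pair[2],
             n_a = ma["n"], n_b = mb["n"],
             mean_a = ma["mean"], sem_a = ma["sem"],
             mean_b = mb["mean"], sem_b = mb["sem"],
             test_name = test_name, statistic = stat, p_value = p,
             p_adjusted = p, significant = p < config$alpha,
             row.names = NULL, stringsAsFactors = FALSE)
}

# Dunn's post hoc rank contrasts after Kruskal-Wallis, with tie correction.
# Returns a data.frame of pairwise z statistics and two-sided p values.
dunn_contrasts <- function(values_by_group) {
  g <- rep(names(values_by_group), lengths(values_by_group))
  x <- unlist(values_by_group, use.names = FALSE)
  n <- length(x)
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  ns <- tapply(r, g, length)
  ties <- table(x)
  tie_corr <- sum(ties^3 - ties) / (12 * (n - 1))
  pairs <- utils::combn(names(values_by_group), 2)
  out <- lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    se <- sqrt((n * (n + 1) / 12 - tie_corr) * (1 / ns[[i]] + 1 / ns[[j]]))
    z <- (rbar[[i]] - rbar[[j]]) / se
    data.frame(group_a = i, group_b = j, statistic = z,
               p_value = 2 * pnorm(-abs(z)), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Compare a scalar feature across the three study arms
#'
#' Kruskal-Wallis omnibus test followed by the three pairwise contrasts
#' with the configured correction: Dunn's rank contrasts (Holm-adjusted)
#' under `"dunn_kw"`, or the per-pair tests of [compare_scalar_feature()]
#' with Holm adjustment under `"holm"`.
#'
#' @param values_by_group Named list with exactly the three study arms.
#' @param config A [stats_config()].
#' @param feature Feature name recorded in the output.
#' @return List: `omnibus` (one-row data.frame: `statistic`, `p_value`) and
#'   `pairwise` (data.frame of the three adjusted contrasts).
#' @export
compare_all_groups <- function(values_by_group, config = stats_config(),
                               feature = "feature") {
  arms <- c("control", "PAE_saline", "PAE_NBOH")
  if (!all(arms %in% names(values_by_group))) {
    stop("missing study arm: need exactly ", paste(arms, collapse = ", "))
  }
  values_by_group <- lapply(values_by_group[arms], function(v) v[is.finite(v)])
  kw <- kruskal.test(values_by_group)
  omnibus <- data.frame(feature = feature, test_name = "kruskal_wallis",
                        statistic = unname(kw$statistic),
                        p_value = kw$p.value, stringsAsFactors = FALSE)
  pairs <- utils::combn(arms, 2)
  if (config$correction == "dunn_kw") {
    pw <- dunn_contrasts(values_by_group)
    pw$test_name <- "dunn"
    ms <- lapply(values_by_group, group_mean_sem)
    pw$feature <- feature
    pw$n_a <- vapply(pw$group_a, function(g) ms[[g]]["n"], numeric(1))
    pw$n_b <- vapply(pw$group_b, function(g) ms[[g]]["n"], numeric(1))
    pw$mean_a <- vapply(pw$group_a, function(g) ms[[g]]["mean"], numeric(1))
    pw$sem_a <- vapply(pw$group_a, function(g) ms[[g]]["sem"], numeric(1))
    pw$mean_b <- vapply(pw$group_b, function(g) ms[[g]]["mean"], numeric(1))
    pw$sem_b <- vapply(pw$group_b, function(g) ms[[g]]["sem"], numeric(1))
  } else {
    pw <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
      compare_scalar_feature(values_by_group, pairs[, k], config, feature)
    }))
  }
  method <- if (config$correction == "none") "none" else "holm"
  pw$p_adjusted <- pmax(p.adjust(pw$p_value, method = method), pw$p_value)
  pw$significant <- pw$p_adjusted < config$alpha
  cols <- c("feature", "group_a", "group_b", "n_a", "n_b", "mean_a", "sem_a",
            "mean_b", "sem_b", "test_name", "statistic", "p_value",
            "p_adjusted", "significant")
  list(omnibus = omnibus, pairwise = pw[, cols])
}

#' Permutation comparison of f-I curves between two groups
#'
#' Cells are the exchangeable units: the observed statistic is the maximum
#' absolute difference of the group mean frequencies across the shared
#' current grid (max-T), and its null distribution is built by permuting
#' cell labels `config$permutations` times with the configured seed. The
#' p value uses the add-one estimator, so identical groups give p = 1.
#'
#' @param curves_by_group Named list of numeric matrices (cells in rows,
#'   currents in columns); all groups must share the current grid, supplied
#'   as column names or an attribute `"currents"`.
#' @param pair The two group names to contrast.
#' @param config A [stats_config()].
#' @return One-row data.frame: groups, cell counts, observed statistic
#'   (`statistic`, Hz), `p_value`, `p_adjusted` (= p), `significant`.
#' @export
compare_fi_curves <- function(curves_by_group, pair, config = stats_config()) {
  a <- curves_by_group[[pair[1]]]
  b <- curves_by_group[[pair[2]]]
  if (ncol(a) != ncol(b)) stop("mismatched current grids")
  ga <- colnames(a); gb <- colnames(b)
  if (!is.null(ga) && !is.null(gb) && !identical(ga, gb)) {
    stop("mismatched current grids")
  }
  # canonical pooling order (sorted group names) makes the permutation
  # stream, and hence the p value, invariant to swapping the two groups
  if (pair[1] > pair[2]) { tmp <- a; a <- b; b <- tmp }
  pooled <- rbind(a, b)
  n_a <- nrow(a)
  n <- nrow(pooled)
  stat_fun <- function(idx) {
    # symmetric in idx vs its complement, so the p value is invariant to
    # swapping the two groups
    max(abs(colMeans(pooled[idx, , drop = FALSE]) -
              colMeans(pooled[-idx, , drop = FALSE])))
  }
  obs <- stat_fun(seq_len(n_a))
  m <- min(n_a, nrow(b))  # permute the smaller group's labels
  perm <- with_seed(config$seed, {
    vapply(seq_len(config$permutations), function(i) {
      stat_fun(sample.int(n, m))
    }, numeric(1))
  })
  p <- (1 + sum(perm >= obs)) / (config$permutations + 1)
  data.frame(feature = "fi_curve", group_a = pair[1], group_b = pair[2],
             n_a = nrow(curves_by_group[[pair[1]]]),
             n_b = nrow(curves_by_group[[pair[2]]]),
             test_name = "max_t_permutation",
             statistic = obs, p_value = p, p_adjusted = p,
             significant = p < config$alpha, stringsAsFactors = FALSE)
}

#' Per-feature per-contrast summary table
#'
#' Builds the reporting table for a set of features: per-group n and
#' mean +/- SEM of QC-passed cells plus the adjusted pairwise contrasts.
#' Every cell in the feature table must be present in the QC table.
#'
#' @param features data.frame with `cell_id`, `group_label` and one column
#'   per feature.
#' @param qc QC table as from [qc_table()] (columns `cell_id`, `passed`).
#' @param feature_names Character vector of feature columns to summarize.
#' @param config A [stats_config()].
#' @return List: `table` (feature x contrast rows) and `omnibus` (one
#'   Kruskal-Wallis row per feature).
#' @export
build_summary_table <- function(features, qc, feature_names,
                                config = stats_config()) {
  missing <- setdiff(features$cell_id, qc$cell_id)
  if (length(missing)) {
    stop("cells present in features but absent from qc: ",
         paste(missing, collapse = ", "))
  }
  keep <- features$cell_id %in% qc$cell_id[qc$passed]
  feat <- features[keep, , drop = FALSE]
  rows <- list()
  omni <- list()
  for (f in feature_names) {
    vals <- split(feat[[f]], feat$group_label)
    cmp <- compare_all_groups(vals, config, feature = f)
    rows[[f]] <- cmp$pairwise
    omni[[f]] <- cmp$omnibus
  }
  list(table = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       omnibus = do.call(rbind, c(omni, list(make.row.names = FALSE))))
}
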