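#' Nonparametric group comparison of lesion metrics
#'
#' Compares a metric (lesion number, TV, VSL, ...) across patient groups:
#' two groups with the Mann-Whitney U test, three or more with the
#' Kruskal-Wallis test followed by Dunn's post-hoc pairwise comparisons.
#'
#' @param values_by_group named list of numeric vectors, one per group; every
#'   group must be nonempty.
#' @param test "auto" picks by group count; or force "mann-whitney" /
#'   "kruskal-wallis".
#' @param posthoc run Dunn's pairwise comparisons when >= 3 groups.
#' @param p_adjust adjustment method for the post-hoc p-values (see
#'   [stats::p.adjust()]); Bonferroni by default, the classical Dunn
#'   correction.
#' @return list with `method`, `statistic`, `p.value`, and for >= 3 groups a
#'   `posthoc` data.frame (group1, group2, z, p_unadjusted, p_adjusted).
#' @export
compare_groups <- function(values_by_group,
                           test = c("auto", "mann-whitney", "kruskal-wallis"),
                           posthoc = TRUE, p_adjust = "bonferroni") {
  test <- match.arg(test)
  if (!is.list(values_by_group) || length(values_by_group) < 2L)
    stop("need at least two groups")
  sizes <- lengths(values_by_group)
  if (any(sizes < 1L)) stop("every group must have at least one observation")
  if (is.null(names(values_by_group)))
    names(values_by_group) <- paste0("g", seq_along(values_by_group))
  k <- length(values_by_group)
  if (test == "auto") test <- if (k == 2L) "mann-whitney" else "kruskal-wallis"
  if (test == "mann-whitney") {
    if (k != 2L) stop("Mann-Whitney requires exactly two groups")
    wt <- suppressWarnings(stats::wilcox.test(values_by_group[[1]],
                                              values_by_group[[2]]))
    return(list(method = "mann-whitney",
                statistic = unname(wt$statistic), p.value = wt$p.value))
  }
  values <- unlist(values_by_group, use.names = FALSE)
  groups <- factor(rep(names(values_by_group), sizes),
                   levels = names(values_by_group))
  kw <- stats::kruskal.test(values, groups)
  out <- list(method = "kruskal-wallis",
              statistic = unname(kw$statistic), p.value = kw$p.value)
  if (posthoc && k >= 3L)
    out$posthoc <- dunn_test(values, groups, p_adjust = p_adjust)
  out
}

#' Dunn's post-hoc pairwise rank comparisons
#'
#' Pairwise z tests on mean ranks after a Kruskal-Wallis test, with the
#' usual tie correction; two-sided p-values adjusted across all pairs.
#'
#' @param values numeric vector of pooled observations.
#' @param groups factor of group membership, same length.
#' @param p_adjust method passed to [stats::p.adjust()].
#' @return data.frame: group1, group2, z, p_unadjusted, p_adjusted.
#' @export
dunn_test <- function(values, groups, p_adjust = "bonferroni") {
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) < 2L) stop("need at least two groups")
  n <- length(values)
  r <- rank(values)
  mean_ranks <- tapply(r, groups, mean)
  sizes <- tabulate(groups)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  sigma2 <- n * (n + 1) / 12 - tie_term
  pairs <- utils::combn(levels(groups), 2)
  z <- apply(pairs, 2, function(p) {
    i <- match(p[1], levels(groups)); j <- match(p[2], levels(groups))
    (mean_ranks[i] - mean_ranks[j]) /
      sqrt(sigma2 * (1 / sizes[i] + 1 / sizes[j]))
  })
  p_un <- 2 * stats::pnorm(-abs(z))
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ], z = as.numeric(z),
             p_unadjusted = p_un,
             p_adjusted = stats::p.adjust(p_un, method = p_adjust),
             stringsAsFactors = FALSE)
}
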