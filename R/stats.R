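#' Mann-Whitney U test (two-sided)
#'
#' Rank-sum comparison of two samples. The exact null distribution is used
#' when both samples have at most 8 observations and no ties are present;
#' otherwise the normal approximation with tie correction (and no continuity
#' correction) is used. The statistic U counts pairs (x_i, y_j) with
#' x_i > y_j, with ties counted one half.
#'
#' @param x,y numeric samples, both non-empty.
#' @return List with `U`, `p_value` and `exact` (logical).
#' @export
#' @examples
#' mannWhitneyU(c(1, 2, 3), c(4, 5, 6))  # U = 0, p = 0.1
mannWhitneyU <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) stop("both samples must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- length(x) <= 8 && length(y) <= 8 && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                       correct = FALSE)
  )
  list(U = unname(wt$statistic), p_value = wt$p.value, exact = exact)
}

#' Kruskal-Wallis rank test
#'
#' Rank-based comparison of two or more groups with tie correction; the
#' p-value is from the chi-square approximation with k - 1 degrees of
#' freedom.
#'
#' @param samples list of two or more non-empty numeric vectors.
#' @return List with `H`, `df` and `p_value`.
#' @export
#' @examples
#' kruskalWallis(list(c(1, 2), c(3, 4), c(5, 6)))
kruskalWallis <- function(samples) {
  if (length(samples) < 2) stop("need at least two groups")
  if (any(lengths(samples) == 0)) stop("all groups must be non-empty")
  kt <- stats::kruskal.test(samples)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p_value = kt$p.value)
}

#' Dunn's post hoc test with Bonferroni correction
#'
#' Pairwise z statistics on pooled ranks after a Kruskal-Wallis test, with
#' the usual tie correction of the rank variance, two-sided p-values and
#' Bonferroni adjustment by the number of pairs (adjusted p capped at 1).
#'
#' @param samples named list of two or more non-empty numeric vectors; names
#'   label the groups.
#' @param pairs optional character matrix (2 columns) or list of length-2
#'   vectors selecting the pairs; defaults to all pairs. The Bonferroni
#'   multiplier is always the total number of pairs among the groups.
#' @return `data.frame` with one row per pair: `group1`, `group2`, `z`,
#'   `p_value`, `p_adjusted`.
#' @export
#' @examples
#' dunnBonferroni(list(a = c(1, 2), b = c(3, 4), c = c(5, 6)))
dunnBonferroni <- function(samples, pairs = NULL) {
  k <- length(samples)
  if (k < 2) stop("need at least two groups")
  if (any(lengths(samples) == 0)) stop("all groups must be non-empty")
  if (is.null(names(samples)) || any(names(samples) == "")) {
    names(samples) <- paste0("group", seq_len(k))
  }
  g <- rep(names(samples), lengths(samples))
  r <- rank(unlist(samples, use.names = FALSE))
  n <- length(r)
  rbar <- tapply(r, g, mean)
  sizes <- tapply(r, g, length)
  tie_tab <- table(r)
  tie_term <- sum(tie_tab^3 - tie_tab) / (12 * (n - 1))
  var_base <- n * (n + 1) / 12 - tie_term
  all_pairs <- utils::combn(names(samples), 2, simplify = FALSE)
  m <- length(all_pairs)
  if (is.null(pairs)) {
    pairs <- all_pairs
  } else {
    if (is.matrix(pairs)) pairs <- asplit(pairs, 1)
    for (p in pairs) {
      if (!all(p %in% names(samples))) {
        stop("pair (", paste(p, collapse = ", "),
             ") does not match the group labels")
      }
    }
  }
  rows <- lapply(pairs, function(p) {
    se <- sqrt(var_base * (1 / sizes[[p[1]]] + 1 / sizes[[p[2]]]))
    z <- if (se == 0) 0 else (rbar[[p[1]]] - rbar[[p[2]]]) / se
    praw <- 2 * stats::pnorm(-abs(z))
    data.frame(group1 = p[1], group2 = p[2], z = z, p_value = praw,
               p_adjusted = min(1, m * praw), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Cohen's d effect size (pooled standard deviation)
#'
#' (mean(x) - mean(y)) divided by the pooled standard deviation with n - 1
#' weights. Antisymmetric in its arguments.
#'
#' @param x,y numeric samples with at least 2 values each.
#' @return Cohen's d.
#' @export
#' @examples
#' cohensD(c(0, 1), c(1, 2))  # -1.414
cohensD <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2) stop("each group needs at least 2 values")
  sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) /
    (n1 + n2 - 2)
  if (sp2 == 0) stop("pooled standard deviation is zero; d is undefined")
  (mean(x) - mean(y)) / sqrt(sp2)
}

#' Post hoc power of a two-sided two-sample comparison
#'
#' Power to detect a standardised effect d with group sizes n1 and n2 at
#' significance level alpha. The default is the normal approximation
#' P(|Z| > z_{1-alpha/2}) under a mean shift of
#' |d| * sqrt(n1 n2 / (n1 + n2)); `method = "t"` uses the noncentral t
#' distribution with n1 + n2 - 2 degrees of freedom instead.
#'
#' @param d standardised effect size (Cohen's d).
#' @param n1,n2 group sizes, each >= 2.
#' @param alpha two-sided significance level in (0, 1).
#' @param method `"normal"` or `"t"`.
#' @return Power in `[0, 1]`; equals `alpha` when `d = 0`.
#' @export
#' @examples
#' posthocPower(0.35, 46, 55)  # about 0.42
posthocPower <- function(d, n1, n2, alpha = 0.05,
                         method = c("normal", "t")) {
  method <- match.arg(method)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (n1 < 2 || n2 < 2) stop("group sizes must be at least 2")
  ncp <- abs(d) * sqrt(n1 * n2 / (n1 + n2))
  if (method == "normal") {
    zc <- stats::qnorm(1 - alpha / 2)
    stats::pnorm(ncp - zc) + stats::pnorm(-ncp - zc)
  } else {
    df <- n1 + n2 - 2
    tc <- stats::qt(1 - alpha / 2, df)
    1 - stats::pt(tc, df, ncp = ncp) + stats::pt(-tc, df, ncp = ncp)
  }
}

#' Group comparison battery over species means
#'
#' Runs the model's statistical battery on a cohort summary table (one row
#' per individual, as returned by [simulateCohort()]): for every species,
#' two-group comparisons use the Mann-Whitney U test plus Cohen's d and post
#' hoc power; with three or more groups a Kruskal-Wallis test is followed by
#' Dunn's post hoc test with Bonferroni correction.
#'
#' @param summaries `data.frame` with a grouping column and
#'   `<species>_mean` columns.
#' @param species character vector of species to compare (default: the five
#'   serotonin-branch species).
#' @param group_col name of the grouping column.
#' @param alpha significance level used for the power calculation.
#' @return `data.frame`, one row per (species, test, pair) with columns
#'   `species`, `test`, `group1`, `group2`, `n1`, `n2`, `statistic`,
#'   `p_value`, `p_adjusted`, `effect_size_d`, `power`.
#' @export
compareGroups <- function(summaries,
                          species = c("htp5", "fc5ht", "v5ht", "e5ht",
                                      "hiaa5"),
                          group_col = "group", alpha = 0.05) {
  groups <- unique(summaries[[group_col]])
  if (length(groups) < 2) stop("need at least two groups to compare")
  rows <- list()
  for (sp in species) {
    col <- paste0(sp, "_mean")
    if (!col %in% names(summaries)) stop("missing column ", col)
    samples <- lapply(groups, function(gr) {
      summaries[[col]][summaries[[group_col]] == gr]
    })
    names(samples) <- groups
    if (length(groups) == 2) {
      mw <- mannWhitneyU(samples[[1]], samples[[2]])
      d <- cohensD(samples[[1]], samples[[2]])
      rows[[length(rows) + 1]] <- data.frame(
        species = sp, test = "mann_whitney",
        group1 = groups[1], group2 = groups[2],
        n1 = length(samples[[1]]), n2 = length(samples[[2]]),
        statistic = mw$U, p_value = mw$p_value, p_adjusted = NA_real_,
        effect_size_d = d,
        power = posthocPower(d, length(samples[[1]]), length(samples[[2]]),
                             alpha = alpha),
        stringsAsFactors = FALSE)
    } else {
      kw <- kruskalWallis(samples)
      rows[[length(rows) + 1]] <- data.frame(
        species = sp, test = "kruskal_wallis",
        group1 = NA_character_, group2 = NA_character_,
        n1 = NA_integer_, n2 = NA_integer_,
        statistic = kw$H, p_value = kw$p_value, p_adjusted = NA_real_,
        effect_size_d = NA_real_, power = NA_real_,
        stringsAsFactors = FALSE)
      dn <- dunnBonferroni(samples)
      for (i in seq_len(nrow(dn))) {
        g1 <- dn$group1[i]; g2 <- dn$group2[i]
        d <- cohensD(samples[[g1]], samples[[g2]])
        rows[[length(rows) + 1]] <- data.frame(
          species = sp, test = "dunn",
          group1 = g1, group2 = g2,
          n1 = length(samples[[g1]]), n2 = length(samples[[g2]]),
          statistic = dn$z[i], p_value = dn$p_value[i],
          p_adjusted = dn$p_adjusted[i],
          effect_size_d = d,
          power = posthocPower(d, length(samples[[g1]]),
                               length(samples[[g2]]), alpha = alpha),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
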