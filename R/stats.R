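#' Pairwise rank-sum tests with Bonferroni correction
#'
#' Two-sided Wilcoxon rank-sum (Mann-Whitney) tests between every
#' unordered pair of groups — regions are independent samples of
#' particles, so the two-sample form applies.  Small untied samples use
#' exact enumeration (via [stats::wilcox.test()]); larger or tied
#' samples use the tie-corrected normal approximation with continuity
#' correction.  Bonferroni correction uses `m = choose(k, 2)`.
#'
#' @param distributions named list of numeric vectors (one per region),
#'   each nonempty.
#' @param alpha significance level for the decision column (default
#'   0.05).
#' @return data.frame with `group1`, `group2`, `p_raw`, `p_bonferroni`,
#'   `significant`.
#' @export
pairwise_wilcoxon_bonferroni <- function(distributions, alpha = 0.05) {
  k <- length(distributions)
  stopifnot(k >= 2L, !is.null(names(distributions)))
  sizes <- lengths(distributions)
  if (any(sizes == 0L))
    stop("empty group(s): ",
         paste(names(distributions)[sizes == 0L], collapse = ", "),
         call. = FALSE)
  pairs <- utils::combn(names(distributions), 2)
  p_raw <- apply(pairs, 2, function(pr) {
    suppressWarnings(stats::wilcox.test(distributions[[pr[1]]],
                                        distributions[[pr[2]]],
                                        alternative = "two.sided")$p.value)
  })
  p_adj <- stats::p.adjust(p_raw, method = "bonferroni")
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ], p_raw = p_raw,
             p_bonferroni = p_adj, significant = p_adj < alpha,
             row.names = NULL)
}

#' Spearman correlation with a Fisher-z confidence interval
#'
#' Spearman's rank correlation (average ranks for ties) between a
#' regional connectivity metric and regional penguin abundance, with the
#' approximate `(1 - alpha)` confidence interval from the Fisher
#' z-transformation using the Fieller-adjusted variance for rank
#' correlations: `tanh(atanh(rho) +/- z[1-alpha/2] * sqrt(1.06 / (n - 3)))`.
#'
#' @param x,y aligned numeric vectors (one value per region); `n >= 4`.
#' @param alpha confidence level complement (default 0.05).
#' @return list with `rho`, `ci` (length 2), `n`, and `undefined`
#'   (`TRUE` when either variable is constant, leaving the correlation
#'   undefined).
#' @export
spearman_fisher_ci <- function(x, y, alpha = 0.05) {
  stopifnot(length(x) == length(y))
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4L) stop("need at least 4 paired observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, ci = c(NA_real_, NA_real_), n = n,
                undefined = TRUE))
  rho <- stats::cor(x, y, method = "spearman")
  z <- stats::qnorm(1 - alpha / 2)
  ci <- tanh(atanh(rho) + c(-1, 1) * z * sqrt(1.06 / (n - 3)))
  list(rho = rho, ci = ci, n = n, undefined = FALSE)
}

#' Regional penguin totals by species
#'
#' Sums nests and counts colonies per species and region, with an
#' all-species total row per region.  Colonies are assigned to the
#' region containing their location; colonies in no region are counted
#' under `offshore` with a warning.
#'
#' @param colonies a colony table (see [read_colonies()]).
#' @param regions a `kf_regionset`.
#' @return data.frame with `region`, `species` (including `"all"`),
#'   `nests`, `colonies`.
#' @export
penguin_region_totals <- function(colonies, regions) {
  loc <- locate_point(colonies$x, colonies$y, regions)
  if (any(loc == "offshore"))
    warning(sum(loc == "offshore"),
            " colony(ies) outside all regions counted as offshore",
            call. = FALSE)
  df <- data.frame(region = loc, species = colonies$species,
                   nests = colonies$nests)
  by_sp <- stats::aggregate(nests ~ region + species, df, sum)
  by_sp$colonies <- stats::aggregate(nests ~ region + species, df,
                                     length)$nests
  tot <- stats::aggregate(nests ~ region, df, sum)
  tot$species <- "all"
  tot$colonies <- stats::aggregate(nests ~ region, df, length)$nests
  out <- rbind(by_sp, tot[, c("region", "species", "nests", "colonies")])
  out[order(out$region, out$species), ]
}

#' Species-by-metric correlation table
#'
#' Builds the species-stratified correlation summary between regional
#' penguin abundance and the median connectivity-timing metrics (transit
#' time; time in region for particles released within; time in region
#' for particles released outside), pooling migrating and passive
#' behaviours.  Species rows use only regions where the species is
#' present unless `include_zero_abundance` is `TRUE`.
#'
#' @param metric_medians data.frame with columns `region`, `metric`
#'   (`transit`, `residence_within`, `residence_transited`) and `value`
#'   (hours).
#' @param totals a [penguin_region_totals()] frame.
#' @param include_zero_abundance keep regions with zero abundance of a
#'   species in that species' row (default `FALSE`).
#' @return data.frame with one row per species (`adelie`, `chinstrap`,
#'   `gentoo`, `all`) x metric: `rho`, `ci_lo`, `ci_hi`, `n`.
#' @export
correlation_table <- function(metric_medians, totals,
                              include_zero_abundance = FALSE) {
  species <- c("adelie", "chinstrap", "gentoo", "all")
  metrics <- c("transit", "residence_within", "residence_transited")
  rows <- list()
  for (sp in species) {
    ab <- totals[totals$species == sp, c("region", "nests")]
    if (!include_zero_abundance && sp != "all")
      ab <- ab[ab$nests > 0, , drop = FALSE]
    for (mt in metrics) {
      mm <- metric_medians[metric_medians$metric == mt, ]
      j <- merge(ab, mm, by = "region")
      res <- if (nrow(j) >= 4L)
        spearman_fisher_ci(j$value, j$nests)
      else list(rho = NA_real_, ci = c(NA_real_, NA_real_),
                n = nrow(j), undefined = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(
        species = sp, metric = mt, rho = res$rho, ci_lo = res$ci[1],
        ci_hi = res$ci[2], n = res$n)
    }
  }
  do.call(rbind, rows)
}
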