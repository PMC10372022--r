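#' Summarize connectivity-timing distributions
#'
#' Pools records (optionally across behaviours/seasons) into the three
#' per-region timing metrics: transit time to the region (particles
#' released outside only), residence time for particles released within,
#' and residence time for particles that transited in.
#'
#' @param records a record frame from [reduce_trajectories()] or a list
#'   of them to pool.
#' @return list of data.frames keyed by metric (`transit`,
#'   `residence_within`, `residence_transited`), each with `region` and
#'   `hours` per qualifying particle.
#' @export
metric_distributions <- function(records) {
  if (is.data.frame(records)) records <- list(records)
  all <- do.call(rbind, lapply(records, function(r)
    r[, c("region", "released_within", "first_entry_h", "residence_h")]))
  list(
    transit = data.frame(
      region = all$region[!all$released_within],
      hours = all$first_entry_h[!all$released_within]),
    residence_within = data.frame(
      region = all$region[all$released_within],
      hours = all$residence_h[all$released_within]),
    residence_transited = data.frame(
      region = all$region[!all$released_within],
      hours = all$residence_h[!all$released_within]))
}

#' Median metric per region
#'
#' @param dists output of [metric_distributions()].
#' @return data.frame with `region`, `metric`, `value` (median hours).
#' @export
metric_medians <- function(dists) {
  out <- lapply(names(dists), function(mt) {
    d <- dists[[mt]]
    if (!nrow(d)) return(NULL)
    ag <- stats::aggregate(hours ~ region, d, stats::median)
    data.frame(region = ag$region, metric = mt, value = ag$hours)
  })
  do.call(rbind, out)
}

#' Write a report bundle
#'
#' Writes CSV tables (connectivity matrix, per-region metric summaries
#' with medians and interquartile ranges, pairwise test results, the
#' species-by-metric correlation table) plus a JSON run manifest
#' (configuration echo, master seed, package version) to a directory.
#'
#' @param out_dir output directory (created if needed).
#' @param connectivity origin x destination matrix (e.g. the interannual
#'   mean).
#' @param dists output of [metric_distributions()].
#' @param tests optional [pairwise_wilcoxon_bonferroni()] frame.
#' @param correlations optional [correlation_table()] frame.
#' @param manifest named list of run metadata (seed, configuration...).
#' @return invisible character vector of files written.
#' @export
build_report <- function(out_dir, connectivity = NULL, dists = NULL,
                         tests = NULL, correlations = NULL,
                         manifest = list()) {
  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir))
    stop("cannot create output directory: ", out_dir, call. = FALSE)
  files <- character()
  wcsv <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    files <<- c(files, p)
  }
  if (!is.null(connectivity)) {
    df <- as.data.frame(as.table(connectivity))
    names(df) <- c("origin", "destination", "count")
    wcsv(df, "connectivity_matrix.csv")
  }
  if (!is.null(dists)) {
    summ <- do.call(rbind, lapply(names(dists), function(mt) {
      d <- dists[[mt]]
      if (!nrow(d)) return(NULL)
      ag <- do.call(rbind, lapply(split(d$hours, d$region), function(v)
        data.frame(n = length(v), median_h = stats::median(v),
                   q25_h = unname(stats::quantile(v, 0.25)),
                   q75_h = unname(stats::quantile(v, 0.75)))))
      data.frame(metric = mt, region = rownames(ag), ag,
                 row.names = NULL)
    }))
    wcsv(summ, "metric_summaries.csv")
  }
  if (!is.null(tests)) wcsv(tests, "pairwise_tests.csv")
  if (!is.null(correlations)) wcsv(correlations, "correlation_table.csv")
  manifest$package_version <-
    as.character(utils::packageVersion("krillflow"))
  manifest$written <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  files <- c(files, mp)
  invisible(files)
}
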