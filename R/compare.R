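# Seasonal comparison of index distributions and derived flow aggregates.

#' Rank-sum comparison of two index distributions
#'
#' Two-sample Wilcoxon (Mann-Whitney) test of equal medians, using the
#' normal approximation with tie correction (the sample sets are MCMC
#' draws, typically tens of thousands of values).
#'
#' @param winter,summer numeric vectors of index values.
#' @param alpha significance level (default 0.01).
#' @param index optional index name carried into the output row.
#' @return one-row data.frame: medians, W statistic, p-value,
#'   `significant` flag (`p < alpha`), and the direction of the median
#'   difference.
#' @export
wilcoxon_compare <- function(winter, summer, alpha = 0.01, index = NA) {
  stopifnot(length(winter) >= 1, length(summer) >= 1)
  if (length(unique(c(winter, summer))) == 1L)
    stop("all pooled values identical; rank-sum test undefined")
  wt <- stats::wilcox.test(winter, summer, exact = FALSE, correct = TRUE)
  mw <- stats::median(winter); ms <- stats::median(summer)
  data.frame(index = index,
             median_winter = mw, median_summer = ms,
             W = unname(wt$statistic), p_value = wt$p.value,
             significant = wt$p.value < alpha,
             direction = if (mw > ms) "winter>summer"
                         else if (mw < ms) "winter<summer" else "equal",
             stringsAsFactors = FALSE)
}

#' Compare seasonal index tables column by column
#'
#' @param winter,summer data.frames of per-sample indices (as returned by
#'   [ena_over_samples()]).
#' @param indices columns to compare (default: all shared numeric ones).
#' @param alpha significance level.
#' @return data.frame with one [wilcoxon_compare()] row per index.
#' @export
compare_seasons <- function(winter, summer, indices = NULL, alpha = 0.01) {
  if (is.null(indices))
    indices <- intersect(names(winter), names(summer))
  rows <- lapply(indices, function(ix)
    wilcoxon_compare(stats::na.omit(winter[[ix]]),
                     stats::na.omit(summer[[ix]]), alpha, index = ix))
  do.call(rbind, rows)
}

#' Boxplot-ready quantile summary of index distributions
#'
#' @param values numeric vector.
#' @param whisker_mult Tukey whisker multiplier.
#' @return one-row data.frame with median, quartiles, whisker ends and
#'   outlier count.
#' @export
index_quantiles <- function(values, whisker_mult = 1.5) {
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE)
  iqr <- q[3] - q[1]
  lo <- min(values[values >= q[1] - whisker_mult * iqr])
  hi <- max(values[values <= q[3] + whisker_mult * iqr])
  data.frame(q1 = q[1], median = q[2], q3 = q[3],
             whisker_low = lo, whisker_high = hi,
             n_outliers = sum(values < lo | values > hi))
}

#' Herbivory, bacterivory and their ratio
#'
#' Herbivory is the total flow from the primary producers into living
#' consumers; bacterivory the total flow out of the benthic bacteria into
#' living consumers.
#'
#' @param net a [flow_network()].
#' @param producer producer compartment (default `"mpb"`).
#' @param bacteria bacterial compartment (default `"bcb"`).
#' @return list with `herbivory`, `bacterivory` and `ratio_pct`
#'   (100 * bacterivory / herbivory).
#' @export
herbivory_bacterivory <- function(net, producer = "mpb", bacteria = "bcb") {
  living <- net$compartments$abbrev[net$compartments$living]
  eat <- function(src) {
    if (!src %in% rownames(net$T)) return(0)
    sum(net$T[src, setdiff(intersect(living, colnames(net$T)), src)])
  }
  H <- eat(producer); B <- eat(bacteria)
  if (H <= 0) stop("zero herbivory; ratio undefined")
  list(herbivory = H, bacterivory = B, ratio_pct = 100 * B / H)
}

#' Total detritivory
#'
#' Sum of the flows leaving the non-living pools into living
#' compartments (including bacterial uptake of dissolved carbon).
#'
#' @param net a [flow_network()].
#' @return list with `detritivory` and `doc_share_pct` (the dissolved
#'   pool's percentage contribution, when a `bdc` pool is present).
#' @export
detritivory <- function(net) {
  pools <- net$compartments$abbrev[net$compartments$nonliving_pool]
  living <- net$compartments$abbrev[net$compartments$living]
  if (!length(pools)) return(list(detritivory = 0, doc_share_pct = NA_real_))
  tot <- sum(net$T[pools, living, drop = FALSE])
  doc <- if ("bdc" %in% pools)
    sum(net$T["bdc", living, drop = FALSE]) else NA_real_
  list(detritivory = tot,
       doc_share_pct = if (tot > 0 && !is.na(doc)) 100 * doc / tot
                       else NA_real_)
}
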