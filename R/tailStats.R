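# Per-unit tail summaries and tail-length divergence scans.

#' Summarize tail lengths per gene / transcript / class
#'
#' Retains units with strictly more than \code{min_reads} observations
#' (optionally per group) and reports count, median and interquartile range
#' per unit (and per group when \code{group_col} is given).
#'
#' @param table data.frame with at least the unit column and
#'   \code{tail_length_nt}.
#' @param unit unit column: "gene_id", "transcript_id" or "class" (or any
#'   column name present in \code{table}).
#' @param min_reads strict minimal coverage; units (or unit-group cells
#'   when grouping) with count <= min_reads are dropped. Default 10.
#' @param group_col optional grouping column (e.g. timepoint).
#' @return data.frame: unit, (group,) n, median, q25, q75.
#' @export
summarizeTails <- function(table, unit = "gene_id", min_reads = 10L,
                           group_col = NULL) {
  if (!is.data.frame(table) || !nrow(table))
    stop("invalid input: empty tail table")
  if (!unit %in% names(table)) stop("no such unit column: ", unit)
  if (!"tail_length_nt" %in% names(table))
    stop("table must have a tail_length_nt column")
  if (any(table$tail_length_nt < 0, na.rm = TRUE))
    stop("tail_length_nt must be >= 0")
  key <- if (is.null(group_col)) list(unit = table[[unit]]) else
    list(unit = table[[unit]], group = table[[group_col]])
  agg <- stats::aggregate(table$tail_length_nt, by = key, FUN = function(x)
    c(n = length(x), median = stats::median(x),
      q25 = unname(stats::quantile(x, 0.25)),
      q75 = unname(stats::quantile(x, 0.75))))
  out <- cbind(agg[setdiff(names(agg), "x")], as.data.frame(agg$x))
  out <- out[out$n > min_reads, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Kruskal-Wallis H with tie correction; Monte-Carlo permutation p for small
# samples, asymptotic chi-square otherwise.
.kwStat <- function(values, groups) {
  n <- length(values)
  r <- rank(values)
  gsum <- tapply(r, groups, sum)
  gn <- tapply(r, groups, length)
  H <- 12 / (n * (n + 1)) * sum(gsum^2 / gn) - 3 * (n + 1)
  ties <- table(values)
  corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  if (corr > 0) H <- H / corr
  H
}

#' Kruskal-Wallis test with small-sample permutation fallback
#'
#' For total n above \code{exact_max_n} this delegates to
#' \code{stats::kruskal.test} (tie-corrected H, chi-square p). For small
#' samples -- where the chi-square approximation is poor and tail tables
#' contain many tied zeros -- the p value is computed by permutation of the
#' group labels (all distinct assignments approximated by \code{B} draws,
#' seeded for reproducibility).
#'
#' @param values numeric observations.
#' @param groups group labels (>= 2 distinct).
#' @param exact_max_n threshold for the permutation fallback (default 20).
#' @param B permutation draws (default 2000).
#' @param perm_seed seed for the permutation draws (default 1).
#' @return list(H, p, method).
#' @export
kwTest <- function(values, groups, exact_max_n = 20L, B = 2000L,
                   perm_seed = 1L) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need >= 2 groups")
  n <- length(values)
  if (length(unique(values)) == 1L)
    return(list(H = 0, p = 1, method = "degenerate"))
  if (n > exact_max_n) {
    kt <- stats::kruskal.test(values, groups)
    return(list(H = unname(kt$statistic), p = kt$p.value,
                method = "asymptotic"))
  }
  H <- .kwStat(values, groups)
  exceed <- withSeed(perm_seed, {
    vapply(seq_len(B), function(b)
      .kwStat(values, sample(groups)) >= H - 1e-12, TRUE)
  })
  list(H = H, p = (1 + sum(exceed)) / (B + 1), method = "permutation")
}

#' Scan units for tail-length divergence across groups
#'
#' For every unit (gene, transcript, ...) with at least two groups of
#' strictly more than \code{min_reads} observations, tests whether tail
#' lengths differ across groups with the Kruskal-Wallis test, then adjusts
#' p values across tested units with Benjamini-Hochberg. Both the raw-p and
#' the adjusted-q significant fractions are reported, since headline
#' fractions are often quoted at raw P < alpha while per-unit calls use q.
#'
#' @param table data.frame with unit column, grouping column and
#'   \code{tail_length_nt}.
#' @param unit unit column name (default "transcript_id").
#' @param grouping grouping column name (default "group").
#' @param min_reads strict per-group coverage filter (default 10).
#' @param alpha significance level (default 0.05).
#' @param policy which p value drives the \code{significant} flag:
#'   "adjusted" (default) or "raw".
#' @return list: \code{comparisons} (data.frame unit, n_groups, n_total, H,
#'   p, q, significant), \code{fraction_significant_raw},
#'   \code{fraction_significant_adjusted}, \code{n_tested},
#'   \code{skipped} (data.frame unit, reason), \code{policy}, \code{alpha}.
#' @export
divergenceScan <- function(table, unit = "transcript_id",
                           grouping = "group", min_reads = 10L,
                           alpha = 0.05, policy = c("adjusted", "raw")) {
  policy <- match.arg(policy)
  stopifnot(unit %in% names(table), grouping %in% names(table))
  units <- split(table, table[[unit]])
  comp <- list(); skipped <- list()
  for (u in names(units)) {
    d <- units[[u]]
    keep_groups <- names(which(table(d[[grouping]]) > min_reads))
    d <- d[d[[grouping]] %in% keep_groups, , drop = FALSE]
    if (length(keep_groups) < 2L) {
      skipped[[u]] <- data.frame(unit = u, reason = "fewer_than_2_groups",
                                 stringsAsFactors = FALSE)
      next
    }
    kt <- kwTest(d$tail_length_nt, d[[grouping]])
    comp[[u]] <- data.frame(unit = u, n_groups = length(keep_groups),
                            n_total = nrow(d), H = kt$H, p = kt$p,
                            stringsAsFactors = FALSE)
  }
  comparisons <- do.call(rbind, comp)
  skipped <- do.call(rbind, skipped) %||%
    data.frame(unit = character(), reason = character())
  if (is.null(comparisons))
    return(list(comparisons = NULL, fraction_significant_raw = NA_real_,
                fraction_significant_adjusted = NA_real_, n_tested = 0L,
                skipped = skipped, policy = policy, alpha = alpha))
  comparisons$q <- stats::p.adjust(comparisons$p, method = "BH")
  comparisons$significant <- if (policy == "adjusted")
    comparisons$q < alpha else comparisons$p < alpha
  rownames(comparisons) <- NULL
  list(comparisons = comparisons,
       fraction_significant_raw = mean(comparisons$p < alpha),
       fraction_significant_adjusted = mean(comparisons$q < alpha),
       n_tested = nrow(comparisons), skipped = skipped,
       policy = policy, alpha = alpha)
}
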