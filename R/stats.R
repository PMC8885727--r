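#' @include AllClasses.R
NULL

#' Spearman rank correlation with exact small-sample p-value
#'
#' Mid-ranks are used for ties and r is the Pearson correlation of the
#' ranks. For n <= 10 the two-sided p-value is computed by exhaustive
#' enumeration of the permutation distribution; for larger n the usual
#' t-approximation t = r sqrt((n - 2) / (1 - r^2)) on n - 2 df is used.
#'
#' @param x,y numeric vectors of equal length (n >= 3), neither constant.
#' @return a [StatResult-class].
#' @export
spearmanTest <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 3) stop("contract error: at least 3 paired observations required")
  if (length(y) != n) stop("contract error: x and y must have equal length")
  rx <- rank(x)
  ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0) {
    stop("undefined-correlation error: constant input")
  }
  r <- cor(rx, ry)
  if (n <= 10) {
    p <- .spearman_exact_p_cpp(rx, ry)
  } else {
    tt <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
    p <- 2 * pt(-abs(tt), n - 2)
  }
  p <- min(max(p, .Machine$double.xmin), 1)
  new("StatResult", statistic = r, p = p, n = n,
      method = "Spearman rank correlation")
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' D is the supremum of |ECDF_x - ECDF_y| over the pooled sample; the
#' two-sided p-value uses the asymptotic Kolmogorov distribution at
#' sqrt(nx ny / (nx + ny)) D.
#'
#' @param x,y numeric samples, each with >= 2 values.
#' @return a [StatResult-class] with `n` holding both sample sizes.
#' @export
ksTest2 <- function(x, y) {
  x <- x[is.finite(x)]
  y <- y[is.finite(y)]
  nx <- length(x)
  ny <- length(y)
  if (nx < 2 || ny < 2) stop("contract error: both samples need >= 2 values")
  pooled <- sort(unique(c(x, y)))
  ex <- vapply(pooled, function(v) mean(x <= v), 0)
  ey <- vapply(pooled, function(v) mean(y <= v), 0)
  D <- max(abs(ex - ey))
  ne <- nx * ny / (nx + ny)
  lambda <- sqrt(ne) * D
  p <- if (lambda < 0.05) {
    1
  } else {
    k <- 1:100
    2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  }
  p <- min(max(p, .Machine$double.xmin), 1)
  new("StatResult", statistic = D, p = p, n = c(nx, ny),
      method = "Two-sample Kolmogorov-Smirnov test")
}

.stat_row <- function(label, res, note = "") {
  if (is.null(res)) {
    data.frame(comparison = label, statistic = NA_real_, p = NA_real_,
               n = "", method = "", note = note)
  } else {
    data.frame(comparison = label, statistic = res@statistic, p = res@p,
               n = paste(res@n, collapse = "/"), method = res@method,
               note = note)
  }
}

#' Summarise structure-function correlations across synapses
#'
#' The per-synapse analysis battery over a table of correlated synapses:
#' (i) Spearman correlation of dG/R vs dR/R, overall and within the
#' single-SSD and multiple-SSD groups; (ii) KS comparison of dG/dR between
#' single- and multiple-SSD synapses; (iii) KS comparisons of the total SSD
#' detection count and the mean SSD density between synapses with and
#' without detectable release; (iv) the SSD-count distribution. Synapses
#' with no SSD are excluded from the single/multiple groupings (they have no
#' colour-2 cluster) but appear in the count distribution. Groups below
#' `minGroup` skip their comparison with a logged reason. No
#' multiple-testing correction is applied; p-values are per comparison.
#'
#' @param correlated data.frame from [matchSynapses()].
#' @param minGroup minimum synapses per tested group (default 3).
#' @return list of class `correlationReport`: `stats` (one row per
#'   comparison), `ssdCounts` (distribution table), `n` and `notes`.
#' @export
summariseCorrelated <- function(correlated, minGroup = 3) {
  cs <- correlated
  notes <- character()
  stats_rows <- list()
  add <- function(label, f, ...) {
    res <- tryCatch(f(...), error = function(e) {
      notes <<- c(notes, sprintf("%s skipped: %s", label, conditionMessage(e)))
      NULL
    })
    stats_rows[[length(stats_rows) + 1L]] <<- .stat_row(label, res)
  }
  grouped <- cs[cs$n_ssd >= 1, , drop = FALSE]
  single <- grouped[grouped$n_ssd == 1, , drop = FALSE]
  multi <- grouped[grouped$n_ssd >= 2, , drop = FALSE]
  rel <- grouped[grouped$release_detected, , drop = FALSE]
  norel <- grouped[!grouped$release_detected, , drop = FALSE]

  if (nrow(cs) >= minGroup) {
    add("dG/R vs dR/R (all synapses)", spearmanTest, cs$dG_over_R, cs$dR_over_R)
  } else {
    notes <- c(notes, "overall correlation skipped: fewer synapses than minGroup")
  }
  for (grp in list(list(d = single, lab = "single SSD"),
                   list(d = multi, lab = "multiple SSDs"))) {
    lab <- sprintf("dG/R vs dR/R (%s)", grp$lab)
    if (nrow(grp$d) >= minGroup) {
      add(lab, spearmanTest, grp$d$dG_over_R, grp$d$dR_over_R)
    } else {
      notes <- c(notes, sprintf("%s skipped: group below %d synapses", lab, minGroup))
    }
  }
  if (nrow(single) >= minGroup && nrow(multi) >= minGroup) {
    add("dG/dR: single vs multiple SSDs", ksTest2,
        single$dG_over_dR[!is.na(single$dG_over_dR)],
        multi$dG_over_dR[!is.na(multi$dG_over_dR)])
  } else {
    notes <- c(notes, "dG/dR single-vs-multiple comparison skipped: group below minimum")
  }
  if (nrow(rel) >= minGroup && nrow(norel) >= minGroup) {
    add("SSD detections: release vs no release", ksTest2,
        rel$ssd_total_detections, norel$ssd_total_detections)
    add("SSD mean density: release vs no release", ksTest2,
        rel$ssd_mean_density[!is.na(rel$ssd_mean_density)],
        norel$ssd_mean_density[!is.na(norel$ssd_mean_density)])
  } else {
    notes <- c(notes, "release-vs-no-release comparisons skipped: group below minimum")
  }
  counts <- table(factor(cs$n_ssd, levels = 0:max(c(cs$n_ssd, 1))))
  out <- list(stats = do.call(rbind, stats_rows),
              ssdCounts = counts, n = nrow(cs), notes = notes,
              footer = "p-values are per comparison; no multiple-testing correction applied")
  class(out) <- "correlationReport"
  out
}

#' @export
print.correlationReport <- function(x, ...) {
  cat(sprintf("Correlation report over %d synapses\n", x$n))
  if (!is.null(x$stats)) print(x$stats, row.names = FALSE)
  cat("SSD count distribution:\n")
  print(x$ssdCounts)
  if (length(x$notes)) cat(paste0("  note: ", x$notes, collapse = "\n"), "\n")
  cat(x$footer, "\n")
  invisible(x)
}
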