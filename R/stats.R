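#' Two-sided p-value of a t statistic
#'
#' Exact central-t tail probability, `2 * P(T_df > |t|)`.
#'
#' @param t t statistic.
#' @param df degrees of freedom (>= 1); `n - 1` for a paired t-test,
#'   `n - 2` for the correlation t-transform.
#' @return two-sided p-value.
#' @export
t_to_p <- function(t, df) {
  if (any(df < 1)) stop("parameter error: df must be >= 1")
  2 * stats::pt(-abs(t), df)
}

stat_result <- function(kind, statistic, df, n, p, estimate,
                        note = NULL) {
  structure(list(kind = kind, statistic = statistic, df = df, n = n,
                 p = p, p_adjusted = NULL, estimate = estimate,
                 note = note),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("<%s> statistic = %.3f, df = %g, p = %.4g (estimate %.4g)\n",
              x$kind, x$statistic, x$df, x$p, x$estimate))
  invisible(x)
}

#' Paired t-test on pre/post scores
#'
#' Wraps [stats::t.test()] with `paired = TRUE` on `d = post - pre`:
#' `t = mean(d) / (sd(d) / sqrt(n))`, two-sided p with `n - 1` degrees of
#' freedom.  Zero variance of the differences with a nonzero mean is
#' reported as an infinite-t result (`p = 0`, `note = "infinite-t"`).
#'
#' @param pre,post numeric vectors of equal length (n >= 2), paired by
#'   participant.
#' @return a `stat_result` with `kind = "paired_t"`, the mean difference as
#'   `estimate`.
#' @export
paired_t <- function(pre, post) {
  if (length(pre) != length(post)) stop("pre and post must pair up")
  n <- length(pre)
  if (n < 2) stop("need at least 2 pairs")
  if (anyNA(pre) || anyNA(post)) stop("missing values in paired scores")
  d <- post - pre
  if (stats::sd(d) == 0) {
    if (mean(d) == 0) {
      return(stat_result("paired_t", 0, n - 1, n, 1, 0,
                         note = "zero differences"))
    }
    return(stat_result("paired_t", sign(mean(d)) * Inf, n - 1, n, 0,
                       mean(d), note = "infinite-t"))
  }
  tt <- stats::t.test(post, pre, paired = TRUE)
  stat_result("paired_t", unname(tt$statistic), unname(tt$parameter), n,
              tt$p.value, unname(tt$estimate))
}

#' Pearson correlation test
#'
#' Wraps [stats::cor.test()]: r with two-sided p from
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)` on `n - 2` degrees of freedom.
#'
#' @param x,y numeric vectors of equal length (n >= 3) with nonzero
#'   variance.
#' @return a `stat_result` with `kind = "pearson"`, r as `estimate`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (anyNA(x) || anyNA(y)) stop("missing values in correlation inputs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined-correlation error: constant input")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  stat_result("pearson", unname(ct$statistic), unname(ct$parameter),
              length(x), ct$p.value, unname(ct$estimate))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' False-discovery-rate adjusted p-values,
#' `adjusted_(i) = min_{j >= i} min(1, (m / j) * p_(j))` on the sorted
#' p-values.  Wraps [stats::p.adjust()] with `method = "BH"`.
#'
#' @param p p-values in `[0, 1]`.
#' @return adjusted p-values in the input order.
#' @export
bh_adjust <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1)) {
    stop("parameter error: p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Stroke Impact Scale domain scores
#'
#' Normalizes SIS subscale raw sum scores to 0-100 with the instrument's
#' transformation `(mean item - 1) / 4 * 100` and maps them onto the three
#' reported domains: Impairment = normalized Strength; Function = mean of
#' normalized ADL and Hand Function; Participation = normalized
#' Participation.
#'
#' @param scores named numeric vector (one participant) or matrix/data
#'   frame (participants x subscales) of raw subscale sums, with names
#'   among `adl`, `hand_function`, `participation`, `strength`.
#' @param item_counts items per subscale (defaults: ADL 10, Hand Function
#'   5, Participation 8, Strength 4); items are rated 1-5.
#' @return named vector (or data frame for matrix input) with
#'   `Impairment`, `Function`, `Participation`, each in `[0, 100]`.
#' @export
sis_domains <- function(scores,
                        item_counts = c(adl = 10, hand_function = 5,
                                        participation = 8, strength = 4)) {
  if (is.matrix(scores) || is.data.frame(scores)) {
    out <- t(apply(as.matrix(scores), 1, sis_domains,
                   item_counts = item_counts))
    return(as.data.frame(out))
  }
  need <- names(item_counts)
  if (!all(need %in% names(scores))) {
    stop("scores must be named with: ", paste(need, collapse = ", "))
  }
  mean_item <- unlist(scores[need]) / item_counts
  if (any(mean_item < 1 - 1e-9) || any(mean_item > 5 + 1e-9)) {
    stop("subscale scores imply item means outside the 1-5 SIS scale")
  }
  norm <- (mean_item - 1) / 4 * 100
  c(Impairment = unname(norm["strength"]),
    Function = unname((norm["adl"] + norm["hand_function"]) / 2),
    Participation = unname(norm["participation"]))
}

#' Correlation matrix with family-wise BH adjustment
#'
#' Pearson correlation of every column of `x` against every column of `y`,
#' with Benjamini-Hochberg adjustment applied across all cells of the
#' matrix (the declared family; recorded in the output).
#'
#' @param x,y data frames or matrices with matching rows (participants).
#' @param family label recorded for the adjustment family.
#' @return data frame with one row per cell: `x`, `y`, `r`, `n`, `df`,
#'   `p`, `p_adjusted`, `family`.
#' @export
correlation_matrix <- function(x, y, family = "matrix") {
  x <- as.data.frame(x)
  y <- as.data.frame(y)
  if (nrow(x) != nrow(y)) stop("x and y must have the same rows")
  cells <- expand.grid(x = names(x), y = names(y),
                       stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(cells)), function(i) {
    s <- pearson(x[[cells$x[i]]], y[[cells$y[i]]])
    data.frame(x = cells$x[i], y = cells$y[i], r = s$estimate, n = s$n,
               df = s$df, p = s$p)
  })
  out <- do.call(rbind, res)
  out$p_adjusted <- bh_adjust(out$p)
  out$family <- family
  out
}
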