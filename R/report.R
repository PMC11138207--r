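#' Group-level pre/post analysis report
#'
#' Reproduces the study-style group analysis from a paired clinical table:
#' paired t-tests per measure (two-sided, unadjusted, the tests being
#' treated as independent domains); SIS domain scores derived from the
#' subscales; correlation matrices between motor-control change scores
#' (extensor-ratio change and active ROM change, separately) and the SIS
#' domains at pre and at post, each matrix BH-adjusted as its own family;
#' and, when laterality or peak-CMC change scores are supplied, paired
#' laterality tests and peak-CMC vs FMA-change correlations.
#'
#' Incomplete pairs are dropped per test (complete-case) and the n used is
#' reported; measures listed but absent from the table are reported as
#' missing rather than silently dropped.
#'
#' @param tab a [clinical_table()].
#' @param cmc_change optional data frame with one row per participant and
#'   columns among `laterality_extension_pre/post`,
#'   `laterality_flexion_pre/post`, `peak_cmc_extension_change`,
#'   `peak_cmc_flexion_change` used for the CMC-level tests.
#' @param alpha significance threshold recorded in the report.
#' @return object of class `group_report`: list with `paired_tests`,
#'   `sis_domains`, `correlations` (list of matrices by family),
#'   `cmc_tests`, `missing_measures`, `alpha`.
#' @export
group_report <- function(tab, cmc_change = NULL, alpha = 0.05) {
  stopifnot(inherits(tab, "clinical_table"))
  measures <- unique(tab$measure)

  one_measure <- function(m, col) {
    sub <- tab[tab$measure == m, ]
    stats::setNames(sub[[col]], sub$participant)
  }

  paired_rows <- lapply(measures, function(m) {
    sub <- tab[tab$measure == m, ]
    ok <- stats::complete.cases(sub$pre, sub$post)
    if (sum(ok) < 2) {
      return(data.frame(measure = m, n = sum(ok), t = NA, df = NA, p = NA,
                        mean_diff = NA, pre_mean = NA, post_mean = NA,
                        significant = NA))
    }
    s <- paired_t(sub$pre[ok], sub$post[ok])
    data.frame(measure = m, n = s$n, t = s$statistic, df = s$df, p = s$p,
               mean_diff = s$estimate, pre_mean = mean(sub$pre[ok]),
               post_mean = mean(sub$post[ok]), significant = s$p < alpha)
  })
  paired_tests <- do.call(rbind, paired_rows)

  # SIS domains per participant and timepoint (needs the four subscales)
  sis_measures <- c(adl = "sis_adl", hand_function = "sis_hand",
                    participation = "sis_participation",
                    strength = "sis_strength")
  domains <- NULL
  correlations <- list()
  missing_measures <- setdiff(unname(sis_measures), measures)
  if (length(missing_measures) == 0) {
    participants <- unique(tab$participant)
    build <- function(col) {
      sub <- sapply(sis_measures, function(m) one_measure(m, col)[participants])
      colnames(sub) <- names(sis_measures)
      sis_domains(sub)
    }
    domains <- list(pre = build("pre"), post = build("post"))
    for (d in names(domains)) {
      rownames(domains[[d]]) <- participants
    }

    # change scores of the motor-control measures
    change_of <- function(m) {
      one_measure(m, "post")[participants] - one_measure(m, "pre")[participants]
    }
    for (motor in intersect(c("er_extension", "active_extension",
                              "er_flexion", "active_flexion"), measures)) {
      ch <- data.frame(change = change_of(motor))
      names(ch) <- paste0(motor, "_change")
      for (d in names(domains)) {
        fam <- paste(motor, d, sep = "_x_sis_")
        correlations[[fam]] <- correlation_matrix(ch, domains[[d]],
                                                  family = fam)
      }
    }
  }

  cmc_tests <- NULL
  if (!is.null(cmc_change)) {
    rows <- list()
    for (task in c("extension", "flexion")) {
      pre_col <- paste0("laterality_", task, "_pre")
      post_col <- paste0("laterality_", task, "_post")
      if (all(c(pre_col, post_col) %in% names(cmc_change))) {
        s <- paired_t(cmc_change[[pre_col]], cmc_change[[post_col]])
        rows[[length(rows) + 1]] <- data.frame(
          test = paste0("laterality_", task), kind = "paired_t",
          statistic = s$statistic, df = s$df, n = s$n, p = s$p,
          estimate = s$estimate)
      }
      pk <- paste0("peak_cmc_", task, "_change")
      if (pk %in% names(cmc_change) && "fma" %in% measures) {
        fma_ch <- one_measure("fma", "post") - one_measure("fma", "pre")
        s <- pearson(cmc_change[[pk]], unname(fma_ch))
        rows[[length(rows) + 1]] <- data.frame(
          test = paste0("peak_cmc_", task, "_vs_fma_change"),
          kind = "pearson", statistic = s$statistic, df = s$df, n = s$n,
          p = s$p, estimate = s$estimate)
      }
    }
    if (length(rows)) cmc_tests <- do.call(rbind, rows)
  }

  structure(list(paired_tests = paired_tests, sis_domains = domains,
                 correlations = correlations, cmc_tests = cmc_tests,
                 missing_measures = missing_measures, alpha = alpha),
            class = "group_report")
}

#' @export
print.group_report <- function(x, ...) {
  cat("<group_report> paired pre/post tests (alpha =", x$alpha, "):\n")
  print(format(x$paired_tests, digits = 3), row.names = FALSE)
  if (length(x$correlations)) {
    cat("\ncorrelation families:", paste(names(x$correlations),
                                         collapse = ", "), "\n")
  }
  if (!is.null(x$cmc_tests)) {
    cat("\nCMC tests:\n")
    print(format(x$cmc_tests, digits = 3), row.names = FALSE)
  }
  if (length(x$missing_measures)) {
    cat("\nmissing measures:", paste(x$missing_measures, collapse = ", "),
        "\n")
  }
  invisible(x)
}
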