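#' Normality-gated paired comparison
#'
#' The inference stage of the analysis: paired differences are first checked
#' for normality with the Shapiro-Wilk test; if normality is not rejected at
#' `alpha` the paired Student t-test is used, otherwise the Wilcoxon
#' signed-rank test. Two-sided throughout.
#'
#' @param x,y Paired samples of equal length (at least 3 complete pairs).
#' @param alpha Significance level for both the normality gate and the
#'   comparison (default 0.05).
#' @return A list of class `paired_test` with `normality_p`, `test_used`
#'   (`"paired-t"` or `"wilcoxon-signed-rank"`), `statistic`, `p_value`,
#'   `alpha`, `significant`, `n_pairs`.
#' @examples
#' set.seed(1)
#' x <- rnorm(20); paired_compare(x + 0.5, x)
#' @export
paired_compare <- function(x, y, alpha = 0.05) {
  if (length(x) != length(y)) {
    stop("`x` and `y` must be paired (equal lengths)", call. = FALSE)
  }
  if (anyNA(x) || anyNA(y)) stop("missing pairs are not allowed",
                                 call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 pairs", call. = FALSE)
  d <- x - y
  if (all(d == d[1L])) {
    stop("degenerate input: paired differences are constant; neither test is defined",
         call. = FALSE)
  }
  normality_p <- stats::shapiro.test(d)$p.value
  if (normality_p >= alpha) {
    ht <- stats::t.test(x, y, paired = TRUE)
    test_used <- "paired-t"
  } else {
    ht <- stats::wilcox.test(x, y, paired = TRUE, exact = FALSE,
                             correct = TRUE)
    test_used <- "wilcoxon-signed-rank"
  }
  structure(
    list(normality_p = normality_p, test_used = test_used,
         statistic = unname(ht$statistic), p_value = ht$p.value,
         alpha = alpha, significant = ht$p.value < alpha,
         n_pairs = length(x)),
    class = "paired_test"
  )
}

#' @export
print.paired_test <- function(x, ...) {
  cat(sprintf(
    "Paired comparison (%s; Shapiro-Wilk p = %.3g): statistic = %.3g, p = %.3g%s\n",
    x$test_used, x$normality_p, x$statistic, x$p_value,
    if (x$significant) " *" else ""))
  invisible(x)
}

#' Paired comparisons across a fitted study table
#'
#' Runs [paired_compare()] for the contrasts of the study design: for each
#' muscle and parameter, the field contrast (low vs high field) within each
#' state, and the activation contrast (baseline vs activated) within each
#' field. Pairing is by subject and slice (`pooling = "slices"`, each slice
#' of each subject one observation) or by subject after averaging slices
#' (`pooling = "subjects"`). Slice-level pooling treats within-subject
#' slices as independent, which overstates the effective sample size; the
#' subject-level pooling is the conservative alternative.
#'
#' @param fits A fit table from [fit_signal_table()] (needs columns
#'   `subject`, `field_T`, `muscle`, `state`, `slice` and the parameter
#'   columns).
#' @param parameters Which fitted parameters to compare (default `d` and
#'   `f`).
#' @param pooling `"slices"` or `"subjects"`.
#' @param alpha Significance level.
#' @return A data.frame with one row per (parameter, muscle, contrast):
#'   `test_used`, `normality_p`, `statistic`, `p_value`, `significant`,
#'   `n_pairs`.
#' @export
compare_study <- function(fits, parameters = c("f", "d"),
                          pooling = c("slices", "subjects"),
                          alpha = 0.05) {
  pooling <- match.arg(pooling)
  stopifnot(all(c("subject", "field_T", "muscle", "state", "slice",
                  parameters) %in% names(fits)))
  if (pooling == "subjects") {
    agg <- stats::aggregate(
      fits[parameters],
      by = fits[c("subject", "field_T", "muscle", "state")], FUN = mean)
    agg$slice <- 1L
    fits <- agg
  }
  fields <- sort(unique(fits$field_T))
  states <- unique(fits$state)
  rows <- list()
  add <- function(parameter, muscle, contrast, x, y) {
    res <- paired_compare(x, y, alpha = alpha)
    rows[[length(rows) + 1L]] <<- data.frame(
      parameter = parameter, muscle = muscle, contrast = contrast,
      test_used = res$test_used, normality_p = res$normality_p,
      statistic = res$statistic, p_value = res$p_value,
      significant = res$significant, n_pairs = res$n_pairs,
      stringsAsFactors = FALSE)
  }
  key <- function(df) paste(df$subject, df$slice)
  for (parameter in parameters) {
    for (mus in unique(fits$muscle)) {
      sub <- fits[fits$muscle == mus, , drop = FALSE]
      if (length(fields) == 2L) {
        for (st in states) {
          a <- sub[sub$state == st & sub$field_T == fields[1L], ]
          b <- sub[sub$state == st & sub$field_T == fields[2L], ]
          b <- b[match(key(a), key(b)), ]
          add(parameter, mus,
              sprintf("%gT vs %gT (%s)", fields[1L], fields[2L], st),
              a[[parameter]], b[[parameter]])
        }
      }
      for (fl in fields) {
        a <- sub[sub$field_T == fl & sub$state == "activated", ]
        b <- sub[sub$field_T == fl & sub$state == "baseline", ]
        b <- b[match(key(a), key(b)), ]
        if (nrow(a) >= 3L && nrow(a) == nrow(b)) {
          add(parameter, mus,
              sprintf("activated vs baseline (%g T)", fl),
              a[[parameter]], b[[parameter]])
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
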