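#' Pearson chi-square test on a group-by-category contingency table
#'
#' Expected counts come from the row/column marginals; df = (R-1)(C-1).
#' Cells with expected count below 5 are flagged in the report details
#' (the asymptotic test is unreliable there). No Yates continuity
#' correction is applied by default (the convention for R x C tables in
#' the screening workflow this reproduces); a toggle is provided.
#'
#' @param gc a [GroupCounts-class].
#' @param correct apply the Yates continuity correction (2 x 2 only).
#' @param alpha significance level recorded in the report.
#' @return a [StatReport-class] with the chi-square statistic, df and
#'   p-value; \code{details} holds the expected counts and low-count flags.
#' @examples
#' gc <- GroupCounts(matrix(c(76, 3, 14, 94), 2,
#'   dimnames = list(c("vehicle", "1e-5 M"), c("MII", "abnormal"))))
#' contingencyChiSquare(gc)
#' @export
contingencyChiSquare <- function(gc, correct = FALSE, alpha = 0.05) {
  stopifnot(is(gc, "GroupCounts"))
  m <- counts(gc)
  if (any(rowSums(m) == 0))
    stop("degenerate table: a group has zero total")
  ct <- suppressWarnings(stats::chisq.test(m, correct = correct))
  lowExp <- which(ct$expected < 5, arr.ind = TRUE)
  new("StatReport",
      testName = "Pearson chi-square",
      statistic = unname(ct$statistic),
      df = unname(ct$parameter),
      pValue = unname(ct$p.value),
      alpha = alpha,
      details = list(expected = ct$expected,
                     low_expected_cells = lowExp,
                     yates_correction = correct))
}

#' Post hoc Bonferroni-corrected two-proportion z-tests
#'
#' For each compared pair of groups the proportion of \code{category}
#' outcomes is compared with the pooled two-proportion z statistic
#' \deqn{z = (p1 - p2) / \sqrt{p(1-p)(1/n_1 + 1/n_2)}}
#' with \eqn{p} the pooled proportion; two-sided p-values are Bonferroni
#' corrected by the number of comparisons performed. When the pooled
#' proportion is 0 or 1 the z statistic is undefined and the pair falls
#' back to Fisher's exact test, flagged in the \code{method} column.
#'
#' @param gc a [GroupCounts-class].
#' @param category the category whose proportion is compared (default:
#'   first category).
#' @param comparisons \code{"all-pairs"} (default; the Bonferroni family is
#'   every pairwise group comparison) or \code{"vs-reference"}.
#' @param reference reference group label for \code{"vs-reference"}.
#' @param alpha significance level for the \code{significant} flags.
#' @return data.frame with one row per comparison: \code{group1},
#'   \code{group2}, \code{category}, \code{statistic}, \code{raw_p},
#'   \code{adjusted_p}, \code{significant}, \code{method}.
#' @examples
#' gc <- GroupCounts(matrix(c(72, 76, 72, 81, 3, 18, 14, 16, 20, 94), 5,
#'   dimnames = list(c("control", "vehicle", "1e-9 M", "1e-7 M", "1e-5 M"),
#'                   c("MII", "abnormal"))))
#' posthocProportionZTests(gc, "MII")
#' @export
posthocProportionZTests <- function(gc, category = NULL,
                                    comparisons = c("all-pairs",
                                                    "vs-reference"),
                                    reference = NULL, alpha = 0.05) {
  stopifnot(is(gc, "GroupCounts"))
  comparisons <- match.arg(comparisons)
  m <- counts(gc)
  if (is.null(category)) category <- colnames(m)[1L]
  if (!category %in% colnames(m))
    stop(sprintf("category '%s' not found", category))
  x <- m[, category]
  n <- rowSums(m)
  groups <- rownames(m)

  if (comparisons == "all-pairs") {
    prs <- utils::combn(groups, 2L)
  } else {
    if (is.null(reference)) reference <- groups[1L]
    if (!reference %in% groups)
      stop(sprintf("reference group '%s' not found", reference))
    others <- setdiff(groups, reference)
    prs <- rbind(rep(reference, length(others)), others)
  }
  nComp <- ncol(prs)

  out <- lapply(seq_len(nComp), function(j) {
    g1 <- prs[1L, j]; g2 <- prs[2L, j]
    pPool <- (x[g1] + x[g2]) / (n[g1] + n[g2])
    if (pPool == 0 || pPool == 1) {
      tab <- rbind(c(x[g1], n[g1] - x[g1]), c(x[g2], n[g2] - x[g2]))
      p <- stats::fisher.test(tab)$p.value
      data.frame(group1 = g1, group2 = g2, category = category,
                 statistic = NA_real_, raw_p = p, method = "fisher-exact",
                 stringsAsFactors = FALSE)
    } else {
      z <- (x[g1] / n[g1] - x[g2] / n[g2]) /
        sqrt(pPool * (1 - pPool) * (1 / n[g1] + 1 / n[g2]))
      data.frame(group1 = g1, group2 = g2, category = category,
                 statistic = unname(z),
                 raw_p = 2 * stats::pnorm(-abs(z)), method = "pooled-z",
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, out)
  out$adjusted_p <- pmin(1, out$raw_p * nComp)
  out$significant <- out$adjusted_p < alpha
  rownames(out) <- NULL
  out[, c("group1", "group2", "category", "statistic", "raw_p",
          "adjusted_p", "significant", "method")]
}

.checkGroupedValues <- function(values, groups) {
  if (length(values) != length(groups))
    stop("values and groups must have equal length")
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2L)
    stop("at least 2 groups are required")
  droplevels(groups)
}

#' One-way ANOVA with Tukey HSD post hoc comparisons
#'
#' F test with (k-1, N-k) degrees of freedom followed by Tukey's honestly
#' significant difference test on all group pairs (studentized-range
#' distribution). When every group is the same constant the F statistic is
#' a 0/0 form; this is reported as no effect (p = NA, no significant
#' pairs).
#'
#' @param values numeric observations.
#' @param groups group labels, same length as \code{values}; every group
#'   needs >= 2 observations.
#' @param alpha significance level for the pairwise flags.
#' @return a [StatReport-class]; \code{pairwise} holds the Tukey
#'   comparisons (difference, raw and adjusted p). Tukey p-values are
#'   already family-adjusted, so \code{raw_p} equals \code{adjusted_p}.
#' @examples
#' anovaTukey(c(1, 2, 3, 7, 8, 9), rep(c("a", "b"), each = 3))
#' @export
anovaTukey <- function(values, groups, alpha = 0.05) {
  groups <- .checkGroupedValues(values, groups)
  if (any(table(groups) < 2L))
    stop("every group needs at least 2 observations")
  k <- nlevels(groups); N <- length(values)
  constantInput <- diff(range(values)) == 0
  if (!constantInput) {
    dfFit <- data.frame(y = values, g = groups)
    fit <- stats::aov(y ~ g, data = dfFit)
    an <- summary(fit)[[1L]]
    fStat <- an[["F value"]][1L]
    p <- an[["Pr(>F)"]][1L]
    dfs <- an[["Df"]]
  } else {
    fStat <- NA_real_; dfs <- c(k - 1, N - k)
  }

  if (constantInput || is.na(fStat)) {
    # zero variance everywhere with equal means: F is a 0/0 form
    pw <- data.frame(group1 = character(0), group2 = character(0),
                     difference = numeric(0), statistic = numeric(0),
                     raw_p = numeric(0), adjusted_p = numeric(0),
                     significant = logical(0))
    return(new("StatReport", testName = "one-way ANOVA",
               statistic = NA_real_, df = dfs, pValue = NA_real_,
               pairwise = pw, alpha = alpha,
               details = list(note = "zero within-group variance, equal means")))
  }

  tk <- stats::TukeyHSD(fit)$g
  cmp <- strsplit(rownames(tk), "-", fixed = TRUE)
  pw <- data.frame(
    group1 = vapply(cmp, `[`, "", 1L),
    group2 = vapply(cmp, `[`, "", 2L),
    difference = tk[, "diff"],
    statistic = NA_real_,
    raw_p = tk[, "p adj"],
    adjusted_p = tk[, "p adj"],
    significant = tk[, "p adj"] < alpha,
    stringsAsFactors = FALSE
  )
  rownames(pw) <- NULL
  new("StatReport", testName = "one-way ANOVA", statistic = fStat,
      df = dfs, pValue = p, pairwise = pw, alpha = alpha,
      details = list(posthoc = "Tukey HSD"))
}

# Kruskal-Wallis H with tie correction, computed from ranks.
.kwH <- function(values, groups) {
  r <- rank(values)
  N <- length(values)
  sums <- tapply(r, groups, sum)
  ns <- tabulate(groups)
  H <- 12 / (N * (N + 1)) * sum(sums^2 / ns) - 3 * (N + 1)
  ties <- table(values)
  C <- 1 - sum(ties^3 - ties) / (N^3 - N)
  if (C > 0) H <- H / C
  H
}

#' Kruskal-Wallis test with Dunn pairwise post hoc comparisons
#'
#' Tie-corrected H with df = k - 1. Pairwise comparisons follow Dunn's
#' procedure: z statistics built from mean ranks with tie-corrected
#' variance
#' \deqn{z_{ij} = (\bar R_i - \bar R_j) / \sqrt{\left(\frac{N(N+1)}{12} -
#'   \frac{\sum (t^3 - t)}{12(N-1)}\right)\left(\frac{1}{n_i} +
#'   \frac{1}{n_j}\right)}}
#' with Bonferroni adjustment over all pairs. All values tied yields H = 0,
#' p = 1.
#'
#' The omnibus p-value is asymptotic (chi-square) by default; with
#' \code{pMethod = "permutation"} it is instead estimated as the fraction
#' of \code{nPerm} random relabelings of the observations whose H reaches
#' the observed H (with the +1 correction for the observed arrangement).
#'
#' @param values numeric observations.
#' @param groups group labels, same length as \code{values}.
#' @param alpha significance level for the pairwise flags.
#' @param pMethod \code{"asymptotic"} or \code{"permutation"}.
#' @param nPerm number of permutations for \code{pMethod = "permutation"}.
#' @param seed seed for the permutation draw.
#' @return a [StatReport-class] with H, df, p and the Dunn pairwise table.
#' @examples
#' kruskalDunn(c(1, 2, 3, 4, 5, 6, 7, 8, 9), rep(c("a", "b", "c"), each = 3))
#' @export
kruskalDunn <- function(values, groups, alpha = 0.05,
                        pMethod = c("asymptotic", "permutation"),
                        nPerm = 1e5, seed = 1L) {
  pMethod <- match.arg(pMethod)
  groups <- .checkGroupedValues(values, groups)
  N <- length(values)
  if (N < 3L) stop("at least 3 observations are required")
  k <- nlevels(groups)

  allTied <- diff(range(values)) == 0
  if (allTied) {
    H <- 0; p <- 1
  } else {
    kt <- stats::kruskal.test(values, groups)
    H <- unname(kt$statistic)
    p <- unname(kt$p.value)
    if (pMethod == "permutation") {
      # permuting labels == permuting the (fixed) rank vector
      gi <- as.integer(groups)
      r0 <- rank(values)
      ns0 <- tabulate(gi)
      ties0 <- table(values)
      C0 <- 1 - sum(ties0^3 - ties0) / (N^3 - N)
      p <- withSeed(seed, {
        R <- vapply(seq_len(nPerm), function(i) sample(r0), numeric(N))
        sums <- rowsum(R, gi)
        hPerm <- 12 / (N * (N + 1)) * colSums(sums^2 / ns0) - 3 * (N + 1)
        if (C0 > 0) hPerm <- hPerm / C0
        (sum(hPerm >= H - 1e-12) + 1) / (nPerm + 1)
      })
    }
  }

  r <- rank(values)
  rbar <- tapply(r, groups, mean)
  ns <- tabulate(groups)
  ties <- table(values)
  T <- sum(ties^3 - ties)
  varTerm <- N * (N + 1) / 12 - T / (12 * (N - 1))

  prs <- utils::combn(levels(groups), 2L)
  nComp <- ncol(prs)
  z <- vapply(seq_len(nComp), function(j) {
    i1 <- match(prs[1L, j], levels(groups))
    i2 <- match(prs[2L, j], levels(groups))
    se <- sqrt(varTerm * (1 / ns[i1] + 1 / ns[i2]))
    if (se == 0) return(0)
    (rbar[i1] - rbar[i2]) / se
  }, numeric(1))
  rawP <- 2 * stats::pnorm(-abs(z))
  pw <- data.frame(
    group1 = prs[1L, ], group2 = prs[2L, ],
    statistic = unname(z), raw_p = rawP,
    adjusted_p = pmin(1, rawP * nComp),
    significant = pmin(1, rawP * nComp) < alpha,
    stringsAsFactors = FALSE
  )
  new("StatReport", testName = "Kruskal-Wallis",
      statistic = H, df = k - 1, pValue = p, pairwise = pw, alpha = alpha,
      details = list(posthoc = "Dunn (Bonferroni)", p_method = pMethod))
}

#' Derive per-group percentages from a contingency table
#'
#' Each group's category counts are expressed as percentages of the group
#' total, reported both at full precision and rounded half-up to integer
#' percent (the printed-table convention). For blastocyst tables the group
#' total is the number of presumptive zygotes entering culture, so the
#' percentage is the blastocyst rate per fertilized oocyte.
#'
#' @param gc a [GroupCounts-class].
#' @param kind endpoint label recorded in the output (\code{"meiotic"},
#'   \code{"cleavage"}, \code{"blastocyst"}, or any string).
#' @return data.frame with columns \code{kind}, \code{group},
#'   \code{category}, \code{count}, \code{total}, \code{pct_exact},
#'   \code{pct}.
#' @examples
#' gc <- GroupCounts(matrix(c(76, 3, 14, 94), 2,
#'   dimnames = list(c("vehicle", "1e-5 M"), c("MII", "abnormal"))))
#' deriveRates(gc, "meiotic")
#' @export
deriveRates <- function(gc, kind = "endpoint") {
  stopifnot(is(gc, "GroupCounts"))
  m <- counts(gc)
  totals <- rowSums(m)
  if (any(totals == 0))
    stop(sprintf("zero denominator for group(s): %s",
                 paste(rownames(m)[totals == 0], collapse = ", ")))
  out <- expand.grid(group = rownames(m), category = colnames(m),
                     stringsAsFactors = FALSE)
  out$kind <- kind
  out$count <- m[cbind(out$group, out$category)]
  out$total <- totals[out$group]
  out$pct_exact <- 100 * out$count / out$total
  out$pct <- roundHalfUp(out$pct_exact)
  out[, c("kind", "group", "category", "count", "total",
          "pct_exact", "pct")]
}
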