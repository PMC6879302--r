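#' Packaged sperm-defect count tables
#'
#' Two per-testis count tables of sperm DNA morphology categories, keyed by
#' genotype and testis index: \code{"table7"} scores post-canoe stage bundles
#' (normal, lagging, kinked, knotted, needle-eyed, decondensed) and
#' \code{"table8"} canoe-stage morphology (normal vs abnormal canoe). They
#' ship as TSV fixtures under \code{inst/extdata}.
#'
#' @param name \code{"table7"} or \code{"table8"}
#' @return data.frame with \code{genotype}, \code{testis} and one column per
#'   phenotype category
#' @export
defect_table_fixture <- function(name = c("table7", "table8")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".tsv"), package = "satanchor",
                      mustWork = TRUE)
  read_defect_table(path)
}

#' Read a per-testis defect count table
#'
#' @param path TSV with a \code{genotype} column, a \code{testis} index
#'   column and one non-negative integer count column per phenotype category
#' @return validated data.frame
#' @export
read_defect_table <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("genotype", "testis") %in% names(d)))
    stop("defect table needs 'genotype' and 'testis' columns")
  cnt <- setdiff(names(d), c("genotype", "testis"))
  for (cc in cnt) {
    if (any(is.na(d[[cc]])) || any(d[[cc]] < 0) || any(d[[cc]] %% 1 != 0))
      stop("counts in column '", cc, "' must be non-negative integers")
  }
  d
}

#' Pooled phenotype proportions per genotype
#'
#' Category counts are summed over testes within each genotype and expressed
#' as the pooled percent of each phenotype relative to the total bundles
#' scored for that genotype. Pooling is invariant to row order and to
#' splitting rows that sum to the same counts.
#'
#' @param counts a defect count table (see [read_defect_table()])
#' @return data.frame in long form: \code{genotype}, \code{category},
#'   \code{count}, \code{total}, \code{percent} (percents sum to 100 within
#'   each genotype)
#' @examples
#' pooled_proportions(defect_table_fixture("table8"))
#' @export
pooled_proportions <- function(counts) {
  if (nrow(counts) == 0L) stop("empty defect table")
  cat_cols <- setdiff(names(counts), c("genotype", "testis"))
  out <- list()
  for (g in unique(counts$genotype)) {
    rows <- counts[counts$genotype == g, cat_cols, drop = FALSE]
    pooled <- vapply(rows, sum, numeric(1))
    tot <- sum(pooled)
    if (tot == 0)
      stop("all-zero counts for genotype '", g, "': proportions undefined")
    out[[g]] <- data.frame(genotype = g, category = cat_cols,
                           count = as.integer(pooled), total = as.integer(tot),
                           percent = 100 * pooled / tot,
                           stringsAsFactors = FALSE, row.names = NULL)
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Welch two-sample t test (two-tailed, unequal variance)
#'
#' The spreadsheet "type 3" t test: Welch statistic with
#' Welch--Satterthwaite degrees of freedom and a two-sided p value from
#' Student's t distribution. Reduces to the equal-variance test when
#' variances and sample sizes are equal.
#'
#' @param x,y numeric samples of size >= 2; at least one must have nonzero
#'   variance
#' @return an object of class \code{"htest"} with \code{statistic} (t),
#'   \code{parameter} (df) and \code{p.value}
#' @examples
#' welch_t_test(c(1, 2, 3, 4), c(2, 4, 6, 9))
#' @export
welch_t_test <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L)
    stop("both samples need at least 2 observations")
  v1 <- var(x); v2 <- var(y)
  if (v1 == 0 && v2 == 0)
    stop("degenerate input: both samples have zero variance")
  n1 <- length(x); n2 <- length(y)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(-abs(tstat), df)
  structure(list(statistic = c(t = tstat), parameter = c(df = df),
                 p.value = p,
                 estimate = c(`mean of x` = mean(x), `mean of y` = mean(y)),
                 method = "Welch two-sample t-test (two-tailed)",
                 data.name = paste(deparse(substitute(x)), "and",
                                   deparse(substitute(y)))),
            class = "htest")
}

#' Per-vial viability ratios and group comparison
#'
#' For each vial, the ratio of RNAi (non-Tubby) to Tubby sibling pupae.
#' Vials with no Tubby pupae are excluded with a warning (ratio undefined).
#' When \code{group} labels two groups, the per-vial ratios are compared with
#' [welch_t_test()].
#'
#' @param n_rnai,n_tubby integer pupae counts per vial
#' @param group optional group label per vial (exactly 2 distinct values to
#'   trigger the test)
#' @return list with \code{vials} (data.frame of surviving vials with
#'   \code{ratio}) and \code{test} (an \code{htest} or \code{NULL})
#' @export
viability_ratio <- function(n_rnai, n_tubby, group = NULL) {
  stopifnot(length(n_rnai) == length(n_tubby))
  if (is.null(group)) group <- rep(NA_character_, length(n_rnai))
  ok <- n_tubby >= 1
  if (!any(ok)) stop("no valid vials (all Tubby counts are zero)")
  if (any(!ok))
    warning(sum(!ok), " vial(s) excluded: no Tubby pupae scored")
  vials <- data.frame(group = group[ok], n_rnai = n_rnai[ok],
                      n_tubby = n_tubby[ok],
                      ratio = n_rnai[ok] / n_tubby[ok],
                      stringsAsFactors = FALSE)
  test <- NULL
  gl <- unique(vials$group)
  if (length(gl) == 2L && !anyNA(gl)) {
    test <- welch_t_test(vials$ratio[vials$group == gl[1]],
                         vials$ratio[vials$group == gl[2]])
  }
  list(vials = vials, test = test)
}

#' Fertility summary across parental sets
#'
#' Males whose survival condition failed (the male or all its females died
#' before the scoring day) are invalid and excluded from denominators.
#' Reports the percent fertile per parental set and the cross-set mean and
#' sample standard deviation.
#'
#' @param outcomes data.frame with columns \code{set} (parental set label),
#'   \code{fertile} (logical) and \code{valid} (logical survival flag)
#' @return list with \code{per_set} (data.frame: \code{set}, \code{n_valid},
#'   \code{n_fertile}, \code{percent}), \code{mean} and \code{sd}
#' @export
fertility_summary <- function(outcomes) {
  stopifnot(all(c("set", "fertile", "valid") %in% names(outcomes)))
  per <- list()
  for (s in unique(outcomes$set)) {
    o <- outcomes[outcomes$set == s & outcomes$valid, , drop = FALSE]
    if (nrow(o) == 0L) {
      warning("parental set '", s, "' has no valid males; excluded")
      next
    }
    per[[length(per) + 1L]] <- data.frame(
      set = s, n_valid = nrow(o), n_fertile = sum(o$fertile),
      percent = 100 * sum(o$fertile) / nrow(o), stringsAsFactors = FALSE)
  }
  if (length(per) == 0L) stop("no parental set with valid males")
  per <- do.call(rbind, per)
  list(per_set = per, mean = mean(per$percent),
       sd = if (nrow(per) > 1L) sd(per$percent) else NA_real_)
}
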