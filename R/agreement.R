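#' Percent error between manual and automatic SUR
#'
#' |manual - automatic| / manual x 100, the denominator being the signed
#' manual value as conventionally printed (identical to the absolute form
#' whenever manual > 0).
#'
#' @param sur_manual,sur_automatic SUR values; `sur_manual` must be nonzero.
#' @return percent error (vectorized).
#' @export
percent_error <- function(sur_manual, sur_automatic) {
  if (any(sur_manual == 0)) stop("sur_manual must be nonzero")
  abs(sur_manual - sur_automatic) / sur_manual * 100
}

#' Between-method variability
#'
#' |manual - automatic| / ((manual + automatic) / 2) per subject; the
#' cohort summary reported elsewhere is mean +/- sample SD.
#'
#' @param sur_manual,sur_automatic SUR values; pair means must be nonzero.
#' @return per-subject variability (vectorized).
#' @export
variability <- function(sur_manual, sur_automatic) {
  mid <- (sur_manual + sur_automatic) / 2
  if (any(mid == 0)) stop("pair mean is zero; variability undefined")
  abs(sur_manual - sur_automatic) / mid
}

#' One-way intraclass correlation
#'
#' ICC = (MSBS - MSWS) / (MSBS + (k - 1) MSWS) from a one-way
#' random-effects ANOVA over subjects, with k = 2 paired measurements
#' (manual and automatic) per subject.  Negative values are returned
#' unclamped: MSWS > MSBS means the between-method disagreement exceeds the
#' between-subject spread.
#'
#' @param x,y paired measurements (k = 2), length n >= 2.
#' @return list with `icc` and `components` (`msbs`, `msws`, `k`, `n`).
#' @export
icc_oneway <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 2) stop("need at least 2 subjects")
  if (anyNA(x) || anyNA(y)) stop("missing values in paired measurements")
  k <- 2
  m <- (x + y) / 2
  g <- mean(m)
  msbs <- k * sum((m - g)^2) / (n - 1)
  msws <- sum((x - m)^2 + (y - m)^2) / (n * (k - 1))
  icc <- (msbs - msws) / (msbs + (k - 1) * msws)
  list(icc = icc, components = list(msbs = msbs, msws = msws, k = k, n = n))
}

#' Pearson correlation of paired SURs
#'
#' @param x,y paired values, n >= 2, each with nonzero variance.
#' @export
pearson <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 2) stop("need at least 2 pairs")
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance; correlation undefined")
  cor(x, y)
}

#' Bland-Altman agreement analysis
#'
#' Differences d_i = manual_i - automatic_i; mean difference (systematic
#' bias) and limits of agreement mean +/- 1.96 SD(d).  Per-subject plotting
#' coordinates (pair mean, difference) are included.
#'
#' @param sur_manual,sur_automatic paired SURs, n >= 2.
#' @param direction `"manual_minus_automatic"` (default) or
#'   `"automatic_minus_manual"`.
#' @return list with `mean_diff`, `loa_low`, `loa_high`, `sd_diff`, and a
#'   data.frame `points` (mean, diff).
#' @export
bland_altman <- function(sur_manual, sur_automatic,
                         direction = c("manual_minus_automatic",
                                       "automatic_minus_manual")) {
  direction <- match.arg(direction)
  stopifnot(length(sur_manual) == length(sur_automatic))
  if (length(sur_manual) < 2) stop("need at least 2 pairs")
  d <- sur_manual - sur_automatic
  if (direction == "automatic_minus_manual") d <- -d
  md <- mean(d); s <- sd(d)
  list(mean_diff = md, loa_low = md - 1.96 * s, loa_high = md + 1.96 * s,
       sd_diff = s,
       points = data.frame(mean = (sur_manual + sur_automatic) / 2, diff = d))
}

#' Two-sample t test
#'
#' Pooled-variance Student t by default (Welch behind `welch = TRUE`),
#' two-sided p from the t distribution.  If both groups are degenerate
#' (zero variance) with equal means, returns t = 0, p = 1 by convention.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @param welch use the Welch (unequal-variance) form.
#' @return list with `t`, `p`, `df`.
#' @export
ttest_two_sample <- function(a, b, welch = FALSE) {
  if (length(a) < 2 || length(b) < 2) stop("each group needs n >= 2")
  if (sd(a) == 0 && sd(b) == 0) {
    if (mean(a) == mean(b))
      return(list(t = 0, p = 1, df = length(a) + length(b) - 2))
    stop("zero variance with unequal means: t is unbounded")
  }
  tt <- stats::t.test(a, b, var.equal = !welch)
  list(t = unname(tt$statistic), p = tt$p.value, df = unname(tt$parameter))
}

#' Method-agreement report for one automatic method
#'
#' Assembles the between-method statistics for `sur_<method>` against
#' `sur_manual` in a paired SUR table: Pearson correlation, per-subject
#' variability summarized as mean +/- sample SD (subjects with a zero pair
#' mean are excluded with a note), Bland-Altman mean difference
#' (manual - automatic) with limits of agreement, and the one-way ICC with
#' its ANOVA components.
#'
#' @param table data.frame with `subject_id`, `sur_manual` and
#'   `sur_<method>` columns (see [sur_table()] / [read_sur_table()]).
#' @param method automatic method label, e.g. `"MBT"`.
#' @return An object of class `agreement_report`.
#' @export
agreement_report <- function(table, method) {
  col <- paste0("sur_", method)
  if (!col %in% names(table))
    stop("method column '", col, "' not found; available: ",
         paste(setdiff(names(table), c("subject_id", "sur_manual")),
               collapse = ", "))
  if (!"sur_manual" %in% names(table)) stop("table lacks 'sur_manual'")
  if (anyDuplicated(table$subject_id)) stop("duplicate subject_ids")
  m <- table$sur_manual; a <- table[[col]]
  if (anyNA(m) || anyNA(a)) stop("missing values within compared pairs")
  ok <- (m + a) / 2 != 0
  v <- variability(m[ok], a[ok])
  structure(list(method = method, n = length(m),
                 pearson_r = pearson(m, a),
                 variability_mean = mean(v),
                 variability_sd = sd(v),
                 n_variability_excluded = sum(!ok),
                 bland_altman = bland_altman(m, a),
                 icc = icc_oneway(m, a)),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement_report> %s vs manual (n = %d)\n", x$method, x$n))
  cat(sprintf("  Pearson r       %6.3f\n", x$pearson_r))
  cat(sprintf("  Variability     %.3f +/- %.3f%s\n", x$variability_mean,
              x$variability_sd,
              if (x$n_variability_excluded)
                sprintf("  (%d excluded: zero pair mean)",
                        x$n_variability_excluded) else ""))
  cat(sprintf("  Mean diff (M-A) %6.3f  [LoA %.3f, %.3f]\n",
              x$bland_altman$mean_diff, x$bland_altman$loa_low,
              x$bland_altman$loa_high))
  cat(sprintf("  ICC (one-way)   %6.3f  (MSBS %.4g, MSWS %.4g)\n",
              x$icc$icc, x$icc$components$msbs, x$icc$components$msws))
  invisible(x)
}

norm_header <- function(x) {
  x <- tolower(trimws(x))
  x <- sub("^sur[ ._-]*", "", x)
  x
}

#' Read a paired SUR table from CSV or XLSX
#'
#' Columns are matched case-insensitively against the synonyms
#' subject/id, manual, and arbitrary automatic method names (e.g. MBT,
#' HBT, HMPAO); an explicit `mapping` (named character vector,
#' standard name -> file column name) overrides the automatic matching.
#'
#' @param path `.csv` or `.xlsx` file.
#' @param mapping optional named character vector, e.g.
#'   `c(subject_id = "Pat ID", manual = "SUR manual")`.
#' @return data.frame with `subject_id`, `sur_manual` and one
#'   `sur_<method>` column per automatic method.
#' @export
read_sur_table <- function(path, mapping = NULL) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    csv = read.csv(path, check.names = FALSE),
    xlsx = {
      if (!requireNamespace("readxl", quietly = TRUE))
        stop("reading .xlsx requires the readxl package")
      as.data.frame(readxl::read_xlsx(path), check.names = FALSE)
    },
    stop("unsupported table format: .", ext))
  hdr <- norm_header(names(raw))
  if (!is.null(mapping)) {
    for (std in names(mapping)) {
      idx <- match(mapping[[std]], names(raw))
      if (is.na(idx)) stop("mapped column not found: ", mapping[[std]])
      hdr[idx] <- norm_header(std)
    }
  }
  id_idx <- which(hdr %in% c("subject", "subject_id", "id", "subj"))
  man_idx <- which(hdr == "manual")
  if (!length(man_idx)) stop("no manual SUR column found in ", path)
  out <- data.frame(
    subject_id = if (length(id_idx)) as.character(raw[[id_idx[1]]])
                 else sprintf("sub%03d", seq_len(nrow(raw))),
    sur_manual = as.numeric(raw[[man_idx[1]]]),
    stringsAsFactors = FALSE)
  for (i in setdiff(seq_along(raw), c(id_idx[1], man_idx[1]))) {
    if (!is.numeric(raw[[i]]) && all(is.na(suppressWarnings(as.numeric(raw[[i]])))))
      next
    out[[paste0("sur_", toupper(hdr[i]))]] <- as.numeric(raw[[i]])
  }
  if (anyDuplicated(out$subject_id)) stop("duplicate subject ids in ", path)
  out
}
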