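# Table-1 layer: cross-tabulations with row percentages, Pearson chi-squared
# tests, median (IQR), and the two-sample rank-sum test. Each table uses its
# own pairwise complete cases.

#' Cross-tabulate two categorical variables
#'
#' Counts over the complete cases for the pair, with label order taken from
#' the declared [variable_spec()] levels, and row percentages.
#'
#' @param records Data frame.
#' @param rowvar,colvar Names of two categorical variables.
#' @param variables A [build_path_diagram()] or list of [variable_spec()];
#'   when `NULL`, labels are taken in order of appearance.
#' @return List of class `contingency_table`: `counts` (matrix),
#'   `row_percent` (each row sums to 100), `n` (complete cases), `rowvar`,
#'   `colvar`.
#' @export
crosstab <- function(records, rowvar, colvar, variables = NULL) {
  if (inherits(variables, "path_diagram")) variables <- variables$variables
  if (!is.null(variables) && is.null(names(variables)))
    names(variables) <- vapply(variables, `[[`, "", "name")
  getcol <- function(nm) {
    v <- if (!is.null(variables)) variables[[nm]]
    if ((!is.null(v) && v$family == "continuous") ||
        (is.null(v) && is.numeric(records[[nm]])))
      stop("variable '", nm, "' is continuous; crosstab needs categorical ",
           "variables", call. = FALSE)
    raw <- trimws(as.character(records[[nm]]))
    raw[raw == "" | raw == "NA"] <- NA_character_
    if (!is.null(v)) factor(raw, levels = v$levels)
    else factor(raw, levels = unique(raw[!is.na(raw)]))
  }
  if (!rowvar %in% names(records) || !colvar %in% names(records))
    stop("records lack column '",
         setdiff(c(rowvar, colvar), names(records))[1L], "'", call. = FALSE)
  r <- getcol(rowvar)
  c_ <- getcol(colvar)
  counts <- table(r, c_, dnn = c(rowvar, colvar))
  counts <- unclass(counts)[, , drop = FALSE]
  rp <- 100 * counts / pmax(rowSums(counts), 1)
  structure(
    list(counts = counts, row_percent = rp, n = sum(counts),
         rowvar = rowvar, colvar = colvar),
    class = "contingency_table"
  )
}

#' Build a contingency table from a count matrix
#'
#' @param counts Non-negative integer matrix of cell counts.
#' @return A `contingency_table`.
#' @export
contingency_table <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(all(counts >= 0))
  structure(
    list(counts = counts,
         row_percent = 100 * counts / pmax(rowSums(counts), 1),
         n = sum(counts), rowvar = NA_character_, colvar = NA_character_),
    class = "contingency_table"
  )
}

#' Pearson chi-squared test of independence
#'
#' General R x C Pearson test without continuity correction, upper-tail
#' p-value on (R-1)(C-1) degrees of freedom.
#'
#' @param table A `contingency_table` or count matrix.
#' @return List with `statistic`, `df`, `p`.
#' @export
chi_squared_test <- function(table) {
  counts <- if (inherits(table, "contingency_table")) table$counts
            else as.matrix(table)
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("degenerate table: zero row or column margin", call. = FALSE)
  ht <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Wilcoxon-Mann-Whitney rank-sum test
#'
#' Two-sided rank-sum test with mid-ranks for ties and the tie-corrected
#' normal approximation for the z statistic.
#'
#' @param values_a,values_b Numeric samples (non-empty, NAs dropped).
#' @return List with `z`, `p`, and the Mann-Whitney `u` statistic of the
#'   first sample.
#' @export
ranksum_test <- function(values_a, values_b) {
  a <- values_a[!is.na(values_a)]
  b <- values_b[!is.na(values_b)]
  if (length(a) == 0L || length(b) == 0L)
    stop("both samples must be non-empty", call. = FALSE)
  n1 <- length(a)
  n2 <- length(b)
  pooled <- c(a, b)
  rk <- rank(pooled)  # mid-ranks for ties
  u <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties)
  n <- n1 + n2
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  if (sigma2 <= 0) return(list(z = 0, p = 1, u = u))
  z <- (u - mu) / sqrt(sigma2)
  list(z = z, p = 2 * stats::pnorm(-abs(z)), u = u)
}

#' Median and interquartile range
#'
#' Quantiles use linear interpolation (type 7), the documented choice.
#'
#' @param values Numeric vector (NAs dropped).
#' @return List with `median`, `q1`, `q3`.
#' @export
median_iqr <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0L) stop("no non-missing values", call. = FALSE)
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  list(median = q[2L], q1 = q[1L], q3 = q[3L])
}

#' Characteristics-by-outcome descriptive table
#'
#' Builds the descriptive layer for a path diagram: for every categorical
#' variable, counts and row percentages across the outcome with a Pearson
#' chi-squared p-value; for every continuous variable, median (IQR) by
#' outcome group with a rank-sum p-value. Each block uses its own pairwise
#' complete cases.
#'
#' @param records Data frame.
#' @param diagram A [build_path_diagram()] result.
#' @return Data frame of class `descriptive_table` with columns
#'   `characteristic`, `level`, one `<outcome level>` summary column per
#'   outcome category, and `p` (reported on each block's first row).
#' @export
describe_table <- function(records, diagram) {
  stopifnot(inherits(diagram, "path_diagram"))
  outcome <- diagram$outcome
  olev <- diagram$variables[[outcome]]$levels
  rows <- list()
  for (v in diagram$variables) {
    if (v$name == outcome) next
    if (v$family == "continuous") {
      vals <- suppressWarnings(as.numeric(records[[v$name]]))
      grp <- trimws(as.character(records[[outcome]]))
      grp[grp == "" | grp == "NA"] <- NA
      keep <- !is.na(vals) & !is.na(grp)
      cells <- vapply(olev, function(l) {
        mi <- median_iqr(vals[keep & grp == l])
        sprintf("%g (%g, %g)", mi$median, mi$q1, mi$q3)
      }, "")
      rs <- ranksum_test(vals[keep & grp == olev[1L]],
                         vals[keep & grp == olev[2L]])
      row <- data.frame(characteristic = v$name,
                        level = "median (IQR)", stringsAsFactors = FALSE)
      row[olev] <- as.list(cells)
      row$p <- rs$p
      rows[[length(rows) + 1L]] <- row
    } else {
      tab <- crosstab(records, v$name, outcome, diagram)
      p <- chi_squared_test(tab)$p
      for (i in seq_along(v$levels)) {
        cells <- sprintf("%d (%.2f)", tab$counts[i, olev],
                         tab$row_percent[i, olev])
        row <- data.frame(characteristic = v$name, level = v$levels[i],
                          stringsAsFactors = FALSE)
        row[olev] <- as.list(cells)
        row$p <- if (i == 1L) p else NA_real_
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("descriptive_table", "data.frame")
  out
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("Contingency table%s (n = %d)\n",
              if (!is.na(x$rowvar))
                paste0(": ", x$rowvar, " x ", x$colvar) else "", x$n))
  disp <- matrix(sprintf("%d (%.2f)", x$counts, x$row_percent),
                 nrow = nrow(x$counts), dimnames = dimnames(x$counts))
  print(disp, quote = FALSE)
  invisible(x)
}
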