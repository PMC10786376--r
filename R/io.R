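#' Read long-format grouped data
#'
#' Reads a delimited text file with one row per observation: a group-label
#' column and a numeric value column.  Two bundled example datasets follow
#' this layout: `system.file("extdata", "testosterone.csv", package =
#' "mimvar")` (testosterone levels of four smoking-habit groups of ten men,
#' control = `"Non-smokers"`) and `system.file("extdata",
#' "blood_counts.csv", package = "mimvar")` (blood counts of three animal
#' groups of unequal sizes, control = `"Control"`).
#'
#' @param path path to a comma- or tab-delimited file with a header row.
#' @param control label of the control group (must occur in the data).
#' @param group_col,value_col header names of the group and value columns.
#' @param sep field separator; `NULL` (default) auto-detects comma vs tab
#'   from the header line.
#' @return a `"long_table"`: a data.frame with columns `group` and `value`
#'   and attribute `"control"`.
#' @examples
#' path <- system.file("extdata", "testosterone.csv", package = "mimvar")
#' tab <- read_long_table(path, control = "Non-smokers")
#' table(tab$group)
#' @export
read_long_table <- function(path, control, group_col = "group",
                            value_col = "value", sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header)) "\t" else ","
  }
  raw <- read.table(path, header = TRUE, sep = sep,
                    colClasses = "character", check.names = FALSE,
                    strip.white = TRUE)
  for (col in c(group_col, value_col))
    if (!col %in% names(raw))
      stop("column '", col, "' not found in ", path,
           " (available: ", paste(names(raw), collapse = ", "), ")")
  values <- suppressWarnings(as.numeric(raw[[value_col]]))
  if (anyNA(values)) {
    bad <- which(is.na(values))[1L]
    stop("non-numeric value '", raw[[value_col]][bad], "' in row ", bad,
         " (group '", raw[[group_col]][bad], "')")
  }
  tab <- data.frame(group = raw[[group_col]], value = values,
                    stringsAsFactors = FALSE)
  counts <- table(tab$group)
  if (!control %in% names(counts))
    stop("control group '", control, "' not present; groups found: ",
         paste(names(counts), collapse = ", "))
  if (length(counts) < 2L)
    stop("need at least one non-control group")
  if (any(counts < 2L))
    stop("every group needs >= 2 observations; offending group(s): ",
         paste(names(counts)[counts < 2L], collapse = ", "))
  structure(tab, control = control, class = c("long_table", "data.frame"))
}

#' Summarize a long table into per-group statistics
#'
#' Computes per-group sample size, mean and sample variance (divisor
#' \eqn{n - 1}); values are kept at full precision and rounded only for
#' display.  Treatment groups keep their order of first appearance in the
#' file.
#'
#' @param table a [read_long_table()] result.
#' @return a `"group_summaries"` data.frame with columns `group`, `role`,
#'   `n`, `mean`, `variance`; the matching [study_summary()] is attached as
#'   attribute `"study"` and retrievable with [as_study()].
#' @examples
#' path <- system.file("extdata", "blood_counts.csv", package = "mimvar")
#' summarize_groups(read_long_table(path, control = "Control"))
#' @export
summarize_groups <- function(table) {
  stopifnot(inherits(table, "long_table"))
  control <- attr(table, "control")
  labels <- unique(table$group)
  labels <- c(control, setdiff(labels, control))
  out <- do.call(rbind, lapply(labels, function(g) {
    v <- table$value[table$group == g]
    data.frame(group = g,
               role = if (g == control) "control" else "treatment",
               n = length(v), mean = mean(v), variance = var(v),
               stringsAsFactors = FALSE)
  }))
  gs <- lapply(seq_len(nrow(out)), function(i)
    group_summary(out$group[i], out$n[i], out$variance[i]))
  attr(out, "study") <- study_summary(gs[[1L]], gs[-1L])
  class(out) <- c("group_summaries", "data.frame")
  out
}

#' @rdname summarize_groups
#' @param x a `"group_summaries"` object.
#' @return `as_study()` returns the attached [study_summary()].
#' @export
as_study <- function(x) {
  stopifnot(inherits(x, "group_summaries"))
  attr(x, "study")
}

#' @export
print.group_summaries <- function(x, digits = 4, ...) {
  y <- as.data.frame(x)
  y$mean <- round(y$mean, digits)
  y$variance <- round(y$variance, digits)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Shapiro-Wilk normality screen
#'
#' Advisory screen of the per-group normality assumption.  Small p-values
#' flag departures from normality, but the screen never blocks the variance
#' tests: with the small samples typical of these designs a passing
#' Shapiro-Wilk test is weak evidence of normality, so the result is
#' reported, not enforced.  Groups with fewer than 3 observations are
#' skipped (the test is undefined) and reported as `NA`.
#'
#' @param table a [read_long_table()] result.
#' @param threshold groups with p-value below this emit a warning.
#' @return named numeric vector of per-group p-values (`NA` when skipped).
#' @examples
#' path <- system.file("extdata", "testosterone.csv", package = "mimvar")
#' normality_screen(read_long_table(path, control = "Non-smokers"))
#' @export
normality_screen <- function(table, threshold = 0.05) {
  stopifnot(inherits(table, "long_table"))
  control <- attr(table, "control")
  labels <- unique(table$group)
  labels <- c(control, setdiff(labels, control))
  p <- vapply(labels, function(g) {
    v <- table$value[table$group == g]
    if (length(v) < 3L) {
      message("normality screen skipped for group '", g,
              "' (fewer than 3 observations)")
      return(NA_real_)
    }
    shapiro.test(v)$p.value
  }, numeric(1))
  low <- !is.na(p) & p < threshold
  if (any(low))
    warning("possible non-normality (Shapiro-Wilk p < ", threshold,
            ") in group(s): ", paste(labels[low], collapse = ", "),
            "; the variance tests assume normal data", call. = FALSE)
  setNames(p, labels)
}
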