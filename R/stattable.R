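# Long-format statistics tables shared by all testing stages.

stat_table_cols <- c("label", "statistic", "value", "df1", "df2",
                     "p", "effect_size", "correction")

#' Assemble a long-format statistics table
#'
#' Every testing stage reports its results as one of these tables: one row
#' per (effect or contrast) x statistic, each row carrying its degrees of
#' freedom, p-value, effect size (where defined) and correction label.
#'
#' @param label effect/contrast label.
#' @param statistic statistic name ("F", "t", "H", "U", ...).
#' @param value statistic value.
#' @param df1,df2 degrees of freedom (`df2 = NA` for single-df statistics).
#' @param p p-value in `[0, 1]`.
#' @param effect_size effect size (e.g. partial eta squared) or `NA`.
#' @param correction correction label (e.g. "none", "bonferroni x3").
#' @return a `data.frame` of class `stat_table`.
#' @export
stat_table <- function(label = character(), statistic = character(),
                       value = numeric(), df1 = numeric(), df2 = numeric(),
                       p = numeric(), effect_size = numeric(),
                       correction = character()) {
  df <- data.frame(label = as.character(label), statistic = as.character(statistic),
                   value = as.numeric(value), df1 = as.numeric(df1),
                   df2 = as.numeric(df2), p = as.numeric(p),
                   effect_size = as.numeric(effect_size),
                   correction = as.character(correction),
                   stringsAsFactors = FALSE)
  validate_stat_table(df)
  class(df) <- c("stat_table", "data.frame")
  df
}

validate_stat_table <- function(df) {
  stopifnot(identical(names(df), stat_table_cols))
  if (nrow(df)) {
    if (any(df$p < 0 | df$p > 1, na.rm = TRUE)) stop_fmt("p outside [0, 1]")
    if (any(df$df1 <= 0, na.rm = TRUE)) stop_fmt("non-positive df")
    if (any(is.na(df$correction) | df$correction == ""))
      stop_fmt("every record must carry a correction label")
  }
  invisible(df)
}

rbind_stat <- function(...) {
  out <- do.call(rbind, lapply(list(...), as.data.frame))
  class(out) <- c("stat_table", "data.frame")
  out
}

#' Write / read a stat_table as TSV
#'
#' Fixed column order; floating-point values at 6 significant digits.
#'
#' @param table a `stat_table`.
#' @param path output path.
#' @export
write_stats <- function(table, path) {
  validate_stat_table(table)
  out <- as.data.frame(table)
  for (nm in c("value", "df1", "df2", "p", "effect_size"))
    out[[nm]] <- signif(out[[nm]], 6)
  ok <- tryCatch({
    write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop_fmt("cannot write '%s'", path)
  invisible(path)
}

#' @rdname write_stats
#' @export
read_stats <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE,
                   colClasses = c("character", "character", rep("numeric", 5),
                                  "character"))
  validate_stat_table(df)
  class(df) <- c("stat_table", "data.frame")
  df
}
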