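# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) stop(..., call. = FALSE)

# coerce a fold_change_matrix or plain matrix to a numeric design matrix
as_design <- function(x) {
  if (inherits(x, "fold_change_matrix")) return(x$log_fc)
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x)) {
    stop_input("expected a fold_change_matrix or numeric matrix")
  }
  x
}

# lossless CSV writer: doubles serialized with %.17g so that read.csv
# recovers them bit-for-bit
write_csv_lossless <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    stop_input("'", name, "' must be TRUE or FALSE")
  }
  x
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_input("'", name, "' must be a single finite number")
  }
  ok <- if (strict_lower) x > lower else x >= lower
  if (!ok || x > upper) {
    stop_input("'", name, "' out of range: ", format(x))
  }
  x
}
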