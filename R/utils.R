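# shared validation / io helpers

stop_onekaryo <- function(msg, class, ...) {
  rlang::abort(msg, class = c(class, "onekaryo_error"), ...)
}

assert_columns <- function(df, cols, what = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop_onekaryo(
      sprintf("%s is missing required column(s): %s", what,
              paste(missing, collapse = ", ")),
      class = "onekaryo_validation_error"
    )
  }
  invisible(df)
}

assert_non_negative <- function(x, what) {
  if (any(!is.na(x) & x < 0)) {
    stop_onekaryo(sprintf("%s must be non-negative", what),
                  class = "onekaryo_validation_error")
  }
  invisible(x)
}

# All stochastic entry points funnel through this so a single integer seed
# makes a whole run reproducible; seed = NULL leaves the RNG stream alone.
with_seed_if <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(as.integer(seed), code)
}

# derive a bounded child seed (< 2^31) from a base seed and an index
child_seed <- function(seed, i) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 48271 + 7919 * i) %% 2147483647)
}

#' Write a table as tab-separated text
#'
#' All machine outputs of the package are plain TSV; intervals on disk are
#' 0-based half-open.
#'
#' @param x data frame.
#' @param path output path (`.gz` is handled transparently).
#' @return `path`, invisibly.
#' @export
write_tsv_report <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}

#' @rdname write_tsv_report
#' @export
read_tsv_report <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}
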