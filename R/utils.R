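# Internal helpers shared across modules.

#' Evaluate code under a fixed RNG seed without touching global RNG state
#' @noRd
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), code)
}

#' Derive a child seed from a parent seed and a label, staying below 2^31
#' @noRd
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(as.character(label)) * seq_along(utf8ToInt(as.character(label))))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

stop_if_not_scalar_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    stop(sprintf("`%s` must be a single integer >= %d", name, min), call. = FALSE)
  }
  invisible(as.integer(x))
}

stop_if_not_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0) {
    stop(sprintf("`%s` must be a single positive number", name), call. = FALSE)
  }
  invisible(as.numeric(x))
}

stop_if_not_fraction <- function(x, name, open_upper = FALSE) {
  bad <- !is.numeric(x) || any(is.na(x)) || any(x < 0) ||
    (if (open_upper) any(x >= 1) else any(x > 1))
  if (bad) stop(sprintf("`%s` must lie in [0,1%s", name,
                        if (open_upper) ")" else "]"), call. = FALSE)
  invisible(as.numeric(x))
}

#' Write a data frame as TSV with '# ' header comment lines
#' @noRd
write_tsv_commented <- function(df, path, comments = character()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (cm in comments) writeLines(paste0("# ", cm), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv_commented <- function(path, ...) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE, ...)
}
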