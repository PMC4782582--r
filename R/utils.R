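# Internal helpers: classed conditions, RNG scoping, deterministic writers.

stop_spinocurve <- function(msg, class, call. = FALSE) {
  stop(structure(
    class = c(class, "spinocurve_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  ))
}

warn_spinocurve <- function(msg, class) {
  warning(structure(
    class = c(class, "spinocurve_warning", "warning", "condition"),
    list(message = msg, call = NULL)
  ))
}

# Run `expr` under a given integer seed without disturbing the caller's RNG.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

is_count <- function(x, min = 1L) {
  length(x) == 1L && is.numeric(x) && !is.na(x) && x == as.integer(x) && x >= min
}

# Fixed-format CSV writer: byte-identical output for identical input.
write_points_csv <- function(df, path, digits = 6L) {
  fmt <- function(v) {
    if (is.numeric(v) && !all(v == round(v))) sprintf(paste0("%.", digits, "f"), v)
    else as.character(v)
  }
  body <- do.call(paste, c(lapply(df, fmt), sep = ","))
  writeLines(c(paste(names(df), collapse = ","), body), path)
  invisible(path)
}
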