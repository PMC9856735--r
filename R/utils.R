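# Internal helpers shared across the pipeline.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Field-named validation error, so callers can see which config/rule field is bad.
stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

as_day <- function(x) {
  if (inherits(x, "Date")) return(x)
  as.Date(x)
}

# prefix match for ICD-10 / ATC codes: does `code` start with any of `prefixes`?
code_matches <- function(code, prefixes) {
  if (length(prefixes) == 0L) return(rep(FALSE, length(code)))
  out <- rep(FALSE, length(code))
  for (p in prefixes) out <- out | startsWith(code, p)
  out
}

require_columns <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(sprintf("%s is missing required column(s): %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

# empty prototype builder: zero-row data.table with the given column classes
empty_table <- function(proto) {
  data.table::as.data.table(lapply(proto, function(cl) {
    switch(cl,
           integer   = integer(0),
           numeric   = numeric(0),
           character = character(0),
           Date      = as.Date(character(0)),
           logical   = logical(0))
  }))
}
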