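# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Significance stars at the conventional 0.05 / 0.01 / 0.001 cut-offs.
p_stars <- function(p) {
  vapply(p, function(pi) {
    if (is.na(pi)) ""
    else if (pi < 0.001) "***"
    else if (pi < 0.01) "**"
    else if (pi < 0.05) "*"
    else ""
  }, character(1))
}

stop_sporoscale <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "sporoscale_error")))
}

# Default response transformation per variable family: square root for
# biomass, log(1 + x) for richness counts, identity for evenness.
default_transformation <- function(response) {
  if (grepl("biomass", response)) "sqrt"
  else if (grepl("richness", response)) "log1p"
  else "identity"
}

assert_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0L) {
    stop_sporoscale(
      sprintf("%s is missing required column(s): %s", what,
              paste(miss, collapse = ", ")),
      "sporoscale_schema_error")
  }
  invisible(df)
}
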