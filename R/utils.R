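# Shared helpers: classed error conditions, deterministic ordering and
# numeric formatting used by every writer.

gn_stop <- function(class, fmt, ...) {
  msg <- sprintf(fmt, ...)
  stop(errorCondition(msg, class = c(class, "gremnet_error")))
}

gn_value_error  <- function(fmt, ...) gn_stop("gremnet_value_error", fmt, ...)
gn_parse_error  <- function(fmt, ...) gn_stop("gremnet_parse_error", fmt, ...)
gn_format_error <- function(fmt, ...) gn_stop("gremnet_format_error", fmt, ...)
gn_schema_error <- function(fmt, ...) gn_stop("gremnet_schema_error", fmt, ...)
gn_layout_error <- function(fmt, ...) gn_stop("gremnet_layout_error", fmt, ...)

# Locale-independent (byte-order) sort/order for reproducible file output.
gn_order <- function(...) order(..., method = "radix")
gn_sort <- function(x) x[gn_order(x)]

# All floating-point file output at 12 significant digits.
gn_fmt <- function(x) {
  out <- sprintf("%.12g", x)
  out[is.na(x)] <- "NA"
  out
}

gn_write_lines <- function(lines, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con = con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

# Fixed RNG kinds so seeded results are identical across platforms/sessions.
gn_set_seed <- function(seed) {
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
}

# Derive a bounded sub-seed (R integers are 32-bit).
gn_subseed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
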