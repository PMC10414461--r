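# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run `fun()` under a fixed RNG seed without disturbing the caller's RNG
# stream; with seed = NULL the current stream is used (non-reproducible).
run_seeded <- function(seed, fun) {
  if (is.null(seed)) fun() else withr::with_seed(as.integer(seed), fun())
}

# x log2(x) with the 0 log 0 = 0 convention used by the map equation.
plogp <- function(x) {
  out <- numeric(length(x))
  pos <- x > 0
  out[pos] <- x[pos] * log2(x[pos])
  out
}

# ZCTA codes are 5-character digit strings; numeric round-trips through CSV
# readers silently drop leading zeros, so everything is normalized here.
pad_zcta <- function(x) {
  x <- trimws(as.character(x))
  bad <- !grepl("^[0-9]{1,5}$", x)
  if (any(bad)) {
    stop("invalid ZCTA/zip code(s): ", paste(unique(x[bad]), collapse = ", "))
  }
  formatC(x, width = 5, flag = "0")
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

msgf <- function(fmt, ...) message(sprintf(fmt, ...))
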