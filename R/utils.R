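# internal helpers: seed derivation and logging

# Deterministically derive a 31-bit sub-seed from a master seed and a tag.
# Keeps every random draw in the package attributable to one master seed.
derive_seed <- function(seed, ...) {
  tag <- paste(c(seed, ...), collapse = "/")
  bytes <- utf8ToInt(tag)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647L
  as.integer(h)
}

# evaluate expr with a temporary RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# One-line audit log entry: timestamped, tagged with subject/stage/preset so
# every registration run is attributable. Writes to `file` when given,
# otherwise emits a message only when verbose.
log_line <- function(..., file = NULL, verbose = getOption("fetalicv.verbose", FALSE)) {
  msg <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " | ",
                paste(..., sep = " | "))
  if (!is.null(file)) cat(msg, "\n", file = file, append = TRUE, sep = "")
  if (isTRUE(verbose)) message(msg)
  invisible(msg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
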