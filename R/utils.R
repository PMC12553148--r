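# internal helpers: argument checks, seeded RNG, tiny hashing for provenance

stop_invalid <- function(...) stop(..., call. = FALSE)

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_invalid("`", name, "` must be a single finite number")
  }
  if (strict_lower && x <= lower) {
    stop_invalid("`", name, "` must be > ", lower, " (got ", x, ")")
  }
  if (!strict_lower && x < lower) {
    stop_invalid("`", name, "` must be >= ", lower, " (got ", x, ")")
  }
  if (x > upper) stop_invalid("`", name, "` must be <= ", upper, " (got ", x, ")")
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x) || x < min) {
    stop_invalid("`", name, "` must be an integer >= ", min)
  }
  as.integer(x)
}

# Run `expr` under a fixed RNG seed and restore the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

# FNV-1a hash of a character scalar -> 8 hex digits; used only to stamp
# configuration provenance into logs and output manifests.
fnv1a_hash <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  h <- 0x811c9dc5  # stored as double; split arithmetic keeps values exact
  for (b in bytes) {
    lo <- h %% 65536
    hi <- h %/% 65536
    lo <- bitwXor(as.integer(lo), b)  # the byte only touches the low half
    h <- hi * 65536 + lo
    # 32-bit multiply by the FNV prime 16777619
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (lo * 16777619 + (hi * 16777619 %% 65536) * 65536) %% 4294967296
  }
  sprintf("%08x", h)
}

config_hash <- function(config) {
  fnv1a_hash(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                              force = TRUE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
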