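# Internal helpers: classed conditions, seeded RNG scopes, validators.

stop_speedcuts <- function(msg, class) {
  stop(structure(
    class = c(class, "speedcuts_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_speedcuts(sprintf("`%s` must be a single finite number", name),
                   "invalid_argument")
  if ((strict_lower && x <= lower) || (!strict_lower && x < lower) || x > upper)
    stop_speedcuts(sprintf("`%s` = %g is out of range", name, x),
                   "invalid_argument")
  invisible(x)
}

is_count_vector <- function(x) {
  is.numeric(x) && all(is.finite(x)) && all(x >= 0) && all(x == floor(x))
}

# Evaluate `code` under a temporary RNG state seeded with `seed`; the
# caller's .Random.seed is restored on exit so simulation helpers do not
# perturb the user's RNG stream.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

# Deterministic sub-stream derivation: fold a master seed with arbitrary
# string/numeric keys into a 31-bit seed. Exact in double arithmetic
# (products stay far below 2^53).
derive_seed <- function(seed, ...) {
  m <- 2147483647
  h <- abs(as.double(seed)) %% m
  for (k in list(...)) {
    ints <- if (is.character(k)) as.double(utf8ToInt(paste(k, collapse = "/")))
            else abs(as.double(k)) * 1009
    for (v in ints) h <- (h * 69069 + (v %% m) + 1) %% m
  }
  as.integer(h)
}
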