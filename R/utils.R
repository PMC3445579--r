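# Internal numeric and seeding helpers.

# Half-up rounding at the reporting boundary. base::round() rounds half to
# even, which turns 13.125 into 13.12; published tables use half-up (13.13).
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

# Derive a stream of child seeds from one integer seed (kept < 2^31 so they
# remain representable as R integers). Deterministic, collision-poor splitting
# for per-replicate RNG streams.
derive_seeds <- function(seed, n, stream = 0L) {
  a <- (as.double(seed) %% 2147483647) + 1
  s <- numeric(n)
  x <- (a * 48271 + stream * 1299721) %% 2147483647
  for (i in seq_len(n)) {
    x <- (x * 48271 + 11) %% 2147483647
    s[i] <- x
  }
  as.integer(s %% 2147483629 + 1)
}

# Evaluate expr with a local RNG state seeded by `seed`; restores the caller's
# RNG so generators never perturb user sessions.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed %% 2147483647))
  }
  force(expr)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_input <- function(msg, class) {
  abort(msg, class = c(class, "metriomorph_error"))
}
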