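# Temporarily seed the RNG; returns a function restoring the previous
# global RNG state. Usage: restore <- local_seed(seed); on.exit(restore()).
local_seed <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  set.seed(as.integer(seed))
  function() {
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
    invisible(NULL)
  }
}

# One draw from a Dirichlet with parameter vector alpha (via gamma draws).
rdirichlet1 <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(x) <= 0) {
    # numerically degenerate draw at tiny alpha: fall back to a point mass
    x <- numeric(length(alpha))
    x[sample.int(length(alpha), 1L, prob = alpha / sum(alpha))] <- 1
    return(x)
  }
  x / sum(x)
}
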