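# internal helpers shared across modules

#' Derive a reproducible child seed from a master seed and a label
#'
#' Child generators (one per population, per pipeline stage, per replicate)
#' are derived by stable hashing of a text label so that adding or reordering
#' populations does not perturb the streams of the others.
#'
#' @param master integer master seed.
#' @param label character scalar mixed into the hash.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
stable_seed <- function(master, label) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(label))
  m <- 2147483647  # 2^31 - 1, keeps derived seeds within R's integer range
  h <- master %% m
  for (code in utf8ToInt(paste(label, collapse = "/"))) {
    h <- (h * 31 + code) %% m
  }
  as.integer(h)
}

# Evaluate expr with a temporarily-seeded RNG, restoring the caller's stream.
# seed = NULL leaves the current stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

logsumexp <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Shortest interval containing prob mass of a sample (highest posterior density
# under a unimodality assumption, the standard empirical construction).
hpd_interval <- function(x, prob = 0.95) {
  x <- sort(x[is.finite(x)])
  n <- length(x)
  if (n == 0L) return(c(NA_real_, NA_real_))
  m <- max(1L, ceiling(prob * n))
  if (m >= n) return(c(x[1L], x[n]))
  widths <- x[(m):n] - x[seq_len(n - m + 1L)]
  i <- which.min(widths)
  c(x[i], x[i + m - 1L])
}

# Effective sample size by the initial positive sequence of autocorrelations.
ess <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 4L || stats::var(x) == 0) return(n)
  rho <- stats::acf(x, lag.max = min(n - 2L, 1000L), plot = FALSE)$acf[-1]
  s <- 0
  for (r in rho) {
    if (r < 0.05) break
    s <- s + r
  }
  n / (1 + 2 * s)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_prob_vector <- function(p, tol = 1e-12, what = "base_freqs") {
  if (length(p) != 4L || any(p < 0) || abs(sum(p) - 1) > tol) {
    stop(sprintf("%s must be 4 nonnegative values summing to 1", what),
         call. = FALSE)
  }
  invisible(p)
}
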