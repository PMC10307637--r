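# Run code under a given seed, restoring the caller's RNG state afterwards,
# so the seeded generators are pure functions of (seed, arguments).
with_preserved_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  force(code)
}

# NB draws parameterized by mean and dispersion alpha (var = mu + alpha mu^2);
# alpha = 0 falls back to Poisson.
rnbinom_disp <- function(n, mu, alpha) {
  if (all(alpha == 0)) return(stats::rpois(n, mu))
  out <- integer(n)
  pois <- alpha == 0
  if (length(alpha) == 1) pois <- rep(pois, n)
  if (length(mu) == 1) mu <- rep(mu, n)
  if (length(alpha) == 1) alpha <- rep(alpha, n)
  if (any(pois)) out[pois] <- stats::rpois(sum(pois), mu[pois])
  if (any(!pois)) out[!pois] <- stats::rnbinom(sum(!pois), mu = mu[!pois],
                                               size = 1 / alpha[!pois])
  out
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(DNA_BASES, n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}
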