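# Internal helpers shared across modules.

# round() in R is banker's rounding; the staircase maps here round halves
# away from zero ("toward the nearest integer"), so .5 always moves up in
# magnitude.
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

is_wholenumber <- function(x, tol = 0) {
  if (tol == 0) all(x == trunc(x)) else all(abs(x - round(x)) <= tol)
}
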