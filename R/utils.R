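# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG
# state afterwards so seeded helpers do not perturb outer simulations.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Mean/sd helpers that return NA instead of erroring on empty input.
mean_or_na <- function(x) if (length(x) == 0L) NA_real_ else mean(x)
sd_or_na <- function(x) if (length(x) < 2L) NA_real_ else stats::sd(x)
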