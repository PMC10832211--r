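# Seed plumbing. All randomness in the package flows from one integer seed;
# per-subject streams are derived so that appending subjects to a cohort
# never reshuffles the draws of earlier subjects.

# Evaluate `expr` under `seed`, restoring the caller's RNG state.
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

# Stable 32-bit stream seed for subject `index` under master `seed`.
subject_seed <- function(seed, index) {
  as.integer((as.double(seed) %% 2147483647 + 779933 * as.double(index)) %%
               2147483647)
}
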