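# Internal helpers shared across modules.

#' Derive a reproducible per-stage seed from a master seed
#'
#' Stage isolation under a single master seed: each pipeline stage draws its
#' own seed deterministically from the master seed and the stage name, so that
#' adding or reordering stages never perturbs the random streams of the others.
#'
#' @param master_seed single integer master seed.
#' @param stage character scalar naming the stage (e.g. `"sparcc"`).
#' @return A single integer in `[0, 2^31 - 1)` usable with [set.seed()].
#' @examples
#' stage_seed(1L, "sparcc")
#' @export
stage_seed <- function(master_seed, stage) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L,
            is.character(stage), length(stage) == 1L)
  h <- 0
  for (k in utf8ToInt(stage)) h <- (h * 131 + k) %% 2147483647
  as.integer((abs(as.numeric(master_seed)) * 48271 + h) %% 2147483647)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards.
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

# Multiplicative log-normal noise with a given coefficient of variation.
# Values stay strictly positive, matching how concentrations and isotope
# ratios behave; cv = 0 returns x unchanged.
ln_noise <- function(x, cv, n = length(x)) {
  if (cv == 0) return(x)
  sdlog <- sqrt(log(1 + cv^2))
  x * exp(stats::rnorm(n, mean = -sdlog^2 / 2, sd = sdlog))
}

# Write a data.frame as TSV without quoting or row names (pipeline exchange
# format used by every module).
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
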