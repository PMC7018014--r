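# Seed plumbing. One study-level seed fans out to per-entity child seeds by
# stable string hashing, so adding an entity never perturbs the draws of any
# other entity, and results are reproducible across platforms.

#' Derive a child seed from a parent seed and entity labels
#'
#' Combines a parent seed with any number of labels (coerced to character)
#' into a deterministic child seed via a polynomial rolling hash over the
#' UTF-8 bytes. Independent of R's RNG state; always in `[0, 2^31 - 2]`.
#'
#' @param seed Integer parent seed.
#' @param ... Labels identifying the entity (ids, side, stage names).
#' @return A single integer seed.
#' @examples
#' child_seed(1, "bear03", "left")
#' @export
child_seed <- function(seed, ...) {
  mod <- 2147483647 # 2^31 - 1, Mersenne prime
  key <- paste(vapply(list(...), function(x) paste(format(x), collapse = "|"),
                      character(1)), collapse = "/")
  h <- (as.numeric(seed) %% mod) + 1
  for (b in utf8ToInt(key)) {
    h <- (h * 131 + b) %% mod
  }
  as.integer(h)
}

# Evaluate `expr` under a local RNG state seeded with `seed`; the caller's
# RNG state is untouched.
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
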