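# Run `code` under a fixed RNG seed without disturbing the caller's RNG
# state. seed = NULL leaves the global stream untouched.
withSeed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

.assertCount <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.finite(x) || x < min || x != as.integer(x))
    stop(sprintf("'%s' must be a single integer >= %d", name, min),
         call. = FALSE)
  as.integer(x)
}

.assertSeed <- function(seed) {
  if (is.null(seed)) return(NULL)
  if (length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite integer", call. = FALSE)
  as.integer(seed)
}

.logmsg <- function(fmt, ...) message(sprintf(paste0("[DeBias] ", fmt), ...))
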