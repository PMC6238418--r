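#' @import stats
#' @import utils
#' @importFrom methods is
NULL

# half-open interval overlap
.overlaps <- function(s1, e1, s2, e2) s1 < e2 & s2 < e1

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

.msgf <- function(verbose, fmt, ...) if (isTRUE(verbose)) message(sprintf(fmt, ...))

.is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == floor(x)

# deterministic per-stage seed fan-out from one global seed; stays < 2^31
stage_seed <- function(seed, stage) {
  stopifnot(.is_count(abs(seed)))
  as.integer((abs(seed) * 131L + stage) %% .Machine$integer.max)
}

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
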