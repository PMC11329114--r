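#' @importFrom rlang abort warn %||% .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   left_join bind_rows n across all_of
#' @importFrom stats pchisq pf pt qt rchisq rnorm rpois rgeom runif rbinom
#'   rmultinom lm anova model.matrix setNames complete.cases p.adjust sd
NULL

# Run `code` under a fixed RNG seed, restoring the caller's RNG state after.
# All seeded randomness in the package funnels through here so that user
# pipelines never clobber the global stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Derive a per-unit substream seed from a base seed and a stream label.
# Keeps results for existing units stable when more units are added.
substream_seed <- function(seed, label) {
  h <- rlang::hash(list(as.integer(seed), as.character(label)))
  # first 7 hex digits < 2^28, comfortably inside 32-bit integer range
  strtoi(substr(h, 1, 7), base = 16L)
}

assert_number <- function(x, name, lower = -Inf, allow_null = FALSE) {
  if (is.null(x) && allow_null) {
    return(invisible(x))
  }
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower) {
    abort(sprintf("`%s` must be a single number >= %s.", name, lower))
  }
  invisible(x)
}

assert_count <- function(x, name, lower = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower ||
      x != as.integer(x)) {
    abort(sprintf("`%s` must be a single integer >= %d.", name, lower))
  }
  invisible(as.integer(x))
}
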