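#' @keywords internal
"_PACKAGE"

#' @importFrom stats aov chisq.test cor.test dist fisher.test kruskal.test
#'   kmeans median p.adjust pchisq phyper pnorm prcomp pt quantile TukeyHSD
#'   rbinom rexp rnbinom rnorm runif sd setNames var wilcox.test rmultinom
#' @importFrom utils head read.delim write.table packageVersion
NULL

# Run code with a local RNG seed, restoring the caller's RNG state.
local_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

stop_config <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min ||
      x != round(x)) {
    stop_config("'%s' must be a single integer >= %d", name, min)
  }
  as.integer(x)
}

check_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x > max) {
    stop_config("'%s' must be a single number in [%s, %s]", name,
                format(min), format(max))
  }
  as.numeric(x)
}
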