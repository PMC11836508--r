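# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that generator calls are
#' reproducible without clobbering the caller's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @noRd
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}

# Deterministic substream seed derived from a master seed and a label.
# Keeps every derived seed strictly below 2^31 - 1.
substream_seed <- function(master, label) {
  h <- sum(utf8ToInt(as.character(label)) * seq_along(utf8ToInt(as.character(label))))
  as.integer((as.numeric(master) * 48271 + h * 2654435.0 + 11) %% 2147483629) + 1L
}

logit <- function(p) log(p / (1 - p))
expit <- function(x) 1 / (1 + exp(-x))

# count of values in sorted vector `s` that are >= v (v on the same exact
# day-index scale; small epsilon guards float halves like 0.5)
count_ge <- function(s, v) length(s) - findInterval(v - 1e-9, s)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_bad_arg <- function(msg) stop(msg, call. = FALSE)
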