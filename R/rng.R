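#' Derive a deterministic child seed for a simulation stage
#'
#' All stochastic stages of the framework draw from their own RNG stream,
#' derived deterministically from a single root seed, the stage name, and an
#' optional per-individual index. This keeps every stage reproducible in
#' isolation and makes the whole pipeline byte-identical for a fixed root seed.
#'
#' @param root integer root seed.
#' @param stage character scalar naming the stage (e.g. `"panel"`, `"reads"`).
#' @param index non-negative integer sub-stream index (e.g. individual number).
#' @return An integer in `[1, 2^31 - 1]` suitable for [set.seed()].
#' @export
child_seed <- function(root, stage, index = 0L) {
  stopifnot(is.numeric(root), length(root) == 1L, is.character(stage))
  m <- 2147483647  # 2^31 - 1, keeps derived seeds valid 32-bit R integers
  h <- as.double(root) %% m
  for (code in utf8ToInt(stage)) {
    h <- (h * 31 + code) %% m
  }
  h <- (h * 31 + as.double(index) + 1) %% m
  as.integer(if (h == 0) 1 else h)
}

with_stage_seed <- function(root, stage, index = 0L, expr) {
  set.seed(child_seed(root, stage, index))
  expr
}
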