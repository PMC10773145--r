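#' @importFrom rlang abort warn inform .data %||%
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   left_join inner_join anti_join distinct bind_rows bind_cols pull rename
#'   across all_of n row_number first slice
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom stats cor fisher.test glm median p.adjust prcomp quantile rnorm
#'   runif sd setNames wilcox.test binomial coef predict rbinom complete.cases
#' @importFrom utils head modifyList
NULL

# Run `expr` under a private RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(expr)
}

#' Derive a stage-specific seed from a global seed
#'
#' A single pipeline seed is fanned out to independent per-stage seeds by a
#' fixed string hash, so adding or reordering stages never perturbs the
#' random stream of the others. The result is always a valid 32-bit seed.
#'
#' @param seed Integer global seed.
#' @param label Character stage label.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(label))
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 131 + ch) %% 2147480009
  as.integer((abs(as.numeric(seed)) + h * 7919) %% 2147480009)
}

abort_arg <- function(msg, ...) abort(msg, class = "linguomics_argument_error", ...)
abort_lookup <- function(msg, ...) abort(msg, class = "linguomics_lookup_error", ...)
abort_structure <- function(msg, ...) abort(msg, class = "linguomics_structure_error", ...)
abort_schema <- function(msg, ...) abort(msg, class = "linguomics_schema_error", ...)

`%na0%` <- function(x, repl) ifelse(is.na(x), repl, x)
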