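# Internal helpers shared across modules.

#' Derive a module-level seed from a single global seed
#'
#' A run is reproduced from one integer; every module that consumes
#' randomness (cohort generation, splitting, fold assignment, weight
#' initialisation, augmentation order) receives its own seed through this
#' fixed arithmetic derivation, so modules can be re-run in isolation.
#' Results stay below 2^31 - 1.
#'
#' @param seed integer global seed.
#' @param module one of `"cohort"`, `"split"`, `"folds"`, `"init"`,
#'   `"train"`, `"eval"`.
#' @return an integer seed.
#' @export
derive_seed <- function(seed, module) {
  offsets <- c(cohort = 101, split = 211, folds = 307, init = 389,
               train = 401, eval = 601)
  if (!module %in% names(offsets)) {
    stop("unknown module '", module, "'", call. = FALSE)
  }
  as.integer((as.numeric(seed) * 7919 + offsets[[module]] * 104729) %%
               2147483647)
}

# Evaluate `expr` under set.seed(seed), restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

stop_invalid <- function(field, msg) {
  stop(structure(
    class = c("dcisnet_config_error", "error", "condition"),
    list(message = sprintf("invalid config: field '%s' %s", field, msg),
         call = NULL)))
}

stop_data <- function(...) {
  stop(structure(class = c("dcisnet_data_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

check_that <- function(cond, field, msg) {
  if (!isTRUE(cond)) stop_invalid(field, msg)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

is_binary <- function(m) all(m %in% c(0, 1))

#' Largest-remainder (quota) allocation of counts
#'
#' Distributes `n` units over categories proportionally to `probs`:
#' each category gets `floor(n * p)` and the remaining units go to the
#' categories with the largest fractional remainders (ties broken by
#' category order). The result always sums to `n` and differs from
#' `n * probs` by strictly less than 1 per category.
#'
#' @param n total count.
#' @param probs non-negative weights summing to 1.
#' @return integer vector of counts summing to `n`.
#' @export
largest_remainder <- function(n, probs) {
  raw <- n * probs
  base <- floor(raw)
  left <- round(n - sum(base))
  if (left > 0) {
    rem <- raw - base
    take <- order(rem, decreasing = TRUE)[seq_len(left)]
    base[take] <- base[take] + 1
  }
  as.integer(base)
}
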