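# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code with a temporary RNG seed
#'
#' Sets the seed, runs `code`, and restores the caller's RNG state on exit,
#' so that seeded package functions do not perturb the session RNG.
#' @noRd
with_seed <- function(seed, code) {
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

# locale-independent (C collation) sort, used wherever ordering reaches output
radix_sort <- function(x) sort(x, method = "radix")

# canonical unordered-pair key "a|b" with a <= b in C collation
pair_key <- function(a, b) {
  swap <- order_pair_swap(a, b)
  paste(ifelse(swap, b, a), ifelse(swap, a, b), sep = "|")
}

# TRUE where b sorts before a in C collation
order_pair_swap <- function(a, b) {
  # radix-ordered ranks over the combined vector give C-collation comparison
  u <- radix_sort(unique(c(a, b)))
  ra <- match(a, u)
  rb <- match(b, u)
  rb < ra
}

stop_ratecov <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "ratecov_error")))
}
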