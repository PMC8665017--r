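#' @keywords internal
"_PACKAGE"

# Run `code` with the RNG seeded at `seed`, restoring any pre-existing
# global RNG state afterwards so generators never leak random state.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

stop_invalid <- function(...) {
  stop(errorCondition(paste0(...), class = c("fcmap_invalid_parameter", "fcmap_error")))
}

stop_data <- function(..., class = "fcmap_data_error") {
  stop(errorCondition(paste0(...), class = c(class, "fcmap_error")))
}

check_scalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_invalid(name, " must be a finite numeric scalar")
  if (positive && x <= 0) stop_invalid(name, " must be > 0")
  if (nonneg && x < 0) stop_invalid(name, " must be >= 0")
  invisible(x)
}

fmt_num <- function(x) formatC(x, digits = 6, format = "g")
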