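# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' @noRd
stop_ddr <- function(..., class) {
  stop(errorCondition(paste0(...), class = c(class, "ddr_error")))
}

assert_prob <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop_ddr(name, " must be a probability in [0, 1]", class = "ddr_config_error")
  }
  invisible(x)
}

assert_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop_ddr(what, " table is missing column(s): ", paste(missing, collapse = ", "),
             class = "ddr_schema_error")
  }
  invisible(df)
}

# Evaluate an expression under a local RNG stream seeded with `seed`,
# restoring the caller's RNG state afterwards. Seeds are kept < 2^31.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed %% 2147483647L))
  }
  force(expr)
}

# Deterministic derived seed for stage k of a run seeded with `master`.
derive_seed <- function(master, k) {
  as.integer((as.double(master) * 7919 + 104729 * k) %% 2147483646) + 1L
}

DAYS_PER_MONTH <- 30.44
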