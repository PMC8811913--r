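#' @keywords internal
"_PACKAGE"

# Internal input-checking helpers. All user-facing errors go through these so
# messages are uniform and name the offending argument.

stop_input <- function(...) {
  stop(..., call. = FALSE)
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, allow_zero_len = FALSE) {
  if (allow_zero_len && length(x) == 0L) return(invisible(x))
  if (!is.numeric(x) || anyNA(x) || !all(is.finite(x))) {
    stop_input(sprintf("`%s` must be finite and numeric", name))
  }
  if (strict_lower) {
    if (any(x <= lower)) {
      stop_input(sprintf("`%s` must be > %g", name, lower))
    }
  } else if (any(x < lower)) {
    stop_input(sprintf("`%s` must be >= %g", name, lower))
  }
  if (any(x > upper)) stop_input(sprintf("`%s` must be <= %g", name, upper))
  invisible(x)
}

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
# Every stochastic operation in the package funnels through this.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Day labels of the form "D-2" ... "D15"; day 10.5 encodes the pooled
# "10/11" metabolomics sampling point and prints as "D10/11".
day_label <- function(day) {
  ifelse(abs(day - round(day)) < 1e-9,
         paste0("D", format(round(day), trim = TRUE, scientific = FALSE)),
         ifelse(abs(day - 10.5) < 1e-9, "D10/11",
                paste0("D", format(day, trim = TRUE))))
}

parse_day_label <- function(lab) {
  x <- sub("^D", "", lab)
  x[x == "10/11"] <- "10.5"
  suppressWarnings(as.numeric(x))
}
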