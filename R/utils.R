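#' @keywords internal
#' @noRd
`%||%` <- rlang::`%||%`

# fail unless x is a single finite number (optionally bounded)
check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single finite number in [%s, %s]", name,
                  format(lower), format(upper)))
  }
  invisible(x)
}

check_count <- function(x, name, lower = 1L) {
  check_number(x, name, lower = lower)
  if (x != as.integer(x)) abort(sprintf("`%s` must be an integer", name))
  as.integer(x)
}

# factor with levels in order of first appearance unless already a factor
as_label_factor <- function(x) {
  if (is.factor(x)) droplevels(x) else factor(x, levels = unique(x))
}

# deterministic RNG scope: evaluates expr under set.seed(seed), restoring state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  expr
}

# stage log used by the end-to-end pipeline
stage_log <- function(verbose, stage, ..., t0 = NULL) {
  if (!isTRUE(verbose)) return(invisible(NULL))
  msg <- sprintf(...)
  if (!is.null(t0)) {
    msg <- sprintf("%s [%.2fs]", msg, as.numeric(Sys.time()) - t0)
  }
  inform(sprintf("[%s] %s", stage, msg))
}
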