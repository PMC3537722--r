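# internal helpers shared across modules

#' Evaluate an expression under a fixed RNG seed
#'
#' Runs `code` with the random number generator seeded to `seed`, then
#' restores the caller's RNG state, so seeded package functions never
#' disturb user-level random streams. A `NULL` seed means "use the current
#' stream".
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

# comma-joined label for a set of sequence ids (stable ordering)
.clade_label <- function(ids) paste(sort(ids), collapse = ",")
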