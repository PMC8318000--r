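#' Evaluate an expression with a temporary RNG seed
#'
#' Sets the R random number generator to a fixed state, evaluates `expr`, and
#' restores the caller's RNG state afterwards, so that seeded simulation calls
#' never disturb the global random stream.
#'
#' @param seed single integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
    if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
        stop("'seed' must be a single finite integer")
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (is.null(old)) {
            if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
                rm(".Random.seed", envir = globalenv())
        } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
    expr
}

#' Derive a child seed from a master seed
#'
#' Deterministic fan-out of one master seed into per-stage / per-replicate
#' seeds, kept below 2^31 so they remain valid R integers.
#'
#' @param master master seed (integer).
#' @param index nonnegative integer index of the child stream.
#' @return single integer seed.
#' @export
derive_seed <- function(master, index) {
    master <- as.double(master); index <- as.double(index)
    as.integer((master * 48271 + index * 7919 + 12345) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_pos <- function(x, name, strict = TRUE) {
    ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
        (if (strict) x > 0 else x >= 0)
    if (!ok) stop(sprintf("'%s' must be a single %s number",
                          name, if (strict) "positive" else "nonnegative"))
    invisible(x)
}
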