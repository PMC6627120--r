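#' @keywords internal
"_PACKAGE"

# Evaluate expr with a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(expr)
}

# Dirichlet draws via independent gamma variates; rows are draws.
rdirichlet <- function(n, alpha) {
  stopifnot(all(alpha > 0))
  g <- matrix(stats::rgamma(n * length(alpha), shape = alpha),
              nrow = n, byrow = TRUE)
  g / rowSums(g)
}

# Commercial rounding: .5 always rounds away from zero (for non-negative x).
round_half_up <- function(x) floor(x + 0.5)

is_wholenumber <- function(x, tol = sqrt(.Machine$double.eps)) {
  abs(x - round(x)) < tol
}
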