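# Internal helpers.

# Evaluate expr with a temporary RNG state seeded by `seed`, restoring the
# caller's RNG state afterwards so library code never perturbs user RNG.
local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# MD5 of any serializable R object (provenance hashes in bundles/reports).
config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                              force = TRUE), f)
  unname(tools::md5sum(f))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Solve a (near-)positive-semidefinite normal-equation system, falling back
# on a truncated-SVD pseudo-inverse when the Gram matrix is singular
# (collinear basis columns).
solve_psd <- function(G, g) {
  out <- tryCatch(solve(G, g), error = function(e) NULL)
  if (!is.null(out)) return(drop(out))
  sv <- svd(G)
  pos <- sv$d > max(sv$d) * 1e-12
  drop(sv$v[, pos, drop = FALSE] %*%
         (crossprod(sv$u[, pos, drop = FALSE], g) / sv$d[pos]))
}
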