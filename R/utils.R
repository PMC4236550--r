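# internal helpers shared across modules

# round-half-up; percentage targets must not depend on IEEE round-to-even
.roundHalfUp <- function(x) floor(x + 0.5)

# deterministic child seed derivation, kept below 2^31 - 1
.childSeed <- function(seed, k) {
  as.integer(((as.numeric(seed) %% 2147483647) * 48271 + k) %% 2147483647)
}

.withSeed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

.checkSimplex <- function(f, tol = 1e-6, what = "probability triplet") {
  if (length(f) != 3 || anyNA(f))
    stop(what, " must be a complete triplet")
  if (any(f < -tol)) stop(what, " has a negative component")
  if (abs(sum(f) - 1) > tol)
    stop(what, " must sum to 1 within ", tol)
  invisible(f)
}

# accept a length-3 vector or an n x 3 matrix; return an n x 3 matrix
.asTripletMatrix <- function(f, tol = 1e-6, what = "probability triplet") {
  if (is.null(dim(f))) f <- matrix(f, nrow = 1)
  if (ncol(f) != 3) stop(what, " must have 3 components")
  if (anyNA(f)) stop(what, " must be complete")
  if (any(f < -tol)) stop(what, " has a negative component")
  if (any(abs(rowSums(f) - 1) > tol))
    stop(what, " must sum to 1 within ", tol)
  f
}
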