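`%||%` <- function(a, b) if (is.null(a)) b else a

stop_mg <- function(...) stop(sprintf(...), call. = FALSE)

warn_mg <- function(...) warning(sprintf(...), call. = FALSE)

#' @noRd
vnorm <- function(x) sqrt(sum(x^2))

rownorms <- function(m) sqrt(rowSums(m^2))

normalize_rows <- function(m) m / pmax(rownorms(m), .Machine$double.xmin)

# md5 of an R object's serialized payload (version-pinned, no file header
# timestamps); used for artifact provenance stamping and determinism checks.
md5_of <- function(x) {
  f <- tempfile()
  on.exit(unlink(f), add = TRUE)
  con <- file(f, "wb")
  serialize(x, con, version = 3L)
  close(con)
  unname(tools::md5sum(f))
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# symmetric inverse via eigen with tolerance check
sym_inv <- function(m, label = "matrix") {
  e <- eigen((m + t(m)) / 2, symmetric = TRUE)
  if (min(e$values) <= .Machine$double.eps * max(abs(e$values)) * nrow(m))
    stop_mg("%s is singular or not positive definite; regularize first", label)
  e$vectors %*% (t(e$vectors) / e$values)
}

# orthonormal basis of the column space of m, rank-truncated
orth_basis <- function(m, tol = NULL) {
  s <- svd(m)
  tol <- tol %||% (max(dim(m)) * .Machine$double.eps * s$d[1])
  r <- sum(s$d > tol)
  s$u[, seq_len(r), drop = FALSE]
}
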