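#' @keywords internal
"_PACKAGE"

# Internal helpers shared across modules. Nothing here is exported.

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

check_scalar <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("'%s' must be a finite numeric scalar", name)
  if (x < lower || x > upper)
    stopf("'%s' = %g outside [%g, %g]", name, x, lower, upper)
  invisible(x)
}

is_symmetric <- function(m, tol = 1e-8) {
  is.matrix(m) && nrow(m) == ncol(m) && max(abs(m - t(m))) <= tol * max(1, max(abs(m)))
}

#' Derive a reproducible per-task seed from a master seed and a label
#'
#' Scans over thousands of microbial traits are embarrassingly parallel; each
#' sub-model gets its own RNG seed derived deterministically from the run's
#' master seed and the trait identifier, so results do not depend on execution
#' order and interrupted scans can be resumed bit-identically.
#'
#' @param master_seed integer master seed for the whole run.
#' @param id character or integer label of the sub-task (e.g. a KO identifier).
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master_seed, id) {
  check_scalar(master_seed, "master_seed")
  h <- sum(utf8ToInt(paste0(as.character(id), collapse = "")) *
             seq_along(utf8ToInt(paste0(as.character(id), collapse = ""))))
  as.integer((abs(master_seed) %% 97771L) * 20011 + (h %% 1046527)) %% 2147483646L
}

# Column-centre a matrix
center_cols <- function(m) sweep(m, 2L, colMeans(m), "-")

read_tsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE, ...)
}

write_tsv <- function(x, path, rownames_as = NULL) {
  if (!is.null(rownames_as)) {
    x <- cbind(stats::setNames(data.frame(rownames(x), stringsAsFactors = FALSE),
                               rownames_as), as.data.frame(x))
  }
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
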