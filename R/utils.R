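# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# random stream. seed = NULL means "use the current stream".
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

stop_if_not_scalar_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < min ||
      x != round(x)) {
    stop(sprintf("`%s` must be a single integer >= %d", name, min),
         call. = FALSE)
  }
  invisible(as.integer(x))
}

# row/column minima of a numeric matrix via max.col (C-level, no apply)
row_mins <- function(m) {
  if (ncol(m) == 1L) return(m[, 1L])
  m[cbind(seq_len(nrow(m)), max.col(-m, ties.method = "first"))]
}

# fast symmetric lookup helpers: pairs stored as i < j index pairs
pair_index <- function(n) {
  i <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  j <- unlist(lapply(seq_len(n - 1L), function(a) (a + 1L):n), use.names = FALSE)
  cbind(i = i, j = j)
}

as_relative_abundance <- function(counts) {
  totals <- rowSums(counts)
  if (any(totals == 0)) {
    stop("samples with zero total counts: ",
         paste(rownames(counts)[totals == 0], collapse = ", "), call. = FALSE)
  }
  counts / totals
}
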