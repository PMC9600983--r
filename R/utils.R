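# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG
# state afterwards so seeded generators never perturb the session stream.
local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}

# Stable per-item seed derivation (kept below .Machine$integer.max).
derive_seed <- function(seed, ordinal, salt = 0L) {
  (abs(as.numeric(seed)) * 1000003 + as.numeric(ordinal) * 7919 +
     as.numeric(salt) * 104729) %% 2147483629 + 1
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

# round() in R rounds half to even; the diagnostic report uses half-up,
# matching how clinical percentages are conventionally printed.
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

is_count <- function(x, min = 0L) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x == as.integer(x) && x >= min
}

stop_cfg <- function(...) abort(paste0(...), class = "cacseg_config_error")
stop_arg <- function(...) abort(paste0(...), class = "cacseg_argument_error")
stop_fmt <- function(...) abort(paste0(...), class = "cacseg_format_error")
stop_state <- function(...) abort(paste0(...), class = "cacseg_state_error")

# Coerce a slice container (slice_stack, 3-D array, list of matrices, or a
# single matrix) to a list of H x W numeric matrices.
as_slice_list <- function(x) {
  if (inherits(x, "slice_stack")) x <- x$slices
  if (is.list(x)) {
    stopifnot(all(vapply(x, is.matrix, logical(1))))
    return(x)
  }
  if (is.matrix(x)) return(list(x))
  if (is.array(x) && length(dim(x)) == 3L) {
    return(lapply(seq_len(dim(x)[3]), function(i) x[, , i]))
  }
  stop_arg("cannot interpret object of class '", class(x)[1], "' as slices")
}
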