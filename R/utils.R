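#' Round half away from zero
#'
#' Rounds to `digits` decimal places with ties going up (0.005 -> 0.01),
#' the convention used when reporting survey percentages. Base `round()`
#' uses banker's rounding and would turn some printed percentages off by
#' one in the last digit.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

# All 2^m disease-state vectors, one row per state, diseases in column
# order; state index i corresponds to bits of i-1, disease d = bit d
# (little-endian), so the all-healthy state is row 1.
state_matrix <- function(m) {
  if (m == 0) return(matrix(integer(0), nrow = 1, ncol = 0))
  idx <- 0:(2^m - 1)
  bits <- vapply(seq_len(m), function(d) bitwAnd(idx, bitwShiftL(1L, d - 1L)) > 0L,
                 integer(2^m))
  matrix(as.integer(bits), nrow = 2^m, ncol = m)
}

# 1-based state index of a 0/1 vector under the little-endian encoding.
state_index <- function(bits) {
  as.integer(sum(bits * 2^(seq_along(bits) - 1))) + 1L
}

state_bitstring <- function(bits) paste0(as.integer(bits), collapse = "")

# Parse a bitstring or pass through a 0/1 vector; validates length.
as_state_bits <- function(state, m) {
  if (is.character(state) && length(state) == 1) {
    state <- as.integer(strsplit(state, "")[[1]])
  }
  state <- as.integer(state)
  if (length(state) != m || anyNA(state) || any(!state %in% c(0L, 1L))) {
    stop("state must be a 0/1 vector or bitstring of length ", m, call. = FALSE)
  }
  state
}

check_prob <- function(x, field) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop(sprintf("field '%s' must contain probabilities in [0, 1]", field),
         call. = FALSE)
  }
  invisible(x)
}

check_sex <- function(sex) {
  if (!all(sex %in% c("male", "female"))) {
    stop("sex must be 'male' or 'female'", call. = FALSE)
  }
  sex
}

`%||%` <- function(a, b) if (is.null(a)) b else a
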