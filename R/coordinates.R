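#' HGVS c. coordinate arithmetic
#'
#' Positions follow the HGVS coding-DNA convention: c.1 is the A of the main
#' AUG, c.-1 the base immediately 5' of it, and there is no position zero.
#' `c_to_index()` maps a coding position to a zero-based offset into the
#' concatenated transcript sequence (5'UTR + CDS + 3'UTR); `index_to_c()` is
#' its inverse; `c_distance()` counts nucleotides between two positions
#' inclusively, skipping the nonexistent zero.
#'
#' @param t A [transcript_model].
#' @param p,q Coding positions (nonzero integers). Vectorised.
#' @return `c_to_index()`: zero-based integer offsets. `index_to_c()`:
#'   coding positions. `c_distance()`: inclusive nucleotide counts.
#' @examples
#' t <- transcript_model(utr5 = strrep("A", 6), cds = "ATGAAATGA")
#' c_to_index(t, -6)   # 0
#' c_to_index(t, 1)    # 6
#' c_distance(-77, 127)  # 204
#' @export
c_to_index <- function(t, p) {
  stopifnot(inherits(t, "transcript_model"))
  p <- as.integer(p)
  if (any(is.na(p)) || any(p == 0L))
    stop("coding position must be a nonzero integer (HGVS c. has no position 0)",
         call. = FALSE)
  L <- t$utr5_len
  hi <- nchar(t$cds) + nchar(t$utr3)
  if (any(p < -L) || any(p > hi))
    stop(sprintf("coding position out of range [c.-%d, c.%d]", L, hi),
         call. = FALSE)
  ifelse(p > 0L, L + p - 1L, L + p)
}

#' @rdname c_to_index
#' @param idx Zero-based offsets into the concatenated sequence. Vectorised.
#' @export
index_to_c <- function(t, idx) {
  stopifnot(inherits(t, "transcript_model"))
  idx <- as.integer(idx)
  n <- t$utr5_len + nchar(t$cds) + nchar(t$utr3)
  if (any(idx < 0L) || any(idx >= n))
    stop("index out of transcript range", call. = FALSE)
  ifelse(idx >= t$utr5_len, idx - t$utr5_len + 1L, idx - t$utr5_len)
}

#' @rdname c_to_index
#' @export
c_distance <- function(p, q) {
  p <- as.integer(p); q <- as.integer(q)
  if (any(p == 0L) || any(q == 0L))
    stop("HGVS c. coordinates have no position 0", call. = FALSE)
  if (any(p > q))
    stop("c_distance() requires p <= q in transcript order", call. = FALSE)
  ifelse(sign(p) == sign(q), q - p + 1L, q - p)
}

#' Parse HGVS c. variant and region notation
#'
#' `parse_hgvs_c("c.-76C>T")` extracts position, reference and alternate
#' base of a substitution; `parse_c_region("c.-303..c.-1")` extracts an
#' inclusive position interval. The "c." prefix is optional.
#'
#' @param x A character scalar.
#' @return `parse_hgvs_c()`: list with `pos`, `ref`, `alt`.
#'   `parse_c_region()`: integer vector of length 2.
#' @export
parse_hgvs_c <- function(x) {
  m <- regmatches(x, regexec("^(?:c\\.)?(-?[0-9]+)([ACGT])>([ACGT])$", x))[[1]]
  if (length(m) == 0L)
    stop(sprintf("cannot parse '%s' as an HGVS c. substitution", x), call. = FALSE)
  list(pos = as.integer(m[2]), ref = m[3], alt = m[4])
}

#' @rdname parse_hgvs_c
#' @export
parse_c_region <- function(x) {
  m <- regmatches(x, regexec("^(?:c\\.)?(-?[0-9]+)\\.\\.(?:c\\.)?(-?[0-9]+)$", x))[[1]]
  if (length(m) == 0L)
    stop(sprintf("cannot parse '%s' as a c. region", x), call. = FALSE)
  r <- as.integer(m[2:3])
  if (any(r == 0L) || r[1] > r[2])
    stop("invalid c. region: needs nonzero start <= end", call. = FALSE)
  r
}

# c. position formatted with its prefix, e.g. "c.-76"
format_c <- function(p) paste0("c.", p)
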