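# internal helpers shared across modules

# shift a matrix by (di, dj) filling vacated cells with `fill`;
# positive di moves content down (towards larger row index)
shift_matrix <- function(m, di, dj, fill = 0) {
  nr <- nrow(m)
  nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  src_i <- seq_len(nr) - di
  src_j <- seq_len(nc) - dj
  ok_i <- src_i >= 1L & src_i <= nr
  ok_j <- src_j >= 1L & src_j <= nc
  out[ok_i, ok_j] <- m[src_i[ok_i], src_j[ok_j]]
  out
}

# shift a 3D array by integer offset (di, dj, dk), zero/FALSE fill
shift_array3 <- function(a, di, dj, dk, fill = 0L) {
  d <- dim(a)
  out <- array(fill, d)
  src_i <- seq_len(d[1]) - di
  src_j <- seq_len(d[2]) - dj
  src_k <- seq_len(d[3]) - dk
  ok_i <- src_i >= 1L & src_i <= d[1]
  ok_j <- src_j >= 1L & src_j <= d[2]
  ok_k <- src_k >= 1L & src_k <= d[3]
  out[ok_i, ok_j, ok_k] <- a[src_i[ok_i], src_j[ok_j], src_k[ok_k]]
  out
}

stop_atvseg <- function(...) stop(..., call. = FALSE)

is_count <- function(x, min = 0L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == as.integer(x)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
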