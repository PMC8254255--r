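# Minimal binary-heap event queue keyed on (time, insertion order) so
# simultaneous events fire in a deterministic order.

#' @noRd
new_heap <- function(capacity = 1024L) {
  h <- new.env(parent = emptyenv())
  h$time <- numeric(capacity)
  h$seq <- integer(capacity)
  h$type <- character(capacity)
  h$a1 <- integer(capacity)
  h$a2 <- integer(capacity)
  h$epoch <- integer(capacity)
  h$n <- 0L
  h$counter <- 0L
  h
}

#' @noRd
heap_less <- function(h, i, j) {
  h$time[i] < h$time[j] || (h$time[i] == h$time[j] && h$seq[i] < h$seq[j])
}

#' @noRd
heap_swap <- function(h, i, j) {
  # direct subassignment keeps the vectors singly-referenced (no copies)
  k <- c(i, j); r <- c(j, i)
  h$time[k] <- h$time[r]
  h$seq[k] <- h$seq[r]
  h$type[k] <- h$type[r]
  h$a1[k] <- h$a1[r]
  h$a2[k] <- h$a2[r]
  h$epoch[k] <- h$epoch[r]
}

#' @noRd
heap_peek_time <- function(h) {
  if (h$n == 0L) Inf else h$time[1]
}

#' @noRd
heap_push <- function(h, time, type, a1 = NA_integer_, a2 = NA_integer_,
                      epoch = NA_integer_) {
  if (h$n + 1L > length(h$time)) {
    grow <- length(h$time)
    h$time <- c(h$time, numeric(grow))
    h$seq <- c(h$seq, integer(grow))
    h$type <- c(h$type, character(grow))
    h$a1 <- c(h$a1, integer(grow))
    h$a2 <- c(h$a2, integer(grow))
    h$epoch <- c(h$epoch, integer(grow))
  }
  h$n <- h$n + 1L
  h$counter <- h$counter + 1L
  i <- h$n
  h$time[i] <- time; h$seq[i] <- h$counter; h$type[i] <- type
  h$a1[i] <- a1; h$a2[i] <- a2; h$epoch[i] <- epoch
  while (i > 1L) {
    par <- i %/% 2L
    if (heap_less(h, i, par)) { heap_swap(h, i, par); i <- par } else break
  }
  invisible(h)
}

#' @noRd
heap_pop <- function(h) {
  if (h$n == 0L) return(NULL)
  out <- list(time = h$time[1], type = h$type[1], a1 = h$a1[1],
              a2 = h$a2[1], epoch = h$epoch[1])
  heap_swap(h, 1L, h$n)
  h$n <- h$n - 1L
  i <- 1L
  repeat {
    l <- 2L * i; r <- l + 1L
    m <- i
    if (l <= h$n && heap_less(h, l, m)) m <- l
    if (r <= h$n && heap_less(h, r, m)) m <- r
    if (m == i) break
    heap_swap(h, i, m); i <- m
  }
  out
}
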