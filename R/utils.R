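`%||%` <- function(x, y) if (is.null(x)) y else x

#' Evaluate an expression with a temporary RNG seed
#'
#' Restores the caller's RNG state on exit, so seeded generators do not
#' perturb the global random stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  expr
}

#' Allocate an integer total across cells proportionally to weights
#'
#' Largest-remainder apportionment with per-cell caps. The returned integer
#' vector sums exactly to `total` (an error is raised if `sum(cap) < total`).
#' Cells with zero weight receive nothing unless capping forces spill-over,
#' in which case remaining capacity is used in cell order.
#' @noRd
integer_allocate <- function(total, weights, cap) {
  stopifnot(length(weights) == length(cap), total >= 0)
  total <- as.integer(round(total))
  n <- length(weights)
  alloc <- numeric(n)
  if (total == 0L || n == 0L) return(as.integer(alloc))
  if (sum(cap) < total) {
    stop("cannot allocate ", total, " across cells with total capacity ", sum(cap))
  }
  # waterfill the real-valued allocation, respecting caps
  remaining <- total
  active <- weights > 0 & cap > alloc
  while (remaining > 1e-9 && any(active)) {
    w <- weights[active]
    add <- remaining * w / sum(w)
    room <- cap[active] - alloc[active]
    add <- pmin(add, room)
    alloc[active] <- alloc[active] + add
    remaining <- total - sum(alloc)
    active <- weights > 0 & (cap - alloc) > 1e-9
    if (all(abs(add) < 1e-12)) break
  }
  if (remaining > 1e-9) {
    # zero-weight spill-over: fill remaining capacity in order
    for (i in seq_len(n)) {
      room <- cap[i] - alloc[i]
      take <- min(room, remaining)
      alloc[i] <- alloc[i] + take
      remaining <- remaining - take
      if (remaining <= 1e-9) break
    }
  }
  # integerise by largest remainder, respecting caps
  base <- floor(alloc + 1e-9)
  short <- total - sum(base)
  if (short > 0) {
    rem <- alloc - base
    rem[base >= cap] <- -Inf
    ord <- order(rem, decreasing = TRUE)
    i <- 1L
    while (short > 0 && i <= n) {
      j <- ord[i]
      if (base[j] < cap[j]) {
        base[j] <- base[j] + 1
        short <- short - 1
      }
      i <- i + 1L
    }
    # if remainder order exhausted (heavy capping), sweep any cell with room
    if (short > 0) {
      for (j in seq_len(n)) {
        while (short > 0 && base[j] < cap[j]) {
          base[j] <- base[j] + 1
          short <- short - 1
        }
      }
    }
  }
  as.integer(base)
}

fmt_count <- function(x) formatC(x, format = "d", big.mark = ",")
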