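#' Dominated hypervolume of a solution set
#'
#' Exact hypervolume (Lebesgue measure of the region dominated by the set and
#' bounded by the reference point) for two or three objectives, used to rank
#' repeated runs and to log search progress. Points beyond the reference
#' point contribute nothing.
#'
#' @param points Matrix or data frame of objective vectors (rows).
#' @param ref Reference point (worst corner), same length as the columns.
#' @param senses `"min"`/`"max"` per objective; maximized objectives are
#'   negated (negate their reference coordinate accordingly is done here).
#' @return A single non-negative number.
#' @export
hypervolume <- function(points, ref, senses = NULL) {
  m <- as.matrix(as.data.frame(points))
  if (is.null(senses)) senses <- rep("min", ncol(m))
  stopifnot(ncol(m) %in% c(2L, 3L), length(ref) == ncol(m),
            all(senses %in% c("min", "max")))
  sgn <- ifelse(senses == "max", -1, 1)
  m <- sweep(m, 2L, sgn, `*`)
  ref <- ref * sgn
  keep <- apply(m, 1, function(x) all(x < ref))
  m <- m[keep, , drop = FALSE]
  if (nrow(m) == 0L) return(0)
  nd <- nd_sort(m)
  m <- m[nd$front == 1L, , drop = FALSE]
  unname(if (ncol(m) == 2L) hv2(m, ref) else hv3(m, ref))
}

# staircase sweep over the first coordinate
hv2 <- function(m, ref) {
  m <- m[order(m[, 1], m[, 2]), , drop = FALSE]
  hv <- 0
  y_prev <- ref[2]
  for (i in seq_len(nrow(m))) {
    if (m[i, 2] < y_prev) {
      hv <- hv + (ref[1] - m[i, 1]) * (y_prev - m[i, 2])
      y_prev <- m[i, 2]
    }
  }
  hv
}

# slice along the third coordinate; each slab contributes its 2-D
# hypervolume times its height
hv3 <- function(m, ref) {
  z <- sort(unique(m[, 3]))
  heights <- diff(c(z, ref[3]))
  hv <- 0
  for (k in seq_along(z)) {
    sl <- m[m[, 3] <= z[k], c(1, 2), drop = FALSE]
    hv <- hv + hv2_nondom(sl, ref[c(1, 2)]) * heights[k]
  }
  hv
}

hv2_nondom <- function(m, ref) {
  keep <- apply(m, 1, function(x) all(x < ref))
  m <- m[keep, , drop = FALSE]
  if (nrow(m) == 0L) return(0)
  hv2(m, ref)
}

#' Hypervolume of a front's objective vectors
#'
#' @param front An `icu_front`.
#' @param ref Optional reference point in the front's objective order
#'   (`f11, f12, f13` for stage 1; `f21, f22` for stage 2). Defaults to a
#'   point slightly worse than the front's worst values.
#' @return A single non-negative number.
#' @export
front_hypervolume <- function(front, ref = NULL) {
  stopifnot(inherits(front, "icu_front"))
  if (attr(front, "stage") == 1L) {
    m <- cbind(front$f11, front$f12, front$f13)
    senses <- c("max", "min", "max")
  } else {
    m <- cbind(front$f21, front$f22)
    senses <- c("max", "min")
  }
  if (is.null(ref)) {
    sgn <- ifelse(senses == "max", -1, 1)
    worst <- apply(sweep(m, 2, sgn, `*`), 2, max)
    ref <- (worst + 0.1 * pmax(1, abs(worst))) * sgn
  }
  hypervolume(m, ref, senses)
}
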