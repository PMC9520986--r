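#' Two-dimensional "knotting": segment intersection of a planar ring
#'
#' In two dimensions no closed curve can be knotted in the topological
#' sense; the analogue studied here calls a planar ring "knotted" iff any
#' two non-adjacent segments intersect (a non-simple polygon). Segments
#' sharing a bead — neighbours along the ring, including the closing
#' segment — are excluded, since every ring trivially meets itself at its
#' joints. Touching within `eps` (tangential or endpoint contact) counts
#' as intersecting; such contacts have measure zero under the Gaussian
#' model so the convention does not affect the measured probabilities.
#'
#' The test is an O(N^2) sweep over segment pairs with orientation
#' predicates, with `eps = eps_rel` times the conformation diameter.
#'
#' @param conformation a 2D `"ring_conformation"` (N >= 3).
#' @param eps_rel contact tolerance relative to the conformation diameter.
#' @return An object of class `"planar_call"`: list with `is_knotted`
#'   (logical) and `first_pair` (integer segment indices of the first
#'   intersecting pair, or `NULL` when simple).
#' @examples
#' sq <- ring_conformation(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)))
#' detect_intersection(sq)$is_knotted            # FALSE: simple polygon
#' bow <- ring_conformation(cbind(c(0, 1, 1, 0), c(0, 1, 0, 1)))
#' detect_intersection(bow)$is_knotted           # TRUE: bowtie
#' @export
detect_intersection <- function(conformation, eps_rel = 1e-12) {
  stopifnot(inherits(conformation, "ring_conformation"))
  if (conformation$d != 2L) stop("detect_intersection needs a 2D ring")
  res <- cpp_any_intersection2d(conformation$positions, eps_rel)
  structure(
    list(is_knotted = res$intersects,
         first_pair = if (res$intersects) c(res$seg_i, res$seg_j) else NULL),
    class = "planar_call")
}

#' @export
print.planar_call <- function(x, ...) {
  if (x$is_knotted)
    cat(sprintf("Planar call: KNOTTED (segments %d and %d intersect)\n",
                x$first_pair[1], x$first_pair[2]))
  else cat("Planar call: simple polygon (unknotted)\n")
  invisible(x)
}

# Internal batch path: positions matrix N x (2*nconf) -> logical knotted vector
intersect_stack <- function(R, nconf, eps_rel = 1e-12) {
  cpp_intersect_stack2d(R, as.integer(nconf), eps_rel)
}
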