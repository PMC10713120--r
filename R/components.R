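#' Label 8-connected foreground components
#'
#' Connected-component labeling with 8-connectivity (the ImageJ particle
#' convention): pixels touching orthogonally or diagonally belong to the same
#' object. Built on `EBImage::bwlabel()` (4-connected) followed by a
#' union-find merge of diagonally adjacent labels; labels are renumbered
#' consecutively in first-appearance order, so the result is deterministic.
#'
#' @param mask Logical matrix.
#' @return Integer matrix of the same shape: 0 for background, `1..k` for the
#'   `k` components.
#' @export
label_components <- function(mask) {
  stopifnot(is.matrix(mask), is.logical(mask))
  if (!any(mask)) return(matrix(0L, nrow(mask), ncol(mask)))
  lab <- EBImage::bwlabel(mask)
  lab <- matrix(as.integer(round(as.numeric(lab))), nrow(mask), ncol(mask))
  n <- max(lab)
  if (n > 1L) {
    nr <- nrow(lab); nc <- ncol(lab)
    if (nr > 1L && nc > 1L) {
      # diagonal adjacencies between distinct 4-connected labels
      a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]    # down-right diagonal
      a2 <- lab[-nr, -1];  b2 <- lab[-1, -nc]   # down-left diagonal
      pr <- rbind(cbind(as.vector(a1), as.vector(b1)),
                  cbind(as.vector(a2), as.vector(b2)))
      pr <- pr[pr[, 1] > 0L & pr[, 2] > 0L & pr[, 1] != pr[, 2], , drop = FALSE]
      if (nrow(pr)) {
        parent <- seq_len(n)
        find <- function(x) {
          while (parent[x] != x) {
            parent[x] <<- parent[parent[x]]
            x <- parent[x]
          }
          x
        }
        for (i in seq_len(nrow(pr))) {
          ra <- find(pr[i, 1]); rb <- find(pr[i, 2])
          if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
        }
        root <- vapply(seq_len(n), find, integer(1))
        newid <- match(root, sort(unique(root)))
        fg <- lab > 0L
        lab[fg] <- newid[lab[fg]]
      }
    }
  }
  lab
}

#' Pixel coordinates of each labeled component
#'
#' @param lab Integer label matrix from [label_components()].
#' @return List of integer matrices, one per label, each with `(row, col)`
#'   pixel coordinates (1-based matrix indices) sorted row-major.
#' @keywords internal
component_pixels <- function(lab) {
  nlab <- max(lab)
  if (nlab == 0L) return(list())
  idx <- which(lab > 0L, arr.ind = TRUE)
  labs <- lab[idx]
  ord <- order(labs, idx[, 1], idx[, 2])
  idx <- idx[ord, , drop = FALSE]
  labs <- labs[ord]
  unname(lapply(split(seq_len(nrow(idx)), labs), function(i) {
    m <- idx[i, , drop = FALSE]
    dimnames(m) <- list(NULL, c("row", "col"))
    m
  }))
}
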