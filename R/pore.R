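# Water-pathway detection across a hydrophobic slab (electroporation demo).

#' Detect a continuous water pathway across an alkane slab
#'
#' Water cores lying inside the alkane z-range are clustered by single
#' linkage with a distance cutoff (periodic in x and y); a cluster whose z
#' extent reaches both interfaces is reported as a pore.
#'
#' @param system a \code{cg_system} with water and alkane molecules (a final
#'   frame of an electroporation run).
#' @param linkage_cutoff single-linkage distance (nm).
#' @param edge_margin how close (nm) a cluster must come to each interface to
#'   count as touching it.
#' @return list with \code{pore} (logical), \code{slab_range} (z interval of
#'   the alkane slab), \code{n_bridge_waters} (size of the largest spanning or
#'   near-spanning cluster inside the slab).
#' @export
detect_pore <- function(system, linkage_cutoff = 0.6, edge_margin = 0.3) {
  stopifnot(inherits(system, "cg_system"))
  s <- system$sites
  box <- system$box
  oct_z <- s$z[s$type == "C1"] %% box[3]
  if (length(oct_z) == 0) stop("no alkane slab in system", call. = FALSE)
  zr <- stats::quantile(oct_z, c(0.05, 0.95), names = FALSE)
  w <- s[s$type %in% c("POL-W", "P4"), ]
  wz <- w$z %% box[3]
  inside <- wz > zr[1] & wz < zr[2]
  if (!any(inside))
    return(list(pore = FALSE, slab_range = zr, n_bridge_waters = 0L))
  pts <- cbind(w$x[inside] %% box[1], w$y[inside] %% box[2], wz[inside])
  n <- nrow(pts)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  cut2 <- linkage_cutoff^2
  for (i in seq_len(max(n - 1, 0))) for (j in seq.int(i + 1, n)) {
    dx <- pts[i, 1] - pts[j, 1]; dx <- dx - box[1] * round(dx / box[1])
    dy <- pts[i, 2] - pts[j, 2]; dy <- dy - box[2] * round(dy / box[2])
    dz <- pts[i, 3] - pts[j, 3]
    if (dx * dx + dy * dy + dz * dz < cut2) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  pore <- FALSE; best <- 0L
  for (cl in split(seq_len(n), roots)) {
    zmin <- min(pts[cl, 3]); zmax <- max(pts[cl, 3])
    spans <- zmin <= zr[1] + edge_margin && zmax >= zr[2] - edge_margin
    if (spans) pore <- TRUE
    if (length(cl) > best && spans) best <- length(cl)
  }
  list(pore = pore, slab_range = zr, n_bridge_waters = best)
}
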